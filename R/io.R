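#' Read and write tweet corpora as JSON-lines
#'
#' One JSON object per line with fields `id` and `text`, plus optional
#' `label` (`"PET"`/`"nonPET"`), `is_retweet`, `lang`, `has_url`. Unparseable
#' lines are skipped with a warning rather than failing the corpus.
#'
#' @param path File path.
#' @param tweets A tweet tibble (as produced by [synth_labeled_corpus()]).
#' @return `read_tweets_jsonl()` returns a tweet tibble.
#' @export
read_tweets_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- map(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
  })
  bad <- map_lgl(recs, function(r) is.null(r) || is.null(r$text))
  if (any(bad)) {
    warn(sprintf("Skipped %d malformed record(s)", sum(bad)))
    recs <- recs[!bad]
  }
  if (length(recs) == 0) {
    return(tibble(id = character(), text = character(),
                  label = character(), is_retweet = logical(),
                  lang = character(), has_url = logical()))
  }
  opt <- function(field, default) {
    map(recs, function(r) r[[field]] %||% default)
  }
  tibble(
    id = map_chr(seq_along(recs),
                 function(i) as.character(recs[[i]]$id %||% i)),
    text = map_chr(recs, function(r) as.character(r$text)),
    label = unlist(opt("label", NA_character_)),
    is_retweet = unlist(opt("is_retweet", FALSE)),
    lang = unlist(opt("lang", NA_character_)),
    has_url = unlist(opt("has_url", FALSE))
  )
}

#' @rdname read_tweets_jsonl
#' @export
write_tweets_jsonl <- function(tweets, path) {
  check_column(tweets, "text", "tweets")
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    rec <- list(id = as.character(tweets$id[i] %||% i),
                text = tweets$text[i])
    for (f in c("label", "lang")) {
      if (f %in% names(tweets) && !is.na(tweets[[f]][i])) rec[[f]] <- tweets[[f]][i]
    }
    for (f in c("is_retweet", "has_url")) {
      if (f %in% names(tweets)) rec[[f]] <- tweets[[f]][i]
    }
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column label/text TSV corpus
#'
#' Plain fixture format: label, a tab, then the tweet text.
#'
#' @param path File path.
#' @return A tweet tibble with columns `id`, `text`, `label`.
#' @export
read_tweets_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  tab <- regexpr("\t", lines, fixed = TRUE)
  if (any(tab < 0)) {
    warn(sprintf("Skipped %d line(s) without a tab separator", sum(tab < 0)))
    lines <- lines[tab > 0]
    tab <- tab[tab > 0]
  }
  tibble(
    id = as.character(seq_along(lines)),
    text = substring(lines, tab + 1L),
    label = substring(lines, 1L, tab - 1L)
  )
}

#' Write phrase merge scores as TSV
#'
#' Columns `token_a`, `token_b`, `score`, best-scoring first.
#'
#' @param phrases A `pet_phrases` object.
#' @param path File path.
#' @param rules_only Write only the pairs above the merge threshold.
#' @export
write_phrases_tsv <- function(phrases, path, rules_only = FALSE) {
  df <- if (rules_only) phrase_rules(phrases) else phrases
  utils::write.table(df[, c("token_a", "token_b", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cross-validation metrics as CSV
#'
#' `per_fold = FALSE` writes the means table (one row per classifier);
#' `per_fold = TRUE` writes the long per-fold table.
#'
#' @param results Named list of `pet_cv` objects.
#' @param path File path.
#' @param per_fold Write per-fold rows instead of means.
#' @export
write_metrics_csv <- function(results, path, per_fold = FALSE) {
  df <- if (per_fold) {
    bind_rows(imap(results, function(cv, nm) {
      add_column(cv$fold_metrics, classifier = nm, .before = 1)
    }))
  } else {
    performance_table(results)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
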