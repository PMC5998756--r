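# Internal helpers shared across modules.

# Normalise a label vector to 0/1 integers (1 = PET, the positive class).
# Accepts "PET"/"nonPET" character labels, logicals, factors, or 0/1 numerics.
as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- !y %in% c(PET_LABEL, NONPET_LABEL)
    if (any(bad)) {
      abort(sprintf(
        "Unrecognised label(s): %s (expected '%s' or '%s')",
        paste(unique(y[bad]), collapse = ", "), PET_LABEL, NONPET_LABEL
      ))
    }
    return(as.integer(y == PET_LABEL))
  }
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) abort("Numeric labels must be 0/1")
    return(as.integer(y))
  }
  abort("Cannot interpret labels of class ", paste(class(y), collapse = "/"))
}

binary_to_label <- function(y01) {
  ifelse(y01 == 1L, PET_LABEL, NONPET_LABEL)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Require a column in a data frame, with a readable error.
check_column <- function(df, col, what = "input") {
  if (!col %in% names(df)) {
    abort(sprintf("%s must have a '%s' column", what, col))
  }
  invisible(df)
}

# Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
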