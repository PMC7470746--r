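#' Check that a data frame carries required columns
#' @noRd
check_columns <- function(df, cols, what = "table") {
  if (!is.data.frame(df)) abort(paste0(what, " must be a data frame"))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Evaluate an expression under a noise spec's seed
#'
#' When the spec carries a seed, the RNG state is set from it and restored
#' afterwards (so generators are bit-reproducible without disturbing the
#' caller's stream); otherwise the expression runs on the current RNG.
#' @noRd
with_noise_seed <- function(noise, expr) {
  if (!is.null(noise$seed)) {
    withr::with_seed(noise$seed, expr)
  } else {
    expr
  }
}

#' Ordinary least-squares slope of y against x
#' @noRd
ols_slope <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}
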