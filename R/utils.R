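# shared internal helpers

# Clamp x into [0, 1] when within `tol` of the interval; values further out
# are returned untouched and flagged. Used for MSF/MCF estimates, where small
# negative values or small excesses over 1 are measurement noise but large
# ones indicate a mis-specified allelic composition.
clamp_fraction <- function(x, tol = 0.05) {
  flagged <- !is.na(x) & (x < -tol | x > 1 + tol)
  clamped <- pmin(pmax(x, 0), 1)
  clamped[flagged] <- x[flagged]
  list(value = clamped, flagged = flagged)
}

check_numeric <- function(x, what, finite = TRUE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric, not %s.", what, class(x)[1]))
  }
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", what))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# deterministic seed derivation for sub-streams, kept well below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483629L
}
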