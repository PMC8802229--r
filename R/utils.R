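# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
ar_message <- function(..., verbose = getOption("amidering.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# numerically stable unit vector; error on near-zero norm
unit_vector <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stopf("degenerate %s: zero norm", what)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# uniform random rotation matrix (via QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# format numeric for STAR/CIF output with fixed decimals, no sci notation
num_fmt <- function(x, digits = 3) formatC(x, format = "f", digits = digits)

assert_columns <- function(df, cols, what = "data frame") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}
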