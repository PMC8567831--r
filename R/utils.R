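# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
.stopf <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "fnmorph_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Deterministic 31-bit substream seed from a base seed plus string tags.
# Keeps derived seeds strictly below 2^31 so set.seed() accepts them.
.substream <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(tags)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

# z-score, returning the centering/scaling used (for later prediction).
.zscore <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    .stopf("fnmorph_degenerate_error", "cannot standardize a constant column")
  }
  list(z = (x - m) / s, center = m, scale = s)
}

.is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)
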