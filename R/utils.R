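#' Weighted quantile with lower interpolation
#'
#' Quantile of the weighted empirical distribution, taking the smallest
#' observed value whose cumulative weight reaches `p` of the total (the
#' "lower" rule; no averaging between order statistics). Used for the
#' Table-3-style weighted medians and IQRs.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length as `x`.
#' @param p Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `p`.
#' @export
#' @examples
#' weighted_quantile(c(1, 2, 3), c(1, 1, 2), 0.5)
weighted_quantile <- function(x, w, p = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0, na.rm = TRUE))
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) stop("no non-missing values for weighted quantile")
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(p, function(pi) {
    stopifnot(pi >= 0, pi <= 1)
    x[which(cw >= pi - 1e-12)[1L]]
  }, numeric(1))
}

# FNV-1a over a character scalar; used for config hashing in run manifests
# (content fingerprint only, not cryptographic).
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h as a double below 2^32
    h <- h - h %% 256 + bitwXor(h %% 256, b %% 256)
    # 64-bit-safe multiply mod 2^32 via split into 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Derive a reproducible substream seed (< 2^31) from a master seed and a
# stream name, so adding one covariate stream never perturbs the others.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
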