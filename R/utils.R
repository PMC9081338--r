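# Shared internal helpers: deterministic sub-seeding, threshold primitives,
# crossing interpolation, peak finding.

#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from one top-level seed; independent
#' stages draw from substreams derived with this helper so that, e.g., the
#' trace generator and the plate generator of one study do not share a stream.
#'
#' @param seed integer top-level seed.
#' @param stream integer counter or short character tag naming the substream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  if (is.character(stream)) {
    h <- 0
    for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003
    stream <- h
  }
  # all intermediate products stay below 2^53, so double arithmetic is exact
  s <- (abs(as.numeric(seed)) %% 97561) * 21001 +
    (as.numeric(stream) %% 1000003) * 7919 + 1
  as.integer(s %% 2147483629 + 1)
}

# mean/CV parameterized log-normal draws (strictly positive, right-skewed)
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Otsu threshold on a numeric vector (histogram-based, deterministic).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# First upward crossing of `level`, linearly interpolated; NA if never reached.
cross_up_time <- function(t, y, level) {
  above <- y >= level
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1L) return(t[1])
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

# Last downward crossing below `level` at or after index `from`; NA if the
# series never falls below `level` within the observation window (censored).
cross_down_time <- function(t, y, level, from = 1L) {
  n <- length(y)
  idx <- from:n
  above <- y[idx] >= level
  if (!any(above)) return(t[from])
  j <- idx[max(which(above))]
  if (j == n) return(NA_real_)
  t[j] + (level - y[j]) / (y[j + 1] - y[j]) * (t[j + 1] - t[j])
}

# Local maxima with prominence >= min_prominence. Returns indices.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    left <- y[1:i]
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(y[max(higher_l):i]) else min(left)
    right <- y[i:n]
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    keep[k] <- (y[i] - max(base_l, base_r)) >= min_prominence
  }
  cand[keep]
}

# Well naming: "B02" style; rows are letters, cols zero-padded.
well_name <- function(row, col) paste0(LETTERS[row], sprintf("%02d", col))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) stop("[", stage, "] ", ..., call. = FALSE)
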