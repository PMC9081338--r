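# Four-state FUCCI classification of segmented nuclei.
#
# Each nucleus is called positive or negative per reporter channel against a
# per-channel threshold and assigned exactly one state:
#   BLUE   mVenus-  mCherry-   (reporter-negative)
#   RED    mVenus-  mCherry+   (G0/G1)
#   YELLOW mVenus+  mCherry+   (G1/S overlap)
#   GREEN  mVenus+  mCherry-   (S/G2/M)
# Intensities exactly equal to a threshold are negative (deterministic tie
# rule). Background-subtracted intensities are floored at 0 before
# classification.

FUCCI_STATES <- c("BLUE", "RED", "YELLOW", "GREEN")

#' Derive a positive/negative threshold for one intensity channel
#'
#' `otsu-on-log` applies Otsu's criterion to `log1p` intensities (robust for
#' skewed fluorescence histograms). `quantile-mixture` fits a two-component
#' Gaussian mixture to `log1p` intensities and places the threshold at the
#' equal-likelihood boundary between the components; if the two components are
#' not separated (unimodal channel), it falls back to `otsu-on-log` with a
#' warning.
#'
#' @param x nonnegative intensities (>= 50 values for histogram methods).
#' @param method `"otsu-on-log"` (default) or `"quantile-mixture"`.
#' @return threshold on the intensity scale (> 0).
#' @export
derive_channel_threshold <- function(x, method = c("otsu-on-log",
                                                   "quantile-mixture")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 50)
    stop("histogram threshold methods need at least 50 records, got ", length(x))
  lx <- log1p(pmax(x, 0))
  if (method == "quantile-mixture") {
    fit <- tryCatch(
      mclust::Mclust(lx, G = 2, modelNames = "V",
                     prior = mclust::priorControl(), verbose = FALSE),
      error = function(e) NULL)
    ok <- FALSE
    if (!is.null(fit)) {
      mu <- fit$parameters$mean
      sig <- sqrt(fit$parameters$variance$sigmasq)
      if (length(sig) == 1) sig <- rep(sig, 2)
      ok <- abs(diff(mu)) > 2 * sqrt(mean(sig^2))
    }
    if (!ok) {
      warning("channel looks unimodal; falling back to otsu-on-log")
    } else {
      o <- order(mu)
      mu <- mu[o]; sig <- sig[o]; w <- fit$parameters$pro[o]
      grid <- seq(mu[1], mu[2], length.out = 2000)
      ll <- log(w[1]) + stats::dnorm(grid, mu[1], sig[1], log = TRUE) -
        log(w[2]) - stats::dnorm(grid, mu[2], sig[2], log = TRUE)
      lt <- grid[which.min(abs(ll))]
      return(max(expm1(lt), .Machine$double.eps))
    }
  }
  max(expm1(otsu_threshold(lx)), .Machine$double.eps)
}

#' FUCCI channel thresholds
#'
#' Either fix both thresholds (`method = "fixed"`) or derive them from the
#' intensity histograms of a record table via [derive_thresholds()].
#'
#' @param mvenus_thr,mcherry_thr positive thresholds, a.u.
#' @param method how the thresholds were obtained.
#' @return list of class `fucci_thresholds`.
#' @export
fucci_thresholds <- function(mvenus_thr, mcherry_thr, method = "fixed") {
  if (!is.finite(mvenus_thr) || !is.finite(mcherry_thr) ||
      mvenus_thr <= 0 || mcherry_thr <= 0)
    stop("thresholds must be positive")
  structure(list(mvenus_thr = mvenus_thr, mcherry_thr = mcherry_thr,
                 method = method),
            class = "fucci_thresholds")
}

#' Derive mVenus and mCherry thresholds from nucleus records
#'
#' @param records data.frame with `mvenus` and `mcherry` columns
#'   (background-subtracted a.u.).
#' @param method `"fixed"`, `"otsu-on-log"` or `"quantile-mixture"`.
#' @param mvenus_thr,mcherry_thr required when `method = "fixed"`; returned
#'   unchanged.
#' @return a [fucci_thresholds()] object.
#' @export
derive_thresholds <- function(records,
                              method = c("otsu-on-log", "quantile-mixture",
                                         "fixed"),
                              mvenus_thr = NULL, mcherry_thr = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(mvenus_thr) || is.null(mcherry_thr))
      stop("fixed method needs mvenus_thr and mcherry_thr")
    return(fucci_thresholds(mvenus_thr, mcherry_thr, "fixed"))
  }
  fucci_thresholds(derive_channel_threshold(records$mvenus, method),
                   derive_channel_threshold(records$mcherry, method),
                   method)
}

#' Classify nuclei into the four FUCCI states
#'
#' @param records data.frame with `mvenus` and `mcherry` columns; intensities
#'   are floored at 0 before comparison. Positivity is strict (`> thr`).
#' @param thr a [fucci_thresholds()] object.
#' @return `records` with a `fucci_state` character column
#'   (BLUE/RED/YELLOW/GREEN).
#' @export
classify_nuclei <- function(records, thr) {
  stopifnot(inherits(thr, "fucci_thresholds"))
  if (is.null(records$mvenus) || is.null(records$mcherry) ||
      anyNA(records$mvenus) || anyNA(records$mcherry))
    stop("records must carry both FUCCI intensities (no missing values)")
  mv <- pmax(records$mvenus, 0) > thr$mvenus_thr
  mc <- pmax(records$mcherry, 0) > thr$mcherry_thr
  records$fucci_state <- ifelse(mv & mc, "YELLOW",
                         ifelse(mv, "GREEN",
                         ifelse(mc, "RED", "BLUE")))
  records
}

#' Classify a single nucleus record
#' @param record one-row data.frame or list with `mvenus`, `mcherry`.
#' @inheritParams classify_nuclei
#' @return one of `"BLUE"`, `"RED"`, `"YELLOW"`, `"GREEN"`.
#' @export
classify_nucleus <- function(record, thr) {
  df <- data.frame(mvenus = record$mvenus, mcherry = record$mcherry)
  classify_nuclei(df, thr)$fucci_state
}

#' Tally FUCCI state counts
#' @param x character vector of states, or a classified record data.frame.
#' @return list of class `state_counts`: `n_blue`, `n_red`, `n_yellow`,
#'   `n_green`.
#' @export
state_counts <- function(x) {
  if (is.data.frame(x)) x <- x$fucci_state
  tab <- table(factor(x, levels = FUCCI_STATES))
  structure(list(n_blue = as.integer(tab[["BLUE"]]),
                 n_red = as.integer(tab[["RED"]]),
                 n_yellow = as.integer(tab[["YELLOW"]]),
                 n_green = as.integer(tab[["GREEN"]])),
            class = "state_counts")
}

.as_counts <- function(counts) {
  if (inherits(counts, "state_counts")) return(counts)
  do.call(state_counts, list(counts))
}

#' State fractions over all nuclei and over FUCCI-positive nuclei
#'
#' FUCCI-positive means RED + YELLOW + GREEN (any reporter expressed).
#'
#' @param counts a [state_counts()] object (or a vector of states).
#' @return list: `total`, `frac_all` (per-state fraction of all nuclei),
#'   `n_fucci_pos`, `frac_fucci` (per-state fraction among FUCCI-positive;
#'   `NA` with `fucci_defined = FALSE` when there are none).
#' @export
state_fractions <- function(counts) {
  counts <- .as_counts(counts)
  total <- counts$n_blue + counts$n_red + counts$n_yellow + counts$n_green
  if (total <= 0) stop("state_fractions: zero nuclei")
  v <- c(BLUE = counts$n_blue, RED = counts$n_red,
         YELLOW = counts$n_yellow, GREEN = counts$n_green)
  fucci <- counts$n_red + counts$n_yellow + counts$n_green
  frac_fucci <- if (fucci > 0) v[c("RED", "YELLOW", "GREEN")] / fucci
                else stats::setNames(rep(NA_real_, 3), c("RED", "YELLOW", "GREEN"))
  list(total = total, frac_all = v / total,
       n_fucci_pos = fucci, frac_fucci = frac_fucci,
       fucci_defined = fucci > 0)
}

#' The screen's main parameter: % mVenus-positive among FUCCI-positive nuclei
#'
#' `100 * (n_green + n_yellow) / (n_red + n_yellow + n_green)`. Double-positive
#' (YELLOW) nuclei are mVenus-positive by the state truth table and are counted
#' by default; `include_yellow = FALSE` restricts the numerator to GREEN.
#'
#' @inheritParams state_fractions
#' @param include_yellow count YELLOW nuclei as mVenus-positive (default TRUE).
#' @return percentage, or `NA_real_` (with a warning) when no nucleus is
#'   FUCCI-positive -- the well must be QC-flagged downstream.
#' @export
main_parameter <- function(counts, include_yellow = TRUE) {
  counts <- .as_counts(counts)
  denom <- counts$n_red + counts$n_yellow + counts$n_green
  if (denom <= 0) {
    warning("main_parameter undefined: no FUCCI-positive nuclei")
    return(NA_real_)
  }
  num <- counts$n_green + if (include_yellow) counts$n_yellow else 0L
  100 * num / denom
}
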