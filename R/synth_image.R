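# Synthetic snapshot renderer: nuclei as non-overlapping bright discs on a
# noisy (optionally uneven) background, one matrix per channel
# (dna / mvenus / mcherry), mirroring a binned 640x480 acquisition.

#' Snapshot state mixture
#'
#' Defaults encode the imaging-flow-cytometry state fractions of
#' TNNT2-expressing cells: 85.4% mCherry-only (G0/G1), 5.1% mVenus-only
#' (S/G2/M), 1.6% double positive (G1/S), remainder reporter-negative.
#'
#' @param p_red,p_green,p_yellow,p_blue state probabilities (sum to 1).
#' @return named numeric of class `snapshot_mixture` (BLUE/RED/YELLOW/GREEN
#'   order).
#' @export
snapshot_mixture <- function(p_red = 0.854, p_green = 0.051,
                             p_yellow = 0.016, p_blue = 0.079) {
  p <- c(BLUE = p_blue, RED = p_red, YELLOW = p_yellow, GREEN = p_green)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) stop("snapshot mixture must sum to 1")
  structure(p, class = "snapshot_mixture")
}

#' Render a synthetic multi-channel FUCCI snapshot
#'
#' Nuclei are discs with radii drawn in `radius_range`, placed by rejection
#' sampling so that no two overlap; all nuclei appear in the DNA channel and
#' the reporter channels are lit according to each nucleus' sampled state.
#' Background is additive Gaussian noise around `background_level`, with an
#' optional low-frequency linear gradient.
#'
#' @param n_nuclei number of nuclei (0 gives a pure-background image).
#' @param mixture a [snapshot_mixture()].
#' @param image_shape `c(rows, cols)` in pixels (default 480 x 640).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param radius_range disc radius range, pixels.
#' @param intensity_scale nuclear intensity scale, a.u.
#' @param background_level mean background, a.u.
#' @param background_noise_sd additive background noise SD, a.u.
#' @param uneven_background add a linear background gradient of this amplitude
#'   (fraction of `intensity_scale`, 0 disables).
#' @param max_tries_per_nucleus rejection-sampling cap before giving up.
#' @return list: `image` (array `[row, col, channel]`, channels
#'   dna/mvenus/mcherry) and `truth` data.frame (`nucleus_id`, `row`, `col`
#'   0-based, `radius_px`, `state`).
#' @export
render_snapshot_image <- function(n_nuclei, mixture = snapshot_mixture(),
                                  image_shape = c(480L, 640L), seed = 1L,
                                  radius_range = c(5, 8),
                                  intensity_scale = 1000,
                                  background_level = 50,
                                  background_noise_sd = 10,
                                  uneven_background = 0,
                                  max_tries_per_nucleus = 2000L) {
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  set.seed(seed)
  h <- image_shape[1]; w <- image_shape[2]

  states <- if (n_nuclei > 0)
    sample(names(mixture), n_nuclei, replace = TRUE, prob = as.numeric(mixture))
  else character(0)
  radii <- stats::runif(n_nuclei, radius_range[1], radius_range[2])

  rows <- cols <- numeric(n_nuclei)
  if (n_nuclei > 0) {
    for (i in seq_len(n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(max_tries_per_nucleus)) {
        r0 <- stats::runif(1, radii[i] + 1, h - radii[i] - 1)
        c0 <- stats::runif(1, radii[i] + 1, w - radii[i] - 1)
        if (i == 1 || all((rows[seq_len(i - 1)] - r0)^2 +
                            (cols[seq_len(i - 1)] - c0)^2 >
                          (radii[seq_len(i - 1)] + radii[i] + 2)^2)) {
          rows[i] <- r0; cols[i] <- c0; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", n_nuclei, " non-overlapping nuclei in a ",
             h, "x", w, " image; use a larger image_shape or fewer nuclei")
    }
  }

  base <- function() {
    m <- matrix(stats::rnorm(h * w, background_level, background_noise_sd), h, w)
    if (uneven_background > 0)
      m <- m + uneven_background * intensity_scale *
        matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
    m
  }
  img <- array(0, dim = c(h, w, 3),
               dimnames = list(NULL, NULL, c("dna", "mvenus", "mcherry")))
  img[, , "dna"] <- base()
  img[, , "mvenus"] <- base()
  img[, , "mcherry"] <- base()

  paint <- function(chan, i, value) {
    r <- radii[i]
    rr <- max(1, floor(rows[i] - r)):min(h, ceiling(rows[i] + r))
    cc <- max(1, floor(cols[i] - r)):min(w, ceiling(cols[i] + r))
    d2 <- outer((rr - 1 - rows[i])^2, (cc - 1 - cols[i])^2, "+")
    sel <- d2 <= r^2
    chan[rr, cc][sel] <- chan[rr, cc][sel] + value
    chan
  }
  if (n_nuclei > 0) {
    dna_int <- intensity_scale * stats::runif(n_nuclei, 0.6, 1.0)
    rep_int <- intensity_scale * rlnorm_mean_cv(n_nuclei, 0.8, 0.15)
    for (i in seq_len(n_nuclei)) {
      img[, , "dna"] <- paint(img[, , "dna"], i, dna_int[i])
      if (states[i] %in% c("GREEN", "YELLOW"))
        img[, , "mvenus"] <- paint(img[, , "mvenus"], i, rep_int[i])
      if (states[i] %in% c("RED", "YELLOW"))
        img[, , "mcherry"] <- paint(img[, , "mcherry"], i, rep_int[i])
    }
  }
  img[img < 0] <- 0

  truth <- data.frame(nucleus_id = seq_len(n_nuclei),
                      row = rows - 1, col = cols - 1,
                      radius_px = radii, state = states,
                      stringsAsFactors = FALSE)
  if (n_nuclei == 0)
    truth <- data.frame(nucleus_id = integer(), row = numeric(),
                        col = numeric(), radius_px = numeric(),
                        state = character(), stringsAsFactors = FALSE)
  list(image = img, truth = truth)
}

#' Write a multi-channel image as a 16-bit multi-page TIFF
#'
#' One page per channel, channel order dna / mvenus / mcherry (/ extras).
#'
#' @param image array `[row, col, channel]` or named list of matrices.
#' @param path output file.
#' @param max_value intensity mapped to the 16-bit ceiling.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, max_value = 4096) {
  chans <- if (is.list(image)) image else
    lapply(seq_len(dim(image)[3]), function(k) image[, , k])
  pages <- lapply(chans, function(m) pmin(pmax(m / max_value, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_tiff()]
#' @param path TIFF file.
#' @param channel_names names assigned to the pages (default
#'   dna/mvenus/mcherry for 3 pages).
#' @param max_value intensity ceiling used when writing.
#' @return array `[row, col, channel]`.
#' @export
read_image_tiff <- function(path, channel_names = NULL, max_value = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(channel_names))
    channel_names <- if (length(pages) == 3) c("dna", "mvenus", "mcherry")
                     else paste0("ch", seq_along(pages))
  img <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, channel_names))
  for (k in seq_along(pages)) img[, , k] <- pages[[k]] * max_value
  img
}
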