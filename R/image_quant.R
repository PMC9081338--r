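# Nuclei segmentation and per-nucleus intensity measurement, plus the two
# geometric measurements (cell area, sarcomere spacing).
#
# Images are plain numeric matrices indexed [row, col]; pixel coordinates in
# records are 0-based (row, col). Segmentation and morphology are delegated to
# EBImage; the DNA channel identifies all nuclei as primary objects and the
# reporter channels are measured inside those masks after background
# subtraction.

#' Segmentation configuration
#'
#' @param method `"adaptive"` (local-mean threshold, robust to uneven
#'   background) or `"global-otsu"`.
#' @param block_size odd window size in pixels for the adaptive method.
#' @param min_area_px,max_area_px retained object area range, pixels^2.
#' @param enhance_uneven_background subtract a large-scale Gaussian background
#'   estimate before thresholding.
#' @param split_touching apply a distance-transform watershed to split
#'   touching nuclei (off by default).
#' @param offset_frac adaptive-threshold offset as a fraction of the image
#'   intensity range.
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(method = c("adaptive", "global-otsu"),
                                block_size = 31L, min_area_px = 30,
                                max_area_px = 3000,
                                enhance_uneven_background = FALSE,
                                split_touching = FALSE,
                                offset_frac = 0.05) {
  method <- match.arg(method)
  if (block_size %% 2 == 0) stop("block_size must be odd")
  if (min_area_px >= max_area_px) stop("min_area_px must be < max_area_px")
  structure(list(method = method, block_size = as.integer(block_size),
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 enhance_uneven_background = enhance_uneven_background,
                 split_touching = split_touching, offset_frac = offset_frac),
            class = "segmentation_config")
}

#' Segment nuclei from a DNA-stain image
#'
#' @param dna_image 2-D nonnegative numeric matrix.
#' @param config a [segmentation_config()].
#' @return list: `labels` (integer label matrix, 0 = background) and
#'   `records` data.frame (`nucleus_id`, `centroid_row`, `centroid_col`
#'   0-based, `area_px`). An all-zero image yields an empty result.
#' @export
segment_nuclei <- function(dna_image, config = segmentation_config()) {
  if (length(dim(dna_image)) != 2) stop("dna_image must be 2-D")
  if (any(dna_image < 0)) stop("dna_image must be nonnegative")
  empty <- list(labels = matrix(0L, nrow(dna_image), ncol(dna_image)),
                records = data.frame(nucleus_id = integer(),
                                     centroid_row = numeric(),
                                     centroid_col = numeric(),
                                     area_px = numeric()))
  mx <- max(dna_image)
  if (mx <= 0) return(empty)

  img <- dna_image / mx
  if (config$enhance_uneven_background) {
    bg <- EBImage::gblur(EBImage::Image(img), sigma = config$block_size)
    img <- pmax(img - as.matrix(bg), 0)
    if (max(img) > 0) img <- img / max(img)
  }
  mask <- if (config$method == "adaptive") {
    w <- (config$block_size - 1L) / 2L
    as.matrix(EBImage::thresh(EBImage::Image(img), w = w, h = w,
                              offset = config$offset_frac))
  } else {
    thr <- EBImage::otsu(EBImage::Image(img))
    (img > thr) * 1
  }
  mask <- EBImage::fillHull(EBImage::Image(mask))
  lab <- EBImage::bwlabel(mask)
  if (config$split_touching && max(lab) > 0) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1)
  }
  lab <- as.matrix(lab)
  if (max(lab) == 0) return(empty)

  shp <- EBImage::computeFeatures.shape(lab)
  drop_ids <- which(shp[, "s.area"] < config$min_area_px |
                      shp[, "s.area"] > config$max_area_px)
  if (length(drop_ids)) {
    lab <- as.matrix(EBImage::rmObjects(EBImage::Image(lab), drop_ids,
                                        reenumerate = TRUE))
    if (max(lab) == 0) return(empty)
  }
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  if (is.null(dim(mom))) { mom <- rbind(mom); shp <- rbind(shp) }
  records <- data.frame(nucleus_id = seq_len(nrow(mom)),
                        centroid_row = mom[, "m.cx"] - 1,
                        centroid_col = mom[, "m.cy"] - 1,
                        area_px = shp[, "s.area"])
  rownames(records) <- NULL
  list(labels = lab, records = records)
}

#' Measure background-subtracted channel intensities per nucleus
#'
#' Per nucleus and channel, the mean intensity inside the mask minus a
#' background estimate, floored at 0. `"local-annulus"` estimates background in
#' a ring `annulus_px` beyond each nucleus (excluding all nuclei);
#' `"global-percentile"` uses the 5th percentile of the whole channel.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param channels named list of channel matrices (same shape as `labels`).
#' @param background_mode `"local-annulus"` (default) or `"global-percentile"`.
#' @param annulus_px ring width beyond the nucleus, pixels.
#' @param percentile background percentile for the global mode.
#' @return data.frame: `nucleus_id` plus one column per channel.
#' @export
measure_intensities <- function(labels, channels,
                                background_mode = c("local-annulus",
                                                    "global-percentile"),
                                annulus_px = 3L, percentile = 0.05) {
  background_mode <- match.arg(background_mode)
  stopifnot(is.list(channels), length(names(channels)) == length(channels))
  for (ch in channels)
    if (!identical(dim(ch), dim(labels)))
      stop("channel and label image shapes differ")
  ids <- sort(unique(labels[labels > 0]))
  out <- data.frame(nucleus_id = ids)
  if (!length(ids)) {
    for (nm in names(channels)) out[[nm]] <- numeric(0)
    return(out)
  }

  ring_lab <- NULL
  if (background_mode == "local-annulus") {
    brush <- EBImage::makeBrush(2L * annulus_px + 1L, shape = "disc")
    dil <- as.matrix(EBImage::dilate(EBImage::Image(labels), brush))
    ring <- dil > 0 & labels == 0
    ring_lab <- dil[ring]
  }
  inside <- labels > 0
  lab_in <- labels[inside]
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    means <- tapply(ch[inside], lab_in, mean)
    bg_global <- stats::quantile(ch, percentile, names = FALSE)
    bg <- rep(bg_global, length(ids))
    if (background_mode == "local-annulus") {
      ring_means <- tapply(ch[ring], ring_lab, mean)
      m <- match(ids, as.integer(names(ring_means)))
      bg[!is.na(m)] <- ring_means[m[!is.na(m)]]
    }
    out[[nm]] <- pmax(as.numeric(means[as.character(ids)]) - bg, 0)
  }
  out
}

#' Segment and measure a multi-channel snapshot in one step
#'
#' @param image 3-D array `[row, col, channel]` with named channels including
#'   `dna`, or a named list of matrices.
#' @param config a [segmentation_config()].
#' @inheritParams measure_intensities
#' @return list: `labels` and `records` (geometry plus per-channel
#'   background-subtracted intensities and an unset `fucci_state`).
#' @export
quantify_snapshot <- function(image, config = segmentation_config(),
                              background_mode = "local-annulus") {
  chans <- if (is.list(image)) image else {
    stats::setNames(lapply(seq_len(dim(image)[3]), function(k) image[, , k]),
                    dimnames(image)[[3]])
  }
  if (is.null(chans$dna)) stop("image must contain a 'dna' channel")
  seg <- segment_nuclei(chans$dna, config)
  ints <- measure_intensities(seg$labels, chans, background_mode)
  records <- merge(seg$records, ints, by = "nucleus_id")
  records$fucci_state <- NA_character_
  list(labels = seg$labels, records = records)
}

#' Cell area from a binary mask
#' @param cell_mask 2-D logical (or 0/1) matrix outlining one cell.
#' @param pixel_size_um pixel edge length, micrometers.
#' @return area in square micrometers.
#' @export
measure_cell_area <- function(cell_mask, pixel_size_um) {
  n <- sum(cell_mask > 0)
  if (n == 0) stop("empty cell mask")
  n * pixel_size_um^2
}

#' Sarcomere spacing from a 1-D intensity profile
#'
#' Detects local maxima with prominence of at least `min_prominence_frac` of
#' the profile range and returns the median inter-peak distance converted to
#' micrometers. The periodic peaks correspond to the spatial frequency of the
#' sarcomeric alpha-actinin pattern.
#'
#' @param intensity_profile numeric vector sampled along a line.
#' @param pixel_size_um sampling step, micrometers per pixel.
#' @param min_peaks minimum number of peaks required (default 10, i.e. at
#'   least 10 sarcomeres in the region of interest).
#' @param min_prominence_frac peak prominence threshold as a fraction of the
#'   profile range.
#' @return spacing in micrometers.
#' @export
sarcomere_spacing <- function(intensity_profile, pixel_size_um,
                              min_peaks = 10L, min_prominence_frac = 0.1) {
  rng <- diff(range(intensity_profile))
  pk <- find_peaks(intensity_profile, min_prominence = min_prominence_frac * rng)
  if (length(pk) < min_peaks)
    stop("found only ", length(pk), " peaks; need at least ", min_peaks)
  stats::median(diff(pk)) * pixel_size_um
}
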