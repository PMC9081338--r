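# Screen analysis chain: site QC -> well aggregation -> percent-of-control
# normalization -> treatment QC -> CV-based timepoint selection -> hit ranking.
#
# Conventions: sample SD (n-1) throughout; site QC is one-sided (low counts
# only); normalization is per plate x timepoint; every exclusion is logged
# with a machine-readable reason code.

#' Site-level quality control
#'
#' Within each plate x timepoint group, sites whose nucleus count falls more
#' than 2 sample SDs below the group mean are excluded (out-of-focus /
#' acquisition failures). Groups with fewer than 3 sites are skipped with a
#' warning.
#'
#' @param sites site-count data.frame from [generate_plate()] or
#'   [read_sites_csv()].
#' @param n_sd exclusion depth in SD units (default 2).
#' @return list: `retained` (data.frame), `exclusions` (data.frame with
#'   `reason` = `"low_nuclei"` and the group mean/SD that triggered it).
#' @export
site_qc <- function(sites, n_sd = 2) {
  key <- interaction(sites$plate_id, sites$timepoint_h, drop = TRUE)
  keep <- rep(TRUE, nrow(sites))
  excl <- list()
  for (g in split(seq_len(nrow(sites)), key)) {
    if (length(g) < 3) {
      warning("site_qc skipped for group with ", length(g), " sites")
      next
    }
    m <- mean(sites$n_nuclei[g]); s <- stats::sd(sites$n_nuclei[g])
    bad <- sites$n_nuclei[g] < m - n_sd * s
    if (any(bad)) {
      keep[g[bad]] <- FALSE
      excl[[length(excl) + 1]] <- cbind(
        sites[g[bad], c("plate_id", "well_id", "site_id", "timepoint_h",
                        "n_nuclei")],
        group_mean = m, group_sd = s, reason = "low_nuclei")
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(plate_id = character(), well_id = character(),
               site_id = integer(), timepoint_h = numeric(),
               n_nuclei = integer(), group_mean = numeric(),
               group_sd = numeric(), reason = character())
  rownames(exclusions) <- NULL
  list(retained = sites[keep, , drop = FALSE], exclusions = exclusions)
}

#' Aggregate retained sites into well summaries
#'
#' State counts are summed over retained sites and the main parameter is
#' computed on the summed counts (unbiased under unequal site populations);
#' `method = "mean-of-sites"` instead averages per-site percentages, mirroring
#' a literal "mean values per well" reading.
#'
#' @param retained retained sites from [site_qc()].
#' @param method `"sum-of-counts"` (default) or `"mean-of-sites"`.
#' @param include_yellow passed to [main_parameter()].
#' @return data.frame, one row per plate x well x timepoint, with summed state
#'   counts, `n_sites`, and `main_parameter_pct` (NA with a `qc_flag` when no
#'   FUCCI-positive nuclei).
#' @export
aggregate_wells <- function(retained, method = c("sum-of-counts",
                                                 "mean-of-sites"),
                            include_yellow = TRUE) {
  method <- match.arg(method)
  if (!nrow(retained)) stop("no retained sites")
  key <- interaction(retained$plate_id, retained$well_id,
                     retained$timepoint_h, drop = TRUE)
  rows <- lapply(split(retained, key), function(d) {
    cnt <- structure(list(n_blue = sum(d$n_blue), n_red = sum(d$n_red),
                          n_yellow = sum(d$n_yellow),
                          n_green = sum(d$n_green)), class = "state_counts")
    mp <- if (method == "sum-of-counts") {
      suppressWarnings(main_parameter(cnt, include_yellow))
    } else {
      per_site <- vapply(seq_len(nrow(d)), function(i) {
        suppressWarnings(main_parameter(
          structure(list(n_blue = d$n_blue[i], n_red = d$n_red[i],
                         n_yellow = d$n_yellow[i], n_green = d$n_green[i]),
                    class = "state_counts"), include_yellow))
      }, 0)
      mean(per_site, na.rm = TRUE)
    }
    data.frame(plate_id = d$plate_id[1], well_id = d$well_id[1],
               timepoint_h = d$timepoint_h[1],
               n_sites = nrow(d), n_nuclei = sum(d$n_nuclei),
               n_blue = cnt$n_blue, n_red = cnt$n_red,
               n_yellow = cnt$n_yellow, n_green = cnt$n_green,
               main_parameter_pct = mp,
               qc_flag = if (is.na(mp)) "no_fucci_positive" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize well main parameters to the plate controls (100%)
#'
#' `normalized_pct = 100 * main_parameter / mean(main_parameter over control
#' wells of the same plate and timepoint)`.
#'
#' @param wells output of [aggregate_wells()].
#' @param plate_map data.frame `well_id`, `compound_id`, `role`.
#' @return `wells` joined with the plate map, plus `normalized_pct`.
#' @export
normalize_to_control <- function(wells, plate_map) {
  wells <- merge(wells, plate_map, by = "well_id", sort = FALSE)
  key <- interaction(wells$plate_id, wells$timepoint_h, drop = TRUE)
  wells$normalized_pct <- NA_real_
  for (g in split(seq_len(nrow(wells)), key)) {
    ctrl <- g[wells$role[g] == "control" & !is.na(wells$main_parameter_pct[g])]
    if (!length(ctrl))
      stop("no usable control well on plate ", wells$plate_id[g[1]],
           " at ", wells$timepoint_h[g[1]], " h")
    cm <- mean(wells$main_parameter_pct[ctrl])
    if (!(cm > 0))
      stop("control mean is zero on plate ", wells$plate_id[g[1]],
           " at ", wells$timepoint_h[g[1]], " h")
    wells$normalized_pct[g] <- 100 * wells$main_parameter_pct[g] / cm
  }
  wells[order(wells$plate_id, wells$timepoint_h, wells$well_id), ]
}

#' Per-compound replicate summary with treatment-level QC
#'
#' Replicate wells (across plates) are grouped by compound and timepoint. A
#' compound x timepoint is excluded when the replicate SD of the normalized
#' value exceeds half its mean (`sd > mean / 2`); equality retains. Single
#' replicates cannot be QC'd and are flagged.
#'
#' @param wells normalized wells from [normalize_to_control()].
#' @return data.frame: `compound_id`, `timepoint_h`, `n_replicates`,
#'   `mean_normalized_pct`, `sd_normalized_pct`, `excluded`, `reason`.
#' @export
treatment_qc <- function(wells) {
  w <- wells[wells$role == "compound" & !is.na(wells$normalized_pct), ]
  key <- interaction(w$compound_id, w$timepoint_h, drop = TRUE)
  rows <- lapply(split(w, key), function(d) {
    m <- mean(d$normalized_pct)
    s <- if (nrow(d) > 1) stats::sd(d$normalized_pct) else NA_real_
    excluded <- FALSE; reason <- ""
    if (nrow(d) < 2) {
      reason <- "single_replicate"
    } else if (s > m / 2) {
      excluded <- TRUE; reason <- "replicate_sd_above_half_mean"
    }
    data.frame(compound_id = d$compound_id[1], timepoint_h = d$timepoint_h[1],
               n_replicates = nrow(d), mean_normalized_pct = m,
               sd_normalized_pct = s, excluded = excluded, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$timepoint_h, out$compound_id), ]
  rownames(out) <- NULL
  out
}

#' Select the acquisition timepoint with the smallest control CV
#'
#' CV = 100 * SD / mean of the control wells' normalized main parameter per
#' timepoint (pooled across plates). Ties go to the earlier timepoint.
#'
#' @param wells normalized wells from [normalize_to_control()].
#' @param timepoints optional subset of timepoints to consider.
#' @return list: `timepoint_h` (selected) and `cv_table` data.frame.
#' @export
select_timepoint <- function(wells, timepoints = NULL) {
  ctrl <- wells[wells$role == "control" & !is.na(wells$normalized_pct), ]
  if (!is.null(timepoints)) ctrl <- ctrl[ctrl$timepoint_h %in% timepoints, ]
  tab <- do.call(rbind, lapply(split(ctrl, ctrl$timepoint_h), function(d) {
    data.frame(timepoint_h = d$timepoint_h[1], n_controls = nrow(d),
               cv_pct = 100 * stats::sd(d$normalized_pct) /
                 mean(d$normalized_pct))
  }))
  tab <- tab[tab$n_controls >= 2, ]
  if (nrow(tab) < 2) stop("need at least 2 timepoints with >= 2 control wells")
  tab <- tab[order(tab$timepoint_h), ]
  rownames(tab) <- NULL
  sel <- tab$timepoint_h[which.min(tab$cv_pct)]   # which.min takes the first
  list(timepoint_h = sel, cv_table = tab)
}

#' Rank retained compounds at a timepoint
#'
#' Descending by mean normalized value; ties broken by lower replicate SD,
#' then by compound id.
#'
#' @param result [treatment_qc()] output.
#' @param timepoint_h timepoint to rank at.
#' @return the retained rows of `result` at that timepoint, ranked, with a
#'   `rank` column.
#' @export
rank_hits <- function(result, timepoint_h) {
  d <- result[result$timepoint_h == timepoint_h & !result$excluded, ]
  if (!nrow(d)) stop("no retained compounds at ", timepoint_h, " h")
  d <- d[order(-d$mean_normalized_pct, d$sd_normalized_pct, d$compound_id), ]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}
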