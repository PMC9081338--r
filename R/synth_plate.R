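# Synthetic 96-well screening plates: per-site FUCCI state counts over
# replicate plates sharing one compound layout, with site dropout to exercise
# QC. Outer wells are left unused (edge effects), five sites are imaged per
# well, and a compound's true effect multiplies the cycling (mVenus-positive)
# probability among FUCCI-positive nuclei.

#' Plate specification for the synthetic screen
#'
#' @param n_rows,n_cols plate geometry (default 96-well, 8 x 12). Outer wells
#'   are excluded from assignment.
#' @param compound_wells data.frame `well_id`, `compound_id`, `effect` (true
#'   multiplier on the cycling probability; 1 = null).
#' @param control_wells character vector of control well ids (compound id
#'   `CTRL`); must be non-empty or later normalization is impossible.
#' @param n_sites_per_well imaged sites per well.
#' @param site_dropout_prob probability that a site drops out (focus failure);
#'   dropout sites have severely reduced nuclei counts.
#' @param mean_nuclei_per_site Poisson mean of nuclei per healthy site.
#' @param timepoints_h acquisition times, hours.
#' @param n_plates replicate plates sharing the layout.
#' @param base_mixture [snapshot_mixture()] of state probabilities in control
#'   conditions.
#' @param dropout_severity nuclei-count multiplier for dropout sites.
#' @param effect_onset_h compound effects apply from this timepoint on (the
#'   baseline acquisition directly after compound addition is unaffected).
#' @return list of class `plate_spec`.
#' @export
plate_spec <- function(n_rows = 8L, n_cols = 12L, compound_wells,
                       control_wells, n_sites_per_well = 5L,
                       site_dropout_prob = 0.02,
                       mean_nuclei_per_site = 150,
                       timepoints_h = c(0, 24, 48, 72),
                       n_plates = 3L,
                       base_mixture = snapshot_mixture(),
                       dropout_severity = 0.05,
                       effect_onset_h = 24) {
  if (length(control_wells) == 0)
    stop("control_wells must not be empty: normalization would be impossible")
  inner <- inner_wells(n_rows, n_cols)
  assigned <- c(compound_wells$well_id, control_wells)
  if (any(duplicated(assigned))) stop("wells assigned more than once")
  if (!all(assigned %in% inner))
    stop("outer wells are excluded from compound/control assignment")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 compound_wells = compound_wells,
                 control_wells = control_wells,
                 n_sites_per_well = as.integer(n_sites_per_well),
                 site_dropout_prob = site_dropout_prob,
                 mean_nuclei_per_site = mean_nuclei_per_site,
                 timepoints_h = timepoints_h, n_plates = as.integer(n_plates),
                 base_mixture = base_mixture,
                 dropout_severity = dropout_severity,
                 effect_onset_h = effect_onset_h),
            class = "plate_spec")
}

#' Inner (usable) wells of a plate
#' @param n_rows,n_cols plate geometry.
#' @return character vector of well ids excluding the outer ring.
#' @export
inner_wells <- function(n_rows = 8L, n_cols = 12L) {
  g <- expand.grid(row = 2:(n_rows - 1), col = 2:(n_cols - 1))
  sort(well_name(g$row, g$col))
}

#' Default plate layout: compounds plus interleaved controls
#'
#' @param n_compounds number of compound wells (ids `C001`, `C002`, ...).
#' @param n_controls number of control wells, spread across the layout.
#' @param effects named numeric of true effects by compound id (others 1).
#' @param ... passed to [plate_spec()].
#' @return a [plate_spec()].
#' @export
default_plate_spec <- function(n_compounds = 54L, n_controls = 6L,
                               effects = NULL, ...) {
  inner <- inner_wells()
  if (n_compounds + n_controls > length(inner))
    stop("layout needs at most ", length(inner), " inner wells")
  ctrl_idx <- round(seq(1, n_compounds + n_controls, length.out = n_controls))
  used <- inner[seq_len(n_compounds + n_controls)]
  control_wells <- used[ctrl_idx]
  cw <- used[-ctrl_idx]
  eff <- rep(1, n_compounds)
  ids <- sprintf("C%03d", seq_len(n_compounds))
  if (!is.null(effects)) {
    m <- match(names(effects), ids)
    if (anyNA(m)) stop("unknown compound id in effects")
    eff[m] <- effects
  }
  plate_spec(compound_wells = data.frame(well_id = cw, compound_id = ids,
                                         effect = eff,
                                         stringsAsFactors = FALSE),
             control_wells = control_wells, ...)
}

# cycling-probability tilt: effect multiplies P(mVenus+ | FUCCI+), the
# green/yellow split is preserved, blue is unaffected
.tilt_mixture <- function(p, effect) {
  fucci <- p[["RED"]] + p[["YELLOW"]] + p[["GREEN"]]
  cyc <- p[["YELLOW"]] + p[["GREEN"]]
  p_cyc <- min(effect * cyc / fucci, 0.95)
  new_cyc <- p_cyc * fucci
  c(BLUE = p[["BLUE"]],
    RED = fucci - new_cyc,
    YELLOW = new_cyc * p[["YELLOW"]] / cyc,
    GREEN = new_cyc * p[["GREEN"]] / cyc)
}

#' Generate per-site FUCCI state count tables for a screen
#'
#' @param spec a [plate_spec()].
#' @param seed integer seed; output is a pure function of (spec, seed).
#' @return list: `sites` data.frame (`plate_id`, `well_id`, `site_id`,
#'   `timepoint_h`, `n_blue`, `n_red`, `n_yellow`, `n_green`, `n_nuclei`),
#'   `plate_map` (`well_id`, `compound_id`, `role`), and `truth` (per-well true
#'   effects and per-site dropout flags -- not read by any pipeline stage).
#' @export
generate_plate <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "plate_spec"))
  set.seed(derive_seed(seed, "plate"))
  wells <- rbind(
    data.frame(well_id = spec$compound_wells$well_id,
               compound_id = spec$compound_wells$compound_id,
               role = "compound", effect = spec$compound_wells$effect,
               stringsAsFactors = FALSE),
    data.frame(well_id = spec$control_wells, compound_id = "CTRL",
               role = "control", effect = 1, stringsAsFactors = FALSE))
  grid <- expand.grid(plate_id = paste0("P", seq_len(spec$n_plates)),
                      well_idx = seq_len(nrow(wells)),
                      site_id = seq_len(spec$n_sites_per_well),
                      timepoint_h = spec$timepoints_h,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nG <- nrow(grid)
  eff <- ifelse(grid$timepoint_h >= spec$effect_onset_h,
                wells$effect[grid$well_idx], 1)
  dropout <- stats::runif(nG) < spec$site_dropout_prob
  lambda <- ifelse(dropout, spec$dropout_severity, 1) * spec$mean_nuclei_per_site
  n <- stats::rpois(nG, lambda)
  p0 <- spec$base_mixture
  counts <- matrix(0L, nG, 4, dimnames = list(NULL, names(p0)))
  for (e in unique(eff)) {
    idx <- which(eff == e)
    pe <- .tilt_mixture(p0, e)
    counts[idx, ] <- t(vapply(idx, function(i) {
      as.integer(stats::rmultinom(1, n[i], pe))
    }, integer(4)))
  }
  sites <- data.frame(plate_id = grid$plate_id,
                      well_id = wells$well_id[grid$well_idx],
                      site_id = grid$site_id,
                      timepoint_h = grid$timepoint_h,
                      n_blue = counts[, "BLUE"], n_red = counts[, "RED"],
                      n_yellow = counts[, "YELLOW"],
                      n_green = counts[, "GREEN"],
                      n_nuclei = n, stringsAsFactors = FALSE)
  truth <- list(
    well_effects = wells[, c("well_id", "compound_id", "role", "effect")],
    site_dropout = data.frame(plate_id = grid$plate_id,
                              well_id = wells$well_id[grid$well_idx],
                              site_id = grid$site_id,
                              timepoint_h = grid$timepoint_h,
                              dropout = dropout, stringsAsFactors = FALSE))
  list(sites = sites, plate_map = wells[, c("well_id", "compound_id", "role")],
       truth = truth)
}
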