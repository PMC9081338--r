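make_sites <- function(n_nuclei, plate = "P1", tp = 48) {
  n <- length(n_nuclei)
  data.frame(plate_id = plate, well_id = well_name(2, seq_len(n) %% 10 + 2),
             site_id = seq_len(n), timepoint_h = tp,
             n_blue = 0L, n_red = n_nuclei, n_yellow = 0L, n_green = 0L,
             n_nuclei = n_nuclei, stringsAsFactors = FALSE)
}

test_that("site QC excludes counts more than 2 SD below the group mean", {
  # group engineered to mean 100, sd 5
  base <- c(95, 97, 99, 100, 100, 101, 103, 105, 108, 92)
  base <- round((base - mean(base)) / sd(base) * 5 + 100)
  sites <- make_sites(c(base, 85, 95))
  qc <- site_qc(sites)
  m <- mean(sites$n_nuclei); s <- sd(sites$n_nuclei)
  expect_true(85 < m - 2 * s)           # fixture sanity
  expect_true(85 %in% qc$exclusions$n_nuclei)
  expect_false(95 %in% qc$exclusions$n_nuclei)
  expect_identical(unique(qc$exclusions$reason), "low_nuclei")
  expect_warning(site_qc(make_sites(c(100, 100))), "skipped")
})

test_that("site QC catches generator dropouts with at most one false exclusion", {
  spec <- default_plate_spec(n_compounds = 16, n_controls = 4, n_plates = 1,
                             site_dropout_prob = 0.05,
                             timepoints_h = c(24))
  plate <- generate_plate(spec, seed = 17)     # 100 sites, 5% dropout at 5% of mean
  qc <- site_qc(plate$sites)
  drop <- plate$truth$site_dropout
  key <- function(d) paste(d$plate_id, d$well_id, d$site_id, d$timepoint_h)
  excluded <- key(qc$exclusions)
  true_drop <- key(drop[drop$dropout, ])
  expect_true(all(true_drop %in% excluded))
  expect_lte(length(setdiff(excluded, true_drop)), 1)
})

test_that("well aggregation matches sites when sites are homogeneous", {
  sites <- data.frame(plate_id = "P1", well_id = "B02", site_id = 1:5,
                      timepoint_h = 48, n_blue = 2L, n_red = 80L,
                      n_yellow = 5L, n_green = 15L, n_nuclei = 102L)
  w <- aggregate_wells(sites)
  expect_equal(w$main_parameter_pct, 20.0)
  expect_equal(w$n_sites, 5)
  # sum-of-counts and mean-of-sites agree for homogeneous sites
  w2 <- aggregate_wells(sites, method = "mean-of-sites")
  expect_equal(w$main_parameter_pct, w2$main_parameter_pct)
})

test_that("normalization fixes controls at 100% and is idempotent there", {
  wells <- data.frame(plate_id = "P1",
                      well_id = c("B02", "B03", "B04"),
                      timepoint_h = 48, n_sites = 5, n_nuclei = 500,
                      n_blue = 0, n_red = c(90, 90, 85),
                      n_yellow = 0, n_green = c(10, 10, 15),
                      main_parameter_pct = c(10, 10, 15),
                      qc_flag = "", stringsAsFactors = FALSE)
  pm <- data.frame(well_id = c("B02", "B03", "B04"),
                   compound_id = c("CTRL", "CTRL", "C001"),
                   role = c("control", "control", "compound"))
  norm <- normalize_to_control(wells, pm)
  expect_equal(mean(norm$normalized_pct[norm$role == "control"]), 100)
  expect_equal(norm$normalized_pct[norm$compound_id == "C001"], 150)
  # renormalizing the already-normalized control values leaves 100 fixed
  wells2 <- norm
  wells2$main_parameter_pct <- wells2$normalized_pct
  norm2 <- normalize_to_control(wells2[, names(wells)], pm)
  expect_equal(norm2$normalized_pct[norm2$role == "control"], c(100, 100))
  # a missing control errors with the plate and timepoint named
  pm_none <- transform(pm, role = "compound")
  expect_error(normalize_to_control(wells, pm_none), "P1.*48")
})

test_that("treatment QC excludes on SD > mean/2 with equality retained", {
  w <- function(vals, id) data.frame(
    plate_id = paste0("P", seq_along(vals)), well_id = "B02", timepoint_h = 48,
    compound_id = id, role = "compound", normalized_pct = vals)
  res <- treatment_qc(rbind(
    w(c(20, 50, 80), "A"),     # mean 50, sd 30 -> excluded
    w(c(40, 50, 60), "B"),     # mean 50, sd 10 -> retained
    w(c(101, 200, 299), "C"),  # mean 200, sd 99 -> retained (99 <= 100)
    w(150, "D")))              # single replicate -> flagged
  expect_true(res$excluded[res$compound_id == "A"])
  expect_false(res$excluded[res$compound_id == "B"])
  expect_false(res$excluded[res$compound_id == "C"])
  expect_identical(res$reason[res$compound_id == "D"], "single_replicate")
})

test_that("timepoint selection takes the smallest control CV, earlier on ties", {
  mk <- function(tp, vals) data.frame(
    plate_id = "P1", well_id = well_name(2, seq_along(vals) + 1),
    timepoint_h = tp, compound_id = "CTRL", role = "control",
    normalized_pct = vals)
  # CVs approximately 13.1, 12.1, 28.0 -> 48 h wins
  wells <- rbind(mk(24, c(100 - 13.1, 100 + 13.1)),
                 mk(48, c(100 - 12.1, 100 + 12.1)),
                 mk(72, c(100 - 28.0, 100 + 28.0)))
  sel <- select_timepoint(wells)
  expect_equal(sel$timepoint_h, 48)
  expect_equal(sel$cv_table$cv_pct,
               c(13.1, 12.1, 28.0) * sqrt(2), tolerance = 1e-6)
  # exact tie -> earlier timepoint
  tie <- rbind(mk(24, c(90, 110)), mk(48, c(90, 110)))
  expect_equal(select_timepoint(tie)$timepoint_h, 24)
  # identical controls -> CV 0 everywhere, earliest picked
  flat <- rbind(mk(24, c(100, 100)), mk(48, c(100, 100)))
  sel0 <- select_timepoint(flat)
  expect_true(all(sel0$cv_table$cv_pct == 0))
  expect_equal(sel0$timepoint_h, 24)
})

test_that("hit ranking orders by mean, then SD, then id", {
  res <- data.frame(compound_id = c("X", "Y", "Z", "W"),
                    timepoint_h = 48, n_replicates = 3,
                    mean_normalized_pct = c(150, 250, 90, 150),
                    sd_normalized_pct = c(20, 10, 5, 5),
                    excluded = FALSE, reason = "")
  r <- rank_hits(res, 48)
  expect_identical(r$compound_id, c("Y", "W", "X", "Z"))
})

test_that("null plates center on 100% and a doubled compound reads ~200%", {
  spec <- default_plate_spec(effects = c(C010 = 2.0))
  res <- run_screen_study(spec, seed = 5)
  nulls <- res$result[res$result$compound_id != "C010" &
                        res$result$timepoint_h == 48, ]
  expect_lt(abs(mean(nulls$mean_normalized_pct) - 100), 10)
  hit <- res$result[res$result$compound_id == "C010" &
                      res$result$timepoint_h == 48, ]
  expect_lt(abs(hit$mean_normalized_pct - 200), 35)
  expect_identical(res$ranked$compound_id[1], "C010")
  # replicate SDs are computed over the triplicate plates
  expect_true(all(res$result$n_replicates == 3))
})

test_that("plate generation is deterministic and validates its spec", {
  spec <- default_plate_spec(n_compounds = 8, n_controls = 2, n_plates = 1)
  expect_identical(generate_plate(spec, seed = 3), generate_plate(spec, seed = 3))
  expect_error(plate_spec(compound_wells = data.frame(
    well_id = "B02", compound_id = "C1", effect = 1),
    control_wells = character(0)), "control")
  expect_error(plate_spec(compound_wells = data.frame(
    well_id = "A01", compound_id = "C1", effect = 1),
    control_wells = "B02"), "[Oo]uter")
  # total dropout makes every site flag-eligible
  spec_d <- default_plate_spec(n_compounds = 4, n_controls = 2, n_plates = 1,
                               site_dropout_prob = 1, timepoints_h = 24)
  plate_d <- generate_plate(spec_d, seed = 1)
  expect_true(all(plate_d$sites$n_nuclei <
                    0.5 * spec_d$mean_nuclei_per_site))
})

test_that("the pipeline is invariant to input row order", {
  spec <- default_plate_spec(n_compounds = 10, n_controls = 3, n_plates = 2,
                             timepoints_h = c(24, 48))
  plate <- generate_plate(spec, seed = 9)
  run <- function(sites) {
    qc <- site_qc(sites)
    wells <- normalize_to_control(aggregate_wells(qc$retained), plate$plate_map)
    r <- treatment_qc(wells)
    r[order(r$compound_id, r$timepoint_h), ]
  }
  a <- run(plate$sites)
  set.seed(1)
  b <- run(plate$sites[sample(nrow(plate$sites)), ])
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
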