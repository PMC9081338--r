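test_that("ploidy population generation matches its spec", {
  spec <- ploidy_population_spec(c(1, 0, 0), intensity_cv = 1e-9,
                                 n_nuclei = 200)
  pop <- generate_ploidy_population(spec, seed = 1)
  expect_equal(pop$dna_intensity, rep(1.0, 200), tolerance = 1e-6)
  expect_error(ploidy_population_spec(n_nuclei = 5), ">= 10")
  # no binucleation -> every cell id unique
  pop1 <- generate_ploidy_population(
    ploidy_population_spec(frac_binucleated = 0, n_nuclei = 300), seed = 2)
  expect_equal(max(table(pop1$cell_id)), 1)
  expect_identical(generate_ploidy_population(seed = 4),
                   generate_ploidy_population(seed = 4))
})

test_that("a 50/50 2N-4N mixture has its boundary in the histogram valley", {
  spec <- ploidy_population_spec(c(0.5, 0.5, 0), intensity_cv = 0.05,
                                 n_nuclei = 5000)
  pop <- generate_ploidy_population(spec, seed = 5)
  thr <- derive_ploidy_thresholds(pop$dna_intensity)
  expect_gt(thr$boundaries[1], 1.2)
  expect_lt(thr$boundaries[1], 1.8)
  # mixture-density oracle: the analytic valley of the two equal log-normal
  # components lies at the equal-density point between the modes
  dens <- function(x) 0.5 * dlnorm(x, log(1), 0.05) +
    0.5 * dlnorm(x, log(2), 0.05)
  grid <- seq(1.1, 1.9, by = 0.001)
  valley <- grid[which.min(dens(grid))]
  expect_lt(abs(thr$boundaries[1] - valley), 0.25)
})

test_that("a pure 2N population falls back to the sqrt(2) boundary", {
  spec <- ploidy_population_spec(c(1, 0, 0), intensity_cv = 0.1,
                                 n_nuclei = 1000)
  pop <- generate_ploidy_population(spec, seed = 6)
  thr <- derive_ploidy_thresholds(pop$dna_intensity)
  expect_equal(thr$boundaries[1], sqrt(2) * thr$reference_2n_mode,
               tolerance = 1e-9)
  expect_equal(thr$boundaries[2], 2 * sqrt(2) * thr$reference_2n_mode,
               tolerance = 1e-9)
  expect_error(derive_ploidy_thresholds(rlnorm(50)), "100")
})

test_that("ploidy thresholds and calls are scale equivariant", {
  pop <- generate_ploidy_population(seed = 7)
  thr1 <- derive_ploidy_thresholds(pop$dna_intensity)
  thr3 <- derive_ploidy_thresholds(3 * pop$dna_intensity)
  expect_equal(thr3$boundaries, 3 * thr1$boundaries, tolerance = 1e-6)
  expect_identical(call_ploidy(pop$dna_intensity, thr1)$classes,
                   call_ploidy(3 * pop$dna_intensity, thr3)$classes)
})

test_that("class calls use interval membership with lower-class ties", {
  thr <- structure(list(boundaries = c(1.5, 3.0), reference_2n_mode = 1),
                   class = "ploidy_thresholds")
  r <- call_ploidy(c(1.0, 1.5, 2.0, 3.0, 5.0), thr)
  expect_identical(r$classes, c("2N", "2N", "4N", "4N", "8N+"))
  expect_equal(sum(r$fractions), 1)
})

test_that("generator ploidy fractions are recovered within 2 points", {
  pop <- generate_ploidy_population(ploidy_population_spec(n_nuclei = 5000),
                                    seed = 8)
  gated <- gate_nuclei(pop)
  thr <- derive_ploidy_thresholds(gated$dna_intensity)
  r <- call_ploidy(gated, thr)
  expect_true(all(abs(r$fractions - c(0.70, 0.27, 0.03)) < 0.02))
})

test_that("marker gating retains marker-positive, Ki-67-negative nuclei", {
  pop <- generate_ploidy_population(ploidy_population_spec(
    n_nuclei = 2000, frac_ki67_pos = 0.2), seed = 9)
  gated <- gate_nuclei(pop)
  se <- sqrt(0.2 * 0.8 / 2000)
  expect_lt(abs(nrow(gated) / nrow(pop) - 0.8), 3 * se + 0.02)
  # recovered gate is consistent with generator truth
  expect_gt(mean(!gated$true_ki67), 0.98)
  # unimodal marker channel (all positive) gates nothing
  all_pos <- pop
  all_pos$ki67 <- rlnorm(nrow(pop), log(10), 0.3)   # all negative
  g2 <- gate_nuclei(all_pos)
  expect_equal(nrow(g2), nrow(all_pos))
  # explicit threshold on an all-positive Ki-67 channel empties the gate
  hot <- pop
  hot$ki67 <- 500
  expect_error(gate_nuclei(hot, ki67_thr = 100), "empty gate")
  # gate order does not matter: thresholds are derived before gating
  g_rev <- gate_nuclei(pop, marker_thr = NULL, ki67_thr = NULL)
  expect_identical(sort(gated$nucleus_id), sort(g_rev$nucleus_id))
})

test_that("binucleation and marker fractions recover generator truth", {
  pop <- generate_ploidy_population(ploidy_population_spec(
    n_nuclei = 2600, frac_binucleated = 0.3), seed = 10)
  bf <- binucleation_fraction(pop)
  se <- sqrt(0.3 * 0.7 / bf$n_cells)
  expect_lt(abs(bf$fractions[["bi"]] - 0.3), 3 * se + 0.01)
  one_cell <- data.frame(cell_id = c("a", "a", "a"))
  expect_equal(unname(binucleation_fraction(one_cell)$fractions["multi"]), 1)

  pop2 <- generate_ploidy_population(ploidy_population_spec(
    n_nuclei = 2000, frac_ki67_pos = 0.22), seed = 11)
  est <- marker_positive_fraction(pop2, "ki67")
  se2 <- 100 * sqrt(0.22 * 0.78 / 2000)
  expect_lt(abs(est - 22), 3 * se2 + 1)
  expect_equal(marker_positive_fraction(data.frame(ki67 = c(500, 600)),
                                        "ki67", thr = 100), 100)
  expect_equal(marker_positive_fraction(data.frame(ki67 = c(5, 6)),
                                        "ki67", thr = 100), 0)
})
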