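small_spec <- function(...) {
  simulation_spec(n_proteins = 120,
                  batches = list(b1 = c(UT = 4, T1 = 4),
                                 b2 = c(UT = 5, T1 = 4)),
                  ...)
}

test_that("the generator respects its own specification", {
  sp <- small_spec(seed = 42)
  sim <- simulate_secretome(sp)
  expect_equal(nrow(sim$truth$proteins), 120L)
  expect_equal(sum(!sim$truth$proteins$secreted), round(0.2 * 120))
  # decoy/contaminant rows flagged in the MaxQuant dialect
  pg <- sim$protein_groups
  expect_equal(sum(pg$Reverse == "+"), round(0.02 * 120))
  expect_equal(sum(pg[["Potential contaminant"]] == "+"), round(0.02 * 120))
  # planted effects only on secreted proteins, at the configured scale
  eff <- sim$truth$effects
  expect_equal(nrow(eff), round(0.02 * 120) * 2)  # two (batch, treatment) pairs
  expect_true(all(eff$true_log2fc %in% c(-2, -1.5, 1.5, 2)))
  sec <- sim$truth$proteins$protein_id[sim$truth$proteins$secreted]
  expect_true(all(eff$protein_id %in% sec))
  # raw intensities are 2^log2 rounded to 6 significant digits, 0 = missing
  lfq <- as.matrix(pg[pg$Reverse != "+" & pg[["Potential contaminant"]] != "+",
                      grep("^LFQ intensity", names(pg))])
  x <- sim$truth$log2
  obs <- sim$truth$cause == "detected"
  expect_equal(lfq[obs], signif(2^x[obs], 6), tolerance = 1e-12)
  expect_true(all(lfq[!obs] == 0))
})

test_that("same seed gives byte-identical files; different seed differs", {
  sp <- small_spec(seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_secretome(sp), d1)
  write_simulation(simulate_secretome(sp), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  sp2 <- small_spec(seed = 10)
  sim3 <- simulate_secretome(sp2)
  expect_false(identical(sim3$protein_groups, simulate_secretome(sp)$protein_groups))
})

test_that("limiting cases: no effects, no missingness, MCAR", {
  sim0 <- simulate_secretome(small_spec(fraction_affected = 0, seed = 1))
  expect_equal(nrow(sim0$truth$effects), 0L)

  simf <- simulate_secretome(small_spec(miss_mid = -Inf, n_degenerate = 0,
                                        seed = 1))
  expect_true(all(simf$truth$cause == "detected"))

  simm <- simulate_secretome(small_spec(missing_mode = "mcar",
                                        mcar_rate = 0.3, seed = 1))
  expect_gt(sum(simm$truth$cause == "censored"), 0L)
})

test_that("degenerate samples exceed 95% missingness and are listed for exclusion", {
  sp <- simulation_spec(seed = 1)  # full study defaults
  sim <- simulate_secretome(sp)
  expect_equal(nrow(sim$exclusions), 2L)
  deg <- sim$design$sample_id[sim$design$donor %in% sim$exclusions$donor &
                                sim$design$condition == "UT" &
                                sim$design$batch == "term"]
  expect_length(deg, 2L)
  pg <- sim$protein_groups
  for (s in deg) {
    v <- pg[[paste("LFQ intensity", s)]][seq_len(1400)]
    expect_gt(mean(v == 0), 0.95)
  }
  # term untreated: 5 usable + 2 degenerate replicates
  expect_equal(sum(sim$design$batch == "term" & sim$design$condition == "UT"), 7L)
})

test_that("missingness rate decreases with intensity under MNAR", {
  sp <- simulation_spec(n_proteins = 1000,
                        batches = list(b1 = c(UT = 4, T1 = 4)),
                        n_degenerate = 0, seed = 3)
  sim <- simulate_secretome(sp)
  x <- sim$truth$log2
  missing <- sim$truth$cause != "detected"
  dec <- cut(x, quantile(x, 0:10 / 10), include.lowest = TRUE, labels = FALSE)
  rate <- tapply(as.vector(missing), as.vector(dec), mean)
  # non-increasing across intensity deciles up to sampling noise
  expect_true(all(diff(rate) <= 0.02))
  expect_gt(rate[1], rate[10] + 0.2)
})

test_that("replicate counts below 2 are rejected", {
  expect_error(simulation_spec(batches = list(b = c(UT = 1, T1 = 4))),
               "at least 2")
  expect_error(simulation_spec(batches = list(b = c(T1 = 4))), "reference")
})

test_that("pipeline recovers planted effects with near-zero bias when fully observed", {
  sp <- simulation_spec(
    n_proteins = 150,
    batches = list(b1 = c(UT = 4, T1 = 4)),
    fraction_affected = 0.05, effect_sizes = 2, sd_e = 0.5,
    miss_mid = -Inf, n_degenerate = 0, frac_decoy = 0,
    frac_contaminant = 0, seed = 5)
  rec <- recover_truth(sp, n_rep = 5, seed = 11)
  expect_lt(abs(rec$summary$bias), 0.15)
  # Welch at n = 4 with sd 0.5 against a +2 log2FC has moderate power;
  # well over half the planted effects should be recovered
  expect_gt(rec$summary$recall, 0.4)
})

test_that("recall decreases as replicate noise grows", {
  recalls <- vapply(c(0.3, 0.8, 2.0), function(s) {
    sp <- simulation_spec(n_proteins = 150,
                          batches = list(b1 = c(UT = 4, T1 = 4)),
                          fraction_affected = 0.05, effect_sizes = 2,
                          sd_e = s, miss_mid = -Inf, n_degenerate = 0,
                          frac_decoy = 0, frac_contaminant = 0, seed = 5)
    recover_truth(sp, n_rep = 4, seed = 13)$summary$recall
  }, numeric(1))
  expect_true(all(diff(recalls) < 0))
})
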