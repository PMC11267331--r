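assay_fixture <- function() {
  # one analyte, one batch, UT + treated, with technical duplicates
  data.frame(
    analyte = "IL6", batch = "first",
    condition = rep(c("UT", "UT", "TiO2", "TiO2"), each = 2),
    donor = rep(c("d1", "d2", "d1", "d2"), each = 2),
    raw_signal = c(100, 100, 200, 200, 300, 300, 330, 270),
    tissue_protein = c(10, 10, 20, 20, 10, 10, 20, 20),
    replicate = rep(1:2, 4),
    stringsAsFactors = FALSE)
}

test_that("tissue-protein normalization and FC vs untreated follow the rule", {
  out <- normalize_fc(assay_fixture())
  ut <- out$per_donor[out$per_donor$condition == "UT", ]
  # signals (100, 200) over protein (10, 20) normalize to (10, 10)
  expect_equal(ut$normalized, c(10, 10))
  expect_equal(ut$fc, c(1, 1))
  # untreated group FC is exactly 1 by construction
  expect_equal(out$fc$fc[out$fc$condition == "UT"], 1)
  # treated: normalized (30, 15), UT mean 10 -> per-donor FC (3, 1.5), mean 2.25
  tr <- out$fc[out$fc$condition == "TiO2", ]
  expect_equal(tr$fc, 2.25)
  expect_equal(tr$n_donors, 2L)
})

test_that("normalization contract errors fire", {
  t <- assay_fixture()
  t$tissue_protein[1] <- 0
  expect_error(normalize_fc(t), "positive")
  t2 <- assay_fixture()
  t2 <- t2[t2$condition != "UT", ]
  expect_error(normalize_fc(t2), "UT")
})

test_that("untreated FC is 1 on randomized tables", {
  withr::local_seed(77)
  for (i in 1:20) {
    t <- data.frame(
      analyte = sample(c("a1", "a2"), 30, TRUE),
      batch = sample(c("b1", "b2"), 30, TRUE),
      condition = sample(c("UT", "T1"), 30, TRUE),
      donor = sample(c("d1", "d2", "d3"), 30, TRUE),
      raw_signal = runif(30, 50, 500),
      tissue_protein = runif(30, 5, 50), stringsAsFactors = FALSE)
    # make sure every analyte/batch has untreated values
    t$condition[1:8] <- "UT"
    t <- t[order(t$analyte, t$batch, t$condition != "UT"), ]
    has_ut <- with(t, ave(condition == "UT",
                          paste(analyte, batch), FUN = any))
    t <- t[as.logical(has_ut), ]
    out <- normalize_fc(t)
    ut <- out$fc[out$fc$condition == "UT", ]
    expect_equal(ut$fc, rep(1, nrow(ut)), tolerance = 1e-12)
  }
})

test_that("significance flags use the stated p thresholds", {
  withr::local_seed(6)
  # identical groups: p = 1, no flag
  pd <- data.frame(analyte = "A", batch = "b",
                   condition = rep(c("UT", "T1"), each = 3),
                   donor = paste0("d", 1:6),
                   normalized = rep(5, 6), fc = 1, stringsAsFactors = FALSE)
  f <- flag_changes(pd)
  expect_equal(f$p, 1)
  expect_equal(f$flag, "ns")

  # calibrated cases across the 0.05 / 0.09 boundaries
  mk <- function(tr) {
    data.frame(analyte = "A", batch = "b",
               condition = rep(c("UT", "T1"), each = 4),
               donor = paste0("d", 1:8),
               normalized = c(10, 11, 9, 10, tr), stringsAsFactors = FALSE)
  }
  cases <- list(c(14, 15, 13, 14), c(11.5, 12.5, 10.5, 14), c(10.2, 10.8, 9.6, 10.5))
  for (tr in cases) {
    f <- flag_changes(mk(tr))
    ref <- t.test(tr, c(10, 11, 9, 10), var.equal = TRUE)$p.value
    expect_equal(f$p, ref, tolerance = 1e-12)
    expect_equal(f$flag,
                 if (ref < 0.05) "significant" else if (ref < 0.09) "notable" else "ns")
  }

  # singleton groups are skipped with a warning
  pd1 <- data.frame(analyte = "A", batch = "b",
                    condition = c("UT", "UT", "T1"), donor = c("d1", "d2", "d1"),
                    normalized = c(1, 2, 5), stringsAsFactors = FALSE)
  expect_warning(f1 <- flag_changes(pd1), "fewer than 2")
  expect_null(f1)
})

test_that("2^-dCt relative expression matches the forced worked values", {
  ct <- data.frame(
    gene = rep(c("VEGFA", "PPIA", "ACTB"), 2),
    sample = rep(c("s1", "s2"), each = 3),
    ct = c(25, 20, 22, 22, 21, 23),
    condition = rep(c("UT", "T1"), each = 3), stringsAsFactors = FALSE)
  out <- ddct(ct)
  s1 <- out[out$sample == "s1", ]
  expect_equal(s1$dct, 4)
  expect_equal(s1$rel, 2^-4)
  expect_equal(s1$rel, 0.0625)
  # gene Ct equal to the mean reference Ct -> rel = 1
  s2 <- out[out$sample == "s2", ]
  expect_equal(s2$rel, 1)
  # treated rel 1 over UT mean 0.0625 -> fc 16, log2fc 4
  expect_equal(s2$fc, 16)
  expect_equal(s2$log2fc, 4)
  expect_equal(s1$fc, 1)
})

test_that("ddct contract and scale behaviour", {
  ct <- data.frame(gene = c("VEGFA", "PPIA"), sample = "s1", ct = c(25, 20),
                   stringsAsFactors = FALSE)
  expect_error(ddct(ct), "ACTB")

  base <- data.frame(gene = c("VEGFA", "PPIA", "ACTB"), sample = "s1",
                     ct = c(25, 20, 22), stringsAsFactors = FALSE)
  shifted <- base; shifted$ct <- shifted$ct + 3
  # adding a constant to gene and references alike leaves rel unchanged
  expect_equal(ddct(shifted)$rel, ddct(base)$rel)
  # adding it to the gene only changes rel by 2^-3
  gene_only <- base; gene_only$ct[1] <- gene_only$ct[1] + 3
  expect_equal(ddct(gene_only)$rel, ddct(base)$rel * 2^-3)
})
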