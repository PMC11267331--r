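make_pt <- function(flags_c, flags_r, flags_s, n_samp = 2) {
  n <- length(flags_c)
  design <- make_design(list(b = c(UT = n_samp)))
  raw <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    "Protein IDs" = sprintf("P%d", seq_len(n)),
    "Potential contaminant" = ifelse(flags_c, "+", ""),
    "Reverse" = ifelse(flags_r, "+", ""),
    "Only identified by site" = ifelse(flags_s, "+", ""))
  for (s in design$sample_id) raw[[paste("LFQ intensity", s)]] <- 2^20
  list(pt = as_protein_table(raw, design), design = design)
}

test_that("QC filter removes flagged rows with stated priority", {
  x <- make_pt(c(TRUE, FALSE, FALSE, FALSE, FALSE),
               c(FALSE, TRUE, FALSE, FALSE, FALSE),
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- apply_qc_filters(x$pt)
  expect_equal(nrow(out$table$meta), 2L)
  expect_equal(out$report[c("contaminant", "reverse", "site_only")],
               c(contaminant = 1L, reverse = 1L, site_only = 1L))

  # doubly flagged row counted once, under contaminant
  y <- make_pt(TRUE, TRUE, FALSE)
  rep2 <- apply_qc_filters(y$pt)$report
  expect_equal(unname(rep2["contaminant"]), 1L)
  expect_equal(unname(rep2["reverse"]), 0L)

  # all-clean table is the identity with an empty report
  z <- make_pt(rep(FALSE, 3), rep(FALSE, 3), rep(FALSE, 3))
  out3 <- apply_qc_filters(z$pt)
  expect_equal(out3$table$meta, z$pt$meta)
  expect_equal(sum(out3$report[c("contaminant", "reverse", "site_only")]), 0L)
  expect_equal(unname(out3$report["retained"]), 3L)
})

test_that("presence filter applies the >= tau rule per condition group", {
  design <- make_design(list(b = c(UT = 4, T1 = 4)))
  m <- matrix(NA_real_, 3, 8, dimnames = list(c("A", "B", "C"),
                                              design$sample_id))
  m["A", 1:2] <- 20           # 2/4 UT = 0.5 -> retained
  m["B", c(1, 5)] <- 20       # 1/4 everywhere -> removed
  m["C", 5:7] <- 20           # 3/4 T1 -> retained
  out <- presence_filter(m, design, tau = 0.5)
  expect_equal(rownames(out), c("A", "C"))

  # a 3-of-5 group passes at tau = 0.5 (0.6 >= 0.5)
  d5 <- make_design(list(term = c(UT = 5)))
  m5 <- matrix(NA_real_, 1, 5, dimnames = list("X", d5$sample_id))
  m5[1, 1:3] <- 20
  expect_equal(rownames(presence_filter(m5, d5)), "X")
})

test_that("presence filter equals the brute-force group-enumeration oracle", {
  withr::local_seed(11)
  for (i in 1:1000) {
    design <- make_design(list(
      b1 = c(UT = sample(2:5, 1), T1 = sample(2:5, 1)),
      b2 = c(UT = sample(2:5, 1), T1 = sample(2:5, 1))))
    m <- rand_matrix(6, design, miss_rate = runif(1, 0.1, 0.9))
    tau <- sample(c(0.3, 0.5, 0.75, 1), 1)
    got <- presence_filter(m, design, tau = tau)
    expect_equal(as.character(rownames(got)),
                 rownames(m)[presence_oracle(m, design, tau)])
  }
})

test_that("secreted restriction matches terms case-insensitively", {
  design <- make_design(list(b = c(UT = 2)))
  m <- matrix(20, 3, 2, dimnames = list(c("A", "B", "C"), design$sample_id))
  annot <- list(A = c("Extracellular  Exosome"), B = c("nucleus"))
  out <- restrict_secreted(m, annot)
  expect_equal(rownames(out), "A")  # B wrong term, C unannotated
  expect_error(restrict_secreted(m, annot, terms = character(0)))
})

test_that("merge_batches unions proteins and samples with missing blocks", {
  d1 <- make_design(list(b1 = c(UT = 2)))
  d2 <- make_design(list(b2 = c(UT = 2)))
  a <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), d1$sample_id))
  b <- matrix(2, 4, 2, dimnames = list(c("D", "E", "F", "G"), d2$sample_id))
  m <- merge_batches(a, b)
  expect_equal(dim(m), c(7L, 4L))
  expect_true(all(is.na(m[c("A", "B", "C"), d2$sample_id])))
  expect_true(all(is.na(m[c("D", "E", "F", "G"), d1$sample_id])))

  # shared protein keeps both batches' values on one row
  b2 <- matrix(5, 1, 2, dimnames = list("A", d2$sample_id))
  m2 <- merge_batches(a, b2)
  expect_equal(nrow(m2), 3L)
  expect_equal(unname(m2["A", ]), c(1, 1, 5, 5))

  # merging with an empty batch is the identity
  empty <- matrix(numeric(0), 3, 0, dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(merge_batches(a, empty), a, ignore_attr = TRUE)
})

test_that("median centering zeroes each sample's observed median", {
  m <- matrix(c(10, 12, 20, 5, NA, 7), 3, 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  out <- median_center(m)
  expect_equal(unname(out[, "s1"]), c(-2, 0, 8))
  expect_equal(unname(out[, "s2"]), c(-1, NA, 1))
  expect_equal(matrix_stage(out), "centered")

  all_na <- m; all_na[, 2] <- NA
  expect_error(median_center(all_na), "s2")
})

test_that("median centering is idempotent and mask-preserving on random data", {
  withr::local_seed(5)
  for (i in 1:50) {
    design <- make_design(list(b = c(UT = sample(3:6, 1))))
    m <- rand_matrix(sample(5:30, 1), design, miss_rate = runif(1, 0, 0.4))
    while (any(colSums(!is.na(m)) == 0)) {
      m <- rand_matrix(10, design, miss_rate = 0.3)
    }
    c1 <- median_center(m)
    meds <- apply(c1, 2, median, na.rm = TRUE)
    expect_true(all(abs(meds) < 1e-9))
    expect_equal(median_center(c1), c1, tolerance = 1e-12)
    expect_equal(is.na(c1), is.na(m), ignore_attr = TRUE)
  }
})

test_that("the filter report conserves row counts per batch", {
  tp <- toy_paths()
  fit <- suppressWarnings(secretome_da(tp$pg, tp$design, seed = 1))
  fr <- fit$filter_report
  expect_equal(fr$input,
               fr$contaminant + fr$reverse + fr$site_only +
                 fr$presence + fr$non_secreted + fr$retained)
})
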