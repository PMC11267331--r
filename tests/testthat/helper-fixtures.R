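# Shared fixtures and independent oracles for the test suite.

toy_paths <- function() {
  list(pg = system.file("extdata", "toy_proteinGroups.tsv", package = "secretomics"),
       design = system.file("extdata", "toy_design.tsv", package = "secretomics"),
       gocc = system.file("extdata", "toy_gocc.tsv", package = "secretomics"))
}

# design with one batch per element of `batches`; each element a named
# vector of replicate counts per condition
make_design <- function(batches = list(b1 = c(UT = 4, T1 = 4))) {
  rows <- list()
  for (b in names(batches)) {
    for (cond in names(batches[[b]])) {
      nr <- batches[[b]][[cond]]
      rows[[paste(b, cond)]] <- data.frame(
        sample_id = sprintf("%s_%s_%d", b, cond, seq_len(nr)),
        batch = b, condition = cond,
        donor = sprintf("d%d", seq_len(nr)), replicate = seq_len(nr),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# random log-intensity matrix with missing cells
rand_matrix <- function(n_prot, design, miss_rate = 0.2, mu = 25, sd = 2) {
  m <- matrix(rnorm(n_prot * nrow(design), mu, sd), n_prot,
              dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                              design$sample_id))
  m[runif(length(m)) < miss_rate] <- NA_real_
  attr(m, "stage") <- "raw_log2"
  m
}

# brute-force BH step-up: q(i) = min_{j >= i} p(j) * m / j on sorted p
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# brute-force presence rule: enumerate every (batch, condition) group
presence_oracle <- function(m, design, tau = 0.5) {
  keep <- logical(nrow(m))
  groups <- unique(design[, c("batch", "condition")])
  for (i in seq_len(nrow(m))) {
    for (g in seq_len(nrow(groups))) {
      cols <- design$sample_id[design$batch == groups$batch[g] &
                               design$condition == groups$condition[g]]
      if (sum(!is.na(m[i, cols])) / length(cols) >= tau) keep[i] <- TRUE
    }
  }
  keep
}

# matrix whose columns have exactly mean 0 / SD 1 over their observed cells,
# so the per-sample imputation reference is (mu, sigma) = (0, 1) exactly
unit_ref_matrix <- function(n_minor, n_major, n_full, design,
                            miss_major_cols = 2L) {
  n <- n_minor + n_major + n_full
  m <- matrix(NA_real_, n, nrow(design),
              dimnames = list(sprintf("P%05d", seq_len(n)), design$sample_id))
  ut_cols <- design$sample_id[design$condition == "UT"]
  tr_cols <- design$sample_id[design$condition != "UT"]
  rows_minor <- seq_len(n_minor)
  rows_major <- n_minor + seq_len(n_major)
  rows_full <- n_minor + n_major + seq_len(n_full)
  m[, ut_cols] <- rnorm(n * length(ut_cols))
  m[rows_major, tr_cols[-seq_len(miss_major_cols)]] <-
    rnorm(n_major * (length(tr_cols) - miss_major_cols))
  m[rows_full, tr_cols] <- rnorm(n_full * length(tr_cols))
  for (j in seq_len(ncol(m))) {
    obs <- !is.na(m[, j])
    m[obs, j] <- as.numeric(scale(m[obs, j]))
  }
  attr(m, "stage") <- "centered"
  m
}
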