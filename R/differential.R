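#' @title Welch tests, FDR control and hit calling
#' @name differential
#' @description
#' Each treated group is compared with the untreated replicates of the same
#' batch using Welch's unequal-variance t-test on the imputed log2 matrix,
#' so the test and the log2 fold change use the same values. P-values are
#' adjusted with the Benjamini-Hochberg step-up procedure within each
#' (batch, treatment) family, and proteins with q < 0.1 and |log2FC| >= 1
#' are called hits.
NULL

#' Welch's two-sample t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student t distribution. When both groups have zero variance: identical
#' means give `t = 0, p = 1`; different means are tested with the variance
#' floored at machine epsilon and flagged (`var_floored`), preserving the
#' direction of the difference.
#'
#' @param x,y Numeric vectors of at least 2 values each, no missing values.
#' @return List with `t_stat`, `df`, `p`, and logical `var_floored`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  if (anyNA(x) || anyNA(y)) stop("missing values: test after imputation")
  r <- .welch_rows(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(t_stat = r$t[1L], df = r$df[1L], p = r$p[1L],
       var_floored = r$var_floored[1L])
}

# Row-wise Welch test for matrices X (treated) and Y (untreated).
.welch_rows <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1L)
  vy <- rowSums((Y - my)^2) / (ny - 1L)
  floored <- vx == 0 & vy == 0 & mx != my
  vx_f <- ifelse(floored, .Machine$double.eps, vx)
  vy_f <- ifelse(floored, .Machine$double.eps, vy)
  se2 <- vx_f / nx + vy_f / ny
  diff <- mx - my
  t_stat <- ifelse(se2 == 0, 0, diff / sqrt(se2))
  # Welch-Satterthwaite; zero variances with equal means degenerate to df = 1
  denom <- (vx_f / nx)^2 / (nx - 1L) + (vy_f / ny)^2 / (ny - 1L)
  df <- ifelse(denom == 0, nx + ny - 2L, se2^2 / denom)
  p <- ifelse(t_stat == 0, 1, 2 * stats::pt(-abs(t_stat), df))
  list(t = t_stat, df = df, p = pmin(p, 1), log2fc = diff,
       var_floored = floored)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j >= i} p(j) * m / j` over the ascending-sorted p-values,
#' clipped at 1 and returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(scaled))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Test every treatment against untreated, per batch
#'
#' For each batch and each non-reference condition, runs a row-wise Welch
#' test of the treated replicates against the batch's untreated replicates,
#' restricted to proteins quantified in that batch (a merged matrix carries
#' all-missing blocks for proteins absent from a batch). BH adjustment is
#' applied within the chosen family.
#'
#' @param m Imputed log-intensity matrix (stage `"imputed"`).
#' @param design Design covering the matrix columns.
#' @param ref Reference (untreated) condition label. Default `"UT"`.
#' @param family FDR family: `"per_treatment"` (default; each
#'   (batch, contrast) pair is its own family) or `"per_batch"` (all
#'   contrasts of a batch pooled).
#' @param fdr_cut,lfc_cut Hit thresholds passed to [call_hits()].
#' @param genes Optional named vector protein_id -> gene name.
#' @return Data frame with one row per (protein, batch, contrast):
#'   `protein_id`, `gene`, `batch`, `contrast`, `log2fc`, `t_stat`, `df`,
#'   `p`, `q`, `hit`, `var_floored`.
#' @export
test_contrasts <- function(m, design, ref = "UT",
                           family = c("per_treatment", "per_batch"),
                           fdr_cut = 0.1, lfc_cut = 1.0, genes = NULL) {
  family <- match.arg(family)
  if (matrix_stage(m) != "imputed" && anyNA(m)) {
    stop("test_contrasts expects a complete (imputed) matrix")
  }
  design <- as_design(design)
  design <- design[design$sample_id %in% colnames(m), , drop = FALSE]
  res <- list()
  for (b in unique(design$batch)) {
    db <- design[design$batch == b, , drop = FALSE]
    ut_cols <- db$sample_id[db$condition == ref]
    if (length(ut_cols) < 2L) {
      stop("batch '", b, "' has fewer than 2 reference ('", ref, "') samples")
    }
    # proteins quantified in this batch: any pre-imputation value would do,
    # but after merge+impute all cells are filled; restrict by provenance if
    # recorded, else use all rows
    rows <- attr(m, "batch_proteins")[[b]]
    if (is.null(rows)) rows <- rownames(m)
    rows <- intersect(rows, rownames(m))
    Y <- m[rows, ut_cols, drop = FALSE]
    for (tr in setdiff(unique(db$condition), ref)) {
      tr_cols <- db$sample_id[db$condition == tr]
      if (length(tr_cols) < 2L) {
        warning("skipping ", b, "/", tr, ": fewer than 2 replicates")
        next
      }
      X <- m[rows, tr_cols, drop = FALSE]
      w <- .welch_rows(X, Y)
      res[[paste(b, tr, sep = "\r")]] <- data.frame(
        protein_id = rows,
        gene = if (is.null(genes)) NA_character_ else unname(genes[rows]),
        batch = b, contrast = paste0(tr, "_vs_", ref),
        log2fc = w$log2fc, t_stat = w$t, df = w$df, p = w$p,
        var_floored = w$var_floored,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  fam <- if (family == "per_treatment") {
    interaction(res$batch, res$contrast, drop = TRUE)
  } else {
    factor(res$batch)
  }
  res$q <- NA_real_
  for (f in levels(fam)) {
    idx <- fam == f
    res$q[idx] <- bh_adjust(res$p[idx])
  }
  call_hits(res, fdr_cut = fdr_cut, lfc_cut = lfc_cut)
}

#' Call differential-secretion hits
#'
#' A protein is a hit in a contrast if its BH-adjusted q-value is strictly
#' below `fdr_cut` and its absolute log2 fold change is at least `lfc_cut`.
#'
#' @param results Result data frame with columns `q` and `log2fc`.
#' @param fdr_cut FDR threshold (strict `<`). Default 0.1.
#' @param lfc_cut Absolute log2FC threshold (inclusive `>=`). Default 1.
#' @return `results` with a logical `hit` column (re)computed.
#' @export
call_hits <- function(results, fdr_cut = 0.1, lfc_cut = 1.0) {
  results$hit <- results$q < fdr_cut & abs(results$log2fc) >= lfc_cut
  results
}

#' Cross-batch overlap of hits per treatment
#'
#' @param results Result data frame with a `hit` column.
#' @return List with `membership` (named list: protein_id -> character
#'   vector of "batch:contrast" labels in which it is a hit) and `overlap`
#'   (data frame per contrast: number and ids of proteins hit in every batch
#'   tested for that contrast).
#' @export
overlap_summary <- function(results) {
  hits <- results[results$hit, , drop = FALSE]
  membership <- split(paste(hits$batch, hits$contrast, sep = ":"),
                      hits$protein_id)
  contrasts <- unique(results$contrast)
  rows <- lapply(contrasts, function(ct) {
    batches <- unique(results$batch[results$contrast == ct])
    sets <- lapply(batches, function(b) {
      hits$protein_id[hits$batch == b & hits$contrast == ct]
    })
    shared <- Reduce(intersect, sets)
    data.frame(contrast = ct, n_batches = length(batches),
               n_shared = length(shared),
               shared = paste(sort(shared), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  list(membership = membership, overlap = do.call(rbind, rows))
}
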