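#' @title Targeted-assay arithmetic: multiplex/ELISA fold changes and qPCR
#' @name targeted_assays
#' @description
#' Multiplex-array and ELISA readouts are normalized to whole-tissue protein
#' content, and fold changes are computed with reference to the untreated
#' conditioned medium of the same batch. Treatment effects are flagged with
#' a two-sided unpaired Student t-test (significant p < 0.05, notable
#' p < 0.09). qPCR relative expression uses the 2^-dCt method against the
#' mean Ct of the reference genes (PPIA and ACTB by default).
NULL

#' Tissue-protein normalization and fold change vs untreated
#'
#' Technical duplicates (rows sharing analyte/donor/condition/batch) are
#' averaged first. Each signal is divided by its sample's tissue protein
#' content; per-donor fold changes are taken against the mean normalized
#' untreated value of the same (analyte, batch); the condition-level FC is
#' the mean over donors.
#'
#' @param t Data frame with columns `analyte`, `donor`, `condition`,
#'   `batch`, `raw_signal`, `tissue_protein` (and optionally `replicate`
#'   for technical duplicates).
#' @param ref Untreated condition label. Default `"UT"`.
#' @return List with `per_donor` (one row per analyte/batch/condition/donor:
#'   `normalized`, `fc`) and `fc` (one row per analyte/batch/condition: mean
#'   FC over donors, `n_donors`).
#' @export
normalize_fc <- function(t, ref = "UT") {
  need <- c("analyte", "donor", "condition", "batch", "raw_signal",
            "tissue_protein")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("assay table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(t$tissue_protein) | t$tissue_protein <= 0)) {
    stop("tissue_protein must be positive")
  }
  # average technical duplicates
  key <- interaction(t$analyte, t$batch, t$condition, t$donor, drop = TRUE)
  agg <- data.frame(
    analyte = tapply(t$analyte, key, `[`, 1L),
    batch = tapply(t$batch, key, `[`, 1L),
    condition = tapply(t$condition, key, `[`, 1L),
    donor = tapply(t$donor, key, `[`, 1L),
    normalized = as.numeric(tapply(t$raw_signal / t$tissue_protein, key, mean)),
    stringsAsFactors = FALSE, row.names = NULL)

  ab <- interaction(agg$analyte, agg$batch, drop = TRUE)
  agg$fc <- NA_real_
  for (g in levels(ab)) {
    idx <- ab == g
    ut <- agg$normalized[idx & agg$condition == ref]
    if (length(ut) == 0L) {
      stop("no '", ref, "' samples for analyte/batch ", g)
    }
    agg$fc[idx] <- agg$normalized[idx] / mean(ut)
  }
  grp <- interaction(agg$analyte, agg$batch, agg$condition, drop = TRUE)
  fc <- data.frame(
    analyte = tapply(agg$analyte, grp, `[`, 1L),
    batch = tapply(agg$batch, grp, `[`, 1L),
    condition = tapply(agg$condition, grp, `[`, 1L),
    fc = as.numeric(tapply(agg$fc, grp, mean)),
    n_donors = as.integer(tapply(agg$fc, grp, length)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_donor = agg, fc = fc)
}

#' Flag treatment effects in a normalized assay table
#'
#' Two-sided unpaired equal-variance Student t-test of each treated group's
#' per-donor normalized values against the untreated group of the same
#' (analyte, batch). Welch's unequal-variance variant is available via
#' `var_equal = FALSE`.
#'
#' @param per_donor The `per_donor` table from [normalize_fc()].
#' @param ref Untreated condition label. Default `"UT"`.
#' @param alpha_sig Significance threshold (p strictly below). Default 0.05.
#' @param alpha_notable Trend threshold. Default 0.09.
#' @param var_equal Use the pooled-variance Student test. Default `TRUE`.
#' @return Data frame per (analyte, batch, treated condition): `p`, `flag`
#'   in {significant, notable, ns}; groups with fewer than 2 donors are
#'   skipped with a warning.
#' @export
flag_changes <- function(per_donor, ref = "UT", alpha_sig = 0.05,
                         alpha_notable = 0.09, var_equal = TRUE) {
  out <- list()
  ab <- interaction(per_donor$analyte, per_donor$batch, drop = TRUE)
  for (g in levels(ab)) {
    d <- per_donor[ab == g, , drop = FALSE]
    ut <- d$normalized[d$condition == ref]
    for (cond in setdiff(unique(d$condition), ref)) {
      tr <- d$normalized[d$condition == cond]
      if (length(tr) < 2L || length(ut) < 2L) {
        warning("skipping ", d$analyte[1L], "/", d$batch[1L], "/", cond,
                ": fewer than 2 replicates")
        next
      }
      p <- if (stats::sd(tr) == 0 && stats::sd(ut) == 0 &&
               mean(tr) == mean(ut)) {
        1
      } else {
        stats::t.test(tr, ut, var.equal = var_equal)$p.value
      }
      out[[paste(g, cond)]] <- data.frame(
        analyte = d$analyte[1L], batch = d$batch[1L], condition = cond,
        p = p,
        flag = if (p < alpha_sig) "significant"
               else if (p < alpha_notable) "notable" else "ns",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' qPCR relative expression by the 2^-dCt method
#'
#' For each sample, `dCt = Ct_gene - mean(Ct of the reference genes)` and
#' `rel = 2^-dCt`. Relative expression is additionally normalized to the
#' mean of the untreated group per gene (FC, with `log2fc` for heatmaps)
#' when a `condition` column is present.
#'
#' @param ct Data frame with columns `gene`, `sample`, `ct` and optionally
#'   `condition`.
#' @param reference_genes Character vector of reference genes that must be
#'   present in every sample. Default `c("PPIA", "ACTB")`.
#' @param ref Untreated condition label. Default `"UT"`.
#' @return Data frame of the non-reference rows with `dct`, `rel`, and —
#'   when conditions are known — `fc` and `log2fc` vs the untreated mean.
#' @export
ddct <- function(ct, reference_genes = c("PPIA", "ACTB"), ref = "UT") {
  need <- c("gene", "sample", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct))) stop("non-finite Ct values")
  ref_ct <- numeric(0L)
  for (s in unique(ct$sample)) {
    rows <- ct$gene[ct$sample == s]
    absent <- setdiff(reference_genes, rows)
    if (length(absent)) {
      stop("sample '", s, "' lacks reference gene(s): ",
           paste(absent, collapse = ", "))
    }
    ref_ct[s] <- mean(ct$ct[ct$sample == s & ct$gene %in% reference_genes])
  }
  out <- ct[!ct$gene %in% reference_genes, , drop = FALSE]
  out$dct <- out$ct - ref_ct[out$sample]
  out$rel <- 2^(-out$dct)
  if ("condition" %in% names(out)) {
    out$fc <- NA_real_
    for (g in unique(out$gene)) {
      idx <- out$gene == g
      ut <- out$rel[idx & out$condition == ref]
      if (length(ut) == 0L) stop("gene '", g, "' has no '", ref, "' samples")
      out$fc[idx] <- out$rel[idx] / mean(ut)
    }
    out$log2fc <- log2(out$fc)
  }
  rownames(out) <- NULL
  out
}
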