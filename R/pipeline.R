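#' @title End-to-end differential secretion analysis
#' @name pipeline
#' @description
#' [secretome_da()] runs the full cascade — QC-flag removal, sample
#' exclusions, per-batch log2 transform and replicate-presence filter, batch
#' merge, restriction to secreted proteins, median centering, down-shifted
#' imputation, Welch/BH testing and hit calling, and hierarchical clustering
#' — and returns a single classed fit object.
NULL

#' Fit a differential-secretion analysis
#'
#' @param protein_groups One of: a `protein_table`, a proteinGroups-dialect
#'   data frame, a single file path, or a character vector of per-batch file
#'   paths named by batch.
#' @param design Design data frame or TSV path (columns `sample_id`,
#'   `batch`, `condition`, `donor`, `replicate`).
#' @param gocc Optional protein -> GOCC terms annotation (named list, long
#'   data frame with `protein_id`/`term`, or TSV path). When given it takes
#'   precedence over a `GOCC names` column in the protein table; proteins
#'   absent from it fall back to the table's own annotation.
#' @param exclusions Optional data frame of (donor, condition\[, batch\])
#'   pairs dropped before any filtering.
#' @param tau Replicate-presence fraction. Default 0.5.
#' @param secreted_terms GOCC terms defining "secreted". Default
#'   [gocc_secreted_terms()].
#' @param impute_params An [imputation_params()]; its seed is overridden by
#'   `seed` when that is given.
#' @param ref Untreated condition label. Default `"UT"`.
#' @param fdr_cut,lfc_cut Hit thresholds (q strictly below `fdr_cut`,
#'   |log2FC| at least `lfc_cut`). Defaults 0.1 and 1.
#' @param family FDR family scope, see [test_contrasts()].
#' @param cluster Run row/column clustering of the imputed matrix? Default
#'   `TRUE`.
#' @param metric,linkage Clustering options, see [hier_cluster()].
#' @param seed Seed driving the imputation draws. Default 1.
#' @return Object of class `secretome_da` with components `design`,
#'   `filter_report`, `matrices` (list: `filtered`, `centered`, `imputed`),
#'   `results` (full contrast table), `overlap`, `audit`, `cluster`, and
#'   `params`.
#' @seealso [summary.secretome_da()], [coef.secretome_da()],
#'   [plot.secretome_da()], [hit_table()]
#' @export
secretome_da <- function(protein_groups, design, gocc = NULL,
                         exclusions = NULL, tau = 0.5,
                         secreted_terms = gocc_secreted_terms(),
                         impute_params = imputation_params(),
                         ref = "UT", fdr_cut = 0.1, lfc_cut = 1.0,
                         family = c("per_treatment", "per_batch"),
                         cluster = TRUE, metric = "euclidean",
                         linkage = "average", seed = 1L) {
  family <- match.arg(family)
  if (is.character(design) && length(design) == 1L) design <- read_design(design)
  design <- apply_exclusions(as_design(design), exclusions)
  if (is.character(gocc) && length(gocc) == 1L) gocc <- read_gocc(gocc)
  if (is.data.frame(gocc)) gocc <- split(gocc$term, gocc$protein_id)
  if (!is.null(seed)) impute_params$seed <- as.integer(seed)

  batches <- unique(design$batch)

  # one table per batch, or a single table for all
  tables <- list()
  if (is.character(protein_groups)) {
    if (length(protein_groups) == 1L) {
      tables[["all"]] <- read_protein_groups(protein_groups, design)
    } else {
      if (is.null(names(protein_groups)) ||
          !all(batches %in% names(protein_groups))) {
        stop("multiple proteinGroups paths must be named by batch")
      }
      for (b in batches) {
        tables[[b]] <- read_protein_groups(
          protein_groups[[b]], design[design$batch == b, , drop = FALSE])
      }
    }
  } else {
    tables[["all"]] <- as_protein_table(protein_groups, design)
  }

  # per-batch: QC flags -> log2 -> presence filter
  per_batch <- list(); reports <- list(); annot <- list(); genes <- character(0L)
  for (b in batches) {
    pt <- if ("all" %in% names(tables)) tables[["all"]] else tables[[b]]
    qc <- apply_qc_filters(pt)
    db <- design[design$batch == b, , drop = FALSE]
    m <- log2_matrix(qc$table, db)
    mf <- presence_filter(m, db, tau = tau)
    per_batch[[b]] <- mf
    reports[[b]] <- list(qc = qc$report, after_qc = nrow(m),
                         after_presence = nrow(mf))
    if (!is.null(qc$table$gocc)) {
      new <- qc$table$gocc[setdiff(names(qc$table$gocc), names(annot))]
      annot <- c(annot, new)
    }
    g <- qc$table$meta$gene_names
    names(g) <- qc$table$meta$protein_id
    genes <- c(genes, g[setdiff(names(g), names(genes))])
  }
  if (!is.null(gocc)) {
    annot[names(gocc)] <- gocc
  }

  merged <- Reduce(merge_batches, per_batch)
  sec <- restrict_secreted(merged, annot, terms = secreted_terms)
  batch_proteins <- lapply(per_batch, function(m)
    intersect(rownames(m), rownames(sec)))

  freport <- do.call(rbind, lapply(batches, function(b) {
    r <- reports[[b]]
    filter_report(r$qc, r$after_qc, r$after_presence,
                  length(batch_proteins[[b]]), b)
  }))

  centered <- median_center(sec)
  imp <- impute_missing(centered, design, impute_params)
  m_imp <- imp$matrix
  attr(m_imp, "batch_proteins") <- batch_proteins

  results <- test_contrasts(m_imp, design, ref = ref, family = family,
                            fdr_cut = fdr_cut, lfc_cut = lfc_cut,
                            genes = genes)
  cl <- if (cluster && nrow(m_imp) >= 2L) {
    cluster_matrix(m_imp, metric = metric, linkage = linkage)
  }

  structure(list(
    design = design, filter_report = freport,
    matrices = list(filtered = sec, centered = centered, imputed = m_imp),
    results = results, overlap = overlap_summary(results),
    audit = imp$audit, cluster = cl,
    params = list(tau = tau, secreted_terms = secreted_terms,
                  impute = impute_params, ref = ref, fdr_cut = fdr_cut,
                  lfc_cut = lfc_cut, family = family, metric = metric,
                  linkage = linkage, seed = impute_params$seed),
    call = match.call()), class = "secretome_da")
}

#' Hits of a fitted differential-secretion analysis
#'
#' @param fit A `secretome_da` object.
#' @return The rows of the result table called as hits.
#' @export
hit_table <- function(fit) {
  stopifnot(inherits(fit, "secretome_da"))
  fit$results[fit$results$hit, , drop = FALSE]
}

#' @export
print.secretome_da <- function(x, ...) {
  cat("Differential secretion analysis\n")
  cat("  proteins analyzed:", nrow(x$matrices$imputed),
      "| samples:", ncol(x$matrices$imputed), "\n")
  cat("  contrasts:", length(unique(paste(x$results$batch, x$results$contrast))),
      "| hits (q <", x$params$fdr_cut, ", |log2FC| >=", x$params$lfc_cut, "):",
      sum(x$results$hit), "\n")
  invisible(x)
}

#' Summarize a fitted differential-secretion analysis
#'
#' @param object A `secretome_da` object.
#' @param ... Unused.
#' @return List of class `summary.secretome_da`: the filter report, per-
#'   (batch, contrast) hit counts, retained protein counts per batch, and
#'   the cross-batch hit overlap.
#' @export
summary.secretome_da <- function(object, ...) {
  hits <- object$results[object$results$hit, , drop = FALSE]
  tab <- as.data.frame(table(batch = object$results$batch,
                             contrast = object$results$contrast),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n_tested"
  htab <- as.data.frame(table(batch = hits$batch, contrast = hits$contrast),
                        stringsAsFactors = FALSE)
  tab$n_hits <- 0L
  idx <- match(paste(tab$batch, tab$contrast),
               paste(htab$batch, htab$contrast))
  tab$n_hits[!is.na(idx)] <- htab$Freq[idx[!is.na(idx)]]
  tab <- tab[tab$n_tested > 0L, , drop = FALSE]
  structure(list(filter_report = object$filter_report, contrasts = tab,
                 overlap = object$overlap$overlap,
                 params = object$params), class = "summary.secretome_da")
}

#' @export
print.summary.secretome_da <- function(x, ...) {
  cat("Filter report (rows per batch):\n")
  print(x$filter_report, row.names = FALSE)
  cat("\nContrasts:\n")
  print(x$contrasts, row.names = FALSE)
  cat("\nCross-batch hit overlap:\n")
  print(x$overlap, row.names = FALSE)
  invisible(x)
}

#' Log2 fold-change matrix of a fit
#'
#' @param object A `secretome_da` object.
#' @param ... Unused.
#' @return Numeric matrix proteins x (batch:contrast) of log2 fold changes
#'   (`NA` where a protein was not tested in a batch).
#' @export
coef.secretome_da <- function(object, ...) {
  r <- object$results
  cols <- unique(paste(r$batch, r$contrast, sep = ":"))
  prots <- unique(r$protein_id)
  out <- matrix(NA_real_, length(prots), length(cols),
                dimnames = list(prots, cols))
  out[cbind(match(r$protein_id, prots),
            match(paste(r$batch, r$contrast, sep = ":"), cols))] <- r$log2fc
  out
}

#' Heatmap views of a fit
#'
#' `what = "heatmap"` draws the clustered, row-z-scored intensity matrix
#' with the column dendrogram; `what = "hits"` draws the log2FC matrix of
#' hit proteins across contrasts.
#'
#' @param x A `secretome_da` object.
#' @param what `"heatmap"` or `"hits"`.
#' @param ... Passed to the underlying plotting routine.
#' @export
plot.secretome_da <- function(x, what = c("heatmap", "hits"), ...) {
  what <- match.arg(what)
  if (what == "heatmap") {
    if (is.null(x$cluster)) stop("fit was run with cluster = FALSE")
    stats::heatmap(x$cluster$zscored,
                   Rowv = stats::as.dendrogram(x$cluster$row_linkage$hclust),
                   Colv = stats::as.dendrogram(x$cluster$col_linkage$hclust),
                   scale = "none", labRow = NA, ...)
  } else {
    lfc <- coef(x)
    lfc <- lfc[rownames(lfc) %in% hit_table(x)$protein_id, , drop = FALSE]
    if (nrow(lfc) == 0L) stop("no hits to plot")
    lim <- max(abs(lfc), na.rm = TRUE)
    graphics::image(seq_len(ncol(lfc)), seq_len(nrow(lfc)), t(lfc),
                    zlim = c(-lim, lim), axes = FALSE,
                    xlab = "", ylab = "",
                    col = grDevices::hcl.colors(51, "Blue-Red 2"), ...)
    graphics::axis(1, seq_len(ncol(lfc)), colnames(lfc), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(nrow(lfc)), rownames(lfc), las = 2, cex.axis = 0.6)
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' A validated bundle of every pipeline setting, serializable to YAML. The
#' defaults reproduce the analysis' stated settings: 50% presence, the six
#' secreted GOCC terms, imputation shifts 0.5/1.8 SD with width 0.3 SD,
#' FDR < 0.1 and |log2FC| >= 1.
#'
#' @param proteingroups Path(s) to proteinGroups file(s) (optionally named
#'   by batch).
#' @param design,gocc Paths to the design and GOCC tables.
#' @param output_dir Optional output directory for [run_pipeline()].
#' @param tau,secreted_terms,ref,fdr_cut,lfc_cut,family,metric,linkage,seed
#'   As in [secretome_da()].
#' @param imputation Named list of [imputation_params()] arguments.
#' @return Object of class `secretome_config`.
#' @export
pipeline_config <- function(proteingroups = NULL, design = NULL, gocc = NULL,
                            output_dir = NULL, tau = 0.5,
                            secreted_terms = gocc_secreted_terms(),
                            imputation = list(), ref = "UT",
                            fdr_cut = 0.1, lfc_cut = 1.0,
                            family = "per_treatment",
                            metric = "euclidean", linkage = "average",
                            seed = 1L) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    stop("config error: tau must lie in (0, 1]")
  }
  if (!is.numeric(fdr_cut) || fdr_cut <= 0 || fdr_cut > 1) {
    stop("config error: fdr_cut must lie in (0, 1]")
  }
  if (!is.numeric(lfc_cut) || lfc_cut < 0) {
    stop("config error: lfc_cut must be non-negative")
  }
  if (!family %in% c("per_treatment", "per_batch")) {
    stop("config error: unknown family '", family, "'")
  }
  ip <- do.call(imputation_params, imputation)  # validates shift/width/cut
  structure(list(proteingroups = proteingroups, design = design, gocc = gocc,
                 output_dir = output_dir, tau = tau,
                 secreted_terms = secreted_terms,
                 imputation = imputation, ref = ref, fdr_cut = fdr_cut,
                 lfc_cut = lfc_cut, family = family, metric = metric,
                 linkage = linkage, seed = as.integer(seed)),
            class = "secretome_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_config`, a validated `secretome_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `secretome_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "secretome_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the pipeline from a configuration
#'
#' @param config A `secretome_config` (or path to its YAML).
#' @param save_intermediate Also dump the filtered/centered matrices and the
#'   imputation audit to `output_dir`. Default `FALSE`.
#' @return The `secretome_da` fit, invisibly if outputs are written.
#' @export
run_pipeline <- function(config, save_intermediate = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "secretome_config"))
  fit <- secretome_da(
    config$proteingroups, config$design, gocc = config$gocc,
    tau = config$tau, secreted_terms = config$secreted_terms,
    impute_params = do.call(imputation_params, config$imputation),
    ref = config$ref, fdr_cut = config$fdr_cut, lfc_cut = config$lfc_cut,
    family = config$family, metric = config$metric, linkage = config$linkage,
    seed = config$seed)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(fit$results, file.path(config$output_dir, "results.tsv"))
    utils::write.table(fit$filter_report,
                       file.path(config$output_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (save_intermediate) {
      write_matrix(fit$matrices$centered,
                   file.path(config$output_dir, "centered.tsv"))
      write_matrix(fit$matrices$imputed,
                   file.path(config$output_dir, "imputed.tsv"))
      utils::write.table(fit$audit,
                         file.path(config$output_dir, "imputation_audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(fit))
  }
  fit
}
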