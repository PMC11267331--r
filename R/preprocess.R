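#' @title Filter cascade and normalization
#' @name preprocess
#' @description
#' The preprocessing order is: QC-flag removal, per-batch log2 transform and
#' replicate-presence filter, merge of the batches, restriction to secreted
#' proteins, median centering. Sample exclusions are applied to the design
#' before any of this, so excluded samples never enter a presence fraction.
NULL

#' The default GOCC terms defining a secreted protein
#'
#' Six Gene Ontology Cellular Component terms covering secretory granules and
#' the extracellular compartment; proteins annotated with at least one of
#' them are treated as secreted.
#'
#' @return Character vector of six GOCC term strings.
#' @export
gocc_secreted_terms <- function() {
  c("secretory granule",
    "secretory granule lumen",
    "secretory granule membrane",
    "extracellular vesicle",
    "extracellular space",
    "extracellular exosome")
}

#' Remove contaminant, decoy and site-only protein groups
#'
#' Drops rows flagged as potential contaminants, reverse-database decoys, or
#' identified only by modification sites. A multiply-flagged row is counted
#' once, with priority contaminant > reverse > site-only.
#'
#' @param pt A `protein_table`.
#' @return List with the filtered `table` and a `report` (named integer
#'   vector: `input`, `contaminant`, `reverse`, `site_only`, `retained`).
#' @export
apply_qc_filters <- function(pt) {
  stopifnot(inherits(pt, "protein_table"))
  m <- pt$meta
  cls <- ifelse(m$flag_contaminant, "contaminant",
         ifelse(m$flag_reverse, "reverse",
         ifelse(m$flag_site_only, "site_only", "clean")))
  keep <- cls == "clean"
  out <- pt
  out$meta <- m[keep, , drop = FALSE]
  out$intensities <- pt$intensities[keep, , drop = FALSE]
  if (!is.null(pt$gocc)) out$gocc <- pt$gocc[keep]
  report <- c(input = nrow(m),
              contaminant = sum(cls == "contaminant"),
              reverse = sum(cls == "reverse"),
              site_only = sum(cls == "site_only"),
              retained = sum(keep))
  list(table = out, report = report)
}

#' Log2-transform a protein table's intensities
#'
#' @param pt A `protein_table` (raw LFQ intensities, `NA` = missing).
#' @param design Optional design; columns are subset and ordered to its
#'   `sample_id`s.
#' @return Numeric matrix of log2 intensities with stage tag `"raw_log2"`.
#' @export
log2_matrix <- function(pt, design = NULL) {
  stopifnot(inherits(pt, "protein_table"))
  m <- pt$intensities
  if (!is.null(design)) {
    design <- as_design(design)
    absent <- setdiff(design$sample_id, colnames(m))
    if (length(absent) > 0L) {
      stop("design sample(s) absent from protein table: ",
           paste(absent, collapse = ", "))
    }
    m <- m[, design$sample_id, drop = FALSE]
  }
  m <- log2(m)
  matrix_stage(m) <- "raw_log2"
  m
}

#' Replicate-presence filter
#'
#' A protein is retained if, in at least one condition group, it was measured
#' in at least `tau` of that group's replicates (default 50%, compared with
#' `>=` so 2 of 4 passes). Groups are the (batch, condition) combinations of
#' the supplied design, evaluated after exclusions.
#'
#' @param m Log-intensity matrix (`NA` = missing).
#' @param design Design covering the matrix columns.
#' @param tau Presence fraction in (0, 1]; default 0.5.
#' @return The matrix restricted to retained proteins, stage `"filtered"`.
#' @export
presence_filter <- function(m, design, tau = 0.5) {
  design <- as_design(design)
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau <= 1)
  design <- design[design$sample_id %in% colnames(m), , drop = FALSE]
  grp <- interaction(design$batch, design$condition, drop = TRUE)
  if (any(tabulate(grp) == 0L)) stop("empty condition group")
  keep <- rep(FALSE, nrow(m))
  for (g in levels(grp)) {
    cols <- design$sample_id[grp == g]
    if (length(cols) == 0L) stop("empty condition group: ", g)
    frac <- rowSums(!is.na(m[, cols, drop = FALSE])) / length(cols)
    keep <- keep | (frac >= tau)
  }
  out <- m[keep, , drop = FALSE]
  matrix_stage(out) <- "filtered"
  out
}

.norm_term <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Restrict a matrix to secreted proteins
#'
#' Keeps proteins whose GOCC annotation intersects the given term list.
#' Terms are matched case-insensitively after whitespace normalization;
#' proteins without any annotation are removed.
#'
#' @param m Log-intensity matrix with protein ids as row names.
#' @param annot Named list protein_id -> character vector of GOCC terms
#'   (e.g. from [read_gocc()] or a `protein_table`'s `gocc` component).
#' @param terms Character vector of qualifying terms; default
#'   [gocc_secreted_terms()].
#' @return The matrix restricted to secreted proteins.
#' @export
restrict_secreted <- function(m, annot, terms = gocc_secreted_terms()) {
  stopifnot(length(terms) > 0L)
  want <- .norm_term(terms)
  keep <- vapply(rownames(m), function(pid) {
    a <- annot[[pid]]
    !is.null(a) && length(a) > 0L && any(.norm_term(a) %in% want)
  }, logical(1L))
  out <- m[keep, , drop = FALSE]
  matrix_stage(out) <- matrix_stage(m)
  out
}

#' Merge two per-batch matrices
#'
#' Union of proteins and union of samples; cells for a protein absent from a
#' batch are missing.
#'
#' @param first,term Log-intensity matrices with disjoint sample columns.
#' @return Merged matrix.
#' @export
merge_batches <- function(first, term) {
  if (is.null(term) || ncol(term) == 0L) return(first)
  if (is.null(first) || ncol(first) == 0L) return(term)
  if (length(intersect(colnames(first), colnames(term))) > 0L) {
    stop("batches share sample columns")
  }
  prot <- union(rownames(first), rownames(term))
  out <- matrix(NA_real_, nrow = length(prot),
                ncol = ncol(first) + ncol(term),
                dimnames = list(prot, c(colnames(first), colnames(term))))
  out[rownames(first), colnames(first)] <- first
  out[rownames(term), colnames(term)] <- term
  matrix_stage(out) <- "filtered"
  out
}

#' Median-center each sample column
#'
#' Subtracts from each sample column the median of its observed values,
#' removing unwanted global variation and discrete batch offsets. Missing
#' cells are untouched. Idempotent.
#'
#' @param m Log-intensity matrix.
#' @return Centered matrix, stage `"centered"`.
#' @export
median_center <- function(m) {
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0L)) {
    stop("sample(s) with no observed values: ",
         paste(colnames(m)[n_obs == 0L], collapse = ", "))
  }
  med <- apply(m, 2L, stats::median, na.rm = TRUE)
  out <- sweep(m, 2L, med, "-")
  matrix_stage(out) <- "centered"
  out
}

#' Build the per-batch filter report
#'
#' Accounts for every input row of each batch:
#' `input = contaminant + reverse + site_only + presence + non_secreted +
#' retained`.
#'
#' @param qc_report Named vector from [apply_qc_filters()].
#' @param n_after_qc Rows entering the presence filter (per batch).
#' @param n_after_presence Rows surviving the presence filter (per batch).
#' @param n_retained Rows surviving the secreted restriction (per batch).
#' @param batch Batch labels (one per element of the per-batch vectors).
#' @return Data frame, one row per batch, with the per-stage removal counts.
#' @export
filter_report <- function(qc_report, n_after_qc, n_after_presence,
                          n_retained, batch) {
  data.frame(
    batch = batch,
    input = unname(qc_report["input"]),
    contaminant = unname(qc_report["contaminant"]),
    reverse = unname(qc_report["reverse"]),
    site_only = unname(qc_report["site_only"]),
    presence = n_after_qc - n_after_presence,
    non_secreted = n_after_presence - n_retained,
    retained = n_retained,
    stringsAsFactors = FALSE
  )
}
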