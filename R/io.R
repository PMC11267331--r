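#' @title Readers and writers for the pipeline's external tables
#' @name io
#' @description
#' All external tables are UTF-8, tab-separated text with a header row, the
#' dialect written by MaxQuant for `proteinGroups.txt` and plain long-format
#' TSV for the study design, GOCC annotation, result and matrix dumps.
NULL

.flag_cols <- c(
  flag_reverse      = "Reverse",
  flag_contaminant  = "Potential contaminant",
  flag_site_only    = "Only identified by site"
)

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated `proteinGroups.txt` file into a `protein_table`.
#' Per-sample quantifications are taken from the `"LFQ intensity <sample>"`
#' columns named by the study design; an LFQ value of 0 (MaxQuant's
#' non-detection code) or an empty/NA cell is recorded as missing. Flag
#' columns (`Reverse`, `Potential contaminant`, `Only identified by site`)
#' are true for the literal `"+"` only. If a semicolon-separated
#' `"GOCC names"` column is present it is parsed into per-protein term sets.
#'
#' @param path Path to a tab-separated proteinGroups file.
#' @param design Study design data frame as returned by [read_design()];
#'   only its `sample_id` column is consulted here.
#' @return An object of class `protein_table`: a list with components
#'   `meta` (data frame: `protein_ids`, `protein_id` — the leading,
#'   representative accession —, `gene_names`, and the three logical flag
#'   columns), `intensities` (numeric matrix, proteins x design samples, `NA`
#'   encodes missing), and `gocc` (named list of character vectors, possibly
#'   empty).
#' @export
read_protein_groups <- function(path, design) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"Protein IDs" %in% names(raw)) {
    stop("proteinGroups file '", path, "' lacks the required 'Protein IDs' column")
  }
  as_protein_table(raw, design)
}

#' Coerce an in-memory proteinGroups-dialect data frame to a protein_table
#'
#' @param raw Data frame in the proteinGroups dialect (see
#'   [read_protein_groups()]); numeric LFQ columns are accepted.
#' @param design Study design data frame.
#' @return A `protein_table`.
#' @export
as_protein_table <- function(raw, design) {
  if (inherits(raw, "protein_table")) return(raw)
  design <- as_design(design)
  if (!"Protein IDs" %in% names(raw)) {
    stop("protein table lacks the required 'Protein IDs' column")
  }
  lfq_all <- grep("^LFQ intensity ", names(raw), value = TRUE)
  wanted <- paste("LFQ intensity", design$sample_id)
  absent <- setdiff(wanted, names(raw))
  if (length(absent) > 0L) {
    stop("design sample(s) without an LFQ intensity column: ",
         paste(sub("^LFQ intensity ", "", absent), collapse = ", "))
  }
  extra <- setdiff(lfq_all, wanted)
  if (length(extra) > 0L) {
    warning("ignoring ", length(extra), " LFQ column(s) not in the design: ",
            paste(sub("^LFQ intensity ", "", extra), collapse = ", "))
  }

  intens <- vapply(wanted, function(cn) {
    x <- suppressWarnings(as.numeric(raw[[cn]]))
    x[!is.na(x) & x < 0] <- NA_real_
    x[!is.na(x) & x == 0] <- NA_real_
    x
  }, numeric(nrow(raw)))
  intens <- matrix(intens, nrow = nrow(raw),
                   dimnames = list(NULL, design$sample_id))

  meta <- data.frame(
    protein_ids = raw[["Protein IDs"]],
    protein_id  = vapply(strsplit(raw[["Protein IDs"]], ";", fixed = TRUE),
                         `[`, character(1L), 1L),
    gene_names  = if ("Gene names" %in% names(raw)) raw[["Gene names"]] else NA_character_,
    stringsAsFactors = FALSE
  )
  for (f in names(.flag_cols)) {
    col <- .flag_cols[[f]]
    meta[[f]] <- if (col %in% names(raw)) raw[[col]] == "+" else rep(FALSE, nrow(raw))
  }
  rownames(intens) <- meta$protein_id

  gocc <- NULL
  if ("GOCC names" %in% names(raw)) {
    gocc <- lapply(strsplit(raw[["GOCC names"]], ";", fixed = TRUE),
                   function(x) trimws(x[nzchar(trimws(x))]))
    names(gocc) <- meta$protein_id
  }

  structure(list(meta = meta, intensities = intens, gocc = gocc),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat("protein_table:", nrow(x$meta), "protein groups,",
      ncol(x$intensities), "samples\n")
  cat("  flagged: contaminant", sum(x$meta$flag_contaminant),
      "| reverse", sum(x$meta$flag_reverse),
      "| site-only", sum(x$meta$flag_site_only), "\n")
  cat("  missing cells:", sum(is.na(x$intensities)), "/",
      length(x$intensities), "\n")
  invisible(x)
}

#' Read a study design table
#'
#' The design maps each sample to its batch (e.g. first_trimester / term),
#' treatment condition (untreated `UT` or a treatment label), donor and
#' replicate index.
#'
#' @param path Tab-separated file with columns `sample_id`, `batch`,
#'   `condition`, `donor`, `replicate`.
#' @return Data frame with those columns, `sample_id` guaranteed unique.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character")
  as_design(d)
}

as_design <- function(d) {
  need <- c("sample_id", "batch", "condition", "donor", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("design lacks required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  }
  d[need]
}

#' Drop excluded samples from a design
#'
#' Exclusions are (donor, condition) pairs — optionally restricted to one
#' batch — removed before any filtering, so that excluded samples (such as
#' untreated samples with >95% unmeasured entries) never influence presence
#' fractions, centering or tests.
#'
#' @param design Design data frame.
#' @param exclusions `NULL`, or a data frame with columns `donor` and
#'   `condition` (and optionally `batch`).
#' @return The design with matching samples removed.
#' @export
apply_exclusions <- function(design, exclusions) {
  design <- as_design(design)
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(design)
  if (!all(c("donor", "condition") %in% names(exclusions))) {
    stop("exclusions need 'donor' and 'condition' columns")
  }
  drop <- rep(FALSE, nrow(design))
  for (i in seq_len(nrow(exclusions))) {
    hit <- design$donor == exclusions$donor[i] &
      design$condition == exclusions$condition[i]
    if ("batch" %in% names(exclusions) && !is.na(exclusions$batch[i])) {
      hit <- hit & design$batch == exclusions$batch[i]
    }
    drop <- drop | hit
  }
  design[!drop, , drop = FALSE]
}

#' Read a protein-to-GOCC annotation table
#'
#' @param path Tab-separated long-format file with columns `protein_id` and
#'   `term` (one row per protein/term pair).
#' @return Named list mapping protein id to a character vector of GOCC terms.
#' @export
read_gocc <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("protein_id", "term") %in% names(d))) {
    stop("GOCC table needs 'protein_id' and 'term' columns")
  }
  split(d$term, factor(d$protein_id, levels = unique(d$protein_id)))
}

#' Write / read a differential-secretion result table
#'
#' One row per (protein, batch, contrast) with columns `protein_id`, `gene`,
#' `log2fc`, `t_stat`, `df`, `p`, `q`, `hit`.
#'
#' @param results Result data frame from [test_contrasts()] / [call_hits()].
#' @param path Output path (TSV).
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if ("hit" %in% names(d)) d$hit <- as.logical(d$hit)
  d
}

#' Write / read a log-intensity matrix
#'
#' Matrices are written as TSV with a `protein_id` first column; missing
#' cells are written as `NA`. The stage tag (`raw_log2`, `filtered`,
#' `centered`, `imputed`) survives the round trip via a `# stage:` comment
#' line.
#'
#' @param m Numeric matrix (proteins x samples, `NA` = missing).
#' @param path Output path (TSV).
#' @export
write_matrix <- function(m, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# stage: ", matrix_stage(m)), con)
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- if (startsWith(first, "# stage: ")) sub("^# stage: ", "", first) else "raw_log2"
  d <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[-1L])
  rownames(m) <- d$protein_id
  storage.mode(m) <- "double"
  matrix_stage(m) <- stage
  m
}

#' Stage tag of a log-intensity matrix
#'
#' @param m Matrix.
#' @return One of `"raw_log2"`, `"filtered"`, `"centered"`, `"imputed"`.
#' @export
matrix_stage <- function(m) {
  s <- attr(m, "stage")
  if (is.null(s)) "raw_log2" else s
}

#' @rdname matrix_stage
#' @param value New stage tag.
#' @export
`matrix_stage<-` <- function(m, value) {
  stopifnot(value %in% c("raw_log2", "filtered", "centered", "imputed"))
  attr(m, "stage") <- value
  m
}
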