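#' @title Synthetic LFQ secretome data with planted ground truth
#' @name synthetic_data
#' @description
#' Emulates the statistical structure of a two-batch placental-explant LFQ
#' secretome study: lognormal log2 intensities, a discrete batch offset,
#' sparse planted treatment effects, intensity-dependent (left-censoring)
#' missingness, decoy and contaminant rows, a fraction of non-secreted
#' proteins, and optional degenerate samples with forced >95% missingness.
#' The generator writes the same MaxQuant-dialect tables the pipeline reads,
#' so every analysis stage can be validated against known truth.
NULL

#' Simulation specification
#'
#' Defaults reproduce the study layout: 1400 proteins; a first-trimester
#' batch with untreated (UT) and three particle treatments (TiO2, SiO2, DEP)
#' at n = 4 each; a term batch with n = 5 untreated plus two degenerate
#' untreated samples (donors d14/d16, forced >95% missing and listed for
#' exclusion) and n = 4 per treatment.
#'
#' @param n_proteins Number of genuine protein groups. Default 1400.
#' @param batches Named list; each element a named integer vector of
#'   replicate counts per condition for that batch.
#' @param mu0,sd0 Mean and SD of the baseline log2 intensity. Defaults 25, 2.
#' @param sd_e Within-group replicate noise SD (log2 units). Default 0.5.
#' @param batch_offset Magnitude (log2 units) of the batch effect for every
#'   batch after the first, applied as a constant column shift (the discrete
#'   offset that median centering removes) plus a per-protein random sign
#'   times the same magnitude (the protein-specific abundance differences
#'   between gestational stages that survive centering and drive the batch
#'   separation in clustering). Default 2.
#' @param fraction_affected Fraction of proteins with a planted effect per
#'   (batch, treatment). Default 0.02.
#' @param effect_sizes Candidate true log2 fold changes. Default
#'   `c(-2, -1.5, 1.5, 2)`.
#' @param missing_mode `"mnar"` (default; left-censoring) or `"mcar"`.
#' @param miss_mid,miss_width Logistic censoring midpoint and width on the
#'   log2 scale: `P(missing | x) = plogis((miss_mid - x) / miss_width)`.
#'   Defaults 22 and 1. `miss_mid = -Inf` disables missingness.
#' @param mcar_rate Uniform missing probability when `missing_mode = "mcar"`.
#' @param frac_decoy,frac_contaminant Fractions of extra decoy (Reverse) and
#'   contaminant rows. Default 0.02 each.
#' @param frac_nonsecreted Fraction of genuine proteins annotated with
#'   non-secretory GOCC terms only. Default 0.2.
#' @param n_degenerate Number of extra untreated samples in the last batch
#'   with forced missingness; they carry donors d14, d16, ... and appear in
#'   the spec's exclusion list. Default 2.
#' @param degenerate_rate Forced per-cell missing probability for degenerate
#'   samples. Default 0.97.
#' @param ref Reference condition label. Default `"UT"`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_proteins = 1400,
                            batches = list(
                              first_trimester = c(UT = 4, TiO2 = 4, SiO2 = 4, DEP = 4),
                              term            = c(UT = 5, TiO2 = 4, SiO2 = 4, DEP = 4)),
                            mu0 = 25, sd0 = 2, sd_e = 0.5, batch_offset = 2,
                            fraction_affected = 0.02,
                            effect_sizes = c(-2, -1.5, 1.5, 2),
                            missing_mode = c("mnar", "mcar"),
                            miss_mid = 22, miss_width = 1, mcar_rate = 0.1,
                            frac_decoy = 0.02, frac_contaminant = 0.02,
                            frac_nonsecreted = 0.2,
                            n_degenerate = 2, degenerate_rate = 0.97,
                            ref = "UT", seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(n_proteins >= 1, sd0 > 0, sd_e > 0,
            fraction_affected >= 0, fraction_affected <= 1,
            miss_width > 0, degenerate_rate > 0.95, degenerate_rate <= 1)
  for (b in names(batches)) {
    if (any(batches[[b]] < 2L)) {
      stop("batch '", b, "': every condition needs at least 2 replicates")
    }
    if (!ref %in% names(batches[[b]])) {
      stop("batch '", b, "' lacks the reference condition '", ref, "'")
    }
  }
  structure(as.list(environment()), class = "simulation_spec")
}

.nonsecreted_terms <- c("nucleus", "cytoplasm", "mitochondrion")

#' Simulate an LFQ secretome study
#'
#' @param spec A [simulation_spec()].
#' @return List of class `secretome_sim` with components
#'   `protein_groups` (MaxQuant-dialect data frame: flag columns use "+",
#'   raw intensities `= 2^log2` rounded to 6 significant figures, missing
#'   cells written as 0), `design`, `gocc` (long data frame), `exclusions`
#'   (degenerate samples), and `truth` (list: `proteins` with the secreted
#'   flag, `effects` with per-(batch, treatment) true log2FC for every
#'   affected protein, `log2` the noise-free-missingness latent matrix,
#'   `cause` per-cell status in {detected, censored, forced}).
#' @export
simulate_secretome <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  pid <- sprintf("P%05d", seq_len(n))
  gene <- sprintf("GENE%04d", seq_len(n))

  secreted <- rep(TRUE, n)
  n_non <- round(spec$frac_nonsecreted * n)
  if (n_non > 0L) secreted[sample.int(n, n_non)] <- FALSE
  sec_terms <- gocc_secreted_terms()
  gocc_of <- lapply(seq_len(n), function(i) {
    if (secreted[i]) sample(sec_terms, sample(1:2, 1L)) else
      sample(.nonsecreted_terms, 1L)
  })

  # design (degenerate samples attach to the last batch's reference group)
  rows <- list(); last_batch <- names(spec$batches)[length(spec$batches)]
  for (b in names(spec$batches)) {
    for (cond in names(spec$batches[[b]])) {
      nr <- spec$batches[[b]][[cond]]
      rows[[paste(b, cond)]] <- data.frame(
        sample_id = sprintf("%s_%s_%d", b, cond, seq_len(nr)),
        batch = b, condition = cond,
        donor = sprintf("d%d", seq_len(nr)), replicate = seq_len(nr),
        stringsAsFactors = FALSE)
    }
  }
  exclusions <- NULL
  if (spec$n_degenerate > 0L) {
    nr0 <- spec$batches[[last_batch]][[spec$ref]]
    deg_donors <- sprintf("d%d", 13L + seq_len(spec$n_degenerate))
    deg <- data.frame(
      sample_id = sprintf("%s_%s_%d", last_batch, spec$ref,
                          nr0 + seq_len(spec$n_degenerate)),
      batch = last_batch, condition = spec$ref,
      donor = deg_donors, replicate = nr0 + seq_len(spec$n_degenerate),
      stringsAsFactors = FALSE)
    rows[["degenerate"]] <- deg
    exclusions <- data.frame(donor = deg_donors, condition = spec$ref,
                             batch = last_batch, stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  degenerate_ids <- if (is.null(exclusions)) character(0L) else
    design$sample_id[design$donor %in% exclusions$donor &
                     design$condition == spec$ref &
                     design$batch == last_batch]

  # planted effects on secreted proteins only (non-secreted rows are removed
  # before testing, so effects there would be unobservable by design)
  n_aff <- round(spec$fraction_affected * n)
  effects <- list()
  eff_mat <- list()  # batch:condition -> named numeric per protein
  for (b in names(spec$batches)) {
    for (cond in setdiff(names(spec$batches[[b]]), spec$ref)) {
      delta <- numeric(n)
      if (n_aff > 0L) {
        idx <- sample(which(secreted), n_aff)
        delta[idx] <- spec$effect_sizes[
          sample.int(length(spec$effect_sizes), n_aff, replace = TRUE)]
        effects[[paste(b, cond)]] <- data.frame(
          protein_id = pid[idx], batch = b, condition = cond,
          true_log2fc = delta[idx], stringsAsFactors = FALSE)
      }
      eff_mat[[paste(b, cond, sep = "\r")]] <- delta
    }
  }
  effects <- if (length(effects)) do.call(rbind, c(effects, list(make.row.names = FALSE)))
    else data.frame(protein_id = character(0L), batch = character(0L),
                    condition = character(0L), true_log2fc = numeric(0L))

  # latent log2 matrix; batch effect = constant shift + per-protein sign
  base <- stats::rnorm(n, spec$mu0, spec$sd0)
  batch_idx <- match(design$batch, names(spec$batches))
  offs <- spec$batch_offset * (batch_idx - 1L)
  batch_sign <- lapply(names(spec$batches), function(b) {
    if (match(b, names(spec$batches)) == 1L) numeric(n)
    else spec$batch_offset * sample(c(-1, 1), n, replace = TRUE)
  })
  names(batch_sign) <- names(spec$batches)
  x <- matrix(NA_real_, n, nrow(design), dimnames = list(pid, design$sample_id))
  for (j in seq_len(nrow(design))) {
    key <- paste(design$batch[j], design$condition[j], sep = "\r")
    delta <- if (design$condition[j] == spec$ref) 0 else eff_mat[[key]]
    x[, j] <- base + offs[j] + batch_sign[[design$batch[j]]] + delta +
      stats::rnorm(n, 0, spec$sd_e)
  }

  # missingness
  p_miss <- if (spec$missing_mode == "mnar") {
    stats::plogis((spec$miss_mid - x) / spec$miss_width)
  } else {
    matrix(spec$mcar_rate, n, ncol(x))
  }
  miss <- matrix(stats::runif(length(x)) < p_miss, n, ncol(x))
  cause <- matrix("detected", n, ncol(x), dimnames = dimnames(x))
  cause[miss] <- "censored"
  if (length(degenerate_ids) > 0L) {
    for (s in degenerate_ids) {
      forced <- stats::runif(n) < spec$degenerate_rate
      cause[forced & cause[, s] == "detected", s] <- "forced"
      miss[, colnames(x) == s] <- miss[, colnames(x) == s] | forced
    }
  }

  # decoy / contaminant rows (baseline-like, no planted effects)
  n_dec <- round(spec$frac_decoy * n)
  n_con <- round(spec$frac_contaminant * n)
  extra_n <- n_dec + n_con
  if (extra_n > 0L) {
    xb <- matrix(stats::rnorm(extra_n * ncol(x), spec$mu0, spec$sd0),
                 extra_n, ncol(x)) +
      matrix(offs, extra_n, ncol(x), byrow = TRUE)
    xb_miss <- stats::runif(length(xb)) <
      stats::plogis((spec$miss_mid - xb) / spec$miss_width)
    xb[xb_miss] <- NA_real_
  }

  to_raw <- function(mat, missing) {
    raw <- signif(2^mat, 6)
    raw[missing] <- 0
    raw
  }
  raw <- to_raw(x, miss)
  ids <- pid; genes <- gene
  rev_flag <- rep("", n); con_flag <- rep("", n)
  gocc_str <- vapply(gocc_of, paste, character(1L), collapse = ";")
  if (extra_n > 0L) {
    extra_ids <- c(sprintf("REV__Q%05d", seq_len(n_dec)),
                   sprintf("CON__Q%05d", seq_len(n_con)))
    ids <- c(ids, extra_ids)
    genes <- c(genes, rep("", extra_n))
    rev_flag <- c(rev_flag, rep("+", n_dec), rep("", n_con))
    con_flag <- c(con_flag, rep("", n_dec), rep("+", n_con))
    gocc_str <- c(gocc_str, rep("", extra_n))
    raw <- rbind(raw, to_raw(xb, is.na(xb)))
  }

  pg <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    "Protein IDs" = ids, "Gene names" = genes,
    "Reverse" = rev_flag, "Potential contaminant" = con_flag,
    "Only identified by site" = rep("", length(ids)),
    "GOCC names" = gocc_str)
  for (j in seq_len(ncol(raw))) {
    pg[[paste("LFQ intensity", colnames(raw)[j])]] <- raw[, j]
  }

  gocc_long <- data.frame(
    protein_id = rep(pid, lengths(gocc_of)),
    term = unlist(gocc_of), stringsAsFactors = FALSE)

  structure(list(
    protein_groups = pg, design = design, gocc = gocc_long,
    exclusions = exclusions,
    truth = list(
      proteins = data.frame(protein_id = pid, gene = gene,
                            secreted = secreted, stringsAsFactors = FALSE),
      effects = effects, log2 = x, cause = cause),
    spec = spec), class = "secretome_sim")
}

#' @export
print.secretome_sim <- function(x, ...) {
  cat("secretome_sim:", nrow(x$truth$proteins), "proteins,",
      nrow(x$design), "samples,",
      nrow(x$truth$effects), "planted effects\n")
  invisible(x)
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' Writes `proteinGroups.txt`, `design.tsv`, `gocc.tsv`,
#' `truth_effects.tsv` and (if present) `exclusions.tsv` into `dir`.
#' Identical specs (same seed) produce byte-identical files.
#'
#' @param sim A `secretome_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "secretome_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(sim$protein_groups, "proteinGroups.txt")
  w(sim$design, "design.tsv")
  w(sim$gocc, "gocc.tsv")
  w(sim$truth$effects, "truth_effects.tsv")
  if (!is.null(sim$exclusions)) w(sim$exclusions, "exclusions.tsv")
  invisible(dir)
}

#' Parameter-recovery study
#'
#' Repeatedly simulates a study, runs the full differential-secretion
#' pipeline on it, and compares the estimates and hit calls with the planted
#' truth.
#'
#' @param spec A [simulation_spec()]; its seed is replaced per replicate.
#' @param n_rep Number of simulation replicates. Default 20.
#' @param seed Base seed for the replicate seeds.
#' @param ... Further arguments passed to [secretome_da()] (e.g. `tau`,
#'   `fdr_cut`).
#' @return List of class `recovery_report`: `per_rep` data frame (one row
#'   per replicate: `bias`, `rmse` of log2FC over affected fully-observed
#'   proteins, `n_hits`, `fp`, `tp`, `fdr`, `recall`) and `summary` (means
#'   over replicates; `fdr` is pooled FP over pooled hits).
#' @export
recover_truth <- function(spec = simulation_spec(), n_rep = 20, seed = 1L, ...) {
  per <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    sp <- spec
    sp$seed <- (seed * 10007L + r) %% 2147483647L
    sim <- simulate_secretome(sp)
    # excluded degenerate samples leave known extra LFQ columns behind
    fit <- withCallingHandlers(
      secretome_da(sim$protein_groups, sim$design, gocc = NULL,
                   exclusions = sim$exclusions, cluster = FALSE,
                   seed = sp$seed, ...),
      warning = function(w) {
        if (grepl("ignoring .* LFQ column", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    res <- fit$results
    res$condition <- sub("_vs_.*$", "", res$contrast)
    key <- function(d) paste(d$protein_id, d$batch, d$condition, sep = "\r")
    truth <- sim$truth$effects
    res$true_log2fc <- truth$true_log2fc[match(key(res), key(truth))]
    res$true_log2fc[is.na(res$true_log2fc)] <- 0

    # affected proteins with every replicate of both tested groups observed
    cause_obs <- sim$truth$cause == "detected"
    fully_obs <- function(pid, b, cond) {
      cols <- fit$design$sample_id[fit$design$batch == b &
        fit$design$condition %in% c(cond, "UT")]
      all(cause_obs[pid, cols])
    }
    aff <- res[res$true_log2fc != 0, , drop = FALSE]
    if (nrow(aff) > 0L) {
      fo <- mapply(fully_obs, aff$protein_id, aff$batch, aff$condition)
      aff <- aff[fo, , drop = FALSE]
    }
    bias <- if (nrow(aff)) mean(aff$log2fc - aff$true_log2fc) else NA_real_
    rmse <- if (nrow(aff)) sqrt(mean((aff$log2fc - aff$true_log2fc)^2)) else NA_real_
    n_hits <- sum(res$hit)
    fp <- sum(res$hit & res$true_log2fc == 0)
    tp <- n_hits - fp
    n_aff_tested <- sum(res$true_log2fc != 0)
    per[[r]] <- data.frame(
      rep = r, bias = bias, rmse = rmse, n_hits = n_hits, fp = fp, tp = tp,
      fdr = if (n_hits > 0L) fp / n_hits else NA_real_,
      recall = if (n_aff_tested > 0L) tp / n_aff_tested else NA_real_,
      mean_lfc_affected = if (nrow(aff)) mean(abs(aff$log2fc)) else NA_real_)
  }
  per <- do.call(rbind, per)
  structure(list(
    per_rep = per,
    summary = list(
      bias = mean(per$bias, na.rm = TRUE),
      rmse = mean(per$rmse, na.rm = TRUE),
      fdr = if (sum(per$n_hits) > 0L) sum(per$fp) / sum(per$n_hits) else NA_real_,
      recall = mean(per$recall, na.rm = TRUE),
      n_hits = mean(per$n_hits))), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("recovery over %d replicates: bias %.4f, rmse %.3f, ",
                     "pooled FDR %.3f, recall %.3f, mean hits %.1f\n"),
              nrow(x$per_rep), s$bias, s$rmse, s$fdr, s$recall, s$n_hits))
  invisible(x)
}
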