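#' @title Condition-aware down-shifted imputation of left-censored values
#' @name imputation
#' @description
#' In label-free proteomics, missing LFQ values are predominantly
#' left-censored: low-abundance proteins fall below the detection limit.
#' Missing cells are therefore drawn from normal distributions shifted below
#' the mean of the measured values. Two shifts are distinguished per
#' (protein, condition) group: values missing in only a small fraction of a
#' condition's replicates (at least `presence_cut` measured) are treated as
#' near-threshold and drawn with a mild shift of 0.5 SD; values consistently
#' absent in a condition are drawn with a strong shift of 1.8 SD. Both
#' distributions have width 0.3 SD.
NULL

#' Imputation parameters
#'
#' @param shift_major Down-shift (in SD units) when at least `presence_cut`
#'   of a condition's replicates are measured. Default 0.5.
#' @param shift_minor Down-shift (in SD units) otherwise. Default 1.8.
#' @param width Width of the imputation distribution in SD units. Default 0.3.
#' @param presence_cut Measured fraction at or above which the major branch
#'   applies (ties go to the major branch). Default 0.5.
#' @param scope Reference scope for the mean and SD of the measured values:
#'   `"per_sample"` (default; each sample column's observed values, the usual
#'   per-column down-shift), `"per_condition"` (pooled observed values of the
#'   condition group's columns) or `"global"`.
#' @param seed Integer seed; with the same seed the imputation is
#'   reproducible and stable under row/column reordering.
#' @return An object of class `imputation_params`.
#' @export
imputation_params <- function(shift_major = 0.5, shift_minor = 1.8,
                              width = 0.3, presence_cut = 0.5,
                              scope = c("per_sample", "per_condition", "global"),
                              seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(shift_major > 0, shift_minor > 0, width > 0,
            presence_cut > 0, presence_cut <= 1)
  structure(list(shift_major = shift_major, shift_minor = shift_minor,
                 width = width, presence_cut = presence_cut,
                 scope = scope, seed = as.integer(seed)),
            class = "imputation_params")
}

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1),
# used to derive a per-cell RNG seed from (seed, protein_id, sample_id) so
# imputed values do not depend on row/column order.
.str_hash <- function(s) {
  vapply(s, function(one) {
    h <- 0
    for (c in utf8ToInt(one)) h <- (h * 31 + c) %% 2147483647
    h
  }, numeric(1L), USE.NAMES = FALSE)
}

.cell_seed <- function(seed, protein_hash, sample_hash) {
  as.integer((seed %% 2147483647 + protein_hash * 92821 + sample_hash) %% 2147483647)
}

#' Impute missing values from down-shifted normal distributions
#'
#' Every missing cell of a centered log-intensity matrix is replaced by an
#' independent draw from `Normal(mu - s * sigma, (width * sigma)^2)`, where
#' `mu` and `sigma` are the mean and SD of the observed values in the
#' reference scope and `s` is `shift_major` if at least `presence_cut` of the
#' cell's (batch, condition) group is measured, `shift_minor` otherwise.
#' Observed cells are untouched.
#'
#' @param m Log-intensity matrix with stage `"centered"`.
#' @param design Design covering the matrix columns.
#' @param params An [imputation_params()] object.
#' @return List with `matrix` (stage `"imputed"`, no missing cells) and
#'   `audit`, a data frame with one row per (protein, batch, condition)
#'   group: `branch` (`major`/`minor`/`none`), `n_imputed`, and the
#'   reference `mu`/`sigma` (averaged over the group's columns when
#'   `scope = "per_sample"`).
#' @export
impute_missing <- function(m, design, params = imputation_params()) {
  stopifnot(inherits(params, "imputation_params"))
  if (matrix_stage(m) != "centered") {
    stop("impute_missing expects a centered matrix (stage 'centered'), got '",
         matrix_stage(m), "'")
  }
  design <- as_design(design)
  design <- design[design$sample_id %in% colnames(m), , drop = FALSE]

  obs <- !is.na(m)
  grp <- interaction(design$batch, design$condition, drop = TRUE, sep = "\r")
  col_of <- match(design$sample_id, colnames(m))

  # reference mean/SD per column according to scope
  mu_col <- numeric(ncol(m)); sd_col <- numeric(ncol(m))
  if (params$scope == "per_sample") {
    for (j in seq_len(ncol(m))) {
      v <- m[obs[, j], j]
      mu_col[j] <- mean(v); sd_col[j] <- stats::sd(v)
    }
  } else if (params$scope == "per_condition") {
    for (g in levels(grp)) {
      cols <- col_of[grp == g]
      v <- m[, cols, drop = FALSE]; v <- v[!is.na(v)]
      mu_col[cols] <- mean(v); sd_col[cols] <- stats::sd(v)
    }
  } else {
    v <- m[obs]
    mu_col[] <- mean(v); sd_col[] <- stats::sd(v)
  }
  bad <- !is.finite(sd_col) | sd_col <= 0
  if (any(bad)) {
    stop("reference SD undefined or zero for sample(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  }

  ph <- .str_hash(rownames(m))
  sh <- .str_hash(colnames(m))

  out <- m
  audit <- vector("list", nlevels(grp))
  for (gi in seq_len(nlevels(grp))) {
    g <- levels(grp)[gi]
    cols <- col_of[grp == g]
    n_rep <- length(cols)
    n_meas <- rowSums(obs[, cols, drop = FALSE])
    frac <- n_meas / n_rep
    major <- frac >= params$presence_cut
    n_missing <- n_rep - n_meas
    for (i in which(n_missing > 0L)) {
      s <- if (major[i]) params$shift_major else params$shift_minor
      for (j in cols[!obs[i, cols]]) {
        set.seed(.cell_seed(params$seed, ph[i], sh[j]))
        out[i, j] <- stats::rnorm(1L, mean = mu_col[j] - s * sd_col[j],
                                  sd = params$width * sd_col[j])
      }
    }
    bc <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    audit[[gi]] <- data.frame(
      protein_id = rownames(m),
      batch = bc[1L], condition = bc[2L],
      branch = ifelse(n_missing == 0L, "none",
                      ifelse(major, "major", "minor")),
      n_imputed = n_missing,
      mu = mean(mu_col[cols]), sigma = mean(sd_col[cols]),
      stringsAsFactors = FALSE
    )
  }
  matrix_stage(out) <- "imputed"
  list(matrix = out, audit = do.call(rbind, audit))
}
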