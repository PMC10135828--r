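#' Build a cells-per-stratum design table
#'
#' Convenience constructor for the design consumed by [simulate_counts()]:
#' `n_cells` cells for each (cell type, condition), split evenly across
#' `patients_per_condition` patients.
#'
#' @param cell_types character vector; must include the sender and receiver
#'   types used downstream.
#' @param conditions subset of the condition vocabulary.
#' @param n_cells cells per (type, condition) stratum.
#' @param patients_per_condition patients per condition.
#' @return data.frame with columns cell_type, condition, patient, n_cells.
#' @export
simulation_design <- function(cell_types = c("tumor", "macrophage"),
                              conditions = CONDITIONS, n_cells = 300,
                              patients_per_condition = 3) {
  check_conditions(conditions)
  rows <- expand.grid(cell_type = cell_types, condition = conditions,
                      patient_idx = seq_len(patients_per_condition),
                      stringsAsFactors = FALSE)
  rows$patient <- sprintf("P_%s_%d", gsub("[^A-Za-z]", "", rows$condition),
                          rows$patient_idx)
  per <- rep(n_cells %/% patients_per_condition, patients_per_condition)
  per[seq_len(n_cells %% patients_per_condition)] <-
    per[seq_len(n_cells %% patients_per_condition)] + 1L
  rows$n_cells <- per[rows$patient_idx]
  rows$patient_idx <- NULL
  rows
}

#' Simulate multi-condition single-cell counts with planted cascades
#'
#' Counts are drawn from a negative binomial distribution,
#' `NB(mean = mu, size = dispersion)`, the standard overdispersed noise
#' model for scRNA-seq UMI data.  All genes start at `baseline_mean`
#' (scaled by a lognormal per-cell depth factor).  For every planted
#' cascade active in condition `c`, the ligand mean is multiplied by
#' `2^effect_log2fc` in sender-type cells of `c`, and the receptor, TF and
#' target means are multiplied by the same factor in receiver-type cells of
#' `c` — the coordinated sender-signal / receiver-response pattern the
#' consensus network is designed to detect.  A labeled set of `MT-`
#' prefixed mitochondrial genes and a pool of background genes are added so
#' that the default QC filter is exercisable and passes the bulk of cells.
#'
#' @param prior a [prior_network()]; its genes become matrix rows.
#' @param truth a [generate_truth()] object (may be empty).
#' @param design data.frame as from [simulation_design()].
#' @param baseline_mean NB mean for unperturbed gene/cell entries.
#' @param dispersion NB size parameter (variance = mu + mu^2/dispersion).
#' @param n_background_genes extra unperturbed genes (row names `BG*`).
#' @param n_mito_genes mitochondrial genes (row names `MT-*`), with means
#'   set so the expected mitochondrial fraction is ~5%.
#' @param sender_type,receiver_type cell types carrying ligand and
#'   downstream elevation respectively.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return list with elements `counts` (sparse dgCMatrix, genes x cells)
#'   and `cells` (data.frame: cell_id, cell_type, condition, patient,
#'   n_umi, n_genes, pct_mito).
#' @export
simulate_counts <- function(prior, truth, design, baseline_mean = 1,
                            dispersion = 2, n_background_genes = 500,
                            n_mito_genes = 10, sender_type = "tumor",
                            receiver_type = "macrophage", seed = 1L) {
  stopifnot(inherits(prior, "PriorNetwork"), inherits(truth, "PlantedTruth"),
            is.data.frame(design),
            all(c("cell_type", "condition", "patient", "n_cells") %in%
                names(design)))
  check_conditions(design$condition)
  for (cond in unique(design$condition)) {
    tys <- design$cell_type[design$condition == cond]
    if (!(sender_type %in% tys) || !(receiver_type %in% tys)) {
      stop("design must include sender type '", sender_type,
           "' and receiver type '", receiver_type, "' in condition ", cond,
           call. = FALSE)
    }
  }

  genes <- c(prior$nodes$gene,
             if (n_background_genes > 0) sprintf("BG%d", seq_len(n_background_genes)),
             if (n_mito_genes > 0) sprintf("MT-%d", seq_len(n_mito_genes)))
  is_mt <- startsWith(genes, "MT-")
  n_gene <- length(genes)

  cells <- design[rep(seq_len(nrow(design)), design$n_cells),
                  c("cell_type", "condition", "patient")]
  rownames(cells) <- NULL
  cells$cell_id <- sprintf("%s.%s.c%04d", cells$patient, cells$cell_type,
                           stats::ave(seq_len(nrow(cells)),
                                      paste(cells$patient, cells$cell_type),
                                      FUN = seq_along))
  n_cell <- nrow(cells)

  # baseline means; MT genes tuned so expected pct_mito ~ 5%
  mu_gene <- rep(baseline_mean, n_gene)
  if (any(is_mt)) {
    mt_total <- 0.05 / 0.95 * sum(mu_gene[!is_mt])
    mu_gene[is_mt] <- mt_total / sum(is_mt)
  }

  with_seed(seed, {
    mu <- matrix(mu_gene, n_gene, n_cell)
    fac <- 2^truth$effect_log2fc
    for (i in seq_along(truth$cascades)) {
      cs <- truth$cascades[[i]]
      for (cond in truth$active_conditions[[i]]) {
        snd <- cells$cell_type == sender_type & cells$condition == cond
        rcv <- cells$cell_type == receiver_type & cells$condition == cond
        gi <- match(cs$ligand, genes)
        mu[gi, snd] <- mu[gi, snd] * fac
        gj <- match(c(cs$receptor, cs$tf, cs$targets), genes)
        mu[gj, rcv] <- mu[gj, rcv] * fac
      }
    }
    depth <- exp(stats::rnorm(n_cell, 0, 0.25))
    mu <- sweep(mu, 2L, depth, `*`)
    cnt <- matrix(stats::rnbinom(n_gene * n_cell, size = dispersion, mu = mu),
                  n_gene, n_cell, dimnames = list(genes, cells$cell_id))
    counts <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
    cells <- cell_table_covariates(counts, cells)
    list(counts = counts, cells = cells)
  })
}

# recompute QC covariates (n_umi, n_genes, pct_mito) from a count matrix
cell_table_covariates <- function(counts, cells) {
  cells$n_umi <- Matrix::colSums(counts)
  cells$n_genes <- Matrix::colSums(counts > 0)
  mt <- startsWith(rownames(counts), "MT-")
  cells$pct_mito <- if (any(mt)) {
    as.numeric(Matrix::colSums(counts[mt, , drop = FALSE]) /
               pmax(cells$n_umi, 1))
  } else 0
  cells[, c("cell_id", "cell_type", "condition", "patient",
            "n_umi", "n_genes", "pct_mito")]
}

#' Simulate a survival cohort with a continuous biomarker
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(beta * biomarker)`, biomarker ~ N(0, 1).
#' Censoring is independent uniform on `(0, tau)` with `tau` calibrated so
#' the expected censoring fraction approximates `censor_rate`.
#'
#' @param n_patients cohort size (>= 10).
#' @param beta log-hazard per biomarker unit (negative = protective).
#' @param baseline_hazard events per day at biomarker 0.
#' @param censor_rate target fraction censored, in `[0, 1)`.
#' @param seed integer seed.
#' @return data.frame: patient_id, time (days), event (0/1), biomarker.
#' @export
simulate_survival <- function(n_patients, beta = 0, baseline_hazard = 0.001,
                              censor_rate = 0.3, seed = 1L) {
  stopifnot(n_patients >= 10, censor_rate >= 0, censor_rate < 1,
            baseline_hazard > 0)
  with_seed(seed, {
    biomarker <- stats::rnorm(n_patients)
    tt <- stats::rexp(n_patients, rate = baseline_hazard * exp(beta * biomarker))
    if (censor_rate == 0) {
      time <- tt; event <- rep(1L, n_patients)
    } else {
      # with C ~ U(0, tau): P(censored | T = t) = min(t / tau, 1)
      f <- function(tau) mean(pmin(tt / tau, 1)) - censor_rate
      tau <- stats::uniroot(f, lower = min(tt) * 1e-6,
                            upper = max(tt) * 1e6)$root
      cc <- stats::runif(n_patients, 0, tau)
      event <- as.integer(tt <= cc)
      time <- pmin(tt, cc)
    }
    data.frame(patient_id = sprintf("PT%03d", seq_len(n_patients)),
               time = time, event = event, biomarker = biomarker,
               stringsAsFactors = FALSE)
  })
}
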