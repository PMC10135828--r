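#' Quality-control thresholds
#'
#' Defaults follow common droplet scRNA-seq practice: mitochondrial
#' fraction at most 20%, total UMIs between 100 and 150,000, detected genes
#' between 200 and 10,000.  All bounds are inclusive.
#'
#' @param mito_max maximum mitochondrial fraction, in `(0, 1]`.
#' @param umi_range length-2 inclusive UMI range.
#' @param gene_range length-2 inclusive detected-gene range.
#' @return a list of class `QCThresholds`.
#' @export
qc_thresholds <- function(mito_max = 0.20, umi_range = c(100, 150000),
                          gene_range = c(200, 10000)) {
  stopifnot(mito_max > 0, mito_max <= 1,
            length(umi_range) == 2L, umi_range[1] <= umi_range[2],
            length(gene_range) == 2L, gene_range[1] <= gene_range[2])
  structure(list(mito_max = mito_max, umi_range = umi_range,
                 gene_range = gene_range), class = "QCThresholds")
}

#' Filter cells on QC covariates
#'
#' Retains cells satisfying all three criteria (inclusive bounds):
#' mitochondrial fraction `<= mito_max`, UMIs within `umi_range`, detected
#' genes within `gene_range`.  Covariates are recomputed from the count
#' matrix (mitochondrial genes identified by the `MT-` prefix), so the
#' filter is idempotent.  The report tallies removals by the first failing
#' criterion in the fixed order mito, umi, genes.
#'
#' @param counts genes x cells sparse count matrix with dimnames.
#' @param cells cell annotation data.frame with a `cell_id` column matching
#'   `colnames(counts)`.
#' @param thresholds a [qc_thresholds()] object.
#' @return list: `counts`, `cells` (filtered), `report` (list with
#'   `n_input`, `n_retained` and `removed` tally).
#' @export
qc_filter <- function(counts, cells, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"),
            all(colnames(counts) == cells$cell_id))
  cells <- cell_table_covariates(counts, cells)
  fail_mito <- cells$pct_mito > thresholds$mito_max
  fail_umi <- cells$n_umi < thresholds$umi_range[1] |
              cells$n_umi > thresholds$umi_range[2]
  fail_gene <- cells$n_genes < thresholds$gene_range[1] |
               cells$n_genes > thresholds$gene_range[2]
  first_fail <- rep(NA_character_, nrow(cells))
  first_fail[fail_gene] <- "genes"
  first_fail[fail_umi] <- "umi"
  first_fail[fail_mito] <- "mito"
  keep <- is.na(first_fail)
  report <- list(
    n_input = nrow(cells), n_retained = sum(keep),
    removed = c(mito = sum(first_fail == "mito", na.rm = TRUE),
                umi = sum(first_fail == "umi", na.rm = TRUE),
                genes = sum(first_fail == "genes", na.rm = TRUE)))
  if (!any(keep)) {
    stop("qc_filter removed all cells (mito=", report$removed["mito"],
         ", umi=", report$removed["umi"], ", genes=",
         report$removed["genes"], ")", call. = FALSE)
  }
  list(counts = counts[, keep, drop = FALSE],
       cells = cells[keep, , drop = FALSE], report = report)
}

#' Depth-scaled log-normalization
#'
#' `value(g, c) = ln(1 + count(g, c) * scale_factor / depth(c))` where
#' `depth(c)` is the cell's total count.  Zero counts map exactly to zero,
#' so sparsity is preserved; the transform is invertible given the depths.
#'
#' @param counts genes x cells sparse count matrix.
#' @param scale_factor target depth (default 10,000).
#' @return sparse genes x cells matrix of normalized values, with
#'   attributes `scale_factor` and `depth`.
#' @export
normalize_log1p <- function(counts, scale_factor = 10000) {
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) {
    stop("zero-depth cell(s): ",
         paste(head(colnames(counts)[depth == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  normed <- methods::as(counts, "CsparseMatrix") * 1.0
  # scale the nonzero entries column-wise without densifying
  j <- rep(seq_len(ncol(normed)), diff(normed@p))
  normed@x <- log1p(normed@x * scale_factor / depth[j])
  attr(normed, "scale_factor") <- scale_factor
  attr(normed, "depth") <- depth
  normed
}

#' Select highly variable genes
#'
#' The classic binned-dispersion heuristic: per-gene dispersion
#' (variance / mean of normalized values) is z-scored within 20
#' equal-frequency mean bins, and genes are ranked by the standardized
#' dispersion.  Ties are broken lexicographically by gene name; the result
#' depends only on the matrix content, not on row or column order.
#'
#' @param normed normalized matrix from [normalize_log1p()].
#' @param n number of genes to return (default 3000).
#' @param n_bins number of mean bins.
#' @return character vector of gene names in rank order.
#' @export
select_hvg <- function(normed, n = 3000, n_bins = 20) {
  stopifnot(n >= 1, n <= nrow(normed))
  m <- Matrix::rowMeans(normed)
  ex2 <- Matrix::rowMeans(normed^2)
  v <- pmax(ex2 - m^2, 0) * ncol(normed) / max(ncol(normed) - 1, 1)
  v[v < 1e-12] <- 0
  disp <- ifelse(m > 0, v / m, 0)
  if (all(v == 0)) stop("no variable genes: matrix is constant per gene",
                        call. = FALSE)
  n_bins <- max(1L, min(n_bins, length(unique(m))))
  brk <- unique(stats::quantile(m, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(m, breaks = brk, include.lowest = TRUE)
  z <- stats::ave(disp, bin, FUN = function(d) {
    s <- stats::sd(d)
    if (is.na(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
  })
  ord <- order(-z, rownames(normed))
  rownames(normed)[ord][seq_len(n)]
}
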