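#' Read a sparse count matrix from Matrix Market + TSV identifier files
#'
#' Expects the 10x-style triplet: an `.mtx` file (1-based COO indices,
#' genes x cells), a gene TSV (first column = gene id) and a barcode TSV
#' (first column = cell id), both headerless.  Dimensions and identifier
#' uniqueness are validated; errors name the offending file.
#'
#' @param mtx_path,genes_path,barcodes_path file paths.
#' @return sparse `dgCMatrix` with gene row names and cell column names.
#' @export
read_counts <- function(mtx_path, genes_path, barcodes_path) {
  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
    stop("malformed Matrix Market file '", mtx_path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  genes <- read.delim(genes_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  cells <- read.delim(barcodes_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes)) {
    stop("dimension mismatch: ", nrow(m), " matrix rows vs ", length(genes),
         " identifiers in '", genes_path, "'", call. = FALSE)
  }
  if (ncol(m) != length(cells)) {
    stop("dimension mismatch: ", ncol(m), " matrix columns vs ",
         length(cells), " identifiers in '", barcodes_path, "'",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier(s) in '", genes_path, "', e.g. line ",
         anyDuplicated(genes), call. = FALSE)
  }
  if (anyDuplicated(cells)) {
    stop("duplicate cell identifier(s) in '", barcodes_path, "', e.g. line ",
         anyDuplicated(cells), call. = FALSE)
  }
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a sparse count matrix as Matrix Market + TSV identifier files
#'
#' @param counts genes x cells sparse matrix with dimnames.
#' @param dir output directory (created if needed); files are
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return named character vector of the three paths, invisibly.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  genes <- file.path(dir, "genes.tsv")
  barcodes <- file.path(dir, "barcodes.tsv")
  # always write the "general" MM form: writeMM would otherwise pick the
  # symmetric form for incidentally-symmetric matrices, confusing readers
  Matrix::writeMM(methods::as(methods::as(counts, "generalMatrix"),
                              "CsparseMatrix"), mtx)
  writeLines(rownames(counts), genes)
  writeLines(colnames(counts), barcodes)
  invisible(c(mtx = mtx, genes = genes, barcodes = barcodes))
}

#' Read gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40),
                             call. = FALSE)
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1L), USE.NAMES = FALSE)
  sets
}

#' Read / write a cell annotation table
#' @param path TSV path.
#' @param cells data.frame.
#' @export
read_cell_table <- function(path) {
  cells <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("cell_id", "cell_type", "condition", "patient") %in%
                  names(cells)),
              "cell table needs cell_id, cell_type, condition, patient")
  check_conditions(cells$condition)
  cells
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a single YAML file.  Required keys: `paths`
#' (`counts_mtx`, `genes`, `barcodes`, `cells`, `prior_edges`,
#' `prior_nodes`; optional `survival`, `genesets`), `seed` (mandatory),
#' and optional `thresholds` (`mito_max`, `umi_range`, `gene_range`,
#' `alpha`, `top_n_ligands`, `n_perm`, `top_k`, `min_importance`,
#' `minprop`), `condition_pairs` (list of two-element reference/interest
#' pairs), `sender`, `receiver`, `n_states`.  All referenced files must
#' exist at validation time.
#'
#' @param path YAML file.
#' @return list of class `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  assert_that(!is.null(cfg$paths), "config must contain a 'paths' block")
  assert_that(!is.null(cfg$seed), "config must set an explicit seed")
  required <- c("counts_mtx", "genes", "barcodes", "cells",
                "prior_edges", "prior_nodes")
  for (k in required) {
    assert_that(!is.null(cfg$paths[[k]]),
                paste0("config paths must include '", k, "'"))
  }
  base <- dirname(normalizePath(path))
  for (k in names(cfg$paths)) {
    p <- cfg$paths[[k]]
    if (!file.exists(p)) p <- file.path(base, cfg$paths[[k]])
    if (!file.exists(p)) {
      stop("configured file does not exist: ", cfg$paths[[k]],
           " (key '", k, "')", call. = FALSE)
    }
    cfg$paths[[k]] <- normalizePath(p)
  }
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    qc = qc_thresholds(th$mito_max %||% 0.20,
                       unlist(th$umi_range %||% c(100, 150000)),
                       unlist(th$gene_range %||% c(200, 10000))),
    alpha = th$alpha %||% 0.05,
    top_n_ligands = th$top_n_ligands %||% 30,
    n_perm = th$n_perm %||% 1000,
    top_k = th$top_k %||% 50,
    min_importance = th$min_importance %||% 0.1,
    minprop = th$minprop %||% 0.1)
  cfg$condition_pairs <- cfg$condition_pairs %||%
    list(c("nLung", "tLung"), c("tLung", "tL/B"))
  for (pr in cfg$condition_pairs) check_conditions(unlist(pr))
  cfg$sender <- cfg$sender %||% "tumor"
  cfg$receiver <- cfg$receiver %||% "macrophage"
  cfg$n_states <- cfg$n_states %||% 7
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "PipelineConfig")
}
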