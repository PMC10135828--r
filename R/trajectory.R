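#' Signal-gene feature matrix for trajectory analysis
#'
#' Slices the normalized matrix to the receiver cells and the Network-4.0
#' signal genes, transposes to cells x genes and z-scores each gene
#' (constant genes become all-zero columns).  Genes absent from the
#' matrix are dropped with a warning; columns are ordered by gene name so
#' the result is invariant to input gene order.
#'
#' @param normed normalized matrix from [normalize_log1p()].
#' @param cell_ids receiver cell identifiers (>= 10).
#' @param genes signal genes (>= 2 must be present).
#' @return numeric matrix, cells x genes, z-scored columns.
#' @export
signal_features <- function(normed, cell_ids, genes) {
  stopifnot(length(cell_ids) >= 10, all(cell_ids %in% colnames(normed)))
  genes <- sort(unique(genes))
  absent <- setdiff(genes, rownames(normed))
  if (length(absent) > 0L) {
    warning("dropping ", length(absent), " signal gene(s) absent from the ",
            "matrix: ", paste(head(absent, 5), collapse = ", "),
            call. = FALSE)
    genes <- setdiff(genes, absent)
  }
  if (length(genes) < 2L) {
    stop("fewer than 2 signal genes present in the matrix", call. = FALSE)
  }
  m <- t(as.matrix(normed[genes, cell_ids, drop = FALSE]))
  scale_col <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  apply(m, 2L, scale_col)
}

#' Order receiver cells in pseudotime on signal genes
#'
#' A deliberately simple tree trajectory: the feature matrix is reduced to
#' two principal components, cells are clustered into `n_states` states by
#' seeded k-means, and a minimum spanning tree is built on the state
#' centroids.  Each cell is projected onto its nearest tree segment and
#' its pseudotime is the geodesic (along-tree) distance from the root
#' state's centroid to that projected point.  The root state is the state
#' with the largest fraction of root-condition cells, so root-condition
#' cells anchor pseudotime 0 by construction.  Deterministic for a fixed
#' seed.
#'
#' @param features cells x genes matrix from [signal_features()].
#' @param cells cell annotation for those cells (cell_id, condition),
#'   rows aligned with `features`.
#' @param root_condition condition defining the trajectory start
#'   (default "nLung").
#' @param n_states number of states (>= 2; default 7).
#' @param seed integer seed for k-means.
#' @return data.frame (class `PseudotimeResult`): cell_id, state,
#'   pseudotime, dim1, dim2.
#' @export
pseudotime_order <- function(features, cells, root_condition = "nLung",
                             n_states = 7, seed = 1L) {
  stopifnot(n_states >= 2, nrow(features) == nrow(cells))
  if (nrow(features) < n_states) {
    stop("fewer cells than requested states", call. = FALSE)
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = 2)
  coords <- pc$x
  if (ncol(coords) < 2L) {
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
  }
  n_distinct <- nrow(unique(coords))
  if (n_distinct < n_states) {
    # degenerate input: too few distinct points to form the states
    if (n_distinct == 1L) {
      return(pseudotime_result(cells$cell_id, rep(1L, nrow(coords)),
                               rep(0, nrow(coords)), coords))
    }
    n_states <- n_distinct
  }
  km <- with_seed(seed, stats::kmeans(coords, centers = n_states,
                                      nstart = 10, iter.max = 100))
  state <- km$cluster
  cent <- km$centers

  # MST over centroid distances; geodesic distance from the root state
  dmat <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  root_frac <- vapply(seq_len(n_states), function(s) {
    mean(cells$condition[state == s] == root_condition)
  }, numeric(1L))
  root <- which.max(root_frac)
  dist_root <- as.numeric(igraph::distances(tree, v = root))

  # project every cell onto its nearest tree segment; pseudotime is the
  # along-tree distance from the root centroid to the projected point
  edges <- igraph::as_edgelist(tree, names = FALSE)
  raw <- rep(Inf, nrow(coords))
  best_res <- rep(Inf, nrow(coords))
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    if (dist_root[b] < dist_root[a]) { tmp <- a; a <- b; b <- tmp }
    ca <- cent[a, ]; cb <- cent[b, ]
    seg <- cb - ca
    len2 <- sum(seg^2)
    tt <- if (len2 > 0) {
      pmin(pmax(as.numeric(sweep(coords, 2L, ca) %*% seg) / len2, 0), 1)
    } else rep(0, nrow(coords))
    proj <- cbind(ca[1] + tt * seg[1], ca[2] + tt * seg[2])
    res <- sqrt(rowSums((coords - proj)^2))
    pt <- dist_root[a] + tt * sqrt(len2)
    upd <- res < best_res
    raw[upd] <- pt[upd]
    best_res[upd] <- res[upd]
  }
  if (nrow(edges) == 0L) raw <- rep(0, nrow(coords))  # single state
  is_root_cond <- cells$condition == root_condition
  anchor <- if (any(is_root_cond)) min(raw[is_root_cond]) else min(raw)
  pt <- pmax(raw - anchor, 0)
  pseudotime_result(cells$cell_id, state, pt, coords)
}

pseudotime_result <- function(cell_id, state, pseudotime, coords) {
  out <- data.frame(cell_id = cell_id, state = as.integer(state),
                    pseudotime = pseudotime,
                    dim1 = coords[, 1], dim2 = coords[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("PseudotimeResult", "data.frame")
  out
}

#' State composition by condition
#'
#' The proportion of each condition's cells found in each trajectory
#' state; columns (conditions) each sum to 1.
#'
#' @param result a [pseudotime_order()] result.
#' @param cells cell annotation (cell_id, condition).
#' @return numeric matrix, states x conditions.
#' @export
state_composition <- function(result, cells) {
  stopifnot(inherits(result, "PseudotimeResult"))
  cond <- cells$condition[match(result$cell_id, cells$cell_id)]
  if (any(is.na(cond))) stop("cell ids do not align", call. = FALSE)
  tab <- table(state = result$state, condition = cond)
  prop <- sweep(tab, 2L, colSums(tab), `/`)
  as.matrix(unclass(prop))
}
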