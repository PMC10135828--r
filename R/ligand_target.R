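#' Diffusion-based ligand-to-target regulatory potential
#'
#' Personalized PageRank from the ligand over the `lr` + `signaling`
#' layers of the prior network, propagated to target genes through the
#' `gene_regulatory` layer.  The walk restarts at the ligand with
#' probability `1 - damping`; transition probabilities are out-weight
#' normalized; the walk is absorbed at dangling nodes (absorbing rather
#' than restart-redistributing semantics, so that deleting an edge can
#' never increase a score elsewhere).  The
#' score of gene `g` is `sum over TFs of pi[tf] * w(tf -> g) /
#' sum_g' w(tf -> g')` — the stationary visit probability at each TF
#' spread over its normalized regulatory out-weights.  Genes unreachable
#' from the ligand score exactly 0.
#'
#' @param prior a [prior_network()].
#' @param ligand a ligand gene of the prior.
#' @param damping walk continuation probability (default 0.85).
#' @param tol sup-norm convergence tolerance of the power iteration.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return named numeric vector of scores over all target-role genes,
#'   with attribute `ligand`.
#' @export
regulatory_potential <- function(prior, ligand, damping = 0.85,
                                 tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(prior, "PriorNetwork"),
            damping > 0, damping < 1)
  roles <- setNames(prior$nodes$role, prior$nodes$gene)
  if (!ligand %in% names(roles) || roles[[ligand]] != "ligand") {
    stop("'", ligand, "' is not a ligand of the prior network",
         call. = FALSE)
  }
  walk_nodes <- prior$nodes$gene[prior$nodes$role %in%
                                 c("ligand", "receptor", "signaling", "tf")]
  e <- prior$edges[prior$edges$layer %in% c("lr", "signaling"), , drop = FALSE]
  genes <- prior_genes_by_role(prior, "target")
  nw <- length(walk_nodes)
  P <- matrix(0, nw, nw, dimnames = list(walk_nodes, walk_nodes))
  if (nrow(e) > 0L) {
    P[cbind(match(e$from, walk_nodes), match(e$to, walk_nodes))] <- e$weight
    rs <- rowSums(P)
    nz <- rs > 0
    P[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
  }
  restart <- setNames(as.numeric(walk_nodes == ligand), walk_nodes)
  pi <- restart
  for (it in seq_len(max_iter)) {
    pi_new <- (1 - damping) * restart +
      damping * setNames(as.numeric(pi %*% P), walk_nodes)
    if (max(abs(pi_new - pi)) < tol) {
      pi <- pi_new
      break
    }
    pi <- pi_new
    if (it == max_iter) stop("power iteration did not converge in ",
                             max_iter, " iterations", call. = FALSE)
  }
  gr <- prior$edges[prior$edges$layer == "gene_regulatory", , drop = FALSE]
  scores <- setNames(numeric(length(genes)), genes)
  if (nrow(gr) > 0L) {
    wsum <- tapply(gr$weight, gr$from, sum)
    contrib <- pi[gr$from] * gr$weight / as.numeric(wsum[gr$from])
    agg <- tapply(contrib, gr$to, sum)
    scores[names(agg)] <- as.numeric(agg)
  }
  attr(scores, "ligand") <- ligand
  scores
}

#' Rank ligands by activity against receiver differential expression
#'
#' A ligand's activity is the Pearson correlation between its regulatory
#' potential over the gene universe and the 0/1 indicator of receiver
#' DEGs — ligands whose predicted targets coincide with the genes that
#' actually changed in the receiver population rank highest.
#'
#' @param potentials named list mapping ligand to its
#'   [regulatory_potential()] vector.
#' @param receiver_degs character vector of receiver DE genes (subset of
#'   `universe`; must be non-empty).
#' @param universe character vector of genes over which to correlate.
#' @param top_n number of ligands to return (default 30).
#' @return data.frame (class `LigandActivity`): ligand, activity; sorted
#'   by activity descending, ties broken by ligand name.
#' @export
rank_ligands <- function(potentials, receiver_degs, universe, top_n = 30) {
  assert_that(length(potentials) >= 1 && !is.null(names(potentials)),
              "potentials must be a non-empty named list")
  if (length(receiver_degs) == 0L) {
    stop("no receiver signal: DEG set is empty", call. = FALSE)
  }
  assert_that(all(receiver_degs %in% universe),
              "receiver_degs must be contained in the universe")
  ind <- as.numeric(universe %in% receiver_degs)
  act <- vapply(potentials, function(pv) {
    v <- setNames(numeric(length(universe)), universe)
    common <- intersect(names(pv), universe)
    v[common] <- pv[common]
    if (stats::sd(v) == 0 || stats::sd(ind) == 0) return(0)
    stats::cor(v, ind)
  }, numeric(1L))
  out <- data.frame(ligand = names(act), activity = as.numeric(act),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$activity, out$ligand), , drop = FALSE]
  out <- head(out, top_n)
  rownames(out) <- NULL
  class(out) <- c("LigandActivity", "data.frame")
  out
}

#' Extract best ligand -> receptor -> TF -> target signaling paths
#'
#' Exact dynamic programming over the layered DAG: for each requested
#' target, the `k_per_target` highest-scoring paths
#' ligand -> receptor -> (signaling intermediate) -> TF -> target by
#' product of edge weights.  Only the supplied receptors (typically the
#' retained ligand-receptor pairs) may start a path.  Targets with no path
#' are dropped with a warning; chains are never fabricated.
#'
#' @param prior a [prior_network()].
#' @param ligand ligand gene.
#' @param receptors admissible receptor genes.
#' @param targets target genes to connect.
#' @param k_per_target number of best paths per target (default 1).
#' @return data.frame of chains: ligand, receptor, signaling (NA when the
#'   path skips the intermediate layer), tf, target, weight.
#' @export
extract_paths <- function(prior, ligand, receptors, targets,
                          k_per_target = 1) {
  stopifnot(inherits(prior, "PriorNetwork"), k_per_target >= 1)
  e <- prior$edges
  lr <- e[e$layer == "lr" & e$from == ligand & e$to %in% receptors, ,
          drop = FALSE]
  sg <- e[e$layer == "signaling", , drop = FALSE]
  gr <- e[e$layer == "gene_regulatory", , drop = FALSE]
  roles <- setNames(prior$nodes$role, prior$nodes$gene)

  # partial paths ligand -> receptor -> ... -> tf with running weight
  partial <- list()
  for (i in seq_len(nrow(lr))) {
    r <- lr$to[i]; w1 <- lr$weight[i]
    out1 <- sg[sg$from == r, , drop = FALSE]
    for (j in seq_len(nrow(out1))) {
      nxt <- out1$to[j]; w2 <- w1 * out1$weight[j]
      if (roles[[nxt]] == "tf") {
        partial[[length(partial) + 1L]] <-
          list(receptor = r, signaling = NA_character_, tf = nxt, w = w2)
      } else {  # signaling intermediate; one hop to a TF
        out2 <- sg[sg$from == nxt & roles[sg$to] == "tf", , drop = FALSE]
        for (m in seq_len(nrow(out2))) {
          partial[[length(partial) + 1L]] <-
            list(receptor = r, signaling = nxt, tf = out2$to[m],
                 w = w2 * out2$weight[m])
        }
      }
    }
  }

  rows <- list()
  for (g in unique(targets)) {
    tf_edges <- gr[gr$to == g, , drop = FALSE]
    cand <- list()
    for (i in seq_len(nrow(tf_edges))) {
      hits <- Filter(function(p) p$tf == tf_edges$from[i], partial)
      for (p in hits) {
        cand[[length(cand) + 1L]] <-
          data.frame(ligand = ligand, receptor = p$receptor,
                     signaling = p$signaling, tf = p$tf, target = g,
                     weight = p$w * tf_edges$weight[i],
                     stringsAsFactors = FALSE)
      }
    }
    if (length(cand) == 0L) {
      warning("no path from ", ligand, " to target ", g, "; dropped",
              call. = FALSE)
      next
    }
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$weight, cand$receptor, cand$tf,
                       cand$signaling, method = "radix"), , drop = FALSE]
    rows[[length(rows) + 1L]] <- head(cand, k_per_target)
  }
  if (length(rows) == 0L) {
    return(data.frame(ligand = character(0), receptor = character(0),
                      signaling = character(0), tf = character(0),
                      target = character(0), weight = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
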