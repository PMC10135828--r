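#' Construct a prior multilayer signaling network
#'
#' A `PriorNetwork` is a typed, weighted, directed multilayer graph with
#' three layers: `lr` (ligand -> receptor), `signaling`
#' (receptor/signaling-intermediate -> signaling-intermediate/TF) and
#' `gene_regulatory` (TF -> target gene).  It is the structural prior over
#' which ligand-to-target regulatory potential is diffused and signaling
#' paths are extracted.
#'
#' @param nodes data.frame with columns `gene` (character, unique) and
#'   `role` (one of `ligand`, `receptor`, `signaling`, `tf`, `target`).
#' @param edges data.frame with columns `from`, `to`, `weight`
#'   (in `(0, 1]`) and `layer` (one of `lr`, `signaling`,
#'   `gene_regulatory`).
#' @return an object of class `PriorNetwork`.
#' @export
prior_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("gene", "role") %in% names(nodes)),
            is.data.frame(edges),
            all(c("from", "to", "weight", "layer") %in% names(edges)))
  nodes <- data.frame(gene = as.character(nodes$gene),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      weight = as.numeric(edges$weight),
                      layer = as.character(edges$layer),
                      stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(nodes$gene), "duplicate gene identifiers in nodes")
  assert_that(all(nodes$role %in% PRIOR_ROLES), "unknown node role")
  assert_that(all(edges$layer %in% PRIOR_LAYERS), "unknown edge layer")
  assert_that(all(edges$weight > 0 & edges$weight <= 1),
              "edge weights must lie in (0, 1]")
  assert_that(!any(edges$from == edges$to), "self-loops are not allowed")
  assert_that(all(c(edges$from, edges$to) %in% nodes$gene),
              "edge endpoint not present in node table")
  role <- setNames(nodes$role, nodes$gene)
  lr <- edges$layer == "lr"
  assert_that(all(role[edges$from[lr]] == "ligand") &&
              all(role[edges$to[lr]] == "receptor"),
              "lr edges must go ligand -> receptor")
  gr <- edges$layer == "gene_regulatory"
  assert_that(all(role[edges$from[gr]] == "tf"),
              "gene_regulatory edges must originate at a TF")
  sg <- edges$layer == "signaling"
  assert_that(all(role[edges$from[sg]] %in% c("receptor", "signaling")) &&
              all(role[edges$to[sg]] %in% c("signaling", "tf")),
              "signaling edges must go receptor/signaling -> signaling/tf")
  structure(list(nodes = nodes, edges = edges), class = "PriorNetwork")
}

#' @export
print.PriorNetwork <- function(x, ...) {
  cat("PriorNetwork:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  roles: ", paste(sprintf("%s=%d", names(table(x$nodes$role)),
                                 table(x$nodes$role)), collapse = " "), "\n")
  cat("  layers:", paste(sprintf("%s=%d", names(table(x$edges$layer)),
                                 table(x$edges$layer)), collapse = " "), "\n")
  invisible(x)
}

prior_genes_by_role <- function(prior, r) {
  prior$nodes$gene[prior$nodes$role == r]
}

#' Generate a random layered prior network
#'
#' Draws a layered random graph: ligand -> receptor (`lr` layer), receptor
#' -> signaling intermediate -> TF (`signaling` layer; receptors connect to
#' TFs directly when `n_signaling = 0`), and TF -> target gene
#' (`gene_regulatory` layer).  Each admissible edge is included
#' independently with probability `edge_density`; weights are drawn
#' uniformly on `(0.1, 1)`.  Every ligand is guaranteed to reach at least
#' one target gene: when the random draw leaves a ligand disconnected a
#' minimal connecting path is added and a notice is logged.
#'
#' The default density of 0.1 reflects the sparsity of curated signaling
#' priors, where only a small fraction of all role-compatible gene pairs
#' interact.
#'
#' @param n_ligands,n_receptors,n_tfs,n_genes positive counts per role.
#' @param n_signaling count of signaling intermediates (may be 0).
#' @param edge_density inclusion probability in `(0, 1]`.
#' @param seed integer seed; same seed gives identical edge lists.
#' @return a [prior_network()] object.
#' @examples
#' p <- generate_prior_network(2, 2, 0, 2, 5, edge_density = 0.5, seed = 1)
#' @export
generate_prior_network <- function(n_ligands, n_receptors, n_signaling,
                                   n_tfs, n_genes, edge_density = 0.1,
                                   seed = 1L) {
  stopifnot(n_ligands >= 1, n_receptors >= 1, n_signaling >= 0,
            n_tfs >= 1, n_genes >= 1,
            edge_density > 0, edge_density <= 1)
  lig <- sprintf("LIG%d", seq_len(n_ligands))
  rec <- sprintf("REC%d", seq_len(n_receptors))
  sig <- if (n_signaling > 0) sprintf("SIG%d", seq_len(n_signaling)) else character(0)
  tfs <- sprintf("TF%d", seq_len(n_tfs))
  tgt <- sprintf("TGT%d", seq_len(n_genes))
  nodes <- data.frame(
    gene = c(lig, rec, sig, tfs, tgt),
    role = rep(c("ligand", "receptor", "signaling", "tf", "target"),
               c(n_ligands, n_receptors, n_signaling, n_tfs, n_genes)),
    stringsAsFactors = FALSE)

  with_seed(seed, {
    draw_layer <- function(from, to, layer) {
      g <- expand.grid(from = from, to = to, stringsAsFactors = FALSE)
      keep <- stats::runif(nrow(g)) < edge_density
      g <- g[keep, , drop = FALSE]
      if (nrow(g) == 0L) {
        return(data.frame(from = character(0), to = character(0),
                          weight = numeric(0), layer = character(0)))
      }
      g$weight <- stats::runif(nrow(g), 0.1, 1)
      g$layer <- layer
      g
    }
    edges <- rbind(
      draw_layer(lig, rec, "lr"),
      if (n_signaling > 0) rbind(draw_layer(rec, sig, "signaling"),
                                 draw_layer(sig, tfs, "signaling"))
      else draw_layer(rec, tfs, "signaling"),
      draw_layer(tfs, tgt, "gene_regulatory"))
    rownames(edges) <- NULL

    # repair: every ligand must reach >= 1 target gene through the layers
    reach <- ligand_reaches_gene(nodes, edges)
    # connect through nodes unused in the relevant layer where possible, so
    # repair paths do not pile onto the same receptors/TFs/targets
    pick_fresh <- function(pool, used) {
      fresh <- setdiff(pool, used)
      if (length(fresh) > 0L) fresh[sample.int(length(fresh), 1L)]
      else pool[sample.int(length(pool), 1L)]
    }
    for (l in lig[!reach]) {
      walk <- edges[edges$layer %in% c("lr", "signaling"), , drop = FALSE]
      r <- pick_fresh(rec, c(walk$from, walk$to))
      t <- pick_fresh(tfs, edges$to[edges$layer == "signaling"])
      g <- pick_fresh(tgt, edges$to[edges$layer == "gene_regulatory"])
      path <- if (n_signaling > 0) {
        s <- sample(sig, 1L)
        data.frame(from = c(l, r, s, t), to = c(r, s, t, g),
                   weight = stats::runif(4, 0.1, 1),
                   layer = c("lr", "signaling", "signaling", "gene_regulatory"))
      } else {
        data.frame(from = c(l, r, t), to = c(r, t, g),
                   weight = stats::runif(3, 0.1, 1),
                   layer = c("lr", "signaling", "gene_regulatory"))
      }
      # only add edges not already present
      key <- paste(edges$from, edges$to)
      path <- path[!paste(path$from, path$to) %in% key, , drop = FALSE]
      edges <- rbind(edges, path)
      message("generate_prior_network: added minimal connecting path for ",
              "disconnected ligand ", l)
    }
    prior_network(nodes, edges)
  })
}

# forward BFS per ligand over the whole edge set; returns logical per ligand
ligand_reaches_gene <- function(nodes, edges) {
  lig <- nodes$gene[nodes$role == "ligand"]
  tgt <- nodes$gene[nodes$role == "target"]
  adj <- split(edges$to, edges$from)
  vapply(lig, function(l) {
    seen <- character(0)
    frontier <- l
    while (length(frontier) > 0L) {
      seen <- c(seen, frontier)
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      frontier <- setdiff(nxt, seen)
    }
    any(tgt %in% seen)
  }, logical(1L))
}

#' Read / write a prior network as an edge-list TSV
#'
#' The on-disk format is a four-column TSV (`source`, `target`, `weight`,
#' `layer`) plus a two-column node TSV (`gene`, `role`).
#'
#' @param prior a `PriorNetwork`.
#' @param edges_path,nodes_path file paths.
#' @return `write_prior_network` returns the paths invisibly;
#'   `read_prior_network` returns a `PriorNetwork`.
#' @export
write_prior_network <- function(prior, edges_path, nodes_path) {
  stopifnot(inherits(prior, "PriorNetwork"))
  e <- prior$edges
  names(e)[1:2] <- c("source", "target")
  write.table(e, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(prior$nodes, nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(edges = edges_path, nodes = nodes_path))
}

#' @rdname write_prior_network
#' @export
read_prior_network <- function(edges_path, nodes_path) {
  e <- read.delim(edges_path, stringsAsFactors = FALSE)
  n <- read.delim(nodes_path, stringsAsFactors = FALSE)
  names(e)[names(e) == "source"] <- "from"
  names(e)[names(e) == "target"] <- "to"
  prior_network(n, e)
}
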