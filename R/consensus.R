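#' Versioned quad-chain networks
#'
#' A `QuadNetwork` is a set of ligand -> receptor -> TF -> target chains
#' for one (reference, interest) condition pair, together with the
#' consensus version reached so far: 1.0 (constructed), 2.0 (L-R
#' verified), 3.0 (TF-target verified), 4.0 (DEG filtered).  Chains are
#' the unit of filtering, so the chain sets are nested:
#' 4.0 within 3.0 within 2.0 within 1.0.
#'
#' @param chains data.frame with columns ligand, receptor, tf, target,
#'   weight; evidence columns are added if missing.
#' @param version one of "1.0", "2.0", "3.0", "4.0".
#' @param condition_reference,condition_oi the stage pair.
#' @param sender,receiver cell types.
#' @return object of class `QuadNetwork`.
#' @export
quad_network <- function(chains, version, condition_reference, condition_oi,
                         sender = "tumor", receiver = "macrophage") {
  stopifnot(version %in% c("1.0", "2.0", "3.0", "4.0"),
            is.data.frame(chains),
            all(c("ligand", "receptor", "tf", "target", "weight") %in%
                names(chains)))
  for (fl in c("lr_verified", "tf_verified", "deg_passed")) {
    if (is.null(chains[[fl]])) chains[[fl]] <- rep(FALSE, nrow(chains))
  }
  if (is.null(chains$direction)) chains$direction <- rep("na", nrow(chains))
  chains <- chains[order(chains$ligand, chains$receptor, chains$tf,
                         chains$target), , drop = FALSE]
  rownames(chains) <- NULL
  structure(list(version = version,
                 condition_reference = condition_reference,
                 condition_oi = condition_oi,
                 sender = sender, receiver = receiver,
                 chains = chains),
            class = "QuadNetwork")
}

#' @export
print.QuadNetwork <- function(x, ...) {
  cat(sprintf("QuadNetwork v%s [%s -> %s, %s/%s]: %d chain(s), %d signal(s)\n",
              x$version, x$condition_reference, x$condition_oi,
              x$sender, x$receiver, nrow(x$chains),
              length(unique(c(x$chains$receptor, x$chains$tf,
                              x$chains$target)))))
  invisible(x)
}

chain_key <- function(ch) paste(ch$ligand, ch$receptor, ch$tf, ch$target,
                                sep = "|")

#' Build Network 1.0 from extracted signaling chains
#'
#' Deduplicates the chain set on the (ligand, receptor, tf, target)
#' quadruple, keeping the highest-weight path for each; all evidence flags
#' start false.
#'
#' @param chains data.frame of chains from [extract_paths()] (possibly
#'   concatenated over the top-ranked ligands).
#' @inheritParams quad_network
#' @return a `QuadNetwork`, version 1.0.
#' @export
build_network1 <- function(chains, condition_reference, condition_oi,
                           sender = "tumor", receiver = "macrophage") {
  if (is.null(chains) || nrow(chains) == 0L) {
    stop("no chains supplied: Network 1.0 would be empty", call. = FALSE)
  }
  chains <- chains[order(-chains$weight), , drop = FALSE]
  chains <- chains[!duplicated(chain_key(chains)), , drop = FALSE]
  chains <- chains[, c("ligand", "receptor", "tf", "target", "weight")]
  quad_network(chains, "1.0", condition_reference, condition_oi,
               sender, receiver)
}

#' Verify ligand-receptor pairs (Network 1.0 -> 2.0)
#'
#' Keeps chains whose (ligand, receptor) pair is in the retained
#' interaction set (`mean > 0`); everything downstream reachable only
#' through a removed pair disappears with it, because chains are the
#' filtering unit.
#'
#' @param net1 Network 1.0.
#' @param scores an [interaction_means()] / [permutation_test()] table.
#' @return a `QuadNetwork`, version 2.0.
#' @export
verify_lr <- function(net1, scores) {
  stopifnot(inherits(net1, "QuadNetwork"), net1$version == "1.0",
            inherits(scores, "InteractionScores"))
  ok <- scores[scores$retained, , drop = FALSE]
  keep <- paste(net1$chains$ligand, net1$chains$receptor) %in%
          paste(ok$ligand, ok$receptor)
  ch <- net1$chains[keep, , drop = FALSE]
  ch$lr_verified <- rep(TRUE, nrow(ch))
  if (nrow(ch) == 0L) warning("Network 2.0 is empty", call. = FALSE)
  quad_network(ch, "2.0", net1$condition_reference, net1$condition_oi,
               net1$sender, net1$receiver)
}

#' Verify TF-target links against regulons (Network 2.0 -> 3.0)
#'
#' Keeps chains whose (tf, target) pair appears in the co-expression
#' regulons of the receiver population.
#'
#' @param net2 Network 2.0.
#' @param regulons a [build_regulons()] result.
#' @return a `QuadNetwork`, version 3.0.
#' @export
verify_tf <- function(net2, regulons) {
  stopifnot(inherits(net2, "QuadNetwork"),
            net2$version %in% c("2.0", "3.0"))
  keep <- vapply(seq_len(nrow(net2$chains)), function(i) {
    tf <- net2$chains$tf[i]
    tf %in% names(regulons) &&
      net2$chains$target[i] %in% names(regulons[[tf]])
  }, logical(1L))
  ch <- net2$chains[keep, , drop = FALSE]
  ch$tf_verified <- rep(TRUE, nrow(ch))
  quad_network(ch, "3.0", net2$condition_reference, net2$condition_oi,
               net2$sender, net2$receiver)
}

#' Filter by differential expression (Network 3.0 -> 4.0)
#'
#' A chain survives iff its ligand is differentially expressed in the
#' sender population (adjusted p < `alpha`, condition of interest vs
#' reference) AND at least one of its receptor, TF or target is
#' differentially expressed in the receiver population.  The chain
#' direction is annotated from the receiver-side DE sign (target first,
#' then TF, then receptor).
#'
#' @param net3 Network 3.0.
#' @param sender_degs,receiver_degs [rank_sum_deg()] tables for the
#'   network's condition pair.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return a `QuadNetwork`, version 4.0, all evidence flags true.
#' @export
deg_filter <- function(net3, sender_degs, receiver_degs, alpha = 0.05) {
  stopifnot(inherits(net3, "QuadNetwork"), net3$version == "3.0")
  if (is.null(sender_degs) || is.null(receiver_degs)) {
    stop("both sender and receiver DEG tables are required", call. = FALSE)
  }
  sde <- sender_degs[sender_degs$p_adj < alpha, , drop = FALSE]
  rde <- receiver_degs[receiver_degs$p_adj < alpha, , drop = FALSE]
  rdir <- setNames(rde$direction, rde$gene)
  ch <- net3$chains
  keep <- logical(nrow(ch))
  dir <- rep("na", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    down <- c(ch$target[i], ch$tf[i], ch$receptor[i])
    hit <- down[down %in% names(rdir)]
    keep[i] <- ch$ligand[i] %in% sde$gene && length(hit) > 0L
    if (keep[i]) dir[i] <- rdir[[hit[1]]]
  }
  ch <- ch[keep, , drop = FALSE]
  ch$direction <- dir[keep]
  ch$deg_passed <- rep(TRUE, nrow(ch))
  quad_network(ch, "4.0", net3$condition_reference, net3$condition_oi,
               net3$sender, net3$receiver)
}

#' Count network signals
#'
#' The number of distinct genes appearing in any chain of Network 4.0 as
#' receptor, TF or target.  Ligands are excluded: they are the sender-side
#' stimulus, not the receiver-side signal.
#'
#' @param net4 Network 4.0.
#' @return integer count.
#' @export
count_signals <- function(net4) {
  stopifnot(inherits(net4, "QuadNetwork"), net4$version == "4.0")
  length(unique(c(net4$chains$receptor, net4$chains$tf, net4$chains$target)))
}

#' Signal genes of a network
#' @param net4 Network 4.0.
#' @return character vector of distinct receptor/TF/target genes.
#' @export
signal_genes <- function(net4) {
  stopifnot(inherits(net4, "QuadNetwork"), net4$version == "4.0")
  sort(unique(c(net4$chains$receptor, net4$chains$tf, net4$chains$target)))
}

#' Compare two stage networks
#'
#' Exact partition of the union of two Network 4.0 chain sets into shared,
#' a-specific and b-specific chains (keyed on the full quadruple), plus a
#' per-gene direction table merging the receiver-side DE signs of each
#' stage (conflicting within-network signs are reported as "mixed").
#'
#' @param net4_a,net4_b Network 4.0 objects with identical sender and
#'   receiver types.
#' @return list: shared, a_specific, b_specific (chain data.frames),
#'   directions (data.frame gene, direction_a, direction_b).
#' @export
compare_stage_networks <- function(net4_a, net4_b) {
  stopifnot(inherits(net4_a, "QuadNetwork"), inherits(net4_b, "QuadNetwork"),
            net4_a$version == "4.0", net4_b$version == "4.0")
  if (net4_a$sender != net4_b$sender ||
      net4_a$receiver != net4_b$receiver) {
    stop("networks have mismatched sender/receiver cell types",
         call. = FALSE)
  }
  ka <- chain_key(net4_a$chains)
  kb <- chain_key(net4_b$chains)
  gene_dirs <- function(net) {
    ch <- net$chains
    g <- c(ch$receptor, ch$tf, ch$target)
    d <- rep(ch$direction, 3L)
    vapply(split(d, g), function(x) {
      u <- unique(x)
      if (length(u) == 1L) u else "mixed"
    }, character(1L))
  }
  da <- gene_dirs(net4_a); db <- gene_dirs(net4_b)
  genes <- sort(union(names(da), names(db)))
  list(shared = net4_a$chains[ka %in% kb, , drop = FALSE],
       a_specific = net4_a$chains[!ka %in% kb, , drop = FALSE],
       b_specific = net4_b$chains[!kb %in% ka, , drop = FALSE],
       directions = data.frame(gene = genes,
                               direction_a = unname(da[genes]),
                               direction_b = unname(db[genes]),
                               stringsAsFactors = FALSE))
}

#' Serialize / deserialize a quad network
#'
#' JSON is the canonical format (keys sorted, full chain table); the TSV
#' export is a flat edge list (stage, version, role_src, src, role_dst,
#' dst, weight, flags) convenient for spreadsheets.  JSON round-trips are
#' lossless.
#'
#' @param net a `QuadNetwork`.
#' @param path file path.
#' @return the path, invisibly (writers); a `QuadNetwork` (reader).
#' @export
write_quad_network <- function(net, path) {
  stopifnot(inherits(net, "QuadNetwork"))
  obj <- unclass(net)
  obj <- obj[sort(names(obj))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_quad_network
#' @export
read_quad_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- as.data.frame(obj$chains, stringsAsFactors = FALSE)
  if (nrow(ch) == 0L) {
    ch <- data.frame(ligand = character(0), receptor = character(0),
                     tf = character(0), target = character(0),
                     weight = numeric(0))
  }
  net <- quad_network(ch, obj$version, obj$condition_reference,
                      obj$condition_oi, obj$sender, obj$receiver)
  if (nrow(net$chains) > 0L && !is.null(obj$chains$lr_verified)) {
    ord <- order(obj$chains$ligand, obj$chains$receptor, obj$chains$tf,
                 obj$chains$target)
    net$chains$lr_verified <- obj$chains$lr_verified[ord]
    net$chains$tf_verified <- obj$chains$tf_verified[ord]
    net$chains$deg_passed <- obj$chains$deg_passed[ord]
    net$chains$direction <- obj$chains$direction[ord]
  }
  net
}

#' @rdname write_quad_network
#' @param stage label written into the TSV `stage` column (defaults to the
#'   condition of interest).
#' @export
write_quad_network_tsv <- function(net, path, stage = net$condition_oi) {
  stopifnot(inherits(net, "QuadNetwork"))
  ch <- net$chains
  flags <- paste0(ifelse(ch$lr_verified, "L", ""),
                  ifelse(ch$tf_verified, "T", ""),
                  ifelse(ch$deg_passed, "D", ""))
  n <- nrow(ch)
  edge_rows <- function(role_src, src, role_dst, dst) {
    data.frame(stage = rep(stage, n), version = rep(net$version, n),
               role_src = rep(role_src, n), src = src,
               role_dst = rep(role_dst, n), dst = dst,
               weight = ch$weight, flags = flags, stringsAsFactors = FALSE)
  }
  out <- rbind(edge_rows("ligand", ch$ligand, "receptor", ch$receptor),
               edge_rows("receptor", ch$receptor, "tf", ch$tf),
               edge_rows("tf", ch$tf, "target", ch$target))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
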