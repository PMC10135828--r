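#' Planted ground-truth signaling cascades
#'
#' A `PlantedTruth` records which ligand -> receptor -> TF -> target-set
#' cascades the count simulator will activate, in which conditions, and at
#' what multiplicative effect size.  It is the oracle against which network
#' recovery is scored in tests; it is never an input to the inference
#' pipeline itself.
#'
#' @name PlantedTruth
NULL

# all (ligand, receptor, tf) triples realizable in the prior:
# an lr edge L->R plus a signaling-layer path R ->...-> TF
enumerate_lr_tf <- function(prior) {
  e <- prior$edges
  lr <- e[e$layer == "lr", , drop = FALSE]
  sg <- e[e$layer == "signaling", , drop = FALSE]
  tfs <- prior_genes_by_role(prior, "tf")
  adj <- split(sg$to, sg$from)
  reach_tfs <- function(r) {
    seen <- character(0); frontier <- r
    while (length(frontier) > 0L) {
      seen <- c(seen, frontier)
      frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    }
    intersect(seen, tfs)
  }
  out <- list()
  for (i in seq_len(nrow(lr))) {
    for (tf in reach_tfs(lr$to[i])) {
      out[[length(out) + 1L]] <- c(ligand = lr$from[i],
                                   receptor = lr$to[i], tf = tf)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ligand = character(0), receptor = character(0),
                      tf = character(0)))
  }
  as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
}

#' Sample planted cascades from a prior network
#'
#' Cascades are distinct `(ligand, receptor, tf)` paths sampled without
#' replacement from all paths realizable in `prior`; the target set of a
#' cascade is every gene the TF regulates in the `gene_regulatory` layer.
#' Each cascade is assigned the conditions in which it is active according
#' to `active_map`.
#'
#' @param prior a [prior_network()].
#' @param n_cascades number of cascades to plant (0 gives an empty truth).
#' @param effect_log2fc positive log2 fold change applied by the simulator
#'   to the cascade genes in active conditions.
#' @param active_map per-cascade active conditions: a character vector
#'   (recycled) whose elements are comma-separated condition names or the
#'   keyword `"shared"` (all three stages), or a list of character vectors.
#' @param identifiable when TRUE, cascades are additionally required to be
#'   uniquely recoverable from expression data: gene-disjoint (distinct
#'   ligands, receptors, TFs), structurally unambiguous — each cascade TF
#'   is reachable from exactly one ligand of the prior, through exactly
#'   one receptor — and with target sets restricted to genes regulated by
#'   no other TF.  Without these constraints, cascades sharing genes
#'   across stages cancel each other's differential expression, and
#'   alternate-receptor, cross-cascade or shared-target routes create
#'   "phantom" signals every gene of which is genuinely perturbed, so no
#'   expression-based method can distinguish them from the planted truth.
#'   Enable for recovery benchmarking; the default is unconstrained path
#'   sampling.
#' @param seed integer seed.
#' @return an object of class `PlantedTruth` with elements `cascades`
#'   (list of `list(ligand, receptor, tf, targets)`), `active_conditions`,
#'   `effect_log2fc` and `seed`.
#' @export
generate_truth <- function(prior, n_cascades, effect_log2fc = 2,
                           active_map = "tLung", identifiable = FALSE,
                           seed = 1L) {
  stopifnot(inherits(prior, "PriorNetwork"), n_cascades >= 0)
  assert_that(effect_log2fc > 0, "effect_log2fc must be positive")
  paths <- enumerate_lr_tf(prior)
  gr <- prior$edges[prior$edges$layer == "gene_regulatory", , drop = FALSE]
  # only TFs with at least one target can anchor a full quad-chain
  paths <- paths[paths$tf %in% gr$from, , drop = FALSE]
  tf_per_gene <- tapply(gr$from, gr$to, function(x) length(unique(x)))
  if (n_cascades > nrow(paths)) {
    stop(sprintf(paste0("requested %d cascades but the prior only contains ",
                        "%d distinct ligand->receptor->tf paths with targets ",
                        "(deficit %d)"),
                 n_cascades, nrow(paths), n_cascades - nrow(paths)),
         call. = FALSE)
  }
  act <- normalize_active_map(active_map, n_cascades)
  cascades <- list()
  if (n_cascades > 0L) {
    idx <- with_seed(seed, {
      if (identifiable) {
        # admissible paths: a dedicated signaling axis.  The TF is reached
        # by exactly one ligand of the whole prior through exactly one
        # receptor; the ligand's single lr edge and the receptor's single
        # signaling out-edge lie on the planted path (so the ligand's
        # diffusion mass actually flows to its cascade); and the TF
        # regulates at least one gene no other TF regulates
        lig_per_tf <- tapply(paths$ligand, paths$tf,
                             function(x) length(unique(x)))
        rec_per_tf <- tapply(paths$receptor, paths$tf,
                             function(x) length(unique(x)))
        exclusive <- gr[tf_per_gene[gr$to] == 1, , drop = FALSE]
        e <- prior$edges
        lig_out <- table(e$from[e$layer == "lr"])
        rec_out <- table(e$from[e$layer == "signaling"])
        ok <- lig_per_tf[paths$tf] == 1 & rec_per_tf[paths$tf] == 1 &
              paths$tf %in% exclusive$from &
              lig_out[paths$ligand] == 1 & rec_out[paths$receptor] == 1
        cand <- which(ok)
        perm <- cand[sample.int(length(cand))]
        chosen <- integer(0)
        used <- character(0)
        for (i in perm) {
          genes_i <- unlist(paths[i, c("ligand", "receptor", "tf")])
          if (!any(genes_i %in% used)) {
            chosen <- c(chosen, i)
            used <- c(used, genes_i)
            if (length(chosen) == n_cascades) break
          }
        }
        if (length(chosen) < n_cascades) {
          stop(sprintf(paste0("could only plant %d of %d requested ",
                              "identifiable cascades"),
                       length(chosen), n_cascades), call. = FALSE)
        }
        chosen
      } else {
        sample.int(nrow(paths), n_cascades)
      }
    })
    cascades <- lapply(idx, function(i) {
      tgts <- gr$to[gr$from == paths$tf[i]]
      if (identifiable) tgts <- tgts[tf_per_gene[tgts] == 1]
      list(ligand = paths$ligand[i], receptor = paths$receptor[i],
           tf = paths$tf[i], targets = sort(tgts))
    })
  }
  structure(list(cascades = cascades, active_conditions = act,
                 effect_log2fc = effect_log2fc, seed = as.integer(seed)),
            class = "PlantedTruth")
}

normalize_active_map <- function(active_map, n) {
  if (n == 0L) return(list())
  if (is.character(active_map)) {
    active_map <- rep_len(active_map, n)
    active_map <- lapply(active_map, function(s) {
      if (identical(s, "shared")) CONDITIONS
      else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  stopifnot(is.list(active_map))
  active_map <- rep_len(active_map, n)
  lapply(active_map, check_conditions)
}

#' @export
print.PlantedTruth <- function(x, ...) {
  cat("PlantedTruth:", length(x$cascades), "cascade(s), effect_log2fc =",
      x$effect_log2fc, "\n")
  for (i in seq_along(x$cascades)) {
    cs <- x$cascades[[i]]
    cat(sprintf("  %s -> %s -> %s -> {%s}  [%s]\n", cs$ligand, cs$receptor,
                cs$tf, paste(cs$targets, collapse = ","),
                paste(x$active_conditions[[i]], collapse = ",")))
  }
  invisible(x)
}

#' True quad-chains of a planted truth
#'
#' Expands each cascade into its `(ligand, receptor, tf, target)` rows,
#' optionally restricted to cascades whose activity differs between two
#' conditions (i.e. those detectable in that stage-pair network).
#'
#' @param truth a `PlantedTruth`.
#' @param condition_reference,condition_oi optional stage pair; when given,
#'   only cascades active in exactly one of the two conditions are
#'   expanded.
#' @return data.frame with columns ligand, receptor, tf, target.
#' @export
truth_chains <- function(truth, condition_reference = NULL,
                         condition_oi = NULL) {
  stopifnot(inherits(truth, "PlantedTruth"))
  keep <- seq_along(truth$cascades)
  if (!is.null(condition_reference) && !is.null(condition_oi)) {
    keep <- which(vapply(truth$active_conditions, function(a) {
      xor(condition_reference %in% a, condition_oi %in% a)
    }, logical(1L)))
  }
  rows <- lapply(keep, function(i) {
    cs <- truth$cascades[[i]]
    data.frame(ligand = cs$ligand, receptor = cs$receptor, tf = cs$tf,
               target = cs$targets, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(ligand = character(0), receptor = character(0),
                      tf = character(0), target = character(0)))
  }
  unique(do.call(rbind, rows))
}

#' Serialize a planted truth to JSON
#' @param truth a `PlantedTruth`.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
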