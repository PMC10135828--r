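#' Ligand-receptor interaction means
#'
#' For each candidate ligand-receptor pair, the interaction score is the
#' arithmetic mean of the ligand's average normalized expression in the
#' sender cluster and the receptor's average in the receiver cluster.
#' Following the both-expressed convention, the mean is set to 0 when
#' either cluster average is 0.  Pairs are `retained` when the mean is
#' strictly positive.
#'
#' @param normed normalized matrix from [normalize_log1p()].
#' @param cells cell annotation (cell_id, cell_type).
#' @param pairs data.frame with columns `ligand` and `receptor`; pairs
#'   whose genes are absent from the matrix are dropped with a warning.
#' @param sender,receiver cell-type labels.
#' @return data.frame (class `InteractionScores`): ligand, receptor,
#'   sender, receiver, mean, retained.
#' @export
interaction_means <- function(normed, cells, pairs, sender, receiver) {
  stopifnot(all(c("ligand", "receptor") %in% names(pairs)))
  snd <- cells$cell_id[cells$cell_type == sender]
  rcv <- cells$cell_id[cells$cell_type == receiver]
  if (length(snd) == 0L) stop("no cells of sender type '", sender, "'",
                              call. = FALSE)
  if (length(rcv) == 0L) stop("no cells of receiver type '", receiver, "'",
                              call. = FALSE)
  present <- pairs$ligand %in% rownames(normed) &
             pairs$receptor %in% rownames(normed)
  if (any(!present)) {
    warning("dropping ", sum(!present),
            " pair(s) with genes absent from the matrix", call. = FALSE)
    pairs <- pairs[present, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no testable ligand-receptor pairs",
                              call. = FALSE)
  ml <- Matrix::rowMeans(normed[pairs$ligand, snd, drop = FALSE])
  mr <- Matrix::rowMeans(normed[pairs$receptor, rcv, drop = FALSE])
  mean_score <- ifelse(ml == 0 | mr == 0, 0, (ml + mr) / 2)
  out <- data.frame(ligand = pairs$ligand, receptor = pairs$receptor,
                    sender = sender, receiver = receiver,
                    mean = as.numeric(mean_score),
                    retained = as.numeric(mean_score) > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("InteractionScores", "data.frame")
  out
}

#' Permutation test for ligand-receptor interactions
#'
#' Cell-type labels are shuffled jointly among the sender + receiver cells
#' (the smallest exchangeable set), the interaction mean is recomputed for
#' every pair, and the empirical upper-tail p-value is
#' `(1 + #\{permuted mean >= observed\}) / (1 + n_perm)`, so p is never
#' exactly 0.  Retention still follows the strict `mean > 0` rule; p is
#' carried as metadata.
#'
#' @inheritParams interaction_means
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return an `InteractionScores` data.frame with an extra `p` column.
#' @export
permutation_test <- function(normed, cells, pairs, sender, receiver,
                             n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 100)
  obs <- interaction_means(normed, cells, pairs, sender, receiver)
  pool <- cells[cells$cell_type %in% c(sender, receiver), , drop = FALSE]
  n_snd <- sum(pool$cell_type == sender)
  n_rcv <- sum(pool$cell_type == receiver)
  if (n_snd < 2L || n_rcv < 2L) {
    stop("need at least 2 cells per type in the shuffle pool", call. = FALSE)
  }
  genes <- unique(c(obs$ligand, obs$receptor))
  x <- as.matrix(normed[genes, pool$cell_id, drop = FALSE])
  li <- match(obs$ligand, genes)
  ri <- match(obs$receptor, genes)
  n_pool <- nrow(pool)
  count_ge <- numeric(nrow(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      snd_idx <- sample.int(n_pool, n_snd)
      rcv_idx <- setdiff(seq_len(n_pool), snd_idx)[seq_len(n_rcv)]
      ml <- rowMeans(x[, snd_idx, drop = FALSE])[li]
      mr <- rowMeans(x[, rcv_idx, drop = FALSE])[ri]
      perm_mean <- ifelse(ml == 0 | mr == 0, 0, (ml + mr) / 2)
      count_ge <- count_ge + (perm_mean >= obs$mean)
    }
  })
  obs$p <- (1 + count_ge) / (1 + n_perm)
  obs
}
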