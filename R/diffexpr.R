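#' Benjamini-Hochberg step-up adjustment
#'
#' Native implementation of the BH step-up procedure: sorted p-values are
#' scaled by `n / rank`, running minima are taken from the largest rank
#' down, results are capped at 1 and returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Wilcoxon rank-sum differential expression
#'
#' Marker-style two-group testing on normalized expression: per gene, a
#' two-sided Wilcoxon rank-sum test using the normal approximation with
#' tie correction and continuity correction.  Genes expressed in fewer
#' than `min_pct` of cells in both groups, or with
#' `|log2fc| < min_abs_log2fc`, are excluded before testing; BH adjustment
#' is applied to the tested set only.  `log2fc` is computed on the mean
#' de-logged (expm1) expression scale with pseudocount 1, group of
#' interest over reference.
#'
#' @param normed normalized matrix from [normalize_log1p()].
#' @param cells_interest,cells_reference disjoint character vectors of cell
#'   ids (each of length >= 3).
#' @param min_pct minimum expressing fraction (default 0.1).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 0.25).
#' @return data.frame (class `DEGTable`): gene, log2fc, p, p_adj, pct_in,
#'   pct_ref, direction; ordered by p.
#' @export
rank_sum_deg <- function(normed, cells_interest, cells_reference,
                         min_pct = 0.1, min_abs_log2fc = 0.25) {
  stopifnot(all(cells_interest %in% colnames(normed)),
            all(cells_reference %in% colnames(normed)))
  if (length(intersect(cells_interest, cells_reference)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(cells_interest) < 3L || length(cells_reference) < 3L) {
    stop("both groups need at least 3 cells", call. = FALSE)
  }
  xa <- normed[, cells_interest, drop = FALSE]
  xb <- normed[, cells_reference, drop = FALSE]
  pct_in <- Matrix::rowMeans(xa > 0)
  pct_ref <- Matrix::rowMeans(xb > 0)
  log2fc <- log2((Matrix::rowMeans(expm1(xa)) + 1) /
                 (Matrix::rowMeans(expm1(xb)) + 1))
  keep <- (pct_in >= min_pct | pct_ref >= min_pct) &
          abs(log2fc) >= min_abs_log2fc
  genes <- rownames(normed)[keep]
  if (length(genes) == 0L) {
    out <- data.frame(gene = character(0), log2fc = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      pct_in = numeric(0), pct_ref = numeric(0),
                      direction = character(0))
    class(out) <- c("DEGTable", "data.frame")
    return(out)
  }
  na <- length(cells_interest); nb <- length(cells_reference)
  xa <- as.matrix(xa[genes, , drop = FALSE])
  xb <- as.matrix(xb[genes, , drop = FALSE])
  p <- vapply(seq_along(genes), function(i) {
    wilcox_p(xa[i, ], xb[i, ], na, nb)
  }, numeric(1L))
  out <- data.frame(gene = genes, log2fc = log2fc[keep], p = p,
                    p_adj = bh_adjust(p), pct_in = pct_in[keep],
                    pct_ref = pct_ref[keep],
                    direction = ifelse(log2fc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("DEGTable", "data.frame")
  out
}

# two-sided rank-sum p, normal approximation, tie + continuity correction
wilcox_p <- function(a, b, na, nb) {
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2  # Mann-Whitney U for group a
  n <- na + nb
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - na * nb / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of the overlap
#' between a query gene set and each collection set, within a stated
#' background universe; BH adjustment across sets.  Sets are intersected
#' with the background before testing.
#'
#' @param query character vector of genes (must lie in `background`).
#' @param collections named list of character vectors.
#' @param background character vector, the gene universe.
#' @return data.frame (class `EnrichmentTable`): set_id, overlap, set_size,
#'   query_size, background, p, p_adj.
#' @export
hypergeom_enrich <- function(query, collections, background) {
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  background <- unique(background)
  query <- unique(query)
  assert_that(all(query %in% background), "query genes must be in background")
  assert_that(length(collections) > 0 && !is.null(names(collections)),
              "collections must be a non-empty named list")
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(names(collections), function(id) {
    s <- intersect(unique(collections[[id]]), background)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), n_bg - length(s), n_q,
                       lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = length(s),
               query_size = n_q, background = n_bg, p = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_id), ]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}
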