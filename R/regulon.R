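#' TF-to-target co-expression importance
#'
#' Quantifies, within the receiver cell population, how strongly each TF's
#' expression predicts each candidate target's expression.  Two methods:
#'
#' * `correlation` (default, deterministic): absolute Spearman rank
#'   correlation per (TF, target) pair.
#' * `tree_ensemble`: per-target gradient-boosted regression stumps over
#'   all TF predictors; a TF's importance is its share of the total
#'   squared-error reduction, normalized per target.  Stochastic
#'   (row subsampling), reproducible under `seed`.
#'
#' A constant TF has importance 0 for every target, and a gene paired
#' with itself is excluded (importance 0).
#'
#' @param normed normalized matrix restricted to receiver cells
#'   (genes x cells; >= 20 cells required).
#' @param tfs,targets character vectors of gene names present in `normed`.
#' @param method `"correlation"` or `"tree_ensemble"`.
#' @param seed integer seed (tree_ensemble only).
#' @param n_rounds,shrinkage,subsample boosting hyper-parameters.
#' @return numeric matrix, rows = TFs, cols = targets, non-negative.
#' @export
coexpression_importance <- function(normed, tfs, targets,
                                    method = c("correlation", "tree_ensemble"),
                                    seed = 1L, n_rounds = 50,
                                    shrinkage = 0.1, subsample = 0.8) {
  method <- match.arg(method)
  stopifnot(ncol(normed) >= 20)
  tfs <- intersect(tfs, rownames(normed))
  targets <- intersect(targets, rownames(normed))
  assert_that(length(tfs) >= 1 && length(targets) >= 1,
              "tfs and targets must be present in the matrix")
  xt <- t(as.matrix(normed[tfs, , drop = FALSE]))      # cells x tfs
  yt <- t(as.matrix(normed[targets, , drop = FALSE]))  # cells x targets
  imp <- if (method == "correlation") {
    # constant genes yield NA (zero-sd warning) and are mapped to 0
    m <- abs(suppressWarnings(stats::cor(xt, yt, method = "spearman")))
    m[is.na(m)] <- 0
    m
  } else {
    with_seed(seed, boosted_stump_importance(xt, yt, n_rounds, shrinkage,
                                             subsample))
  }
  dimnames(imp) <- list(tfs, targets)
  for (g in intersect(tfs, targets)) imp[g, g] <- 0
  imp
}

# gradient boosting with depth-1 trees; importance = SSE reduction share
boosted_stump_importance <- function(x, y, n_rounds, shrinkage, subsample) {
  n <- nrow(x); p <- ncol(x)
  imp <- matrix(0, p, ncol(y))
  splits <- lapply(seq_len(p), function(j) {
    unique(stats::quantile(x[, j], probs = seq(0.1, 0.9, by = 0.1),
                           names = FALSE))
  })
  for (k in seq_len(ncol(y))) {
    resid <- y[, k] - mean(y[, k])
    for (b in seq_len(n_rounds)) {
      idx <- sample.int(n, max(2L, floor(subsample * n)))
      r <- resid[idx]
      base_sse <- sum((r - mean(r))^2)
      best <- list(gain = 0)
      for (j in seq_len(p)) {
        xj <- x[idx, j]
        for (s in splits[[j]]) {
          left <- xj <= s
          nl <- sum(left)
          if (nl == 0L || nl == length(r)) next
          ml <- mean(r[left]); mr <- mean(r[!left])
          sse <- sum((r[left] - ml)^2) + sum((r[!left] - mr)^2)
          gain <- base_sse - sse
          if (gain > best$gain) {
            best <- list(gain = gain, j = j, s = s, ml = ml, mr = mr)
          }
        }
      }
      if (best$gain <= 0) break
      imp[best$j, k] <- imp[best$j, k] + best$gain
      pred <- ifelse(x[, best$j] <= best$s, best$ml, best$mr)
      resid <- resid - shrinkage * pred
    }
    tot <- sum(imp[, k])
    if (tot > 0) imp[, k] <- imp[, k] / tot
  }
  imp
}

#' Assemble regulons from an importance matrix
#'
#' Per TF: targets with importance at least `min_importance` (and > 0),
#' truncated to the `top_k` most important; ties broken by gene name.
#' Empty regulons are allowed.
#'
#' @param importances matrix from [coexpression_importance()].
#' @param top_k maximum regulon size (default 50).
#' @param min_importance inclusion threshold (default 0.1, a weak-evidence
#'   floor on `|Spearman rho|`; no published value exists for this filter).
#' @return named list (class `Regulons`) mapping TF to a named numeric
#'   vector of target importances, sorted descending.
#' @export
build_regulons <- function(importances, top_k = 50, min_importance = 0.1) {
  stopifnot(is.matrix(importances), top_k >= 1)
  out <- lapply(rownames(importances), function(tf) {
    v <- importances[tf, ]
    v <- v[v >= min_importance & v > 0]
    if (length(v) == 0L) return(setNames(numeric(0), character(0)))
    v <- v[order(-v, names(v), method = "radix")]
    head(v, top_k)
  })
  names(out) <- rownames(importances)
  structure(out, class = "Regulons")
}

#' @export
print.Regulons <- function(x, ...) {
  sizes <- vapply(x, length, integer(1L))
  cat("Regulons:", length(x), "TF(s),", sum(sizes), "TF-target link(s)\n")
  invisible(x)
}

#' Write regulons as JSON
#' @param regulons a [build_regulons()] result.
#' @param path output file.
#' @export
write_regulons <- function(regulons, path) {
  jsonlite::write_json(lapply(unclass(regulons), as.list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
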