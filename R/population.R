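#' Per-patient cell-type proportions within a compartment
#'
#' For each patient (within each condition), the fraction of compartment
#' cells belonging to each compartment cell type.  Patients with zero
#' compartment cells in a condition are omitted with a warning.
#'
#' @param cells cell annotation data.frame (cell_type, condition, patient).
#' @param compartment character vector of cell types defining the
#'   denominator (e.g. the immune compartment); all must occur in `cells`.
#' @return data.frame (class `ProportionTable`): patient_id, condition,
#'   cell_type, fraction.  Fractions sum to 1 per (patient, condition).
#' @export
proportions_by_patient <- function(cells, compartment) {
  assert_that(length(compartment) > 0, "compartment must be non-empty")
  bad <- setdiff(compartment, unique(cells$cell_type))
  if (length(bad) > 0L) {
    stop("unknown cell type(s) in compartment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sub <- cells[cells$cell_type %in% compartment, , drop = FALSE]
  all_pc <- unique(cells[, c("patient", "condition")])
  have <- unique(sub[, c("patient", "condition")])
  missing <- !paste(all_pc$patient, all_pc$condition) %in%
              paste(have$patient, have$condition)
  if (any(missing)) {
    warning("omitting ", sum(missing),
            " patient/condition group(s) with zero compartment cells",
            call. = FALSE)
  }
  grp <- paste(sub$patient, sub$condition, sep = "\r")
  rows <- lapply(split(sub, grp), function(d) {
    tab <- table(factor(d$cell_type, levels = compartment))
    data.frame(patient_id = d$patient[1], condition = d$condition[1],
               cell_type = compartment,
               fraction = as.numeric(tab) / nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ProportionTable", "data.frame")
  out
}

#' Compare a cell type's proportion between two conditions
#'
#' Welch (unequal-variance) two-sample t-test on per-patient fractions,
#' with BH adjustment computed across all cell types present in the
#' proportion table.  With two patients per group the test is computed but
#' flagged as low-power.
#'
#' @param props a [proportions_by_patient()] table.
#' @param type cell type of interest.
#' @param cond_a,cond_b conditions to compare.
#' @return list: t, p, p_adj, n_a, n_b, low_power.
#' @export
compare_proportions <- function(props, type, cond_a, cond_b) {
  stopifnot(type %in% props$cell_type)
  types <- unique(props$cell_type)
  res <- lapply(types, function(ty) {
    a <- props$fraction[props$cell_type == ty & props$condition == cond_a]
    b <- props$fraction[props$cell_type == ty & props$condition == cond_b]
    if (length(a) < 2L || length(b) < 2L) {
      stop("need >= 2 patients per condition (cell type ", ty, ")",
           call. = FALSE)
    }
    welch_t(a, b)
  })
  p_adj <- bh_adjust(vapply(res, `[[`, numeric(1L), "p"))
  i <- match(type, types)
  c(res[[i]][c("t", "p", "n_a", "n_b", "low_power")],
    list(p_adj = p_adj[i]))
}

welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (t == 0) 1 else 0
    return(list(t = t, p = p, n_a = na, n_b = nb,
                low_power = na <= 2 || nb <= 2))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df), n_a = na, n_b = nb,
       low_power = na <= 2 || nb <= 2)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Native product-limit estimator per group and the standard two-group
#' log-rank test: at each distinct event time the observed minus expected
#' events in group 1 are accumulated with hypergeometric variance;
#' `chi2 = (sum(O - E))^2 / sum(V)`, p from the upper tail of chi-square
#' with 1 df.
#'
#' @param surv data.frame with columns patient_id, time (> 0), event (0/1).
#' @param groups named character vector mapping patient_id to a group
#'   label; exactly two distinct labels required.
#' @return list of class `KMResult`: `groups` (labels), `curves` (per
#'   group: data.frame time, n_risk, n_event, surv starting at S(0)=1),
#'   `logrank_chi2`, `p`.
#' @export
km_logrank <- function(surv, groups) {
  stopifnot(all(c("patient_id", "time", "event") %in% names(surv)),
            all(surv$time > 0), all(surv$event %in% c(0, 1)))
  g <- groups[surv$patient_id]
  if (any(is.na(g))) stop("group missing for some patients", call. = FALSE)
  labs <- sort(unique(g))
  if (length(labs) != 2L) stop("exactly two groups required", call. = FALSE)
  if (min(table(g)) < 2L) stop("both groups need >= 2 patients", call. = FALSE)
  if (sum(surv$event) < 1L) stop("at least one event required", call. = FALSE)

  curves <- lapply(labs, function(l) km_curve(surv[g == l, , drop = FALSE]))
  names(curves) <- labs

  ev_times <- sort(unique(surv$time[surv$event == 1]))
  o_minus_e <- 0; vsum <- 0
  for (tt in ev_times) {
    at1 <- sum(surv$time >= tt & g == labs[1])
    at2 <- sum(surv$time >= tt & g == labs[2])
    n <- at1 + at2
    d <- sum(surv$time == tt & surv$event == 1)
    d1 <- sum(surv$time == tt & surv$event == 1 & g == labs[1])
    o_minus_e <- o_minus_e + d1 - d * at1 / n
    if (n > 1) vsum <- vsum + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (vsum > 0) o_minus_e^2 / vsum else 0
  p <- if (vsum > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  structure(list(groups = labs, curves = curves, logrank_chi2 = chi2, p = p),
            class = "KMResult")
}

km_curve <- function(d) {
  tt <- sort(unique(d$time[d$event == 1]))
  n_risk <- vapply(tt, function(x) sum(d$time >= x), numeric(1L))
  n_event <- vapply(tt, function(x) sum(d$time == x & d$event == 1),
                    numeric(1L))
  s <- cumprod(1 - n_event / n_risk)
  data.frame(time = c(0, tt), n_risk = c(nrow(d), n_risk),
             n_event = c(0, n_event), surv = c(1, s))
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every admissible biomarker cutoff (midpoints between consecutive
#' distinct values, keeping both groups at least `minprop * n` patients)
#' and returns the cutoff maximizing the two-group log-rank statistic.
#' The reported p-value is the naive log-rank p at the selected cutoff and
#' is selection-biased (flagged, not corrected).
#'
#' @param surv data.frame with patient_id, time, event and a biomarker
#'   column.
#' @param biomarker name of the biomarker column (default "biomarker").
#' @param minprop minimum group-size fraction (default 0.1).
#' @return list: cutoff, chi2, p, selection_biased = TRUE.
#' @export
optimal_cutpoint <- function(surv, biomarker = "biomarker", minprop = 0.1) {
  b <- surv[[biomarker]]
  stopifnot(!is.null(b), length(unique(b)) >= 3L)
  n <- nrow(surv)
  vals <- sort(unique(b))
  cand <- (vals[-1] + vals[-length(vals)]) / 2
  min_n <- minprop * n
  best <- NULL
  for (ct in cand) {
    hi <- b > ct
    if (sum(hi) < min_n || sum(!hi) < min_n) next
    g <- setNames(ifelse(hi, "high", "low"), surv$patient_id)
    if (min(table(g)) < 2L) next
    km <- km_logrank(surv, g)
    if (is.null(best) || km$logrank_chi2 > best$chi2) {
      best <- list(cutoff = ct, chi2 = km$logrank_chi2, p = km$p,
                   selection_biased = TRUE)
    }
  }
  if (is.null(best)) stop("no admissible cutoff at minprop = ", minprop,
                          call. = FALSE)
  best
}
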