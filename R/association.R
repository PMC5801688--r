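## Intra-association statistics: mutation-dependent threshold, 2x2
## contingency table, phi coefficient, chi-squared statistic and p-value,
## and Benjamini-Hochberg step-up control.

#' Mutation-dependent logIC50 threshold for one drug-gene association
#'
#' Characterises each group of cell lines (mutant and wild-type) by its
#' median logIC50 and places the decision boundary midway between the two
#' medians. Medians are robust to the skew and outliers typical of drug
#' response distributions, and the midpoint is equidistant to both groups
#' regardless of their sizes. If the mutant median is lower, mutants tend
#' to respond at lower concentrations and the association is a
#' *sensitivity* marker; otherwise (including the exact tie, which is
#' flagged degenerate) it is a *resistance* marker.
#'
#' @param responses numeric vector of logIC50 values (log10 uM).
#' @param flags binary vector (same length): 1 = mutated, 0 = wild-type.
#' @return a list of class `assoc_threshold`: `med_mt`, `med_wt`, `thres`
#'   (= their mean), `direction` (`"sensitivity"` or `"resistance"`), and
#'   `degenerate` (`TRUE` when the medians tie exactly).
#' @examples
#' compute_threshold(c(-2, -2, 0, 0), c(1, 1, 0, 0))
#' @export
compute_threshold <- function(responses, flags) {
  .check_assoc_data(responses, flags)
  med_mt <- stats::median(responses[flags == 1])
  med_wt <- stats::median(responses[flags == 0])
  structure(list(
    med_mt = med_mt, med_wt = med_wt,
    thres = (med_mt + med_wt) / 2,
    direction = if (med_mt < med_wt) "sensitivity" else "resistance",
    degenerate = med_mt == med_wt
  ), class = "assoc_threshold")
}

.check_assoc_data <- function(responses, flags) {
  if (length(responses) != length(flags))
    stop("'responses' and 'flags' must have the same length")
  if (length(responses) < 2)
    stop("an association needs at least two cell lines")
  if (any(!is.finite(responses)))
    stop("all responses must be finite")
  if (!all(flags %in% c(0, 1)))
    stop("'flags' must be binary (0 = wild-type, 1 = mutated)")
  if (sum(flags == 1) == 0 || sum(flags == 0) == 0)
    stop("association needs at least one mutated and one wild-type cell line")
  invisible(TRUE)
}

#' Contingency table of mutation status against threshold side
#'
#' Cross-classifies cell lines by mutation status (the prediction: mutated
#' cells are predicted positive) against which side of the threshold their
#' response falls (the observation). For a sensitivity marker, observed
#' positives are cells with logIC50 strictly below the threshold; for a
#' resistance marker the roles swap and observed positives are cells with
#' logIC50 at or above it. Ties at the threshold always fall on the `>=`
#' side.
#'
#' @inheritParams compute_threshold
#' @param thres an `assoc_threshold` from [compute_threshold()] computed on
#'   the same data.
#' @return a list of class `contingency2x2` with integer counts `tp`, `fn`,
#'   `fp`, `tn` (`tp` = mutated and observed positive, `fp` = mutated and
#'   observed negative, `fn` = wild-type and observed positive, `tn` =
#'   wild-type and observed negative) and `n = tp + fn + fp + tn`.
#' @export
build_contingency <- function(responses, flags, thres) {
  .check_assoc_data(responses, flags)
  stopifnot(inherits(thres, "assoc_threshold"))
  below <- responses < thres$thres
  obs_pos <- if (thres$direction == "sensitivity") below else !below
  mut <- flags == 1
  contingency2x2(tp = sum(mut & obs_pos), fn = sum(!mut & obs_pos),
                 fp = sum(mut & !obs_pos), tn = sum(!mut & !obs_pos))
}

#' @rdname build_contingency
#' @param tp,fn,fp,tn non-negative integer counts.
#' @export
contingency2x2 <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 n = as.integer(tp + fn + fp + tn)),
            class = "contingency2x2")
}

#' Phi coefficient (Matthews correlation coefficient) of a 2x2 table
#'
#' `phi = (TP*TN - FP*FN) / sqrt((TP+FN)(FN+TN)(TN+FP)(FP+TP))`. phi and
#' the MCC are the same statistic; this package reports it as phi when the
#' mutation-dependent threshold on training data is used (discrimination)
#' and as MCC on held-out test sets (prediction). For tables built by
#' [build_contingency()] with distinct group medians, the value lies in
#' [0, 1].
#'
#' @param tab a `contingency2x2`.
#' @return phi in [-1, 1].
#' @examples
#' phi_coefficient(contingency2x2(tp = 8, fn = 2, fp = 2, tn = 8))  # 0.6
#' @export
phi_coefficient <- function(tab) {
  stopifnot(inherits(tab, "contingency2x2"))
  with(tab, {
    marg <- c(tp + fn, fn + tn, tn + fp, fp + tp)
    if (any(marg == 0))
      stop("phi is undefined: a contingency-table marginal is zero")
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(prod(as.numeric(marg)))
  })
}

#' Pearson chi-squared statistic of a 2x2 table
#'
#' Computed as the sum of `(O - E)^2 / E` over the four cells, with
#' expected counts from the product of the marginals (e.g.
#' `E(TP) = PP * OP / n` where PP = predicted positives = mutated cells and
#' OP = observed positives). No continuity correction is applied, so the
#' identity `chi2 = n * phi^2` holds exactly.
#'
#' @param tab a `contingency2x2` with all marginals positive.
#' @return chi-squared statistic (>= 0).
#' @examples
#' chi2_statistic(contingency2x2(tp = 8, fn = 2, fp = 2, tn = 8))  # 7.2
#' @export
chi2_statistic <- function(tab) {
  stopifnot(inherits(tab, "contingency2x2"))
  with(tab, {
    o <- c(tp, fn, fp, tn)
    pp <- tp + fp; pn <- fn + tn; op <- tp + fn; on <- fp + tn
    e <- c(pp * op, pn * op, pp * on, pn * on) / n
    if (any(e == 0))
      stop("chi-squared is undefined: an expected count is zero")
    sum((o - e)^2 / e)
  })
}

#' Upper-tail p-value of the chi-squared statistic (df = 1)
#'
#' The 2x2 statistic follows a chi-squared distribution with one degree of
#' freedom under the null of no association. The survival function is
#' evaluated directly (not via 1 - CDF), so extremely discriminative
#' associations keep representable p-values down to ~1e-300.
#'
#' @param chi2 numeric vector of chi-squared statistics (>= 0).
#' @return upper-tail p-values in (0, 1].
#' @examples
#' chi2_pvalue(284 * 0.65^2)  # ~6.4e-28
#' @export
chi2_pvalue <- function(chi2) {
  if (any(!is.finite(chi2)) || any(chi2 < 0))
    stop("'chi2' must be finite and non-negative")
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up significance calls
#'
#' Standard step-up procedure controlling the false discovery rate at
#' level `q`: sort the m p-values ascending, find the largest rank i with
#' `p(i) <= i*q/m`, and call significant every p-value at or below that
#' critical p-value. When no rank qualifies, nothing is significant and
#' the critical value is `NA`.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param q FDR level in (0, 1). Defaults to 0.20.
#' @param strict use `p < critical` instead of `p <= critical` when
#'   flagging (the step-up search itself always uses `<=`).
#' @return list with `significant` (logical mask, same order as input),
#'   `critical` (the critical p-value, NA if none), and `n_significant`.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.5), q = 0.2)  # 3 significant, critical 0.02
#' @export
bh_fdr <- function(pvalues, q = 0.20, strict = FALSE) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1)
    stop("'q' must be a single value in (0, 1)")
  m <- length(pvalues)
  sp <- sort(pvalues)
  ok <- which(sp <= seq_len(m) * q / m)
  if (length(ok) == 0) {
    return(list(significant = rep(FALSE, m), critical = NA_real_,
                n_significant = 0L))
  }
  crit <- sp[max(ok)]
  mask <- if (strict) pvalues < crit else pvalues <= crit
  list(significant = mask, critical = crit, n_significant = sum(mask))
}

#' Minimal phi reaching significance at a given sample size
#'
#' Inverts the identity `chi2 = n * phi^2`: any association evaluated on
#' `n` cell lines with `phi >= sqrt(chi2_crit / n)` has a chi-squared
#' p-value at or below `critical_p`, where `chi2_crit` is the df = 1
#' quantile with upper-tail probability `critical_p`. Useful to read
#' significance directly off a phi value: e.g. at the FDR = 20% critical
#' p-value 0.00940155, phi >= 0.15 suffices for drugs screened on ~300
#' cell lines and phi >= 0.12 for ~450.
#'
#' @param n number of cell lines (vectorised).
#' @param critical_p the significance threshold on the p-value scale.
#' @return minimal significant phi (same length as `n`).
#' @examples
#' phi_significance_cutoff(c(300, 450), 0.00940155)  # ~0.15, ~0.12
#' @export
phi_significance_cutoff <- function(n, critical_p) {
  if (any(n < 2)) stop("'n' must be >= 2")
  if (critical_p <= 0 || critical_p >= 1)
    stop("'critical_p' must lie in (0, 1)")
  sqrt(stats::qchisq(critical_p, df = 1, lower.tail = FALSE) / n)
}

#' Score a single drug-gene association
#'
#' Convenience wrapper running the full intra-association pipeline:
#' threshold, contingency table, phi, chi-squared and p-value.
#'
#' @inheritParams compute_threshold
#' @return list with `threshold`, `table`, `phi`, `chi2`, `p`.
#' @export
association_test <- function(responses, flags) {
  thr <- compute_threshold(responses, flags)
  tab <- build_contingency(responses, flags, thr)
  phi <- phi_coefficient(tab)
  chi2 <- chi2_statistic(tab)
  list(threshold = thr, table = tab, phi = phi, chi2 = chi2,
       p = chi2_pvalue(chi2))
}

#' @export
print.assoc_threshold <- function(x, ...) {
  cat(sprintf("logIC50 threshold %.4f (mutant median %.4f, wild-type median %.4f): %s marker%s\n",
              x$thres, x$med_mt, x$med_wt, x$direction,
              if (x$degenerate) " [degenerate tie]" else ""))
  invisible(x)
}

#' @export
print.contingency2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("mutated", "wild-type"),
                              c("obs.positive", "obs.negative")))
  print(m)
  invisible(x)
}
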