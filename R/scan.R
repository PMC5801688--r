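## Panel-wide discovery scan and the marker_scan S3 class.

#' Scan a drug-response panel for discriminative genomic markers
#'
#' The central fitting function. For every (drug, feature) pair with at
#' least one mutated and one wild-type cell line among the drug's tested
#' cells, the association is scored as an intra-association binary
#' classification problem: a mutation-dependent logIC50 threshold (mean of
#' the mutant and wild-type median responses, [compute_threshold()])
#' defines observed positives, mutation status is the prediction, and the
#' resulting 2x2 table yields the phi coefficient, the chi-squared
#' statistic (`chi2 = n * phi^2`) and its df = 1 upper-tail p-value.
#' Benjamini-Hochberg step-up control at FDR level `q` is then applied
#' once, jointly over all scored associations. Pairs that cannot be scored
#' (drug untested, a group empty, fewer than two cells) are skipped and
#' listed with reasons.
#'
#' @param response a [response_panel] (cells x drugs, logIC50 in log10 uM).
#' @param mutation a [mutation_panel] (cells x features, 0/1/NA) sharing
#'   cell-line identifiers with `response`; cells are matched by name, so
#'   order is irrelevant.
#' @param q FDR level for the Benjamini-Hochberg adjustment (default 0.20).
#' @param strict passed to [bh_fdr()]: flag significance with strict `<`
#'   rather than `<=` at the critical p-value.
#' @return an object of class `marker_scan`, a list with:
#'   \describe{
#'     \item{results}{data frame, one row per scored association: `drug`,
#'       `feature`, `n`, `n_mut`, `prevalence`, `med_mt`, `med_wt`,
#'       `thres`, `direction`, `degenerate`, `tp`, `fn`, `fp`, `tn`,
#'       `phi`, `chi2`, `p`, `significant`.}
#'     \item{critical_p}{the BH critical p-value (NA if nothing is
#'       significant).}
#'     \item{q}{the FDR level used.}
#'     \item{skipped}{data frame of untestable pairs with reasons.}
#'     \item{response, mutation}{the input panels, retained so that
#'       `plot()` and downstream validation can reuse them.}
#'   }
#' @examples
#' sp <- synthetic_spec(n_cells = 120, n_drugs = 2, n_features = 10,
#'                      planted = data.frame(drug = "drug01",
#'                                           feature = "gene01",
#'                                           delta = -2),
#'                      seed = 7)
#' panel <- simulate_panel(sp)
#' fit <- marker_scan(panel$response, panel$mutation, q = 0.2)
#' summary(fit)
#' @seealso [validate_markers()] for held-out validation,
#'   [consensus_calls()] for intersecting with an external p-value set.
#' @export
marker_scan <- function(response, mutation, q = 0.20, strict = FALSE) {
  stopifnot(inherits(response, "response_panel"),
            inherits(mutation, "mutation_panel"))
  common <- intersect(rownames(response), rownames(mutation))
  if (length(common) == 0)
    stop("response and mutation panels share no cell lines")
  resp <- unclass(response)[common, , drop = FALSE]
  mut <- unclass(mutation)[common, , drop = FALSE]

  drugs <- colnames(resp); feats <- colnames(mut)
  rows <- vector("list", length(drugs) * length(feats))
  skip <- vector("list", length(rows))
  k <- 0L
  for (d in drugs) {
    rv <- resp[, d]
    tested <- !is.na(rv)
    for (f in feats) {
      k <- k + 1L
      fl <- mut[tested, f]
      use <- !is.na(fl)
      y <- rv[tested][use]
      x <- fl[use]
      n <- length(y)
      reason <- if (n < 2) "fewer than two usable cell lines"
        else if (sum(x == 1) == 0) "no mutated cell line among tested cells"
        else if (sum(x == 0) == 0) "no wild-type cell line among tested cells"
        else NA_character_
      if (!is.na(reason)) {
        skip[[k]] <- data.frame(drug = d, feature = f, reason = reason,
                                stringsAsFactors = FALSE)
        next
      }
      thr <- compute_threshold(y, x)
      tab <- build_contingency(y, x, thr)
      phi <- phi_coefficient(tab)
      chi2 <- chi2_statistic(tab)
      rows[[k]] <- data.frame(
        drug = d, feature = f, n = n, n_mut = sum(x == 1),
        prevalence = sum(x == 1) / n,
        med_mt = thr$med_mt, med_wt = thr$med_wt, thres = thr$thres,
        direction = thr$direction, degenerate = thr$degenerate,
        tp = tab$tp, fn = tab$fn, fp = tab$fp, tn = tab$tn,
        phi = phi, chi2 = chi2, p = chi2_pvalue(chi2),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  skipped <- do.call(rbind, skip[!vapply(skip, is.null, logical(1))])
  if (is.null(skipped))
    skipped <- data.frame(drug = character(), feature = character(),
                          reason = character(), stringsAsFactors = FALSE)
  if (is.null(results) || nrow(results) == 0)
    stop("no testable drug-feature pair in the panel")

  bh <- bh_fdr(results$p, q = q, strict = strict)
  results$significant <- bh$significant
  structure(list(results = results, critical_p = bh$critical, q = q,
                 strict = strict, skipped = skipped,
                 response = response, mutation = mutation,
                 call = match.call()),
            class = "marker_scan")
}

#' Intersect scan calls with an external p-value set
#'
#' Applies Benjamini-Hochberg control (same FDR level as the scan, unless
#' overridden) to an external per-association p-value table — e.g. the
#' MANOVA p-values released with a screen — restricted to the pairs the
#' scan actually scored, and records three call sets on the fit:
#' significant under both tests (`consensus`), under the chi-squared scan
#' only, and under the external test only. Scored pairs missing from the
#' external table count as externally non-significant; external pairs that
#' were not scorable are ignored.
#'
#' @param fit a [marker_scan] object.
#' @param external a data frame with columns `drug`, `feature`, `p` (see
#'   [read_pvalue_table()]).
#' @param q FDR level for the external adjustment; defaults to the scan's.
#' @return `fit`, with columns `p_external`, `external_significant` and
#'   `consensus` added to `fit$results`, plus `critical_p_external`.
#' @export
consensus_calls <- function(fit, external, q = fit$q) {
  stopifnot(inherits(fit, "marker_scan"))
  if (!all(c("drug", "feature", "p") %in% names(external)))
    stop("'external' must have columns drug, feature, p")
  res <- fit$results
  key <- paste(res$drug, res$feature, sep = "\r")
  ekey <- paste(external$drug, external$feature, sep = "\r")
  res$p_external <- external$p[match(key, ekey)]
  covered <- !is.na(res$p_external)
  res$external_significant <- FALSE
  crit <- NA_real_
  if (any(covered)) {
    bh <- bh_fdr(res$p_external[covered], q = q, strict = fit$strict)
    res$external_significant[covered] <- bh$significant
    crit <- bh$critical
  }
  res$consensus <- res$significant & res$external_significant
  fit$results <- res
  fit$critical_p_external <- crit
  fit$q_external <- q
  fit
}

#' @export
print.marker_scan <- function(x, ...) {
  r <- x$results
  cat("Genomic-marker scan (mutation-dependent threshold + chi-squared test)\n")
  cat(sprintf("  %d associations scored (%d drugs x %d features; %d pairs skipped)\n",
              nrow(r), length(unique(r$drug)), length(unique(r$feature)),
              nrow(x$skipped)))
  cat(sprintf("  FDR level q = %g, BH critical p-value = %s\n", x$q,
              if (is.na(x$critical_p)) "none" else
                format(x$critical_p, digits = 6)))
  cat(sprintf("  %d significant associations", sum(r$significant)))
  if (!is.null(r$consensus))
    cat(sprintf(" (%d external, %d consensus)",
                sum(r$external_significant), sum(r$consensus)))
  cat("\n")
  invisible(x)
}

#' @describeIn marker_scan summarise significance counts and, per sample
#'   size, the minimal phi that reaches significance.
#' @param object,x a `marker_scan` object.
#' @param ... unused.
#' @export
summary.marker_scan <- function(object, ...) {
  r <- object$results
  top <- r[order(r$p), c("drug", "feature", "n", "prevalence", "direction",
                         "phi", "chi2", "p", "significant")]
  cutoffs <- NULL
  if (!is.na(object$critical_p)) {
    ns <- sort(unique(r$n))
    cutoffs <- data.frame(n = ns,
                          phi_cutoff = phi_significance_cutoff(ns, object$critical_p))
  }
  structure(list(n_assoc = nrow(r), n_significant = sum(r$significant),
                 critical_p = object$critical_p, q = object$q,
                 n_skipped = nrow(object$skipped),
                 phi_cutoffs = cutoffs, top = utils::head(top, 10)),
            class = "summary.marker_scan")
}

#' @export
print.summary.marker_scan <- function(x, ...) {
  cat(sprintf("%d associations scored, %d significant at FDR q = %g (critical p = %s)\n",
              x$n_assoc, x$n_significant, x$q,
              if (is.na(x$critical_p)) "none" else
                format(x$critical_p, digits = 6)))
  if (x$n_skipped > 0)
    cat(sprintf("%d pairs skipped (see $skipped)\n", x$n_skipped))
  if (!is.null(x$phi_cutoffs) && nrow(x$phi_cutoffs) <= 12) {
    cat("Minimal significant phi by sample size:\n")
    print(x$phi_cutoffs, row.names = FALSE, digits = 3)
  }
  cat("Strongest associations:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn marker_scan phi coefficients of all scored associations, as
#'   a named vector (`"drug:feature"`).
#' @export
coef.marker_scan <- function(object, ...) {
  stats::setNames(object$results$phi,
                  paste(object$results$drug, object$results$feature, sep = ":"))
}

#' Plot a marker scan
#'
#' With `drug` and `feature` named, draws the association's response
#' scatter: logIC50 of mutated vs wild-type cell lines with group medians
#' and the mutation-dependent threshold (dotted). Without them, draws phi
#' against -log10 p for all scored associations, coloured by sample size,
#' with the significance cutoff (if any) as a vertical line.
#'
#' @param x a [marker_scan] object.
#' @param drug,feature identify one scored association (optional).
#' @param ... passed to the underlying plotting functions.
#' @return `x`, invisibly.
#' @export
plot.marker_scan <- function(x, drug = NULL, feature = NULL, ...) {
  r <- x$results
  if (is.null(drug) != is.null(feature))
    stop("give both 'drug' and 'feature', or neither")
  if (is.null(drug)) {
    logp <- -log10(pmax(r$p, 1e-300))
    cols <- grDevices::hcl.colors(max(3L, length(unique(r$n))), "Dark 2")
    ci <- as.integer(factor(r$n))
    graphics::plot(logp, r$phi, xlab = expression(-log[10] ~ p),
                   ylab = expression(phi), col = cols[ci], pch = 3, ...)
    if (!is.na(x$critical_p))
      graphics::abline(v = -log10(x$critical_p), col = "blue", lty = 2)
    return(invisible(x))
  }
  i <- which(r$drug == drug & r$feature == feature)
  if (length(i) != 1)
    stop(sprintf("association %s:%s was not scored", drug, feature))
  common <- intersect(rownames(x$response), rownames(x$mutation))
  y <- unclass(x$response)[common, drug]
  fl <- unclass(x$mutation)[common, feature]
  use <- !is.na(y) & !is.na(fl)
  grp <- factor(ifelse(fl[use] == 1, "mutated", "wild-type"),
                levels = c("mutated", "wild-type"))
  off <- stats::ave(rep(0, length(grp)), grp,  # deterministic spread, no RNG
                    FUN = function(v) seq(-0.12, 0.12, length.out = length(v)))
  graphics::plot(as.integer(grp) + off, y[use],
                 xaxt = "n", xlim = c(0.5, 2.5),
                 xlab = "", ylab = expression(logIC[50] ~ (log[10] ~ mu * M)),
                 main = sprintf("%s : %s (phi = %.2f, p = %.2g)",
                                drug, feature, r$phi[i], r$p[i]), ...)
  graphics::axis(1, at = 1:2, labels = levels(grp))
  graphics::segments(c(0.8, 1.8), c(r$med_mt[i], r$med_wt[i]),
                     c(1.2, 2.2), lwd = 2)
  graphics::abline(h = r$thres[i], col = "red", lty = 3)
  invisible(x)
}

#' Predict drug sensitivity from a fitted marker
#'
#' Uses one scored association as a classifier: mutated cell lines are
#' predicted on the marker's response side (sensitive for a sensitivity
#' marker, resistant for a resistance marker), wild-type cell lines on the
#' other side.
#'
#' @param object a [marker_scan] object.
#' @param drug,feature identify one scored association.
#' @param newdata a [mutation_panel] with the cells to classify; defaults
#'   to the panel the scan was fitted on.
#' @param ... unused.
#' @return factor of levels `c("sensitive", "resistant")`, `NA` where the
#'   mutation call is missing, named by cell line.
#' @export
predict.marker_scan <- function(object, drug, feature, newdata = NULL, ...) {
  r <- object$results
  i <- which(r$drug == drug & r$feature == feature)
  if (length(i) != 1)
    stop(sprintf("association %s:%s was not scored", drug, feature))
  mp <- if (is.null(newdata)) object$mutation else newdata
  stopifnot(inherits(mp, "mutation_panel"))
  if (!feature %in% colnames(mp))
    stop(sprintf("feature %s not in mutation panel", feature))
  fl <- unclass(mp)[, feature]
  mut_side <- if (r$direction[i] == "sensitivity") "sensitive" else "resistant"
  wt_side <- setdiff(c("sensitive", "resistant"), mut_side)
  out <- factor(ifelse(is.na(fl), NA, ifelse(fl == 1, mut_side, wt_side)),
                levels = c("sensitive", "resistant"))
  names(out) <- rownames(mp)
  out
}
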