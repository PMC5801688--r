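## Held-out validation: drug-level sensitivity threshold from training
## data, test-set contingency and MCC, per-method benchmark.

#' Per-drug held-out test cell lines between two panel releases
#'
#' For each drug present in both panels, the test set is the cell lines
#' with a response in the test panel that were *not* tested with that drug
#' in the training panel, so training and test sets are disjoint per drug
#' by construction. Drugs absent from either panel are dropped (and
#' reported).
#'
#' @param train_response,test_response [response_panel] objects sharing a
#'   cell-line identifier scheme.
#' @return list with `test_cells` (named list: drug -> character vector of
#'   test cell lines, possibly empty) and `dropped` (drugs in only one
#'   panel).
#' @export
split_by_release <- function(train_response, test_response) {
  stopifnot(inherits(train_response, "response_panel"),
            inherits(test_response, "response_panel"))
  tr_drugs <- colnames(train_response)
  te_drugs <- colnames(test_response)
  common <- intersect(tr_drugs, te_drugs)
  if (length(common) == 0)
    stop("no drugs in common between training and test panels")
  dropped <- setdiff(union(tr_drugs, te_drugs), common)
  test_cells <- lapply(common, function(d) {
    tested_te <- rownames(test_response)[!is.na(unclass(test_response)[, d])]
    tested_tr <- rownames(train_response)[!is.na(unclass(train_response)[, d])]
    setdiff(tested_te, tested_tr)
  })
  names(test_cells) <- common
  list(test_cells = test_cells, dropped = dropped)
}

## Score one marker on its test set. Returns a one-row data frame.
.validate_one <- function(drug, feature, direction, drug_threshold,
                          test_resp, test_flags) {
  use <- !is.na(test_resp) & !is.na(test_flags)
  y <- test_resp[use]; fl <- test_flags[use]
  n_test <- length(y)
  if (n_test == 0 || sum(fl == 1) == 0) {
    return(data.frame(drug = drug, feature = feature,
                      direction = direction, drug_threshold = drug_threshold,
                      n_test = n_test, tp = NA_integer_, fn = NA_integer_,
                      fp = NA_integer_, tn = NA_integer_,
                      mcc_test = NA_real_, evaluable = FALSE,
                      degenerate = FALSE, stringsAsFactors = FALSE))
  }
  sens <- y < drug_threshold          # ties go to the resistant side
  obs_pos <- if (direction == "sensitivity") sens else !sens
  mut <- fl == 1
  tab <- contingency2x2(tp = sum(mut & obs_pos), fn = sum(!mut & obs_pos),
                        fp = sum(mut & !obs_pos), tn = sum(!mut & !obs_pos))
  marg0 <- with(tab, any(c(tp + fn, fn + tn, tn + fp, fp + tp) == 0))
  mcc <- if (marg0) 0 else phi_coefficient(tab)  # no prediction ~ random
  data.frame(drug = drug, feature = feature, direction = direction,
             drug_threshold = drug_threshold, n_test = n_test,
             tp = tab$tp, fn = tab$fn, fp = tab$fp, tn = tab$tn,
             mcc_test = mcc, evaluable = TRUE, degenerate = marg0,
             stringsAsFactors = FALSE)
}

#' Validate discovered markers on held-out cell lines
#'
#' Evaluates each selected association as a predictor of drug sensitivity
#' on cell lines not used for discovery. The sensitivity threshold is the
#' median of *all* training logIC50 values for the drug (an absolute,
#' drug-level notion of sensitivity, unlike the mutation-dependent
#' discovery threshold) and is computed exclusively from training data.
#' Test cells with logIC50 below the threshold are sensitive; at or above
#' it, resistant. The marker predicts the mutated cells on its training
#' direction's side, and performance is summarised by the MCC on the test
#' 2x2 table. Markers with no mutated test cell yield no prediction and
#' are recorded as non-evaluable (`mcc_test = NA`); markers whose test
#' table has a zero marginal for any other reason score `mcc_test = 0`
#' with a degenerate flag.
#'
#' @param fit a [marker_scan] fitted on the training panel.
#' @param test_response a [response_panel] with the newer release.
#' @param test_mutation a [mutation_panel] covering the test cell lines.
#' @param subset which call set to validate: rows of `fit$results` that
#'   are `"significant"` (chi-squared calls, default), `"consensus"`,
#'   `"external"`, `"chi2_only"`, `"external_only"` (these three require
#'   [consensus_calls()] first), or `"all"`.
#' @return object of class `marker_validation`: a list with `results` (one
#'   row per marker: identifiers, nTrain, prevalence, p-values, direction,
#'   drug threshold, nTest, test table, `mcc_test`, `evaluable`) and the
#'   split bookkeeping.
#' @export
validate_markers <- function(fit, test_response, test_mutation,
                             subset = c("significant", "consensus",
                                        "external", "chi2_only",
                                        "external_only", "all")) {
  stopifnot(inherits(fit, "marker_scan"),
            inherits(test_response, "response_panel"),
            inherits(test_mutation, "mutation_panel"))
  subset <- match.arg(subset)
  r <- fit$results
  pick <- switch(subset,
    all = rep(TRUE, nrow(r)),
    significant = r$significant,
    consensus = .need_consensus(r)$consensus,
    external = .need_consensus(r)$external_significant,
    chi2_only = r$significant & !.need_consensus(r)$external_significant,
    external_only = .need_consensus(r)$external_significant & !r$significant)
  markers <- r[pick, , drop = FALSE]
  if (nrow(markers) == 0) {
    warning("no markers in the '", subset, "' call set; empty validation")
    return(structure(list(results = NULL, subset = subset,
                          dropped_drugs = character()),
                     class = "marker_validation"))
  }

  split <- split_by_release(fit$response, test_response)
  common_drugs <- names(split$test_cells)
  tr_resp <- unclass(fit$response)
  te_resp <- unclass(test_response)
  te_mut <- unclass(test_mutation)

  rows <- lapply(seq_len(nrow(markers)), function(i) {
    m <- markers[i, ]
    base <- data.frame(m[c("drug", "feature", "n", "prevalence", "phi",
                           "chi2", "p", "direction")],
                       row.names = NULL, stringsAsFactors = FALSE)
    names(base)[names(base) == "n"] <- "n_train"
    if (!m$drug %in% common_drugs)
      return(cbind(base, data.frame(
        drug_threshold = NA_real_, n_test = 0L, tp = NA_integer_,
        fn = NA_integer_, fp = NA_integer_, tn = NA_integer_,
        mcc_test = NA_real_, evaluable = FALSE, degenerate = FALSE)))
    drug_thr <- stats::median(tr_resp[, m$drug], na.rm = TRUE)
    cells <- split$test_cells[[m$drug]]
    y <- te_resp[cells, m$drug]
    fl <- if (m$feature %in% colnames(te_mut))
      te_mut[cells, m$feature] else rep(NA_integer_, length(cells))
    v <- .validate_one(m$drug, m$feature, m$direction, drug_thr, y, fl)
    cbind(base, v[setdiff(names(v), names(base))])
  })
  results <- do.call(rbind, rows)
  ## disjointness is structural; assert it anyway
  for (d in intersect(unique(results$drug), common_drugs))
    stopifnot(length(intersect(
      split$test_cells[[d]],
      rownames(fit$response)[!is.na(tr_resp[, d])])) == 0)

  structure(list(results = results, subset = subset,
                 dropped_drugs = split$dropped),
            class = "marker_validation")
}

.need_consensus <- function(r) {
  if (is.null(r$consensus))
    stop("run consensus_calls() before validating external/consensus sets")
  r
}

#' Compare call-set methods on the held-out benchmark
#'
#' Validates several call sets (by default the consensus, the chi-squared
#' calls and the external calls) on identical train/test splits and
#' summarises each by its median test MCC and the fraction of evaluable
#' markers beating random classification (MCC > 0).
#'
#' @param fit a [marker_scan] after [consensus_calls()].
#' @inheritParams validate_markers
#' @param methods character vector of call sets (see [validate_markers()]).
#' @return object of class `marker_benchmark`: `summary` data frame
#'   (method, n_markers, n_evaluable, median_mcc, frac_mcc_positive) and
#'   `per_marker`, the per-marker validation rows by method.
#' @export
benchmark_methods <- function(fit, test_response, test_mutation,
                              methods = c("consensus", "significant",
                                          "external")) {
  vals <- lapply(methods, function(m)
    validate_markers(fit, test_response, test_mutation, subset = m))
  names(vals) <- methods
  summ <- do.call(rbind, lapply(methods, function(m) {
    r <- vals[[m]]$results
    ev <- if (is.null(r)) logical(0) else r$evaluable
    mcc <- if (is.null(r)) numeric(0) else r$mcc_test[ev]
    data.frame(method = m,
               n_markers = if (is.null(r)) 0L else nrow(r),
               n_evaluable = sum(ev),
               median_mcc = if (length(mcc)) stats::median(mcc) else NA_real_,
               frac_mcc_positive = if (length(mcc)) mean(mcc > 0) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ,
                 per_marker = lapply(vals, `[[`, "results")),
            class = "marker_benchmark")
}

#' @export
print.marker_validation <- function(x, ...) {
  cat(sprintf("Held-out marker validation ('%s' call set)\n", x$subset))
  if (is.null(x$results)) {
    cat("  no markers to validate\n")
    return(invisible(x))
  }
  r <- x$results
  ev <- r$evaluable
  cat(sprintf("  %d markers, %d evaluable on the test release\n",
              nrow(r), sum(ev)))
  if (any(ev))
    cat(sprintf("  median test MCC %.3f; %.0f%% beat random (MCC > 0)\n",
                stats::median(r$mcc_test[ev]),
                100 * mean(r$mcc_test[ev] > 0)))
  if (length(x$dropped_drugs))
    cat(sprintf("  %d drugs absent from one release were dropped\n",
                length(x$dropped_drugs)))
  invisible(x)
}

#' @export
summary.marker_validation <- function(object, ...) {
  print(object)
  if (!is.null(object$results))
    print(utils::head(object$results[order(-object$results$mcc_test), ], 10),
          row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
print.marker_benchmark <- function(x, ...) {
  cat("Benchmark of marker-calling methods on held-out cell lines\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
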