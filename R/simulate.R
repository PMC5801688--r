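## Synthetic GDSC-shaped panels with planted drug-gene effects, for
## calibration (type I error) and power studies.

#' Specification of a synthetic drug-response panel
#'
#' Describes a cells x drugs logIC50 panel and a cells x features binary
#' mutation panel with known ground truth. Defaults emulate a typical
#' large-screen drug group: 300 cell lines per drug, 70% of drug-cell
#' pairs measured, per-feature mutation prevalence log-uniform between
#' rare (2%) and common (50%), per-drug baseline logIC50 centred uniformly
#' in [-1, 2] log10 uM with spread 1 log10 unit. Planted effects shift the
#' mutant group additively on the log10 scale: a negative `delta` makes
#' mutants more sensitive (lower logIC50), a positive one more resistant.
#'
#' @param n_cells,n_drugs,n_features panel dimensions.
#' @param missing_fraction probability in [0, 1) that a (cell, drug)
#'   response is unmeasured.
#' @param prevalence per-feature mutation probability: a scalar, a vector
#'   recycled over features, or `NULL` to draw each feature's prevalence
#'   log-uniformly from [0.02, 0.5].
#' @param baseline_mean per-drug central logIC50; scalar, vector, or
#'   `NULL` to draw uniformly from [-1, 2].
#' @param noise_sd response spread around the drug baseline (log10 units).
#' @param noise_family `"gaussian"`, `"skewed"` (variance-standardised
#'   centred log-normal, sigma = 0.75), or `"contaminated"` (gaussian with
#'   `outlier_fraction` of draws inflated by `outlier_scale`).
#' @param outlier_fraction,outlier_scale contamination parameters.
#' @param planted data frame with columns `drug`, `feature`, `delta`
#'   (signed shift in log10 units), or `NULL` for a null panel. Drug and
#'   feature identifiers follow the generated naming (`drug01`...,
#'   `gene01`..., zero-padded).
#' @param seed integer seed; the generator is bit-reproducible for a fixed
#'   seed (R's default Mersenne-Twister RNG).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 300, n_drugs = 10, n_features = 50,
                           missing_fraction = 0.3, prevalence = NULL,
                           baseline_mean = NULL, noise_sd = 1,
                           noise_family = c("gaussian", "skewed",
                                            "contaminated"),
                           outlier_fraction = 0.05, outlier_scale = 5,
                           planted = NULL, seed = 1) {
  noise_family <- match.arg(noise_family)
  stopifnot(n_cells >= 2, n_drugs >= 1, n_features >= 1,
            missing_fraction >= 0, missing_fraction < 1, noise_sd > 0,
            outlier_fraction >= 0, outlier_fraction <= 1, outlier_scale > 0)
  if (!is.null(prevalence) &&
      (any(prevalence <= 0) || any(prevalence >= 1)))
    stop("'prevalence' values must lie in (0, 1)")
  if (!is.null(planted)) {
    if (!all(c("drug", "feature", "delta") %in% names(planted)))
      stop("'planted' needs columns drug, feature, delta")
    if (any(!is.finite(planted$delta)))
      stop("planted shifts must be finite")
  }
  structure(list(n_cells = n_cells, n_drugs = n_drugs,
                 n_features = n_features,
                 missing_fraction = missing_fraction,
                 prevalence = prevalence, baseline_mean = baseline_mean,
                 noise_sd = noise_sd, noise_family = noise_family,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale,
                 planted = planted, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.noise_draw <- function(n, sd, family, out_frac, out_scale) {
  switch(family,
    gaussian = stats::rnorm(n, 0, sd),
    skewed = {
      s <- 0.75  # log-normal shape; skewness ~ 2.9
      raw <- stats::rlnorm(n, 0, s)
      sd * (raw - exp(s^2 / 2)) / sqrt((exp(s^2) - 1) * exp(s^2))
    },
    contaminated = {
      big <- stats::runif(n) < out_frac
      stats::rnorm(n, 0, ifelse(big, out_scale * sd, sd))
    })
}

#' Generate a synthetic panel with known ground truth
#'
#' Draws mutation flags per feature from its prevalence, responses per
#' drug as baseline + noise, adds each planted pair's shift to its mutant
#' group, and removes responses at the specified missing fraction. The
#' output panels round-trip exactly through [write_panel()] /
#' [read_gdsc_panel()]. Features that come out all-mutant or all-wild-type
#' are legal (they exercise the scan's skip path) but flagged.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `response` ([response_panel]), `mutation`
#'   ([mutation_panel]), `truth` (the planted table, zero rows for a null
#'   panel) and `monomorphic` (features without both states).
#' @examples
#' panel <- simulate_panel(synthetic_spec(n_cells = 100, n_drugs = 2,
#'                                        n_features = 5, seed = 42))
#' panel$response
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  cells <- sprintf("cell%04d", seq_len(spec$n_cells))
  drugs <- sprintf("drug%02d", seq_len(spec$n_drugs))
  feats <- sprintf("gene%02d", seq_len(spec$n_features))

  prev <- spec$prevalence
  if (is.null(prev))
    prev <- exp(stats::runif(spec$n_features, log(0.02), log(0.5)))
  prev <- rep_len(prev, spec$n_features)
  mut <- vapply(prev, function(p)
    stats::rbinom(spec$n_cells, 1L, p), integer(spec$n_cells))
  dimnames(mut) <- list(cells, feats)

  base <- spec$baseline_mean
  if (is.null(base)) base <- stats::runif(spec$n_drugs, -1, 2)
  base <- rep_len(base, spec$n_drugs)
  resp <- vapply(seq_len(spec$n_drugs), function(j)
    base[j] + .noise_draw(spec$n_cells, spec$noise_sd, spec$noise_family,
                          spec$outlier_fraction, spec$outlier_scale),
    numeric(spec$n_cells))
  dimnames(resp) <- list(cells, drugs)

  truth <- spec$planted
  if (is.null(truth))
    truth <- data.frame(drug = character(), feature = character(),
                        delta = numeric(), stringsAsFactors = FALSE)
  if (nrow(truth) > 0) {
    bad_d <- setdiff(truth$drug, drugs)
    bad_f <- setdiff(truth$feature, feats)
    if (length(bad_d) || length(bad_f))
      stop("planted pair names unknown: ",
           paste(c(bad_d, bad_f), collapse = ", "))
    for (i in seq_len(nrow(truth))) {
      carriers <- mut[, truth$feature[i]] == 1L
      resp[carriers, truth$drug[i]] <-
        resp[carriers, truth$drug[i]] + truth$delta[i]
    }
  }
  truth$sign <- ifelse(truth$delta < 0, "sensitivity", "resistance")

  if (spec$missing_fraction > 0) {
    drop <- matrix(stats::runif(length(resp)) < spec$missing_fraction,
                   nrow(resp))
    resp[drop] <- NA_real_
  }
  mono <- feats[colSums(mut) == 0L | colSums(mut) == spec$n_cells]
  list(response = response_panel(resp), mutation = mutation_panel(mut),
       truth = truth, monomorphic = mono)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic panel spec: %d cells x %d drugs x %d features, %s noise (sd %.2g), %.0f%% missing, %d planted pair(s), seed %d\n",
    x$n_cells, x$n_drugs, x$n_features, x$noise_family, x$noise_sd,
    100 * x$missing_fraction,
    if (is.null(x$planted)) 0L else nrow(x$planted), x$seed))
  invisible(x)
}

#' Power and type-I-error study of the discovery scan
#'
#' For each grid point (shift `delta`, prevalence, sample size `n`),
#' generates `replicates` single-drug panels each carrying one planted
#' feature (shifted by `-delta`, i.e. a sensitivity effect, when
#' `delta > 0`) alongside `n_null_features` null features, runs
#' [marker_scan()], and records the detection rate of the planted pair and
#' the false-discovery proportion among null features. At `delta = 0` the
#' planted pair is itself null, so its "detection" rate estimates the
#' per-association false-positive level under BH control.
#'
#' @param deltas,prevalences,ns numeric grids (crossed).
#' @param q FDR level.
#' @param replicates panels per grid point.
#' @param n_null_features null features per panel.
#' @param noise_sd,noise_family,missing_fraction forwarded to
#'   [synthetic_spec()].
#' @param seed base seed; each replicate r of grid row g uses seed
#'   `seed + 1000 * g + r`.
#' @return data frame: grid columns plus `detection_rate`, `fdp` (mean
#'   false-discovery proportion over replicates) and `replicates`.
#' @export
power_study <- function(deltas, prevalences, ns, q = 0.20, replicates = 20,
                        n_null_features = 20, noise_sd = 0.5,
                        noise_family = "gaussian", missing_fraction = 0,
                        seed = 1) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(delta = deltas, prevalence = prevalences, n = ns,
                      KEEP.OUT.ATTRS = FALSE)
  out <- grid
  out$detection_rate <- NA_real_
  out$fdp <- NA_real_
  out$replicates <- replicates
  for (g in seq_len(nrow(grid))) {
    hit <- logical(replicates)
    fdp <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sp <- synthetic_spec(
        n_cells = grid$n[g], n_drugs = 1,
        n_features = n_null_features + 1,
        missing_fraction = missing_fraction,
        prevalence = grid$prevalence[g], noise_sd = noise_sd,
        noise_family = noise_family,
        planted = if (grid$delta[g] != 0)
          data.frame(drug = "drug01", feature = "gene01",
                     delta = -grid$delta[g]) else NULL,
        seed = seed + 1000L * g + r)
      panel <- simulate_panel(sp)
      fit <- tryCatch(marker_scan(panel$response, panel$mutation, q = q),
                      error = function(e) NULL)
      if (is.null(fit)) next  # all pairs monomorphic; count as no detection
      res <- fit$results
      planted_row <- res$feature == "gene01"
      hit[r] <- any(res$significant[planted_row])
      null_sig <- sum(res$significant[!planted_row])
      total_sig <- sum(res$significant)
      fdp[r] <- if (total_sig == 0) 0 else null_sig / total_sig
    }
    out$detection_rate[g] <- mean(hit)
    out$fdp[g] <- mean(fdp)
  }
  out
}
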