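#' Drug-response panel
#'
#' A `response_panel` holds the drug-response side of a pharmacogenomic
#' screen: one logIC50 value (log10 of the half-maximal inhibitory
#' concentration, in micromolar units) per tested (cell line, drug) pair.
#' Untested pairs are `NA`; every stored value must be finite. A logIC50 of
#' 1 corresponds to an IC50 of 10 uM, negative values to sub-micromolar
#' potency.
#'
#' @param values numeric matrix, cell lines in rows and drugs in columns,
#'   with `dimnames` giving the cell-line and drug identifiers. `NA` marks
#'   an untested pair.
#' @return an object of class `response_panel` (a validated matrix).
#' @examples
#' m <- matrix(c(-1, 0.5, NA, 2), 2, 2,
#'             dimnames = list(c("C1", "C2"), c("drugA", "drugB")))
#' rp <- response_panel(m)
#' dim(rp)
#' @export
response_panel <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (cells x drugs)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("response panel needs cell-line row names and drug column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell-line identifiers in response panel")
  if (anyDuplicated(colnames(values)))
    stop("duplicate drug identifiers in response panel")
  if (any(is.infinite(values) | is.nan(values)))
    stop("response panel values must be finite or NA")
  structure(values, class = c("response_panel", "matrix", "array"))
}

#' Binary mutation panel
#'
#' A `mutation_panel` holds binary genomic-feature calls (point-mutated
#' genes, gene fusions such as BCR_ABL, microsatellite-instability status)
#' per cell line: 1 = altered ("mutated"), 0 = wild-type, `NA` = call not
#' available.
#'
#' @param calls numeric (or integer) matrix of 0/1/NA, cell lines in rows
#'   and genomic features in columns, with `dimnames` giving identifiers.
#' @return an object of class `mutation_panel`.
#' @examples
#' m <- matrix(c(1, 0, 0, NA), 2, 2,
#'             dimnames = list(c("C1", "C2"), c("TP53", "BRAF")))
#' mutation_panel(m)
#' @export
mutation_panel <- function(calls) {
  if (!is.matrix(calls) || !is.numeric(calls))
    stop("'calls' must be a numeric matrix (cells x features)")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("mutation panel needs cell-line row names and feature column names")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate cell-line identifiers in mutation panel")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate feature identifiers in mutation panel")
  ok <- is.na(calls) | calls == 0 | calls == 1
  if (!all(ok))
    stop("mutation calls must be 0, 1 or NA")
  storage.mode(calls) <- "integer"
  structure(calls, class = c("mutation_panel", "matrix", "array"))
}

#' @export
print.response_panel <- function(x, ...) {
  n_val <- sum(!is.na(x))
  cat(sprintf(
    "Drug-response panel: %d cell lines x %d drugs, %d logIC50 values (%.1f%% filled)\n",
    nrow(x), ncol(x), n_val, 100 * n_val / length(x)))
  if (n_val > 0)
    cat(sprintf("logIC50 range: [%.2f, %.2f] log10 uM\n",
                min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.mutation_panel <- function(x, ...) {
  prev <- colMeans(x == 1, na.rm = TRUE)
  cat(sprintf(
    "Mutation panel: %d cell lines x %d features, prevalence %.3f-%.3f (median %.3f)\n",
    nrow(x), ncol(x), min(prev), max(prev), stats::median(prev)))
  invisible(x)
}
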