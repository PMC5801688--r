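## Panel file I/O: the 'x::y' mutation-descriptor dialect, logIC50
## conversion, and round-trip safe result tables.

#' Convert natural-log IC50 values to log10
#'
#' Screening files often ship IC50 summaries as the natural logarithm of
#' IC50 in micromolar units. All statistics in this package operate on
#' log10 IC50 (so differences read directly as orders of magnitude on the
#' molar scale); this converts between the two.
#'
#' @param ln_ic50 numeric vector of natural-log IC50 values (log_e uM).
#' @return numeric vector of logIC50 values (log10 uM).
#' @examples
#' to_log10(log(10))   # IC50 = 10 uM -> logIC50 = 1
#' to_log10(0)         # IC50 = 1 uM  -> logIC50 = 0
#' @export
to_log10 <- function(ln_ic50) {
  if (!is.numeric(ln_ic50))
    stop("'ln_ic50' must be numeric")
  if (any(!is.finite(ln_ic50) & !is.na(ln_ic50)))
    stop("non-finite IC50 value")
  ln_ic50 / log(10)
}

## token-level classification used by parse_mutation_descriptor
.variant_state <- function(x) {
  ## "mut": a coding variant; "none": wt/na (no variant); "unknown": junk
  out <- rep("unknown", length(x))
  out[x %in% c("wt", "na")] <- "none"
  is_var <- !(x %in% c("wt", "na")) & x != "" & !is.na(x)
  out[is_var] <- "mut"
  out
}

.cn_state <- function(y) {
  ## "mut": cn = 0 or cn >= 8; "wtrange": 0 < cn < 8; "unknown" otherwise
  out <- rep("unknown", length(y))
  out[y == "0<cn<8"] <- "wtrange"
  m <- regmatches(y, regexec("^cn=([0-9]+)$", y))
  k <- vapply(m, function(g) if (length(g) == 2) as.numeric(g[2]) else NA_real_,
              numeric(1))
  out[!is.na(k) & (k == 0 | k >= 8)] <- "mut"
  out[!is.na(k) & k > 0 & k < 8] <- "wtrange"
  out
}

#' Parse a GDSC-style 'x::y' mutation descriptor
#'
#' A descriptor combines a coding-variant token `x` and a copy-number token
#' `y`, separated by `::`. A feature is called mutated if a protein
#' sequence variant is present (`x` differs from both `wt` and `na`) or if
#' the copy number lies outside the wild-type range `0 < cn < 8` (i.e. a
#' homozygous deletion `cn=0` or an amplification `cn>=8`). It is called
#' wild-type if no variant is present (`x` is `wt` or `na`) and the copy
#' number is inside the wild-type range. If neither token supports a call
#' (for example `"na::na"`), the state is missing; unrecognised token
#' shapes degrade to missing with a warning rather than failing.
#'
#' @param descriptor character vector of 'x::y' strings. An empty string or
#'   `NA` is a missing call.
#' @param context optional label (e.g. "gene TP53 / cell SKBR3") used in
#'   error messages for malformed descriptors.
#' @return character vector with elements in
#'   `c("mutated", "wild-type", "missing")`.
#' @examples
#' parse_mutation_descriptor("wt::0<cn<8")       # wild-type
#' parse_mutation_descriptor("p.V600E::0<cn<8")  # mutated (coding variant)
#' parse_mutation_descriptor("wt::cn=0")         # mutated (deletion)
#' parse_mutation_descriptor("na::na")           # missing
#' @export
parse_mutation_descriptor <- function(descriptor, context = NULL) {
  if (!is.character(descriptor))
    descriptor <- as.character(descriptor)
  out <- rep("missing", length(descriptor))
  blank <- is.na(descriptor) | descriptor == ""
  todo <- which(!blank)
  if (length(todo) == 0) return(out)

  has_sep <- grepl("::", descriptor[todo], fixed = TRUE)
  if (any(!has_sep)) {
    bad <- descriptor[todo][!has_sep][1]
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    stop(sprintf("malformed mutation descriptor '%s'%s: missing '::' separator",
                 bad, where))
  }
  parts <- strsplit(descriptor[todo], "::", fixed = TRUE)
  x <- vapply(parts, `[`, character(1), 1)
  y <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "",
              character(1))

  vs <- .variant_state(x)
  cs <- .cn_state(y)
  call <- ifelse(vs == "mut" | cs == "mut", "mutated",
          ifelse(vs == "none" & cs == "wtrange", "wild-type", "missing"))
  n_odd <- sum(call == "missing" & (vs == "unknown" | cs == "unknown") &
               !(x == "na" & y == "na"))
  if (n_odd > 0)
    warning(sprintf("%d descriptor(s) with unrecognised token shapes treated as missing%s",
                    n_odd, if (is.null(context)) "" else paste0(" (", context, ")")))
  out[todo] <- call
  out
}

#' Format mutation call states in the canonical 'x::y' dialect
#'
#' Inverse of [parse_mutation_descriptor()] at the call-state level:
#' formatting a state and re-parsing it returns the same state.
#'
#' @param state character vector in `c("mutated", "wild-type", "missing")`,
#'   or a numeric vector of 1/0/NA.
#' @return character vector of descriptors.
#' @export
format_mutation_call <- function(state) {
  if (is.numeric(state))
    state <- ifelse(is.na(state), "missing",
                    ifelse(state == 1, "mutated", "wild-type"))
  if (!all(state %in% c("mutated", "wild-type", "missing")))
    stop("unknown call state")
  c(mutated = "p.mut::0<cn<8", `wild-type` = "wt::0<cn<8",
    missing = "na::na")[state]
}

#' Read a combined response + mutation panel file
#'
#' Reads the one-row-per-cell-line CSV dialect used throughout this
#' package: a cell-identifier column, one response column per drug (column
#' name = drug prefix + drug identifier; blank field = untested), and one
#' descriptor column per genomic feature in the 'x::y' dialect. Response
#' values are converted to log10 uM at ingest according to the file's
#' declared scale, so the in-memory panel is always logIC50.
#'
#' If the same drug appears in two columns (a re-screened compound), only
#' the more broadly tested instance is kept (ties broken by first
#' occurrence).
#'
#' @param path CSV file path.
#' @param scale `"ln"` if the file stores natural-log IC50 (as the raw GDSC
#'   exports do) or `"log10"` if already converted.
#' @param cell_col name of the cell-identifier column.
#' @param drug_prefix prefix identifying drug response columns; the drug
#'   identifier is the remainder of the column name.
#' @return a list with components `response` ([response_panel]) and
#'   `mutation` ([mutation_panel]).
#' @seealso [write_panel()] for the inverse.
#' @export
read_gdsc_panel <- function(path, scale = c("log10", "ln"),
                            cell_col = "CellLine", drug_prefix = "IC50_") {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!cell_col %in% names(df))
    stop(sprintf("panel file lacks the cell-identifier column '%s'", cell_col))
  cells <- df[[cell_col]]
  if (anyDuplicated(cells))
    stop("duplicate cell-line identifiers in ", path)

  is_drug <- startsWith(names(df), drug_prefix) & names(df) != cell_col
  is_feat <- !is_drug & names(df) != cell_col
  if (!any(is_drug)) stop("no drug response columns (prefix '", drug_prefix,
                          "') in ", path)

  resp <- vapply(which(is_drug), function(j) {
    v <- df[[j]]
    v[v == ""] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(nrow(df)))
  resp <- matrix(resp, nrow = nrow(df))
  drugs <- substring(names(df)[is_drug], nchar(drug_prefix) + 1L)

  ## duplicate drug columns: keep the more broadly tested instance
  if (anyDuplicated(drugs)) {
    keep <- logical(length(drugs))
    for (d in unique(drugs)) {
      idx <- which(drugs == d)
      counts <- colSums(!is.na(resp[, idx, drop = FALSE]))
      keep[idx[which.max(counts)]] <- TRUE  # which.max: first on ties
    }
    dropped <- sum(!keep)
    message(sprintf("dropped %d duplicate drug column(s), keeping the most broadly tested instance",
                    dropped))
    resp <- resp[, keep, drop = FALSE]
    drugs <- drugs[keep]
  }
  if (scale == "ln") resp <- to_log10(resp)
  dimnames(resp) <- list(cells, drugs)

  feats <- names(df)[is_feat]
  calls <- matrix(NA_integer_, nrow(df), length(feats),
                  dimnames = list(cells, feats))
  for (j in seq_along(feats)) {
    st <- parse_mutation_descriptor(df[[feats[j]]],
                                    context = paste("feature", feats[j]))
    calls[, j] <- ifelse(st == "mutated", 1L,
                         ifelse(st == "wild-type", 0L, NA_integer_))
  }
  list(response = response_panel(resp), mutation = mutation_panel(calls))
}

#' Write a response + mutation panel in the package CSV dialect
#'
#' @param response a [response_panel].
#' @param mutation a [mutation_panel] over the same cell lines.
#' @param path output CSV path.
#' @inheritParams read_gdsc_panel
#' @return `path`, invisibly.
#' @export
write_panel <- function(response, mutation, path,
                        cell_col = "CellLine", drug_prefix = "IC50_") {
  stopifnot(inherits(response, "response_panel"),
            inherits(mutation, "mutation_panel"))
  if (!identical(rownames(response), rownames(mutation)))
    stop("response and mutation panels must list the same cell lines in the same order")
  resp_chr <- apply(unclass(response), 2, function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  if (is.null(dim(resp_chr)))   # single cell line
    resp_chr <- matrix(resp_chr, nrow = 1)
  mut_chr <- apply(unclass(mutation), 2, format_mutation_call)
  if (is.null(dim(mut_chr)))
    mut_chr <- matrix(mut_chr, nrow = 1)
  df <- data.frame(rownames(response), resp_chr, mut_chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(cell_col, paste0(drug_prefix, colnames(response)),
                 colnames(mutation))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an external per-association p-value table
#'
#' External tables (for example the released MANOVA p-values accompanying a
#' screen) provide an independent significance call per (drug, feature)
#' pair for consensus marking.
#'
#' @param path CSV with columns `drug`, `feature`, `p` (extra columns are
#'   ignored).
#' @return data frame with columns drug, feature, p.
#' @export
read_pvalue_table <- function(path) {
  if (!file.exists(path)) stop("p-value table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "feature", "p")
  if (!all(need %in% names(df)))
    stop("p-value table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$p <- as.numeric(df$p)
  if (any(!is.finite(df$p)) || any(df$p < 0 | df$p > 1))
    stop("p-values must lie in [0, 1]")
  if (anyDuplicated(df[c("drug", "feature")]))
    stop("duplicate (drug, feature) entries in p-value table")
  df
}

#' Write association or validation results to CSV at full precision
#'
#' Numeric fields are written with 17 significant digits so that
#' [read_results()] reproduces them bit-for-bit.
#'
#' @param results a data frame (e.g. the `results` component of a
#'   [marker_scan] fit, or a [validate_markers()] table).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || !is.data.frame(results) || nrow(results) == 0)
    stop("'results' must be a non-empty data frame")
  out <- results
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return data frame with numeric columns restored to full precision.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
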