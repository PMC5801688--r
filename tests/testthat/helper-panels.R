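# Fixtures built in code: tiny panels and random contingency tables.

make_response <- function(values, cells = NULL, drugs = NULL) {
  m <- as.matrix(values)
  if (is.null(cells)) cells <- sprintf("C%d", seq_len(nrow(m)))
  if (is.null(drugs)) drugs <- sprintf("d%d", seq_len(ncol(m)))
  dimnames(m) <- list(cells, drugs)
  response_panel(m)
}

make_mutation <- function(calls, cells = NULL, features = NULL) {
  m <- as.matrix(calls)
  if (is.null(cells)) cells <- sprintf("C%d", seq_len(nrow(m)))
  if (is.null(features)) features <- sprintf("g%d", seq_len(ncol(m)))
  dimnames(m) <- list(cells, features)
  mutation_panel(m)
}

# random 2x2 table with all four marginals (and expected counts) positive
random_table <- function(max_count = 50) {
  repeat {
    cnt <- sample.int(max_count + 1, 4, replace = TRUE) - 1L
    tab <- contingency2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    marg <- with(tab, c(tp + fn, fn + tn, tn + fp, fp + tp))
    if (all(marg > 0)) return(tab)
  }
}

# write a small panel CSV from raw text lines
write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
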