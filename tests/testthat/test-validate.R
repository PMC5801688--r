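# small deterministic train/test pair with one strong sensitivity marker
fit_train <- function(seed = 31, delta = -2) {
  panel <- simulate_panel(synthetic_spec(
    n_cells = 150, n_drugs = 2, n_features = 10, missing_fraction = 0.1,
    prevalence = 0.3, baseline_mean = c(0, 1), noise_sd = 0.5,
    planted = data.frame(drug = "drug01", feature = "gene01", delta = delta),
    seed = seed))
  marker_scan(panel$response, panel$mutation, q = 0.2)
}

test_panel <- function(seed = 32, n = 250, delta = -2, n_drugs = 2) {
  simulate_panel(synthetic_spec(
    n_cells = n, n_drugs = n_drugs, n_features = 10, missing_fraction = 0.1,
    prevalence = 0.3, baseline_mean = c(0, 1), noise_sd = 0.5,
    planted = data.frame(drug = "drug01", feature = "gene01", delta = delta),
    seed = seed))
}

test_that("release split takes the drug-wise set difference of tested cells", {
  train <- make_response(matrix(c(1, 2), 2, 1), cells = c("A", "B"),
                         drugs = "d1")
  test <- make_response(matrix(1:4, 4, 1), cells = c("A", "B", "C", "D"),
                        drugs = "d1")
  sp <- split_by_release(train, test)
  expect_setequal(sp$test_cells$d1, c("C", "D"))

  # drug only in train is dropped
  train2 <- make_response(matrix(1:4, 2, 2), cells = c("A", "B"),
                          drugs = c("d1", "d2"))
  sp2 <- split_by_release(train2, test)
  expect_identical(sp2$dropped, "d2")
  expect_named(sp2$test_cells, "d1")

  # disjoint panels: every test cell is new
  test3 <- make_response(matrix(1:2, 2, 1), cells = c("X", "Y"), drugs = "d1")
  expect_setequal(split_by_release(train, test3)$test_cells$d1, c("X", "Y"))

  # no common drugs
  test4 <- make_response(matrix(1, 1, 1), cells = "A", drugs = "other")
  expect_error(split_by_release(train, test4), "no drugs in common")
})

test_that("a perfectly separating test set scores MCC = 1", {
  fit <- fit_train()
  thr <- median(unclass(fit$response)[, "drug01"], na.rm = TRUE)
  # build a test release: new cells, mutants clearly below the training
  # median (sensitive), wild-types clearly above
  cells <- sprintf("new%02d", 1:40)
  flags <- rep(c(1, 0), each = 20)
  y <- ifelse(flags == 1, thr - 2, thr + 2)
  te_resp <- make_response(matrix(c(y, rnorm(40)), 40, 2), cells = cells,
                           drugs = c("drug01", "drug02"))
  te_mut <- make_mutation(matrix(c(flags, rep(c(0, 1), 20), rep(0, 40 * 8)),
                                 40, 10),
                          cells = cells,
                          features = sprintf("gene%02d", 1:10))
  val <- validate_markers(fit, te_resp, te_mut)
  row <- val$results[val$results$drug == "drug01" &
                     val$results$feature == "gene01", ]
  expect_true(row$evaluable)
  expect_equal(row$mcc_test, 1)
  expect_equal(row$n_test, 40)
  expect_equal(row$drug_threshold, thr)
})

test_that("markers without mutant test cells are non-evaluable, zero marginals score 0", {
  fit <- fit_train()
  cells <- sprintf("new%02d", 1:30)
  te_resp <- make_response(matrix(rnorm(30), 30, 1), cells = cells,
                           drugs = "drug01")
  # gene01 never mutated in the test release -> no prediction
  te_mut <- make_mutation(matrix(0L, 30, 10), cells = cells,
                          features = sprintf("gene%02d", 1:10))
  val <- validate_markers(fit, te_resp, te_mut)
  row <- val$results[val$results$feature == "gene01", ]
  expect_false(row$evaluable)
  expect_true(is.na(row$mcc_test))

  # all test cells on one side of the drug threshold -> zero marginal -> 0
  thr <- median(unclass(fit$response)[, "drug01"], na.rm = TRUE)
  te_resp2 <- make_response(matrix(thr + 1 + runif(30), 30, 1),
                            cells = cells, drugs = "drug01")
  te_mut2 <- make_mutation(matrix(rep(c(1L, 0L), 15), 30, 10,
                                  dimnames = NULL), cells = cells,
                           features = sprintf("gene%02d", 1:10))
  val2 <- validate_markers(fit, te_resp2, te_mut2)
  row2 <- val2$results[val2$results$feature == "gene01", ]
  expect_true(row2$evaluable)
  expect_true(row2$degenerate)
  expect_equal(row2$mcc_test, 0)
})

test_that("the drug threshold comes from training data only", {
  fit <- fit_train()
  thr <- median(unclass(fit$response)[, "drug01"], na.rm = TRUE)
  v1 <- validate_markers(fit, test_panel(seed = 41)$response,
                         test_panel(seed = 41)$mutation)
  v2 <- validate_markers(fit, test_panel(seed = 42, n = 400)$response,
                         test_panel(seed = 42, n = 400)$mutation)
  expect_true(all(v1$results$drug_threshold == thr |
                  v1$results$drug != "drug01"))
  expect_identical(v1$results$drug_threshold, v2$results$drug_threshold)
})

test_that("train and test cells are disjoint per drug", {
  fit <- fit_train()
  te <- test_panel()
  sp <- split_by_release(fit$response, te$response)
  for (d in names(sp$test_cells)) {
    trained <- rownames(fit$response)[!is.na(unclass(fit$response)[, d])]
    expect_length(intersect(sp$test_cells[[d]], trained), 0)
  }
})

test_that("planted markers validate positive; null features hover near zero", {
  fit <- fit_train()
  te <- test_panel()
  val <- validate_markers(fit, te$response, te$mutation, subset = "all")
  planted <- val$results$drug == "drug01" & val$results$feature == "gene01"
  expect_gt(val$results$mcc_test[planted], 0.3)
  nulls <- val$results$mcc_test[!planted & val$results$evaluable]
  expect_lt(max(abs(nulls)), 0.3)
  expect_lt(abs(mean(nulls)), 0.1)
})

test_that("benchmark summarises call sets consistently", {
  fit <- fit_train()
  r <- fit$results
  ext <- data.frame(drug = r$drug, feature = r$feature, p = r$p)
  fit <- consensus_calls(fit, ext)
  te <- test_panel()
  bench <- benchmark_methods(fit, te$response, te$mutation)
  # identical call sets give identical distributions
  expect_equal(bench$summary$median_mcc[1], bench$summary$median_mcc[2])
  expect_equal(bench$summary$n_markers[1], bench$summary$n_markers[3])
  expect_output(print(bench), "Benchmark")
  # fraction beating random is computed over evaluable markers only
  per <- bench$per_marker$consensus
  expect_equal(bench$summary$frac_mcc_positive[1],
               mean(per$mcc_test[per$evaluable] > 0))

  # empty call set warns and yields an empty summary row
  fit0 <- fit
  fit0$results$significant <- FALSE
  fit0$results$consensus <- FALSE
  expect_warning(v0 <- validate_markers(fit0, te$response, te$mutation),
                 "no markers")
  expect_null(v0$results)
})
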