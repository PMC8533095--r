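test_that("run_case aggregates replicate metrics into non-NA medians", {
  case <- separable_case(n_per_class = 6, n_noise = 6)
  res <- run_case(case, "rf_all", fast_cfg(), seeds = 1:4)
  expect_s3_class(res, "case_result")
  expect_equal(nrow(res$replicates), 4)
  expect_equal(res$median[["mcc"]],
               median(res$replicates$mcc, na.rm = TRUE))

  # deterministic single-gene model: identical replicates
  sg <- run_case(case, "single_gene", seeds = 1:4)
  expect_equal(length(unique(sg$replicates$mcc)), 1)
  expect_equal(sg$feature_summary$fold_genes,
               single_gene_marker_loocv(case)$genes)

  # NA replicates are excluded from the median unless all are NA
  expect_equal(pdxomc:::median_na(c(0.1, NA, 0.3, NA, 0.2)), 0.2)
  expect_true(is.na(pdxomc:::median_na(c(NA_real_, NA_real_))))
  expect_equal(pdxomc:::median_na(c(rep(0.1, 5), rep(0.3, 5))), 0.2)
})

test_that("a degenerate case yields an all-NA result with a reason", {
  x <- matrix(rbinom(40, 1, 0.3), 10, 4,
              dimnames = list(sprintf("P%d", 1:10), sprintf("g%d", 1:4)))
  case <- pdxomc:::case_from_matrix(x, rep("resistant", 10))
  res <- run_case(case, "rf_all", fast_cfg(), seeds = 1:3)
  expect_true(all(is.na(res$replicates$mcc)))
  expect_true(is.na(res$median[["mcc"]]))
  expect_match(res$reason, "degenerate")
})

test_that("rf_omc case results carry a selected-feature summary", {
  co <- generate_cohort(synthetic_cohort_spec(
    n_samples = 16, n_binary_features = 30, odds_ratio = 50, seed = 2))
  case <- cohort_case(co, min_n = 10)
  res <- run_case(case, "rf_omc", fast_cfg(), seeds = 1:2)
  fs <- res$feature_summary
  expect_true(!is.null(fs$selection_frequency))
  expect_true(fs$median_selected_size >= 2)
  expect_true("sens_gene_01" %in% names(fs$selection_frequency))
})

test_that("best_predictor_per_case picks the argmax and resolves ties by parsimony", {
  case <- separable_case()
  mk <- function(model, mcc_val, profile = "SNV") {
    r <- run_case(case, model, fast_cfg(), seeds = 1:2)
    r$median[["mcc"]] <- mcc_val
    r$profile_kind <- profile
    r
  }
  res <- best_predictor_per_case(list(mk("rf_all", 0.2, "GEX"),
                                      mk("rf_omc", 0.5),
                                      mk("single_gene", 0.3)))
  expect_equal(nrow(res), 1)
  expect_equal(res$model, "rf_omc")

  # exact tie: the model with fewer features wins
  tie <- best_predictor_per_case(list(mk("rf_all", 0.5), mk("rf_omc", 0.5)))
  expect_equal(tie$model, "rf_omc")
  tie2 <- best_predictor_per_case(list(mk("single_gene", 0.5), mk("rf_omc", 0.5)))
  expect_equal(tie2$model, "single_gene")

  # single model wins by default; all-NA cases are reported unpredictable
  solo <- best_predictor_per_case(list(mk("rf_all", 0.1)))
  expect_equal(solo$model, "rf_all")
  na_case <- mk("rf_all", NA_real_)
  expect_true(is.na(best_predictor_per_case(list(na_case))$model))
  # an all-NA entry is never selected when a numeric one exists
  both <- best_predictor_per_case(list(na_case, mk("rf_omc", 0.05)))
  expect_equal(both$model, "rf_omc")
})

test_that("compare_models pairs replicates or treatments and feeds paired_t", {
  case <- separable_case()
  a <- run_case(case, "rf_all", fast_cfg(), seeds = 1:10)
  b <- a
  b$replicates$mcc <- a$replicates$mcc - 0.2  # uniformly worse by 0.2
  expect_lt(compare_models(a, b, "replicates", "greater"), 0.01)
  expect_true(is.na(suppressMessages(compare_models(a, a, "replicates"))))
  c2 <- a; c2$seeds <- 21:30
  expect_error(compare_models(a, c2, "replicates"), "matched seed lists")

  # across-treatment mode
  mk_t <- function(trt, m) { r <- a; r$treatment <- trt; r$median[["mcc"]] <- m; r }
  xs <- lapply(1:6, function(i) mk_t(paste0("t", i), 0.3 + 0.05 * i))
  ys <- lapply(1:6, function(i) mk_t(paste0("t", i), 0.1 + 0.05 * i))
  expect_lt(compare_models(xs, ys, "treatments", "greater"), 0.001)
  expect_error(compare_models(xs, ys[1:5], "treatments"), "equal treatment lists")
})

test_that("plan_benchmark counts equal the product of grid dimensions", {
  # property over random grids
  set.seed(99)
  for (i in 1:50) {
    na <- sample(1:3, 1); nc <- sample(1:3, 1); nt <- sample(1:5, 1)
    np <- sample(1:4, 1); nr <- sample(1:4, 1)
    plan <- plan_benchmark(paste0("a", 1:na), paste0("c", 1:nc),
                           paste0("t", 1:nt), paste0("p", 1:np), nr)
    expect_equal(attr(plan, "total"), na * nc * nt * np * nr)
  }
  one <- plan_benchmark("a", "c", "t", "p", 1)
  expect_equal(attr(one, "total"), 1)
  # dropping one of four profiles removes exactly a quarter of the runs
  full <- plan_benchmark(c("a1", "a2"), "c", paste0("t", 1:3),
                         paste0("p", 1:4), 5)
  less <- plan_benchmark(c("a1", "a2"), "c", paste0("t", 1:3),
                         paste0("p", 1:3), 5)
  expect_equal(attr(less, "total"), attr(full, "total") * 3 / 4)
  expect_error(plan_benchmark(character(0), "c", "t", "p", 1), "non-empty")
  # per-cancer-type treatment lists
  named <- plan_benchmark("a", c("BRCA", "CRC"),
                          list(BRCA = c("x", "y"), CRC = c("u", "v")),
                          "SNV", 2)
  expect_equal(attr(named, "total"), 1 * 2 * 2 * 1 * 2)
})

test_that("recall_comparison reports medians, winner and incomplete flags", {
  case <- separable_case()
  multi <- run_case(case, "rf_all", fast_cfg(), seeds = 1:2)
  single <- run_case(case, "single_gene", seeds = 1:2)
  multi$median[["rc"]] <- 0.91; single$median[["rc"]] <- 0.68
  out <- recall_comparison(multi, single)
  expect_equal(out$winner, "multi")
  single$median[["rc"]] <- 0.91
  expect_equal(recall_comparison(multi, single)$winner, "tie")
  single$median[["rc"]] <- NA_real_
  inc <- recall_comparison(multi, single)
  expect_false(inc$complete)
  single$treatment <- "other"
  expect_error(recall_comparison(multi, single), "share the")
})

test_that("replicate metric CSVs are byte-reproducible", {
  case <- separable_case()
  res <- run_case(case, "rf_all", fast_cfg(), seeds = 1:3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_case_results(list(res), f1)
  write_case_results(list(run_case(case, "rf_all", fast_cfg(), seeds = 1:3)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
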