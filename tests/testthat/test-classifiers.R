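test_that("rf_config validates and derives mtry / class weights", {
  expect_error(rf_config(n_trees = 5), ">= 10")
  cfg <- fast_cfg()
  expect_equal(pdxomc:::mtry_for(2, cfg), 1)     # floor(sqrt(2))
  expect_equal(pdxomc:::mtry_for(500, cfg), 22)
  y <- factor(c(rep("sensitive", 3), rep("resistant", 9)),
              levels = c("resistant", "sensitive"))
  w <- pdxomc:::class_weights(y, cfg)
  # minority (sensitive) penalised with the majority proportion
  expect_equal(unname(w["sensitive"]), 0.75)
  expect_equal(unname(w["resistant"]), 0.25)
  yb <- factor(rep(c("sensitive", "resistant"), 6),
               levels = c("resistant", "sensitive"))
  expect_equal(unname(diff(pdxomc:::class_weights(yb, cfg))), 0)
})

test_that("both forest backends separate a linearly separable fixture", {
  case <- separable_case(n_per_class = 8)
  for (backend in c("randomForest", "ranger")) {
    set.seed(2)
    model <- train_rf(case, cfg = rf_config(n_trees = 100, backend = backend))
    sc <- predict_rf(model, case$features)
    expect_true(all(sc[case$classes == "sensitive"] > 0.5))
    expect_true(all(sc[case$classes == "resistant"] < 0.5))
  }
  expect_error(train_rf(case, features = character(0)), "empty feature subset")
  expect_error(train_rf(case, features = "nope"), "unknown feature")
})

test_that("loocv_rf yields one prediction per PDX and is seed-reproducible", {
  case <- noise_case(n = 12, p = 8)
  p1 <- loocv_rf(case, fast_cfg(), seed = 42)
  p2 <- loocv_rf(case, fast_cfg(), seed = 42)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), case$n)
  expect_setequal(p1$pdx_id, rownames(case$features))
  p3 <- loocv_rf(case, fast_cfg(), seed = 43)
  expect_false(identical(p1$score, p3$score))
})

test_that("OMC candidate grid follows the n/2 rule and selection prefers parsimony", {
  # n = 20 training fold: candidates 2..10 plus ALL; two duplicated perfect
  # markers make every candidate's inner MCC 1, so the tie must resolve to
  # the smallest subset
  set.seed(61)
  n <- 20
  sens <- rep(c(1, 0), each = 10)
  x <- cbind(markerA = sens, markerB = sens,
             matrix(rbinom(n * 12, 1, 0.3), n, 12,
                    dimnames = list(NULL, sprintf("noise%02d", 1:12))))
  rownames(x) <- sprintf("P%02d", 1:n)
  case <- pdxomc:::case_from_matrix(x, ifelse(sens == 1, "sensitive", "resistant"))
  tr <- rf_omc_select(case, rf_config(n_trees = 100))
  expect_equal(tr$candidate_sizes, c(as.character(2:10), "ALL"))
  expect_setequal(tr$selected_features[1:2], c("markerA", "markerB"))
  expect_equal(tr$inner_mcc[1], 1)
  expect_equal(tr$selected_size, "2")
})

test_that("candidate grid caps at the feature count when the profile is small", {
  case <- separable_case(n_per_class = 10, n_noise = 2)  # 3 features, n = 20
  tr <- rf_omc_select(case, fast_cfg())
  expect_equal(tr$candidate_sizes, c("2", "3", "ALL"))
})

test_that("nested LOOCV never exposes the held-out PDX to model selection", {
  case <- noise_case(n = 14, p = 10)
  res <- nested_loocv_rf_omc(case, fast_cfg(), seed = 7)
  expect_equal(nrow(res$predictions), case$n)
  for (i in seq_len(case$n)) {
    tr <- res$traces[[i]]
    if (is.null(tr)) next
    expect_false(res$predictions$pdx_id[i] %in% tr$train_ids)
    expect_length(tr$train_ids, case$n - 1)
  }
  # determinism of the full nested pipeline
  res2 <- nested_loocv_rf_omc(case, fast_cfg(), seed = 7)
  expect_identical(res$predictions, res2$predictions)
})

test_that("nested MCC tracks the selected model's plain LOOCV MCC on a strong signal", {
  co <- generate_cohort(synthetic_cohort_spec(
    n_samples = 20, n_binary_features = 60, odds_ratio = 50, seed = 19))
  case <- cohort_case(co, min_n = 10)
  cfg <- fast_cfg()
  nested <- nested_loocv_rf_omc(case, cfg, seed = 1)
  nested_mcc <- classification_metrics(nested$predictions)$mcc
  sel <- rf_omc_select(case, cfg)
  plain <- loocv_rf(case, cfg, features = sel$selected_features, seed = 1)
  plain_mcc <- classification_metrics(plain)$mcc
  expect_lte(abs(nested_mcc - plain_mcc), 0.15)
})

test_that("single-gene marker LOOCV matches an exhaustive per-gene Fisher scan", {
  case <- separable_case(n_per_class = 7, n_noise = 19)  # 20 genes
  res <- single_gene_marker_loocv(case)
  expect_equal(nrow(res$predictions), case$n)
  expect_true(all(res$predictions$score %in% c(0, 1)))
  # oracle: per fold, scan every gene with fisher.test and keep phi > 0
  sens_of <- function(y) y == "sensitive"
  for (i in seq_len(case$n)) {
    x <- case$features[-i, , drop = FALSE]
    y <- case$classes[-i]
    stats <- lapply(colnames(x), function(g) {
      v <- x[, g]
      if (length(unique(v)) == 1) return(list(p = 1, phi = 0))
      tab <- matrix(c(sum(v & sens_of(y)), sum(v & !sens_of(y)),
                      sum(!v & sens_of(y)), sum(!v & !sens_of(y))),
                    2, byrow = TRUE)
      phi <- (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
        sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
      list(p = stats::fisher.test(tab)$p.value, phi = phi)
    })
    p <- vapply(stats, `[[`, numeric(1), "p")
    phi <- vapply(stats, `[[`, numeric(1), "phi")
    elig <- phi > 0
    expected <- if (!any(elig)) NA_character_ else {
      o <- order(p, -abs(phi), colnames(x))
      colnames(x)[o[elig[o]][1]]
    }
    expect_equal(res$genes[i], expected)
  }
  # the marker gene drives the prediction
  expect_equal(res$predictions$score,
               unname(vapply(seq_len(case$n), function(i)
                 if (is.na(res$genes[i])) 0
                 else case$features[i, res$genes[i]], numeric(1))))
})

test_that("all-wild-type profiles predict resistant in every fold", {
  x <- matrix(0, 10, 4, dimnames = list(sprintf("P%d", 1:10), sprintf("g%d", 1:4)))
  case <- pdxomc:::case_from_matrix(x, rep(c("sensitive", "resistant"), 5))
  res <- single_gene_marker_loocv(case)
  expect_true(all(res$predictions$predicted == "resistant"))
  expect_true(all(is.na(res$genes)))
  expect_null(final_single_gene_marker(case))
})

test_that("final_single_gene_marker recovers the planted marker on all data", {
  case <- separable_case()
  best <- final_single_gene_marker(case)
  expect_equal(best$gene, "marker")
  expect_equal(best$phi, 1)
  expect_equal(best$p_value,
               fisher_oracle(case$n_sensitive, 0, 0, case$n_resistant),
               tolerance = 1e-12)
})

test_that("random baselines are seed-stable and behave as chance", {
  case <- noise_case(n = 16, p = 10)
  r1 <- random_prior_baseline(case, seed = 9)
  r2 <- random_prior_baseline(case, seed = 9)
  expect_identical(r1, r2)
  # training-fold priors: scores near the balanced prevalence
  expect_true(all(abs(r1$score - 0.5) < 0.1))

  rf <- random_feature_rf(case, k = 3, fast_cfg(), seeds = 1:3)
  expect_equal(nrow(rf), 3)
  expect_length(attr(rf, "features")[[1]], 3)
  rf2 <- random_feature_rf(case, k = 3, fast_cfg(), seeds = 1:3)
  expect_equal(rf, rf2, ignore_attr = TRUE)
  expect_error(random_feature_rf(case, k = 99, fast_cfg()), "out of range")
})
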