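test_that("the same spec reproduces the identical cohort", {
  sp <- synthetic_cohort_spec(n_samples = 25, n_binary_features = 40,
                              n_real_features = 10, n_planted_real = 2,
                              seed = 77)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$profiles$SNV$values, b$profiles$SNV$values)
  expect_identical(a$profiles$GEX$values, b$profiles$GEX$values)
  expect_identical(a$classes, b$classes)
  expect_identical(a$responses, b$responses)
  c2 <- generate_cohort(synthetic_cohort_spec(n_samples = 25,
                                              n_binary_features = 40, seed = 78))
  expect_false(identical(a$profiles$SNV$values, c2$profiles$SNV$values))
})

test_that("class prevalence behaves binomially", {
  # P(12 <= X <= 28) > 0.99 for X ~ Binom(40, 0.5); check across seeds
  counts <- vapply(1:30, function(s)
    sum(generate_cohort(synthetic_cohort_spec(n_samples = 40,
                                              n_binary_features = 5,
                                              seed = s))$classes == "sensitive"),
    numeric(1))
  expect_true(mean(counts >= 12 & counts <= 28) >= 29 / 30)
})

test_that("planted binary features realise the requested odds ratio and rates", {
  # large-n calibration: empirical class-conditional rates near spec values
  sp <- synthetic_cohort_spec(n_samples = 2000, n_binary_features = 5,
                              n_planted_binary = 1, odds_ratio = 20,
                              baseline_rate = 0.1, seed = 10)
  co <- generate_cohort(sp)
  g <- co$profiles$SNV$values[, "sens_gene_01"]
  sens <- co$classes == "sensitive"
  p0 <- mean(g[!sens]); p1 <- mean(g[sens])
  expect_equal(p0, 0.1, tolerance = 0.25)
  expect_equal(p1, pdxomc:::planted_sensitive_rate(0.1, 20), tolerance = 0.1)
  or_hat <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_gt(or_hat, 10); expect_lt(or_hat, 40)

  # direction -1 enriches the alteration among resistant PDXs
  rev_co <- generate_cohort(synthetic_cohort_spec(
    n_samples = 1000, n_binary_features = 2, n_planted_binary = 1,
    direction = -1, seed = 11))
  gr <- rev_co$profiles$SNV$values[, "sens_gene_01"]
  sr <- rev_co$classes == "sensitive"
  expect_gt(mean(gr[!sr]), mean(gr[sr]))
})

test_that("noise features are class-independent (uniform null p-values)", {
  co <- generate_cohort(synthetic_cohort_spec(
    n_samples = 60, n_binary_features = 500, n_planted_binary = 0, seed = 6))
  rk <- rank_features(cohort_case(co, min_n = 10))
  p <- rk$p_value[rk$p_value < 1]  # drop the atom at 1 from constant genes
  # Fisher p-values are discrete and conservative; a KS sanity bound suffices
  ks <- suppressWarnings(ks.test(p, "punif"))$statistic
  expect_lt(as.numeric(ks), 0.35)
  expect_gt(mean(p), 0.35)  # no systematic enrichment of small p
})

test_that("permute_labels shuffles classes but preserves counts and features", {
  co <- generate_cohort(synthetic_cohort_spec(n_samples = 30,
                                              n_binary_features = 20, seed = 3))
  pe <- permute_labels(co, seed = 5)
  expect_identical(pe$profiles$SNV$values, co$profiles$SNV$values)
  expect_equal(table(pe$classes), table(co$classes))
  expect_identical(permute_labels(co, seed = 5)$classes, pe$classes)
  # the response records stay consistent with the permuted classes
  expect_identical(unname(binarize_response(pe$responses$category)),
                   unname(pe$responses$binary_class))
  case <- cohort_case(pe, min_n = 10)
  expect_identical(unname(as.character(case$classes[pe$responses$pdx_id])),
                   pe$responses$binary_class)
})

test_that("planted association dissolves under label permutation", {
  ps <- vapply(1:40, function(s) {
    co <- generate_cohort(synthetic_cohort_spec(
      n_samples = 40, n_binary_features = 5, odds_ratio = 30, seed = 1))
    pe <- permute_labels(co, seed = s)
    case <- cohort_case(pe, min_n = 10)
    rk <- rank_features(case)
    rk$p_value[rk$feature_id == "sens_gene_01"]
  }, numeric(1))
  # roughly uniform: not concentrated near 0
  expect_gt(mean(ps), 0.25)
  expect_gt(mean(ps > 0.05), 0.75)
})

test_that("generated volume curves round-trip their target category", {
  rules <- response_rules()
  set.seed(33)
  for (cat in c("CR", "PR", "SD", "PD")) {
    for (i in 1:50) {
      s <- generate_volume_series(cat, rules, noise_sd = 5)
      expect_equal(categorize_response(s, rules), cat)
    }
  }
  # zero-noise CR curve shrinks monotonically below the CR thresholds
  s <- generate_volume_series("CR", rules, noise_sd = 0, seed = 1)
  expect_true(all(diff(s$pct_delta_tvol) <= 0))
  st <- best_response_stats(s, rules = rules)
  expect_lt(st$best_response, rules$cr_best)
  expect_lt(st$best_avg_response, rules$cr_avg)
  # infeasible margins error out instead of looping forever
  expect_error(generate_volume_series("SD", rules, noise_sd = 500,
                                      max_tries = 5), "could not generate")
})

test_that("written cohorts are read back through the standard readers", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(synthetic_cohort_spec(
    n_samples = 12, n_binary_features = 8, n_real_features = 6,
    n_planted_real = 1, seed = 21))
  write_cohort(co, dir, curves = TRUE)
  snv <- read_profile_table(file.path(dir, "snv.tsv"))
  expect_identical(t(snv), co$profiles$SNV$values)
  gex <- read_profile_table(file.path(dir, "gex.tsv"))
  expect_identical(t(gex), co$profiles$GEX$values)
  recs <- read_curve_metrics(file.path(dir, "curve_metrics.tsv"))
  expect_equal(recs$category[match(co$responses$pdx_id, recs$pdx_id)],
               co$responses$category)
  # raw curves agree with the written categories
  series <- read_raw_response(file.path(dir, "raw_response.tsv"))
  expect_length(series, 12)
  cats <- vapply(series, categorize_response, character(1))
  ids <- vapply(series, function(s) attr(s, "pdx_id"), character(1))
  expect_equal(unname(cats),
               co$responses$category[match(ids, co$responses$pdx_id)])
})
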