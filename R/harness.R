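MODEL_KINDS <- c("rf_all", "rf_omc", "single_gene", "random_prior")

metric_row <- function(m, seed) {
  data.frame(seed = seed, mcc = m$mcc, pr = m$pr, rc = m$rc, f1 = m$f1,
             specificity = m$specificity, auc = m$auc)
}

# median over non-NA replicate values; all-NA stays NA
median_na <- function(v) if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)

#' Run one model on one case over replicate seeds
#'
#' Executes the requested model's (nested) LOOCV once per replicate seed
#' and aggregates per-replicate metrics into medians. Stochastic models
#' (the forests and the random-prior baseline) vary over seeds; the
#' single-gene marker is deterministic, so its replicates are identical.
#' The median of each metric is taken over the non-NA replicate values and
#' is NA only when every replicate is NA. A degenerate (single-class) case
#' returns an all-NA result with the reason recorded.
#'
#' @param case a \code{\link{build_case_dataset}}.
#' @param model one of "rf_all", "rf_omc", "single_gene", "random_prior".
#' @param cfg an \code{\link{rf_config}}.
#' @param seeds integer vector of replicate seeds (default 1:10); the same
#'   seed list should be shared across the models being compared.
#' @return Object of class \code{case_result}: case identifiers,
#'   \code{replicates} (per-seed metric data frame), \code{median}
#'   (named metric vector), and \code{feature_summary} (for "rf_omc" a
#'   frequency table of selected features plus median selected size; for
#'   "single_gene" the per-fold marker genes).
#' @export
run_case <- function(case, model = c("rf_all", "rf_omc", "single_gene",
                                     "random_prior"),
                     cfg = rf_config(), seeds = 1:10) {
  model <- match.arg(model)
  stopifnot(inherits(case, "case_dataset"))
  base <- list(treatment = case$treatment, cancer_type = case$cancer_type,
               profile_kind = case$profile_kind, model = model, n = case$n,
               seeds = seeds)
  if (case$degenerate) {
    na_m <- data.frame(seed = seeds, mcc = NA_real_, pr = NA_real_,
                       rc = NA_real_, f1 = NA_real_, specificity = NA_real_,
                       auc = NA_real_)
    return(structure(c(base, list(replicates = na_m,
                                  median = c(mcc = NA_real_, pr = NA_real_,
                                             rc = NA_real_, f1 = NA_real_,
                                             specificity = NA_real_,
                                             auc = NA_real_),
                                  feature_summary = NULL,
                                  reason = "degenerate case: single response class")),
                     class = "case_result"))
  }
  rows <- vector("list", length(seeds))
  feat <- list()
  for (s in seq_along(seeds)) {
    seed <- seeds[s]
    res <- switch(model,
      rf_all = list(predictions = loocv_rf(case, cfg, seed = seed)),
      rf_omc = nested_loocv_rf_omc(case, cfg, seed = seed),
      single_gene = single_gene_marker_loocv(case),
      random_prior = list(predictions = random_prior_baseline(case, seed)))
    rows[[s]] <- metric_row(classification_metrics(res$predictions), seed)
    if (model == "rf_omc")
      feat[[s]] <- res$traces
    if (model == "single_gene" && s == 1L)
      feat <- res$genes
  }
  reps <- do.call(rbind, rows)
  med <- vapply(reps[, -1], median_na, numeric(1))
  feature_summary <- NULL
  if (model == "rf_omc") {
    sel <- lapply(feat, function(traces)
      lapply(traces, function(tr) if (is.null(tr)) character(0) else tr$selected_features))
    all_sel <- unlist(sel)
    sizes <- unlist(lapply(feat, function(traces)
      vapply(traces, function(tr)
        if (is.null(tr)) NA_real_ else length(tr$selected_features), numeric(1))))
    feature_summary <- list(
      selection_frequency = sort(table(all_sel), decreasing = TRUE),
      median_selected_size = median_na(sizes),
      selected_by_replicate = sel)
  }
  if (model == "single_gene") feature_summary <- list(fold_genes = feat)
  structure(c(base, list(replicates = reps, median = med,
                         feature_summary = feature_summary)),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("case_result: %s / %s / %s / %s (n = %d, %d replicates)\n",
              x$treatment, x$cancer_type, x$profile_kind, x$model, x$n,
              nrow(x$replicates)))
  cat("  median metrics: ",
      paste(names(x$median), sprintf("%.2f", x$median), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

model_feature_count <- function(r) {
  switch(r$model,
         single_gene = 1,
         rf_omc = r$feature_summary$median_selected_size %||% Inf,
         Inf)  # rf_all / random models use the full profile
}

# parsimony order for ties: fewer features; then SG < RF-OMC < RF-all
model_order <- c(single_gene = 1, rf_omc = 2, rf_all = 3, random_prior = 4)

#' Best predictor per treatment-cancer type case
#'
#' Across a collection of \code{\link{run_case}} results, reports for each
#' (treatment, cancer type) the model x profile combination with the
#' highest median MCC, together with the winner's feature count (1 for the
#' single-gene marker, the median selected size for RF-OMC, all features
#' for RF-all). Exact MCC ties resolve toward fewer features (single-gene,
#' then RF-OMC, then RF-all). Cases whose results are all NA are reported
#' unpredictable.
#'
#' @param results list of \code{case_result} objects.
#' @return Data frame with one row per case: \code{treatment},
#'   \code{cancer_type}, \code{model}, \code{profile_kind}, \code{mcc},
#'   \code{n_features} (NA when unpredictable).
#' @export
best_predictor_per_case <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "case_result")))
  key <- vapply(results, function(r) paste(r$treatment, r$cancer_type, sep = "|"),
                character(1))
  out <- lapply(split(results, key), function(rs) {
    mccs <- vapply(rs, function(r) r$median[["mcc"]], numeric(1))
    info <- data.frame(treatment = rs[[1]]$treatment,
                       cancer_type = rs[[1]]$cancer_type)
    if (all(is.na(mccs)))
      return(cbind(info, model = NA_character_, profile_kind = NA_character_,
                   mcc = NA_real_, n_features = NA_real_))
    nf <- vapply(rs, model_feature_count, numeric(1))
    mo <- model_order[vapply(rs, function(r) r$model, character(1))]
    keyv <- ifelse(is.na(mccs), -Inf, mccs)
    w <- order(-keyv, nf, mo)[1]
    cbind(info, model = rs[[w]]$model, profile_kind = rs[[w]]$profile_kind,
          mcc = mccs[w],
          n_features = if (is.finite(nf[w])) nf[w] else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired comparison of two models' MCCs
#'
#' Within-case mode pairs the replicate MCCs of two \code{case_result}s run
#' with the same seed list (e.g. a forest against the random-prior
#' baseline, one-sided). Across-treatment mode pairs per-treatment median
#' MCCs of two result collections covering the same treatments.
#'
#' @param a,b \code{case_result} objects (mode "replicates") or lists of
#'   them (mode "treatments").
#' @param mode "replicates" or "treatments".
#' @param alternative passed to \code{\link{paired_t}}; "greater" tests
#'   whether \code{a} outperforms \code{b}.
#' @return The paired-t p-value.
#' @export
compare_models <- function(a, b, mode = c("replicates", "treatments"),
                           alternative = c("greater", "two.sided", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (mode == "replicates") {
    stopifnot(inherits(a, "case_result"), inherits(b, "case_result"))
    if (!identical(a$seeds, b$seeds))
      stop("replicate comparison requires matched seed lists")
    paired_t(a$replicates$mcc, b$replicates$mcc, alternative)
  } else {
    ta <- vapply(a, function(r) r$treatment, character(1))
    tb <- vapply(b, function(r) r$treatment, character(1))
    if (!identical(sort(ta), sort(tb)))
      stop("across-treatment comparison requires equal treatment lists")
    ma <- vapply(a, function(r) r$median[["mcc"]], numeric(1))[order(ta)]
    mb <- vapply(b, function(r) r$median[["mcc"]], numeric(1))[order(tb)]
    paired_t(ma, mb, alternative)
  }
}

#' Enumerate a benchmark grid of LOOCV runs
#'
#' Cartesian product of algorithms, cancer types, treatments per type,
#' molecular profiles and replicates, with one seed per planned run. The
#' full-study grid of 2 algorithms x 2 cancer types x 13 treatments x 4
#' profiles x 10 replicates enumerates 2080 LOOCV runs.
#'
#' @param algorithms,cancer_types,profiles character vectors.
#' @param treatments treatments per cancer type: either a character vector
#'   (same treatments for every type) or a named list keyed by cancer type
#'   with equal-length elements.
#' @param n_replicates replicates per combination.
#' @param base_seed replicate r of every combination gets seed
#'   \code{base_seed + r - 1} (the same seed list shared across models).
#' @return Object of class \code{benchmark_plan}: data frame of planned
#'   runs with attribute \code{total} = run count.
#' @export
plan_benchmark <- function(algorithms, cancer_types, treatments, profiles,
                           n_replicates = 10, base_seed = 1) {
  if (!length(algorithms) || !length(cancer_types) || !length(profiles) ||
      n_replicates < 1)
    stop("every grid dimension must be non-empty")
  if (is.list(treatments)) {
    if (!setequal(names(treatments), cancer_types))
      stop("treatment list must be keyed by cancer type")
    lens <- lengths(treatments)
    if (length(unique(lens)) != 1)
      stop("each cancer type must have the same number of treatments")
    tt <- do.call(rbind, lapply(cancer_types, function(ct)
      data.frame(cancer_type = ct, treatment = treatments[[ct]])))
  } else {
    if (!length(treatments)) stop("every grid dimension must be non-empty")
    tt <- expand.grid(cancer_type = cancer_types, treatment = treatments,
                      stringsAsFactors = FALSE)
  }
  grid <- merge(expand.grid(algorithm = algorithms, profile = profiles,
                            replicate = seq_len(n_replicates),
                            stringsAsFactors = FALSE),
                tt, by = NULL)
  grid$seed <- base_seed + grid$replicate - 1L
  grid <- grid[order(grid$algorithm, grid$cancer_type, grid$treatment,
                     grid$profile, grid$replicate), ]
  rownames(grid) <- NULL
  structure(grid, total = nrow(grid), class = c("benchmark_plan", "data.frame"))
}

#' @export
print.benchmark_plan <- function(x, ...) {
  cat(sprintf("benchmark_plan: %d LOOCV runs\n", attr(x, "total")))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Recall comparison of a multi-gene and a single-gene result
#'
#' @param multi,single \code{case_result}s for the same case.
#' @return List with both median recalls, \code{winner} ("multi", "single"
#'   or "tie") and \code{complete} (FALSE when either recall is NA).
#' @export
recall_comparison <- function(multi, single) {
  stopifnot(inherits(multi, "case_result"), inherits(single, "case_result"))
  if (!(identical(multi$treatment, single$treatment) &&
        identical(multi$cancer_type, single$cancer_type)))
    stop("results must share the treatment-cancer type case")
  rm_ <- multi$median[["rc"]]; rs <- single$median[["rc"]]
  if (is.na(rm_) || is.na(rs))
    return(list(multi_rc = rm_, single_rc = rs, winner = NA_character_,
                complete = FALSE))
  list(multi_rc = rm_, single_rc = rs,
       winner = if (rm_ > rs) "multi" else if (rs > rm_) "single" else "tie",
       complete = TRUE)
}

#' Write per-replicate metrics of case results to CSV
#'
#' One row per case x model x replicate, reproducible byte-for-byte for
#' identical inputs and seeds.
#'
#' @param results list of \code{case_result}s.
#' @param path output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_case_results <- function(results, path) {
  rows <- lapply(results, function(r)
    cbind(treatment = r$treatment, cancer_type = r$cancer_type,
          profile = r$profile_kind, model = r$model, n = r$n, r$replicates))
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
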