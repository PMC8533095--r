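#' Specification of a synthetic PDX cohort
#'
#' Describes a cohort of PDX-like samples with a binary response class drawn
#' at a given prevalence, plus molecular profiles containing a handful of
#' planted response-associated features among many class-independent noise
#' features. Binary (SNV-like) planted features are parameterised by the
#' alteration rate in the resistant class and the odds ratio relating the
#' two classes; real-valued (expression-like) planted features by a
#' standardised mean shift between classes. Defaults are a desk-scale cohort
#' in which feature-selection recovery is expected: 40 samples, 0.5
#' prevalence, 3 planted binary features (odds ratio 20 over a 0.1 baseline
#' rate) among 500 noise features.
#'
#' @param n_samples cohort size (default 40).
#' @param prevalence sensitive fraction in (0, 1) (default 0.5).
#' @param n_binary_features number of binary noise features (default 500).
#' @param n_real_features number of real-valued noise features (default 0).
#' @param n_planted_binary planted binary features (default 3).
#' @param odds_ratio class odds ratio of planted binary features, recycled
#'   (default 20).
#' @param baseline_rate alteration rate of planted binary features in the
#'   resistant class, recycled (default 0.1).
#' @param direction +1 (alteration enriched in sensitive) or -1, recycled.
#' @param n_planted_real planted real-valued features (default 0).
#' @param real_shift standardised mean shift of planted real features,
#'   recycled (default 1.5).
#' @param background_rate alteration rate of binary noise features
#'   (default 0.1).
#' @param curve_noise_sd Gaussian noise (in percentage points) on generated
#'   tumour-volume curves (default 5).
#' @param seed integer driving all of the cohort's randomness.
#' @return Object of class \code{synthetic_cohort_spec}.
#' @export
synthetic_cohort_spec <- function(n_samples = 40, prevalence = 0.5,
                                  n_binary_features = 500,
                                  n_real_features = 0,
                                  n_planted_binary = 3, odds_ratio = 20,
                                  baseline_rate = 0.1, direction = 1,
                                  n_planted_real = 0, real_shift = 1.5,
                                  background_rate = 0.1,
                                  curve_noise_sd = 5, seed = 1) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (any(odds_ratio <= 0) || any(real_shift <= 0))
    stop("effect sizes must be > 0")
  if (n_planted_binary > 0 && n_binary_features + n_planted_binary < 1)
    stop("no binary features")
  structure(list(
    n_samples = n_samples, prevalence = prevalence,
    n_binary_features = n_binary_features, n_real_features = n_real_features,
    n_planted_binary = n_planted_binary,
    odds_ratio = rep_len(odds_ratio, max(1, n_planted_binary)),
    baseline_rate = rep_len(baseline_rate, max(1, n_planted_binary)),
    direction = rep_len(direction, max(1, n_planted_binary)),
    n_planted_real = n_planted_real,
    real_shift = rep_len(real_shift, max(1, n_planted_real)),
    background_rate = background_rate, curve_noise_sd = curve_noise_sd,
    seed = seed), class = "synthetic_cohort_spec")
}

# sensitive-class alteration rate implied by (baseline rate, odds ratio)
planted_sensitive_rate <- function(baseline_rate, odds_ratio) {
  odds <- odds_ratio * baseline_rate / (1 - baseline_rate)
  odds / (1 + odds)
}

#' Generate a synthetic PDX cohort
#'
#' Draws response classes Bernoulli(prevalence), then builds an SNV-like
#' binary profile (planted features first, named \code{sens_gene_*}, then
#' noise features \code{noise_gene_*}) and, if requested, a GEX-like
#' real-valued profile (\code{sens_expr_*}, \code{noise_expr_*}; Gaussian
#' around a positive baseline, clamped at zero to respect the non-negative
#' expression scale). Response categories are drawn per class (sensitive:
#' CR/PR/SD; resistant: PD). All randomness derives from \code{spec$seed}:
#' the same spec reproduces the identical cohort.
#'
#' @param spec a \code{\link{synthetic_cohort_spec}}.
#' @return List of class \code{synthetic_cohort}: \code{profiles} (named
#'   list of \code{\link{feature_matrix}}), \code{responses} (response
#'   records), \code{classes} (factor), \code{planted} (ids of planted
#'   features per profile), \code{spec}.
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  ids <- sprintf("PDX%03d", seq_len(n))
  sens <- stats::rbinom(n, 1, spec$prevalence) == 1
  classes <- factor(ifelse(sens, "sensitive", "resistant"),
                    levels = c("resistant", "sensitive"))
  names(classes) <- ids

  profiles <- list()
  planted <- list()

  np <- spec$n_planted_binary
  nb <- spec$n_binary_features
  if (np + nb > 0) {
    cols <- vector("list", np + nb)
    nm <- c(if (np > 0) sprintf("sens_gene_%02d", seq_len(np)),
            if (nb > 0) sprintf("noise_gene_%04d", seq_len(nb)))
    for (j in seq_len(np)) {
      p0 <- spec$baseline_rate[j]
      p1 <- planted_sensitive_rate(p0, spec$odds_ratio[j])
      if (spec$direction[j] < 0) { tmp <- p0; p0 <- p1; p1 <- tmp }
      cols[[j]] <- stats::rbinom(n, 1, ifelse(sens, p1, p0))
    }
    for (j in seq_len(nb))
      cols[[np + j]] <- stats::rbinom(n, 1, spec$background_rate)
    m <- do.call(cbind, cols)
    dimnames(m) <- list(ids, nm)
    profiles$SNV <- feature_matrix(m, "SNV")
    planted$SNV <- utils::head(nm, np)
  }

  npr <- spec$n_planted_real
  nr <- spec$n_real_features
  if (npr + nr > 0) {
    nm <- c(if (npr > 0) sprintf("sens_expr_%02d", seq_len(npr)),
            if (nr > 0) sprintf("noise_expr_%04d", seq_len(nr)))
    m <- matrix(stats::rnorm((npr + nr) * n, mean = 8, sd = 1), n, npr + nr,
                dimnames = list(ids, nm))
    for (j in seq_len(npr))
      m[sens, j] <- m[sens, j] + spec$real_shift[j]
    m[m < 0] <- 0
    profiles$GEX <- feature_matrix(m, "GEX")
    planted$GEX <- utils::head(nm, npr)
  }

  category <- ifelse(sens,
                     sample(c("CR", "PR", "SD"), n, replace = TRUE,
                            prob = c(0.15, 0.35, 0.5)),
                     "PD")
  responses <- response_records(ids, "synthetic", category)

  structure(list(profiles = profiles, responses = responses,
                 classes = classes, planted = planted, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples (%d sensitive), profiles: %s\n",
              x$spec$n_samples, sum(x$classes == "sensitive"),
              paste(names(x$profiles), collapse = ", ")))
  invisible(x)
}

#' Case dataset from a synthetic cohort
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param profile which profile to use (default "SNV").
#' @param cancer_type label for reporting (default "synthetic").
#' @param min_n inclusion threshold (default 35).
#' @return A \code{\link{build_case_dataset}} object.
#' @export
cohort_case <- function(cohort, profile = "SNV", cancer_type = "synthetic",
                        min_n = 35) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!profile %in% names(cohort$profiles))
    stop("cohort has no ", profile, " profile")
  build_case_dataset(cohort$profiles[[profile]], cohort$responses,
                     treatment = "synthetic", cancer_type = cancer_type,
                     min_n = min_n)
}

#' Permute a cohort's response classes
#'
#' Uniformly shuffles the class labels (and the category/binary-class
#' columns of the response records with them) while leaving every feature
#' untouched: the null-model fixture in which no feature is truly
#' associated with response. Class counts are preserved.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param seed permutation seed.
#' @return The cohort with permuted labels.
#' @export
permute_labels <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  set.seed(seed)
  perm <- sample(length(cohort$classes))
  ids <- names(cohort$classes)
  cl <- cohort$classes[perm]
  names(cl) <- ids
  cohort$classes <- cl
  resp <- cohort$responses
  o <- match(ids, resp$pdx_id)
  resp$category <- resp$category[o][perm]
  resp$binary_class <- resp$binary_class[o][perm]
  resp$pdx_id <- ids
  cohort$responses <- resp
  cohort
}

# category-region membership with a symmetric margin (in percentage
# points); non-strict at the margins so a curve pinned at -100 can still
# qualify as CR.
category_with_margin <- function(b, a, rules, margin) {
  inside <- function(x, thr) x <= thr - margin
  outside <- function(x, thr) x >= thr + margin
  if (inside(b, rules$cr_best) && inside(a, rules$cr_avg)) return("CR")
  if (inside(b, rules$pr_best) && inside(a, rules$pr_avg) &&
      (outside(b, rules$cr_best) || outside(a, rules$cr_avg))) return("PR")
  if (inside(b, rules$sd_best) && inside(a, rules$sd_avg) &&
      (outside(b, rules$pr_best) || outside(a, rules$pr_avg))) return("SD")
  if (outside(b, rules$sd_best) || outside(a, rules$sd_avg)) return("PD")
  NA_character_  # within the margin band of a threshold
}

#' Generate a tumour-volume curve for a target response category
#'
#' Builds a piecewise-linear volume trend typical of the requested category
#' (complete regression to -100% for CR, partial regression for PR, nearly
#' flat for SD, rapid growth for PD), samples it every 3-4 days, adds
#' Gaussian noise, and accepts the curve only if its best-response
#' statistics fall inside the requested category's region with a margin of
#' at least \code{margin} percentage points under the supplied rules
#' (rejection sampling with bounded retries, so the round trip
#' categorise(generate(category)) == category holds by construction).
#'
#' @param category target category, one of CR/PR/SD/PD.
#' @param rules a \code{\link{response_rules}}.
#' @param noise_sd Gaussian noise scale in percentage points (default 5).
#' @param seed optional seed.
#' @param horizon last measurement day (default 42).
#' @param margin required distance from every deciding threshold
#'   (default 5).
#' @param max_tries rejection-sampling bound (default 100).
#' @return A \code{\link{volume_series}}.
#' @export
generate_volume_series <- function(category, rules = response_rules(),
                                   noise_sd = 5, seed = NULL, horizon = 42,
                                   margin = 5, max_tries = 100) {
  category <- match.arg(category, RESPONSE_CATEGORIES)
  if (!is.null(seed)) set.seed(seed)
  trend <- switch(category,
    CR = function(d) pmax(-100, -100 * d / 12),
    PR = function(d) pmax(-72, -72 * d / 14),
    SD = function(d) pmax(-8, -8 * d / 10),
    PD = function(d) pmin(150, 9 * d))
  for (try in seq_len(max_tries)) {
    day <- 0
    while (utils::tail(day, 1) < horizon)
      day <- c(day, utils::tail(day, 1) + sample(3:4, 1))
    day <- day[day <= horizon]
    v <- trend(day[-1]) + stats::rnorm(length(day) - 1, 0, noise_sd)
    if (category == "CR")  # regrowth noise is not biological at -100
      v[trend(day[-1]) <= -100] <- -100
    v <- pmax(v, -100)
    series <- volume_series(day, c(0, v))
    s <- best_response_stats(series, rules = rules)
    hit <- category_with_margin(s$best_response, s$best_avg_response,
                                rules, margin)
    if (identical(hit, category)) return(series)
  }
  stop("could not generate a ", category,
       " curve within the margin; noise scale too large?")
}

#' Write a synthetic cohort as the delimited-text formats the readers expect
#'
#' Profile tables are written gene x sample via
#' \code{\link{write_profile_table}}; response categories as a
#' curve-metrics TSV; and, when requested, one raw %TVol curve per PDX
#' consistent with its category.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory (created if needed).
#' @param curves also write raw volume curves (default FALSE).
#' @param rules rules used when generating curves.
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir, curves = FALSE,
                         rules = response_rules()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (kind in names(cohort$profiles)) {
    p <- file.path(dir, paste0(tolower(kind), ".tsv"))
    write_profile_table(t(cohort$profiles[[kind]]$values), p)
    paths <- c(paths, p)
  }
  cm <- file.path(dir, "curve_metrics.tsv")
  utils::write.table(cohort$responses[, c("pdx_id", "treatment", "category")],
                     cm, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, cm)
  if (curves) {
    set.seed(cohort$spec$seed + 1L)
    rows <- lapply(seq_len(nrow(cohort$responses)), function(i) {
      s <- generate_volume_series(cohort$responses$category[i], rules,
                                  noise_sd = cohort$spec$curve_noise_sd)
      data.frame(pdx_id = cohort$responses$pdx_id[i],
                 treatment = cohort$responses$treatment[i],
                 day = s$day, pct_delta_tvol = s$pct_delta_tvol)
    })
    rr <- file.path(dir, "raw_response.tsv")
    utils::write.table(do.call(rbind, rows), rr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, rr)
  }
  invisible(paths)
}
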