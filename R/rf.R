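#' Random-forest configuration
#'
#' Hyperparameters shared by every forest in the package: number of trees
#' (default 1000; a high count is recommended, though forests on the tiny
#' feature subsets favoured by OMC do as well with 10-50 trees, which the
#' test suite exploits), the mtry rule (floor of the square root of the
#' number of considered features, never below 1), and class weighting that
#' counterbalances class imbalance by penalising misclassification of the
#' minority class with the majority-class proportion (and vice versa).
#'
#' Two interchangeable forest backends are supported. \code{"auto"} (the
#' default) picks \code{randomForest} for feature subsets up to
#' \code{backend_cutoff} columns, where its call overhead is lowest, and
#' \code{ranger} above it, where its tree construction scales much better;
#' both receive identical hyperparameters. Either backend can be forced.
#'
#' @param n_trees number of trees (>= 10; default 1000).
#' @param mtry_rule only "sqrt" is implemented.
#' @param class_weighting enable inverse-prevalence class weights
#'   (default TRUE).
#' @param seed optional default seed used by top-level drivers when no seed
#'   argument is given.
#' @param backend "auto", "randomForest" or "ranger".
#' @param backend_cutoff feature count up to which "auto" uses
#'   \code{randomForest} (default 64).
#' @param decision_threshold sensitivity-score cut-off for the class call
#'   (default 0.5).
#' @param rerank_inner stricter OMC mode re-ranking features inside every
#'   inner fold (default FALSE: features are ranked once per outer training
#'   fold and reused across its inner cross-validation; outer estimates are
#'   leakage-free either way since the outer test sample never enters the
#'   ranking).
#' @return Object of class \code{rf_config}.
#' @export
rf_config <- function(n_trees = 1000, mtry_rule = "sqrt",
                      class_weighting = TRUE, seed = NULL,
                      backend = c("auto", "randomForest", "ranger"),
                      backend_cutoff = 64, decision_threshold = 0.5,
                      rerank_inner = FALSE) {
  backend <- match.arg(backend)
  mtry_rule <- match.arg(mtry_rule, "sqrt")
  if (n_trees < 10) stop("n_trees must be >= 10")
  structure(list(n_trees = n_trees, mtry_rule = mtry_rule,
                 class_weighting = class_weighting, seed = seed,
                 backend = backend, backend_cutoff = backend_cutoff,
                 decision_threshold = decision_threshold,
                 rerank_inner = rerank_inner),
            class = "rf_config")
}

mtry_for <- function(p, cfg) max(1L, floor(sqrt(p)))

# D-cl-1 weights: each class is penalised with the *other* class's
# prevalence, so the minority class gets the heavier penalty.
class_weights <- function(y, cfg) {
  if (!cfg$class_weighting)
    return(c(resistant = 0.5, sensitive = 0.5))
  p_sens <- mean(y == "sensitive")
  c(resistant = p_sens, sensitive = 1 - p_sens)
}

pick_backend <- function(p, cfg) {
  if (cfg$backend != "auto") return(cfg$backend)
  if (p <= cfg$backend_cutoff) "randomForest" else "ranger"
}

# Fit a forest on (xtr, ytr) and return sensitivity scores for xte rows.
# Hot path of every (nested) LOOCV: no S3 wrapping, test prediction in the
# same call where the backend allows it.
rf_fit_predict <- function(xtr, ytr, xte, cfg) {
  cw <- class_weights(ytr, cfg)
  backend <- pick_backend(ncol(xtr), cfg)
  mtry <- mtry_for(ncol(xtr), cfg)
  if (backend == "randomForest") {
    fit <- randomForest::randomForest(
      xtr, ytr, xtest = xte, ntree = cfg$n_trees, mtry = mtry,
      classwt = cw, keep.forest = FALSE)
    v <- fit$test$votes
    unname(v[, "sensitive"])
  } else {
    fit <- ranger::ranger(
      x = xtr, y = ytr, num.trees = cfg$n_trees, mtry = mtry,
      class.weights = unname(cw[levels(ytr)]), probability = TRUE,
      oob.error = FALSE, verbose = FALSE, num.threads = 1,
      seed = sample.int(.Machine$integer.max, 1))
    pr <- stats::predict(fit, data = xte, num.threads = 1,
                         verbose = FALSE)$predictions
    unname(pr[, "sensitive"])
  }
}

score_to_class <- function(score, cfg) {
  factor(ifelse(score > cfg$decision_threshold, "sensitive", "resistant"),
         levels = c("resistant", "sensitive"))
}

#' Train a class-weighted random forest on a case
#'
#' @param train a \code{\link{build_case_dataset}} with both classes present.
#' @param features character vector of feature ids to use, or \code{"all"}.
#' @param cfg an \code{\link{rf_config}}.
#' @return Object of class \code{pdx_rf} with the fitted backend object;
#'   use \code{\link{predict_rf}} for sensitivity scores.
#' @export
train_rf <- function(train, features = "all", cfg = rf_config()) {
  stopifnot(inherits(train, "case_dataset"))
  if (train$degenerate) stop("cannot train on single-class data")
  x <- train$features
  if (!identical(features, "all")) {
    if (!length(features)) stop("empty feature subset")
    missing <- setdiff(features, colnames(x))
    if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  y <- train$classes
  cw <- class_weights(y, cfg)
  backend <- pick_backend(ncol(x), cfg)
  mtry <- mtry_for(ncol(x), cfg)
  fit <- if (backend == "randomForest") {
    randomForest::randomForest(x, y, ntree = cfg$n_trees, mtry = mtry,
                               classwt = cw)
  } else {
    ranger::ranger(x = x, y = y, num.trees = cfg$n_trees, mtry = mtry,
                   class.weights = unname(cw[levels(y)]), probability = TRUE,
                   oob.error = FALSE, verbose = FALSE, num.threads = 1,
                   seed = sample.int(.Machine$integer.max, 1))
  }
  structure(list(fit = fit, backend = backend, features = colnames(x),
                 cfg = cfg), class = "pdx_rf")
}

#' Sensitivity scores from a trained forest
#'
#' @param model a \code{\link{train_rf}} object.
#' @param newx samples x features numeric matrix covering the model's
#'   features.
#' @return Numeric vector of sensitivity probabilities in [0, 1].
#' @export
predict_rf <- function(model, newx) {
  stopifnot(inherits(model, "pdx_rf"))
  newx <- newx[, model$features, drop = FALSE]
  if (model$backend == "randomForest") {
    unname(stats::predict(model$fit, newx, type = "prob")[, "sensitive"])
  } else {
    unname(stats::predict(model$fit, data = newx, num.threads = 1,
                          verbose = FALSE)$predictions[, "sensitive"])
  }
}

fold_prediction_row <- function(pdx_id, truth, score, cfg) {
  data.frame(pdx_id = pdx_id, truth = as.character(truth),
             predicted = as.character(score_to_class(score, cfg)),
             score = score, stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validation of a random forest
#'
#' Standard LOOCV: for each PDX, a forest is trained on the remaining n - 1
#' and predicts the held-out one. A fold whose training set collapses to a
#' single class predicts that majority class (logged).
#'
#' @param case a \code{\link{build_case_dataset}} with n >= 3.
#' @param cfg an \code{\link{rf_config}}.
#' @param features feature-id subset or "all".
#' @param seed optional seed set before the first fold (one seed drives the
#'   whole LOOCV pass).
#' @return Data frame of fold predictions: \code{pdx_id}, \code{truth},
#'   \code{predicted}, \code{score}.
#' @export
loocv_rf <- function(case, cfg = rf_config(), features = "all", seed = NULL) {
  stopifnot(inherits(case, "case_dataset"))
  if (case$n < 3) stop("LOOCV needs n >= 3")
  if (!is.null(seed %||% cfg$seed)) set.seed(seed %||% cfg$seed)
  x <- case$features
  if (!identical(features, "all")) x <- x[, features, drop = FALSE]
  y <- case$classes
  out <- vector("list", case$n)
  for (i in seq_len(case$n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) {
      maj <- names(which.max(table(y[-i])))
      score <- if (maj == "sensitive") 1 else 0
    } else {
      score <- rf_fit_predict(x[-i, , drop = FALSE], y[-i],
                              x[i, , drop = FALSE], cfg)
    }
    out[[i]] <- fold_prediction_row(rownames(x)[i], y[i], score, cfg)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Inner LOOCV MCC of a forest restricted to `ids` (or re-ranked top-k when
# cfg$rerank_inner). Used only inside rf_omc_select.
inner_loocv_mcc <- function(x, y, ids, k, cfg, train_case = NULL) {
  n <- nrow(x)
  scores <- numeric(n)
  for (j in seq_len(n)) {
    yj <- y[-j]
    if (length(unique(yj)) < 2) {
      scores[j] <- if (names(which.max(table(yj))) == "sensitive") 1 else 0
      next
    }
    idj <- ids
    if (cfg$rerank_inner && !is.null(k)) {
      rj <- rank_features(case_subset(train_case, setdiff(seq_len(n), j)),
                          cfg = cfg)
      idj <- top_k(rj, min(k, nrow(rj)))
    }
    scores[j] <- rf_fit_predict(x[-j, idj, drop = FALSE], yj,
                                x[j, idj, drop = FALSE], cfg)
  }
  pred <- score_to_class(scores, cfg)
  mcc(confusion(as.character(pred), as.character(y)))
}

#' Optimal-model-complexity selection on a training fold
#'
#' The OMC procedure: rank all features of the training fold univariately,
#' then for every candidate subset size k in 2, 3, ..., floor(n/2) -- plus
#' the full feature set, kept to detect cases needing more than the top n/2
#' features -- run an inner LOOCV of the class-weighted forest on the top-k
#' features and record its MCC. The selected model is the candidate with
#' the highest inner-LOOCV MCC; ties resolve to the smallest subset
#' (parsimony), and an NA inner MCC is worse than any numeric value. The
#' n/2 cap keeps at least two training samples per considered feature.
#'
#' @param train a \code{\link{build_case_dataset}} training fold, both
#'   classes present, n >= 6.
#' @param cfg an \code{\link{rf_config}}.
#' @param ranking optional precomputed \code{\link{rank_features}} result.
#' @return Object of class \code{omc_trace}: \code{candidate_sizes}
#'   (character, sizes plus "ALL"), \code{inner_mcc}, \code{selected_size},
#'   \code{selected_features}, \code{ranking}, \code{n_features}.
#' @export
rf_omc_select <- function(train, cfg = rf_config(), ranking = NULL) {
  stopifnot(inherits(train, "case_dataset"))
  if (train$degenerate) stop("single-class training fold")
  if (train$n < 6) stop("OMC selection needs n >= 6")
  if (is.null(ranking)) ranking <- rank_features(train, cfg = cfg)
  nf <- nrow(ranking)
  kmax <- min(floor(train$n / 2), nf)
  ks <- if (kmax >= 2) seq(2L, kmax) else integer(0)
  sizes <- c(as.character(ks), "ALL")
  x <- train$features
  y <- train$classes
  inner <- vapply(seq_along(sizes), function(i) {
    if (sizes[i] == "ALL") {
      inner_loocv_mcc(x, y, colnames(x), NULL, cfg, train)
    } else {
      k <- as.integer(sizes[i])
      inner_loocv_mcc(x, y, top_k(ranking, k), k, cfg, train)
    }
  }, numeric(1))
  # selection: highest inner MCC; NA is worst; ties -> fewest features
  eff_size <- ifelse(sizes == "ALL", nf, suppressWarnings(as.integer(sizes)))
  key <- ifelse(is.na(inner), -Inf, inner)
  best <- order(-key, eff_size)[1]
  selected_features <- if (sizes[best] == "ALL") colnames(x)
                       else top_k(ranking, as.integer(sizes[best]))
  structure(list(candidate_sizes = sizes, inner_mcc = inner,
                 selected_size = sizes[best],
                 selected_features = selected_features,
                 ranking = ranking, n_features = nf,
                 train_ids = rownames(x)),
            class = "omc_trace")
}

#' @export
print.omc_trace <- function(x, ...) {
  cat(sprintf("OMC selection: %d candidates, selected size %s (inner MCC %s)\n",
              length(x$candidate_sizes), x$selected_size,
              format(x$inner_mcc[x$candidate_sizes == x$selected_size],
                     digits = 3)))
  invisible(x)
}

#' Nested LOOCV of the OMC random forest
#'
#' Outer LOOCV in which each fold's model is chosen by
#' \code{\link{rf_omc_select}} on that fold's training set alone: the
#' held-out PDX never influences feature ranking, subset-size selection or
#' forest training, so the pooled outer predictions give an unbiased
#' performance estimate. The inner LOOCV only selects the model complexity
#' used to predict the fold's left-out PDX.
#'
#' @param case a \code{\link{build_case_dataset}} with n >= 7.
#' @param cfg an \code{\link{rf_config}}.
#' @param seed optional seed for the full replicate (one seed drives outer
#'   and inner loops alike).
#' @return List with \code{predictions} (fold-prediction data frame) and
#'   \code{traces} (one \code{omc_trace} per outer fold; NULL for
#'   degenerate training folds, which predict the training majority).
#' @export
nested_loocv_rf_omc <- function(case, cfg = rf_config(), seed = NULL) {
  stopifnot(inherits(case, "case_dataset"))
  if (case$n < 7) stop("nested LOOCV needs n >= 7")
  if (!is.null(seed %||% cfg$seed)) set.seed(seed %||% cfg$seed)
  x <- case$features; y <- case$classes
  preds <- vector("list", case$n)
  traces <- vector("list", case$n)
  for (i in seq_len(case$n)) {
    train <- case_subset(case, setdiff(seq_len(case$n), i))
    if (train$degenerate) {
      maj <- names(which.max(table(train$classes)))
      score <- if (maj == "sensitive") 1 else 0
      message("outer fold ", i, ": degenerate training fold, predicting majority")
    } else {
      tr <- rf_omc_select(train, cfg)
      traces[[i]] <- tr
      score <- rf_fit_predict(train$features[, tr$selected_features, drop = FALSE],
                              train$classes,
                              x[i, tr$selected_features, drop = FALSE], cfg)
    }
    preds[[i]] <- fold_prediction_row(rownames(x)[i], y[i], score, cfg)
  }
  list(predictions = do.call(rbind, preds), traces = traces)
}

# Fisher scan of a binary profile: best sensitising gene (phi > 0, lowest p).
# Returns NULL when no gene has phi > 0.
best_sensitising_gene <- function(x, y) {
  sens <- y == "sensitive"
  a <- colSums(x[sens, , drop = FALSE])
  m <- colSums(x)
  ns <- sum(sens); nr <- sum(!sens)
  p <- fisher_p_vec(a, m, ns, nr)
  p[m == 0 | m == nrow(x)] <- 1            # unelectable: constant genes
  phi <- phi_coefficient(a, m - a, ns - a, nr - (m - a))
  eligible <- phi > 0
  if (!any(eligible)) return(NULL)
  ids <- colnames(x)
  o <- order(p, -abs(phi), ids)
  o <- o[eligible[o]]
  list(gene = ids[o[1]], p_value = p[o[1]], phi = phi[o[1]])
}

#' LOOCV of the best single-gene mutation marker
#'
#' The standard actionable-mutation protocol: per LOOCV fold, a two-sided
#' Fisher's exact test is computed for every gene of the (binary) SNV
#' profile on the training fold, and the lowest-p gene among sensitising
#' mutations (phi > 0) becomes the marker; the held-out PDX is predicted
#' sensitive iff it carries an SNV in the marker gene. When no training
#' gene has phi > 0, the fold predicts resistant (no marker, no
#' sensitivity call).
#'
#' @param case a \code{\link{build_case_dataset}} on a binary profile.
#' @return List with \code{predictions} (fold predictions, scores in
#'   \{0, 1\}) and \code{genes} (character vector of the marker gene chosen
#'   per fold, NA where none existed).
#' @export
single_gene_marker_loocv <- function(case) {
  stopifnot(inherits(case, "case_dataset"))
  if (!case$profile_kind %in% c("SNV", "CNA"))
    stop("single-gene markers require a binary profile")
  if (case$n < 3) stop("LOOCV needs n >= 3")
  x <- case$features; y <- case$classes
  cfg <- rf_config(n_trees = 10)  # only for the 0.5 decision threshold
  preds <- vector("list", case$n)
  genes <- character(case$n)
  for (i in seq_len(case$n)) {
    yi <- droplevels(y[-i])
    best <- if (nlevels(yi) < 2) NULL
            else best_sensitising_gene(x[-i, , drop = FALSE], y[-i])
    if (is.null(best)) {
      genes[i] <- NA_character_
      score <- 0
    } else {
      genes[i] <- best$gene
      score <- unname(x[i, best$gene])
    }
    preds[[i]] <- fold_prediction_row(rownames(x)[i], y[i], score, cfg)
  }
  list(predictions = do.call(rbind, preds), genes = genes)
}

#' Best single-gene marker on the full case
#'
#' Recalculates the marker on all samples, so it is ready for use on
#' forthcoming tumours.
#'
#' @param case a \code{\link{build_case_dataset}} on a binary profile.
#' @return List with \code{gene}, \code{p_value} and \code{phi}, or NULL
#'   when no sensitising gene exists.
#' @export
final_single_gene_marker <- function(case) {
  stopifnot(inherits(case, "case_dataset"))
  if (!case$profile_kind %in% c("SNV", "CNA"))
    stop("single-gene markers require a binary profile")
  if (case$degenerate) stop("single-class case")
  best_sensitising_gene(case$features, case$classes)
}

#' Prior-probability random baseline
#'
#' Per LOOCV fold, the proportion of sensitive PDXs in the training fold
#' estimates the probability of a PDX being sensitive; a uniform draw below
#' that estimate predicts the held-out PDX sensitive. One MCC results per
#' full LOOCV pass.
#'
#' @param case a \code{\link{build_case_dataset}} with n >= 3.
#' @param seed seed for the uniform draws.
#' @return Fold-prediction data frame (scores are the fold prior estimates;
#'   \code{predicted} comes from the draw, not the 0.5 threshold).
#' @export
random_prior_baseline <- function(case, seed = NULL) {
  stopifnot(inherits(case, "case_dataset"))
  if (case$n < 3) stop("LOOCV needs n >= 3")
  if (!is.null(seed)) set.seed(seed)
  y <- case$classes
  out <- vector("list", case$n)
  for (i in seq_len(case$n)) {
    p_hat <- mean(y[-i] == "sensitive")
    hit <- stats::runif(1) < p_hat
    out[[i]] <- data.frame(pdx_id = names(y)[i], truth = as.character(y[i]),
                           predicted = if (hit) "sensitive" else "resistant",
                           score = p_hat, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Random-feature control forests
#'
#' Control for the value of OMC-selected features: draw k features
#' uniformly without replacement and run a standard LOOCV of the
#' class-weighted forest on them, once per replicate seed. NA metrics (a
#' replicate that never predicted one of the classes) propagate.
#'
#' @param case a \code{\link{build_case_dataset}}.
#' @param k number of features to draw (k = all features reduces to RF-all).
#' @param cfg an \code{\link{rf_config}}.
#' @param seeds integer vector of replicate seeds (default 1:10).
#' @return Data frame with one row per replicate: \code{seed}, \code{k},
#'   \code{mcc}, \code{pr}, \code{rc}, \code{f1}, \code{specificity},
#'   \code{auc}; drawn feature ids in attribute "features".
#' @export
random_feature_rf <- function(case, k, cfg = rf_config(), seeds = 1:10) {
  stopifnot(inherits(case, "case_dataset"))
  nf <- ncol(case$features)
  if (k < 1 || k > nf) stop("k out of range [1, ", nf, "]")
  rows <- vector("list", length(seeds))
  feats <- vector("list", length(seeds))
  for (s in seq_along(seeds)) {
    set.seed(seeds[s])
    ids <- sample(colnames(case$features), k)
    feats[[s]] <- ids
    pr <- loocv_rf(case, cfg, features = ids, seed = NULL)
    m <- classification_metrics(pr)
    rows[[s]] <- data.frame(seed = seeds[s], k = k, mcc = m$mcc, pr = m$pr,
                            rc = m$rc, f1 = m$f1, specificity = m$specificity,
                            auc = m$auc)
  }
  out <- do.call(rbind, rows)
  attr(out, "features") <- feats
  out
}
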