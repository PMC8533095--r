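#' Rank a training fold's features by association with response
#'
#' Univariate ranking (the default) scores every feature by how strongly it
#' alone discriminates sensitive from resistant PDXs in the training fold:
#' binary features (SNV/CNA) by the two-sided Fisher's exact test, real
#' valued features (CN/GEX) by the two-sided unpaired Welch t-test. For a
#' MERGED profile each feature is tested according to its own type (binary
#' iff all its values are 0/1). Features are sorted by ascending p-value;
#' ties break by decreasing absolute effect size, then lexicographic
#' feature id, so reruns and column permutations give identical rankings.
#' Degenerate (constant) features get p = 1 and rank last. Both effect
#' directions are kept: a forest can exploit markers of sensitivity and of
#' resistance alike.
#'
#' The alternative \code{"permutation_importance"} backend ranks features
#' by the mean decrease in out-of-bag accuracy of a class-weighted random
#' forest trained on all features. It accounts for correlations between
#' features, at the cost of a full-profile forest fit; it is offered as a
#' configuration switch only, never the default.
#'
#' @param train a \code{\link{build_case_dataset}} training fold with both
#'   classes present.
#' @param method "univariate" (default) or "permutation_importance".
#' @param cfg an \code{\link{rf_config}}, used only by the permutation
#'   backend.
#' @return Data frame of class \code{ranked_features} with columns
#'   \code{feature_id}, \code{p_value}, \code{effect}, \code{rank} (1-based,
#'   in rank order).
#' @export
rank_features <- function(train, method = c("univariate", "permutation_importance"),
                          cfg = rf_config()) {
  method <- match.arg(method)
  stopifnot(inherits(train, "case_dataset"))
  if (train$degenerate)
    stop("cannot rank features on a single-class training fold")
  x <- train$features
  sens <- train$classes == "sensitive"
  if (method == "univariate") {
    binary_col <- if (train$profile_kind %in% c("SNV", "CNA")) {
      rep(TRUE, ncol(x))
    } else if (train$profile_kind %in% c("CN", "GEX")) {
      rep(FALSE, ncol(x))
    } else {
      apply(x, 2, function(v) all(v %in% c(0, 1)))
    }
    p <- numeric(ncol(x)); eff <- numeric(ncol(x))
    if (any(binary_col)) {
      xb <- x[, binary_col, drop = FALSE]
      a <- colSums(xb[sens, , drop = FALSE])      # altered among sensitive
      m <- colSums(xb)                            # altered total
      ns <- sum(sens); nr <- sum(!sens)
      pb <- fisher_p_vec(a, m, ns, nr)
      degenerate <- m == 0 | m == nrow(xb)        # constant feature
      pb[degenerate] <- 1
      p[binary_col] <- pb
      eff[binary_col] <- phi_coefficient(a, m - a, ns - a, nr - (m - a))
    }
    if (any(!binary_col)) {
      w <- welch_p_vec(x[, !binary_col, drop = FALSE], sens)
      p[!binary_col] <- w$p_value
      eff[!binary_col] <- w$effect
    }
  } else {
    fit <- randomForest::randomForest(
      x, train$classes, ntree = cfg$n_trees,
      mtry = mtry_for(ncol(x), cfg), classwt = class_weights(train$classes, cfg),
      importance = TRUE)
    imp <- randomForest::importance(fit, type = 1, scale = FALSE)
    p <- rep(NA_real_, ncol(x))
    eff <- as.numeric(imp[, 1])
  }
  ids <- colnames(x)
  o <- if (method == "univariate") order(p, -abs(eff), ids)
       else order(-eff, ids)
  out <- data.frame(feature_id = ids[o], p_value = p[o], effect = eff[o],
                    rank = seq_along(ids), stringsAsFactors = FALSE)
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Top-k features of a ranking
#'
#' @param ranked a \code{\link{rank_features}} result.
#' @param k number of leading features, 1 <= k <= number of features.
#' @return Character vector of the first \code{k} feature ids in rank order.
#' @export
top_k <- function(ranked, k) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (k < 1 || k > nrow(ranked)) stop("k out of range [1, ", nrow(ranked), "]")
  ranked$feature_id[seq_len(k)]
}
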