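#' Confusion counts for a binary response classifier
#'
#' Positives are treatment-sensitive (responder) PDXs; negatives are
#' resistant PDXs.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return Object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) < 1) stop("confusion counts must sum to >= 1")
  structure(as.list(counts), class = "confusion_counts")
}

#' Tabulate predicted against observed response classes
#'
#' @param pred,truth vectors (or factors) of "sensitive"/"resistant" calls
#'   for the same samples; if both are named, names must match as sets and
#'   are used for alignment.
#' @return A \code{\link{confusion_counts}} object.
#' @export
confusion <- function(pred, truth) {
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    if (!setequal(names(pred), names(truth)))
      stop("prediction and truth cover different sample sets")
    pred <- pred[names(truth)]
  }
  if (length(pred) != length(truth))
    stop("prediction and truth differ in length")
  pred <- as.character(pred); truth <- as.character(truth)
  ok <- c("sensitive", "resistant")
  if (!all(pred %in% ok) || !all(truth %in% ok))
    stop("classes must be 'sensitive' or 'resistant'")
  confusion_counts(tp = sum(pred == "sensitive" & truth == "sensitive"),
                   tn = sum(pred == "resistant" & truth == "resistant"),
                   fp = sum(pred == "sensitive" & truth == "resistant"),
                   fn = sum(pred == "resistant" & truth == "sensitive"))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(FN+TN)(TN+FP)(FP+TP)), ranging from
#' -1 (perfect disagreement) through 0 (random-level) to 1 (perfect
#' agreement). When any of the four marginal sums is zero -- e.g. the
#' classifier never predicted one of the classes -- the coefficient is
#' undefined and \code{NA} is returned (never coerced to 0).
#'
#' @param cc a \code{\link{confusion_counts}} object.
#' @return MCC in [-1, 1], or \code{NA}.
#' @export
mcc <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  denom <- (tp + fn) * (fn + tn) * (tn + fp) * (fp + tp)
  if (denom == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Precision, recall, F1 and specificity
#'
#' PR = TP/(TP+FP), RC = TP/(TP+FN), F1 their equally-weighted harmonic
#' mean, specificity = TN/(TN+FP). A metric with a zero denominator is
#' \code{NA}; F1 is \code{NA} when PR or RC is \code{NA}, and 0 when both
#' PR and RC are 0.
#'
#' @param cc a \code{\link{confusion_counts}} object.
#' @return List with elements \code{pr}, \code{rc}, \code{f1},
#'   \code{specificity}.
#' @export
precision_recall_f1 <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  pr <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rc <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(pr) || is.na(rc)) NA_real_
        else if (pr == 0 && rc == 0) 0
        else 2 * pr * rc / (pr + rc)
  sp <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  list(pr = pr, rc = rc, f1 = f1, specificity = sp)
}

# ---- Fisher's exact test (vectorised exact hypergeometric) -----------------

# Two-sided p for tables with fixed margins: a = altered among sensitive,
# m = total altered, ns/nr = sensitive/resistant totals. The two-sided
# p-value sums the probabilities of all tables (same margins) whose
# hypergeometric probability does not exceed that of the observed table,
# with the customary (1 + 1e-7) relative tolerance on the comparison.
fisher_p_one <- function(a, m, ns, nr) {
  support <- max(0L, m - nr):min(m, ns)
  d <- stats::dhyper(support, ns, nr, m)
  obs <- stats::dhyper(a, ns, nr, m)
  sum(d[d <= obs * (1 + 1e-7)])
}

# Vectorised over features: a and m are vectors, ns/nr scalars. Unique
# (a, m) pairs are computed once; thousands of gene features collapse to a
# few dozen distinct tables per training fold.
fisher_p_vec <- function(a, m, ns, nr) {
  key <- paste(a, m)
  u <- !duplicated(key)
  pu <- mapply(fisher_p_one, a[u], m[u], MoreArgs = list(ns = ns, nr = nr))
  unname(pu[match(key, key[u])])
}

phi_coefficient <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  denom <- sqrt((a + b) * (c + d) * (a + c) * (b + d))
  ifelse(denom == 0, 0, (a * d - b * c) / denom)
}

#' Two-sided Fisher's exact test with phi effect size
#'
#' Exact hypergeometric two-sided test on a 2x2 contingency table of
#' alteration status against response class, as used to rank binary gene
#' features. The two-sided p-value is the sum of probabilities of all
#' tables with the same margins that are no more probable than the observed
#' one (the convention of \code{stats::fisher.test}). The effect size is
#' the phi coefficient, signed so that phi > 0 means the alteration is
#' enriched among sensitive PDXs (a sensitising marker). A table with a
#' zero row or column margin is degenerate: p = 1, phi = 0.
#'
#' @param tab 2x2 matrix of counts: rows = (altered, wild-type), columns =
#'   (sensitive, resistant).
#' @return List with \code{p_value}, \code{effect} (phi) and
#'   \code{direction} (sign of phi).
#' @export
fisher_two_sided <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  if (sum(tab) < 1) stop("empty table")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  ns <- a + c; nr <- b + d; m <- a + b
  if (ns == 0 || nr == 0 || m == 0 || (c + d) == 0)
    return(list(p_value = 1, effect = 0, direction = 0))
  p <- fisher_p_one(a, m, ns, nr)
  phi <- phi_coefficient(a, b, c, d)
  list(p_value = min(p, 1), effect = phi, direction = sign(phi))
}

# ---- Welch t-test (vectorised over features) -------------------------------

# x: samples x features matrix; sens: logical vector of sensitive samples.
# Returns list of vectors p_value and effect = mean(sensitive) - mean(resistant).
# Features whose between-group variance term is zero get p = 1 (ranked last).
welch_p_vec <- function(x, sens) {
  n1 <- sum(sens); n2 <- sum(!sens)
  if (n1 < 2 || n2 < 2)
    return(list(p_value = rep(NA_real_, ncol(x)),
                effect = rep(NA_real_, ncol(x))))
  x1 <- x[sens, , drop = FALSE]; x2 <- x[!sens, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums((x1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((x2 - rep(m2, each = n2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1  # degenerate: no within-group variance
  list(p_value = unname(p), effect = unname(m1 - m2))
}

#' Two-sided unpaired t-test (Welch) with mean-difference effect
#'
#' Welch's unequal-variance t-test, as used to rank real-valued gene
#' features. The effect size is mean(sensitive) - mean(resistant). A
#' feature with no within-group variance in either group is degenerate and
#' receives p = 1 (so it ranks last); a group with fewer than 2 values
#' yields an \code{NA} result.
#'
#' @param values_sensitive,values_resistant numeric vectors of the feature's
#'   values in the two classes.
#' @param var_equal use the pooled-variance (classical) t-test instead of
#'   Welch (default \code{FALSE}).
#' @return List with \code{p_value}, \code{effect} and \code{direction}.
#' @export
t_test_two_sided <- function(values_sensitive, values_resistant,
                             var_equal = FALSE) {
  if (length(values_sensitive) < 2 || length(values_resistant) < 2)
    return(list(p_value = NA_real_, effect = NA_real_, direction = NA_real_))
  eff <- mean(values_sensitive) - mean(values_resistant)
  if (stats::var(values_sensitive) == 0 && stats::var(values_resistant) == 0)
    return(list(p_value = 1, effect = eff, direction = sign(eff)))
  p <- stats::t.test(values_sensitive, values_resistant,
                     var.equal = var_equal)$p.value
  list(p_value = p, effect = eff, direction = sign(eff))
}

#' Paired t-test on matched performance vectors
#'
#' Classical paired t-test on the differences \code{a - b}, used to compare
#' the replicate MCCs of two models run with the same seed list, or their
#' per-treatment MCCs. With all differences zero the test is undefined and
#' \code{NA} is returned; with a constant non-zero difference the
#' zero-variance limit applies (p taken to 0 on the favoured side, 1 on the
#' other for one-sided tests).
#'
#' @param a,b equal-length numeric vectors (length >= 2). NA pairs are
#'   dropped.
#' @param alternative "two.sided", "greater" (mean of a - b > 0) or "less".
#' @return The p-value.
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) return(NA_real_)
  d <- a - b
  if (all(d == 0)) {
    message("paired_t: all differences zero; test undefined")
    return(NA_real_)
  }
  stderr <- stats::sd(d) / sqrt(length(d))
  if (stderr < 10 * .Machine$double.eps * abs(mean(d))) {
    # (numerically) constant non-zero difference: degenerate limit
    md <- d[1]
    return(switch(alternative,
                  two.sided = 0,
                  greater = if (md > 0) 0 else 1,
                  less = if (md < 0) 0 else 1))
  }
  stats::t.test(a, b, paired = TRUE, alternative = alternative)$p.value
}

#' ROC curve and AUC from sensitivity scores
#'
#' Sweeps the operating threshold over all distinct score values, recording
#' the (FPR, TPR) pair at each, from (0, 0) to (1, 1); the AUC is the
#' trapezoidal area under these points. A hard binary 0/1 predictor yields
#' a single intermediate point, for which the trapezoid reduces to
#' AUC = (TPR + 1 - FPR) / 2.
#'
#' @param scores numeric sensitivity scores in [0, 1].
#' @param truth "sensitive"/"resistant" observed classes.
#' @return List of class \code{roc_curve}: \code{points} (data frame with
#'   \code{fpr}, \code{tpr}), and \code{auc} (\code{NA} when only one class
#'   is present in \code{truth}).
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  truth <- as.character(truth)
  pos <- truth == "sensitive"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    return(structure(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                          auc = NA_real_), class = "roc_curve"))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp <- cumsum(!duplicated(s))          # tie groups share one threshold
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %s\n", nrow(x$points),
              format(x$auc, digits = 3)))
  invisible(x)
}

#' Full metric set from per-fold predictions
#'
#' Convenience wrapper computing the confusion counts and every reported
#' metric (MCC, PR, RC, F1, specificity, AUC) from a fold-prediction data
#' frame as returned by the cross-validation drivers.
#'
#' @param predictions data frame with columns \code{truth}, \code{predicted}
#'   and \code{score}.
#' @return List with \code{counts} and the six metrics.
#' @export
classification_metrics <- function(predictions) {
  cc <- confusion(predictions$predicted, predictions$truth)
  prf <- precision_recall_f1(cc)
  auc <- if ("score" %in% names(predictions))
    roc_auc(predictions$score, predictions$truth)$auc else NA_real_
  list(counts = cc, mcc = mcc(cc), pr = prf$pr, rc = prf$rc, f1 = prf$f1,
       specificity = prf$specificity, auc = auc)
}
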