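#' mRECIST-like response categorisation rules
#'
#' Thresholds applied to the two summary statistics of a tumour-volume curve
#' (BestResponse and BestAvgResponse, both in % volume change relative to
#' treatment start) to assign one of the four response categories CR, PR, SD
#' or PD. Defaults follow the criteria of the PDX encyclopedia study the
#' curve metrics derive from: CR if BestResponse < -95 and BestAvgResponse
#' < -40; else PR if < -50 and < -20; else SD if < 35 and < 30; else PD;
#' with measurements before day 10 excluded (\code{min_day}). All
#' comparisons are strict; a statistic exactly at a threshold falls to the
#' less responsive class. The thresholds are configuration, not constants.
#'
#' @param min_day earliest day (inclusive) eligible for the best-response
#'   statistics (default 10).
#' @param cr_best,cr_avg CR thresholds on BestResponse / BestAvgResponse.
#' @param pr_best,pr_avg PR thresholds.
#' @param sd_best,sd_avg SD thresholds.
#' @return An object of class \code{response_rules}.
#' @export
response_rules <- function(min_day = 10, cr_best = -95, cr_avg = -40,
                           pr_best = -50, pr_avg = -20,
                           sd_best = 35, sd_avg = 30) {
  if (!(cr_best < pr_best && pr_best < sd_best))
    stop("BestResponse thresholds must satisfy cr_best < pr_best < sd_best")
  if (!(cr_avg < pr_avg))
    stop("BestAvgResponse thresholds must satisfy cr_avg < pr_avg")
  structure(list(min_day = min_day, cr_best = cr_best, cr_avg = cr_avg,
                 pr_best = pr_best, pr_avg = pr_avg,
                 sd_best = sd_best, sd_avg = sd_avg),
            class = "response_rules")
}

RESPONSE_CATEGORIES <- c("CR", "PR", "SD", "PD")

#' Construct a tumour-volume series
#'
#' Observations of percentage tumour-volume change relative to the volume at
#' treatment start (day 0, value 0 by definition), recorded on strictly
#' increasing days. Measurement spacing is not enforced.
#'
#' @param day integer-like vector of measurement days (>= 0).
#' @param pct_delta_tvol percentage volume change at each day (>= -100).
#' @param pdx_id,treatment optional identifiers carried along.
#' @return A data frame of class \code{volume_series}.
#' @export
volume_series <- function(day, pct_delta_tvol, pdx_id = NA_character_,
                          treatment = NA_character_) {
  stopifnot(length(day) == length(pct_delta_tvol))
  o <- order(day)
  day <- day[o]; pct_delta_tvol <- pct_delta_tvol[o]
  if (any(day < 0)) stop("days must be >= 0")
  if (anyDuplicated(day)) stop("days must be strictly increasing")
  if (any(pct_delta_tvol < -100))
    stop("%TVol change cannot be below -100")
  if (!any(day == 0)) {
    day <- c(0, day); pct_delta_tvol <- c(0, pct_delta_tvol)
  } else if (pct_delta_tvol[day == 0] != 0) {
    stop("day 0 is the baseline and must have value 0")
  }
  structure(data.frame(day = day, pct_delta_tvol = pct_delta_tvol),
            pdx_id = pdx_id, treatment = treatment,
            class = c("volume_series", "data.frame"))
}

#' Best response and best average response of a volume curve
#'
#' \code{best_response} is the minimum %TVol change over post-baseline
#' observations at or after \code{min_day}. \code{best_avg_response} is the
#' minimum, over the same eligible days t, of the running mean of %TVol
#' change from the first post-baseline observation up to t. The eligibility
#' window applies to both the running-average start and the minimum search.
#'
#' @param series a \code{\link{volume_series}} (or data frame with columns
#'   \code{day}, \code{pct_delta_tvol}).
#' @param min_day earliest eligible day; defaults to the value stored in
#'   \code{rules} if given, else 10.
#' @param rules optional \code{\link{response_rules}} supplying
#'   \code{min_day}.
#' @return List with elements \code{best_response} and
#'   \code{best_avg_response}.
#' @export
best_response_stats <- function(series, min_day = NULL, rules = NULL) {
  if (is.null(min_day)) min_day <- if (is.null(rules)) 10 else rules$min_day
  post <- series[series$day > 0, , drop = FALSE]
  post <- post[order(post$day), , drop = FALSE]
  eligible <- post$day >= min_day
  if (!any(eligible))
    stop("no observation at or after day ", min_day)
  v <- post$pct_delta_tvol[eligible]
  list(best_response = min(v),
       best_avg_response = min(cumsum(v) / seq_along(v)))
}

#' Assign a response category to a volume curve
#'
#' Applies the rule cascade of \code{\link{response_rules}} to the curve's
#' \code{\link{best_response_stats}}. All threshold comparisons are strict,
#' so boundary curves fall to the less responsive class. Curves with a
#' single eligible observation are categorised from that point alone.
#'
#' @param series a \code{\link{volume_series}}.
#' @param rules a \code{\link{response_rules}} object.
#' @return One of \code{"CR"}, \code{"PR"}, \code{"SD"}, \code{"PD"}.
#' @export
categorize_response <- function(series, rules = response_rules()) {
  s <- best_response_stats(series, rules = rules)
  b <- s$best_response; a <- s$best_avg_response
  if (b < rules$cr_best && a < rules$cr_avg) return("CR")
  if (b < rules$pr_best && a < rules$pr_avg) return("PR")
  if (b < rules$sd_best && a < rules$sd_avg) return("SD")
  "PD"
}

#' Collapse a response category to the binary response class
#'
#' PDXs showing any level of sensitivity (CR, PR or SD) are responders
#' ("sensitive"); progressive disease (PD) marks non-responders
#' ("resistant").
#'
#' @param category character vector of categories among CR/PR/SD/PD.
#' @return Character vector of "sensitive"/"resistant".
#' @export
binarize_response <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), RESPONSE_CATEGORIES)
  if (length(bad)) stop("unknown response category: ", paste(bad, collapse = ", "))
  ifelse(category == "PD", "resistant", "sensitive")
}

#' Reconcile retrieved and calculated response categories
#'
#' When a category retrieved from a processed curve-metrics table disagrees
#' with the category recalculated from the raw volume curve, the calculated
#' one wins, so that every PDX-treatment pair is categorised under one set
#' of rules. A missing side falls back to the present one.
#'
#' @param retrieved,calculated character vectors of categories (NA allowed).
#' @return Data frame with columns \code{final}, \code{discrepant} (TRUE
#'   where both sides were present and differed) and \code{fallback} (TRUE
#'   where one side was missing); the number of discrepancies is available
#'   as \code{sum(out$discrepant)}.
#' @export
reconcile_categories <- function(retrieved, calculated) {
  stopifnot(length(retrieved) == length(calculated))
  retrieved <- as.character(retrieved); calculated <- as.character(calculated)
  if (any(is.na(retrieved) & is.na(calculated)))
    stop("a pair with both categories missing cannot be reconciled")
  final <- ifelse(is.na(calculated), retrieved, calculated)
  discrepant <- !is.na(retrieved) & !is.na(calculated) & retrieved != calculated
  fallback <- is.na(retrieved) | is.na(calculated)
  if (any(fallback))
    message(sum(fallback), " pair(s) had a single category available; used as-is")
  data.frame(final = final, discrepant = discrepant, fallback = fallback)
}

#' Build response records from categories
#'
#' @param pdx_id,treatment identifier vectors (recycled if length 1).
#' @param category response categories among CR/PR/SD/PD.
#' @param source "retrieved" or "calculated" provenance tag.
#' @return Data frame with columns \code{pdx_id}, \code{treatment},
#'   \code{category}, \code{binary_class}, \code{source}.
#' @export
response_records <- function(pdx_id, treatment, category,
                             source = "calculated") {
  data.frame(pdx_id = as.character(pdx_id),
             treatment = as.character(treatment),
             category = as.character(category),
             binary_class = binarize_response(category),
             source = source,
             stringsAsFactors = FALSE)
}

#' Read a raw tumour-volume response table
#'
#' Long-format TSV/CSV with columns \code{pdx_id}, \code{treatment},
#' \code{day}, \code{pct_delta_tvol}; returns one
#' \code{\link{volume_series}} per PDX-treatment pair.
#'
#' @param path file path.
#' @param sep separator; inferred from extension when \code{NULL}.
#' @return Named list of \code{\link{volume_series}} keyed by
#'   "pdx_id|treatment".
#' @export
read_raw_response <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("pdx_id", "treatment", "day", "pct_delta_tvol")
  if (!all(need %in% names(tab)))
    stop("raw response table needs columns: ", paste(need, collapse = ", "))
  key <- paste(tab$pdx_id, tab$treatment, sep = "|")
  lapply(split(tab, key), function(d)
    volume_series(d$day, d$pct_delta_tvol,
                  pdx_id = d$pdx_id[1], treatment = d$treatment[1]))
}

#' Read a processed curve-metrics table of response categories
#'
#' @param path TSV/CSV with columns \code{pdx_id}, \code{treatment},
#'   \code{category}.
#' @param sep separator; inferred from extension when \code{NULL}.
#' @return Response-record data frame (see \code{\link{response_records}})
#'   with \code{source = "retrieved"}.
#' @export
read_curve_metrics <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("pdx_id", "treatment", "category")
  if (!all(need %in% names(tab)))
    stop("curve-metrics table needs columns: ", paste(need, collapse = ", "))
  response_records(tab$pdx_id, tab$treatment, tab$category,
                   source = "retrieved")
}
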