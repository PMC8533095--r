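#' Profile kinds understood by the package
#'
#' The four molecular profiles of a PDX cohort plus the merged profile:
#' \code{SNV} (binary mutation presence per gene), \code{CNA} (binarised
#' copy-number aberration), \code{CN} (real-valued copy number), \code{GEX}
#' (real-valued gene expression, FPKM scale) and \code{MERGED} (column-wise
#' concatenation of several profiles with profile-prefixed feature ids).
#'
#' @format A character vector of the five profile kind labels.
#' @export
PROFILE_KINDS <- c("SNV", "CNA", "CN", "GEX", "MERGED")

.binary_kinds <- c("SNV", "CNA")

#' Construct a feature matrix for one molecular profile
#'
#' A \code{feature_matrix} holds model-ready gene-level features for a set of
#' PDX samples: samples in rows, features (genes) in columns. Binary profiles
#' (\code{SNV}, \code{CNA}) must contain only 0/1; real-valued profiles
#' (\code{CN}, \code{GEX}) must contain finite non-negative values. Missing
#' values are not allowed: encoding is expected to have resolved them.
#'
#' @param values numeric matrix, samples x features, with both dimnames set
#'   (row names are PDX identifiers, column names gene/feature identifiers).
#' @param profile_kind one of \code{\link{PROFILE_KINDS}}.
#' @return An object of class \code{feature_matrix}: a list with elements
#'   \code{values}, \code{profile_kind}, \code{sample_ids}, \code{feature_ids}.
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2,
#'             dimnames = list(c("X1", "X2"), c("TP53", "KRAS")))
#' fm <- feature_matrix(m, "SNV")
#' @export
feature_matrix <- function(values, profile_kind) {
  profile_kind <- match.arg(profile_kind, PROFILE_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and feature column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in feature matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids in feature matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature matrix contains missing or non-finite values")
  if (profile_kind %in% .binary_kinds && !all(values %in% c(0, 1)))
    stop(sprintf("%s features must be binary (0/1)", profile_kind))
  if (!(profile_kind %in% .binary_kinds) && any(values < 0))
    stop(sprintf("%s features must be non-negative", profile_kind))
  structure(
    list(values = values, profile_kind = profile_kind,
         sample_ids = rownames(values), feature_ids = colnames(values)),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d samples x %d features\n",
              x$profile_kind, length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

is_binary_profile <- function(x) x$profile_kind %in% .binary_kinds

#' Copy-number binarisation thresholds
#'
#' Thresholds delimiting the three aberrant copy-number bands used to
#' binarise real-valued copy number: moderate amplification (copy number
#' >= \code{amp5_low} and < \code{amp8_low}), strong amplification
#' (>= \code{amp8_low}) and deletion (<= \code{del_high}). Values between
#' \code{del_high} and \code{amp5_low} are considered copy-number neutral.
#'
#' @param amp5_low lower bound of the moderate-amplification band (default 5).
#' @param amp8_low lower bound of the strong-amplification band (default 8).
#' @param del_high upper bound of the deletion band (default 0.8).
#' @return An object of class \code{cna_thresholds}.
#' @export
cna_thresholds <- function(amp5_low = 5, amp8_low = 8, del_high = 0.8) {
  stopifnot(is.numeric(amp5_low), is.numeric(amp8_low), is.numeric(del_high))
  if (!(del_high < amp5_low && amp5_low < amp8_low))
    stop("thresholds must satisfy del_high < amp5_low < amp8_low")
  structure(list(amp5_low = amp5_low, amp8_low = amp8_low,
                 del_high = del_high), class = "cna_thresholds")
}

#' Read a gene x sample profile table from delimited text
#'
#' Reads a TSV/CSV table laid out like the public PDX workbook tabs: one
#' header row of sample identifiers, one row per gene, first column the gene
#' symbol. Sample identifiers are whitespace-trimmed and matched
#' case-sensitively. Duplicate gene rows are resolved by keeping, for each
#' duplicated gene, the row whose values deviate most (in absolute sum) from
#' the profile median; a message reports how many rows were dropped.
#'
#' @param path path to the delimited text file.
#' @param sep field separator; \code{NULL} (default) infers from the file
#'   extension (".csv" is comma, anything else tab).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_profile_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2) stop("profile table needs a gene column plus >= 1 sample column")
  genes <- trimws(as.character(tab[[1]]))
  samples <- trimws(colnames(tab)[-1])
  if (anyDuplicated(samples))
    stop("duplicate sample column(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cell in profile table body")
  rownames(vals) <- genes
  colnames(vals) <- samples
  if (anyDuplicated(genes)) {
    med <- stats::median(vals, na.rm = TRUE)
    dev <- rowSums(abs(vals - med))
    keep <- !logical(nrow(vals))
    for (g in unique(genes[duplicated(genes)])) {
      idx <- which(genes == g)
      keep[idx] <- FALSE
      keep[idx[which.max(dev[idx])]] <- TRUE
    }
    message(sum(!keep), " duplicate gene row(s) dropped (kept largest deviation from profile median)")
    vals <- vals[keep, , drop = FALSE]
  }
  vals
}

#' Write a gene x sample profile table as delimited text
#'
#' Inverse of \code{\link{read_profile_table}}: writes a matrix (genes in
#' rows, samples in columns) with a leading gene-symbol column.
#'
#' @param mat numeric matrix with gene row names and sample column names.
#' @param path output file path; extension picks the separator as in
#'   \code{\link{read_profile_table}}.
#' @param gene_col name of the leading gene column (default "gene").
#' @return Invisibly, \code{path}.
#' @export
write_profile_table <- function(mat, path, gene_col = "gene") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))  # full precision: exact round-trip
  df <- data.frame(rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode detected SNVs as a binary gene x sample feature matrix
#'
#' A gene's SNV feature for a PDX is 1 if at least one single-nucleotide
#' variant was detected in that gene for that PDX, and 0 (wild type)
#' otherwise. Collapsing all variants of a gene into one presence/absence
#' feature gives a far denser matrix than one feature per variant, since a
#' gene typically carries several distinct SNVs.
#'
#' @param calls data frame of detected variants with columns \code{sample_id}
#'   and \code{gene}; one row per detected SNV (repeated gene-sample rows are
#'   allowed and collapse to 1).
#' @param sample_ids character vector of all profiled PDX ids (samples without
#'   any call become all-zero rows).
#' @param genes optional character vector fixing the feature universe;
#'   defaults to the genes present in \code{calls}.
#' @return A \code{\link{feature_matrix}} of kind \code{SNV}.
#' @export
encode_snv <- function(calls, sample_ids, genes = NULL) {
  stopifnot(is.data.frame(calls), all(c("sample_id", "gene") %in% names(calls)))
  sample_ids <- trimws(as.character(sample_ids))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  cs <- trimws(as.character(calls$sample_id))
  cg <- trimws(as.character(calls$gene))
  unknown <- setdiff(unique(cs), sample_ids)
  if (length(unknown))
    stop("mutation call(s) for unknown sample id(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(genes)) genes <- sort(unique(cg))
  m <- matrix(0, length(sample_ids), length(genes),
              dimnames = list(sample_ids, genes))
  if (nrow(calls)) {
    keep <- cg %in% genes
    m[cbind(cs[keep], cg[keep])] <- 1
  }
  feature_matrix(m, "SNV")
}

#' Binarise copy number into copy-number-alteration features
#'
#' The CNA feature of a gene is 1 when its copy number is aberrant --
#' strongly amplified (>= \code{amp8_low}), moderately amplified
#' (>= \code{amp5_low} and < \code{amp8_low}) or deleted
#' (<= \code{del_high}) -- and 0 otherwise.
#'
#' @param cn numeric matrix of copy numbers, genes x samples (as read by
#'   \code{\link{read_profile_table}}) or samples x genes with
#'   \code{genes_in_rows = FALSE}.
#' @param thresholds a \code{\link{cna_thresholds}} object.
#' @param genes_in_rows whether genes are in rows (default TRUE).
#' @return A \code{\link{feature_matrix}} of kind \code{CNA} (samples x genes).
#' @export
encode_cna <- function(cn, thresholds = cna_thresholds(), genes_in_rows = TRUE) {
  stopifnot(inherits(thresholds, "cna_thresholds"))
  if (anyNA(cn) || any(!is.finite(cn)) || any(cn < 0))
    stop("copy numbers must be finite and non-negative")
  if (genes_in_rows) cn <- t(cn)
  aberrant <- cn >= thresholds$amp5_low | cn <= thresholds$del_high
  m <- matrix(as.numeric(aberrant), nrow(cn), ncol(cn), dimnames = dimnames(cn))
  feature_matrix(m, "CNA")
}

#' Wrap real-valued copy number as a feature matrix
#'
#' @param cn numeric matrix of copy numbers (genes x samples by default).
#' @param genes_in_rows whether genes are in rows (default TRUE).
#' @return A \code{\link{feature_matrix}} of kind \code{CN}.
#' @export
encode_cn <- function(cn, genes_in_rows = TRUE) {
  if (genes_in_rows) cn <- t(cn)
  feature_matrix(cn, "CN")
}

#' Wrap gene expression (FPKM) as a feature matrix
#'
#' Expression values are used as provided, on the FPKM scale, with no log
#' transform or normalisation.
#'
#' @param fpkm numeric matrix of expression values (genes x samples by default).
#' @param genes_in_rows whether genes are in rows (default TRUE).
#' @return A \code{\link{feature_matrix}} of kind \code{GEX}.
#' @export
encode_gex <- function(fpkm, genes_in_rows = TRUE) {
  if (genes_in_rows) fpkm <- t(fpkm)
  feature_matrix(fpkm, "GEX")
}

#' Merge several profiles into one feature matrix
#'
#' Column-wise concatenation over the intersection of the profiles' sample
#' sets. Feature ids are prefixed with the profile kind ("SNV:TP53",
#' "GEX:TP53", ...) so the same gene contributed by two profiles yields two
#' distinct features.
#'
#' @param profiles list of two or more \code{\link{feature_matrix}} objects.
#' @return A \code{\link{feature_matrix}} of kind \code{MERGED}.
#' @export
merge_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  if (!all(vapply(profiles, inherits, logical(1), "feature_matrix")))
    stop("all elements must be feature_matrix objects")
  common <- Reduce(intersect, lapply(profiles, function(p) p$sample_ids))
  if (!length(common)) stop("profiles share no samples")
  blocks <- lapply(profiles, function(p) {
    v <- p$values[common, , drop = FALSE]
    colnames(v) <- paste(p$profile_kind, colnames(v), sep = ":")
    v
  })
  merged <- do.call(cbind, blocks)
  # MERGED mixes binary and real features; validated only for finiteness
  fm <- feature_matrix(merged, "MERGED")
  fm
}

#' Assemble the modelling dataset for one treatment-cancer type case
#'
#' Intersects the PDXs of a molecular profile with those carrying a response
#' record for the given treatment, yielding the paired feature vectors and
#' binary response classes on which classifiers are trained and evaluated.
#' Cases with fewer samples than \code{min_n} are flagged (not rejected):
#' the inclusion threshold is configuration, not code. Cases where only one
#' response class is present are flagged degenerate.
#'
#' @param profile a \code{\link{feature_matrix}}.
#' @param responses a response-record data frame (see
#'   \code{\link{response_records}}) with columns \code{pdx_id},
#'   \code{treatment} and \code{binary_class}.
#' @param treatment treatment identifier to select from \code{responses}.
#' @param cancer_type cancer-type label carried along for reporting.
#' @param min_n minimum sample count below which the case is flagged
#'   (default 35).
#' @return An object of class \code{case_dataset}: list with the restricted
#'   feature matrix \code{features} (samples x features), factor
#'   \code{classes} (levels resistant, sensitive), counts and flags.
#' @export
build_case_dataset <- function(profile, responses, treatment,
                               cancer_type = NA_character_, min_n = 35) {
  stopifnot(inherits(profile, "feature_matrix"))
  stopifnot(all(c("pdx_id", "treatment", "binary_class") %in% names(responses)))
  resp <- responses[responses$treatment == treatment, , drop = FALSE]
  if (anyDuplicated(resp$pdx_id))
    stop("multiple response records for one PDX under treatment ", treatment)
  common <- intersect(profile$sample_ids, trimws(as.character(resp$pdx_id)))
  if (!length(common))
    stop("no PDX is both profiled and treated with ", treatment)
  cls <- resp$binary_class[match(common, trimws(as.character(resp$pdx_id)))]
  classes <- factor(as.character(cls), levels = c("resistant", "sensitive"))
  if (anyNA(classes)) stop("binary_class must be 'resistant' or 'sensitive'")
  names(classes) <- common
  n <- length(common)
  structure(list(
    features = profile$values[common, , drop = FALSE],
    classes = classes,
    treatment = treatment,
    cancer_type = cancer_type,
    profile_kind = profile$profile_kind,
    n = n,
    n_sensitive = sum(classes == "sensitive"),
    n_resistant = sum(classes == "resistant"),
    degenerate = length(unique(classes)) < 2L,
    below_min_n = n < min_n,
    min_n = min_n
  ), class = "case_dataset")
}

#' @export
print.case_dataset <- function(x, ...) {
  cat(sprintf("case_dataset: %s / %s / %s, n = %d (%d sensitive, %d resistant)\n",
              x$treatment, x$cancer_type, x$profile_kind,
              x$n, x$n_sensitive, x$n_resistant))
  if (x$degenerate) cat("  [degenerate: single response class]\n")
  if (x$below_min_n) cat(sprintf("  [below the %d-PDX inclusion threshold]\n", x$min_n))
  invisible(x)
}

# internal: case_dataset straight from a samples x features matrix + classes
case_from_matrix <- function(x, classes, treatment = "synthetic",
                             cancer_type = "synthetic", profile_kind = "SNV",
                             min_n = 35) {
  classes <- factor(as.character(classes), levels = c("resistant", "sensitive"))
  names(classes) <- rownames(x)
  structure(list(
    features = x, classes = classes, treatment = treatment,
    cancer_type = cancer_type, profile_kind = profile_kind,
    n = nrow(x),
    n_sensitive = sum(classes == "sensitive"),
    n_resistant = sum(classes == "resistant"),
    degenerate = length(unique(classes)) < 2L,
    below_min_n = nrow(x) < min_n, min_n = min_n
  ), class = "case_dataset")
}

# internal: drop samples (by index) from a case, re-deriving counts/flags
case_subset <- function(case, keep) {
  case_from_matrix(case$features[keep, , drop = FALSE],
                   case$classes[keep],
                   treatment = case$treatment,
                   cancer_type = case$cancer_type,
                   profile_kind = case$profile_kind,
                   min_n = case$min_n)
}
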