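#' Classify aligned sites for a sequence pair
#'
#' Compares two aligned sequences position by position under pairwise
#' deletion: a column contributes only when both residues are unambiguous
#' bases (gaps, missing data and IUPAC ambiguity codes are excluded).
#' Mismatches between purines (A/G) or between pyrimidines (C/T) are
#' transitions; all other base mismatches are transversions.
#'
#' @param seq_a,seq_b Character vectors of single residues, or length-1
#'   strings; must be equal length.
#' @return A list of class `pairwise_counts` with integer elements
#'   `n_sites`, `n_transitions` and `n_transversions`.
#' @examples
#' count_site_patterns("ACGT", "GCGA")
#' @export
count_site_patterns <- function(seq_a, seq_b) {
  a <- as_residue_vector(seq_a)
  b <- as_residue_vector(seq_b)
  if (length(a) != length(b)) {
    stop(sprintf("alignment error: sequence lengths differ (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  }
  ea <- encode_residues(normalize_residues(a, "seq_a"))
  eb <- encode_residues(normalize_residues(b, "seq_b"))
  ok <- ea >= 1L & ea <= 4L & eb >= 1L & eb <= 4L
  diff <- ok & ea != eb
  ts <- diff & (ea %% 2L) == (eb %% 2L)
  structure(list(n_sites = sum(ok), n_transitions = sum(ts),
                 n_transversions = sum(diff) - sum(ts)),
            class = "pairwise_counts")
}

#' @keywords internal
#' @noRd
as_residue_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1L]] else x
}

#' Kimura 2-parameter distance from site-pattern counts
#'
#' With transition proportion `P` and transversion proportion `Q`, the K2P
#' distance is `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` substitutions
#' per site. The distance is undefined (returned as `NA`) when no sites
#' overlap or when the logarithm's argument is non-positive (saturation).
#'
#' @param counts A `pairwise_counts` object, or a list with elements
#'   `n_sites`, `n_transitions`, `n_transversions`.
#' @return Numeric distance in substitutions/site, or `NA_real_` when
#'   undefined.
#' @examples
#' k2p_distance(list(n_sites = 100, n_transitions = 3, n_transversions = 2))
#' @export
k2p_distance <- function(counts) {
  n <- counts$n_sites
  if (is.null(n) || n < 1L) return(NA_real_)
  P <- counts$n_transitions / n
  Q <- counts$n_transversions / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix for a dataset
#'
#' Computes all pairwise K2P distances with pairwise deletion. Pairs whose
#' site overlap falls below `min_overlap`, and pairs where the K2P formula
#' is undefined, are flagged undefined (`NA` distance, `FALSE` in the
#' defined mask) and excluded from all downstream summaries.
#'
#' @param ds A `barcode_dataset`.
#' @param min_overlap Minimum number of mutually unambiguous sites required
#'   for a defined distance (default 100).
#' @return An object of class `k2p_dm`: list with `labels`, `values`
#'   (numeric matrix, `NA` where undefined), `defined` (logical matrix) and
#'   `overlap` (integer matrix of shared unambiguous sites).
#' @export
distance_matrix <- function(ds, min_overlap = 100) {
  stopifnot(inherits(ds, "barcode_dataset"))
  enc <- encode_alignment(ds$matrix)
  n <- nrow(enc)
  labels <- rownames(enc)

  # Cross-product formulation: indicator matrices per base give, for every
  # pair at once, the overlap, match and same-parity counts.
  ind <- lapply(1:4, function(b) (enc == b) * 1)
  okm <- ind[[1]] + ind[[2]] + ind[[3]] + ind[[4]]
  overlap <- okm %*% t(okm)
  matches <- Reduce(`+`, lapply(ind, function(m) m %*% t(m)))
  pur <- ind[[1]] + ind[[3]]
  pyr <- ind[[2]] + ind[[4]]
  same_parity <- pur %*% t(pur) + pyr %*% t(pyr)
  ts <- same_parity - matches
  tv <- overlap - same_parity

  P <- ts / overlap
  Q <- tv / overlap
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  values <- suppressWarnings(-0.5 * log(w1 * sqrt(w2)))
  defined <- overlap >= max(1L, min_overlap) & w1 > 0 & w2 > 0
  values[!defined] <- NA_real_
  diag(values) <- 0
  diag(defined) <- TRUE

  dimnames(values) <- dimnames(defined) <- list(labels, labels)
  overlap <- matrix(as.integer(round(overlap)), n, n,
                    dimnames = list(labels, labels))
  structure(list(labels = labels, values = values, defined = defined,
                 overlap = overlap, min_overlap = min_overlap),
            class = "k2p_dm")
}

#' @export
print.k2p_dm <- function(x, ...) {
  off <- upper.tri(x$values)
  cat(sprintf("k2p_dm: %d sequences, %d pairs (%d undefined)\n",
              length(x$labels), sum(off), sum(!x$defined[off])))
  invisible(x)
}

#' Write a distance matrix in PHYLIP square format
#'
#' Undefined distances are written as `-1.0000` (PHYLIP has no missing-value
#' convention); use the long-form TSV to preserve the defined mask exactly.
#'
#' @param dm A `k2p_dm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(dm, path) {
  vals <- dm$values
  vals[!dm$defined] <- -1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$labels)), con)
  for (i in seq_along(dm$labels)) {
    writeLines(paste(c(sprintf("%-10s", dm$labels[[i]]),
                       sprintf("%.4f", vals[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Write a distance matrix as long-form TSV
#'
#' One row per unordered pair, with columns `accession_a`, `accession_b`,
#' `distance`, `n_sites`, `defined`.
#'
#' @param dm A `k2p_dm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_long <- function(dm, path) {
  idx <- which(upper.tri(dm$values), arr.ind = TRUE)
  df <- data.frame(
    accession_a = dm$labels[idx[, 1]],
    accession_b = dm$labels[idx[, 2]],
    distance = ifelse(dm$defined[idx], sprintf("%.6f", dm$values[idx]), "NA"),
    n_sites = dm$overlap[idx],
    defined = as.integer(dm$defined[idx]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-form distance TSV written by [write_distance_long()]
#'
#' @param path Input path.
#' @return A `data.frame` with numeric `distance` (`NA` where undefined).
#' @export
read_distance_long <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$distance <- suppressWarnings(as.numeric(df$distance))
  df$defined <- as.logical(df$defined)
  df
}
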