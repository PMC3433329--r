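#' Split pairwise distances into intra- and interspecific sets
#'
#' Interspecific comparisons use one representative accession per species,
#' so species are compared one-to-one regardless of how many accessions
#' each has. Intraspecific comparisons use all accession pairs within each
#' species represented by two or more accessions. Undefined distances are
#' excluded from both sets and counted.
#'
#' @param dm A `k2p_dm` distance matrix.
#' @param meta Metadata `data.frame` covering every matrix label.
#' @return An object of class `distance_partition`: list with
#'   `interspecific` (data.frame: `species_a`, `species_b`, `accession_a`,
#'   `accession_b`, `distance`), `intraspecific` (data.frame: `species`,
#'   `accession_a`, `accession_b`, `distance`), `n_undefined_excluded`,
#'   and `representatives` (named vector species -> accession).
#' @export
partition_distances <- function(dm, meta) {
  stopifnot(inherits(dm, "k2p_dm"))
  missing_meta <- setdiff(dm$labels, meta$accession)
  if (length(missing_meta) > 0L) {
    stop(sprintf("no metadata for accession '%s'", missing_meta[[1L]]),
         call. = FALSE)
  }
  meta <- meta[match(dm$labels, meta$accession), , drop = FALSE]
  species <- meta$species

  # one representative per species: the flagged accession when present,
  # otherwise the accession with the most informative sites (ties broken
  # lexicographically)
  reps <- vapply(split(seq_along(dm$labels), species), function(rows) {
    flagged <- rows[meta$representative[rows]]
    if (length(flagged) >= 1L) rows <- flagged
    own <- diag(dm$overlap)[rows]
    cand <- dm$labels[rows][own == max(own)]
    sort(cand)[[1L]]
  }, character(1))

  n_undef <- 0L

  rep_idx <- match(reps, dm$labels)
  inter <- NULL
  if (length(rep_idx) >= 2L) {
    cmb <- utils::combn(seq_along(rep_idx), 2L)
    i <- rep_idx[cmb[1L, ]]; j <- rep_idx[cmb[2L, ]]
    d <- dm$values[cbind(i, j)]
    def <- dm$defined[cbind(i, j)]
    n_undef <- n_undef + sum(!def)
    inter <- data.frame(species_a = species[i][def],
                        species_b = species[j][def],
                        accession_a = dm$labels[i][def],
                        accession_b = dm$labels[j][def],
                        distance = d[def])
  }
  if (is.null(inter)) {
    inter <- data.frame(species_a = character(0), species_b = character(0),
                        accession_a = character(0),
                        accession_b = character(0), distance = numeric(0))
  }

  intra_list <- lapply(split(seq_along(dm$labels), species), function(rows) {
    if (length(rows) < 2L) return(NULL)
    cmb <- utils::combn(rows, 2L)
    i <- cmb[1L, ]; j <- cmb[2L, ]
    d <- dm$values[cbind(i, j)]
    def <- dm$defined[cbind(i, j)]
    n_undef <<- n_undef + sum(!def)
    if (!any(def)) return(NULL)
    data.frame(species = species[i][def],
               accession_a = dm$labels[i][def],
               accession_b = dm$labels[j][def],
               distance = d[def])
  })
  intra <- do.call(rbind, intra_list)
  if (is.null(intra)) {
    intra <- data.frame(species = character(0), accession_a = character(0),
                        accession_b = character(0), distance = numeric(0))
  }
  rownames(inter) <- rownames(intra) <- NULL

  structure(list(interspecific = inter, intraspecific = intra,
                 n_undefined_excluded = n_undef, representatives = reps),
            class = "distance_partition")
}

#' @export
print.distance_partition <- function(x, ...) {
  cat(sprintf(
    "distance_partition: %d interspecific pairs (%d species), %d intraspecific pairs, %d undefined excluded\n",
    nrow(x$interspecific), length(x$representatives),
    nrow(x$intraspecific), x$n_undefined_excluded))
  invisible(x)
}

#' Summarise intraspecific divergence
#'
#' Because species contribute unequal numbers of accessions, the pairwise
#' distances within each species are averaged first; the reported mean and
#' SD are taken over these per-species means, so every species contributes
#' one value. The maximum is the global maximum over all intraspecific
#' pairs.
#'
#' @param part A `distance_partition`.
#' @return List with `mean`, `sd`, `max`, `n_accessions` (accessions in
#'   multi-accession species) and `n_species` (species with at least one
#'   defined intraspecific pair). All-`NA` values with `n_species = 0` when
#'   no species has two accessions.
#' @export
intraspecific_summary <- function(part) {
  stopifnot(inherits(part, "distance_partition"))
  d <- part$intraspecific
  if (nrow(d) == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, max = NA_real_,
                n_accessions = 0L, n_species = 0L))
  }
  per_species <- vapply(split(d$distance, d$species), mean, numeric(1))
  list(mean = mean(per_species),
       sd = if (length(per_species) > 1L) stats::sd(per_species) else 0,
       max = max(d$distance),
       n_accessions = length(unique(c(d$accession_a, d$accession_b))),
       n_species = length(per_species))
}

#' Summarise interspecific divergence
#'
#' Plain mean, standard deviation and maximum over all defined
#' interspecific (representative-to-representative) distances.
#'
#' @param part A `distance_partition`.
#' @return List with `mean`, `sd`, `max` and `n_pairs`.
#' @export
interspecific_summary <- function(part) {
  stopifnot(inherits(part, "distance_partition"))
  d <- part$interspecific$distance
  if (length(d) == 0L) {
    stop("no defined interspecific pairs", call. = FALSE)
  }
  list(mean = mean(d),
       sd = if (length(d) > 1L) stats::sd(d) else 0,
       max = max(d), n_pairs = length(d))
}

#' Percentage of interspecific comparisons exceeding a threshold
#'
#' Uses a strict inequality (`distance > threshold`); undefined distances
#' were already excluded from both numerator and denominator when the
#' partition was built.
#'
#' @param part A `distance_partition`.
#' @param threshold Distance threshold in substitutions/site (>= 0),
#'   e.g. `0.01` for the 1% cutoff.
#' @return Percentage of pairs above the threshold, rounded to 2 decimals.
#' @export
fraction_above <- function(part, threshold) {
  stopifnot(inherits(part, "distance_partition"), threshold >= 0)
  d <- part$interspecific$distance
  if (length(d) == 0L) stop("no defined interspecific pairs", call. = FALSE)
  round(100 * sum(d > threshold) / length(d), 2)
}

#' Barcoding-gap diagnostic
#'
#' A barcoding gap exists when the smallest interspecific distance exceeds
#' the largest intraspecific distance; the margin is their difference
#' (negative when the distributions overlap). Histograms of both
#' distributions are binned from zero with a common bin width.
#'
#' @param part A `distance_partition`.
#' @param bin_width Histogram bin width in substitutions/site.
#' @return List with `gap_exists` (logical, `NA` when no intraspecific
#'   pairs exist), `gap_margin`, and `histogram` (data.frame with
#'   `bin_start`, `bin_end`, `intra_count`, `inter_count`).
#' @export
barcoding_gap <- function(part, bin_width = 0.005) {
  stopifnot(inherits(part, "distance_partition"), bin_width > 0)
  inter <- part$interspecific$distance
  intra <- part$intraspecific$distance
  if (length(inter) == 0L) stop("no defined interspecific pairs", call. = FALSE)

  hi <- max(c(inter, intra, bin_width))
  breaks <- seq(0, (floor(hi / bin_width) + 1L) * bin_width, by = bin_width)
  bin_counts <- function(x) {
    if (length(x) == 0L) return(integer(length(breaks) - 1L))
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                          left.open = FALSE),
             nbins = length(breaks) - 1L)
  }
  hist_df <- data.frame(bin_start = breaks[-length(breaks)],
                        bin_end = breaks[-1L],
                        intra_count = bin_counts(intra),
                        inter_count = bin_counts(inter))

  if (length(intra) == 0L) {
    return(list(gap_exists = NA, gap_margin = NA_real_, histogram = hist_df))
  }
  margin <- min(inter) - max(intra)
  list(gap_exists = margin > 0, gap_margin = margin, histogram = hist_df)
}

#' Assemble the discrimination report for one dataset
#'
#' Computes every summary for one dataset: the character view (variable
#' sites, unique haplotypes under both gap conventions, max ID rate) on the
#' one-representative-per-species dataset, and the distance view
#' (inter/intraspecific summaries, threshold fractions, barcoding gap) from
#' the full accession set.
#'
#' @param ds A `barcode_dataset` containing all accessions.
#' @param thresholds Distance thresholds for exceedance percentages
#'   (default `c(0.01, 0.02)`).
#' @param min_overlap Minimum pairwise site overlap for a defined distance.
#' @param bin_width Histogram bin width.
#' @param subset_label Optional label for the stratum this dataset
#'   represents (clade or region); empty for a global analysis.
#' @return An object of class `discrimination_report` (a list; see fields in
#'   the source or print it). The histogram and the underlying partition are
#'   attached as attributes `histogram` and `partition`.
#' @export
evaluate_dataset <- function(ds, thresholds = c(0.01, 0.02),
                             min_overlap = 100, bin_width = 0.005,
                             subset_label = "") {
  stopifnot(inherits(ds, "barcode_dataset"))
  ds_rep <- representative_dataset(ds)

  hap_missing <- collapse_haplotypes(ds_rep, "gap_as_missing")
  hap_fifth <- collapse_haplotypes(ds_rep, "gap_as_fifth_state")
  n_var <- count_variable_sites(ds_rep)

  dm <- distance_matrix(ds, min_overlap = min_overlap)
  part <- partition_distances(dm, ds$meta)
  inter <- interspecific_summary(part)
  intra <- intraspecific_summary(part)
  gap <- barcoding_gap(part, bin_width = bin_width)
  pct <- vapply(sort(thresholds), function(th) fraction_above(part, th),
                numeric(1))
  names(pct) <- sprintf("pct_gt_%g", 100 * sort(thresholds))

  report <- structure(list(
    dataset_name = ds$name,
    subset = subset_label,
    n_species = ds_rep$n_species,
    aligned_length = ds$aligned_length,
    n_variable = n_var,
    n_unique = hap_missing$n_unique,
    n_unique_fifth = hap_fifth$n_unique,
    max_id_rate_pct = max_id_rate(hap_missing$n_unique, ds_rep$n_species),
    inter_max = inter$max, inter_mean = inter$mean, inter_sd = inter$sd,
    thresholds = sort(thresholds), pct_above = pct,
    intra_max = intra$max, intra_mean = intra$mean, intra_sd = intra$sd,
    intra_n_accessions = intra$n_accessions,
    intra_n_species = intra$n_species,
    gap_exists = gap$gap_exists, gap_margin = gap$gap_margin,
    n_undefined_excluded = part$n_undefined_excluded),
    class = "discrimination_report")
  attr(report, "histogram") <- gap$histogram
  attr(report, "partition") <- part
  report
}

#' Assemble a report row from precomputed components
#'
#' Lower-level constructor behind [evaluate_dataset()], for callers that
#' computed the partition and haplotype collapses themselves.
#'
#' @param ds The (all-accession) `barcode_dataset`.
#' @param part A `distance_partition` for `ds`.
#' @param hap_missing,hap_fifth `haplotype_partition`s of the
#'   representative dataset under the two gap conventions.
#' @param n_species Number of species (denominator of the max ID rate).
#' @param n_variable Number of variable sites in the representative dataset.
#' @param thresholds Thresholds for exceedance percentages.
#' @param bin_width Histogram bin width.
#' @param subset_label Stratum label.
#' @return A `discrimination_report`.
#' @export
build_report <- function(ds, part, hap_missing, hap_fifth, n_species,
                         n_variable, thresholds = c(0.01, 0.02),
                         bin_width = 0.005, subset_label = "") {
  inter <- interspecific_summary(part)
  intra <- intraspecific_summary(part)
  gap <- barcoding_gap(part, bin_width = bin_width)
  pct <- vapply(sort(thresholds), function(th) fraction_above(part, th),
                numeric(1))
  names(pct) <- sprintf("pct_gt_%g", 100 * sort(thresholds))
  report <- structure(list(
    dataset_name = ds$name, subset = subset_label,
    n_species = n_species, aligned_length = ds$aligned_length,
    n_variable = n_variable,
    n_unique = hap_missing$n_unique, n_unique_fifth = hap_fifth$n_unique,
    max_id_rate_pct = max_id_rate(hap_missing$n_unique, n_species),
    inter_max = inter$max, inter_mean = inter$mean, inter_sd = inter$sd,
    thresholds = sort(thresholds), pct_above = pct,
    intra_max = intra$max, intra_mean = intra$mean, intra_sd = intra$sd,
    intra_n_accessions = intra$n_accessions,
    intra_n_species = intra$n_species,
    gap_exists = gap$gap_exists, gap_margin = gap$gap_margin,
    n_undefined_excluded = part$n_undefined_excluded),
    class = "discrimination_report")
  attr(report, "histogram") <- gap$histogram
  attr(report, "partition") <- part
  report
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("discrimination_report: %s%s\n", x$dataset_name,
              if (nzchar(x$subset)) paste0(" [", x$subset, "]") else ""))
  cat(sprintf("  species %d | %d sites | %d variable | unique %d (%d as 5th state) | max ID %.2f%%\n",
              x$n_species, x$aligned_length, x$n_variable, x$n_unique,
              x$n_unique_fifth, x$max_id_rate_pct))
  cat(sprintf("  inter: mean %.4f (SD %.4f), max %.4f | %s\n",
              x$inter_mean, x$inter_sd, x$inter_max,
              paste(sprintf(">%g%%: %.2f%%", 100 * x$thresholds,
                            x$pct_above), collapse = " | ")))
  if (x$intra_n_species > 0L) {
    cat(sprintf("  intra: mean %.4f (SD %.4f), max %.4f over %d species / %d accessions\n",
                x$intra_mean, x$intra_sd, x$intra_max, x$intra_n_species,
                x$intra_n_accessions))
    cat(sprintf("  barcoding gap: %s (margin %.4f)\n",
                ifelse(isTRUE(x$gap_exists), "yes", "no"), x$gap_margin))
  } else {
    cat("  intra: no species with multiple accessions\n")
  }
  invisible(x)
}

# One formatted table row per report: column layout of the interspecific
# summary tables (percentages at 2 decimals, distances at 4; fifth-state
# unique count in parentheses when it differs).
#' @keywords internal
#' @noRd
format_report_row <- function(x) {
  uniq <- if (x$n_unique_fifth != x$n_unique) {
    sprintf("%d (%d)", x$n_unique, x$n_unique_fifth)
  } else {
    sprintf("%d", x$n_unique)
  }
  row <- c(`Gene Region` = x$dataset_name,
           Species = sprintf("%d", x$n_species),
           `Aligned Length` = sprintf("%d", x$aligned_length),
           `Variable characters` = sprintf("%d", x$n_variable),
           `Unique sequences` = uniq,
           `% Max ID rate` = sprintf("%.2f", x$max_id_rate_pct),
           Max = sprintf("%.4f", x$inter_max),
           `Mean (SD)` = sprintf("%.4f (%.4f)", x$inter_mean, x$inter_sd))
  pcts <- sprintf("%.2f", x$pct_above)
  names(pcts) <- sprintf("> %g%%", 100 * x$thresholds)
  c(row, pcts)
}

#' Write discrimination reports as a TSV table
#'
#' One row per report, in the standard interspecific-summary layout:
#' `Gene Region`, `Species`, `Aligned Length`, `Variable characters`,
#' `Unique sequences`, `% Max ID rate`, `Max`, `Mean (SD)` and one `> x%`
#' column per threshold, plus a leading `Subset` column when any report is
#' stratified.
#'
#' @param reports A `discrimination_report` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(reports, path) {
  if (inherits(reports, "discrimination_report")) reports <- list(reports)
  rows <- lapply(reports, format_report_row)
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  subsets <- vapply(reports, `[[`, character(1), "subset")
  if (any(nzchar(subsets))) {
    df <- cbind(Subset = ifelse(nzchar(subsets), subsets, "global"), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a barcoding-gap histogram as TSV
#'
#' @param report A `discrimination_report` (uses its `histogram` attribute),
#'   or the histogram `data.frame` itself.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(report, path) {
  hist_df <- if (inherits(report, "discrimination_report")) {
    attr(report, "histogram")
  } else {
    report
  }
  utils::write.table(hist_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
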