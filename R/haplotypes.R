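#' Collapse a dataset into unique haplotypes
#'
#' Two accessions share a haplotype when they have zero mismatches at the
#' positions where both carry informative symbols; clusters are the
#' connected components of this zero-mismatch link relation (identity under
#' wildcards is not transitive, so the maximal merge is taken).
#'
#' Gap conventions:
#' \describe{
#'   \item{`gap_as_missing`}{gaps, missing data and ambiguity codes are all
#'     wildcards; only point mutations separate haplotypes.}
#'   \item{`gap_as_fifth_state`}{the gap is an ordinary fifth symbol, so
#'     gap-vs-base and gap-vs-missing columns count as mismatches; missing
#'     data and ambiguity codes remain wildcards.}
#' }
#' The fifth-state convention can only split clusters, never merge them, so
#' its unique count is always at least the gap-as-missing count.
#'
#' @param ds A `barcode_dataset`.
#' @param gap_mode `"gap_as_missing"` or `"gap_as_fifth_state"`.
#' @return An object of class `haplotype_partition`: list with `gap_mode`,
#'   `clusters` (list of accession-id vectors, in order of first
#'   appearance) and `n_unique`.
#' @export
collapse_haplotypes <- function(ds,
                                gap_mode = c("gap_as_missing",
                                             "gap_as_fifth_state")) {
  stopifnot(inherits(ds, "barcode_dataset"))
  gap_mode <- match.arg(gap_mode)
  enc <- encode_alignment(ds$matrix)
  n <- nrow(enc)
  if (gap_mode == "gap_as_missing") enc[enc == 5L] <- 0L

  # Mismatch counts for all pairs at once: informative symbols are 1..4
  # (plus 5 in fifth-state mode); a wildcard (0) matches anything.
  symbols <- sort(setdiff(unique(as.integer(enc)), 0L))
  if (length(symbols) == 0L || n == 1L) {
    linked <- matrix(TRUE, n, n)
  } else {
    ind <- lapply(symbols, function(s) (enc == s) * 1)
    inf <- Reduce(`+`, ind)
    both <- inf %*% t(inf)
    matches <- Reduce(`+`, lapply(ind, function(m) m %*% t(m)))
    mismatches <- both - matches
    if (gap_mode == "gap_as_fifth_state") {
      # a gap opposite missing data is a mismatch too: the fifth state is an
      # observed symbol, so missing acts as a wildcard only against bases
      gap <- (enc == 5L) * 1
      mis <- (enc == 0L) * 1
      mismatches <- mismatches + gap %*% t(mis) + mis %*% t(gap)
    }
    linked <- mismatches < 0.5
  }

  comp <- connected_components(linked)
  ord <- order(vapply(split(seq_len(n), comp), min, integer(1)))
  clusters <- unname(split(rownames(enc), comp)[ord])
  structure(list(gap_mode = gap_mode, clusters = clusters,
                 n_unique = length(clusters)),
            class = "haplotype_partition")
}

# Union-find over a logical adjacency matrix.
#' @keywords internal
#' @noRd
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in which(adj[i, ])) {
      if (j > i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' @export
print.haplotype_partition <- function(x, ...) {
  cat(sprintf("haplotype_partition (%s): %d unique haplotypes / %d accessions\n",
              x$gap_mode, x$n_unique, sum(lengths(x$clusters))))
  invisible(x)
}

#' Write a haplotype partition as TSV
#'
#' @param part A `haplotype_partition`.
#' @param meta Metadata `data.frame` supplying the species of each accession.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(part, meta, path) {
  df <- do.call(rbind, lapply(seq_along(part$clusters), function(i) {
    acc <- part$clusters[[i]]
    data.frame(cluster_id = i, accession = acc,
               species = meta$species[match(acc, meta$accession)])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Maximum identification rate
#'
#' The ceiling on character-based species discrimination: the number of
#' unique haplotypes divided by the number of species sampled, as a
#' percentage reported to two decimals. A rate above 100 is possible only
#' when a dataset holds several accessions per species and triggers a
#' warning.
#'
#' @param n_unique Number of unique haplotypes (>= 1).
#' @param n_species Number of species in the dataset (>= 1).
#' @return Percentage, rounded to 2 decimals.
#' @examples
#' max_id_rate(38, 98)  # 38.78
#' @export
max_id_rate <- function(n_unique, n_species) {
  if (length(n_species) != 1L || is.na(n_species) || n_species < 1) {
    stop("n_species must be a positive integer", call. = FALSE)
  }
  if (length(n_unique) != 1L || is.na(n_unique) || n_unique < 1) {
    stop("n_unique must be a positive integer", call. = FALSE)
  }
  rate <- round(100 * n_unique / n_species, 2)
  if (rate > 100) {
    warning("max ID rate exceeds 100%: dataset holds more haplotypes than species",
            call. = FALSE)
  }
  rate
}

#' Count variable alignment columns
#'
#' A column is variable when at least two distinct unambiguous bases occur
#' in it; gaps, missing data and ambiguity codes are ignored.
#'
#' @param ds A `barcode_dataset`.
#' @return Integer count of variable columns.
#' @export
count_variable_sites <- function(ds) {
  stopifnot(inherits(ds, "barcode_dataset"))
  enc <- encode_alignment(ds$matrix)
  sum(vapply(seq_len(ncol(enc)), function(j) {
    b <- enc[, j]
    length(unique(b[b >= 1L & b <= 4L])) >= 2L
  }, logical(1)))
}
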