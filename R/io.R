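#' Read one locus of an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format. Sequences are
#' uppercased, `?` is normalised to `N`, and all sequences must have equal
#' length (the file must already be aligned; no alignment is performed).
#'
#' @param path Path to a FASTA file.
#' @param locus Name of the locus the alignment belongs to.
#' @return A character matrix of single residues with one row per accession
#'   (row names are the FASTA identifiers) and attribute `locus`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">acc1", "ACGT", ">acc2", "AC-T"), fa)
#' aln <- read_fasta_alignment(fa, "rbcL")
#' dim(aln)
#' @export
read_fasta_alignment <- function(path, locus) {
  seqs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE),
    error = function(e) stop(sprintf("cannot read FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(seqs) == 0L) {
    stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  }
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate accession '%s' in locus %s",
                 ids[duplicated(ids)][[1L]], locus), call. = FALSE)
  }
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L) {
    stop(sprintf(
      "alignment error in locus %s: sequence lengths differ (%s)",
      locus, paste(unique(lens), collapse = ", ")), call. = FALSE)
  }
  mat <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    normalize_residues(as.character(seqs[[i]]),
                       context = sprintf("%s:%s", locus, ids[[i]]))
  }))
  rownames(mat) <- ids
  attr(mat, "locus") <- locus
  mat
}

#' Write an aligned matrix to FASTA
#'
#' @param mat Character alignment matrix (rows = accessions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(mat, path) {
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(mat)), function(i) mat[i, ]),
    names = rownames(mat), file.out = path, nbchar = 80)
  invisible(path)
}

#' Read the sample metadata table
#'
#' The metadata table is a TSV with header columns `accession`, `species`,
#' `clade_path`, `region` and `representative`. `clade_path` lists clade
#' names from outermost to innermost, joined by `clade_delim`; `region` may
#' be empty; `representative` is 0/1 and flags the single accession per
#' species used for interspecific comparisons.
#'
#' @param path Path to the TSV file.
#' @param clade_delim Delimiter separating clade names within `clade_path`.
#' @return A `data.frame` with columns `accession`, `species`, `clade_path`
#'   (delimited string), `region` (`NA` when absent) and `representative`
#'   (logical).
#' @export
read_metadata <- function(path, clade_delim = ";") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  required <- c("accession", "species", "clade_path", "region",
                "representative")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("metadata is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  validate_metadata(df[required], clade_delim = clade_delim)
}

#' @keywords internal
#' @noRd
validate_metadata <- function(df, clade_delim = ";") {
  if (anyDuplicated(df$accession)) {
    stop(sprintf("duplicate accession in metadata: %s",
                 df$accession[duplicated(df$accession)][[1L]]),
         call. = FALSE)
  }
  if (any(is.na(df$species) | !nzchar(df$species))) {
    stop("metadata rows with missing species", call. = FALSE)
  }
  if (any(is.na(df$clade_path) | !nzchar(df$clade_path))) {
    stop("metadata rows with empty clade_path", call. = FALSE)
  }
  df$region <- ifelse(is.na(df$region) | !nzchar(df$region),
                      NA_character_, df$region)
  df$representative <- as.logical(as.integer(df$representative))
  if (anyNA(df$representative)) {
    stop("representative column must be 0 or 1", call. = FALSE)
  }
  attr(df, "clade_delim") <- clade_delim
  # first clade_path element must be shared (a single root clade)
  roots <- vapply(strsplit(df$clade_path, clade_delim, fixed = TRUE),
                  `[[`, character(1), 1L)
  if (length(unique(roots)) > 1L) {
    stop("clade_path entries disagree on the root clade name", call. = FALSE)
  }
  df
}

#' Write a metadata table
#'
#' @param meta Metadata `data.frame` as returned by [read_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$representative <- as.integer(out$representative)
  out$region <- ifelse(is.na(out$region), "", out$region)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundle per-locus alignments with sample metadata
#'
#' @param loci Named list of aligned character matrices (as from
#'   [read_fasta_alignment()]); names are locus names.
#' @param metadata Metadata `data.frame` (see [read_metadata()]).
#' @return An object of class `alignment_set`.
#' @export
alignment_set <- function(loci, metadata) {
  if (is.null(names(loci)) || any(!nzchar(names(loci)))) {
    stop("loci must be a named list", call. = FALSE)
  }
  metadata <- validate_metadata(metadata,
                                clade_delim = attr(metadata, "clade_delim") %||% ";")
  for (loc in names(loci)) {
    mat <- loci[[loc]]
    if (!is.matrix(mat) || is.null(rownames(mat))) {
      stop(sprintf("locus %s: expected a character matrix with row names", loc),
           call. = FALSE)
    }
    unknown <- setdiff(rownames(mat), metadata$accession)
    if (length(unknown) > 0L) {
      stop(sprintf("locus %s: accession '%s' absent from metadata",
                   loc, unknown[[1L]]), call. = FALSE)
    }
  }
  structure(list(loci = loci, metadata = metadata), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d loci, %d accessions, %d species\n",
              length(x$loci), nrow(x$metadata),
              length(unique(x$metadata$species))))
  for (loc in names(x$loci)) {
    cat(sprintf("  %-12s %4d seqs x %5d sites\n", loc,
                nrow(x$loci[[loc]]), ncol(x$loci[[loc]])))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble an analysis dataset from one or more loci
#'
#' Concatenates the requested loci in the given order, keeping only
#' accessions sequenced for *all* requested loci (complete cases). This is
#' why a combined dataset can contain fewer species than either component
#' locus. Optionally restricts to the one flagged representative accession
#' per species.
#'
#' @param aset An [alignment_set()].
#' @param loci Character vector of locus names, in concatenation order.
#' @param representatives_only If `TRUE`, keep only accessions flagged as
#'   the species representative (falling back to [choose_representatives()]
#'   for species without a flagged accession in this dataset).
#' @param name Dataset label; defaults to the loci joined by `+`.
#' @return An object of class `barcode_dataset` with elements `name`,
#'   `matrix` (residue character matrix), `meta` (metadata rows for included
#'   accessions), `loci`, `n_species` and `aligned_length`.
#' @export
build_dataset <- function(aset, loci, representatives_only = FALSE,
                          name = paste(loci, collapse = "+")) {
  stopifnot(inherits(aset, "alignment_set"))
  absent <- setdiff(loci, names(aset$loci))
  if (length(absent) > 0L) {
    stop(sprintf("unknown locus: %s", paste(absent, collapse = ", ")),
         call. = FALSE)
  }
  acc_sets <- lapply(aset$loci[loci], rownames)
  accessions <- Reduce(intersect, acc_sets)
  if (length(accessions) == 0L) {
    stop(sprintf("no accession has complete data for %s", name),
         call. = FALSE)
  }
  mat <- do.call(cbind, lapply(aset$loci[loci],
                               function(m) m[accessions, , drop = FALSE]))
  rownames(mat) <- accessions
  meta <- aset$metadata[match(accessions, aset$metadata$accession), ,
                        drop = FALSE]
  rownames(meta) <- NULL
  ds <- structure(list(name = name, matrix = mat, meta = meta, loci = loci,
                       n_species = length(unique(meta$species)),
                       aligned_length = ncol(mat)),
                  class = "barcode_dataset")
  if (representatives_only) ds <- representative_dataset(ds) else ds
}

#' Pick one representative accession per species
#'
#' When the metadata flags a representative that is present in the dataset
#' it is used; otherwise the accession with the fewest gap/missing/ambiguous
#' residues is chosen, ties broken lexicographically by accession id.
#'
#' @param ds A `barcode_dataset`.
#' @return Named character vector: species -> accession id.
#' @export
choose_representatives <- function(ds) {
  stopifnot(inherits(ds, "barcode_dataset"))
  enc <- encode_alignment(ds$matrix)
  informative <- rowSums(enc >= 1L & enc <= 4L)
  meta <- ds$meta
  reps <- vapply(split(seq_len(nrow(meta)), meta$species), function(rows) {
    flagged <- rows[meta$representative[rows]]
    if (length(flagged) == 1L) return(meta$accession[flagged])
    if (length(flagged) > 1L) rows <- flagged
    cand <- meta$accession[rows]
    best <- cand[informative[match(cand, rownames(enc))] ==
                   max(informative[match(cand, rownames(enc))])]
    sort(best)[[1L]]
  }, character(1))
  reps
}

#' @keywords internal
#' @noRd
representative_dataset <- function(ds) {
  reps <- choose_representatives(ds)
  keep <- ds$meta$accession %in% reps
  subset_rows(ds, keep)
}

#' @keywords internal
#' @noRd
subset_rows <- function(ds, keep) {
  meta <- ds$meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(name = ds$name,
                 matrix = ds$matrix[ds$meta$accession[keep], , drop = FALSE],
                 meta = meta, loci = ds$loci,
                 n_species = length(unique(meta$species)),
                 aligned_length = ncol(ds$matrix)),
            class = "barcode_dataset")
}

#' Restrict a dataset to a clade or a region
#'
#' Clade selectors match any element of an accession's `clade_path`;
#' region selectors match the region tag exactly.
#'
#' @param ds A `barcode_dataset`.
#' @param clade Clade name, or `NULL`.
#' @param region Region tag, or `NULL`.
#' @return A `barcode_dataset` restricted to matching accessions, with
#'   `n_species` recomputed.
#' @export
subset_dataset <- function(ds, clade = NULL, region = NULL) {
  stopifnot(inherits(ds, "barcode_dataset"))
  if (is.null(clade) == is.null(region)) {
    stop("give exactly one of 'clade' or 'region'", call. = FALSE)
  }
  delim <- attr(ds$meta, "clade_delim") %||% ";"
  if (!is.null(clade)) {
    paths <- strsplit(ds$meta$clade_path, delim, fixed = TRUE)
    keep <- vapply(paths, function(p) clade %in% p, logical(1))
    selector <- sprintf("clade:%s", clade)
  } else {
    keep <- !is.na(ds$meta$region) & ds$meta$region == region
    selector <- sprintf("region:%s", region)
  }
  if (!any(keep)) {
    stop(sprintf("empty subset: no accession matches %s in dataset %s",
                 selector, ds$name), call. = FALSE)
  }
  out <- subset_rows(ds, keep)
  out$name <- ds$name
  out
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("barcode_dataset '%s': %d accessions, %d species, %d sites (%s)\n",
              x$name, nrow(x$matrix), x$n_species, x$aligned_length,
              paste(x$loci, collapse = "+")))
  invisible(x)
}
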