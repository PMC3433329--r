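#' Run the full discrimination evaluation
#'
#' Evaluates every requested locus combination on the full data and on each
#' requested clade/region stratum, producing one discrimination report per
#' dataset-by-stratum cell, and optionally writing the report table,
#' per-dataset histograms and a run log to an output directory.
#'
#' @param aset An [alignment_set()].
#' @param combinations List of character vectors of locus names; each vector
#'   is one dataset (defaults to every single locus).
#' @param subsets List of strata, each `list(clade = "...")` or
#'   `list(region = "...")`; the unstratified analysis is always included.
#' @param thresholds Distance thresholds (default 1% and 2%).
#' @param min_overlap Minimum pairwise site overlap for a defined distance.
#' @param bin_width Histogram bin width.
#' @param out Optional output directory; created if needed. Writes
#'   `report.tsv`, `hist_<dataset>[_<subset>].tsv` and `run.log`.
#' @return List of class `evaluation_bundle`: `reports` (list of
#'   `discrimination_report`, skipped strata omitted) and `log` (character
#'   vector; records empty strata and undefined-distance counts).
#' @export
run_evaluate <- function(aset,
                         combinations = as.list(names(aset$loci)),
                         subsets = list(),
                         thresholds = c(0.01, 0.02),
                         min_overlap = 100,
                         bin_width = 0.005,
                         out = NULL) {
  stopifnot(inherits(aset, "alignment_set"))
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  thresholds <- sort(thresholds)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(fmt, ...)))
  }

  strata <- c(list(NULL), subsets)
  reports <- list()
  for (loci in combinations) {
    ds_name <- paste(loci, collapse = "+")
    ds_all <- build_dataset(aset, loci)
    for (stratum in strata) {
      label <- if (is.null(stratum)) "" else {
        paste(names(stratum)[[1L]], stratum[[1L]], sep = ":")
      }
      ds <- if (is.null(stratum)) ds_all else {
        tryCatch(do.call(subset_dataset, c(list(ds_all), stratum)),
                 error = function(e) NULL)
      }
      if (is.null(ds)) {
        note("skipped %s [%s]: empty subset", ds_name, label)
        next
      }
      rep_row <- tryCatch(
        evaluate_dataset(ds, thresholds = thresholds,
                         min_overlap = min_overlap, bin_width = bin_width,
                         subset_label = label),
        error = function(e) {
          note("skipped %s [%s]: %s", ds_name,
               if (nzchar(label)) label else "global", conditionMessage(e))
          NULL
        })
      if (is.null(rep_row)) next
      if (rep_row$n_undefined_excluded > 0L) {
        note("%s [%s]: %d undefined distance(s) excluded", ds_name,
             if (nzchar(label)) label else "global",
             rep_row$n_undefined_excluded)
      }
      reports[[length(reports) + 1L]] <- rep_row
    }
  }
  note("evaluated %d dataset x stratum cells", length(reports))

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_report_tsv(reports, file.path(out, "report.tsv"))
    for (r in reports) {
      tag <- gsub("[^A-Za-z0-9_+-]", "_",
                  paste0(r$dataset_name,
                         if (nzchar(r$subset)) paste0("_", r$subset) else ""))
      write_histogram_tsv(r, file.path(out, sprintf("hist_%s.tsv", tag)))
    }
    writeLines(log_lines, file.path(out, "run.log"))
  }
  structure(list(reports = reports, log = log_lines),
            class = "evaluation_bundle")
}

#' @export
print.evaluation_bundle <- function(x, ...) {
  cat(sprintf("evaluation_bundle: %d report rows\n", length(x$reports)))
  for (r in x$reports) {
    cat(sprintf("  %-28s %-28s species %3d  maxID %6.2f%%  inter mean %.4f\n",
                r$dataset_name,
                if (nzchar(r$subset)) paste0("[", r$subset, "]") else "[global]",
                r$n_species, r$max_id_rate_pct, r$inter_mean))
  }
  invisible(x)
}

#' Collect report rows into a data.frame
#'
#' @param bundle An `evaluation_bundle` from [run_evaluate()].
#' @return A `data.frame`, one row per report, with numeric summary columns.
#' @export
report_table <- function(bundle) {
  stopifnot(inherits(bundle, "evaluation_bundle"))
  do.call(rbind, lapply(bundle$reports, function(r) {
    row <- data.frame(
      dataset = r$dataset_name,
      subset = if (nzchar(r$subset)) r$subset else "global",
      n_species = r$n_species, aligned_length = r$aligned_length,
      n_variable = r$n_variable, n_unique = r$n_unique,
      n_unique_fifth = r$n_unique_fifth,
      max_id_rate_pct = r$max_id_rate_pct,
      inter_max = r$inter_max, inter_mean = r$inter_mean,
      inter_sd = r$inter_sd,
      intra_max = r$intra_max, intra_mean = r$intra_mean,
      gap_exists = r$gap_exists, gap_margin = r$gap_margin,
      stringsAsFactors = FALSE)
    for (i in seq_along(r$thresholds)) {
      row[[sprintf("pct_gt_%g", 100 * r$thresholds[[i]])]] <- r$pct_above[[i]]
    }
    row
  }))
}

#' Simulate a barcode study and write the input bundle to disk
#'
#' Writes one aligned FASTA per locus, the metadata TSV, the species tree
#' (Newick, clade nodes labelled) and the per-pair expected-divergence
#' table, then prints a short summary.
#'
#' @param cfg A [simulation_config()].
#' @param out Output directory (created if needed).
#' @return The simulation result of [simulate_barcode_data()], invisibly.
#' @export
run_simulate <- function(cfg = simulation_config(), out) {
  sim <- simulate_barcode_data(cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (loc in names(sim$aset$loci)) {
    write_fasta_alignment(sim$aset$loci[[loc]],
                          file.path(out, paste0(loc, ".fasta")))
  }
  write_metadata(sim$aset$metadata, file.path(out, "metadata.tsv"))
  ape::write.tree(sim$truth$tree, file.path(out, "species_tree.nwk"))
  utils::write.table(
    within(sim$expected_divergence,
           expected_divergence <- sprintf("%.6f", expected_divergence)),
    file.path(out, "expected_divergence.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("simulated %d species, %d accessions, %d loci -> %s\n",
              nrow(sim$truth$species_meta), nrow(sim$aset$metadata),
              length(sim$aset$loci), out))
  invisible(sim)
}

#' Load a simulated (or real) input bundle from disk
#'
#' Reads every `<locus>.fasta` in a directory together with `metadata.tsv`.
#'
#' @param dir Directory written by [run_simulate()] (or laid out the same
#'   way).
#' @return An [alignment_set()].
#' @export
read_input_bundle <- function(dir) {
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(fastas) == 0L) stop("no .fasta files in ", dir, call. = FALSE)
  loci <- lapply(fastas, function(f)
    read_fasta_alignment(f, sub("\\.fasta$", "", basename(f))))
  names(loci) <- sub("\\.fasta$", "", basename(fastas))
  alignment_set(loci, read_metadata(file.path(dir, "metadata.tsv")))
}
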