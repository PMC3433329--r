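# Shared fixtures and independent brute-force oracles.

# Build a barcode_dataset directly from named residue strings.
toy_dataset <- function(seqs, species = NULL, representative = NULL,
                        clade = NULL, region = NULL, name = "toy",
                        locus = "locusA") {
  acc <- names(seqs)
  if (is.null(acc)) acc <- sprintf("acc%02d", seq_along(seqs))
  if (is.null(species)) species <- acc
  if (is.null(representative)) {
    representative <- !duplicated(species)
  }
  if (is.null(clade)) clade <- rep("Root;CladeX", length(seqs))
  if (is.null(region)) region <- rep(NA_character_, length(seqs))
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(mat) <- acc
  attr(mat, "locus") <- locus
  meta <- data.frame(accession = acc, species = species,
                     clade_path = clade, region = region,
                     representative = representative,
                     stringsAsFactors = FALSE)
  loci <- list(mat); names(loci) <- locus
  aset <- alignment_set(loci, meta)
  build_dataset(aset, locus, name = name)
}

# Random aligned sequences over bases plus optional gap/missing/ambiguity.
random_seqs <- function(n, len, p_special = 0) {
  pool <- c("A", "C", "G", "T")
  special <- c("-", "N", "R", "Y")
  vapply(seq_len(n), function(i) {
    x <- sample(pool, len, replace = TRUE)
    if (p_special > 0) {
      sel <- runif(len) < p_special
      x[sel] <- sample(special, sum(sel), replace = TRUE)
    }
    paste(x, collapse = "")
  }, character(1))
}

# --- independent oracles (deliberately naive) -------------------------------

oracle_counts <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  bases <- c("A", "C", "G", "T")
  n <- ts <- tv <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% bases && b[i] %in% bases) {
      n <- n + 1L
      if (a[i] != b[i]) {
        if ((a[i] %in% c("A", "G")) == (b[i] %in% c("A", "G"))) ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  list(n_sites = n, n_transitions = ts, n_transversions = tv)
}

oracle_k2p <- function(cnt) {
  if (cnt$n_sites == 0) return(NA_real_)
  P <- cnt$n_transitions / cnt$n_sites
  Q <- cnt$n_transversions / cnt$n_sites
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

oracle_distance_matrix <- function(seqs, min_overlap = 1) {
  n <- length(seqs)
  vals <- matrix(NA_real_, n, n, dimnames = list(names(seqs), names(seqs)))
  diag(vals) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    cnt <- oracle_counts(seqs[[i]], seqs[[j]])
    d <- if (cnt$n_sites >= min_overlap) oracle_k2p(cnt) else NA_real_
    vals[i, j] <- vals[j, i] <- d
  }
  vals
}

# Zero-mismatch haplotype collapse by explicit link matrix + label merging.
oracle_collapse <- function(seqs, fifth_state = FALSE) {
  chars <- strsplit(seqs, "")
  informative <- function(x) {
    x %in% c("A", "C", "G", "T", if (fifth_state) "-")
  }
  n <- length(seqs)
  linked <- matrix(FALSE, n, n); diag(linked) <- TRUE
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    a <- chars[[i]]; b <- chars[[j]]
    both <- informative(a) & informative(b)
    same <- !any(a[both] != b[both])
    if (fifth_state) {
      # a gap facing missing data is a mismatch in fifth-state mode
      same <- same && !any((a == "-" & b == "N") | (a == "N" & b == "-"))
    }
    linked[i, j] <- linked[j, i] <- same
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (linked[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# Small simulated study used by several test files (kept small for speed).
small_study <- function(seed = 11L, n_species = 16L) {
  cfg <- simulation_config(
    n_species = n_species,
    clade_spec = data.frame(
      clade = c("Alpha", "Beta"),
      n_species = c(ceiling(n_species / 2), floor(n_species / 2)),
      region = c(NA, "East"), stringsAsFactors = FALSE),
    loci = data.frame(locus = c("slow", "fast"),
                      length = c(400L, 400L),
                      rate = c(0.005, 0.04), kappa = c(2, 2),
                      stringsAsFactors = FALSE),
    seed = seed)
  simulate_barcode_data(cfg)
}
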