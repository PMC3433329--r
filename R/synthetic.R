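#' Configuration for the synthetic barcode-data generator
#'
#' The defaults emulate the sampling design the pipeline was built for: a
#' genus-scale study of ~112 species with four named subclades (two of them
#' tied to geographic regions), six loci spanning a slow chloroplast gene to
#' a fast nuclear spacer, one to six accessions per species with
#' intraspecific divergence far below interspecific divergence, and indel
#' and missing-data noise.
#'
#' @param n_species Total number of species.
#' @param clade_spec `data.frame` with columns `clade` (name), `n_species`
#'   and `region` (tag or `NA`); sizes must sum to `n_species`.
#' @param loci `data.frame` with columns `locus`, `length` (alignment
#'   columns), `rate` (substitutions/site per unit tree height) and `kappa`
#'   (transition/transversion rate ratio of the K80 process).
#' @param accession_range Two integers: min and max accessions per species.
#' @param p_multi Probability a species gets more than one accession
#'   (default 40/112, i.e. 40 of 112 species resampled).
#' @param intraspecific_depth Expected within-species divergence, in units
#'   of tree height (multiplied by each locus rate).
#' @param gap_rate Expected fraction of sites deleted per noisy accession
#'   (gaps are inserted as contiguous runs of geometric length, mean 3).
#' @param missing_rate Expected fraction of terminal sites truncated to
#'   missing per noisy accession.
#' @param root_name Name of the root clade (first `clade_path` element).
#' @param seed Integer seed fixing tree, sequences and noise.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 112L,
                              clade_spec = default_clade_spec(),
                              loci = default_locus_panel(),
                              accession_range = c(1L, 6L),
                              p_multi = 40 / 112,
                              intraspecific_depth = 0.05,
                              gap_rate = 0.01,
                              missing_rate = 0.02,
                              root_name = "Root",
                              seed = 1L) {
  stopifnot(is.data.frame(clade_spec),
            all(c("clade", "n_species", "region") %in% names(clade_spec)),
            is.data.frame(loci),
            all(c("locus", "length", "rate", "kappa") %in% names(loci)))
  if (sum(clade_spec$n_species) != n_species) {
    stop(sprintf("clade sizes sum to %d but n_species is %d",
                 sum(clade_spec$n_species), n_species), call. = FALSE)
  }
  if (any(loci$rate <= 0) || any(loci$kappa <= 0)) {
    stop("locus rates and kappa must be positive", call. = FALSE)
  }
  if (any(clade_spec$n_species < 1L)) {
    stop("every clade needs at least one species", call. = FALSE)
  }
  stopifnot(length(accession_range) == 2L,
            accession_range[1] >= 1L,
            accession_range[2] >= accession_range[1],
            p_multi >= 0, p_multi <= 1,
            intraspecific_depth >= 0, gap_rate >= 0, gap_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_species = as.integer(n_species), clade_spec = clade_spec,
                 loci = loci, accession_range = as.integer(accession_range),
                 p_multi = p_multi,
                 intraspecific_depth = intraspecific_depth,
                 gap_rate = gap_rate, missing_rate = missing_rate,
                 root_name = root_name, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default clade layout of the generator
#'
#' Four named subclades of 11, 28, 12 and 21 species — two carrying region
#' tags — plus a residual clade, totalling 112 species.
#'
#' @return A `data.frame` with columns `clade`, `n_species`, `region`.
#' @export
default_clade_spec <- function() {
  data.frame(
    clade = c("CladeA", "CladeB", "CladeC", "CladeD", "CladeE"),
    n_species = c(11L, 28L, 12L, 21L, 40L),
    region = c(NA, "MexicoCentralAmerica", NA, "Japan", NA),
    stringsAsFactors = FALSE)
}

#' Default six-locus barcode panel
#'
#' Lengths match typical aligned lengths for the six classic plant barcode
#' regions; rates are ordered rbcL (slowest) < matK < trnK < rpl32-trnL <
#' trnH-psbA < nrITS (fastest), scaled so mean interspecific divergences on
#' a unit-height tree land near the percent-scale values seen in practice.
#'
#' @return A `data.frame` with columns `locus`, `length`, `rate`, `kappa`.
#' @export
default_locus_panel <- function() {
  data.frame(
    locus = c("rbcL", "matK", "trnK", "rpl32-trnL", "trnH-psbA", "nrITS"),
    length = c(491L, 725L, 1068L, 942L, 491L, 628L),
    rate = c(0.004, 0.006, 0.0075, 0.0105, 0.0127, 0.0365),
    kappa = c(2, 2, 2, 2, 2, 2),
    stringsAsFactors = FALSE)
}

#' Simulate the species tree and clade/region assignments
#'
#' Each clade is simulated as a pure-birth (Yule) tree rescaled to height
#' 0.5 and grafted onto a deterministic pectinate backbone so that the full
#' tree is ultrametric with unit height and every named clade is
#' monophyletic, its root node labelled with the clade name.
#'
#' @param cfg A [simulation_config()]. The RNG is seeded from `cfg$seed`.
#' @return An object of class `simulated_truth`: list with `tree`
#'   (`phylo`, branch lengths in units of tree height), `species_meta`
#'   (data.frame: `species`, `clade`, `region`, `clade_path`) and
#'   `path_length` (species x species matrix of patristic path lengths, the
#'   per-unit-rate expected divergence).
#' @export
simulate_species_tree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  k <- nrow(cfg$clade_spec)
  clade_height <- if (k > 1L) 0.5 else 1

  clade_newick <- function(name, n) {
    tips <- sprintf("%s_sp%02d", name, seq_len(n))
    if (n == 1L) {
      # single-species clade: bare tip; stem supplies the full depth
      return(list(str = tips, extra = clade_height))
    }
    tr <- ape::rphylo(n, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * clade_height / depth
    tr$tip.label <- tips
    tr$node.label <- c(name, rep("", tr$Nnode - 1L))
    list(str = sub(";$", "", ape::write.tree(tr)), extra = 0)
  }

  parts <- lapply(seq_len(k), function(i) {
    clade_newick(cfg$clade_spec$clade[[i]], cfg$clade_spec$n_species[[i]]) })

  if (k == 1L) {
    newick <- paste0(parts[[1L]]$str, ";")
  } else {
    # pectinate backbone: clade i attaches at depth (i-1) * delta, all clade
    # roots sit at depth 0.5, all tips at depth 1
    delta <- 0.5 / (k - 1)
    stem <- function(i, depth) clade_height - depth + parts[[i]]$extra
    inner <- sprintf("(%s:%g,%s:%g)", parts[[k - 1L]]$str,
                     stem(k - 1L, (k - 2L) * delta),
                     parts[[k]]$str, stem(k, (k - 2L) * delta))
    if (k > 2L) {
      for (i in (k - 2L):1L) {
        inner <- sprintf("(%s:%g,%s:%g)", parts[[i]]$str,
                         stem(i, (i - 1L) * delta), inner, delta)
      }
    }
    newick <- paste0(inner, cfg$root_name, ";")
  }
  tree <- ape::read.tree(text = newick)

  clade_of <- rep(cfg$clade_spec$clade, cfg$clade_spec$n_species)
  species <- unlist(lapply(seq_len(k), function(i)
    sprintf("%s_sp%02d", cfg$clade_spec$clade[[i]],
            seq_len(cfg$clade_spec$n_species[[i]]))))
  region <- rep(cfg$clade_spec$region, cfg$clade_spec$n_species)
  species_meta <- data.frame(
    species = species, clade = clade_of, region = region,
    clade_path = paste(cfg$root_name, clade_of, sep = ";"),
    stringsAsFactors = FALSE)

  path_length <- ape::cophenetic.phylo(tree)
  path_length <- path_length[species, species]

  structure(list(tree = tree, species_meta = species_meta,
                 path_length = path_length, config = cfg),
            class = "simulated_truth")
}

# K80 substitution step, vectorised over sites: returns the child state
# vector given the parent states (integers 1..4), branch length t in
# expected substitutions/site, and transition/transversion rate ratio kappa.
#' @keywords internal
#' @noRd
k80_evolve <- function(parent, t, kappa) {
  if (t <= 0) return(parent)
  e1 <- exp(-4 * t / (kappa + 2))
  e2 <- exp(-2 * t * (kappa + 1) / (kappa + 2))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1          # each of the two transversion targets
  u <- stats::runif(length(parent))
  child <- parent
  ts_partner <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)          # first transversion target
  tv2 <- c(4L, 3L, 4L, 3L)          # second transversion target
  sel <- u < p_ts
  child[sel] <- ts_partner[parent[sel]]
  sel <- u >= p_ts & u < p_ts + p_tv
  child[sel] <- tv1[parent[sel]]
  sel <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  child[sel] <- tv2[parent[sel]]
  child
}

#' Evolve one locus along the simulated species tree
#'
#' The root sequence is uniform over A, C, G, T; each site then evolves
#' independently along every branch under the K80 model with the locus'
#' transition/transversion ratio, branch lengths multiplied by the locus
#' rate.
#'
#' @param truth A `simulated_truth`.
#' @param locus One row of the locus table (list/row with `locus`, `length`,
#'   `rate`, `kappa`).
#' @return Character matrix (species x sites) of residues, attribute
#'   `locus` set. Deterministic given the RNG state.
#' @export
evolve_alignment <- function(truth, locus) {
  stopifnot(inherits(truth, "simulated_truth"))
  L <- as.integer(locus$length)
  tree <- ape::reorder.phylo(truth$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  seqs <- matrix(0L, n_tip + tree$Nnode, L)
  seqs[n_tip + 1L, ] <- sample.int(4L, L, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    seqs[child, ] <- k80_evolve(seqs[par, ],
                                tree$edge.length[[e]] * locus$rate,
                                locus$kappa)
  }
  out <- matrix(.BG_BASES[seqs[seq_len(n_tip), ]], n_tip, L)
  rownames(out) <- tree$tip.label
  out <- out[truth$species_meta$species, , drop = FALSE]
  attr(out, "locus") <- locus$locus
  out
}

# Replace `k` gap runs (geometric length, mean `mean_len`) in a residue
# vector; runs may overlap, matching how alignment gaps cluster.
#' @keywords internal
#' @noRd
inject_gap_runs <- function(x, gap_rate, mean_len = 3) {
  L <- length(x)
  n_runs <- stats::rpois(1L, gap_rate * L / mean_len)
  for (r in seq_len(n_runs)) {
    len <- stats::rgeom(1L, 1 / mean_len) + 1L
    start <- sample.int(L, 1L)
    x[start:min(L, start + len - 1L)] <- "-"
  }
  x
}

# Truncate one sequence end to missing; expected truncated fraction is
# missing_rate.
#' @keywords internal
#' @noRd
inject_terminal_missing <- function(x, missing_rate) {
  L <- length(x)
  len <- stats::rgeom(1L, 1 / (1 + missing_rate * L))
  if (len > 0L) {
    len <- min(len, L)
    if (stats::runif(1L) < 0.5) x[seq_len(len)] <- "N"
    else x[(L - len + 1L):L] <- "N"
  }
  x
}

#' Expand species sequences into accessions and add sampling noise
#'
#' Each species receives one noise-free representative accession plus,
#' with probability `p_multi`, further accessions evolved from the species
#' sequence for an additional expected `intraspecific_depth` (scaled by
#' each locus rate), then degraded with indel runs and terminal missing
#' data.
#'
#' @param species_seqs Named list (per locus) of species x sites residue
#'   matrices from [evolve_alignment()].
#' @param truth A `simulated_truth`.
#' @param cfg The [simulation_config()] in use.
#' @return An [alignment_set()] whose metadata flags the representative
#'   accessions.
#' @export
add_accessions_and_noise <- function(species_seqs, truth, cfg) {
  meta_rows <- list()
  sp_meta <- truth$species_meta
  amin <- cfg$accession_range[[1L]]
  amax <- cfg$accession_range[[2L]]
  n_acc <- vapply(seq_len(nrow(sp_meta)), function(i) {
    if (amax > amin && stats::runif(1L) < cfg$p_multi) {
      sample(seq(max(2L, amin), amax), 1L)
    } else {
      max(1L, amin)
    }
  }, integer(1))

  loci_out <- lapply(names(species_seqs), function(loc) {
    rate <- cfg$loci$rate[cfg$loci$locus == loc]
    kappa <- cfg$loci$kappa[cfg$loci$locus == loc]
    mats <- lapply(seq_len(nrow(sp_meta)), function(i) {
      sp <- sp_meta$species[[i]]
      base <- species_seqs[[loc]][sp, ]
      rows <- matrix("", n_acc[[i]], length(base))
      rows[1L, ] <- base
      for (a in seq_len(n_acc[[i]])[-1L]) {
        enc <- encode_residues(base)
        mutated <- .BG_BASES[k80_evolve(enc, cfg$intraspecific_depth * rate,
                                        kappa)]
        mutated <- inject_gap_runs(mutated, cfg$gap_rate)
        mutated <- inject_terminal_missing(mutated, cfg$missing_rate)
        rows[a, ] <- mutated
      }
      rownames(rows) <- sprintf("%s_a%d", sp, seq_len(n_acc[[i]]))
      rows
    })
    out <- do.call(rbind, mats)
    attr(out, "locus") <- loc
    out
  })
  names(loci_out) <- names(species_seqs)

  metadata <- do.call(rbind, lapply(seq_len(nrow(sp_meta)), function(i) {
    data.frame(
      accession = sprintf("%s_a%d", sp_meta$species[[i]],
                          seq_len(n_acc[[i]])),
      species = sp_meta$species[[i]],
      clade_path = sp_meta$clade_path[[i]],
      region = sp_meta$region[[i]],
      representative = c(TRUE, rep(FALSE, n_acc[[i]] - 1L)),
      stringsAsFactors = FALSE)
  }))
  rownames(metadata) <- NULL
  alignment_set(loci_out, metadata)
}

#' Simulate a complete multi-locus barcode dataset
#'
#' Runs [simulate_species_tree()], [evolve_alignment()] per locus and
#' [add_accessions_and_noise()] under a single seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `aset` (an [alignment_set()]), `truth`
#'   (`simulated_truth`) and `expected_divergence` (long data.frame:
#'   `species_a`, `species_b`, `locus`, `expected_divergence`).
#' @export
simulate_barcode_data <- function(cfg = simulation_config()) {
  truth <- simulate_species_tree(cfg)   # seeds the RNG
  species_seqs <- lapply(seq_len(nrow(cfg$loci)), function(i)
    evolve_alignment(truth, cfg$loci[i, ]))
  names(species_seqs) <- cfg$loci$locus
  aset <- add_accessions_and_noise(species_seqs, truth, cfg)

  sp <- truth$species_meta$species
  pair_idx <- which(upper.tri(truth$path_length), arr.ind = TRUE)
  expected <- do.call(rbind, lapply(seq_len(nrow(cfg$loci)), function(i) {
    data.frame(species_a = sp[pair_idx[, 1]], species_b = sp[pair_idx[, 2]],
               locus = cfg$loci$locus[[i]],
               expected_divergence =
                 cfg$loci$rate[[i]] * truth$path_length[pair_idx],
               stringsAsFactors = FALSE)
  }))
  list(aset = aset, truth = truth, expected_divergence = expected)
}
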