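two_clade_cfg <- function(seed = 1L, ...) {
  simulation_config(
    n_species = 4L,
    clade_spec = data.frame(clade = c("A", "B"), n_species = c(2L, 2L),
                            region = c(NA, "East"), stringsAsFactors = FALSE),
    loci = data.frame(locus = "L", length = 200L, rate = 0.02, kappa = 2,
                      stringsAsFactors = FALSE),
    seed = seed, ...)
}

test_that("config validation enforces the study-design invariants", {
  expect_error(simulation_config(
    n_species = 5L,
    clade_spec = data.frame(clade = c("A", "B"), n_species = c(2L, 2L),
                            region = NA)),
    "clade sizes sum")
  expect_error(simulation_config(
    loci = data.frame(locus = "L", length = 10L, rate = -1, kappa = 2)),
    "positive")
  expect_equal(sum(default_clade_spec()$n_species), 112L)
  panel <- default_locus_panel()
  expect_equal(panel$locus[order(panel$rate)],
               c("rbcL", "matK", "trnK", "rpl32-trnL", "trnH-psbA", "nrITS"))
})

test_that("species trees are ultrametric with labelled monophyletic clades", {
  truth <- simulate_species_tree(two_clade_cfg())
  tree <- truth$tree
  expect_equal(length(tree$tip.label), 4L)
  depths <- ape::node.depth.edgelength(tree)[seq_len(4L)]
  expect_equal(depths, rep(1, 4), tolerance = 1e-8)
  # two cherries: each clade's tips form a clade of size 2
  for (cl in c("A", "B")) {
    tips <- truth$species_meta$species[truth$species_meta$clade == cl]
    expect_true(ape::is.monophyletic(tree, tips))
  }
  expect_true("A" %in% tree$node.label && "B" %in% tree$node.label)
  expect_equal(truth$species_meta$clade_path,
               paste("Root", truth$species_meta$clade, sep = ";"))
  expect_equal(truth$species_meta$region[truth$species_meta$clade == "B"],
               rep("East", 2))

  big <- simulate_species_tree(simulation_config(seed = 3L))
  expect_equal(ape::node.depth.edgelength(big$tree)[seq_len(112L)],
               rep(1, 112), tolerance = 1e-8)
})

test_that("simulation is deterministic under a fixed seed", {
  t1 <- simulate_species_tree(two_clade_cfg(seed = 99L))
  t2 <- simulate_species_tree(two_clade_cfg(seed = 99L))
  expect_equal(ape::write.tree(t1$tree), ape::write.tree(t2$tree))

  s1 <- simulate_barcode_data(two_clade_cfg(seed = 99L))
  s2 <- simulate_barcode_data(two_clade_cfg(seed = 99L))
  expect_identical(s1$aset$loci, s2$aset$loci)
  expect_identical(s1$aset$metadata, s2$aset$metadata)

  s3 <- simulate_barcode_data(two_clade_cfg(seed = 100L))
  expect_false(identical(s1$aset$loci, s3$aset$loci))
})

test_that("rate zero copies the root; huge kappa suppresses transversions", {
  truth <- simulate_species_tree(two_clade_cfg())
  frozen <- evolve_alignment(truth, list(locus = "L", length = 300L,
                                         rate = 0, kappa = 2))
  expect_true(all(frozen == matrix(frozen[1, ], nrow(frozen), ncol(frozen),
                                   byrow = TRUE)))

  ts_biased <- evolve_alignment(truth, list(locus = "L", length = 5000L,
                                            rate = 0.01, kappa = 1e9))
  cnt <- count_site_patterns(paste(ts_biased[1, ], collapse = ""),
                             paste(ts_biased[3, ], collapse = ""))
  expect_equal(cnt$n_transversions, 0L)
  expect_gt(cnt$n_transitions, 0L)
})

test_that("K2P estimates recover the simulated expected divergence", {
  # two tips at expected divergence d: estimate over replicates must sit
  # within 3 Monte-Carlo SE of d (kept small here; the full-size check runs
  # in the acceptance suite)
  set.seed(5)
  for (case in list(list(d = 0.02, kappa = 2), list(d = 0.08, kappa = 5))) {
    n_rep <- 60; L <- 2000
    est <- vapply(seq_len(n_rep), function(r) {
      root <- sample.int(4L, L, replace = TRUE)
      a <- barcodegap:::k80_evolve(root, case$d / 2, case$kappa)
      b <- barcodegap:::k80_evolve(root, case$d / 2, case$kappa)
      k2p_distance(list(n_sites = L,
                        n_transitions = sum(a != b & (a %% 2) == (b %% 2)),
                        n_transversions = sum(a != b & (a %% 2) != (b %% 2))))
    }, numeric(1))
    mc_se <- stats::sd(est) / sqrt(n_rep)
    expect_lt(abs(mean(est) - case$d), 3 * mc_se + 1e-9)
  }
})

test_that("accession noise behaves at its limits", {
  cfg0 <- two_clade_cfg()
  cfg0$intraspecific_depth <- 0; cfg0$gap_rate <- 0; cfg0$missing_rate <- 0
  cfg0$p_multi <- 1
  sim <- simulate_barcode_data(cfg0)
  ds <- build_dataset(sim$aset, "L")
  # every accession of a species identical to its representative
  for (sp in unique(ds$meta$species)) {
    rows <- ds$matrix[ds$meta$accession[ds$meta$species == sp], ,
                      drop = FALSE]
    expect_true(all(rows == matrix(rows[1, ], nrow(rows), ncol(rows),
                                   byrow = TRUE)))
  }
  # no gaps/missing: the two gap conventions agree
  expect_equal(collapse_haplotypes(ds, "gap_as_fifth_state")$n_unique,
               collapse_haplotypes(ds, "gap_as_missing")$n_unique)

  cfg_gap <- two_clade_cfg(seed = 42L)
  cfg_gap$gap_rate <- 0.05; cfg_gap$p_multi <- 1
  sim_gap <- simulate_barcode_data(cfg_gap)
  ds_gap <- build_dataset(sim_gap$aset, "L")
  expect_true(any(ds_gap$matrix == "-"))
  expect_gte(collapse_haplotypes(ds_gap, "gap_as_fifth_state")$n_unique,
             collapse_haplotypes(ds_gap, "gap_as_missing")$n_unique)
})

test_that("expected-divergence truth table matches the tree path lengths", {
  sim <- simulate_barcode_data(two_clade_cfg(seed = 6L))
  exp_tab <- sim$expected_divergence
  expect_equal(nrow(exp_tab), choose(4, 2))
  ph <- sim$truth$path_length
  for (k in seq_len(nrow(exp_tab))) {
    expect_equal(exp_tab$expected_divergence[k],
                 0.02 * ph[exp_tab$species_a[k], exp_tab$species_b[k]],
                 tolerance = 1e-12)
  }
  # within-clade paths are shorter than between-clade paths
  within <- ph["A_sp01", "A_sp02"]
  between <- ph["A_sp01", "B_sp01"]
  expect_lt(within, between)
  expect_equal(between, 2, tolerance = 1e-8)  # through the root
})
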