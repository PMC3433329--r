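make_partition <- function(seqs, species, representative = NULL,
                           min_overlap = 1) {
  ds <- toy_dataset(seqs, species = species, representative = representative)
  partition_distances(distance_matrix(ds, min_overlap = min_overlap), ds$meta)
}

test_that("distance partition separates intra- and interspecific pairs", {
  # 3 species x 1 accession: all pairs interspecific
  p <- make_partition(c(a = "ACGTACGT", b = "ACGAACGT", c = "AGGTACGT"),
                      species = c("s1", "s2", "s3"))
  expect_equal(nrow(p$interspecific), 3L)
  expect_equal(nrow(p$intraspecific), 0L)

  # 1 species x 3 accessions: all pairs intraspecific
  p <- make_partition(c(a = "ACGTACGT", b = "ACGAACGT", c = "AGGTACGT"),
                      species = c("s1", "s1", "s1"))
  expect_equal(nrow(p$interspecific), 0L)
  expect_equal(nrow(p$intraspecific), 3L)

  # 2 species x 2 accessions: 1 representative pair + 2 within-species pairs
  p <- make_partition(
    c(x1 = "ACGTACGT", x2 = "ACGTACGA", y1 = "AGGTACGT", y2 = "AGGTACGC"),
    species = c("sX", "sX", "sY", "sY"),
    representative = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(p$interspecific), 1L)
  expect_equal(p$interspecific$accession_a, "x1")
  expect_equal(p$interspecific$accession_b, "y1")
  expect_equal(nrow(p$intraspecific), 2L)
  expect_equal(unname(p$representatives), c("x1", "y1"))
})

test_that("labels without metadata are rejected", {
  ds <- toy_dataset(c(a = "ACGT", b = "ACGA"), species = c("s1", "s2"))
  dm <- distance_matrix(ds, min_overlap = 1)
  meta <- ds$meta[1, , drop = FALSE]
  expect_error(partition_distances(dm, meta), "no metadata")
})

test_that("undefined distances are excluded and counted", {
  # b overlaps nobody at >= 4 sites
  p <- make_partition(c(a = "ACGTNNNN", b = "NNNNACGT", c = "ACGANNNN"),
                      species = c("s1", "s2", "s3"), min_overlap = 4)
  expect_equal(nrow(p$interspecific), 1L)  # only a-c defined
  expect_equal(p$n_undefined_excluded, 2L)
})

test_that("intraspecific summary averages within species first", {
  # species X pairs {0, 0}, species Y pair {0.01}:
  # per-species means {0, 0.01} -> mean 0.005, max 0.01
  part <- structure(list(
    interspecific = data.frame(distance = 0.05),
    intraspecific = data.frame(
      species = c("X", "X", "Y"),
      accession_a = c("x1", "x1", "y1"),
      accession_b = c("x2", "x3", "y2"),
      distance = c(0, 0, 0.01)),
    n_undefined_excluded = 0L), class = "distance_partition")
  s <- intraspecific_summary(part)
  expect_equal(s$mean, 0.005)
  expect_equal(s$max, 0.01)
  expect_equal(s$n_species, 2L)
  expect_equal(s$n_accessions, 5L)

  # single species, single pair
  part$intraspecific <- data.frame(species = "X", accession_a = "x1",
                                   accession_b = "x2", distance = 0.003)
  s <- intraspecific_summary(part)
  expect_equal(s$mean, 0.003)
  expect_equal(s$sd, 0)
  expect_equal(s$max, 0.003)

  # no multi-accession species: empty marker
  part$intraspecific <- part$intraspecific[0, ]
  s <- intraspecific_summary(part)
  expect_true(is.na(s$mean))
  expect_equal(s$n_species, 0L)
})

test_that("interspecific summary equals brute-force recomputation", {
  set.seed(17)
  d <- runif(10, 0, 0.1)
  part <- structure(list(
    interspecific = data.frame(distance = d),
    intraspecific = data.frame(species = character(0),
                               accession_a = character(0),
                               accession_b = character(0),
                               distance = numeric(0)),
    n_undefined_excluded = 0L), class = "distance_partition")
  s <- interspecific_summary(part)
  expect_equal(s$mean, sum(d) / length(d))
  expect_equal(s$sd, sqrt(sum((d - mean(d))^2) / (length(d) - 1)))
  expect_equal(s$max, max(d))

  part$interspecific <- data.frame(distance = 0.02)
  expect_equal(interspecific_summary(part)$sd, 0)
})

test_that("threshold exceedance uses strict inequality and is monotone", {
  part <- structure(list(
    interspecific = data.frame(distance = c(0.005, 0.015, 0.025)),
    intraspecific = data.frame(distance = numeric(0)),
    n_undefined_excluded = 0L), class = "distance_partition")
  expect_equal(fraction_above(part, 0.01), 66.67)
  expect_equal(fraction_above(part, 0.02), 33.33)
  expect_equal(fraction_above(part, 0), 100.00)
  expect_equal(fraction_above(part, 0.025), 0)   # strict: d == threshold out

  set.seed(2)
  part$interspecific <- data.frame(distance = runif(50, 0, 0.05))
  ths <- seq(0, 0.05, by = 0.005)
  vals <- vapply(ths, function(t) fraction_above(part, t), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("barcoding gap compares distribution extremes strictly", {
  mk <- function(intra, inter) structure(list(
    interspecific = data.frame(distance = inter),
    intraspecific = data.frame(species = rep("s", length(intra)),
                               accession_a = rep("", length(intra)),
                               accession_b = rep("", length(intra)),
                               distance = intra),
    n_undefined_excluded = 0L), class = "distance_partition")

  g <- barcoding_gap(mk(0.001, c(0.02, 0.03)))
  expect_true(g$gap_exists)
  expect_equal(g$gap_margin, 0.019)

  g <- barcoding_gap(mk(0.01, 0.005))
  expect_false(g$gap_exists)
  expect_equal(g$gap_margin, -0.005)

  g <- barcoding_gap(mk(0, 0))
  expect_false(g$gap_exists)  # margin 0 is not a gap
  expect_equal(g$gap_margin, 0)

  g <- barcoding_gap(mk(numeric(0), c(0.01, 0.02)))
  expect_true(is.na(g$gap_exists))

  # histogram bins cover the pooled range and count every distance once
  g <- barcoding_gap(mk(c(0.001, 0.004), c(0.012, 0.019, 0.03)),
                     bin_width = 0.005)
  h <- g$histogram
  expect_equal(h$bin_start[1], 0)
  expect_equal(sum(h$intra_count), 2)
  expect_equal(sum(h$inter_count), 3)
  expect_true(all(abs(h$bin_end - h$bin_start - 0.005) < 1e-12))
})

test_that("evaluate_dataset assembles a coherent report row", {
  set.seed(8)
  sim <- small_study(seed = 8, n_species = 12)
  ds <- build_dataset(sim$aset, c("slow", "fast"))
  r <- evaluate_dataset(ds, min_overlap = 50)

  expect_s3_class(r, "discrimination_report")
  expect_equal(r$n_species, 12L)
  expect_equal(r$aligned_length, 800L)
  expect_equal(r$max_id_rate_pct, max_id_rate(r$n_unique, r$n_species))
  expect_gte(r$n_unique_fifth, r$n_unique)
  expect_lte(r$inter_mean, r$inter_max)
  expect_true(all(diff(r$pct_above) <= 0))     # pct > 2% <= pct > 1%
  expect_true(all(r$pct_above >= 0 & r$pct_above <= 100))
  if (r$intra_n_species > 0) expect_lte(r$intra_mean, r$intra_max)

  # interspecific pair count = C(n_species, 2) minus undefined exclusions
  part <- attr(r, "partition")
  missing_pairs <- choose(r$n_species, 2) - nrow(part$interspecific)
  expect_gte(missing_pairs, 0)
  expect_lte(missing_pairs, r$n_undefined_excluded)
})

test_that("zero-distance representatives are indistinguishable at any threshold", {
  p <- make_partition(c(a = "ACGTACGT", b = "ACGTACGT", c = "AGGAACGT"),
                      species = c("s1", "s2", "s3"))
  expect_true(any(p$interspecific$distance == 0))
  # the s1-s2 pair never counts toward any positive threshold
  for (th in c(0.001, 0.01, 0.02)) {
    expect_lte(fraction_above(p, th), round(100 * 2 / 3, 2))
  }
})

test_that("report rows serialise in the standard table layout", {
  sim <- small_study(seed = 4, n_species = 10)
  ds <- build_dataset(sim$aset, "fast")
  r <- evaluate_dataset(ds, min_overlap = 50)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(r, tsv)
  tab <- utils::read.delim(tsv, check.names = FALSE)
  expect_identical(names(tab),
                   c("Gene Region", "Species", "Aligned Length",
                     "Variable characters", "Unique sequences",
                     "% Max ID rate", "Max", "Mean (SD)", "> 1%", "> 2%"))
  expect_equal(tab$Species, r$n_species)
  expect_equal(tab$`% Max ID rate`, r$max_id_rate_pct)
  # distances at 4 decimals, "mean (sd)" composite
  expect_match(as.character(tab$`Mean (SD)`),
               "^\\d+\\.\\d{4} \\(\\d+\\.\\d{4}\\)$")
})
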