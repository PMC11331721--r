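test_that("community sampling is normalised, positive and seed-deterministic", {
  one <- sample_community(1, seed = 1)
  expect_equal(unname(one$theta), 1)

  com <- sample_community(10, seed = 42)
  expect_equal(sum(com$theta), 1)
  expect_true(all(com$theta > 0))
  expect_equal(sum(com$copies), 100)

  again <- sample_community(10, seed = 42)
  expect_identical(com$theta, again$theta)
  expect_identical(com$genome_lengths, again$genome_lengths)
  expect_error(sample_community(0), "k must be")
  expect_error(sample_community(3, ambiguity = cbind(1, 9)), "unknown")
})

test_that("taxonomic to sequence abundance weights by genome length", {
  expect_equal(taxonomic_to_sequence_abundance(c(0.5, 0.5), c(1e6, 1e6)),
               c(0.5, 0.5))
  expect_equal(taxonomic_to_sequence_abundance(c(0.5, 0.5), c(1e6, 3e6)),
               c(0.25, 0.75))
  expect_equal(taxonomic_to_sequence_abundance(1, 5e6), 1)
  expect_error(taxonomic_to_sequence_abundance(c(1, 1), c(0, 1)), "positive")
  expect_error(taxonomic_to_sequence_abundance(c(0, 0), c(1, 1)), "zero")
})

test_that("fixture files are byte-identical under a fixed seed", {
  truth <- sample_community(4, seed = 9, total_copies = 30)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_marker_alignments(truth, ambiguity_frac = 0.3, seed = 9, dir = d1)
  simulate_marker_alignments(truth, ambiguity_frac = 0.3, seed = 9, dir = d2)
  for (f in c("hits.tsv", "alignments.paf", "ref2species.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("unambiguous fixtures recover planted copies within 1/8 granularity", {
  truth <- sample_community(6, seed = 17, total_copies = 60)
  sim <- simulate_marker_alignments(truth, seed = 17)
  hits <- filter_protein_hits(sim$hits)
  est <- prokaryotic_genome_copies(hits)$total
  # per species, round(copies * 8)/8 is the attainable granularity
  attainable <- sum(round(truth$copies * 8)) / 8
  expect_equal(est, attainable)
  expect_lte(abs(est - sum(truth$copies)), length(truth$copies) / 16 + 1 / 8)

  # single species, copies 2.0: 16 reads, estimate exactly 2.0
  t1 <- sample_community(1, seed = 3, total_copies = 2)
  s1 <- simulate_marker_alignments(t1, reads_per_copy = 8, seed = 3)
  expect_equal(nrow(s1$hits), 16L)
  expect_equal(prokaryotic_genome_copies(s1$hits)$total, 2)
})

test_that("ambiguous reads list both species in the read-species matrix", {
  truth <- sample_community(2, seed = 23, total_copies = 20)
  sim <- simulate_marker_alignments(truth, ambiguity_frac = 1, seed = 23)
  m <- build_read_species_matrix(sim$alignments)
  expect_true(all(rowSums(m$x) == 2))  # every read near-tied to the neighbour

  clean <- simulate_marker_alignments(truth, ambiguity_frac = 0, seed = 23)
  mc <- build_read_species_matrix(clean$alignments)
  expect_true(all(rowSums(mc$x) == 1))
  fit <- em_iterate(mc)
  counts <- table(clean$reads$species)
  expect_equal(unname(coef(fit)[names(counts)]),
               unname(as.numeric(counts) / sum(counts)))
})

test_that("sub-threshold ambiguity offsets fail all three validity conditions", {
  truth <- sample_community(2, seed = 29, total_copies = 20)
  sim <- simulate_marker_alignments(truth, ambiguity_frac = 1, seed = 29,
                                    ambiguous_score_frac = 0.98,
                                    ambiguous_id_frac = 0.998)
  m <- build_read_species_matrix(sim$alignments)
  expect_true(all(rowSums(m$x) == 1))
})

test_that("simulate() on a fitted profile reproduces its abundances", {
  sim <- simulate_marker_alignments(
    sample_community(3, seed = 31, total_copies = 60), seed = 31)
  cp <- profile_community(sim$hits, sim$alignments, sim$truth$lineages)
  boot <- simulate(cp, nsim = 1, seed = 31)[[1]]
  expect_equal(sort(names(boot$truth$theta)),
               sort(sprintf("Genus%03d species%03d", 1:3, 1:3)))
  expect_equal(sum(boot$truth$theta), 1)
  expect_equal(sum(boot$truth$copies), sum(cp$profile$copies), tolerance = 1e-9)
})
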