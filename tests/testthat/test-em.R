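test_that("alignment validity follows the three strict score conditions", {
  single <- nucleotide_alignments("r1", "w", "A", 100, 100, 0.99)
  m <- build_read_species_matrix(single)
  expect_equal(dim(m$x), c(1L, 1L))
  expect_equal(sum(m$x), 1)

  # B at ID 0.9885: all of 98 > 99, 98 > 99, 0.9885 > 0.98901 fail -> A only
  ab <- nucleotide_alignments(c("r1", "r1"), "w", c("A", "B"),
                              c(100, 98), c(100, 98), c(0.990, 0.9885))
  expect_equal(unname(build_read_species_matrix(ab)$x[1, ]), c(1, 0))

  # B at ID 0.9895 > 0.999 * 0.990 = 0.98901 -> both valid
  ab2 <- nucleotide_alignments(c("r1", "r1"), "w", c("A", "B"),
                               c(100, 98), c(100, 98), c(0.990, 0.9895))
  expect_equal(unname(build_read_species_matrix(ab2)$x[1, ]), c(1, 1))

  # all three conditions fail by a wide margin -> excluded
  far <- nucleotide_alignments(c("r1", "r1"), "w", c("A", "B"),
                               c(100, 90), c(100, 90), c(0.99, 0.95))
  expect_equal(unname(build_read_species_matrix(far)$x[1, ]), c(1, 0))

  empty <- build_read_species_matrix(
    nucleotide_alignments(character(0), character(0), character(0),
                          numeric(0), numeric(0), numeric(0), logical(0)))
  expect_equal(nrow(empty$x), 0L)
})

test_that("only the best alignment per read-species pair is retained", {
  dup <- nucleotide_alignments(c("r1", "r1"), c("w1", "w2"), "A",
                               c(900, 1000), c(900, 1000), c(0.98, 0.99))
  m <- build_read_species_matrix(dup)
  expect_equal(unname(m$AS[1, "A"]), 1000)
  expect_equal(unname(m$ID[1, "A"]), 0.99)
})

test_that("EM recovers empirical proportions for uniquely mapped reads", {
  m <- build_read_species_matrix(aln_from_sets(list("A", "A", "A", "B")))
  fit <- em_iterate(m)
  expect_equal(unname(coef(fit)[c("A", "B")]), c(0.75, 0.25))
  expect_true(fit$converged)
})

test_that("EM resolves the symmetric and asymmetric toy instances", {
  sym <- em_iterate(build_read_species_matrix(
    aln_from_sets(list("A", "B", c("A", "B")))))
  expect_equal(unname(coef(sym)[c("A", "B")]), c(0.5, 0.5), tolerance = 1e-4)

  # {A},{A},{B},{A,B}: fixed point a = (2 + a)/4 -> a = 2/3
  asym <- em_iterate(build_read_species_matrix(
    aln_from_sets(list("A", "A", "B", c("A", "B")))))
  expect_equal(unname(coef(asym)[c("A", "B")]), c(2 / 3, 1 / 3),
               tolerance = 1e-4)
  amb_row <- asym$z["r004", c("A", "B")]
  expect_equal(unname(amb_row), c(2 / 3, 1 / 3), tolerance = 1e-4)
})

test_that("EM invariants hold on random matrices", {
  set.seed(99)
  for (trial in 1:25) {
    k <- sample(2:6, 1)
    species <- LETTERS[seq_len(k)]
    sets <- lapply(seq_len(sample(5:30, 1)), function(i) {
      sz <- sample(seq_len(k), 1, prob = k:1)
      sample(species, sz)
    })
    m <- build_read_species_matrix(aln_from_sets(sets))
    fit <- em_iterate(m, t_max = 10000L)
    theta <- unname(coef(fit))
    expect_equal(sum(theta), 1, tolerance = 1e-9)
    expect_equal(unname(rowSums(fit$z)), rep(1, fit$n), tolerance = 1e-9)
    expect_true(all(fit$z[m$x == 0] == 0))
    # log-likelihood non-decreasing
    expect_true(all(diff(fit$loglik) >= -1e-9))
    # returned theta is a fixed point of one E+M sweep
    num <- sweep(m$x, 2, coef(fit), `*`)
    z <- num / rowSums(num)
    expect_lt(sum(abs(colSums(z) / fit$n - coef(fit))), fit$eps)
    # uniquely mapped reads are never reassigned
    uniq <- rowSums(m$x) == 1
    expect_true(all(fit$z[uniq, ][m$x[uniq, , drop = FALSE] == 1] == 1))
  }
})

test_that("EM rejects degenerate input", {
  m <- build_read_species_matrix(aln_from_sets(list("A")))
  m$x[1, 1] <- 0
  expect_error(em_iterate(m), "no valid species")
})

test_that("hard assignment follows the deterministic tie-break chain", {
  m <- build_read_species_matrix(aln_from_sets(list("A", "A", "B",
                                                    c("A", "B"))))
  fit <- em_iterate(m)
  lin <- tax_lineages(c("A", "B"))
  asg <- hard_assign(fit, m, lin)
  expect_equal(unname(asg[c("r001", "r003")]), c("A", "B"))
  expect_equal(unname(asg["r004"]), "A")  # z = (2/3, 1/3)

  # z tie: well-defined species beats a placeholder at equal scores
  aln <- nucleotide_alignments(
    c("r1", "r1"), "w", c("Escherichia coli", "Escherichia sp."),
    AS = c(100, 100), MS = c(100, 100), ID = c(0.99, 0.99))
  m2 <- build_read_species_matrix(aln)
  fit2 <- em_iterate(m2)
  lin2 <- tax_lineages(c("Escherichia coli", "Escherichia sp."))
  expect_equal(unname(hard_assign(fit2, m2, lin2)), "Escherichia coli")

  # equal z and definedness: higher AS wins
  aln3 <- nucleotide_alignments(
    c("r1", "r1", "r2", "r2"), "w", c("Aa bb", "Cc dd"),
    AS = c(1000, 995, 995, 1000), MS = 1000, ID = 0.99)
  m3 <- build_read_species_matrix(aln3)
  fit3 <- em_iterate(m3)
  asg3 <- hard_assign(fit3, m3, tax_lineages(c("Aa bb", "Cc dd")))
  expect_equal(unname(asg3), c("Aa bb", "Cc dd"))
})

test_that("aggregation apportions copies by assigned read counts", {
  lin <- tax_lineages(c("Aa bb", "Cc dd"))
  asg <- c(rep("Aa bb", 6), rep("Cc dd", 2))
  names(asg) <- sprintf("r%d", 1:8)
  prof <- aggregate_profile(asg, total_copies = 1, lin)  # 8 reads / 8 markers
  expect_equal(prof$copies, c(0.75, 0.25))
  expect_equal(prof$rel_abundance, c(0.75, 0.25))

  one <- aggregate_profile(c(r1 = "Aa bb"), 2, lin)
  expect_equal(one$rel_abundance[1], 1)
  expect_equal(attr(one, "total_copies"), 2)

  none <- aggregate_profile(character(0), 0, lin)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "total_copies"), 0)
  expect_error(aggregate_profile(c(r1 = "Zz qq"), 1, lin), "missing")
})

test_that("profile_community ties the stages together", {
  sim <- simulate_marker_alignments(
    sample_community(4, seed = 2, total_copies = 40),
    ambiguity_frac = 0.25, seed = 2)
  cp <- profile_community(sim$hits, sim$alignments, sim$truth$lineages)
  expect_s3_class(cp, "community_profile")
  expect_equal(length(cp$assignments), nrow(sim$reads))
  expect_equal(attr(cp$profile, "total_copies"), cp$copies$total)
  expect_equal(sum(coef(cp)), 1, tolerance = 1e-9)
  expect_output(print(cp), "Community profile")
  expect_s3_class(logLik(cp), "logLik")
})
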