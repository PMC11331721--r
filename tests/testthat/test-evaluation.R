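test_that("copy recovery ratios and correlation", {
  eq <- copy_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$ratio, c(1, 1, 1))
  expect_equal(eq$pearson_r, 1)

  dbl <- copy_metrics(c(2, 4, 6), c(1, 2, 3))
  expect_equal(dbl$ratio, c(2, 2, 2))
  expect_equal(dbl$pearson_r, 1)

  # closed-form covariance check for (1,2,3) vs (1,2,4)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(copy_metrics(x, y)$pearson_r, r_closed)
  expect_error(copy_metrics(1, 0), "positive")
})

test_that("species-set precision, recall and F1", {
  ident <- set_metrics(c("A", "B"), c("A", "B"))
  expect_equal(unlist(ident), c(precision = 1, recall = 1, f1 = 1))

  part <- set_metrics(c("A", "B", "C"), c("A", "B", "D"))
  expect_equal(unlist(part),
               c(precision = 2 / 3, recall = 2 / 3, f1 = 2 / 3))

  disj <- set_metrics(c("A"), c("B"))
  expect_equal(unlist(disj), c(precision = 0, recall = 0, f1 = 0))
  expect_error(set_metrics(character(0), "A"), "empty")
  # unclassified entries are excluded before counting
  expect_equal(set_metrics(c("A", "unclassified"), c("A"))$precision, 1)
})

test_that("dissimilarities match closed forms and the summation oracle", {
  disj <- dissimilarities(c(A = 1), c(B = 1))
  expect_equal(unlist(disj),
               c(manhattan = 2, euclidean = sqrt(2), bray_curtis = 1,
                 jensen_shannon = 1))

  same <- dissimilarities(c(A = 0.3, B = 0.7), c(A = 0.3, B = 0.7))
  expect_equal(unlist(same), c(manhattan = 0, euclidean = 0,
                               bray_curtis = 0, jensen_shannon = 0))

  p <- c(A = 0.5, B = 0.5); q <- c(A = 0.25, B = 0.75)
  d <- dissimilarities(p, q)
  expect_equal(d$manhattan, 0.5)
  expect_equal(d$euclidean, sqrt(2 * 0.25^2))
  expect_equal(d$bray_curtis, 0.25)
  expect_equal(d$jensen_shannon, jsd_oracle(p, q))
  expect_error(dissimilarities(c(A = -1), c(A = 1)), "non-negative")
})

test_that("dissimilarities are symmetric, zero iff equal, JS bounded by 1", {
  skip_if_not_installed("vegan")
  set.seed(4)
  for (trial in 1:30) {
    k <- sample(2:10, 1)
    p <- stats::setNames(stats::runif(k), paste0("s", 1:k))
    q <- stats::setNames(stats::runif(k), paste0("s", 1:k))
    d1 <- dissimilarities(p, q)
    d2 <- dissimilarities(q, p)
    expect_equal(unlist(d1), unlist(d2))
    expect_lte(d1$jensen_shannon, 1)
    expect_gt(d1$manhattan, 0)
    # independent Bray-Curtis route on the renormalised vectors
    bc <- as.numeric(vegan::vegdist(rbind(p / sum(p), q / sum(q)),
                                    method = "bray"))
    expect_equal(d1$bray_curtis, bc, tolerance = 1e-12)
    expect_equal(unlist(dissimilarities(p, p)),
                 c(manhattan = 0, euclidean = 0, bray_curtis = 0,
                   jensen_shannon = 0))
  }
})

test_that("evaluate_profiles combines set metrics and dissimilarities", {
  est <- abundance_profile(tax_lineages(c("Aa bb", "Cc dd")), c(3, 1))
  tru <- abundance_profile(tax_lineages(c("Aa bb", "Ee ff")), c(2, 2))
  rep <- evaluate_profiles(est, tru)
  expect_equal(rep$precision, 0.5)
  expect_equal(rep$recall, 0.5)
  expect_equal(rep$f1, 0.5)
  expect_equal(rep$manhattan,
               dissimilarities(c("Aa bb" = 0.75, "Cc dd" = 0.25),
                               c("Aa bb" = 0.5, "Ee ff" = 0.5))$manhattan)
})

test_that("the genome-size database averages over descendant leaves", {
  taxonomy <- data.frame(
    taxid = c("sp1", "sp2", "sp3", "gen1", "gen2", "fam1"),
    parent = c("gen1", "gen1", "gen2", "fam1", "fam1", NA),
    stringsAsFactors = FALSE)
  db <- build_genome_size_db(c(sp1 = 4e6, sp2 = 6e6, sp3 = 3e6), taxonomy)
  expect_equal(db$size[["gen1"]], 5e6)
  expect_equal(db$size[["gen2"]], 3e6)
  expect_equal(db$size[["fam1"]], mean(c(4e6, 6e6, 3e6)))

  single <- build_genome_size_db(c(sp1 = 4e6), taxonomy)
  expect_equal(unname(single$size[c("gen1", "fam1")]), c(4e6, 4e6))

  empty <- build_genome_size_db(stats::setNames(numeric(0), character(0)),
                                taxonomy)
  expect_equal(length(empty$size), 0L)

  cyc <- data.frame(taxid = c("a", "b"), parent = c("b", "a"),
                    stringsAsFactors = FALSE)
  expect_error(build_genome_size_db(c(a = 1e6), cyc), "cycle")
})

test_that("genome-size correction divides bp by size with ancestor fallback", {
  taxonomy <- data.frame(taxid = c("sp1", "sp2", "gen1"),
                         parent = c("gen1", "gen1", NA),
                         stringsAsFactors = FALSE)
  db <- build_genome_size_db(c(sp1 = 5e6), taxonomy)
  expect_equal(unname(genome_size_correct(c(sp1 = 1e7), db)), 2)
  # sp2 has no size: falls back to its genus (5e6)
  expect_equal(unname(genome_size_correct(c(sp2 = 1e7), db)), 2)
  expect_equal(unname(genome_size_correct(c(sp1 = 0), db)), 0)
  # scale equivariance
  expect_equal(unname(genome_size_correct(c(sp1 = 2e7), db)),
               2 * unname(genome_size_correct(c(sp1 = 1e7), db)))
  expect_warning(out <- genome_size_correct(c(orphan = 1e6), db),
                 "no sized ancestor")
  expect_true(is.na(out[["orphan"]]))
})
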