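test_that("universality and deviance match their definitions", {
  m <- cbind(g1 = c(1, 1, 1, 1), g2 = c(1, 1, 0, 2), g3 = c(2, 2, 2, 2))
  rownames(m) <- paste0("a", 1:4)
  st <- compute_marker_stats(m)
  expect_equal(st$universality, c(1, 0.75, 1))
  expect_equal(st$deviance, c(0, 0, 1))  # g2 mean copy is exactly 1

  sub <- compute_marker_stats(m, subsets = list(full = rownames(m),
                                                tiny = c("a1", "a2")))
  expect_equal(sub$universality[sub$subset == "tiny"], c(1, 1, 1))
  expect_error(compute_marker_stats(m, subsets = list(bad = character(0))),
               "empty")
})

test_that("F0.5 weighs precision over recall", {
  expect_equal(f05_score(10, 0, 0), 1)
  expect_equal(f05_score(50, 50, 0), 0.625 / 1.125)
  expect_equal(f05_score(0, 5, 5), 0)
  expect_error(f05_score(0, 0, 0), "undefined")
})

test_that("circular distances are shortest-arc, normalised, capped at 0.5", {
  pos <- list(a1 = list(g1 = 100, g2 = 900, g3 = 100, g4 = 600))
  d <- mean_relative_distance_matrix(pos, c(a1 = 1000))
  expect_equal(d["g1", "g2"], 0.2)   # min(800, 200) / 1000
  expect_equal(d["g1", "g3"], 0)     # same position
  expect_equal(d["g1", "g4"], 0.5)   # antipodal maximum
  expect_true(all(d[!is.na(d)] <= 0.5))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
})

test_that("multi-copy genes use the minimum over copy pairs and averages span assemblies", {
  pos <- list(
    a1 = list(g1 = c(0, 500), g2 = 100),
    a2 = list(g1 = 0, g2 = 300),
    a3 = list(g3 = 10)  # never co-occurs with g1
  )
  d <- mean_relative_distance_matrix(pos, c(a1 = 1000, a2 = 1000, a3 = 1000))
  expect_equal(d["g1", "g2"], (0.1 + 0.3) / 2)  # copy at 0 is nearer in a1
  expect_true(is.na(d["g1", "g3"]))
})

test_that("single-linkage clusters are cutoff components, matching hclust", {
  genes <- c("a", "b", "c", "d")
  d <- matrix(1, 4, 4, dimnames = list(genes, genes))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.03
  d["b", "c"] <- d["c", "b"] <- 0.04
  d["a", "c"] <- d["c", "a"] <- 0.2
  cl <- single_linkage_clusters(d, 0.05)
  expect_equal(cl, list(c("a", "b", "c"), "d"))  # chained through b

  # order invariance
  perm <- c("d", "c", "a", "b")
  cl2 <- single_linkage_clusters(d[perm, perm], 0.05)
  expect_equal(sort(vapply(cl2, paste, "", collapse = "+")),
               sort(vapply(cl, paste, "", collapse = "+")))

  # independent route: single-linkage dendrogram cut just below the cutoff
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  ct <- stats::cutree(hc, h = 0.05 - 1e-12)
  expect_equal(length(cl), length(unique(ct)))
  for (grp in split(names(ct), ct)) {
    expect_true(any(vapply(cl, function(g) setequal(g, grp), logical(1))))
  }

  singletons <- single_linkage_clusters(
    matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y"))),
    0.05)
  expect_equal(singletons, list("x", "y"))

  zero <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(single_linkage_clusters(zero, 0.05), list(c("x", "y")))
})

test_that("representatives are ranked by universality, then deviance", {
  stats <- data.frame(
    gene = rep(c("g1", "g2", "g3"), each = 1), subset = "full",
    universality = c(1, 0.995, 0.98), deviance = c(0.001, 0, 0),
    f05 = c(0.995, 0.995, 0.999), stringsAsFactors = FALSE)
  reps <- select_representatives(list(c("g1", "g2", "g3")), stats)
  expect_equal(reps, "g1")  # universality dominates; g3 screened out (U=0.98)
  expect_equal(select_representatives(list("g2"), stats), "g2")
  expect_error(select_representatives(list(character(0)), stats), "empty")
})

test_that("planted spatial clusters each yield one representative", {
  set.seed(13)
  genes <- sprintf("g%02d", 1:16)
  # two co-located blocks of 8 genes on opposite sides of the circle
  base <- c(rep(0.05e6, 8), rep(2.55e6, 8))
  n_asm <- 20
  positions <- lapply(seq_len(n_asm), function(a) {
    L <- 5e6
    jitter <- runif(16, 0, 0.02e6)
    stats::setNames(as.list(pmin(base + jitter, L - 1)), genes)
  })
  names(positions) <- sprintf("a%02d", seq_len(n_asm))
  lengths <- stats::setNames(rep(5e6, n_asm), names(positions))
  copy_table <- matrix(1, n_asm, 16,
                       dimnames = list(names(positions), genes))
  f05 <- stats::setNames(rep(0.995, 16), genes)
  sel <- select_markers(copy_table, f05, positions, lengths)
  expect_equal(length(sel$clusters), 2L)
  expect_equal(length(sel$markers), 2L)
  blocks <- list(genes[1:8], genes[9:16])
  for (b in blocks) {
    expect_equal(sum(sel$markers %in% b), 1L)
  }
})
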