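# Benchmark metrics for comparing estimated against expected profiles:
# genome-copy recovery (x/y ratio, Pearson), species-set precision/recall/F1,
# four abundance dissimilarities, and the hierarchical genome-size database
# used to convert sequence abundance into genome copies for read-binning
# profilers.

#' Genome-copy recovery metrics across samples
#'
#' The x/y ratio is the estimated over the expected total genome copies,
#' computed per sample; Pearson's correlation is computed once over the
#' paired sample totals.
#'
#' @param estimated,expected Numeric vectors of per-sample total genome
#'   copies (parallel); `expected` must be positive.
#' @return List with `ratio` (per sample) and `pearson_r` (`NA` with fewer
#'   than 3 samples).
#' @export
copy_metrics <- function(estimated, expected) {
  stopifnot(length(estimated) == length(expected))
  if (any(expected <= 0)) stop("expected totals must be positive")
  r <- if (length(estimated) >= 3) stats::cor(estimated, expected) else NA_real_
  list(ratio = estimated / expected, pearson_r = r)
}

#' Precision, recall and F1 of a detected species set
#'
#' True positives are species present in both the estimated and the expected
#' profile; unclassified entries must be removed upstream. F1 is the
#' harmonic mean `2pr/(p + r)`.
#'
#' @param estimated,expected Character vectors of species labels (sets).
#' @return List with `precision`, `recall`, `f1`.
#' @export
set_metrics <- function(estimated, expected) {
  estimated <- setdiff(unique(estimated), "unclassified")
  expected <- setdiff(unique(expected), "unclassified")
  if (length(estimated) == 0) stop("estimated species set is empty")
  tp <- length(intersect(estimated, expected))
  p <- tp / length(estimated)
  r <- tp / length(expected)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Dissimilarities between two relative-abundance profiles
#'
#' Aligns the two profiles on the union of their species, renormalises each
#' to sum one, and computes Manhattan (L1) distance, Euclidean (L2)
#' distance, Bray-Curtis dissimilarity `sum|p-q| / sum(p+q)`, and the
#' Jensen-Shannon distance (square root of the JS divergence with base-2
#' logarithms, hence bounded by 1).
#'
#' @param p,q Named non-negative abundance vectors (names = species).
#' @return List with `manhattan`, `euclidean`, `bray_curtis`,
#'   `jensen_shannon`.
#' @examples
#' dissimilarities(c(A = 1), c(B = 1))  # 2, sqrt(2), 1, 1
#' @export
dissimilarities <- function(p, q) {
  if (any(p < 0) || any(q < 0)) stop("abundances must be non-negative")
  species <- union(names(p), names(q))
  if (is.null(species)) stop("abundance vectors must be named by species")
  species <- setdiff(species, "unclassified")
  pv <- stats::setNames(numeric(length(species)), species)
  qv <- pv
  pv[intersect(names(p), species)] <- p[intersect(names(p), species)]
  qv[intersect(names(q), species)] <- q[intersect(names(q), species)]
  if (sum(pv) == 0 || sum(qv) == 0) stop("profiles must have positive mass")
  pv <- pv / sum(pv)
  qv <- qv / sum(qv)
  list(
    manhattan = sum(abs(pv - qv)),
    euclidean = sqrt(sum((pv - qv)^2)),
    bray_curtis = sum(abs(pv - qv)) / sum(pv + qv),
    jensen_shannon = sqrt(max(0, js_divergence(pv, qv)))  # guard fp negatives
  )
}

#' Evaluate an estimated profile against an expected one
#'
#' Convenience wrapper producing the full report: set metrics on the
#' classified species and the four dissimilarities on the renormalised
#' relative abundances.
#'
#' @param estimated,expected [abundance_profile()] objects.
#' @return List of class `eval_report` with `precision`, `recall`, `f1` and
#'   the four dissimilarities.
#' @export
evaluate_profiles <- function(estimated, expected) {
  getvec <- function(pr) {
    cl <- pr$species != "unclassified"
    stats::setNames(pr$copies[cl], pr$species[cl])
  }
  sm <- set_metrics(estimated$species, expected$species)
  ds <- dissimilarities(getvec(estimated), getvec(expected))
  structure(c(sm, ds), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("L1 %.4f  L2 %.4f  Bray-Curtis %.4f  Jensen-Shannon %.4f\n",
              x$manhattan, x$euclidean, x$bray_curtis, x$jensen_shannon))
  invisible(x)
}

#' Build a hierarchical genome-size database
#'
#' Leaf taxa keep their given genome sizes (plasmids and other
#' extrachromosomal elements counted single-copy and included upstream);
#' every internal taxon's size is the unweighted mean over its descendant
#' leaf genomes.
#'
#' @param species_sizes Named numeric vector: genome size (bp) per leaf
#'   taxid.
#' @param taxonomy `data.frame` with columns `taxid` and `parent` (parent of
#'   a root is `NA` or `""`); must be a tree.
#' @return List of class `genome_size_db` with `size` (named numeric over
#'   all taxids) and `parent` (named character).
#' @export
build_genome_size_db <- function(species_sizes, taxonomy) {
  if (length(species_sizes) == 0) {
    return(structure(list(size = stats::setNames(numeric(0), character(0)),
                          parent = stats::setNames(character(0), character(0))),
                     class = "genome_size_db"))
  }
  stopifnot(all(c("taxid", "parent") %in% names(taxonomy)))
  parent <- stats::setNames(as.character(taxonomy$parent),
                            as.character(taxonomy$taxid))
  parent[parent %in% c("", "NA")] <- NA_character_
  # cycle check: walk up from every node
  for (t in names(parent)) {
    seen <- character(0)
    cur <- t
    while (!is.na(cur) && cur %in% names(parent)) {
      if (cur %in% seen) stop("cycle in taxonomy at taxid ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  leaves <- names(species_sizes)
  acc <- new.env(parent = emptyenv())
  for (lf in leaves) {
    cur <- lf
    repeat {
      prev <- if (is.null(acc[[cur]])) c(0, 0) else acc[[cur]]
      acc[[cur]] <- prev + c(species_sizes[[lf]], 1)
      cur <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
      if (is.na(cur)) break
    }
  }
  ids <- ls(acc)
  size <- vapply(ids, function(t) acc[[t]][1] / acc[[t]][2], numeric(1))
  structure(list(size = size, parent = parent), class = "genome_size_db")
}

#' @export
print.genome_size_db <- function(x, ...) {
  cat(sprintf("Genome-size database: %d taxids (mean %.3g bp)\n",
              length(x$size), mean(x$size)))
  invisible(x)
}

#' Convert assigned base pairs into genome copies
#'
#' Divides the base pairs assigned to each taxid by its genome size. Taxa
#' missing from the database walk up the taxonomy to the lowest sized
#' ancestor; taxa with no sized ancestor are returned uncorrected (`NA`)
#' with a warning. Read-count-only inputs should be converted upstream as
#' `bp = reads x mean read length`.
#'
#' @param assigned_bp Named numeric vector: base pairs per taxid.
#' @param db A [build_genome_size_db()] result.
#' @return Named numeric vector of genome copies (`NA` where uncorrectable).
#' @export
genome_size_correct <- function(assigned_bp, db) {
  stopifnot(inherits(db, "genome_size_db"))
  lookup <- function(taxid) {
    cur <- taxid
    while (!is.na(cur)) {
      if (cur %in% names(db$size)) return(db$size[[cur]])
      cur <- if (cur %in% names(db$parent)) db$parent[[cur]] else NA_character_
    }
    NA_real_
  }
  sizes <- vapply(names(assigned_bp), lookup, numeric(1))
  if (anyNA(sizes)) {
    warning("no sized ancestor for taxids: ",
            paste(names(assigned_bp)[is.na(sizes)], collapse = ", "),
            "; reported uncorrected")
  }
  assigned_bp / sizes
}
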