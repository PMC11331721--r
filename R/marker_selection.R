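# Statistics and clustering used to screen ribosomal protein genes (RPGs) as
# markers: universality and deviance over assembly panels, F0.5-scores of the
# annotation models, circular genomic distances, single-linkage clustering and
# representative selection.

#' Universality and deviance of candidate genes
#'
#' For every gene in an assembly-by-gene copy table, computes its
#' universality U (the proportion of assemblies containing at least one copy)
#' and deviance D (the absolute difference between its mean copy number,
#' zeros included, and the ideal single-copy count of one). Statistics can be
#' computed per assembly subset (e.g. the full panel and a tiny-genome
#' subset under 1 Mb) by passing a named list of assembly id vectors.
#'
#' @param copy_table Numeric matrix, assemblies (rows, named) x genes
#'   (columns, named), of non-negative copy counts.
#' @param subsets Named list of row-name vectors; default one subset
#'   (`full`) covering all assemblies.
#' @return `data.frame` with columns `gene`, `subset`, `universality`,
#'   `deviance`.
#' @examples
#' m <- rbind(a1 = c(g = 1), a2 = c(g = 1), a3 = c(g = 0), a4 = c(g = 2))
#' compute_marker_stats(m)  # U = 0.75, D = 0 (mean copy exactly 1)
#' @export
compute_marker_stats <- function(copy_table,
                                 subsets = list(full = rownames(copy_table))) {
  stopifnot(is.matrix(copy_table), nrow(copy_table) > 0,
            !is.null(rownames(copy_table)), !is.null(colnames(copy_table)))
  if (any(copy_table < 0)) stop("copy counts must be non-negative")
  res <- lapply(names(subsets), function(sn) {
    ids <- subsets[[sn]]
    if (length(ids) == 0) stop("empty assembly subset: ", sn)
    bad <- setdiff(ids, rownames(copy_table))
    if (length(bad)) stop("subset ", sn, " references unknown assemblies")
    sub <- copy_table[ids, , drop = FALSE]
    data.frame(gene = colnames(sub), subset = sn,
               universality = colMeans(sub >= 1),
               deviance = abs(colMeans(sub) - 1),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' F0.5-score from confusion counts
#'
#' Precision-weighted harmonic mean of precision and recall (beta = 0.5):
#' `1.25 p r / (0.25 p + r)` with `p = tp/(tp+fp)`, `r = tp/(tp+fn)`.
#' Returns 0 when recall is 0; errors when both denominators vanish.
#'
#' @param tp,fp,fn Non-negative counts (vectorised).
#' @return F0.5-scores in `[0, 1]`.
#' @export
f05_score <- function(tp, fp, fn) {
  if (any(tp + fp == 0 & tp + fn == 0)) {
    stop("F0.5 undefined: tp + fp and tp + fn are both zero")
  }
  if (any(tp + fp == 0)) stop("precision undefined: tp + fp is zero")
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  ifelse(r == 0, 0, 1.25 * p * r / (0.25 * p + r))
}

circ_dist <- function(p, q, L) {
  d <- abs(p - q)
  min(d, L - d) / L
}

#' Mean relative genomic distance matrix between genes
#'
#' Within each circular genome assembly, the distance between two genes is
#' their shortest genomic distance on the circle, normalised by genome
#' length: `min(|p - q|, L - |p - q|) / L` (at most 0.5, the antipodal
#' maximum). Multi-copy genes use the minimum over copy pairs. Per-assembly
#' distances are averaged over all assemblies containing both genes; pairs
#' co-occurring in no assembly get `NA`.
#'
#' @param positions Named list (per assembly) of named lists (per gene) of
#'   numeric position vectors in `[0, L)`.
#' @param genome_lengths Named numeric vector of genome lengths, covering
#'   every assembly in `positions`.
#' @return Symmetric matrix of mean relative distances with zero diagonal.
#' @export
mean_relative_distance_matrix <- function(positions, genome_lengths) {
  stopifnot(length(positions) > 0)
  asm <- names(positions)
  if (is.null(asm) || anyNA(match(asm, names(genome_lengths)))) {
    stop("every assembly needs a genome length")
  }
  genes <- sort(unique(unlist(lapply(positions, names))))
  G <- length(genes)
  acc <- matrix(0, G, G, dimnames = list(genes, genes))
  cnt <- matrix(0L, G, G, dimnames = list(genes, genes))
  for (a in asm) {
    L <- genome_lengths[[a]]
    pos <- positions[[a]]
    if (any(unlist(pos) < 0 | unlist(pos) >= L)) {
      stop("positions must lie in [0, genome length) for assembly ", a)
    }
    present <- names(pos)
    for (gi in seq_along(present)) {
      for (gj in seq_len(gi - 1L)) {
        g1 <- present[gi]; g2 <- present[gj]
        d <- min(outer(pos[[g1]], pos[[g2]],
                       Vectorize(function(p, q) circ_dist(p, q, L))))
        acc[g1, g2] <- acc[g1, g2] + d
        cnt[g1, g2] <- cnt[g1, g2] + 1L
      }
    }
  }
  acc <- acc + t(acc); cnt <- cnt + t(cnt)
  d <- acc / cnt  # NaN where cnt == 0
  d[cnt == 0] <- NA_real_
  diag(d) <- 0
  d
}

#' Single-linkage gene clusters at a distance cutoff
#'
#' Clusters are the connected components of the graph joining gene pairs with
#' distance strictly below the cutoff — exactly the groups produced by
#' cutting a single-linkage dendrogram below that height. `NA` entries
#' (pairs never co-occurring) contribute no edge.
#'
#' @param d Symmetric distance matrix with gene dimnames.
#' @param cutoff Linkage cutoff (default 0.05).
#' @return List of character vectors, one per cluster, in order of first
#'   appearance; genes within a cluster sorted lexicographically.
#' @export
single_linkage_clusters <- function(d, cutoff = 0.05) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  genes <- rownames(d)
  n <- length(genes)
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (!is.na(d[i, j]) && d[i, j] < cutoff) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
  }
  groups <- split(genes, comp)
  groups <- groups[order(vapply(groups, function(g) min(match(g, genes)),
                                numeric(1)))]
  lapply(unname(groups), sort)
}

#' Select one representative marker per cluster
#'
#' Genes are first screened by universality, deviance and F0.5 thresholds in
#' every subset (a gene failing any criterion anywhere is excluded before
#' clustering); within each cluster the representative is the gene ranked by
#' higher universality, then lower deviance, then higher F0.5, then
#' lexicographic label (ranking statistics from the `rank_subset`).
#'
#' @param clusters List of gene clusters, as from
#'   [single_linkage_clusters()].
#' @param stats `data.frame` from [compute_marker_stats()] with an added
#'   `f05` column (per gene, constant across subsets).
#' @param u_min,d_max,f05_min Screening thresholds (defaults 0.99, 0.01,
#'   0.99): universality must exceed `u_min`, deviance fall below `d_max`,
#'   F0.5 exceed `f05_min`, in every subset.
#' @param rank_subset Subset whose statistics rank genes within clusters.
#' @return Character vector of selected marker genes.
#' @export
select_representatives <- function(clusters, stats, u_min = 0.99,
                                   d_max = 0.01, f05_min = 0.99,
                                   rank_subset = stats$subset[1]) {
  stopifnot(all(c("gene", "subset", "universality", "deviance", "f05") %in%
                  names(stats)))
  pass <- tapply(
    stats$universality > u_min & stats$deviance < d_max &
      stats$f05 > f05_min,
    stats$gene, all)
  valid <- names(pass)[pass]
  rk <- stats[stats$subset == rank_subset, , drop = FALSE]
  reps <- character(0)
  for (cl in clusters) {
    if (length(cl) == 0) stop("empty cluster")
    cand <- intersect(cl, valid)
    if (!length(cand)) next
    s <- rk[match(cand, rk$gene), , drop = FALSE]
    ord <- order(-s$universality, s$deviance, -s$f05, s$gene)
    reps <- c(reps, cand[ord[1]])
  }
  reps
}

#' Screen candidate genes into a marker set
#'
#' End-to-end marker selection: screen genes by the three criteria in all
#' subsets, cluster the survivors by mean relative genomic distance
#' (single linkage, cutoff 0.05) and pick one representative per cluster.
#'
#' @inheritParams compute_marker_stats
#' @inheritParams select_representatives
#' @param f05 Named numeric vector of per-gene F0.5-scores.
#' @param positions,genome_lengths Passed to
#'   [mean_relative_distance_matrix()].
#' @param cutoff Linkage cutoff.
#' @return List with `markers`, `stats`, `distance`, `clusters`.
#' @export
select_markers <- function(copy_table, f05, positions, genome_lengths,
                           subsets = list(full = rownames(copy_table)),
                           u_min = 0.99, d_max = 0.01, f05_min = 0.99,
                           cutoff = 0.05) {
  stats <- compute_marker_stats(copy_table, subsets)
  stats$f05 <- unname(f05[stats$gene])
  if (anyNA(stats$f05)) stop("every gene needs an F0.5-score")
  pass <- tapply(
    stats$universality > u_min & stats$deviance < d_max &
      stats$f05 > f05_min,
    stats$gene, all)
  valid <- names(pass)[pass]
  d <- mean_relative_distance_matrix(positions, genome_lengths)
  keep <- intersect(rownames(d), valid)
  d <- d[keep, keep, drop = FALSE]
  clusters <- single_linkage_clusters(d, cutoff)
  markers <- select_representatives(clusters, stats, u_min, d_max, f05_min,
                                    rank_subset = names(subsets)[1])
  list(markers = markers, stats = stats, distance = d, clusters = clusters)
}
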