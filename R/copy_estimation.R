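# Genome-copy estimation from marker-gene coverage: positional trimmed means
# per subject sequence, summed per marker, averaged over the eight-gene set.

#' Trimmed mean coverage of one marker subject sequence
#'
#' Builds the positional coverage vector over subject amino-acid positions
#' 1..L from the hits' subject ranges, discards the leftmost and rightmost
#' 25% of *positions*, and returns the mean over the central 50%. The trim is
#' positional (by coordinate), not an order statistic: with the 75%
#' subject-cover floor every hit fully covers the central window, so the
#' trimmed mean equals the number of mapped hits exactly. The central window
#' is positions `floor(0.25 L) + 1` through `ceiling(0.75 L)`.
#'
#' @param hits Protein-hit table, all rows on the same subject sequence (may
#'   be empty).
#' @param subject_len_aa Subject length in amino acids (`> 0`).
#' @return Non-negative trimmed mean coverage.
#' @examples
#' h <- protein_hits("r1", "l2|x", "l2", 1, 240, 1, 80, 1e-30, 95, 300, 100)
#' trimmed_mean_coverage(h, 100)  # 1: the central window 26..75 is covered
#' @export
trimmed_mean_coverage <- function(hits, subject_len_aa) {
  L <- as.integer(subject_len_aa)
  if (is.na(L) || L <= 0) stop("subject_len_aa must be a positive integer")
  lo <- floor(0.25 * L) + 1L
  hi <- ceiling(0.75 * L)
  if (nrow(hits) == 0) return(0)
  if (any(hits$subject_end > L)) {
    stop("hit subject_end exceeds subject_len_aa")
  }
  cov <- numeric(L)
  for (i in seq_len(nrow(hits))) {
    idx <- hits$subject_start[i]:hits$subject_end[i]
    cov[idx] <- cov[idx] + 1
  }
  mean(cov[lo:hi])
}

#' Per-marker coverage from filtered hits
#'
#' Computes the trimmed mean coverage of every subject sequence present in
#' `hits` and sums it within markers: the coverage of a marker gene is the
#' sum over all its constituent subject sequences.
#'
#' @param hits Filtered protein-hit table (any markers, any subjects).
#' @return Named numeric vector: coverage per marker label present.
#' @export
marker_coverage <- function(hits) {
  validate_protein_hits(hits)
  if (nrow(hits) == 0) return(stats::setNames(numeric(0), character(0)))
  per_subject <- vapply(
    split(hits, hits$subject_id),
    function(h) trimmed_mean_coverage(h, h$subject_len_aa[1]),
    numeric(1)
  )
  subj_marker <- vapply(split(hits$marker, hits$subject_id), `[[`, "", 1L)
  cov <- tapply(per_subject, subj_marker[names(per_subject)], sum)
  stats::setNames(as.numeric(cov), names(cov))
}

#' Total genome copies from marker coverages
#'
#' The total number of genome copies of a domain is the average coverage over
#' its fixed marker-gene set; markers without any coverage contribute zero to
#' the sum but still count in the denominator. A species supported by a
#' single marker-containing read therefore receives 1/8 = 0.125 copies — the
#' method's detection floor.
#'
#' @param coverages Named numeric vector of per-marker coverage; names must
#'   be a subset of `markers`.
#' @param markers The marker-gene set defining the average (default the
#'   eight bacterial markers).
#' @return Estimated genome copies (mean coverage over `markers`).
#' @examples
#' total_genome_copies(c(l2 = 1))           # 0.125, one marker read
#' total_genome_copies(stats::setNames(rep(2, 8), marker_genes()))  # 2
#' @export
total_genome_copies <- function(coverages, markers = marker_genes()) {
  unknown <- setdiff(names(coverages), markers)
  if (length(unknown)) {
    stop("coverage keyed by markers outside the marker set: ",
         paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(markers)), markers)
  full[names(coverages)] <- coverages
  sum(full) / length(markers)
}

#' Genome copies of both prokaryotic domains
#'
#' Bacterial and archaeal marker sets are estimated separately (each over its
#' own eight genes) and summed for the prokaryotic total.
#'
#' @param hits Filtered protein-hit table; markers must belong to one of the
#'   two domain sets.
#' @return List with `bacteria`, `archaea` and `total` genome copies.
#' @export
prokaryotic_genome_copies <- function(hits) {
  cov <- marker_coverage(hits)
  bac <- cov[names(cov) %in% marker_genes("bacteria")]
  arc <- cov[names(cov) %in% marker_genes("archaea")]
  stray <- setdiff(names(cov),
                   c(marker_genes("bacteria"), marker_genes("archaea")))
  if (length(stray)) {
    stop("markers outside both domain sets: ", paste(stray, collapse = ", "))
  }
  b <- total_genome_copies(bac, marker_genes("bacteria"))
  a <- total_genome_copies(arc, marker_genes("archaea"))
  list(bacteria = b, archaea = a, total = b + a)
}
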