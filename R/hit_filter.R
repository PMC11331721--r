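# Post-filtering of protein homology hits, shared by profiling and database
# construction: e-value/subject-cover thresholds, greedy overlap culling,
# contig-boundary filtering, and best-hit-per-marker selection.

#' Hit-culling configuration
#'
#' Thresholds applied to raw blastx-style hits before any coverage or
#' assignment step: the e-value cutoff and minimum subject cover mirror the
#' alignment search settings (1e-15 and 75%), and `max_overlap_frac` is the
#' pairwise query-range overlap allowed during greedy culling (25%, measured
#' as a fraction of the shorter range).
#'
#' @param max_overlap_frac Maximum allowed pairwise overlap fraction, in
#'   `(0, 1]`.
#' @param min_subject_cover Minimum aligned fraction of the subject length,
#'   in `(0, 1]`.
#' @param evalue_cutoff Maximum e-value, `> 0`.
#' @return A list of class `cull_config`.
#' @export
cull_config <- function(max_overlap_frac = 0.25,
                        min_subject_cover = 0.75,
                        evalue_cutoff = 1e-15) {
  stopifnot(max_overlap_frac > 0, max_overlap_frac <= 1,
            min_subject_cover > 0, min_subject_cover <= 1,
            evalue_cutoff > 0)
  structure(list(max_overlap_frac = max_overlap_frac,
                 min_subject_cover = min_subject_cover,
                 evalue_cutoff = evalue_cutoff),
            class = "cull_config")
}

# Closed 1-based interval overlap in nucleotides.
range_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
}

#' Cull overlapping hits of one query
#'
#' Greedy overlap culling: hits of a single query are sorted by e-value in
#' ascending order (ties by higher bitscore, then input order) and added to
#' the kept collection iff their query-range overlap with every already-kept
#' hit is below `max_overlap_frac` of the shorter of the two ranges. Multiple
#' copies of the same gene on one query may survive, as long as their ranges
#' are (mostly) disjoint.
#'
#' @param hits Protein-hit table, all rows sharing one `query_id`.
#' @param cfg A [cull_config()].
#' @return The kept subset, sorted by e-value ascending.
#' @export
cull_overlapping_hits <- function(hits, cfg = cull_config()) {
  validate_protein_hits(hits)
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$query_id)) != 1) {
    stop("cull_overlapping_hits expects hits of a single query")
  }
  bs <- ifelse(is.na(hits$bitscore), -Inf, hits$bitscore)
  ord <- order(hits$evalue, -bs, seq_len(nrow(hits)))
  hits <- hits[ord, , drop = FALSE]
  len <- hits$query_end - hits$query_start + 1
  kept <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (length(kept)) {
      ov <- range_overlap(hits$query_start[i], hits$query_end[i],
                          hits$query_start[kept], hits$query_end[kept])
      frac <- ov / pmin(len[i], len[kept])
      if (any(frac >= cfg$max_overlap_frac)) next
    }
    kept <- c(kept, i)
  }
  out <- hits[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply thresholds and per-query culling to a hit table
#'
#' Convenience wrapper used by both the profiling and the database paths:
#' drops hits above the e-value cutoff or below the subject-cover floor, then
#' applies [cull_overlapping_hits()] within each query.
#'
#' @param hits Protein-hit table (any number of queries).
#' @param cfg A [cull_config()].
#' @return Filtered and culled hit table.
#' @export
filter_protein_hits <- function(hits, cfg = cull_config()) {
  validate_protein_hits(hits)
  keep <- hits$evalue <= cfg$evalue_cutoff &
    hits$subject_cover >= cfg$min_subject_cover
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  pieces <- split(hits, hits$query_id)
  out <- do.call(rbind, lapply(pieces, cull_overlapping_hits, cfg = cfg))
  rownames(out) <- NULL
  out
}

#' Discard hits close to contig boundaries
#'
#' Partial alignments near contig ends would bias window extraction, so hits
#' whose distance to either contig end is less than the subject length
#' (expressed in nucleotides, 3 x amino-acid length) are removed. Distance is
#' measured from the nearer hit endpoint to the nearer contig end: the left
#' distance is `query_start - 1`, the right distance
#' `contig_len - query_end`.
#'
#' @param hits Protein-hit table located on one contig.
#' @param contig_len Contig length in nucleotides.
#' @return The subset of hits far enough from both ends.
#' @export
boundary_filter <- function(hits, contig_len) {
  validate_protein_hits(hits)
  if (nrow(hits) == 0) return(hits)
  if (any(hits$query_end > contig_len)) {
    stop("contig_len is shorter than a hit's end coordinate")
  }
  min_nt <- 3 * hits$subject_len_aa
  left <- hits$query_start - 1
  right <- contig_len - hits$query_end
  out <- hits[left >= min_nt & right >= min_nt, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep at most one hit per marker gene for a query
#'
#' Within one query sequence (contig), retains for each marker label the hit
#' with the highest alignment identity; ties are broken by lower e-value,
#' then input order. Reduces the impact of misassembled duplicated regions.
#'
#' @param hits Protein-hit table, all rows sharing one `query_id`.
#' @return One hit per marker, in input order.
#' @export
best_hit_per_marker <- function(hits) {
  validate_protein_hits(hits)
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$query_id)) != 1) {
    stop("best_hit_per_marker expects hits of a single query")
  }
  ord <- order(hits$marker, -hits$identity_pct, hits$evalue,
               seq_len(nrow(hits)))
  first <- !duplicated(hits$marker[ord])
  keep <- sort(ord[first])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
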