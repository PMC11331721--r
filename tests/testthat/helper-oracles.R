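# Independent oracles and cheap fixture builders used across the suite.

# Build a protein-hit table quickly from parallel vectors (single query).
make_hits <- function(qstart, qend, evalue, query = "q1",
                      marker = "l2", identity = 95, slen = 100L,
                      qlen = if (length(qend)) max(qend) + 10L else 1000L,
                      sstart = 16L, send = 95L,
                      bitscore = NA_real_) {
  protein_hits(query_id = rep_len(query, length(qstart)),
               subject_id = paste0(marker, "|ref"),
               marker = rep_len(marker, length(qstart)),
               query_start = qstart, query_end = qend,
               subject_start = rep_len(sstart, length(qstart)),
               subject_end = rep_len(send, length(qstart)),
               evalue = evalue, identity_pct = identity,
               bitscore = bitscore,
               query_len_nt = qlen, subject_len_aa = slen)
}

# Independent replay of the greedy-by-e-value culling rule: precompute the
# full pairwise overlap-fraction matrix, then walk the e-value order keeping
# a hit iff all its overlaps with previously kept hits are < the threshold.
cull_oracle <- function(qstart, qend, evalue, bitscore = NULL,
                        max_overlap_frac = 0.25) {
  n <- length(qstart)
  len <- qend - qstart + 1
  frac <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ov <- max(0, min(qend[i], qend[j]) - max(qstart[i], qstart[j]) + 1)
      frac[i, j] <- ov / min(len[i], len[j])
    }
  }
  bs <- if (is.null(bitscore)) rep(0, n) else bitscore
  ord <- order(evalue, -bs, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    if (all(frac[i, kept] < max_overlap_frac)) kept <- c(kept, i)
  }
  sort(kept)
}

# Direct-summation Jensen-Shannon distance oracle (base-2 logs).
jsd_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  acc <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) acc <- acc + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) acc <- acc + 0.5 * q[i] * log2(q[i] / m[i])
  }
  unname(sqrt(acc))
}

# Positional trimmed-mean oracle built coordinate by coordinate.
trimmed_mean_oracle <- function(sstart, send, L) {
  cov <- numeric(L)
  for (i in seq_along(sstart)) {
    for (pos in sstart[i]:send[i]) cov[pos] <- cov[pos] + 1
  }
  window <- (floor(0.25 * L) + 1):ceiling(0.75 * L)
  mean(cov[window])
}

# Tiny alignment-table builder for EM tests: `sets` is a list of character
# vectors, one per read, naming the species the read aligns to (first = true
# species, scores 1000/0.99; rest near-tied at 995/0.9895).
aln_from_sets <- function(sets) {
  rows <- lapply(seq_along(sets), function(i) {
    sp <- sets[[i]]
    data.frame(read_id = sprintf("r%03d", i),
               ref_id = paste0(sp, "|w"), species = sp,
               AS = c(1000, rep(995, length(sp) - 1)),
               MS = c(1000, rep(995, length(sp) - 1)),
               ID = c(0.99, rep(0.9895, length(sp) - 1)),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  nucleotide_alignments(d$read_id, d$ref_id, d$species, d$AS, d$MS, d$ID)
}
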