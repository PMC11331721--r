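# Synthetic fixture generator: log-normal communities, marker-read protein
# hits and PAF alignments with known ground truth. Reads are emitted directly
# as alignment-level records (the testable core of the profiler sits
# downstream of the aligners); no base-level error model is simulated.

#' Sample a synthetic community with known truth
#'
#' Draws k species and assigns each a taxonomic abundance from a log-normal
#' distribution (default mu = 0, sigma = 1), normalised to sum one. Genome
#' copies are the abundances scaled to `total_copies`; genome lengths are
#' drawn uniformly from a realistic prokaryotic range (2-8 Mb). An ambiguity
#' graph marks species pairs that share indistinguishable marker windows
#' (default: consecutive species paired), driving cross-species alignment
#' ambiguity downstream.
#'
#' @param k Number of species (`>= 1`).
#' @param mu,sigma Log-normal parameters of the taxonomic abundances.
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @param total_copies Total genome copies the abundances are scaled to.
#' @param genome_length_range Range (bp) for uniform genome lengths.
#' @param ambiguity Either `"paired"` (species 1-2, 3-4, ... share windows)
#'   or a two-column matrix/data.frame of species-index pairs.
#' @return A list of class `community_truth`: `lineages`, `theta`
#'   (named, sums to 1), `genome_lengths`, `copies`, `ambiguity`
#'   (data.frame `from`/`to` of species labels), and the parameters used.
#' @export
sample_community <- function(k, mu = 0, sigma = 1, seed = NULL,
                             total_copies = 100,
                             genome_length_range = c(2e6, 8e6),
                             ambiguity = "paired") {
  if (k < 1) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::rlnorm(k, meanlog = mu, sdlog = sigma)
  theta <- theta / sum(theta)
  species <- sprintf("Genus%03d species%03d", seq_len(k), seq_len(k))
  lineages <- tax_lineages(species,
                           superkingdom = "Bacteria",
                           phylum = sprintf("Phylum%03d",
                                            (seq_len(k) - 1) %% 4 + 1))
  lengths <- stats::setNames(
    stats::runif(k, genome_length_range[1], genome_length_range[2]), species)
  amb <- if (identical(ambiguity, "paired")) {
    if (k >= 2) {
      i <- seq(1, k - 1, by = 2)
      data.frame(from = species[i], to = species[i + 1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(0), to = character(0))
    }
  } else {
    amb <- as.data.frame(ambiguity)
    names(amb) <- c("from", "to")
    amb$from <- species[amb$from]
    amb$to <- species[amb$to]
    if (anyNA(amb$from) || anyNA(amb$to)) {
      stop("ambiguity edge to unknown species index")
    }
    amb
  }
  structure(list(lineages = lineages,
                 theta = stats::setNames(theta, species),
                 genome_lengths = lengths,
                 copies = stats::setNames(theta * total_copies, species),
                 ambiguity = amb,
                 params = list(k = k, mu = mu, sigma = sigma,
                               total_copies = total_copies, seed = seed)),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf("Synthetic community: %d species, %.4g total genome copies\n",
              x$params$k, sum(x$copies)))
  invisible(x)
}

#' Convert taxonomic into sequence abundances
#'
#' Sequence abundance (read/base fraction) weights each species' taxonomic
#' abundance (cell fraction) by its genome length:
#' `s_j = theta_j L_j / sum(theta L)`.
#'
#' @param theta Taxonomic abundances (non-negative).
#' @param genome_lengths Positive genome lengths, parallel to `theta`.
#' @return Sequence abundances summing to one.
#' @export
taxonomic_to_sequence_abundance <- function(theta, genome_lengths) {
  stopifnot(length(theta) == length(genome_lengths))
  if (any(genome_lengths <= 0)) stop("genome lengths must be positive")
  w <- theta * genome_lengths
  tot <- sum(w)
  if (tot <= 0) stop("total weighted abundance is zero")
  w / tot
}

SIM_SUBJECT_LEN_AA <- 150L   # marker protein length; hits cover 120/150 = 80%
SIM_READ_LEN <- 1000L

#' Simulate marker-read alignment fixtures
#'
#' Emits, for a sampled community, the two alignment-file dialects the
#' profiler consumes, with ground truth attached. Each species contributes
#' `round(copies * reads_per_copy)` marker-containing reads spread uniformly
#' over the eight bacterial markers; at the default `reads_per_copy = 8`
#' (one read per marker per genome copy) the coverage-based copy estimate
#' equals the planted copies up to rounding. Every read yields one protein
#' hit (subject cover 80%, passing the 75% floor) and one nucleotide
#' alignment to its own species' window (AS = MS = 1000, ID = 0.99). A
#' fraction `ambiguity_frac` of reads of species with an ambiguity-graph
#' neighbour additionally receive a near-tied alignment to that neighbour,
#' with scores at `ambiguous_score_frac` of the true scores — straddle the
#' 0.99 (AS/MS) and 0.999 (ID) validity thresholds to exercise both
#' branches.
#'
#' @param truth A [sample_community()] result.
#' @param reads_per_copy Marker reads emitted per genome copy (default 8).
#' @param ambiguity_frac Fraction of a species' reads receiving an extra
#'   near-tied neighbour alignment.
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   files.
#' @param dir Optional directory: writes `hits.tsv` (tabular protein hits),
#'   `alignments.paf`, `ref2species.tsv`, `truth.tsv` and `config.tsv`.
#' @param ambiguous_score_frac Multiplier on AS/MS for ambiguous neighbour
#'   alignments (default 0.995, inside the 0.99 validity band).
#' @param ambiguous_id_frac Multiplier on ID (default 0.9995, inside the
#'   0.999 band).
#' @return List with `hits`, `alignments`, `ref2species`, `reads` (read id,
#'   true species, marker), and `truth`.
#' @export
simulate_marker_alignments <- function(truth, reads_per_copy = 8,
                                       ambiguity_frac = 0, seed = NULL,
                                       dir = NULL,
                                       ambiguous_score_frac = 0.995,
                                       ambiguous_id_frac = 0.9995) {
  stopifnot(inherits(truth, "community_truth"))
  if (!is.null(seed)) set.seed(seed)
  species <- names(truth$copies)
  markers <- marker_genes("bacteria")
  neighbour <- stats::setNames(rep(NA_character_, length(species)), species)
  for (i in seq_len(nrow(truth$ambiguity))) {
    a <- truth$ambiguity$from[i]; b <- truth$ambiguity$to[i]
    if (!all(c(a, b) %in% species)) stop("ambiguity edge to unknown species")
    neighbour[[a]] <- b
    neighbour[[b]] <- a
  }
  rows <- list()
  for (j in seq_along(species)) {
    sp <- species[j]
    n_j <- max(1L, round(truth$copies[[sp]] * reads_per_copy))
    mk <- markers[sample.int(length(markers), n_j, replace = TRUE)]
    amb <- stats::runif(n_j) < ambiguity_frac & !is.na(neighbour[[sp]])
    rows[[j]] <- data.frame(
      read_id = sprintf("sp%03d_r%05d", j, seq_len(n_j)),
      species = sp, marker = mk, ambiguous = amb,
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, rows)

  hits <- protein_hits(
    query_id = reads$read_id,
    subject_id = paste0(reads$marker, "|", reads$species),
    marker = reads$marker,
    query_start = 101L, query_end = 460L,
    subject_start = 16L, subject_end = 135L,
    evalue = 1e-50, identity_pct = 97, bitscore = 200,
    query_len_nt = SIM_READ_LEN, subject_len_aa = SIM_SUBJECT_LEN_AA
  )

  ref_of <- function(sp, mk) paste(sp, mk, "w1", sep = "|")
  own <- data.frame(
    read_id = reads$read_id,
    ref_id = ref_of(reads$species, reads$marker),
    species = reads$species,
    AS = 1000, MS = 1000, ID = 0.99,
    is_primary = TRUE, stringsAsFactors = FALSE)
  amb_reads <- reads[reads$ambiguous, , drop = FALSE]
  extra <- if (nrow(amb_reads)) {
    nb <- unname(neighbour[amb_reads$species])
    data.frame(
      read_id = amb_reads$read_id,
      ref_id = ref_of(nb, amb_reads$marker),
      species = nb,
      AS = round(1000 * ambiguous_score_frac),
      MS = round(1000 * ambiguous_score_frac),
      ID = 0.99 * ambiguous_id_frac,
      is_primary = FALSE, stringsAsFactors = FALSE)
  } else {
    own[0, , drop = FALSE]
  }
  aln <- rbind(own, extra)
  aln <- aln[order(aln$read_id, -aln$AS, aln$ref_id), , drop = FALSE]
  rownames(aln) <- NULL
  alignments <- nucleotide_alignments(aln$read_id, aln$ref_id, aln$species,
                                      aln$AS, aln$MS, aln$ID, aln$is_primary)
  refs <- unique(alignments$ref_id)
  ref2species <- stats::setNames(
    vapply(strsplit(refs, "|", fixed = TRUE), `[[`, "", 1L), refs)

  out <- list(hits = hits, alignments = alignments,
              ref2species = ref2species,
              reads = reads[c("read_id", "species", "marker")],
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_protein_hits(hits, file.path(dir, "hits.tsv"))
    write_paf(alignments, file.path(dir, "alignments.paf"))
    utils::write.table(
      data.frame(ref_id = names(ref2species), species = unname(ref2species)),
      file.path(dir, "ref2species.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    tt <- data.frame(species = species,
                     theta = sprintf("%.10f", truth$theta),
                     copies = sprintf("%.10f", truth$copies),
                     genome_length = sprintf("%.1f", truth$genome_lengths))
    utils::write.table(tt, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- data.frame(
      key = c("k", "mu", "sigma", "total_copies", "reads_per_copy",
              "ambiguity_frac", "seed"),
      value = c(truth$params$k, truth$params$mu, truth$params$sigma,
                truth$params$total_copies, reads_per_copy, ambiguity_frac,
                if (is.null(seed)) NA else seed))
    utils::write.table(cfg, file.path(dir, "config.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write nucleotide alignments as PAF
#'
#' Emits minimap2-style PAF records with `AS:i`, `ms:i`, `de:f` and `tp:A`
#' tags; the inverse of [read_paf_alignments()] for fixture round-trips.
#' Mandatory coordinate columns are filled with the fixture geometry (read
#' length 1000, window length 10000).
#'
#' @param alignments Nucleotide-alignment table.
#' @param path Output path.
#' @export
write_paf <- function(alignments, path) {
  validate_alignments(alignments)
  lines <- sprintf(
    "%s\t%d\t%d\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t%d\tAS:i:%d\tms:i:%d\tde:f:%.6f\ttp:A:%s",
    alignments$read_id, SIM_READ_LEN, 0L, SIM_READ_LEN,
    alignments$ref_id, 10000L, 0L, SIM_READ_LEN,
    as.integer(round(alignments$ID * SIM_READ_LEN)), SIM_READ_LEN, 60L,
    as.integer(alignments$AS), as.integer(alignments$MS),
    1 - alignments$ID,
    ifelse(alignments$is_primary, "P", "S"))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate new fixtures from a fitted community profile
#'
#' Uses the fitted relative abundances and total genome copies as the truth
#' of a new synthetic community and emits alignment fixtures from it, so a
#' fitted profile can be parametrically bootstrapped end to end.
#'
#' @param object A [profile_community()] result.
#' @param nsim Number of fixture sets.
#' @param seed Optional integer seed.
#' @param reads_per_copy,ambiguity_frac Passed to
#'   [simulate_marker_alignments()].
#' @param ... Unused.
#' @return A list of `nsim` fixture lists.
#' @export
simulate.community_profile <- function(object, nsim = 1, seed = NULL,
                                       reads_per_copy = 8,
                                       ambiguity_frac = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  prof <- object$profile
  cl <- prof$species != "unclassified"
  k <- sum(cl)
  truth <- sample_community(k, total_copies = sum(prof$copies[cl]))
  # overwrite the drawn abundances with the fitted ones
  sp <- names(truth$theta)
  theta <- prof$copies[cl] / sum(prof$copies[cl])
  truth$theta <- stats::setNames(theta, sp)
  truth$copies <- stats::setNames(prof$copies[cl], sp)
  lapply(seq_len(nsim), function(i)
    simulate_marker_alignments(truth, reads_per_copy = reads_per_copy,
                               ambiguity_frac = ambiguity_frac))
}
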