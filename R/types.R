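# Shared domain containers: protein hits, nucleotide alignments, lineages and
# abundance profiles. All are plain data.frames with validated columns;
# abundance profiles additionally carry a class and a total-copies attribute.

TAX_RANKS <- c("superkingdom", "phylum", "class", "order",
               "family", "genus", "species")

PROTEIN_HIT_COLS <- c("query_id", "subject_id", "marker", "query_start",
                      "query_end", "subject_start", "subject_end", "strand",
                      "evalue", "identity_pct", "bitscore", "query_len_nt",
                      "subject_len_aa", "subject_cover")

ALIGNMENT_COLS <- c("read_id", "ref_id", "species", "AS", "MS", "ID",
                    "is_primary")

#' Construct a table of protein homology hits
#'
#' One row per blastx-style hit of a query (read or contig) against a marker
#' protein sequence. Query coordinates are nucleotide positions (1-based,
#' inclusive) and are normalised so `query_start <= query_end`, with the
#' original orientation kept in `strand`. Subject coordinates are amino-acid
#' positions on the marker protein; `subject_cover` is the aligned fraction of
#' the subject length.
#'
#' @param query_id,subject_id Character identifiers of query and subject.
#' @param marker Marker gene label for each hit (see [marker_genes()]).
#' @param query_start,query_end Nucleotide range on the query; swapped pairs
#'   (minus-strand hits) are normalised.
#' @param subject_start,subject_end Amino-acid range on the subject.
#' @param evalue Non-negative e-values.
#' @param identity_pct Percent identity in `[0, 100]`.
#' @param bitscore Bit scores (used only for deterministic tie-breaking).
#' @param query_len_nt,subject_len_aa Full lengths of query (nt) and subject
#'   (aa).
#' @return A `data.frame` with one row per hit and the columns above plus
#'   `strand` and `subject_cover`.
#' @export
protein_hits <- function(query_id, subject_id, marker,
                         query_start, query_end,
                         subject_start, subject_end,
                         evalue, identity_pct,
                         query_len_nt, subject_len_aa,
                         bitscore = NA_real_) {
  n <- length(query_id)
  rl <- function(x) rep_len(x, n)
  query_start <- rl(query_start); query_end <- rl(query_end)
  strand <- ifelse(query_start <= query_end, "+", "-")
  hits <- data.frame(
    query_id = as.character(query_id),
    subject_id = rl(as.character(subject_id)),
    marker = rl(as.character(marker)),
    query_start = as.integer(pmin(query_start, query_end)),
    query_end = as.integer(pmax(query_start, query_end)),
    subject_start = as.integer(rl(pmin(subject_start, subject_end))),
    subject_end = as.integer(rl(pmax(subject_start, subject_end))),
    strand = strand,
    evalue = rl(as.numeric(evalue)),
    identity_pct = rl(as.numeric(identity_pct)),
    bitscore = rl(as.numeric(bitscore)),
    query_len_nt = rl(as.integer(query_len_nt)),
    subject_len_aa = rl(as.integer(subject_len_aa)),
    stringsAsFactors = FALSE
  )
  hits$subject_cover <- (hits$subject_end - hits$subject_start + 1) /
    hits$subject_len_aa
  validate_protein_hits(hits)
  hits
}

validate_protein_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  missing <- setdiff(PROTEIN_HIT_COLS, names(hits))
  if (length(missing)) {
    stop("protein hit table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(hits) == 0) return(invisible(hits))
  if (any(hits$query_start < 1 | hits$query_start > hits$query_end))
    stop("query ranges must satisfy 1 <= query_start <= query_end")
  if (any(hits$query_end > hits$query_len_nt))
    stop("query_end exceeds query_len_nt")
  if (any(hits$evalue < 0)) stop("e-values must be non-negative")
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100))
    stop("identity_pct must lie in [0, 100]")
  if (any(hits$subject_len_aa <= 0)) stop("subject_len_aa must be positive")
  if (any(hits$subject_cover < 0)) stop("subject_cover must be >= 0")
  invisible(hits)
}

#' Construct a table of nucleotide alignments
#'
#' One row per read-vs-reference-window alignment, carrying the three scores
#' used for validity screening and tie-breaking: alignment score `AS`,
#' local-best alignment score `MS`, and gap-compressed per-base identity `ID`
#' in `[0, 1]`. Each reference window is labelled with the species it was
#' extracted from.
#'
#' @param read_id,ref_id,species Character identifiers.
#' @param AS,MS Integer alignment scores.
#' @param ID Gap-compressed identity in `[0, 1]`.
#' @param is_primary Logical; whether the aligner flagged the record primary.
#' @return A `data.frame` with one row per alignment.
#' @export
nucleotide_alignments <- function(read_id, ref_id, species, AS, MS, ID,
                                  is_primary = TRUE) {
  aln <- data.frame(
    read_id = as.character(read_id),
    ref_id = as.character(ref_id),
    species = as.character(species),
    AS = as.numeric(AS),
    MS = as.numeric(MS),
    ID = as.numeric(ID),
    is_primary = rep_len(as.logical(is_primary), length(read_id)),
    stringsAsFactors = FALSE
  )
  validate_alignments(aln)
  aln
}

validate_alignments <- function(aln) {
  stopifnot(is.data.frame(aln))
  missing <- setdiff(ALIGNMENT_COLS, names(aln))
  if (length(missing)) {
    stop("alignment table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(aln) == 0) return(invisible(aln))
  if (any(!is.finite(aln$AS)) || any(!is.finite(aln$MS)))
    stop("AS and MS must be finite")
  if (any(aln$ID < 0 | aln$ID > 1)) stop("ID must lie in [0, 1]")
  invisible(aln)
}

#' Build a ranked lineage table
#'
#' Maps species labels to full ranked lineages (superkingdom to species). A
#' species is "well defined" unless it is a placeholder such as
#' `"Escherichia sp."` or the reserved `"unclassified"` label; placeholder
#' species are down-weighted in hard-assignment tie-breaks and excluded from
#' relative-abundance normalisation.
#'
#' @param species Character vector of species labels (unique).
#' @param ... Optional named rank vectors (`superkingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`); missing ranks default to `"unknown"` except
#'   `genus`, which defaults to the first word of the species label.
#' @return A `data.frame` with the seven rank columns plus `is_well_defined`.
#' @export
tax_lineages <- function(species, ...) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species labels must be unique")
  extra <- list(...)
  bad <- setdiff(names(extra), setdiff(TAX_RANKS, "species"))
  if (length(bad)) stop("unknown rank columns: ", paste(bad, collapse = ", "))
  out <- data.frame(matrix("unknown", nrow = length(species),
                           ncol = length(TAX_RANKS),
                           dimnames = list(NULL, TAX_RANKS)),
                    stringsAsFactors = FALSE)
  out$species <- species
  out$genus <- vapply(strsplit(species, " ", fixed = TRUE), `[[`, "", 1L)
  for (rk in names(extra)) out[[rk]] <- rep_len(as.character(extra[[rk]]),
                                                length(species))
  out$is_well_defined <- is_well_defined_species(species)
  out
}

#' @rdname tax_lineages
#' @export
is_well_defined_species <- function(species) {
  !(grepl("\\bsp\\.?$", species) | species == "unclassified")
}

#' Construct an abundance profile
#'
#' The profiler's end product: per-species genome copies and relative
#' (taxonomic, i.e. cell-fraction) abundances. Relative abundances are
#' normalised over classified species only; a reserved `"unclassified"` row
#' may carry copies but gets `NA` relative abundance. Rows are ordered by
#' copies descending, then lexicographically by lineage.
#'
#' @param lineages Lineage table as from [tax_lineages()], one row per entry.
#' @param copies Non-negative genome copies, parallel to `lineages`.
#' @return A `data.frame` of class `abundance_profile` with rank columns,
#'   `copies` and `rel_abundance`; total copies in `attr(, "total_copies")`.
#' @examples
#' abundance_profile(tax_lineages(c("Escherichia coli", "Bacillus subtilis")),
#'                   copies = c(3, 1))
#' @export
abundance_profile <- function(lineages, copies) {
  stopifnot(is.data.frame(lineages), length(copies) == nrow(lineages))
  if (any(copies < 0)) stop("copies must be non-negative")
  prof <- lineages[, TAX_RANKS, drop = FALSE]
  prof$copies <- as.numeric(copies)
  classified <- prof$species != "unclassified"
  denom <- sum(prof$copies[classified])
  prof$rel_abundance <- rep(NA_real_, nrow(prof))
  if (denom > 0) prof$rel_abundance[classified] <- prof$copies[classified] / denom
  ord <- order(-prof$copies, do.call(paste, prof[TAX_RANKS]))
  prof <- prof[ord, , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "total_copies") <- sum(prof$copies)
  class(prof) <- c("abundance_profile", "data.frame")
  prof
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("Abundance profile: %d entr%s, %.4g total genome copies\n",
              nrow(x), if (nrow(x) == 1) "y" else "ies",
              attr(x, "total_copies")))
  if (nrow(x)) {
    print.data.frame(x[, c("species", "copies", "rel_abundance")],
                     digits = 4, row.names = FALSE)
  }
  invisible(x)
}
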