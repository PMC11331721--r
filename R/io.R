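# Readers/writers for the tabular formats the profiler touches: blastx-style
# protein hit tables (DIAMOND dialect), PAF nucleotide alignments, and the
# tab-delimited abundance profile.

#' The tabular protein-hit column dialect
#'
#' Fixed 14-column order for blastx-style tabular output: the standard twelve
#' columns plus `qlen` and `slen`. Declared explicitly because tabular output
#' column sets vary between aligner configurations.
#'
#' @return Character vector of column names in file order.
#' @export
diamond_dialect <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore",
    "qlen", "slen")
}

#' Read a tabular protein-hit file
#'
#' Parses a tab-separated, headerless homology-search result (frame-shift
#' blastx style) into a protein-hit table. Reverse-strand hits (qstart >
#' qend) are normalised so that `query_start <= query_end`, with the original
#' orientation retained in `strand`.
#'
#' The marker gene label of each hit is taken from `subject2marker[sseqid]`
#' when a mapping is supplied; otherwise the subject id is assumed to encode
#' the marker as its first `|`-separated field (`"<marker>|<accession>"`).
#'
#' @param path Path to the tab-separated file (no header).
#' @param dialect Column names in file order; see [diamond_dialect()].
#' @param subject2marker Optional named character vector mapping subject ids
#'   to marker labels.
#' @return A protein-hit `data.frame` (see [protein_hits()]).
#' @export
read_protein_hits <- function(path, dialect = diamond_dialect(),
                              subject2marker = NULL) {
  required <- c("qseqid", "sseqid", "pident", "qstart", "qend", "sstart",
                "send", "evalue", "bitscore", "qlen", "slen")
  missing <- setdiff(required, dialect)
  if (length(missing)) {
    stop("dialect lacks required columns: ", paste(missing, collapse = ", "))
  }
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                      comment.char = "", col.names = dialect,
                      colClasses = "character"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop("failed to parse ", path, ": ", conditionMessage(e))
    }
  )
  if (is.null(raw) || nrow(raw) == 0) {
    return(protein_hits(character(), character(), character(), integer(),
                        integer(), integer(), integer(), numeric(), numeric(),
                        integer(), integer()))
  }
  num_cols <- c("pident", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore", "qlen", "slen")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    if (anyNA(v)) {
      stop("malformed value in column '", cl, "' at line ",
           which(is.na(v))[1], " of ", path)
    }
    raw[[cl]] <- v
  }
  marker <- if (!is.null(subject2marker)) {
    m <- unname(subject2marker[raw$sseqid])
    if (anyNA(m)) {
      stop("subject ids absent from subject2marker: ",
           paste(unique(raw$sseqid[is.na(m)]), collapse = ", "))
    }
    m
  } else {
    vapply(strsplit(raw$sseqid, "|", fixed = TRUE), `[[`, "", 1L)
  }
  protein_hits(
    query_id = raw$qseqid, subject_id = raw$sseqid, marker = marker,
    query_start = raw$qstart, query_end = raw$qend,
    subject_start = raw$sstart, subject_end = raw$send,
    evalue = raw$evalue, identity_pct = raw$pident, bitscore = raw$bitscore,
    query_len_nt = raw$qlen, subject_len_aa = raw$slen
  )
}

#' Write a protein-hit table in the tabular dialect
#'
#' Inverse of [read_protein_hits()]: emits the 14-column headerless TSV.
#' Minus-strand hits are written with `qstart > qend`, as aligners do.
#'
#' @param hits Protein-hit table.
#' @param path Output path.
#' @param dialect Column order; see [diamond_dialect()].
#' @export
write_protein_hits <- function(hits, path, dialect = diamond_dialect()) {
  validate_protein_hits(hits)
  qs <- ifelse(hits$strand == "-", hits$query_end, hits$query_start)
  qe <- ifelse(hits$strand == "-", hits$query_start, hits$query_end)
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = hits$identity_pct,
    length = hits$subject_end - hits$subject_start + 1,
    mismatch = 0L, gapopen = 0L,
    qstart = qs, qend = qe,
    sstart = hits$subject_start, send = hits$subject_end,
    evalue = format(hits$evalue, digits = 3, scientific = TRUE),
    bitscore = ifelse(is.na(hits$bitscore), 0, hits$bitscore),
    qlen = hits$query_len_nt, slen = hits$subject_len_aa,
    stringsAsFactors = FALSE
  )
  utils::write.table(out[, dialect], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

paf_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(paste0("^", tag, ":[A-Za-z]:"), "", hit[1])
}

#' Read a PAF alignment file
#'
#' Parses minimap2-style PAF records into a nucleotide-alignment table and
#' labels every alignment with the species of its reference window. The three
#' scores used downstream are taken from typed tags: `AS:i` (alignment
#' score), `ms:i` (local-best score), and identity from `de:f`
#' (gap-compressed per-base divergence, ID = 1 - de). When no `de` tag is
#' present, identity falls back to residue matches / alignment block length
#' (mandatory columns 10/11); without a CIGAR the gap-compressed event count
#' cannot be reconstructed exactly.
#'
#' @param path Path to a PAF file.
#' @param ref2species Named character vector mapping reference ids to species
#'   labels; unknown reference ids are an error.
#' @return A nucleotide-alignment `data.frame` (see
#'   [nucleotide_alignments()]).
#' @export
read_paf_alignments <- function(path, ref2species) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(nucleotide_alignments(character(), character(), character(),
                                 numeric(), numeric(), numeric(), logical()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parse_one <- function(fields, lineno) {
    if (length(fields) < 12) {
      stop("PAF line ", lineno, " has fewer than 12 mandatory columns")
    }
    as_tag <- paf_tag(fields, "AS")
    ms_tag <- paf_tag(fields, "ms")
    if (is.na(as_tag)) stop("PAF line ", lineno, " lacks the AS:i tag")
    if (is.na(ms_tag)) stop("PAF line ", lineno, " lacks the ms:i tag")
    de_tag <- paf_tag(fields, "de")
    id <- if (!is.na(de_tag)) {
      1 - as.numeric(de_tag)
    } else {
      as.numeric(fields[10]) / as.numeric(fields[11])
    }
    tp_tag <- paf_tag(fields, "tp")
    c(read_id = fields[1], ref_id = fields[6],
      AS = as_tag, MS = ms_tag, ID = as.character(id),
      is_primary = as.character(is.na(tp_tag) || tp_tag == "P"))
  }
  rec <- mapply(parse_one, parts, seq_along(parts), SIMPLIFY = FALSE)
  rec <- as.data.frame(do.call(rbind, rec), stringsAsFactors = FALSE)
  unknown <- setdiff(unique(rec$ref_id), names(ref2species))
  if (length(unknown)) {
    stop("reference ids absent from ref2species: ",
         paste(unknown, collapse = ", "))
  }
  nucleotide_alignments(
    read_id = rec$read_id, ref_id = rec$ref_id,
    species = unname(ref2species[rec$ref_id]),
    AS = as.numeric(rec$AS), MS = as.numeric(rec$MS),
    ID = as.numeric(rec$ID), is_primary = as.logical(rec$is_primary)
  )
}

#' Write / read an abundance profile TSV
#'
#' The profile is written as a tab-delimited table with one column per
#' taxonomic rank (superkingdom to species) plus `copies` and
#' `rel_abundance`, in the profile's deterministic row order (copies
#' descending, then lexicographic lineage). `read_profile()` is the exact
#' inverse.
#'
#' @param profile An [abundance_profile()].
#' @param path Output (or input) path.
#' @return `read_profile()` returns an `abundance_profile`;
#'   `write_profile()` returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "abundance_profile"))
  out <- as.data.frame(profile)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(rep("character", length(TAX_RANKS)),
                                          "numeric", "numeric"),
                           stringsAsFactors = FALSE)
  abundance_profile(tab[, TAX_RANKS, drop = FALSE], tab$copies)
}
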