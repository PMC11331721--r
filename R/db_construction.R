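# Extraction of marker-gene-containing nucleotide windows from assemblies:
# these windows, grouped by (species, marker), form the nucleotide reference
# database that marker-containing reads are later mapped against.

#' Extract a marker-centred window from a contig
#'
#' Takes the 5000 bp left and right flanking regions of the hit's centre —
#' a 10,000 bp window whenever the contig permits, clipped (not shifted) at
#' contig ends. The centre of the hit's nucleotide query range is
#' `floor((query_start + query_end) / 2)` (1-based); the window is reported
#' in 0-based half-open coordinates `[center - 5000, center + 5000)`.
#'
#' @param contig_seq Contig sequence: a character string or
#'   [Biostrings::DNAString].
#' @param hit A single-row protein-hit table locating the marker on the
#'   contig (after [boundary_filter()] and [best_hit_per_marker()]).
#' @param species Species label of the source assembly.
#' @param window Window length in bp (default 10000).
#' @return A list of class `window_record`: `species`, `marker`, `contig`,
#'   `start`, `end` (0-based half-open) and `seq` (character).
#' @export
extract_window <- function(contig_seq, hit, species, window = 10000L) {
  seq <- as.character(contig_seq)
  L <- nchar(seq)
  stopifnot(nrow(hit) == 1)
  if (hit$query_end > L) stop("hit extends beyond the contig")
  center <- floor((hit$query_start + hit$query_end) / 2)
  if (center < 1 || center > L) stop("hit center outside contig")
  half <- window %/% 2L
  start <- max(0L, center - half)          # 0-based inclusive
  end <- min(L, center + half)             # 0-based exclusive
  structure(list(species = species, marker = hit$marker,
                 contig = hit$query_id, start = start, end = end,
                 seq = substr(seq, start + 1L, end)),
            class = "window_record")
}

#' @export
print.window_record <- function(x, ...) {
  cat(sprintf("window %s|%s|%s|%d-%d (%d bp)\n", x$species, x$marker,
              x$contig, x$start, x$end, nchar(x$seq)))
  invisible(x)
}

#' Build the marker-window FASTA database
#'
#' Extracts one window per filtered hit and writes them grouped by
#' (species, marker), removing exact duplicate sequences within each group.
#' Headers encode `species|marker|contig|start-end` so that the reference ->
#' species mapping needed by [read_paf_alignments()] can be reconstructed
#' from the FASTA alone (see [window_ref2species()]).
#'
#' @param assemblies Named character vector (or
#'   [Biostrings::DNAStringSet]) of contig sequences, named by contig id.
#' @param hits Filtered protein-hit table; `query_id` must name contigs in
#'   `assemblies`.
#' @param contig2species Named character vector mapping contig ids to
#'   species labels.
#' @param path Optional FASTA output path; written with
#'   [Biostrings::writeXStringSet()] when given.
#' @param window Window length in bp.
#' @return A [Biostrings::DNAStringSet] of deduplicated windows (invisibly
#'   when `path` is given).
#' @export
build_window_fasta <- function(assemblies, hits, contig2species, path = NULL,
                               window = 10000L) {
  validate_protein_hits(hits)
  seqs <- if (inherits(assemblies, "DNAStringSet")) {
    stats::setNames(as.character(assemblies), names(assemblies))
  } else {
    assemblies
  }
  if (nrow(hits)) {
    unknown <- setdiff(unique(hits$query_id), names(seqs))
    if (length(unknown)) {
      stop("hits reference contigs absent from assemblies: ",
           paste(unknown, collapse = ", "))
    }
    nosp <- setdiff(unique(hits$query_id), names(contig2species))
    if (length(nosp)) {
      stop("contigs without a species label: ", paste(nosp, collapse = ", "))
    }
  }
  recs <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, , drop = FALSE]
    extract_window(seqs[[h$query_id]], h, contig2species[[h$query_id]],
                   window)
  })
  if (length(recs)) {
    tab <- data.frame(
      group = vapply(recs, function(r) paste(r$species, r$marker, sep = "|"),
                     ""),
      header = vapply(recs, function(r)
        sprintf("%s|%s|%s|%d-%d", r$species, r$marker, r$contig,
                r$start, r$end), ""),
      seq = vapply(recs, `[[`, "", "seq"),
      stringsAsFactors = FALSE
    )
    tab <- tab[order(tab$group, tab$header), , drop = FALSE]
    dup <- duplicated(tab[c("group", "seq")])
    tab <- tab[!dup, , drop = FALSE]
    out <- Biostrings::DNAStringSet(stats::setNames(tab$seq, tab$header))
  } else {
    out <- Biostrings::DNAStringSet()
  }
  if (!is.null(path)) {
    Biostrings::writeXStringSet(out, path, width = 80L)
    return(invisible(out))
  }
  out
}

#' Reference-to-species mapping from window headers
#'
#' Recovers the `ref_id -> species` mapping from the
#' `species|marker|contig|start-end` header convention of
#' [build_window_fasta()].
#'
#' @param ref_ids Character vector of window headers.
#' @return Named character vector mapping each header to its species.
#' @export
window_ref2species <- function(ref_ids) {
  sp <- vapply(strsplit(ref_ids, "|", fixed = TRUE), `[[`, "", 1L)
  stats::setNames(sp, ref_ids)
}
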