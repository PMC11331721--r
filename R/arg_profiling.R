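# Species-resolved quantification of antibiotic resistance genes (ARGs):
# host-alignment filtering against the community profile, and copies-per-cell
# arithmetic (assuming one genome copy per cell).

#' Filter ARG host alignments against a community profile
#'
#' For every ARG-containing read, keeps the single best alignment (by AS,
#' then MS, then ID), then drops the read if (a) the best alignment's species
#' is absent from the community profile, (b) the best alignment ties between
#' a chromosomal and a plasmid/virus reference (dropped conservatively),
#' (c) the retained reference is plasmid- or virus-sourced (mobile genetic
#' elements), or (d) the hit's ARG family is flagged multidrug (multidrug
#' efflux pumps are not antibiotic-specific).
#'
#' @param alignments Nucleotide-alignment table with additional columns
#'   `arg_family` and `source` (one of `"chromosome"`, `"plasmid"`,
#'   `"virus"`).
#' @param profile An [abundance_profile()] of the same sample.
#' @param drop_multidrug Drop hits whose family is `"multidrug"` (default
#'   `TRUE`).
#' @return `data.frame` of kept hits: `read_id`, `arg_family`,
#'   `host_species`, `source`.
#' @export
filter_arg_host_alignments <- function(alignments, profile,
                                       drop_multidrug = TRUE) {
  validate_alignments(alignments)
  stopifnot(all(c("arg_family", "source") %in% names(alignments)))
  bad <- setdiff(unique(alignments$source),
                 c("chromosome", "plasmid", "virus"))
  if (length(bad)) {
    stop("unknown source labels: ", paste(bad, collapse = ", "))
  }
  empty <- data.frame(read_id = character(0), arg_family = character(0),
                      host_species = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0) return(empty)
  ord <- order(alignments$read_id, -alignments$AS, -alignments$MS,
               -alignments$ID)
  aln <- alignments[ord, , drop = FALSE]
  keep <- !duplicated(aln$read_id)
  best <- aln[keep, , drop = FALSE]
  # conservative: drop reads whose top score ties across different sources
  top_key <- paste(aln$read_id, aln$AS, aln$MS, aln$ID)
  best_key <- top_key[keep]
  tied_src <- tapply(aln$source[top_key %in% best_key],
                     aln$read_id[top_key %in% best_key],
                     function(s) length(unique(s)) > 1)
  best <- best[!tied_src[best$read_id], , drop = FALSE]
  present <- profile$species[profile$species != "unclassified"]
  best <- best[best$species %in% present, , drop = FALSE]
  best <- best[best$source == "chromosome", , drop = FALSE]
  if (drop_multidrug) {
    best <- best[best$arg_family != "multidrug", , drop = FALSE]
  }
  if (nrow(best) == 0) return(empty)
  data.frame(read_id = best$read_id, arg_family = best$arg_family,
             host_species = best$species, source = best$source,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ARG copies per cell
#'
#' Divides estimated ARG copies by total genome copies, assuming one genome
#' copy per cell. Works per sample (totals) or per species (vectorised).
#'
#' @param arg_copies Non-negative ARG copies.
#' @param total_genome_copies Positive genome copies (recycled).
#' @return ARG copies per cell.
#' @examples
#' arg_copies_per_cell(10, 20)  # 0.5
#' @export
arg_copies_per_cell <- function(arg_copies, total_genome_copies) {
  if (any(total_genome_copies <= 0)) {
    stop("total genome copies must be positive")
  }
  if (any(arg_copies < 0)) stop("ARG copies must be non-negative")
  arg_copies / total_genome_copies
}

#' Per-species ARG abundance table
#'
#' Counts filtered ARG hits per (host species, ARG family) and divides by
#' the species' genome copies from the profile.
#'
#' @param arg_hits Output of [filter_arg_host_alignments()].
#' @param profile An [abundance_profile()] with per-species copies.
#' @return `data.frame` with `species`, `arg_family`, `arg_copies`,
#'   `genome_copies`, `copies_per_cell`.
#' @export
arg_profile <- function(arg_hits, profile) {
  if (nrow(arg_hits) == 0) {
    return(data.frame(species = character(0), arg_family = character(0),
                      arg_copies = numeric(0), genome_copies = numeric(0),
                      copies_per_cell = numeric(0), stringsAsFactors = FALSE))
  }
  counts <- as.data.frame(table(species = arg_hits$host_species,
                                arg_family = arg_hits$arg_family),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  gcopies <- stats::setNames(profile$copies, profile$species)
  out <- data.frame(
    species = counts$species,
    arg_family = counts$arg_family,
    arg_copies = as.numeric(counts$Freq),
    genome_copies = unname(gcopies[counts$species]),
    stringsAsFactors = FALSE
  )
  out$copies_per_cell <- arg_copies_per_cell(out$arg_copies,
                                             out$genome_copies)
  out <- out[order(out$species, out$arg_family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
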