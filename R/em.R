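# EM-based species assignment of marker-containing reads: alignment validity
# screening, the binary read-species matrix, the E/M iteration, hard
# assignment and profile aggregation. profile_community() ties the pieces
# together and is the package's main fitting function.

#' Build the binary read-species matrix
#'
#' For each read-species combination only the best alignment (by AS, then
#' MS, then ID, descending) is retained. An alignment of read i to species j
#' is then considered valid if it meets at least one of three conditions
#' relative to the read's best scores over all species:
#' `AS_ij > 0.99 * max_j AS_ij`, `MS_ij > 0.99 * max_j MS_ij`, or
#' `ID_ij > 0.999 * max_j ID_ij` (strict inequalities). Valid cells form the
#' binary n x k membership matrix handed to the EM; the per-cell best AS, MS
#' and ID are kept for tie-breaking in the final hard assignment.
#'
#' @param alignments Nucleotide-alignment table (see
#'   [nucleotide_alignments()]).
#' @return An object of class `read_species_matrix`: a list with binary
#'   matrix `x` (reads x species, dimnames set) and score matrices `AS`,
#'   `MS`, `ID` (NA where no alignment exists).
#' @export
build_read_species_matrix <- function(alignments) {
  validate_alignments(alignments)
  if (nrow(alignments) == 0) {
    m <- matrix(0, 0, 0)
    return(structure(list(x = m, AS = m, MS = m, ID = m),
                     class = "read_species_matrix"))
  }
  ord <- order(alignments$read_id, alignments$species,
               -alignments$AS, -alignments$MS, -alignments$ID)
  aln <- alignments[ord, , drop = FALSE]
  best <- aln[!duplicated(aln[c("read_id", "species")]), , drop = FALSE]

  reads <- unique(best$read_id)
  species <- sort(unique(best$species))
  n <- length(reads); k <- length(species)
  ri <- match(best$read_id, reads)
  sj <- match(best$species, species)
  mk <- function(v) {
    m <- matrix(NA_real_, n, k, dimnames = list(reads, species))
    m[cbind(ri, sj)] <- v
    m
  }
  AS <- mk(best$AS); MS <- mk(best$MS); ID <- mk(best$ID)

  max_as <- apply(AS, 1, max, na.rm = TRUE)
  max_ms <- apply(MS, 1, max, na.rm = TRUE)
  max_id <- apply(ID, 1, max, na.rm = TRUE)
  valid <- (AS > 0.99 * max_as) | (MS > 0.99 * max_ms) |
    (ID > 0.999 * max_id)
  valid[is.na(valid)] <- FALSE
  x <- matrix(as.numeric(valid), n, k, dimnames = list(reads, species))

  empty <- rowSums(x) == 0
  if (any(empty)) {
    # With non-positive best scores all strict conditions can fail; the
    # best-scoring species of such a read is still its only candidate.
    for (i in which(empty)) {
      j <- order(-AS[i, ], -MS[i, ], -ID[i, ], na.last = TRUE)[1]
      x[i, j] <- 1
    }
  }
  structure(list(x = x, AS = AS, MS = MS, ID = ID),
            class = "read_species_matrix")
}

#' @export
print.read_species_matrix <- function(x, ...) {
  cat(sprintf("Read-species matrix: %d reads x %d species, %d valid cells\n",
              nrow(x$x), ncol(x$x), sum(x$x)))
  invisible(x)
}

em_loglik <- function(x, theta) sum(log(x %*% theta))

#' EM reassignment of ambiguous reads
#'
#' Iterates the E-step (posterior soft assignment
#' `z_ij = x_ij theta_j / sum_j x_ij theta_j`) and M-step
#' (`theta_j = sum_i z_ij / n`) from a uniform start `theta_j = 1/k`, until
#' the L1 change in theta drops below `eps` or `t_max` iterations are
#' exceeded. Candidate species are those with at least one valid alignment
#' (k is not the database size). Abundances underflowing below 1e-12 are
#' clamped to zero and theta renormalised.
#'
#' @param matrix A `read_species_matrix` with at least one read; every row
#'   must have at least one valid cell.
#' @param eps Convergence tolerance on the L1 change of theta.
#' @param t_max Maximum number of iterations.
#' @return An object of class `em_fit`: list with abundance vector `theta`
#'   (named by species), soft assignment matrix `z`, iteration count `t`,
#'   `converged`, per-iteration observed-data log-likelihood `loglik`, and
#'   the inputs `eps`, `t_max`, `n`, `k`.
#' @examples
#' aln <- nucleotide_alignments(
#'   c("r1", "r2", "r3", "r4", "r4"),
#'   "w", c("A", "A", "B", "A", "B"),
#'   AS = 100, MS = 100, ID = 0.99)
#' fit <- em_iterate(build_read_species_matrix(aln))
#' coef(fit)  # theta = (2/3, 1/3)
#' @export
em_iterate <- function(matrix, eps = 1e-5, t_max = 100L) {
  stopifnot(inherits(matrix, "read_species_matrix"))
  x <- matrix$x
  n <- nrow(x); k <- ncol(x)
  if (n < 1) stop("EM requires at least one read")
  if (any(rowSums(x) == 0)) stop("matrix has a read with no valid species")
  theta <- rep(1 / k, k)
  loglik <- numeric(0)
  t <- 0L
  converged <- FALSE
  repeat {
    t <- t + 1L
    num <- sweep(x, 2, theta, `*`)
    z <- num / rowSums(num)
    theta_new <- colSums(z) / n
    theta_new[theta_new < 1e-12] <- 0
    theta_new <- theta_new / sum(theta_new)
    loglik <- c(loglik, em_loglik(x, theta_new))
    delta <- sum(abs(theta_new - theta))
    theta <- theta_new
    if (delta < eps) { converged <- TRUE; break }
    if (t > t_max) break
  }
  structure(list(theta = stats::setNames(theta, colnames(x)),
                 z = z, t = t, converged = converged, loglik = loglik,
                 eps = eps, t_max = t_max, n = n, k = k),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("EM fit: n = %d reads, k = %d species; %s after %d iteration%s\n",
              x$n, x$k,
              if (x$converged) "converged" else "stopped (t_max)",
              x$t, if (x$t == 1) "" else "s"))
  cat("theta:\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.em_fit <- function(object, ...) object$theta

#' @export
logLik.em_fit <- function(object, ...) {
  ll <- object$loglik[length(object$loglik)]
  structure(ll, df = object$k - 1, nobs = object$n, class = "logLik")
}

#' @export
fitted.em_fit <- function(object, ...) object$z

#' @export
summary.em_fit <- function(object, ...) {
  out <- list(theta = sort(object$theta, decreasing = TRUE),
              t = object$t, converged = object$converged,
              loglik = object$loglik, n = object$n, k = object$k)
  class(out) <- "summary.em_fit"
  out
}

#' @export
print.summary.em_fit <- function(x, ...) {
  cat(sprintf("EM fit over %d reads and %d candidate species\n", x$n, x$k))
  cat(sprintf("%s after %d iterations; final log-likelihood %.6g\n",
              if (x$converged) "Converged" else "Stopped at t_max",
              x$t, x$loglik[length(x$loglik)]))
  cat("Abundances (descending):\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Hard assignment of reads after EM
#'
#' Maps every read to the species with the largest soft assignment z. Ties
#' (within 1e-12) are broken by a deterministic chain: well-defined species
#' over placeholder names (e.g. "Escherichia sp."), then larger AS, MS, ID,
#' then lexicographic species label.
#'
#' @param fit An [em_iterate()] result.
#' @param matrix The `read_species_matrix` the fit was computed from.
#' @param lineages Lineage table covering every candidate species (used for
#'   the well-definedness tie-break); may be `NULL`, in which case
#'   definedness is derived from the species label.
#' @return Named character vector: species per read.
#' @export
hard_assign <- function(fit, matrix, lineages = NULL) {
  stopifnot(inherits(fit, "em_fit"), inherits(matrix, "read_species_matrix"))
  species <- colnames(matrix$x)
  defined <- if (is.null(lineages)) {
    is_well_defined_species(species)
  } else {
    idx <- match(species, lineages$species)
    if (anyNA(idx)) {
      stop("species missing from lineage table: ",
           paste(species[is.na(idx)], collapse = ", "))
    }
    lineages$is_well_defined[idx]
  }
  z <- fit$z
  pick <- function(i) {
    cand <- which(matrix$x[i, ] == 1)
    zi <- z[i, cand]
    cand <- cand[zi > max(zi) - 1e-12]
    if (length(cand) > 1) {
      key <- order(-defined[cand],
                   -ifelse(is.na(matrix$AS[i, cand]), -Inf, matrix$AS[i, cand]),
                   -ifelse(is.na(matrix$MS[i, cand]), -Inf, matrix$MS[i, cand]),
                   -ifelse(is.na(matrix$ID[i, cand]), -Inf, matrix$ID[i, cand]),
                   species[cand])
      cand <- cand[key]
    }
    species[cand[1]]
  }
  stats::setNames(vapply(seq_len(nrow(z)), pick, ""), rownames(matrix$x))
}

#' Aggregate read assignments into an abundance profile
#'
#' Apportions the estimated total genome copies over species by their
#' hard-assigned marker-read counts: `copies_j = total * n_j / n`. When the
#' coverage total is the read count divided by the number of marker genes
#' (the usual case), this reduces to `copies_j = n_j / 8`. Relative
#' abundances are the copies normalised over classified species.
#'
#' @param assignments Named character vector read -> species, as from
#'   [hard_assign()].
#' @param total_copies Total genome copies from [total_genome_copies()] /
#'   [prokaryotic_genome_copies()].
#' @param lineages Lineage table covering every assigned species.
#' @return An [abundance_profile()].
#' @export
aggregate_profile <- function(assignments, total_copies, lineages) {
  if (length(assignments) == 0) {
    return(abundance_profile(tax_lineages(character(0)), numeric(0)))
  }
  counts <- table(assignments)
  idx <- match(names(counts), lineages$species)
  if (anyNA(idx)) {
    stop("species missing from lineage table: ",
         paste(names(counts)[is.na(idx)], collapse = ", "))
  }
  copies <- total_copies * as.numeric(counts) / length(assignments)
  abundance_profile(lineages[idx, , drop = FALSE], copies)
}

#' Profile a community from marker hits and nucleotide alignments
#'
#' The package's main fitting function: estimates total genome copies from
#' the filtered protein hits (positional trimmed mean per subject, summed per
#' marker, averaged over the eight-gene set per domain), screens the
#' nucleotide alignments of marker-containing reads into a binary
#' read-species matrix, runs the EM reassignment, hard-assigns every read and
#' aggregates the result into a species-level abundance profile.
#'
#' @param hits Protein-hit table of marker-containing reads (filtered via
#'   [filter_protein_hits()] unless `prefiltered = TRUE`).
#' @param alignments Nucleotide-alignment table of the same reads against the
#'   marker-window database.
#' @param lineages Lineage table covering all candidate species.
#' @param cfg A [cull_config()] applied when `prefiltered = FALSE`.
#' @param eps,t_max EM convergence tolerance and iteration cap.
#' @param prefiltered Set `TRUE` when `hits` already passed filtering.
#' @return An object of class `community_profile`: list with the
#'   [abundance_profile()] (`profile`), the `em_fit` (`fit`), the
#'   `read_species_matrix` (`matrix`), the hard `assignments`, and the
#'   per-domain `copies`.
#' @examples
#' sim <- simulate_marker_alignments(sample_community(3, seed = 1,
#'                                                    total_copies = 20),
#'                                   seed = 1)
#' cp <- profile_community(sim$hits, sim$alignments, sim$truth$lineages)
#' coef(cp)
#' @export
profile_community <- function(hits, alignments, lineages,
                              cfg = cull_config(), eps = 1e-5, t_max = 100L,
                              prefiltered = FALSE) {
  if (!prefiltered) hits <- filter_protein_hits(hits, cfg)
  copies <- prokaryotic_genome_copies(hits)
  matrix <- build_read_species_matrix(alignments)
  if (nrow(matrix$x) == 0) {
    prof <- abundance_profile(tax_lineages(character(0)), numeric(0))
    out <- list(profile = prof, fit = NULL, matrix = matrix,
                assignments = character(0), copies = copies)
    class(out) <- "community_profile"
    return(out)
  }
  fit <- em_iterate(matrix, eps = eps, t_max = t_max)
  assignments <- hard_assign(fit, matrix, lineages)
  profile <- aggregate_profile(assignments, copies$total, lineages)
  out <- list(profile = profile, fit = fit, matrix = matrix,
              assignments = assignments, copies = copies)
  class(out) <- "community_profile"
  out
}

#' @export
print.community_profile <- function(x, ...) {
  cat("Community profile\n")
  cat(sprintf("  total genome copies: %.4g (bacteria %.4g, archaea %.4g)\n",
              x$copies$total, x$copies$bacteria, x$copies$archaea))
  cat(sprintf("  marker reads assigned: %d; candidate species: %d\n",
              length(x$assignments), ncol(x$matrix$x)))
  print(x$profile)
  invisible(x)
}

#' @export
coef.community_profile <- function(object, ...) {
  if (is.null(object$fit)) return(stats::setNames(numeric(0), character(0)))
  coef(object$fit)
}

#' @export
summary.community_profile <- function(object, ...) {
  cat(sprintf("Profiled %d marker reads over %d candidate species\n",
              length(object$assignments), ncol(object$matrix$x)))
  if (!is.null(object$fit)) print(summary(object$fit))
  invisible(object)
}

#' @export
logLik.community_profile <- function(object, ...) logLik(object$fit)
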