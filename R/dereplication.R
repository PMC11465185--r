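# Species-level dereplication at 95% ANI, serial-ID assignment by coverage
# rank, and polB diversity-capture assessment.

#' Greedy centroid clustering of genomes at an ANI threshold
#'
#' Genomes are visited in decreasing quality-score order (ties broken by
#' mag_id); each genome joins the first existing representative with ANI at
#' or above the threshold, otherwise it founds a new cluster. Because visits
#' are score-ordered, every representative is the highest-scoring member of
#' its cluster and representatives are pairwise below the threshold.
#' Missing ANI pairs are treated as below threshold (sparse tables are
#' allowed); where both orientations are present the larger value is used.
#'
#' @param ani_table data frame with columns query, subject, ani (percent).
#' @param quality_scores named numeric vector over all genomes; the default
#'   recommendation is completeness_pct + 10*log10(N50) (see
#'   \code{\link{quality_score}}).
#' @param threshold ANI percentage defining species (default 95; join uses
#'   \code{>=}).
#' @return list of class \code{"species_clusters"}: \code{clusters} (data
#'   frame representative/member) and \code{representatives} (character
#'   vector in founding order).
#' @export
cluster_species <- function(ani_table, quality_scores, threshold = 95) {
  stopifnot(!is.null(names(quality_scores)))
  if (nrow(ani_table) > 0) {
    if (any(ani_table$ani < 0 | ani_table$ani > 100))
      stop("ANI values must lie in [0, 100]")
  }
  ids <- names(quality_scores)
  ord <- ids[order(-quality_scores, ids)]
  ani_lookup <- new.env(parent = emptyenv())
  if (nrow(ani_table) > 0) {
    for (r in seq_len(nrow(ani_table))) {
      key <- paste(sort(c(ani_table$query[r], ani_table$subject[r])), collapse = "\r")
      prev <- ani_lookup[[key]]
      ani_lookup[[key]] <- if (is.null(prev)) ani_table$ani[r] else max(prev, ani_table$ani[r])
    }
  }
  get_ani <- function(a, b) {
    v <- ani_lookup[[paste(sort(c(a, b)), collapse = "\r")]]
    if (is.null(v)) -Inf else v
  }
  reps <- character(0)
  assignment <- character(length(ord)); names(assignment) <- ord
  for (g in ord) {
    joined <- FALSE
    for (r in reps) {
      if (get_ani(g, r) >= threshold) {
        assignment[g] <- r; joined <- TRUE; break
      }
    }
    if (!joined) { reps <- c(reps, g); assignment[g] <- g }
  }
  clusters <- data.frame(representative = unname(assignment),
                         member = names(assignment))
  structure(list(clusters = clusters, representatives = reps),
            class = "species_clusters")
}

#' Default dereplication quality score
#'
#' \code{completeness_pct + 10 * log10(N50)}, the usual completeness/
#' contiguity compromise for picking cluster representatives.
#'
#' @param completeness_pct completeness percentage.
#' @param n50 assembly N50 in bp.
#' @return numeric score.
#' @export
quality_score <- function(completeness_pct, n50) {
  completeness_pct + 10 * log10(n50)
}

#' Assign four-digit serial IDs by maximum coverage rank
#'
#' Representatives are ordered by their maximum per-sample coverage
#' (descending; ties broken by mag_id) and numbered 0001, 0002, ...
#'
#' @param representatives character vector of representative mag_ids.
#' @param coverage_matrix genomes x samples coverage matrix with rownames.
#' @return named character vector mag_id -> zero-padded serial ID.
#' @export
assign_serial_ids <- function(representatives, coverage_matrix) {
  missing <- setdiff(representatives, rownames(coverage_matrix))
  if (length(missing) > 0)
    stop("representative(s) missing from coverage matrix: ",
         paste(missing, collapse = ", "))
  max_cov <- apply(coverage_matrix[representatives, , drop = FALSE], 1, max)
  ord <- representatives[order(-max_cov, representatives)]
  setNames(sprintf("%04d", seq_along(ord)), ord)
}

#' Species-level match rule for polB sequences
#'
#' True iff nucleotide identity exceeds 96% and the aligned length covers
#' more than 60% of the shorter sequence (both strict), the operational
#' species boundary used for the diversity-capture assessment.
#'
#' @param identity_pct percent identity in [0, 100].
#' @param aligned_len aligned length in bp.
#' @param len_query,len_subject sequence lengths (bp, > 0).
#' @param min_identity,min_cover thresholds (defaults 96 and 0.60).
#' @return logical scalar.
#' @export
species_match <- function(identity_pct, aligned_len, len_query, len_subject,
                          min_identity = 96, min_cover = 0.60) {
  stopifnot(len_query > 0, len_subject > 0,
            identity_pct >= 0, identity_pct <= 100)
  shorter <- min(len_query, len_subject)
  if (aligned_len > shorter) stop("inconsistent alignment: aligned_len exceeds the shorter sequence")
  identity_pct > min_identity && aligned_len / shorter > min_cover
}

#' Global alignment of two short nucleotide sequences
#'
#' Exact Needleman-Wunsch dynamic programming with match +1, mismatch -1,
#' gap -2; identity is matches over alignment columns. Intended for
#' fixture-scale sequences (kb range), not genome-scale search.
#'
#' @param a,b uppercase ACGT strings.
#' @return list: score, matches, mismatches, gaps, columns, identity.
#' @export
align_global <- function(a, b) {
  check_acgt(a); check_acgt(b)
  .nw_align(a, b)
}

#' polB diversity-capture fraction
#'
#' For each representative polB (from clustering the whole assembly's polB
#' genes), decide whether any MAG polB matches it at the species boundary
#' (\code{\link{species_match}}); the captured fraction estimates how much
#' of the giant-virus diversity in the lake the MAG catalogue represents.
#' Identities come either from the built-in global aligner or from a
#' precomputed alignment table.
#'
#' @param polb_cluster_reps named character vector of representative polB
#'   sequences (non-empty).
#' @param mag_polb_sequences named character vector of polB sequences found
#'   in the MAGs (may be empty: fraction 0 with a warning).
#' @param alignment_table optional precomputed table with columns query
#'   (rep id), subject (MAG polB id), identity_pct, aligned_len; when
#'   supplied the aligner is not run.
#' @return list: fraction, verdicts (data frame rep_id/captured/best_match).
#' @export
capture_fraction <- function(polb_cluster_reps, mag_polb_sequences,
                             alignment_table = NULL) {
  stopifnot(length(polb_cluster_reps) >= 1)
  rep_ids <- names(polb_cluster_reps)
  if (length(mag_polb_sequences) == 0 &&
      (is.null(alignment_table) || nrow(alignment_table) == 0)) {
    warning("no MAG polB sequences; capture fraction is 0")
    verdicts <- data.frame(rep_id = rep_ids, captured = FALSE,
                           best_match = NA_character_)
    return(list(fraction = 0, verdicts = verdicts))
  }
  verdicts <- lapply(rep_ids, function(rid) {
    captured <- FALSE; best <- NA_character_
    if (!is.null(alignment_table)) {
      sub <- alignment_table[alignment_table$query == rid, , drop = FALSE]
      for (r in seq_len(nrow(sub))) {
        lq <- nchar(polb_cluster_reps[[rid]])
        ls <- if (sub$subject[r] %in% names(mag_polb_sequences))
          nchar(mag_polb_sequences[[sub$subject[r]]]) else lq
        if (species_match(sub$identity_pct[r], sub$aligned_len[r], lq, ls)) {
          captured <- TRUE; best <- sub$subject[r]; break
        }
      }
    } else {
      for (mid in names(mag_polb_sequences)) {
        al <- align_global(polb_cluster_reps[[rid]], mag_polb_sequences[[mid]])
        aligned_len <- al$matches + al$mismatches
        lq <- nchar(polb_cluster_reps[[rid]])
        ls <- nchar(mag_polb_sequences[[mid]])
        if (species_match(100 * al$identity, aligned_len, lq, ls)) {
          captured <- TRUE; best <- mid; break
        }
      }
    }
    data.frame(rep_id = rid, captured = captured, best_match = best)
  })
  verdicts <- do.call(rbind, verdicts)
  rownames(verdicts) <- NULL
  list(fraction = mean(verdicts$captured), verdicts = verdicts)
}
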