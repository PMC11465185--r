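# Screening of giant-virus MAG candidates and assembly quality metrics.
#
# The decision rules are the published ones: a candidate must exceed 50 kb
# and show a giant-virus signal (at least one of the seven nucleocytovirus
# marker genes, or a mirusvirus HK97 MCP hit with bit score > 100); bins
# with CheckM completeness > 15 (bacteria) or > 20 (archaea) are excluded as
# prokaryotes; nucleocytovirus identity is confirmed by a core-gene density
# index over 20 core genes.

#' Is a sequence/bin a giant-virus candidate?
#'
#' True iff the genome exceeds 50 kb and carries at least one of the seven
#' nucleocytovirus marker genes, or an HK97 MCP (mirusvirus) hit with bit
#' score above 100. Unknown gene names are ignored with a warning.
#'
#' @param length_bp total genome length in bp (> 0).
#' @param marker_hits data frame with columns \code{gene} and
#'   \code{bit_score} (may have zero rows).
#' @param min_length_bp length threshold (default 50000, strict >).
#' @param hk97_min_bitscore HK97 MCP bit-score threshold (default 100,
#'   strict >).
#' @return logical scalar.
#' @export
is_gv_candidate <- function(length_bp, marker_hits,
                            min_length_bp = 50000, hk97_min_bitscore = 100) {
  stopifnot(length_bp > 0)
  marker_hits <- as_hit_table(marker_hits)
  unknown <- setdiff(unique(marker_hits$gene), known_genes())
  if (length(unknown) > 0) {
    warning("ignoring unknown gene name(s): ", paste(unknown, collapse = ", "))
    marker_hits <- marker_hits[marker_hits$gene %in% known_genes(), , drop = FALSE]
  }
  if (length_bp <= min_length_bp) return(FALSE)
  has_ncldv <- any(marker_hits$gene %in% NCLDV_MARKERS)
  has_mirus <- any(marker_hits$gene == MIRUS_MARKER &
                     marker_hits$bit_score > hk97_min_bitscore)
  has_ncldv || has_mirus
}

as_hit_table <- function(marker_hits) {
  if (is.null(marker_hits) || nrow(as.data.frame(marker_hits)) == 0)
    return(data.frame(gene = character(), bit_score = numeric()))
  marker_hits <- as.data.frame(marker_hits)
  stopifnot(all(c("gene", "bit_score") %in% names(marker_hits)))
  marker_hits
}

#' Exclude prokaryote bins by CheckM-style completeness
#'
#' @param bac_completeness bacterial completeness percentage in [0, 100];
#'   \code{NA} is treated as 0 with a warning.
#' @param arc_completeness archaeal completeness percentage, same rules.
#' @return \code{TRUE} when the bin should be excluded as a prokaryote
#'   (bacterial completeness > 15 or archaeal > 20, strict).
#' @export
exclude_prokaryote <- function(bac_completeness, arc_completeness) {
  if (is.na(bac_completeness)) {
    warning("missing bacterial completeness treated as 0")
    bac_completeness <- 0
  }
  if (is.na(arc_completeness)) {
    warning("missing archaeal completeness treated as 0")
    arc_completeness <- 0
  }
  stopifnot(bac_completeness >= 0, bac_completeness <= 100,
            arc_completeness >= 0, arc_completeness <= 100)
  bac_completeness > 15 || arc_completeness > 20
}

#' Core-gene density index
#'
#' Number of distinct nucleocytovirus core genes (out of 20) with at least
#' one hit, per 100 kb of genome. The density screen separates marker-dense
#' viral genomes from megabase-scale cellular sequences with sporadic hits.
#'
#' @param marker_hits hit table (columns \code{gene}, \code{bit_score}).
#' @param total_length_bp genome length in bp (> 0).
#' @param threshold acceptance cutoff on the density (default 0.5; verdict
#'   uses \code{>=}).
#' @return list with \code{density} and logical \code{is_nucleocytovirus}.
#' @export
core_gene_density <- function(marker_hits, total_length_bp, threshold = 0.5) {
  stopifnot(total_length_bp > 0)
  marker_hits <- as_hit_table(marker_hits)
  n_core <- length(unique(intersect(marker_hits$gene, NCLDV_CORE_GENES)))
  density <- n_core / (total_length_bp / 1e5)
  list(density = density, is_nucleocytovirus = density >= threshold)
}

#' Assembly N50
#'
#' The largest length L such that contigs of length >= L together cover at
#' least half the assembly.
#'
#' @param contig_lengths vector of positive contig lengths.
#' @return the N50 value.
#' @export
n50 <- function(contig_lengths) {
  stopifnot(length(contig_lengths) >= 1, all(contig_lengths > 0))
  s <- sort(contig_lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Quality summary of a MAG
#'
#' Completeness tier ("high" strictly above 90, "medium" at or above 50,
#' else "low"), N50, contig count, number of distinct nucleocytovirus marker
#' genes (of 7), and a single-contig flag.
#'
#' @param contig_lengths vector of contig lengths (bp).
#' @param completeness_pct completeness percentage in [0, 100] (externally
#'   estimated).
#' @param marker_hits hit table (columns \code{gene}, \code{bit_score}).
#' @return list: tier, n50, n_contigs, marker_count_of_7, single_contig.
#' @export
quality_summary <- function(contig_lengths, completeness_pct, marker_hits) {
  stopifnot(length(contig_lengths) >= 1)
  marker_hits <- as_hit_table(marker_hits)
  tier <- if (is.na(completeness_pct)) NA_character_
          else if (completeness_pct > 90) "high"
          else if (completeness_pct >= 50) "medium"
          else "low"
  list(tier = tier,
       n50 = n50(contig_lengths),
       n_contigs = length(contig_lengths),
       marker_count_of_7 = length(unique(intersect(marker_hits$gene, NCLDV_MARKERS))),
       single_contig = length(contig_lengths) == 1L)
}

#' Marker-based completeness fallback
#'
#' \code{marker_count_of_7 / 7 * 100}; provided for use when no external
#' completeness estimate exists, never substituted silently.
#' @param marker_hits hit table.
#' @return percentage in [0, 100].
#' @export
marker_completeness <- function(marker_hits) {
  marker_hits <- as_hit_table(marker_hits)
  length(unique(intersect(marker_hits$gene, NCLDV_MARKERS))) / 7 * 100
}

#' Detect a terminal inverted repeat (TIR)
#'
#' Finds the longest genome prefix (searched up to \code{window} bp,
#' truncated to half the sequence) whose reverse complement matches the
#' same-length suffix with a mismatch fraction at most
#' \code{max_mismatch_frac}. TIRs on a single contig are the signature of a
#' complete linear genome. Coordinates are 0-based, half-open.
#'
#' @param sequence uppercase ACGT string.
#' @param min_len minimum repeat length (default 20).
#' @param window maximum prefix length searched (default 5000).
#' @param max_mismatch_frac maximum allowed mismatches / repeat length.
#' @return \code{NULL} when no repeat qualifies, else a list
#'   (\code{repeat_length}, \code{start_offset} = 0, \code{mismatches}).
#' @export
find_tir <- function(sequence, min_len = 20, window = 5000,
                     max_mismatch_frac = 0.05) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  check_acgt(sequence)
  n <- nchar(sequence)
  w <- min(window, floor(n / 2))
  if (w < min_len) return(NULL)
  x <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # prefix position i pairs with the complement of position n + 1 - i for
  # every candidate repeat length, so one mismatch profile serves all L
  comp <- chartr("ACGT", "TGCA", x)
  mism <- cumsum(x[1:w] != comp[n + 1 - (1:w)])
  ok <- which(seq_len(w) >= min_len & mism / seq_len(w) <= max_mismatch_frac)
  if (length(ok) == 0) return(NULL)
  L <- max(ok)
  list(repeat_length = L, start_offset = 0L, mismatches = unname(mism[L]))
}

#' POA90 indel-error proxy
#'
#' Percentage of protein alignment coverages at or above 0.90. High values
#' indicate few unpolished indel errors truncating predicted proteins.
#'
#' @param coverages vector of per-protein alignment coverages in [0, 1].
#' @return percentage, or \code{NA} for an empty input (reported missing,
#'   never 0).
#' @export
poa90 <- function(coverages) {
  if (length(coverages) == 0) {
    message("POA90 undefined for empty coverage list; reported as missing")
    return(NA_real_)
  }
  stopifnot(all(coverages >= 0 & coverages <= 1))
  100 * mean(coverages >= 0.90)
}

#' Compare fragmentation (or any per-MAG metric) between two MAG groups
#'
#' Reports the two group medians and a two-sided Mann-Whitney U p-value.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return list: median_a, median_b, p_value (NA when either group has
#'   fewer than 2 values).
#' @export
fragmentation_compare <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  p <- if (length(group_a) < 2 || length(group_b) < 2) NA_real_ else
    suppressWarnings(wilcox.test(group_a, group_b,
                                 alternative = "two.sided")$p.value)
  list(median_a = median(group_a), median_b = median(group_b), p_value = p)
}

#' Screen a set of MAGs end to end
#'
#' Applies, in order: prokaryote exclusion (CheckM completeness), the >50 kb
#' length plus marker-signal candidacy rule, and the core-gene-density
#' confirmation for nucleocytoviruses (mirusvirus calls rest on the HK97 MCP
#' hit alone). Emits one row per MAG with the decision and its reason plus
#' quality metrics.
#'
#' @param genomes data frame with mag_id, length_bp and either
#'   \code{contig_lengths} (list column) or \code{n_contigs}; optional
#'   completeness_pct.
#' @param markers hit table (seq_id, gene, bit_score).
#' @param checkm completeness table (seq_id, bac_completeness,
#'   arc_completeness).
#' @param contig_lengths optional named list of per-MAG contig length
#'   vectors (used for N50 when present).
#' @param density_threshold core-gene-density cutoff.
#' @return data frame: mag_id, decision ("gv" / "excluded"), reason, class
#'   ("nucleocytovirus", "mirusvirus" or NA), n_contigs, n50, tier,
#'   marker_count.
#' @export
screen_mags <- function(genomes, markers, checkm, contig_lengths = NULL,
                        density_threshold = 0.5) {
  rows <- lapply(seq_len(nrow(genomes)), function(i) {
    id <- genomes$mag_id[i]
    hits <- markers[markers$seq_id == id, c("gene", "bit_score"), drop = FALSE]
    ck <- checkm[checkm$seq_id == id, , drop = FALSE]
    bac <- if (nrow(ck)) ck$bac_completeness[1] else NA_real_
    arc <- if (nrow(ck)) ck$arc_completeness[1] else NA_real_
    cl <- if (!is.null(contig_lengths) && !is.null(contig_lengths[[id]]))
      contig_lengths[[id]] else rep(genomes$length_bp[i] / genomes$n_contigs[i],
                                    genomes$n_contigs[i])
    comp <- if ("completeness_pct" %in% names(genomes)) genomes$completeness_pct[i] else NA_real_
    qs <- quality_summary(cl, comp, hits)

    decision <- "gv"; reason <- "passed"; klass <- NA_character_
    if (suppressWarnings(exclude_prokaryote(bac, arc))) {
      decision <- "excluded"; reason <- "prokaryote_completeness"
    } else if (!is_gv_candidate(genomes$length_bp[i], hits)) {
      decision <- "excluded"
      reason <- if (genomes$length_bp[i] <= 50000) "below_50kb" else "no_gv_marker"
    } else {
      is_mirus <- any(hits$gene == MIRUS_MARKER & hits$bit_score > 100)
      cgd <- core_gene_density(hits, genomes$length_bp[i], density_threshold)
      if (is_mirus) {
        klass <- "mirusvirus"
      } else if (cgd$is_nucleocytovirus ||
                 any(hits$gene %in% NCLDV_MARKERS)) {
        # marker-bearing genomes below the density cutoff stay candidates
        # only when density confirms; the seven-marker signal alone is
        # sufficient for candidacy but density gates the final call
        if (cgd$is_nucleocytovirus) {
          klass <- "nucleocytovirus"
        } else {
          decision <- "excluded"; reason <- "low_core_gene_density"
        }
      }
    }
    data.frame(mag_id = id, decision = decision, reason = reason, class = klass,
               n_contigs = qs$n_contigs, n50 = qs$n50, tier = qs$tier,
               marker_count = qs$marker_count_of_7)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
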