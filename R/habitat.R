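# Habitat preference (P_epi), occupancy persistence, group comparisons and
# the headline summary statistics.

#' Habitat-preference index P_epi
#'
#' Cumulative epilimnion RPKM divided by the cumulative RPKM of both layers
#' over the stratified months. Undefined (NA) when the genome was never
#' detected in either layer during stratification.
#'
#' @param rpkm_epi_by_month,rpkm_hypo_by_month non-negative numeric vectors
#'   named by month, covering the same months.
#' @param stratified_months months over which to accumulate.
#' @return value in [0, 1], or NA when the denominator is zero.
#' @export
p_epi <- function(rpkm_epi_by_month, rpkm_hypo_by_month, stratified_months) {
  if (is.null(names(rpkm_epi_by_month)) || is.null(names(rpkm_hypo_by_month)) ||
      !identical(names(rpkm_epi_by_month), names(rpkm_hypo_by_month)))
    stop("misaligned series: both layers must be named by the same months")
  if (!all(stratified_months %in% names(rpkm_epi_by_month)))
    stop("misaligned series: stratified months missing from the series")
  if (any(rpkm_epi_by_month < 0) || any(rpkm_hypo_by_month < 0))
    stop("RPKM series must be non-negative")
  e <- sum(rpkm_epi_by_month[stratified_months])
  h <- sum(rpkm_hypo_by_month[stratified_months])
  if (e + h == 0) return(NA_real_)
  e / (e + h)
}

#' Classify habitat preference from P_epi
#'
#' P_epi above 0.95 is epilimnion-specific, below 0.05 hypolimnion-specific,
#' in between generalist; an undefined P_epi is unclassified.
#'
#' @param p P_epi values in [0, 1] (NA allowed); vectorized.
#' @param epi_threshold,hypo_threshold classification cutoffs (strict).
#' @return character vector of labels.
#' @export
classify_habitat <- function(p, epi_threshold = 0.95, hypo_threshold = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("P_epi must lie in [0, 1]")
  ifelse(is.na(p), "unclassified",
         ifelse(p > epi_threshold, "epilimnion-specific",
                ifelse(p < hypo_threshold, "hypolimnion-specific", "generalist")))
}

#' Occupancy persistence
#'
#' The longest run of consecutive stratified months in which the genome's
#' covered fraction exceeds the threshold (default 20%, strict). Months
#' outside the stratified period are ignored; runs do not wrap around.
#'
#' @param covered_fraction_by_month values in [0, 1] named by month.
#' @param stratified_months the stratified period, in month order
#'   (non-empty).
#' @param threshold covered-fraction cutoff (default 0.20).
#' @return integer number of months.
#' @export
persistence <- function(covered_fraction_by_month, stratified_months,
                        threshold = 0.20) {
  if (length(stratified_months) == 0) stop("empty stratified period")
  if (is.null(names(covered_fraction_by_month)) ||
      !all(stratified_months %in% names(covered_fraction_by_month)))
    stop("covered-fraction series must be named by month and cover the stratified period")
  v <- covered_fraction_by_month[stratified_months]
  if (any(v < 0 | v > 1)) stop("covered fractions must lie in [0, 1]")
  longest_run(v > threshold)
}

longest_run <- function(b) {
  if (!any(b)) return(0L)
  r <- rle(b)
  max(r$lengths[r$values])
}

#' Welch's unequal-variance t-test
#'
#' t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb) with Welch-Satterthwaite
#' degrees of freedom and a two-sided p from the t distribution. Degenerate
#' zero-variance inputs: equal means give p = 1; unequal means give an
#' underflow-safe minimal p.
#'
#' @param group_a,group_b numeric vectors of length >= 2.
#' @return list: t, df, p_value.
#' @export
welch_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  na <- length(group_a); nb <- length(group_b)
  va <- var(group_a); vb <- var(group_b)
  se2 <- va / na + vb / nb
  dm <- mean(group_a) - mean(group_b)
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = sign(dm) * Inf, df = NA_real_,
                p_value = .Machine$double.xmin))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p_value = max(p, .Machine$double.xmin))
}

#' @importFrom stats var
NULL

#' Habitat calls for a full RPKM tensor
#'
#' Computes P_epi and the habitat label for every genome from an RPKM
#' matrix and sample metadata.
#'
#' @param rpkm_mat genomes x samples RPKM matrix (columns named by
#'   sample_id).
#' @param samples data frame: sample_id, month, layer, stratified.
#' @param stratified_months the stratified period (defaults to the
#'   stratified months found in \code{samples}).
#' @return data frame: mag_id, p_epi, label.
#' @export
habitat_calls <- function(rpkm_mat, samples,
                          stratified_months = unique(samples$month[samples$stratified])) {
  epi_ids <- samples$sample_id[samples$layer == "epilimnion"]
  hypo_ids <- samples$sample_id[samples$layer == "hypolimnion"]
  epi_months <- setNames(epi_ids, samples$month[match(epi_ids, samples$sample_id)])
  hypo_months <- setNames(hypo_ids, samples$month[match(hypo_ids, samples$sample_id)])
  common <- intersect(names(epi_months), names(hypo_months))
  p <- vapply(rownames(rpkm_mat), function(id) {
    e <- setNames(rpkm_mat[id, epi_months[common]], common)
    h <- setNames(rpkm_mat[id, hypo_months[common]], common)
    p_epi(e, h, intersect(stratified_months, common))
  }, numeric(1))
  data.frame(mag_id = rownames(rpkm_mat), p_epi = unname(p),
             label = classify_habitat(unname(p)))
}

#' Persistence by habitat cohort
#'
#' Computes persistence for each specialist in its own layer (epilimnion
#' specialists from epilimnion samples, hypolimnion specialists from
#' hypolimnion samples), then compares mean persistence between the two
#' specialist groups with Welch's t-test. Generalists are excluded by
#' default; when included they are scored in the layer with the higher
#' cumulative RPKM (requires \code{rpkm_mat}).
#'
#' @param calls data frame from \code{\link{habitat_calls}}.
#' @param covfrac_mat genomes x samples covered-fraction matrix.
#' @param samples sample metadata (sample_id, month, layer, stratified).
#' @param stratified_months the stratified period.
#' @param include_generalists score generalists too (default FALSE).
#' @param rpkm_mat RPKM matrix, needed only for generalist layer choice.
#' @param threshold covered-fraction cutoff passed to
#'   \code{\link{persistence}}.
#' @return list: table (mag_id, label, layer_used, persistence_months),
#'   medians (named), welch (list t/df/p_value or NULL).
#' @export
persistence_cohort <- function(calls, covfrac_mat, samples,
                               stratified_months = unique(samples$month[samples$stratified]),
                               include_generalists = FALSE,
                               rpkm_mat = NULL, threshold = 0.20) {
  layer_samples <- function(layer) {
    ids <- samples$sample_id[samples$layer == layer]
    setNames(ids, samples$month[match(ids, samples$sample_id)])
  }
  epi_s <- layer_samples("epilimnion"); hypo_s <- layer_samples("hypolimnion")
  series <- function(id, smap) setNames(covfrac_mat[id, smap], names(smap))
  keep <- calls$label %in% c("epilimnion-specific", "hypolimnion-specific")
  if (include_generalists) keep <- keep | calls$label == "generalist"
  sel <- calls[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    id <- sel$mag_id[i]; lab <- sel$label[i]
    layer <- if (lab == "epilimnion-specific") "epilimnion"
             else if (lab == "hypolimnion-specific") "hypolimnion"
             else {
               if (is.null(rpkm_mat))
                 stop("rpkm_mat required to score generalists")
               if (sum(rpkm_mat[id, epi_s]) >= sum(rpkm_mat[id, hypo_s]))
                 "epilimnion" else "hypolimnion"
             }
    smap <- if (layer == "epilimnion") epi_s else hypo_s
    data.frame(mag_id = id, label = lab, layer_used = layer,
               persistence_months = persistence(series(id, smap),
                                                stratified_months, threshold))
  })
  tab <- do.call(rbind, rows)
  epi_p <- tab$persistence_months[tab$label == "epilimnion-specific"]
  hypo_p <- tab$persistence_months[tab$label == "hypolimnion-specific"]
  medians <- c(`epilimnion-specific` = if (length(epi_p)) median(epi_p) else NA_real_,
               `hypolimnion-specific` = if (length(hypo_p)) median(hypo_p) else NA_real_)
  welch <- if (length(epi_p) >= 2 && length(hypo_p) >= 2)
    welch_t(epi_p, hypo_p)
  else { warning("a specialist group is too small; Welch comparison skipped"); NULL }
  list(table = tab, medians = medians, welch = welch)
}

#' Shared / exclusive gene-content partition across habitat classes
#'
#' Exclusive-to-class terms occur in that class and in no other class;
#' shared terms occur both in at least one specialist class (epilimnion or
#' hypolimnion) and in the generalist class.
#'
#' @param gene_sets_by_class named list of character vectors of annotation
#'   terms (e.g. KEGG Orthology IDs); names must include
#'   "epilimnion-specific", "hypolimnion-specific" and "generalist".
#' @return list: shared_count, shared_terms, exclusive_counts (named),
#'   exclusive_terms (named list), total_terms.
#' @export
gene_sharing_partition <- function(gene_sets_by_class) {
  need <- c("epilimnion-specific", "hypolimnion-specific", "generalist")
  stopifnot(all(need %in% names(gene_sets_by_class)))
  sets <- lapply(gene_sets_by_class, unique)
  all_terms <- unique(unlist(sets))
  exclusive <- lapply(names(sets), function(l) {
    others <- unique(unlist(sets[setdiff(names(sets), l)]))
    setdiff(sets[[l]], others)
  })
  names(exclusive) <- names(sets)
  shared <- intersect(union(sets[["epilimnion-specific"]],
                            sets[["hypolimnion-specific"]]),
                      sets[["generalist"]])
  list(shared_count = length(shared), shared_terms = shared,
       exclusive_counts = lengths(exclusive), exclusive_terms = exclusive,
       total_terms = length(all_terms))
}

#' Headline summary percentages from catalogue counts
#'
#' Computes the printed-report percentages (half-up rounding to one
#' decimal): niche-specific fraction, per-label fractions, high-quality
#' fraction, single-contig share of high-quality genomes, the share of
#' high-quality genomes carrying all seven marker genes, and per-order
#' shares.
#'
#' @param n_total total number of species-level MAGs (> 0).
#' @param n_epi,n_hypo numbers of epilimnion-/hypolimnion-specific MAGs.
#' @param n_high_quality number with completeness above 90.
#' @param n_single_contig_hq number of high-quality MAGs made of one contig.
#' @param n_all_seven_hq number of high-quality MAGs with all 7 markers.
#' @param order_counts optional named vector of per-order MAG counts.
#' @return data frame: statistic, count, denominator, percent.
#' @export
summary_percentages <- function(n_total, n_epi, n_hypo,
                                n_high_quality = NA, n_single_contig_hq = NA,
                                n_all_seven_hq = NA, order_counts = NULL) {
  if (n_total <= 0) stop("zero total")
  pct <- function(num, den) round_half_up(100 * num / den, 1)
  rows <- data.frame(
    statistic = c("niche_specific", "epilimnion_specific", "hypolimnion_specific",
                  "high_quality", "single_contig_high_quality",
                  "all_seven_markers_of_high_quality"),
    count = c(n_epi + n_hypo, n_epi, n_hypo,
              n_high_quality, n_single_contig_hq, n_all_seven_hq),
    denominator = c(n_total, n_total, n_total,
                    n_total, n_total, n_high_quality))
  if (!is.null(order_counts)) {
    rows <- rbind(rows, data.frame(
      statistic = paste0("order_", names(order_counts)),
      count = as.numeric(order_counts), denominator = n_total))
  }
  rows$percent <- pct(rows$count, rows$denominator)
  rows
}

#' Headline summary report from pipeline objects
#'
#' Derives the catalogue counts from habitat calls, quality summaries and
#' taxonomy, then delegates to \code{\link{summary_percentages}}.
#' Denominators use all species-level MAGs, including unclassified ones,
#' unless \code{drop_unclassified} is set.
#'
#' @param calls data frame with mag_id and label.
#' @param quality data frame with mag_id, tier, n_contigs, marker_count.
#' @param taxonomy optional named vector mag_id -> order label.
#' @param drop_unclassified exclude unclassified MAGs from denominators.
#' @return data frame as in \code{\link{summary_percentages}}.
#' @export
summary_report <- function(calls, quality, taxonomy = NULL,
                           drop_unclassified = FALSE) {
  if (drop_unclassified) calls <- calls[calls$label != "unclassified", , drop = FALSE]
  q <- quality[quality$mag_id %in% calls$mag_id, , drop = FALSE]
  hq <- q[!is.na(q$tier) & q$tier == "high", , drop = FALSE]
  order_counts <- if (!is.null(taxonomy))
    table(taxonomy[calls$mag_id]) else NULL
  summary_percentages(
    n_total = nrow(calls),
    n_epi = sum(calls$label == "epilimnion-specific"),
    n_hypo = sum(calls$label == "hypolimnion-specific"),
    n_high_quality = nrow(hq),
    n_single_contig_hq = sum(hq$n_contigs == 1),
    n_all_seven_hq = sum(hq$marker_count == 7),
    order_counts = order_counts)
}
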