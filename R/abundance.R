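# Read-count to RPKM conversion, a toy read mapper for fixture-scale
# end-to-end tests, Bray-Curtis dissimilarities and community summaries.

#' Reads per kilobase of genome per million mapped reads (RPKM)
#'
#' @param read_count mapped reads for the genome in the sample.
#' @param genome_length_bp genome length (> 0).
#' @param total_mapped_reads total mapped reads in the sample (> 0).
#' @return RPKM value.
#' @export
rpkm <- function(read_count, genome_length_bp, total_mapped_reads) {
  if (any(genome_length_bp <= 0)) stop("genome_length_bp must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  read_count / ((genome_length_bp / 1000) * (total_mapped_reads / 1e6))
}

#' RPKM matrix from a count matrix
#'
#' Applies \code{\link{rpkm}} column-wise; per-sample totals are the column
#' sums of the count matrix. Samples with zero mapped reads yield all-zero
#' RPKM columns.
#'
#' @param counts genomes x samples count matrix (rownames = mag ids).
#' @param genome_lengths named vector of genome lengths (bp).
#' @return matrix of the same shape.
#' @export
rpkm_matrix <- function(counts, genome_lengths) {
  genome_lengths <- genome_lengths[rownames(counts)]
  if (anyNA(genome_lengths)) stop("missing genome length for some rows")
  totals <- colSums(counts)
  out <- counts * 0
  nz <- totals > 0
  if (any(nz))
    out[, nz] <- sweep(counts[, nz, drop = FALSE] / (genome_lengths / 1000),
                       2, totals[nz] / 1e6, "/")
  out
}

#' Toy read mapper (k-mer seeded, ungapped)
#'
#' Maps each read (both strands) to its best ungapped location among the
#' genome sequences, seeded by exact k-mer matches tiled across the read.
#' Reads whose best identity falls below \code{min_identity} are discarded;
#' ties in best identity are broken uniformly at random under the seed.
#' Only full-length placements (no overhang) are considered. The tiling
#' guarantees a seed whenever the read has a clean stretch of k bases, which
#' holds for any read within the identity threshold at the default k.
#'
#' @param reads character vector of ACGT reads.
#' @param genome_sequences named character vector of genome sequences
#'   (non-empty).
#' @param min_identity minimum read identity (default 0.92, \code{>=} kept).
#' @param k seed k-mer length (default 10).
#' @param seed integer seed for tie breaking.
#' @return list: counts (named per genome), covered_fraction, depth (mean
#'   per-base depth per genome), n_mapped, n_unmapped, assignments (data
#'   frame read/genome/position/strand/identity; unmapped reads have NA).
#' @export
toy_map_reads <- function(reads, genome_sequences, min_identity = 0.92,
                          k = 10, seed = 1L) {
  if (length(genome_sequences) == 0) stop("empty genome set")
  gids <- names(genome_sequences)
  glen <- nchar(genome_sequences)
  covered <- lapply(glen, function(n) logical(n))
  counts <- setNames(integer(length(gids)), gids)
  bases <- setNames(numeric(length(gids)), gids)
  with_seed(seed, {
    assn <- vector("list", length(reads))
    for (ri in seq_along(reads)) {
      read <- reads[[ri]]
      n <- nchar(read)
      if (n < k) { assn[ri] <- list(NULL); next }
      cands <- list()
      for (strand in c("+", "-")) {
        q <- if (strand == "+") read else revcomp(read)
        seed_pos <- unique(c(seq(1, max(1, n - k + 1), by = k), n - k + 1))
        seed_pos <- seed_pos[seed_pos >= 1]
        for (gi in seq_along(gids)) {
          g <- genome_sequences[[gi]]
          for (sp in seed_pos) {
            kmer <- substr(q, sp, sp + k - 1)
            hits <- gregexpr(kmer, g, fixed = TRUE)[[1]]
            if (hits[1] == -1) next
            for (h in hits) {
              start <- h - sp + 1
              if (start < 1 || start + n - 1 > glen[gi]) next
              key <- paste(gi, strand, start)
              if (!is.null(cands[[key]])) next
              sub <- substr(g, start, start + n - 1)
              ident <- sum(strsplit(q, "", fixed = TRUE)[[1]] ==
                             strsplit(sub, "", fixed = TRUE)[[1]]) / n
              cands[[key]] <- list(genome = gi, strand = strand,
                                   start = start, identity = ident)
            }
          }
        }
      }
      if (length(cands) == 0) next  # stays NULL = unmapped
      idents <- vapply(cands, `[[`, numeric(1), "identity")
      best <- max(idents)
      if (best < min_identity) next
      top <- which(idents == best)
      pick <- cands[[if (length(top) == 1) top else sample(top, 1)]]
      gi <- pick$genome
      counts[gi] <- counts[gi] + 1L
      bases[gi] <- bases[gi] + n
      covered[[gi]][pick$start:(pick$start + n - 1)] <- TRUE
      assn[[ri]] <- data.frame(read = ri, genome = gids[gi],
                               position = pick$start, strand = pick$strand,
                               identity = pick$identity)
    }
    mapped <- !vapply(assn, is.null, logical(1))
    assignments <- if (any(mapped)) do.call(rbind, assn[mapped]) else
      data.frame(read = integer(), genome = character(),
                 position = integer(), strand = character(),
                 identity = numeric())
    list(counts = counts,
         covered_fraction = vapply(covered, mean, numeric(1)),
         depth = bases / glen,
         n_mapped = sum(mapped),
         n_unmapped = sum(!mapped),
         assignments = assignments)
  })
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' \code{sum(|x - y|) / sum(x + y)}; defined as 0 when both profiles are
#' entirely zero (logged via \code{message}).
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("profiles must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) {
    message("both profiles all-zero; Bray-Curtis defined as 0")
    return(0)
  }
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param profiles genomes x samples abundance matrix (columns are samples).
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(profiles) {
  s <- ncol(profiles)
  out <- matrix(0, s, s, dimnames = list(colnames(profiles), colnames(profiles)))
  for (i in seq_len(s)) for (j in seq_len(s)) {
    if (j > i) out[i, j] <- out[j, i] <- suppressMessages(
      bray_curtis(profiles[, i], profiles[, j]))
  }
  out
}

#' Within-layer community dispersion during stratification
#'
#' All pairwise Bray-Curtis dissimilarities among samples of the same depth
#' layer, restricted (by default) to stratified months, with a two-sided
#' Mann-Whitney comparison between layers. The hypolimnion community of a
#' stratified lake is expected to vary less than the epilimnion one.
#'
#' @param beta samples x samples dissimilarity matrix with dimnames.
#' @param sample_meta data frame with sample_id, layer, stratified.
#' @param stratified_only restrict to stratified samples (default TRUE).
#' @return list: per-layer dissimilarity vectors, medians, p_value.
#' @export
within_layer_dispersion <- function(beta, sample_meta, stratified_only = TRUE) {
  meta <- sample_meta
  if (stratified_only) meta <- meta[meta$stratified, , drop = FALSE]
  layers <- unique(meta$layer)
  vals <- lapply(layers, function(l) {
    ids <- meta$sample_id[meta$layer == l]
    ids <- intersect(ids, rownames(beta))
    if (length(ids) < 2) return(numeric(0))
    m <- beta[ids, ids, drop = FALSE]
    m[upper.tri(m)]
  })
  names(vals) <- layers
  p <- if (all(lengths(vals) >= 2) && length(vals) == 2)
    suppressWarnings(wilcox.test(vals[[1]], vals[[2]])$p.value) else NA_real_
  list(values = vals,
       medians = vapply(vals, function(v) if (length(v)) median(v) else NA_real_,
                        numeric(1)),
       p_value = p)
}

#' Per-sample composition by taxonomic group
#'
#' Sums RPKM by group (e.g. virus order) per sample; group sums equal the
#' sample totals. MAGs without a label must be labelled "unassigned" by the
#' caller (enforced here by erroring on missing labels).
#'
#' @param rpkm_mat genomes x samples RPKM matrix.
#' @param taxonomy named character vector mag_id -> group label.
#' @return groups x samples matrix.
#' @export
composition_by_group <- function(rpkm_mat, taxonomy) {
  labs <- taxonomy[rownames(rpkm_mat)]
  if (anyNA(labs)) stop("every MAG needs a taxonomy label (use \"unassigned\")")
  rowsum(rpkm_mat, group = labs)
}
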