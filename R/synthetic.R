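# Synthetic stratified-lake community generator.
#
# The generator emulates the study design the pipeline was built for: a deep
# monomictic lake sampled monthly over one year (May..April) at two depths
# (epilimnion, hypolimnion), thermally stratified May..December, hosting
# three ecological guilds of giant viruses -- transient epilimnion
# specialists with short abundance peaks, persistent hypolimnion specialists,
# and generalists present in both layers -- plus cellular decoy genomes used
# to exercise the prokaryote-exclusion screen.

#' Default month labels (hydrological year, May through April)
#' @export
LAKE_MONTHS <- c("May", "Jun", "Jul", "Aug", "Sep", "Oct", "Nov", "Dec",
                 "Jan", "Feb", "Mar", "Apr")

#' Default stratified months (May through December)
#' @export
STRATIFIED_MONTHS <- LAKE_MONTHS[1:8]

#' Configuration of a synthetic lake virus community
#'
#' Bundles and validates every knob of the generator. The defaults describe
#' the community used throughout the package's tests: 60 epilimnion
#' specialists, 30 hypolimnion specialists, 30 generalists and a handful of
#' cellular decoys, sampled over 12 months x 2 depth layers (24 samples),
#' stratified May--December.
#'
#' @param n_epi_specialists number of epilimnion-specialist virus genomes.
#' @param n_hypo_specialists number of hypolimnion-specialist virus genomes.
#' @param n_generalists number of generalist virus genomes.
#' @param n_cellular number of cellular (prokaryote) decoy genomes; decoys
#'   carry high bacterial completeness and no giant-virus markers.
#' @param months ordered month labels.
#' @param stratified_months subset of \code{months} during which the water
#'   column is thermally stratified.
#' @param epi_peak_duration_months length (months) of the contiguous
#'   epilimnion abundance peak of each epilimnion specialist.
#' @param hypo_occupancy_prob per-stratified-month presence probability of a
#'   hypolimnion specialist in the hypolimnion.
#' @param abundance_lognormal_sigma sdlog of the multiplicative lognormal
#'   noise applied to guild abundance templates (also used for per-genome
#'   baseline variation).
#' @param reads_per_sample expected total read count per sample.
#' @param read_length read length in bp.
#' @param genome_length_range min/max virus genome length in bp.
#' @param cellular_length_range min/max decoy genome length in bp.
#' @param mirus_fraction fraction of virus genomes that are mirusviruses
#'   (carry an HK97 MCP hit instead of the seven nucleocytovirus markers).
#' @param tir_prob probability that a single-contig linear virus genome
#'   carries a planted terminal inverted repeat.
#' @param tir_length length (bp) of planted terminal inverted repeats.
#' @param seed integer seed; identical configurations give bit-identical
#'   outputs.
#' @return a validated list of class \code{"community_config"}.
#' @export
community_config <- function(n_epi_specialists = 60,
                             n_hypo_specialists = 30,
                             n_generalists = 30,
                             n_cellular = 6,
                             months = LAKE_MONTHS,
                             stratified_months = STRATIFIED_MONTHS,
                             epi_peak_duration_months = 2,
                             hypo_occupancy_prob = 0.95,
                             abundance_lognormal_sigma = 0.5,
                             reads_per_sample = 2e5,
                             read_length = 150,
                             genome_length_range = c(80e3, 250e3),
                             cellular_length_range = c(300e3, 600e3),
                             mirus_fraction = 0.08,
                             tir_prob = 0.3,
                             tir_length = 50,
                             seed = 1L) {
  cfg <- list(n_epi_specialists = as.integer(n_epi_specialists),
              n_hypo_specialists = as.integer(n_hypo_specialists),
              n_generalists = as.integer(n_generalists),
              n_cellular = as.integer(n_cellular),
              months = as.character(months),
              stratified_months = as.character(stratified_months),
              epi_peak_duration_months = as.integer(epi_peak_duration_months),
              hypo_occupancy_prob = as.numeric(hypo_occupancy_prob),
              abundance_lognormal_sigma = as.numeric(abundance_lognormal_sigma),
              reads_per_sample = as.numeric(reads_per_sample),
              read_length = as.integer(read_length),
              genome_length_range = as.numeric(genome_length_range),
              cellular_length_range = as.numeric(cellular_length_range),
              mirus_fraction = as.numeric(mirus_fraction),
              tir_prob = as.numeric(tir_prob),
              tir_length = as.integer(tir_length),
              seed = as.integer(seed))
  validate_community_config(cfg)
  structure(cfg, class = "community_config")
}

validate_community_config <- function(cfg) {
  counts <- c(cfg$n_epi_specialists, cfg$n_hypo_specialists,
              cfg$n_generalists, cfg$n_cellular)
  if (any(counts < 0)) stop("guild counts must be >= 0")
  if (!all(cfg$stratified_months %in% cfg$months))
    stop("stratified_months must be a subset of months")
  probs <- c(cfg$hypo_occupancy_prob, cfg$mirus_fraction, cfg$tir_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$epi_peak_duration_months < 1) stop("epi_peak_duration_months must be >= 1")
  if (cfg$epi_peak_duration_months > length(cfg$stratified_months))
    stop("epi peak cannot be longer than the stratified period")
  if (cfg$abundance_lognormal_sigma < 0) stop("abundance_lognormal_sigma must be >= 0")
  if (cfg$reads_per_sample <= 0 || cfg$read_length <= 0)
    stop("reads_per_sample and read_length must be positive")
  invisible(cfg)
}

guild_counts <- function(cfg) {
  c(epi = cfg$n_epi_specialists, hypo = cfg$n_hypo_specialists,
    generalist = cfg$n_generalists, cellular = cfg$n_cellular)
}

#' Generate genomes, contig sequences and annotation tables
#'
#' Draws a genome roster from the configured guild counts, materializes
#' contig sequences (uppercase ACGT) and emits the annotation tables the
#' screening stage consumes: a marker-hit table (one row per planted gene
#' hit) and a CheckM-style completeness table. Marker hits are planted as
#' table rows, not as recognizable gene sequence. Virus genomes carry either
#' three to seven of the nucleocytovirus markers (plus enough of the 20 core
#' genes to pass the density screen) or, for mirusviruses, an HK97 MCP hit
#' with bit score above 100. Cellular decoys carry high bacterial
#' completeness and no virus markers. A subset of single-contig linear virus
#' genomes carries a literal terminal inverted repeat (genome prefix equal to
#' the reverse complement of its suffix).
#'
#' @param config a \code{\link{community_config}}.
#' @param sequences if \code{FALSE}, skip sequence materialization (the
#'   roster and tables are still produced; useful when only abundance
#'   dynamics are needed).
#' @return a list with elements \code{genomes} (data frame: mag_id,
#'   true_guild, length_bp, n_contigs, is_circular, tir_length,
#'   tir_mismatches, completeness_pct), \code{contigs} (named character
#'   vector of contig sequences, or NULL), \code{contig_map} (data frame
#'   contig_id/mag_id/length, or NULL), \code{markers} (data frame: seq_id,
#'   gene, bit_score) and \code{checkm} (data frame: seq_id,
#'   bac_completeness, arc_completeness).
#' @export
generate_genomes <- function(config, sequences = TRUE) {
  validate_community_config(config)
  counts <- guild_counts(config)
  n_total <- sum(counts)
  if (n_total == 0L) stop("empty community")
  with_seed(config$seed, {
    guilds <- rep(names(counts), counts)
    n_virus <- n_total - config$n_cellular
    mag_id <- sprintf("MAG_%03d", seq_len(n_total))
    is_virus <- guilds != "cellular"
    length_bp <- integer(n_total)
    length_bp[is_virus] <- as.integer(round(runif(
      sum(is_virus), config$genome_length_range[1], config$genome_length_range[2])))
    length_bp[!is_virus] <- as.integer(round(runif(
      sum(!is_virus), config$cellular_length_range[1], config$cellular_length_range[2])))

    is_mirus <- is_virus & (runif(n_total) < config$mirus_fraction)
    n_contigs <- ifelse(is_virus, sample(1:8, n_total, replace = TRUE),
                        sample(5:30, n_total, replace = TRUE))
    is_circular <- is_virus & n_contigs == 1L & (runif(n_total) < 0.15)
    has_tir <- is_virus & n_contigs == 1L & !is_circular & (runif(n_total) < config$tir_prob)

    # marker-hit table
    markers <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      if (!is_virus[i]) next
      if (is_mirus[i]) {
        genes <- MIRUS_MARKER
        scores <- runif(1, 150, 500)
      } else {
        n_mark <- sample(3:7, 1)
        genes <- sample(NCLDV_MARKERS, n_mark)
        # enough distinct core genes to clear density >= 0.5 per 100 kb
        n_core_min <- ceiling(0.5 * length_bp[i] / 1e5)
        core_range <- seq(min(n_core_min + 1L, 20L), 20L)
        n_core <- if (length(core_range) == 1L) core_range else sample(core_range, 1)
        genes <- c(genes, sample(NCLDV_CORE_GENES, n_core))
        scores <- runif(length(genes), 120, 600)
      }
      markers[[i]] <- data.frame(seq_id = mag_id[i], gene = genes,
                                 bit_score = round(scores, 1))
    }
    markers <- do.call(rbind, markers[!vapply(markers, is.null, logical(1))])
    rownames(markers) <- NULL

    # CheckM-style completeness: decoys look bacterial, viruses do not
    bac <- ifelse(is_virus, runif(n_total, 0, 8), runif(n_total, 40, 100))
    arc <- runif(n_total, 0, 5)
    checkm <- data.frame(seq_id = mag_id,
                         bac_completeness = round(bac, 2),
                         arc_completeness = round(arc, 2))

    # virus genome completeness (externally-estimated stand-in)
    completeness <- ifelse(is_virus, round(runif(n_total, 55, 100), 1), NA_real_)

    genomes <- data.frame(mag_id = mag_id, true_guild = guilds,
                          length_bp = length_bp, n_contigs = n_contigs,
                          is_circular = is_circular,
                          tir_length = ifelse(has_tir, config$tir_length, NA_integer_),
                          tir_mismatches = ifelse(has_tir, 0L, NA_integer_),
                          completeness_pct = completeness)

    contigs <- NULL
    contig_map <- NULL
    if (sequences) {
      seqs <- list(); map <- vector("list", n_total)
      for (i in seq_len(n_total)) {
        pieces <- split_lengths(length_bp[i], n_contigs[i])
        ids <- if (n_contigs[i] == 1L) mag_id[i] else
          sprintf("%s_c%02d", mag_id[i], seq_along(pieces))
        for (j in seq_along(pieces)) {
          s <- random_dna(pieces[j])
          if (j == 1L && has_tir[i]) {
            tl <- config$tir_length
            prefix <- substr(s, 1, tl)
            substr(s, nchar(s) - tl + 1L, nchar(s)) <- revcomp(prefix)
          }
          seqs[[ids[j]]] <- s
        }
        map[[i]] <- data.frame(contig_id = ids, mag_id = mag_id[i], length = pieces)
      }
      contigs <- unlist(seqs)
      contig_map <- do.call(rbind, map)
      rownames(contig_map) <- NULL
    }

    list(genomes = genomes, contigs = contigs, contig_map = contig_map,
         markers = markers, checkm = checkm)
  })
}

# split a total length into k contig lengths (each >= 1000 bp where possible)
split_lengths <- function(total, k) {
  if (k == 1L) return(total)
  cuts <- sort(sample(seq(1000L, total - 1000L), k - 1L))
  diff(c(0L, cuts, total))
}

#' Simulate guild-structured abundance dynamics
#'
#' Builds the true (noise-free template times lognormal noise) abundance of
#' every virus genome in every (month, layer) sample. Epilimnion specialists
#' receive one contiguous abundance peak of \code{epi_peak_duration_months}
#' months in the epilimnion during stratification and are absent from the
#' hypolimnion while the column is stratified. Hypolimnion specialists are
#' present in the hypolimnion in each stratified month with probability
#' \code{hypo_occupancy_prob} and absent from the epilimnion. Generalists are
#' present in both layers. During the mixing months the two layers converge
#' linearly toward their common mean and are fully mixed from the second
#' mixing month onward. Cellular decoys are excluded (they exist only for
#' the screening stage).
#'
#' @param config a \code{\link{community_config}}.
#' @param genomes optional genome roster from \code{\link{generate_genomes}};
#'   regenerated (without sequences) when missing.
#' @param noise_sigma override for the lognormal noise sdlog (e.g. 0 for the
#'   deterministic template).
#' @return a list of class \code{"abundance_tensor"}: \code{abundance} (matrix
#'   genomes x samples), \code{samples} (data frame sample_id/month/layer/
#'   stratified) and \code{genomes} (the roster used).
#' @export
simulate_dynamics <- function(config, genomes = NULL, noise_sigma = NULL) {
  validate_community_config(config)
  if (is.null(genomes)) genomes <- generate_genomes(config, sequences = FALSE)$genomes
  sigma <- if (is.null(noise_sigma)) config$abundance_lognormal_sigma else noise_sigma
  months <- config$months
  strat <- months %in% config$stratified_months
  mixing_idx <- which(!strat)
  virus <- genomes[genomes$true_guild != "cellular", , drop = FALSE]
  n <- nrow(virus)
  samples <- data.frame(
    sample_id = c(paste0(months, "_epi"), paste0(months, "_hypo")),
    month = rep(months, 2),
    layer = rep(c("epilimnion", "hypolimnion"), each = length(months)),
    stratified = rep(strat, 2))

  with_seed(config$seed + 1L, {
    epi <- matrix(0, n, length(months), dimnames = list(virus$mag_id, months))
    hypo <- epi
    strat_pos <- which(strat)
    for (i in seq_len(n)) {
      base <- exp(rnorm(1, 0, sigma))  # per-genome baseline level
      g <- virus$true_guild[i]
      if (g == "epi") {
        start <- sample(seq_len(length(strat_pos) - config$epi_peak_duration_months + 1L), 1)
        peak <- strat_pos[seq(start, start + config$epi_peak_duration_months - 1L)]
        epi[i, peak] <- base
      } else if (g == "hypo") {
        occ <- runif(length(strat_pos)) < config$hypo_occupancy_prob
        hypo[i, strat_pos[occ]] <- base
      } else {  # generalist
        epi[i, strat_pos] <- base
        hypo[i, strat_pos] <- base
      }
    }
    # mixing months: both layers converge linearly to the mean of their last
    # stratified values; fully mixed from the second mixing month onward
    last_strat <- max(strat_pos)
    e0 <- epi[, last_strat]; h0 <- hypo[, last_strat]
    mid <- (e0 + h0) / 2
    for (t in seq_along(mixing_idx)) {
      w <- min(1, t / 2)
      epi[, mixing_idx[t]] <- (1 - w) * e0 + w * mid
      hypo[, mixing_idx[t]] <- (1 - w) * h0 + w * mid
    }
    if (sigma > 0) {
      epi <- epi * matrix(exp(rnorm(length(epi), 0, sigma)), n)
      hypo <- hypo * matrix(exp(rnorm(length(hypo), 0, sigma)), n)
    }
    abundance <- cbind(epi, hypo)
    colnames(abundance) <- samples$sample_id
    structure(list(abundance = abundance, samples = samples, genomes = virus),
              class = "abundance_tensor")
  })
}

#' Convert true abundances to read counts, coverage depth and covered fraction
#'
#' Per sample, read counts are Poisson with mean proportional to abundance
#' times genome length, normalized so the expected sample total equals
#' \code{reads_per_sample}. Coverage depth is \code{count * read_length /
#' genome_length}; the covered fraction follows the Lander-Waterman
#' approximation \code{1 - exp(-depth)}.
#'
#' @param dynamics an \code{abundance_tensor} from
#'   \code{\link{simulate_dynamics}}.
#' @param genome_lengths named vector of genome lengths (bp), defaulting to
#'   the roster inside \code{dynamics}.
#' @param config a \code{\link{community_config}} (supplies
#'   reads_per_sample, read_length and the seed).
#' @return list with matrices \code{counts}, \code{depth}, \code{covfrac}
#'   (same dimnames as the abundance matrix) plus \code{samples}.
#' @export
abundance_to_reads <- function(dynamics, genome_lengths = NULL, config) {
  validate_community_config(config)
  ab <- dynamics$abundance
  if (any(ab < 0)) stop("abundances must be non-negative")
  if (is.null(genome_lengths))
    genome_lengths <- setNames(dynamics$genomes$length_bp, dynamics$genomes$mag_id)
  genome_lengths <- genome_lengths[rownames(ab)]
  if (anyNA(genome_lengths)) stop("missing genome length for some genomes")
  with_seed(config$seed + 2L, {
    counts <- matrix(0L, nrow(ab), ncol(ab), dimnames = dimnames(ab))
    for (s in seq_len(ncol(ab))) {
      w <- ab[, s] * genome_lengths
      tot <- sum(w)
      if (tot == 0) next
      counts[, s] <- rpois(nrow(ab), config$reads_per_sample * w / tot)
    }
    depth <- counts * config$read_length / genome_lengths
    covfrac <- 1 - exp(-depth)
    list(counts = counts, depth = depth, covfrac = covfrac,
         samples = dynamics$samples)
  })
}

#' Mutate reference sequences by point substitutions
#'
#' Introduces independent per-site substitutions (never indels), so the
#' realized identity of each mutant to its source is exactly the fraction of
#' unmutated sites.
#'
#' @param reference_sequences named character vector of ACGT sequences.
#' @param per_site_divergence substitution probability per site, in [0, 0.5];
#'   recycled across references.
#' @param seed integer seed.
#' @return data frame with columns source_id, sequence, n_substitutions,
#'   identity.
#' @export
mutate_polb <- function(reference_sequences, per_site_divergence, seed = 1L) {
  stopifnot(length(reference_sequences) >= 1)
  if (any(per_site_divergence < 0 | per_site_divergence > 0.5))
    stop("per_site_divergence must lie in [0, 0.5]")
  div <- rep_len(per_site_divergence, length(reference_sequences))
  ids <- names(reference_sequences)
  if (is.null(ids)) ids <- sprintf("ref_%02d", seq_along(reference_sequences))
  with_seed(seed, {
    out <- lapply(seq_along(reference_sequences), function(i) {
      s <- strsplit(reference_sequences[[i]], "", fixed = TRUE)[[1]]
      hit <- which(runif(length(s)) < div[i])
      for (j in hit) s[j] <- sample(setdiff(c("A", "C", "G", "T"), s[j]), 1)
      data.frame(source_id = ids[i],
                 sequence = paste(s, collapse = ""),
                 n_substitutions = length(hit),
                 identity = 1 - length(hit) / length(s))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}
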