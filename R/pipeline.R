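# Pipeline orchestration: configuration, fixture generation, stage wiring
# and report emission. All tables are tab-separated with one header line;
# FASTA is written at 80 columns via Biostrings.

#' Write sequences to FASTA (80-column wrap)
#' @param sequences named character vector of ACGT sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Pipeline configuration
#'
#' Bundles every decision threshold of the workflow with the stratified
#' month set and the seed, validating each against its documented range.
#' The defaults are the published decision rules.
#'
#' @param min_length_bp genome length screen (default 50000).
#' @param hk97_min_bitscore HK97 MCP bit-score cutoff (default 100).
#' @param max_bac_completeness,max_arc_completeness prokaryote-exclusion
#'   cutoffs (defaults 15 and 20).
#' @param core_density_threshold core-gene-density cutoff (default 0.5).
#' @param ani_threshold species ANI boundary in percent (default 95).
#' @param polb_min_identity,polb_min_cover polB species-match thresholds
#'   (defaults 96 and 0.60).
#' @param min_read_identity toy-mapper identity floor (default 0.92).
#' @param p_epi_high,p_epi_low habitat classification cutoffs (defaults
#'   0.95 / 0.05).
#' @param persistence_covfrac covered-fraction cutoff for persistence
#'   (default 0.20).
#' @param stratified_months stratified period month labels.
#' @param seed integer seed.
#' @return validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(min_length_bp = 50000,
                            hk97_min_bitscore = 100,
                            max_bac_completeness = 15,
                            max_arc_completeness = 20,
                            core_density_threshold = 0.5,
                            ani_threshold = 95,
                            polb_min_identity = 96,
                            polb_min_cover = 0.60,
                            min_read_identity = 0.92,
                            p_epi_high = 0.95,
                            p_epi_low = 0.05,
                            persistence_covfrac = 0.20,
                            stratified_months = STRATIFIED_MONTHS,
                            seed = 1L) {
  cfg <- list(min_length_bp = as.numeric(min_length_bp),
              hk97_min_bitscore = as.numeric(hk97_min_bitscore),
              max_bac_completeness = as.numeric(max_bac_completeness),
              max_arc_completeness = as.numeric(max_arc_completeness),
              core_density_threshold = as.numeric(core_density_threshold),
              ani_threshold = as.numeric(ani_threshold),
              polb_min_identity = as.numeric(polb_min_identity),
              polb_min_cover = as.numeric(polb_min_cover),
              min_read_identity = as.numeric(min_read_identity),
              p_epi_high = as.numeric(p_epi_high),
              p_epi_low = as.numeric(p_epi_low),
              persistence_covfrac = as.numeric(persistence_covfrac),
              stratified_months = as.character(stratified_months),
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  in_range <- function(x, lo, hi) is.numeric(x) && length(x) == 1 && x >= lo && x <= hi
  checks <- c(
    min_length_bp = in_range(cfg$min_length_bp, 0, Inf),
    hk97_min_bitscore = in_range(cfg$hk97_min_bitscore, 0, Inf),
    max_bac_completeness = in_range(cfg$max_bac_completeness, 0, 100),
    max_arc_completeness = in_range(cfg$max_arc_completeness, 0, 100),
    core_density_threshold = in_range(cfg$core_density_threshold, 0, Inf),
    ani_threshold = in_range(cfg$ani_threshold, 0, 100),
    polb_min_identity = in_range(cfg$polb_min_identity, 0, 100),
    polb_min_cover = in_range(cfg$polb_min_cover, 0, 1),
    min_read_identity = in_range(cfg$min_read_identity, 0, 1),
    p_epi_high = in_range(cfg$p_epi_high, 0, 1),
    p_epi_low = in_range(cfg$p_epi_low, 0, 1),
    persistence_covfrac = in_range(cfg$persistence_covfrac, 0, 1))
  if (!all(checks))
    stop("pipeline config validation failed for: ",
         paste(names(checks)[!checks], collapse = ", "))
  if (cfg$p_epi_low >= cfg$p_epi_high)
    stop("pipeline config validation failed: p_epi_low must be below p_epi_high")
  invisible(cfg)
}

#' Write a configuration to JSON (lossless round trip)
#' @param config a \code{pipeline_config} or \code{community_config}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a configuration written by \code{\link{write_config}}
#' @param path JSON path.
#' @param type "pipeline" or "community".
#' @return the reconstructed, re-validated config object.
#' @export
read_config <- function(path, type = c("pipeline", "community")) {
  type <- match.arg(type)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (type == "pipeline") do.call(pipeline_config, raw)
  else do.call(community_config, raw)
}

#' Write the full synthetic fixture bundle
#'
#' Generates genomes, dynamics and read tables from a community
#' configuration and writes: contigs.fasta, markers.tsv, checkm.tsv,
#' lengths.tsv, samples.tsv, truth.tsv, and long-format abundance.tsv,
#' counts.tsv and covfrac.tsv (columns mag_id, month, layer, value).
#'
#' @param config a \code{\link{community_config}}.
#' @param dir output directory.
#' @param force overwrite an existing directory (default FALSE: error).
#' @param sequences materialize contig sequences (default TRUE).
#' @return the directory, invisibly.
#' @export
make_fixtures <- function(config, dir, force = FALSE, sequences = TRUE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("fixture directory exists (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genomes(config, sequences = sequences)
  dyn <- simulate_dynamics(config, genomes = gen$genomes)
  rd <- abundance_to_reads(dyn, config = config)

  if (sequences) write_fasta(gen$contigs, file.path(dir, "contigs.fasta"))
  write_tsv(gen$markers, file.path(dir, "markers.tsv"))
  write_tsv(gen$checkm, file.path(dir, "checkm.tsv"))
  write_tsv(gen$genomes[, c("mag_id", "length_bp", "n_contigs", "completeness_pct")],
            file.path(dir, "lengths.tsv"))
  write_tsv(dyn$samples, file.path(dir, "samples.tsv"))
  write_tsv(data.frame(mag_id = gen$genomes$mag_id, guild = gen$genomes$true_guild),
            file.path(dir, "truth.tsv"))
  long <- function(m) {
    meta <- dyn$samples[match(colnames(m), dyn$samples$sample_id), ]
    data.frame(mag_id = rep(rownames(m), times = ncol(m)),
               month = rep(meta$month, each = nrow(m)),
               layer = rep(meta$layer, each = nrow(m)),
               value = as.vector(m))
  }
  write_tsv(long(dyn$abundance), file.path(dir, "abundance.tsv"))
  write_tsv(long(rd$counts), file.path(dir, "counts.tsv"))
  write_tsv(long(rd$covfrac), file.path(dir, "covfrac.tsv"))
  write_config(config, file.path(dir, "community_config.json"))
  invisible(dir)
}

# long (mag_id, month, layer, value) -> genomes x samples matrix
long_to_matrix <- function(df, samples) {
  key <- paste0(df$month, "_", ifelse(df$layer == "epilimnion", "epi", "hypo"))
  ids <- unique(df$mag_id)
  m <- matrix(0, length(ids), nrow(samples),
              dimnames = list(ids, samples$sample_id))
  m[cbind(match(df$mag_id, ids), match(key, samples$sample_id))] <- df$value
  m
}

#' Run the full analysis pipeline on a fixture/input directory
#'
#' Executes screen -> dereplicate -> profile -> classify -> report over the
#' tables produced by \code{\link{make_fixtures}} (or equivalently formatted
#' real inputs), writing each stage's table plus report.json and a manifest
#' recording the seed and every threshold.
#'
#' @param input_dir directory holding markers.tsv, checkm.tsv, lengths.tsv,
#'   samples.tsv, counts.tsv, covfrac.tsv (and optionally ani.tsv,
#'   taxonomy.tsv).
#' @param out_dir output directory (created; default \code{input_dir}).
#' @param config a \code{\link{pipeline_config}}.
#' @return invisible list with every stage's in-memory result.
#' @export
run_pipeline <- function(input_dir, out_dir = input_dir,
                         config = pipeline_config()) {
  validate_pipeline_config(config)
  need <- c("markers.tsv", "checkm.tsv", "lengths.tsv", "samples.tsv",
            "counts.tsv", "covfrac.tsv")
  for (f in need) {
    p <- file.path(input_dir, f)
    if (!file.exists(p)) stop("missing input: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }

  markers <- read_tsv(file.path(input_dir, "markers.tsv"))
  checkm <- read_tsv(file.path(input_dir, "checkm.tsv"))
  lengths <- read_tsv(file.path(input_dir, "lengths.tsv"))
  samples <- read_tsv(file.path(input_dir, "samples.tsv"))
  counts_long <- read_tsv(file.path(input_dir, "counts.tsv"))
  covfrac_long <- read_tsv(file.path(input_dir, "covfrac.tsv"))

  screened <- stage("screen", screen_mags(
    lengths, markers, checkm,
    density_threshold = config$core_density_threshold))
  write_tsv(screened, file.path(out_dir, "mags_screened.tsv"))
  gv <- screened$mag_id[screened$decision == "gv"]

  counts <- long_to_matrix(counts_long, samples)
  covfrac <- long_to_matrix(covfrac_long, samples)
  glen <- setNames(lengths$length_bp, lengths$mag_id)
  counts <- counts[intersect(rownames(counts), gv), , drop = FALSE]
  covfrac <- covfrac[intersect(rownames(covfrac), gv), , drop = FALSE]

  derep <- stage("derep", {
    ani_path <- file.path(input_dir, "ani.tsv")
    ani <- if (file.exists(ani_path)) read_tsv(ani_path) else
      data.frame(query = character(), subject = character(), ani = numeric())
    qs <- setNames(
      quality_score(ifelse(is.na(lengths$completeness_pct), 50,
                           lengths$completeness_pct),
                    pmax(1, lengths$length_bp / lengths$n_contigs)),
      lengths$mag_id)[gv]
    cl <- cluster_species(ani, qs, threshold = config$ani_threshold)
    depth_proxy <- sweep(counts, 1, glen[rownames(counts)], "/")
    reps <- intersect(cl$representatives, rownames(depth_proxy))
    ids <- assign_serial_ids(reps, depth_proxy)
    list(clusters = cl, serial_ids = ids)
  })
  write_tsv(derep$clusters$clusters, file.path(out_dir, "clusters.tsv"))
  write_tsv(data.frame(mag_id = names(derep$serial_ids),
                       serial_id = unname(derep$serial_ids)),
            file.path(out_dir, "ids.tsv"))

  profile <- stage("profile", {
    rp <- rpkm_matrix(counts, glen)
    beta <- bray_curtis_matrix(rp)
    ord <- nmds(beta, k = 2, seed = config$seed)
    disp <- within_layer_dispersion(beta, samples)
    list(rpkm = rp, beta = beta, nmds = ord, dispersion = disp)
  })
  write_tsv(data.frame(sample_id = rownames(profile$beta), profile$beta,
                       check.names = FALSE),
            file.path(out_dir, "beta.tsv"))
  write_tsv(data.frame(sample_id = rownames(profile$nmds$points),
                       dim1 = profile$nmds$points[, 1],
                       dim2 = profile$nmds$points[, 2],
                       stress = profile$nmds$stress),
            file.path(out_dir, "nmds.tsv"))

  classify <- stage("classify", {
    calls <- habitat_calls(profile$rpkm, samples,
                           stratified_months = config$stratified_months)
    pers <- persistence_cohort(calls, covfrac, samples,
                               stratified_months = config$stratified_months,
                               threshold = config$persistence_covfrac)
    list(calls = calls, persistence = pers)
  })
  write_tsv(classify$calls, file.path(out_dir, "habitat_calls.tsv"))
  write_tsv(classify$persistence$table, file.path(out_dir, "persistence.tsv"))

  report <- stage("report", {
    quality <- screened[, c("mag_id", "tier", "n_contigs", "marker_count")]
    taxonomy_path <- file.path(input_dir, "taxonomy.tsv")
    taxonomy <- if (file.exists(taxonomy_path)) {
      t0 <- read_tsv(taxonomy_path); setNames(t0$order, t0$mag_id)
    } else NULL
    summary_report(classify$calls, quality, taxonomy)
  })
  write_tsv(report, file.path(out_dir, "report.tsv"))
  jsonlite::write_json(
    list(report = report,
         medians = as.list(classify$persistence$medians),
         welch_p = if (is.null(classify$persistence$welch)) NULL else
           classify$persistence$welch$p_value,
         nmds_stress = profile$nmds$stress),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  manifest <- c(list(package_version = as.character(utils::packageVersion("stratovir")),
                     generated = "run_pipeline"), unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(screened = screened, derep = derep, profile = profile,
                 classify = classify, report = report))
}
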