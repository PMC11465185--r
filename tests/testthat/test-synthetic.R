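# Synthetic lake-community generator: construction, determinism, dynamics
# templates and the read-sampling model.

small_cfg <- function(...) {
  community_config(n_epi_specialists = 3, n_hypo_specialists = 3,
                   n_generalists = 2, n_cellular = 2,
                   genome_length_range = c(60e3, 90e3),
                   cellular_length_range = c(100e3, 150e3),
                   reads_per_sample = 5e4, seed = 11, ...)
}

test_that("config validation rejects out-of-range settings", {
  expect_error(community_config(n_epi_specialists = -1), "counts")
  expect_error(community_config(stratified_months = c("May", "NotAMonth")),
               "subset")
  expect_error(community_config(hypo_occupancy_prob = 1.2), "probabilities")
  expect_error(generate_genomes(community_config(
    n_epi_specialists = 0, n_hypo_specialists = 0,
    n_generalists = 0, n_cellular = 0)), "empty community")
})

test_that("generated genomes carry the planted annotations", {
  cfg <- community_config(n_epi_specialists = 1, n_hypo_specialists = 0,
                          n_generalists = 0, n_cellular = 1,
                          genome_length_range = c(60e3, 60e3),
                          mirus_fraction = 0, tir_prob = 1, seed = 3)
  g <- generate_genomes(cfg)
  virus <- g$genomes$mag_id[g$genomes$true_guild == "epi"]
  hits <- g$markers[g$markers$seq_id == virus, ]
  # every nucleocytovirus guild genome carries >= 1 of the seven markers
  expect_gt(sum(hits$gene %in% NCLDV_MARKERS), 0)
  # cellular decoys carry no marker rows and high bacterial completeness
  decoy <- g$genomes$mag_id[g$genomes$true_guild == "cellular"]
  expect_false(decoy %in% g$markers$seq_id)
  expect_gt(g$checkm$bac_completeness[g$checkm$seq_id == decoy], 15)
})

test_that("planted TIRs appear literally in the sequence", {
  cfg <- community_config(n_epi_specialists = 25, n_hypo_specialists = 0,
                          n_generalists = 0, n_cellular = 0,
                          genome_length_range = c(60e3, 70e3),
                          tir_prob = 1, tir_length = 50, mirus_fraction = 0,
                          seed = 5)
  g <- generate_genomes(cfg)
  with_tir <- g$genomes[!is.na(g$genomes$tir_length), ]
  expect_gt(nrow(with_tir), 0)
  for (id in with_tir$mag_id) {
    s <- g$contigs[[id]]  # TIR genomes are single-contig
    expect_identical(substr(s, 1, 50), revcomp(substr(s, nchar(s) - 49, nchar(s))))
  }
})

test_that("identical config and seed give byte-identical FASTA", {
  cfg <- small_cfg()
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(generate_genomes(cfg)$contigs, f1)
  write_fasta(generate_genomes(cfg)$contigs, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("dynamics follow the guild templates", {
  cfg <- small_cfg()
  g <- generate_genomes(cfg, sequences = FALSE)
  d0 <- simulate_dynamics(cfg, g$genomes, noise_sigma = 0)
  strat <- cfg$stratified_months
  epi_cols <- paste0(strat, "_epi"); hypo_cols <- paste0(strat, "_hypo")
  for (i in seq_len(nrow(d0$genomes))) {
    id <- d0$genomes$mag_id[i]; guild <- d0$genomes$true_guild[i]
    e <- d0$abundance[id, epi_cols]; h <- d0$abundance[id, hypo_cols]
    if (guild == "epi") {
      # exactly one contiguous run of the configured peak duration
      r <- rle(e > 0)
      expect_identical(sum(r$values), 1L)
      expect_identical(max(r$lengths[r$values]), cfg$epi_peak_duration_months)
      expect_true(all(h == 0))
      # epilimnion sums of a hypo specialist stay < 5% of its total
    } else if (guild == "hypo") {
      expect_lt(sum(e), 0.05 * sum(d0$abundance[id, ]))
    } else {
      expect_true(all(e > 0) && all(h > 0))
    }
  }
  # noise-free run is reproducible and equals the template exactly
  d0b <- simulate_dynamics(cfg, g$genomes, noise_sigma = 0)
  expect_identical(d0$abundance, d0b$abundance)
})

test_that("layers converge during the mixing period", {
  cfg <- small_cfg()
  d0 <- simulate_dynamics(cfg, noise_sigma = 0)
  mixing <- setdiff(cfg$months, cfg$stratified_months)
  # from the second mixing month the two layers are identical
  for (m in mixing[-1]) {
    expect_equal(d0$abundance[, paste0(m, "_epi")],
                 d0$abundance[, paste0(m, "_hypo")])
  }
})

test_that("true P_epi separates guilds on noise-free abundances", {
  cfg <- community_config(seed = 2)  # default 60/30/30 community
  d0 <- simulate_dynamics(cfg, noise_sigma = 0)
  strat <- cfg$stratified_months
  for (i in seq_len(nrow(d0$genomes))) {
    id <- d0$genomes$mag_id[i]
    e <- setNames(d0$abundance[id, paste0(cfg$months, "_epi")], cfg$months)
    h <- setNames(d0$abundance[id, paste0(cfg$months, "_hypo")], cfg$months)
    p <- p_epi(e, h, strat)
    if (d0$genomes$true_guild[i] == "epi") expect_gt(p, 0.95)
    if (d0$genomes$true_guild[i] == "hypo") expect_lt(p, 0.05)
  }
})

test_that("read sampling matches the Poisson/Lander-Waterman model", {
  cfg <- small_cfg()
  d <- simulate_dynamics(cfg)
  r <- abundance_to_reads(d, config = cfg)
  # zero abundance -> zero count and zero covered fraction
  zero <- d$abundance == 0
  expect_true(all(r$counts[zero] == 0))
  expect_true(all(r$covfrac[zero] == 0))
  # covered fraction follows 1 - exp(-depth)
  expect_equal(r$covfrac, 1 - exp(-r$depth))
  expect_lt(abs((1 - exp(-0.2231)) - 0.2), 1e-4)
  # per-sample totals approximate reads_per_sample within 3 Poisson sd
  tot <- colSums(r$counts)
  active <- colSums(d$abundance) > 0
  expect_true(all(abs(tot[active] - cfg$reads_per_sample) <=
                    3 * sqrt(cfg$reads_per_sample)))
  # determinism
  r2 <- abundance_to_reads(d, config = cfg)
  expect_identical(r$counts, r2$counts)
})

test_that("covered fraction is monotone in depth, 0 at 0, and saturates", {
  d <- c(0, 10^seq(-3, 1, length.out = 40))
  cf <- 1 - exp(-d)
  expect_identical(cf[1], 0)
  expect_true(all(diff(cf) > 0))
  expect_gt(1 - exp(-30), 1 - 1e-12)
})

test_that("mutate_polb plants substitutions with exact bookkeeping", {
  ref <- c(one = rand_seq(300, 41))
  same <- mutate_polb(ref, 0, seed = 9)
  expect_identical(same$sequence, unname(ref))
  expect_identical(same$identity, 1)

  mut <- mutate_polb(ref, 0.1, seed = 9)
  diffs <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                  ref, mut$sequence)
  expect_identical(as.integer(unname(diffs)), as.integer(mut$n_substitutions))
  expect_equal(mut$identity, 1 - mut$n_substitutions / 300)

  # realized divergence over many sites is near the nominal rate
  long <- mutate_polb(c(r = rand_seq(1000, 42)), 0.2, seed = 10)
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs((1 - long$identity) - 0.2), 4 * se)
  expect_error(mutate_polb(ref, 0.6), "0.5")
})
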