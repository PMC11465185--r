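# Screening rules and assembly quality metrics.

hits <- function(genes, scores = rep(200, length(genes))) {
  data.frame(gene = genes, bit_score = scores)
}

test_that("candidacy requires >50 kb plus a marker or HK97 signal", {
  expect_true(is_gv_candidate(60000, hits("PolB")))
  expect_false(is_gv_candidate(40000, hits(c("PolB", "MCP", "A32"))))
  expect_true(is_gv_candidate(60000, hits("HK97_MCP", 150)))
  expect_false(is_gv_candidate(60000, hits("HK97_MCP", 90)))
  expect_false(is_gv_candidate(50000, hits("PolB")))  # strict >
  expect_false(is_gv_candidate(60000, hits("core_3")))  # core genes alone
  expect_warning(v <- is_gv_candidate(60000, hits("rpoB")), "unknown")
  expect_false(v)
})

test_that("candidacy is monotone in length and hit set", {
  set.seed(1)
  for (rep in 1:25) {
    L <- sample(30000:200000, 1)
    genes <- sample(c(NCLDV_MARKERS, NCLDV_CORE_GENES), sample(0:5, 1))
    h <- hits(genes)
    base <- is_gv_candidate(L, h)
    expect_true(!base || is_gv_candidate(L + 50000, h))  # longer never flips
    more <- rbind(h, hits(sample(NCLDV_MARKERS, 1)))
    expect_true(!base || is_gv_candidate(L, more))  # extra hits never flip
  }
})

test_that("prokaryote exclusion uses strict >15 / >20 cutoffs", {
  expect_true(exclude_prokaryote(16, 0))
  expect_true(exclude_prokaryote(10, 21))
  expect_false(exclude_prokaryote(15, 20))
  expect_false(exclude_prokaryote(0, 0))
  expect_warning(v <- exclude_prokaryote(NA, 0), "missing")
  expect_false(v)
})

test_that("core gene density counts distinct core genes per 100 kb", {
  ten <- hits(paste0("core_", 1:10))
  r <- core_gene_density(ten, 5e5)
  expect_equal(r$density, 2.0)
  expect_true(r$is_nucleocytovirus)

  two <- hits(c("core_1", "core_2", "core_2"))  # duplicates don't count
  r2 <- core_gene_density(two, 3e6)
  expect_equal(r2$density, 2 / 30, tolerance = 1e-10)
  expect_false(r2$is_nucleocytovirus)

  r3 <- core_gene_density(hits(character(0)), 1e5)
  expect_identical(r3$density, 0)
  expect_false(r3$is_nucleocytovirus)
})

test_that("N50 matches its definition and the brute-force oracle", {
  expect_equal(n50(c(40, 30, 20, 10) * 1000), 30000)
  for (ls in all_multisets(c(1, 2, 3, 5, 8, 13), 8)) {
    expect_identical(n50(ls), oracle_n50(ls))
  }
})

test_that("quality tiers and marker counts follow the stated boundaries", {
  q <- quality_summary(c(50e3), 90.0, hits(c("PolB", "PolB", "MCP")))
  expect_identical(q$tier, "medium")  # strict > 90
  expect_identical(q$marker_count_of_7, 2L)
  expect_true(q$single_contig)
  expect_identical(quality_summary(1e5, 90.1, hits("PolB"))$tier, "high")
  expect_identical(quality_summary(1e5, 49.9, hits("PolB"))$tier, "low")
  expect_equal(marker_completeness(hits(NCLDV_MARKERS)), 100)
})

test_that("find_tir recovers planted repeats and matches the exhaustive oracle", {
  x <- rand_seq(50, 7)
  core <- rand_seq(800, 8)
  s <- paste0(x, core, revcomp(x))
  hit <- find_tir(s)
  expect_identical(hit[c("repeat_length", "start_offset", "mismatches")],
                   oracle_tir(s)[c("repeat_length", "start_offset", "mismatches")])
  expect_gte(hit$repeat_length, 50)
  expect_identical(hit$start_offset, 0L)

  # mismatch budget: 2/40 > 0.05 rejected, accepted at 0.06
  x40 <- rand_seq(40, 9)
  tail40 <- revcomp(x40)
  substr(tail40, 5, 5) <- if (substr(tail40, 5, 5) == "A") "C" else "A"
  substr(tail40, 25, 25) <- if (substr(tail40, 25, 25) == "G") "T" else "G"
  s2 <- paste0(x40, rand_seq(600, 10), tail40)
  expect_identical(find_tir(s2, max_mismatch_frac = 0.05),
                   oracle_tir(s2, max_mismatch_frac = 0.05))
  h2 <- find_tir(s2, max_mismatch_frac = 0.06)
  o2 <- oracle_tir(s2, max_mismatch_frac = 0.06)
  expect_identical(h2[c("repeat_length", "mismatches")],
                   o2[c("repeat_length", "mismatches")])

  # random sequences: oracle agreement (usually no hit at min_len 20)
  for (seed in 1:6) {
    s3 <- rand_seq(sample(500:5000, 1), 100 + seed)
    expect_identical(find_tir(s3), oracle_tir(s3))
  }
  expect_null(find_tir(rand_seq(10000, 55)))
  expect_error(find_tir("ACGTN"), "invalid alphabet")
})

test_that("poa90 counts coverages at or above 0.90", {
  expect_equal(poa90(c(0.95, 0.99, 0.50, 0.92)), 75.0)
  expect_equal(poa90(rep(1, 5)), 100.0)
  expect_true(is.na(suppressMessages(poa90(numeric(0)))))
})

test_that("fragmentation comparison reports medians and a Mann-Whitney p", {
  same <- fragmentation_compare(c(4, 6, 8), c(4, 6, 8))
  expect_equal(same$p_value, 1, tolerance = 0.05)
  expect_identical(same$median_a, same$median_b)

  sep <- fragmentation_compare(1:10, 11:20)
  expect_equal(sep$median_a, 5.5)
  expect_equal(sep$median_b, 15.5)
  expect_lt(sep$p_value, 0.01)
  # closed form for complete separation: 2 / choose(20, 10)
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  expect_equal(fragmentation_compare(c(6, 6, 10), c(1, 2))$median_a, 6)
  expect_true(is.na(fragmentation_compare(c(6, 6, 10), 5)$p_value))
})

test_that("screening separates planted viruses from cellular decoys", {
  cfg <- community_config(n_epi_specialists = 8, n_hypo_specialists = 6,
                          n_generalists = 6, n_cellular = 8,
                          genome_length_range = c(60e3, 120e3),
                          seed = 21)
  g <- generate_genomes(cfg, sequences = FALSE)
  screened <- screen_mags(g$genomes, g$markers, g$checkm)
  truth_gv <- g$genomes$true_guild != "cellular"
  called_gv <- screened$decision == "gv"
  expect_identical(called_gv, truth_gv)  # precision = recall = 1
  expect_true(all(screened$reason[!truth_gv] == "prokaryote_completeness"))
})
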