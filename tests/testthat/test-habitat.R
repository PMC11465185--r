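# P_epi, habitat classification, persistence, Welch t and report arithmetic.

months8 <- STRATIFIED_MONTHS

test_that("p_epi is the stratified epilimnion share of cumulative RPKM", {
  e <- setNames(c(rep(1, 5), rep(0, 7)), LAKE_MONTHS)
  h <- setNames(rep(0, 12), LAKE_MONTHS)
  expect_identical(p_epi(e, h, months8), 1)

  e19 <- setNames(c(rep(19 / 8, 8), rep(0, 4)), LAKE_MONTHS)
  h1 <- setNames(c(rep(1 / 8, 8), rep(0, 4)), LAKE_MONTHS)
  p <- p_epi(e19, h1, months8)
  expect_equal(p, 0.95)
  expect_identical(classify_habitat(p), "generalist")  # strict > 0.95

  both0 <- setNames(rep(0, 12), LAKE_MONTHS)
  expect_true(is.na(p_epi(both0, both0, months8)))
  expect_identical(classify_habitat(p_epi(both0, both0, months8)), "unclassified")
  expect_error(p_epi(e[-1], h, months8), "misaligned")
})

test_that("p_epi of swapped layers sums to one when defined", {
  set.seed(44)
  for (rep in 1:20) {
    e <- setNames(runif(12), LAKE_MONTHS)
    h <- setNames(runif(12), LAKE_MONTHS)
    expect_equal(p_epi(e, h, months8) + p_epi(h, e, months8), 1)
  }
})

test_that("classification thresholds partition every value", {
  expect_identical(classify_habitat(0.96), "epilimnion-specific")
  expect_identical(classify_habitat(0.04), "hypolimnion-specific")
  expect_identical(classify_habitat(0.50), "generalist")
  expect_error(classify_habitat(1.2), "\\[0, 1\\]")
  set.seed(4)
  labs <- classify_habitat(c(runif(50), NA))
  expect_identical(length(labs), 51L)
  expect_true(all(labs %in% c("epilimnion-specific", "hypolimnion-specific",
                              "generalist", "unclassified")))
})

test_that("persistence is the longest qualifying run over stratified months", {
  v <- setNames(c(0.25, 0.30, 0.15, 0.21, 0.22, 0.23, 0.05, 0.90), months8)
  expect_identical(persistence(v, months8), 3L)
  expect_identical(persistence(setNames(rep(0.2, 8), months8), months8), 0L)
  expect_identical(persistence(setNames(rep(0.21, 8), months8), months8), 8L)
  # months outside the stratified period are ignored
  v12 <- setNames(c(rep(0, 8), rep(1, 4)), LAKE_MONTHS)
  expect_identical(persistence(v12, months8), 0L)
  expect_error(persistence(v, character(0)), "empty stratified")
})

test_that("persistence agrees with the run-scan oracle on all binary series", {
  for (n in 1:12) {
    grid <- expand.grid(rep(list(c(0, 0.5)), n))
    for (r in seq_len(nrow(grid))) {
      v <- setNames(as.numeric(grid[r, ]), paste0("m", 1:n))
      expect_identical(persistence(v, paste0("m", 1:n)),
                       oracle_persistence(v))
    }
  }
})

test_that("welch_t matches its closed form and the stats oracle", {
  r <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t, -1.549, tolerance = 1e-3)
  expect_equal(r$df, 2.941, tolerance = 1e-3)

  same <- welch_t(c(5, 6, 7), c(5, 6, 7))
  expect_identical(same$t, 0)
  expect_equal(same$p_value, 1)

  set.seed(60)
  for (rep in 1:100) {
    a <- rnorm(sample(2:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:30, 1), mean = runif(1, -1, 1))
    mine <- welch_t(a, b)
    ref <- t.test(a, b, var.equal = FALSE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    swapped <- welch_t(b, a)
    expect_equal(swapped$t, -mine$t)
    expect_equal(swapped$p_value, mine$p_value)
  }

  degen <- welch_t(c(1, 1), c(2, 2))
  expect_true(degen$p_value > 0 && degen$p_value < 1e-300)
})

test_that("specialists recover their planted labels in the default community", {
  cfg <- community_config(seed = 101)  # 60 epi / 30 hypo / 30 generalists
  d <- simulate_dynamics(cfg)
  rd <- abundance_to_reads(d, config = cfg)
  rp <- rpkm_matrix(rd$counts, setNames(d$genomes$length_bp, d$genomes$mag_id))
  calls <- habitat_calls(rp, d$samples)
  truth <- setNames(d$genomes$true_guild, d$genomes$mag_id)
  want <- c(epi = "epilimnion-specific", hypo = "hypolimnion-specific")
  spec <- names(truth)[truth %in% names(want)]
  hit <- calls$label[match(spec, calls$mag_id)] == want[truth[spec]]
  expect_gte(mean(hit), 0.95)

  pc <- persistence_cohort(calls, rd$covfrac, d$samples)
  expect_gt(pc$medians["hypolimnion-specific"], pc$medians["epilimnion-specific"])
  expect_lt(pc$welch$p_value, 0.01)
  # classification is a partition
  expect_identical(nrow(calls), nrow(d$genomes))
  expect_identical(sum(table(calls$label)), nrow(calls))
})

test_that("persistence cohorts use each specialist's own layer", {
  months <- LAKE_MONTHS
  samples <- data.frame(
    sample_id = c(paste0(months, "_epi"), paste0(months, "_hypo")),
    month = rep(months, 2),
    layer = rep(c("epilimnion", "hypolimnion"), each = 12),
    stratified = rep(months %in% months8, 2))
  cf <- matrix(0, 3, 24, dimnames = list(c("E", "H", "G"), samples$sample_id))
  cf["E", paste0(c("May", "Jun"), "_epi")] <- 0.9     # 2-month epi run
  cf["E", paste0(months8, "_hypo")] <- 0.9            # must be ignored
  cf["H", paste0(months8[1:6], "_hypo")] <- 0.5       # 6-month hypo run
  calls <- data.frame(mag_id = c("E", "H", "G"),
                      p_epi = c(1, 0, 0.5),
                      label = c("epilimnion-specific", "hypolimnion-specific",
                                "generalist"))
  pc <- suppressWarnings(persistence_cohort(calls, cf, samples))
  expect_identical(pc$table$persistence_months[pc$table$mag_id == "E"], 2L)
  expect_identical(pc$table$persistence_months[pc$table$mag_id == "H"], 6L)
  # generalists excluded by default
  expect_false("G" %in% pc$table$mag_id)
  expect_identical(nrow(pc$table), 2L)
})

test_that("gene sharing partition follows the set algebra", {
  sets <- list(`epilimnion-specific` = c("a", "b", "c"),
               `hypolimnion-specific` = c("b", "d"),
               generalist = c("b", "c", "e"))
  r <- gene_sharing_partition(sets)
  expect_identical(r$exclusive_counts[["epilimnion-specific"]], 1L)
  expect_identical(r$exclusive_counts[["hypolimnion-specific"]], 1L)
  expect_identical(sort(r$shared_terms), c("b", "c"))
  expect_identical(r$shared_count, 2L)

  disjoint <- list(`epilimnion-specific` = "a", `hypolimnion-specific` = "b",
                   generalist = "c")
  expect_identical(gene_sharing_partition(disjoint)$shared_count, 0L)

  same <- list(`epilimnion-specific` = c("x", "y"),
               `hypolimnion-specific` = c("x", "y"), generalist = c("x", "y"))
  expect_true(all(gene_sharing_partition(same)$exclusive_counts == 0L))
})

test_that("summary percentages use half-up one-decimal rounding", {
  expect_identical(round_half_up(65.55), 65.6)  # not banker's rounding
  expect_identical(round_half_up(0.25, 1), 0.3)
  tab <- summary_percentages(n_total = 293, n_epi = 143, n_hypo = 49,
                             n_high_quality = 118, n_single_contig_hq = 42,
                             n_all_seven_hq = 74,
                             order_counts = c(Imitervirales = 237))
  get <- function(s) tab$percent[tab$statistic == s]
  expect_identical(get("niche_specific"), 65.5)
  expect_identical(get("epilimnion_specific"), 48.8)
  expect_identical(get("hypolimnion_specific"), 16.7)
  expect_identical(get("high_quality"), 40.3)
  expect_identical(get("single_contig_high_quality"), 14.3)
  expect_identical(get("all_seven_markers_of_high_quality"), 62.7)
  expect_identical(get("order_Imitervirales"), 80.9)
  expect_error(summary_percentages(0, 0, 0), "zero total")
})
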