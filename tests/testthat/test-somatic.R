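test_that("per-read filters drop reads below the quality criteria", {
  # single read failing mapping quality
  low_mq <- make_obs(1, "A", mq = 24)
  expect_equal(filter_read_observations(low_mq)$depth, 0)
  # boundary: mq exactly 25 is kept
  expect_equal(filter_read_observations(make_obs(1, "A", mq = 25))$depth, 1)
  # empty input gives a depth-0 column
  expect_equal(filter_read_observations(make_obs(0, "A"))$depth, 0)
  # base quality 14 excludes the C read, keeping the two A reads
  obs <- rbind(make_obs(2, "A"), make_obs(1, "C", bq = 14))
  col <- filter_read_observations(obs)
  expect_equal(unname(col$counts["A"]), 2)
  expect_equal(unname(col$counts["C"]), 0)
  expect_equal(col$depth, 2)
  # mismatches above 5 and N alleles are dropped
  obs2 <- rbind(make_obs(3, "A"), make_obs(1, "A", mm = 6), make_obs(1, "N"))
  expect_equal(filter_read_observations(obs2)$depth, 3)
  # observations spanning positions are an input error
  mixed <- rbind(make_obs(1, "A", pos = 100L), make_obs(1, "A", pos = 101L))
  expect_error(filter_read_observations(mixed), "multiple positions")
})

test_that("vaf uses filtered depth and rejects alt == ref", {
  expect_equal(vaf(col_of(c(A = 3998, T = 2)), "T"), 0.0005)
  expect_equal(vaf(col_of(c(A = 70, T = 30)), "T"), 0.30)
  expect_equal(vaf(col_of(c(A = 100)), "T"), 0)
  expect_equal(vaf(col_of(c()), "T"), 0)          # depth 0
  expect_error(vaf(col_of(c(A = 10)), "A"), "alt allele equals")
})

test_that("one-sided Fisher p matches brute-force fixed-margin enumeration", {
  expect_equal(fisher_exact_2x2(0, 100, 0, 100), 1.0)
  # frozen value from the enumeration oracle
  expect_equal(fisher_exact_2x2(5, 95, 0, 100), 0.0296916052342932,
               tolerance = 1e-12)
  # a heavier tail is more significant
  expect_lt(fisher_exact_2x2(10, 90, 0, 100), fisher_exact_2x2(5, 95, 0, 100))
  expect_error(fisher_exact_2x2(-1, 10, 0, 10), "counts")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "positive")
  # random tables against the oracle
  set.seed(7)
  for (i in 1:200) {
    tab <- sample(0:20, 4, replace = TRUE)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("site-level calling applies depth, VAF and Fisher criteria as printed", {
  thr <- tumor_thresholds()
  # tumor depth 99 fails criterion iv whatever the AF
  c99 <- call_somatic_site(col_of(c(A = 69, T = 30)), col_of(c(A = 200)), thr)
  expect_false(c99$pass)
  expect_match(c99$failed, "tumor_depth")
  # clean signal passes; p agrees with the enumeration oracle
  ok <- call_somatic_site(col_of(c(A = 70, T = 30)), col_of(c(A = 200)), thr)
  expect_true(ok$pass)
  expect_equal(ok$tumor_af, 0.30)
  expect_equal(ok$fisher_p, oracle_fisher(30, 70, 0, 200), tolerance = 1e-12)
  # tumor AF 0.04 fails criterion v
  low <- call_somatic_site(col_of(c(A = 96, T = 4)), col_of(c(A = 200)), thr)
  expect_false(low$pass)
  expect_match(low$failed, "tumor_vaf")
  # normal AF 0.06 fails criterion vi
  germ <- call_somatic_site(col_of(c(A = 70, T = 30)),
                            col_of(c(A = 188, T = 12)), thr)
  expect_false(germ$pass)
  expect_match(germ$failed, "normal_vaf")
  # mismatched positions are an input error
  expect_error(call_somatic_site(col_of(c(A = 10)),
                                 col_of(c(A = 10), pos = 101L)),
               "different positions")
})

test_that("calling a sample against itself never passes", {
  set.seed(31)
  for (i in 1:20) {
    counts <- setNames(rpois(4, c(200, 30, 2, 2)), c("A", "T", "C", "G"))
    col <- col_of(counts)
    self <- call_somatic_site(col, col)
    expect_true(all(!self$pass))
    # equal AFs: whenever tumor AF passes, normal AF fails, and p = 1
    expect_true(all(self$fisher_p > 0.5))
  }
})

test_that("germline heterozygous sites (AF 0.5 in both) are excluded", {
  set.seed(17)
  tum <- filter_read_observations(simulate_pileup_site(0.5, 400))
  nor <- filter_read_observations(simulate_pileup_site(0.5, 400))
  res <- call_somatic_site(tum, nor)
  expect_true(all(!res$pass))
  expect_true(all(grepl("normal_vaf", res$failed[res$alt == "T"])))
})

test_that("raising any threshold never increases the number of passing calls", {
  cfg <- simulation_config(n_patients = 1,
                           mutations_per_patient = list(dist = "fixed", n = 6),
                           depth_tumor = 400, depth_normal = 400,
                           n_background_sites = 5, seed = 12)
  co <- simulate_cohort(cfg, scenarios = NULL)
  s <- co$samples$patient_1
  base_n <- nrow(call_patient(s$tumor, s$normal, co$panel, tumor_thresholds()))
  stricter <- list(
    tumor_thresholds(min_mapping_quality = 70),
    tumor_thresholds(min_base_quality = 40),
    tumor_thresholds(max_mismatches = 0),
    tumor_thresholds(min_depth = 1000),
    tumor_thresholds(min_tumor_vaf = 0.4),
    tumor_thresholds(max_normal_vaf = 0),
    tumor_thresholds(max_fisher_p = 1e-30)
  )
  for (thr in stricter) {
    n <- nrow(call_patient(s$tumor, s$normal, co$panel, thr))
    expect_lte(n, base_n)
  }
})

test_that("patient-level calling recovers strong truncal mutations exactly", {
  cfg <- simulation_config(n_patients = 1,
                           mutations_per_patient = list(dist = "fixed", n = 5),
                           vaf_range = c(0.25, 0.25), tumor_purity = 1,
                           depth_tumor = 400, depth_normal = 400,
                           error_rate = 0, n_background_sites = 5, seed = 2)
  co <- simulate_cohort(cfg, scenarios = NULL)
  s <- co$samples$patient_1
  calls <- call_patient(s$tumor, s$normal, co$panel)
  expect_equal(nrow(calls), 5)
  truth_key <- paste(co$ground_truth$chrom, co$ground_truth$pos,
                     co$ground_truth$alt)
  expect_setequal(paste(calls$chrom, calls$pos, calls$alt), truth_key)
  expect_identical(calls$gene,
                   panel_gene_at(co$panel, calls$chrom, calls$pos))
})

test_that("a tumor without mutations yields an empty call set", {
  cfg <- simulation_config(n_patients = 1,
                           mutations_per_patient = list(dist = "fixed", n = 0),
                           depth_tumor = 200, depth_normal = 200,
                           error_rate = 0, n_background_sites = 4, seed = 5)
  co <- simulate_cohort(cfg, scenarios = NULL)
  calls <- call_patient(co$samples$patient_1$tumor,
                        co$samples$patient_1$normal, co$panel)
  expect_equal(nrow(calls), 0)
})

test_that("a passing call outside every panel region is a consistency error", {
  tum <- make_obs(200, c(rep("T", 60), rep("A", 140)), pos = 5L)
  nor <- make_obs(200, "A", pos = 5L)
  expect_error(call_patient(tum, nor, default_panel()), "outside every panel region")
})
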