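test_that("plasma criteria gate detection exactly as printed", {
  thr <- cfdna_thresholds()
  # one supporting read is never enough
  r1 <- cfdna_detect(1, 1000, 0, 1000, thr)
  expect_false(r1$detected)
  expect_match(r1$failed, "supporting_reads")
  # AF exactly 0.0005 (2/4000) passes the inclusive AF bound
  r2 <- cfdna_detect(2, 4000, 0, 4000, thr)
  expect_equal(r2$af, 0.0005)
  expect_false(grepl("cfdna_vaf", r2$failed))
  expect_false(grepl("supporting_reads", r2$failed))
  # ... but its final status is set by the Fisher criterion
  expect_equal(r2$detected, r2$fisher_p < thr$max_fisher_p)
  # depth 99 fails the depth criterion
  r3 <- cfdna_detect(2, 99, 0, 1000, thr)
  expect_false(r3$detected)
  expect_match(r3$failed, "cfdna_depth")
  # zero alt reads: AF 0, not detected
  r4 <- cfdna_detect(0, 5000, 0, 5000, thr)
  expect_equal(r4$af, 0)
  expect_false(r4$detected)
  # a clear signal against a clean deep normal is detected
  r5 <- cfdna_detect(40, 4000, 0, 4000, thr)
  expect_true(r5$detected)
  expect_equal(r5$fisher_p, oracle_fisher(40, 3960, 0, 4000), tolerance = 1e-12)
})

test_that("read-level plasma calling requires the matched normal", {
  site <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
  plasma <- make_obs(150, c(rep("T", 5), rep("A", 145)))
  expect_error(call_cfdna_site(site, plasma, NULL), "normal")
  res <- call_cfdna_site(site, plasma, col_of(c(A = 400)))
  expect_true(res$detected)
  expect_equal(res$alt_count, 5)
  # per-read filters apply before counting support
  low <- make_obs(150, c(rep("T", 5), rep("A", 145)), bq = 10)
  res_low <- call_cfdna_site(site, low, col_of(c(A = 400)))
  expect_equal(res_low$depth, 0)
  expect_false(res_low$detected)
})

test_that("responder trajectories collapse to zero after treatment", {
  cfg <- simulation_config(n_patients = 1,
                           mutations_per_patient = list(dist = "fixed", n = 3),
                           depth_tumor = 600, depth_normal = 600,
                           depth_plasma = 600, error_rate = 0,
                           n_background_sites = 2, seed = 41)
  sc <- list(patient_1 = trajectory_scenario("responder"))
  co <- simulate_cohort(cfg, sc)
  s <- co$samples$patient_1
  calls <- call_patient(s$tumor, s$normal, co$panel)
  expect_gt(nrow(calls), 0)
  traj <- track_patient(calls, s$plasma, s$normal, sc$patient_1$timepoints,
                        patient = "patient_1")
  # one observation per tracked mutation per timepoint
  expect_equal(nrow(traj), nrow(calls) * nrow(sc$patient_1$timepoints))
  post <- traj[traj$month > sc$patient_1$treatment_end_month, ]
  expect_true(all(post$af == 0))
  expect_true(all(!post$detected))
  # and no molecular recurrence is flagged
  conc <- concordance_status(traj)
  expect_gt(nrow(conc), 0)              # shedding at diagnosis
  expect_true(is.na(detect_molecular_recurrence(
    traj, conc, sc$patient_1$treatment_end_month)))
})

test_that("non-shedding tumors are never detected in plasma", {
  cfg <- simulation_config(n_patients = 1,
                           mutations_per_patient = list(dist = "fixed", n = 3),
                           depth_tumor = 600, depth_normal = 600,
                           depth_plasma = 600, error_rate = 0,
                           n_background_sites = 2, seed = 43)
  sc <- list(patient_1 = trajectory_scenario("nonshedding"))
  co <- simulate_cohort(cfg, sc)
  s <- co$samples$patient_1
  calls <- call_patient(s$tumor, s$normal, co$panel)
  traj <- track_patient(calls, s$plasma, s$normal, sc$patient_1$timepoints)
  expect_true(all(!traj$detected))
  expect_true(all(traj$af == 0))
  expect_equal(nrow(concordance_status(traj)), 0)
})

test_that("subclonal mutations give one rising and one flat trajectory", {
  # two tracked mutations; only the first reappears at follow-up
  calls <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A",
                      alt = "T", gene = c("TP53", "NOTCH1"),
                      stringsAsFactors = FALSE)
  tp <- data.frame(label = c("diagnosis", "postop", "followup"),
                   month = c(0, 2, 8))
  shed <- function(pos, n_alt, n_ref)
    make_obs(n_alt + n_ref, c(rep("T", n_alt), rep("A", n_ref)), pos = pos)
  plasma <- list(
    diagnosis = rbind(shed(100L, 30, 270), shed(200L, 25, 275)),
    postop    = rbind(shed(100L, 0, 300), shed(200L, 0, 300)),
    followup  = rbind(shed(100L, 12, 288), shed(200L, 0, 300))
  )
  normal <- rbind(make_obs(400, "A", pos = 100L), make_obs(400, "A", pos = 200L))
  traj <- track_patient(calls, plasma, normal, tp)
  rising <- traj[traj$pos == 100L, ]
  flat <- traj[traj$pos == 200L, ]
  expect_true(rising$detected[rising$month == 8])
  expect_gt(rising$af[rising$month == 8], 0)
  expect_true(all(flat$af[flat$month > 0] == 0))
  expect_true(all(!flat$detected[flat$month > 0]))
  # molecular recurrence driven by the rising clone only
  conc <- concordance_status(traj)
  expect_equal(sort(conc$pos), c(100L, 200L))
  expect_equal(detect_molecular_recurrence(traj, conc, 0), 8)
})

test_that("concordance is decided on the pre-treatment draw", {
  # strong shedding at diagnosis: all truth mutations concordant
  cfg <- simulation_config(n_patients = 1,
                           mutations_per_patient = list(dist = "fixed", n = 4),
                           vaf_range = c(0.5, 0.5), depth_plasma = 3810,
                           depth_tumor = 1000, depth_normal = 1000,
                           error_rate = 1e-4, n_background_sites = 2, seed = 6)
  sc <- list(patient_1 = trajectory_scenario("responder",
                                             baseline_fraction = 0.05))
  co <- simulate_cohort(cfg, sc)
  s <- co$samples$patient_1
  calls <- call_patient(s$tumor, s$normal, co$panel)
  traj <- track_patient(calls, s$plasma, s$normal, sc$patient_1$timepoints)
  conc <- concordance_status(traj)
  expect_equal(nrow(conc), nrow(calls))
  # a missing pre-treatment draw is an input error
  expect_error(concordance_status(traj, "baseline"), "baseline")
  # post-treatment draws never create concordance: drop the diagnosis rows
  # of one mutation whose post-treatment series is all negative
  m1 <- traj$mutation[1]
  sub <- traj[!(traj$mutation == m1 & traj$timepoint == "diagnosis"), ]
  expect_false(m1 %in% concordance_status(
    sub[sub$mutation == m1 | sub$timepoint == "diagnosis", ])$mutation)
})

test_that("molecular recurrence and lead time follow the serial draws", {
  traj <- data.frame(
    mutation = rep(c("m1", "m2"), each = 5),
    month = rep(c(0, 2, 4, 6, 8), 2),
    detected = c(TRUE, FALSE, TRUE, TRUE, TRUE,
                 TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  conc <- data.frame(mutation = c("m1", "m2"), stringsAsFactors = FALSE)
  expect_equal(detect_molecular_recurrence(traj, conc, 2), 4)
  # consecutive rule skips the isolated detection
  expect_equal(detect_molecular_recurrence(traj, conc, 2, rule = "consecutive"), 4)
  single <- traj[traj$mutation == "m2", ]
  expect_equal(detect_molecular_recurrence(single, conc[2, , drop = FALSE], 2), 8)
  expect_true(is.na(detect_molecular_recurrence(
    single, conc[2, , drop = FALSE], 2, rule = "consecutive")))
  # empty concordant set: none
  expect_true(is.na(detect_molecular_recurrence(traj, conc[0, , drop = FALSE], 2)))

  expect_equal(lead_time(3, 12), 9)
  expect_equal(lead_time(6, 12), 6)
  expect_equal(lead_time(12, 12), 0)
  expect_true(is.na(lead_time(NA, 12)))
  expect_warning(lt <- lead_time(14, 12), "negative")
  expect_equal(lt, -2)
})

test_that("detection power matches the closed-form binomial tail", {
  expect_equal(detection_power(0, 0.5, 1000, error_rate = 0), 0)
  expect_gt(detection_power(1, 0.5, 1000, error_rate = 0), 0.999999)
  # threshold: max(2, ceiling(0.0005 * 3810)) = 2 supporting reads
  p <- detection_power(0.001, 0.5, 3810, error_rate = 0)
  expect_equal(p, 1 - pbinom(1, 3810, 0.0005), tolerance = 1e-12)
  # Monte-Carlo agreement at n = 100,000
  set.seed(55)
  x <- rbinom(1e5, 3810, 0.0005)
  mc <- mean(x >= 2)
  expect_lt(abs(mc - p), 4 * sqrt(p * (1 - p) / 1e5))
})

test_that("detection power is monotone in tumor fraction and depth", {
  f <- seq(0, 0.01, length.out = 30)
  pw <- detection_power(f, 0.5, 3810, error_rate = 1e-4)
  expect_true(all(diff(pw) >= -1e-12))
  # in depth, monotone wherever the required read count is constant; the
  # count jumps at ceiling(min_cfdna_vaf * depth) boundaries (4000, 6000, ...)
  d <- seq(100, 4000, by = 100)
  pw_d <- detection_power(0.001, 0.5, d, error_rate = 1e-4)
  expect_true(all(diff(pw_d) >= -1e-12))
  d2 <- seq(4100, 6000, by = 100)
  pw_d2 <- detection_power(0.001, 0.5, d2, error_rate = 1e-4)
  expect_true(all(diff(pw_d2) >= -1e-12))
  # ... and the sawtooth at a boundary is real: 3 reads needed at 4001
  expect_lt(detection_power(0.001, 0.5, 4001, error_rate = 0),
            detection_power(0.001, 0.5, 4000, error_rate = 0))
  expect_true(all(pw >= 0 & pw <= 1))
})

test_that("mean concordant plasma AF tracks the simulated tumor fraction", {
  cfg <- simulation_config(n_patients = 1,
                           mutations_per_patient = list(dist = "fixed", n = 4),
                           vaf_range = c(0.4, 0.5), depth_plasma = 2000,
                           depth_tumor = 800, depth_normal = 800,
                           n_background_sites = 2, seed = 77)
  sc <- list(patient_1 = trajectory_scenario("recurrence", lead_months = 9))
  co <- simulate_cohort(cfg, sc)
  s <- co$samples$patient_1
  calls <- call_patient(s$tumor, s$normal, co$panel)
  traj <- track_patient(calls, s$plasma, s$normal, sc$patient_1$timepoints)
  conc <- concordance_status(traj)
  ctraj <- traj[traj$mutation %in% conc$mutation, ]
  mean_af <- tapply(ctraj$af, ctraj$timepoint, mean)
  frac <- sc$patient_1$tumor_fraction[names(mean_af)]
  expect_gte(cor(mean_af, frac, method = "spearman"), 0.9)
})
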