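# Synthetic cohort generator.
#
# Emulates a tumor-informed ctDNA study: a 53-gene targeted panel sequenced
# to ~3810x mean depth in tumor biopsy, matched normal tissue and serial
# plasma draws; ~4-5 truncal somatic SNVs per patient; plasma tumor
# fractions spanning 0-0.3 with a treatment-induced collapse and an optional
# pre-imaging recurrence ramp; per-base sequencing error ~1e-4-1e-3.
#
# Read-level model: at a site with tracked alt-allele probability p and
# per-base error rate e, each read carries the alt allele with probability
# p (= f*v + e/3 in plasma, where f is the timepoint tumor fraction and v
# the clonal VAF), each of the two remaining non-reference bases with
# probability e/3, and the reference otherwise. Per-site depth is Poisson
# around the configured mean, so AF-threshold boundaries are exercised at
# varying depths.

#' Read-quality model for simulated observations
#'
#' Mapping quality is a point mass at `mq_high` with mass `p_mq_low` at
#' `mq_low`; base quality likewise; per-read mismatch count is Poisson with
#' mean `mismatch_mean` truncated at `mismatch_max`. The low-quality masses
#' sit below the default calling filters, so every per-read filter rejects a
#' nonzero (and testable) fraction of reads.
#'
#' @param mq_high,mq_low,p_mq_low mapping-quality point masses and low-mass weight
#' @param bq_high,bq_low,p_bq_low base-quality point masses and low-mass weight
#' @param mismatch_mean,mismatch_max Poisson mean and truncation point
#' @return classed list
#' @export
quality_model <- function(mq_high = 60, mq_low = 20, p_mq_low = 0.02,
                          bq_high = 30, bq_low = 10, p_bq_low = 0.05,
                          mismatch_mean = 1, mismatch_max = 10) {
  qm <- list(mq_high = mq_high, mq_low = mq_low, p_mq_low = p_mq_low,
             bq_high = bq_high, bq_low = bq_low, p_bq_low = p_bq_low,
             mismatch_mean = mismatch_mean, mismatch_max = mismatch_max)
  for (f in c("p_mq_low", "p_bq_low"))
    if (qm[[f]] < 0 || qm[[f]] > 1)
      stop_input("quality_model: `%s` must lie in [0, 1]", f)
  structure(qm, class = "quality_model")
}

#' Simulation configuration
#'
#' Study-level knobs of the synthetic cohort. Defaults encode the emulated
#' study conditions: 13 patients, Poisson(4.3) truncal mutations per
#' patient, all samples at 3810x mean depth, per-base error 1e-4.
#'
#' @param n_patients number of patients
#' @param mutations_per_patient either a single number (Poisson mean) or a
#'   list `list(dist = "poisson", mean = )` / `list(dist = "fixed", value = )`
#'   (the alias `n` for `value` is also accepted)
#' @param vaf_range range of clonal VAFs (before purity scaling), in (0, 0.5]
#' @param tumor_purity tumor-sample purity in (0, 1]; tumor VAF = clonal
#'   VAF x purity
#' @param depth_tumor,depth_normal,depth_plasma mean sequencing depths
#' @param error_rate per-base miscall probability, in \[0, 0.01\]
#' @param n_background_sites wild-type panel sites simulated per patient in
#'   addition to the mutated sites (exercise the null)
#' @param quality_model a [quality_model()]
#' @param seed integer seed; a fixed seed makes the cohort byte-identical
#'   across runs
#' @return classed list
#' @export
simulation_config <- function(n_patients = 13,
                              mutations_per_patient = list(dist = "poisson", mean = 4.3),
                              vaf_range = c(0.2, 0.5),
                              tumor_purity = 0.5,
                              depth_tumor = 3810,
                              depth_normal = 3810,
                              depth_plasma = 3810,
                              error_rate = 1e-4,
                              n_background_sites = 10,
                              quality_model = plasmatrack::quality_model(),
                              seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop_input("simulation_config: `n_patients` must be >= 1")
  if (is.numeric(mutations_per_patient))
    mutations_per_patient <- list(dist = "poisson", mean = mutations_per_patient)
  if (!is.list(mutations_per_patient) ||
      is.null(mutations_per_patient$dist) ||
      !mutations_per_patient$dist %in% c("poisson", "fixed"))
    stop_input("simulation_config: `mutations_per_patient` dist must be 'poisson' or 'fixed'")
  if (mutations_per_patient$dist == "fixed") {
    # accept `value` or `n` (YAML 1.1 readers turn a bare `n` key into FALSE)
    cnt <- mutations_per_patient$value %||% mutations_per_patient$n %||%
      mutations_per_patient[["FALSE"]]
    if (is.null(cnt) || is.na(cnt) || cnt < 0)
      stop_input("simulation_config: `mutations_per_patient` fixed count must be >= 0")
    mutations_per_patient <- list(dist = "fixed", value = as.integer(cnt))
  } else {
    if (is.null(mutations_per_patient$mean) || mutations_per_patient$mean < 0)
      stop_input("simulation_config: `mutations_per_patient` Poisson mean must be >= 0")
    mutations_per_patient <- list(dist = "poisson",
                                  mean = mutations_per_patient$mean)
  }
  if (!is.numeric(vaf_range) || length(vaf_range) != 2L ||
      vaf_range[1] <= 0 || vaf_range[2] > 0.5 || vaf_range[1] > vaf_range[2])
    stop_input("simulation_config: `vaf_range` must lie in (0, 0.5]")
  if (!is.numeric(tumor_purity) || tumor_purity <= 0 || tumor_purity > 1)
    stop_input("simulation_config: `tumor_purity` must lie in (0, 1]")
  for (f in c("depth_tumor", "depth_normal", "depth_plasma")) {
    v <- get(f)
    if (!is.numeric(v) || v < 1)
      stop_input("simulation_config: `%s` must be >= 1", f)
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 0.01)
    stop_input("simulation_config: `error_rate` must lie in [0, 0.01]")
  if (n_background_sites < 0)
    stop_input("simulation_config: `n_background_sites` must be >= 0")
  if (!inherits(quality_model, "quality_model"))
    stop_input("simulation_config: `quality_model` must be a quality_model()")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_input("simulation_config: `seed` must be a single integer")
  structure(list(
    n_patients = as.integer(n_patients),
    mutations_per_patient = mutations_per_patient,
    vaf_range = vaf_range,
    tumor_purity = tumor_purity,
    depth_tumor = depth_tumor,
    depth_normal = depth_normal,
    depth_plasma = depth_plasma,
    error_rate = error_rate,
    n_background_sites = as.integer(n_background_sites),
    quality_model = quality_model,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# -- trajectory scenarios ------------------------------------------------

#' Plasma tumor-fraction trajectory presets
#'
#' Timepoints follow the sampling schedule of the emulated study: plasma at
#' initial diagnosis, at surgery, at postoperative day 14, and at follow-up
#' visits; offsets are integer calendar months.
#'
#' Presets:
#' \describe{
#'   \item{responder}{fraction collapses to 0 after treatment and stays 0}
#'   \item{recurrence}{0 post-operatively, then monthly follow-up draws with
#'     the fraction rising from `recurrence_fraction / 2` at onset
#'     (`imaging_recurrence_month - lead_months`) to `recurrence_fraction`
#'     at the imaging month}
#'   \item{nonshedding}{0 at every plasma timepoint despite tumor mutations}
#' }
#'
#' @param preset one of `"responder"`, `"recurrence"`, `"nonshedding"`
#' @param imaging_recurrence_month month at which imaging detects recurrence
#'   (recurrence preset only)
#' @param lead_months months by which the fraction starts rising before the
#'   imaging month
#' @param recurrence_fraction plasma tumor fraction reached at the imaging month
#' @param baseline_fraction pre-treatment (diagnosis) plasma tumor fraction
#' @param surgery_fraction fraction at the time-of-surgery draw (post
#'   neoadjuvant chemotherapy)
#' @return a `trajectory_scenario`: list with `timepoints` (label, month),
#'   `tumor_fraction` (per timepoint), `treatment_end_month`,
#'   `imaging_recurrence_month` (`NA` unless recurrence)
#' @examples
#' trajectory_scenario("recurrence", imaging_recurrence_month = 12,
#'                     lead_months = 9)
#' @export
trajectory_scenario <- function(preset = c("responder", "recurrence", "nonshedding"),
                                imaging_recurrence_month = 12,
                                lead_months = 9,
                                recurrence_fraction = 0.02,
                                baseline_fraction = 0.1,
                                surgery_fraction = 0.02) {
  preset <- match.arg(preset)
  surgery_month <- 1; postop_month <- 2
  if (preset %in% c("responder", "nonshedding")) {
    months <- c(0, surgery_month, postop_month, 6, 9, 12)
    labels <- c("diagnosis", "surgery", "postop_d14",
                paste0("followup_m", c(6, 9, 12)))
    frac <- if (preset == "nonshedding") rep(0, length(months))
            else c(baseline_fraction, surgery_fraction, rep(0, 4))
    imaging <- NA_real_
  } else {
    onset <- imaging_recurrence_month - lead_months
    if (onset <= postop_month)
      stop_input("trajectory_scenario: ramp onset (imaging - lead = %g) must fall after the post-operative draw (month %g)",
                 onset, postop_month)
    follow <- seq(postop_month + 1, imaging_recurrence_month)
    months <- c(0, surgery_month, postop_month, follow)
    labels <- c("diagnosis", "surgery", "postop_d14",
                paste0("followup_m", follow))
    ramp <- ifelse(follow < onset, 0,
                   recurrence_fraction *
                     (0.5 + 0.5 * (follow - onset) /
                        max(1, imaging_recurrence_month - onset)))
    frac <- c(baseline_fraction, surgery_fraction, 0, ramp)
    imaging <- imaging_recurrence_month
  }
  validate_scenario(structure(list(
    preset = preset,
    timepoints = data.frame(label = labels, month = months,
                            stringsAsFactors = FALSE),
    tumor_fraction = setNames(frac, labels),
    treatment_end_month = surgery_month,
    imaging_recurrence_month = imaging
  ), class = "trajectory_scenario"))
}

validate_scenario <- function(sc) {
  tf <- sc$tumor_fraction
  if (any(tf < 0 | tf > 1))
    stop_input("trajectory_scenario: tumor fractions must lie in [0, 1]")
  m <- sc$timepoints$month
  if (length(m) < 1L || any(diff(m) <= 0))
    stop_input("trajectory_scenario: month offsets must be strictly increasing")
  if (length(tf) != length(m))
    stop_input("trajectory_scenario: one tumor fraction per timepoint required")
  sc
}

#' Default scenario assignment for a cohort
#'
#' Emulates the monitored cases of the study design: patient 1 has a
#' non-shedding tumor, patients 4 and 6 recur (molecular lead of 9 and 6
#' months respectively), all remaining patients respond without recurrence.
#'
#' @param n_patients cohort size
#' @return named list of [trajectory_scenario()] objects
#' @export
default_scenarios <- function(n_patients = 13) {
  sc <- lapply(seq_len(n_patients), function(i) {
    if (i == 1) trajectory_scenario("nonshedding")
    else if (i == 4) trajectory_scenario("recurrence", lead_months = 9)
    else if (i == 6) trajectory_scenario("recurrence", lead_months = 6)
    else trajectory_scenario("responder")
  })
  names(sc) <- paste0("patient_", seq_len(n_patients))
  sc
}

# -- read-level simulation ----------------------------------------------

# Vectorised read generator over many sites.
# sites: data.frame(chrom, pos, ref, alt); p_alt: per-site tracked-alt
# probability (already including the e/3 error channel for that base).
sim_reads <- function(sites, p_alt, depth_mean, qm, error_rate,
                      poisson_depth = TRUE) {
  n_sites <- nrow(sites)
  depth <- if (poisson_depth) rpois(n_sites, depth_mean)
           else rep.int(as.integer(depth_mean), n_sites)
  idx <- rep.int(seq_len(n_sites), depth)
  n <- length(idx)
  ref <- sites$ref[idx]
  alt <- sites$alt[idx]
  # the two non-ref, non-alt bases at each site
  others <- t(vapply(seq_len(n_sites), function(i)
    setdiff(DNA_BASES, c(sites$ref[i], sites$alt[i]))[1:2], character(2)))
  e3 <- error_rate / 3
  pa <- pmin(p_alt[idx], 1)
  u <- runif(n)
  allele <- ref
  allele[u < pa] <- alt[u < pa]
  s2 <- u >= pa & u < pa + e3
  allele[s2] <- others[idx, 1L][s2]
  s3 <- u >= pa + e3 & u < pa + 2 * e3
  allele[s3] <- others[idx, 2L][s3]
  data.frame(
    chrom = sites$chrom[idx],
    pos = sites$pos[idx],
    ref = ref,
    allele = allele,
    base_quality = ifelse(runif(n) < qm$p_bq_low, qm$bq_low, qm$bq_high),
    mapping_quality = ifelse(runif(n) < qm$p_mq_low, qm$mq_low, qm$mq_high),
    mismatch_count = pmin(rpois(n, qm$mismatch_mean), qm$mismatch_max),
    stringsAsFactors = FALSE
  )
}

#' Simulate read observations at a single site
#'
#' Draws exactly `depth` reads; each carries the alt allele with probability
#' `true_alt_prob` and the reference otherwise, plus base quality, mapping
#' quality and mismatch count from the quality model.
#'
#' @param true_alt_prob probability in \[0, 1\] that a read carries the alt
#' @param depth number of reads (0 gives an empty table, not an error)
#' @param quality_model a [quality_model()]
#' @param seed optional seed set before drawing
#' @param chrom,pos,ref,alt site annotation carried on every read
#' @return read-observation `data.frame` with `depth` rows
#' @export
simulate_pileup_site <- function(true_alt_prob, depth,
                                 quality_model = plasmatrack::quality_model(),
                                 seed = NULL,
                                 chrom = "chr1", pos = 1000L,
                                 ref = "A", alt = "T") {
  if (!is.numeric(true_alt_prob) || true_alt_prob < 0 || true_alt_prob > 1)
    stop_input("simulate_pileup_site: `true_alt_prob` must lie in [0, 1]")
  if (depth < 0) stop_input("simulate_pileup_site: `depth` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  sim_reads(sites, true_alt_prob, depth, quality_model, error_rate = 0,
            poisson_depth = FALSE)
}

#' Simulate alt-supporting read counts over many sites
#'
#' Count-level companion to the read-level generator: per-site depth is
#' Poisson around `depth_mean` (or fixed) and the alt count is binomial with
#' success probability `p_alt`. Useful for Monte-Carlo checks at large site
#' counts where materialising individual reads would be wasteful.
#'
#' @param n_sites number of independent sites
#' @param depth_mean mean depth
#' @param p_alt per-read alt probability (scalar or length `n_sites`)
#' @param poisson_depth draw depth from Poisson (default) or keep it fixed
#' @return `data.frame` with columns `depth`, `alt_count`
#' @export
simulate_site_counts <- function(n_sites, depth_mean, p_alt,
                                 poisson_depth = TRUE) {
  depth <- if (poisson_depth) rpois(n_sites, depth_mean)
           else rep.int(as.integer(depth_mean), n_sites)
  data.frame(depth = depth, alt_count = rbinom(n_sites, depth, p_alt))
}

# -- ground truth --------------------------------------------------------

# Gene-sampling weights: TP53 carries 0.4 of the mass (emulating its ~92%
# patient prevalence in the cohort), the rest is uniform.
gene_weights <- function(genes) {
  i <- match("TP53", genes)
  if (is.na(i) || length(genes) == 1L)
    return(rep(1 / length(genes), length(genes)))
  w <- rep(0.6 / (length(genes) - 1), length(genes))
  w[i] <- 0.4
  w
}

sim_ground_truth_patient <- function(patient, n_mut, panel, config) {
  if (n_mut == 0L)
    return(data.frame(patient = character(), gene = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vaf = numeric(), stringsAsFactors = FALSE))
  w <- gene_weights(panel$gene)
  rows <- sample.int(nrow(panel), n_mut, replace = TRUE, prob = w)
  # distinct positions within each gene region
  pos <- integer(n_mut)
  for (g in unique(rows)) {
    k <- which(rows == g)
    span <- panel$start[g]:panel$end[g]
    pos[k] <- sample(span, min(length(k), length(span)))
  }
  ref <- sample(DNA_BASES, n_mut, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
  data.frame(
    patient = patient,
    gene = panel$gene[rows],
    chrom = panel$chrom[rows],
    pos = pos,
    ref = ref,
    alt = unname(alt),
    vaf = runif(n_mut, config$vaf_range[1], config$vaf_range[2]),
    stringsAsFactors = FALSE
  )
}

sim_background_sites <- function(truth, n_bg, panel) {
  if (n_bg == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  rows <- sample.int(nrow(panel), n_bg, replace = TRUE)
  pos <- panel$start[rows] +
    vapply(rows, function(g) sample.int(panel$end[g] - panel$start[g] + 1L, 1L) - 1L,
           integer(1))
  keep <- !(paste(panel$chrom[rows], pos) %in% paste(truth$chrom, truth$pos))
  ref <- sample(DNA_BASES, n_bg, replace = TRUE)
  # designate one non-ref base as the tracked "alt" channel; with p_alt =
  # error/3 this is equivalent to a uniform e/3 miscall toward each alternate
  alt <- vapply(ref, function(r) setdiff(DNA_BASES, r)[1], character(1))
  out <- data.frame(chrom = panel$chrom[rows], pos = pos, ref = ref,
                    alt = unname(alt), stringsAsFactors = FALSE)
  out[keep & !duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
}

# -- cohort --------------------------------------------------------------

#' Simulate a full tumor/normal/plasma cohort
#'
#' Generates ground-truth truncal mutations for every patient, then
#' read-observation tables for the tumor biopsy, the matched normal tissue,
#' and one plasma draw per scenario timepoint. Plasma alt draws are binomial
#' with success probability `f * v + e/3` (tumor fraction x clonal VAF plus
#' the error channel); tumor alt probability is `v * purity + e/3`; the
#' normal carries error only.
#'
#' @param config a [simulation_config()]
#' @param scenarios named list of [trajectory_scenario()]s, one per patient
#'   (`NULL` simulates tumor/normal only), default [default_scenarios()]
#' @param panel panel `data.frame` (default [default_panel()])
#' @return object of class `ctdna_cohort`: list with `ground_truth`,
#'   `samples` (per patient: `tumor`, `normal`, `plasma` list by timepoint),
#'   `scenarios`, `panel`, `config`
#' @examples
#' cfg <- simulation_config(n_patients = 2, depth_tumor = 200,
#'                          depth_normal = 200, depth_plasma = 200, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' head(cohort$ground_truth)
#' @export
simulate_cohort <- function(config = simulation_config(),
                            scenarios = default_scenarios(config$n_patients),
                            panel = default_panel()) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  panel <- validate_panel(panel)
  if (!is.null(scenarios)) {
    if (length(scenarios) != config$n_patients)
      stop_input("simulate_cohort: need one scenario per patient (%d given, %d patients)",
                 length(scenarios), config$n_patients)
    for (sc in scenarios) {
      if (!inherits(sc, "trajectory_scenario"))
        stop_input("simulate_cohort: scenarios must be trajectory_scenario objects")
      if (nrow(sc$timepoints) < 1L)
        stop_input("simulate_cohort: scenario with no timepoints")
    }
  }
  set.seed(config$seed)
  ids <- paste0("patient_", seq_len(config$n_patients))
  mp <- config$mutations_per_patient
  n_mut <- if (mp$dist == "poisson") rpois(config$n_patients, mp$mean)
           else rep.int(mp$value, config$n_patients)
  qm <- config$quality_model
  e <- config$error_rate

  truth_list <- vector("list", config$n_patients)
  samples <- vector("list", config$n_patients)
  names(samples) <- ids
  for (i in seq_len(config$n_patients)) {
    truth <- sim_ground_truth_patient(ids[i], n_mut[i], panel, config)
    truth_list[[i]] <- truth
    bg <- sim_background_sites(truth, config$n_background_sites, panel)
    sites <- rbind(truth[c("chrom", "pos", "ref", "alt")], bg)
    vaf <- c(truth$vaf, rep(0, nrow(bg)))
    p_tumor <- vaf * config$tumor_purity + e / 3
    p_null <- rep(e / 3, nrow(sites))
    tumor <- sim_reads(sites, p_tumor, config$depth_tumor, qm, e)
    normal <- sim_reads(sites, p_null, config$depth_normal, qm, e)
    plasma <- NULL
    if (!is.null(scenarios)) {
      sc <- scenarios[[i]]
      plasma <- lapply(seq_len(nrow(sc$timepoints)), function(t) {
        f <- sc$tumor_fraction[t]
        p_plasma <- f * vaf + e / 3
        sim_reads(sites, p_plasma, config$depth_plasma, qm, e)
      })
      names(plasma) <- sc$timepoints$label
    }
    samples[[i]] <- list(tumor = tumor, normal = normal, plasma = plasma)
  }
  structure(list(
    ground_truth = do.call(rbind, truth_list),
    samples = samples,
    scenarios = scenarios,
    panel = panel,
    config = config
  ), class = "ctdna_cohort")
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat(sprintf("ctdna_cohort: %d patients, %d ground-truth mutations, %d panel genes\n",
              x$config$n_patients, nrow(x$ground_truth), nrow(x$panel)))
  if (!is.null(x$scenarios)) {
    tab <- table(vapply(x$scenarios, function(s) s$preset, character(1)))
    cat("scenarios:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
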