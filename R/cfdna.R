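# Tumor-informed mutation detection in plasma cfDNA.
#
# Plasma calling is restricted to positions already mutated in the
# patient's tumor. A tracked mutation is detected in a draw when, after the
# per-read filters: filtered depth >= 100, AF >= 0.0005 (inclusive),
# supporting reads >= 2, and the one-sided Fisher exact p against the
# matched normal-tissue pileup is < 0.05. The normal tissue is the only
# germline comparator available, hence it anchors criterion (vii).

#' Count-level cfDNA detection
#'
#' Vectorised core of the plasma criteria (iv)-(vii) given already-filtered
#' counts. Used by [call_cfdna_site()] and convenient for Monte-Carlo
#' studies at many sites.
#'
#' @param alt_count,depth filtered plasma alt-supporting reads and depth
#' @param normal_alt,normal_depth filtered counts in the matched normal
#' @param thresholds a [cfdna_thresholds()]
#' @param alternative Fisher sidedness, see [fisher_exact_2x2()]
#' @return `data.frame` with `af`, `fisher_p`, `detected`, `failed`
#' @export
cfdna_detect <- function(alt_count, depth, normal_alt, normal_depth,
                         thresholds = cfdna_thresholds(),
                         alternative = "greater") {
  n <- max(length(alt_count), length(depth),
           length(normal_alt), length(normal_depth))
  alt_count <- rep_len(alt_count, n); depth <- rep_len(depth, n)
  normal_alt <- rep_len(normal_alt, n); normal_depth <- rep_len(normal_depth, n)
  if (any(c(alt_count, depth, normal_alt, normal_depth) < 0))
    stop_input("cfdna_detect: counts must be >= 0")
  if (any(alt_count > depth))
    stop_input("cfdna_detect: alt_count exceeds depth")
  af <- ifelse(depth > 0, alt_count / depth, 0)
  tot <- alt_count + depth - alt_count + normal_alt + normal_depth - normal_alt
  p <- rep(1, n)
  pos <- tot > 0
  p[pos] <- fisher_exact_2x2(alt_count[pos], depth[pos] - alt_count[pos],
                             normal_alt[pos], normal_depth[pos] - normal_alt[pos],
                             alternative = alternative)
  fail_depth <- depth < thresholds$min_depth
  fail_af <- af < thresholds$min_cfdna_vaf
  fail_reads <- alt_count < thresholds$min_supporting_reads
  fail_p <- !(p < thresholds$max_fisher_p)
  failed <- vapply(seq_len(n), function(i)
    paste(c(if (fail_depth[i]) "cfdna_depth",
            if (fail_af[i]) "cfdna_vaf",
            if (fail_reads[i]) "supporting_reads",
            if (fail_p[i]) "fisher_p"), collapse = ";"),
    character(1))
  data.frame(
    alt_count = alt_count, depth = depth, af = af, fisher_p = p,
    detected = !(fail_depth | fail_af | fail_reads | fail_p),
    failed = failed, stringsAsFactors = FALSE
  )
}

#' Detect one tracked mutation in one plasma draw
#'
#' Filters the plasma read observations at the tracked site and applies the
#' plasma criteria against the matched normal pileup.
#'
#' @param site list or one-row `data.frame` with `chrom`, `pos`, `ref`,
#'   `alt` (the tumor-identified mutation)
#' @param plasma_obs read observations at the site for one plasma draw
#' @param normal a [pileup_column()] for the matched normal tissue at the
#'   site (required)
#' @param thresholds a [cfdna_thresholds()]
#' @param alternative Fisher sidedness
#' @return one-row `data.frame`: site fields plus `alt_count`, `depth`,
#'   `af`, `fisher_p`, `detected`, `failed`
#' @export
call_cfdna_site <- function(site, plasma_obs, normal,
                            thresholds = cfdna_thresholds(),
                            alternative = "greater") {
  if (missing(normal) || is.null(normal) || !inherits(normal, "pileup_column"))
    stop_input("call_cfdna_site: a matched normal pileup_column is required")
  if (is.null(site$alt) || is.null(site$ref) || site$alt == site$ref)
    stop_input("call_cfdna_site: site must carry ref and a distinct alt allele")
  col <- filter_read_observations(plasma_obs, thresholds)
  if (nrow(plasma_obs) > 0 &&
      (!isTRUE(col$chrom == site$chrom) || !isTRUE(col$pos == site$pos)))
    stop_input("call_cfdna_site: plasma observations are not at the tracked site")
  res <- cfdna_detect(unname(col$counts[site$alt]), col$depth,
                      unname(normal$counts[site$alt]),
                      normal$depth, thresholds, alternative)
  cbind(data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
                   alt = site$alt, stringsAsFactors = FALSE),
        res)
}

#' Build serial plasma trajectories for one patient
#'
#' For every tumor call and every plasma timepoint, runs
#' [call_cfdna_site()] and assembles the ordered allele-frequency series.
#' Mutations never seen in plasma are retained as all-negative series.
#'
#' @param calls passing tumor calls for the patient (`data.frame` with
#'   `chrom`, `pos`, `ref`, `alt` and optionally `gene`)
#' @param plasma_samples named list of read-observation tables, one per
#'   timepoint label
#' @param normal_obs read-observation table for the matched normal tissue
#' @param timepoints `data.frame` with `label` and `month`, ordered by month;
#'   labels must match `names(plasma_samples)`
#' @param thresholds a [cfdna_thresholds()]
#' @param alternative Fisher sidedness
#' @param patient optional patient id carried on every row
#' @return trajectory `data.frame`: one row per tracked mutation per
#'   timepoint with `mutation`, `timepoint`, `month`, `alt_count`, `depth`,
#'   `af`, `fisher_p`, `detected`
#' @export
track_patient <- function(calls, plasma_samples, normal_obs, timepoints,
                          thresholds = cfdna_thresholds(),
                          alternative = "greater", patient = NA_character_) {
  if (nrow(calls) < 1L)
    stop_input("track_patient: at least one tumor call is required")
  if (length(plasma_samples) < 1L)
    stop_input("track_patient: at least one plasma timepoint is required")
  if (!all(c("label", "month") %in% names(timepoints)))
    stop_input("track_patient: `timepoints` needs columns label, month")
  if (any(diff(timepoints$month) <= 0))
    stop_input("track_patient: timepoint months must be strictly increasing")
  miss <- setdiff(timepoints$label, names(plasma_samples))
  if (length(miss))
    stop_input("track_patient: no plasma sample for timepoint(s) %s",
               paste(miss, collapse = ", "))
  normal_sites <- split_by_site(validate_observations(normal_obs))
  plasma_sites <- lapply(plasma_samples, function(s)
    split_by_site(validate_observations(s)))
  empty_obs <- validate_observations(
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               allele = character(), base_quality = numeric(),
               mapping_quality = numeric(), mismatch_count = numeric(),
               stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    site <- calls[i, ]
    key <- paste(site$chrom, site$pos)
    n_obs <- normal_sites[[key]]
    n_col <- if (is.null(n_obs)) pileup_column(site$chrom, site$pos, site$ref)
             else filter_read_observations(n_obs, thresholds)
    per_tp <- lapply(seq_len(nrow(timepoints)), function(t) {
      lab <- timepoints$label[t]
      p_obs <- plasma_sites[[lab]][[key]]
      if (is.null(p_obs)) p_obs <- empty_obs
      out <- call_cfdna_site(site, p_obs, n_col, thresholds, alternative)
      out$timepoint <- lab
      out$month <- timepoints$month[t]
      out
    })
    tp <- do.call(rbind, per_tp)
    tp$gene <- if ("gene" %in% names(site)) site$gene else NA_character_
    tp
  })
  traj <- do.call(rbind, rows)
  traj$patient <- patient
  traj$mutation <- mutation_id(traj$gene, traj$chrom, traj$pos,
                               traj$ref, traj$alt)
  traj <- traj[order(traj$mutation, traj$month), , drop = FALSE]
  rownames(traj) <- NULL
  class(traj) <- c("ctdna_trajectories", "data.frame")
  traj
}

#' Concordant mutations between tumor and pre-treatment plasma
#'
#' A tumor call is concordant when it is detected in the designated
#' pre-treatment plasma draw. Post-treatment detections do not create new
#' concordant mutations.
#'
#' @param trajectories output of [track_patient()]
#' @param pretreatment_label label of the pre-treatment draw
#'   (default `"diagnosis"`)
#' @return `data.frame` of concordant mutations (`mutation`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`), zero rows when none
#' @export
concordance_status <- function(trajectories, pretreatment_label = "diagnosis") {
  pre <- trajectories[trajectories$timepoint == pretreatment_label, , drop = FALSE]
  if (nrow(pre) == 0L)
    stop_input("concordance_status: no plasma draw labelled '%s'",
               pretreatment_label)
  conc <- pre[pre$detected, c("mutation", "chrom", "pos", "ref", "alt", "gene"),
              drop = FALSE]
  rownames(conc) <- NULL
  conc
}

#' Earliest post-treatment month with a detected concordant mutation
#'
#' Operationalises molecular recurrence as: at least one concordant mutation
#' detected (plasma criteria) at a draw strictly after treatment end. The
#' `"consecutive"` rule additionally requires detection at two consecutive
#' draws and reports the first month of the pair.
#'
#' @param trajectories output of [track_patient()]
#' @param concordant concordant mutation set from [concordance_status()]
#' @param treatment_end_month last month of treatment (e.g. surgery)
#' @param rule `"any"` (default) or `"consecutive"`
#' @return the molecular-recurrence month, or `NA` if never
#' @export
detect_molecular_recurrence <- function(trajectories, concordant,
                                        treatment_end_month,
                                        rule = c("any", "consecutive")) {
  rule <- match.arg(rule)
  if (nrow(concordant) == 0L) return(NA_real_)
  post <- trajectories[trajectories$mutation %in% concordant$mutation &
                         trajectories$month > treatment_end_month, ,
                       drop = FALSE]
  if (nrow(post) == 0L) return(NA_real_)
  if (rule == "any") {
    hits <- post$month[post$detected]
    return(if (length(hits)) min(hits) else NA_real_)
  }
  cand <- Inf
  for (m in unique(post$mutation)) {
    s <- post[post$mutation == m, , drop = FALSE]
    s <- s[order(s$month), ]
    ok <- s$detected[-nrow(s)] & s$detected[-1L]
    if (any(ok)) cand <- min(cand, s$month[which(ok)[1]])
  }
  if (is.finite(cand)) cand else NA_real_
}

#' Lead time of molecular over imaging recurrence
#'
#' @param molecular_month month of molecular recurrence
#' @param imaging_month month of imaging-detected recurrence
#' @return `imaging_month - molecular_month` in months; `NA` if either is
#'   missing; a negative value (molecular after imaging) is returned with a
#'   warning rather than an error
#' @examples
#' lead_time(3, 12)  # 9
#' @export
lead_time <- function(molecular_month, imaging_month) {
  if (is.na(molecular_month) || is.na(imaging_month)) return(NA_real_)
  lt <- imaging_month - molecular_month
  if (lt < 0)
    warning("molecular recurrence called after imaging recurrence (negative lead time)")
  lt
}

#' Analytic detection power of the plasma read-count criteria
#'
#' Probability that the alt-supporting read count reaches
#' `max(min_supporting_reads, ceiling(min_cfdna_vaf * depth))` under
#' `Binomial(depth, f * v + e/3)`. The Fisher criterion is ignored, so this
#' is an upper bound on full detection power. Vectorised over
#' `tumor_fraction` and `depth`.
#'
#' @param tumor_fraction plasma tumor fraction(s) in \[0, 1\]
#' @param clonal_vaf clonal VAF of the tracked mutation
#' @param depth plasma depth(s)
#' @param error_rate per-base miscall probability
#' @param thresholds a [cfdna_thresholds()]
#' @return detection probability in \[0, 1\]
#' @export
detection_power <- function(tumor_fraction, clonal_vaf, depth,
                            error_rate = 0,
                            thresholds = cfdna_thresholds()) {
  if (any(tumor_fraction < 0 | tumor_fraction > 1))
    stop_input("detection_power: `tumor_fraction` must lie in [0, 1]")
  if (any(clonal_vaf < 0 | clonal_vaf > 1))
    stop_input("detection_power: `clonal_vaf` must lie in [0, 1]")
  if (any(depth < 0)) stop_input("detection_power: `depth` must be >= 0")
  p <- pmin(tumor_fraction * clonal_vaf + error_rate / 3, 1)
  k <- pmax(thresholds$min_supporting_reads,
            ceiling(thresholds$min_cfdna_vaf * depth))
  pbinom(k - 1, depth, p, lower.tail = FALSE)
}
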