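# End-to-end pipeline: simulate -> call-tumor -> call-cfdna -> monitor ->
# metrics. Every artifact is a plain-text table; the run log captures the
# seed, versions and thresholds (and nothing time-dependent, so reruns of
# the same config are byte-identical).

#' Pipeline configuration
#'
#' @param sim a [simulation_config()]
#' @param scenarios `"default"` ([default_scenarios()]), `NULL` (no plasma,
#'   monitoring skipped), or a named list of [trajectory_scenario()]s
#' @param panel panel `data.frame`
#' @param tumor_thr a [tumor_thresholds()]
#' @param cfdna_thr a [cfdna_thresholds()]
#' @param diagnostic_genes genes tabulated in the diagnostic-accuracy table
#' @param percent_mode `"truncate"` or `"round"`
#' @param alternative Fisher sidedness used throughout
#' @param recurrence_rule molecular-recurrence rule, `"any"` or
#'   `"consecutive"` (see [detect_molecular_recurrence()])
#' @param write_observations also dump every simulated read-observation TSV
#' @return classed list
#' @export
pipeline_config <- function(sim = simulation_config(),
                            scenarios = "default",
                            panel = default_panel(),
                            tumor_thr = tumor_thresholds(),
                            cfdna_thr = cfdna_thresholds(),
                            diagnostic_genes = c("TP53", "FAT3", "MLL3", "AJUBA"),
                            percent_mode = c("truncate", "round"),
                            alternative = c("greater", "two.sided"),
                            recurrence_rule = c("any", "consecutive"),
                            write_observations = FALSE) {
  if (!inherits(sim, "simulation_config")) sim <- do.call(simulation_config, sim)
  if (identical(scenarios, "default"))
    scenarios <- default_scenarios(sim$n_patients)
  structure(list(
    sim = sim, scenarios = scenarios, panel = validate_panel(panel),
    tumor_thr = tumor_thr, cfdna_thr = cfdna_thr,
    diagnostic_genes = diagnostic_genes,
    percent_mode = match.arg(percent_mode),
    alternative = match.arg(alternative),
    recurrence_rule = match.arg(recurrence_rule),
    write_observations = isTRUE(write_observations)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level blocks mirror [pipeline_config()]: `sim` (fields of
#' [simulation_config()]), `tumor_thresholds`, `cfdna_thresholds`,
#' `diagnostic_genes`, `percent_mode`, `alternative`, `recurrence_rule`,
#' `panel_bed` (path), `write_observations`. Missing blocks fall back to
#' defaults.
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (is.null(y$sim)) simulation_config()
         else do.call(simulation_config, y$sim)
  pipeline_config(
    sim = sim,
    scenarios = y$scenarios %||% "default",
    panel = if (is.null(y$panel_bed)) default_panel()
            else read_panel_bed(file.path(dirname(path), y$panel_bed)),
    tumor_thr = do.call(tumor_thresholds, y$tumor_thresholds %||% list()),
    cfdna_thr = do.call(cfdna_thresholds, y$cfdna_thresholds %||% list()),
    diagnostic_genes = y$diagnostic_genes %||% c("TP53", "FAT3", "MLL3", "AJUBA"),
    percent_mode = y$percent_mode %||% "truncate",
    alternative = y$alternative %||% "greater",
    recurrence_rule = y$recurrence_rule %||% "any",
    write_observations = y$write_observations %||% FALSE
  )
}

pipeline_log <- function(config) {
  c(sprintf("plasmatrack %s", as.character(packageVersion("plasmatrack"))),
    R.version.string,
    sprintf("seed: %d", config$sim$seed),
    "tumor thresholds:",
    sprintf("  %s: %g", names(config$tumor_thr), unlist(config$tumor_thr)),
    "cfdna thresholds:",
    sprintf("  %s: %g", names(config$cfdna_thr), unlist(config$cfdna_thr)),
    "simulation:",
    sprintf("  n_patients: %d", config$sim$n_patients),
    sprintf("  depths (tumor/normal/plasma): %g/%g/%g",
            config$sim$depth_tumor, config$sim$depth_normal,
            config$sim$depth_plasma),
    sprintf("  error_rate: %g", config$sim$error_rate),
    sprintf("  tumor_purity: %g", config$sim$tumor_purity),
    sprintf("percent_mode: %s", config$percent_mode),
    sprintf("alternative: %s", config$alternative),
    sprintf("recurrence_rule: %s", config$recurrence_rule))
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort, calls tumor somatic mutations per patient, tracks
#' them through the serial plasma draws, flags molecular recurrence with
#' lead time against the scenario's imaging month, and writes the
#' diagnostic-accuracy and cohort-summary tables.
#'
#' Artifacts written to `out_dir`: `calls.tsv`, `calls/<patient>.vcf`,
#' `trajectories.tsv`, `monitoring_report.tsv`, `metrics.tsv`,
#' `gene_frequency.tsv`, `cohort_summary.tsv`, `ground_truth.tsv`,
#' `run_log.txt` (plus per-sample observation TSVs under `observations/`
#' when `write_observations` is set).
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @param quiet suppress progress messages
#' @return invisibly, a list with `cohort`, `calls`, `trajectories`,
#'   `monitoring`, `metrics`, `summary`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[simulate] %d patients, seed %d", config$sim$n_patients, config$sim$seed)
  cohort <- simulate_cohort(config$sim, config$scenarios, config$panel)
  write_tsv(cohort$ground_truth, file.path(out_dir, "ground_truth.tsv"))
  if (config$write_observations)
    write_cohort(cohort, file.path(out_dir, "observations"))

  say("[call-tumor] somatic calling in %d patients", length(cohort$samples))
  dir.create(file.path(out_dir, "calls"), showWarnings = FALSE)
  calls_by_patient <- lapply(names(cohort$samples), function(p) {
    s <- cohort$samples[[p]]
    calls <- call_patient(s$tumor, s$normal, cohort$panel, config$tumor_thr,
                          config$alternative)
    write_vcf(calls, file.path(out_dir, "calls", paste0(p, ".vcf")))
    if (nrow(calls)) calls$patient <- p else calls$patient <- character(0)
    calls
  })
  names(calls_by_patient) <- names(cohort$samples)
  all_calls <- do.call(rbind, calls_by_patient)
  rownames(all_calls) <- NULL
  write_tsv(all_calls, file.path(out_dir, "calls.tsv"))

  have_plasma <- !is.null(cohort$scenarios) &&
    any(vapply(cohort$samples, function(s) length(s$plasma) > 0, logical(1)))
  traj_all <- NULL; monitoring <- NULL
  empty_conc <- data.frame(mutation = character(), chrom = character(),
                           pos = numeric(), ref = character(),
                           alt = character(), gene = character(),
                           patient = character(), stringsAsFactors = FALSE)
  concordant_by_patient <- lapply(calls_by_patient, function(x) empty_conc)
  if (!have_plasma) {
    warning("run_pipeline: no plasma samples; monitoring stage skipped")
  } else {
    say("[call-cfdna/monitor] tracking serial plasma draws")
    mon_rows <- list()
    traj_list <- list()
    for (p in names(cohort$samples)) {
      s <- cohort$samples[[p]]
      sc <- cohort$scenarios[[p]]
      calls <- calls_by_patient[[p]]
      imaging <- sc$imaging_recurrence_month
      if (nrow(calls) == 0L || is.null(s$plasma)) {
        mon_rows[[p]] <- data.frame(
          patient = p, n_tumor_mutations = nrow(calls), n_concordant = 0L,
          molecular_recurrence_month = NA_real_,
          imaging_recurrence_month = imaging,
          lead_time_months = NA_real_, stringsAsFactors = FALSE)
        next
      }
      traj <- track_patient(calls, s$plasma, s$normal, sc$timepoints,
                            config$cfdna_thr, config$alternative, patient = p)
      conc <- concordance_status(traj, pretreatment_label = sc$timepoints$label[1])
      conc$patient <- if (nrow(conc)) p else character(0)
      concordant_by_patient[[p]] <- conc
      mol <- detect_molecular_recurrence(traj, conc, sc$treatment_end_month,
                                         config$recurrence_rule)
      mon_rows[[p]] <- data.frame(
        patient = p, n_tumor_mutations = nrow(calls), n_concordant = nrow(conc),
        molecular_recurrence_month = mol,
        imaging_recurrence_month = imaging,
        lead_time_months = lead_time(mol, imaging), stringsAsFactors = FALSE)
      traj_list[[p]] <- traj
    }
    traj_all <- do.call(rbind, traj_list)
    rownames(traj_all) <- NULL
    monitoring <- do.call(rbind, mon_rows)
    rownames(monitoring) <- NULL
    write_tsv(traj_all, file.path(out_dir, "trajectories.tsv"))
    write_tsv(monitoring, file.path(out_dir, "monitoring_report.tsv"))
  }

  say("[metrics] diagnostic accuracy over %s",
      paste(config$diagnostic_genes, collapse = ", "))
  statuses <- do.call(rbind, lapply(names(cohort$samples), function(p) {
    do.call(rbind, lapply(config$diagnostic_genes, function(g) {
      st <- patient_gene_status(calls_by_patient[[p]],
                                concordant_by_patient[[p]], g, cohort$panel)
      data.frame(patient = p, gene = g,
                 tumor_mutant = st[["tumor_mutant"]],
                 cfdna_positive = st[["cfdna_positive"]],
                 stringsAsFactors = FALSE)
    }))
  }))
  metrics <- diagnostic_metrics(
    build_contingency(statuses, config$diagnostic_genes), config$percent_mode)
  write_tsv(metrics, file.path(out_dir, "metrics.tsv"))

  all_conc <- do.call(rbind, concordant_by_patient)
  summary <- cohort_summary(all_calls, all_conc, names(cohort$samples))
  write_tsv(summary$gene_frequency, file.path(out_dir, "gene_frequency.tsv"))
  scalar <- summary[setdiff(names(summary), "gene_frequency")]
  write_tsv(data.frame(key = names(scalar),
                       value = unlist(lapply(scalar, as.character)),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "cohort_summary.tsv"))

  writeLines(pipeline_log(config), file.path(out_dir, "run_log.txt"))
  say("[done] artifacts in %s", out_dir)
  invisible(list(cohort = cohort, calls = all_calls, trajectories = traj_all,
                 monitoring = monitoring, metrics = metrics,
                 summary = summary, statuses = statuses))
}
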