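#' Run the end-to-end workflow from a configuration
#'
#' Orchestrates the stages in order — panel design, acquisition
#' scheduling, synthetic-data generation (or reading a measured transition
#' report), quantification and protein-mRNA correlation — persisting every
#' intermediate table as CSV under `out_dir` and writing a run manifest
#' (JSON) listing inputs, the config hash, the seed, package version and
#' every file written. Reruns with the same config and seed produce
#' byte-identical result files.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   named list. Recognised keys: `seed`, `control_condition`,
#'   `report` (optional path to a measured transition report; when absent
#'   a synthetic time course is generated), `ct` (optional Ct table path),
#'   `snr_threshold`, `fdr_alpha`, `window_width`, `dwell_time`,
#'   `max_cycle_time`, `gradient_length`, `replicates`. Unknown keys are
#'   an error (strict mode).
#' @param out_dir Output directory.
#' @param overrides Named list of config overrides (flags win over file).
#' @return A `run_manifest` list, invisibly; results live in `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = "srmflow_out",
                         overrides = list()) {
  config_path <- NA_character_
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config_path)
    if (is.null(config)) config <- list()
  }
  known <- c("seed", "control_condition", "report", "ct", "snr_threshold",
             "fdr_alpha", "window_width", "dwell_time", "max_cycle_time",
             "gradient_length", "replicates")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config[names(overrides)] <- overrides
  get_opt <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  seed <- as.integer(get_opt("seed", 1L))
  control <- get_opt("control_condition", "NSC")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] rows in: %s, rows out: %s", stage,
                    format(n_in), format(n_out)))
  }

  # --- design ---------------------------------------------------------
  panel <- default_panel()
  validation <- validate_panel(panel)
  if (!validation$valid) stop("default panel failed validation",
                              call. = FALSE)
  p <- file.path(out_dir, "panel.csv")
  write_transition_list(panel, p); outputs <- c(outputs, p)
  log_stage("design", nrow(panel$transitions), nrow(panel$transitions))

  # --- schedule -------------------------------------------------------
  sched_cfg <- schedule_config(
    window_width = get_opt("window_width", 4),
    dwell_time = get_opt("dwell_time", 0.010),
    max_cycle_time = get_opt("max_cycle_time", 1.7),
    gradient_length = get_opt("gradient_length", 30))
  cal <- structure(list(slope = 0.28, intercept = 2, residual_sd = 0,
                        n_points = 2L), class = "rt_calibration")
  method <- assign_windows(panel, cal, sched_cfg)
  p <- file.path(out_dir, "scheduled_method.csv")
  write_scheduled_method(method, p); outputs <- c(outputs, p)
  log_stage("schedule", nrow(panel$transitions), nrow(method$entries))

  # --- simulate / read ------------------------------------------------
  if (!is.null(config$report)) {
    report <- read_transition_report(config$report)
    ct <- if (!is.null(config$ct)) read_ct_table(config$ct) else NULL
    truth <- NULL
  } else {
    sim <- generate_timecourse(simulation_config(
      panel = panel, replicates = get_opt("replicates", 4L),
      control_condition = control, seed = seed))
    report <- sim$report; ct <- sim$ct; truth <- sim$truth
    p <- file.path(out_dir, "report.csv")
    utils::write.csv(report, p, row.names = FALSE); outputs <- c(outputs, p)
    p <- file.path(out_dir, "ct.csv")
    utils::write.csv(ct, p, row.names = FALSE); outputs <- c(outputs, p)
    p <- file.path(out_dir, "truth.csv")
    utils::write.csv(truth, p, row.names = FALSE); outputs <- c(outputs, p)
  }
  log_stage("simulate", NA_integer_, nrow(report))

  # --- quantify -------------------------------------------------------
  qcfg <- quant_config(snr_threshold = get_opt("snr_threshold", 3),
                       fdr_alpha = get_opt("fdr_alpha", 0.05),
                       control_condition = control)
  result <- quantify_experiment(report, qcfg)
  outputs <- c(outputs, write_quant_results(result,
                                            file.path(out_dir, "quant")))
  log_stage("quantify", nrow(report),
            if (is.null(result$comparisons)) 0L else nrow(result$comparisons))

  # --- correlate ------------------------------------------------------
  if (!is.null(ct)) {
    qp <- qpcr_config()
    dct <- dct_table(ct, qp)
    dct_summary <- do.call(rbind, lapply(
      split(dct, list(dct$gene, dct$condition), drop = TRUE),
      function(d) cbind(data.frame(gene = d$gene[1],
                                   condition = d$condition[1],
                                   stringsAsFactors = FALSE),
                        summarize_dct(d$dct, qp$ci_level))))
    names(dct_summary)[names(dct_summary) == "mean"] <- "mean_dct"
    p <- file.path(out_dir, "dct_summary.csv")
    utils::write.csv(dct_summary[order(dct_summary$gene,
                                       dct_summary$condition), ],
                     p, row.names = FALSE)
    outputs <- c(outputs, p)

    corr <- correlate_abundance_dct(result, dct, conditions_order =
                                      unique(report$condition))
    p <- file.path(out_dir, "correlations.csv")
    utils::write.csv(corr, p, row.names = FALSE)
    outputs <- c(outputs, p)
    log_stage("correlate", nrow(ct), nrow(corr))
  }

  manifest <- structure(list(
    subcommand = "run",
    inputs = list(config = config_path, report = config$report,
                  ct = config$ct),
    config_hash = if (!is.na(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    seed = seed,
    versions = list(srmflow = as.character(utils::packageVersion("srmflow")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = outputs), class = "run_manifest")
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), p, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(manifest)
}

#' Protein-mRNA correlation table for a quantified experiment
#'
#' For every protein with a matching transcript, correlates the
#' per-condition mean protein abundance with the per-condition mean dCt
#' over the ordered conditions (both z-scaled).
#'
#' @param result An `srm_quant_result`.
#' @param dct A dCt table from [dct_table()].
#' @param conditions_order Ordered condition labels to correlate over.
#' @return Data frame: target_a, target_b, r, p, significant.
#' @export
correlate_abundance_dct <- function(result, dct,
                                    conditions_order = NULL) {
  prot_ab <- result$protein_abundance
  if (is.null(conditions_order)) {
    conditions_order <- unique(prot_ab$condition)
  }
  rows <- lapply(sort(intersect(unique(prot_ab$protein),
                                unique(dct$gene))), function(g) {
    pa <- vapply(conditions_order, function(cd) {
      v <- prot_ab$abundance[prot_ab$protein == g &
                               prot_ab$condition == cd]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    md <- vapply(conditions_order, function(cd) {
      v <- dct$dct[dct$gene == g & dct$condition == cd]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    ok <- is.finite(pa) & is.finite(md)
    if (sum(ok) < 3 || stats::sd(pa[ok]) == 0 || stats::sd(md[ok]) == 0) {
      return(NULL)
    }
    ct <- correlate_protein_mrna(pa[ok], md[ok])
    data.frame(target_a = paste0(g, "_protein"),
               target_b = paste0(g, "_mrna"), r = ct$r, p = ct$p,
               significant = ct$p < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(target_a = character(), target_b = character(),
                      r = numeric(), p = numeric(),
                      significant = logical())
  }
  out
}
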