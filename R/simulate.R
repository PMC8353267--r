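#' @importFrom stats rnorm runif setNames
NULL

# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.MARKERS <- c("OCT4", "SOX2", "NES", "DCX", "TUBB3", "MAP2", "GFAP",
              "S100B", "GALC", "OLIG1")

#' Synthetic marker proteome
#'
#' Deterministic synthetic sequences for the ten differentiation markers
#' (OCT4, SOX2, NES, DCX, TUBB3, MAP2, GFAP, S100B, GALC, OLIG1). These
#' are NOT the biological sequences: each synthetic protein is a
#' concatenation of unique tryptic peptides (length 8-14, K/R terminus, no
#' internal K/R/P) so that digestion, proteotypicity and panel rules can
#' be exercised without external sequence resources.
#'
#' @param n_peptides Tryptic peptides per protein.
#' @param seed RNG seed for the deterministic construction.
#' @return Named character vector `protein_id -> sequence`.
#' @export
synthetic_proteome <- function(n_peptides = 6L, seed = 20210806L) {
  alphabet <- setdiff(names(.AA_MONO), c("K", "R", "P"))
  .with_seed(seed, {
    seqs <- vapply(.MARKERS, function(p) {
      peps <- vapply(seq_len(n_peptides), function(i) {
        len <- sample(8:14, 1)
        paste0(paste(sample(alphabet, len - 1, replace = TRUE),
                     collapse = ""),
               sample(c("K", "R"), 1))
      }, character(1))
      paste(peps, collapse = "")
    }, character(1))
    # sanity: every tryptic peptide unique to its parent
    all_peps <- unlist(lapply(seqs, digest_protein))
    stopifnot(!anyDuplicated(all_peps))
    seqs
  })
}

#' Synthetic spectral library for a proteome
#'
#' Per tryptic peptide: intensity fractions over its candidate y/b
#' fragments (normalised gamma draws, so they sum to 1) with the derived
#' intensity ranks, plus an iRT score. Ranks and fractions are consistent:
#' rank 1 is the largest fraction. Deterministic under `seed`.
#'
#' @param proteome Named character vector `protein_id -> sequence`.
#' @param n_fragments Ranked fragments per peptide.
#' @param seed RNG seed.
#' @param config A [design_config()] (length window for candidates).
#' @return List with `ranks` (peptide_sequence, fragment, fragment_charge,
#'   rank), `fractions` (same keys plus `fraction`) and `irts` (named
#'   vector).
#' @export
synthetic_library <- function(proteome, n_fragments = 7L,
                              seed = 20210807L,
                              config = design_config()) {
  peps <- unique(unlist(lapply(proteome, digest_protein, config = config)))
  len <- nchar(peps)
  peps <- peps[len >= config$min_peptide_length &
                 len <= config$max_peptide_length]
  .with_seed(seed, {
    rows <- lapply(sort(peps), function(p) {
      n <- nchar(p)
      # candidate singly charged y ions (skip y1/y2: weakly informative)
      idx <- seq.int(3, n - 1)
      frags <- paste0("y", idx)
      take <- utils::head(sample(frags), min(n_fragments, length(frags)))
      w <- stats::rgamma(length(take), shape = 2)
      frac <- w / sum(w)
      ord <- order(-frac)
      data.frame(peptide_sequence = p, fragment = take,
                 fragment_charge = 1L,
                 rank = match(seq_along(take), ord),
                 fraction = frac, stringsAsFactors = FALSE)
    })
    lib <- do.call(rbind, rows)
    irts <- setNames(runif(length(peps), 5, 95), sort(peps))
    list(ranks = lib[, c("peptide_sequence", "fragment", "fragment_charge",
                         "rank")],
         fractions = lib[, c("peptide_sequence", "fragment",
                             "fragment_charge", "fraction")],
         irts = irts)
  })
}

#' The shipped default ten-marker panel
#'
#' Builds the validated multiplexed panel from the synthetic marker
#' proteome and its synthetic spectral library: ten proteins, each with
#' proteotypic peptides within the panel bounds and each peptide carrying
#' its best-ranked transitions. Fully deterministic.
#'
#' @param config A [design_config()].
#' @return A `protein_panel`.
#' @export
default_panel <- function(config = design_config()) {
  proteome <- synthetic_proteome()
  lib <- synthetic_library(proteome, config = config)
  targets <- data.frame(protein_id = names(proteome),
                        sequence = unname(proteome),
                        stringsAsFactors = FALSE)
  build_panel(targets, proteome = proteome, library_ranks = lib$ranks,
              irts = lib$irts, config = config)
}

#' Default log2 abundance trajectories over a differentiation time course
#'
#' Piecewise-linear shapes over days 0/7/14/21/28 reflecting a neural
#' differentiation time course: neuronal markers rise (the DCX-like
#' trajectory ends +3 log2 units over control), stem-cell markers fall,
#' S100B dips then recovers, the pluripotency marker sits below the
#' detection limit, GFAP is borderline, oligodendrocyte markers stay flat.
#' Values are absolute log2 peak-area scale.
#'
#' @param times Numeric vector of time points (days) at which to evaluate.
#' @return Matrix proteins x time points.
#' @export
default_trajectories <- function(times = c(0, 7, 14, 21, 28)) {
  base_t <- c(0, 7, 14, 21, 28)
  shapes <- rbind(
    OCT4  = c(5.5, 5.5, 5.5, 5.5, 5.5),
    SOX2  = c(14, 13.9, 13.4, 12.9, 12.5),
    NES   = c(15, 14.5, 13.8, 13.3, 13),
    DCX   = c(10, 11, 12, 13.2, 13),
    TUBB3 = c(13, 13.2, 14, 14.7, 15),
    MAP2  = c(12, 12.8, 13.4, 13.8, 14),
    GFAP  = c(7, 7, 7, 7, 7),
    S100B = c(13, 12, 12.3, 13.2, 13.5),
    GALC  = c(11, 10.8, 10.9, 11, 11.1),
    OLIG1 = c(10.5, 10.5, 10.5, 10.5, 10.5)
  )
  out <- t(apply(shapes, 1, function(v) {
    stats::approx(base_t, v, xout = times, rule = 2)$y
  }))
  colnames(out) <- as.character(times)
  out
}

#' Simulation configuration for the synthetic time course
#'
#' The generative model behind the synthetic transition report mirrors the
#' model the quantification stage fits: per-transition log2 light area =
#' protein trajectory + peptide digestion-efficiency offset + log2 of the
#' transition's fixed fragment-intensity fraction + run random effect +
#' Gaussian noise. Heavy spike-ins are constant; backgrounds are
#' transition-specific; S/N is reported as area/background (declared
#' proxy for the upstream peak-picker's S/N). Matched qPCR Ct values are
#' linearly coupled to the protein trajectory with a negative slope, so
#' higher protein implies lower Ct and higher dCt.
#'
#' @param panel A `protein_panel` (default [default_panel()]).
#' @param conditions Named numeric vector `label -> time (days)`.
#' @param replicates Biological replicates per condition.
#' @param trajectories Matrix proteins x conditions of true log2
#'   abundances; default [default_trajectories()] at the condition times.
#' @param peptide_offset_sd SD of per-peptide log2 offsets (digestion
#'   efficiency).
#' @param sigma_run SD of the per-run random effect (log2).
#' @param sigma_noise SD of the residual noise (log2).
#' @param background_log2_mean,background_log2_sd Per-transition
#'   background level distribution (log2 area units).
#' @param heavy_log2 Constant heavy spike-in level (log2 area, per
#'   peptide, split over fragments by the fragment profile).
#' @param lod_censoring Replace signals that fall below their background
#'   with noise-floor draws, so the pipeline's imputation is exercised?
#' @param ct_base,ct_slope Ct coupling: `ct = ct_base - ct_slope * T_p`.
#' @param sigma_ct SD of Ct noise (cycles).
#' @param hk_ct Named vector of constant housekeeping Ct levels.
#' @param ct_replicates qPCR replicates per condition.
#' @param control_condition Label of the control condition.
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(panel = default_panel(),
                              conditions = c(NSC = 0, BG7 = 7, BG14 = 14,
                                             BG21 = 21, BG28 = 28),
                              replicates = 4L,
                              trajectories = NULL,
                              peptide_offset_sd = 0.5,
                              sigma_run = 0.1,
                              sigma_noise = 0.2,
                              background_log2_mean = 4,
                              background_log2_sd = 0.5,
                              heavy_log2 = 12,
                              lod_censoring = TRUE,
                              ct_base = 32, ct_slope = 0.8,
                              sigma_ct = 0.15,
                              hk_ct = c(GAPDH = 18, ATP5F1B = 20),
                              ct_replicates = 3L,
                              control_condition = "NSC",
                              seed = 1L) {
  if (is.null(trajectories)) {
    trajectories <- default_trajectories(unname(conditions))
    colnames(trajectories) <- names(conditions)
    missing_tr <- setdiff(unique(panel$transitions$protein),
                          rownames(trajectories))
    if (length(missing_tr)) {
      stop("no default trajectory for protein(s): ",
           paste(missing_tr, collapse = ", "),
           " — supply a 'trajectories' matrix", call. = FALSE)
    }
  }
  stopifnot(replicates >= 2, peptide_offset_sd >= 0, sigma_run >= 0,
            sigma_noise >= 0, sigma_ct >= 0,
            control_condition %in% names(conditions),
            all(names(conditions) %in% colnames(trajectories)))
  structure(list(panel = panel, conditions = conditions,
                 replicates = as.integer(replicates),
                 trajectories = trajectories,
                 peptide_offset_sd = peptide_offset_sd,
                 sigma_run = sigma_run, sigma_noise = sigma_noise,
                 background_log2_mean = background_log2_mean,
                 background_log2_sd = background_log2_sd,
                 heavy_log2 = heavy_log2,
                 lod_censoring = isTRUE(lod_censoring),
                 ct_base = ct_base, ct_slope = ct_slope,
                 sigma_ct = sigma_ct, hk_ct = hk_ct,
                 ct_replicates = as.integer(ct_replicates),
                 control_condition = control_condition,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a ground-truth-annotated synthetic time course
#'
#' Produces a transition report (light + heavy rows), a matched qPCR Ct
#' table and the ground truth (true log2 abundances and fold-changes
#' versus control, realised run effects). See [simulation_config()] for
#' the generative model. Output is byte-identical for identical seeds.
#'
#' @param config A [simulation_config()].
#' @return An `srm_simulation` list: `report`, `ct`, `truth`,
#'   `run_effects`, `config`.
#' @export
generate_timecourse <- function(config = simulation_config()) {
  panel <- config$panel
  lt <- panel$transitions[panel$transitions$label == "light", ]
  lt <- lt[order(lt$protein, lt$peptide_sequence, lt$fragment,
                 lt$fragment_charge), ]

  # fragment profile: intensity fractions from the library ranks
  # (geometric decay by rank, normalised per peptide: rank 1 largest)
  frac <- stats::ave(0.7^(lt$rank - 1),
                     lt$peptide_sequence,
                     FUN = function(x) x / sum(x))

  conds <- names(config$conditions)
  reps <- seq_len(config$replicates)
  peptides <- sort(unique(lt$peptide_sequence))
  runs <- expand.grid(replicate = reps, condition = conds,
                      stringsAsFactors = FALSE)
  runs$run_id <- paste(runs$condition, runs$replicate, sep = "_r")

  .with_seed(config$seed, {
    beta <- setNames(rnorm(length(peptides), 0, config$peptide_offset_sd),
                     peptides)
    u <- setNames(rnorm(nrow(runs), 0, config$sigma_run), runs$run_id)
    bg_key <- paste(lt$peptide_sequence, lt$fragment, lt$fragment_charge)
    background <- setNames(
      2^rnorm(nrow(lt), config$background_log2_mean,
              config$background_log2_sd), bg_key)
    # RT jitter shared between labels: peptide x run
    rt_jitter <- matrix(rnorm(length(peptides) * nrow(runs), 0, 0.05),
                        nrow = length(peptides),
                        dimnames = list(peptides, runs$run_id))

    n_tr <- nrow(lt); n_run <- nrow(runs)
    tr_ix <- rep(seq_len(n_tr), times = n_run)
    run_ix <- rep(seq_len(n_run), each = n_tr)
    prot <- lt$protein[tr_ix]
    cond <- runs$condition[run_ix]
    truth_mean <- config$trajectories[cbind(prot, cond)]
    log2_light <- truth_mean + beta[lt$peptide_sequence[tr_ix]] +
      log2(frac[tr_ix]) + u[runs$run_id[run_ix]] +
      rnorm(n_tr * n_run, 0, config$sigma_noise)
    area <- 2^log2_light
    bg <- background[bg_key[tr_ix]]
    if (config$lod_censoring) {
      below <- area < bg
      # true signal lost in the noise floor: report a sub-background area
      area[below] <- bg[below] * runif(sum(below), 0.1, 0.9)
    }
    rt <- 2 + 0.28 * lt$irt[tr_ix] +
      rt_jitter[cbind(lt$peptide_sequence[tr_ix], runs$run_id[run_ix])]

    light_rows <- data.frame(
      protein = prot,
      peptide_sequence = lt$peptide_sequence[tr_ix],
      precursor_charge = lt$precursor_charge[tr_ix],
      fragment = lt$fragment[tr_ix],
      fragment_charge = lt$fragment_charge[tr_ix],
      label = "light",
      condition = cond,
      replicate = runs$replicate[run_ix],
      run_id = runs$run_id[run_ix],
      rt_observed = round(rt, 3),
      peak_area = round(unname(area), 2),
      background = round(unname(bg), 2),
      stringsAsFactors = FALSE)
    light_rows$snr <- round(light_rows$peak_area / light_rows$background, 3)

    heavy_area <- 2^(config$heavy_log2) * frac[tr_ix]
    heavy_rows <- light_rows
    heavy_rows$label <- "heavy"
    heavy_rows$peak_area <- round(unname(heavy_area), 2)
    heavy_rows$snr <- round(heavy_rows$peak_area / heavy_rows$background, 3)

    report <- rbind(light_rows, heavy_rows)
    report <- report[order(report$protein, report$peptide_sequence,
                           report$fragment, report$label, report$run_id), ]
    rownames(report) <- NULL

    # matched qPCR Ct table
    prot_levels <- rownames(config$trajectories)
    prot_levels <- prot_levels[prot_levels %in% unique(lt$protein)]
    ct_grid <- expand.grid(gene = prot_levels, condition = conds,
                           replicate = seq_len(config$ct_replicates),
                           stringsAsFactors = FALSE)
    ct_grid$ct <- round(config$ct_base -
      config$ct_slope *
        config$trajectories[cbind(ct_grid$gene, ct_grid$condition)] +
      rnorm(nrow(ct_grid), 0, config$sigma_ct), 3)
    hk_grid <- expand.grid(gene = names(config$hk_ct), condition = conds,
                           replicate = seq_len(config$ct_replicates),
                           stringsAsFactors = FALSE)
    hk_grid$ct <- round(config$hk_ct[hk_grid$gene] +
                          rnorm(nrow(hk_grid), 0, config$sigma_ct), 3)
    ct <- rbind(ct_grid, hk_grid)
    rownames(ct) <- NULL

    truth <- expand.grid(protein = prot_levels, condition = conds,
                         stringsAsFactors = FALSE)
    truth$true_log2_abundance <-
      config$trajectories[cbind(truth$protein, truth$condition)]
    ctrl <- config$control_condition
    ctrl_ab <- config$trajectories[, ctrl]
    truth$true_log2fc <- truth$true_log2_abundance - ctrl_ab[truth$protein]

    structure(list(report = report, ct = ct, truth = truth,
                   run_effects = data.frame(run_id = runs$run_id,
                                            effect = unname(u),
                                            stringsAsFactors = FALSE),
                   config = config),
              class = "srm_simulation")
  })
}

#' @export
print.srm_simulation <- function(x, ...) {
  cat(sprintf(paste0("srm_simulation: %d report rows (%d runs, %d ",
                     "conditions), %d Ct rows\n"),
              nrow(x$report), length(unique(x$report$run_id)),
              length(unique(x$report$condition)), nrow(x$ct)))
  invisible(x)
}

#' Remove peptides of a protein in a condition (dropout fixture)
#'
#' Keeps the first `keep_peptides` peptides (alphabetical) of `protein` in
#' `condition` and removes the rest, to drive a protein towards the
#' "detectable" (keep 1) or "not_detected" (keep 0) call downstream.
#'
#' @param report Transition-report data frame.
#' @param protein,condition Target keys.
#' @param keep_peptides Number of peptides to keep.
#' @return Modified report.
#' @export
inject_dropout <- function(report, protein, condition, keep_peptides) {
  peps <- sort(unique(report$peptide_sequence[report$protein == protein]))
  if (!length(peps)) stop("protein not present in report", call. = FALSE)
  if (keep_peptides > length(peps)) {
    stop(sprintf("keep_peptides (%d) exceeds available peptides (%d)",
                 keep_peptides, length(peps)), call. = FALSE)
  }
  keep <- utils::head(peps, keep_peptides)
  drop <- report$protein == protein & report$condition == condition &
    !(report$peptide_sequence %in% keep)
  report[!drop, , drop = FALSE]
}
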