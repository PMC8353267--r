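# Independent oracles used to cross-check the implementation.
# These deliberately share no code with the package: masses come from
# elemental compositions, BH is the literal step-up, concurrency is a
# brute-force time grid, correlations use the textbook formulas.

# --- mass oracle from elemental compositions -------------------------------
.ORACLE_ISOTOPES <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                      O = 15.9949146221, S = 31.97207069)
# residue formulas (C, H, N, O, S)
.ORACLE_FORMULAS <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
.oracle_mass_from_formula <- function(counts) {
  sum(counts * .ORACLE_ISOTOPES[c("C", "H", "N", "O", "S")])
}
oracle_residue_mass <- function(aa) {
  m <- .oracle_mass_from_formula(.ORACLE_FORMULAS[[aa]])
  if (aa == "C") m <- m + .oracle_mass_from_formula(c(2, 3, 1, 1, 0))
  m
}
ORACLE_PROTON <- 1.00727646
ORACLE_WATER <- 2 * .ORACLE_ISOTOPES["H"] + .ORACLE_ISOTOPES["O"]
oracle_heavy_shift <- function(seq) {
  ct <- substr(seq, nchar(seq), nchar(seq))
  c(K = 8.014199, R = 10.008269)[[ct]]
}
oracle_peptide_mz <- function(seq, charge, heavy = FALSE) {
  res <- strsplit(seq, "")[[1]]
  m <- sum(vapply(res, oracle_residue_mass, numeric(1))) + ORACLE_WATER
  if (heavy) m <- m + oracle_heavy_shift(seq)
  unname((m + charge * ORACLE_PROTON) / charge)
}
oracle_fragment_mz <- function(seq, series, index, charge, heavy = FALSE) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  part <- if (series == "b") res[seq_len(index)] else
    res[seq.int(n - index + 1, n)]
  m <- sum(vapply(part, oracle_residue_mass, numeric(1)))
  if (series == "y") {
    m <- m + ORACLE_WATER
    if (heavy) m <- m + oracle_heavy_shift(seq)
  }
  unname((m + charge * ORACLE_PROTON) / charge)
}

random_peptides <- function(n, min_len = 6, max_len = 20,
                            tryptic = TRUE) {
  aa <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
          "K", "E", "M", "H", "F", "R", "Y", "W")
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    body <- paste(sample(aa, len - 1, replace = TRUE), collapse = "")
    last <- if (tryptic) sample(c("K", "R"), 1) else sample(aa, 1)
    paste0(body, last)
  }, character(1))
}

# --- BH step-up oracle -----------------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- brute-force window concurrency ---------------------------------------
oracle_concurrency <- function(starts, ends, step = 0.01) {
  if (!length(starts)) return(0L)
  grid <- seq(min(starts) - step, max(ends) + step, by = step)
  max(vapply(grid, function(t) sum(starts <= t & t < ends), integer(1)))
}

# --- Pearson r and p from the textbook formulas ---------------------------
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# --- manual average-linkage agglomeration ---------------------------------
oracle_average_linkage_heights <- function(mat) {
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# --- shared fixtures -------------------------------------------------------

# tiny transition report built in code: one protein, two peptides,
# 2 transitions each, 2 conditions x 2 replicates
make_tiny_report <- function() {
  grid <- expand.grid(
    peptide_sequence = c("AAAAELK", "CCCDDFR"),
    fragment = c("y3", "y4"),
    condition = c("NSC", "BG28"),
    replicate = 1:2, stringsAsFactors = FALSE)
  grid$protein <- "P1"
  grid$precursor_charge <- 2L
  grid$fragment_charge <- 1L
  grid$label <- "light"
  grid$run_id <- paste(grid$condition, grid$replicate, sep = "_r")
  grid$rt_observed <- 12
  grid$peak_area <- 1000 + 10 * seq_len(nrow(grid))
  grid$background <- 50
  grid$snr <- grid$peak_area / grid$background
  grid[, c("protein", "peptide_sequence", "precursor_charge", "fragment",
           "fragment_charge", "label", "condition", "replicate", "run_id",
           "rt_observed", "peak_area", "background", "snr")]
}

# small two-condition simulation panel: 2 peptides x 3 transitions per
# protein, matching the reduced layout used for recovery/null studies
make_sim_panel <- function() {
  cfg <- design_config(min_peptides = 2, max_peptides = 2,
                       min_transitions = 3, max_transitions = 3,
                       top_n_fragments = 3)
  proteome <- synthetic_proteome(n_peptides = 2)
  lib <- synthetic_library(proteome, n_fragments = 4, config = cfg)
  build_panel(data.frame(protein_id = names(proteome),
                         sequence = unname(proteome),
                         stringsAsFactors = FALSE),
              proteome = proteome, library_ranks = lib$ranks,
              irts = lib$irts, config = cfg)
}

# simulate one two-condition experiment for the panel with given true
# BG28-vs-NSC log2 fold-changes (named by protein), quantify it, and
# return the comparisons joined with the truth
simulate_and_fit <- function(panel, true_fc, seed, baseline = 13) {
  proteins <- names(true_fc)
  traj <- cbind(NSC = rep(baseline, length(proteins)),
                BG28 = baseline + unname(true_fc))
  rownames(traj) <- proteins
  sim <- generate_timecourse(simulation_config(
    panel = panel, conditions = c(NSC = 0, BG28 = 28),
    trajectories = traj, seed = seed))
  res <- quantify_experiment(sim$report)
  cmp <- res$comparisons
  cmp$true_log2fc <- unname(true_fc[cmp$protein])
  cmp
}
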