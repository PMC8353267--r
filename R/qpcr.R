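#' qPCR analysis configuration
#'
#' @param housekeeping Pair of housekeeping gene identifiers whose mean Ct
#'   normalises every target.
#' @param ci_level Confidence level of replicate summaries.
#' @param sig_alpha Per-pair significance level for correlations.
#' @param dct_sign `+1` for the `mean(HK) - Ct(target)` convention (larger
#'   dCt = more expressed, so induction plots upward), `-1` for the
#'   opposite.
#' @return A `qpcr_config` list.
#' @export
qpcr_config <- function(housekeeping = c("GAPDH", "ATP5F1B"),
                        ci_level = 0.95, sig_alpha = 0.05, dct_sign = 1) {
  stopifnot(length(housekeeping) == 2, dct_sign %in% c(-1, 1))
  structure(list(housekeeping = housekeeping, ci_level = ci_level,
                 sig_alpha = sig_alpha, dct_sign = dct_sign),
            class = "qpcr_config")
}

#' Read a Ct table CSV
#'
#' Columns: gene, condition, replicate, ct.
#' @param path CSV path.
#' @return Data frame of Ct records.
#' @export
read_ct_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "condition", "replicate", "ct"), names(d))
  if (length(missing)) {
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Delta-Ct against the mean of two housekeeping genes
#'
#' `dCt = mean(ct_hk1, ct_hk2) - ct_target` under the default sign
#' convention, so a more abundant transcript (lower Ct) gets a larger dCt.
#' Invariant to swapping the two housekeeping genes.
#'
#' @param ct_target,ct_hk1,ct_hk2 Ct values (cycles); vectorised.
#' @param sign `+1` (default) or `-1`, flips the convention.
#' @return dCt value(s).
#' @examples
#' compute_dct(25, 20, 22)  # -4
#' @export
compute_dct <- function(ct_target, ct_hk1, ct_hk2, sign = 1) {
  if (any(!is.finite(ct_hk1)) || any(!is.finite(ct_hk2))) {
    stop("missing housekeeping Ct value", call. = FALSE)
  }
  if (any(!is.finite(ct_target))) {
    stop("missing target Ct value", call. = FALSE)
  }
  sign * ((ct_hk1 + ct_hk2) / 2 - ct_target)
}

#' Per-gene, per-condition dCt from a Ct table
#'
#' Matches each target replicate with the same condition/replicate's
#' housekeeping Cts and computes the dCt.
#'
#' @param ct Data frame with columns gene, condition, replicate, ct.
#' @param config A [qpcr_config()].
#' @return Data frame: gene, condition, replicate, dct.
#' @export
dct_table <- function(ct, config = qpcr_config()) {
  hk <- config$housekeeping
  targets <- ct[!(ct$gene %in% hk), , drop = FALSE]
  key <- function(d) paste(d$condition, d$replicate)
  hk1 <- ct[ct$gene == hk[1], ]; hk2 <- ct[ct$gene == hk[2], ]
  ct1 <- hk1$ct[match(key(targets), key(hk1))]
  ct2 <- hk2$ct[match(key(targets), key(hk2))]
  data.frame(gene = targets$gene, condition = targets$condition,
             replicate = targets$replicate,
             dct = compute_dct(targets$ct, ct1, ct2,
                               sign = config$dct_sign),
             stringsAsFactors = FALSE)
}

#' Summarise replicate dCt values
#'
#' Mean with a t-based confidence interval; with a single replicate the
#' interval is undefined.
#'
#' @param dcts Numeric vector of replicate dCt values.
#' @param ci_level Confidence level.
#' @return One-row data frame: `mean`, `ci_low`, `ci_high`, `n`.
#' @export
summarize_dct <- function(dcts, ci_level = 0.95) {
  dcts <- dcts[is.finite(dcts)]
  n <- length(dcts)
  if (!n) return(data.frame(mean = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, n = 0L))
  m <- mean(dcts)
  if (n < 2) return(data.frame(mean = m, ci_low = NA_real_,
                               ci_high = NA_real_, n = n))
  half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1) *
    stats::sd(dcts) / sqrt(n)
  data.frame(mean = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Scale and centre a profile to mean 0, sample SD 1
#'
#' @param values Numeric vector (length >= 2, non-constant).
#' @return Z-scaled values.
#' @export
zscale_profile <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("constant profile cannot be scaled",
                                    call. = FALSE)
  (values - mean(values)) / s
}

#' Pairwise Pearson correlations across expression profiles
#'
#' Pearson correlation of every pair of profiles over their shared,
#' ordered time labels, with a two-sided t-test p-value per pair and a
#' significance flag at `alpha` (per-cell, no multiplicity correction, as
#' in a correlogram).
#'
#' @param profiles Named list of numeric vectors, all with identical names
#'   (time labels) in identical order, length >= 3.
#' @param alpha Per-pair significance level.
#' @return List with matrices `r`, `p` and logical `significant`.
#' @export
correlate_pairwise <- function(profiles, alpha = 0.05) {
  if (length(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
  labs <- names(profiles[[1]])
  for (p in profiles) {
    if (!identical(names(p), labs)) {
      stop("profiles have mismatched time labels", call. = FALSE)
    }
  }
  if (length(labs) < 3) stop("need at least 3 time points", call. = FALSE)
  k <- length(profiles)
  ids <- names(profiles)
  r <- diag(1, k); pm <- matrix(0, k, k)
  dimnames(r) <- dimnames(pm) <- list(ids, ids)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- stats::cor.test(profiles[[i]], profiles[[j]],
                            method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      pm[i, j] <- pm[j, i] <- ct$p.value
    }
  }
  list(r = r, p = pm, significant = pm < alpha & !diag(k))
}

#' Protein-mRNA correlation over a time course
#'
#' Pearson correlation between a protein abundance profile and the
#' matching transcript dCt profile, computed on z-scaled series (Pearson
#' is affine-invariant, so scaling does not change r; it matches how the
#' two series are displayed on a common axis).
#'
#' @param protein,mrna Numeric vectors over the same ordered time points
#'   (length >= 3).
#' @return List with `r` and `p`.
#' @export
correlate_protein_mrna <- function(protein, mrna) {
  if (length(protein) != length(mrna)) {
    stop("profiles have mismatched time labels", call. = FALSE)
  }
  if (length(protein) < 3) stop("need at least 3 time points",
                                call. = FALSE)
  ct <- stats::cor.test(zscale_profile(protein), zscale_profile(mrna),
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) of profile rows, as behind a co-expression heatmap. Rows are
#' sorted by label before clustering so the result is invariant to input
#' order; remaining ties break on the alphabetical label order.
#'
#' @param mat Numeric matrix, one profile per row (rownames = targets).
#' @param method Linkage method passed to [stats::hclust()].
#' @return The `hclust` object, with leaf labels in `$labels[$order]`.
#' @export
cluster_profiles <- function(mat, method = "average") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 profiles", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  stats::hclust(stats::dist(mat, method = "euclidean"), method = method)
}
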