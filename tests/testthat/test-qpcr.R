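test_that("dCt against two housekeeping genes", {
  expect_equal(compute_dct(25, 20, 22), -4)
  expect_equal(compute_dct(21, 20, 22), 0)
  # invariant to swapping the housekeeping genes
  expect_equal(compute_dct(25, 20, 22), compute_dct(25, 22, 20))
  # sign convention is configurable
  expect_equal(compute_dct(25, 20, 22, sign = -1), 4)
  expect_error(compute_dct(25, NA, 22), "housekeeping")

  # linearity: per-replicate dCt averaged equals dCt of averaged Cts
  ct_t <- c(24, 25, 26); ct_h1 <- c(20, 20.5, 19.5); ct_h2 <- c(22, 22, 22)
  expect_equal(mean(compute_dct(ct_t, ct_h1, ct_h2)),
               compute_dct(mean(ct_t), mean(ct_h1), mean(ct_h2)))
})

test_that("dct_table matches targets with their condition/replicate HKs", {
  ct <- rbind(
    data.frame(gene = "DCX", condition = "NSC", replicate = 1:2,
               ct = c(25, 26)),
    data.frame(gene = "GAPDH", condition = "NSC", replicate = 1:2,
               ct = c(20, 20)),
    data.frame(gene = "ATP5F1B", condition = "NSC", replicate = 1:2,
               ct = c(22, 22)))
  d <- dct_table(ct)
  expect_equal(d$dct, c(-4, -5))
  expect_identical(d$gene, c("DCX", "DCX"))
})

test_that("replicate dCt summaries use the t-interval", {
  s <- summarize_dct(c(-4, -4, -4))
  expect_equal(s$mean, -4)
  expect_equal(s$ci_high - s$ci_low, 0)

  s2 <- summarize_dct(c(-3, -4, -5))
  expect_equal(s2$mean, -4)
  expect_equal(s2$ci_high - s2$mean, qt(0.975, 2) * 1 / sqrt(3))

  expect_true(is.na(summarize_dct(-4)$ci_low))
})

test_that("z-scaling centres to mean 0 and sample SD 1", {
  expect_equal(zscale_profile(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscale_profile(rnorm(10))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  # affine invariance
  x <- c(2, 5, 3, 9, 7)
  expect_equal(zscale_profile(x), zscale_profile(3 * x - 11))
  expect_error(zscale_profile(c(5, 5, 5)), "constant")
  expect_error(zscale_profile(5), "2 values")
})

test_that("pairwise correlations match the brute-force formulas", {
  labs <- paste0("t", 1:5)
  mk <- function(v) setNames(v, labs)
  profiles <- list(up = mk(c(1, 2, 3, 4, 5)),
                   down = mk(c(10, 8, 6, 4, 2)),
                   noisy = mk(c(0.3, -1, 2, 0.7, 1.4)))
  cp <- correlate_pairwise(profiles)
  expect_equal(unname(diag(cp$r)), rep(1, 3))
  expect_equal(cp$r, t(cp$r))
  expect_true(all(cp$r >= -1 & cp$r <= 1))
  expect_equal(cp$r["up", "down"], -1)  # opposite affine profiles

  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    o <- oracle_pearson(profiles[[pair[1]]], profiles[[pair[2]]])
    i <- names(profiles)[pair[1]]; j <- names(profiles)[pair[2]]
    expect_equal(cp$r[i, j], o$r, tolerance = 1e-12)
    expect_equal(cp$p[i, j], o$p, tolerance = 1e-9)
  }

  bad <- profiles
  names(bad$noisy) <- rev(labs)
  expect_error(correlate_pairwise(bad), "mismatched")
})

test_that("z-scaling does not change Pearson correlations", {
  set.seed(51)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(cor(zscale_profile(x), zscale_profile(y)), cor(x, y),
               tolerance = 1e-12)
})

test_that("protein-mRNA correlation: shape identity and coupled series", {
  expect_equal(correlate_protein_mrna(c(1, 2, 3, 4), c(1, 2, 3, 4))$r, 1)
  # constant offset leaves r = 1 (shift invariance)
  expect_equal(correlate_protein_mrna(c(1, 2, 3, 4), c(5, 6, 7, 8))$r, 1)

  # shared latent trajectory with independent noise sigma = 0.3
  set.seed(52)
  latent <- c(0, 1.2, 2.4, 3.0, 2.8)
  prot <- latent + rnorm(5, 0, 0.3)
  mrna <- latent + rnorm(5, 0, 0.3)
  expect_gt(correlate_protein_mrna(prot, mrna)$r, 0.8)

  expect_error(correlate_protein_mrna(1:4, 1:5), "mismatched")
})

test_that("profile clustering merges identical profiles first and is
           order-invariant", {
  mat <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
               c = c(4, 1, -2, 5))
  hc <- cluster_profiles(mat)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("a", "b"))
  expect_equal(hc$height[1], 0)

  perm <- cluster_profiles(mat[c(3, 1, 2), ])
  expect_equal(perm$height, hc$height)
  expect_identical(perm$labels[perm$order], hc$labels[hc$order])

  expect_error(cluster_profiles(mat[1, , drop = FALSE]), "2 profiles")
})

test_that("average-linkage merge heights match manual agglomeration", {
  set.seed(53)
  mat <- matrix(rnorm(25), nrow = 5,
                dimnames = list(letters[1:5], NULL))
  hc <- cluster_profiles(mat)
  expect_equal(sort(hc$height),
               sort(oracle_average_linkage_heights(mat)),
               tolerance = 1e-10)
})
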