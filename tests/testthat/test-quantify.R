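test_that("transition-report reader validates, types and logs rejects", {
  rep10 <- make_tiny_report()[1:10, ]
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep10, path, row.names = FALSE)
  d <- read_transition_report(path)
  expect_equal(nrow(d), 10)
  expect_equal(nrow(attr(d, "rejected")), 0)

  bad <- rep10
  bad$peak_area[3] <- -5
  utils::write.csv(bad, path, row.names = FALSE)
  d2 <- read_transition_report(path)
  expect_equal(nrow(d2), 9)
  rej <- attr(d2, "rejected")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$line, 4L)  # header + 3 data rows

  utils::write.csv(rep10[, setdiff(names(rep10), "background")], path,
                   row.names = FALSE)
  expect_error(read_transition_report(path), "background")
})

test_that("co-elution check: dot product and RT tolerance", {
  light <- data.frame(fragment = c("y3", "y4", "y5"), fragment_charge = 1,
                      peak_area = c(100, 50, 25), rt_observed = 12.0)
  heavy <- light
  res <- verify_coelution(light, heavy)
  expect_true(res$pass)
  expect_equal(res$dotp, 1.0)
  expect_equal(res$rt_delta, 0)

  # 100x scaled heavy still passes: normalised dot product is
  # scale-invariant
  heavy2 <- light; heavy2$peak_area <- light$peak_area * 100
  expect_true(verify_coelution(light, heavy2)$pass)
  expect_equal(verify_coelution(light, heavy2)$dotp, 1.0)

  # orthogonal intensity vectors fail with dotp 0
  heavy3 <- light; heavy3$peak_area <- c(0, 0, 25)
  light3 <- light; light3$peak_area <- c(100, 50, 0)
  res3 <- verify_coelution(light3, heavy3)
  expect_false(res3$pass)
  expect_equal(res3$dotp, 0)

  # RT shift beyond tolerance fails despite matching intensities
  heavy4 <- light; heavy4$rt_observed <- 13.0
  expect_false(verify_coelution(light, heavy4)$pass)

  expect_error(verify_coelution(light,
                                transform(heavy, fragment = c("b2", "b3",
                                                              "b4"))),
               "shared")
})

test_that("peak-group S/N filter acts on the top transition, per group", {
  rep <- make_tiny_report()
  # group AAAAELK/NSC/r1: give top-area transition S/N 5, others low
  g <- rep$peptide_sequence == "AAAAELK" & rep$condition == "NSC" &
    rep$replicate == 1
  rep$peak_area[g] <- c(500, 300)
  rep$snr[g] <- c(5, 0.5)
  # group CCCDDFR/NSC/r1: all S/N exactly 3 -> rejected (strict >)
  g2 <- rep$peptide_sequence == "CCCDDFR" & rep$condition == "NSC" &
    rep$replicate == 1
  rep$snr[g2] <- 3

  out <- filter_peak_groups(rep)
  rej <- attr(out, "rejected")
  expect_equal(nrow(out) + nrow(rej), nrow(rep))  # conservation
  kept_key <- paste(out$peptide_sequence, out$condition, out$replicate)
  expect_true(all(c("AAAAELK NSC 1") %in% kept_key))
  expect_false(any(grepl("CCCDDFR NSC 1", kept_key)))
  # whole groups move together
  expect_equal(sum(grepl("AAAAELK NSC 1", kept_key)), 2)

  empty <- filter_peak_groups(rep[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("below-background imputation assigns one-third of background", {
  expect_equal(impute_below_background(50, 300), 100)
  expect_equal(impute_below_background(400, 300), 400)
  expect_equal(impute_below_background(300, 300), 300)  # strict "below"
  expect_error(impute_below_background(-1, 300), "non-negative")
  # idempotent
  once <- impute_below_background(c(50, 400, 300), c(300, 300, 300))
  expect_identical(impute_below_background(once, c(300, 300, 300)), once)
})

test_that("peptide abundance is the median of transition log2 areas", {
  expect_equal(peptide_abundance(c(8, 9, 13)), 9)
  expect_equal(peptide_abundance(c(8, 10)), 9)
  expect_equal(peptide_abundance(c(13, 8, 9)), peptide_abundance(c(8, 9, 13)))
  expect_true(is.na(peptide_abundance(numeric(0))))
})

test_that("detection calls follow the peptide/replicate truth table", {
  cfg <- quant_config()
  # peptide A in 3 of 4 replicates, B in all 4 -> quantifiable
  m <- rbind(A = c(TRUE, TRUE, TRUE, FALSE), B = rep(TRUE, 4))
  expect_equal(call_detection(m, cfg)$status, "quantifiable")
  # only one peptide detected -> detectable
  m2 <- rbind(A = rep(TRUE, 4), B = rep(FALSE, 4))
  expect_equal(call_detection(m2, cfg)$status, "detectable")
  # peptides present but never meeting the 3-replicate rule -> detectable
  m3 <- rbind(A = c(TRUE, TRUE, FALSE, FALSE),
              B = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(call_detection(m3, cfg)$status, "detectable")
  expect_equal(call_detection(m3, cfg)$n_peptides_detected, 0L)
  # nothing detected
  m4 <- rbind(A = rep(FALSE, 4), B = rep(FALSE, 4))
  expect_equal(call_detection(m4, cfg)$status, "not_detected")
})

test_that("detection calls are monotone in detected peptide-replicates", {
  cfg <- quant_config()
  rank_of <- c(not_detected = 1, detectable = 2, quantifiable = 3)
  set.seed(41)
  for (i in 1:50) {
    m <- matrix(runif(12) < 0.4, nrow = 3,
                dimnames = list(c("A", "B", "C"), NULL))
    before <- rank_of[call_detection(m, cfg)$status]
    off <- which(!m)
    if (!length(off)) next
    m[sample(off, 1)] <- TRUE
    after <- rank_of[call_detection(m, cfg)$status]
    expect_gte(after, before)
  }
})

test_that("BH adjustment matches the hand-computed example and caps", {
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(42)
  p <- runif(20)
  expect_true(all(adjust_bh(p) >= p))
  expect_true(all(adjust_bh(p) <= 1))
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("condition summaries report median and a t-interval", {
  s <- summarize_condition(c(10, 10, 10, 10))
  expect_equal(s$median, 10)
  expect_equal(s$ci_high - s$ci_low, 0)

  s2 <- summarize_condition(c(9, 10, 11, 10))
  expect_equal(s2$median, 10)
  half <- qt(0.975, 3) * sd(c(9, 10, 11, 10)) / 2
  expect_equal(s2$ci_high, 10 + half)
  expect_equal(s2$ci_low, 10 - half)

  s1 <- summarize_condition(5)
  expect_equal(s1$median, 5)
  expect_true(is.na(s1$ci_low))
})
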