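test_that("transition enumeration respects counts and pairs labels", {
  # 3-residue peptide: 2 series x 2 indices x 2 charges = 8 candidates
  ranks <- expand.grid(fragment = c("y1", "y2", "b1", "b2"),
                       fragment_charge = 1:2, stringsAsFactors = FALSE)
  ranks$rank <- seq_len(nrow(ranks))
  cfg <- design_config(top_n_fragments = 4, min_transitions = 4,
                       max_transitions = 4)
  tr <- enumerate_transitions(peptide_spec("AGK"), ranks, cfg)
  # 4 per precursor charge per label
  expect_equal(sum(tr$label == "light" & tr$precursor_charge == 2), 4)
  expect_equal(sum(tr$label == "heavy" & tr$precursor_charge == 3), 4)
  # light and heavy twins share fragment coordinates
  lt <- tr[tr$label == "light" & tr$precursor_charge == 2, ]
  hv <- tr[tr$label == "heavy" & tr$precursor_charge == 2, ]
  expect_identical(lt$fragment, hv$fragment)
  expect_identical(lt$fragment_charge, hv$fragment_charge)

  expect_error(enumerate_transitions(
    peptide_spec("AGK"),
    data.frame(fragment = "y9", fragment_charge = 1, rank = 1)),
    "no rankable")
})

test_that("rank ties break y-before-b, lower index, lower charge", {
  ranks <- data.frame(fragment = c("b2", "y2", "y1", "b1"),
                      fragment_charge = 1L, rank = 1L)
  cfg4 <- design_config(top_n_fragments = 4, min_transitions = 4,
                        max_transitions = 4)
  tr <- enumerate_transitions(peptide_spec("AGK"), ranks, cfg4)
  lt <- tr[tr$label == "light" & tr$precursor_charge == 2, ]
  expect_identical(lt$fragment, c("y1", "y2", "b1", "b2"))

  # same fragment at both charges: lower charge first
  ranks2 <- data.frame(fragment = "y2", fragment_charge = c(2L, 1L),
                       rank = 1L)
  tr2 <- enumerate_transitions(peptide_spec("AGK"), ranks2, cfg4)
  lt2 <- tr2[tr2$label == "light" & tr2$precursor_charge == 2, ]
  expect_identical(lt2$fragment_charge, c(1L, 2L))
})

test_that("panel assembly filters, excludes with reasons, and validates", {
  panel <- default_panel()
  expect_length(panel$proteins, 10)
  v <- validate_panel(panel)
  expect_true(v$valid)
  expect_true(all(v$protein_summary$n_peptides >= 2 &
                    v$protein_summary$n_peptides <= 8))
  expect_true(all(v$peptide_summary$n_transitions >= 4 &
                    v$peptide_summary$n_transitions <= 10))

  # a target whose every peptide is shared with another proteome entry
  # is excluded for lack of proteotypic peptides
  t1 <- paste0("AAADDEEFFK", "GGHHLLMMNK")
  proteome <- c(T1 = t1,
                DECOY = paste0("WWYYVVSSTK", t1),
                T2 = "CCEELLGGWWKVVNNDDSSYR")
  lib <- synthetic_library(proteome, seed = 5)
  panel2 <- build_panel(
    data.frame(protein_id = c("T1", "T2"),
               sequence = unname(proteome[c("T1", "T2")])),
    proteome = proteome, library_ranks = lib$ranks, irts = lib$irts)
  expect_false("T1" %in% panel2$proteins)
  expect_match(panel2$excluded$reason[panel2$excluded$protein == "T1"],
               "no proteotypic peptides")
  expect_true("T2" %in% panel2$proteins)

  expect_error(build_panel(data.frame(protein_id = character(),
                                      sequence = character())),
               "empty")
})

test_that("panel validation flags bound violations", {
  panel <- default_panel()
  # drop all but one peptide of the first protein: min-peptides failure
  broken <- panel
  pr <- panel$proteins[1]
  keep_pep <- panel$peptides$peptide_sequence[
    panel$peptides$protein == pr][1]
  drop <- broken$peptides$protein == pr &
    broken$peptides$peptide_sequence != keep_pep
  broken$peptides <- broken$peptides[!drop, ]
  broken$transitions <- broken$transitions[
    !(broken$transitions$protein == pr &
        broken$transitions$peptide_sequence != keep_pep), ]
  v <- validate_panel(broken)
  expect_false(v$valid)
  expect_false(v$protein_summary$peptides_ok[
    v$protein_summary$protein == pr])

  # duplicate a transition block to exceed the max-transitions bound
  broken2 <- panel
  pep <- panel$transitions$peptide_sequence[1]
  extra <- panel$transitions[panel$transitions$peptide_sequence == pep, ]
  extra$fragment <- paste0(extra$fragment, "9")
  broken2$transitions <- rbind(broken2$transitions, extra)
  v2 <- validate_panel(broken2)
  expect_false(v2$valid)
})

test_that("transition list CSV round-trips with exact columns", {
  panel <- default_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_list(panel, path)
  d <- read_transition_list(path)
  expect_identical(names(d),
                   c("protein", "peptide_sequence", "label",
                     "precursor_mz", "precursor_charge", "fragment",
                     "fragment_charge", "product_mz", "irt", "rank"))
  expect_equal(nrow(d), nrow(panel$transitions))
  expect_equal(d$precursor_mz, round(panel$transitions$precursor_mz, 4),
               tolerance = 1e-9)
  counts <- transition_counts(d)
  expect_equal(unname(counts["total"]),
               unname(counts["light"] + counts["heavy"]))
  expect_equal(unname(counts["light"]), unname(counts["heavy"]))

  bad <- d[, -3]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_transition_list(path2), "label")
})
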