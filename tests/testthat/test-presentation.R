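# PHBR scoring, binding calls and mutant-allele bias statistics.

test_that("phbr_score equals the direct reciprocal-sum harmonic mean", {
  expect_equal(phbr_score(rep(2, 6)), 2)
  expect_equal(phbr_score(1:6), 6 / (1 + 1/2 + 1/3 + 1/4 + 1/5 + 1/6))
  expect_equal(phbr_score(c(0.5, 0.5, 0.5, 50, 50, 50)), 6 / 6.06)
  set.seed(101)
  for (i in 1:200) {
    r <- runif(6, 0.01, 100)
    expect_equal(phbr_score(r), harmonic_mean_oracle(r), tolerance = 1e-12)
    expect_gte(phbr_score(r), min(r))
    expect_lte(phbr_score(r), max(r))
  }
})

test_that("phbr_score is strictly increasing in each coordinate", {
  set.seed(7)
  for (i in 1:50) {
    r <- runif(6, 0.1, 50)
    j <- sample(6, 1)
    r2 <- r
    r2[j] <- r[j] * 1.5
    expect_gt(phbr_score(r2), phbr_score(r))
  }
})

test_that("phbr_score validates arity and positivity", {
  expect_error(phbr_score(1:5), class = "neoescape_validation_error")
  expect_error(phbr_score(c(1, 2, 3, 4, 5, 0)),
               class = "neoescape_validation_error")
  expect_error(best_rank_per_allele(numeric(0)),
               class = "neoescape_validation_error")
})

test_that("best_rank_per_allele takes the minimum peptide rank", {
  expect_equal(best_rank_per_allele(c(5, 0.3, 12)), 0.3)
  expect_equal(best_rank_per_allele(2), 2)
  expect_equal(best_rank_per_allele(c(7, 7, 7)), 7)
})

test_that("binding call boundary is inclusive at the cutoff", {
  expect_true(is_binding(2.0))
  expect_false(is_binding(2.0001))
  expect_true(is_binding(0.1))
})

test_that("binding_fraction counts PHBR calls over the expressed set", {
  expect_equal(binding_fraction(c(1, 3, 1.5, 5), cutoff = 2), 0.5)
  expect_equal(binding_fraction(c(1, 3, 1.5, 5), cutoff = 100), 1)
  expect_equal(binding_fraction(c(1, 3, 1.5, 5), cutoff = 0.5), 0)
  expect_true(is.na(binding_fraction(numeric(0))))
})

test_that("score_phbr reduces peptide-level duplicates to best ranks", {
  ranks <- tibble::tibble(
    mutation_id = rep("m1", 8),
    slot = c(1, 1, 1, 2, 3, 4, 5, 6),
    rank = c(5, 0.3, 12, 2, 2, 2, 2, 2)
  )
  out <- score_phbr(ranks)
  expect_equal(out$phbr, harmonic_mean_oracle(c(0.3, 2, 2, 2, 2, 2)))
  expect_error(score_phbr(dplyr::filter(ranks, slot != 2)),
               class = "neoescape_validation_error")
})

test_that("binding fraction is nondecreasing in the cutoff per patient", {
  co <- tiny_cohort(seed = 3, n = 40)
  curve <- binding_fraction_curve(
    co$mutations, co$ranks,
    dplyr::select(co$patients, patient_id, group),
    cutoffs = c(0.5, 1, 2, 4, 8, 16, 50, 100))
  diffs <- curve %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(ok = all(diff(median_fraction) >= 0))
  expect_true(all(diffs$ok))
  # every rank is <= 100, so the curve saturates at 1
  expect_true(all(curve$median_fraction[curve$cutoff == 100] == 1))
})

test_that("allele_binding_counts counts per-slot best ranks, not PHBR", {
  muts <- tibble::tibble(
    mutation_id = c("m1", "m2"), patient_id = "p1", gene = "G",
    variant_classification = c("missense", "missense"),
    chrom = "1", pos = c(1L, 2L), protein_pos = c(1L, 2L),
    t_alt_count = 5L, t_depth = 10L, rna_read_count = c(10L, 0L)
  )
  ranks <- tibble::tibble(
    mutation_id = rep(c("m1", "m2"), each = 6),
    slot = rep(1:6, 2),
    rank = c(1, 50, 50, 50, 50, 50, 1, 1, 1, 1, 1, 1)
  )
  counts <- allele_binding_counts(muts, ranks, cutoff = 2)
  # m2 is not expressed, so only m1 counts; only slot 1 binds
  expect_equal(counts$n_binding[order(counts$slot)], c(1L, rep(0L, 5)))
})

test_that("mutant_allele_bias compares the mutated slot to the mean of the rest", {
  muts <- tibble::tibble(
    mutation_id = sprintf("m%d", 1:9), patient_id = "p1", gene = "G",
    variant_classification = "missense", chrom = "1", pos = 1:9,
    protein_pos = 1:9, t_alt_count = 5L, t_depth = 10L, rna_read_count = 10L
  )
  mk_ranks <- function(slot_binders) {
    # slot_binders: named vector slot -> number of binding mutations
    tidyr::expand_grid(mutation_id = muts$mutation_id, slot = 1:6) %>%
      dplyr::group_by(slot) %>%
      dplyr::mutate(rank = ifelse(dplyr::row_number() <=
                                    slot_binders[slot], 1, 50)) %>%
      dplyr::ungroup()
  }
  pats <- tibble::tibble(patient_id = "p1", group = "HLA_MUT",
                         mutated_slot = 1L, mantis_score = 0.1)
  b <- mutant_allele_bias(muts, mk_ranks(c(4, 1, 1, 1, 1, 1)), pats)
  expect_equal(b$n_mut_allele, 4L)
  expect_equal(b$mean_other, 1)
  expect_equal(b$direction, "mut_higher")

  b2 <- mutant_allele_bias(muts, mk_ranks(rep(2, 6)), pats)
  expect_equal(b2$direction, "tied")

  b3 <- mutant_allele_bias(muts, mk_ranks(c(0, 2, 2, 2, 2, 2)), pats)
  expect_equal(b3$direction, "other_higher")

  expect_error(
    mutant_allele_bias(muts, mk_ranks(rep(1, 6)),
                       dplyr::mutate(pats, mutated_slot = NA_integer_)),
    class = "neoescape_validation_error")
})

test_that("bias_test matches the sign-enumeration oracle and flags degeneracy", {
  bias <- tibble::tibble(patient_id = sprintf("p%d", 1:5),
                         n_mut_allele = c(5, 6, 7, 8, 9),
                         mean_other = c(1, 2, 3, 4, 5))
  res <- bias_test(bias)
  expect_equal(res$raw_p, 0.0625)
  expect_equal(res$raw_p,
               wilcox_sign_enum_p(bias$n_mut_allele - bias$mean_other))

  sym <- tibble::tibble(patient_id = c("a", "b"),
                        n_mut_allele = c(3, 1), mean_other = c(1, 3))
  expect_equal(bias_test(sym)$raw_p, 1)

  flat <- tibble::tibble(patient_id = "a", n_mut_allele = 2, mean_other = 2)
  res_flat <- bias_test(flat)
  expect_true(res_flat$degenerate)
  expect_equal(res_flat$raw_p, 1)
})

test_that("bias_test detects the simulated mutant-allele boost", {
  hits <- 0L
  for (s in 1:8) {
    co <- simulate_cohort(cohort_config(n_patients = 250, seed = 4000 + s))
    pats <- dplyr::filter(co$patients, group == "HLA_MUT")
    bias <- mutant_allele_bias(co$mutations, co$ranks, pats)
    if (bias_test(bias)$raw_p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("HLA-mutant binding curve dominates wild-type at the binding cutoff", {
  wins <- 0L
  for (s in 1:8) {
    co <- simulate_cohort(cohort_config(n_patients = 300, seed = 900 + s))
    curve <- binding_fraction_curve(
      co$mutations, co$ranks,
      dplyr::filter(dplyr::select(co$patients, patient_id, group),
                    group %in% c("WT", "HLA_MUT")),
      cutoffs = 2)
    med <- setNames(curve$median_fraction, curve$group)
    if (med["HLA_MUT"] >= med["WT"]) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("timing_bias_contrast reproduces the permutation oracle on fixed strata", {
  res <- mann_whitney(c(5, 6, 7), c(1, 2, 3), contrast = "early vs late")
  expect_equal(res$statistic, 9)
  expect_equal(res$raw_p, 0.1)
  expect_equal(res$raw_p, mw_enum_p(c(5, 6, 7), c(1, 2, 3)))
})
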