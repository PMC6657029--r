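# Synthetic cohort generator: determinism, group structure, invariants and
# parameter recovery at small scale.

test_that("group sizes follow deterministic rounding of the fractions", {
  co <- simulate_cohort(cohort_config(
    n_patients = 100, frac_b2m_mut = 0.1, frac_hla_mut = 0.2, frac_both = 0,
    seed = 7))
  tab <- table(co$patients$group)
  expect_equal(unname(tab[["B2M_MUT"]]), 10)
  expect_equal(unname(tab[["HLA_MUT"]]), 20)
  expect_equal(unname(tab[["WT"]]), 70)
})

test_that("the same config and seed reproduce an identical cohort", {
  cfg <- cohort_config(n_patients = 80, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(cohort_config(n_patients = 80, seed = 124))
  expect_false(identical(a, c2))
})

test_that("a fixed seed reproduces byte-identical cohort files", {
  cfg <- cohort_config(n_patients = 40, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("generated values respect their domains", {
  co <- simulate_cohort(cohort_config(n_patients = 150, seed = 17))
  expect_true(all(co$ranks$rank > 0 & co$ranks$rank <= 100))
  expect_true(all(co$mutations$t_alt_count <= co$mutations$t_depth))
  expect_true(all(co$mutations$t_alt_count >= 0))
  expect_true(all(co$mutations$t_depth >= 1))
  expect_true(all(co$mutations$rna_read_count >= 0))
  expect_true(all(co$patients$mantis_score >= 0))
  expect_true(all(co$segments$start <= co$segments$end))
  # every mutation with rank entries has all six slots
  slot_counts <- dplyr::count(co$ranks, mutation_id)
  expect_true(all(slot_counts$n == 6))
})

test_that("escape-group patients carry exactly their escape mutations", {
  co <- simulate_cohort(cohort_config(n_patients = 200, seed = 23))
  esc <- co$mutations %>%
    dplyr::filter(gene %in% c("B2M", "HLA-A", "HLA-B", "HLA-C")) %>%
    dplyr::count(patient_id, b2m = gene == "B2M")
  by_pat <- tidyr::pivot_wider(esc, names_from = "b2m", values_from = "n",
                               values_fill = 0L, names_prefix = "b2m_")
  pats <- dplyr::left_join(co$patients, by_pat, by = "patient_id") %>%
    dplyr::mutate(n_b2m = dplyr::coalesce(b2m_TRUE, 0L),
                  n_hla = dplyr::coalesce(b2m_FALSE, 0L))
  expect_true(all(pats$n_b2m[pats$group == "B2M_MUT"] == 1))
  expect_true(all(pats$n_hla[pats$group == "B2M_MUT"] == 0))
  expect_true(all(pats$n_hla[pats$group == "HLA_MUT"] == 1))
  expect_true(all(pats$n_b2m[pats$group == "BOTH"] == 1 &
                    pats$n_hla[pats$group == "BOTH"] == 1))
  expect_true(all(pats$n_b2m[pats$group == "WT"] == 0 &
                    pats$n_hla[pats$group == "WT"] == 0))
  # the HLA escape mutation's gene matches the mutated slot
  slots <- pats %>% dplyr::filter(group %in% c("HLA_MUT", "BOTH"))
  expect_true(all(!is.na(slots$mutated_slot)))
  hla_mut <- co$mutations %>%
    dplyr::filter(gene %in% c("HLA-A", "HLA-B", "HLA-C")) %>%
    dplyr::inner_join(dplyr::select(co$patients, patient_id, mutated_slot),
                      by = "patient_id")
  gene_of_slot <- c("HLA-A", "HLA-A", "HLA-B", "HLA-B", "HLA-C", "HLA-C")
  expect_equal(hla_mut$gene, gene_of_slot[hla_mut$mutated_slot])
})

test_that("generator groups agree with assign_groups on the emitted calls", {
  co <- simulate_cohort(cohort_config(n_patients = 150, seed = 29))
  g <- assign_groups(co$mutations, co$patients$patient_id)
  joined <- dplyr::inner_join(co$patients, g, by = "patient_id",
                              suffix = c("_gen", "_called"))
  expect_equal(joined$group_called, joined$group_gen)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(frac_b2m_mut = 0.7, frac_hla_mut = 0.5),
               class = "neoescape_config_error")
  expect_error(cohort_config(frac_msi = 1.4),
               class = "neoescape_config_error")
  expect_error(cohort_config(burden_multiplier_b2m = 0),
               class = "neoescape_config_error")
  expect_error(cohort_config(rank_min = 10, rank_max = 5),
               class = "neoescape_config_error")
  expect_error(simulate_cohort(list(n_patients = 5)),
               class = "neoescape_config_error")
})

test_that("a YAML config file round-trips through read_cohort_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 64",
    "frac_b2m_mut: 0.125",
    "bias_strength: 0.3",
    "seed: 5",
    "vaf_model:",
    "  b2m_shape1: 8",
    "  b2m_shape2: 2",
    "  hla_low_shape1: 2",
    "  hla_low_shape2: 8",
    "  hla_high_weight: 0.5"
  ), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_patients, 64L)
  expect_equal(cfg$bias_strength, 0.3)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_patientss: 10", bad)
  expect_error(read_cohort_config(bad), "unknown config keys",
               class = "neoescape_config_error")
})

test_that("burden multiplier and MSI enrichment are recovered at small scale", {
  ratios <- ors <- numeric(5)
  for (s in 1:5) {
    co <- simulate_cohort(cohort_config(n_patients = 1000, seed = 60 + s))
    pats <- co$patients %>%
      dplyr::mutate(msi = msi_status(mantis_score))
    burden <- mutation_burden(co$mutations) %>%
      dplyr::inner_join(pats, by = "patient_id") %>%
      dplyr::filter(msi == "MSS")
    ratios[s] <- mean(burden$burden[burden$group == "B2M_MUT"]) /
      mean(burden$burden[burden$group == "WT"])
    ors[s] <- msi_enrichment(pats, "ESCAPE")$odds_ratio
  }
  expect_gt(median(ratios), 1.6)
  expect_lt(median(ratios), 2.4)
  expect_gt(median(ors), 15 / 2)
  expect_lt(median(ors), 15 * 2)
})

test_that("MSI assignment hits the target marginal fraction and odds ratio", {
  pr <- neoescape:::solve_msi_probs(0.15, 0.3, 15)
  p0 <- pr[["p_wt"]]; p1 <- pr[["p_mut"]]
  expect_equal(0.3 * p1 + 0.7 * p0, 0.15, tolerance = 1e-8)
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), 15, tolerance = 1e-6)
  flat <- neoescape:::solve_msi_probs(0.2, 0.3, 1)
  expect_equal(unname(flat), c(0.2, 0.2))
})
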