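# Filters, burden, MSI, group assignment, cytolytic score and the contrast
# layer.

test_that("expression filter is inclusive at 5 reads", {
  expect_true(is_expressed(5))
  expect_false(is_expressed(4))
  expect_false(is_expressed(0))
  expect_true(is_expressed(3, min_reads = 3))
})

test_that("nonsynonymous filter enumerates the coding non-silent classes", {
  expect_true(all(is_nonsynonymous(c("missense", "nonsense",
                                     "frameshift_indel", "inframe_indel",
                                     "splice"))))
  expect_false(any(is_nonsynonymous(c("silent", "noncoding"))))
})

test_that("mutation_burden counts expressed nonsynonymous mutations plus one", {
  mk <- function(cls, rna) tibble::tibble(
    mutation_id = sprintf("m%d", seq_along(cls)), patient_id = "p1",
    gene = "G", variant_classification = cls, chrom = "1",
    pos = seq_along(cls), protein_pos = 1L, t_alt_count = 1L, t_depth = 2L,
    rna_read_count = rna)
  b <- mutation_burden(mk(rep("missense", 10), rep(10L, 10)))
  expect_equal(b$burden, 11)
  expect_equal(nrow(mutation_burden(mk(character(0), integer(0)))), 0)
  b2 <- mutation_burden(mk(c("missense", "missense", "nonsense"),
                           c(10L, 2L, 0L)))
  expect_equal(b2$burden, 2)
  b3 <- mutation_burden(mk(c("silent", "silent"), c(10L, 10L)))
  expect_equal(b3$burden, 1)
})

test_that("MANTIS binarization assigns the 0.4 boundary to MSI-H", {
  expect_equal(msi_status(0.55), "MSI_H")
  expect_equal(msi_status(0.1), "MSS")
  expect_equal(msi_status(0.4), "MSI_H")
  expect_error(msi_status(-0.2), class = "neoescape_validation_error")
})

test_that("group assignment distinguishes WT, single, both and synonymous-only", {
  muts <- tibble::tibble(
    mutation_id = sprintf("m%d", 1:5),
    patient_id = c("a", "b", "c", "c", "d"),
    gene = c("B2M", "HLA-A", "B2M", "HLA-B", "HLA-C"),
    variant_classification = c("missense", "silent", "nonsense", "missense",
                               "missense"),
    chrom = "1", pos = 1:5, protein_pos = 1:5,
    t_alt_count = 1L, t_depth = 2L, rna_read_count = 10L
  )
  g <- assign_groups(muts, c("a", "b", "c", "d", "e"))
  expect_equal(g$group, c("B2M_MUT", "SYN_ONLY", "BOTH", "HLA_MUT", "WT"))
})

test_that("cytolytic score sums per-gene z-scores and centers at zero", {
  expr <- tibble::tibble(
    patient_id = rep(c("a", "b", "c"), each = 2),
    gene = rep(c("GZMA", "PRF1"), 3),
    log2_tpm = c(4, 6, 5, 5, 6, 4)
  )
  cs <- cytolytic_score(expr)
  expect_equal(sum(cs$cytolytic_score), 0)
  expect_equal(cs$cytolytic_score[cs$patient_id == "b"], 0)  # at both means
  one_sd_up <- cytolytic_score(tibble::tibble(
    patient_id = rep(c("a", "b", "c"), each = 2),
    gene = rep(c("GZMA", "PRF1"), 3),
    log2_tpm = c(5, 5, 6, 6, 7, 7)))
  expect_equal(one_sd_up$cytolytic_score[one_sd_up$patient_id == "c"], 2)
  flat <- dplyr::mutate(expr, log2_tpm = 5)
  expect_error(cytolytic_score(flat), class = "neoescape_validation_error")
})

test_that("mann_whitney matches enumeration and is symmetric", {
  res <- mann_whitney(1:3, 4:6)
  expect_equal(res$raw_p, 0.1)
  expect_equal(res$raw_p, mw_enum_p(1:3, 4:6))
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$raw_p, 1)
  set.seed(8)
  x <- rnorm(6); y <- rnorm(5)
  expect_equal(mann_whitney(x, y)$raw_p, mann_whitney(y, x)$raw_p)
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "neoescape_validation_error")
})

test_that("fisher_exact reports the cross-product odds ratio", {
  res <- fisher_exact(matrix(c(10, 90, 1, 99), 2, 2, byrow = TRUE))
  expect_equal(res$odds_ratio, 11)
  flat <- fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
  zero <- fisher_exact(matrix(c(4, 0, 1, 5), 2, 2, byrow = TRUE))
  expect_true(zero$unbounded)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2, 2)),
               class = "neoescape_validation_error")
})

test_that("fisher_exact p equals hypergeometric enumeration on random tables", {
  set.seed(12)
  for (i in 1:60) {
    cells <- rmultinom(1, sample(8:30, 1), prob = runif(4, 0.05, 1))[, 1]
    tab <- matrix(cells, 2, 2)
    expect_equal(fisher_exact(tab)$p_value,
                 fisher_enum_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("bh_adjust matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  p <- runif(25)
  expect_equal(bh_adjust(p), bh_oracle(p))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "neoescape_validation_error")
})

test_that("per-tumor-type contrasts merge CRC, threshold and BH-adjust", {
  set.seed(14)
  mk <- function(type, group, n, shift = 0) tibble::tibble(
    tumor_type = type, group = group, burden = rnorm(n, 10 + shift))
  data <- dplyr::bind_rows(
    mk("COAD", "B2M_MUT", 3, shift = 3), mk("READ", "B2M_MUT", 2, shift = 3),
    mk("COAD", "WT", 20), mk("READ", "WT", 10),
    mk("LUAD", "B2M_MUT", 4, shift = 3), mk("LUAD", "WT", 20),
    mk("STAD", "B2M_MUT", 6, shift = 3), mk("STAD", "WT", 20)
  )
  res <- per_tumor_type_contrast(data, "burden", groups = "B2M_MUT")
  # COAD+READ merge to CRC (5 mutated, retained); LUAD has only 4 (dropped)
  expect_setequal(res$tumor_type, c("CRC", "STAD"))
  expect_equal(res$adjusted_p, bh_adjust(res$raw_p))

  single <- per_tumor_type_contrast(
    dplyr::bind_rows(mk("STAD", "B2M_MUT", 6), mk("STAD", "WT", 10)),
    "burden", groups = "B2M_MUT")
  expect_equal(single$adjusted_p, single$raw_p)

  expect_warning(
    empty <- per_tumor_type_contrast(
      dplyr::bind_rows(mk("LUAD", "B2M_MUT", 2), mk("LUAD", "WT", 5)),
      "burden", groups = "B2M_MUT"),
    "no tumor type")
  expect_equal(nrow(empty), 0)
})

test_that("msi_enrichment tests group membership against MSI-H status", {
  pats <- tibble::tibble(
    patient_id = sprintf("p%d", 1:40),
    group = rep(c("B2M_MUT", "WT"), c(10, 30)),
    mantis_score = c(rep(0.6, 8), rep(0.1, 2), rep(0.6, 3), rep(0.1, 27))
  )
  res <- msi_enrichment(pats, "B2M_MUT")
  expect_equal(res$odds_ratio, (8 * 27) / (2 * 3))
  expect_equal(res$p_value, fisher_enum_p(8, 2, 3, 27), tolerance = 1e-10)

  mss_only <- dplyr::mutate(pats, mantis_score = 0.1)
  expect_true(msi_enrichment(mss_only, "B2M_MUT")$degenerate)
})

test_that("tidy and glance return one-row tibbles for contrasts", {
  res <- mann_whitney(1:5, 6:10, contrast = "demo")
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("contrast", "test", "statistic", "raw_p", "adjusted_p",
                     "n1", "n2", "degenerate"))
  expect_equal(generics::glance(res), td)
})
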