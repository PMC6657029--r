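# Filters, burden and immune scores, group assignment, and the statistical
# contrast layer shared by the burden / presentation / timing / immune
# analyses.

#' Expression filter
#'
#' A mutation counts as expressed when at least `min_reads` RNA-seq reads
#' cover the mutant position (inclusive; default 5).
#'
#' @param rna_read_count Nonnegative read count(s).
#' @param min_reads Threshold (default 5).
#' @return Logical vector.
#' @export
is_expressed <- function(rna_read_count, min_reads = 5) {
  !is.na(rna_read_count) & rna_read_count >= min_reads
}

#' Nonsynonymous filter
#'
#' Coding, non-silent classifications: missense, nonsense, frameshift and
#' in-frame indels, and splice-site. Silent and noncoding mutations are
#' excluded.
#'
#' @param variant_classification Character vector of classifications.
#' @return Logical vector.
#' @export
is_nonsynonymous <- function(variant_classification) {
  variant_classification %in% NONSYNONYMOUS_CLASSES
}

#' Expressed nonsynonymous mutation burden
#'
#' Per patient: the number of expressed nonsynonymous mutations plus a
#' pseudocount of 1 (so empty patients contribute burden 1 and log-scale
#' summaries stay finite).
#'
#' @param mutations Mutation tibble (may cover many patients; may be empty).
#' @param min_reads RNA read threshold of the expression filter.
#' @return Tibble `patient_id`, `burden` covering every patient present in
#'   `mutations`.
#' @export
mutation_burden <- function(mutations, min_reads = 5) {
  if (nrow(mutations) == 0) {
    return(tibble(patient_id = character(), burden = double()))
  }
  mutations %>%
    group_by(.data$patient_id) %>%
    summarise(burden = sum(is_nonsynonymous(.data$variant_classification) &
                             is_expressed(.data$rna_read_count, min_reads)) + 1,
              .groups = "drop")
}

#' Microsatellite status from a MANTIS score
#'
#' Scores at or above the threshold (default 0.4, boundary inclusive) are
#' MSI-H, below it MSS.
#'
#' @param mantis_score Nonnegative score(s).
#' @param threshold MANTIS threshold (default 0.4).
#' @return Character vector in `c("MSI_H", "MSS")`.
#' @export
msi_status <- function(mantis_score, threshold = 0.4) {
  if (any(mantis_score < 0, na.rm = TRUE)) {
    abort_validation("MANTIS score must be nonnegative")
  }
  ifelse(mantis_score >= threshold, "MSI_H", "MSS")
}

#' Escape-group assignment from mutation calls
#'
#' Classifies each patient by their somatic B2M / HLA-A/B/C mutations:
#' nonsynonymous mutations in both genes give `BOTH`, in B2M only `B2M_MUT`,
#' in HLA only `HLA_MUT`; patients whose B2M/HLA mutations are all synonymous
#' are `SYN_ONLY` (excluded from every contrast); patients with no B2M/HLA
#' mutation are `WT`.
#'
#' @param mutations Mutation tibble.
#' @param patient_ids All patient ids of the cohort (patients without any
#'   escape-gene mutation are `WT`).
#' @return Tibble `patient_id`, `group`.
#' @export
assign_groups <- function(mutations, patient_ids) {
  esc <- mutations %>%
    filter(.data$gene %in% ESCAPE_GENES) %>%
    mutate(is_b2m = .data$gene == "B2M",
           nonsyn = is_nonsynonymous(.data$variant_classification)) %>%
    group_by(.data$patient_id) %>%
    summarise(b2m_ns = any(.data$is_b2m & .data$nonsyn),
              hla_ns = any(!.data$is_b2m & .data$nonsyn),
              any_esc = TRUE, .groups = "drop")
  tibble(patient_id = patient_ids) %>%
    left_join(esc, by = "patient_id") %>%
    mutate(group = case_when(
      is.na(.data$any_esc) ~ "WT",
      .data$b2m_ns & .data$hla_ns ~ "BOTH",
      .data$b2m_ns ~ "B2M_MUT",
      .data$hla_ns ~ "HLA_MUT",
      TRUE ~ "SYN_ONLY"
    )) %>%
    select("patient_id", "group")
}

#' Cytolytic immune activity score
#'
#' Per-patient sum of the cohort-wise z-scored log2 TPM expression of
#' granzyme A (GZMA) and perforin (PRF1); by construction the cohort mean of
#' the score is 0 and a patient one standard deviation above the mean on both
#' genes scores 2.
#'
#' @param expression Long tibble `patient_id`, `gene`, `log2_tpm` containing
#'   GZMA and PRF1 rows for at least two patients with nonzero variance.
#' @return Tibble `patient_id`, `gzma`, `prf1`, `cytolytic_score`.
#' @export
cytolytic_score <- function(expression) {
  wide <- expression %>%
    filter(.data$gene %in% c("GZMA", "PRF1")) %>%
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "gene",
                       values_from = "log2_tpm")
  if (!all(c("GZMA", "PRF1") %in% names(wide)) || nrow(wide) < 2) {
    abort_validation("need GZMA and PRF1 values for at least 2 patients")
  }
  if (sd(wide$GZMA) == 0 || sd(wide$PRF1) == 0) {
    abort_validation("zero variance in GZMA or PRF1 across the cohort")
  }
  wide %>%
    mutate(cytolytic_score = as.numeric(scale(.data$GZMA)) +
             as.numeric(scale(.data$PRF1))) %>%
    select("patient_id", gzma = "GZMA", prf1 = "PRF1", "cytolytic_score")
}

#' Two-sided Mann-Whitney (rank-sum) test
#'
#' Unpaired, two-sided comparison of two samples. The exact null distribution
#' is used for small samples without ties; otherwise the normal approximation
#' with tie correction (the `stats::wilcox.test` conventions).
#'
#' @param x,y Numeric samples (both nonempty).
#' @param contrast Label stored in the result.
#' @return A `"neo_test"` with the U statistic of `x` as reference.
#' @export
mann_whitney <- function(x, y, contrast = "x vs y") {
  if (length(x) == 0 || length(y) == 0) {
    abort_validation("both samples must be nonempty")
  }
  ht <- suppressWarnings(wilcox.test(x, y))
  new_neo_test(contrast, "mann_whitney", statistic = unname(ht$statistic),
               p_value = ht$p.value, n1 = length(x), n2 = length(y))
}

#' Fisher's exact test with the sample odds ratio
#'
#' Two-sided exact p-value (hypergeometric enumeration, via
#' `stats::fisher.test`) together with the sample cross-product odds ratio
#' `(a*d)/(b*c)` — not the conditional MLE. A zero off-diagonal cell makes
#' the odds ratio unbounded (`Inf`), flagged in the result.
#'
#' @param table 2x2 matrix of nonnegative integer counts, rows = exposure
#'   (e.g. mutant / wild-type), columns = outcome (e.g. MSI-H / MSS).
#' @param contrast Label stored in the result.
#' @return Tibble `contrast`, `odds_ratio`, `p_value`, `unbounded`, plus the
#'   four cell counts.
#' @export
fisher_exact <- function(table, contrast = "2x2 association") {
  if (!is.matrix(table) || any(dim(table) != c(2, 2))) {
    abort_validation("`table` must be a 2x2 matrix")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort_validation("cell counts must be nonnegative integers")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c)
  degenerate <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  p <- if (degenerate) 1 else stats::fisher.test(table)$p.value
  tibble(contrast = contrast, a = a, b = b, c = c, d = d,
         odds_ratio = or, p_value = p,
         unbounded = is.nan(or) | is.infinite(or) | or == 0,
         degenerate = degenerate)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply by
#' `m / i`, enforce monotonicity from the largest p down, cap at 1, return in
#' the original order. Delegates to `stats::p.adjust(method = "BH")` after
#' validating the input range.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, elementwise at least the raw ones.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    abort_validation("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Merge colon and rectal tumor types
#'
#' COAD and READ are merged under the code CRC before cancer-type-specific
#' stratification.
#'
#' @param tumor_type Character vector of tumor-type codes.
#' @return Character vector with COAD/READ replaced by CRC.
#' @export
merge_crc <- function(tumor_type) {
  ifelse(tumor_type %in% c("COAD", "READ"), "CRC", tumor_type)
}

#' Per-tumor-type group contrasts
#'
#' Stratified analysis of a per-patient variable (burden, cytolytic score,
#' CD8/NK level, ...): COAD and READ are merged to CRC, tumor types with
#' fewer than `min_mutated` mutated patients in a group are dropped, each
#' retained (type, group) stratum is compared against the wild-type patients
#' of the same type with a two-sided Mann-Whitney test, and the emitted
#' family of p-values is BH-adjusted.
#'
#' @param data Per-patient tibble with `tumor_type`, `group` and the variable.
#' @param variable Name of the numeric column to compare.
#' @param min_mutated Minimum mutated patients per retained tumor type
#'   (default 5).
#' @param groups Mutant groups contrasted against `WT`.
#' @return Tibble of contrasts (possibly zero rows, with a warning) with
#'   `raw_p` and BH `adjusted_p`.
#' @export
per_tumor_type_contrast <- function(data, variable, min_mutated = 5,
                                    groups = c("B2M_MUT", "HLA_MUT")) {
  if (!variable %in% names(data)) {
    abort_validation(sprintf("no column `%s` in data", variable))
  }
  data <- data %>% mutate(tumor_type = merge_crc(.data$tumor_type))
  res <- list()
  for (g in groups) {
    strata <- data %>%
      filter(.data$group %in% c(g, "WT")) %>%
      group_by(.data$tumor_type) %>%
      filter(sum(.data$group == g) >= min_mutated,
             sum(.data$group == "WT") >= 1) %>%
      ungroup()
    for (tt in unique(strata$tumor_type)) {
      x <- strata[[variable]][strata$tumor_type == tt & strata$group == g]
      y <- strata[[variable]][strata$tumor_type == tt & strata$group == "WT"]
      res[[length(res) + 1L]] <- tidy(mann_whitney(
        x, y, contrast = sprintf("%s: %s vs WT (%s)", tt, g, variable))) %>%
        mutate(tumor_type = tt, group = g)
    }
  }
  if (length(res) == 0) {
    warning("no tumor type retained at min_mutated = ", min_mutated)
    return(tibble(contrast = character(), test = character(),
                  statistic = double(), raw_p = double(),
                  adjusted_p = double(), n1 = integer(), n2 = integer(),
                  degenerate = logical(), tumor_type = character(),
                  group = character()))
  }
  bind_rows(res) %>%
    mutate(adjusted_p = bh_adjust(.data$raw_p))
}

#' MSI enrichment of an escape group
#'
#' Fisher's exact association between carrying an escape mutation (the given
#' group versus wild-type) and MSI-H status, with the sample odds ratio.
#'
#' @param patients Patient tibble with `group` and `mantis_score`.
#' @param group Escape group to test (e.g. `"B2M_MUT"`); `"ESCAPE"` pools
#'   B2M_MUT, HLA_MUT and BOTH.
#' @param msi_threshold MANTIS threshold (default 0.4).
#' @return A [fisher_exact()] result tibble; degenerate margins (e.g. no
#'   MSI-H patient at all) are flagged rather than an error.
#' @export
msi_enrichment <- function(patients, group = "B2M_MUT", msi_threshold = 0.4) {
  mut_groups <- if (identical(group, "ESCAPE")) {
    c("B2M_MUT", "HLA_MUT", "BOTH")
  } else {
    group
  }
  df <- patients %>%
    filter(.data$group %in% c(mut_groups, "WT")) %>%
    mutate(mutant = .data$group %in% mut_groups,
           msi = msi_status(.data$mantis_score, msi_threshold) == "MSI_H")
  tab <- matrix(c(sum(df$mutant & df$msi), sum(df$mutant & !df$msi),
                  sum(!df$mutant & df$msi), sum(!df$mutant & !df$msi)),
                2, 2, byrow = TRUE)
  fisher_exact(tab, contrast = sprintf("%s x MSI-H", group))
}
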