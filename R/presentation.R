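# MHC-I presentation scoring: patient harmonic-mean best rank (PHBR) over the
# six HLA allele slots, binding calls, binding-fraction curves, and the
# mutant-allele bias statistics for HLA-mutant patients.

#' Best binding rank of a mutation at one allele
#'
#' Reduces the peptide-level binding percentile ranks of one (mutation, allele
#' slot) pair to the best (minimum) rank — the quantity the PHBR score is
#' built from.
#'
#' @param peptide_ranks Numeric vector of positive percentile ranks.
#' @return The minimum rank.
#' @export
best_rank_per_allele <- function(peptide_ranks) {
  if (length(peptide_ranks) == 0) {
    abort_validation("no peptide ranks supplied")
  }
  if (any(peptide_ranks <= 0 | is.na(peptide_ranks))) {
    abort_validation("peptide ranks must be positive")
  }
  min(peptide_ranks)
}

#' Patient harmonic-mean best rank (PHBR)
#'
#' The PHBR score of a mutation is the harmonic mean of its best binding
#' percentile rank across the patient's six HLA allele slots (homozygous
#' alleles contribute duplicate values): `6 / sum(1 / r_i)`. The score is
#' bounded by the per-slot extremes and dominated by the strongest-binding
#' allele, so a single well-presenting allele keeps the score low.
#'
#' @param best_ranks Numeric vector of exactly 6 positive best ranks.
#' @return The PHBR score.
#' @examples
#' phbr_score(c(1, 2, 3, 4, 5, 6))
#' @export
phbr_score <- function(best_ranks) {
  if (length(best_ranks) != 6) {
    abort_validation("PHBR requires exactly 6 per-allele best ranks")
  }
  if (any(best_ranks <= 0 | is.na(best_ranks))) {
    abort_validation("best ranks must be positive")
  }
  6 / sum(1 / best_ranks)
}

#' Binding call at a PHBR cutoff
#'
#' A mutation is called a binding neoantigen when its PHBR score is less than
#' or equal to the cutoff (inclusive boundary; default 2).
#'
#' @param phbr Positive PHBR score(s).
#' @param cutoff Positive cutoff, default 2.
#' @return Logical vector.
#' @export
is_binding <- function(phbr, cutoff = 2) {
  if (any(phbr <= 0 | is.na(phbr))) abort_validation("PHBR must be positive")
  phbr <= cutoff
}

#' PHBR scores for every mutation in a rank table
#'
#' Data-frame-first wrapper: collapses a long rank table (one or more rows per
#' mutation and allele slot) to per-slot best ranks, computes the PHBR score
#' per mutation and calls binding at `cutoff`.
#'
#' @param ranks Tibble with `mutation_id`, `slot`, `rank`.
#' @param cutoff Binding cutoff on the PHBR score (default 2).
#' @return Tibble `mutation_id`, `phbr`, `binding`.
#' @export
score_phbr <- function(ranks, cutoff = 2) {
  if (nrow(ranks) == 0) {
    return(tibble(mutation_id = character(), phbr = double(),
                  binding = logical()))
  }
  if (any(ranks$rank <= 0)) abort_validation("ranks must be positive")
  out <- ranks %>%
    group_by(.data$mutation_id, .data$slot) %>%
    summarise(best = min(.data$rank), .groups = "drop_last") %>%
    summarise(n_slots = n(), phbr = 6 / sum(1 / .data$best),
              .groups = "drop")
  if (any(out$n_slots != 6)) {
    abort_validation("every mutation must have best ranks for all 6 slots")
  }
  out %>%
    mutate(binding = .data$phbr <= cutoff) %>%
    select("mutation_id", "phbr", "binding")
}

# Expressed missense+indel mutations: the denominator set of the
# binding-fraction analyses.
neoantigenic_expressed <- function(mutations, min_reads = 5) {
  mutations %>%
    filter(.data$variant_classification %in% NEOANTIGENIC_CLASSES,
           is_expressed(.data$rna_read_count, min_reads))
}

#' Fraction of binding neoantigens
#'
#' `binding_fraction()` is the per-patient summary statistic of the
#' presentation analysis: among a patient's expressed missense and indel
#' mutations, the proportion whose PHBR score is at or below the cutoff. An
#' empty denominator yields `NA` and the patient is excluded from group
#' summaries.
#'
#' @param phbr Numeric vector of PHBR scores of the patient's expressed
#'   missense/indel mutations (may be empty).
#' @param cutoff Binding cutoff (default 2).
#' @return A proportion, or `NA` for an empty input.
#' @export
binding_fraction <- function(phbr, cutoff = 2) {
  if (length(phbr) == 0) return(NA_real_)
  mean(phbr <= cutoff)
}

#' Per-patient binding fractions
#'
#' @param mutations Cohort mutation tibble.
#' @param ranks Rank tibble.
#' @param cutoff Binding cutoff (default 2).
#' @param min_reads RNA read threshold for the expression filter.
#' @return Tibble `patient_id`, `n_expressed`, `fraction`.
#' @export
patient_binding_fractions <- function(mutations, ranks, cutoff = 2,
                                      min_reads = 5) {
  denom <- neoantigenic_expressed(mutations, min_reads)
  scored <- score_phbr(semi_join(ranks, denom, by = "mutation_id"),
                       cutoff = cutoff)
  denom %>%
    left_join(scored, by = "mutation_id") %>%
    group_by(.data$patient_id) %>%
    summarise(n_expressed = n(),
              fraction = mean(.data$phbr <= cutoff, na.rm = TRUE),
              .groups = "drop")
}

#' Median binding-fraction curve by patient group
#'
#' For each cutoff, computes each patient's binding fraction and takes the
#' median across the patients of each group — the empirical curve used to
#' compare groups over a range of PHBR cutoffs. The curve is nondecreasing in
#' the cutoff.
#'
#' @param mutations,ranks Cohort tables.
#' @param groups Tibble `patient_id`, `group` (patients without expressed
#'   missense/indel mutations are excluded).
#' @param cutoffs Numeric vector of PHBR cutoffs.
#' @param min_reads RNA read threshold for the expression filter.
#' @return Tibble `group`, `cutoff`, `median_fraction`, `n_patients`.
#' @export
binding_fraction_curve <- function(mutations, ranks, groups,
                                   cutoffs = c(0.5, 1, 2, 4, 8, 16, 32, 64,
                                               100),
                                   min_reads = 5) {
  denom <- neoantigenic_expressed(mutations, min_reads)
  denom <- semi_join(denom, groups, by = "patient_id")
  if (nrow(denom) == 0) {
    abort_validation("no expressed missense/indel mutations in any group")
  }
  scored <- score_phbr(semi_join(ranks, denom, by = "mutation_id"),
                       cutoff = max(cutoffs))
  per_mut <- denom %>%
    inner_join(scored, by = "mutation_id") %>%
    inner_join(groups, by = "patient_id")
  purrr::map(cutoffs, function(ct) {
    per_mut %>%
      group_by(.data$group, .data$patient_id) %>%
      summarise(fraction = mean(.data$phbr <= ct), .groups = "drop_last") %>%
      summarise(cutoff = ct, median_fraction = median(.data$fraction),
                n_patients = n(), .groups = "drop")
  }) %>%
    bind_rows() %>%
    arrange(.data$group, .data$cutoff)
}

#' Allele-specific binding counts per patient
#'
#' Counts, for each of the six allele slots, how many of a patient's expressed
#' missense/indel mutations have a per-slot best rank at or below the cutoff.
#' This is the allele-level call (the slot's own best rank), not the PHBR.
#'
#' @param mutations,ranks Cohort tables.
#' @param cutoff Allele-level rank cutoff (default 2).
#' @param min_reads RNA read threshold.
#' @return Tibble `patient_id`, `slot`, `n_binding` with all 6 slots per
#'   patient (zero-filled).
#' @export
allele_binding_counts <- function(mutations, ranks, cutoff = 2,
                                  min_reads = 5) {
  denom <- neoantigenic_expressed(mutations, min_reads)
  pats <- distinct(mutations, .data$patient_id)
  grid <- tidyr::expand_grid(patient_id = pats$patient_id, slot = 1:6)
  if (nrow(denom) == 0) {
    return(grid %>% mutate(n_binding = 0L))
  }
  counts <- ranks %>%
    inner_join(select(denom, "mutation_id", "patient_id"),
               by = "mutation_id") %>%
    group_by(.data$patient_id, .data$mutation_id, .data$slot) %>%
    summarise(best = min(.data$rank), .groups = "drop") %>%
    filter(.data$best <= cutoff) %>%
    count(.data$patient_id, .data$slot, name = "n_binding")
  grid %>%
    left_join(counts, by = c("patient_id", "slot")) %>%
    mutate(n_binding = dplyr::coalesce(.data$n_binding, 0L))
}

#' Mutant-allele binding bias of HLA-mutant patients
#'
#' For each HLA-mutant patient, compares the number of expressed neoantigens
#' that bind the mutated HLA allele slot against the arithmetic mean count
#' across the five other slots, and records the direction (`mut_higher`,
#' `other_higher`, `tied`). Duplicate allele strings (homozygosity) are still
#' distinct slots.
#'
#' @param mutations,ranks Cohort tables.
#' @param patients Patient tibble; only rows with a defined `mutated_slot`
#'   (groups `HLA_MUT`/`BOTH`) are used.
#' @param cutoff Allele-level rank cutoff (default 2).
#' @param min_reads RNA read threshold.
#' @return Tibble `patient_id`, `n_mut_allele`, `mean_other`, `direction`.
#' @export
mutant_allele_bias <- function(mutations, ranks, patients, cutoff = 2,
                               min_reads = 5) {
  carriers <- patients %>% filter(.data$group %in% c("HLA_MUT", "BOTH"))
  if (any(is.na(carriers$mutated_slot))) {
    abort_validation("HLA-mutant patient without a mutated_slot")
  }
  if (nrow(carriers) == 0) {
    return(tibble(patient_id = character(), n_mut_allele = integer(),
                  mean_other = double(), direction = character()))
  }
  counts <- allele_binding_counts(
    semi_join(mutations, carriers, by = "patient_id"), ranks,
    cutoff = cutoff, min_reads = min_reads)
  counts %>%
    inner_join(select(carriers, "patient_id", "mutated_slot"),
               by = "patient_id") %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_mut_allele = sum(.data$n_binding[.data$slot == .data$mutated_slot]),
      mean_other = mean(.data$n_binding[.data$slot != .data$mutated_slot]),
      .groups = "drop") %>%
    mutate(direction = case_when(
      .data$n_mut_allele > .data$mean_other ~ "mut_higher",
      .data$n_mut_allele < .data$mean_other ~ "other_higher",
      TRUE ~ "tied"
    ))
}

#' Paired test of mutant-allele binding bias
#'
#' Two-sided paired Wilcoxon signed-rank test of the per-patient difference
#' between the mutated-slot neoantigen count and the mean count across the
#' five other slots. Zero differences are dropped (Wilcoxon convention); the
#' exact null is used for n <= 25 nonzero pairs without ties, the normal
#' approximation otherwise. If every difference is zero the result is flagged
#' degenerate with p = 1.
#'
#' @param bias Tibble from [mutant_allele_bias()].
#' @return A `"neo_test"` object (see [tidy.neo_test()]).
#' @export
bias_test <- function(bias) {
  d <- bias$n_mut_allele - bias$mean_other
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(new_neo_test("mutant allele bias", "wilcoxon_paired",
                        statistic = NA_real_, p_value = 1,
                        n1 = nrow(bias), n2 = nrow(bias), degenerate = TRUE))
  }
  if (length(nz) < 2) {
    abort_validation("need >= 2 patients with nonzero paired difference")
  }
  v <- sum(rank(abs(nz))[nz > 0])
  p <- if (length(nz) <= 25) {
    exact_signed_rank_p(nz)
  } else {
    suppressWarnings(wilcox.test(bias$n_mut_allele, bias$mean_other,
                                 paired = TRUE, exact = FALSE))$p.value
  }
  new_neo_test("mutant allele bias", "wilcoxon_paired",
               statistic = v, p_value = p,
               n1 = nrow(bias), n2 = nrow(bias))
}

# Exact two-sided signed-rank p-value under the sign-flip null, valid with
# tied |differences| (mid-ranks). The null distribution of V = sum of ranks
# of positive differences is built by generating-function convolution over
# doubled ranks (so mid-ranks become integers); it is symmetric about
# sum(ranks)/2, and the two-sided p is the symmetric tail mass at the
# observed V.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  v_obs <- sum(r2[d > 0])
  total <- sum(r2)
  coef <- numeric(total + 1)
  coef[1] <- 1
  for (r in r2) {
    coef <- coef + c(rep(0, r), coef[seq_len(total + 1 - r)])
  }
  probs <- coef / 2^n
  center <- total / 2
  sum(probs[abs(seq(0, total) - center) >= abs(v_obs - center) - 1e-9])
}

#' Early-versus-late contrast of mutant-allele binding
#'
#' Stratifies HLA-mutant patients by the allelic-fraction percentile of their
#' HLA escape mutation — early (> 60th percentile) versus late (< 40th) — and
#' compares the number of expressed neoantigens binding the mutated allele
#' between the strata with a two-sided unpaired Mann-Whitney test. MSI-H
#' patients and patients mutated in both B2M and HLA are excluded;
#' intermediate-percentile patients fall in neither stratum.
#'
#' @param cohort A `"neo_cohort"`.
#' @param cutoff Allele-level rank cutoff (default 2).
#' @param min_reads RNA read threshold.
#' @param msi_threshold MANTIS threshold for the MSI-H exclusion.
#' @return A `"neo_test"` with the early stratum as reference sample.
#' @export
timing_bias_contrast <- function(cohort, cutoff = 2, min_reads = 5,
                                 msi_threshold = 0.4) {
  pats <- cohort$patients %>%
    filter(.data$group == "HLA_MUT",
           msi_status(.data$mantis_score, msi_threshold) == "MSS")
  if (nrow(pats) == 0) abort_validation("no eligible HLA-mutant patients")
  timing <- annotate_timing(
    semi_join(cohort$mutations, pats, by = "patient_id"),
    min_reads = min_reads)
  esc <- timing %>%
    inner_join(select(cohort$mutations, "mutation_id", "gene",
                      "variant_classification"), by = "mutation_id") %>%
    filter(.data$gene %in% c("HLA-A", "HLA-B", "HLA-C"),
           .data$variant_classification %in% NONSYNONYMOUS_CLASSES,
           !is.na(.data$timing_class))
  bias <- mutant_allele_bias(
    semi_join(cohort$mutations, pats, by = "patient_id"),
    cohort$ranks, pats, cutoff = cutoff, min_reads = min_reads)
  strata <- esc %>%
    inner_join(bias, by = "patient_id") %>%
    filter(.data$timing_class %in% c("early", "late"))
  early <- strata$n_mut_allele[strata$timing_class == "early"]
  late <- strata$n_mut_allele[strata$timing_class == "late"]
  if (length(early) == 0 || length(late) == 0) {
    abort_validation("empty early or late stratum")
  }
  mann_whitney(early, late, contrast = "early vs late mutant-allele binding")
}
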