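# Mutation timing from variant allelic fractions: AF computation, within-tumor
# percentile ranking, copy-number exclusion and early/late classification.

#' Tumor allelic fraction
#'
#' `t_alt_count / t_depth`: the fraction of tumor reads supporting the mutant
#' allele. Vectorized.
#'
#' @param t_alt_count Alternate-allele read count(s).
#' @param t_depth Total read depth(s); must be positive and at least
#'   `t_alt_count`.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
allelic_fraction <- function(t_alt_count, t_depth) {
  if (any(t_depth <= 0 | is.na(t_depth))) {
    abort_validation("t_depth must be positive")
  }
  if (any(t_alt_count < 0 | t_alt_count > t_depth, na.rm = TRUE)) {
    abort_validation("t_alt_count must be in [0, t_depth]")
  }
  t_alt_count / t_depth
}

# Mid-rank percentile of each value within its own vector: for value i,
# 100 * (c_below + 0.5 * c_tied_others) / (n - 1). Unique minimum -> 0,
# unique maximum -> 100, all-tied -> 50. Singleton -> NA.
af_percentiles <- function(af) {
  n <- length(af)
  if (n < 2) return(rep(NA_real_, n))
  100 * (rank(af, ties.method = "average") - 1) / (n - 1)
}

#' Within-tumor allelic-fraction percentile
#'
#' Ranks one mutation's allelic fraction against all other mutations observed
#' in the same tumor: `100 * (c_below + 0.5 * c_tied) / (n - 1)`, where
#' `c_below` counts other mutations with strictly smaller AF and `c_tied`
#' those tied with the target. A unique minimum scores 0, a unique maximum
#' 100; tumors with a single mutation have no defined percentile (`NA`).
#'
#' @param target_af The AF of the mutation of interest; must be an element of
#'   `patient_afs`.
#' @param patient_afs AFs of all analyzed mutations in the same tumor,
#'   including the target.
#' @return Percentile in \[0, 100\], or `NA` for a singleton list.
#' @export
af_percentile <- function(target_af, patient_afs) {
  idx <- which(patient_afs == target_af)
  if (length(idx) == 0) {
    abort_validation("target_af must be a member of patient_afs")
  }
  if (length(patient_afs) < 2) return(NA_real_)
  others <- patient_afs[-idx[1]]
  100 * (sum(others < target_af) + 0.5 * sum(others == target_af)) /
    (length(patient_afs) - 1)
}

#' Copy-number overlap of mutations
#'
#' Flags mutations falling inside a copy-number-variant segment of the same
#' patient: a segment counts as CNV when its log2 fold-change is strictly
#' greater than 0.1 or strictly smaller than -0.1 (a segment at exactly 0.1
#' is copy-neutral). Coordinates are 1-based inclusive.
#'
#' @param mutations Tibble with `mutation_id`, `patient_id`, `chrom`, `pos`.
#' @param segments Tibble with `patient_id`, `chrom`, `start`, `end`,
#'   `log2fc`.
#' @param threshold Absolute log2 fold-change above which a segment is CNV
#'   (default 0.1, strict).
#' @return Logical vector along the rows of `mutations`.
#' @export
in_cnv <- function(mutations, segments, threshold = 0.1) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(rep(FALSE, nrow(mutations)))
  }
  cnv <- segments %>% filter(abs(.data$log2fc) > threshold)
  if (nrow(cnv) == 0) return(rep(FALSE, nrow(mutations)))
  hits <- mutations %>%
    mutate(.row = row_number()) %>%
    inner_join(cnv, by = join_by(patient_id, chrom,
                                 between(pos, start, end))) %>%
    distinct(.data$.row)
  seq_len(nrow(mutations)) %in% hits$.row
}

#' Early/late classification from a VAF percentile
#'
#' Mutations above the 60th within-tumor AF percentile are classed `early`
#' (clonal, high cell fraction), below the 40th `late` (subclonal), and the
#' band in between `intermediate` (excluded from the early/late contrast).
#' Boundaries are strict.
#'
#' @param percentile Percentile(s) in \[0, 100\].
#' @param low,high Stratum cutoffs (default 40 / 60).
#' @return Character vector in `c("early", "late", "intermediate")`.
#' @export
classify_timing <- function(percentile, low = 40, high = 60) {
  ok <- !is.na(percentile)
  if (any(percentile[ok] < 0 | percentile[ok] > 100)) {
    abort_validation("percentile must be in [0, 100]")
  }
  out <- rep(NA_character_, length(percentile))
  out[ok] <- dplyr::case_when(
    percentile[ok] < low ~ "late",
    percentile[ok] > high ~ "early",
    TRUE ~ "intermediate"
  )
  out
}

#' Timing annotation of expressed mutations
#'
#' Computes, per patient, the allelic fraction of every expressed mutation,
#' its percentile within the patient's expressed mutations, its copy-number
#' overlap, and the early/late/intermediate class. With `exclude_cnv = TRUE`
#' (the copy-number robustness variant) mutations in CNV regions are dropped
#' before percentiles are computed; the default retains them.
#'
#' @param mutations Cohort mutation tibble.
#' @param segments Optional segment tibble for the CNV flag.
#' @param exclude_cnv Drop CNV-region mutations before ranking?
#' @param min_reads RNA read threshold for the expression filter.
#' @param low,high Percentile cutoffs passed to [classify_timing()].
#' @return Tibble `mutation_id`, `patient_id`, `af`, `percentile`, `in_cnv`,
#'   `timing_class`.
#' @export
annotate_timing <- function(mutations, segments = NULL, exclude_cnv = FALSE,
                            min_reads = 5, low = 40, high = 60) {
  expressed <- mutations %>%
    filter(is_expressed(.data$rna_read_count, min_reads))
  expressed$in_cnv <- in_cnv(expressed, segments)
  if (exclude_cnv) expressed <- expressed %>% filter(!.data$in_cnv)
  expressed %>%
    mutate(af = allelic_fraction(.data$t_alt_count, .data$t_depth)) %>%
    group_by(.data$patient_id) %>%
    mutate(percentile = af_percentiles(.data$af)) %>%
    ungroup() %>%
    mutate(timing_class = classify_timing(.data$percentile, low, high)) %>%
    select("mutation_id", "patient_id", "af", "percentile", "in_cnv",
           "timing_class")
}

#' Escape-mutation VAF percentiles by group
#'
#' Convenience layer over [annotate_timing()]: returns the within-tumor AF
#' percentile of each patient's B2M / HLA escape mutation together with the
#' patient group, the input of the timing distribution comparison.
#'
#' @param cohort A `"neo_cohort"`.
#' @inheritParams annotate_timing
#' @return Tibble `patient_id`, `group`, `gene`, `mutation_id`, `af`,
#'   `percentile`, `in_cnv`, `timing_class`.
#' @export
escape_timing <- function(cohort, segments = NULL, exclude_cnv = FALSE,
                          min_reads = 5) {
  timing <- annotate_timing(cohort$mutations, segments = segments,
                            exclude_cnv = exclude_cnv, min_reads = min_reads)
  cohort$mutations %>%
    filter(.data$gene %in% ESCAPE_GENES,
           .data$variant_classification %in% NONSYNONYMOUS_CLASSES) %>%
    inner_join(timing, by = c("mutation_id", "patient_id")) %>%
    inner_join(select(cohort$patients, "patient_id", "group"),
               by = "patient_id") %>%
    select("patient_id", "group", "gene", "mutation_id", "af", "percentile",
           "in_cnv", "timing_class") %>%
    filter(!is.na(.data$percentile))
}

#' Kolmogorov-Smirnov comparison of two percentile distributions
#'
#' Two-sample, two-sided KS test of the B2M versus HLA escape-mutation VAF
#' percentile distributions (or any two numeric samples).
#'
#' @param x,y Numeric samples (e.g. B2M and HLA percentiles).
#' @param contrast Label stored in the result.
#' @return A `"neo_test"` with the KS statistic D.
#' @export
timing_distribution_test <- function(x, y,
                                     contrast = "B2M vs HLA VAF percentile") {
  if (length(x) == 0 || length(y) == 0) {
    abort_validation("both samples must be nonempty")
  }
  ht <- suppressWarnings(ks.test(x, y))
  new_neo_test(contrast, "ks_two_sample", statistic = unname(ht$statistic),
               p_value = ht$p.value, n1 = length(x), n2 = length(y))
}
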