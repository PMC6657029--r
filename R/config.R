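#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of [simulate_cohort()]. Defaults describe
#' a cohort with the qualitative structure seen in pan-cancer immune-escape
#' analyses: escape-mutant patients carry an inflated expressed nonsynonymous
#' burden, escape mutations are strongly enriched in microsatellite-instable
#' (MSI-H) tumors, neoantigens in HLA-mutant patients are biased toward the
#' mutated allele, B2M escape mutations sit at high variant-allele-fraction
#' (VAF) percentiles while HLA escape mutations are bimodal.
#'
#' @param n_patients Number of patients.
#' @param frac_b2m_mut,frac_hla_mut,frac_both Fractions of patients carrying a
#'   nonsynonymous B2M mutation only, an HLA mutation only, or one of each.
#'   Must sum to at most 1.
#' @param frac_msi Marginal fraction of MSI-H patients.
#' @param msi_enrichment_or Target odds ratio of escape mutation given MSI-H
#'   status; MSI is assigned per group so the population OR equals this value
#'   while the marginal MSI fraction stays at `frac_msi`.
#' @param baseline_burden_mean Mean number of expressed nonsynonymous
#'   mutations in a wild-type MSS patient (negative-binomial).
#' @param burden_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param burden_multiplier_b2m,burden_multiplier_hla,burden_multiplier_msi
#'   Fold-changes applied to `baseline_burden_mean` for B2M-mutant,
#'   HLA-mutant and MSI-H patients (patients with both a B2M and HLA mutation
#'   use the B2M multiplier; the MSI multiplier compounds multiplicatively).
#' @param bias_strength Probability that a neoantigen in an HLA-mutant patient
#'   has its rank at the mutated allele slot replaced by a strong-binder draw
#'   (uniform on (0, 2]). 0 disables the mutant-allele bias.
#' @param rank_distribution `"uniform"` (percentile ranks uniform on
#'   `(rank_min, rank_max]`, the literal behaviour of a percentile rank for a
#'   random peptide) or `"loguniform"`.
#' @param rank_min,rank_max Support of the per-allele rank distribution.
#' @param vaf_model Named list of Beta parameters for escape-mutation VAFs:
#'   `b2m_shape1/b2m_shape2` (high-VAF component, also the high half of the
#'   HLA mixture), `hla_low_shape1/hla_low_shape2` (low-VAF component) and
#'   `hla_high_weight` (mixture weight of the high component for HLA
#'   mutations). Setting `hla_high_weight = 1` with identical shapes makes the
#'   two groups exchangeable (the null of the timing comparison).
#' @param depth_mean Mean sequencing depth (Poisson); alt reads are
#'   binomial(depth, VAF).
#' @param expressed_prob Probability a mutation passes the RNA expression
#'   filter.
#' @param cnv_fraction Probability that a generated copy-number segment has
#'   |log2 fold-change| > 0.1 (i.e. counts as a CNV region).
#' @param homozygous_prob Per-gene probability that a patient's two allele
#'   slots carry the same allele string.
#' @param silent_rate Expected silent passengers as a fraction of
#'   nonsynonymous passengers.
#' @param rna_mean Mean RNA read count of an expressed mutation (shifted
#'   Poisson, minimum 5).
#' @param tumor_types Character vector of tumor-type codes sampled uniformly.
#' @param seed Integer seed; a fixed seed makes [simulate_cohort()] and
#'   [write_cohort()] byte-reproducible. `NULL` uses the session RNG stream.
#'
#' @return A validated list of class `"cohort_config"`.
#' @seealso [simulate_cohort()], [read_cohort_config()]
#' @examples
#' cfg <- cohort_config(n_patients = 100, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
cohort_config <- function(n_patients = 500,
                          frac_b2m_mut = 0.10,
                          frac_hla_mut = 0.20,
                          frac_both = 0.01,
                          frac_msi = 0.15,
                          msi_enrichment_or = 15,
                          baseline_burden_mean = 50,
                          burden_dispersion = 2,
                          burden_multiplier_b2m = 2,
                          burden_multiplier_hla = 1.5,
                          burden_multiplier_msi = 4,
                          bias_strength = 0.15,
                          rank_distribution = c("uniform", "loguniform"),
                          rank_min = 0.01,
                          rank_max = 100,
                          vaf_model = list(
                            b2m_shape1 = 8, b2m_shape2 = 2,
                            hla_low_shape1 = 2, hla_low_shape2 = 8,
                            hla_high_weight = 0.5
                          ),
                          depth_mean = 80,
                          expressed_prob = 0.8,
                          cnv_fraction = 0.1,
                          homozygous_prob = 0.15,
                          silent_rate = 0.15,
                          rna_mean = 30,
                          tumor_types = c("COAD", "READ", "STAD", "UCEC",
                                          "LUAD", "CESC", "BRCA", "SKCM"),
                          seed = NULL) {
  rank_distribution <- match.arg(rank_distribution)
  cfg <- list(
    n_patients = as.integer(n_patients),
    frac_b2m_mut = frac_b2m_mut, frac_hla_mut = frac_hla_mut,
    frac_both = frac_both, frac_msi = frac_msi,
    msi_enrichment_or = msi_enrichment_or,
    baseline_burden_mean = baseline_burden_mean,
    burden_dispersion = burden_dispersion,
    burden_multiplier_b2m = burden_multiplier_b2m,
    burden_multiplier_hla = burden_multiplier_hla,
    burden_multiplier_msi = burden_multiplier_msi,
    bias_strength = bias_strength,
    rank_distribution = rank_distribution,
    rank_min = rank_min, rank_max = rank_max,
    vaf_model = vaf_model,
    depth_mean = depth_mean, expressed_prob = expressed_prob,
    cnv_fraction = cnv_fraction, homozygous_prob = homozygous_prob,
    silent_rate = silent_rate, rna_mean = rna_mean,
    tumor_types = tumor_types,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  props <- c("frac_b2m_mut", "frac_hla_mut", "frac_both", "frac_msi",
             "bias_strength", "expressed_prob", "cnv_fraction",
             "homozygous_prob")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort_config(sprintf("`%s` must be a single proportion in [0, 1]", p))
    }
  }
  tot <- cfg$frac_b2m_mut + cfg$frac_hla_mut + cfg$frac_both
  if (tot > 1 + 1e-12) {
    abort_config("frac_b2m_mut + frac_hla_mut + frac_both must be <= 1")
  }
  pos <- c("msi_enrichment_or", "baseline_burden_mean", "burden_dispersion",
           "burden_multiplier_b2m", "burden_multiplier_hla",
           "burden_multiplier_msi", "rank_min", "rank_max", "depth_mean",
           "rna_mean")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      abort_config(sprintf("`%s` must be a single positive number", p))
    }
  }
  if (cfg$n_patients < 1) abort_config("`n_patients` must be >= 1")
  if (cfg$rank_min >= cfg$rank_max) {
    abort_config("`rank_min` must be smaller than `rank_max`")
  }
  needed <- c("b2m_shape1", "b2m_shape2", "hla_low_shape1", "hla_low_shape2",
              "hla_high_weight")
  if (!all(needed %in% names(cfg$vaf_model))) {
    abort_config("`vaf_model` is missing required components")
  }
  invisible(cfg)
}

#' Read a cohort configuration from a YAML file
#'
#' The file holds a flat mapping mirroring the arguments of
#' [cohort_config()]; `vaf_model` may be a nested mapping. Unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"cohort_config"` object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such config file: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort_config(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  }
  do.call(cohort_config, vals)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients (B2M %.0f%%, HLA %.0f%%, both %.0f%%, MSI %.0f%%)\n",
              x$n_patients, 100 * x$frac_b2m_mut, 100 * x$frac_hla_mut,
              100 * x$frac_both, 100 * x$frac_msi))
  cat(sprintf("  burden NB(mean %.1f, size %.1f); multipliers B2M %.2g / HLA %.2g / MSI %.2g\n",
              x$baseline_burden_mean, x$burden_dispersion,
              x$burden_multiplier_b2m, x$burden_multiplier_hla,
              x$burden_multiplier_msi))
  cat(sprintf("  ranks %s(%g, %g], bias_strength %.2f, seed %s\n",
              x$rank_distribution, x$rank_min, x$rank_max, x$bias_strength,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}
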