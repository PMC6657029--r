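# Synthetic cohort generation.
#
# The generator emulates the statistical structure the downstream analyses
# assume, not the sequence level: mutation burdens are negative-binomial with
# group- and MSI-specific means, per-allele binding percentile ranks are drawn
# directly (no peptides), escape-mutation VAFs follow group-specific Beta
# models, and read counts are binomial over Poisson depths.

ALLELE_POOLS <- list(
  "HLA-A" = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*11:01",
              "HLA-A*24:02"),
  "HLA-B" = c("HLA-B*07:02", "HLA-B*08:01", "HLA-B*15:01", "HLA-B*35:01",
              "HLA-B*44:02"),
  "HLA-C" = c("HLA-C*03:04", "HLA-C*04:01", "HLA-C*05:01", "HLA-C*07:01",
              "HLA-C*07:02")
)

# Slot layout: 1-2 = HLA-A, 3-4 = HLA-B, 5-6 = HLA-C.
SLOT_GENE <- c("HLA-A", "HLA-A", "HLA-B", "HLA-B", "HLA-C", "HLA-C")

# Synthetic genomic anchors for the escape genes (chrom, representative span).
ESCAPE_LOCI <- list(
  "B2M"   = list(chrom = "15", lo = 45003675L, hi = 45011075L),
  "HLA-A" = list(chrom = "6", lo = 29942532L, hi = 29945870L),
  "HLA-B" = list(chrom = "6", lo = 31353872L, hi = 31357188L),
  "HLA-C" = list(chrom = "6", lo = 31268749L, hi = 31272130L)
)

# Solve P(MSI | wild-type) so that the escape/MSI odds ratio equals `or` while
# the marginal MSI fraction stays at `m`; `q` is the mutant fraction.
solve_msi_probs <- function(m, q, or) {
  if (m <= 0) return(c(p_wt = 0, p_mut = 0))
  if (m >= 1) return(c(p_wt = 1, p_mut = 1))
  if (q <= 0 || or == 1) return(c(p_wt = m, p_mut = m))
  f <- function(p0) {
    p1 <- or * p0 / (1 - p0 + or * p0)
    q * p1 + (1 - q) * p0 - m
  }
  p0 <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(p_wt = p0, p_mut = or * p0 / (1 - p0 + or * p0))
}

#' Simulate a synthetic tumor cohort
#'
#' Generates a full [new_cohort()] object under a [cohort_config()]: patient
#' groups in the configured proportions (each escape-group patient carries
#' exactly one nonsynonymous B2M and/or HLA escape mutation), negative-binomial
#' expressed nonsynonymous burdens with group/MSI multipliers, per-allele
#' binding percentile ranks with an optional bias toward the mutated HLA
#' allele, Beta-model escape-mutation VAFs (high for B2M, a high/low mixture
#' for HLA), binomial read counts over Poisson depths, copy-number segments
#' and cytolytic marker expression.
#'
#' With a fixed `seed` in the config the result is reproducible to the byte.
#'
#' @param config A [cohort_config()].
#' @return A `"neo_cohort"` object.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 50, seed = 42))
#' cohort$patients
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_config("`config` must be created by cohort_config()")
  }
  if (is.null(config$seed)) {
    generate_cohort_impl(config)
  } else {
    withr::with_seed(config$seed, generate_cohort_impl(config))
  }
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  n_b2m <- round(n * cfg$frac_b2m_mut)
  n_hla <- round(n * cfg$frac_hla_mut)
  n_both <- round(n * cfg$frac_both)
  if (n_b2m + n_hla + n_both > n) {
    abort_config("group fractions round to more patients than n_patients")
  }
  group <- rep(c("B2M_MUT", "HLA_MUT", "BOTH", "WT"),
               c(n_b2m, n_hla, n_both, n - n_b2m - n_hla - n_both))

  patient_id <- sprintf("P%05d", seq_len(n))
  tumor_type <- sample(cfg$tumor_types, n, replace = TRUE)
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.3, 0.3, 0.25, 0.15))

  # MSI status: per-group probabilities hitting the target odds ratio.
  is_mut <- group %in% c("B2M_MUT", "HLA_MUT", "BOTH")
  pr <- solve_msi_probs(cfg$frac_msi, mean(is_mut), cfg$msi_enrichment_or)
  msi <- runif(n) < ifelse(is_mut, pr["p_mut"], pr["p_wt"])
  mantis_score <- ifelse(msi, runif(n, 0.4, 1.0), runif(n, 0, 0.39))

  genotype <- genotype_matrix(n, cfg$homozygous_prob)
  mutated_slot <- rep(NA_integer_, n)
  needs_slot <- group %in% c("HLA_MUT", "BOTH")
  mutated_slot[needs_slot] <- sample(6L, sum(needs_slot), replace = TRUE)

  patients <- tibble(
    patient_id = patient_id, tumor_type = tumor_type, stage = stage,
    allele_1 = genotype[, 1], allele_2 = genotype[, 2],
    allele_3 = genotype[, 3], allele_4 = genotype[, 4],
    allele_5 = genotype[, 5], allele_6 = genotype[, 6],
    mantis_score = mantis_score, group = group, mutated_slot = mutated_slot
  )

  # Passenger burden: NB mean scaled so the *expressed* nonsynonymous count
  # has the configured mean after expression thinning.
  mult <- dplyr::case_match(group,
    "B2M_MUT" ~ cfg$burden_multiplier_b2m,
    "HLA_MUT" ~ cfg$burden_multiplier_hla,
    "BOTH" ~ cfg$burden_multiplier_b2m,
    .default = 1
  )
  mult <- mult * ifelse(msi, cfg$burden_multiplier_msi, 1)
  mu <- cfg$baseline_burden_mean * mult / cfg$expressed_prob
  n_nonsyn <- rnbinom(n, size = cfg$burden_dispersion, mu = mu)
  n_silent <- rpois(n, cfg$silent_rate * n_nonsyn)

  passengers <- passenger_mutations(patients, n_nonsyn, n_silent, cfg)
  escapes <- escape_mutations(patients, cfg)
  mutations <- bind_rows(passengers, escapes) %>%
    arrange(.data$patient_id) %>%
    group_by(.data$patient_id) %>%
    mutate(mutation_id = sprintf("%s_M%04d", .data$patient_id, row_number())) %>%
    ungroup() %>%
    select("mutation_id", "patient_id", "gene", "variant_classification",
           "chrom", "pos", "protein_pos", "t_alt_count", "t_depth",
           "rna_read_count")

  ranks <- rank_table(mutations, patients, cfg)
  segments <- cnv_segments(patients, cfg)
  expression <- tibble(
    patient_id = rep(patient_id, each = 2),
    gene = rep(c("GZMA", "PRF1"), n),
    log2_tpm = rnorm(2 * n, mean = 5, sd = 1)
  )

  new_cohort(patients, mutations, ranks, segments, expression)
}

genotype_matrix <- function(n, homozygous_prob) {
  out <- matrix("", n, 6)
  for (g in seq_along(ALLELE_POOLS)) {
    pool <- ALLELE_POOLS[[g]]
    a1 <- sample(pool, n, replace = TRUE)
    a2 <- sample(pool, n, replace = TRUE)
    hom <- runif(n) < homozygous_prob
    a2[hom] <- a1[hom]
    out[, 2 * g - 1] <- a1
    out[, 2 * g] <- a2
  }
  out
}

# Read-count layer shared by passengers and escape mutations.
draw_reads <- function(vaf, cfg) {
  n <- length(vaf)
  depth <- pmax(1L, rpois(n, cfg$depth_mean))
  alt <- rbinom(n, depth, vaf)
  expressed <- runif(n) < cfg$expressed_prob
  rna <- integer(n)
  rna[expressed] <- 5L + rpois(sum(expressed), max(cfg$rna_mean - 5, 1))
  rna[!expressed] <- sample(0:4, sum(!expressed), replace = TRUE)
  tibble(t_alt_count = as.integer(alt), t_depth = as.integer(depth),
         rna_read_count = rna)
}

passenger_mutations <- function(patients, n_nonsyn, n_silent, cfg) {
  total <- n_nonsyn + n_silent
  pid <- rep(patients$patient_id, total)
  m <- length(pid)
  cls <- character(m)
  nonsyn_idx <- sequence(total) <= rep(n_nonsyn, total)
  cls[nonsyn_idx] <- sample(NONSYNONYMOUS_CLASSES, sum(nonsyn_idx),
                            replace = TRUE,
                            prob = c(0.75, 0.10, 0.06, 0.03, 0.06))
  cls[!nonsyn_idx] <- "silent"
  vaf <- runif(m, 0.01, 1)
  reads <- draw_reads(vaf, cfg)
  tibble(
    patient_id = pid,
    gene = sprintf("GENE%04d", sample.int(5000L, m, replace = TRUE)),
    variant_classification = cls,
    chrom = as.character(sample(c(1:5, 7:14, 16:22), m, replace = TRUE)),
    pos = sample.int(200000000L, m, replace = TRUE),
    protein_pos = ifelse(cls == "splice", NA_integer_,
                         sample.int(500L, m, replace = TRUE)),
    t_alt_count = reads$t_alt_count, t_depth = reads$t_depth,
    rna_read_count = reads$rna_read_count
  )
}

escape_vaf <- function(n, gene_is_b2m, vm) {
  vaf <- numeric(n)
  b2m <- which(gene_is_b2m)
  hla <- which(!gene_is_b2m)
  vaf[b2m] <- rbeta(length(b2m), vm$b2m_shape1, vm$b2m_shape2)
  if (length(hla)) {
    high <- runif(length(hla)) < vm$hla_high_weight
    vaf[hla[high]] <- rbeta(sum(high), vm$b2m_shape1, vm$b2m_shape2)
    vaf[hla[!high]] <- rbeta(sum(!high), vm$hla_low_shape1, vm$hla_low_shape2)
  }
  pmin(pmax(vaf, 1e-4), 1)
}

escape_mutations <- function(patients, cfg) {
  b2m_carriers <- patients %>% filter(.data$group %in% c("B2M_MUT", "BOTH"))
  hla_carriers <- patients %>% filter(.data$group %in% c("HLA_MUT", "BOTH"))

  mk <- function(pid, gene, protein_len_lo, protein_len_hi, class_prob) {
    m <- length(pid)
    if (m == 0) return(NULL)
    gene <- rep(gene, length.out = m)
    loci <- ESCAPE_LOCI[gene]
    tibble(
      patient_id = pid,
      gene = gene,
      variant_classification = sample(c("missense", "nonsense",
                                        "frameshift_indel"), m,
                                      replace = TRUE, prob = class_prob),
      chrom = unname(vapply(loci, function(l) l$chrom, character(1))),
      pos = unname(vapply(loci, function(l) sample(l$lo:l$hi, 1L),
                          integer(1))),
      protein_pos = sample(protein_len_lo:protein_len_hi, m, replace = TRUE)
    )
  }

  b2m <- mk(b2m_carriers$patient_id, "B2M", 21L, 119L, c(0.4, 0.3, 0.3))
  hla <- NULL
  if (nrow(hla_carriers)) {
    genes <- SLOT_GENE[hla_carriers$mutated_slot]
    hla <- mk(hla_carriers$patient_id, genes, 25L, 340L, c(0.8, 0.1, 0.1))
  }
  esc <- bind_rows(b2m, hla)
  if (is.null(esc) || nrow(esc) == 0) return(NULL)
  vaf <- escape_vaf(nrow(esc), esc$gene == "B2M", cfg$vaf_model)
  dplyr::bind_cols(esc, draw_reads(vaf, cfg))
}

rank_table <- function(mutations, patients, cfg) {
  neo <- mutations %>%
    filter(.data$variant_classification %in% NEOANTIGENIC_CLASSES)
  m <- nrow(neo)
  if (m == 0) {
    return(tibble(mutation_id = character(), slot = integer(),
                  rank = double()))
  }
  nr <- 6L * m
  rank <- if (cfg$rank_distribution == "uniform") {
    runif(nr, cfg$rank_min, cfg$rank_max)
  } else {
    exp(runif(nr, log(cfg$rank_min), log(cfg$rank_max)))
  }
  ranks <- tibble(
    mutation_id = rep(neo$mutation_id, each = 6L),
    slot = rep(1:6, m),
    rank = rank
  )
  if (cfg$bias_strength > 0) {
    slot_of <- patients$mutated_slot[match(rep(neo$patient_id, each = 6L),
                                           patients$patient_id)]
    hit <- !is.na(slot_of) & ranks$slot == slot_of &
      runif(nr) < cfg$bias_strength
    ranks$rank[hit] <- runif(sum(hit), 0.01, 2)
  }
  ranks
}

cnv_segments <- function(patients, cfg) {
  n <- nrow(patients)
  n_seg <- 5L
  total <- n * n_seg
  pid <- rep(patients$patient_id, each = n_seg)
  start <- sample.int(150000000L, total, replace = TRUE)
  len <- sample.int(50000000L, total, replace = TRUE)
  is_cnv <- runif(total) < cfg$cnv_fraction
  fc <- runif(total, -0.08, 0.08)
  fc[is_cnv] <- sample(c(-1, 1), sum(is_cnv), replace = TRUE) *
    runif(sum(is_cnv), 0.15, 1)
  tibble(
    patient_id = pid,
    chrom = as.character(sample.int(22L, total, replace = TRUE)),
    start = start, end = start + len, log2fc = fc
  )
}
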