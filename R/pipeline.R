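# End-to-end cohort analysis: group assignment, MSS restriction, burden /
# presentation / timing / immune contrasts and their figure-analog tables.

#' Run the full escape-mutation analysis on a cohort
#'
#' Executes every stage on one cohort: (re)assigns escape groups from the
#' mutation calls, drops synonymous-only patients, computes the MSI
#' enrichment of the escape groups on the full cohort, restricts to MSS
#' patients (default), then produces the expressed nonsynonymous burden table
#' with pan-cancer and per-tumor-type contrasts, the median binding-fraction
#' curve and binding contrasts at the PHBR cutoff, the mutant-allele bias
#' results with the paired Wilcoxon test, the escape-mutation VAF percentile
#' table with the B2M-vs-HLA Kolmogorov-Smirnov comparison and the early/late
#' mutant-allele contrast, and the cytolytic-score table with its contrasts.
#'
#' @param cohort A `"neo_cohort"` (e.g. from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param out_dir Optional directory; when given, every result table is also
#'   written as a tab-delimited file.
#' @param cutoff PHBR / allele-level binding cutoff (default 2).
#' @param mss_only Restrict all contrasts to MSS patients (default `TRUE`);
#'   the MSI enrichment itself always uses the full cohort.
#' @param exclude_cnv Use the copy-number robustness variant of the timing
#'   analysis (drop mutations in CNV regions before percentile ranking).
#' @param min_reads RNA read threshold of the expression filter.
#' @param min_mutated Minimum mutated patients per retained tumor type.
#' @return A list of class `"neo_pipeline"` with elements `analysis_patients`,
#'   `burden`, `burden_contrasts`, `burden_by_type`, `binding_curve`,
#'   `binding_contrasts`, `bias`, `bias_test`, `timing`, `timing_test`,
#'   `timing_bias`, `immune`, `immune_contrasts`, `immune_by_type`,
#'   `msi_enrichment`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, cutoff = 2, mss_only = TRUE,
                         exclude_cnv = FALSE, min_reads = 5,
                         min_mutated = 5) {
  if (!inherits(cohort, "neo_cohort")) {
    abort_validation("`cohort` must be a neo_cohort object")
  }
  groups <- assign_groups(cohort$mutations, cohort$patients$patient_id)
  patients <- cohort$patients %>%
    select(-dplyr::any_of("group")) %>%
    inner_join(groups, by = "patient_id") %>%
    mutate(msi_status = msi_status(.data$mantis_score))

  # MSI enrichment is computed before the MSS restriction, on all patients.
  msi_tbl <- bind_rows(
    msi_enrichment(patients, "B2M_MUT"),
    msi_enrichment(patients, "HLA_MUT"),
    msi_enrichment(patients, "ESCAPE")
  )

  analysis <- patients %>% filter(.data$group != "SYN_ONLY")
  if (mss_only) analysis <- analysis %>% filter(.data$msi_status == "MSS")
  muts <- semi_join(cohort$mutations, analysis, by = "patient_id")

  # Burden ------------------------------------------------------------------
  burden <- mutation_burden(muts, min_reads = min_reads) %>%
    inner_join(select(analysis, "patient_id", "tumor_type", "group"),
               by = "patient_id")
  bvals <- function(g) burden$burden[burden$group == g]
  burden_contrasts <- bind_rows(
    tidy(mann_whitney(bvals("B2M_MUT"), bvals("WT"), "burden: B2M_MUT vs WT")),
    tidy(mann_whitney(bvals("HLA_MUT"), bvals("WT"), "burden: HLA_MUT vs WT")),
    tidy(mann_whitney(bvals("B2M_MUT"), bvals("HLA_MUT"),
                      "burden: B2M_MUT vs HLA_MUT"))
  )
  burden_by_type <- per_tumor_type_contrast(burden, "burden",
                                            min_mutated = min_mutated)

  # Presentation -------------------------------------------------------------
  grp <- analysis %>%
    filter(.data$group %in% c("WT", "B2M_MUT", "HLA_MUT")) %>%
    select("patient_id", "group")
  binding_curve <- binding_fraction_curve(muts, cohort$ranks, grp,
                                          min_reads = min_reads)
  fractions <- patient_binding_fractions(muts, cohort$ranks, cutoff = cutoff,
                                         min_reads = min_reads) %>%
    inner_join(grp, by = "patient_id")
  fvals <- function(g) fractions$fraction[fractions$group == g]
  binding_contrasts <- bind_rows(
    tidy(mann_whitney(fvals("B2M_MUT"), fvals("WT"),
                      "binding fraction: B2M_MUT vs WT")),
    tidy(mann_whitney(fvals("HLA_MUT"), fvals("WT"),
                      "binding fraction: HLA_MUT vs WT"))
  )

  bias <- mutant_allele_bias(muts, cohort$ranks, analysis, cutoff = cutoff,
                             min_reads = min_reads)
  bias_res <- if (nrow(bias)) tidy(bias_test(bias)) else NULL

  # Timing -------------------------------------------------------------------
  acohort <- new_cohort(analysis, muts,
                        semi_join(cohort$ranks, muts, by = "mutation_id"),
                        semi_join(cohort$segments, analysis,
                                  by = "patient_id"),
                        semi_join(cohort$expression, analysis,
                                  by = "patient_id"))
  timing <- escape_timing(acohort, segments = acohort$segments,
                          exclude_cnv = exclude_cnv, min_reads = min_reads)
  b2m_pct <- timing$percentile[timing$group == "B2M_MUT" &
                                 timing$gene == "B2M"]
  hla_pct <- timing$percentile[timing$group == "HLA_MUT" &
                                 timing$gene != "B2M"]
  timing_test <- if (length(b2m_pct) && length(hla_pct)) {
    tidy(timing_distribution_test(b2m_pct, hla_pct))
  } else {
    NULL
  }
  timing_bias <- tryCatch(
    tidy(timing_bias_contrast(acohort, cutoff = cutoff,
                              min_reads = min_reads)),
    neoescape_validation_error = function(e) NULL
  )

  # Immune -------------------------------------------------------------------
  immune <- cytolytic_score(acohort$expression) %>%
    inner_join(select(analysis, "patient_id", "tumor_type", "group"),
               by = "patient_id")
  ivals <- function(g) immune$cytolytic_score[immune$group == g]
  immune_contrasts <- bind_rows(
    tidy(mann_whitney(ivals("B2M_MUT"), ivals("WT"),
                      "cytolytic: B2M_MUT vs WT")),
    tidy(mann_whitney(ivals("HLA_MUT"), ivals("WT"),
                      "cytolytic: HLA_MUT vs WT"))
  )
  immune_by_type <- per_tumor_type_contrast(immune, "cytolytic_score",
                                            min_mutated = min_mutated)

  out <- structure(list(
    analysis_patients = analysis,
    burden = burden, burden_contrasts = burden_contrasts,
    burden_by_type = burden_by_type,
    binding_curve = binding_curve, binding_contrasts = binding_contrasts,
    bias = bias, bias_test = bias_res,
    timing = timing, timing_test = timing_test, timing_bias = timing_bias,
    immune = immune, immune_contrasts = immune_contrasts,
    immune_by_type = immune_by_type,
    msi_enrichment = msi_tbl
  ), class = "neo_pipeline")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(out)) {
      tbl <- out[[nm]]
      if (is.data.frame(tbl) && nrow(tbl) > 0) {
        readr::write_tsv(tbl, file.path(out_dir, paste0(nm, ".tsv")),
                         progress = FALSE)
      }
    }
  }
  out
}

#' @export
print.neo_pipeline <- function(x, ...) {
  cat(sprintf("<neo_pipeline> %d analysis patients\n",
              nrow(x$analysis_patients)))
  cat("  tables:", paste(names(x)[!vapply(x, is.null, logical(1))],
                         collapse = ", "), "\n")
  invisible(x)
}
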