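#' Construct a cohort object from its component tables
#'
#' A cohort is a light container of five tibbles: `patients`, `mutations`,
#' `ranks` (per-mutation, per-allele-slot best binding percentile ranks),
#' `segments` (copy-number segments) and `expression` (log2 TPM of the
#' cytolytic marker genes). Referential integrity is checked on construction:
#' every mutation belongs to a known patient and every rank entry refers to a
#' known mutation and a slot in 1..6.
#'
#' @param patients Tibble with columns `patient_id`, `tumor_type`, `stage`,
#'   `allele_1`..`allele_6`, `mantis_score`, `group`, `mutated_slot`.
#' @param mutations Tibble of somatic mutations (see [read_maf()] for the
#'   column contract).
#' @param ranks Tibble with `mutation_id`, `slot`, `rank`.
#' @param segments Tibble with `patient_id`, `chrom`, `start`, `end`,
#'   `log2fc`.
#' @param expression Long tibble with `patient_id`, `gene`, `log2_tpm`.
#' @return An object of class `"neo_cohort"`.
#' @export
new_cohort <- function(patients, mutations, ranks, segments, expression) {
  cohort <- structure(
    list(patients = as_tibble(patients), mutations = as_tibble(mutations),
         ranks = as_tibble(ranks), segments = as_tibble(segments),
         expression = as_tibble(expression)),
    class = "neo_cohort"
  )
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  if (anyDuplicated(cohort$patients$patient_id)) {
    abort_validation("duplicate patient_id in patients table")
  }
  bad_pat <- setdiff(cohort$mutations$patient_id, cohort$patients$patient_id)
  if (length(bad_pat)) {
    abort_validation(sprintf(
      "mutations refer to unknown patients: %s",
      paste(head(bad_pat, 3), collapse = ", ")))
  }
  if (nrow(cohort$ranks)) {
    if (!all(cohort$ranks$slot %in% 1:6)) {
      abort_validation("rank table slots must be in 1..6")
    }
    bad_mut <- setdiff(cohort$ranks$mutation_id, cohort$mutations$mutation_id)
    if (length(bad_mut)) {
      abort_validation(sprintf(
        "rank table refers to unknown mutations: %s",
        paste(head(bad_mut, 3), collapse = ", ")))
    }
  }
  invisible(cohort)
}

#' @export
print.neo_cohort <- function(x, ...) {
  grp <- table(factor(x$patients$group, levels = PATIENT_GROUPS))
  cat(sprintf("<neo_cohort> %d patients, %d mutations, %d rank entries\n",
              nrow(x$patients), nrow(x$mutations), nrow(x$ranks)))
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = " "), "\n")
  invisible(x)
}
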