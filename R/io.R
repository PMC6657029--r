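# Tabular I/O for the pipeline's five file dialects. All files are
# tab-delimited with a header row; '#'-prefixed comment lines are skipped.
# Coordinates are 1-based inclusive (MAF convention) throughout.

MAF_CLASS_MAP <- c(
  "Missense_Mutation" = "missense",
  "Nonsense_Mutation" = "nonsense",
  "Nonstop_Mutation" = "nonsense",
  "Frame_Shift_Del" = "frameshift_indel",
  "Frame_Shift_Ins" = "frameshift_indel",
  "In_Frame_Del" = "inframe_indel",
  "In_Frame_Ins" = "inframe_indel",
  "Splice_Site" = "splice",
  "Splice_Region" = "splice",
  "Silent" = "silent"
)

MAF_CLASS_UNMAP <- c(
  "missense" = "Missense_Mutation",
  "nonsense" = "Nonsense_Mutation",
  "frameshift_indel" = "Frame_Shift_Del",
  "inframe_indel" = "In_Frame_Del",
  "splice" = "Splice_Site",
  "silent" = "Silent",
  "noncoding" = "IGR"
)

read_tsv_quiet <- function(path, col_types) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, na = c("", "NA"))
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_format(sprintf("%s: missing required column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
}

#' Read a minimal MAF-subset mutation table
#'
#' Parses a tab-delimited mutation annotation table restricted to the column
#' subset the pipeline needs: `Hugo_Symbol`, `Variant_Classification`,
#' `Chromosome`, `Start_Position`, `Protein_position`, `t_alt_count`,
#' `t_depth`, plus `Tumor_Sample_Barcode` (patient id), `rna_read_count` and
#' `mutation_id` when present. Extra columns are ignored. MAF classification
#' vocabulary is mapped to the internal enum (`Missense_Mutation` ->
#' `missense`, `Silent` -> `silent`, ...); unmappable classifications become
#' `noncoding`. Rows with `t_alt_count > t_depth` or negative counts are
#' rejected with the offending row number.
#'
#' If `Protein_position` carries multi-transcript values ("12/393" or
#' "10-12"), the first listed position is taken.
#'
#' @param path Path to a tab-delimited MAF-subset file.
#' @return A tibble with columns `mutation_id`, `patient_id`, `gene`,
#'   `variant_classification`, `chrom`, `pos`, `protein_pos`, `t_alt_count`,
#'   `t_depth`, `rna_read_count`.
#' @export
read_maf <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(raw, c("Hugo_Symbol", "Variant_Classification", "Chromosome",
                         "Start_Position", "t_alt_count", "t_depth"), path)
  n <- nrow(raw)
  first_pos <- function(x) {
    # "12/393" (pos/length) or "10-12" ranges: keep the first listed position
    suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", x)))
  }
  out <- tibble(
    mutation_id = if ("mutation_id" %in% names(raw)) raw$mutation_id
                  else sprintf("row%d", seq_len(n)),
    patient_id = if ("Tumor_Sample_Barcode" %in% names(raw))
                   raw$Tumor_Sample_Barcode else NA_character_,
    gene = raw$Hugo_Symbol,
    variant_classification = unname(
      ifelse(raw$Variant_Classification %in% names(MAF_CLASS_MAP),
             MAF_CLASS_MAP[raw$Variant_Classification], "noncoding")),
    chrom = raw$Chromosome,
    pos = suppressWarnings(as.integer(raw$Start_Position)),
    protein_pos = if ("Protein_position" %in% names(raw))
                    first_pos(raw$Protein_position) else NA_integer_,
    t_alt_count = suppressWarnings(as.integer(raw$t_alt_count)),
    t_depth = suppressWarnings(as.integer(raw$t_depth)),
    rna_read_count = if ("rna_read_count" %in% names(raw))
                       suppressWarnings(as.integer(raw$rna_read_count))
                     else NA_integer_
  )
  bad_count <- which(is.na(out$t_alt_count) | is.na(out$t_depth) |
                       is.na(out$pos))
  if (length(bad_count)) {
    abort_validation(sprintf("%s: malformed count/position at row %d",
                             path, bad_count[1]))
  }
  bad <- which(out$t_alt_count > out$t_depth | out$t_alt_count < 0 |
                 out$pos < 1)
  if (length(bad)) {
    abort_validation(sprintf(
      "%s: t_alt_count > t_depth (or negative/invalid field) at row %d",
      path, bad[1]))
  }
  out
}

#' Write a mutation table in the MAF-subset dialect
#'
#' Inverse of [read_maf()]: internal classification values are mapped back to
#' MAF vocabulary and the id/RNA columns are carried so the file round-trips.
#'
#' @param mutations Mutation tibble as returned by [read_maf()] or found in a
#'   cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  out <- tibble(
    Hugo_Symbol = mutations$gene,
    Variant_Classification = unname(
      MAF_CLASS_UNMAP[mutations$variant_classification]),
    Chromosome = mutations$chrom,
    Start_Position = mutations$pos,
    Protein_position = mutations$protein_pos,
    t_alt_count = mutations$t_alt_count,
    t_depth = mutations$t_depth,
    Tumor_Sample_Barcode = mutations$patient_id,
    rna_read_count = mutations$rna_read_count,
    mutation_id = mutations$mutation_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a per-allele binding rank table
#'
#' Expects tab-delimited columns `mutation_id`, `slot` (1-6) and `rank`
#' (binding percentile rank in (0, 100], lower = stronger predicted binding).
#' Duplicate (mutation, slot) rows are peptide-level ranks and are reduced to
#' their minimum — the best rank per allele. Every mutation present must have
#' entries for all 6 allele slots.
#'
#' @param path Path to the rank table.
#' @return Tibble `mutation_id`, `slot`, `rank` with one row per (mutation,
#'   slot).
#' @export
read_rank_table <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    mutation_id = "c", slot = "i", rank = "d"))
  require_columns(df, c("mutation_id", "slot", "rank"), path)
  if (any(df$rank <= 0 | is.na(df$rank))) {
    abort_validation(sprintf("%s: ranks must be positive", path))
  }
  if (any(!df$slot %in% 1:6)) {
    abort_validation(sprintf("%s: slot must be in 1..6", path))
  }
  out <- df %>%
    group_by(.data$mutation_id, .data$slot) %>%
    summarise(rank = min(.data$rank), .groups = "drop")
  slots_per_mut <- out %>% count(.data$mutation_id)
  incomplete <- slots_per_mut$mutation_id[slots_per_mut$n != 6L]
  if (length(incomplete)) {
    abort_validation(sprintf(
      "%s: mutation(s) without all 6 allele slots: %s",
      path, paste(head(incomplete, 3), collapse = ", ")))
  }
  out
}

#' Read / write copy-number segment tables
#'
#' SEG-like tab-delimited columns `patient_id`, `chrom`, `start`, `end`
#' (1-based inclusive) and `log2fc`. Segments with `start > end` are rejected.
#'
#' @param path File path.
#' @return Tibble of segments.
#' @export
read_segments <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    patient_id = "c", chrom = "c", start = "i", end = "i", log2fc = "d"))
  require_columns(df, c("patient_id", "chrom", "start", "end", "log2fc"), path)
  bad <- which(df$start > df$end)
  if (length(bad)) {
    abort_validation(sprintf("%s: start > end at row %d", path, bad[1]))
  }
  df
}

#' @rdname read_segments
#' @param segments Segment tibble.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(segments, path, progress = FALSE)
  invisible(path)
}

#' Read / write patient metadata tables
#'
#' Tab-delimited, one row per patient, keyed by `patient_id`, with
#' `tumor_type`, `stage`, the six HLA genotype columns `allele_1`..`allele_6`
#' (duplicate allele strings are allowed — homozygous patients), a
#' `mantis_score` and, when already assigned, `group` and `mutated_slot`.
#' A patient with any missing genotype slot is rejected.
#'
#' @param path File path.
#' @return Tibble of patients.
#' @export
read_patients <- function(path) {
  allele_cols <- sprintf("allele_%d", 1:6)
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(df, c("patient_id", "tumor_type", allele_cols,
                        "mantis_score"), path)
  df <- df %>% mutate(
    mantis_score = suppressWarnings(as.double(.data$mantis_score)),
    stage = if ("stage" %in% names(df)) .data$stage else "unknown",
    group = if ("group" %in% names(df)) .data$group else NA_character_,
    mutated_slot = if ("mutated_slot" %in% names(df))
      suppressWarnings(as.integer(.data$mutated_slot)) else NA_integer_
  )
  geno <- as.matrix(df[allele_cols])
  bad <- which(rowSums(is.na(geno) | geno == "") > 0)
  if (length(bad)) {
    abort_validation(sprintf(
      "%s: patient %s does not have 6 genotype slots",
      path, df$patient_id[bad[1]]))
  }
  if (any(df$mantis_score < 0, na.rm = TRUE)) {
    abort_validation(sprintf("%s: mantis_score must be nonnegative", path))
  }
  df
}

#' @rdname read_patients
#' @param patients Patient tibble.
#' @export
write_patients <- function(patients, path) {
  readr::write_tsv(patients, path, progress = FALSE)
  invisible(path)
}

#' Read / write expression tables
#'
#' Long tab-delimited table `patient_id`, `gene`, `log2_tpm` holding log2 TPM
#' values (used for the GZMA/PRF1 cytolytic score).
#'
#' @param path File path.
#' @return Tibble of expression records.
#' @export
read_expression <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    patient_id = "c", gene = "c", log2_tpm = "d"))
  require_columns(df, c("patient_id", "gene", "log2_tpm"), path)
  df
}

#' @rdname read_expression
#' @param expression Expression tibble.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_rank_table
#' @param ranks Rank tibble.
#' @export
write_rank_table <- function(ranks, path) {
  readr::write_tsv(ranks, path, progress = FALSE)
  invisible(path)
}

COHORT_FILES <- c(patients = "patients.tsv", mutations = "mutations.maf",
                  ranks = "ranks.tsv", segments = "segments.seg",
                  expression = "expression.tsv")

#' Write / read a whole cohort directory
#'
#' `write_cohort()` emits the five cohort tables (`patients.tsv`,
#' `mutations.maf`, `ranks.tsv`, `segments.seg`, `expression.tsv`) into a
#' directory; `read_cohort()` reassembles them into a [new_cohort()] object.
#' Writing then reading reproduces the in-memory cohort field-by-field.
#'
#' @param cohort A `"neo_cohort"` object.
#' @param dir Directory path (created if needed).
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`: a
#'   `"neo_cohort"`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "neo_cohort")) {
    abort_validation("`cohort` must be a neo_cohort object")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(sprintf("cannot write to directory: %s", dir),
          class = c("neoescape_io_error", "neoescape_error"))
  }
  write_patients(cohort$patients, file.path(dir, COHORT_FILES["patients"]))
  write_maf(cohort$mutations, file.path(dir, COHORT_FILES["mutations"]))
  write_rank_table(cohort$ranks, file.path(dir, COHORT_FILES["ranks"]))
  write_segments(cohort$segments, file.path(dir, COHORT_FILES["segments"]))
  write_expression(cohort$expression, file.path(dir, COHORT_FILES["expression"]))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, COHORT_FILES)
  names(paths) <- names(COHORT_FILES)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort_format(sprintf("cohort directory %s is missing: %s", dir,
                         paste(basename(missing), collapse = ", ")))
  }
  new_cohort(
    patients = read_patients(paths["patients"]),
    mutations = read_maf(paths["mutations"]),
    ranks = read_rank_table(paths["ranks"]),
    segments = read_segments(paths["segments"]),
    expression = read_expression(paths["expression"])
  )
}
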