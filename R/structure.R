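# Residue-level structural annotation of the B2M/HLA proteins from
# precomputed relative solvent accessibility (RSA) tables and interface
# residue sets, plus hotspot detection and domain enrichment of mutation
# positions. RSA computation and interface prediction happen upstream; their
# tabular outputs are consumed here. Positions are 1-based UniProt indices
# over the full-length protein (signal peptide included).

STRUCTURE_LABELS <- c("interface", "core", "surface", "ambiguous")

#' Core/surface classification from relative solvent accessibility
#'
#' Residues with RSA strictly above 15 are `surface`, strictly below 5 are
#' `core`, and values in the closed band \[5, 15\] are `ambiguous` (both
#' boundaries fall in the ambiguous band).
#'
#' @param rsa Nonnegative RSA value(s), percentage-like.
#' @return Character vector in `c("core", "surface", "ambiguous")`.
#' @examples
#' classify_rsa(c(2, 7.17, 20))
#' @export
classify_rsa <- function(rsa) {
  if (any(rsa < 0 | is.na(rsa))) abort_validation("RSA must be nonnegative")
  dplyr::case_when(
    rsa > 15 ~ "surface",
    rsa < 5 ~ "core",
    TRUE ~ "ambiguous"
  )
}

#' Per-structure residue labels
#'
#' Labels every position of each structure: positions in the structure's
#' interface set are `interface` (the interface call overrides the RSA
#' class); all others take [classify_rsa()]. Positions absent from a
#' structure receive no label at this stage.
#'
#' @param rsa Tibble with `structure_id`, `protein`, `position`, `rsa`.
#' @param interface Tibble with `structure_id`, `position` listing predicted
#'   interface residues (may be empty or `NULL`).
#' @return Tibble `structure_id`, `protein`, `position`, `label`.
#' @export
annotate_structure <- function(rsa, interface = NULL) {
  out <- rsa %>%
    mutate(label = classify_rsa(.data$rsa)) %>%
    select("structure_id", "protein", "position", "label")
  if (!is.null(interface) && nrow(interface)) {
    iface <- interface %>%
      distinct(.data$structure_id, .data$position) %>%
      mutate(.iface = TRUE)
    out <- out %>%
      left_join(iface, by = c("structure_id", "position")) %>%
      mutate(label = ifelse(!is.na(.data$.iface), "interface", .data$label)) %>%
      select(-".iface")
  }
  out
}

#' Consensus over structure-level residue labels
#'
#' Plurality vote over the labels a position received across structures (and
#' alleles): the strictly most frequent label wins; a tie for the top count —
#' and a position with no labels at all (no known 3D structure) — resolves to
#' `ambiguous`.
#'
#' @param labels Character vector of labels from
#'   `c("interface", "core", "surface", "ambiguous")`; may be empty.
#' @return A single label.
#' @examples
#' consensus_label(c("core", "core", "surface"))
#' consensus_label(c("core", "surface")) # tie -> ambiguous
#' @export
consensus_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return("ambiguous")
  bad <- setdiff(unique(labels), STRUCTURE_LABELS)
  if (length(bad)) {
    abort_validation(sprintf("unknown residue label(s): %s",
                             paste(bad, collapse = ", ")))
  }
  tab <- table(labels)
  top <- tab[tab == max(tab)]
  if (length(top) > 1) "ambiguous" else names(top)
}

#' Consensus residue annotation of one protein
#'
#' Pools the per-structure labels of all structures of one protein (all
#' alleles together) and takes a single plurality consensus per position via
#' [consensus_label()]. Positions from 1 to `protein_length` never observed in
#' any structure are `ambiguous` (no known 3D structure).
#'
#' @param structure_labels Output of [annotate_structure()]; all rows must
#'   belong to a single protein.
#' @param protein_length Full-length (UniProt) protein length; defaults to the
#'   largest observed position.
#' @return Tibble `protein`, `position`, `label`, one row per position
#'   1..`protein_length`.
#' @export
annotate_protein <- function(structure_labels,
                             protein_length = max(structure_labels$position)) {
  prots <- unique(structure_labels$protein)
  if (length(prots) != 1) {
    abort_validation("structures from different proteins cannot be mixed")
  }
  voted <- structure_labels %>%
    group_by(.data$position) %>%
    summarise(label = consensus_label(.data$label), .groups = "drop")
  tibble(protein = prots, position = seq_len(protein_length)) %>%
    left_join(voted, by = "position") %>%
    mutate(label = dplyr::coalesce(.data$label, "ambiguous"))
}

#' UniProt to IMGT/HLA residue numbering
#'
#' The IMGT/HLA numbering starts at the mature protein; mapping from UniProt
#' full-length numbering subtracts the 24-residue signal peptide. Positions
#' inside the signal peptide have no IMGT equivalent and are an error.
#'
#' @param position UniProt position(s), must be > 24.
#' @return IMGT position(s).
#' @examples
#' uniprot_to_imgt(231) # 207
#' @export
uniprot_to_imgt <- function(position) {
  if (any(position <= 24 | is.na(position))) {
    abort_validation("position lies within the 24-residue signal peptide")
  }
  position - 24L
}

HOTSPOT_THRESHOLDS <- c("HLA-A" = 3L, "HLA-B" = 3L, "HLA-C" = 1L)

#' Recurrently mutated (hotspot) positions
#'
#' Positions whose mutation count strictly exceeds the per-gene recurrence
#' threshold (defaults: HLA-A > 3, HLA-B > 3, HLA-C > 1).
#'
#' @param position_counts Tibble with `position`, `count`.
#' @param gene Gene symbol; must have a threshold.
#' @param thresholds Named integer vector of per-gene thresholds.
#' @return Integer vector of hotspot positions.
#' @export
find_hotspots <- function(position_counts, gene,
                          thresholds = HOTSPOT_THRESHOLDS) {
  if (!gene %in% names(thresholds)) {
    abort_validation(sprintf("no hotspot threshold defined for gene %s", gene))
  }
  if (any(position_counts$count < 0)) {
    abort_validation("counts must be nonnegative")
  }
  sort(position_counts$position[position_counts$count > thresholds[[gene]]])
}

#' Functional domain map of the HLA class I heavy chain
#'
#' Named intervals over UniProt full-length positions: the 24-residue signal
#' peptide, the alpha1/alpha2 peptide-binding domains, the alpha3
#' immunoglobulin-like domain, the connecting peptide, the transmembrane
#' segment and the cytoplasmic tail (canonical boundaries of the class I
#' heavy chain fold).
#'
#' @param protein_length Full-length protein length (default 365).
#' @return Tibble `domain`, `start`, `end`.
#' @export
hla_domain_map <- function(protein_length = 365) {
  tibble(
    domain = c("signal_peptide", "alpha1", "alpha2", "alpha3", "connecting",
               "transmembrane", "cytoplasmic"),
    start = c(1L, 25L, 115L, 207L, 299L, 309L, 333L),
    end = c(24L, 114L, 206L, 298L, 308L, 332L, as.integer(protein_length))
  )
}

#' Domain enrichment of mutation positions
#'
#' Builds the 2x2 table (mutations inside/outside the domain x residues
#' inside/outside the domain) and reports the sample (cross-product) odds
#' ratio with a two-sided Fisher exact p-value. An empty off-diagonal cell
#' gives an unbounded odds ratio (`Inf`), flagged in the result.
#'
#' @param mutation_positions Integer vector of mutated positions (one entry
#'   per mutation; recurrent positions repeat).
#' @param domain_map Tibble `domain`, `start`, `end` (e.g.
#'   [hla_domain_map()]).
#' @param domain Name of the domain to test.
#' @param protein_length Total number of residues (exposure denominator).
#' @return Tibble `domain`, `n_in`, `n_out`, `residues_in`, `residues_out`,
#'   `odds_ratio`, `p_value`, `unbounded`.
#' @export
domain_enrichment <- function(mutation_positions, domain_map, domain,
                              protein_length = max(domain_map$end)) {
  row <- domain_map %>% filter(.data$domain == !!domain)
  if (nrow(row) != 1) {
    abort_validation(sprintf("domain %s not defined in the map", domain))
  }
  if (length(mutation_positions) == 0) {
    abort_validation("at least one mutation position is required")
  }
  res_in <- row$end - row$start + 1L
  res_out <- protein_length - res_in
  if (res_in <= 0 || res_out <= 0) {
    abort_validation("domain must cover a nonempty strict subset of residues")
  }
  n_in <- sum(mutation_positions >= row$start & mutation_positions <= row$end)
  n_out <- length(mutation_positions) - n_in
  # Exposure model: residue counts form the background column of the 2x2
  # table (mutations in/out of domain x residues in/out of domain).
  or <- (n_in * res_out) / (n_out * res_in)
  p <- stats::fisher.test(matrix(c(n_in, n_out, res_in, res_out), 2, 2))$p.value
  tibble(domain = domain, n_in = n_in, n_out = n_out,
         residues_in = res_in, residues_out = res_out,
         odds_ratio = or, p_value = p,
         unbounded = !is.finite(or) | or == 0)
}

#' Read residue RSA and interface tables
#'
#' `read_rsa_table()` expects tab-delimited columns `structure_id`,
#' `protein`, `position`, `rsa`; `read_interface_table()` expects
#' `structure_id`, `position`. Negative RSA values are rejected.
#'
#' @param path File path.
#' @return A tibble in the shape [annotate_structure()] consumes.
#' @export
read_rsa_table <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    structure_id = "c", protein = "c", position = "i", rsa = "d"))
  require_columns(df, c("structure_id", "protein", "position", "rsa"), path)
  if (any(df$rsa < 0 | is.na(df$rsa))) {
    abort_validation(sprintf("%s: RSA must be nonnegative", path))
  }
  df
}

#' @rdname read_rsa_table
#' @export
read_interface_table <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    structure_id = "c", position = "i"))
  require_columns(df, c("structure_id", "position"), path)
  df
}
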