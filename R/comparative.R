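#' @title Cross-substrate comparison of labeled OTUs
#' @description Overlap categories between two substrate incubations,
#'   min-max EAF normalization, and per-taxon summaries.
#' @name comparative
NULL

#' Min-max normalize EAF values within one incubation
#'
#' Maps the labeled OTUs' EAFs of one incubation onto `[0, 1]` with 1 as the
#' highest and 0 as the lowest value. Normalization is computed across *all*
#' labeled OTUs of the incubation, before any category split, so overlap and
#' substrate-specific subsets remain on a common scale.
#'
#' @param values Numeric EAF values (>= 2 values expected).
#' @return `(values - min) / (max - min)`; if all values are identical they
#'   all map to 0 with a warning.
#' @export
minmax_normalize_eaf <- function(values) {
  if (length(values) == 0) return(numeric(0))
  rng <- range(values, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("all EAF values identical; normalized values set to 0",
            call. = FALSE)
    return(rep(0, length(values)))
  }
  (values - rng[1]) / diff(rng)
}

#' Assign labeled OTUs to the four cross-substrate overlap categories
#'
#' Partitions the union of the two incubations' labeled OTU sets:
#' category 1 = labeled only with substrate A (bicarbonate), category 2 =
#' overlap OTUs with their EAF in incubation A, category 3 = the same overlap
#' OTUs with their EAF in incubation B, category 4 = labeled only with
#' substrate B (HMW organic matter). Overlap OTUs therefore appear twice,
#' with independent EAF values.
#'
#' @param labeled_a,labeled_b Data frames with columns `otu_id` and `eaf`
#'   (typically `boot_median` of labeled OTUs), one per incubation.
#' @param substrates Length-2 character: substrate names of A and B.
#' @param norm_scope `"per-incubation"` (default: min-max over all labeled
#'   OTUs of the incubation, then split) or `"per-category"`.
#' @return A tibble `otu_id`, `substrate`, `category` (integer 1-4), `eaf`,
#'   `eaf_norm`, with attribute `"counts"` giving the per-category and
#'   overlap counts.
#' @examples
#' a <- data.frame(otu_id = c("x", "y"), eaf = c(0.10, 0.05))
#' b <- data.frame(otu_id = c("y", "z"), eaf = c(0.20, 0.15))
#' assign_categories(a, b)
#' @export
assign_categories <- function(labeled_a, labeled_b,
                              substrates = c("bicarbonate", "hmw_om"),
                              norm_scope = c("per-incubation",
                                             "per-category")) {
  norm_scope <- match.arg(norm_scope)
  labeled_a <- tibble::as_tibble(labeled_a)
  labeled_b <- tibble::as_tibble(labeled_b)
  shared <- intersect(labeled_a$otu_id, labeled_b$otu_id)

  a_norm <- minmax_normalize_eaf(labeled_a$eaf)
  b_norm <- minmax_normalize_eaf(labeled_b$eaf)

  build <- function(tab, norm, in_overlap, cat_only, cat_overlap, substrate) {
    ov <- tab$otu_id %in% in_overlap
    tibble::tibble(
      otu_id = tab$otu_id,
      substrate = substrate,
      category = ifelse(ov, cat_overlap, cat_only),
      eaf = tab$eaf,
      eaf_norm = norm
    )
  }
  out <- dplyr::bind_rows(
    build(labeled_a, a_norm, shared, 1L, 2L, substrates[1]),
    build(labeled_b, b_norm, shared, 4L, 3L, substrates[2])
  )
  if (norm_scope == "per-category") {
    out <- out |>
      dplyr::group_by(.data$category) |>
      dplyr::mutate(eaf_norm = minmax_normalize_eaf(.data$eaf)) |>
      dplyr::ungroup()
  }
  out <- dplyr::arrange(out, .data$category, .data$otu_id)
  counts <- c(table(factor(out$category, levels = 1:4)))
  attr(out, "counts") <- list(
    category = stats::setNames(as.integer(counts), paste0("cat", 1:4)),
    n_labeled_a = nrow(labeled_a),
    n_labeled_b = nrow(labeled_b),
    n_overlap = length(shared)
  )
  out
}

#' Per-taxon summary of labeled OTUs
#'
#' Aggregates labeled OTUs at a taxonomic rank: the unweighted mean of their
#' bootstrap-median EAFs, the number of labeled OTUs (CI excluding zero),
#' their summed reads and share of all labeled-OTU reads. Groups with no
#' labeled OTU emit no row.
#'
#' @param eaf_table Output of [estimate_eaf()] (needs `otu_id`,
#'   `boot_median`, `labeled`).
#' @param taxonomy Tibble `otu_id`, `lineage` (semicolon-delimited). OTUs
#'   with no lineage group as `"unclassified"`.
#' @param counts OTU count matrix of the same dataset (for read totals).
#' @param rank 1-based position in the lineage string (default 2 = phylum
#'   for domain-led lineages).
#' @return Tibble `taxon_group`, `mean_boot_median`, `n_labeled`,
#'   `n_sequences`, `pct_sequences`, sorted by descending `n_labeled`.
#' @export
summarize_by_taxon <- function(eaf_table, taxonomy, counts, rank = 2) {
  lab <- eaf_table[call_labeled(eaf_table), , drop = FALSE]
  if (nrow(lab) == 0) {
    return(tibble::tibble(taxon_group = character(0),
                          mean_boot_median = numeric(0),
                          n_labeled = integer(0), n_sequences = numeric(0),
                          pct_sequences = numeric(0)))
  }
  lineage <- stats::setNames(taxonomy$lineage, taxonomy$otu_id)
  group_of <- function(id) {
    lin <- lineage[id]
    if (is.na(lin) || !nzchar(lin)) return("unclassified")
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    if (length(parts) < rank || !nzchar(parts[rank])) return("unclassified")
    parts[rank]
  }
  reads <- rowSums(counts)[lab$otu_id]
  reads[is.na(reads)] <- 0
  lab$taxon_group <- vapply(lab$otu_id, group_of, character(1),
                            USE.NAMES = FALSE)
  lab$n_sequences <- reads
  total_reads <- sum(reads)
  lab |>
    dplyr::group_by(.data$taxon_group) |>
    dplyr::summarise(
      mean_boot_median = mean(.data$boot_median),
      n_labeled = dplyr::n(),
      n_sequences = sum(.data$n_sequences),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_sequences = 100 * .data$n_sequences / total_reads) |>
    dplyr::arrange(dplyr::desc(.data$n_labeled), .data$taxon_group)
}

#' Paired EAF table for overlap OTUs
#'
#' One row per OTU labeled in both incubations, with its EAF under each
#' substrate and its position relative to the 1:1 line (equal labeling rate
#' in both incubations).
#'
#' @param category_table Output of [assign_categories()].
#' @return Tibble `otu_id`, `eaf_a` (category 2 value), `eaf_b` (category 3
#'   value), `eaf_norm_a`, `eaf_norm_b`, `position` in
#'   `{"above", "on", "below"}` (of `eaf_b` vs `eaf_a`).
#' @export
paired_overlap_scatter <- function(category_table) {
  a <- category_table[category_table$category == 2L, ]
  b <- category_table[category_table$category == 3L, ]
  m <- match(a$otu_id, b$otu_id)
  tibble::tibble(
    otu_id = a$otu_id,
    eaf_a = a$eaf,
    eaf_b = b$eaf[m],
    eaf_norm_a = a$eaf_norm,
    eaf_norm_b = b$eaf_norm[m],
    position = dplyr::case_when(
      b$eaf[m] > a$eaf ~ "above",
      b$eaf[m] < a$eaf ~ "below",
      TRUE ~ "on"
    )
  )
}
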