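#' @title OTU filtering rules
#' @description Abundance and contaminant filters applied before EAF
#'   estimation, each returning the filtered dataset together with an
#'   auditable report of what was removed and why.
#' @name filtering
NULL

new_filter_report <- function(stage, n_in, removed) {
  removed <- tibble::as_tibble(removed)
  structure(
    list(stage = stage, n_in = n_in, n_out = n_in - nrow(removed),
         removed = removed),
    class = "qsip_filter_report"
  )
}

#' @export
print.qsip_filter_report <- function(x, ...) {
  cat("Filter stage '", x$stage, "': ", x$n_in, " -> ", x$n_out,
      " OTUs (", nrow(x$removed), " removed)\n", sep = "")
  invisible(x)
}

per_replicate_sums <- function(dataset) {
  fr <- dataset$fractions
  grp <- paste(fr$treatment, fr$replicate, sep = "|")
  sums <- t(rowsum(t(dataset$counts), group = grp))
  sums  # OTU x (treatment|replicate) matrix
}

#' Minimum per-replicate abundance filter
#'
#' Retains an OTU only if its read count, summed across the sequenced
#' fractions of a replicate, is strictly greater than `min_total` in *every*
#' replicate of *both* the labeled and control treatments. This is the
#' strictest reading of a per-replicate abundance rule and guarantees each
#' retained OTU has enough reads in every tube for a defined weighted-average
#' density.
#'
#' @param dataset A `qsip_dataset`.
#' @param min_total Threshold; retained OTUs have per-replicate sums
#'   `> min_total` (default 12, i.e. at least 13 reads per replicate).
#' @return A list `list(dataset, report)`: the filtered dataset and a
#'   `qsip_filter_report` whose `removed` table names, per OTU, the first
#'   failing replicate and its sum.
#' @examples
#' ds <- simulate_qsip_experiment(simulation_config(n_taxa = 8, depth = 500),
#'                                seed = 1)$dataset
#' filter_min_count(ds)$report
#' @export
filter_min_count <- function(dataset, min_total = 12) {
  stopifnot_dataset(dataset)
  if (!is.numeric(min_total) || length(min_total) != 1 || min_total < 0) {
    stop("`min_total` must be a single non-negative number", call. = FALSE)
  }
  sums <- per_replicate_sums(dataset)
  ok <- sums > min_total
  keep <- rowSums(ok) == ncol(ok)
  removed_ids <- rownames(sums)[!keep]
  reason <- vapply(removed_ids, function(id) {
    fail <- which(!ok[id, ])[1]
    sprintf("replicate %s sum %s <= %s", colnames(sums)[fail],
            format(sums[id, fail]), format(min_total))
  }, character(1))
  report <- new_filter_report(
    "min_count", nrow(dataset$counts),
    tibble::tibble(otu_id = removed_ids, reason = unname(reason))
  )
  list(dataset = subset_otus(dataset, rownames(sums)[keep]), report = report)
}

#' Defensive singleton removal
#'
#' OTUs represented by a single read across the whole dataset are normally
#' discarded at the clustering stage; this re-applies the rule so downstream
#' estimates never see them.
#'
#' @param dataset A `qsip_dataset`.
#' @return `list(dataset, report)` as for [filter_min_count()].
#' @export
filter_singletons <- function(dataset) {
  totals <- rowSums(dataset$counts)
  keep <- totals >= 2
  report <- new_filter_report(
    "singletons", nrow(dataset$counts),
    tibble::tibble(otu_id = names(totals)[!keep],
                   reason = rep("singleton (dataset-wide count < 2)",
                                sum(!keep)))
  )
  list(dataset = subset_otus(dataset, names(totals)[keep]), report = report)
}

#' Remove OTUs dominated by contaminant libraries
#'
#' Contaminant libraries (DNA extraction blanks, laboratory-dust amplicons)
#' sequenced alongside the samples flag reagent and aerosol contamination.
#' An OTU is removed when its total read count over all contaminant libraries
#' exceeds its total count over all sample libraries.
#'
#' @param dataset A `qsip_dataset`.
#' @param contaminants Matrix or data frame of contaminant counts: rows = OTU
#'   ids (sharing the dataset's OTU universe; ids absent from the dataset are
#'   ignored), columns = contaminant libraries. `NULL` is a no-op with a
#'   warning.
#' @return `list(dataset, report)`; the report's `removed` table carries both
#'   totals per removed OTU.
#' @export
remove_contaminants <- function(dataset, contaminants) {
  stopifnot_dataset(dataset)
  n_in <- nrow(dataset$counts)
  if (is.null(contaminants) ||
      (is.matrix(contaminants) && ncol(contaminants) == 0)) {
    warning("no contaminant libraries supplied; contaminant filter skipped",
            call. = FALSE)
    return(list(dataset = dataset,
                report = new_filter_report("contaminants", n_in,
                                           tibble::tibble(otu_id = character(0),
                                                          reason = character(0)))))
  }
  contaminants <- as.matrix(contaminants)
  blank_tot <- rowSums(contaminants)
  sample_tot <- rowSums(dataset$counts)
  ids <- rownames(dataset$counts)
  blanks <- ifelse(ids %in% names(blank_tot), blank_tot[ids], 0)
  remove <- blanks > sample_tot[ids]
  removed_ids <- ids[remove]
  report <- new_filter_report(
    "contaminants", n_in,
    tibble::tibble(
      otu_id = removed_ids,
      reason = sprintf("contaminant reads %d > sample reads %d",
                       as.integer(blanks[remove]),
                       as.integer(sample_tot[removed_ids]))
    )
  )
  list(dataset = subset_otus(dataset, ids[!remove]), report = report)
}

#' OTU universes of two substrate datasets and their intersection
#'
#' After filtering, the overlap analysis needs each substrate's eligible OTU
#' universe and the shared subset.
#'
#' @param dataset_a,dataset_b Filtered `qsip_dataset`s (or plain character
#'   vectors of OTU ids).
#' @return `list(universe_a, universe_b, shared)` of OTU-id character vectors.
#' @export
shared_otu_subset <- function(dataset_a, dataset_b) {
  ids <- function(x) if (inherits(x, "qsip_dataset")) otu_ids(x) else
    as.character(x)
  a <- ids(dataset_a)
  b <- ids(dataset_b)
  shared <- intersect(a, b)
  if (length(shared) == 0) {
    warning("OTU universes are disjoint", call. = FALSE)
  }
  list(universe_a = a, universe_b = b, shared = shared)
}
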