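#' Assemble a qSIP dataset from fraction metadata and an OTU count matrix
#'
#' A qSIP dataset pairs, for one substrate, the labeled and unlabeled-control
#' replicate density gradients: one row of `fractions` per sequenced density
#' fraction (its buoyant density and qPCR total gene copies) and one column of
#' `counts` per fraction library. Fractions are indexed 1..F from the bottom
#' of the tube, so fraction 1 is the densest; internally libraries are kept
#' ordered heavy to light within each replicate.
#'
#' @param fractions A data frame with columns `replicate`, `treatment`
#'   (`"labeled"` or `"control"`), `substrate`, `fraction` (1-based integer),
#'   `density` (g/ml) and `total_copies` (gene copies per g, from qPCR).
#'   Additional columns are preserved as provenance.
#' @param counts Integer matrix, rows = OTU ids, columns = library keys
#'   `"replicate|treatment|substrate|fraction"`. Columns must cover every row
#'   of `fractions`; extra columns are an error.
#' @param taxonomy Optional data frame with columns `otu_id` and `lineage`
#'   (semicolon-delimited, domain..genus).
#' @param provenance Free-form list of metadata recorded in run summaries.
#'
#' @return An object of class `qsip_dataset` with elements `fractions`
#'   (tibble, one row per library, ordered by replicate then descending
#'   density), `counts` (integer matrix), `taxonomy`, `provenance`.
#' @examples
#' fr <- data.frame(
#'   replicate = rep(c("L1", "C1"), each = 3),
#'   treatment = rep(c("labeled", "control"), each = 3),
#'   substrate = "bicarbonate", fraction = rep(1:3, 2),
#'   density = rep(c(1.72, 1.70, 1.68), 2), total_copies = 1e6
#' )
#' cnt <- matrix(5L, 2, 6, dimnames = list(
#'   c("OTU_1", "OTU_2"), library_key(fr)
#' ))
#' qsip_dataset(fr, cnt)
#' @export
qsip_dataset <- function(fractions, counts, taxonomy = NULL,
                         provenance = list()) {
  fractions <- tibble::as_tibble(fractions)
  required <- c("replicate", "treatment", "substrate", "fraction",
                "density", "total_copies")
  missing_cols <- setdiff(required, names(fractions))
  if (length(missing_cols) > 0) {
    stop("`fractions` is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(fractions$treatment %in% c("labeled", "control"))) {
    stop("`treatment` must be 'labeled' or 'control'", call. = FALSE)
  }
  if (any(!is.finite(fractions$density) | fractions$density < 1.60 |
          fractions$density > 1.80)) {
    stop("fraction densities must lie in [1.60, 1.80] g/ml", call. = FALSE)
  }
  if (any(fractions$total_copies < 0)) {
    stop("`total_copies` must be non-negative", call. = FALSE)
  }
  fractions$library_id <- library_key(fractions)
  if (anyDuplicated(fractions$library_id)) {
    stop("duplicate (replicate, treatment, substrate, fraction) libraries",
         call. = FALSE)
  }

  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry OTU row names and library column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate OTU ids in count matrix", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts are invalid", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  unknown <- setdiff(colnames(counts), fractions$library_id)
  if (length(unknown) > 0) {
    stop("count columns with no matching fraction record: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(fractions$library_id, colnames(counts))
  if (length(absent) > 0) {
    # a fraction with no recoverable DNA: keep the record, zero-fill counts
    zeros <- matrix(0L, nrow(counts), length(absent),
                    dimnames = list(rownames(counts), absent))
    counts <- cbind(counts, zeros)
    warning("no count column for ", length(absent),
            " fraction librar(ies); treated as zero-yield: ",
            paste(utils::head(absent, 3), collapse = ", "), call. = FALSE)
  }

  # heavy -> light within replicate, matching bottom-up fractionation
  ord <- order(fractions$substrate, fractions$treatment, fractions$replicate,
               fractions$fraction)
  fractions <- fractions[ord, ]
  counts <- counts[, fractions$library_id, drop = FALSE]

  validate_gradient(fractions)

  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    if (!all(c("otu_id", "lineage") %in% names(taxonomy))) {
      stop("`taxonomy` needs columns otu_id and lineage", call. = FALSE)
    }
  }

  structure(
    list(fractions = fractions, counts = counts, taxonomy = taxonomy,
         provenance = provenance),
    class = "qsip_dataset"
  )
}

#' Canonical library key for fraction records
#'
#' @param fractions Data frame with replicate, treatment, substrate, fraction.
#' @return Character vector `"replicate|treatment|substrate|fraction"`.
#' @export
library_key <- function(fractions) {
  paste(fractions$replicate, fractions$treatment, fractions$substrate,
        fractions$fraction, sep = "|")
}

validate_gradient <- function(fractions) {
  split_keys <- interaction(fractions$replicate, fractions$treatment,
                            fractions$substrate, drop = TRUE)
  for (grp in split(fractions, split_keys)) {
    if (nrow(grp) < 2) {
      warning("replicate ", grp$replicate[1], " (", grp$treatment[1],
              ") has fewer than 2 fractions", call. = FALSE)
    }
    g <- grp[order(grp$fraction), ]
    if (is.unsorted(rev(g$density), strictly = TRUE)) {
      stop("densities must decrease strictly with fraction index in ",
           "replicate ", g$replicate[1], " (", g$treatment[1], ")",
           call. = FALSE)
    }
    idx <- sort(g$fraction)
    gaps <- setdiff(seq(min(idx), max(idx)), idx)
    if (length(gaps) > 0) {
      warning("replicate ", g$replicate[1], " (", g$treatment[1],
              ") is missing fraction(s) ", paste(gaps, collapse = ", "),
              call. = FALSE)
    }
  }
  invisible(fractions)
}

#' @export
print.qsip_dataset <- function(x, ...) {
  n_rep <- dplyr::n_distinct(x$fractions$replicate)
  cat("qSIP dataset: ", nrow(x$counts), " OTUs, ",
      nrow(x$fractions), " fraction libraries, ",
      n_rep, " replicates (",
      paste(unique(x$fractions$substrate), collapse = ", "), ")\n", sep = "")
  tr <- table(unique(x$fractions[c("replicate", "treatment")])$treatment)
  cat("  treatments:",
      paste(names(tr), tr, sep = " x ", collapse = ", "), "\n")
  invisible(x)
}

#' OTU identifiers of a qSIP dataset
#' @param dataset A `qsip_dataset`.
#' @return Character vector of OTU ids.
#' @export
otu_ids <- function(dataset) rownames(dataset$counts)

#' Restrict a qSIP dataset to a subset of OTUs
#' @param dataset A `qsip_dataset`.
#' @param keep Character vector of OTU ids to retain.
#' @return The dataset with `counts` subset to `keep` (original row order).
#' @export
subset_otus <- function(dataset, keep) {
  keep <- intersect(rownames(dataset$counts), keep)
  dataset$counts <- dataset$counts[keep, , drop = FALSE]
  if (!is.null(dataset$taxonomy)) {
    dataset$taxonomy <-
      dataset$taxonomy[dataset$taxonomy$otu_id %in% keep, , drop = FALSE]
  }
  dataset
}

stopifnot_dataset <- function(dataset) {
  if (!inherits(dataset, "qsip_dataset")) {
    stop("expected a `qsip_dataset`", call. = FALSE)
  }
  tr <- unique(dataset$fractions$treatment)
  if (!all(c("labeled", "control") %in% tr)) {
    stop("dataset needs at least one labeled and one control replicate",
         call. = FALSE)
  }
  invisible(dataset)
}
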