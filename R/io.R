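#' Read per-fraction metadata from a TSV file
#'
#' The fraction table is the experiment's backbone: one row per sequenced
#' density fraction with its replicate, treatment, substrate, 1-based fraction
#' index, measured buoyant density (g/ml) and total gene copies from qPCR.
#' Column names `density_g_ml`/`total_copies_per_g` (the on-disk convention)
#' and `density`/`total_copies` are both accepted.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of validated fraction records with a `library_id` column.
#' @export
read_fraction_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  names(raw)[names(raw) == "density_g_ml"] <- "density"
  names(raw)[names(raw) == "total_copies_per_g"] <- "total_copies"
  required <- c("replicate", "treatment", "substrate", "fraction",
                "density", "total_copies")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("fraction table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("fraction", "density", "total_copies")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           " of ", path, ": '", raw[[col]][bad[1]], "'", call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  raw$fraction <- as.integer(raw$fraction)
  out <- tibble::as_tibble(raw)
  out$library_id <- library_key(out)
  validate_gradient(out)
  out
}

#' Read an OTU count matrix (TSV or BIOM)
#'
#' @param path Path to the matrix. TSV layout: first column `otu_id`, one
#'   column per library key (`"replicate|treatment|substrate|fraction"`).
#'   BIOM files (JSON dialect) are read through the biomformat package and
#'   yield the identical in-memory matrix.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return Integer matrix, rows = OTUs, columns = library keys.
#' @export
read_otu_matrix <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")
  } else {
    raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
    id_col <- names(raw)[1]
    ids <- as.character(raw[[id_col]])
    mat <- as.matrix(raw[, -1, drop = FALSE])
    rownames(mat) <- ids
  }
  if (nrow(mat) == 0) {
    warning("OTU matrix ", path, " is empty", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1]
    stop("duplicate OTU row id '", dup, "' in ", path, call. = FALSE)
  }
  if (any(mat < 0)) stop("negative count in ", path, call. = FALSE)
  if (any(mat != round(mat))) {
    stop("non-integer count in ", path, call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Read a taxonomy map
#'
#' @param path TSV with columns `otu_id` and `lineage` (semicolon-delimited
#'   domain..genus string).
#' @return Tibble with columns `otu_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(raw))) {
    stop("taxonomy file needs columns otu_id and lineage", call. = FALSE)
  }
  tibble::as_tibble(raw[c("otu_id", "lineage")])
}

#' Read a phylogenetic tree from newick
#'
#' Trees are inputs here (built externally from aligned marker genes); this
#' wraps [ape::read.tree] with the validation qSIP traits need: unique tip
#' labels and non-missing branch lengths (missing lengths are imputed as 0
#' with a warning).
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
read_qsip_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse newick file ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("cannot parse newick file ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in ", path, call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths imputed as 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths in ", path, call. = FALSE)
  }
  tree
}

#' Write result tables plus a run summary and manifest
#'
#' @param tables Named list of data frames; each is written as
#'   `<name>.tsv` under `dir`. An empty data frame writes headers only.
#' @param dir Output directory (created if needed).
#' @param summary Named list serialized as `run_summary.json` (parameters,
#'   seed, per-stage OTU counts).
#' @return Tibble manifest (`file`, `md5`), one row per file written,
#'   invisibly also saved as `manifest.tsv`.
#' @export
write_results <- function(tables, dir, summary = list()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir, call. = FALSE)
  }
  if (file.access(dir, 2) != 0) {
    stop("output directory ", dir, " is not writable", call. = FALSE)
  }
  paths <- character(0)
  for (name in names(tables)) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(tables[[name]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, "run_summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, sp)
  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
  utils::write.table(as.data.frame(manifest), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Load a full qSIP dataset from its on-disk components
#'
#' @param fractions_path,counts_path Paths to the fraction table and OTU
#'   count matrix TSVs.
#' @param taxonomy_path Optional taxonomy TSV.
#' @param counts_format Passed to [read_otu_matrix()].
#' @return A `qsip_dataset`.
#' @export
load_qsip_dataset <- function(fractions_path, counts_path,
                              taxonomy_path = NULL,
                              counts_format = "tsv") {
  fr <- read_fraction_table(fractions_path)
  cnt <- read_otu_matrix(counts_path, counts_format)
  tax <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path) else NULL
  qsip_dataset(fr, cnt, taxonomy = tax,
               provenance = list(fractions = fractions_path,
                                 counts = counts_path))
}
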