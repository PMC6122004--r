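#' Run the full qSIP analysis for one substrate
#'
#' Orchestrates the canonical stage order — defensive singleton removal,
#' per-replicate abundance filter, contaminant removal, EAF estimation with
#' bootstrap labeling calls, per-taxon summary, and (when a tree is given)
#' phylogenetic-signal tests — writing all result tables, a JSON run summary
#' with per-stage OTU bookkeeping, and a checksummed manifest.
#'
#' @param dataset A `qsip_dataset`, or a list of input paths
#'   (`fractions`, `counts`, and optionally `taxonomy`) handed to
#'   [load_qsip_dataset()].
#' @param out_dir Output directory for result tables.
#' @param contaminants Optional contaminant count matrix (see
#'   [remove_contaminants()]).
#' @param tree Optional [ape::phylo] tree over OTU ids; when absent the
#'   signal stage is skipped and logged as such.
#' @param min_total Abundance filter threshold (default 12).
#' @param n_boot,conf,constants,seed Passed to [estimate_eaf()].
#' @param rank Taxonomic rank position for the summary (default 2 = phylum).
#' @param quiet Suppress stage messages.
#' @return List with `eaf` (estimate table), `summary` (per-taxon rows),
#'   `reports` (filter reports), `signal` (or `NULL`), `manifest`,
#'   `run_summary` — everything also written under `out_dir`.
#' @examples
#' sim <- simulate_qsip_experiment(simulation_config(n_taxa = 12,
#'                                                   depth = 3000), seed = 1)
#' res <- qsip_run(sim$dataset, out_dir = tempfile("qsip"),
#'                 contaminants = sim$contaminants, n_boot = 100, seed = 1)
#' res$reports$min_count
#' @export
qsip_run <- function(dataset, out_dir, contaminants = NULL, tree = NULL,
                     min_total = 12, n_boot = 1000, conf = 90,
                     constants = qsip_constants(), seed = 1L, rank = 2,
                     quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (!inherits(dataset, "qsip_dataset")) {
    dataset <- load_qsip_dataset(dataset$fractions, dataset$counts,
                                 dataset$taxonomy)
  }
  stage <- "singletons"
  res <- tryCatch({
    s1 <- filter_singletons(dataset)
    say("singletons: ", s1$report$n_in, " -> ", s1$report$n_out, " OTUs")
    stage <- "min_count"
    s2 <- filter_min_count(s1$dataset, min_total = min_total)
    say("min_count: ", s2$report$n_in, " -> ", s2$report$n_out, " OTUs")
    stage <- "contaminants"
    s3 <- if (is.null(contaminants)) {
      list(dataset = s2$dataset,
           report = new_filter_report("contaminants",
                                      nrow(s2$dataset$counts),
                                      tibble::tibble(otu_id = character(0),
                                                     reason = character(0))))
    } else {
      remove_contaminants(s2$dataset, contaminants)
    }
    say("contaminants: ", s3$report$n_in, " -> ", s3$report$n_out, " OTUs")
    stage <- "estimate"
    eaf <- estimate_eaf(s3$dataset, n_boot = n_boot, conf = conf,
                        constants = constants, seed = seed)
    say("estimate: ", nrow(eaf), " OTUs estimated, ",
        sum(eaf$labeled), " labeled")
    stage <- "summarize"
    summary_tab <- if (!is.null(s3$dataset$taxonomy)) {
      summarize_by_taxon(eaf, s3$dataset$taxonomy, s3$dataset$counts,
                         rank = rank)
    } else {
      tibble::tibble()
    }
    stage <- "phylosignal"
    signal <- NULL
    if (!is.null(tree)) {
      signal <- signal_for_labelset(tree, eaf, seed = seed)
      say("phylosignal: K = ", round(signal$K$estimate, 3),
          ", lambda = ", round(signal$lambda$estimate, 3))
    } else {
      say("phylosignal: skipped (no tree supplied)")
    }
    list(filtered = s3$dataset, eaf = eaf, summary = summary_tab,
         signal = signal,
         reports = list(singletons = s1$report, min_count = s2$report,
                        contaminants = s3$report))
  }, error = function(e) {
    stop("qSIP pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  excluded <- attr(res$eaf, "excluded")
  run_summary <- list(
    parameters = list(min_total = min_total, n_boot = n_boot, conf = conf,
                      seed = seed, rank = rank,
                      constants = unclass(constants)),
    stages = lapply(res$reports, function(r) {
      list(stage = r$stage, n_in = r$n_in, n_out = r$n_out,
           n_removed = nrow(r$removed))
    }),
    n_estimated = nrow(res$eaf),
    n_excluded_undefined = if (is.null(excluded)) 0L else nrow(excluded),
    n_labeled = sum(res$eaf$labeled),
    signal = if (is.null(res$signal)) NULL else list(
      K = res$signal$K$estimate, p_K = res$signal$K$p_value,
      lambda = res$signal$lambda$estimate,
      p_lambda = res$signal$lambda$p_value,
      n_tips = res$signal$n_matched
    )
  )
  tables <- list(
    eaf_table = res$eaf,
    taxon_summary = res$summary,
    filter_report = dplyr::bind_rows(lapply(res$reports, function(r) {
      if (nrow(r$removed) == 0) {
        tibble::tibble(stage = character(0), otu_id = character(0),
                       reason = character(0))
      } else {
        dplyr::bind_cols(tibble::tibble(stage = r$stage), r$removed)
      }
    })),
    excluded_otus = if (is.null(excluded)) tibble::tibble() else excluded
  )
  manifest <- write_results(tables, out_dir, summary = run_summary)
  c(res, list(manifest = manifest, run_summary = run_summary))
}

#' Back-calculate biomass from DNA content
#'
#' Converts a measured DNA concentration into total cellular biomass using
#' the assumed DNA share of cell biomass, and into isotopically labeled
#' biomass using the DNA labeling fraction: `total = dna_conc / dna_fraction`
#' and `labeled = total * labeling_fraction`. Values are returned unrounded;
#' round only at reporting.
#'
#' @param dna_conc DNA concentration (ug per g sediment).
#' @param dna_fraction_of_biomass DNA share of cellular biomass, in (0, 1]
#'   (a typical assumption is 0.031).
#' @param labeling_fraction Atom fraction labeling of the DNA, in (0, 1].
#' @return List `total_biomass`, `labeled_biomass` (ug per g sediment).
#' @examples
#' biomass_estimate(3, 0.031, 0.35)
#' @export
biomass_estimate <- function(dna_conc, dna_fraction_of_biomass,
                             labeling_fraction) {
  if (dna_conc <= 0) stop("`dna_conc` must be positive", call. = FALSE)
  if (dna_fraction_of_biomass <= 0 || dna_fraction_of_biomass > 1) {
    stop("`dna_fraction_of_biomass` must lie in (0, 1]", call. = FALSE)
  }
  if (labeling_fraction <= 0 || labeling_fraction > 1) {
    stop("`labeling_fraction` must lie in (0, 1]", call. = FALSE)
  }
  total <- dna_conc / dna_fraction_of_biomass
  list(total_biomass = total, labeled_biomass = total * labeling_fraction)
}
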