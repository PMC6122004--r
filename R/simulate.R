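#' Configuration for the qSIP experiment simulator
#'
#' Describes one substrate incubation of the emulated design: paired labeled
#' and unlabeled-control treatments, `n_replicates` biological replicates per
#' treatment, each fractionated into `n_fractions` equal density fractions
#' collected bottom-up (heavy to light) across `density_range`, with
#' per-fraction qPCR totals and multinomially sampled amplicon libraries.
#'
#' @param n_taxa Number of simulated taxa.
#' @param n_replicates Biological replicates per treatment (default 3,
#'   triplicate design).
#' @param n_fractions Density fractions per replicate (default 15).
#' @param density_range Heaviest and lightest fraction densities in g/ml
#'   (default `c(1.745, 1.675)`, a CsCl gradient bracketing a 1.70 g/ml
#'   starting density).
#' @param depth Reads per fraction library (default 20000).
#' @param eaf_distribution Spike-and-slab labeling spec:
#'   `p_unlabeled` (probability a taxon assimilates nothing) and the uniform
#'   range `eaf_min`..`eaf_max` for labeled taxa; this bimodal community
#'   (a distinctly labeled subpopulation over an unlabeled background) is the
#'   default because it is what replicated 13C incubations produce.
#'   Alternatively `list(levels = c(...))` assigns the given true-EAF levels
#'   to taxa in rotation (fixed recovery designs).
#' @param gc_distribution Uniform GC range (default 0.3-0.7).
#' @param abundance_distribution Lognormal parameters (`meanlog`, `sdlog`)
#'   for mean taxon abundance.
#' @param band_sd Within-gradient density spread of a taxon's DNA band
#'   (Gaussian s.d., g/ml; default 0.006, spreading a band over several
#'   fractions).
#' @param qpcr_cv Lognormal coefficient of variation of measured qPCR totals
#'   (default 0.10).
#' @param replicate_sd Between-replicate jitter of each taxon's band center
#'   (g/ml; default 0.001, drawn independently per taxon and replicate).
#' @param n_contaminant_otus Contaminant-only OTUs spiked into blank
#'   libraries (default 5).
#' @param n_blank_libraries Contaminant libraries (extraction blanks, dust;
#'   default 2).
#' @param contaminant_blank_mean Mean blank reads per contaminant OTU per
#'   blank library (default 300).
#' @param bleed_mean Mean low-level bleed of each real OTU into each blank
#'   library (default 0.5 reads).
#' @param tree_model Pure-birth parameters for [simulate_tree_and_traits()]
#'   (`birth` rate).
#' @param trait_lambda Target Pagel's lambda of simulated tip traits.
#' @param substrate Substrate label (default `"bicarbonate"`).
#' @return A validated `qsip_sim_config` list.
#' @export
simulation_config <- function(n_taxa = 200,
                              n_replicates = 3,
                              n_fractions = 15,
                              density_range = c(1.745, 1.675),
                              depth = 20000,
                              eaf_distribution = list(p_unlabeled = 0.35,
                                                      eaf_min = 0.05,
                                                      eaf_max = 0.25),
                              gc_distribution = list(min = 0.3, max = 0.7),
                              abundance_distribution = list(meanlog = 0,
                                                            sdlog = 1),
                              band_sd = 0.006,
                              qpcr_cv = 0.10,
                              replicate_sd = 0.001,
                              n_contaminant_otus = 5,
                              n_blank_libraries = 2,
                              contaminant_blank_mean = 300,
                              bleed_mean = 0.5,
                              tree_model = list(birth = 1),
                              trait_lambda = 1,
                              substrate = "bicarbonate") {
  cfg <- as.list(environment())
  if (n_taxa < 1 || n_replicates < 1 || n_fractions < 2 || depth < 1) {
    stop("taxa, replicate, fraction and depth counts must be positive",
         call. = FALSE)
  }
  if (band_sd <= 0) stop("`band_sd` must be positive", call. = FALSE)
  if (density_range[1] <= density_range[2]) {
    stop("`density_range` must be (heavy, light) with heavy > light",
         call. = FALSE)
  }
  structure(cfg, class = "qsip_sim_config")
}

#' Fraction density grid of a simulation config
#' @param config A [simulation_config()].
#' @return Descending density grid (g/ml), fraction 1 = heaviest.
#' @export
fraction_densities <- function(config) {
  seq(config$density_range[1], config$density_range[2],
      length.out = config$n_fractions)
}

#' Expected per-fraction copies of one taxon's DNA band
#'
#' Forward model inverting the EAF equations: the band centers at
#' `rho* = W_light(GC) * M_lab / M_light`, where
#' `M_lab = M_light + (true_eaf / (1 - nat_13c)) * (M_heavymax - M_light)`
#' for the labeled treatment and `rho* = W_light(GC)` for the control, and
#' copies follow a Gaussian of s.d. `band_sd` evaluated on the fraction grid,
#' renormalized to the taxon's abundance.
#'
#' @param gc GC fraction of the taxon.
#' @param true_eaf True excess atom fraction, in `[0, 1 - nat_13c]`.
#' @param abundance Total copies of the taxon in the tube.
#' @param treatment `"labeled"` or `"control"`.
#' @param config A [simulation_config()].
#' @param constants A [qsip_constants()] object.
#' @param center_shift Additive jitter on the band center (g/ml).
#' @return Numeric vector of expected copies per fraction (sums to
#'   `abundance`).
#' @export
simulate_taxon_profile <- function(gc, true_eaf, abundance, treatment,
                                   config = simulation_config(),
                                   constants = qsip_constants(),
                                   center_shift = 0) {
  constants <- as_qsip_constants(constants)
  if (gc < 0 || gc > 1) stop("`gc` must lie in [0, 1]", call. = FALSE)
  if (true_eaf < 0 || true_eaf > 1 - constants$nat_13c) {
    stop("`true_eaf` must lie in [0, 1 - nat_13c]", call. = FALSE)
  }
  rho <- fraction_densities(config)
  center <- taxon_band_center(gc, true_eaf, treatment, constants) +
    center_shift
  dens <- stats::dnorm(rho, mean = center, sd = config$band_sd)
  if (sum(dens) == 0) {
    # band entirely outside the sampled window; park all copies at the edge
    dens <- as.numeric(seq_along(rho) == which.min(abs(rho - center)))
  }
  dens / sum(dens) * abundance
}

taxon_band_center <- function(gc, true_eaf, treatment,
                              constants = qsip_constants()) {
  w_light <- constants$gc_intercept + constants$gc_slope * gc
  if (treatment == "control") return(w_light)
  mw <- molecular_weights(gc, constants)
  m_lab <- mw$m_light +
    true_eaf / (1 - constants$nat_13c) * (mw$m_heavymax - mw$m_light)
  w_light * m_lab / mw$m_light
}

#' Simulate a full paired labeled/control qSIP dataset
#'
#' Draws per-taxon GC, true EAF (spike-and-slab) and lognormal abundances,
#' then for every replicate and treatment builds the density profiles, adds
#' per-taxon replicate jitter, applies lognormal qPCR noise to the measured
#' totals, and samples each library's reads from a multinomial at the
#' configured depth. Deterministic for a given `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param noise One of `"default"` (all noise terms on) or `"off"`
#'   (no replicate jitter, no qPCR noise, expected counts rounded instead of
#'   multinomially sampled) for forward/inverse consistency checks.
#' @return List with `dataset` (a `qsip_dataset` containing both treatments
#'   and a generated taxonomy), `truth` (tibble `otu_id`, `true_eaf`, `gc`,
#'   `mean_abundance`, `phylum`) and `config`.
#' @export
simulate_qsip_dataset <- function(config = simulation_config(), seed = 1L,
                                  noise = c("default", "off")) {
  noise <- match.arg(noise)
  constants <- qsip_constants()
  set.seed(seed)
  n <- config$n_taxa
  ids <- sprintf("OTU_%04d", seq_len(n))
  gc <- stats::runif(n, config$gc_distribution$min, config$gc_distribution$max)
  if (!is.null(config$eaf_distribution$levels)) {
    # fixed design: cycle the requested EAF levels across taxa
    lv <- config$eaf_distribution$levels
    true_eaf <- lv[(seq_len(n) - 1L) %% length(lv) + 1L]
  } else {
    labeled_taxon <- stats::runif(n) >= config$eaf_distribution$p_unlabeled
    true_eaf <- ifelse(labeled_taxon,
                       stats::runif(n, config$eaf_distribution$eaf_min,
                                    config$eaf_distribution$eaf_max),
                       0)
  }
  abundance <- stats::rlnorm(n, config$abundance_distribution$meanlog,
                             config$abundance_distribution$sdlog)
  abundance <- abundance / sum(abundance) * 1e8  # copies per g sediment
  phyla <- c("Proteobacteria", "Bacteroidetes", "Verrucomicrobia",
             "Chloroflexi", "Acidobacteria", "Actinobacteria",
             "Planctomycetes", "Thaumarchaeota")
  phylum <- phyla[(seq_len(n) - 1L) %% length(phyla) + 1L]
  domain <- ifelse(phylum == "Thaumarchaeota", "Archaea", "Bacteria")

  if (stats::median(abundance / sum(abundance)) * config$depth < 0.1) {
    warning("depth too low to represent most taxa (median expected count ",
            "< 0.1 reads/library)", call. = FALSE)
  }

  rho <- fraction_densities(config)
  fr_rows <- list()
  count_cols <- list()
  for (treatment in c("labeled", "control")) {
    for (r in seq_len(config$n_replicates)) {
      rep_id <- paste0(ifelse(treatment == "labeled", "L", "C"), r)
      jitter <- if (noise == "off") rep(0, n) else
        stats::rnorm(n, 0, config$replicate_sd)
      profiles <- vapply(seq_len(n), function(i) {
        simulate_taxon_profile(gc[i], true_eaf[i], abundance[i], treatment,
                               config, constants, center_shift = jitter[i])
      }, numeric(config$n_fractions))
      # profiles: fraction x taxon expected copies
      frac_totals <- rowSums(profiles)
      qpcr_noise <- if (noise == "off") rep(1, config$n_fractions) else {
        sdlog <- sqrt(log(1 + config$qpcr_cv^2))
        stats::rlnorm(config$n_fractions, -sdlog^2 / 2, sdlog)
      }
      for (f in seq_len(config$n_fractions)) {
        expected <- profiles[f, ]
        prob <- expected / sum(expected)
        reads <- if (noise == "off") {
          round(prob * config$depth)
        } else {
          as.vector(stats::rmultinom(1, config$depth, prob))
        }
        key <- paste(rep_id, treatment, config$substrate, f, sep = "|")
        fr_rows[[key]] <- tibble::tibble(
          replicate = rep_id, treatment = treatment,
          substrate = config$substrate, fraction = f,
          density = rho[f],
          total_copies = frac_totals[f] * qpcr_noise[f]
        )
        count_cols[[key]] <- reads
      }
    }
  }
  fractions <- dplyr::bind_rows(fr_rows)
  counts <- do.call(cbind, count_cols)
  rownames(counts) <- ids
  storage.mode(counts) <- "integer"
  taxonomy <- tibble::tibble(
    otu_id = ids,
    lineage = paste(domain, phylum, "order_unc", "family_unc", "genus_unc",
                    sep = ";")
  )
  truth <- tibble::tibble(otu_id = ids, true_eaf = true_eaf, gc = gc,
                          mean_abundance = abundance, phylum = phylum)
  dataset <- qsip_dataset(fractions, counts, taxonomy = taxonomy,
                          provenance = list(simulated = TRUE, seed = seed,
                                            substrate = config$substrate))
  list(dataset = dataset, truth = truth, config = config)
}

#' Simulate contaminant (blank) libraries for a dataset
#'
#' Adds `n_contaminant_otus` contaminant-only OTUs (high blank counts, trace
#' sample counts) to the dataset and builds blank count libraries including a
#' low-level bleed of the real OTUs, with truth flags saying which OTUs the
#' contaminant rule (blank total > sample total) should remove.
#'
#' @param dataset A `qsip_dataset` (typically from
#'   [simulate_qsip_dataset()]).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List: `dataset` (with contaminant OTU rows appended),
#'   `contaminants` (blank count matrix over all OTUs), `truth` (tibble
#'   `otu_id`, `is_contaminant`, `remove_expected`).
#' @export
simulate_contaminant_libraries <- function(dataset,
                                           config = simulation_config(),
                                           seed = 1L) {
  set.seed(seed)
  n_blank <- config$n_blank_libraries
  n_cont <- config$n_contaminant_otus
  real_ids <- otu_ids(dataset)
  cont_ids <- if (n_cont > 0) sprintf("CONT_%03d", seq_len(n_cont)) else
    character(0)

  if (n_cont > 0) {
    # contaminants appear in samples only as rare carryover
    cont_sample <- matrix(
      stats::rpois(n_cont * ncol(dataset$counts), 0.2),
      nrow = n_cont,
      dimnames = list(cont_ids, colnames(dataset$counts))
    )
    storage.mode(cont_sample) <- "integer"
    dataset$counts <- rbind(dataset$counts, cont_sample)
    if (!is.null(dataset$taxonomy)) {
      dataset$taxonomy <- dplyr::bind_rows(
        dataset$taxonomy,
        tibble::tibble(otu_id = cont_ids, lineage = "Bacteria;contaminant")
      )
    }
  }
  all_ids <- c(real_ids, cont_ids)
  blanks <- matrix(0L, length(all_ids), n_blank,
                   dimnames = list(all_ids,
                                   paste0("blank_", seq_len(n_blank))))
  if (n_blank > 0) {
    blanks[real_ids, ] <- stats::rpois(length(real_ids) * n_blank,
                                       config$bleed_mean)
    if (n_cont > 0) {
      blanks[cont_ids, ] <- stats::rpois(n_cont * n_blank,
                                         config$contaminant_blank_mean)
    }
  }
  sample_tot <- rowSums(dataset$counts)[all_ids]
  truth <- tibble::tibble(
    otu_id = all_ids,
    is_contaminant = all_ids %in% cont_ids,
    remove_expected = rowSums(blanks) > sample_tot
  )
  list(dataset = dataset, contaminants = blanks, truth = truth)
}

#' Simulate a pure-birth tree with traits of tunable phylogenetic signal
#'
#' Generates a pure-birth (Yule) tree and draws tip traits from a
#' multivariate normal whose covariance is the tree's BM covariance with
#' off-diagonal entries scaled by `trait_lambda`: `lambda = 1` gives pure BM
#' traits, `lambda = 0` i.i.d. traits.
#'
#' @param n_taxa Number of tips (>= 4).
#' @param trait_lambda Target lambda in `[0, 1]`.
#' @param birth Speciation rate of the pure-birth process.
#' @param seed Integer seed.
#' @param tip_labels Optional tip names (default `OTU_0001`...).
#' @param trait_mean,trait_sd Location and BM-scale of the trait.
#' @return List `tree` ([ape::phylo]), `trait` (named vector), `lambda`.
#' @export
simulate_tree_and_traits <- function(n_taxa, trait_lambda = 1, birth = 1,
                                     seed = 1L, tip_labels = NULL,
                                     trait_mean = 0.1, trait_sd = 0.05) {
  if (n_taxa < 4) stop("need >= 4 taxa for a usable tree", call. = FALSE)
  if (trait_lambda < 0 || trait_lambda > 1) {
    stop("`trait_lambda` must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth, death = 0)
  if (!is.null(tip_labels)) tree$tip.label <- tip_labels
  C <- ape::vcv(tree)
  C <- C / mean(diag(C))  # unit tip variance so trait_sd is interpretable
  V <- lambda_transform(C, trait_lambda)
  z <- stats::rnorm(n_taxa)
  trait <- trait_mean + trait_sd * drop(t(chol(V)) %*% z)
  names(trait) <- tree$tip.label
  list(tree = tree, trait = trait, lambda = trait_lambda)
}

#' Simulate the complete experiment for one substrate
#'
#' Convenience wrapper chaining [simulate_qsip_dataset()],
#' [simulate_contaminant_libraries()] and [simulate_tree_and_traits()] from
#' one seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List `dataset`, `truth`, `contaminants`, `contaminant_truth`,
#'   `tree`, `tree_trait`, `config`.
#' @export
simulate_qsip_experiment <- function(config = simulation_config(),
                                     seed = 1L) {
  sim <- simulate_qsip_dataset(config, seed = seed)
  cont <- simulate_contaminant_libraries(sim$dataset, config, seed = seed + 1L)
  tt <- simulate_tree_and_traits(config$n_taxa,
                                 trait_lambda = config$trait_lambda,
                                 birth = config$tree_model$birth,
                                 seed = seed + 2L,
                                 tip_labels = sim$truth$otu_id)
  list(dataset = cont$dataset, truth = sim$truth,
       contaminants = cont$contaminants, contaminant_truth = cont$truth,
       tree = tt$tree, tree_trait = tt$trait, config = config)
}

#' Write a simulated experiment to disk in the package's interchange formats
#'
#' @param sim Output of [simulate_qsip_experiment()].
#' @param dir Output directory.
#' @return Invisibly, the vector of files written (`fractions.tsv`,
#'   `otu_counts.tsv`, `taxonomy.tsv`, `contaminants.tsv`, `tree.nwk`,
#'   `truth.tsv`).
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- sim$dataset
  fr <- ds$fractions
  fr_out <- data.frame(replicate = fr$replicate, treatment = fr$treatment,
                       substrate = fr$substrate, fraction = fr$fraction,
                       density_g_ml = fr$density,
                       total_copies_per_g = fr$total_copies)
  files <- c(fractions = file.path(dir, "fractions.tsv"),
             otu_counts = file.path(dir, "otu_counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             contaminants = file.path(dir, "contaminants.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(fr_out, files["fractions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cnt <- data.frame(otu_id = rownames(ds$counts), ds$counts,
                    check.names = FALSE)
  utils::write.table(cnt, files["otu_counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(ds$taxonomy), files["taxonomy"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cont <- data.frame(otu_id = rownames(sim$contaminants), sim$contaminants,
                     check.names = FALSE)
  utils::write.table(cont, files["contaminants"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ape::write.tree(sim$tree, files["tree"])
  utils::write.table(as.data.frame(sim$truth), files["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(files)
}
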