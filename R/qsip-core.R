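#' @title Excess atom fraction estimation from density shifts
#' @description The quantitative core of qSIP: per-taxon weighted-average
#'   buoyant densities, the GC/molar-mass isotope model, per-OTU 13C excess
#'   atom fraction (EAF), bootstrap confidence intervals and labeling calls.
#' @name qsip_core
NULL

#' Convert library read counts to per-OTU gene copies
#'
#' Sequencing gives relative abundances; qPCR gives the library's total gene
#' copies. Their product assigns absolute copies to each OTU in a fraction:
#' `y_i(otu) = (count / depth) * total_copies`.
#'
#' @param counts Named non-negative integer vector of OTU read counts for one
#'   fraction library.
#' @param total_copies Total gene copies in that fraction (qPCR).
#' @return Named numeric vector of copies per OTU, summing to `total_copies`.
#' @examples
#' per_fraction_copies(c(A = 10, B = 30, C = 60), 1000)
#' @export
per_fraction_copies <- function(counts, total_copies) {
  depth <- sum(counts)
  if (depth <= 0) {
    warning("library has zero read depth; excluded", call. = FALSE)
    return(NULL)
  }
  counts / depth * total_copies
}

#' Weighted-average buoyant density of one OTU
#'
#' `W = sum(rho_i * y_i) / sum(y_i)` over the fractions of one replicate:
#' the copy-weighted mean density at which a taxon's DNA bands.
#'
#' @param y Per-fraction gene copies of the OTU.
#' @param rho Matching fraction densities (g/ml).
#' @return Scalar W (g/ml), or `NA` if `sum(y) == 0` (the OTU is absent from
#'   that replicate and its density is undefined).
#' @examples
#' weighted_average_density(c(100, 300, 600), c(1.68, 1.70, 1.72))
#' @export
weighted_average_density <- function(y, rho) {
  if (length(y) != length(rho)) {
    stop("`y` and `rho` must align by fraction", call. = FALSE)
  }
  tot <- sum(y)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(rho * y) / tot
}

#' GC content inferred from unlabeled buoyant density
#'
#' @param w_light Weighted-average density in the control (unlabeled)
#'   incubation (g/ml). Vectorized.
#' @param constants A [qsip_constants()] object.
#' @return GC fraction, clamped to `[0, 1]` with a warning when the density
#'   implies a value outside it.
#' @export
gc_from_density <- function(w_light, constants = qsip_constants()) {
  constants <- as_qsip_constants(constants)
  gc <- (w_light - constants$gc_intercept) / constants$gc_slope
  out_of_range <- !is.na(gc) & (gc < -1e-9 | gc > 1 + 1e-9)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " density value(s) imply GC outside [0, 1]; ",
            "clamped", call. = FALSE)
  }
  pmin(pmax(gc, 0), 1)
}

#' Mean nucleotide molar masses at a given GC content
#'
#' @param gc GC fraction in `[0, 1]`. Vectorized.
#' @param constants A [qsip_constants()] object.
#' @return List with `m_light` (unlabeled mean nucleotide mass, g/mol) and
#'   `m_heavymax` (mass under complete 13C substitution).
#' @export
molecular_weights <- function(gc, constants = qsip_constants()) {
  constants <- as_qsip_constants(constants)
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) {
    stop("`gc` must lie in [0, 1]", call. = FALSE)
  }
  m_light <- constants$mw_slope * gc + constants$mw_intercept
  dmax <- constants$dmax_intercept + constants$dmax_slope * gc
  list(m_light = m_light, m_heavymax = m_light + dmax)
}

#' Point estimate of 13C excess atom fraction from a density shift
#'
#' Chains the isotope model: GC from the light density, the labeled molar
#' mass `M_lab = (W_lab / W_light) * M_light` from the relative density
#' shift, and
#' `A = (M_lab - M_light) / (M_heavymax - M_light) * (1 - nat_13c)`.
#' A is 0 at zero shift and saturates at `1 - nat_13c` when the labeled mass
#' reaches `M_heavymax`. Negative shifts give negative A; values are not
#' truncated at 0, since truncation would bias the CI-above-zero labeling
#' test.
#'
#' @param w_light,w_lab Weighted-average densities (g/ml) in control and
#'   labeled incubations. Vectorized.
#' @param constants A [qsip_constants()] object.
#' @return EAF (atom fraction excess of 13C), same length as inputs.
#' @examples
#' eaf_point(1.700, 1.706)
#' @export
eaf_point <- function(w_light, w_lab, constants = qsip_constants()) {
  constants <- as_qsip_constants(constants)
  if (any(w_light <= 0, na.rm = TRUE)) {
    stop("`w_light` must be positive", call. = FALSE)
  }
  gc <- gc_from_density(w_light, constants)
  mw <- molecular_weights(gc, constants)
  m_lab <- (w_lab / w_light) * mw$m_light
  (m_lab - mw$m_light) / (mw$m_heavymax - mw$m_light) * (1 - constants$nat_13c)
}

#' Per-replicate weighted-average densities for every OTU
#'
#' @param dataset A `qsip_dataset`.
#' @return Tibble with columns `otu_id`, `replicate`, `treatment`,
#'   `substrate`, `w` (weighted-average density, `NA` when the OTU has no
#'   copies in that replicate) and `total_y` (summed copies behind the
#'   weights). Zero-depth libraries are excluded with a warning.
#' @export
weighted_densities <- function(dataset) {
  stopifnot_dataset(dataset)
  fr <- dataset$fractions
  depth <- colSums(dataset$counts)
  if (any(depth == 0)) {
    warning(sum(depth == 0), " librar(ies) with zero read depth excluded",
            call. = FALSE)
  }
  grp_id <- paste(fr$replicate, fr$treatment, fr$substrate, sep = "|")
  out <- vector("list", length(unique(grp_id)))
  i <- 0
  for (g in unique(grp_id)) {
    sel <- grp_id == g & depth[fr$library_id] > 0
    if (!any(sel)) next
    sub <- fr[sel, ]
    # OTU x fraction copies: counts scaled to qPCR totals
    cnt <- dataset$counts[, sub$library_id, drop = FALSE]
    y <- sweep(cnt, 2, depth[sub$library_id], "/")
    y <- sweep(y, 2, sub$total_copies, "*")
    tot <- rowSums(y)
    w <- as.vector(y %*% sub$density) / tot
    w[tot <= 0] <- NA_real_
    i <- i + 1
    out[[i]] <- tibble::tibble(
      otu_id = rownames(cnt),
      replicate = sub$replicate[1],
      treatment = sub$treatment[1],
      substrate = sub$substrate[1],
      w = w, total_y = tot
    )
  }
  dplyr::bind_rows(out[seq_len(i)])
}

#' Decide whether an OTU is 13C labeled
#'
#' The labeling rule: an OTU is called labeled when the lower bound of the
#' bootstrap confidence interval of its EAF lies strictly above zero.
#'
#' @param ci_low Lower CI bound(s), or an estimate table with a `ci_low`
#'   column.
#' @return Logical vector.
#' @export
call_labeled <- function(ci_low) {
  if (is.data.frame(ci_low)) ci_low <- ci_low$ci_low
  !is.na(ci_low) & ci_low > 0
}

boot_group_means <- function(w, n_boot) {
  n <- length(w)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  matrix(w[idx], nrow = n_boot) |> rowMeans()
}

#' Bootstrap EAF estimate for one OTU
#'
#' Resamples biological replicates (the only exchangeable unit of the
#' design) with replacement within each treatment group, keeping group sizes;
#' each resample's group means give one bootstrap EAF. The reported estimate
#' is the bootstrap median with a two-sided percentile CI (linear
#' interpolation between order statistics).
#'
#' @param w_lab,w_light Weighted-average densities of the OTU in the labeled
#'   and control replicates (NA entries dropped).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param conf Two-sided confidence level in percent (default 90).
#' @param constants A [qsip_constants()] object.
#' @param seed Optional integer seed for this OTU's resampling stream.
#' @return One-row tibble: `n_reps_labeled`, `n_reps_control`,
#'   `w_light_mean`, `w_lab_mean`, `point_eaf`, `boot_median`, `ci_low`,
#'   `ci_high`, `labeled`.
#' @export
bootstrap_eaf <- function(w_lab, w_light, n_boot = 1000, conf = 90,
                          constants = qsip_constants(), seed = NULL) {
  constants <- as_qsip_constants(constants)
  w_lab <- w_lab[!is.na(w_lab)]
  w_light <- w_light[!is.na(w_light)]
  if (length(w_light) == 0) {
    stop("OTU absent from all control replicates: EAF undefined",
         call. = FALSE)
  }
  if (length(w_lab) == 0) {
    stop("OTU absent from all labeled replicates: EAF undefined",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lab_means <- boot_group_means(w_lab, n_boot)
  light_means <- boot_group_means(w_light, n_boot)
  boots <- eaf_point(light_means, lab_means, constants)
  probs <- c((1 - conf / 100) / 2, 1 - (1 - conf / 100) / 2)
  ci <- stats::quantile(boots, probs, names = FALSE, type = 7)
  tibble::tibble(
    n_reps_labeled = length(w_lab),
    n_reps_control = length(w_light),
    w_light_mean = mean(w_light),
    w_lab_mean = mean(w_lab),
    point_eaf = eaf_point(mean(w_light), mean(w_lab), constants),
    boot_median = stats::median(boots),
    ci_low = ci[1],
    ci_high = ci[2],
    n_boot = n_boot,
    labeled = call_labeled(ci[1])
  )
}

#' Estimate EAF with bootstrap CIs for every OTU in a dataset
#'
#' The main estimation driver: computes per-replicate weighted-average
#' densities, then for each OTU bootstraps replicate resamples to a median
#' EAF, percentile CI and labeling call. One master seed fans out into
#' per-OTU streams (assigned by sorted OTU id), so results do not depend on
#' OTU iteration order.
#'
#' @param dataset A `qsip_dataset` (already filtered).
#' @param n_boot Bootstrap replicates per OTU (default 1000).
#' @param conf Two-sided CI level in percent (default 90).
#' @param constants A [qsip_constants()] object.
#' @param seed Master seed (integer).
#' @return Tibble with one row per estimable OTU (columns as in
#'   [bootstrap_eaf()] plus `otu_id`), and an attribute `"excluded"`: a
#'   tibble of OTUs with undefined EAF (absent from all control or all
#'   labeled replicates) and the reason.
#' @examples
#' sim <- simulate_qsip_experiment(simulation_config(n_taxa = 10,
#'                                                   depth = 2000), seed = 1)
#' est <- estimate_eaf(sim$dataset, n_boot = 200, seed = 1)
#' head(est)
#' @export
estimate_eaf <- function(dataset, n_boot = 1000, conf = 90,
                         constants = qsip_constants(), seed = 1L) {
  stopifnot_dataset(dataset)
  constants <- as_qsip_constants(constants)
  wads <- weighted_densities(dataset)
  ids <- sort(unique(wads$otu_id))
  set.seed(seed)
  otu_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  names(otu_seeds) <- ids

  w_lab_list <- split(wads$w[wads$treatment == "labeled"],
                      wads$otu_id[wads$treatment == "labeled"])
  w_light_list <- split(wads$w[wads$treatment == "control"],
                        wads$otu_id[wads$treatment == "control"])

  rows <- vector("list", length(ids))
  excluded <- list()
  for (id in ids) {
    w_lab <- w_lab_list[[id]]
    w_light <- w_light_list[[id]]
    if (is.null(w_light) || all(is.na(w_light))) {
      excluded[[id]] <- "absent from all control replicates"
      next
    }
    if (is.null(w_lab) || all(is.na(w_lab))) {
      excluded[[id]] <- "absent from all labeled replicates"
      next
    }
    est <- bootstrap_eaf(w_lab, w_light, n_boot = n_boot, conf = conf,
                         constants = constants, seed = otu_seeds[[id]])
    rows[[id]] <- dplyr::bind_cols(tibble::tibble(otu_id = id), est)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- tibble::tibble(
    otu_id = names(excluded),
    reason = unlist(excluded, use.names = FALSE)
  )
  out
}

#' Normalize a per-fraction abundance profile to its maximum
#'
#' Single-gene density profiles (e.g. qPCR of a marker gene across the
#' gradient) are compared after scaling each profile so its maximum is 1.
#'
#' @param values Non-negative per-fraction quantities, at least one positive.
#' @param label Profile name used in error messages.
#' @return `values / max(values)`.
#' @export
normalize_profile <- function(values, label = "profile") {
  if (all(values == 0) || all(is.na(values))) {
    stop("all-zero profile in ", label, ": cannot normalize", call. = FALSE)
  }
  values / max(values, na.rm = TRUE)
}

#' Density shift between labeled and control gradient profiles
#'
#' Compares two single-gene profiles on a shared density grid. The default
#' `"weighted"` mode is the difference of abundance-weighted mean densities
#' (robust on a 15-point grid); `"peak"` mode is the difference of peak
#' densities, with plateaus (tied maxima) resolved to the centroid of the
#' argmax set.
#'
#' @param labeled_profile,control_profile Non-negative abundances on `rho`.
#' @param rho Shared density grid (g/ml).
#' @param mode `"weighted"` (default) or `"peak"`.
#' @return Shift in g/ml (labeled minus control).
#' @export
peak_density_shift <- function(labeled_profile, control_profile, rho,
                               mode = c("weighted", "peak")) {
  mode <- match.arg(mode)
  if (all(labeled_profile == 0) || all(control_profile == 0)) {
    stop("all-zero profile: shift undefined", call. = FALSE)
  }
  center <- function(v) {
    if (mode == "weighted") {
      sum(rho * v) / sum(v)
    } else {
      mean(rho[v == max(v)])  # centroid of tied maxima
    }
  }
  center(labeled_profile) - center(control_profile)
}

#' Exact resampling distribution of the bootstrap EAF
#'
#' Enumerates all `n_lab^n_lab * n_light^n_light` with-replacement resamples
#' of the replicate density vectors and the EAF of each, with its
#' probability. Feasible for small groups (<= 4 replicates); serves as the
#' exact reference distribution the stochastic bootstrap converges to.
#'
#' @param w_lab,w_light Replicate weighted-average densities.
#' @param constants A [qsip_constants()] object.
#' @return Tibble `eaf`, `prob`, aggregated over equal-EAF resamples and
#'   sorted by `eaf`; probabilities sum to 1.
#' @export
enumerate_bootstrap_eaf <- function(w_lab, w_light,
                                    constants = qsip_constants()) {
  constants <- as_qsip_constants(constants)
  mean_support <- function(w) {
    n <- length(w)
    grids <- rep(list(seq_len(n)), n)
    idx <- as.matrix(expand.grid(grids))
    means <- rowMeans(matrix(w[idx], nrow = nrow(idx)))
    agg <- tapply(rep(1 / n^n, length(means)), round(means, 12), sum)
    tibble::tibble(mean = as.numeric(names(agg)), prob = as.numeric(agg))
  }
  lab <- mean_support(w_lab)
  light <- mean_support(w_light)
  grid <- tidyr::expand_grid(i = seq_len(nrow(lab)), j = seq_len(nrow(light)))
  eaf <- eaf_point(light$mean[grid$j], lab$mean[grid$i], constants)
  prob <- lab$prob[grid$i] * light$prob[grid$j]
  agg <- tapply(prob, round(eaf, 12), sum)
  tibble::tibble(eaf = as.numeric(names(agg)), prob = as.numeric(agg)) |>
    dplyr::arrange(.data$eaf)
}
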