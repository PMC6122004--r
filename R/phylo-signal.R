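#' @title Phylogenetic signal of EAF traits
#' @description Blomberg's K and Pagel's lambda for continuous traits on a
#'   tree, with permutation and likelihood-ratio significance tests. Used to
#'   ask whether carbon assimilation (EAF) is phylogenetically conserved
#'   among labeled taxa.
#' @name phylo_signal
NULL

# align trait to tips, validate, and return a positive-definite covariance
prepare_signal_input <- function(tree, trait) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo", call. = FALSE)
  n <- length(tree$tip.label)
  if (n < 4) stop("need >= 4 tips for signal tests", call. = FALSE)
  if (is.null(names(trait))) {
    if (length(trait) != n) {
      stop("unnamed trait must have one value per tip", call. = FALSE)
    }
    names(trait) <- tree$tip.label
  }
  missing_tips <- setdiff(tree$tip.label, names(trait))
  if (length(missing_tips) > 0) {
    stop("trait missing for tip(s): ",
         paste(utils::head(missing_tips, 3), collapse = ", "), call. = FALSE)
  }
  x <- trait[tree$tip.label]
  if (stats::var(x) == 0) {
    stop("constant trait: phylogenetic signal undefined", call. = FALSE)
  }
  # zero-length terminal branches make the covariance singular
  term <- tree$edge[, 2] <= n
  if (any(tree$edge.length[term] == 0)) {
    eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    if (eps == 0) eps <- 1e-8
    warning("zero-length terminal branch(es) perturbed by ",
            format(eps), " for covariance invertibility", call. = FALSE)
    tree$edge.length[term & tree$edge.length == 0] <- eps
  }
  C <- ape::vcv(tree)
  list(x = x, C = C, n = n, tree = tree)
}

# GLS mean and quadratic form under covariance V (via its Cholesky factor R)
gls_stats <- function(x, V, R = chol(V)) {
  xi <- backsolve(R, x, transpose = TRUE)
  oi <- backsolve(R, rep(1, length(x)), transpose = TRUE)
  a <- sum(oi * xi) / sum(oi * oi)
  r <- xi - a * oi
  list(a = a, quad = sum(r * r), logdet = 2 * sum(log(diag(R))),
       one_quad = sum(oi * oi))
}

blomberg_k_stat <- function(x, C, R = chol(C)) {
  n <- length(x)
  g <- gls_stats(x, C, R)
  mse <- g$quad / (n - 1)
  # numerator variance is around the GLS (phylogenetic) mean, not the
  # arithmetic mean
  mse0 <- sum((x - g$a)^2) / (n - 1)
  expected <- (sum(diag(C)) - n / g$one_quad) / (n - 1)
  (mse0 / mse) / expected
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed ratio of tip variance to phylogenetically
#' corrected variance with its expectation under Brownian motion (BM) on the
#' same tree: K near 1 indicates BM-like signal, near 0 phylogenetic
#' independence. Significance is assessed by shuffling trait values across
#' tips: the p-value is the plus-one-corrected fraction of permuted K values
#' at least as large as the observed one.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param trait Named numeric vector (names = tip labels), e.g. bootstrap
#'   median EAFs.
#' @param n_perm Number of tip-label permutations (default 999).
#' @param seed Optional seed for the permutation stream.
#' @return A `qsip_signal` object: list with `statistic = "K"`, `estimate`,
#'   `p_value`, `n_tips`, `method_detail`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  inp <- prepare_signal_input(tree, trait)
  R <- chol(inp$C)
  k_obs <- blomberg_k_stat(inp$x, inp$C, R)
  if (!is.null(seed)) set.seed(seed)
  k_perm <- vapply(seq_len(n_perm), function(i) {
    blomberg_k_stat(sample(inp$x), inp$C, R)
  }, numeric(1))
  p <- (sum(k_perm >= k_obs) + 1) / (n_perm + 1)
  star <- inp$tree$Nnode == 1
  detail <- sprintf("permutation test, %d tip shuffles, plus-one correction",
                    n_perm)
  if (star) {
    detail <- paste0(detail, "; star tree: no internal structure, low power")
  }
  structure(list(statistic = "K", estimate = unname(k_obs),
                 p_value = unname(p), n_tips = inp$n,
                 method_detail = detail, low_power = star),
            class = "qsip_signal")
}

lambda_transform <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

lambda_loglik <- function(lambda, x, C) {
  n <- length(x)
  V <- lambda_transform(C, lambda)
  g <- tryCatch(gls_stats(x, V), error = function(e) NULL)
  if (is.null(g)) return(-Inf)
  sigma2 <- g$quad / n
  if (sigma2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * sigma2) + g$logdet + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' lambda scales the off-diagonal (shared-history) entries of the tree's BM
#' covariance, leaving the diagonal unchanged; the ML estimate over
#' `[0, 1]` measures how much shared history explains trait covariance
#' (0 = independence, 1 = pure BM). Significance is a likelihood-ratio test
#' of the ML fit against lambda = 0, compared to a chi-squared distribution
#' with 1 df (or, optionally, the 50:50 boundary mixture of chi-squared 0
#' and 1 df).
#'
#' @inheritParams blomberg_k
#' @param null_dist `"chisq1"` (default) or `"mixture"` for the boundary
#'   mixture.
#' @return A `qsip_signal` object with `statistic = "lambda"`, plus
#'   `loglik`, `loglik0` and `lrt_stat`.
#' @export
pagel_lambda <- function(tree, trait, null_dist = c("chisq1", "mixture")) {
  null_dist <- match.arg(null_dist)
  inp <- prepare_signal_input(tree, trait)
  obj <- function(l) lambda_loglik(l, inp$x, inp$C)
  opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  # optimize() never evaluates the exact endpoints; check them explicitly
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, obj(0), obj(1))
  best <- which.max(ll)
  lambda_hat <- cand[best]
  ll_hat <- ll[best]
  ll0 <- ll[2]
  if (!is.finite(ll_hat)) {
    stop("lambda likelihood optimization failed; log-likelihoods: ",
         paste(format(ll), collapse = ", "), call. = FALSE)
  }
  stat <- max(0, 2 * (ll_hat - ll0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (null_dist == "mixture") {
    p <- if (stat == 0) 1 else 0.5 * p
  }
  structure(list(statistic = "lambda", estimate = lambda_hat, p_value = p,
                 n_tips = inp$n,
                 method_detail = sprintf(
                   "ML over [0,1], LRT vs lambda=0 against %s",
                   if (null_dist == "chisq1") "chi-squared(1)"
                   else "0.5*chi2(0) + 0.5*chi2(1) boundary mixture"),
                 loglik = ll_hat, loglik0 = ll0, lrt_stat = stat),
            class = "qsip_signal")
}

#' @export
print.qsip_signal <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (n = %d tips)\n  %s\n",
              x$statistic, x$estimate, x$p_value, x$n_tips, x$method_detail))
  invisible(x)
}

#' Phylogenetic signal of the labeled OTUs' EAF values
#'
#' Prunes the tree to the labeled OTUs (CI above zero), reports coverage, and
#' runs both Blomberg's K and Pagel's lambda on their EAF trait (bootstrap
#' medians by default) or on the binary labeled/unlabeled trait across all
#' estimable OTUs.
#'
#' @param tree An [ape::phylo] tree whose tips are OTU ids.
#' @param eaf_table Output of [estimate_eaf()].
#' @param trait_mode `"eaf"` (default: boot_median of labeled OTUs) or
#'   `"binary"` (labeled flag over all OTUs in the table).
#' @param n_perm Permutations for the K test.
#' @param seed Seed for the K permutation stream.
#' @return List with elements `K` and `lambda` (both `qsip_signal`),
#'   `n_matched`, `n_requested`, `dropped_tips` (ids in the trait set but not
#'   the tree).
#' @export
signal_for_labelset <- function(tree, eaf_table,
                                trait_mode = c("eaf", "binary"),
                                n_perm = 999, seed = NULL) {
  trait_mode <- match.arg(trait_mode)
  if (trait_mode == "eaf") {
    tab <- eaf_table[call_labeled(eaf_table), ]
    trait <- stats::setNames(tab$boot_median, tab$otu_id)
  } else {
    trait <- stats::setNames(as.numeric(call_labeled(eaf_table)),
                             eaf_table$otu_id)
  }
  n_requested <- length(trait)
  dropped <- setdiff(names(trait), tree$tip.label)
  matched <- intersect(tree$tip.label, names(trait))
  if (length(matched) < 4) {
    stop("fewer than 4 labeled OTUs match tree tips (",
         length(matched), ")", call. = FALSE)
  }
  pruned <- ape::keep.tip(tree, matched)
  trait <- trait[matched]
  list(
    K = blomberg_k(pruned, trait, n_perm = n_perm, seed = seed),
    lambda = pagel_lambda(pruned, trait),
    n_matched = length(matched),
    n_requested = n_requested,
    dropped_tips = dropped
  )
}
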