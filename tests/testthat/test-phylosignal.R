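test_that("lambda transform keeps the diagonal and scales shared history", {
  tt <- simulate_tree_and_traits(8, trait_lambda = 1, seed = 2)
  C <- ape::vcv(tt$tree)
  V1 <- qsipflow:::lambda_transform(C, 1)
  V0 <- qsipflow:::lambda_transform(C, 0)
  expect_equal(V1, C)  # lambda = 1: BM covariance unchanged
  expect_equal(V0, diag(diag(C)), ignore_attr = TRUE)
  expect_equal(diag(qsipflow:::lambda_transform(C, 0.4)), diag(C))
  # lambda = 1 covariance is the shared-path-length matrix by definition
  expect_equal(unname(C), unname(ape::vcv(tt$tree)))
})

test_that("K and lambda are invariant to affine trait transforms", {
  tt <- simulate_tree_and_traits(32, trait_lambda = 0.6, seed = 11)
  k1 <- blomberg_k(tt$tree, tt$trait, n_perm = 99, seed = 1)
  k2 <- blomberg_k(tt$tree, 3 + 2 * tt$trait, n_perm = 99, seed = 1)
  expect_equal(k1$estimate, k2$estimate, tolerance = 1e-12)
  expect_equal(k1$p_value, k2$p_value)
  l1 <- pagel_lambda(tt$tree, tt$trait)
  l2 <- pagel_lambda(tt$tree, 3 + 2 * tt$trait)
  expect_equal(l1$estimate, l2$estimate, tolerance = 1e-6)
  expect_equal(l1$lrt_stat, l2$lrt_stat, tolerance = 1e-6)
})

test_that("lambda likelihood is maximal at the estimate", {
  tt <- simulate_tree_and_traits(32, trait_lambda = 0.5, seed = 3)
  fit <- pagel_lambda(tt$tree, tt$trait)
  expect_gte(fit$loglik, fit$loglik0)
  expect_gte(fit$loglik,
             qsipflow:::lambda_loglik(1, tt$trait[tt$tree$tip.label],
                                      ape::vcv(tt$tree)))
  expect_true(fit$estimate >= 0 && fit$estimate <= 1)
  expect_gte(fit$p_value, 0)
  expect_lte(fit$p_value, 1)
})

test_that("estimates agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tt <- simulate_tree_and_traits(48, trait_lambda = 0.7, seed = 21)
  k <- blomberg_k(tt$tree, tt$trait, n_perm = 49, seed = 1)
  k_ref <- phytools::phylosig(tt$tree, tt$trait, method = "K")
  expect_equal(k$estimate, as.numeric(k_ref), tolerance = 1e-6)
  l <- pagel_lambda(tt$tree, tt$trait)
  l_ref <- phytools::phylosig(tt$tree, tt$trait, method = "lambda")
  expect_equal(l$estimate, l_ref$lambda, tolerance = 1e-3)
})

test_that("BM traits give K near 1 and lambda near 1; shuffled traits do not", {
  set.seed(31)
  k_bm <- lam_bm <- lam_null <- p_null <- numeric(15)
  for (i in 1:15) {
    tt <- simulate_tree_and_traits(64, trait_lambda = 1, seed = 100 + i)
    k_bm[i] <- blomberg_k(tt$tree, tt$trait, n_perm = 49,
                          seed = i)$estimate
    lam_bm[i] <- pagel_lambda(tt$tree, tt$trait)$estimate
    t0 <- simulate_tree_and_traits(64, trait_lambda = 0, seed = 300 + i)
    fit0 <- pagel_lambda(t0$tree, t0$trait)
    lam_null[i] <- fit0$estimate
    p_null[i] <- fit0$p_value
  }
  expect_gt(median(k_bm), 0.6)
  expect_lt(median(k_bm), 1.6)
  expect_gte(median(lam_bm), 0.85)
  expect_lte(median(lam_null), 0.15)
  expect_gt(mean(p_null > 0.05), 0.6)
})

test_that("degenerate trait and tree inputs are rejected or flagged", {
  tt <- simulate_tree_and_traits(8, seed = 5)
  expect_error(blomberg_k(tt$tree, rep(1, 8)), "constant trait")
  small <- ape::rtree(3)
  expect_error(blomberg_k(small, setNames(1:3, small$tip.label)), ">= 4")
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  trait <- setNames(rnorm(6), star$tip.label)
  k <- blomberg_k(star, trait, n_perm = 49, seed = 1)
  expect_true(k$low_power)
  expect_match(k$method_detail, "low power")
})

test_that("zero-length terminal branches are perturbed with a warning", {
  tr <- ape::rtree(6)
  tr$edge.length[tr$edge[, 2] == 1] <- 0
  trait <- setNames(rnorm(6), tr$tip.label)
  expect_warning(k <- blomberg_k(tr, trait, n_perm = 19, seed = 1),
                 "zero-length")
  expect_true(is.finite(k$estimate))
})

test_that("signal_for_labelset prunes to labeled OTUs and reports coverage", {
  tt <- simulate_tree_and_traits(24, trait_lambda = 1, seed = 8,
                                 trait_mean = 0.15, trait_sd = 0.03)
  ids <- tt$tree$tip.label
  eaf <- tibble::tibble(
    otu_id = c(ids, "NOT_IN_TREE"),
    boot_median = c(tt$trait, 0.2),
    ci_low = c(ifelse(seq_along(ids) <= 16, 0.05, -0.05), 0.05),
    labeled = c(seq_along(ids) <= 16, TRUE)
  )
  out <- signal_for_labelset(tt$tree, eaf, n_perm = 49, seed = 1)
  expect_equal(out$n_matched, 16)
  expect_equal(out$n_requested, 17)
  expect_identical(out$dropped_tips, "NOT_IN_TREE")
  expect_s3_class(out$K, "qsip_signal")
  expect_equal(out$lambda$n_tips, 16)
  # binary mode uses the labeled flag across all estimable OTUs
  bin <- signal_for_labelset(tt$tree, eaf, trait_mode = "binary",
                             n_perm = 49, seed = 1)
  expect_equal(bin$n_matched, 24)
  # constant traits propagate the statistic's error
  eaf_const <- eaf
  eaf_const$boot_median <- 0.1
  expect_error(signal_for_labelset(tt$tree, eaf_const), "constant trait")
})

test_that("clade-structured traits yield strong, significant signal", {
  tt <- simulate_tree_and_traits(40, trait_lambda = 1, seed = 13)
  # exaggerate clade structure: offset one clade's trait values
  C <- ape::vcv(tt$tree)
  clade <- ape::extract.clade(tt$tree, ape::Ntip(tt$tree) + 2)$tip.label
  trait <- tt$trait
  trait[clade] <- trait[clade] + 5 * sd(trait)
  k <- blomberg_k(tt$tree, trait, n_perm = 199, seed = 2)
  lam <- pagel_lambda(tt$tree, trait)
  expect_gt(lam$estimate, 0.7)
  expect_lt(k$p_value, 0.05)
})
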