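test_that("read counts scale to qPCR copies", {
  expect_equal(per_fraction_copies(c(a = 20, b = 80), 1e6)[["a"]], 2e5)
  expect_equal(per_fraction_copies(c(a = 50, b = 0), 123)[["a"]], 123)
  expect_equal(unname(per_fraction_copies(c(10, 30, 60), 1e3)),
               c(100, 300, 600))
  expect_warning(out <- per_fraction_copies(c(a = 0, b = 0), 10), "depth")
  expect_null(out)
})

test_that("weighted-average density is the copy-weighted mean", {
  expect_equal(weighted_average_density(c(0, 10, 0), c(1.68, 1.70, 1.72)),
               1.70)
  expect_equal(weighted_average_density(c(5, 0, 5), c(1.68, 1.70, 1.72)),
               1.70)
  expect_equal(weighted_average_density(c(100, 300, 600),
                                        c(1.68, 1.70, 1.72)), 1.710)
  expect_true(is.na(weighted_average_density(c(0, 0), c(1.7, 1.71))))
  # invariance to qPCR scaling of the copy vector
  y <- c(3, 9, 1)
  rho <- c(1.69, 1.70, 1.71)
  expect_equal(weighted_average_density(y * 7.3, rho),
               weighted_average_density(y, rho))
})

test_that("GC follows the density regression with clamping", {
  const <- qsip_constants()
  expect_equal(gc_from_density(const$gc_intercept), 0)
  expect_equal(gc_from_density(const$gc_intercept + const$gc_slope), 1)
  expect_equal(gc_from_density(1.700), (1.700 - 1.646057) / 0.083506,
               tolerance = 1e-12)
  expect_equal(gc_from_density(1.700), 0.6460, tolerance = 1e-4)
  expect_warning(gc0 <- gc_from_density(1.62), "clamped")
  expect_equal(gc0, 0)
})

test_that("molecular weights match the GC model and the carbon-count oracle", {
  mw0 <- molecular_weights(0)
  mw1 <- molecular_weights(1)
  expect_equal(mw0$m_light, 307.691)
  expect_equal(mw0$m_heavymax - mw0$m_light, 9.974564)
  expect_equal(mw1$m_light, 308.187)
  expect_equal(mw1$m_heavymax - mw1$m_light, 9.475836, tolerance = 1e-7)

  # independent oracle: mean carbons per nucleotide (10 - 0.5 GC; dCMP has
  # 9 carbons, the others 10) times the 13C-12C mass difference corrected
  # for natural abundance. Agrees with the canonical regression constants to
  # better than 1%.
  gc <- seq(0, 1, length.out = 101)
  mw <- molecular_weights(gc)
  dmax <- mw$m_heavymax - mw$m_light
  oracle <- (10 - 0.5 * gc) * (13.0033548 - 12) * (1 - 0.01111233)
  expect_true(all(abs(dmax / oracle - 1) < 0.01))
  expect_true(all(dmax > 0))
  expect_error(molecular_weights(1.2), "\\[0, 1\\]")
})

test_that("EAF has its closed-form limits and hand-computed value", {
  const <- qsip_constants()
  # zero shift -> exactly zero
  expect_identical(eaf_point(1.700, 1.700), 0)
  # saturation: labeled mass at m_heavymax -> 1 - nat_13c to 1e-9
  mw <- molecular_weights(gc_from_density(1.700))
  w_sat <- 1.700 * mw$m_heavymax / mw$m_light
  expect_equal(eaf_point(1.700, w_sat), 1 - 0.01111233, tolerance = 1e-9)
  # hand-chained value for a 0.006 g/ml shift at W_light = 1.700
  expect_equal(eaf_point(1.700, 1.706), oracle_eaf(1.700, 1.706),
               tolerance = 1e-12)
  expect_lt(abs(eaf_point(1.700, 1.706) - 0.1114), 1e-4)
  # negative shifts give negative, untruncated EAF
  expect_lt(eaf_point(1.700, 1.698), 0)
  expect_error(eaf_point(-1, 1.7), "positive")
})

test_that("EAF is strictly increasing in the labeled density", {
  w_lab <- seq(1.695, 1.730, by = 0.0005)
  a <- eaf_point(rep(1.700, length(w_lab)), w_lab)
  expect_true(all(diff(a) > 0))
})

test_that("labeling calls use a strict zero cutoff", {
  expect_true(call_labeled(0.01))
  expect_false(call_labeled(-0.01))
  expect_false(call_labeled(0.00))
  expect_identical(call_labeled(data.frame(ci_low = c(0.2, 0, NA))),
                   c(TRUE, FALSE, FALSE))
})

test_that("bootstrap collapses to the point estimate for identical replicates", {
  est <- bootstrap_eaf(w_lab = c(1.706, 1.706, 1.706),
                       w_light = c(1.700, 1.700, 1.700),
                       n_boot = 200, seed = 1)
  expect_equal(est$ci_high - est$ci_low, 0)
  expect_equal(est$boot_median, est$point_eaf)
  expect_true(est$labeled)
})

test_that("enumeration oracle: the 2+2 instance has 3 support points", {
  en <- enumerate_bootstrap_eaf(c(1.706, 1.708), c(1.700, 1.700))
  expect_equal(nrow(en), 3)
  expect_equal(en$prob, c(0.25, 0.5, 0.25))
  # middle support point: EAF at labeled mean 1.707, hand-chained
  expect_equal(en$eaf[2], oracle_eaf(1.700, 1.707), tolerance = 1e-9)
  expect_lt(abs(en$eaf[2] - 0.1299), 1e-4)
  expect_equal(sum(en$prob), 1)
  # bootstrap median converges on the distribution's median support point
  est <- bootstrap_eaf(c(1.706, 1.708), c(1.700, 1.700), n_boot = 4000,
                       seed = 2)
  expect_equal(est$boot_median, en$eaf[2], tolerance = 1e-9)
})

test_that("bootstrap frequencies converge on the enumeration (TV distance)", {
  w_lab <- c(1.705, 1.708)
  w_light <- c(1.699, 1.701)
  en <- enumerate_bootstrap_eaf(w_lab, w_light)
  set.seed(5)
  n_boot <- 20000
  lab <- replicate(n_boot, mean(sample(w_lab, 2, TRUE)))
  lig <- replicate(n_boot, mean(sample(w_light, 2, TRUE)))
  draws <- eaf_point(lig, lab)
  # support points are well separated; bin draws to the nearest one
  emp <- vapply(en$eaf, function(e) mean(abs(draws - e) < 1e-9), numeric(1))
  expect_equal(sum(emp), 1)  # every draw lands on an enumerated point
  tv <- 0.5 * sum(abs(emp - en$prob))
  expect_lt(tv, 0.02)
})

test_that("estimate_eaf is invariant to OTU row order and reproducible", {
  sim <- simulate_qsip_dataset(simulation_config(n_taxa = 8, depth = 2000),
                               seed = 3)
  ds <- sim$dataset
  ds_perm <- ds
  perm <- rev(seq_len(nrow(ds$counts)))
  ds_perm$counts <- ds_perm$counts[perm, , drop = FALSE]
  e1 <- suppressWarnings(estimate_eaf(ds, n_boot = 100, seed = 42))
  e2 <- suppressWarnings(estimate_eaf(ds_perm, n_boot = 100, seed = 42))
  e3 <- suppressWarnings(estimate_eaf(ds, n_boot = 100, seed = 42))
  expect_equal(e1, e3)
  expect_equal(dplyr::arrange(e1, otu_id), dplyr::arrange(e2, otu_id))
})

test_that("OTUs absent from a treatment are excluded with a reason", {
  ds <- toy_dataset(list(
    both = c(10L, 10L, 10L),
    lab_only = list(L1 = c(9L, 9L, 9L), L2 = c(9L, 9L, 9L),
                    C1 = c(0L, 0L, 0L), C2 = c(0L, 0L, 0L))
  ))
  est <- estimate_eaf(ds, n_boot = 50, seed = 1)
  expect_identical(est$otu_id, "both")
  excl <- attr(est, "excluded")
  expect_identical(excl$otu_id, "lab_only")
  expect_match(excl$reason, "control")
})

test_that("profiles normalize to unit maximum preserving order", {
  expect_equal(normalize_profile(c(2, 8, 4)), c(0.25, 1, 0.5))
  expect_equal(normalize_profile(c(5, 5, 5)), c(1, 1, 1))
  v <- c(0.2, 9, 3, 3.5)
  expect_equal(order(normalize_profile(v)), order(v))
  expect_equal(max(normalize_profile(v)), 1)
  expect_error(normalize_profile(c(0, 0), label = "lib7"), "lib7")
})

test_that("density shifts are recovered from translated profiles", {
  rho <- seq(1.76, 1.64, by = -0.005)
  ctrl <- dnorm(rho, 1.70, 0.006)
  lab <- dnorm(rho, 1.71, 0.006)  # translated by 0.010 on the grid
  expect_equal(peak_density_shift(ctrl, ctrl, rho), 0)
  expect_equal(peak_density_shift(lab, ctrl, rho), 0.010, tolerance = 1e-6)
  # peak mode resolves plateaus by the centroid of tied maxima
  i70 <- which.min(abs(rho - 1.70))
  i72 <- which.min(abs(rho - 1.72))
  prof <- rep(0, length(rho))
  prof[c(i70, i72)] <- 1
  ref <- rep(0, length(rho)); ref[i70] <- 1
  expect_equal(peak_density_shift(prof, ref, rho, mode = "peak"), 0.01)
  expect_error(peak_density_shift(rep(0, 3), c(1, 0, 0), c(1.7, 1.71, 1.72)),
               "all-zero")
})
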