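test_that("overlap categories partition the labeled sets", {
  a <- data.frame(otu_id = c("x", "y"), eaf = c(0.10, 0.05))
  b <- data.frame(otu_id = c("y", "z"), eaf = c(0.20, 0.15))
  tab <- assign_categories(a, b)
  expect_equal(tab$category[tab$otu_id == "x"], 1L)
  expect_setequal(tab$category[tab$otu_id == "y"], c(2L, 3L))
  expect_equal(tab$category[tab$otu_id == "z"], 4L)
  cnt <- attr(tab, "counts")
  expect_equal(cnt$category, c(cat1 = 1L, cat2 = 1L, cat3 = 1L, cat4 = 1L))
  # overlap OTUs keep independent EAF values per incubation
  expect_equal(sort(tab$eaf[tab$otu_id == "y"]), c(0.05, 0.20))
})

test_that("set-partition conservation holds for arbitrary labeled sets", {
  set.seed(9)
  for (i in 1:20) {
    ids <- paste0("OTU_", 1:60)
    a <- data.frame(otu_id = sample(ids, sample(5:40, 1)), eaf = NA)
    b <- data.frame(otu_id = sample(ids, sample(5:40, 1)), eaf = NA)
    a$eaf <- runif(nrow(a)); b$eaf <- runif(nrow(b))
    cnt <- attr(assign_categories(a, b), "counts")
    expect_equal(cnt$category[["cat1"]] + cnt$n_overlap, nrow(a))
    expect_equal(cnt$category[["cat4"]] + cnt$n_overlap, nrow(b))
    expect_equal(cnt$category[["cat2"]], cnt$n_overlap)
    expect_equal(cnt$category[["cat3"]], cnt$n_overlap)
  }
})

test_that("one empty labeled set sends everything to one category", {
  a <- data.frame(otu_id = c("x", "y"), eaf = c(0.1, 0.2))
  b <- data.frame(otu_id = character(0), eaf = numeric(0))
  tab <- assign_categories(a, b)
  expect_true(all(tab$category == 1L))
  expect_equal(nrow(tab), 2)
})

test_that("min-max normalization maps extremes to 0 and 1, keeping order", {
  expect_equal(minmax_normalize_eaf(c(0.05, 0.10, 0.25)), c(0, 0.25, 1))
  v <- c(0.3, -0.1, 0.07, 0.21)
  nv <- minmax_normalize_eaf(v)
  expect_equal(nv[which.min(v)], 0)
  expect_equal(nv[which.max(v)], 1)
  expect_equal(order(nv), order(v))
  expect_warning(z <- minmax_normalize_eaf(c(0.1, 0.1)), "identical")
  expect_equal(z, c(0, 0))
})

test_that("normalization scope is the whole incubation by default", {
  a <- data.frame(otu_id = c("u", "v", "w"), eaf = c(0.0, 0.1, 0.2))
  b <- data.frame(otu_id = c("w", "q"), eaf = c(0.4, 0.6))
  tab <- assign_categories(a, b)
  # category 1 + category 2 values of incubation A share one scale
  av <- tab[tab$substrate == "bicarbonate", ]
  expect_equal(sort(av$eaf_norm), c(0, 0.5, 1))
  # single-member overlap categories normalize degenerately (warned)
  per_cat <- suppressWarnings(
    assign_categories(a, b, norm_scope = "per-category"))
  c1 <- per_cat[per_cat$category == 1L, ]
  expect_equal(sort(c1$eaf_norm), c(0, 1))
})

test_that("taxon summaries average labeled OTUs and apportion reads", {
  ds <- toy_dataset(
    list(p1 = c(10L, 10L, 10L), p2 = c(30L, 30L, 30L), q1 = c(60L, 0L, 0L)),
    taxonomy = data.frame(
      otu_id = c("p1", "p2", "q1"),
      lineage = c("Bacteria;PhylA;x", "Bacteria;PhylA;y", "Bacteria;PhylB;z"))
  )
  eaf <- tibble::tibble(
    otu_id = c("p1", "p2", "q1"),
    boot_median = c(0.10, 0.20, 0.40),
    ci_low = c(0.05, 0.02, -0.01), ci_high = c(0.2, 0.3, 0.5),
    labeled = c(TRUE, TRUE, FALSE)
  )
  out <- summarize_by_taxon(eaf, ds$taxonomy, ds$counts)
  expect_equal(nrow(out), 1)  # PhylB has no labeled OTU -> no row
  expect_equal(out$taxon_group, "PhylA")
  expect_equal(out$mean_boot_median, 0.15)
  expect_equal(out$n_labeled, 2L)
  # reads: p1 = 120, p2 = 360 over 4 replicates; only labeled OTUs count
  expect_equal(out$n_sequences, 480)
  expect_equal(out$pct_sequences, 100)
})

test_that("read percentages split between phyla as hand-computed", {
  ds <- toy_dataset(
    list(a = c(10L, 0L, 0L), b = c(20L, 0L, 0L), c = c(70L, 0L, 0L)),
    taxonomy = data.frame(
      otu_id = c("a", "b", "c"),
      lineage = c("Bacteria;P1;", "Bacteria;P2;", "Bacteria;P3;"))
  )
  eaf <- tibble::tibble(otu_id = c("a", "b", "c"),
                        boot_median = c(0.1, 0.1, 0.1),
                        ci_low = c(0.1, 0.1, 0.1), labeled = TRUE)
  out <- summarize_by_taxon(eaf, ds$taxonomy, ds$counts)
  expect_equal(out$pct_sequences[match(c("P1", "P2", "P3"),
                                       out$taxon_group)],
               c(10, 20, 70))
  expect_lte(sum(out$pct_sequences), 100 + 1e-9)
  # OTU with no lineage groups as unclassified
  eaf2 <- rbind(eaf, tibble::tibble(otu_id = "zz", boot_median = 0.2,
                                    ci_low = 0.1, labeled = TRUE))
  out2 <- summarize_by_taxon(eaf2, ds$taxonomy, ds$counts)
  expect_true("unclassified" %in% out2$taxon_group)
})

test_that("overlap pairs sit on the right side of the 1:1 line", {
  a <- data.frame(otu_id = c("o1", "o2", "o3"), eaf = c(0.08, 0.15, 0.10))
  b <- data.frame(otu_id = c("o1", "o2", "o3"), eaf = c(0.14, 0.15, 0.02))
  pairs <- paired_overlap_scatter(assign_categories(a, b))
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$position[pairs$otu_id == "o1"], "above")
  expect_equal(pairs$position[pairs$otu_id == "o2"], "on")
  expect_equal(pairs$position[pairs$otu_id == "o3"], "below")
})

test_that("a simulated uniform substrate contrast lands fully above the line", {
  set.seed(4)
  n <- 40
  ids <- sprintf("OTU_%02d", 1:n)
  eaf_a <- runif(n, 0.051, 0.165)   # slower assimilation, substrate A
  eaf_b <- eaf_a + runif(n, 0.01, 0.06)  # uniformly faster on substrate B
  tab <- assign_categories(data.frame(otu_id = ids, eaf = eaf_a),
                           data.frame(otu_id = ids, eaf = eaf_b))
  pairs <- paired_overlap_scatter(tab)
  expect_true(all(pairs$position == "above"))
  expect_equal(mean(pairs$eaf_b) - mean(pairs$eaf_a),
               mean(eaf_b) - mean(eaf_a))
})
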