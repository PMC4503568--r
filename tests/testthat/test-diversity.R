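test_that("gene diversity and PIC match their closed forms", {
  expect_equal(nei_diversity(0.5), 0.5)
  expect_equal(nei_diversity(0), 0)
  expect_equal(nei_diversity(1), 0)
  expect_equal(round(nei_diversity(0.745), 3), 0.380)
  expect_equal(pic(0.5), 0.375)
  expect_equal(pic(0), 0)
  expect_equal(pic(0.1), 0.1638)
  expect_error(nei_diversity(1.2), class = "gbsdiv_config_error")
  expect_error(pic(-0.1), class = "gbsdiv_config_error")
})

test_that("DI and PIC are symmetric in allele labels and PIC <= DI", {
  p <- seq(0, 1, by = 0.01)
  expect_equal(nei_diversity(p), nei_diversity(1 - p))
  expect_equal(pic(p), pic(1 - p))
  expect_true(all(pic(p) <= nei_diversity(p) + 1e-15))
  inner <- p > 0 & p < 1
  expect_true(all(pic(p[inner]) < nei_diversity(p[inner])))
})

test_that("panel-level summary equals the hand mean and handles monomorphy", {
  g <- geno_from_cols(list(m1 = c(1L, 1L, 0L, 0L), m2 = c(0L, 0L, 0L, 0L)))
  s <- summarize_diversity(g, level = "panel")
  expect_equal(s$mean_DI, 0.25)  # (0.5 + 0) / 2
  expect_equal(s$n_markers, 2L)

  mono <- geno_from_cols(list(m1 = rep(0L, 4), m2 = rep(1L, 4)))
  s2 <- summarize_diversity(mono, level = "panel")
  expect_equal(s2$mean_DI, 0)
})

test_that("subgenome means are the marker-weighted combination of linkage-group means", {
  sim <- simulate_structured_snp_panel(n_per_group = c(A = 40), n_loci = 210,
                                       fst = 0, missing_rate = 0.05, seed = 3)
  by_lg <- summarize_diversity(sim$geno, sim$map, level = "linkage_group")
  by_sg <- summarize_diversity(sim$geno, sim$map, level = "subgenome")
  for (sg in c("A", "B", "D")) {
    lgs <- by_lg[substr(by_lg$level_value, 2, 2) == sg, ]
    expect_equal(
      by_sg$mean_DI[by_sg$level_value == sg],
      sum(lgs$mean_DI * lgs$n_markers) / sum(lgs$n_markers))
  }
})

test_that("group diversity ordering reflects the constructed frequencies", {
  # group B's frequencies pushed toward fixation -> lower expected diversity
  set.seed(19)
  pA <- runif(400, 0.3, 0.7)   # high-diversity frequencies
  pB <- runif(400, 0.01, 0.08) # near-fixed
  xA <- matrix(rbinom(80 * 400, 1L, rep(pA, each = 80)), nrow = 80)
  xB <- matrix(rbinom(80 * 400, 1L, rep(pB, each = 80)), nrow = 80)
  x <- rbind(xA, xB)
  dimnames(x) <- list(sprintf("a%03d", 1:160), sprintf("m%03d", 1:400))
  groups <- tibble::tibble(accession = rownames(x),
                           group = rep(c("A", "B"), each = 80))
  s <- summarize_diversity(geno_matrix(x), groups = groups, level = "panel")
  expect_gt(s$mean_DI[s$group == "A"], s$mean_DI[s$group == "B"])
})

test_that("DI histogram bins are right-closed with the first bin including 0", {
  h <- di_histogram(c(0.05, 0.1, 0.15))
  expect_equal(h$pct[h$bin_upper == 0.1], 200 / 3)
  expect_equal(h$pct[h$bin_upper == 0.2], 100 / 3)
  expect_equal(sum(h$pct), 100)

  h2 <- di_histogram(rep(0.5, 10))
  expect_equal(h2$pct[h2$bin_upper == 0.5], 100)
  expect_equal(sum(h2$n), 10)

  h3 <- di_histogram(c(0, 0.1, 0.100000001, 0.2))
  expect_equal(h3$n[h3$bin_upper == 0.1], 2L)  # 0 and 0.1 in the first bin
  expect_equal(h3$n[h3$bin_upper == 0.2], 2L)

  expect_error(di_histogram(numeric(0)), class = "gbsdiv_empty_panel_error")
})

test_that("mean pairwise distance counts mismatches over co-called loci", {
  g <- geno_from_cols(rep(list(c(0L, 0L)), 10))
  expect_equal(mean_pairwise_distance(g), 0)

  cols <- rep(list(c(0L, 0L)), 10)
  cols[[1]] <- c(0L, 1L)
  expect_equal(mean_pairwise_distance(geno_from_cols(cols)), 0.1)

  clones <- geno_from_cols(rep(list(rep(0L, 6)), 12))
  expect_equal(mean_pairwise_distance(clones), 0)

  expect_error(mean_pairwise_distance(geno_from_cols(list(m1 = 0L))),
               class = "gbsdiv_config_error")
})

test_that("mean distance is invariant to marker and accession order", {
  sim <- simulate_structured_snp_panel(n_per_group = c(A = 12), n_loci = 100,
                                       fst = 0, missing_rate = 0.1, seed = 4)
  x <- unclass(sim$geno)
  d1 <- mean_pairwise_distance(geno_matrix(x))
  d2 <- mean_pairwise_distance(geno_matrix(x[sample(nrow(x)), sample(ncol(x))]))
  expect_equal(d1, d2)
})

test_that("equal-size resampling is deterministic and exact at full size", {
  sim <- simulate_structured_snp_panel(n_per_group = c(A = 25, B = 25),
                                       n_loci = 120, fst = 0.1,
                                       missing_rate = 0.05, seed = 14)
  r1 <- equal_size_resample_diversity(sim$geno, sim$groups, n = 20,
                                      n_reps = 10, seed = 99)
  r2 <- equal_size_resample_diversity(sim$geno, sim$groups, n = 20,
                                      n_reps = 10, seed = 99)
  expect_identical(r1, r2)

  # n = full group size: every replicate equals the full-data group DI
  full <- equal_size_resample_diversity(sim$geno, sim$groups, n = 25,
                                        n_reps = 5, seed = 1)
  ref <- summarize_diversity(sim$geno, groups = sim$groups, level = "panel")
  expect_equal(full$mean_DI, ref$mean_DI[match(full$group, ref$group)])
  expect_equal(full$sd_DI, c(0, 0))

  expect_error(
    equal_size_resample_diversity(sim$geno, sim$groups, n = 26, n_reps = 2),
    "smaller", class = "gbsdiv_config_error")
})

test_that("resampling preserves a constructed diversity ordering", {
  set.seed(6)
  pA <- runif(150, 0.35, 0.65)
  pB <- runif(150, 0.02, 0.1)
  xA <- matrix(rbinom(60 * 150, 1L, rep(pA, each = 60)), nrow = 60)
  xB <- matrix(rbinom(60 * 150, 1L, rep(pB, each = 60)), nrow = 60)
  x <- rbind(xA, xB)
  dimnames(x) <- list(sprintf("a%03d", 1:120), sprintf("m%03d", 1:150))
  groups <- tibble::tibble(accession = rownames(x),
                           group = rep(c("A", "B"), each = 60))
  res <- equal_size_resample_diversity(geno_matrix(x), groups, n = 30,
                                       n_reps = 100, seed = 8)
  expect_gt(res$mean_DI[res$group == "A"], res$mean_DI[res$group == "B"])
})

test_that("the wide diversity table has the panel shape", {
  sim <- simulate_structured_snp_panel(n_per_group = c(A = 10, B = 10),
                                       n_loci = 84, fst = 0.1,
                                       missing_rate = 0, seed = 2)
  tab <- diversity_table(sim$geno, sim$map, sim$groups)
  expect_identical(tab$LG, c(sort(wheat_linkage_groups()), "Mean DI", "Mean GD"))
  expect_identical(colnames(tab), c("LG", "A", "B"))
})
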