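test_that("Euclidean distances on complete 0/1 data are plain Euclidean", {
  g <- geno_from_cols(list(m1 = c(0L, 1L, 0L), m2 = c(0L, 1L, 0L),
                           m3 = c(0L, 1L, 1L), m4 = c(0L, 1L, 1L)))
  D <- as.matrix(genetic_distance(g))
  expect_equal(D["acc01", "acc02"], 2)      # sqrt(4)
  expect_equal(D["acc01", "acc03"], sqrt(2))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))
})

test_that("identical accessions are at distance zero", {
  g <- geno_from_cols(rep(list(c(0L, 0L, 1L)), 8))
  D <- as.matrix(genetic_distance(g))
  expect_equal(D["acc01", "acc02"], 0)
})

test_that("a pair with no co-called loci is an error naming the pair", {
  x <- rbind(a1 = c(0L, NA, NA), a2 = c(NA, 1L, 0L), a3 = c(0L, 1L, 0L))
  colnames(x) <- c("m1", "m2", "m3")
  err <- expect_error(genetic_distance(geno_matrix(x)),
                      class = "gbsdiv_format_error")
  expect_match(conditionMessage(err), "a1")
  expect_match(conditionMessage(err), "a2")
})

test_that("the L/m rescaling leaves expected distances unchanged under masking", {
  sim <- simulate_structured_snp_panel(n_per_group = c(A = 10), n_loci = 2000,
                                       fst = 0, missing_rate = 0, seed = 3)
  D_full <- as.matrix(genetic_distance(sim$geno))
  set.seed(33)
  reps <- replicate(20, {
    x <- unclass(sim$geno)
    x[matrix(runif(length(x)) < 0.5, nrow(x))] <- NA
    mean(as.matrix(genetic_distance(geno_matrix(x))) / D_full,
         na.rm = TRUE)
  })
  # squared distances are unbiased; the sqrt ratio should sit near 1
  expect_lt(abs(mean(reps) - 1), 0.02)
})

test_that("distance matrix is invariant to marker permutation", {
  sim <- simulate_structured_snp_panel(n_per_group = c(A = 8), n_loci = 60,
                                       fst = 0, missing_rate = 0.1, seed = 9)
  x <- unclass(sim$geno)
  d1 <- genetic_distance(geno_matrix(x))
  d2 <- genetic_distance(geno_matrix(x[, sample(ncol(x))]))
  expect_equal(as.matrix(d1), as.matrix(d2))
})

test_that("three-taxon neighbor joining solves the three-point formulas", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 0.5)
  expect_equal(len[["B"]], 1.5)
  expect_equal(len[["C"]], 2.5)
})

test_that("NJ exactly recovers additive trees (topology and branch lengths)", {
  for (s in 1:25) {
    n <- sample(4:12, 1)
    at <- random_additive_tree(n, seed = 1000 + s)
    rec <- neighbor_joining(at$D)
    expect_equal(ape::dist.topo(ape::unroot(at$tree), rec), 0,
                 ignore_attr = TRUE)
    Drec <- ape::cophenetic.phylo(rec)
    Drec <- Drec[rownames(at$D), colnames(at$D)]
    expect_equal(Drec, at$D, tolerance = 1e-8)
  }
})

test_that("equidistant taxa give zero internal branch lengths", {
  D <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
})

test_that("negative branch lengths are clamped and counted", {
  # classic non-additive matrix producing a negative NJ branch
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(as.dist(D))
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clamped") >= 0)
})

test_that("bootstrap supports are deterministic and bounded", {
  sim <- simulate_structured_snp_panel(n_per_group = c(X = 6, Y = 6),
                                       n_loci = 120, fst = 0.3,
                                       missing_rate = 0, seed = 71)
  t1 <- bootstrap_support(sim$geno, n_reps = 25, seed = 5)
  t2 <- bootstrap_support(sim$geno, n_reps = 25, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("a single bootstrap replicate yields supports of 0 or 100", {
  sim <- simulate_structured_snp_panel(n_per_group = c(X = 5, Y = 5),
                                       n_loci = 80, fst = 0.3,
                                       missing_rate = 0, seed = 81)
  tr <- bootstrap_support(sim$geno, n_reps = 1, seed = 7)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("supports are invariant to accession order", {
  sim <- simulate_structured_snp_panel(n_per_group = c(X = 5, Y = 5),
                                       n_loci = 100, fst = 0.4,
                                       missing_rate = 0, seed = 91)
  split_tips <- sim$groups$accession[sim$groups$group == "X"]
  t1 <- bootstrap_support(sim$geno, n_reps = 50, seed = 11)
  perm <- unclass(sim$geno)[sample(nrow(sim$geno)), , drop = FALSE]
  t2 <- bootstrap_support(geno_matrix(perm), n_reps = 50, seed = 11)
  expect_identical(split_support(t1, split_tips), split_support(t2, split_tips))
})

test_that("duplicating every locus preserves the full-data topology", {
  sim <- simulate_structured_snp_panel(n_per_group = c(X = 5, Y = 5),
                                       n_loci = 90, fst = 0.3,
                                       missing_rate = 0, seed = 15)
  x <- unclass(sim$geno)
  dup <- cbind(x, x)
  colnames(dup) <- sprintf("m%03d", seq_len(ncol(dup)))
  t1 <- neighbor_joining(genetic_distance(sim$geno))
  t2 <- neighbor_joining(genetic_distance(geno_matrix(dup)))
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("cluster composition reports per-group fractions for a cut", {
  # hand-built 6-leaf tree with a 4/2 split
  tr <- ape::read.tree(text = "((a:1,b:1):1,((c:1,d:1):1,(e:1,f:1):1):1);")
  tr <- ape::unroot(tr)
  groups <- tibble::tibble(accession = letters[1:6],
                           group = c("L", "L", "L", "L", "E", "E"))
  # cut the edge above the (e,f) clade
  node_ef <- ape::getMRCA(tr, c("e", "f"))
  comp <- cluster_composition(tr, groups, cut = node_ef)
  expect_identical(sort(unique(comp$block)), c(1L, 2L))
  frac_L <- comp$fraction_of_group[comp$group == "L"]
  expect_equal(sort(frac_L), 1)  # all L leaves in one block
  # the 4/2 leaf split itself
  sizes <- comp |> dplyr::group_by(block) |> dplyr::summarise(n = sum(n))
  expect_setequal(sizes$n, c(4L, 2L))

  # two synthetic clusters: cutting the cluster-separating edge gives 100/0
  sim <- simulate_structured_snp_panel(n_per_group = c(X = 8, Y = 8),
                                       n_loci = 300, fst = 0.5,
                                       missing_rate = 0, seed = 25)
  full <- neighbor_joining(genetic_distance(sim$geno))
  tips_y <- sim$groups$accession[sim$groups$group == "Y"]
  ntip <- length(full$tip.label)
  clade_sets <- lapply(seq_len(full$Nnode - 1) + ntip + 1, function(nd) {
    ape::extract.clade(full, nd)$tip.label
  })
  hit <- which(vapply(clade_sets, function(s) {
    setequal(s, tips_y) || setequal(s, setdiff(full$tip.label, tips_y))
  }, logical(1)))
  expect_length(hit, 1L)  # the separating bipartition exists in the tree
  comp2 <- cluster_composition(full, sim$groups, cut = hit[1] + ntip + 1)
  expect_equal(max(comp2$fraction_of_group[comp2$group == "X"]), 1)
  expect_equal(max(comp2$fraction_of_group[comp2$group == "Y"]), 1)
  expect_identical(nrow(comp2), 2L)  # no group straddles the cut

  # single group: one block holds 100%
  one <- tibble::tibble(accession = letters[1:6], group = "only")
  comp3 <- cluster_composition(tr, one, cut = integer(0))
  expect_equal(comp3$fraction_of_group, 1)
})
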