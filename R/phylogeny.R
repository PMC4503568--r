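#' Euclidean distance matrix with missing-data rescaling
#'
#' For accessions i and j, `d(i,j) = sqrt((L / m_ij) * sum (x_i - x_j)^2)`
#' over loci called in both, where `m_ij` is the co-called locus count and
#' `L` the total locus count. With complete data this is the plain Euclidean
#' distance on 0/1 vectors; the `L/m` factor makes the expected squared
#' distance unbiased under loci missing at random. A pair with no co-called
#' loci is an error naming the pair.
#'
#' @param geno A [geno_matrix()] or coercible matrix with >= 3 accessions.
#' @param method `"euclidean"` (default) or `"allele_sharing"` (mismatch
#'   proportion over co-called loci).
#' @return A `stats::dist` object labeled by accession id.
#' @export
genetic_distance <- function(geno, method = c("euclidean", "allele_sharing")) {
  method <- match.arg(method)
  geno <- as_geno_matrix(geno)
  if (nrow(geno) < 3) {
    rlang::abort("at least three accessions are required",
                 class = "gbsdiv_config_error")
  }
  x <- unclass(geno)
  pc <- pairwise_counts(x)
  up <- which(upper.tri(pc$m), arr.ind = TRUE)
  zero <- up[pc$m[up] == 0, , drop = FALSE]
  if (nrow(zero)) {
    rlang::abort(sprintf(
      "accessions '%s' and '%s' share no called loci; distance undefined",
      rownames(x)[zero[1, 1]], rownames(x)[zero[1, 2]]),
      class = "gbsdiv_format_error")
  }
  L <- ncol(x)
  D <- if (method == "euclidean") sqrt(L * pc$mismatch / pc$m)
       else pc$mismatch / pc$m
  diag(D) <- 0
  stats::as.dist(D)
}

#' Neighbor-joining tree
#'
#' Standard agglomerative neighbor joining on a distance matrix: an
#' unrooted tree with a trifurcating root that exactly recovers topology
#' and branch lengths from any additive matrix. Negative branch lengths
#' (possible for non-additive input) are clamped to zero; the number of
#' clamped edges is recorded in the `clamped` attribute.
#'
#' @param d A `stats::dist` or symmetric matrix over >= 3 taxa.
#' @return An `ape::phylo` with attribute `clamped`.
#' @export
neighbor_joining <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  if (attr(d, "Size") < 3) {
    rlang::abort("neighbor joining needs at least three taxa",
                 class = "gbsdiv_config_error")
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    rlang::abort("distance matrix must be finite and non-negative",
                 class = "gbsdiv_config_error")
  }
  tr <- ape::nj(d)
  n_neg <- sum(tr$edge.length < 0)
  if (n_neg) tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- n_neg
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the full-data NJ tree, then resamples loci with replacement
#' `n_reps` times, rebuilding distance matrix and tree each time. The
#' support of each internal bipartition of the full-data tree is the
#' percentage of replicate trees containing it (the fixed-dendrogram
#' convention, not a majority-rule consensus); supports are stored as
#' integer node labels. Deterministic under `seed`.
#'
#' @param geno A [geno_matrix()] or coercible matrix.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param method Distance method, see [genetic_distance()].
#' @return An `ape::phylo` with `node.label` percentages (root label empty).
#' @export
bootstrap_support <- function(geno, n_reps = 1000, seed = 1L,
                              method = "euclidean") {
  if (n_reps < 1) rlang::abort("n_reps must be >= 1",
                               class = "gbsdiv_config_error")
  geno <- as_geno_matrix(geno)
  full <- neighbor_joining(genetic_distance(geno, method = method))
  set.seed(seed)
  L <- ncol(geno)
  reps <- lapply(seq_len(n_reps), function(i) {
    idx <- sample.int(L, L, replace = TRUE)
    g <- unclass(geno)[, idx, drop = FALSE]
    colnames(g) <- sprintf("B%06d", seq_len(L))  # duplicates renamed
    neighbor_joining(genetic_distance(geno_matrix(g), method = method))
  })
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / n_reps)
  supports[1] <- NA  # root trifurcation: not a bipartition
  full$node.label <- ifelse(is.na(supports), "", as.character(supports))
  full
}

#' Support of a given bipartition
#'
#' Looks up the bootstrap support attached to the internal edge separating
#' `tips` from the remaining leaves, if such an edge exists in the tree.
#'
#' @param tree An `ape::phylo` with support node labels, as from
#'   [bootstrap_support()].
#' @param tips Character vector of leaf labels on one side of the split.
#' @return Support percentage (numeric), or `NA` if the bipartition is not
#'   an edge of the tree.
#' @export
split_support <- function(tree, tips) {
  all_tips <- tree$tip.label
  if (!all(tips %in% all_tips)) {
    rlang::abort("tips not in tree", class = "gbsdiv_config_error")
  }
  internal <- seq_len(tree$Nnode) + length(all_tips)
  for (node in internal[-1]) {  # skip root
    clade <- ape::extract.clade(tree, node)$tip.label
    if (setequal(clade, tips) || setequal(clade, setdiff(all_tips, tips))) {
      return(suppressWarnings(as.numeric(tree$node.label[node - length(all_tips)])))
    }
  }
  NA_real_
}

#' Group composition of tree clusters
#'
#' Cuts the tree into leaf blocks and reports, for each block, the fraction
#' of every group's accessions falling in it. `cut` is either a vector of
#' internal node numbers (each severs the edge above that node) or
#' `list(support = s)`, which severs every internal edge whose bootstrap
#' support is at least `s`.
#'
#' @param tree An `ape::phylo`, leaf labels = accession ids.
#' @param groups Tibble (`accession`, `group`) covering all leaves.
#' @param cut Internal node number(s), or `list(support = s)`.
#' @return Tibble with columns `block`, `group`, `n`, `fraction_of_group`.
#' @export
cluster_composition <- function(tree, groups, cut) {
  ntip <- length(tree$tip.label)
  missing_acc <- setdiff(tree$tip.label, groups$accession)
  if (length(missing_acc)) {
    rlang::abort(paste0("leaf without group assignment: ",
                        paste(utils::head(missing_acc, 5), collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  if (is.list(cut)) {
    if (is.null(cut$support)) {
      rlang::abort("cut must be node numbers or list(support = s)",
                   class = "gbsdiv_config_error")
    }
    sup <- suppressWarnings(as.numeric(tree$node.label))
    cut_nodes <- which(!is.na(sup) & sup >= cut$support) + ntip
  } else {
    cut_nodes <- as.integer(cut)
    if (any(cut_nodes <= ntip | cut_nodes > ntip + tree$Nnode)) {
      rlang::abort("cut node(s) not internal nodes of the tree",
                   class = "gbsdiv_config_error")
    }
  }
  # components of the tree after removing the edges above cut_nodes
  keep <- !(tree$edge[, 2] %in% cut_nodes)
  comp <- seq_len(ntip + tree$Nnode)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (e in which(keep)) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) comp[a] <- b
  }
  block_of <- vapply(seq_len(ntip), find, integer(1))
  block_id <- match(block_of, sort(unique(block_of)))
  membership <- tibble::tibble(accession = tree$tip.label, block = block_id) |>
    dplyr::inner_join(groups, by = "accession")
  group_sizes <- groups |>
    dplyr::filter(.data$accession %in% tree$tip.label) |>
    dplyr::count(.data$group, name = "group_n")
  membership |>
    dplyr::count(.data$block, .data$group, name = "n") |>
    dplyr::inner_join(group_sizes, by = "group") |>
    dplyr::mutate(fraction_of_group = .data$n / .data$group_n) |>
    dplyr::select("block", "group", "n", "fraction_of_group")
}
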