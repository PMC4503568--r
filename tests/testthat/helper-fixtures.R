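# Small in-code fixtures shared across test files.

# build a geno_matrix column-wise from a list of marker call vectors
geno_from_cols <- function(cols, acc = NULL) {
  m <- do.call(cbind, cols)
  if (is.null(acc)) acc <- sprintf("acc%02d", seq_len(nrow(m)))
  rownames(m) <- acc
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%02d", seq_len(ncol(m)))
  geno_matrix(m)
}

two_group_labels <- function(geno, split = nrow(geno) / 2) {
  tibble::tibble(
    accession = rownames(geno),
    group = rep(c("G1", "G2"), c(split, nrow(geno) - split)))
}

# naive per-read reimplementation of the read-QC rule, used as oracle
oracle_read_filter <- function(reads, q_body = 30, frac_body = 0.5,
                               q_barcode = 10, frac_barcode = 0.75,
                               barcode_length = 8) {
  kept <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    n_body <- 0L
    for (b in q) if (b >= q_body) n_body <- n_body + 1L
    n_bc <- 0L
    for (b in q[1:barcode_length]) if (b >= q_barcode) n_bc <- n_bc + 1L
    kept[i] <- (n_body / length(q) >= frac_body) &&
      (n_bc / barcode_length >= frac_barcode)
  }
  kept
}

# spreadsheet-style Ht/Hs oracle: explicit loops over groups and loci
oracle_ht_hs <- function(geno, groups) {
  x <- unclass(geno)
  glab <- sort(unique(groups$group))
  ht_l <- hs_l <- numeric(0)
  for (j in seq_len(ncol(x))) {
    ps <- numeric(0)
    ok <- TRUE
    for (g in glab) {
      v <- x[groups$accession[groups$group == g], j]
      v <- v[!is.na(v)]
      if (!length(v)) { ok <- FALSE; break }
      ps <- c(ps, mean(v))
    }
    if (!ok) next
    pbar <- mean(ps)
    ht_l <- c(ht_l, 2 * pbar * (1 - pbar))
    hs_l <- c(hs_l, mean(2 * ps * (1 - ps)))
  }
  c(Ht = mean(ht_l), Hs = mean(hs_l))
}

# brute-force group sharing oracle over <= 50 markers
oracle_sharing <- function(geno, groups) {
  x <- unclass(geno)
  glab <- sort(unique(groups$group))
  out <- list()
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    called <- v[!is.na(v)]
    p <- mean(called)
    if (p == 0 || p == 1 || !length(called)) next
    minor <- if (p <= 0.5) 1L else 0L
    with_minor <- character(0)
    for (g in glab) {
      vg <- x[groups$accession[groups$group == g], j]
      if (any(vg == minor, na.rm = TRUE)) with_minor <- c(with_minor, g)
    }
    out[[colnames(x)[j]]] <- with_minor
  }
  out
}

# a random additive tree and its exact distance matrix
random_additive_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.1, 2))
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D[order(rownames(D)), order(colnames(D))])
}
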