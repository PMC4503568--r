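#' Nei's gene diversity for a biallelic locus
#'
#' Expected heterozygosity `DI = 1 - p^2 - (1-p)^2 = 2 p (1-p)`; maximal
#' (0.5) at `p = 0.5`, zero for monomorphic loci, symmetric under allele
#' relabeling.
#'
#' @param p Allele frequency (vectorized), in `[0, 1]`.
#' @param unbiased Apply the small-sample factor `n/(n-1)`; off by default.
#' @param n Sample size (number of called inbred accessions), required when
#'   `unbiased = TRUE`.
#' @return Numeric vector of diversities in `[0, 0.5]` (unbiased values may
#'   slightly exceed 0.5).
#' @examples
#' nei_diversity(c(0, 0.5, 0.745))
#' @export
nei_diversity <- function(p, unbiased = FALSE, n = NULL) {
  check_freq(p)
  di <- 2 * p * (1 - p)
  if (unbiased) {
    if (is.null(n)) rlang::abort("n is required when unbiased = TRUE",
                                 class = "gbsdiv_config_error")
    di <- di * n / (n - 1)
  }
  di
}

#' Polymorphic information content for a biallelic locus
#'
#' Botstein's PIC: `1 - p^2 - q^2 - 2 p^2 q^2` with `q = 1 - p`. Bounded by
#' 0.375 for biallelic markers and never exceeds the gene diversity at the
#' same frequency.
#'
#' @inheritParams nei_diversity
#' @return Numeric vector in `[0, 0.375]`.
#' @examples
#' pic(c(0.1, 0.5))
#' @export
pic <- function(p) {
  check_freq(p)
  q <- 1 - p
  1 - p^2 - q^2 - 2 * p^2 * q^2
}

check_freq <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    rlang::abort("allele frequencies must lie in [0, 1]",
                 class = "gbsdiv_config_error")
  }
  invisible(p)
}

# groups x loci within-group allele-frequency matrix and call-count matrix
group_freq_matrix <- function(geno, groups) {
  geno <- as_geno_matrix(geno)
  check_groups_cover(geno, groups)
  x <- unclass(geno)
  glab <- sort(unique(groups$group))
  P <- matrix(NA_real_, nrow = length(glab), ncol = ncol(x),
              dimnames = list(glab, colnames(x)))
  N <- matrix(0L, nrow = length(glab), ncol = ncol(x),
              dimnames = list(glab, colnames(x)))
  for (g in glab) {
    xg <- x[groups$accession[groups$group == g], , drop = FALSE]
    n_called <- colSums(!is.na(xg))
    N[g, ] <- n_called
    P[g, ] <- ifelse(n_called > 0, colMeans(xg, na.rm = TRUE), NA_real_)
  }
  list(P = P, N = N, groups = glab)
}

#' Mean diversity by linkage group, subgenome or panel
#'
#' Within each group, allele frequencies are computed from that group's
#' called cells only; per-locus DI and PIC are then averaged (unweighted,
#' each locus counted once) over the markers of each level. Markers with no
#' calls inside a group are excluded from that group's means; a level with
#' no markers reports `n_markers = 0` and `NA` means.
#'
#' @param geno A [geno_matrix()] or coercible matrix (normally the filtered
#'   panel).
#' @param map Tibble as from [read_marker_map()]; required unless
#'   `level = "panel"`.
#' @param groups Optional tibble (`accession`, `group`); when `NULL` the
#'   whole matrix is a single group `"all"`.
#' @param level `"linkage_group"`, `"subgenome"` or `"panel"`.
#' @return Tibble of class `gbsdiv_diversity_summary` with columns `group`,
#'   `level`, `level_value`, `n_markers`, `mean_DI`, `mean_PIC`.
#' @export
summarize_diversity <- function(geno, map = NULL, groups = NULL,
                                level = c("linkage_group", "subgenome", "panel")) {
  level <- match.arg(level)
  geno <- as_geno_matrix(geno)
  if (is.null(groups)) {
    groups <- tibble::tibble(accession = rownames(geno), group = "all")
  }
  if (level != "panel") {
    if (is.null(map)) rlang::abort("a marker map is required for this level",
                                   class = "gbsdiv_config_error")
    missing_mk <- setdiff(colnames(geno), map$marker)
    if (length(missing_mk)) {
      rlang::abort(paste0("marker(s) without map position: ",
                          paste(utils::head(missing_mk, 5), collapse = ", ")),
                   class = "gbsdiv_format_error")
    }
  }
  gf <- group_freq_matrix(geno, groups)
  lv <- switch(level,
    panel = rep("panel", ncol(geno)),
    linkage_group = map$chrom[match(colnames(geno), map$marker)],
    subgenome = map$subgenome[match(colnames(geno), map$marker)])

  out <- tidyr::expand_grid(group = gf$groups, level_value = sort(unique(lv)))
  res <- purrr::pmap(out, function(group, level_value) {
    sel <- lv == level_value
    p <- gf$P[group, sel]
    p <- p[!is.na(p)]
    tibble::tibble(n_markers = sum(sel),
                   mean_DI = if (length(p)) mean(nei_diversity(p)) else NA_real_,
                   mean_PIC = if (length(p)) mean(pic(p)) else NA_real_)
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(res))
  out$level <- level
  out <- out[c("group", "level", "level_value", "n_markers", "mean_DI", "mean_PIC")]
  class(out) <- c("gbsdiv_diversity_summary", class(out))
  out
}

#' Distribution of per-locus diversities
#'
#' Bins per-locus DI values into left-open, right-closed intervals whose
#' upper edges are `edges` (the first bin includes 0) and reports the
#' percentage of markers per bin, the display used for marker-panel
#' diversity profiles.
#'
#' @param di Numeric vector of per-locus diversities in `[0, 0.5]`.
#' @param edges Increasing bin upper edges (default 0.1 ... 0.5).
#' @return Tibble of class `gbsdiv_di_histogram` with columns `bin_upper`,
#'   `n`, `pct`.
#' @export
di_histogram <- function(di, edges = seq(0.1, 0.5, by = 0.1)) {
  if (!length(di)) {
    rlang::abort("no diversities to bin (empty panel?)",
                 class = "gbsdiv_empty_panel_error")
  }
  if (any(di < 0 | di > max(edges))) {
    rlang::abort("diversities outside [0, max(edges)]",
                 class = "gbsdiv_config_error")
  }
  cuts <- cut(di, breaks = c(0, edges), include.lowest = TRUE, right = TRUE)
  n <- as.integer(table(cuts))
  out <- tibble::tibble(bin_upper = edges, n = n, pct = 100 * n / length(di))
  class(out) <- c("gbsdiv_di_histogram", class(out))
  out
}

#' Mean pairwise genetic distance within a set of accessions
#'
#' The default allele-sharing distance between two accessions is the
#' proportion of mismatching calls among loci called in both
#' (pairwise-complete); `method = "euclidean"` instead averages the
#' missing-rescaled Euclidean distance of [genetic_distance()]. Pairs with
#' no co-called loci are excluded with a warning.
#'
#' @param geno A [geno_matrix()] restricted to one group; needs >= 2 rows.
#' @param method `"allele_sharing"` (default) or `"euclidean"`.
#' @return Mean over unordered accession pairs (a scalar).
#' @export
mean_pairwise_distance <- function(geno, method = c("allele_sharing", "euclidean")) {
  method <- match.arg(method)
  geno <- as_geno_matrix(geno)
  if (nrow(geno) < 2) {
    rlang::abort("at least two accessions are required",
                 class = "gbsdiv_config_error")
  }
  pc <- pairwise_counts(unclass(geno))
  up <- upper.tri(pc$m)
  empty <- pc$m[up] == 0
  if (any(empty)) {
    rlang::warn(sprintf("%d accession pair(s) share no called loci; excluded",
                        sum(empty)))
  }
  if (method == "allele_sharing") {
    d <- pc$mismatch[up][!empty] / pc$m[up][!empty]
  } else {
    L <- ncol(geno)
    d <- sqrt(L * pc$mismatch[up][!empty] / pc$m[up][!empty])
  }
  if (!length(d)) {
    rlang::abort("no accession pair shares called loci",
                 class = "gbsdiv_empty_panel_error")
  }
  mean(d)
}

# pairwise co-called counts m and mismatch counts for a 0/1/NA matrix
pairwise_counts <- function(x) {
  M <- (!is.na(x)) * 1
  x0 <- x; x0[is.na(x0)] <- 0L
  m <- M %*% t(M)
  A <- x0 %*% t(x0)            # co-called double-1 counts
  XM <- x0 %*% t(M)            # x_i = 1 among loci called in both
  mismatch <- XM + t(XM) - 2 * A
  list(m = m, mismatch = mismatch)
}

#' Equal-size resampled group diversity
#'
#' Draws `n` accessions per group without replacement in each replicate and
#' recomputes the group mean DI, removing the confounding of diversity
#' comparisons by unequal group sizes. Deterministic under `seed`.
#'
#' @param geno A [geno_matrix()] or coercible matrix.
#' @param groups Tibble (`accession`, `group`); every group must have at
#'   least `n` members.
#' @param n Subsample size per group (default 211).
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return Tibble of class `gbsdiv_resample_diversity` with columns `group`,
#'   `n`, `n_reps`, `mean_DI`, `sd_DI`.
#' @export
equal_size_resample_diversity <- function(geno, groups, n = 211, n_reps = 100,
                                          seed = 1L) {
  geno <- as_geno_matrix(geno)
  check_groups_cover(geno, groups)
  sizes <- table(groups$group)
  small <- names(sizes)[sizes < n]
  if (length(small)) {
    rlang::abort(paste0("group(s) smaller than n = ", n, ": ",
                        paste(small, collapse = ", ")),
                 class = "gbsdiv_config_error")
  }
  set.seed(seed)
  glab <- sort(unique(groups$group))
  x <- unclass(geno)
  reps <- matrix(NA_real_, nrow = n_reps, ncol = length(glab),
                 dimnames = list(NULL, glab))
  for (r in seq_len(n_reps)) {
    for (g in glab) {
      ids <- sample(groups$accession[groups$group == g], n)
      xg <- x[ids, , drop = FALSE]
      n_called <- colSums(!is.na(xg))
      p <- colMeans(xg, na.rm = TRUE)[n_called > 0]
      reps[r, g] <- mean(nei_diversity(p))
    }
  }
  out <- tibble::tibble(group = glab, n = n, n_reps = n_reps,
                        mean_DI = unname(colMeans(reps)),
                        sd_DI = unname(apply(reps, 2, stats::sd)))
  class(out) <- c("gbsdiv_resample_diversity", class(out))
  out
}

#' Diversity table across groups and linkage groups
#'
#' Wide summary with one row per linkage group plus `Mean DI` and `Mean GD`
#' rows and one column per group — the standard panel-characterization
#' table for germplasm sets.
#'
#' @inheritParams summarize_diversity
#' @param gd_method Distance used for the `Mean GD` row; see
#'   [mean_pairwise_distance()].
#' @return Tibble with first column `LG`.
#' @export
diversity_table <- function(geno, map, groups, gd_method = "allele_sharing") {
  by_lg <- summarize_diversity(geno, map, groups, level = "linkage_group")
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(by_lg)[c("group", "level_value", "mean_DI")],
    names_from = "group", values_from = "mean_DI")
  names(wide)[1] <- "LG"
  panel <- summarize_diversity(geno, groups = groups, level = "panel")
  glab <- sort(unique(groups$group))
  gd <- vapply(glab, function(g) {
    mean_pairwise_distance(
      unclass(as_geno_matrix(geno))[groups$accession[groups$group == g], ,
                                    drop = FALSE],
      method = gd_method)
  }, numeric(1))
  extra <- tibble::tibble(LG = c("Mean DI", "Mean GD"))
  for (g in glab) {
    extra[[g]] <- c(panel$mean_DI[panel$group == g], gd[[g]])
  }
  dplyr::bind_rows(wide, extra)
}
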