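#' Total and within-group gene diversity (Ht, Hs)
#'
#' Per locus, the pooled frequency `p_bar` is the unweighted mean of the
#' group allele frequencies (each group counts once, regardless of size;
#' a sample-size-weighted pooling is available via `weighted = TRUE`).
#' Then `h_t = 2 p_bar (1 - p_bar)` and `h_s` is the unweighted mean over
#' groups of `2 p_g (1 - p_g)`; `Ht` and `Hs` average these over loci.
#' Loci with zero calls in any group are dropped and counted in the
#' `dropped_loci` attribute.
#'
#' @param geno A [geno_matrix()] or coercible matrix.
#' @param groups Tibble (`accession`, `group`) with at least two groups.
#' @param weighted Weight groups by their called sample size when pooling.
#' @return Named numeric `c(Ht = , Hs = )` with attributes `per_locus`
#'   (tibble of `marker`, `ht`, `hs`) and `dropped_loci`.
#' @export
ht_hs <- function(geno, groups, weighted = FALSE) {
  gf <- group_freq_matrix(geno, groups)
  if (length(gf$groups) < 2) {
    rlang::abort("at least two groups are required", class = "gbsdiv_config_error")
  }
  callable <- colSums(is.na(gf$P)) == 0
  if (!any(callable)) {
    rlang::abort("no locus is callable in every group",
                 class = "gbsdiv_empty_panel_error")
  }
  P <- gf$P[, callable, drop = FALSE]
  if (weighted) {
    N <- gf$N[, callable, drop = FALSE]
    p_bar <- colSums(P * N) / colSums(N)
  } else {
    p_bar <- colMeans(P)
  }
  ht_l <- 2 * p_bar * (1 - p_bar)
  hs_l <- colMeans(2 * P * (1 - P))
  out <- c(Ht = mean(ht_l), Hs = mean(hs_l))
  attr(out, "per_locus") <- tibble::tibble(marker = colnames(P),
                                           ht = unname(ht_l), hs = unname(hs_l))
  attr(out, "dropped_loci") <- sum(!callable)
  out
}

#' Coefficient of gene differentiation
#'
#' `Gst = 1 - Hs / Ht`, the proportion of total gene diversity residing
#' between subpopulations.
#'
#' @param ht Total gene diversity, must be positive.
#' @param hs Mean within-subpopulation diversity; `hs > ht` is an error
#'   (never silently clamped).
#' @return Gst in `[0, 1]`.
#' @examples
#' gst(0.360, 0.301)
#' @export
gst <- function(ht, hs) {
  if (any(ht <= 0)) {
    rlang::abort("Gst is undefined for Ht = 0 (no total diversity)",
                 class = "gbsdiv_undefined_error")
  }
  if (any(hs < 0)) rlang::abort("Hs must be >= 0", class = "gbsdiv_config_error")
  if (any(hs > ht * (1 + 1e-12))) {
    rlang::abort("invariant violation: Hs exceeds Ht",
                 class = "gbsdiv_invariant_error")
  }
  pmin(pmax(1 - hs / ht, 0), 1)
}

#' Island-model gene-flow estimate
#'
#' `Nm = 0.5 (1 - Gst) / Gst`, the effective number of migrants implied by
#' the observed differentiation; strictly decreasing in Gst. `Gst = 0`
#' returns `Inf` with a warning, `Gst = 1` returns 0.
#'
#' @param gst_value Gst in `[0, 1]`.
#' @return Nm (non-negative, possibly `Inf`).
#' @examples
#' nm(gst(0.360, 0.301))
#' @export
nm <- function(gst_value) {
  if (any(gst_value < 0 | gst_value > 1)) {
    rlang::abort("Gst must lie in [0, 1]", class = "gbsdiv_config_error")
  }
  out <- ifelse(gst_value == 0, Inf, 0.5 * (1 - gst_value) / gst_value)
  if (any(gst_value == 0)) {
    rlang::warn("Gst = 0: gene flow is unbounded (+Inf)")
  }
  out
}

#' Diversity partitioning for a grouping
#'
#' One-stop computation of Ht, Hs, Gst and Nm for a genotype matrix and a
#' grouping, the row format of a differentiation table.
#'
#' @inheritParams ht_hs
#' @param grouping_label Optional label naming the comparison.
#' @return Tibble of class `gbsdiv_differentiation` with columns `grouping`,
#'   `n_groups`, `n_loci`, `Ht`, `Hs`, `Gst`, `Nm`.
#' @export
differentiation_stats <- function(geno, groups, weighted = FALSE,
                                  grouping_label = "groups") {
  hh <- ht_hs(geno, groups, weighted = weighted)
  g <- gst(hh[["Ht"]], hh[["Hs"]])
  out <- tibble::tibble(
    grouping = grouping_label,
    n_groups = length(unique(groups$group)),
    n_loci = nrow(attr(hh, "per_locus")),
    Ht = hh[["Ht"]], Hs = hh[["Hs"]], Gst = g, Nm = nm(g))
  class(out) <- c("gbsdiv_differentiation", class(out))
  out
}

#' Differentiation parameter corrected for the number of groups
#'
#' With `k` subpopulations, the raw Gst of a panel whose group frequencies
#' have variance `F p0 (1 - p0)` around the ancestral frequency (the
#' Balding-Nichols / island model parameter `F`) has expectation
#' `F (k - 1) / (k - F)`: the pooled frequency is estimated from only `k`
#' draws, which absorbs part of the between-group variance into `Hs`'s
#' denominator. Inverting that moment relation gives the estimator
#' `F = k Gst / (k - 1 + Gst)`, which is consistent for `F` as loci grow.
#' Use this, not raw Gst, when recovering a simulated differentiation
#' parameter or comparing groupings with different `k`.
#'
#' @inheritParams ht_hs
#' @return Scalar estimate of `F`.
#' @seealso [simulate_structured_snp_panel()] for the generative model.
#' @export
estimate_fst <- function(geno, groups, weighted = FALSE) {
  hh <- ht_hs(geno, groups, weighted = weighted)
  g <- gst(hh[["Ht"]], hh[["Hs"]])
  k <- length(unique(groups$group))
  k * g / (k - 1 + g)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a differentiation result
#' @param x A `gbsdiv_differentiation` tibble.
#' @param ... Unused.
#' @return The underlying tibble (long-format friendly).
#' @exportS3Method generics::tidy
tidy.gbsdiv_differentiation <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a sharing report
#' @param x A `gbsdiv_sharing_report`.
#' @param ... Unused.
#' @return Tibble with polymorphic, private and exclusively shared counts.
#' @exportS3Method generics::glance
glance.gbsdiv_sharing_report <- function(x, ...) {
  tibble::tibble(n_polymorphic = x$n_polymorphic,
                 n_private = sum(x$private$n),
                 n_exclusive_pairs = sum(x$exclusive_pairs$n),
                 n_wider_shared = x$n_polymorphic - sum(x$private$n) -
                   sum(x$exclusive_pairs$n))
}

#' Tidy a sharing report
#' @param x A `gbsdiv_sharing_report`.
#' @param ... Unused.
#' @return The per-marker detail tibble.
#' @exportS3Method generics::tidy
tidy.gbsdiv_sharing_report <- function(x, ...) {
  x$detail
}
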