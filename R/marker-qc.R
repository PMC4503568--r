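#' Quality-filter raw reads
#'
#' Implements the two-part read rule used for GBS libraries: a read is kept
#' iff at least `frac_body` of all its bases reach Phred `q_body` (default:
#' half the bases at Q30) and at least `frac_barcode` of its barcode bases
#' (the first `barcode_length` bases) reach Phred `q_barcode` (default:
#' three quarters at Q10).
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (Phred+33), as from
#'   [read_fastq()] or [simulate_fastq()].
#' @param q_body,frac_body Body rule: minimum Phred and minimum fraction of
#'   all bases meeting it.
#' @param q_barcode,frac_barcode Barcode rule, applied to the first
#'   `barcode_length` bases.
#' @param barcode_length Barcode length in bases (default 8).
#' @return List with tibbles `kept` and `rejected`; `rejected` carries a
#'   `reason` column (`"body"` or `"barcode"`, first rule failed).
#' @export
qc_filter_reads <- function(reads, q_body = 30, frac_body = 0.5,
                            q_barcode = 10, frac_barcode = 0.75,
                            barcode_length = 8L) {
  len <- nchar(reads$qual)
  if (any(len < barcode_length)) {
    short <- which(len < barcode_length)[1]
    rlang::abort(sprintf(
      "read '%s' (%d bases) is shorter than the barcode length %d",
      reads$id[short], len[short], barcode_length),
      class = "gbsdiv_format_error")
  }
  scores <- phred_scores(reads)
  body_ok <- vapply(scores, function(q) mean(q >= q_body) >= frac_body,
                    logical(1))
  bc_ok <- vapply(scores, function(q) {
    mean(q[seq_len(barcode_length)] >= q_barcode) >= frac_barcode
  }, logical(1))
  keep <- body_ok & bc_ok
  rejected <- reads[!keep, , drop = FALSE]
  rejected$reason <- ifelse(!body_ok[!keep], "body", "barcode")
  list(kept = reads[keep, , drop = FALSE], rejected = rejected)
}

#' Per-locus call statistics
#'
#' Allele frequency `p` (of allele 1) is computed over called cells only;
#' loci with zero calls get `p = NA` and are flagged.
#'
#' @param geno A [geno_matrix()] or coercible matrix.
#' @return Tibble with columns `marker`, `n_called`, `n_missing`, `p`,
#'   `maf`, `call_rate`, `no_calls`.
#' @export
compute_locus_stats <- function(geno) {
  geno <- as_geno_matrix(geno)
  x <- unclass(geno)
  n_called <- colSums(!is.na(x))
  n_missing <- nrow(x) - n_called
  p <- unname(ifelse(n_called > 0, colMeans(x, na.rm = TRUE), NA_real_))
  n_called <- unname(n_called); n_missing <- unname(n_missing)
  tibble::tibble(
    marker = colnames(x),
    n_called = as.integer(n_called),
    n_missing = as.integer(n_missing),
    p = p,
    maf = pmin(p, 1 - p),
    call_rate = n_called / nrow(x),
    no_calls = n_called == 0L)
}

#' Filter markers by the stated panel QC rules
#'
#' Keeps a marker iff its missing fraction is at most `max_missing`, its
#' minor allele frequency is at least `min_maf` (so `maf == min_maf` is
#' kept), its call rate is at least `min_call_rate`, it has a map position
#' when `require_mapped`, and — when technical replicate pairs are supplied —
#' its call concordance across replicate pairs is at least
#' `min_reproducibility`. Rules are conjunctive; the order below only
#' determines which rule a dropped marker is logged under
#' (no_calls, call_rate, missing, maf, unmapped, reproducibility).
#' Loci with zero calls are always dropped.
#'
#' @param geno A [geno_matrix()] or coercible matrix.
#' @param map Optional tibble as from [read_marker_map()]; required when
#'   `require_mapped = TRUE`.
#' @param max_missing Maximum tolerated missing fraction (default 0.20).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param min_call_rate Minimum call rate (default 0.50).
#' @param require_mapped Drop markers absent from `map`.
#' @param replicate_pairs Optional list of length-2 character vectors naming
#'   accession pairs that are technical replicates.
#' @param min_reproducibility Minimum replicate concordance (default 0.995),
#'   computed per marker over pairs where both replicates are called.
#' @return Filtered [geno_matrix()] with attribute `filter_log`, a tibble of
#'   `marker` and `rule` for every dropped marker. Marker order is
#'   preserved. Removing every marker is an error.
#' @export
filter_markers <- function(geno, map = NULL, max_missing = 0.20,
                           min_maf = 0.05, min_call_rate = 0.50,
                           require_mapped = TRUE, replicate_pairs = NULL,
                           min_reproducibility = 0.995) {
  for (thr in c(max_missing, min_maf, min_call_rate, min_reproducibility)) {
    if (thr < 0 || thr > 1) {
      rlang::abort("thresholds must lie in [0, 1]", class = "gbsdiv_config_error")
    }
  }
  geno <- as_geno_matrix(geno)
  if (require_mapped && is.null(map)) {
    rlang::abort("require_mapped = TRUE but no marker map supplied",
                 class = "gbsdiv_config_error")
  }
  st <- compute_locus_stats(geno)
  missing_frac <- st$n_missing / (st$n_called + st$n_missing)

  rule <- rep(NA_character_, nrow(st))
  rule[is.na(rule) & st$no_calls] <- "no_calls"
  rule[is.na(rule) & st$call_rate < min_call_rate] <- "call_rate"
  rule[is.na(rule) & missing_frac > max_missing] <- "missing"
  rule[is.na(rule) & st$maf < min_maf] <- "maf"
  if (require_mapped) {
    rule[is.na(rule) & !(st$marker %in% map$marker)] <- "unmapped"
  }
  if (!is.null(replicate_pairs) && length(replicate_pairs)) {
    conc <- replicate_concordance(geno, replicate_pairs)
    rule[is.na(rule) & !is.na(conc) & conc < min_reproducibility] <- "reproducibility"
  }

  keep <- is.na(rule)
  if (!any(keep)) {
    rlang::abort("all markers removed by QC filters (empty panel)",
                 class = "gbsdiv_empty_panel_error")
  }
  out <- geno[, keep, drop = FALSE]
  attr(out, "filter_log") <- tibble::tibble(marker = st$marker[!keep],
                                            rule = rule[!keep])
  out
}

# per-marker concordance of called technical replicate pairs; NA when no
# pair has both members called at the marker
replicate_concordance <- function(geno, replicate_pairs) {
  x <- unclass(geno)
  agree <- matrix(0L, nrow = length(replicate_pairs), ncol = ncol(x))
  both <- matrix(0L, nrow = length(replicate_pairs), ncol = ncol(x))
  for (i in seq_along(replicate_pairs)) {
    pr <- replicate_pairs[[i]]
    missing_acc <- setdiff(pr, rownames(x))
    if (length(missing_acc)) {
      rlang::abort(paste0("replicate accession not in matrix: ",
                          paste(missing_acc, collapse = ", ")),
                   class = "gbsdiv_config_error")
    }
    a <- x[pr[1], ]; b <- x[pr[2], ]
    ok <- !is.na(a) & !is.na(b)
    both[i, ] <- ok
    agree[i, ok] <- a[ok] == b[ok]
  }
  n_both <- colSums(both)
  ifelse(n_both > 0, colSums(agree) / n_both, NA_real_)
}

#' Filter log of a filtered genotype matrix
#' @param geno Result of [filter_markers()].
#' @return Tibble with columns `marker`, `rule`.
#' @export
filter_log <- function(geno) {
  lg <- attr(geno, "filter_log")
  if (is.null(lg)) tibble::tibble(marker = character(0), rule = character(0))
  else lg
}

#' Group-private and exclusively shared markers
#'
#' A polymorphic marker is "specific to group g" when its minor allele
#' (the globally rarer call; ties resolved to allele 1) is observed in g and
#' in no other group, and "shared exclusively between g and h" when it is
#' observed in exactly those two groups. Monomorphic markers are excluded.
#'
#' @param geno A [geno_matrix()] or coercible matrix.
#' @param groups Tibble with columns `accession`, `group` covering at least
#'   two groups.
#' @return A `gbsdiv_sharing_report`: list with `detail` (tibble: `marker`,
#'   `minor_allele`, `groups_with_minor` list-column, `n_groups`, `class`),
#'   `private` (tibble: `group`, `n`), `exclusive_pairs` (tibble: `group1`,
#'   `group2`, `n`) and `n_polymorphic`.
#' @export
group_specific_markers <- function(geno, groups) {
  geno <- as_geno_matrix(geno)
  check_groups_cover(geno, groups)
  glab <- sort(unique(groups$group))
  if (length(glab) < 2) {
    rlang::abort("at least two groups are required", class = "gbsdiv_config_error")
  }
  x <- unclass(geno)
  st <- compute_locus_stats(geno)
  poly <- !st$no_calls & st$p > 0 & st$p < 1
  minor <- ifelse(st$p <= 0.5, 1L, 0L)

  seen <- vapply(glab, function(g) {
    rows <- groups$accession[groups$group == g]
    xg <- x[rows, , drop = FALSE]
    colSums(xg == rep(minor, each = nrow(xg)), na.rm = TRUE) > 0
  }, logical(ncol(x)))  # markers x groups
  if (!is.matrix(seen)) seen <- matrix(seen, nrow = 1, dimnames = list(NULL, glab))

  detail <- tibble::tibble(
    marker = st$marker[poly],
    minor_allele = minor[poly],
    groups_with_minor = apply(seen[poly, , drop = FALSE], 1,
                              function(r) glab[r], simplify = FALSE),
    n_groups = rowSums(seen[poly, , drop = FALSE]))
  detail$class <- dplyr::case_when(
    detail$n_groups == 1 ~ "private",
    detail$n_groups == 2 ~ "exclusive_pair",
    TRUE ~ "shared")

  private <- tibble::tibble(
    group = glab,
    n = vapply(glab, function(g) {
      sum(detail$class == "private" &
            vapply(detail$groups_with_minor, function(s) identical(s, g), logical(1)))
    }, integer(1)))

  combs <- utils::combn(glab, 2)
  exclusive_pairs <- tibble::tibble(
    group1 = combs[1, ], group2 = combs[2, ],
    n = vapply(seq_len(ncol(combs)), function(i) {
      sum(detail$class == "exclusive_pair" &
            vapply(detail$groups_with_minor,
                   function(s) setequal(s, combs[, i]), logical(1)))
    }, integer(1)))

  structure(list(detail = detail, private = private,
                 exclusive_pairs = exclusive_pairs,
                 n_polymorphic = sum(poly)),
            class = "gbsdiv_sharing_report")
}

#' @export
print.gbsdiv_sharing_report <- function(x, ...) {
  cat(sprintf("<sharing report> %d polymorphic markers\n", x$n_polymorphic))
  cat("private:\n"); print(x$private)
  cat("exclusively shared pairs:\n"); print(x$exclusive_pairs)
  invisible(x)
}

check_groups_cover <- function(geno, groups) {
  unknown <- setdiff(groups$accession, rownames(geno))
  if (length(unknown)) {
    rlang::abort(paste0("group table references accession(s) not in matrix: ",
                        paste(utils::head(unknown, 5), collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  invisible(TRUE)
}
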