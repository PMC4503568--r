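#' Per-group allele frequencies for a gene-marker panel
#'
#' For each allele-specific assay and group, the frequency is
#' `present / (present + absent)`; missing calls are excluded from the
#' denominator. Alleles never observed in a group report 0; a group whose
#' calls for an allele are all missing reports `NA`.
#'
#' @param calls Tibble with columns `accession`, `allele_id`, `call`
#'   (one of `"present"`, `"absent"`, `"missing"`).
#' @param groups Tibble (`accession`, `group`).
#' @return Tibble with columns `allele_id`, `group`, `n_present`,
#'   `n_absent`, `n_missing`, `freq`.
#' @export
allele_frequency_table <- function(calls, groups) {
  if (!nrow(calls)) rlang::abort("empty gene-marker panel",
                                 class = "gbsdiv_empty_panel_error")
  bad <- setdiff(unique(calls$call), c("present", "absent", "missing"))
  if (length(bad)) {
    rlang::abort(paste0("invalid call value(s): ", paste(bad, collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  calls |>
    dplyr::inner_join(groups, by = "accession") |>
    dplyr::group_by(.data$allele_id, .data$group) |>
    dplyr::summarise(
      n_present = sum(.data$call == "present"),
      n_absent = sum(.data$call == "absent"),
      n_missing = sum(.data$call == "missing"),
      .groups = "drop") |>
    dplyr::mutate(freq = ifelse(.data$n_present + .data$n_absent > 0,
                                .data$n_present / (.data$n_present + .data$n_absent),
                                NA_real_))
}

#' Mean gene diversity from allele-specific markers
#'
#' Treats each allele row as an independent biallelic presence/absence
#' locus: `DI = 2 p (1 - p)` at the observed per-group frequency, averaged
#' over alleles with a defined frequency. Frequencies of alleles of one
#' gene are deliberately not renormalized to sum to one — assays are scored
#' independently.
#'
#' @param freqs Output of [allele_frequency_table()], or any tibble with
#'   columns `group`, `allele_id`, `freq`.
#' @return Tibble with columns `group`, `n_alleles`, `mean_DI`, `mean_PIC`.
#' @export
gene_based_diversity <- function(freqs) {
  freqs |>
    dplyr::filter(!is.na(.data$freq)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_alleles = dplyr::n(),
                     mean_DI = mean(nei_diversity(.data$freq)),
                     mean_PIC = mean(pic(.data$freq)),
                     .groups = "drop")
}

#' Flag novel PCR band sizes
#'
#' Compares observed amplicon sizes with the expected band of each
#' allele-specific STS assay at a relative gel-resolution tolerance.
#' Observations within `tolerance * expected` are `known`; smaller bands
#' beyond tolerance are `novel_smaller` (putative deletion), larger are
#' `novel_larger` (putative insertion).
#'
#' @param observations Tibble with columns `accession`, `allele_id`,
#'   `observed_bp`.
#' @param panel Tibble with columns `allele_id` and `expected_bp`
#'   (`NA` for SNP assays, which have no band and are errors to observe).
#' @param tolerance Relative size tolerance (default 0.10).
#' @return Tibble with columns `accession`, `allele_id`, `expected_bp`,
#'   `observed_bp`, `size_delta_bp`, `class`.
#' @export
flag_novel_bands <- function(observations, panel, tolerance = 0.10) {
  if (tolerance < 0) rlang::abort("tolerance must be >= 0",
                                  class = "gbsdiv_config_error")
  unknown <- setdiff(observations$allele_id, panel$allele_id)
  if (length(unknown)) {
    rlang::abort(paste0("observation(s) for allele(s) not in panel: ",
                        paste(unique(unknown), collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  if (any(observations$observed_bp <= 0)) {
    rlang::abort("observed band sizes must be positive",
                 class = "gbsdiv_format_error")
  }
  joined <- dplyr::inner_join(observations,
                              panel[c("allele_id", "expected_bp")],
                              by = "allele_id")
  no_band <- is.na(joined$expected_bp)
  if (any(no_band)) {
    rlang::abort(paste0("band observation for SNP assay (no expected size): ",
                        paste(unique(joined$allele_id[no_band]), collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  joined |>
    dplyr::mutate(
      size_delta_bp = .data$observed_bp - .data$expected_bp,
      class = dplyr::case_when(
        abs(.data$size_delta_bp) <= tolerance * .data$expected_bp ~ "known",
        .data$size_delta_bp < 0 ~ "novel_smaller",
        TRUE ~ "novel_larger")) |>
    dplyr::select("accession", "allele_id", "expected_bp", "observed_bp",
                  "size_delta_bp", "class")
}
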