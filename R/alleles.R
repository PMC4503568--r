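#' Detect a single indel by the affix method
#'
#' For a reference/query pair that differ by exactly one contiguous
#' insertion or deletion (no substitutions), the longest common prefix and
#' suffix delimit the event. Among the placements a repeat allows, the
#' leftmost is reported. Coordinates are 1-based in the reference:
#' `ref_anchor` is the last retained base before the event (0 when the
#' event starts at position 1) and, for deletions, `ref_end` is the last
#' deleted base, so `length = ref_end - ref_anchor`. For insertions
#' `ref_end == ref_anchor` and the inserted sequence is returned.
#'
#' @param reference,query DNA strings, or single-row tibbles with a `seq`
#'   column (as produced by [read_fasta()] / [simulate_indel_pair()]).
#' @return List of class `gbsdiv_indel_call` with elements `type`,
#'   `ref_anchor`, `ref_end`, `length`, `inserted_sequence`.
#' @examples
#' detect_single_indel("ACGTACGTAA", "ACGGTAA")
#' @export
detect_single_indel <- function(reference, query) {
  ref <- as_sequence(reference)
  qry <- as_sequence(query)
  if (nchar(ref) == nchar(qry)) {
    if (ref == qry) {
      rlang::abort("sequences are identical: no event to detect",
                   class = "gbsdiv_no_event_error")
    }
    rlang::abort("equal-length sequences cannot differ by a single indel; use align_and_call()",
                 class = "gbsdiv_not_single_indel_error")
  }
  long <- if (nchar(ref) > nchar(qry)) ref else qry
  short <- if (nchar(ref) > nchar(qry)) qry else ref
  nl <- nchar(long); ns <- nchar(short)
  lv <- strsplit(long, "")[[1]]
  sv <- strsplit(short, "")[[1]]

  P <- common_prefix_length(lv, sv)
  S <- common_suffix_length(lv, sv)
  if (P + S < ns) {
    rlang::abort("sequences differ by more than one indel (substitutions present); use align_and_call()",
                 class = "gbsdiv_not_single_indel_error")
  }
  event_len <- nl - ns
  anchor <- max(0L, ns - S)  # leftmost placement
  event_seq <- paste(lv[seq(anchor + 1L, anchor + event_len)], collapse = "")

  if (nchar(ref) > nchar(qry)) {
    out <- indel_call("deletion", ref_anchor = anchor,
                      ref_end = anchor + event_len, length = event_len)
  } else {
    out <- indel_call("insertion", ref_anchor = anchor, ref_end = anchor,
                      length = event_len, inserted_sequence = event_seq)
  }
  out
}

indel_call <- function(type, ref_anchor, ref_end, length,
                       inserted_sequence = NULL) {
  structure(list(type = type, ref_anchor = as.integer(ref_anchor),
                 ref_end = as.integer(ref_end), length = as.integer(length),
                 inserted_sequence = inserted_sequence),
            class = "gbsdiv_indel_call")
}

#' @export
print.gbsdiv_indel_call <- function(x, ...) {
  cat(sprintf("<indel call> %s of %d bp, ref anchor %d, ref end %d\n",
              x$type, x$length, x$ref_anchor, x$ref_end))
  invisible(x)
}

as_sequence <- function(x) {
  if (is.data.frame(x)) x <- x$seq[1]
  x <- toupper(as.character(x))
  if (!nzchar(x)) rlang::abort("empty sequence", class = "gbsdiv_format_error")
  check_dna_alphabet(x, "sequence")
  x
}

common_prefix_length <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0) return(0L)
  diff <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(diff)) diff[1] - 1L else n
}

common_suffix_length <- function(a, b) {
  common_prefix_length(rev(a), rev(b))
}

#' Global alignment and variant calling
#'
#' Aligns query to reference with a global (Needleman-Wunsch) affine-gap
#' alignment, then collapses gap runs into indel calls and mismatch columns
#' into substitutions. Indels inside repeats are shifted to their leftmost
#' equivalent placement. Coordinates follow the [detect_single_indel()]
#' convention.
#'
#' @inheritParams detect_single_indel
#' @param scoring Named list with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (gap penalties as positive costs).
#' @return List of class `gbsdiv_variant_report` with `indels` (tibble:
#'   `type`, `ref_anchor`, `ref_end`, `length`, `inserted_sequence`) and
#'   `substitutions` (tibble: `ref_pos`, `ref_base`, `alt_base`).
#' @export
align_and_call <- function(reference, query,
                           scoring = list(match = 1, mismatch = -1,
                                          gap_open = 10, gap_extend = 0.5)) {
  ref <- as_sequence(reference)
  qry <- as_sequence(query)
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qry), subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = sm,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  aq <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ar <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  calls_from_alignment(ar, aq, strsplit(ref, "")[[1]])
}

# walk alignment columns; ar/aq are gapped reference/query, refv the raw
# reference vector for left-normalization
calls_from_alignment <- function(ar, aq, refv) {
  indels <- list()
  subs <- tibble::tibble(ref_pos = integer(0), ref_base = character(0),
                         alt_base = character(0))
  rp <- 0L  # reference position of the last consumed ref base
  i <- 1L
  ncol <- length(ar)
  min_anchor <- 0L  # events may not left-shift past the previous variant
  while (i <= ncol) {
    if (ar[i] != "-" && aq[i] != "-") {
      rp <- rp + 1L
      if (ar[i] != aq[i]) {
        subs <- dplyr::bind_rows(subs, tibble::tibble(
          ref_pos = rp, ref_base = ar[i], alt_base = aq[i]))
        min_anchor <- rp
      }
      i <- i + 1L
    } else if (aq[i] == "-") {
      j <- i
      while (j <= ncol && aq[j] == "-") j <- j + 1L
      len <- j - i
      a <- rp; b <- rp + len
      # left-shift deletion while the base before equals the last deleted base
      while (a > min_anchor && refv[a] == refv[b]) { a <- a - 1L; b <- b - 1L }
      indels <- c(indels, list(indel_call("deletion", a, b, len)))
      min_anchor <- b
      rp <- rp + len
      i <- j
    } else {
      j <- i
      while (j <= ncol && ar[j] == "-") j <- j + 1L
      len <- j - i
      ins <- aq[seq(i, j - 1L)]
      a <- rp
      while (a > min_anchor && ins[len] == refv[a]) {
        ins <- c(refv[a], ins[-len]); a <- a - 1L
      }
      indels <- c(indels, list(indel_call("insertion", a, a, len,
                                          paste(ins, collapse = ""))))
      min_anchor <- a
      i <- j
    }
  }
  indel_tbl <- if (length(indels)) {
    dplyr::bind_rows(lapply(indels, function(e) tibble::tibble(
      type = e$type, ref_anchor = e$ref_anchor, ref_end = e$ref_end,
      length = e$length,
      inserted_sequence = e$inserted_sequence %||% NA_character_)))
  } else {
    tibble::tibble(type = character(0), ref_anchor = integer(0),
                   ref_end = integer(0), length = integer(0),
                   inserted_sequence = character(0))
  }
  structure(list(indels = indel_tbl, substitutions = subs),
            class = "gbsdiv_variant_report")
}

#' @export
print.gbsdiv_variant_report <- function(x, ...) {
  cat(sprintf("<variant report> %d indel(s), %d substitution(s)\n",
              nrow(x$indels), nrow(x$substitutions)))
  if (nrow(x$indels)) print(x$indels)
  if (nrow(x$substitutions)) print(x$substitutions)
  invisible(x)
}

#' Compare a novel deletion against a known nested deletion
#'
#' Both calls must be deletions in the same reference coordinates, with the
#' known event nested within (or equal to) the novel one. Returns how far
#' the novel deletion extends beyond the known one on each side; for nested
#' intervals `additional_bp = upstream_extension_bp + downstream_extension_bp`
#' always holds.
#'
#' @param novel,known `gbsdiv_indel_call` deletions (or lists with
#'   `type`, `ref_anchor`, `ref_end`, `length`).
#' @return Tibble with columns `upstream_extension_bp`,
#'   `downstream_extension_bp`, `additional_bp`.
#' @export
compare_deletion_intervals <- function(novel, known) {
  for (ev in list(novel, known)) {
    if (!identical(ev$type, "deletion")) {
      rlang::abort("both events must be deletions",
                   class = "gbsdiv_config_error")
    }
  }
  nested <- novel$ref_anchor <= known$ref_anchor &&
    novel$ref_end >= known$ref_end
  if (!nested) {
    ov_start <- max(novel$ref_anchor, known$ref_anchor)
    ov_end <- min(novel$ref_end, known$ref_end)
    rlang::abort(sprintf(
      paste0("known deletion (%d,%d] is not nested within novel (%d,%d]; ",
             "overlap is (%d,%d] = %d bp"),
      known$ref_anchor, known$ref_end, novel$ref_anchor, novel$ref_end,
      ov_start, ov_end, max(0L, ov_end - ov_start)),
      class = "gbsdiv_not_nested_error")
  }
  tibble::tibble(
    upstream_extension_bp = known$ref_anchor - novel$ref_anchor,
    downstream_extension_bp = novel$ref_end - known$ref_end,
    additional_bp = novel$length - known$length)
}

#' Classify an allele against a catalog of variant signatures
#'
#' A catalog entry matches when the report contains an indel of the entry's
#' type and length whose anchor lies in the entry's position window, and —
#' when the entry provides a sequence — whose inserted sequence is exactly
#' identical. An empty report returns `reference_label`; a non-empty report
#' matching nothing returns `"novel"`; multiple matches are an error
#' listing the candidates.
#'
#' @param report A `gbsdiv_variant_report`.
#' @param catalog Tibble with columns `label`, `type`, `length`,
#'   `pos_min`, `pos_max` and optional `sequence`.
#' @param reference_label Label for a variant-free report.
#' @return Character label.
#' @export
classify_allele <- function(report, catalog, reference_label = "reference") {
  if (!nrow(report$indels) && !nrow(report$substitutions)) {
    return(reference_label)
  }
  hits <- vapply(seq_len(nrow(catalog)), function(i) {
    entry <- catalog[i, ]
    cand <- report$indels[report$indels$type == entry$type &
                            report$indels$length == entry$length &
                            report$indels$ref_anchor >= entry$pos_min &
                            report$indels$ref_anchor <= entry$pos_max, ]
    if (!nrow(cand)) return(FALSE)
    if (!is.null(catalog$sequence) && !is.na(entry$sequence)) {
      any(!is.na(cand$inserted_sequence) &
            cand$inserted_sequence == entry$sequence)
    } else TRUE
  }, logical(1))
  if (sum(hits) > 1) {
    rlang::abort(paste0("ambiguous classification; candidates: ",
                        paste(catalog$label[hits], collapse = ", ")),
                 class = "gbsdiv_ambiguous_error")
  }
  if (any(hits)) catalog$label[hits] else "novel"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
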