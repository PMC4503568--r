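#' Simulate a structured multi-group SNP panel
#'
#' Generates a biallelic genotype matrix with population structure under the
#' Balding-Nichols model: each locus draws an ancestral allele frequency
#' `p0` from `ancestral_freq_range` (uniform), then each group draws its own
#' frequency from a Beta distribution with mean `p0` and variance
#' `fst * p0 * (1 - p0)`. Inbred calls (one allele per accession) are
#' Bernoulli draws from the group frequency, and cells are masked missing
#' independently at `missing_rate`. Markers are assigned round-robin to the
#' 21 wheat linkage groups with uniform cM positions.
#'
#' Defaults mirror a germplasm-bank study design of four sets (280 + 281
#' landraces, 651 synthetic hexaploids, 211 elite lines) genotyped at 11,874
#' mapped GBS markers. At `fst = 0` groups share the ancestral frequency and
#' the expected panel Gst is ~0; the expected raw Gst at `fst = F` with `k`
#' groups is `F (k-1) / (k - F)` (see [estimate_fst()] for the inversion).
#'
#' @param n_per_group Named integer vector of accessions per group; names
#'   become group labels.
#' @param n_loci Number of markers.
#' @param fst Differentiation parameter `F` in `[0, 1)`.
#' @param ancestral_freq_range Support of the uniform ancestral frequency
#'   law; kept away from 0/1 by default so loci stay informative.
#' @param missing_rate Independent per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed; identical seed and configuration give identical
#'   output.
#' @return List with elements `geno` ([geno_matrix()]), `map` (tibble as
#'   [read_marker_map()]), `groups` (tibble as [read_groups()]) and
#'   `group_freqs` (groups x loci matrix of the frequencies actually drawn).
#' @examples
#' sim <- simulate_structured_snp_panel(n_per_group = c(A = 20, B = 20),
#'                                      n_loci = 50, fst = 0.1, seed = 1)
#' dim(sim$geno)
#' @export
simulate_structured_snp_panel <- function(n_per_group = c(FD = 280, AH = 281,
                                                          SH = 651, E = 211),
                                          n_loci = 11874,
                                          fst = 0.15,
                                          ancestral_freq_range = c(0.05, 0.95),
                                          missing_rate = 0.05,
                                          seed = 1L) {
  if (any(n_per_group < 1)) rlang::abort("all group sizes must be >= 1",
                                         class = "gbsdiv_config_error")
  if (n_loci < 1) rlang::abort("n_loci must be >= 1", class = "gbsdiv_config_error")
  if (fst < 0 || fst >= 1) rlang::abort("fst must be in [0, 1)",
                                        class = "gbsdiv_config_error")
  if (missing_rate < 0 || missing_rate >= 1) {
    rlang::abort("missing_rate must be in [0, 1)", class = "gbsdiv_config_error")
  }
  if (is.null(names(n_per_group))) {
    names(n_per_group) <- paste0("G", seq_along(n_per_group))
  }
  set.seed(seed)
  k <- length(n_per_group)
  p0 <- stats::runif(n_loci, ancestral_freq_range[1], ancestral_freq_range[2])
  if (fst > 0) {
    shape_scale <- (1 - fst) / fst
    pf <- matrix(stats::rbeta(k * n_loci,
                              shape1 = rep(p0, each = k) * shape_scale,
                              shape2 = rep(1 - p0, each = k) * shape_scale),
                 nrow = k)
  } else {
    pf <- matrix(rep(p0, each = k), nrow = k)
  }
  rownames(pf) <- names(n_per_group)

  marker_ids <- sprintf("M%05d", seq_len(n_loci))
  acc_ids <- unlist(lapply(names(n_per_group), function(g) {
    sprintf("%s_%04d", g, seq_len(n_per_group[[g]]))
  }), use.names = FALSE)

  calls <- matrix(NA_integer_, nrow = sum(n_per_group), ncol = n_loci,
                  dimnames = list(acc_ids, marker_ids))
  row0 <- 0L
  for (gi in seq_len(k)) {
    ng <- n_per_group[[gi]]
    block <- matrix(stats::rbinom(ng * n_loci, 1L, rep(pf[gi, ], each = ng)),
                    nrow = ng)
    calls[row0 + seq_len(ng), ] <- block
    row0 <- row0 + ng
  }
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  }

  lg <- wheat_linkage_groups()
  map <- make_marker_map(marker_ids,
                         lg[((seq_len(n_loci) - 1L) %% 21L) + 1L],
                         round(stats::runif(n_loci, 0, 150), 2))
  groups <- tibble::tibble(
    accession = acc_ids,
    group = rep(names(n_per_group), times = n_per_group))

  list(geno = geno_matrix(calls), map = map, groups = groups, group_freqs = pf)
}

#' Simulate presence/absence calls for an allele-specific marker panel
#'
#' Draws independent Bernoulli presence calls per accession for each allele
#' and group at the given target frequencies, emulating a dominant
#' (presence/absence) gene-marker screen across germplasm sets.
#'
#' @param group_sizes Named integer vector of accessions per group.
#' @param target_frequencies Tibble with columns `allele_id`, `group`,
#'   `freq` (in `[0, 1]`), or a matrix with alleles as rows and groups as
#'   columns.
#' @param missing_rate Per-call missingness probability.
#' @param seed Integer seed.
#' @return List with `calls` (tibble: `accession`, `allele_id`, `call` in
#'   present/absent/missing) and `groups` (tibble: `accession`, `group`).
#' @export
simulate_gene_marker_panel <- function(group_sizes, target_frequencies,
                                       missing_rate = 0, seed = 1L) {
  if (is.matrix(target_frequencies)) {
    target_frequencies <- tibble::as_tibble(as.data.frame.table(
      target_frequencies, responseName = "freq", stringsAsFactors = FALSE))
    names(target_frequencies) <- c("allele_id", "group", "freq")
  }
  if (any(target_frequencies$freq < 0 | target_frequencies$freq > 1)) {
    rlang::abort("target frequencies must be in [0, 1]",
                 class = "gbsdiv_config_error")
  }
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  }
  set.seed(seed)
  groups <- tibble::tibble(
    accession = unlist(lapply(names(group_sizes), function(g) {
      sprintf("%s_%04d", g, seq_len(group_sizes[[g]]))
    }), use.names = FALSE),
    group = rep(names(group_sizes), times = group_sizes))

  calls <- target_frequencies |>
    dplyr::inner_join(groups, by = "group",
                      relationship = "many-to-many") |>
    dplyr::mutate(call = ifelse(stats::rbinom(dplyr::n(), 1L, .data$freq) == 1L,
                                "present", "absent"))
  if (missing_rate > 0) {
    mask <- stats::runif(nrow(calls)) < missing_rate
    calls$call[mask] <- "missing"
  }
  list(calls = calls[c("accession", "allele_id", "call")], groups = groups)
}

#' Simulate a reference/query pair differing by one indel
#'
#' Builds a random DNA reference of `ref_length` bases and a query carrying
#' exactly one insertion or deletion of `event_length` bases placed after
#' `breakpoint` (the last retained reference base, 1-based), plus
#' `n_substitutions` point changes outside the event. The returned truth
#' record uses reference coordinates: for a deletion, `ref_anchor` is the
#' last retained base and `ref_end` the last deleted base, so
#' `length = ref_end - ref_anchor`.
#'
#' Unless `allow_ambiguous = TRUE`, bases flanking the event are resampled so
#' the planted event cannot be slid left or right through a repeat; the truth
#' then coincides with the left-normalized call of the detection operations.
#'
#' @param ref_length Reference length in bp.
#' @param event `"deletion"` or `"insertion"`.
#' @param event_length Event size in bp; 0 returns identical sequences and a
#'   `NULL` truth.
#' @param breakpoint 1-based position of the last reference base retained
#'   before the event.
#' @param n_substitutions Point substitutions placed outside the event.
#' @param allow_ambiguous Keep repeat-induced placement ambiguity.
#' @param seed Integer seed.
#' @return List with `reference` and `query` (tibbles with `id`, `seq`) and
#'   `truth` (list with `type`, `ref_anchor`, `ref_end`, `length`,
#'   `inserted_sequence`, plus `substitutions` tibble).
#' @export
simulate_indel_pair <- function(ref_length, event = c("deletion", "insertion"),
                                event_length, breakpoint,
                                n_substitutions = 0, allow_ambiguous = FALSE,
                                seed = 1L) {
  event <- match.arg(event)
  if (ref_length < 2) rlang::abort("ref_length must be >= 2",
                                   class = "gbsdiv_config_error")
  if (event_length < 0) rlang::abort("event_length must be >= 0",
                                     class = "gbsdiv_config_error")
  if (breakpoint < 1) rlang::abort("breakpoint must be >= 1 (1-based)",
                                   class = "gbsdiv_config_error")
  if (event == "deletion" && breakpoint + event_length > ref_length) {
    rlang::abort("deletion does not fit: breakpoint + event_length > ref_length",
                 class = "gbsdiv_config_error")
  }
  if (event == "insertion" && breakpoint > ref_length) {
    rlang::abort("breakpoint beyond reference end", class = "gbsdiv_config_error")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ref_length, replace = TRUE)

  if (event_length == 0) {
    return(list(
      reference = tibble::tibble(id = "ref", seq = paste(ref, collapse = "")),
      query = tibble::tibble(id = "query", seq = paste(ref, collapse = "")),
      truth = NULL))
  }

  if (event == "deletion") {
    a <- breakpoint; b <- breakpoint + event_length
    if (!allow_ambiguous) {
      # forbid left shift (ref[a] == ref[b]) and right shift (ref[a+1] == ref[b+1])
      if (ref[a] == ref[b]) ref[b] <- sample(setdiff(bases, ref[a]), 1)
      if (b + 1 <= ref_length && ref[a + 1] == ref[b + 1]) {
        ref[a + 1] <- sample(setdiff(bases, c(ref[b + 1], ref[b])), 1)
      }
    }
    query <- ref[-(seq(a + 1, b))]
    ins_seq <- NULL
    truth <- list(type = "deletion", ref_anchor = as.integer(a),
                  ref_end = as.integer(b),
                  length = as.integer(event_length), inserted_sequence = NULL)
    excluded <- seq(a + 1, b)
  } else {
    a <- breakpoint
    ins <- sample(bases, event_length, replace = TRUE)
    if (!allow_ambiguous) {
      if (ins[event_length] == ref[a]) {
        ins[event_length] <- sample(setdiff(bases, ref[a]), 1)
      }
      if (a + 1 <= ref_length && ins[1] == ref[a + 1]) {
        ins[1] <- sample(setdiff(bases, c(ref[a + 1],
                                          if (event_length == 1) ref[a])), 1)
      }
    }
    query <- append(ref, ins, after = a)
    ins_seq <- paste(ins, collapse = "")
    truth <- list(type = "insertion", ref_anchor = as.integer(a),
                  ref_end = as.integer(a),
                  length = as.integer(event_length),
                  inserted_sequence = ins_seq)
    excluded <- integer(0)
  }

  subs <- tibble::tibble(ref_pos = integer(0), ref_base = character(0),
                         alt_base = character(0))
  if (n_substitutions > 0) {
    # keep substitutions clear of the event and of sequence ends so they can
    # never merge with the indel in an alignment
    margin <- 2L
    candidates <- setdiff(seq(margin + 1L, ref_length - margin),
                          c(excluded, seq(max(1, breakpoint - margin),
                                          min(ref_length, (if (event == "deletion")
                                            breakpoint + event_length else breakpoint) + margin))))
    if (length(candidates) < n_substitutions) {
      rlang::abort("not enough room outside the event for the requested substitutions",
                   class = "gbsdiv_config_error")
    }
    pos <- sort(sample(candidates, n_substitutions))
    ref_to_query <- function(p) {
      if (event == "deletion") ifelse(p > breakpoint + event_length,
                                      p - event_length, p)
      else ifelse(p > breakpoint, p + event_length, p)
    }
    for (p in pos) {
      newb <- sample(setdiff(bases, ref[p]), 1)
      query[ref_to_query(p)] <- newb
      subs <- dplyr::bind_rows(subs, tibble::tibble(
        ref_pos = p, ref_base = ref[p], alt_base = newb))
    }
  }
  truth$substitutions <- subs

  list(reference = tibble::tibble(id = "ref", seq = paste(ref, collapse = "")),
       query = tibble::tibble(id = "query", seq = paste(query, collapse = "")),
       truth = truth)
}

#' Simulate short FASTQ reads with a controlled quality profile
#'
#' Emulates 77-bp GBS reads. The profile is a data frame with one row per
#' read class and columns `weight` (relative class size), `q_high`,
#' `frac_high` (fraction of bases, rounded down, set to `q_high`) and
#' `q_low` (quality of the remaining bases). Class counts are apportioned
#' deterministically by largest remainder, so pass/fail counts under a
#' threshold rule are exact ground truth; read order is then shuffled.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bases (default 77).
#' @param quality_profile Data frame as described; default: all bases Q40.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `seq`, `qual` and `class` (profile row
#'   index each read was generated from).
#' @export
simulate_fastq <- function(n_reads, read_length = 77,
                           quality_profile = data.frame(weight = 1, q_high = 40,
                                                        frac_high = 1, q_low = 40),
                           seed = 1L) {
  qp <- quality_profile
  if (any(qp$q_high < 0 | qp$q_high > 41 | qp$q_low < 0 | qp$q_low > 41)) {
    rlang::abort("Phred scores must be in [0, 41]", class = "gbsdiv_config_error")
  }
  set.seed(seed)
  w <- qp$weight / sum(qp$weight)
  n_class <- floor(w * n_reads)
  rem <- n_reads - sum(n_class)
  if (rem > 0) {
    frac <- w * n_reads - floor(w * n_reads)
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_class[add] <- n_class[add] + 1L
  }
  class_of <- sample(rep(seq_len(nrow(qp)), times = n_class))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_reads), function(i) {
    paste(sample(bases, read_length, replace = TRUE), collapse = "")
  }, character(1))
  quals <- vapply(seq_len(n_reads), function(i) {
    cl <- class_of[i]
    q <- rep.int(qp$q_low[cl], read_length)
    n_hi <- floor(qp$frac_high[cl] * read_length)
    if (n_hi > 0) q[sample(read_length, n_hi)] <- qp$q_high[cl]
    intToUtf8(q + 33L)
  }, character(1))
  tibble::tibble(id = sprintf("read_%06d", seq_len(n_reads)),
                 seq = seqs, qual = quals, class = class_of)
}
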