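test_that("the affix method finds single deletions leftmost-normalized", {
  ic <- detect_single_indel("ACGTACGTAA", "ACGGTAA")
  expect_identical(ic$type, "deletion")
  expect_identical(ic$ref_anchor, 3L)
  expect_identical(ic$ref_end, 6L)
  expect_identical(ic$length, 3L)

  # homopolymer: every placement equivalent, anchor must be the smallest
  h <- detect_single_indel("AAAAA", "AAA")
  expect_identical(h$ref_anchor, 0L)
  expect_identical(h$ref_end, 2L)

  ins <- detect_single_indel("ACGT", "ACGGGT")
  expect_identical(ins$type, "insertion")
  expect_identical(ins$length, 2L)
  expect_identical(ins$ref_anchor, ins$ref_end)
})

test_that("non-single-indel pairs are rejected with guidance", {
  expect_error(detect_single_indel("ACGT", "ACGT"),
               class = "gbsdiv_no_event_error")
  expect_error(detect_single_indel("ACGT", "AGGT"),
               class = "gbsdiv_not_single_indel_error")
  # substitution plus deletion cannot be explained by one event
  expect_error(detect_single_indel("ACGTACGT", "AGGTACG"),
               class = "gbsdiv_not_single_indel_error")
})

test_that("detection recovers generator truth over random indel geometries", {
  for (s in 1:20) {
    set.seed(s)
    ev <- sample(c("deletion", "insertion"), 1)
    len <- sample(1:40, 1)
    bp <- sample(5:150, 1)
    pair <- simulate_indel_pair(200, ev, len, bp, seed = 500 + s)
    ic <- detect_single_indel(pair$reference, pair$query)
    expect_identical(ic$type, pair$truth$type)
    expect_identical(ic$ref_anchor, pair$truth$ref_anchor)
    expect_identical(ic$ref_end, pair$truth$ref_end)
    expect_identical(ic$length, pair$truth$length)
    if (ev == "insertion") {
      expect_identical(ic$inserted_sequence, pair$truth$inserted_sequence)
    }
  }
})

test_that("alignment-based calling agrees with the affix method on single indels", {
  for (s in 1:8) {
    pair <- simulate_indel_pair(400, if (s %% 2) "deletion" else "insertion",
                                sample(1:30, 1), sample(10:300, 1),
                                seed = 700 + s)
    affix <- detect_single_indel(pair$reference, pair$query)
    rep_ <- align_and_call(pair$reference, pair$query)
    expect_identical(nrow(rep_$indels), 1L)
    expect_identical(nrow(rep_$substitutions), 0L)
    expect_identical(rep_$indels$type, affix$type)
    expect_identical(rep_$indels$ref_anchor, affix$ref_anchor)
    expect_identical(rep_$indels$length, affix$length)
  }
})

test_that("alignment calling reports exact event multisets from the generator", {
  pair <- simulate_indel_pair(2500, "insertion", 300, 900,
                              n_substitutions = 3, seed = 42)
  rep_ <- align_and_call(pair$reference, pair$query)
  expect_identical(nrow(rep_$indels), 1L)
  expect_identical(rep_$indels$type, "insertion")
  expect_identical(rep_$indels$length, 300L)
  expect_identical(rep_$indels$ref_anchor, 900L)
  expect_identical(rep_$indels$inserted_sequence,
                   pair$truth$inserted_sequence)
  expect_equal(rep_$substitutions, pair$truth$substitutions)

  # substitution-only pair
  p2 <- simulate_indel_pair(600, "deletion", 0, 100, seed = 9)
  q <- strsplit(p2$query$seq, "")[[1]]
  q[c(50, 200)] <- vapply(q[c(50, 200)],
                          function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  r2 <- align_and_call(p2$reference, paste(q, collapse = ""))
  expect_identical(nrow(r2$indels), 0L)
  expect_identical(r2$substitutions$ref_pos, c(50L, 200L))

  # identical pair -> empty report
  r3 <- align_and_call(p2$reference, p2$reference)
  expect_identical(nrow(r3$indels), 0L)
  expect_identical(nrow(r3$substitutions), 0L)
})

test_that("swapping reference and query mirrors deletions into insertions", {
  pair <- simulate_indel_pair(300, "deletion", 12, 80, seed = 77)
  fwd <- detect_single_indel(pair$reference, pair$query)
  rev <- detect_single_indel(pair$query, pair$reference)
  expect_identical(fwd$type, "deletion")
  expect_identical(rev$type, "insertion")
  expect_identical(rev$length, fwd$length)
  # the re-inserted content equals the deleted reference segment
  refv <- strsplit(pair$reference$seq, "")[[1]]
  deleted <- paste(refv[(fwd$ref_anchor + 1):fwd$ref_end], collapse = "")
  expect_identical(rev$inserted_sequence, deleted)
})

test_that("nested deletion comparison returns the extension arithmetic", {
  novel <- detect_single_indel(
    simulate_indel_pair(10000, "deletion", 5997, 1807, seed = 1)$reference,
    simulate_indel_pair(10000, "deletion", 5997, 1807, seed = 1)$query)
  known <- list(type = "deletion", ref_anchor = 1860L, ref_end = 7364L,
                length = 5504L)
  cmp <- compare_deletion_intervals(novel, known)
  expect_identical(cmp$upstream_extension_bp, 53L)
  expect_identical(cmp$downstream_extension_bp, 440L)
  expect_identical(cmp$additional_bp, 493L)

  same <- compare_deletion_intervals(novel, novel)
  expect_identical(unlist(same), c(upstream_extension_bp = 0L,
                                   downstream_extension_bp = 0L,
                                   additional_bp = 0L))

  # random nested pairs: additional = upstream + downstream always
  set.seed(3)
  for (i in 1:50) {
    a <- sample(1:100, 1); b <- a + sample(10:200, 1)
    ka <- a + sample(0:5, 1); kb <- b - sample(0:5, 1)
    if (kb <= ka) next
    nv <- list(type = "deletion", ref_anchor = a, ref_end = b, length = b - a)
    kn <- list(type = "deletion", ref_anchor = ka, ref_end = kb,
               length = kb - ka)
    cc <- compare_deletion_intervals(nv, kn)
    expect_identical(cc$additional_bp,
                     cc$upstream_extension_bp + cc$downstream_extension_bp)
  }

  # partial overlap is an error with an overlap breakdown
  err <- expect_error(compare_deletion_intervals(
    list(type = "deletion", ref_anchor = 10L, ref_end = 50L, length = 40L),
    list(type = "deletion", ref_anchor = 40L, ref_end = 80L, length = 40L)),
    class = "gbsdiv_not_nested_error")
  expect_match(conditionMessage(err), "overlap")
})

test_that("allele classification matches catalog signatures exactly", {
  pair <- simulate_indel_pair(3000, "insertion", 890, 1200, seed = 55)
  rep_ <- align_and_call(pair$reference, pair$query)
  catalog <- tibble::tibble(
    label = c("Vrn-B3b", "Vrn-A1f"),
    type = c("insertion", "deletion"),
    length = c(890L, 5997L),
    pos_min = c(1000L, 1800L), pos_max = c(1400L, 1820L),
    sequence = c(pair$truth$inserted_sequence, NA))
  expect_identical(classify_allele(rep_, catalog), "Vrn-B3b")

  # same length, one mismatching inserted base -> novel
  cat2 <- catalog
  seqv <- strsplit(cat2$sequence[1], "")[[1]]
  seqv[10] <- setdiff(c("A", "C", "G", "T"), seqv[10])[1]
  cat2$sequence[1] <- paste(seqv, collapse = "")
  expect_identical(classify_allele(rep_, cat2), "novel")

  # empty report -> reference label
  empty <- align_and_call(pair$reference, pair$reference)
  expect_identical(classify_allele(empty, catalog, reference_label = "vrn-B3"),
                   "vrn-B3")

  # ambiguous double match is an error listing candidates
  cat3 <- dplyr::bind_rows(catalog[1, ],
                           dplyr::mutate(catalog[1, ], label = "dup"))
  err <- expect_error(classify_allele(rep_, cat3),
                      class = "gbsdiv_ambiguous_error")
  expect_match(conditionMessage(err), "dup")
})
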