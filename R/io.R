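#' Read a genotype matrix from disk
#'
#' Two on-disk dialects are supported. `"csv"` is a comma-separated table
#' whose header row holds marker ids, whose first column holds accession ids,
#' and whose cells are `0`, `1`, `NA` or empty (missing). `"hapmap-like"` is a
#' marker-per-row TSV with columns `marker`, `chrom`, `cM`, then one column
#' per accession with the same cell vocabulary; the embedded map can be
#' recovered with [read_marker_map()] semantics via the `map` attribute.
#'
#' Cells outside `{0, 1, NA, ""}` and duplicated accession or marker ids are
#' format errors that name the offending cell or id; nothing is silently
#' coerced.
#'
#' @param path File to read.
#' @param dialect `"csv"` (default) or `"hapmap-like"`.
#' @return A [geno_matrix()]. For the hapmap-like dialect the marker map is
#'   attached as attribute `"map"` (a tibble as from [read_marker_map()]).
#' @seealso [write_genotype_matrix()]
#' @export
read_genotype_matrix <- function(path, dialect = c("csv", "hapmap-like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "gbsdiv_format_error")
  }
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
    acc <- df[[1]]
    mk <- colnames(df)[-1]
    cells <- as.matrix(df[, -1, drop = FALSE])
    x <- parse_call_cells(cells, acc, mk, path)
    geno_matrix(x)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                            na.strings = NULL)
    need <- c("marker", "chrom", "cM")
    if (!all(need %in% colnames(df)[1:3])) {
      rlang::abort("hapmap-like file must start with columns marker, chrom, cM",
                   class = "gbsdiv_format_error")
    }
    acc <- colnames(df)[-(1:3)]
    cells <- t(as.matrix(df[, -(1:3), drop = FALSE]))
    x <- parse_call_cells(cells, acc, df$marker, path)
    g <- geno_matrix(x)
    attr(g, "map") <- make_marker_map(df$marker, df$chrom, as.numeric(df$cM))
    g
  }
}

parse_call_cells <- function(cells, accession_ids, marker_ids, path) {
  cells[cells %in% c("NA", "")] <- NA_character_
  ok <- is.na(cells) | cells %in% c("0", "1")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "%s: invalid cell '%s' at row %d (accession '%s'), column '%s'; expected 0, 1, NA or empty",
      path, cells[bad[1], bad[2]], bad[1], accession_ids[bad[1]],
      marker_ids[bad[2]]),
      class = "gbsdiv_format_error")
  }
  x <- matrix(as.integer(cells), nrow = length(accession_ids),
              dimnames = list(accession_ids, marker_ids))
  x
}

#' Write a genotype matrix as CSV
#'
#' Inverse of [read_genotype_matrix()] for the `"csv"` dialect; missing calls
#' are written as `NA`. `read(write(x)) == x` for any valid matrix.
#'
#' @param geno A [geno_matrix()] or coercible matrix.
#' @param path Output file.
#' @param header_lines Optional character vector of `#`-prefixed comment
#'   lines written before the table (used by the pipeline for provenance).
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(geno, path, header_lines = NULL) {
  geno <- as_geno_matrix(geno)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("accession", colnames(geno)), collapse = ","), con)
  body <- apply(unclass(geno), 1, function(r) paste(ifelse(is.na(r), "NA", r),
                                                    collapse = ","))
  writeLines(paste(rownames(geno), body, sep = ","), con)
  invisible(path)
}

make_marker_map <- function(marker, chrom, cM) {
  lg <- wheat_linkage_groups()
  bad <- setdiff(unique(chrom), lg)
  if (length(bad)) {
    rlang::abort(paste0("unknown linkage group(s): ", paste(bad, collapse = ", "),
                        " (expected 1A-7D)"),
                 class = "gbsdiv_format_error")
  }
  if (anyDuplicated(marker)) {
    rlang::abort(paste0("duplicated marker id(s) in map: ",
                        paste(unique(marker[duplicated(marker)]), collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  if (any(is.na(cM)) || any(cM < 0)) {
    rlang::abort("cM positions must be numeric and >= 0",
                 class = "gbsdiv_format_error")
  }
  tibble::tibble(marker = marker, chrom = chrom, cM = cM,
                 subgenome = substr(chrom, nchar(chrom), nchar(chrom)))
}

#' Read a marker map
#'
#' TSV with header columns `marker`, `chrom` (one of the 21 wheat linkage
#' groups 1A-7D) and `cM`. The subgenome (A/B/D) is derived from the last
#' character of the linkage group.
#'
#' @param path File to read.
#' @return Tibble with columns `marker`, `chrom`, `cM`, `subgenome`.
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("marker", "chrom", "cM")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    rlang::abort(paste0("marker map is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  make_marker_map(df$marker, df$chrom, suppressWarnings(as.numeric(df$cM)))
}

#' Read a group assignment table
#'
#' TSV with header columns `accession` and `group` (germplasm set or
#' country). Accessions absent from a genotype matrix are allowed at read
#' time; consistency is checked when tables are joined in an analysis.
#'
#' @param path File to read.
#' @return Tibble with columns `accession`, `group`.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  miss <- setdiff(c("accession", "group"), colnames(df))
  if (length(miss)) {
    rlang::abort(paste0("group table is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  if (anyDuplicated(df$accession)) {
    rlang::abort(paste0("duplicated accession id(s) in groups: ",
                        paste(unique(df$accession[duplicated(df$accession)]),
                              collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  if (!nrow(df)) {
    rlang::abort("group table is empty", class = "gbsdiv_format_error")
  }
  tibble::as_tibble(df[c("accession", "group")])
}

#' Write a group assignment table
#' @param groups Tibble with columns `accession`, `group`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a marker map
#' @param map Tibble as returned by [read_marker_map()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map[c("marker", "chrom", "cM")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA
#'
#' Thin tidy wrappers over Biostrings. Sequences are returned as a tibble of
#' `id`, `desc` and `seq` (uppercase DNA, alphabet ACGTN enforced).
#'
#' @param path File to read or write.
#' @return `read_fasta()`: tibble with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(ss))
  check_dna_alphabet(seqs, names(ss))
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  tibble::tibble(id = id, desc = desc, seq = unname(seqs))
}

check_dna_alphabet <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) {
      rlang::abort(paste0("empty sequence for record '", ids[i], "'"),
                   class = "gbsdiv_format_error")
    }
    bad <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    if (length(bad) && nzchar(bad)) {
      pos <- regexpr("[^ACGTN]", seqs[i])
      rlang::abort(sprintf(
        "record '%s': non-DNA symbol '%s' at position %d (alphabet ACGTN)",
        ids[i], bad, pos), class = "gbsdiv_format_error")
    }
  }
  invisible(seqs)
}

#' @rdname read_fasta
#' @param records Tibble with columns `id`, `seq` and optionally `desc`.
#' @export
write_fasta <- function(records, path) {
  seqs <- toupper(records$seq)
  check_dna_alphabet(seqs, records$id)
  ss <- Biostrings::DNAStringSet(seqs)
  desc <- if ("desc" %in% names(records)) records$desc else ""
  names(ss) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Read and write FASTQ (Sanger Phred+33)
#'
#' Reads are returned as a tibble of `id`, `seq` and `qual` (the raw
#' Phred+33 quality string). Per-base integer scores are available through
#' [phred_scores()]. A record whose quality string length differs from its
#' sequence length is a format error.
#'
#' @param path File to read or write.
#' @return `read_fastq()`: tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(ss)$qualities)
  out <- tibble::tibble(id = sub("\\s.*$", "", names(ss)),
                        seq = unname(as.character(ss)),
                        qual = unname(qual))
  bad <- which(nchar(out$seq) != nchar(out$qual))
  if (length(bad)) {
    rlang::abort(sprintf(
      "FASTQ record '%s': sequence length %d != quality length %d",
      out$id[bad[1]], nchar(out$seq[bad[1]]), nchar(out$qual[bad[1]])),
      class = "gbsdiv_format_error")
  }
  out
}

#' @rdname read_fastq
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad)) {
    rlang::abort(sprintf(
      "FASTQ record '%s': sequence length %d != quality length %d",
      reads$id[bad[1]], nchar(reads$seq[bad[1]]), nchar(reads$qual[bad[1]])),
      class = "gbsdiv_format_error")
  }
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Per-base Phred scores of FASTQ reads
#'
#' @param reads Tibble as returned by [read_fastq()] or [simulate_fastq()].
#' @return List of integer vectors, one per read (Phred+33 decoding).
#' @export
phred_scores <- function(reads) {
  lapply(reads$qual, function(q) utf8ToInt(q) - 33L)
}

#' Read and write Newick trees
#'
#' Wrappers over ape preserving topology, branch lengths and internal-node
#' support labels. Unrooted trees are serialized with a trifurcating root,
#' the convention neighbor joining produces.
#'
#' @param tree An `ape::phylo` object.
#' @param path File to read or write.
#' @return `read_newick()`: an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
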