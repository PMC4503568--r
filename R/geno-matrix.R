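#' Genotype matrix for inbred biallelic panels
#'
#' A `geno_matrix` is an integer matrix of accessions (rows) by markers
#' (columns) holding calls in `{0, 1, NA}`. Accessions are treated as fully
#' inbred, so each cell is a single homozygous call: 0 for the
#' major/reference allele, 1 for the alternate, `NA` for missing. Row and
#' column names are the accession and marker identifiers and must be unique.
#'
#' @param calls Integer (or coercible) matrix with values in `{0, 1, NA}`.
#' @param accession_ids,marker_ids Optional character vectors overriding the
#'   dimnames of `calls`.
#'
#' @return An object of class `geno_matrix` (an integer matrix).
#' @examples
#' g <- geno_matrix(rbind(acc1 = c(m1 = 0L, m2 = 1L),
#'                        acc2 = c(m1 = 1L, m2 = NA)))
#' dim(g)
#' @export
geno_matrix <- function(calls, accession_ids = NULL, marker_ids = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!is.null(accession_ids)) rownames(calls) <- accession_ids
  if (!is.null(marker_ids)) colnames(calls) <- marker_ids
  validate_geno_matrix(calls)
  structure(calls, class = c("geno_matrix", class(unclass(calls))))
}

validate_geno_matrix <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L) {
    rlang::abort("genotype matrix needs at least 1 accession and 1 marker",
                 class = "gbsdiv_format_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    rlang::abort("genotype matrix must carry accession and marker ids as dimnames",
                 class = "gbsdiv_format_error")
  }
  dup_acc <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_acc)) {
    rlang::abort(paste0("duplicated accession id(s): ",
                        paste(unique(dup_acc), collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  dup_mk <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_mk)) {
    rlang::abort(paste0("duplicated marker id(s): ",
                        paste(unique(dup_mk), collapse = ", ")),
                 class = "gbsdiv_format_error")
  }
  bad <- which(!(x %in% c(0L, 1L)) & !is.na(x), arr.ind = TRUE)
  if (nrow(bad)) {
    rlang::abort(sprintf(
      "invalid genotype call %s at accession '%s', marker '%s' (only 0, 1, NA allowed)",
      x[bad[1, 1], bad[1, 2]], rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]),
      class = "gbsdiv_format_error")
  }
  invisible(x)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d accessions x %d markers, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  n <- min(6L, nrow(x)); m <- min(8L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) class(out) <- c("geno_matrix", class(out))
  out
}

# coerce a plain matrix coming from user code, with validation
as_geno_matrix <- function(x) {
  if (inherits(x, "geno_matrix")) return(x)
  geno_matrix(x)
}

#' The 21 bread-wheat linkage groups
#'
#' Chromosomes 1A-7D of hexaploid wheat; the last character names the
#' subgenome (A, B or D).
#'
#' @return Character vector of length 21.
#' @export
wheat_linkage_groups <- function() {
  paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
}
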