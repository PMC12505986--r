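# Alignment container: a thin S3 wrapper around a named character vector of
# equal-length gapped rows. FASTA I/O goes through Biostrings.

#' Construct an alignment object
#'
#' @param rows named character vector of equal-length gapped sequences
#'   (gap symbol \code{"-"}; \code{X} is tolerated and counted as a mismatch).
#' @return an object of class \code{stator_alignment}
#' @export
alignment <- function(rows) {
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stopf("alignment rows must be named by sequence id")
  if (anyDuplicated(names(rows)))
    stopf("duplicate sequence ids in alignment")
  rows <- stats::setNames(toupper(as.character(rows)), names(rows))
  w <- unique(nchar(rows))
  if (length(rows) > 0 && length(w) != 1)
    stopf("alignment rows have unequal lengths: %s", paste(w, collapse = ", "))
  structure(list(rows = rows, length = if (length(rows)) w else 0L),
            class = "stator_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA file (amino acids, gaps as '-')
#' @return a \code{stator_alignment}
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  alignment(stats::setNames(as.character(ss), names(ss)))
}

#' Write an alignment to FASTA
#'
#' @param aln a \code{stator_alignment}
#' @param path output path
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.stator_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              length(x$rows), x$length))
  invisible(x)
}

# character matrix view (rows = sequences, cols = alignment columns)
#' @keywords internal
#' @noRd
aln_matrix <- function(aln) {
  if (length(aln$rows) == 0) return(matrix(character(), 0, 0))
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  m
}
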