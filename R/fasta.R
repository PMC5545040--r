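# FASTA input/output. Sequences are kept verbatim (including case: lowercase
# marks softmasked repeat sequence) as a character column of a tibble, so an
# assembly pipes straight into dplyr verbs. Biostrings does the parsing.

#' Read an assembly from FASTA
#'
#' Reads a (multi-)FASTA file into an assembly tibble with one row per
#' scaffold. Sequences are preserved verbatim, including lowercase softmasking.
#' Duplicate headers and non-IUPAC characters are errors.
#'
#' @param path path to a FASTA file.
#' @param name assembly label stored in the `assembly` attribute (defaults to
#'   the file name without extension).
#' @return a tibble with columns `scaffold` and `sequence`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTNNNNACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicated FASTA header(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- as.character(ss)
  bad <- stringr::str_locate(seqs, "[^ACGTUMRWSYKVHDBNacgtumrwsykvhdbn]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop(sprintf("non-IUPAC character in record '%s' at position %d",
                 ids[i], bad[i]), call. = FALSE)
  }
  out <- tibble(scaffold = unname(ids), sequence = unname(seqs))
  attr(out, "assembly") <- name %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  out
}

#' Write an assembly to FASTA
#'
#' @param assembly assembly tibble (`scaffold`, `sequence`).
#' @param path output file.
#' @param width line width for wrapping (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 80L) {
  assert_assembly(assembly)
  ss <- Biostrings::BStringSet(setNames(assembly$sequence, assembly$scaffold))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct an assembly tibble from named sequences
#'
#' Convenience constructor used heavily in examples and tests.
#'
#' @param ... named character scalars, one per scaffold.
#' @param name optional assembly label.
#' @return an assembly tibble.
#' @examples
#' assembly(s1 = "ACGT", s2 = strrep("A", 10))
#' @export
assembly <- function(..., name = NULL) {
  seqs <- c(...)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  out <- tibble(scaffold = names(seqs), sequence = unname(seqs))
  attr(out, "assembly") <- name
  out
}
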