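#' Sequence file input and output
#'
#' Thin tidy wrappers around Biostrings readers/writers. FASTA is wrapped at
#' 60 columns on output; FASTQ qualities are Phred+33. Paths may be plain or
#' gzipped.
#'
#' @param path File path (`.gz` accepted).
#' @return `read_fasta()` returns a tibble with columns `id`, `sequence`;
#'   `read_fastq()` a tibble with columns `id`, `seq`, `qual`.
#' @name sequence_io
NULL

#' @rdname sequence_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble(id = sub("\\s.*$", "", names(x)), sequence = unname(as.character(x)))
}

#' @rdname sequence_io
#' @param genomes Tibble with columns `id`, `sequence`.
#' @export
write_fasta <- function(genomes, path) {
  x <- Biostrings::DNAStringSet(genomes$sequence)
  names(x) <- genomes$id
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 60L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
}

#' @rdname sequence_io
#' @param reads Tibble with columns `id`, `seq`, `qual` (Phred+33 strings).
#' @export
write_fastq <- function(reads, path) {
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("sequence and quality strings differ in length",
          class = "palaeomito_error_consistency")
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::PhredQuality(reads$qual)
  # Biostrings warns about dropping mcols even when there are none to drop
  withCallingHandlers(
    {
      xq <- Biostrings::QualityScaledDNAStringSet(x, q)
      Biostrings::writeQualityScaledXStringSet(xq, path,
                                               compress = grepl("\\.gz$", path))
    },
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  invisible(path)
}

#' Newick tree input and output
#'
#' @param path File path.
#' @param tree An `ape::phylo` object.
#' @return `read_newick()` returns an `ape::phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort("could not parse Newick file", class = "palaeomito_error_parse")
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# phred helpers: integer scores <-> Phred+33 strings
phred_to_string <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(x) as.integer(charToRaw(x)) - 33L)
}
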