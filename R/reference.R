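#' Circular reference frame
#'
#' A circular mitochondrial reference: a named base string over `{A,C,G,T,N}`
#' together with its length. All coordinates in the package are 1-based and
#' inclusive in this frame, and position arithmetic wraps modulo the length,
#' so position `length + 1` is position 1.
#'
#' @param sequence Single base string over `A`, `C`, `G`, `T`, `N`
#'   (lower case accepted and upper-cased).
#' @param name Text label for the frame.
#' @return An object of class `circular_reference` with elements `name`,
#'   `sequence` and `length`.
#' @examples
#' ref <- circular_reference("ACGTACGT", name = "toy")
#' ref$length
#' @export
circular_reference <- function(sequence, name = "ref") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    abort("reference sequence must be non-empty", class = "palaeomito_error_config")
  }
  if (grepl("[^ACGTN]", sequence)) {
    abort("reference sequence may contain only A, C, G, T, N",
          class = "palaeomito_error_parse")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "circular_reference"
  )
}

#' @export
print.circular_reference <- function(x, ...) {
  cat(sprintf("<circular_reference '%s': %s bp>\n", x$name,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Wrap positions onto a circular frame
#'
#' Maps arbitrary integer positions onto `1..frame_length`, so that
#' `frame_length + 1` becomes 1 and 0 becomes `frame_length`.
#'
#' @param pos Integer vector of (possibly out-of-range) 1-based positions.
#' @param frame_length Length of the circular frame.
#' @return Integer vector in `1..frame_length`.
#' @export
wrap_positions <- function(pos, frame_length) {
  ((as.integer(pos) - 1L) %% as.integer(frame_length)) + 1L
}

# circular substring: start 1-based, may run past the origin
circular_substring <- function(sequence, start, len) {
  L <- nchar(sequence)
  start <- wrap_positions(start, L)
  doubled <- paste0(sequence, substr(sequence, 1L, min(L, max(len))))
  substring(doubled, start, start + len - 1L)
}

#' Reverse complement
#'
#' @param x Character vector of base strings (may contain `N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reference bases that the deterministic fixture is constrained to carry,
# so that the printed-style variant labels and the bundled haplogroup tree
# always have matching reference alleles
fixture_constraints <- function() {
  c(
    # alleles required by the worked variant lists
    `408` = "T", `2581` = "A", `3591` = "G", `4824` = "A", `10822` = "C",
    `11279` = "C", `11431` = "C", `11884` = "A", `16086` = "T", `16261` = "C",
    `16355` = "C", `16399` = "A",
    # alleles required by the bundled mini haplogroup tree
    `1000` = "A", `2000` = "C", `3000` = "G", `4000` = "T", `5000` = "A",
    `6000` = "C", `7000` = "A", `8000` = "G", `9000` = "T"
  )
}

#' Deterministic 16,569-bp reference fixture
#'
#' Generates the bundled mitochondrial-scale reference frame: a fixed-seed
#' random base sequence of length 16,569 with human-mtDNA-like base
#' composition, constrained so that every variant label used by the bundled
#' fixtures and the mini haplogroup tree has a matching reference allele.
#' This is a synthetic stand-in frame, not the rCRS; a real rCRS FASTA can be
#' supplied wherever a `circular_reference` is accepted.
#'
#' @return A [circular_reference] of length 16,569 named `"fixture_ref"`.
#' @examples
#' ref <- fixture_reference()
#' substr(ref$sequence, 10822, 10822) # "C"
#' @export
fixture_reference <- function() {
  bases <- withr::with_seed(16569L, {
    sample(c("A", "C", "G", "T"), 16569L, replace = TRUE,
           prob = c(0.31, 0.31, 0.13, 0.25))
  })
  cons <- fixture_constraints()
  bases[as.integer(names(cons))] <- unname(cons)
  circular_reference(paste(bases, collapse = ""), name = "fixture_ref")
}
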