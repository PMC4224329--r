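#' Parse and format variant labels
#'
#' Substitution variants use the field's printed notation
#' `<ref><position><alt>`, e.g. `"C10822A"` for a C-to-A change at position
#' 10822 of the reference frame. [parse_variant()] is vectorized and returns
#' a tidy variant table; [format_variant()] is its exact inverse.
#'
#' @param label Character vector of variant labels.
#' @param frame_length Optional frame length; positions outside
#'   `1..frame_length` are rejected.
#' @return A tibble with columns `position` (integer), `ref`, `alt`
#'   (single bases) and `label`.
#' @examples
#' parse_variant(c("C10822A", "C16355T"))
#' @export
parse_variant <- function(label, frame_length = NULL) {
  label <- as.character(label)
  m <- stringr::str_match(label, "^([ACGT])([0-9]+)([ACGT])$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0L) {
    abort(sprintf("malformed variant label: '%s'", label[bad[1]]),
          class = "palaeomito_error_parse")
  }
  position <- as.integer(m[, 3])
  if (any(position < 1L)) {
    abort("variant position must be >= 1", class = "palaeomito_error_range")
  }
  if (!is.null(frame_length) && any(position > frame_length)) {
    p <- position[position > frame_length][1]
    abort(sprintf("variant position %d outside reference frame of length %d",
                  p, frame_length),
          class = "palaeomito_error_range")
  }
  same <- m[, 2] == m[, 4]
  if (any(same)) {
    abort(sprintf("degenerate variant '%s': ref equals alt", label[which(same)[1]]),
          class = "palaeomito_error_parse")
  }
  tibble(position = position, ref = m[, 2], alt = m[, 4],
         label = paste0(m[, 2], position, m[, 4]))
}

#' @rdname parse_variant
#' @param variants A variant tibble as returned by [parse_variant()].
#' @export
format_variant <- function(variants) {
  paste0(variants$ref, variants$position, variants$alt)
}

#' Genome records
#'
#' Genomes are stored as tidy one-row-per-genome tibbles with columns `id`
#' and `sequence`; every sequence has the length of its reference frame
#' (substitution-only model, `N` allowed).
#'
#' @param id Character vector of genome ids.
#' @param sequence Character vector of base strings.
#' @return A tibble with columns `id`, `sequence`.
#' @export
genome_record <- function(id, sequence) {
  tibble(id = as.character(id), sequence = toupper(as.character(sequence)))
}

#' Apply substitution variants to a genome
#'
#' Returns a genome differing from the input at exactly the variant
#' positions, carrying each variant's alternate base there. The genome's
#' current base must equal each variant's reference base; a mismatch is a
#' consistency error reporting position, expected and found base.
#'
#' @param genome A one-row genome tibble ([genome_record()]) or a single
#'   base string.
#' @param variants A variant tibble from [parse_variant()] (may be empty).
#' @param id Optional new id for the returned genome record.
#' @return Same shape as `genome` with the substitutions applied.
#' @examples
#' g <- genome_record("anc", "ACGT")
#' apply_variants(g, parse_variant("C2T"))$sequence # "ATGT"
#' @export
apply_variants <- function(genome, variants, id = NULL) {
  as_string <- is.character(genome)
  seq <- if (as_string) genome else genome$sequence
  stopifnot(length(seq) == 1L)
  if (nrow(variants) > 0L) {
    if (any(variants$position > nchar(seq))) {
      abort("variant position outside genome", class = "palaeomito_error_range")
    }
    found <- substring(seq, variants$position, variants$position)
    bad <- which(found != variants$ref)
    if (length(bad) > 0L) {
      b <- bad[1]
      abort(sprintf("reference mismatch at position %d: expected %s, found %s",
                    variants$position[b], variants$ref[b], found[b]),
            class = "palaeomito_error_consistency")
    }
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[variants$position] <- variants$alt
    seq <- paste(chars, collapse = "")
  }
  if (as_string) return(seq)
  out <- genome
  out$sequence <- seq
  if (!is.null(id)) out$id <- id
  out
}

#' Reverse a variant set
#'
#' Swaps `ref` and `alt` so that applying the result undoes
#' [apply_variants()].
#'
#' @param variants A variant tibble.
#' @return A variant tibble with `ref`/`alt` exchanged and labels rebuilt.
#' @export
invert_variants <- function(variants) {
  out <- tibble(position = variants$position, ref = variants$alt,
                alt = variants$ref)
  out$label <- format_variant(out)
  out
}

#' Read and write variant-list TSV files
#'
#' One variant label per line, no header; plain or gzipped.
#'
#' @param path File path.
#' @param variants A variant tibble.
#' @return `read_variant_tsv()` returns a variant tibble;
#'   `write_variant_tsv()` returns `path` invisibly.
#' @export
read_variant_tsv <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(parse_variant(character(0)))
  parse_variant(lines)
}

#' @rdname read_variant_tsv
#' @export
write_variant_tsv <- function(variants, path) {
  readr::write_lines(variants$label, path)
  invisible(path)
}
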