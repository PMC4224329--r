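#' Align reads to a circular reference
#'
#' Ungapped (substitution-only) placement of short reads on a circular
#' reference. Candidate placements come from an exact k-mer seed index
#' (default k = 12) over the wrap-extended reference, supplemented by a
#' shorter seed (default 7) so that heavily deaminated reads, whose long
#' k-mers may all carry damage, remain alignable; every candidate offset is
#' then scored exhaustively on both strands. Damage-aware scoring reduces
#' the penalty of damage-consistent mismatches (reference C read as T,
#' reference G read as A, in the orientation scored); because complementing
#' maps C-to-T onto G-to-A, the same rule serves both strands. Ties are
#' broken deterministically: higher score, then plus before minus strand,
#' then the smallest start coordinate.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (as from
#'   [simulate_reads()] or [read_fastq()]).
#' @param ref A [circular_reference] (or base string).
#' @param k Primary seed length.
#' @param k_supp Supplementary seed length (`0` disables the supplement).
#' @param damage_aware `"half"` (damage-consistent mismatches cost half the
#'   mismatch penalty; default), `"off"` (full penalty) or `"full"` (no
#'   penalty).
#' @param match,mismatch Match reward and mismatch penalty per base.
#' @param min_score_frac Minimum best score, as a fraction of
#'   `match * read length`, for a placement to be reported; below it the
#'   read is unaligned.
#' @return A tibble with one row per input read: `id`, `aligned`,
#'   `ref_start`, `ref_end` (1-based inclusive, wrapping), `strand`,
#'   `length`, `score`, `n_mismatch`, and the reference-frame base and
#'   quality strings `seq_ref`, `qual_ref` (reverse-complemented /
#'   reversed for minus-strand placements).
#' @examples
#' ref <- circular_reference(strrep("ACGTTGCA", 40))
#' rd <- tibble::tibble(id = "r1", seq = substr(ref$sequence, 11, 40),
#'                      qual = strrep("I", 30))
#' align_reads(rd, ref)
#' @export
align_reads <- function(reads, ref, k = 12L, k_supp = 7L,
                        damage_aware = c("half", "off", "full"),
                        match = 1, mismatch = 1, min_score_frac = 0.25) {
  damage_aware <- match.arg(damage_aware)
  ref_seq <- if (inherits(ref, "circular_reference")) ref$sequence else ref
  L <- nchar(ref_seq)
  if (k < 4L || k > 13L) abort("k must be in [4, 13]", class = "palaeomito_error_config")
  dpen <- switch(damage_aware, half = mismatch / 2, off = mismatch, full = 0)
  hit <- align_reads_cpp(reads$seq, ref_seq, k = as.integer(k),
                         k_supp = as.integer(k_supp),
                         match = match, mismatch = mismatch,
                         damage_mismatch = dpen,
                         min_score_frac = min_score_frac)
  len <- nchar(reads$seq)
  out <- tibble(
    id = reads$id,
    aligned = hit$aligned,
    ref_start = hit$ref_start,
    ref_end = ifelse(hit$aligned, wrap_positions(hit$ref_start + len - 1L, L),
                     NA_integer_),
    strand = as.character(hit$strand),
    length = len,
    score = hit$score,
    n_mismatch = hit$n_mismatch,
    seq_ref = reads$seq,
    qual_ref = reads$qual
  )
  minus <- which(out$aligned & out$strand == "-")
  if (length(minus) > 0L) {
    out$seq_ref[minus] <- revcomp(out$seq_ref[minus])
    out$qual_ref[minus] <- reverse_strings(out$qual_ref[minus])
  }
  out
}

reverse_strings <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

#' Aligned molecules ready for consensus calling
#'
#' @param alignments Output of [align_reads()].
#' @return The aligned rows only.
#' @export
aligned_molecules <- function(alignments) {
  dplyr::filter(alignments, .data$aligned)
}
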