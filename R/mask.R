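#' Region masks
#'
#' A region mask is a tibble of 1-based inclusive intervals (`start`, `end`)
#' on a reference frame; singleton intervals (`start == end`) are allowed.
#' [region_mask()] normalizes its input: intervals are sorted, validated
#' (`start <= end`) and overlapping or adjacent-duplicate positions merged,
#' so the masked-position count is exactly `sum(end - start + 1)`.
#'
#' @param start,end Integer vectors of equal length (1-based, inclusive).
#' @return A tibble with columns `start`, `end`, class `region_mask`.
#' @examples
#' default_hotspot_mask()
#' masked_length(16569, default_hotspot_mask())
#' @export
region_mask <- function(start = integer(0), end = integer(0)) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    abort("start and end must have equal length", class = "palaeomito_error_config")
  }
  if (any(is.na(start) | is.na(end)) || any(start < 1L)) {
    abort("mask intervals must be positive and non-missing",
          class = "palaeomito_error_range")
  }
  if (any(end < start)) {
    bad <- which(end < start)[1]
    abort(sprintf("mask interval %d has end < start (%d < %d)", bad, end[bad], start[bad]),
          class = "palaeomito_error_range")
  }
  out <- tibble(start = start, end = end)
  out <- normalize_mask(out)
  class(out) <- c("region_mask", class(out))
  out
}

# merge sorted overlapping/adjacent intervals; idempotent
normalize_mask <- function(mask) {
  if (nrow(mask) == 0L) return(mask[, c("start", "end")])
  mask <- dplyr::arrange(mask, .data$start, .data$end)
  s <- mask$start; e <- mask$end
  ks <- integer(0); ke <- integer(0)
  cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ce + 1L) {
      ce <- max(ce, e[i])
    } else {
      ks <- c(ks, cs); ke <- c(ke, ce)
      cs <- s[i]; ce <- e[i]
    }
  }
  tibble(start = c(ks, cs), end = c(ke, ce))
}

#' @rdname region_mask
#' @details [default_hotspot_mask()] returns the standard mitochondrial
#'   hypermutable-region mask used for phylogenetic comparison: the two
#'   poly-C runs at 303-315 and 16182-16194, the AC repeat at 515-525, and
#'   the hotspot site 16519 (stored as a singleton interval).
#' @export
default_hotspot_mask <- function() {
  region_mask(start = c(303L, 515L, 16182L, 16519L),
              end = c(315L, 525L, 16194L, 16519L))
}

#' Coding-region window of the mitochondrial frame
#'
#' The coding-region window used for region-restricted comparison, fixed at
#' positions 577-16023 inclusive (the standard mtDNA coding span outside the
#' control region).
#'
#' @return Integer vector `c(start, end)`.
#' @export
coding_region_window <- function() c(577L, 16023L)

#' Count unmasked positions
#'
#' Number of positions of a frame (or of a window within it) that are not
#' covered by a mask. With the default hotspot mask on a 16,569-position
#' frame this is 16,531 genome-wide and 15,447 in the coding window.
#'
#' @param frame_length Length of the (linearized) coordinate frame.
#' @param mask A [region_mask()].
#' @param window Optional `c(start, end)` 1-based inclusive window.
#' @return Integer count of unmasked positions.
#' @examples
#' masked_length(16569, default_hotspot_mask())                 # 16531
#' masked_length(16569, default_hotspot_mask(), c(577, 16023))  # 15447
#' @export
masked_length <- function(frame_length, mask = region_mask(), window = NULL) {
  frame_length <- as.integer(frame_length)
  if (nrow(mask) > 0L && (min(mask$start) < 1L || max(mask$end) > frame_length)) {
    abort("mask interval outside [1, frame_length]", class = "palaeomito_error_range")
  }
  if (is.null(window)) window <- c(1L, frame_length)
  window <- as.integer(window)
  if (window[1] < 1L || window[2] > frame_length || window[1] > window[2]) {
    abort("window outside frame", class = "palaeomito_error_range")
  }
  total <- window[2] - window[1] + 1L
  if (nrow(mask) == 0L) return(total)
  ov_start <- pmax(mask$start, window[1])
  ov_end <- pmin(mask$end, window[2])
  covered <- sum(pmax(0L, ov_end - ov_start + 1L))
  total - as.integer(covered)
}

#' Positions covered by a mask
#'
#' @param mask A [region_mask()].
#' @return Sorted integer vector of all masked positions.
#' @export
mask_positions <- function(mask) {
  if (nrow(mask) == 0L) return(integer(0))
  sort(unique(unlist(Map(seq.int, mask$start, mask$end))))
}

#' Read and write mask TSV files
#'
#' Masks are stored as two-column headerless TSV (`start<TAB>end`), plain or
#' gzipped.
#'
#' @param path File path (`.gz` accepted).
#' @param mask A [region_mask()].
#' @return `read_mask_tsv()` returns a [region_mask()]; `write_mask_tsv()`
#'   returns `path` invisibly.
#' @export
read_mask_tsv <- function(path) {
  df <- readr::read_tsv(path, col_names = c("start", "end"),
                        col_types = readr::cols(readr::col_integer(), readr::col_integer()),
                        progress = FALSE)
  region_mask(df$start, df$end)
}

#' @rdname read_mask_tsv
#' @export
write_mask_tsv <- function(mask, path) {
  readr::write_tsv(tibble(start = mask$start, end = mask$end), path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
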