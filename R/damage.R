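#' Substitution-frequency damage profile
#'
#' Tabulates, for every aligned molecule and every position within `window`
#' bases of each fragment end, the reference base X and the read base Y, and
#' reports the frequency of each of the 12 possible substitutions X-to-Y as
#' a function of distance from the 5' and from the 3' end. Frequencies are
#' the proportion of reads carrying the alternate allele Y among reads whose
#' reference allele is X at that distance. Minus-strand molecules are
#' oriented read-wise before tabulation (their 5' end is the alignment's
#' right edge and bases are complemented), so profiles reflect molecule
#' ends, not reference orientation. Authentic ancient DNA shows elevated
#' C-to-T near the 5' end and G-to-A near the 3' end.
#'
#' @param molecules Tibble of aligned molecules (post-collapse by default in
#'   the pipeline; any [align_reads()] output works).
#' @param ref Reference the profile is computed against: the final consensus
#'   by default in the pipeline (so true variants do not inflate apparent
#'   damage), or the initial reference for a classical profile. A
#'   [circular_reference] or base string.
#' @param window Number of positions from each end to profile (default 25).
#' @return A tibble of class `damage_profile` with columns `end`
#'   (`"5p"`/`"3p"`), `distance` (1..window), `sub` (e.g. `"C>T"`), `count`,
#'   `denominator` and `frequency` (`NA` where the denominator is zero);
#'   always `2 * window * 12` rows.
#' @export
damage_profile <- function(molecules, ref, window = 25L) {
  window <- as.integer(window)
  if (window < 1L) abort("window must be >= 1", class = "palaeomito_error_config")
  ref_seq <- if (inherits(ref, "circular_reference")) ref$sequence else ref
  L <- nchar(ref_seq)
  bases <- c("A", "C", "G", "T")
  subs <- outer(bases, bases, paste, sep = ">")
  subs <- sort(subs[outer(bases, bases, "!=")])

  grid <- tidyr::expand_grid(end = c("5p", "3p"), distance = seq_len(window),
                             sub = subs)
  grid$count <- 0L
  grid$denominator <- 0L

  if (nrow(molecules) > 0L) {
    lens <- molecules$length
    refctx <- circular_substring(ref_seq, molecules$ref_start, lens)
    # length of each context must equal molecule length
    refctx <- substring(refctx, 1L, lens)
    read_b <- molecules$seq_ref
    minus <- molecules$strand == "-"
    if (any(minus)) {
      read_b[minus] <- revcomp(read_b[minus])
      refctx[minus] <- revcomp(refctx[minus])
    }
    rb <- unlist(strsplit(read_b, "", fixed = TRUE), use.names = FALSE)
    xb <- unlist(strsplit(refctx, "", fixed = TRUE), use.names = FALSE)
    ridx <- rep.int(seq_len(nrow(molecules)), lens)
    d5 <- sequence(lens)
    d3 <- lens[ridx] - d5 + 1L
    ok <- xb %in% bases & rb %in% bases

    tab_end <- function(dist) {
      keep <- ok & dist <= window
      x <- factor(xb[keep], levels = bases)
      y <- factor(rb[keep], levels = bases)
      d <- factor(dist[keep], levels = seq_len(window))
      denom <- table(x, d)
      cnt <- table(x, y, d)
      list(denom = denom, cnt = cnt)
    }
    t5 <- tab_end(d5)
    t3 <- tab_end(d3)
    for (i in seq_len(nrow(grid))) {
      parts <- strsplit(grid$sub[i], ">", fixed = TRUE)[[1]]
      t <- if (grid$end[i] == "5p") t5 else t3
      grid$count[i] <- as.integer(t$cnt[parts[1], parts[2], grid$distance[i]])
      grid$denominator[i] <- as.integer(t$denom[parts[1], grid$distance[i]])
    }
  }
  grid$frequency <- ifelse(grid$denominator > 0L,
                           grid$count / grid$denominator, NA_real_)
  attr(grid, "window") <- window
  class(grid) <- c("damage_profile", class(grid))
  grid
}

#' Summarize terminal deamination
#'
#' Reports the C-to-T frequency at distance 1 from the 5' end, the G-to-A
#' frequency at distance 1 from the 3' end, their averages over distances
#' 1-3, and an "aDNA-consistent" flag set when both distance-1 frequencies
#' reach `threshold`. Authentic ancient libraries typically show terminal
#' deamination well above 10%, and degraded samples can exceed 35%.
#'
#' @param profile A [damage_profile()].
#' @param threshold Minimum distance-1 frequency on both ends for the flag
#'   (default 0.10).
#' @return One-row tibble: `ct5_d1`, `ga3_d1`, `ct5_d1to3`, `ga3_d1to3`,
#'   `adna_consistent`.
#' @export
terminal_damage_summary <- function(profile, threshold = 0.10) {
  cell <- function(e, s, d) {
    dplyr::filter(profile, .data$end == e, .data$sub == s,
                  .data$distance %in% d)
  }
  ct1 <- cell("5p", "C>T", 1L)
  ga1 <- cell("3p", "G>A", 1L)
  if (ct1$denominator == 0L || ga1$denominator == 0L) {
    abort("no distance-1 observations: insufficient data",
          class = "palaeomito_error_insufficient")
  }
  ct13 <- cell("5p", "C>T", 1:3)
  ga13 <- cell("3p", "G>A", 1:3)
  ct5_d1 <- ct1$frequency
  ga3_d1 <- ga1$frequency
  tibble(
    ct5_d1 = ct5_d1,
    ga3_d1 = ga3_d1,
    ct5_d1to3 = sum(ct13$count) / sum(ct13$denominator),
    ga3_d1to3 = sum(ga13$count) / sum(ga13$denominator),
    adna_consistent = ct5_d1 >= threshold && ga3_d1 >= threshold
  )
}

#' Read and write damage-profile TSV files
#'
#' Columns `end`, `distance`, `sub_type`, `count`, `denominator`,
#' `frequency`; lossless round trip.
#'
#' @param profile A [damage_profile()].
#' @param path File path.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- tibble(end = profile$end, distance = profile$distance,
                sub_type = profile$sub, count = profile$count,
                denominator = profile$denominator,
                frequency = profile$frequency)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = "cicnnn", progress = FALSE)
  out <- tibble(end = df$end, distance = as.integer(df$distance),
                sub = df$sub_type, count = as.integer(df$count),
                denominator = as.integer(df$denominator),
                frequency = df$frequency)
  attr(out, "window") <- max(out$distance)
  class(out) <- c("damage_profile", class(out))
  out
}

#' Plot a damage profile
#'
#' Draws the 12 substitution-frequency curves against distance from each
#' fragment end, with the deamination-diagnostic C-to-T (5') and G-to-A
#' (3') curves emphasized.
#'
#' @param object A [damage_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.damage_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$diagnostic <- (df$end == "5p" & df$sub == "C>T") |
    (df$end == "3p" & df$sub == "G>A")
  df$end <- factor(df$end, levels = c("5p", "3p"),
                   labels = c("distance from 5' end", "distance from 3' end"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$frequency,
                                   group = .data$sub, colour = .data$diagnostic,
                                   linewidth = .data$diagnostic)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3, `TRUE` = 0.9),
                                    guide = "none") +
    ggplot2::facet_wrap(~end) +
    ggplot2::labs(x = "distance from fragment end (nt)",
                  y = "substitution frequency") +
    ggplot2::theme_minimal()
}
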