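#' Find diagnostic positions against a modern panel
#'
#' A diagnostic position is a site where at least `threshold` of the non-`N`
#' panel bases agree on one base and that base differs from the sample's
#' (non-`N`) base. Reads covering such sites reveal modern-human
#' contamination: a read carrying the sample base is "clean", one carrying
#' the panel-consensus base is "contaminating".
#'
#' @param sample A one-row genome tibble ([genome_record()]) or base string.
#' @param panel Tibble of panel genomes (`id`, `sequence`), all in the
#'   sample's coordinate frame.
#' @param threshold Minimum panel agreement (default 0.99, i.e. "at least
#'   99% of the panel").
#' @return A tibble of class `diagnostic_panel`: `position`, `sample_base`,
#'   `contaminant_base`, `panel_agreement`; attribute `panel_size`.
#' @export
find_diagnostic_positions <- function(sample, panel, threshold = 0.99) {
  sample_seq <- if (is.character(sample)) sample else sample$sequence
  stopifnot(length(sample_seq) == 1L)
  if (is.null(panel) || nrow(panel) == 0L) {
    abort("panel must contain at least one genome", class = "palaeomito_error_config")
  }
  L <- nchar(sample_seq)
  if (any(nchar(panel$sequence) != L)) {
    abort("panel genomes must share the sample's frame",
          class = "palaeomito_error_consistency")
  }
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, bases))
  for (s in panel$sequence) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (b in bases) counts[, b] <- counts[, b] + (ch == b)
  }
  non_n <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  top_count <- counts[cbind(seq_len(L), top)]
  agreement <- ifelse(non_n > 0L, top_count / non_n, 0)
  samp <- strsplit(sample_seq, "", fixed = TRUE)[[1]]
  is_diag <- non_n > 0L & agreement >= threshold & samp %in% bases &
    bases[top] != samp
  out <- tibble(position = which(is_diag),
                sample_base = samp[is_diag],
                contaminant_base = bases[top[is_diag]],
                panel_agreement = agreement[is_diag])
  attr(out, "panel_size") <- nrow(panel)
  attr(out, "threshold") <- threshold
  class(out) <- c("diagnostic_panel", class(out))
  out
}

#' Count clean and contaminating observations at diagnostic positions
#'
#' Each (molecule, covered diagnostic position) pair contributes one
#' observation: "clean" if the molecule carries the diagnostic sample base
#' there, "contaminant" if it matches the panel-consensus base, "other" if
#' it carries `N` or a third base (excluded from the estimate's
#' denominator). A molecule covering several diagnostic positions
#' contributes one observation per position.
#'
#' @param molecules Tibble of aligned molecules in the sample frame.
#' @param panel A [find_diagnostic_positions()] result (or tibble with
#'   `position`, `sample_base`, `contaminant_base`).
#' @param frame_length Length of the circular frame.
#' @return One-row tibble: `n_clean`, `n_contaminant`, `n_other`.
#' @export
count_diagnostic_reads <- function(molecules, panel, frame_length) {
  L <- as.integer(frame_length)
  n_clean <- 0L; n_cont <- 0L; n_other <- 0L
  if (nrow(molecules) > 0L && nrow(panel) > 0L) {
    for (i in seq_len(nrow(panel))) {
      p <- panel$position[i]
      off <- (p - molecules$ref_start) %% L  # circular offset into molecule
      covers <- off < molecules$length
      if (!any(covers)) next
      obs <- substring(molecules$seq_ref[covers], off[covers] + 1L,
                       off[covers] + 1L)
      n_clean <- n_clean + sum(obs == panel$sample_base[i])
      n_cont <- n_cont + sum(obs == panel$contaminant_base[i])
      n_other <- n_other + sum(obs != panel$sample_base[i] &
                               obs != panel$contaminant_base[i])
    }
  }
  tibble(n_clean = n_clean, n_contaminant = n_cont, n_other = n_other)
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form score interval for `k` successes in `n` trials at the given
#' confidence: with `p = k/n` and `z` the standard-normal quantile,
#' `bounds = (p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`,
#' clipped to `[0, 1]`. The upper endpoint behaves sensibly at `k = 0`,
#' making it the conventional conservative bound for contamination rates.
#'
#' @param k Number of successes (contaminating observations).
#' @param n Number of trials (informative observations); must be >= 1.
#' @param confidence Confidence level (default 0.95).
#' @return `wilson_upper()`/`wilson_lower()` return a single proportion;
#'   `wilson_interval()` a one-row tibble `lower`, `upper`.
#' @examples
#' round(100 * wilson_upper(4, 1678), 1)  # 0.6 (%)
#' round(100 * wilson_upper(0, 391), 0)   # 1  (%)
#' @export
wilson_upper <- function(k, n, confidence = 0.95) {
  wilson_interval(k, n, confidence)$upper
}

#' @rdname wilson_upper
#' @export
wilson_lower <- function(k, n, confidence = 0.95) {
  wilson_interval(k, n, confidence)$lower
}

#' @rdname wilson_upper
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (any(n < 1)) {
    abort("n must be >= 1: estimate undefined", class = "palaeomito_error_undefined")
  }
  if (any(k < 0) || any(k > n)) {
    abort("k must lie in [0, n]", class = "palaeomito_error_range")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  tibble(lower = pmax(0, (centre - half) / denom),
         upper = pmin(1, (centre + half) / denom))
}

#' Estimate contamination from diagnostic positions
#'
#' Composes [count_diagnostic_reads()] and the Wilson score interval: the
#' point estimate is `n_contaminant / (n_clean + n_contaminant)` (third-base
#' and `N` observations are excluded from the denominator) and the interval
#' endpoints are the Wilson score bounds at the given confidence. The upper
#' endpoint is the conservative contamination bound.
#'
#' @inheritParams count_diagnostic_reads
#' @param confidence Confidence level for the Wilson interval.
#' @return A one-row tibble of class `contam_estimate`: `n_clean`,
#'   `n_contaminant`, `n_other`, `point`, `wilson_low`, `wilson_high`,
#'   `confidence`.
#' @export
estimate_contamination <- function(molecules, panel, frame_length,
                                   confidence = 0.95) {
  cnt <- count_diagnostic_reads(molecules, panel, frame_length)
  n_inf <- cnt$n_clean + cnt$n_contaminant
  if (n_inf == 0L) {
    abort("no informative observations at diagnostic positions",
          class = "palaeomito_error_undefined")
  }
  ci <- wilson_interval(cnt$n_contaminant, n_inf, confidence)
  out <- tibble(n_clean = cnt$n_clean, n_contaminant = cnt$n_contaminant,
                n_other = cnt$n_other,
                point = cnt$n_contaminant / n_inf,
                wilson_low = ci$lower, wilson_high = ci$upper,
                confidence = confidence)
  class(out) <- c("contam_estimate", class(out))
  out
}

#' @rdname estimate_contamination
#' @param x A `contam_estimate`.
#' @param ... Ignored.
#' @exportS3Method generics::glance
glance.contam_estimate <- function(x, ...) as_tibble(unclass2(x))

#' @rdname estimate_contamination
#' @exportS3Method generics::tidy
tidy.contam_estimate <- function(x, ...) {
  tibble(class = c("clean", "contaminant", "other"),
         n = c(x$n_clean, x$n_contaminant, x$n_other))
}

unclass2 <- function(x) {
  class(x) <- setdiff(class(x), c("contam_estimate", "diagnostic_panel",
                                  "damage_profile"))
  x
}
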