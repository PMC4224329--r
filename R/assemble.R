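#' Collapse PCR duplicates into unique molecules
#'
#' Reads sharing start and end coordinate (and strand) are treated as PCR
#' duplicates of one original fragment and collapsed to a single
#' representative. At each position the representative carries the base of
#' the duplicate with the highest quality there (ties: the base that sorts
#' first among `A < C < G < T`; `N` never outranks a called base) and the
#' quality of that winning observation. Idempotent: collapsing twice equals
#' collapsing once.
#'
#' @param molecules Tibble of aligned molecules (see [align_reads()]); must
#'   all be on one reference frame.
#' @return A tibble of the same shape with one row per distinct
#'   `(ref_start, ref_end, strand)` key, plus a column `n_dup` giving the
#'   number of reads collapsed into each molecule.
#' @export
collapse_unique_molecules <- function(molecules) {
  if (nrow(molecules) == 0L) {
    return(dplyr::mutate(molecules, n_dup = integer(0)))
  }
  key <- paste(molecules$ref_start, molecules$ref_end, molecules$strand,
               sep = "\r")
  groups <- split(seq_len(nrow(molecules)), key)
  rep_idx <- vapply(groups, `[[`, integer(1), 1L)
  out <- molecules[rep_idx, , drop = FALSE]
  out$n_dup <- unname(lengths(groups))

  multi <- which(lengths(groups) > 1L)
  for (g in multi) {
    idx <- groups[[g]]
    bmat <- do.call(rbind, strsplit(molecules$seq_ref[idx], "", fixed = TRUE))
    qmat <- do.call(rbind, string_to_phred(molecules$qual_ref[idx]))
    qmat[bmat == "N"] <- -1L  # N never beats a called base
    best_b <- character(ncol(bmat))
    best_q <- integer(ncol(bmat))
    for (j in seq_len(ncol(bmat))) {
      qj <- qmat[, j]
      top <- max(qj)
      if (top < 0L) { best_b[j] <- "N"; best_q[j] <- 0L; next }
      cand <- bmat[qj == top, j]
      best_b[j] <- min(cand)
      best_q[j] <- top
    }
    row <- which(rep_idx == idx[1])
    out$seq_ref[row] <- paste(best_b, collapse = "")
    out$qual_ref[row] <- phred_to_string(list(best_q))
  }
  dplyr::arrange(out, .data$ref_start, .data$ref_end, .data$strand)
}

#' Call a consensus genome from unique molecules
#'
#' At each reference position the qualities of all molecules carrying each
#' base are summed and the base with the highest summed quality is called;
#' ties go to the current reference base if it is among the tied bases,
#' otherwise to the base sorting first. Positions covered by fewer than
#' `min_depth` molecules (non-`N` observations) are reported as `N`.
#'
#' @param molecules Tibble of (collapsed) aligned molecules.
#' @param ref_length Length of the circular frame.
#' @param min_depth Minimum unique-molecule depth for a call (default 2,
#'   the conventional floor for ancient-genome consensus positions).
#' @param ref Optional current reference base string used for tie-breaking.
#' @return A `consensus_genome` list: `sequence` (base string, `N` where
#'   unresolved), `depth` (per-position molecule count) and `support`
#'   (per-position summed quality of the called base).
#' @export
call_consensus <- function(molecules, ref_length, min_depth = 2L, ref = NULL) {
  L <- as.integer(ref_length)
  depth <- integer(L)
  support <- numeric(L)
  seq_out <- rep("N", L)
  if (nrow(molecules) > 0L) {
    chars <- unlist(strsplit(molecules$seq_ref, "", fixed = TRUE),
                    use.names = FALSE)
    quals <- unlist(string_to_phred(molecules$qual_ref), use.names = FALSE)
    lens <- molecules$length
    ridx <- rep.int(seq_len(nrow(molecules)), lens)
    pos <- wrap_positions(molecules$ref_start[ridx] + sequence(lens) - 1L, L)
    bcode <- match(chars, c("A", "C", "G", "T"))
    keep <- !is.na(bcode)
    pos <- pos[keep]; bcode <- bcode[keep]; quals <- quals[keep]

    depth <- tabulate(pos, nbins = L)
    cell <- (pos - 1L) * 4L + bcode
    agg <- rowsum(as.numeric(quals), cell)
    cells <- as.integer(rownames(agg))
    m <- matrix(0, nrow = L, ncol = 4L)
    m[cbind((cells - 1L) %/% 4L + 1L, (cells - 1L) %% 4L + 1L)] <- agg[, 1]
    support <- pmax(m[, 1], m[, 2], m[, 3], m[, 4])
    call_idx <- max.col(m, ties.method = "first")  # lexicographic on ties
    if (!is.null(ref)) {
      rb <- match(strsplit(toupper(ref), "", fixed = TRUE)[[1]],
                  c("A", "C", "G", "T"))
      tie_to_ref <- !is.na(rb) & m[cbind(seq_len(L), ifelse(is.na(rb), 1L, rb))] == support
      call_idx[tie_to_ref] <- rb[tie_to_ref]
    }
    seq_out <- c("A", "C", "G", "T")[call_idx]
    seq_out[depth < min_depth] <- "N"
    support[depth < min_depth] <- 0
  }
  structure(list(sequence = paste(seq_out, collapse = ""),
                 depth = depth, support = support),
            class = "consensus_genome")
}

#' @export
print.consensus_genome <- function(x, ...) {
  n_N <- sum(strsplit(x$sequence, "", fixed = TRUE)[[1]] == "N")
  cat(sprintf("<consensus_genome: %d bp, %d unresolved (N), mean depth %.1f>\n",
              nchar(x$sequence), n_N, mean(x$depth)))
  invisible(x)
}

#' Iterative reference-guided assembly of a circular mitochondrial genome
#'
#' Repeats align / collapse / call-consensus cycles, each round realigning
#' all reads against the previous round's consensus (with unresolved `N`
#' positions backfilled from the current reference so seeding is not
#' interrupted), until the consensus no longer changes between successive
#' iterations (positions that are `N` in either iterate are excluded from
#' the comparison) or `max_iter` is reached.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param initial_ref A [circular_reference] or base string to seed the
#'   first iteration.
#' @param min_depth Minimum unique-molecule depth for a consensus call.
#' @param max_iter Maximum number of align/consensus rounds.
#' @param ... Further arguments passed to [align_reads()] (e.g.
#'   `damage_aware`, `k`).
#' @return A `mito_assembly` list with elements `consensus`
#'   (a `consensus_genome`), `molecules` (the final collapsed alignment
#'   tibble) and `report` (one-row tibble: `n_input_reads`, `n_aligned`,
#'   `on_target_fraction`, `n_unique_molecules`, `mean_coverage` and
#'   `min_coverage` in unique molecules over called positions,
#'   `mean_raw_coverage` in reads, `n_iterations`, `converged`).
#' @examples
#' \donttest{
#' ref <- fixture_reference()
#' sim <- simulate_reads(sim_config(ref$sequence, n_reads = 4000, seed = 7),
#'                       damage = NULL)
#' asm <- iterative_assemble(sim$reads, ref)
#' glance(asm)
#' }
#' @export
iterative_assemble <- function(reads, initial_ref, min_depth = 2L,
                               max_iter = 10L, ...) {
  ref_seq <- if (inherits(initial_ref, "circular_reference"))
    initial_ref$sequence else initial_ref
  if (is.null(ref_seq) || !nzchar(ref_seq)) {
    abort("initial reference must be non-empty", class = "palaeomito_error_config")
  }
  L <- nchar(ref_seq)
  current <- ref_seq
  prev_called <- NULL
  converged <- FALSE
  iter <- 0L
  aln <- NULL
  mols <- NULL
  cons <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    aln <- align_reads(reads, current, ...)
    mols <- collapse_unique_molecules(aligned_molecules(aln))
    if (nrow(mols) == 0L) {
      abort("no reads aligned: empty assembly", class = "palaeomito_error_empty")
    }
    cons <- call_consensus(mols, L, min_depth = min_depth, ref = current)
    called <- strsplit(cons$sequence, "", fixed = TRUE)[[1]]
    if (!is.null(prev_called)) {
      comparable <- called != "N" & prev_called != "N"
      if (!any(called[comparable] != prev_called[comparable])) {
        converged <- TRUE
        break
      }
    }
    prev_called <- called
    # backfill N from the running reference so the next round can seed there
    cur_chars <- strsplit(current, "", fixed = TRUE)[[1]]
    nn <- called == "N"
    called[nn] <- cur_chars[nn]
    current <- paste(called, collapse = "")
  }

  called <- strsplit(cons$sequence, "", fixed = TRUE)[[1]]
  resolved <- called != "N"
  raw <- aligned_molecules(aln)
  report <- tibble(
    n_input_reads = nrow(reads),
    n_aligned = nrow(raw),
    on_target_fraction = nrow(raw) / nrow(reads),
    n_unique_molecules = nrow(mols),
    mean_coverage = if (any(resolved)) mean(cons$depth[resolved]) else 0,
    min_coverage = if (any(resolved)) min(cons$depth[resolved]) else 0L,
    mean_raw_coverage = sum(raw$length) / nchar(cons$sequence),
    n_iterations = iter,
    converged = converged
  )
  structure(list(consensus = cons, molecules = mols, report = report),
            class = "mito_assembly")
}

#' Assembly bookkeeping report
#'
#' Standalone constructor for the assembly report row, deriving
#' `on_target_fraction` as `n_aligned / n_input_reads`. Useful for
#' recomputing published-style read bookkeeping (e.g. 34,274 of 1,021,385
#' reads on target is 3.4%).
#'
#' @param n_input_reads,n_aligned Read counts.
#' @param n_unique_molecules,mean_coverage,min_coverage,mean_raw_coverage,n_iterations,converged
#'   Optional remaining report fields.
#' @return A one-row tibble with the same columns as
#'   [iterative_assemble()]'s report.
#' @examples
#' assembly_report(1021385, 34274)$on_target_fraction # 0.0336
#' @export
assembly_report <- function(n_input_reads, n_aligned,
                            n_unique_molecules = NA_integer_,
                            mean_coverage = NA_real_,
                            min_coverage = NA_real_,
                            mean_raw_coverage = NA_real_,
                            n_iterations = NA_integer_, converged = NA) {
  if (n_aligned > n_input_reads || n_aligned < 0) {
    abort("n_aligned must lie in [0, n_input_reads]",
          class = "palaeomito_error_range")
  }
  tibble(n_input_reads = n_input_reads, n_aligned = n_aligned,
         on_target_fraction = n_aligned / n_input_reads,
         n_unique_molecules = n_unique_molecules,
         mean_coverage = mean_coverage, min_coverage = min_coverage,
         mean_raw_coverage = mean_raw_coverage,
         n_iterations = n_iterations, converged = converged)
}

#' @export
print.mito_assembly <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<mito_assembly: %d/%d reads aligned (%.1f%%), ",
                     "%d unique molecules, mean depth %.1fx, ",
                     "%d iteration(s), converged: %s>\n"),
              r$n_aligned, r$n_input_reads, 100 * r$on_target_fraction,
              r$n_unique_molecules, r$mean_coverage, r$n_iterations,
              r$converged))
  invisible(x)
}

#' @rdname iterative_assemble
#' @param x A `mito_assembly`.
#' @exportS3Method generics::glance
glance.mito_assembly <- function(x, ...) x$report

#' @rdname iterative_assemble
#' @exportS3Method generics::tidy
tidy.mito_assembly <- function(x, ...) {
  tibble(position = seq_along(x$consensus$depth),
         base = strsplit(x$consensus$sequence, "", fixed = TRUE)[[1]],
         depth = x$consensus$depth,
         support = x$consensus$support)
}

#' Per-position coverage plot for an assembly
#'
#' @param object A `mito_assembly`.
#' @param ... Ignored.
#' @return A ggplot object showing unique-molecule depth along the genome.
#' @exportS3Method ggplot2::autoplot
autoplot.mito_assembly <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$report$mean_coverage,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "reference position", y = "unique-molecule depth") +
    ggplot2::theme_minimal()
}
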