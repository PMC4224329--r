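#' Terminal-deamination damage model
#'
#' Post-mortem cytosine deamination is concentrated at single-stranded
#' fragment ends: C-to-T substitutions near the 5' end and the complementary
#' G-to-A near the 3' end. The per-position substitution probability decays
#' exponentially with distance from the relevant end,
#' `p(d) = baseline + p_max * exp(-decay * (d - 1))`, the standard
#' single-strand-overhang approximation.
#'
#' @param p5_max C-to-T probability at the 5'-terminal position (distance 1).
#' @param p3_max G-to-A probability at the 3'-terminal position.
#' @param decay Per-base exponential decay rate (>= 0); 0 gives a flat
#'   profile.
#' @param baseline Background per-base substitution probability added at all
#'   distances.
#' @return A `damage_model` list.
#' @examples
#' damage_model(p5_max = 0.4, decay = 0.3)
#' @export
damage_model <- function(p5_max = 0.35, p3_max = p5_max, decay = 0.3,
                         baseline = 0.001) {
  probs <- c(p5_max = p5_max, p3_max = p3_max, baseline = baseline)
  if (any(probs < 0 | probs > 1)) {
    abort("damage probabilities must lie in [0, 1]", class = "palaeomito_error_config")
  }
  if (decay < 0) abort("decay must be >= 0", class = "palaeomito_error_config")
  if (baseline + max(p5_max, p3_max) > 1) {
    abort("baseline + p_max exceeds 1", class = "palaeomito_error_config")
  }
  structure(list(p5_max = p5_max, p3_max = p3_max, decay = decay,
                 baseline = baseline),
            class = "damage_model")
}

damage_prob <- function(dist, p_max, decay, baseline) {
  pmin(1, baseline + p_max * exp(-decay * (dist - 1)))
}

#' Read-simulation configuration
#'
#' Describes one simulated sequencing library: how many fragments, their
#' log-normal length distribution, the endogenous (and optionally
#' contaminant) source genome, the contamination fraction, the Phred quality
#' profile, and the seed. Fragment lengths are truncated to
#' `[20, reference length]`.
#'
#' @param endogenous,contaminant One-row genome tibbles ([genome_record()])
#'   or single base strings, in one shared coordinate frame.
#' @param n_reads Number of fragments to simulate.
#' @param mean_fragment_length,fragment_length_sd Fragment-length mean and
#'   standard deviation in bases (study-like libraries use means of 50 for
#'   the tooth and 56 for the rib).
#' @param contamination_fraction Probability that a fragment derives from
#'   the contaminant genome.
#' @param seed Integer seed; mandatory, drives independent per-stage
#'   generators (source assignment / fragmentation / damage / error) so that
#'   toggling one stage does not perturb the others.
#' @param quality_mean,quality_sd Per-base Phred score distribution
#'   (truncated to `[2, 40]`).
#' @param sequencing_error If `FALSE`, the quality-conditioned sequencing
#'   error stage is skipped (qualities are still assigned); used to study
#'   other stages in isolation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(endogenous, n_reads, seed,
                       mean_fragment_length = 50, fragment_length_sd = 15,
                       contamination_fraction = 0, contaminant = NULL,
                       quality_mean = 35, quality_sd = 3,
                       sequencing_error = TRUE) {
  endo <- if (is.character(endogenous)) endogenous else endogenous$sequence
  stopifnot(length(endo) == 1L)
  cont <- if (is.null(contaminant)) NULL
          else if (is.character(contaminant)) contaminant else contaminant$sequence
  if (contamination_fraction < 0 || contamination_fraction > 1) {
    abort("contamination_fraction must lie in [0, 1]", class = "palaeomito_error_config")
  }
  if (contamination_fraction > 0 && is.null(cont)) {
    abort("contaminant genome required when contamination_fraction > 0",
          class = "palaeomito_error_config")
  }
  if (!is.null(cont) && nchar(cont) != nchar(endo)) {
    abort("endogenous and contaminant genomes must share one frame",
          class = "palaeomito_error_config")
  }
  if (mean_fragment_length < 20) {
    abort("mean fragment length must be >= 20", class = "palaeomito_error_config")
  }
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("a seed is mandatory for simulation", class = "palaeomito_error_config")
  }
  structure(list(endogenous = endo, contaminant = cont,
                 n_reads = as.integer(n_reads),
                 mean_fragment_length = mean_fragment_length,
                 fragment_length_sd = fragment_length_sd,
                 contamination_fraction = contamination_fraction,
                 seed = as.integer(seed),
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 sequencing_error = isTRUE(sequencing_error)),
            class = "sim_config")
}

#' Simulate an ancient-DNA sequencing library
#'
#' Draws fragments uniformly from a circular genome (uniform start and
#' strand, log-normal lengths), applies terminal deamination damage on the
#' read strand (so minus-strand fragments show the complementary pattern
#' when viewed in reference orientation; contaminant fragments, being modern
#' DNA, are left undamaged), assigns per-base Phred qualities
#' and quality-conditioned sequencing error, and mixes in contaminant-source
#' fragments at the configured fraction. Fully deterministic at fixed seed.
#'
#' @param config A [sim_config()].
#' @param damage A [damage_model()]; `NULL` disables damage.
#' @return A list with `reads` (tibble `id`, `seq`, `qual`; FASTQ-writable
#'   via [write_fastq()]) and `truth` (tibble `id`, `source`, `start`,
#'   `end`, `strand`, `length`, `n_damaged`, `damaged_pos` list-column of
#'   damaged read positions, `n_error`).
#' @examples
#' ref <- fixture_reference()
#' cfg <- sim_config(ref$sequence, n_reads = 100, seed = 1)
#' sim <- simulate_reads(cfg, damage_model(0.35))
#' sim$reads
#' @export
simulate_reads <- function(config, damage = damage_model()) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(damage)) damage <- damage_model(0, 0, 0, 0)
  n <- config$n_reads
  L <- nchar(config$endogenous)
  stage_seed <- withr::with_seed(config$seed,
                                 sample.int(.Machine$integer.max - 1L, 4L))

  from_cont <- withr::with_seed(stage_seed[1],
                                runif(n) < config$contamination_fraction)

  frag <- withr::with_seed(stage_seed[2], {
    mu <- config$mean_fragment_length
    sd <- config$fragment_length_sd
    if (sd > 0) {
      sdlog <- sqrt(log1p((sd / mu)^2))
      meanlog <- log(mu) - sdlog^2 / 2
      len <- as.integer(round(rlnorm(n, meanlog, sdlog)))
    } else {
      len <- rep(as.integer(round(mu)), n)
    }
    len <- pmin(pmax(len, 20L), L)
    list(start = sample.int(L, n, replace = TRUE),
         len = len,
         strand = sample(c("+", "-"), n, replace = TRUE))
  })

  maxlen <- max(frag$len)
  doubled <- c(
    paste0(config$endogenous, substr(config$endogenous, 1L, maxlen)),
    if (!is.null(config$contaminant))
      paste0(config$contaminant, substr(config$contaminant, 1L, maxlen))
  )
  src_idx <- ifelse(from_cont, 2L, 1L)
  seqs <- substring(doubled[src_idx], frag$start, frag$start + frag$len - 1L)
  minus <- frag$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])

  # long representation: one row per base of every read
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  ridx <- rep.int(seq_len(n), frag$len)
  d5 <- sequence(frag$len)
  d3 <- frag$len[ridx] - d5 + 1L

  dmg <- withr::with_seed(stage_seed[3], {
    p5 <- damage_prob(d5, damage$p5_max, damage$decay, damage$baseline)
    p3 <- damage_prob(d3, damage$p3_max, damage$decay, damage$baseline)
    u <- runif(length(chars))
    # deamination is post-mortem: modern contaminant fragments stay undamaged
    endo_base <- !from_cont[ridx]
    ct <- chars == "C" & u < p5 & endo_base
    ga <- chars == "G" & u < p3 & endo_base
    list(ct = ct, ga = ga)
  })
  chars[dmg$ct] <- "T"
  chars[dmg$ga] <- "A"
  damaged <- dmg$ct | dmg$ga

  err <- withr::with_seed(stage_seed[4], {
    q <- as.integer(round(rnorm(length(chars), config$quality_mean,
                                config$quality_sd)))
    q <- pmin(pmax(q, 2L), 40L)
    p_err <- 10^(-q / 10)
    hit <- runif(length(chars)) < p_err & chars != "N" &
      config$sequencing_error
    sub <- rep(NA_character_, length(chars))
    if (any(hit)) {
      # uniform over the three alternative bases
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 3,
                    dimnames = list(NULL, c("A","C","G","T")))
      pick <- sample.int(3L, sum(hit), replace = TRUE)
      sub[hit] <- alt[cbind(pick, match(chars[hit], colnames(alt)))]
    }
    list(q = q, hit = hit, sub = sub)
  })
  chars[err$hit] <- err$sub[err$hit]

  # rebuild per-read strings from one concatenated buffer
  ends <- cumsum(frag$len)
  starts <- ends - frag$len + 1L
  big_seq <- paste(chars, collapse = "")
  big_qual <- rawToChar(as.raw(err$q + 33L))
  seq_out <- substring(big_seq, starts, ends)
  qual_out <- substring(big_qual, starts, ends)

  ids <- sprintf("read_%07d", seq_len(n))
  fr <- factor(ridx, levels = seq_len(n))
  damaged_pos <- unname(split(d5[damaged], fr[damaged]))
  reads <- tibble(id = ids, seq = seq_out, qual = qual_out)
  truth <- tibble(
    id = ids,
    source = ifelse(from_cont, "contaminant", "endogenous"),
    start = frag$start,
    end = wrap_positions(frag$start + frag$len - 1L, L),
    strand = frag$strand,
    length = frag$len,
    n_damaged = as.integer(lengths(damaged_pos)),
    damaged_pos = damaged_pos,
    n_error = as.integer(tabulate(ridx[err$hit], nbins = n))
  )
  list(reads = reads, truth = truth)
}
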