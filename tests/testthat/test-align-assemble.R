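test_that("exact substrings place at their true offset with full score", {
  ref <- circular_reference(random_genome(2000, 11), "toy")
  rd <- tibble::tibble(id = "r1",
                       seq = substr(ref$sequence, 101, 150),
                       qual = strrep("I", 50))
  hit <- align_reads(rd, ref)
  expect_true(hit$aligned)
  expect_equal(hit$ref_start, 101L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$score, 50)
  expect_equal(hit$n_mismatch, 0L)

  # reverse-complement read maps to the same span on the minus strand,
  # and its reference-frame bases equal the forward fragment
  rc <- tibble::tibble(id = "r2", seq = revcomp(rd$seq), qual = rd$qual)
  hit2 <- align_reads(rc, ref)
  expect_equal(hit2$ref_start, 101L)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$seq_ref, rd$seq)
})

test_that("reads spanning the origin wrap legally", {
  L <- fx$reference$length
  doubled <- paste0(fx$reference$sequence, fx$reference$sequence)
  rd <- tibble::tibble(id = "wrap",
                       seq = substr(doubled, 16550, 16550 + 49),
                       qual = strrep("I", 50))
  hit <- align_reads(rd, fx$reference)
  expect_true(hit$aligned)
  expect_equal(hit$ref_start, 16550L)
  expect_equal(hit$ref_end, 30L)
})

test_that("seeded alignment equals brute-force all-offset scoring", {
  ref <- random_genome(1500, 21)
  withr::with_seed(22, {
    for (case in 1:25) {
      len <- sample(20:30, 1)
      start <- sample(1500, 1)
      frag <- substr(paste0(ref, ref), start, start + len - 1)
      n_mut <- sample(0:3, 1)
      if (n_mut > 0) {
        ch <- strsplit(frag, "")[[1]]
        at <- sample(len, n_mut)
        ch[at] <- vapply(ch[at],
                         function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                         character(1))
        frag <- paste(ch, collapse = "")
      }
      if (runif(1) < 0.5) frag <- revcomp(frag)
      hit <- align_reads(tibble::tibble(id = "x", seq = frag,
                                        qual = strrep("I", len)), ref)
      oracle <- brute_force_align(frag, ref)
      expect_false(is.null(oracle))
      expect_true(hit$aligned)
      expect_equal(hit$ref_start, oracle$ref_start)
      expect_equal(hit$strand, oracle$strand)
      expect_equal(hit$score, oracle$score)
      expect_equal(hit$n_mismatch, oracle$n_mismatch)
    }
  })
})

test_that("damaged fixture reads recover their truth placement", {
  sthe <- fx_genome("StHe")
  sim <- simulate_reads(sim_config(sthe, n_reads = 5000, seed = 8),
                        damage_model(p5_max = 0.4, decay = 0.3))
  aln <- align_reads(sim$reads, sthe)
  mols <- aligned_molecules(aln)
  m <- match(mols$id, sim$truth$id)
  correct <- mols$ref_start == sim$truth$start[m] &
    mols$strand == sim$truth$strand[m]
  expect_gte(sum(correct) / nrow(sim$reads), 0.99)
})

test_that("duplicate collapsing keeps the highest-quality base per position", {
  base <- tibble::tibble(id = c("a", "b"), aligned = TRUE, ref_start = 10L,
                         ref_end = 13L, strand = "+", length = 4L,
                         score = 4, n_mismatch = 0L,
                         seq_ref = c("ACGT", "GCGT"),
                         qual_ref = c(palaeomito:::phred_to_string(list(c(30L, 20L, 20L, 20L))),
                                      palaeomito:::phred_to_string(list(c(20L, 30L, 20L, 20L)))))
  col <- collapse_unique_molecules(base)
  expect_equal(nrow(col), 1L)
  expect_equal(col$n_dup, 2L)
  expect_equal(col$seq_ref, "ACGT")  # A wins q30 > q20 at pos 1
  expect_equal(palaeomito:::string_to_phred(col$qual_ref)[[1]][1:2], c(30L, 30L))

  # distinct placements pass through; n copies collapse to one; idempotence
  distinct <- dplyr::mutate(base, ref_start = c(10L, 20L), ref_end = c(13L, 23L))
  expect_equal(nrow(collapse_unique_molecules(distinct)), 2L)
  many <- base[rep(1, 7), ]
  expect_equal(nrow(collapse_unique_molecules(many)), 1L)
  expect_equal(collapse_unique_molecules(col)$seq_ref, col$seq_ref)
  expect_equal(collapse_unique_molecules(col)$n_dup, 1L)
})

test_that("consensus calling uses summed-quality argmax with depth floor", {
  mk <- function(id, start, seq, quals) {
    tibble::tibble(id = id, aligned = TRUE, ref_start = start,
                   ref_end = start + nchar(seq) - 1L, strand = "+",
                   length = nchar(seq), score = 0, n_mismatch = 0L,
                   seq_ref = seq, qual_ref = palaeomito:::phred_to_string(list(quals)))
  }
  mols <- dplyr::bind_rows(
    mk("m1", 5L, "T", 30L), mk("m2", 5L, "T", 20L), mk("m3", 5L, "C", 40L))
  cons <- call_consensus(mols, 10L, min_depth = 2L)
  expect_equal(substr(cons$sequence, 5, 5), "T")  # 50 beats 40
  expect_equal(cons$depth[5], 3L)
  expect_equal(cons$support[5], 50)

  # single-molecule position falls below the depth floor
  cons1 <- call_consensus(mk("m", 3L, "ACG", c(30L, 30L, 30L)), 10L,
                          min_depth = 2L)
  expect_equal(cons1$sequence, strrep("N", 10))

  # no coverage at all
  cons0 <- call_consensus(mols[0, ], 8L)
  expect_equal(cons0$sequence, strrep("N", 8))
  expect_equal(cons0$depth, rep(0L, 8))
})

test_that("coverage is conserved through collapse and consensus", {
  sthe <- fx_genome("StHe")
  sim <- simulate_reads(sim_config(sthe, n_reads = 2000, seed = 14),
                        damage = NULL)
  mols <- collapse_unique_molecules(aligned_molecules(align_reads(sim$reads, sthe)))
  cons <- call_consensus(mols, nchar(sthe), min_depth = 1L)
  expect_equal(sum(cons$depth), sum(mols$length))
})

test_that("iterative assembly converges to the true genome", {
  ref <- fx$reference$sequence
  truegen <- withr::with_seed(55, {
    apply_variants(ref, palaeomito:::random_substitutions(
      ref, sort(sample(1000:16000, 10))))
  })
  sim <- simulate_reads(sim_config(truegen, n_reads = 8000, seed = 3,
                                   quality_mean = 40, quality_sd = 0,
                                   sequencing_error = FALSE), damage = NULL)
  asm <- iterative_assemble(sim$reads, ref)
  expect_true(asm$report$converged)
  expect_lte(asm$report$n_iterations, 3L)
  expect_identical(asm$consensus$sequence, truegen)
  expect_gte(asm$report$min_coverage, 2)
})

test_that("independent libraries from one genome agree where both are called", {
  sthe <- fx_genome("StHe")
  ref <- fx$reference$sequence
  dm <- damage_model(p5_max = 0.35, decay = 0.3)
  tooth <- simulate_reads(sim_config(sthe, n_reads = 12000, seed = 1001,
                                     mean_fragment_length = 50), dm)
  rib <- simulate_reads(sim_config(sthe, n_reads = 6150, seed = 1002,
                                   mean_fragment_length = 56), dm)
  asm_t <- iterative_assemble(tooth$reads, ref)
  asm_r <- iterative_assemble(rib$reads, ref)
  ct <- strsplit(asm_t$consensus$sequence, "")[[1]]
  cr <- strsplit(asm_r$consensus$sequence, "")[[1]]
  both <- ct != "N" & cr != "N"
  expect_gt(sum(both), 16000)
  expect_identical(ct[both], cr[both])
})

test_that("off-target reads are excluded and bookkeeping fractions add up", {
  sthe <- fx_genome("StHe")
  n_mito <- 200; n_junk <- 5800
  sim <- simulate_reads(sim_config(sthe, n_reads = n_mito, seed = 6), damage = NULL)
  junk <- withr::with_seed(60, {
    tibble::tibble(id = sprintf("junk_%04d", seq_len(n_junk)),
                   seq = vapply(seq_len(n_junk),
                                function(i) paste(sample(c("A","C","G","T"), 50,
                                                         replace = TRUE),
                                                  collapse = ""),
                                character(1)),
                   qual = strrep("I", 50))
  })
  reads <- dplyr::bind_rows(sim$reads, junk)
  asm <- iterative_assemble(reads, fx$reference$sequence, max_iter = 2L)
  frac <- asm$report$on_target_fraction
  expect_lt(abs(frac - n_mito / (n_mito + n_junk)), 0.005)
  expect_equal(asm$report$n_aligned / asm$report$n_input_reads, frac)
  expect_error(iterative_assemble(junk[1:5, ], fx$reference$sequence),
               class = "palaeomito_error_empty")
  expect_error(iterative_assemble(reads, ""), class = "palaeomito_error_config")
})
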