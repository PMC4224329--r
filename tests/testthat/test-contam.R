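test_that("Wilson bounds reproduce closed-form and score-test inversion", {
  # worked contamination bounds: 4/1678 -> 0.6%, 0/391 -> 1%
  expect_equal(round(100 * wilson_upper(4, 1678), 1), 0.6)
  expect_equal(round(100 * wilson_upper(0, 391), 0), 1)

  # independent oracle: invert the score test numerically
  score_upper <- function(k, n, conf = 0.95) {
    z <- qnorm(1 - (1 - conf) / 2)
    p_hat <- k / n
    f <- function(p) (p_hat - p) / sqrt(p * (1 - p) / n) + z
    stats::uniroot(f, c(p_hat + 1e-12, 1 - 1e-12), tol = 1e-14)$root
  }
  for (k in c(0, 1, 4, 17, 100)) {
    for (n in c(120, 391, 1678, 5000)) {
      expect_equal(wilson_upper(k, n), score_upper(k, n), tolerance = 1e-9)
    }
  }
  # cross-check against the score interval in stats::prop.test
  pt <- stats::prop.test(4, 1678, correct = FALSE)
  expect_equal(wilson_upper(4, 1678), unname(pt$conf.int[2]), tolerance = 1e-12)
  expect_equal(wilson_lower(4, 1678), unname(pt$conf.int[1]), tolerance = 1e-12)

  # boundary and monotonicity properties
  expect_equal(wilson_upper(10, 10), 1)
  ks <- 0:20
  up <- vapply(ks, wilson_upper, numeric(1), n = 100)
  expect_true(all(diff(up) > 0))
  ns <- c(50, 100, 500, 2000)
  up0 <- vapply(ns, function(n) wilson_upper(0, n), numeric(1))
  expect_true(all(diff(up0) < 0))
  expect_error(wilson_upper(1, 0), class = "palaeomito_error_undefined")
  expect_error(wilson_upper(5, 4), class = "palaeomito_error_range")
})

test_that("diagnostic positions are found against engineered panels", {
  sthe <- fx_genome("StHe")
  # identical panel -> nothing diagnostic
  same <- genome_record(paste0("p", 1:5), rep(sthe, 5))
  expect_equal(nrow(find_diagnostic_positions(sthe, same)), 0L)

  # a single engineered site across a 311-genome unanimous panel
  one_site <- apply_variants(sthe, tibble::tibble(
    position = 5000L, ref = substr(sthe, 5000, 5000),
    alt = setdiff(c("A", "C", "G", "T"), substr(sthe, 5000, 5000))[1],
    label = "x"))
  panel1 <- genome_record(paste0("p", 1:311), rep(one_site, 311))
  dp1 <- find_diagnostic_positions(sthe, panel1)
  expect_equal(dp1$position, 5000L)
  expect_equal(dp1$sample_base, substr(sthe, 5000, 5000))

  # noisy panel: 311 copies of the 32-site contaminant, 0.5% N-masked each,
  # recovers exactly the engineered diagnostic panel
  cont <- fx_genome("contaminant")
  noisy <- withr::with_seed(17, {
    vapply(1:311, function(i) {
      ch <- strsplit(cont, "")[[1]]
      ch[sample(length(ch), round(0.005 * length(ch)))] <- "N"
      paste(ch, collapse = "")
    }, character(1))
  })
  dp <- find_diagnostic_positions(sthe, genome_record(paste0("m", 1:311), noisy))
  expect_equal(nrow(dp), 32L)
  expect_equal(dp$position, sort(fx$contaminant_sites$position))
  expect_true(all(dp$panel_agreement >= 0.99))
  expect_true(all(dp$sample_base != dp$contaminant_base))

  expect_error(find_diagnostic_positions(sthe, genome_record(character(0), character(0))),
               class = "palaeomito_error_config")
})

test_that("diagnostic-read counting matches the published-style arithmetic", {
  panel <- tibble::tibble(position = 100L, sample_base = "A",
                          contaminant_base = "G")
  mk <- function(n, base) {
    tibble::tibble(id = sprintf("m%d", seq_len(n)), aligned = TRUE,
                   ref_start = 91L, ref_end = 110L, strand = "+", length = 20L,
                   score = 20, n_mismatch = 0L,
                   seq_ref = paste0(strrep("T", 9), base, strrep("T", 10)),
                   qual_ref = strrep("I", 20))
  }
  # 1,678 observations of which 4 carry the contaminant base
  mols <- dplyr::bind_rows(mk(1674, "A"), mk(4, "G"))
  cnt <- count_diagnostic_reads(mols, panel, 16569L)
  expect_equal(unlist(cnt), c(n_clean = 1674L, n_contaminant = 4L, n_other = 0L))
  est <- estimate_contamination(mols, panel, 16569L)
  expect_equal(round(100 * est$wilson_high, 1), 0.6)
  expect_equal(est$point, 4 / 1678)

  # N and third bases land in n_other; classification is exhaustive
  mols2 <- dplyr::bind_rows(mk(3, "A"), mk(2, "N"), mk(1, "C"))
  cnt2 <- count_diagnostic_reads(mols2, panel, 16569L)
  expect_equal(unlist(cnt2), c(n_clean = 3L, n_contaminant = 0L, n_other = 3L))
  expect_equal(sum(unlist(cnt2)), nrow(mols2))

  # no molecule covering any diagnostic position
  far <- tibble::tibble(position = 9000L, sample_base = "A",
                        contaminant_base = "G")
  expect_equal(sum(unlist(count_diagnostic_reads(mols, far, 16569L))), 0L)
  expect_error(estimate_contamination(mols, far, 16569L),
               class = "palaeomito_error_undefined")

  # tidy/glance accessors
  expect_equal(tidy(est)$n, c(1674L, 4L, 0L))
  expect_equal(glance(est)$wilson_high, est$wilson_high)
})

test_that("diagnostic positions wrapping the origin are counted", {
  panel <- tibble::tibble(position = 2L, sample_base = "A",
                          contaminant_base = "G")
  mol <- tibble::tibble(id = "w", aligned = TRUE, ref_start = 16560L,
                        ref_end = 11L, strand = "+", length = 21L,
                        score = 21, n_mismatch = 0L,
                        seq_ref = paste0(strrep("T", 11), "A", strrep("T", 9)),
                        qual_ref = strrep("I", 21))
  cnt <- count_diagnostic_reads(mol, panel, 16569L)
  expect_equal(cnt$n_clean, 1L)
})
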