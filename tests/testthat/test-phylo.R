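test_that("pairwise comparison is masked, symmetric and exact on fixtures", {
  sthe <- fx_genome("StHe")
  nam117 <- fx_genome("NAM117")
  self <- pairwise_comparison(sthe, sthe)
  expect_equal(self$similarity, 1)
  expect_equal(nrow(self$diffs[[1]]), 0L)
  expect_equal(self$n_compared, 16531L)

  ab <- pairwise_comparison(sthe, nam117)
  ba <- pairwise_comparison(nam117, sthe)
  expect_equal(ab$n_diff, 9L)
  expect_gt(ab$similarity, 0.999)
  expect_equal(ab$n_diff, ba$n_diff)
  expect_equal(ab$similarity, ba$similarity)
  # diff orientation reverses
  expect_equal(sort(ab$diffs[[1]]$label),
               sort(invert_variants(ba$diffs[[1]])$label))

  # coding-region restriction
  cod <- pairwise_comparison(sthe, nam117, window = coding_region_window())
  expect_equal(cod$n_compared, 15447L)

  expect_error(pairwise_comparison(sthe, strrep("N", 16569)),
               class = "palaeomito_error_undefined")
  expect_error(pairwise_comparison(sthe, "ACGT"),
               class = "palaeomito_error_consistency")
})

test_that("private variants reproduce the fixture's printed lists", {
  clade <- fx$genomes[fx$genomes$id %in% c("StHe", "NAM117", "NAM168"), ]
  pv <- private_variants(clade, "StHe")
  expect_equal(sort(pv$label),
               sort(c("T408A", "A2581G", "A4824G", "C11279T", "C11431T",
                      "A11884G", "T16086C", "C16261T", "A16399C")))
  pv168 <- private_variants(clade, "NAM168")
  expect_equal(pv168$label, "G3591A")
  # NAM117 has no private variants: it is ancestral within the trio
  expect_equal(nrow(private_variants(clade, "NAM117")), 0L)
  # identical genomes: nothing private
  twins <- genome_record(c("a", "b"), rep(fx_genome("StHe"), 2))
  expect_equal(nrow(private_variants(twins, "a")), 0L)
  # masked sites are never reported
  sthe_chars <- strsplit(fx_genome("StHe"), "")[[1]]
  sthe_chars[310] <- setdiff(c("A", "C", "G", "T"), sthe_chars[310])[1]
  clade2 <- clade
  clade2$sequence[clade2$id == "StHe"] <- paste(sthe_chars, collapse = "")
  expect_equal(nrow(private_variants(clade2, "StHe")), 9L)
  expect_error(private_variants(clade, "nope"),
               class = "palaeomito_error_lookup")
})

test_that("haplogroup classification descends to the defined subclade", {
  tree <- read_haplogroup_tree(system.file("extdata", "haplogroup_tree.tsv",
                                           package = "palaeomito"))
  call <- classify_haplogroup(fx_genome("StHe"), tree)
  expect_equal(call$call, "L0d2c1c")
  expect_false(call$ambiguous)
  expect_equal(tidy(call)$node, c("root", "L0d2c", "L0d2c1", "L0d2c1c"))
  leaf <- tidy(call)[tidy(call)$node == "L0d2c1c", ]
  expect_equal(c(leaf$matched, leaf$total), c(2L, 2L))

  # the bare reference stays at the root
  root_call <- classify_haplogroup(fx$reference$sequence, tree)
  expect_equal(root_call$call, "root")
  # a genome carrying only the upstream path stops at L0d2c1
  anc_call <- classify_haplogroup(fx_genome("ancestral"), tree)
  expect_equal(anc_call$call, "L0d2c1")
  # sister subclades classify to themselves
  expect_equal(classify_haplogroup(fx_genome("L0d2c1a"), tree)$call, "L0d2c1a")

  expect_error(haplogroup_tree(c("a", "a"), c(NA, "a"), c("", "")),
               class = "palaeomito_error_tree")
})

test_that("genomes built from a root-to-leaf path always classify to that leaf", {
  base <- random_genome(4000, 13)
  for (case in 1:5) {
    ht <- random_haplotree(base, depth = 3L, seed = 100 + case)
    leaves <- setdiff(ht$tree$node, ht$tree$parent)
    for (leaf in leaves[c(1, length(leaves))]) {
      g <- haplotree_genome(base, ht$tree, leaf)
      call <- classify_haplogroup(g, ht$tree, mask = region_mask())
      expect_equal(call$call, leaf)
      expect_false(call$ambiguous)
    }
  }
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  # distances from known branch lengths a=2, b=3, c=4
  d <- matrix(c(0, 5, 6, 5, 0, 7, 6, 7, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[["A"]], 2)
  expect_equal(bl[["B"]], 3)
  expect_equal(bl[["C"]], 4)
})

test_that("neighbor joining is exact on additive matrices", {
  withr::with_seed(71, {
    for (ntax in 5:8) {
      src <- ape::rtree(ntax, br = function(n) runif(n, 0.05, 1))
      d <- ape::cophenetic.phylo(src)
      d <- d[sort(rownames(d)), sort(colnames(d))]
      tr <- nj_tree(d)
      # recovered tree reproduces all pairwise path lengths exactly
      d2 <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
      expect_lt(max(abs(d2 - d)), 1e-8)
      # topology agrees with an independent implementation
      ref_tr <- ape::nj(d)
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref_tr)), 0,
                   ignore_attr = TRUE)
    }
  })
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3)
  expect_error(nj_tree(bad), class = "palaeomito_error_validation")
  expect_error(nj_tree(matrix(0, 2, 2)), class = "palaeomito_error_config")
})

test_that("fixture phylogeny places the ancient genome with the !Xun pair", {
  ids <- c("StHe", "NAM117", "NAM168", "L0d2c1a", "outgroup")
  genomes <- fx$genomes[match(ids, fx$genomes$id), ]
  d <- p_distance_matrix(genomes)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  # identical input genomes give a zero matrix
  twins <- genome_record(c("a", "b", "c"), rep(fx_genome("StHe"), 3))
  expect_true(all(p_distance_matrix(twins) == 0))

  tr <- nj_tree(d, outgroup = "outgroup")
  expect_true(ape::is.monophyletic(tr, c("NAM117", "NAM168")))
  expect_true(ape::is.monophyletic(tr, c("StHe", "NAM117", "NAM168")))
})
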