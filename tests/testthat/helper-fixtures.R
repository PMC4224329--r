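# shared fixtures and independent oracles for the test suite

# study fixture built once per test run
fx <- make_study_fixture(seed = 1L)
fx_genome <- function(id) fx$genomes$sequence[fx$genomes$id == id]

random_genome <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# independent brute-force aligner: scores every offset on both strands with
# the same scoring and tie-break contract (plus strand first, then smallest
# start), without any seeding
brute_force_align <- function(seq, ref, match = 1, mismatch = 1, dpen = 0.5,
                              min_score_frac = 0.25) {
  L <- nchar(ref)
  len <- nchar(seq)
  extc <- strsplit(paste0(ref, substr(ref, 1, len - 1)), "")[[1]]
  best <- -Inf
  hit <- NULL
  for (st in c("+", "-")) {
    rc <- strsplit(if (st == "+") seq else revcomp(seq), "")[[1]]
    informative <- rc %in% c("A", "C", "G", "T")
    for (o in seq_len(L)) {
      g <- extc[o:(o + len - 1)]
      ok <- informative & g %in% c("A", "C", "G", "T")
      same <- ok & rc == g
      mis <- ok & rc != g
      dmg <- mis & ((g == "C" & rc == "T") | (g == "G" & rc == "A"))
      sc <- sum(same) * match - sum(dmg) * dpen - sum(mis & !dmg) * mismatch
      if (sc > best) {
        best <- sc
        hit <- list(ref_start = o, strand = st, score = sc,
                    n_mismatch = sum(mis))
      }
    }
  }
  if (best >= min_score_frac * match * len) hit else NULL
}

# random haplogroup mini-tree on a small linear frame: binary tree of given
# depth with distinct defining-variant positions per node
random_haplotree <- function(ref_seq, depth = 3L, seed = 1L) {
  withr::with_seed(seed, {
    L <- nchar(ref_seq)
    n_nodes <- 2^(depth + 1) - 1
    pos_pool <- sample(seq_len(L), n_nodes * 2)
    nodes <- "root"
    parents <- NA_character_
    varstr <- ""
    take <- 0L
    for (d in seq_len(depth)) {
      level_parents <- nodes[(2^(d - 1)):(2^d - 1)]
      for (p in level_parents) {
        for (s in c("x", "y")) {
          nm <- paste0(p, "_", s)
          vp <- pos_pool[take + 1:2]
          take <- take + 2L
          refb <- substring(ref_seq, vp, vp)
          altb <- vapply(refb, function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                         character(1))
          nodes <- c(nodes, nm)
          parents <- c(parents, p)
          varstr <- c(varstr, paste0(refb, vp, altb, collapse = ","))
        }
      }
    }
    list(tree = haplogroup_tree(nodes, parents, varstr),
         nodes = nodes, parents = parents)
  })
}

# apply all defining variants on the root-to-node path of a haplotree
haplotree_genome <- function(ref_seq, tree, node) {
  path <- node
  while (!is.na(tree$parent[match(path[1], tree$node)])) {
    path <- c(tree$parent[match(path[1], tree$node)], path)
  }
  g <- ref_seq
  for (nd in path) {
    v <- tree$variants[[match(nd, tree$node)]]
    if (nrow(v) > 0) g <- apply_variants(g, v)
  }
  g
}
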