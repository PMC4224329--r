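#' Hotspot-masked pairwise genome comparison
#'
#' Compares two same-frame genomes position by position, excluding masked
#' positions and positions that are `N` in either genome. Similarity is
#' `1 - n_diff / n_compared`; differences are returned as variants oriented
#' from `a` to `b` (ref = `a`'s base, alt = `b`'s base).
#'
#' @param a,b One-row genome tibbles ([genome_record()]) or base strings in
#'   one coordinate frame.
#' @param mask A [region_mask()] of excluded hypermutable regions.
#' @param window Optional `c(start, end)` window restricting the comparison
#'   (e.g. [coding_region_window()]).
#' @return A one-row tibble: `n_compared`, `n_diff`, `similarity`, and
#'   `diffs` (list-column holding the variant tibble).
#' @export
pairwise_comparison <- function(a, b, mask = default_hotspot_mask(),
                                window = NULL) {
  sa <- if (is.character(a)) a else a$sequence
  sb <- if (is.character(b)) b else b$sequence
  stopifnot(length(sa) == 1L, length(sb) == 1L)
  if (nchar(sa) != nchar(sb)) {
    abort("genomes must share one coordinate frame",
          class = "palaeomito_error_consistency")
  }
  L <- nchar(sa)
  ca <- strsplit(sa, "", fixed = TRUE)[[1]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, L)
  keep[mask_positions(mask)] <- FALSE
  if (!is.null(window)) {
    w <- rep(FALSE, L)
    w[window[1]:window[2]] <- TRUE
    keep <- keep & w
  }
  keep <- keep & ca != "N" & cb != "N"
  if (!any(keep)) {
    abort("no comparable positions: similarity undefined",
          class = "palaeomito_error_undefined")
  }
  diff_pos <- which(keep & ca != cb)
  diffs <- tibble(position = diff_pos, ref = ca[diff_pos], alt = cb[diff_pos])
  diffs$label <- format_variant(diffs)
  tibble(n_compared = sum(keep), n_diff = length(diff_pos),
         similarity = 1 - length(diff_pos) / sum(keep),
         diffs = list(diffs))
}

#' Private variants of one genome within a clade
#'
#' Positions (unmasked, `N`-free in all members) where the focal genome
#' differs from every other clade member while the other members agree with
#' each other. Hotspot-masked sites are never reported. Variants are
#' oriented from the shared clade state to the focal genome's base.
#'
#' @param clade Tibble of genomes (`id`, `sequence`), at least two rows.
#' @param focal Id of the focal genome.
#' @param mask A [region_mask()].
#' @return A variant tibble (`position`, `ref`, `alt`, `label`).
#' @export
private_variants <- function(clade, focal, mask = default_hotspot_mask()) {
  if (nrow(clade) < 2L) {
    abort("clade must contain at least two genomes", class = "palaeomito_error_config")
  }
  if (!focal %in% clade$id) {
    abort(sprintf("focal genome '%s' not found in clade", focal),
          class = "palaeomito_error_lookup")
  }
  mat <- do.call(rbind, strsplit(clade$sequence, "", fixed = TRUE))
  fi <- match(focal, clade$id)
  f <- mat[fi, ]
  others <- mat[-fi, , drop = FALSE]
  agree <- colSums(others != others[rep(1L, nrow(others)), , drop = FALSE]) == 0L
  no_n <- f != "N" & colSums(others == "N") == 0L
  keep <- rep(TRUE, ncol(mat))
  keep[mask_positions(mask)] <- FALSE
  is_priv <- keep & no_n & agree & f != others[1L, ]
  pos <- which(is_priv)
  out <- tibble(position = pos, ref = others[1L, pos], alt = f[pos])
  out$label <- format_variant(out)
  out
}

#' Pairwise p-distance matrix over masked genomes
#'
#' For every genome pair, the proportion of differing positions among
#' unmasked, mutually non-`N` positions, optionally restricted to the
#' coding region. With the default hotspot mask and `N`-free full-length
#' genomes the comparable-position count is 16,531 genome-wide and 15,447
#' in the coding region.
#'
#' @param genomes Tibble of genomes (`id`, `sequence`), at least two rows.
#' @param mask A [region_mask()].
#' @param region `"complete"` (whole frame) or `"coding"`
#'   ([coding_region_window()]).
#' @return A symmetric numeric matrix with genome ids as dimnames.
#' @export
p_distance_matrix <- function(genomes, mask = default_hotspot_mask(),
                              region = c("complete", "coding")) {
  region <- match.arg(region)
  if (nrow(genomes) < 2L) {
    abort("need at least two genomes", class = "palaeomito_error_config")
  }
  window <- if (region == "coding") coding_region_window() else NULL
  n <- nrow(genomes)
  d <- matrix(0, n, n, dimnames = list(genomes$id, genomes$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pc <- pairwise_comparison(genomes$sequence[i], genomes$sequence[j],
                                mask = mask, window = window)
      d[i, j] <- d[j, i] <- pc$n_diff / pc$n_compared
    }
  }
  d
}

#' Read a haplogroup defining-variant tree
#'
#' Trees are stored as three-column TSV `node<TAB>parent<TAB>variants`
#' (comma-separated variant labels; empty for the root and for nodes with
#' no defining variants; parent empty for the root). The bundled mini tree
#' covering the L0d2c backbone is at
#' `system.file("extdata", "haplogroup_tree.tsv", package = "palaeomito")`.
#'
#' @param path TSV file path.
#' @return A tibble of class `haplogroup_tree`: `node`, `parent`,
#'   `variants` (list-column of variant tibbles).
#' @export
read_haplogroup_tree <- function(path) {
  df <- readr::read_tsv(path, col_names = c("node", "parent", "variants"),
                        col_types = "ccc", progress = FALSE)
  haplogroup_tree(df$node, df$parent, df$variants)
}

#' @rdname read_haplogroup_tree
#' @param node,parent Character vectors; `parent` is `NA` or `""` for the
#'   root.
#' @param variants Character vector of comma-separated variant labels.
#' @export
haplogroup_tree <- function(node, parent, variants) {
  parent[!is.na(parent) & parent == ""] <- NA_character_
  if (anyDuplicated(node)) {
    abort(sprintf("duplicate node name '%s' in haplogroup tree",
                  node[duplicated(node)][1]),
          class = "palaeomito_error_tree")
  }
  if (sum(is.na(parent)) != 1L) {
    abort("haplogroup tree must have exactly one root", class = "palaeomito_error_tree")
  }
  if (!all(parent[!is.na(parent)] %in% node)) {
    abort("haplogroup tree parent refers to unknown node", class = "palaeomito_error_tree")
  }
  vl <- lapply(variants, function(v) {
    if (is.na(v) || !nzchar(v)) return(parse_variant(character(0)))
    parse_variant(trimws(strsplit(v, ",", fixed = TRUE)[[1]]))
  })
  out <- tibble(node = node, parent = parent, variants = vl)
  class(out) <- c("haplogroup_tree", class(out))
  out
}

#' Classify a genome onto a haplogroup tree
#'
#' Greedy descent from the root: at each node, a child clade is entered if
#' the genome carries at least `min_fraction` of the child's unmasked
#' defining variants (a variant counts as carried when the genome's base
#' equals its alternate base; masked-position variants are excluded from
#' the total; `N` positions count as not carried, which is why the default
#' threshold is 0.8 rather than 1). The deepest node reached is the call;
#' if two or more children qualify at any step the best-supported one is
#' followed and the call is flagged ambiguous.
#'
#' @param genome A one-row genome tibble or base string.
#' @param tree A [haplogroup_tree()].
#' @param mask A [region_mask()].
#' @param min_fraction Minimum fraction of defining variants carried
#'   (default 0.8; use 1 for exact matching).
#' @return A list of class `haplogroup_call`: `call` (node name),
#'   `ambiguous` (flag), `ambiguous_nodes`, and `path` (tibble `node`,
#'   `matched`, `total`, `fraction` from root to call).
#' @export
classify_haplogroup <- function(genome, tree, mask = default_hotspot_mask(),
                                min_fraction = 0.8) {
  seq <- if (is.character(genome)) genome else genome$sequence
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  masked <- rep(FALSE, length(chars))
  masked[mask_positions(mask)] <- TRUE

  node_score <- function(node) {
    v <- tree$variants[[match(node, tree$node)]]
    if (nrow(v) > 0L) v <- v[!masked[v$position], , drop = FALSE]
    total <- nrow(v)
    matched <- if (total > 0L) sum(chars[v$position] == v$alt) else 0L
    list(matched = matched, total = total,
         fraction = if (total > 0L) matched / total else 1)
  }

  root <- tree$node[is.na(tree$parent)]
  path <- tibble(node = character(0), matched = integer(0),
                 total = integer(0), fraction = numeric(0))
  rs <- node_score(root)
  path <- dplyr::bind_rows(path, tibble(node = root, matched = rs$matched,
                                        total = rs$total, fraction = rs$fraction))
  current <- root
  ambiguous <- FALSE
  ambiguous_nodes <- character(0)
  repeat {
    kids <- tree$node[!is.na(tree$parent) & tree$parent == current]
    if (length(kids) == 0L) break
    scores <- lapply(kids, node_score)
    frac <- vapply(scores, `[[`, numeric(1), "fraction")
    total <- vapply(scores, `[[`, integer(1), "total")
    qual <- which(total > 0L & frac >= min_fraction)
    if (length(qual) == 0L) break
    if (length(qual) > 1L) {
      ambiguous <- TRUE
      ambiguous_nodes <- union(ambiguous_nodes, kids[qual])
    }
    best <- qual[order(-frac[qual], kids[qual])][1]
    s <- scores[[best]]
    path <- dplyr::bind_rows(path, tibble(node = kids[best],
                                          matched = s$matched,
                                          total = s$total,
                                          fraction = s$fraction))
    current <- kids[best]
  }
  structure(list(call = current, ambiguous = ambiguous,
                 ambiguous_nodes = ambiguous_nodes, path = path),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("<haplogroup_call: %s%s; path %s>\n", x$call,
              if (x$ambiguous) " (ambiguous)" else "",
              paste(x$path$node, collapse = " > ")))
  invisible(x)
}

#' @rdname classify_haplogroup
#' @param x A `haplogroup_call`.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.haplogroup_call <- function(x, ...) x$path

#' @rdname classify_haplogroup
#' @exportS3Method generics::glance
glance.haplogroup_call <- function(x, ...) {
  tibble(call = x$call, ambiguous = x$ambiguous,
         depth = nrow(x$path),
         matched = sum(x$path$matched), total = sum(x$path$total))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: at each step the pair minimizing the
#' Saitou-Nei Q criterion is joined, branch lengths follow the usual
#' three-point formulas, and distances to the new node are
#' `(d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q are broken
#' deterministically by the current label order, so results are
#' reproducible. Exact on additive matrices: the generating tree (topology
#' and branch lengths) is recovered.
#'
#' @param d Symmetric numeric matrix with zero diagonal and labels as
#'   dimnames (e.g. from [p_distance_matrix()]); at least 3 taxa.
#' @param outgroup Optional taxon label; if given, the returned tree is
#'   rooted on that taxon.
#' @return An `ape::phylo` tree (unrooted unless `outgroup` is given).
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("d must be a square matrix", class = "palaeomito_error_validation")
  }
  if (nrow(d) < 3L) {
    abort("neighbor joining needs at least 3 taxa", class = "palaeomito_error_config")
  }
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
    abort("d must be symmetric with zero diagonal",
          class = "palaeomito_error_validation")
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  if (!is.null(outgroup) && !outgroup %in% labels) {
    abort("outgroup not among taxa", class = "palaeomito_error_lookup")
  }
  # subtree Newick fragments, merged as pairs are joined
  nodes <- labels
  D <- d
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    new_label <- sprintf("(%s:%.15g,%s:%.15g)", nodes[i], bi, nodes[j], bj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], new_label)
    D <- D2
  }
  # final three-point attachment
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 nodes[1], b1, nodes[2], b2, nodes[3], b3)
  tr <- ape::read.tree(text = nwk)
  if (!is.null(outgroup)) {
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}
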