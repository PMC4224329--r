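#' Build the study-like fixture bundle
#'
#' Constructs, from the deterministic [fixture_reference()], a small set of
#' same-frame genomes emulating the study system: an ancestral
#' L0d2c1-like genome; an ancient "StHe-like" genome carrying the subclade
#' defining variants C10822A and C16355T plus nine private variants; two
#' contemporary clade members ("NAM117-like" with the defining variants
#' only, "NAM168-like" additionally carrying G3591A); sister-subclade
#' genomes (L0d2c1a/b-like); a divergent outgroup; and a modern contaminant
#' genome engineered to differ from the StHe-like genome at exactly 32
#' unmasked seeded positions, mirroring a 32-site diagnostic panel.
#'
#' @param seed Integer seed for the random outgroup and contaminant
#'   substitutions.
#' @param dir Optional directory; if given, genomes (FASTA), variant lists
#'   (TSV) and the hotspot mask (TSV) are written there.
#' @return A list with `reference` (a [circular_reference]), `genomes`
#'   (tibble `id`, `sequence`), `mask`, and variant tibbles
#'   `clade_defining`, `private_sthe`, `private_nam168`,
#'   `contaminant_sites`.
#' @examples
#' fx <- make_study_fixture(seed = 1)
#' fx$genomes$id
#' @export
make_study_fixture <- function(seed = 1L, dir = NULL) {
  ref <- fixture_reference()
  mask <- default_hotspot_mask()
  L <- ref$length

  v_l0d2c  <- parse_variant(c("A1000G", "C2000T", "G3000A"))
  v_l0d2c1 <- parse_variant(c("T4000C", "A5000G"))
  v_c1a    <- parse_variant(c("C6000T", "A7000G"))
  v_c1b    <- parse_variant(c("G8000A", "T9000C"))
  v_c1c    <- parse_variant(c("C10822A", "C16355T"))
  v_priv   <- parse_variant(c("T408A", "A2581G", "A4824G", "C11279T",
                              "C11431T", "A11884G", "T16086C", "C16261T",
                              "A16399C"))
  v_nam168 <- parse_variant("G3591A")

  anc    <- apply_variants(ref$sequence, dplyr::bind_rows(v_l0d2c, v_l0d2c1))
  sthe   <- apply_variants(anc, dplyr::bind_rows(v_c1c, v_priv))
  nam117 <- apply_variants(anc, v_c1c)
  nam168 <- apply_variants(nam117, v_nam168)
  c1a    <- apply_variants(anc, v_c1a)
  c1b    <- apply_variants(anc, v_c1b)

  used <- sort(unique(c(as.integer(names(fixture_constraints())),
                        v_l0d2c$position, v_l0d2c1$position,
                        v_c1a$position, v_c1b$position,
                        mask_positions(mask))))
  free <- setdiff(seq_len(L), used)

  rand <- withr::with_seed(seed, {
    pos_out <- sort(sample(free, 25L))
    pos_con <- sort(sample(setdiff(free, pos_out), 32L))
    list(out = random_substitutions(ref$sequence, pos_out),
         con = random_substitutions(sthe, pos_con))
  })
  outgroup <- apply_variants(ref$sequence, rand$out)
  contam <- apply_variants(sthe, rand$con)

  genomes <- genome_record(
    id = c("ancestral", "StHe", "NAM117", "NAM168",
           "L0d2c1a", "L0d2c1b", "outgroup", "contaminant"),
    sequence = c(anc, sthe, nam117, nam168, c1a, c1b, outgroup, contam)
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(genomes, file.path(dir, "genomes.fasta"))
    write_fasta(genome_record(ref$name, ref$sequence),
                file.path(dir, "reference.fasta"))
    write_variant_tsv(v_c1c, file.path(dir, "clade_defining.tsv"))
    write_variant_tsv(v_priv, file.path(dir, "private_sthe.tsv"))
    write_variant_tsv(v_nam168, file.path(dir, "private_nam168.tsv"))
    write_variant_tsv(rand$con, file.path(dir, "contaminant_sites.tsv"))
    write_mask_tsv(mask, file.path(dir, "hotspot_mask.tsv"))
  }

  list(reference = ref, genomes = genomes, mask = mask,
       clade_defining = v_c1c, private_sthe = v_priv,
       private_nam168 = v_nam168, contaminant_sites = rand$con)
}

# draw one non-reference base at each position (RNG state of the caller)
random_substitutions <- function(sequence, positions) {
  refb <- substring(sequence, positions, positions)
  alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  out <- tibble(position = as.integer(positions), ref = refb, alt = alt)
  out$label <- format_variant(out)
  out
}
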