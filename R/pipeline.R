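#' Validate and normalize a pipeline configuration
#'
#' Configurations are nested lists (or YAML/JSON files) with a `seed`, an
#' output directory, per-stage enable flags under `stages`, and per-stage
#' parameter blocks mirroring the module functions. Unknown keys are
#' rejected; all errors are aggregated and reported together; defaults are
#' filled in so the returned configuration is fully explicit. A seed is
#' mandatory whenever the simulation stage is enabled.
#'
#' @param config A named list, or a path to a YAML or JSON file.
#' @return The normalized configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    abort("config must be a named list or a file path", class = "palaeomito_error_config")
  }
  defaults <- list(
    seed = NULL,
    outdir = NULL,
    stages = list(simulate = TRUE, assemble = TRUE, damage = TRUE,
                  contam = TRUE, classify = TRUE, tree = TRUE),
    simulate = list(n_reads = 20000L, mean_fragment_length = 50,
                    fragment_length_sd = 15, contamination_fraction = 0.02,
                    quality_mean = 35, quality_sd = 3,
                    p5_max = 0.35, p3_max = 0.35, decay = 0.3,
                    baseline = 0.001),
    assemble = list(min_depth = 2L, max_iter = 10L, damage_aware = "half",
                    k = 12L),
    damage = list(window = 25L, against = "consensus"),
    contam = list(threshold = 0.99),
    classify = list(min_fraction = 0.8),
    tree = list(region = "complete")
  )
  errs <- character(0)
  bad_keys <- setdiff(names(config), names(defaults))
  if (length(bad_keys) > 0L) {
    errs <- c(errs, sprintf("unknown key: %s", bad_keys))
  }
  merged <- defaults
  for (k in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[k]])) {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad) > 0L) {
        errs <- c(errs, sprintf("unknown key: %s$%s", k, bad))
      }
      for (k2 in intersect(names(config[[k]]), names(defaults[[k]]))) {
        merged[[k]][[k2]] <- config[[k]][[k2]]
      }
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  cf <- merged$simulate$contamination_fraction
  if (!is.numeric(cf) || cf < 0 || cf > 1) {
    errs <- c(errs, "simulate$contamination_fraction must lie in [0, 1]")
  }
  if (merged$simulate$mean_fragment_length < 20) {
    errs <- c(errs, "simulate$mean_fragment_length must be >= 20")
  }
  if (!merged$damage$against %in% c("consensus", "reference")) {
    errs <- c(errs, "damage$against must be 'consensus' or 'reference'")
  }
  if (!merged$tree$region %in% c("complete", "coding")) {
    errs <- c(errs, "tree$region must be 'complete' or 'coding'")
  }
  if (isTRUE(merged$stages$simulate) && is.null(merged$seed)) {
    errs <- c(errs, "seed is mandatory when the simulation stage is enabled")
  }
  if (length(errs) > 0L) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", errs, collapse = "\n")),
          class = "palaeomito_error_config")
  }
  if (!is.null(merged$seed)) merged$seed <- as.integer(merged$seed)
  class(merged) <- c("pipeline_config", "list")
  merged
}

#' Run the full study-like pipeline
#'
#' Executes the enabled stages in order — simulate, assemble, damage,
#' contam, classify, tree — handing results between stages as plain files
#' in the run directory (FASTA/FASTQ/TSV/JSON), so every stage is
#' independently inspectable and re-runnable. A `manifest.json` records the
#' package version, seed, serialized configuration and the MD5 checksum of
#' every stage output; re-running a downstream stage first verifies its
#' declared inputs against the manifest and fails on a checksum mismatch.
#' Re-running the whole pipeline with the same configuration is
#' byte-identical.
#'
#' @param config A configuration accepted by [validate_config()].
#' @param outdir Output directory (overrides `config$outdir`).
#' @return The run directory path, invisibly; the manifest is returned as
#'   attribute `"manifest"`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- validate_config(config)
  dir <- outdir %||% cfg$outdir
  if (is.null(dir)) abort("an output directory is required",
                          class = "palaeomito_error_config")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- cfg$stages
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list(package = "palaeomito",
         version = as.character(utils::packageVersion("palaeomito")),
         seed = cfg$seed, config = unclass(cfg), files = list())
  }

  fp <- function(name) file.path(dir, name)
  record <- function(names) {
    for (nm in names) {
      manifest$files[[nm]] <<- unname(tools::md5sum(fp(nm)))
    }
  }
  require_inputs <- function(stage, names) {
    for (nm in names) {
      if (!file.exists(fp(nm))) {
        abort(sprintf("stage '%s' needs missing upstream output '%s'", stage, nm),
              class = "palaeomito_error_dependency")
      }
      rec <- manifest$files[[nm]]
      if (!is.null(rec) && !identical(unname(tools::md5sum(fp(nm))), rec)) {
        abort(sprintf("checksum mismatch for '%s': file was modified after it was produced",
                      nm),
              class = "palaeomito_error_checksum")
      }
    }
  }
  log_stage <- function(...) message(sprintf(...))

  fx <- make_study_fixture(seed = cfg$seed %||% 1L)

  if (isTRUE(st$simulate)) {
    sc <- cfg$simulate
    config_sim <- sim_config(
      endogenous = fx$genomes$sequence[fx$genomes$id == "StHe"],
      contaminant = fx$genomes$sequence[fx$genomes$id == "contaminant"],
      n_reads = sc$n_reads, seed = cfg$seed,
      mean_fragment_length = sc$mean_fragment_length,
      fragment_length_sd = sc$fragment_length_sd,
      contamination_fraction = sc$contamination_fraction,
      quality_mean = sc$quality_mean, quality_sd = sc$quality_sd)
    dm <- damage_model(sc$p5_max, sc$p3_max, sc$decay, sc$baseline)
    sim <- simulate_reads(config_sim, dm)
    write_fastq(sim$reads, fp("reads.fastq"))
    truth_flat <- dplyr::select(sim$truth, -"damaged_pos")
    readr::write_tsv(truth_flat, fp("truth.tsv"), progress = FALSE)
    write_fasta(fx$genomes, fp("genomes.fasta"))
    write_fasta(genome_record(fx$reference$name, fx$reference$sequence),
                fp("reference.fasta"))
    record(c("reads.fastq", "truth.tsv", "genomes.fasta", "reference.fasta"))
    log_stage("simulate: %d reads written", nrow(sim$reads))
  }

  if (isTRUE(st$assemble)) {
    require_inputs("assemble", c("reads.fastq", "reference.fasta"))
    reads <- read_fastq(fp("reads.fastq"))
    init <- read_fasta(fp("reference.fasta"))$sequence[1]
    asm <- iterative_assemble(reads, init,
                              min_depth = cfg$assemble$min_depth,
                              max_iter = cfg$assemble$max_iter,
                              damage_aware = cfg$assemble$damage_aware,
                              k = cfg$assemble$k)
    write_fasta(genome_record("consensus", asm$consensus$sequence),
                fp("consensus.fasta"))
    readr::write_tsv(dplyr::select(asm$molecules, -"aligned"),
                     fp("molecules.tsv"), progress = FALSE)
    jsonlite::write_json(as.list(asm$report), fp("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    record(c("consensus.fasta", "molecules.tsv", "report.json"))
    log_stage("assemble: %d/%d reads aligned, %d unique molecules, %d iteration(s)",
              asm$report$n_aligned, asm$report$n_input_reads,
              asm$report$n_unique_molecules, asm$report$n_iterations)
  }

  if (isTRUE(st$damage)) {
    require_inputs("damage", c("molecules.tsv", "consensus.fasta",
                               "reference.fasta"))
    mols <- read_molecules_tsv(fp("molecules.tsv"))
    against <- if (cfg$damage$against == "consensus") {
      read_fasta(fp("consensus.fasta"))$sequence[1]
    } else {
      read_fasta(fp("reference.fasta"))$sequence[1]
    }
    prof <- damage_profile(mols, against, window = cfg$damage$window)
    write_profile_tsv(prof, fp("damage_profile.tsv"))
    record("damage_profile.tsv")
    ts <- terminal_damage_summary(prof)
    log_stage("damage: 5' C>T at distance 1 = %.3f, 3' G>A = %.3f",
              ts$ct5_d1, ts$ga3_d1)
  }

  if (isTRUE(st$contam)) {
    require_inputs("contam", c("molecules.tsv", "genomes.fasta"))
    mols <- read_molecules_tsv(fp("molecules.tsv"))
    genomes <- read_fasta(fp("genomes.fasta"))
    sthe <- genomes$sequence[genomes$id == "StHe"]
    cont <- genomes$sequence[genomes$id == "contaminant"]
    panel <- find_diagnostic_positions(sthe, genome_record("contaminant", cont),
                                       threshold = cfg$contam$threshold)
    est <- estimate_contamination(mols, panel, nchar(sthe))
    jsonlite::write_json(as.list(glance(est)), fp("contamination.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    record("contamination.json")
    log_stage("contam: %d clean / %d contaminant observations, Wilson upper %.4f",
              est$n_clean, est$n_contaminant, est$wilson_high)
  }

  if (isTRUE(st$classify)) {
    require_inputs("classify", "consensus.fasta")
    cons <- read_fasta(fp("consensus.fasta"))$sequence[1]
    tree <- read_haplogroup_tree(system.file("extdata", "haplogroup_tree.tsv",
                                             package = "palaeomito"))
    call <- classify_haplogroup(cons, tree,
                                min_fraction = cfg$classify$min_fraction)
    out <- c(glance(call), list(path = tidy(call)))
    jsonlite::write_json(out, fp("classification.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    record("classification.json")
    log_stage("classify: %s", call$call)
  }

  if (isTRUE(st$tree)) {
    require_inputs("tree", c("consensus.fasta", "genomes.fasta"))
    cons <- read_fasta(fp("consensus.fasta"))$sequence[1]
    genomes <- read_fasta(fp("genomes.fasta"))
    keep <- genomes$id %in% c("NAM117", "NAM168", "L0d2c1a", "L0d2c1b",
                              "outgroup")
    taxa <- dplyr::bind_rows(genome_record("consensus", cons),
                             genomes[keep, ])
    d <- p_distance_matrix(taxa, region = cfg$tree$region)
    tr <- nj_tree(d, outgroup = "outgroup")
    write_newick(tr, fp("tree.nwk"))
    record("tree.nwk")
    log_stage("tree: %d taxa", nrow(taxa))
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(dir, "manifest") <- manifest
  invisible(dir)
}

#' Read a molecules TSV written by the pipeline
#'
#' @param path File path.
#' @return Tibble of aligned molecules.
#' @export
read_molecules_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = "c", ref_start = "i", ref_end = "i", strand = "c", length = "i",
    score = "d", n_mismatch = "i", seq_ref = "c", qual_ref = "c",
    .default = readr::col_guess()), progress = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
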