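#' Pipeline configuration
#'
#' A single configuration object drives the full analysis. Exactly one of
#' `reads_fasta` (with `metadata_tsv`) or `simulation` must be supplied.
#'
#' @param reference either a [germline_reference()] or a list with
#'   `fasta` and `bounds` file paths; `NULL` uses the packaged synthetic
#'   reference ([synthetic_reference()]).
#' @param reads_fasta path to a reads FASTA file.
#' @param metadata_tsv path to a per-read metadata TSV (columns `read_id`,
#'   `isotype`, `tissue`, `treatment`, `animal`).
#' @param simulation list with elements `model` (a [targeting_model()] or a
#'   list of its arguments) and `config` (a [sim_config()] or a list of its
#'   arguments).
#' @param homology_threshold germline identity threshold (default 0.90,
#'   strict `>`).
#' @param group_by metadata keys for the mutation-load summary.
#' @param tree_min_size smallest clone size for which a lineage tree is
#'   built (default 2).
#' @param seed integer seed; overrides the simulation block's seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference = NULL, reads_fasta = NULL,
                            metadata_tsv = NULL, simulation = NULL,
                            homology_threshold = 0.90,
                            group_by = c("isotype", "treatment"),
                            tree_min_size = 2L, seed = 1L) {
  if (is.null(simulation) == is.null(reads_fasta)) {
    abort("exactly one of `reads_fasta` or `simulation` must be given")
  }
  if (!is_scalar_number(homology_threshold) ||
      homology_threshold <= 0 || homology_threshold >= 1) {
    stop_field("homology_threshold", "must be in (0,1)")
  }
  structure(
    list(reference = reference, reads_fasta = reads_fasta,
         metadata_tsv = metadata_tsv, simulation = simulation,
         homology_threshold = homology_threshold, group_by = group_by,
         tree_min_size = as.integer(tree_min_size), seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [pipeline_config()]; the `simulation`
#' block holds `model` and `config` argument lists.
#'
#' @param path YAML or JSON file.
#' @param seed optional seed override.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- cfg[intersect(names(cfg), names(formals(pipeline_config)))]
  if (!is.null(seed)) args$seed <- seed
  do.call(pipeline_config, args)
}

resolve_reference <- function(reference) {
  if (is.null(reference)) return(synthetic_reference())
  if (inherits(reference, "germline_reference")) return(reference)
  if (is.list(reference) && !is.null(reference$fasta)) {
    return(load_reference(reference$fasta, reference$bounds))
  }
  abort("`reference` must be a germline_reference or list(fasta=, bounds=)")
}

resolve_simulation <- function(sim_block, seed) {
  model <- sim_block$model
  if (!inherits(model, "targeting_model")) {
    model <- do.call(targeting_model, as.list(model %||% list()))
  }
  config <- sim_block$config
  if (!inherits(config, "sim_config")) {
    config <- as.list(config %||% list())
    config$seed <- seed
    config <- do.call(sim_config, config)
  }
  list(model = model, config = config)
}

#' Run the full repertoire analysis pipeline
#'
#' Stages: obtain reads (simulation or FASTA) -> align to the germline ->
#' filter (full-length, productive, germline identity) -> group clones by
#' CDR3 junction -> build clone consensuses -> call and classify mutations ->
#' summarise (loads, transition/transversion, mutability, hotspot fractions,
#' R/S by region) -> reconstruct lineage trees. All tables are returned in a
#' report bundle; when `out_dir` is given every artifact is also written to
#' disk (AIRR-style TSV, consensus FASTA, Newick trees, JSON run log).
#'
#' @param config a `pipeline_config` (or path to a YAML/JSON file).
#' @param out_dir optional output directory.
#' @return list of class `shm_report`; see Details for components.
#' @details Components: `funnel` (filter counts), `airr` (per-read alignment
#'   table), `clones`, `composition`, `consensus`, `mutations` (consensus
#'   based), `titv`, `mutability`, `hotspot_fractions`, `rs`, `load_summary`,
#'   `loads`, `trees`, `truth` (simulation only), `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  ref <- resolve_reference(config$reference)

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- resolve_simulation(config$simulation, config$seed)
    simulation <- simulate_repertoire(ref, sim$model, sim$config)
    reads <- simulation$reads
    metadata <- simulation$metadata
    truth <- simulation$truth
  } else {
    reads <- as_read_table(Biostrings::readDNAStringSet(config$reads_fasta))
    metadata <- if (!is.null(config$metadata_tsv)) {
      readr::read_tsv(config$metadata_tsv, show_col_types = FALSE,
                      progress = FALSE)
    } else {
      tibble(read_id = reads$read_id, isotype = NA_character_,
             tissue = NA_character_, treatment = NA_character_,
             animal = NA_character_)
    }
  }

  airr <- align_reads(reads, ref)
  full_length <- !airr$partial & !airr$indel
  productive <- full_length & airr$productive
  homology <- productive & passes_homology_filter(airr, config$homology_threshold)
  airr$passes_filters <- homology
  funnel <- tibble(
    stage = c("input", "full_length", "productive", "homology"),
    n = c(nrow(airr), sum(full_length), sum(productive), sum(homology)))

  filtered <- airr[homology, ]
  clones <- group_clones(filtered)
  empty <- nrow(clones) == 0L

  composition <- if (!empty) clone_composition(clones) else NULL
  consensus <- if (!empty) clone_consensus_set(clones, ref) else
    tibble(clone_id = integer(), junction = character(), size = integer(),
           consensus = character())
  mutations <- bind_rows(lapply(seq_len(nrow(consensus)), function(i) {
    call_mutations(consensus$consensus[i], ref,
                   id = paste0("clone", consensus$clone_id[i]))
  }))
  if (nrow(mutations) == 0L) mutations <- empty_mutation_table()

  titv <- summarize_titv(mutations)
  mutability <- if (nrow(mutations) > 0L) {
    estimate_mutability(consensus, ref)
  } else {
    NULL
  }
  hotspot <- if (nrow(mutations) > 0L) {
    summarize_hotspot_fractions(mutations)
  } else {
    tibble(context_group = c("hotspot", "neutral", "coldspot"),
           n = 0L, fraction = NA_real_)
  }
  rs <- summarize_rs_by_region(mutations, ref)

  loads <- sequence_loads(filtered, ref)
  load_summary <- mutation_load_summary(loads, metadata,
                                        group_by = config$group_by)

  trees <- if (!empty) {
    build_clone_trees(clones, ref, min_size = config$tree_min_size)
  } else {
    list()
  }

  report <- structure(
    list(funnel = funnel, airr = airr, clones = clones,
         composition = composition, consensus = consensus,
         mutations = mutations, titv = titv, mutability = mutability,
         hotspot_fractions = hotspot, rs = rs, loads = loads,
         load_summary = load_summary, trees = trees, truth = truth,
         log = list(package_version = as.character(utils::packageVersion("shmrep")),
                    seed = config$seed,
                    homology_threshold = config$homology_threshold,
                    reference = ref$name,
                    config_hash = rlang::hash(unclass(config)))),
    class = "shm_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.shm_report <- function(x, ...) {
  cat("<shm_report>\n")
  cat("  filter funnel: ",
      paste(sprintf("%s=%d", x$funnel$stage, x$funnel$n), collapse = " -> "),
      "\n", sep = "")
  cat(sprintf("  clones: %d; consensus mutations: %d; trees: %d\n",
              nrow(x$clones), nrow(x$mutations), length(x$trees)))
  if (nrow(x$mutations) > 0) {
    hs <- x$hotspot_fractions
    cat(sprintf("  hotspot/neutral/coldspot: %.1f%% / %.1f%% / %.1f%%\n",
                100 * hs$fraction[1], 100 * hs$fraction[2],
                100 * hs$fraction[3]))
    cat(sprintf("  transitions: %.1f%%\n", 100 * x$titv$fraction[1]))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' @param report an `shm_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "shm_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_tsv(df, file.path(dir, name))
  w(report$funnel, "funnel.tsv")
  w(select(report$airr, -"v_seq"), "rearrangements.tsv")
  w(select(as_tibble(report$clones), -"read_ids", -"v_seqs"), "clones.tsv")
  w(report$mutations, "mutations.tsv")
  w(report$titv, "titv.tsv")
  if (!is.null(report$mutability)) w(report$mutability, "mutability.tsv")
  w(report$hotspot_fractions, "hotspot_fractions.tsv")
  w(report$rs$by_region, "rs_by_region.tsv")
  w(report$rs$by_position, "rs_by_position.tsv")
  w(report$loads, "loads.tsv")
  w(report$load_summary, "load_summary.tsv")
  if (nrow(report$consensus) > 0) {
    seqs <- Biostrings::DNAStringSet(setNames(
      report$consensus$consensus,
      paste0("clone", report$consensus$clone_id)))
    Biostrings::writeXStringSet(seqs, file.path(dir, "consensus.fasta"))
  }
  if (!is.null(report$composition)) {
    jsonlite::write_json(report$composition, file.path(dir, "composition.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (length(report$trees)) {
    tree_dir <- file.path(dir, "trees")
    dir.create(tree_dir, showWarnings = FALSE)
    for (nm in names(report$trees)) {
      write_newick(report$trees[[nm]], file.path(tree_dir, paste0(nm, ".nwk")))
    }
    w(tree_edge_table(report$trees), "tree_edges.tsv")
  }
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
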