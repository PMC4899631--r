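#' Apply somatic hypermutation to a sequence
#'
#' Introduces exactly `n_mutations` substitutions at distinct positions.
#' Positions are sampled with probability proportional to the targeting
#' model's mutability evaluated on the *current* sequence at each step, so
#' contexts drift as mutations accrue, mirroring the iterative action of SHM.
#' The base change follows the model's transition bias.
#'
#' @param sequence nucleotide string over `{A,C,G,T}`.
#' @param model a [targeting_model()].
#' @param n_mutations number of positions to mutate (must not exceed the
#'   sequence length).
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (so callers embedding this in a larger simulation stay seedable).
#' @return list with `sequence` (mutated string) and `mutations`, a tibble
#'   `(position, from, to)` ordered by position (1-based).
#' @export
apply_shm <- function(sequence, model, n_mutations, seed = NULL) {
  stopifnot(inherits(model, "targeting_model"))
  sequence <- toupper(sequence)
  check_dna(sequence)
  n_mutations <- as.integer(n_mutations)
  L <- nchar(sequence)
  if (n_mutations < 0L) stop_field("n_mutations", "must be non-negative")
  if (n_mutations > L) {
    stop_field("n_mutations", sprintf("exceeds sequence length (%d > %d)",
                                      n_mutations, L))
  }
  if (!is.null(seed)) set.seed(seed)
  chars <- s2c(sequence)
  hit <- logical(L)
  pos <- integer(n_mutations)
  from <- character(n_mutations)
  to <- character(n_mutations)
  for (i in seq_len(n_mutations)) {
    w <- position_mutability(chars, model)
    w[hit] <- 0
    if (sum(w) <= 0) abort("no position with positive mutability remains")
    p <- sample.int(L, 1L, prob = w)
    b <- draw_substitution(chars[p], model$transition_fraction)
    pos[i] <- p; from[i] <- chars[p]; to[i] <- b
    chars[p] <- b
    hit[p] <- TRUE
  }
  ord <- order(pos)
  list(sequence = c2s(chars),
       mutations = tibble(position = pos[ord], from = from[ord], to = to[ord]))
}

#' Simulation configuration for synthetic repertoires
#'
#' @param n_clones number of clones (>= 1).
#' @param clone_size_law one of `"fixed"`, `"geometric"`, `"zipf"`; `zipf`
#'   (power-law clone sizes) is the default, reflecting the strongly skewed
#'   clone-size distributions seen in expanded plasma-cell repertoires.
#' @param clone_size_param law parameter: the fixed size, the geometric mean
#'   size, or the zipf exponent.
#' @param max_clone_size truncation for the zipf law.
#' @param mutations_per_lineage_step Poisson mean number of new V-region
#'   mutations added on each lineage edge.
#' @param offspring_mean mean number of children per lineage node (random
#'   attachment is biased towards recent nodes when larger).
#' @param max_depth maximum lineage depth below the clone founder.
#' @param junction_length_range integer pair: CDR3 junction length range in nt.
#' @param junction_in_frame when `TRUE` junction lengths are rounded to
#'   multiples of 3 so productive reads stay in frame.
#' @param sequencing_error_rate per-base uniform error probability applied to
#'   finished reads (recorded separately from true SHM in the truth tables);
#'   emulates a platform error floor.
#' @param founder_mutations Poisson mean number of mutations carried by each
#'   clone founder itself (0 keeps founders germline).
#' @param metadata named list of per-read metadata applied to all reads
#'   (`isotype`, `tissue`, `treatment`, `animal`).
#' @param seed integer root seed; per-clone substreams are derived from it
#'   deterministically so output is byte-reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_clones = 20,
                       clone_size_law = c("zipf", "fixed", "geometric"),
                       clone_size_param = 1.5,
                       max_clone_size = 100L,
                       mutations_per_lineage_step = 1.5,
                       offspring_mean = 1.5,
                       max_depth = 6L,
                       junction_length_range = c(24L, 45L),
                       junction_in_frame = TRUE,
                       sequencing_error_rate = 0,
                       founder_mutations = 0,
                       metadata = list(isotype = "IgM", tissue = "spleen",
                                       treatment = "control", animal = "sim1"),
                       seed = 1L) {
  clone_size_law <- match.arg(clone_size_law)
  n_clones <- as.integer(n_clones)
  if (is.na(n_clones) || n_clones < 1L) stop_field("n_clones", "must be >= 1")
  if (!is_scalar_number(clone_size_param) || clone_size_param <= 0) {
    stop_field("clone_size_param", "must be a positive number")
  }
  if (!is_scalar_number(mutations_per_lineage_step) ||
      mutations_per_lineage_step < 0) {
    stop_field("mutations_per_lineage_step", "must be non-negative")
  }
  if (!is_scalar_number(offspring_mean) || offspring_mean <= 0) {
    stop_field("offspring_mean", "must be positive")
  }
  jr <- as.integer(junction_length_range)
  if (length(jr) != 2L || anyNA(jr) || jr[1] < 3L || jr[2] < jr[1]) {
    stop_field("junction_length_range", "must be an increasing pair >= 3")
  }
  if (!is_scalar_number(sequencing_error_rate) ||
      sequencing_error_rate < 0 || sequencing_error_rate >= 1) {
    stop_field("sequencing_error_rate", "must be in [0,1)")
  }
  if (!is_scalar_number(founder_mutations) || founder_mutations < 0) {
    stop_field("founder_mutations", "must be non-negative")
  }
  structure(
    list(n_clones = n_clones, clone_size_law = clone_size_law,
         clone_size_param = clone_size_param,
         max_clone_size = as.integer(max_clone_size),
         mutations_per_lineage_step = mutations_per_lineage_step,
         offspring_mean = offspring_mean, max_depth = as.integer(max_depth),
         junction_length_range = jr, junction_in_frame = junction_in_frame,
         sequencing_error_rate = sequencing_error_rate,
         founder_mutations = founder_mutations,
         metadata = metadata, seed = as.integer(seed)),
    class = "sim_config"
  )
}

draw_clone_sizes <- function(config) {
  n <- config$n_clones
  switch(config$clone_size_law,
    fixed = rep(as.integer(round(config$clone_size_param)), n),
    geometric = 1L + stats::rgeom(n, 1 / max(1, config$clone_size_param)),
    zipf = {
      k <- seq_len(config$max_clone_size)
      p <- k^(-config$clone_size_param)
      sample(k, n, replace = TRUE, prob = p / sum(p))
    })
}

random_junction <- function(config) {
  r <- config$junction_length_range
  len <- sample(seq(r[1], r[2]), 1L)
  if (config$junction_in_frame) len <- max(r[1], 3L * (len %/% 3L))
  c2s(sample(DNA_BASES, len, replace = TRUE))
}

#' Simulate a clonally structured heavy-chain repertoire with ground truth
#'
#' Generates reads with the structure the downstream analysis assumes: each
#' clone is founded by the germline V segment joined to a unique random CDR3
#' junction (followed by a fixed 12-nt J anchor), clone sizes follow a skewed
#' law, members descend from the founder through a branching lineage that adds
#' Poisson-distributed V-region mutations per step under the targeting model,
#' and an optional uniform sequencing-error floor is applied last. Truth
#' tables record the clone partition, every true V mutation per read (as the
#' diff against the germline, so back-mutations cancel), sequencing errors,
#' and the lineage edge list.
#'
#' @param reference a [germline_reference()].
#' @param model a [targeting_model()].
#' @param config a [sim_config()].
#' @return object of class `shm_simulation`: list with `reads` (tibble
#'   `read_id, sequence`), `metadata` (per-read tibble), and `truth` (list of
#'   tibbles `clones`, `mutations`, `errors`, `lineage`, `junctions`), plus
#'   the echoed `model` and `config`.
#' @export
simulate_repertoire <- function(reference, model, config) {
  stopifnot(inherits(reference, "germline_reference"),
            inherits(model, "targeting_model"),
            inherits(config, "sim_config"))
  v_seq <- reference$sequence
  L <- nchar(v_seq)

  set.seed(config$seed)
  sizes <- draw_clone_sizes(config)

  reads <- vector("list", config$n_clones)
  truth_mut <- vector("list", config$n_clones)
  truth_err <- vector("list", config$n_clones)
  lineage <- vector("list", config$n_clones)
  junctions <- character(config$n_clones)

  for (k in seq_len(config$n_clones)) {
    set.seed(substream_seed(config$seed, k))
    junction <- random_junction(config)
    junctions[k] <- junction

    founder_v <- v_seq
    if (config$founder_mutations > 0) {
      nf <- rpois(1L, config$founder_mutations)
      nf <- min(nf, L)
      founder_v <- apply_shm(founder_v, model, nf)$sequence
    }

    # branching lineage over the V portion; node 1 is the founder
    node_v <- list(founder_v)
    node_depth <- 0L
    node_label <- "founder"
    edges <- tibble(parent = character(), child = character(),
                    n_mut = integer())
    n_members <- sizes[k]
    member_idx <- integer(n_members)
    for (m in seq_len(n_members)) {
      eligible <- which(node_depth < config$max_depth)
      if (length(eligible) == 0L) eligible <- length(node_v)
      # weight recent nodes up as offspring_mean grows beyond 1
      w <- seq_along(eligible)^(config$offspring_mean - 1)
      parent <- eligible[sample.int(length(eligible), 1L, prob = w)]
      n_new <- rpois(1L, config$mutations_per_lineage_step)
      n_new <- min(n_new, L)
      child_v <- if (n_new > 0) {
        apply_shm(node_v[[parent]], model, n_new)$sequence
      } else {
        node_v[[parent]]
      }
      node_v[[length(node_v) + 1L]] <- child_v
      node_depth <- c(node_depth, node_depth[parent] + 1L)
      lbl <- sprintf("clone%03d_read%03d", k, m)
      node_label <- c(node_label, lbl)
      edges <- bind_rows(edges, tibble(
        parent = node_label[parent], child = lbl, n_mut = n_new))
      member_idx[m] <- length(node_v)
    }

    read_ids <- node_label[member_idx]
    v_reads <- unlist(node_v[member_idx])
    full <- paste0(v_reads, junction, J_ANCHOR)

    # truth mutations: diff of each member's V portion against germline
    muts <- lapply(seq_len(n_members), function(m) {
      a <- s2c(v_reads[m]); g <- s2c(v_seq)
      d <- which(a != g)
      tibble(read_id = read_ids[m], position = d, from = g[d], to = a[d])
    })
    truth_mut[[k]] <- bind_rows(muts)

    # uniform sequencing error, applied last over the entire read
    errs <- list()
    if (config$sequencing_error_rate > 0) {
      for (m in seq_len(n_members)) {
        chars <- s2c(full[m])
        ne <- rbinom(1L, length(chars), config$sequencing_error_rate)
        if (ne > 0) {
          at <- sort(sample.int(length(chars), ne))
          old <- chars[at]
          new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
          chars[at] <- new
          full[m] <- c2s(chars)
          errs[[length(errs) + 1L]] <-
            tibble(read_id = read_ids[m], position = at, from = old, to = new)
        }
      }
    }
    truth_err[[k]] <- if (length(errs)) bind_rows(errs) else
      tibble(read_id = character(), position = integer(),
             from = character(), to = character())

    reads[[k]] <- tibble(read_id = read_ids, clone_id = k, sequence = full)
    lineage[[k]] <- mutate(edges, clone_id = k, .before = 1)
  }

  reads_tbl <- bind_rows(reads)
  md <- config$metadata
  metadata <- tibble(read_id = reads_tbl$read_id,
                     isotype = md$isotype %||% "IgM",
                     tissue = md$tissue %||% "spleen",
                     treatment = md$treatment %||% "control",
                     animal = md$animal %||% "sim1")
  structure(
    list(reads = select(reads_tbl, "read_id", "sequence"),
         metadata = metadata,
         truth = list(
           clones = select(reads_tbl, "read_id", "clone_id"),
           mutations = bind_rows(truth_mut),
           errors = bind_rows(truth_err),
           lineage = bind_rows(lineage),
           junctions = tibble(clone_id = seq_len(config$n_clones),
                              junction = junctions)),
         model = model, config = config),
    class = "shm_simulation"
  )
}

#' @export
print.shm_simulation <- function(x, ...) {
  cat(sprintf("<shm_simulation> %d reads in %d clones, %d true mutations\n",
              nrow(x$reads), x$config$n_clones, nrow(x$truth$mutations)))
  invisible(x)
}

#' Write a simulated repertoire to disk
#'
#' Emits `reads.fasta`, `metadata.tsv`, the truth tables
#' (`truth_clones.tsv`, `truth_mutations.tsv`, `truth_errors.tsv`,
#' `truth_lineage.tsv`, `truth_junctions.tsv`) and a JSON echo of the
#' configuration. All positions are 1-based.
#'
#' @param sim an `shm_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_repertoire <- function(sim, dir) {
  stopifnot(inherits(sim, "shm_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(setNames(sim$reads$sequence,
                                            sim$reads$read_id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "reads.fasta"))
  readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  for (nm in names(sim$truth)) {
    readr::write_tsv(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
  }
  cfg <- sim$config
  cfg$metadata <- as.list(cfg$metadata)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate an exponential-decay time course
#'
#' Counts follow `y0 * 2^(-t / half_life)` with multiplicative lognormal
#' noise of the given coefficient of variation (mean-1 noise, so the expected
#' trajectory is unchanged); noiseless when `cv_noise = 0`.
#'
#' @param y0 initial count (> 0).
#' @param half_life_days half-life in days (> 0).
#' @param timepoints non-empty vector of non-negative days.
#' @param cv_noise coefficient of variation of the noise (>= 0).
#' @param seed optional integer seed.
#' @return a [decay_series()].
#' @export
simulate_decay_series <- function(y0, half_life_days, timepoints,
                                  cv_noise = 0, seed = NULL) {
  if (!is_scalar_number(y0) || y0 <= 0) stop_field("y0", "must be positive")
  if (!is_scalar_number(half_life_days) || half_life_days <= 0) {
    stop_field("half_life_days", "must be positive")
  }
  if (length(timepoints) == 0L || any(timepoints < 0)) {
    stop_field("timepoints", "must be non-empty and non-negative")
  }
  if (!is_scalar_number(cv_noise) || cv_noise < 0) {
    stop_field("cv_noise", "must be >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  y <- y0 * 2^(-timepoints / half_life_days)
  if (cv_noise > 0) {
    sdlog <- sqrt(log(1 + cv_noise^2))
    y <- y * exp(rnorm(length(y), mean = -sdlog^2 / 2, sd = sdlog))
  }
  decay_series(timepoints, y)
}
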