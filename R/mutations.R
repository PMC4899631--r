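#' Call substitution mutations against the germline
#'
#' Compares an aligned V sequence to the germline position by position.
#' Only positions in the V region up to the CDR3 start are considered;
#' the junction and anything 3' of it are never reported. Each mutation is
#' fully classified: region, transition/transversion, germline-centred 5-mer
#' context and its hotspot class, and replacement/silent effect.
#'
#' The 5-mer context is taken from the germline sequence around the mutated
#' position (mutability targets the pre-mutation state). Positions within two
#' bases of a sequence end have no complete 5-mer and are classed
#' `"unscored"`.
#'
#' @param v_seq aligned V sequence (string of length equal to the germline V;
#'   `N` positions are skipped).
#' @param ref a [germline_reference()].
#' @param id optional identifier recorded in the `sequence_id` column.
#' @return tibble with columns `sequence_id`, `position` (1-based), `from`,
#'   `to`, `region`, `substitution`, `fivemer`, `context_class`,
#'   `coding_class`.
#' @export
call_mutations <- function(v_seq, ref, id = NA_character_) {
  stopifnot(inherits(ref, "germline_reference"))
  if (nchar(v_seq) != nchar(ref$sequence)) {
    abort(sprintf("aligned sequence length (%d) differs from germline (%d)",
                  nchar(v_seq), nchar(ref$sequence)))
  }
  gc <- s2c(ref$sequence)
  vc <- s2c(toupper(v_seq))
  scope <- seq_len(ref$cdr3_start)
  pos <- scope[vc[scope] != gc[scope] & vc[scope] %in% DNA_BASES]
  if (length(pos) == 0L) return(empty_mutation_table())
  fivemer <- germline_context(ref, pos)
  tibble(
    sequence_id = id,
    position = pos,
    from = gc[pos],
    to = vc[pos],
    region = region_of_position(ref, pos),
    substitution = classify_substitution(gc[pos], vc[pos]),
    fivemer = fivemer,
    context_class = context_class(fivemer),
    coding_class = classify_rs(pos, vc[pos], ref)
  )
}

empty_mutation_table <- function() {
  tibble(sequence_id = character(), position = integer(), from = character(),
         to = character(), region = character(), substitution = character(),
         fivemer = character(), context_class = character(),
         coding_class = character())
}

#' Replacement/silent classification of substitutions
#'
#' The germline codon containing each position is translated with and without
#' the substitution (the other codon positions held at their germline state);
#' a mutation is a replacement when the amino acids differ. Substitutions
#' creating a stop codon are replacements. Positions upstream of the reading
#' frame offset (no complete codon) return `NA`.
#'
#' @param position 1-based germline positions (must lie within the V region).
#' @param to substituted base at each position.
#' @param ref a [germline_reference()].
#' @return character vector, `"replacement"` or `"silent"`.
#' @export
classify_rs <- function(position, to, ref) {
  stopifnot(inherits(ref, "germline_reference"))
  if (any(position < 1L | position > ref$cdr3_start)) {
    abort("position outside the coding V region")
  }
  gc <- s2c(ref$sequence)
  out <- rep(NA_character_, length(position))
  p0 <- position - 1L                       # 0-based
  in_frame <- p0 >= ref$frame_offset
  codon_i <- (p0 - ref$frame_offset) %/% 3L
  codon_start <- ref$frame_offset + codon_i * 3L  # 0-based
  for (i in seq_along(position)) {
    if (!in_frame[i]) next
    idx <- codon_start[i] + 1:3
    germ <- gc[idx]
    mut <- germ
    mut[p0[i] - codon_start[i] + 1L] <- toupper(to[i])
    aa_g <- Biostrings::GENETIC_CODE[[c2s(germ)]]
    aa_m <- Biostrings::GENETIC_CODE[[c2s(mut)]]
    out[i] <- if (identical(aa_g, aa_m)) "silent" else "replacement"
  }
  out
}

#' Estimate background-adjusted 5-mer mutabilities (hedgehog data)
#'
#' For every 5-mer observed as a germline context, counts the consensus
#' mutations carrying that context and the number of germline positions
#' offering it across the analysed consensuses (the background). The raw rate
#' is `mutations / background`; normalized mutabilities are scaled so their
#' background-weighted mean is 1. Using one consensus per clone avoids
#' double-counting mutational events shared within a clone.
#'
#' @param consensuses tibble with a `consensus` column (e.g. from
#'   [clone_consensus_set()]), or a character vector of consensus V
#'   sequences.
#' @param ref a [germline_reference()].
#' @return a `mutability_table`: tibble `fivemer, mutations, background,
#'   raw_rate, mutability, context_class`, sorted by descending mutability.
#' @export
estimate_mutability <- function(consensuses, ref) {
  stopifnot(inherits(ref, "germline_reference"))
  seqs <- if (is.data.frame(consensuses)) consensuses$consensus else consensuses
  n_cons <- length(seqs)
  if (n_cons == 0L) abort("no consensus sequences supplied")

  L <- nchar(ref$sequence)
  scored_pos <- seq(3L, min(ref$cdr3_start, L - 2L))
  germ_ctx <- germline_context(ref, scored_pos)
  background <- table(germ_ctx) * n_cons

  muts <- bind_rows(lapply(seq_along(seqs), function(i) {
    call_mutations(seqs[i], ref, id = as.character(i))
  }))
  muts <- filter(muts, !is.na(.data$fivemer),
                 .data$position %in% scored_pos)
  counts <- table(factor(muts$fivemer, levels = names(background)))

  out <- tibble(
    fivemer = names(background),
    mutations = as.integer(counts),
    background = as.integer(background),
    raw_rate = as.integer(counts) / as.integer(background)
  )
  overall <- sum(out$mutations) / sum(out$background)
  out$mutability <- if (overall > 0) out$raw_rate / overall else NA_real_
  out$context_class <- context_class(out$fivemer)
  out <- arrange(out, desc(.data$mutability), .data$fivemer)
  class(out) <- c("mutability_table", class(out))
  out
}

#' Fraction of mutations in hotspot, neutral and coldspot contexts
#'
#' @param mutations mutation tibble from [call_mutations()] (rows with an
#'   `"unscored"` context are excluded from the denominator).
#' @return tibble `context_group, n, fraction`; fractions sum to 1. With zero
#'   scored mutations the fractions are `NA` and a warning is raised.
#' @export
summarize_hotspot_fractions <- function(mutations) {
  grp <- context_group(mutations$context_class)
  scored <- grp[grp != "unscored"]
  levels <- c("hotspot", "neutral", "coldspot")
  n <- as.integer(table(factor(scored, levels = levels)))
  if (sum(n) == 0L) {
    warn("no scored mutations; hotspot fractions undefined")
    return(tibble(context_group = levels, n = n, fraction = NA_real_))
  }
  tibble(context_group = levels, n = n, fraction = n / sum(n))
}

#' Transition/transversion summary
#'
#' @param mutations mutation tibble from [call_mutations()].
#' @return tibble `substitution, n, fraction`.
#' @export
summarize_titv <- function(mutations) {
  levels <- c("transition", "transversion")
  n <- as.integer(table(factor(mutations$substitution, levels = levels)))
  tibble(substitution = levels, n = n,
         fraction = if (sum(n) > 0) n / sum(n) else NA_real_)
}

#' Replacement/silent counts and R/S ratios by region
#'
#' @param mutations mutation tibble from [call_mutations()].
#' @param ref a [germline_reference()] (fixes the region ordering).
#' @return list of class `rs_summary`: `by_region` (tibble `region,
#'   replacement, silent, rs_ratio`; the ratio is `Inf` when silent = 0 with
#'   replacements present and `NA` when the region is empty) and
#'   `by_position` (tibble `position, region, coding_class, n` — the bar data
#'   of positional mutation-frequency plots).
#' @export
summarize_rs_by_region <- function(mutations, ref) {
  regions <- ref$region_bounds$region
  scored <- filter(mutations, !is.na(.data$coding_class))
  by_region <- bind_rows(lapply(regions, function(rg) {
    m <- scored[scored$region == rg, ]
    r <- sum(m$coding_class == "replacement")
    s <- sum(m$coding_class == "silent")
    ratio <- if (r + s == 0L) NA_real_ else if (s == 0L) Inf else r / s
    tibble(region = rg, replacement = r, silent = s, rs_ratio = ratio)
  }))
  by_position <- scored |>
    count(.data$position, .data$region, .data$coding_class, name = "n") |>
    arrange(.data$position)
  structure(list(by_region = by_region, by_position = by_position),
            class = "rs_summary")
}

#' Per-group mutation-load summary
#'
#' Mutation load is a per-sequence statistic (each read's own mutation count,
#' not the clone consensus). Groups are formed from the requested metadata
#' keys; set `pool_tissues = TRUE` to merge spleen and bone marrow.
#'
#' @param loads tibble with columns `read_id` and `n_mutations`.
#' @param metadata tibble with `read_id` plus metadata columns (`isotype`,
#'   `tissue`, `treatment`, `animal`).
#' @param group_by character vector of metadata keys to group on.
#' @param pool_tissues drop the `tissue` key from grouping.
#' @return tibble with one row per group: `n_sequences`, `mean_load`,
#'   `median_load`, `fraction_unmutated`.
#' @export
mutation_load_summary <- function(loads, metadata,
                                  group_by = c("isotype", "treatment"),
                                  pool_tissues = TRUE) {
  if (pool_tissues) group_by <- setdiff(group_by, "tissue")
  df <- left_join(loads, metadata, by = "read_id")
  missing <- setdiff(group_by, names(df))
  if (length(missing)) {
    abort(sprintf("metadata lacks grouping keys: %s",
                  paste(missing, collapse = ", ")))
  }
  df |>
    group_by(dplyr::across(dplyr::all_of(group_by))) |>
    summarise(n_sequences = dplyr::n(),
              mean_load = mean(.data$n_mutations),
              median_load = stats::median(.data$n_mutations),
              fraction_unmutated = mean(.data$n_mutations == 0),
              .groups = "drop")
}

#' Per-sequence mutation loads from an alignment table
#'
#' Counts V-region mutations (positions before the CDR3 start) for each
#' productive, indel-free read.
#'
#' @param alignments alignment tibble from [align_reads()].
#' @param ref a [germline_reference()].
#' @return tibble `read_id, n_mutations`.
#' @export
sequence_loads <- function(alignments, ref) {
  keep <- alignments[!alignments$partial & !alignments$indel, ]
  n <- vapply(keep$v_seq, function(v) nrow(call_mutations(v, ref)), 1L)
  tibble(read_id = keep$read_id, n_mutations = unname(n))
}
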