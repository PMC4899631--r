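#' Align a read to the germline V reference
#'
#' Performs a semi-global alignment: the germline V segment is aligned
#' globally while the read's 3' tail (the CDR3 junction and anything beyond)
#' is left unaligned. Identity is computed over the covered germline interval
#' only, with internal gaps counting as mismatches; the junction is the read
#' suffix beginning immediately after the base pairing with the last germline
#' position. Reads whose best alignment contains a V-region indel are flagged
#' (`indel = TRUE`) and are excluded from mutation statistics downstream;
#' reads shorter than half the V segment are flagged `partial`.
#'
#' For the common indel-free case a fast ungapped path is used: when the read
#' prefix matches the germline with at most 15% mismatches the trivial
#' position-by-position pairing is already the optimal alignment and the
#' dynamic-programming aligner is skipped.
#'
#' @param read a single read: either a one-row data frame with columns
#'   `read_id` and `sequence`, or a plain nucleotide string (optionally named).
#' @param ref a [germline_reference()].
#' @return a one-row tibble with columns `read_id`, `v_identity`,
#'   `covered_start`, `covered_end` (1-based germline interval),
#'   `n_mismatch`, `indel`, `partial`, `productive`, `filter_reason`,
#'   `junction`, `v_seq` (read bases projected onto germline coordinates,
#'   `-` for deletions).
#' @export
align_to_germline <- function(read, ref) {
  stopifnot(inherits(ref, "germline_reference"))
  if (is.data.frame(read)) {
    id <- read$read_id[1]
    seqs <- read$sequence[1]
  } else {
    id <- names(read) %||% "read1"
    seqs <- unname(read)
  }
  align_one(id, toupper(seqs), ref)
}

align_one <- function(id, seq, ref) {
  check_dna(seq, allow_n = TRUE, what = sprintf("read %s", id))
  g <- ref$sequence
  L <- nchar(g)
  n <- nchar(seq)

  if (n < ceiling(0.5 * L)) {
    return(alignment_row(id, v_identity = NA_real_, covered = c(NA, NA),
                         n_mismatch = NA_integer_, indel = FALSE,
                         partial = TRUE, productive = FALSE,
                         filter_reason = "partial", junction = NA_character_,
                         v_seq = NA_character_))
  }

  gc <- s2c(g)
  # fast ungapped path: read prefix vs germline
  prefix <- s2c(substr(seq, 1L, min(n, L)))
  if (length(prefix) == L) {
    mm <- sum(prefix != gc)
    if (mm <= 0.15 * L) {
      v_seq <- c2s(prefix)
      return(finish_alignment(id, ref, v_seq, covered = c(1L, L),
                              junction = substr(seq, L + 1L, n)))
    }
  }

  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(g),
    subject = Biostrings::DNAString(seq),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2, baseOnly = FALSE),
    gapOpening = 6, gapExtension = 2)

  ap <- s2c(as.character(Biostrings::alignedPattern(pa)))
  as_ <- s2c(as.character(Biostrings::alignedSubject(pa)))
  sub_start <- Biostrings::start(Biostrings::subject(pa))
  sub_end <- Biostrings::end(Biostrings::subject(pa))

  # project read bases onto germline coordinates
  v_chars <- rep("-", L)
  gpos <- 0L
  insertion <- FALSE
  for (i in seq_along(ap)) {
    if (ap[i] == "-") {
      insertion <- TRUE  # read base with no germline partner inside V
    } else {
      gpos <- gpos + 1L
      if (as_[i] != "-") v_chars[gpos] <- as_[i]
    }
  }
  covered_idx <- which(v_chars != "-")
  if (length(covered_idx) == 0L) {
    return(alignment_row(id, v_identity = 0, covered = c(NA, NA),
                         n_mismatch = NA_integer_, indel = FALSE,
                         partial = TRUE, productive = FALSE,
                         filter_reason = "partial", junction = NA_character_,
                         v_seq = NA_character_))
  }
  covered <- c(min(covered_idx), max(covered_idx))
  deletion <- any(v_chars[covered[1]:covered[2]] == "-")
  junction <- if (covered[2] == L) substr(seq, sub_end + 1L, n) else NA_character_
  finish_alignment(id, ref, c2s(v_chars), covered = covered,
                   junction = junction, indel = insertion || deletion)
}

finish_alignment <- function(id, ref, v_seq, covered, junction,
                             indel = FALSE) {
  gc <- s2c(ref$sequence)
  vc <- s2c(v_seq)
  span <- covered[1]:covered[2]
  aligned_n <- length(span)
  match_n <- sum(vc[span] == gc[span])
  identity <- match_n / aligned_n
  n_mismatch <- sum(vc[span] != gc[span] & vc[span] %in% DNA_BASES)

  full_length <- covered[1] == 1L && covered[2] == ref$cdr3_start
  reason <- NA_character_
  productive <- FALSE
  if (!full_length) {
    reason <- "partial"
  } else if (indel) {
    reason <- "indel"
  } else if (any(vc[span] == "N")) {
    reason <- "ambiguous_base"
  } else {
    aa <- translate_nt(substr(v_seq, ref$frame_offset + 1L, ref$cdr3_start))
    if (grepl("*", aa, fixed = TRUE)) {
      reason <- "stop_codon"
    } else {
      productive <- TRUE
    }
  }
  alignment_row(id, v_identity = identity, covered = covered,
                n_mismatch = n_mismatch, indel = indel,
                partial = !full_length, productive = productive,
                filter_reason = reason, junction = junction, v_seq = v_seq)
}

alignment_row <- function(id, v_identity, covered, n_mismatch, indel, partial,
                          productive, filter_reason, junction, v_seq) {
  tibble(read_id = id, v_identity = v_identity,
         covered_start = covered[1], covered_end = covered[2],
         n_mismatch = n_mismatch, indel = indel, partial = partial,
         productive = productive, filter_reason = filter_reason,
         junction = junction, v_seq = v_seq)
}

#' Align a set of reads to the germline reference
#'
#' @param reads tibble with columns `read_id`, `sequence` (as produced by
#'   [simulate_repertoire()]), or a named character vector / `DNAStringSet`.
#' @param ref a [germline_reference()].
#' @return an AIRR-style rearrangement tibble, one row per read (see
#'   [align_to_germline()] for columns).
#' @export
align_reads <- function(reads, ref) {
  reads <- as_read_table(reads)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    align_one(reads$read_id[i], toupper(reads$sequence[i]), ref)
  })
  bind_rows(rows)
}

as_read_table <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    as_tibble(reads[c("read_id", "sequence")])
  } else if (methods::is(reads, "DNAStringSet")) {
    tibble(read_id = names(reads) %||% paste0("read", seq_along(reads)),
           sequence = as.character(reads))
  } else if (is.character(reads)) {
    tibble(read_id = names(reads) %||% paste0("read", seq_along(reads)),
           sequence = unname(reads))
  } else {
    abort("`reads` must be a data frame, character vector or DNAStringSet")
  }
}

#' Germline homology filter
#'
#' A read passes when its V-segment identity strictly exceeds the threshold
#' (the conventional "> 90% identity" rule).
#'
#' @param alignment alignment tibble from [align_reads()] (any number of rows).
#' @param threshold identity threshold, default 0.90.
#' @return logical vector.
#' @export
passes_homology_filter <- function(alignment, threshold = 0.90) {
  !is.na(alignment$v_identity) & alignment$v_identity > threshold
}

#' Productivity filter
#'
#' A read is productive when it covers the full V segment (FR1 start through
#' the CDR3 start), contains no V-region indel or ambiguous base, and its
#' in-frame translation up to the CDR3 start contains no stop codon.
#'
#' @param alignment alignment tibble from [align_reads()].
#' @return logical vector (the `productive` column).
#' @export
is_productive <- function(alignment) {
  alignment$productive
}

#' Extract the CDR3 junction from an alignment
#'
#' Returns the read suffix beginning at the position pairing with the CDR3
#' start. For synthetic reads the fixed J anchor (see
#' `shmrep:::J_ANCHOR`) is stripped when present; otherwise the suffix runs
#' to the read end.
#'
#' @param alignment one-row (or vectorised) alignment tibble.
#' @param strip_anchor strip the synthetic J anchor when the junction ends
#'   with it (default `TRUE`).
#' @return character vector of junction sequences.
#' @export
extract_junction <- function(alignment, strip_anchor = TRUE) {
  j <- alignment$junction
  if (any(is.na(j) | j == "")) abort("no CDR3: read truncated before the CDR3 start")
  if (strip_anchor) {
    has <- endsWith(j, J_ANCHOR)
    j[has] <- substr(j[has], 1L, nchar(j[has]) - nchar(J_ANCHOR))
    if (any(j == "")) abort("no CDR3: junction empty after removing the J anchor")
  }
  j
}
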