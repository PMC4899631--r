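#' Construct a germline V-segment reference
#'
#' The reference bundles the germline V nucleotide sequence with its
#' framework/CDR region boundaries and reading frame. All mutation positions
#' reported by the package are coordinates on this sequence (1-based in every
#' emitted table; 0-based half-open internally for the region map).
#'
#' @param name reference identifier, e.g. `"IGHV1-72"`.
#' @param sequence germline V nucleotide string over `{A,C,G,T}`, running from
#'   the start of FR1 to the end of FR3 (the CDR3 begins immediately after).
#' @param region_bounds a data frame with columns `region`
#'   (`FR1,CDR1,FR2,CDR2,FR3`), `start`, `end` giving 0-based half-open
#'   intervals on `sequence`. Regions must be contiguous, non-overlapping and
#'   ordered; FR3 must end at `nchar(sequence)`.
#' @param frame_offset reading-frame offset in `{0,1,2}`: translation starts at
#'   0-based position `frame_offset`. `(cdr3_start - frame_offset)` must be a
#'   multiple of 3 so that the V portion ends on a codon boundary.
#' @return an object of class `germline_reference` with fields `name`,
#'   `sequence`, `region_bounds`, `cdr3_start` (0-based index of the first
#'   CDR3 position = end of FR3) and `frame_offset`.
#' @seealso [load_reference()] to read the bundle from FASTA + TSV files.
#' @export
germline_reference <- function(name, sequence, region_bounds, frame_offset = 0L) {
  sequence <- toupper(sequence)
  check_dna(sequence, what = "germline sequence")
  bounds <- as_tibble(region_bounds)
  required <- c("region", "start", "end")
  if (!all(required %in% names(bounds))) {
    stop_field("region_bounds", "must have columns region, start, end")
  }
  order_expected <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")
  bounds <- bounds[match(order_expected, bounds$region), , drop = FALSE]
  if (anyNA(bounds$region)) {
    stop_field("region_bounds", "must define FR1, CDR1, FR2, CDR2 and FR3")
  }
  bounds$start <- as.integer(bounds$start)
  bounds$end <- as.integer(bounds$end)
  if (any(bounds$end <= bounds$start)) {
    stop_field("region_bounds", "each region must have end > start")
  }
  if (bounds$start[1] != 0L) {
    stop_field("region_bounds", "FR1 must start at position 0")
  }
  if (any(bounds$start[-1] != bounds$end[-5])) {
    stop_field("region_bounds",
               "regions must be contiguous and ordered FR1<CDR1<FR2<CDR2<FR3")
  }
  if (bounds$end[5] != nchar(sequence)) {
    stop_field("region_bounds", "FR3 must end at the end of the V sequence")
  }
  cdr3_start <- bounds$end[5]
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) stop_field("frame_offset", "must be 0, 1 or 2")
  if ((cdr3_start - frame_offset) %% 3L != 0L) {
    stop_field("frame_offset",
               sprintf("(cdr3_start - frame_offset) = %d is not divisible by 3",
                       cdr3_start - frame_offset))
  }
  structure(
    list(name = name, sequence = sequence, region_bounds = bounds,
         cdr3_start = cdr3_start, frame_offset = frame_offset),
    class = "germline_reference"
  )
}

#' @export
print.germline_reference <- function(x, ...) {
  cat(sprintf("<germline_reference> %s: %d nt, CDR3 starts at %d (frame %d)\n",
              x$name, nchar(x$sequence), x$cdr3_start + 1L, x$frame_offset))
  print(x$region_bounds)
  invisible(x)
}

#' Load a germline reference from FASTA and region-boundary files
#'
#' @param fasta_path FASTA file holding the single germline V sequence.
#' @param bounds_path TSV with columns `region`, `start`, `end` (0-based
#'   half-open) and optionally a single-row column `frame_offset`.
#' @param frame_offset reading-frame offset; overridden by a `frame_offset`
#'   column in the bounds file when present.
#' @return a [germline_reference()].
#' @export
load_reference <- function(fasta_path, bounds_path, frame_offset = 0L) {
  if (!file.exists(fasta_path)) abort(sprintf("FASTA not found: %s", fasta_path))
  if (!file.exists(bounds_path)) abort(sprintf("bounds TSV not found: %s", bounds_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) < 1L) abort("reference FASTA holds no sequence")
  if (length(seqs) > 1L) {
    warn("reference FASTA holds multiple sequences; using the first")
  }
  bounds <- readr::read_tsv(bounds_path, show_col_types = FALSE,
                            progress = FALSE)
  if ("frame_offset" %in% names(bounds)) {
    frame_offset <- bounds$frame_offset[1]
    bounds$frame_offset <- NULL
  }
  germline_reference(
    name = sub("\\s.*$", "", names(seqs)[1]),
    sequence = as.character(seqs[[1]]),
    region_bounds = bounds,
    frame_offset = frame_offset
  )
}

#' Region of each germline position
#'
#' @param ref a [germline_reference()].
#' @param position 1-based positions on the germline V sequence.
#' @return character vector of region names (`FR1`..`FR3`); `NA` outside the V.
#' @export
region_of_position <- function(ref, position) {
  stopifnot(inherits(ref, "germline_reference"))
  b <- ref$region_bounds
  idx <- findInterval(position - 1L, b$start)
  out <- rep(NA_character_, length(position))
  ok <- position >= 1L & position <= ref$cdr3_start
  out[ok] <- b$region[idx[ok]]
  out
}

#' Germline-centred 5-mer context of each V position
#'
#' Positions within two bases of either sequence end lack a complete 5-mer and
#' return `NA` (their context class is "unscored").
#'
#' @param ref a [germline_reference()].
#' @param position 1-based positions.
#' @return character vector of 5-mers (or `NA`).
#' @export
germline_context <- function(ref, position) {
  L <- nchar(ref$sequence)
  out <- rep(NA_character_, length(position))
  ok <- position >= 3L & position <= L - 2L
  if (any(ok)) {
    out[ok] <- substring(ref$sequence, position[ok] - 2L, position[ok] + 2L)
  }
  out
}
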