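#' Group filtered reads into clones by shared CDR3 junction
#'
#' Clone membership is defined by the exact CDR3 junction nucleotide string:
#' reads sharing an identical junction belong to one clone. Clones are sorted
#' by size (descending), ties broken by junction lexicographic order.
#'
#' @param alignments alignment tibble (rows should already have passed the
#'   homology and productivity filters); must contain `read_id`, `junction`
#'   and `v_seq`.
#' @param strip_anchor passed to [extract_junction()].
#' @return a `clone_set`: tibble with columns `clone_id`, `junction`, `size`,
#'   and list-columns `read_ids`, `v_seqs`.
#' @export
group_clones <- function(alignments, strip_anchor = TRUE) {
  if (nrow(alignments) == 0L) {
    out <- tibble(clone_id = integer(), junction = character(),
                  size = integer(), read_ids = list(), v_seqs = list())
    class(out) <- c("clone_set", class(out))
    return(out)
  }
  junction <- extract_junction(alignments, strip_anchor = strip_anchor)
  grp <- split(seq_len(nrow(alignments)), junction)
  out <- tibble(
    junction = names(grp),
    size = unname(vapply(grp, length, 1L)),
    read_ids = unname(lapply(grp, function(i) alignments$read_id[i])),
    v_seqs = unname(lapply(grp, function(i) alignments$v_seq[i]))
  )
  out <- arrange(out, desc(.data$size), .data$junction)
  out <- mutate(out, clone_id = dplyr::row_number(), .before = 1)
  class(out) <- c("clone_set", class(out))
  out
}

#' Clonal composition summary (pie-chart data)
#'
#' @param clones a `clone_set` from [group_clones()].
#' @param k number of top clones for the top-k share (default 3); when `k`
#'   exceeds the clone count the share is over all clones.
#' @return list with `clones` (tibble `clone_id, junction, size, fraction`),
#'   `n_sequences`, `n_clones` and `top_k_share` (fraction of all sequences
#'   in the `k` largest clones).
#' @export
clone_composition <- function(clones, k = 3L) {
  if (nrow(clones) == 0L) abort("empty clone set")
  total <- sum(clones$size)
  tab <- tibble(clone_id = clones$clone_id, junction = clones$junction,
                size = clones$size, fraction = clones$size / total)
  kk <- min(k, nrow(tab))
  list(clones = tab,
       n_sequences = total,
       n_clones = nrow(tab),
       top_k_share = sum(tab$fraction[seq_len(kk)]))
}

#' Majority-vote consensus sequence of a clone
#'
#' Collapses a clone to a single mutated consensus so that shared mutational
#' events are counted once. At each germline position, if a strict majority
#' (> half) of the voting members carry the same non-germline base, the
#' consensus takes that base; ties and sub-majority pluralities revert to the
#' germline base. Members with `N` at a position abstain there.
#'
#' @param v_seqs character vector of member V sequences, all aligned to the
#'   germline (equal length, no indels). A one-row slice of a `clone_set`
#'   also works via [clone_consensus_set()].
#' @param ref a [germline_reference()].
#' @return list of class `consensus_sequence`: `sequence` (consensus string)
#'   and `votes`, a tibble `(position, base, n)` of vote tallies at positions
#'   where any member differs from germline.
#' @export
clone_consensus <- function(v_seqs, ref) {
  stopifnot(inherits(ref, "germline_reference"))
  v_seqs <- unlist(v_seqs)
  L <- nchar(ref$sequence)
  if (any(nchar(v_seqs) != L)) {
    abort("members must all have the aligned germline length")
  }
  gc <- s2c(ref$sequence)
  mat <- do.call(rbind, lapply(v_seqs, s2c))
  cons <- gc
  votes <- list()
  for (p in seq_len(L)) {
    col <- mat[, p]
    col <- col[col %in% DNA_BASES]          # N and gaps abstain
    if (length(col) == 0L) next
    if (all(col == gc[p])) next
    tab <- table(col)
    top <- names(tab)[which.max(tab)]
    if (top != gc[p] && tab[[top]] > length(col) / 2) cons[p] <- top
    votes[[length(votes) + 1L]] <-
      tibble(position = p, base = names(tab), n = as.integer(tab))
  }
  structure(list(sequence = c2s(cons),
                 votes = if (length(votes)) bind_rows(votes) else
                   tibble(position = integer(), base = character(),
                          n = integer())),
            class = "consensus_sequence")
}

#' Consensus sequences for every clone in a clone set
#'
#' @param clones a `clone_set` from [group_clones()].
#' @param ref a [germline_reference()].
#' @return tibble `clone_id, junction, size, consensus`.
#' @export
clone_consensus_set <- function(clones, ref) {
  cons <- vapply(clones$v_seqs, function(v) clone_consensus(v, ref)$sequence, "")
  tibble(clone_id = clones$clone_id, junction = clones$junction,
         size = clones$size, consensus = unname(cons))
}
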