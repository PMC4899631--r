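# shared fixtures and independent oracles

# 60-nt toy germline, stop-free in frame 0
toy_reference <- function() {
  germline_reference(
    name = "toyV",
    sequence = "ATGGCACGTATTACCGGTTCAGCAATGGCACGTATTACCGGTTCAGCAATGGCACGTATT",
    region_bounds = data.frame(
      region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
      start = c(0, 9, 15, 27, 33),
      end = c(9, 15, 27, 33, 60)),
    frame_offset = 0L)
}

# 12-nt germline for small lineage-tree instances
tiny_reference <- function() {
  germline_reference(
    name = "tinyV",
    sequence = "ATGGCACGTATT",
    region_bounds = data.frame(
      region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
      start = c(0, 2, 4, 6, 8),
      end = c(2, 4, 6, 8, 12)),
    frame_offset = 0L)
}

# apply point substitutions (list of c(position, base)) to a reference sequence
mutate_seq <- function(ref, ...) {
  chars <- strsplit(ref$sequence, "")[[1]]
  for (m in list(...)) chars[[as.integer(m[[1]])]] <- m[[2]]
  paste(chars, collapse = "")
}

# regex-based oracle for hotspot/coldspot motif classification
oracle_context <- function(fivemer) {
  hot <- grepl("^[AT][AG]C", fivemer) |          # WRC, centre C
    grepl("^..G[CT][AT]$", fivemer) |            # GYW, centre G
    grepl("^.[AT]A", fivemer) |                  # WA, centre A
    grepl("^..T[AT]", fivemer)                   # TW, centre T
  cold <- grepl("^[CG][CT]C", fivemer) |         # SYC, centre C
    grepl("^..G[AG][CG]$", fivemer)              # GRS, centre G
  ifelse(hot, "hotspot", ifelse(cold, "coldspot", "neutral"))
}

all_fivemers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g, 1, paste, collapse = "")
}

# translate-and-compare oracle for replacement/silent, via seqinr
oracle_rs <- function(codon, pos_in_codon, to) {
  mut <- strsplit(codon, "")[[1]]
  mut[pos_in_codon] <- to
  aa1 <- seqinr::translate(strsplit(tolower(codon), "")[[1]])
  aa2 <- seqinr::translate(tolower(mut))
  if (identical(aa1, aa2)) "silent" else "replacement"
}

# ---- exhaustive Steiner-tree oracle over candidate intermediates -----------
# mutation sets are character vectors like "5:T"; the candidate pool is the
# closure of the observed sets under union and intersection
set_key <- function(s) paste(sort(s), collapse = ",")

set_closure <- function(sets) {
  pool <- unique(lapply(sets, sort))
  repeat {
    added <- FALSE
    for (i in seq_along(pool)) for (j in seq_along(pool)) {
      for (cand in list(sort(union(pool[[i]], pool[[j]])),
                        sort(intersect(pool[[i]], pool[[j]])))) {
        if (!set_key(cand) %in% vapply(pool, set_key, "")) {
          pool[[length(pool) + 1]] <- cand
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  pool
}

mst_weight <- function(dist_mat) {
  n <- nrow(dist_mat)
  if (n == 1) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  d <- dist_mat[1, ]
  total <- 0
  for (step in seq_len(n - 1)) {
    i <- which(!in_tree)[which.min(d[!in_tree])]
    total <- total + d[i]
    in_tree[i] <- TRUE
    d <- pmin(d, dist_mat[i, ])
  }
  total
}

# minimal total weight of a germline-rooted tree spanning the observed
# mutation sets, allowing up to (n_obs - 1) intermediates from the closure
steiner_min <- function(obs_sets) {
  obs_sets <- lapply(obs_sets, sort)
  base <- c(list(character(0)), obs_sets)
  base_keys <- unique(vapply(base, set_key, ""))
  cands <- Filter(function(s) !set_key(s) %in% base_keys, set_closure(obs_sets))
  base <- base[!duplicated(vapply(base, set_key, ""))]
  hamming <- function(a, b) length(union(a, b)) - length(intersect(a, b))
  best <- Inf
  max_extra <- max(0, length(obs_sets) - 1)
  idx_sets <- list(integer(0))
  if (length(cands) > 0) {
    for (k in seq_len(min(max_extra, length(cands)))) {
      idx_sets <- c(idx_sets,
                    lapply(asplit(utils::combn(length(cands), k), 2), as.integer))
    }
  }
  for (chosen in idx_sets) {
    nodes <- c(base, cands[chosen])
    n <- length(nodes)
    dm <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      dm[i, j] <- hamming(nodes[[i]], nodes[[j]])
    }
    best <- min(best, mst_weight(dm))
  }
  best
}

# random tree-generated mutation-set family on the tiny reference:
# every mutation arises once (fresh position), no reversions
random_lineage_sets <- function(n_obs, seed) {
  set.seed(seed)
  positions <- sample(1:12)
  bases <- c(A = "G", C = "T", G = "A", T = "C")  # use transition partners
  germ <- strsplit(tiny_reference()$sequence, "")[[1]]
  used <- 0
  nodes <- list(character(0))
  for (i in seq_len(n_obs + 2)) {
    parent <- nodes[[sample.int(length(nodes), 1)]]
    n_new <- sample(1:2, 1)
    new <- character(0)
    for (j in seq_len(n_new)) {
      if (used >= length(positions)) break
      used <- used + 1
      p <- positions[used]
      new <- c(new, paste0(p, ":", bases[[germ[p]]]))
    }
    nodes[[length(nodes) + 1]] <- c(parent, new)
  }
  sets <- nodes[-1]
  sets[sample.int(length(sets), min(n_obs, length(sets)))]
}

set_to_seq <- function(ref, set) {
  chars <- strsplit(ref$sequence, "")[[1]]
  for (m in set) {
    p <- strsplit(m, ":", fixed = TRUE)[[1]]
    chars[as.integer(p[1])] <- p[2]
  }
  paste(chars, collapse = "")
}

# mutation set of a sequence vs its reference (same encoding as above)
seq_to_set <- function(ref, seq) {
  g <- strsplit(ref$sequence, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  d <- which(g != s)
  if (length(d) == 0) character(0) else paste0(d, ":", s[d])
}
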