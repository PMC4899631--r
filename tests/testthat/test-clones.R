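aligned_fixture <- function(ref, junctions, v_seqs = NULL) {
  n <- length(junctions)
  tibble::tibble(
    read_id = paste0("r", seq_len(n)),
    junction = paste0(junctions, shmrep:::J_ANCHOR),
    v_seq = v_seqs %||% rep(ref$sequence, n),
    partial = FALSE, indel = FALSE, productive = TRUE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reads sharing a junction form one clone, sorted by size", {
  ref <- toy_reference()
  cl <- group_clones(aligned_fixture(ref, c("J1", "J1", "J1", "J2", "J2")))
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$size, c(3L, 2L))
  expect_equal(cl$junction, c("J1", "J2"))
  single <- group_clones(aligned_fixture(ref, "JX"))
  expect_equal(single$size, 1L)
  empty <- group_clones(aligned_fixture(ref, character(0))[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("clone recovery on synthetic data matches the truth partition", {
  ref <- synthetic_reference()
  cfg <- sim_config(n_clones = 12, mutations_per_lineage_step = 1.5,
                    sequencing_error_rate = 0, seed = 91)
  sim <- simulate_repertoire(ref, targeting_model(), cfg)
  a <- align_reads(sim$reads, ref)
  kept <- a[a$productive & passes_homology_filter(a), ]
  cl <- group_clones(kept)
  # compare against the truth partition over the reads that pass the filters
  # (SHM itself occasionally creates stop codons, which are rightly excluded)
  truth_kept <- sim$truth$clones[sim$truth$clones$read_id %in% kept$read_id, ]
  truth_parts <- split(truth_kept$read_id, truth_kept$clone_id)
  got_parts <- cl$read_ids
  key <- function(parts) sort(vapply(parts, function(x)
    paste(sort(x), collapse = "|"), ""))
  expect_equal(key(got_parts), unname(key(truth_parts)))
})

test_that("composition fractions sum to 1 and top-k share is a brute-force sum", {
  ref <- toy_reference()
  sizes <- c(30, 29, 12, 8)
  junctions <- rep(paste0("J", seq_along(sizes)), times = sizes)
  comp <- clone_composition(group_clones(aligned_fixture(ref, junctions)))
  expect_equal(sum(comp$clones$fraction), 1)
  expect_equal(comp$top_k_share, sum(sort(sizes, decreasing = TRUE)[1:3]) / 79)
  expect_equal(comp$top_k_share, 71 / 79)
  one <- clone_composition(group_clones(aligned_fixture(ref, "J1")))
  expect_equal(one$clones$fraction, 1)
  expect_equal(one$n_clones, 1L)
  # k beyond the clone count covers all clones
  expect_equal(clone_composition(group_clones(aligned_fixture(ref, junctions)),
                                 k = 99)$top_k_share, 1)
})

test_that("consensus takes a strict majority and ties revert to germline", {
  ref <- toy_reference()
  v_major <- c(mutate_seq(ref, c(5, "T")), mutate_seq(ref, c(5, "T")),
               ref$sequence)
  cc <- clone_consensus(v_major, ref)
  expect_equal(substr(cc$sequence, 5, 5), "T")
  v_tie <- c(mutate_seq(ref, c(5, "T")), ref$sequence)
  expect_equal(clone_consensus(v_tie, ref)$sequence, ref$sequence)
  v_single <- mutate_seq(ref, c(8, "A"), c(20, "C"))
  expect_equal(clone_consensus(v_single, ref)$sequence, v_single)
  expect_error(clone_consensus(c(ref$sequence, "ACGT"), ref), "length")
})

test_that("plurality below half reverts to germline; N abstains", {
  ref <- toy_reference()
  # 2/5 carry T, 2/5 carry C, 1/5 germline: no strict majority
  v <- c(mutate_seq(ref, c(5, "T")), mutate_seq(ref, c(5, "T")),
         mutate_seq(ref, c(5, "C")), mutate_seq(ref, c(5, "C")),
         ref$sequence)
  expect_equal(clone_consensus(v, ref)$sequence, ref$sequence)
  # N members abstain: 2 T of 2 voting -> majority
  vn <- c(mutate_seq(ref, c(5, "T")), mutate_seq(ref, c(5, "T")),
          mutate_seq(ref, c(5, "N")))
  expect_equal(substr(clone_consensus(vn, ref)$sequence, 5, 5), "T")
})

test_that("consensus is idempotent and conservative (subset of member mutations)", {
  ref <- synthetic_reference()
  set.seed(101)
  m <- targeting_model()
  founder <- apply_shm(ref$sequence, m, 4)$sequence
  members <- vapply(1:5, function(i) apply_shm(founder, m, 2)$sequence, "")
  cc <- clone_consensus(members, ref)
  member_union <- unique(unlist(lapply(members, function(s)
    seq_to_set(ref, s))))
  expect_true(all(seq_to_set(ref, cc$sequence) %in% member_union))
  expect_equal(clone_consensus(cc$sequence, ref)$sequence, cc$sequence)
})

test_that("star lineages recover the founder mutation set exactly", {
  ref <- synthetic_reference()
  set.seed(111)
  m <- targeting_model()
  for (rep in 1:5) {
    founder <- apply_shm(ref$sequence, m, 5)$sequence
    founder_set <- seq_to_set(ref, founder)
    # each member adds private mutations at fresh positions
    used <- as.integer(sub(":.*", "", founder_set))
    members <- vapply(1:4, function(i) {
      chars <- strsplit(founder, "")[[1]]
      free <- setdiff(seq_along(chars), used)
      at <- sample(free, 2)
      used <<- c(used, at)
      for (p in at) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
      paste(chars, collapse = "")
    }, "")
    cc <- clone_consensus(members, ref)
    expect_setequal(seq_to_set(ref, cc$sequence), founder_set)
  }
})
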