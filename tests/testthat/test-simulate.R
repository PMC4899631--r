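test_that("apply_shm is the identity for zero mutations and errors past the length", {
  ref <- toy_reference()
  m <- targeting_model()
  out <- apply_shm(ref$sequence, m, 0, seed = 1)
  expect_equal(out$sequence, ref$sequence)
  expect_equal(nrow(out$mutations), 0L)
  expect_error(apply_shm("ACGT", m, 5), "exceeds sequence length")
})

test_that("apply_shm mutates exactly n distinct positions, ordered by position", {
  ref <- synthetic_reference()
  m <- targeting_model()
  out <- apply_shm(ref$sequence, m, 25, seed = 3)
  expect_equal(nrow(out$mutations), 25L)
  expect_false(any(duplicated(out$mutations$position)))
  expect_equal(out$mutations$position, sort(out$mutations$position))
  # mutation list is consistent with the sequence diff
  g <- strsplit(ref$sequence, "")[[1]]
  s <- strsplit(out$sequence, "")[[1]]
  d <- which(g != s)
  expect_equal(out$mutations$position, d)
  expect_equal(out$mutations$from, g[d])
  expect_equal(out$mutations$to, s[d])
})

test_that("transition_fraction = 1 forces transitions; = 0 forces transversions", {
  ref <- synthetic_reference()
  out <- apply_shm(ref$sequence, targeting_model(transition_fraction = 1),
                   50, seed = 5)
  expect_true(all(classify_substitution(out$mutations$from,
                                        out$mutations$to) == "transition"))
  out0 <- apply_shm(ref$sequence, targeting_model(transition_fraction = 0),
                    50, seed = 5)
  expect_true(all(classify_substitution(out0$mutations$from,
                                        out0$mutations$to) == "transversion"))
})

test_that("an override table with sole support pins the mutated position", {
  ref <- synthetic_reference()
  # pick a 5-mer context that occurs exactly once in the germline
  ctx <- germline_context(ref, 3:(nchar(ref$sequence) - 2))
  singletons <- names(which(table(ctx) == 1))
  target <- singletons[1]
  centre <- 2L + which(ctx == target)
  m <- targeting_model(hot_mutability = 0, cold_mutability = 0,
                       neutral_mutability = 0,
                       override = stats::setNames(1, target))
  out <- apply_shm(ref$sequence, m, 1, seed = 9)
  expect_equal(out$mutations$position, centre)
})

test_that("targeting model validation names the offending field", {
  expect_error(targeting_model(hot_mutability = -1), "hot_mutability")
  expect_error(targeting_model(transition_fraction = 1.2), "transition_fraction")
  expect_error(targeting_model(override = c(ACG = 1)), "override")
  expect_error(sim_config(n_clones = 0), "n_clones")
  expect_error(sim_config(sequencing_error_rate = 1), "sequencing_error_rate")
})

test_that("zero-mutation, error-free repertoires reproduce germline + junction", {
  ref <- toy_reference()
  cfg <- sim_config(n_clones = 3, clone_size_law = "fixed",
                    clone_size_param = 1, mutations_per_lineage_step = 0,
                    sequencing_error_rate = 0, seed = 11)
  sim <- simulate_repertoire(ref, targeting_model(), cfg)
  expect_equal(nrow(sim$reads), 3L)
  expect_equal(nrow(sim$truth$mutations), 0L)
  junctions <- sim$truth$junctions$junction
  expect_equal(sim$reads$sequence,
               paste0(ref$sequence, junctions, shmrep:::J_ANCHOR))
  # clone founders carry distinct junctions
  expect_false(any(duplicated(junctions)))
})

test_that("identical seeds give byte-identical FASTA and truth tables", {
  ref <- synthetic_reference()
  cfg <- sim_config(n_clones = 6, mutations_per_lineage_step = 2,
                    sequencing_error_rate = 0.002, seed = 21)
  d1 <- tempfile(); d2 <- tempfile()
  write_repertoire(simulate_repertoire(ref, targeting_model(), cfg), d1)
  write_repertoire(simulate_repertoire(ref, targeting_model(), cfg), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
})

test_that("truth mutations equal the diff of each read against its founder", {
  ref <- synthetic_reference()
  cfg <- sim_config(n_clones = 10, mutations_per_lineage_step = 2, seed = 31)
  sim <- simulate_repertoire(ref, targeting_model(), cfg)
  g <- strsplit(ref$sequence, "")[[1]]
  L <- length(g)
  for (i in seq_len(nrow(sim$reads))) {
    v <- strsplit(substr(sim$reads$sequence[i], 1, L), "")[[1]]
    d <- which(v != g)
    tm <- sim$truth$mutations[sim$truth$mutations$read_id ==
                                sim$reads$read_id[i], ]
    expect_equal(tm$position, d)
    expect_equal(tm$to, v[d])
  }
})

test_that("uniform mutability gives uniform per-position counts (chi-square)", {
  ref <- synthetic_reference()
  m <- targeting_model(hot_mutability = 1, cold_mutability = 1,
                       neutral_mutability = 1)
  set.seed(41)
  L <- nchar(ref$sequence)
  counts <- integer(L)
  for (i in 1:100) {
    mu <- apply_shm(ref$sequence, m, 100)$mutations
    counts[mu$position] <- counts[mu$position] + 1L
  }
  expect_gte(sum(counts), 10000L)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("hot-context mutation share matches the germline enumeration", {
  ref <- synthetic_reference()
  m <- targeting_model(hot_mutability = 5, cold_mutability = 0.2,
                       neutral_mutability = 1)
  cfg <- sim_config(n_clones = 1000, clone_size_law = "fixed",
                    clone_size_param = 1, mutations_per_lineage_step = 2,
                    max_depth = 1, seed = 51)
  sim <- simulate_repertoire(ref, m, cfg)
  muts <- sim$truth$mutations
  n <- nrow(muts)
  expect_gte(n, 1500L)
  cls <- shmrep:::context_group(
    shmrep:::context_class(germline_context(ref, muts$position)))
  obs_hot <- mean(cls[cls != "unscored"] == "hotspot")
  # exact expectation by enumerating germline positions and model weights
  w <- position_mutability(ref$sequence, m)
  pos_cls <- shmrep:::context_group(
    shmrep:::context_class(germline_context(ref, seq_len(nchar(ref$sequence)))))
  scored <- pos_cls != "unscored"
  exp_hot <- sum(w[scored & pos_cls == "hotspot"]) / sum(w[scored])
  se <- sqrt(exp_hot * (1 - exp_hot) / n)
  expect_lt(abs(obs_hot - exp_hot), 3 * se)
})

test_that("decay series follow the closed form and validate inputs", {
  s <- simulate_decay_series(100, 10, c(0, 10, 20), cv_noise = 0)
  expect_equal(s$count, c(100, 50, 25))
  expect_equal(s$ratio[1], 1)
  expect_error(simulate_decay_series(-1, 10, c(0, 1, 2)), "y0")
  expect_error(simulate_decay_series(10, 0, c(0, 1, 2)), "half_life")
  expect_error(simulate_decay_series(10, 10, numeric(0)), "timepoints")
})
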