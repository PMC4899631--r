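test_that("mutation calling reports V-region substitutions only, fully classified", {
  ref <- toy_reference()
  expect_equal(nrow(call_mutations(ref$sequence, ref)), 0L)
  v <- mutate_seq(ref, c(10, "C"), c(40, "A"))
  mu <- call_mutations(v, ref, id = "s1")
  expect_equal(mu$position, c(10L, 40L))
  expect_equal(mu$region, c("CDR1", "FR3"))
  expect_equal(mu$from, c(substr(ref$sequence, 10, 10),
                          substr(ref$sequence, 40, 40)))
  expect_true(all(mu$substitution %in% c("transition", "transversion")))
  expect_true(all(mu$coding_class %in% c("replacement", "silent")))
  expect_error(call_mutations("ACGT", ref), "length")
})

test_that("edge positions are unscored for context but still called", {
  ref <- toy_reference()
  g1 <- substr(ref$sequence, 1, 1)
  v <- mutate_seq(ref, c(1, setdiff(c("A", "C", "G", "T"), g1)[1]))
  mu <- call_mutations(v, ref)
  expect_equal(mu$position, 1L)
  expect_equal(mu$context_class, "unscored")
  expect_true(is.na(mu$fivemer))
})

test_that("single-consensus mutability counting matches the worked example", {
  # germline with the mutated position's 5-mer occurring 4 times
  bounds <- data.frame(region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
                       start = c(0, 6, 12, 18, 24), end = c(6, 12, 18, 24, 33))
  g <- "AACGTTAACGTTAACGTTAACGTTGGGCCCGGG"
  ref <- germline_reference("quad", g, bounds)
  ctx <- germline_context(ref, 4)  # CGTTA... position 4 centre
  occurrences <- sum(vapply(3:31, function(p)
    identical(germline_context(ref, p), ctx), TRUE))
  expect_equal(occurrences, 4L)
  cons <- mutate_seq(ref, c(4, "A"))  # G -> A at the centre of that 5-mer
  tab <- estimate_mutability(cons, ref)
  row <- tab[tab$fivemer == ctx, ]
  expect_equal(row$mutations, 1L)
  expect_equal(row$background, 4L)
  expect_equal(row$raw_rate, 0.25)
  expect_true(all(tab$raw_rate[tab$fivemer != ctx] == 0))
})

test_that("mutability table is normalized to background-weighted mean 1", {
  ref <- synthetic_reference()
  set.seed(121)
  cons <- vapply(1:50, function(i)
    apply_shm(ref$sequence, targeting_model(), 3)$sequence, "")
  tab <- estimate_mutability(cons, ref)
  expect_equal(sum(tab$mutations),
               nrow(dplyr::filter(
                 dplyr::bind_rows(lapply(cons, call_mutations, ref = ref)),
                 !is.na(fivemer))))
  wm <- sum(tab$mutability * tab$background) / sum(tab$background)
  expect_equal(wm, 1, tolerance = 1e-9)
})

test_that("hotspot fractions sum to one and flag empty input", {
  ref <- toy_reference()
  v <- mutate_seq(ref, c(10, "C"), c(20, "A"), c(40, "G"))
  fr <- summarize_hotspot_fractions(call_mutations(v, ref))
  expect_equal(sum(fr$fraction), 1)
  expect_warning(summarize_hotspot_fractions(call_mutations(ref$sequence, ref)),
                 "undefined")
})

test_that("transitions + transversions = total for any mutation set", {
  ref <- synthetic_reference()
  set.seed(131)
  mu <- dplyr::bind_rows(lapply(1:10, function(i)
    call_mutations(apply_shm(ref$sequence, targeting_model(), 8)$sequence,
                   ref, id = as.character(i))))
  tv <- summarize_titv(mu)
  expect_equal(sum(tv$n), nrow(mu))
  expect_equal(sum(tv$fraction), 1)
})

test_that("R/S ratios by region follow the counts, with Inf/NA markers", {
  mu <- tibble::tibble(
    sequence_id = "x",
    position = 1:8,
    region = c(rep("CDR1", 8))[1:8],
    coding_class = c(rep("replacement", 6), rep("silent", 2)),
    context_class = "neutral", fivemer = NA, from = "A", to = "G",
    substitution = "transition")
  rs <- summarize_rs_by_region(mu, toy_reference())
  cdr1 <- rs$by_region[rs$by_region$region == "CDR1", ]
  expect_equal(cdr1$rs_ratio, 3)
  empty <- rs$by_region[rs$by_region$region == "FR2", ]
  expect_equal(empty$replacement, 0L)
  expect_true(is.na(empty$rs_ratio))
  mu_r <- dplyr::mutate(mu, coding_class = "replacement")
  rs_r <- summarize_rs_by_region(mu_r, toy_reference())
  expect_equal(rs_r$by_region$rs_ratio[2], Inf)
})

test_that("uniform substitutions reproduce the enumerated expected R/S by region", {
  ref <- toy_reference()
  g <- strsplit(ref$sequence, "")[[1]]
  # enumeration oracle: all 180 possible single substitutions
  enum <- do.call(rbind, lapply(seq_len(60), function(p) {
    data.frame(position = p,
               to = setdiff(c("A", "C", "G", "T"), g[p]))
  }))
  enum$region <- region_of_position(ref, enum$position)
  enum$rs <- classify_rs(enum$position, enum$to, ref)
  exp_by_region <- tapply(enum$rs == "replacement", enum$region, mean)

  set.seed(141)
  n <- 6000
  pos <- sample(60, n, replace = TRUE)
  to <- vapply(pos, function(p) sample(setdiff(c("A", "C", "G", "T"), g[p]), 1), "")
  mu <- tibble::tibble(sequence_id = "sim", position = pos, from = g[pos],
                       to = to, region = region_of_position(ref, pos),
                       substitution = "transition", fivemer = NA,
                       context_class = "neutral",
                       coding_class = classify_rs(pos, to, ref))
  rs <- summarize_rs_by_region(mu, ref)
  for (rg in rs$by_region$region) {
    row <- rs$by_region[rs$by_region$region == rg, ]
    tot <- row$replacement + row$silent
    p_exp <- exp_by_region[[rg]]
    se <- sqrt(p_exp * (1 - p_exp) / tot)
    expect_lt(abs(row$replacement / tot - p_exp), 3 * se + 1e-9)
  }
})

test_that("mutation load summaries group and pool correctly", {
  loads <- tibble::tibble(read_id = c("a", "b", "c", "d"),
                          n_mutations = c(2L, 4L, 0L, 0L))
  md <- tibble::tibble(read_id = c("a", "b", "c", "d"),
                       isotype = c("IgG", "IgG", "IgM", "IgM"),
                       tissue = c("spleen", "bone_marrow", "spleen", "spleen"),
                       treatment = "control", animal = "m1")
  s <- mutation_load_summary(loads, md, group_by = c("isotype"))
  expect_equal(s$mean_load[s$isotype == "IgG"], 3)
  expect_equal(s$fraction_unmutated[s$isotype == "IgM"], 1)
  loads2 <- tibble::tibble(read_id = c("a", "b", "c"),
                           n_mutations = c(0L, 0L, 3L))
  md2 <- tibble::tibble(read_id = c("a", "b", "c"), isotype = "IgM",
                        tissue = "spleen", treatment = "control",
                        animal = "m1")
  s2 <- mutation_load_summary(loads2, md2, group_by = "isotype")
  expect_equal(s2$fraction_unmutated, 2 / 3)
  expect_error(mutation_load_summary(loads, md, group_by = "nope"), "keys")
})

test_that("poisson mutation loads are recovered from simulated reads", {
  ref <- synthetic_reference()
  cfg <- sim_config(n_clones = 500, clone_size_law = "fixed",
                    clone_size_param = 1, mutations_per_lineage_step = 3.3,
                    max_depth = 1, seed = 151)
  sim <- simulate_repertoire(ref, targeting_model(), cfg)
  a <- align_reads(sim$reads, ref)
  loads <- sequence_loads(a, ref)
  s <- mutation_load_summary(loads, sim$metadata, group_by = "isotype")
  se <- sqrt(3.3 / 500)
  expect_lt(abs(s$mean_load - 3.3), 3 * se)
})

test_that("error-only reads show the error floor but no AID signature", {
  ref <- synthetic_reference()
  cfg <- sim_config(n_clones = 150, clone_size_law = "fixed",
                    clone_size_param = 1, mutations_per_lineage_step = 0,
                    sequencing_error_rate = 0.002, seed = 161,
                    metadata = list(isotype = "preB", tissue = "bone_marrow",
                                    treatment = "control", animal = "m1"))
  sim <- simulate_repertoire(ref, targeting_model(), cfg)
  a <- align_reads(sim$reads, ref)
  keep <- !a$partial & !a$indel
  loads <- sequence_loads(a[keep, ], ref)
  expect_lt(abs(mean(loads$n_mutations) - 294 * 0.002), 3 * sqrt(294 * 0.002 / 150))
  mu <- dplyr::bind_rows(lapply(a$v_seq[keep], call_mutations, ref = ref))
  fr <- summarize_hotspot_fractions(mu)
  # germline context share of hotspots among scored positions
  cls <- shmrep:::context_group(shmrep:::context_class(
    germline_context(ref, 3:292)))
  share <- mean(cls == "hotspot")
  n <- sum(fr$n)
  expect_lt(abs(fr$fraction[fr$context_group == "hotspot"] - share),
            3 * sqrt(share * (1 - share) / n) + 0.05)
})
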