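# Curation filter, redundancy reduction, chain clustering, domain
# decomposition and the serialisable index.

test_that("filter_entries applies the length and resolution thresholds", {
  mk <- function(id, n, res) toy_chain(id, n = n, seed = nchar(id),
                                       resolution = res)
  entries <- list(mk("a_A", 15, 2.0),   # too short
                  mk("b_A", 16, 3.5),   # boundary: kept
                  mk("c_A", 200, NA),   # unknown resolution: dropped
                  mk("d_A", 40, 3.6),   # resolution too low
                  mk("e_A", 40, 1.2))
  kept <- filter_entries(entries)
  expect_equal(vapply(kept, `[[`, "", "entry_id"), c("b_A", "e_A"))
  reasons <- attr(kept, "removed")
  expect_equal(unname(reasons[c("a_A", "c_A", "d_A")]),
               c("too short", "resolution unknown", "resolution too low"))
  # idempotence
  again <- filter_entries(kept)
  expect_equal(vapply(again, `[[`, "", "entry_id"),
               vapply(kept, `[[`, "", "entry_id"))
})

test_that("redundancy reduction keeps the higher-resolution duplicate", {
  base <- toy_chain("hi_A", n = 40, seed = 11, resolution = 1.5)
  dup <- chain_entry("lo_A", new_sequence("lo_A", base$sequence$residues),
                     perturb_coords(base$ca, 0.2, 3), resolution = 2.0)
  kept <- redundancy_reduce(list(dup, base))
  expect_equal(vapply(kept, `[[`, "", "entry_id"), "hi_A")
  expect_equal(attr(kept, "displaced")[["lo_A"]], "hi_A")
})

test_that("conformational variants are both retained", {
  base <- toy_chain("one_A", n = 40, seed = 12, resolution = 1.5)
  # same sequence, different conformation (rmsd far above 1 A)
  variant <- chain_entry("two_A",
                         new_sequence("two_A", base$sequence$residues),
                         perturb_coords(base$ca, 3.0, 5), resolution = 2.0)
  kept <- redundancy_reduce(list(base, variant))
  expect_setequal(vapply(kept, `[[`, "", "entry_id"), c("one_A", "two_A"))
})

test_that("redundancy reduction matches the exhaustive pairwise oracle", {
  entries <- planted_redundant_set(n_groups = 2, per_group = 3, n_single = 2)
  ids <- names(entries)
  n <- length(ids)
  idm <- matrix(0, n, n, dimnames = list(ids, ids))
  rmsdm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { idm[i, j] <- 1; rmsdm[i, j] <- 0; next }
    al <- align_pair(entries[[i]]$sequence, entries[[j]]$sequence)
    idm[i, j] <- al$identity
    rmsdm[i, j] <- aligned_ca_rmsd(entries[[i]], entries[[j]], al)
  }
  expected <- oracle_redundancy(ids,
                                vapply(entries, `[[`, 0, "resolution"),
                                idm, rmsdm)
  kept <- redundancy_reduce(entries)
  expect_equal(sort(vapply(kept, `[[`, "", "entry_id")), expected)
  # order independence: a shuffled input gives the same retained set
  set.seed(9)
  kept2 <- redundancy_reduce(sample(entries))
  expect_equal(sort(vapply(kept2, `[[`, "", "entry_id")), expected)
  # fixed point: re-running removes nothing
  kept3 <- redundancy_reduce(kept)
  expect_equal(vapply(kept3, `[[`, "", "entry_id"),
               vapply(kept, `[[`, "", "entry_id"))
  # every displaced entry has a retained representative at least as good
  disp <- attr(kept, "displaced")
  res <- vapply(entries, `[[`, 0, "resolution")
  for (rm in names(disp)) expect_lte(res[[disp[[rm]]]], res[[rm]])
})

test_that("chain clustering degenerates cleanly and orders merges by identity", {
  single <- cluster_chains(list(toy_chain("only_A", n = 20, seed = 1)))
  expect_equal(single$labels, "only_A")
  expect_equal(nrow(single$merge), 0L)

  s <- random_seq_string(30, 77)
  twins_plus <- list(
    chain_entry("t1_A", new_sequence("t1_A", s), make_globule(30, 1)),
    chain_entry("t2_A", new_sequence("t2_A", s), make_globule(30, 2)),
    toy_chain("far_A", n = 30, seed = 99))
  h <- cluster_chains(twins_plus)
  # the identical pair merges first, at height ~0
  expect_equal(sort(h$merge[1, ]), c(-2L, -1L))
  expect_lt(h$height[1], 1e-9)
})

test_that("chain clustering equals naive average linkage on the identity matrix", {
  entries <- lapply(1:8, function(i) toy_chain(sprintf("c%d_A", i),
                                               n = 25, seed = 300 + i))
  # make some related pairs so the tree is non-trivial
  entries[[2]] <- chain_entry("c2_A",
    new_sequence("c2_A", mutate_string(entries[[1]]$sequence$residues, 2, 5)),
    make_globule(25, 302))
  entries[[5]] <- chain_entry("c5_A",
    new_sequence("c5_A", mutate_string(entries[[4]]$sequence$residues, 5, 6)),
    make_globule(25, 305))
  h <- cluster_chains(entries)
  hc <- mrpilot:::as_hclust(h)
  got <- as.matrix(stats::cophenetic(hc))
  want <- oracle_average_linkage_cophenetic(1 - h$identity)
  dimnames(want) <- dimnames(got)
  expect_equal(got[h$labels, h$labels], want[h$labels, h$labels],
               tolerance = 1e-9)
})

test_that("domain decomposition splits a dumbbell at the linker", {
  n1 <- 60; n2 <- 60; linker <- 5
  ca <- make_dumbbell(n1, n2, linker, separation = 40, seed = 8)
  n <- nrow(ca)
  entry <- chain_entry("db_A", new_sequence("db_A", random_seq_string(n, 8)),
                       ca, resolution = 2.0)
  doms <- decompose_domains(entry, min_domain_len = 40)
  expect_length(doms, 2L)
  # oracle: exhaustive single-cut search minimising severed contacts
  d <- as.matrix(dist(ca))
  contact <- d <= 8 & abs(row(d) - col(d)) >= 3 & upper.tri(d)
  ij <- which(contact, arr.ind = TRUE)
  cuts <- 40:(n - 40)
  sever <- vapply(cuts, function(k) sum(ij[, 1] <= k & ij[, 2] > k), 0L)
  best_cut <- cuts[which.min(sever)]
  expect_lte(abs(doms[[1]]$residue_ranges[1, 2] - best_cut), 2L)
  # ranges partition the chain exactly
  covered <- unlist(lapply(doms, function(dm)
    seq(dm$residue_ranges[1, 1], dm$residue_ranges[1, 2])))
  expect_equal(sort(covered), seq_len(n))
})

test_that("compact and short chains give one whole-chain domain", {
  glob <- toy_chain("g_A", n = 90, seed = 21)
  doms <- decompose_domains(glob, min_domain_len = 40)
  expect_length(doms, 1L)
  expect_equal(doms[[1]]$residue_ranges, cbind(1L, 90L),
               ignore_attr = TRUE)
  short <- toy_chain("s_A", n = 30, seed = 22)
  expect_length(decompose_domains(short, min_domain_len = 40), 1L)
})

test_that("the library index validates references and round-trips", {
  chains <- lapply(1:3, function(i) toy_chain(sprintf("ch%d_A", i),
                                              n = 20, seed = 400 + i))
  names(chains) <- vapply(chains, `[[`, "", "entry_id")
  doms <- list(domain_entry("ch1_A", 1, cbind(1, 10)),
               domain_entry("ch1_A", 2, cbind(11, 20)))
  asm <- list(assembly_record("ch2_A", list(
    identity_operator(),
    list(rotation = rotation_z(180), translation = c(30, 0, 0)))))
  idx <- build_index(chains, doms, asm)
  f <- withr_local_tempfile(fileext = ".json")
  save_index(idx, f)
  back <- load_index(f)
  expect_equal(length(back$chains), 3L)
  expect_equal(back$chains[["ch1_A"]]$sequence$residues,
               chains[["ch1_A"]]$sequence$residues)
  expect_equal(back$chains[["ch3_A"]]$ca, round(chains[["ch3_A"]]$ca, 3),
               ignore_attr = TRUE)
  expect_equal(back$domains[[2]]$residue_ranges, cbind(11L, 20L),
               ignore_attr = TRUE)
  expect_equal(back$assemblies[[1]]$multimer_size, 2L)
  expect_equal(back$assemblies[[1]]$operators[[2]]$rotation,
               rotation_z(180), tolerance = 1e-9)
  # a second save of the reloaded index is byte-identical
  f2 <- withr_local_tempfile(fileext = ".json")
  save_index(back, f2)
  expect_identical(readLines(f), readLines(f2))

  expect_error(build_index(chains,
                           list(domain_entry("ghost_A", 1, cbind(1, 5)))),
               "ghost_A")
  empty <- build_index(list())
  expect_length(empty$chains, 0L)
})

test_that("rotation validation rejects improper operators", {
  expect_error(assembly_record("x_A", list(
    list(rotation = diag(c(1, 1, -1)), translation = c(0, 0, 0)))),
    "proper rotation")
})
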