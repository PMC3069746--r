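# Model editing: side-chain pruning, polyalanine, domain extraction,
# superposition, ensembles and assembly expansion.

test_that("the shared-atom rule keeps the longest common side-chain prefix", {
  expect_setequal(mrpilot:::shared_atoms("LYS", "ALA"),
                  c("N", "CA", "C", "O", "CB"))
  expect_setequal(mrpilot:::shared_atoms("PHE", "TYR"),
                  c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2",
                    "CE1", "CE2", "CZ"))
  expect_setequal(mrpilot:::shared_atoms("TYR", "PHE"),
                  c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2",
                    "CE1", "CE2", "CZ"))
  expect_setequal(mrpilot:::shared_atoms("LYS", "GLY"),
                  c("N", "CA", "C", "O"))
  # branch mismatch truncates at the divergence point
  expect_setequal(mrpilot:::shared_atoms("ILE", "LEU"),
                  c("N", "CA", "C", "O", "CB"))
  expect_setequal(mrpilot:::shared_atoms("GLU", "GLN"),
                  c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1"))
})

test_that("mixed models prune, relabel and delete as the alignment dictates", {
  tpl <- toy_chain("tpl_A", residues = "KFVLGKMKVL", seed = 31)
  # target substitutes K1->A, F2->Y and deletes the template's last residue
  tgt <- new_sequence("tgt", "AYVLGKMKV")
  al <- align_pair(tgt, tpl$sequence)
  m <- make_mixed_model(tpl, al, tgt)
  r1 <- m$atoms[m$atoms$resno == 1, ]
  expect_setequal(r1$elety, c("N", "CA", "C", "O", "CB"))
  expect_true(all(r1$resid == "ALA"))
  r2 <- m$atoms[m$atoms$resno == 2, ]
  expect_setequal(r2$elety, c("N", "CA", "C", "O", "CB", "CG", "CD1",
                              "CD2", "CE1", "CE2", "CZ"))
  expect_true(all(r2$resid == "TYR"))
  expect_false(10 %in% m$atoms$resno)   # unaligned template residue gone
  # conserved residues keep every template atom
  r3 <- m$atoms[m$atoms$resno == 3, ]
  expect_setequal(r3$elety, tpl$atoms$elety[tpl$atoms$resno == 3])
})

test_that("identity alignment reproduces the template atoms exactly", {
  tpl <- toy_chain("tpl_A", n = 10, seed = 32)
  tgt <- new_sequence("tgt", tpl$sequence$residues)
  m <- make_mixed_model(tpl, align_pair(tgt, tpl$sequence), tgt)
  expect_equal(m$atoms[, c("elety", "resid", "x", "y", "z")],
               tpl$atoms[, c("elety", "resid", "x", "y", "z")],
               ignore_attr = TRUE)
})

test_that("mixed models never add atoms and error on sparse alignments", {
  tpl <- toy_chain("tpl_A", n = 20, seed = 33)
  tgt <- new_sequence("tgt", mutate_string(tpl$sequence$residues, 8, 34))
  m <- make_mixed_model(tpl, align_pair(tgt, tpl$sequence), tgt)
  for (rn in unique(m$atoms$resno)) {
    expect_true(all(m$atoms$elety[m$atoms$resno == rn] %in%
                      tpl$atoms$elety[tpl$atoms$resno == rn]))
  }
  sparse <- list(pairs = cbind(target = 1:2, template = 1:2))
  expect_error(make_mixed_model(tpl, sparse, tgt), "too sparse")
})

test_that("polyalanine reduction hits the atom-count formula and is idempotent", {
  tpl <- toy_chain("tpl_A", residues = "GKVGF", seed = 35)
  pa <- make_polyalanine(tpl)
  n_gly <- 2
  expect_equal(nrow(pa$atoms), 5 * 5 - n_gly)
  expect_true(all(pa$atoms$resid == "ALA"))
  gly_atoms <- pa$atoms[pa$atoms$resno == 1, ]
  expect_setequal(gly_atoms$elety, c("N", "CA", "C", "O"))
  pa2 <- make_polyalanine(pa)
  expect_equal(pa2$atoms, pa$atoms, ignore_attr = TRUE)
})

test_that("domain extraction respects inclusive ranges and round-trips", {
  tpl <- toy_chain("tpl_A", n = 30, seed = 36)
  d <- domain_entry("tpl_A", 1, cbind(10, 20))
  m <- extract_domain(tpl, d)
  expect_equal(sort(unique(m$atoms$resno)), 10:20)
  f <- withr_local_tempfile(fileext = ".pdb")
  write_model(m, f)
  back <- read_structure(f)[[1]]
  expect_equal(range(back$resno), c(10L, 20L))
  # two ranges concatenate in order
  d2 <- domain_entry("tpl_A", 2, rbind(c(3, 5), c(25, 27)))
  m2 <- extract_domain(tpl, d2)
  expect_equal(sort(unique(m2$atoms$resno)), c(3:5, 25:27))
  expect_error(extract_domain(tpl, domain_entry("tpl_A", 3, cbind(90, 95))),
               "no atoms")
})

test_that("superposition recovers known transforms", {
  set.seed(37)
  x <- matrix(rnorm(60), 20, 3)
  s0 <- superpose(x, x)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  rot <- rotation_z(90)
  y <- sweep(x %*% t(rot), 2, c(5, -3, 2), `+`)
  s1 <- superpose(x, y)
  expect_lt(s1$rmsd, 1e-9)
  expect_equal(s1$rotation, rot, tolerance = 1e-9)
  expect_equal(s1$translation, c(5, -3, 2), tolerance = 1e-9)
  expect_equal(apply_transform(x, s1), y, tolerance = 1e-9)
})

test_that("superposition matches the quaternion oracle and is rigid-invariant", {
  set.seed(38)
  for (k in 1:5) {
    a <- matrix(rnorm(150), 50, 3)
    b <- matrix(rnorm(150), 50, 3)
    expect_equal(superpose(a, b)$rmsd, oracle_superpose_rmsd(a, b),
                 tolerance = 1e-9)
    # pre-rotating both sets leaves the rmsd unchanged
    r <- rotation_z(33)
    a2 <- sweep(a %*% t(r), 2, c(1, 2, 3), `+`)
    b2 <- sweep(b %*% t(r), 2, c(1, 2, 3), `+`)
    expect_equal(superpose(a2, b2)$rmsd, superpose(a, b)$rmsd,
                 tolerance = 1e-9)
  }
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), ">= 3")
})

test_that("ensembles superpose members over the common core", {
  m1 <- chain_as_model(toy_chain("e1_A", n = 25, seed = 39))
  m2 <- m1; m2$source <- "e2_A"
  ens <- build_ensemble(list(m1, m2))
  ca1 <- ens$atoms[ens$atoms$model == 1 & ens$atoms$elety == "CA",
                   c("x", "y", "z")]
  ca2 <- ens$atoms[ens$atoms$model == 2 & ens$atoms$elety == "CA",
                   c("x", "y", "z")]
  expect_equal(sqrt(mean(rowSums((ca1 - ca2)^2))), 0, tolerance = 1e-9)
  expect_error(build_ensemble(list(m1)), ">= 2")
  # disjoint sequences share no core
  u1 <- chain_as_model(toy_chain("u1_A", residues = strrep("K", 12)))
  u2 <- chain_as_model(toy_chain("u2_A", residues = strrep("D", 12)))
  expect_error(build_ensemble(list(u1, u2)), "common core")
})

test_that("ensemble spread tracks the planted conformer noise", {
  rmsds <- vapply(1:20, function(s) {
    base <- toy_chain("b_A", n = 50, seed = 700 + s)
    members <- lapply(1:4, function(k) {
      chain_entry(sprintf("m%d_A", k), base$sequence,
                  perturb_coords(base$ca, 0.3, 800 + 10 * s + k))
    })
    ens <- build_ensemble(members)
    cas <- lapply(1:4, function(k)
      as.matrix(ens$atoms[ens$atoms$model == k & ens$atoms$elety == "CA",
                          c("x", "y", "z")]))
    prs <- utils::combn(4, 2)
    mean(vapply(seq_len(ncol(prs)), function(j)
      sqrt(mean(rowSums((cas[[prs[1, j]]] - cas[[prs[2, j]]])^2))), 0))
  }, 0)
  expect_gt(mean(rmsds), 0.2)
  expect_lt(mean(rmsds), 0.6)
})

test_that("ensembles are permutation-stable", {
  base <- toy_chain("b_A", n = 30, seed = 41)
  members <- lapply(1:3, function(k)
    chain_entry(sprintf("m%d_A", k), base$sequence,
                perturb_coords(base$ca, 0.4, 850 + k)))
  e1 <- build_ensemble(members, prescores = c(3, 2, 1))
  e2 <- build_ensemble(rev(members), prescores = c(1, 2, 3))
  expect_identical(e1$members, e2$members)
  expect_equal(e1$atoms, e2$atoms, ignore_attr = TRUE)
})

test_that("assembly expansion transforms one copy per operator", {
  mono <- chain_as_model(toy_chain("m_A", n = 15, seed = 42))
  idm <- assembly_record("m_A", list(identity_operator()))
  same <- apply_assembly(mono, idm)
  expect_equal(same$atoms[, c("x", "y", "z")],
               mono$atoms[, c("x", "y", "z")], ignore_attr = TRUE)
  expect_true(all(same$atoms$chain == "A"))

  rot <- rotation_z(120)
  rec <- assembly_record("m_A", list(
    identity_operator(),
    list(rotation = rot, translation = c(25, 0, 0))))
  dimer <- apply_assembly(mono, rec)
  expect_equal(nrow(dimer$atoms), 2 * nrow(mono$atoms))
  expect_setequal(unique(dimer$atoms$chain), c("A", "B"))
  # superposing copy B onto copy A recovers the relative transform
  ca_a <- as.matrix(dimer$atoms[dimer$atoms$chain == "A" &
                                  dimer$atoms$elety == "CA",
                                c("x", "y", "z")])
  ca_b <- as.matrix(dimer$atoms[dimer$atoms$chain == "B" &
                                  dimer$atoms$elety == "CA",
                                c("x", "y", "z")])
  s <- superpose(ca_a, ca_b)
  expect_equal(s$rotation, rot, tolerance = 1e-9)
  expect_equal(s$translation, c(25, 0, 0), tolerance = 1e-9)
  expect_error(apply_assembly(mono, list(operators = list())),
               "no operators")
})
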