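# Synthetic-problem generation: compact Calpha walks with full
# backbones, homologues at controlled sequence identity and coordinate
# error, decoys, and serialisation to standard files.
#
# The generator exists so that the decision layer can be exercised at
# desk scale with known ground truth; it emulates chain geometry only
# coarsely (self-avoiding compact walks, idealised local frames) and no
# diffraction physics at all.

#' Random amino-acid sequence
#'
#' @param n length in residues
#' @param seed RNG seed
#' @return an [new_sequence()] record
#' @export
random_aa_sequence <- function(n, seed, id = sprintf("rand%d", seed)) {
  with_seed(seed, {
    new_sequence(id, paste(sample(setdiff(AA_LETTERS, "X"), n,
                                  replace = TRUE), collapse = ""))
  })
}

#' Compact random Calpha walk
#'
#' Successive 3.8-Angstrom steps in random directions, reflected back
#' towards the centroid when the walk leaves a sphere of radius
#' `radius` (default `3 * n^(1/3)`, a globular protein's scale), and
#' rejected when they clash with previous positions.
#'
#' @param n residues
#' @param seed RNG seed
#' @param step Calpha-Calpha distance in Angstrom
#' @param radius confinement radius in Angstrom
#' @param min_sep clash distance in Angstrom
#' @return n x 3 coordinate matrix
#' @export
make_globule <- function(n, seed, step = 3.8, radius = 3 * n^(1 / 3),
                         min_sep = 3.5) {
  with_seed(seed, {
    ca <- matrix(0, n, 3)
    for (i in seq_len(n)[-1L]) {
      for (try in 1:50) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- ca[i - 1L, ] + step * u
        if (sqrt(sum(cand^2)) > radius) {
          # step biased back inside
          u <- -cand / sqrt(sum(cand^2)) + 0.5 * stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- ca[i - 1L, ] + step * u
        }
        prev <- ca[seq_len(max(1L, i - 2L)), , drop = FALSE]
        if (i <= 2L ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) break
      }
      ca[i, ] <- cand
    }
    ca
  })
}

#' Two-lobed ("dumbbell") Calpha trace
#'
#' Two compact globules joined by an extended linker, the classic
#' two-domain geometry used to exercise domain decomposition.
#'
#' @param n1,n2 lobe sizes in residues
#' @param linker linker length in residues
#' @param separation centre-to-centre distance in Angstrom
#' @param seed RNG seed
#' @return (n1 + linker + n2) x 3 coordinate matrix
#' @export
make_dumbbell <- function(n1 = 60, n2 = 60, linker = 5, separation = 40,
                          seed = 1) {
  g1 <- make_globule(n1, seed)
  g2 <- sweep(make_globule(n2, seed + 1L), 2, c(separation, 0, 0), `+`)
  start <- g1[n1, ]
  end <- g2[1L, ]
  lk <- t(vapply(seq_len(linker), function(k)
    start + (end - start) * k / (linker + 1L), numeric(3)))
  rbind(g1, lk, g2)
}

#' Full-atom records for a Calpha trace
#'
#' Places an idealised backbone (N, C, O) in the local chain frame of
#' each Calpha plus side-chain atoms for the given sequence along the
#' outward direction.  Geometry is schematic - sufficient for model
#' editing and superposition, not for stereochemistry.
#'
#' @param ca n x 3 Calpha matrix
#' @param sequence an [new_sequence()] of matching length
#' @param chain chain identifier
#' @param resno residue numbers (default 1..n)
#' @return atom data frame
#' @export
backbone_atoms <- function(ca, sequence, chain = "A", resno = NULL) {
  n <- nrow(ca)
  if (is.null(resno)) resno <- seq_len(n)
  res3 <- aa1to3(sequence$residues)
  centroid <- colMeans(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- if (i < n) ca[i + 1L, ] - ca[i, ] else ca[i, ] - ca[i - 1L, ]
    t <- t / sqrt(sum(t^2))
    u <- ca[i, ] - centroid
    u <- u - sum(u * t) * t
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-6) {
      v <- c(t[2], -t[1], 0); v / sqrt(sum(v^2))
    } else u / nu
    pos <- list(N = ca[i, ] - 1.46 * t,
                CA = ca[i, ],
                C = ca[i, ] + 1.52 * t,
                O = ca[i, ] + 1.52 * t + 1.23 * u)
    side <- SIDECHAIN_ATOMS[[res3[i]]]
    for (k in seq_along(side)) {
      pos[[side[k]]] <- ca[i, ] + (1.2 + 1.3 * k) * u + 0.15 * k * t
    }
    m <- do.call(rbind, pos)
    rows[[i]] <- atom_frame(chain, resno[i], res3[i], rownames(m),
                            m[, 1], m[, 2], m[, 3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
chain_from_ca <- function(entry_id, sequence, ca, resolution,
                          chain = "A") {
  chain_entry(entry_id, sequence, ca, resolution = resolution,
              atoms = backbone_atoms(ca, sequence, chain = chain))
}

#' Mutate a sequence to a requested identity
#'
#' Exactly `round(n * (1 - identity))` positions are substituted with a
#' different residue, so the realised identity to the original equals
#' the request up to rounding.
#'
#' @param sequence an [new_sequence()]
#' @param identity requested fractional identity in \[0, 1\]
#' @param seed RNG seed
#' @param id label for the mutant
#' @return an `mrp_sequence`
#' @export
mutate_sequence <- function(sequence, identity, seed,
                            id = paste0(sequence$id, "_mut")) {
  if (identity < 0 || identity > 1) stop("infeasible identity: ", identity)
  letters <- strsplit(sequence$residues, "")[[1]]
  n <- length(letters)
  k <- round(n * (1 - identity))
  with_seed(seed, {
    pos <- sample.int(n, k)
    for (p in pos) {
      letters[p] <- sample(setdiff(setdiff(AA_LETTERS, "X"), letters[p]), 1)
    }
  })
  new_sequence(id, paste(letters, collapse = ""))
}

#' Perturb coordinates to a target RMSD
#'
#' Adds isotropic Gaussian noise with per-coordinate standard deviation
#' `sigma / sqrt(3)`, so the expected Calpha RMSD to the original is
#' `sigma` (the per-atom displacement magnitude is chi-distributed with
#' mean close to `sigma` for realistic chain lengths).
#'
#' @param coords n x 3 matrix
#' @param sigma target RMSD in Angstrom
#' @param seed RNG seed
#' @return perturbed matrix
#' @export
perturb_coords <- function(coords, sigma, seed) {
  with_seed(seed, {
    coords + matrix(stats::rnorm(length(coords), 0, sigma / sqrt(3)),
                    nrow(coords), 3)
  })
}

#' Generate a seeded synthetic MR problem
#'
#' Builds ground-truth chain(s) as compact Calpha walks with full
#' backbones, homologue templates at the requested sequence identities
#' and coordinate errors, unrelated decoys, and the target crystal
#' metadata (a P 1 cell sized for roughly 50% solvent).  With
#' `n_targets > 1` the targets are near-identical mutants of one truth
#' chain and a planted multimer assembly of the truth is added, the
#' regime in which assembly models are tried first.  Regenerating with
#' the same seed reproduces the problem bit-identically.
#'
#' @param seed RNG seed
#' @param n_residues truth-chain length
#' @param n_targets number of target sequences
#' @param homologue_identities sequence identities of planted homologues
#' @param homologue_sigmas coordinate error (Calpha RMSD, Angstrom) of
#'   each homologue; recycled against the identities
#' @param n_decoys unrelated library chains
#' @param resolution template resolutions are drawn near this value
#' @param with_assembly plant a multimer assembly record (default: when
#'   `n_targets > 1`)
#' @return object of class `synthetic_problem`: fields `truth` (chains),
#'   `target` ([target_data()]), `library` ([build_index()] result),
#'   `seed`
#' @export
make_synthetic_problem <- function(seed, n_residues = 80, n_targets = 1,
                                   homologue_identities = c(0.85),
                                   homologue_sigmas = c(0.4),
                                   n_decoys = 10, resolution = 2.0,
                                   with_assembly = n_targets > 1) {
  if (any(homologue_identities > 1 | homologue_identities < 0)) {
    stop("infeasible identity requested")
  }
  homologue_sigmas <- rep_len(homologue_sigmas,
                              length(homologue_identities))
  truth_seq <- random_aa_sequence(n_residues, derive_seed(seed, 1),
                                  id = "truth")
  truth_ca <- make_globule(n_residues, derive_seed(seed, 2))
  truth <- chain_from_ca("truth_A", truth_seq, truth_ca, resolution)

  targets <- lapply(seq_len(n_targets), function(i) {
    if (i == 1L) new_sequence("target1", truth_seq$residues)
    else mutate_sequence(truth_seq, 0.95, derive_seed(seed, 100 + i),
                         id = sprintf("target%d", i))
  })

  chains <- list()
  for (h in seq_along(homologue_identities)) {
    hs <- mutate_sequence(truth_seq, homologue_identities[h],
                          derive_seed(seed, 200 + h),
                          id = sprintf("hom%d_A", h))
    hc <- perturb_coords(truth_ca, homologue_sigmas[h],
                         derive_seed(seed, 300 + h))
    chains[[length(chains) + 1L]] <-
      chain_from_ca(sprintf("hom%d_A", h), hs, hc,
                    resolution = resolution + 0.1 * h)
  }
  for (d in seq_len(n_decoys)) {
    ds <- random_aa_sequence(n_residues, derive_seed(seed, 400 + d),
                             id = sprintf("dec%d_A", d))
    dc <- make_globule(n_residues, derive_seed(seed, 500 + d))
    chains[[length(chains) + 1L]] <-
      chain_from_ca(sprintf("dec%d_A", d), ds, dc,
                    resolution = resolution + 0.05 * d)
  }

  assemblies <- list()
  if (with_assembly && length(chains) > 0L) {
    ops <- lapply(seq_len(max(2L, n_targets)), function(k)
      list(rotation = diag(3),
           translation = c(0, 0, 50 * (k - 1L))))
    assemblies <- list(assembly_record(chains[[1L]]$entry_id, ops))
  }

  library <- build_index(chains, domains = list(),
                         assemblies = assemblies)

  mw <- sequence_weight(n_residues) * n_targets
  v <- 2.69 * mw   # P 1, one copy at Vm = 2.69 (about 50% solvent)
  a <- v^(1 / 3)
  target <- target_data(targets, cell = c(a, a, a, 90, 90, 90),
                        space_group = "P 1", resolution = resolution)

  structure(list(truth = list(chains = list(truth), sequence = truth_seq),
                 target = target, library = library, seed = seed),
            class = "synthetic_problem")
}

#' Serialise a synthetic problem to standard files
#'
#' Writes the target sequences (FASTA), every library chain (PDB), the
#' ground truth (PDB), the target descriptor (YAML) and a metadata
#' table (TSV of entry id and resolution).
#'
#' @param problem a [make_synthetic_problem()] result
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_problem <- function(problem, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(problem$target$sequences, file.path(dir, "target.fasta"))
  write_target(problem$target, file.path(dir, "target.yaml"))
  write_model(list(atoms = problem$truth$chains[[1L]]$atoms),
              file.path(dir, "truth.pdb"))
  meta <- data.frame(entry_id = character(0), resolution = numeric(0))
  for (ch in problem$library$chains) {
    write_model(list(atoms = ch$atoms),
                file.path(dir, paste0(ch$entry_id, ".pdb")))
    meta <- rbind(meta, data.frame(entry_id = ch$entry_id,
                                   resolution = ch$resolution))
  }
  utils::write.table(meta, file.path(dir, "templates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
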