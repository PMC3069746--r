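# Independent oracles and small fixture builders shared across tests.
# Each oracle is a from-scratch implementation kept deliberately naive;
# none shares code with the package internals it checks.

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Quadratic-space Gotoh dynamic programme (affine gaps, global).
# Convention: a gap of length L costs open + L * ext.
oracle_align_score <- function(a, b, sm = blosum62, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); ni <- -1e9
  M <- matrix(ni, n + 1, m + 1)
  X <- matrix(ni, n + 1, m + 1)
  Y <- matrix(ni, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- sm[A[i], B[j]] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Horn quaternion method for optimal rigid superposition: an
# independent route to the least-squares rotation via the largest
# eigenvector of the 4x4 key matrix.
oracle_superpose_rmsd <- function(mobile, fixed) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(fixed, 2, colMeans(fixed))
  s <- crossprod(p, q)   # Sxy = sum p_x q_y
  key <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],        s[2,2]-s[1,1]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],        s[3,3]-s[1,1]-s[2,2]),
    4, 4, byrow = TRUE)
  ev <- eigen(key, symmetric = TRUE)
  qv <- ev$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
  sqrt(mean(rowSums((p %*% t(rot) - q)^2)))
}

# Naive average-linkage agglomeration over a distance matrix; returns
# the cophenetic distance matrix for topology comparison.
oracle_average_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  dist_cl <- function(ci, cj) mean(d[ci, cj])
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        dd <- dist_cl(clusters[[idx[a]]], clusters[[idx[b]]])
        if (dd < bd) { bd <- dd; best <- c(idx[a], idx[b]) }
      }
    }
    for (i in clusters[[best[1]]]) for (j in clusters[[best[2]]]) {
      coph[i, j] <- coph[j, i] <- bd
    }
    clusters[[length(clusters) + 1L]] <-
      c(clusters[[best[1]]], clusters[[best[2]]])
    active[best] <- FALSE
    active[length(clusters)] <- TRUE
  }
  coph
}

# Greedy redundancy reduction straight from the curation rule, applied
# to precomputed identity/rmsd matrices (ground truth of a planted set).
oracle_redundancy <- function(ids, resolutions, identity, rmsd,
                              id_thr = 0.80, rmsd_thr = 1.0) {
  ord <- order(resolutions, ids)
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      if (identity[i, j] > id_thr && !is.na(rmsd[i, j]) &&
          rmsd[i, j] < rmsd_thr) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  sort(ids[kept])
}

# Direct transcription of the solution-class rule (final Rfree level
# plus its drop over the refinement), kept separate from the package's.
oracle_classify <- function(rfree_first, rfree_last, eps = 1e-9) {
  drop <- rfree_first - rfree_last
  if (rfree_last <= 0.45 + eps && drop >= 0.05 - eps) "good"
  else if (rfree_last <= 0.50 + eps && drop >= 0.02 - eps) "marginal"
  else "poor"
}

# ---- fixture builders ------------------------------------------------------

withr_local_tempfile <- function(fileext = "") {
  withr::local_tempfile(fileext = fileext, .local_envir = parent.frame())
}

withr_local_tempdir <- function() {
  withr::local_tempdir(.local_envir = parent.frame())
}

random_seq_string <- function(n, seed) {
  set.seed(seed)
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

# Full-atom toy chain on a compact walk.
toy_chain <- function(id, residues = NULL, n = 30, seed = 1,
                      resolution = 2.0, ca = NULL) {
  if (is.null(residues)) residues <- random_seq_string(n, seed)
  sq <- new_sequence(id, residues)
  if (is.null(ca)) ca <- make_globule(nchar(residues), seed)
  chain_entry(id, sq, ca, resolution = resolution,
              atoms = backbone_atoms(ca, sq))
}

# Mutate a plain residue string at exactly k positions.
mutate_string <- function(s, k, seed) {
  set.seed(seed)
  letters <- strsplit(s, "")[[1]]
  for (p in sample(length(letters), k)) {
    letters[p] <- sample(setdiff(aa20, letters[p]), 1)
  }
  paste(letters, collapse = "")
}

# Planted redundancy structure: groups of near-identical chains plus
# singletons, with ground-truth similarity known by construction (group
# members differ by ~4% mutations and 0.3 A noise; groups and
# singletons are unrelated).
planted_redundant_set <- function(n_groups = 3, per_group = 2,
                                  n_single = 2, n = 50, seed = 100) {
  entries <- list()
  for (g in seq_len(n_groups)) {
    s <- random_seq_string(n, seed + g)
    ca <- make_globule(n, seed + g)
    for (m in seq_len(per_group)) {
      id <- sprintf("g%dm%d_A", g, m)
      sq <- if (m == 1) s else
        mutate_string(s, round(n * 0.04), seed + 10 * g + m)
      cam <- if (m == 1) ca else perturb_coords(ca, 0.3, seed + 20 * g + m)
      entries[[id]] <- chain_entry(id, new_sequence(id, sq), cam,
                                   resolution = 1.5 + 0.25 * m)
    }
  }
  for (u in seq_len(n_single)) {
    id <- sprintf("solo%d_A", u)
    entries[[id]] <- chain_entry(id,
      new_sequence(id, random_seq_string(n, seed + 50 + u)),
      make_globule(n, seed + 50 + u), resolution = 2.0)
  }
  entries
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

flat_trace <- function(level, n = 30) {
  refinement_trace(rep(level, n), rep(level, n))
}

falling_trace <- function(from, to, n = 30, r_gap = 0.03) {
  rf <- seq(from, to, length.out = n)
  refinement_trace(pmax(rf - r_gap, 0), rf)
}
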