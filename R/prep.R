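# Search-model preparation: rigid-body superposition, side-chain
# pruning (mixed models), polyalanine reduction, domain extraction,
# ensemble building and assembly expansion.

#' @keywords internal
search_model <- function(model_type, atoms, source, alignment = NULL,
                         model_index = NA_character_, members = NULL) {
  model_type <- match.arg(model_type,
                          c("unmodified", "mixed", "mixed_msa",
                            "polyalanine", "domain", "multimer",
                            "ensemble"))
  structure(list(model_type = model_type, atoms = atoms, source = source,
                 alignment = alignment, model_index = model_index,
                 members = members),
            class = "search_model")
}

#' @export
print.search_model <- function(x, ...) {
  cat(sprintf("<search model> %s from %s  (%d atoms, %d residues)\n",
              x$model_type, paste(x$source, collapse = "+"),
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno,
                                  x$atoms$model)))))
  invisible(x)
}

#' Wrap a template chain as an unmodified search model
#'
#' @param template a [chain_entry()]
#' @param model_index optional hierarchical id
#' @return a `search_model` of type `"unmodified"`
#' @export
chain_as_model <- function(template, model_index = NA_character_) {
  search_model("unmodified", template_atoms(template), template$entry_id,
               model_index = model_index)
}

# Full atoms if present, else the Calpha trace promoted to atom records.
#' @keywords internal
template_atoms <- function(template) {
  if (!is.null(template$atoms)) return(template$atoms)
  atom_frame(chain = "A", resno = template$resno,
             resid = aa1to3(template$sequence$residues),
             elety = "CA", x = template$ca[, 1], y = template$ca[, 2],
             z = template$ca[, 3])
}

# ---- superposition ---------------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `mobile %*% t(R) + t` and `fixed` over the given point pairs.
#' The SVD-based solution constrains `det(R) = +1`.
#'
#' @param mobile n x 3 coordinate matrix to move
#' @param fixed n x 3 coordinate matrix to match (row i pairs with row i
#'   of `mobile`; use `pairs` to select rows)
#' @param pairs optional m x 2 index matrix (mobile row, fixed row)
#' @return object of class `superposition` with fields `rotation`
#'   (3 x 3, orthogonal, det +1), `translation`, `rmsd` (post-transform,
#'   Angstrom) and `n_pairs`
#' @export
superpose <- function(mobile, fixed, pairs = NULL) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (!is.null(pairs)) {
    mobile <- mobile[pairs[, 1], , drop = FALSE]
    fixed <- fixed[pairs[, 2], , drop = FALSE]
  }
  n <- nrow(mobile)
  if (n < 3L || nrow(fixed) != n) stop("superposition needs >= 3 point pairs")
  cm <- unname(colMeans(mobile)); cf <- unname(colMeans(fixed))
  p <- sweep(mobile, 2, cm); q <- sweep(fixed, 2, cf)
  # collinear/degenerate sets leave the rotation under-determined
  sq <- svd(q, nu = 0, nv = 0)$d
  if (sq[2] < 1e-8 * max(1, sq[1])) stop("degenerate (collinear) point set")
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cf - as.numeric(rot %*% cm)
  moved <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 n_pairs = n),
            class = "superposition")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix
#' @param sup a [superpose()] result, or a list with `rotation` and
#'   `translation`
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(coords, sup) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' Calpha RMSD between two chains over an alignment
#'
#' Convenience wrapper: superposes the template Calphas onto the
#' target's over the alignment's residue-pair map and returns the
#' post-fit RMSD (`NA` when fewer than 3 pairs exist).
#'
#' @param a,b [chain_entry()] records (a = target side of `alignment`)
#' @param alignment an [align_pair()] result mapping `a` onto `b`
#' @return RMSD in Angstrom, or `NA`
#' @export
aligned_ca_rmsd <- function(a, b, alignment) {
  pr <- alignment$pairs
  if (nrow(pr) < 3L) return(NA_real_)
  out <- tryCatch(superpose(b$ca, a$ca, pairs = pr[, c("template", "target")]),
                  error = function(e) NULL)
  if (is.null(out)) NA_real_ else out$rmsd
}

# ---- model editing ---------------------------------------------------------

#' Build a mixed model by pruning nonconserved side chains
#'
#' Edits a full-atom template according to its alignment with the
#' target: identical aligned residues keep their side chains,
#' substituted residues are truncated to the atoms shared with the
#' target residue type (longest common prefix of the canonical
#' side-chain atom lists, minimum CB; a glycine target keeps no CB) and
#' relabelled to the target type, and template residues unaligned to any
#' target position are deleted.
#'
#' @param template a full-atom [chain_entry()]
#' @param alignment an [align_pair()] result with the target as pattern
#'   and the template as subject
#' @param target the target [new_sequence()]
#' @param model_type label for the resulting model, `"mixed"` (pairwise
#'   alignment source) or `"mixed_msa"` (multiple-alignment-informed)
#' @return a `search_model`
#' @export
make_mixed_model <- function(template, alignment, target,
                             model_type = "mixed") {
  if (is.null(template$atoms)) stop("template has no full atom records")
  pr <- alignment$pairs
  if (nrow(pr) < 3L) stop("model too sparse: alignment covers ",
                          nrow(pr), " residues")
  tgt <- strsplit(target$residues, "")[[1]]
  tpl <- strsplit(template$sequence$residues, "")[[1]]
  keep <- list()
  for (i in seq_len(nrow(pr))) {
    ti <- pr[i, "target"]; bi <- pr[i, "template"]
    resno <- template$resno[bi]
    a <- template$atoms[template$atoms$resno == resno, , drop = FALSE]
    if (nrow(a) == 0L) next
    if (tgt[ti] == tpl[bi]) {
      keep[[length(keep) + 1L]] <- a
    } else {
      target3 <- AA_THREE[[tgt[ti]]]
      allowed <- shared_atoms(a$resid[1L], target3)
      a <- a[a$elety %in% allowed, , drop = FALSE]
      a$resid <- target3
      keep[[length(keep) + 1L]] <- a
    }
  }
  atoms <- do.call(rbind, keep)
  rownames(atoms) <- NULL
  search_model(model_type, atoms, template$entry_id, alignment = alignment)
}

#' Reduce a model to polyalanine
#'
#' Every residue is cut back to N, CA, C, O and CB (glycine keeps no CB)
#' and relabelled ALA.  Idempotent.
#'
#' @param template a [chain_entry()] or `search_model`
#' @return a `search_model` of type `"polyalanine"`
#' @export
make_polyalanine <- function(template) {
  atoms <- if (inherits(template, "search_model")) template$atoms
           else template_atoms(template)
  src <- if (inherits(template, "search_model")) template$source
         else template$entry_id
  keep <- atoms$elety %in% BACKBONE_ATOMS |
    (atoms$elety == "CB" & atoms$resid != "GLY")
  atoms <- atoms[keep, , drop = FALSE]
  atoms$resid <- "ALA"
  rownames(atoms) <- NULL
  search_model("polyalanine", atoms, src)
}

#' Extract a domain from a template
#'
#' @param template a [chain_entry()]
#' @param domain a [domain_entry()] whose ranges refer to the template's
#'   source residue numbering
#' @return a `search_model` of type `"domain"`, numbering preserved
#' @export
extract_domain <- function(template, domain) {
  atoms <- template_atoms(template)
  keep <- rep(FALSE, nrow(atoms))
  for (k in seq_len(nrow(domain$residue_ranges))) {
    keep <- keep | (atoms$resno >= domain$residue_ranges[k, 1] &
                      atoms$resno <= domain$residue_ranges[k, 2])
  }
  if (!any(keep)) stop("domain ranges select no atoms of ",
                       template$entry_id)
  search_model("domain", atoms[keep, , drop = FALSE],
               paste0(template$entry_id, "_d", domain$domain_index))
}

#' Build an ensemble of superposed models
#'
#' Members are normalised to a deterministic order (prescore descending,
#' then source id), trimmed to the common aligned core (residues present
#' in every member; retaining full length is available via
#' `trim = FALSE`), and superposed onto the first member over the core
#' Calphas.  The result is written as a multi-MODEL PDB by
#' [write_model()].
#'
#' @param models list of >= 2 chain-like `search_model`s or
#'   [chain_entry()] records
#' @param aligner pairwise alignment function (member i vs member 1)
#' @param prescores optional numeric vector used for ordering
#' @param trim drop residues absent from any member (default TRUE)
#' @param min_identity members aligning to the first below this
#'   identity are considered unalignable (no shared core)
#' @return a `search_model` of type `"ensemble"`; `members` holds the
#'   source ids, and the `core` attribute the member-1 residue numbers of
#'   the common core
#' @export
build_ensemble <- function(models, aligner = align_pair,
                           prescores = NULL, trim = TRUE,
                           min_identity = 0.15) {
  if (length(models) < 2L) stop("an ensemble needs >= 2 members")
  entries <- lapply(models, function(m) {
    if (inherits(m, "chain_entry")) m else model_as_chain(m)
  })
  ids <- vapply(entries, function(e) e$entry_id, "")
  if (is.null(prescores)) prescores <- rep(0, length(entries))
  ord <- order(-prescores, ids)
  entries <- entries[ord]
  # core = member-1 residues aligned & present in all members
  ref <- entries[[1L]]
  maps <- list()
  core <- seq_len(ref$length)
  for (j in seq_along(entries)[-1L]) {
    al <- aligner(ref$sequence, entries[[j]]$sequence)
    map <- rep(NA_integer_, ref$length)
    if (al$identity >= min_identity) {
      map[al$pairs[, "target"]] <- al$pairs[, "template"]
    }
    maps[[j]] <- map
    core <- intersect(core, which(!is.na(map)))
  }
  if (length(core) < 3L) stop("no common core across ensemble members")
  all_atoms <- list()
  for (j in seq_along(entries)) {
    e <- entries[[j]]
    rows <- if (j == 1L) core else maps[[j]][core]
    sup <- superpose(e$ca[rows, , drop = FALSE],
                     ref$ca[core, , drop = FALSE])
    atoms <- template_atoms(e)
    if (trim) atoms <- atoms[atoms$resno %in% e$resno[rows], , drop = FALSE]
    xyz <- apply_transform(as.matrix(atoms[, c("x", "y", "z")]), sup)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    atoms$model <- j
    all_atoms[[j]] <- atoms
  }
  out <- search_model("ensemble", do.call(rbind, all_atoms),
                      source = vapply(entries, function(e) e$entry_id, ""),
                      members = vapply(entries, function(e) e$entry_id, ""))
  attr(out, "core") <- ref$resno[core]
  out
}

# First chain of the first member, as a chain_entry (used wherever a
# multi-chain or multi-member model must be compared as a single chain).
#' @keywords internal
model_as_chain <- function(model) {
  a <- model$atoms[model$atoms$model == 1L, , drop = FALSE]
  a <- a[a$chain == a$chain[1L], , drop = FALSE]
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  chain_entry(paste(model$source, collapse = "+"),
              new_sequence(paste(model$source, collapse = "+"),
                           paste(aa3to1(ca$resid), collapse = "")),
              as.matrix(ca[, c("x", "y", "z")]),
              resno = ca$resno, atoms = a)
}

#' Expand a monomer into a multimer via assembly operators
#'
#' One chain copy per operator, transformed and assigned chain ids A,
#' B, C, ... in operator order.
#'
#' @param monomer a chain-like `search_model` or [chain_entry()]
#' @param record an [assembly_record()]
#' @return a `search_model` of type `"multimer"`
#' @export
apply_assembly <- function(monomer, record) {
  if (length(record$operators) == 0L) stop("assembly record has no operators")
  atoms <- if (inherits(monomer, "chain_entry")) template_atoms(monomer)
           else monomer$atoms
  src <- if (inherits(monomer, "chain_entry")) monomer$entry_id
         else monomer$source
  copies <- list()
  for (k in seq_along(record$operators)) {
    op <- record$operators[[k]]
    a <- atoms
    xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(op$rotation), 2,
                 op$translation, `+`)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a$chain <- LETTERS[((k - 1L) %% 26L) + 1L]
    copies[[k]] <- a
  }
  search_model("multimer", do.call(rbind, copies), src)
}
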