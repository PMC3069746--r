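# Structure containers and PDB/mmCIF input, PDB output.
#
# Atoms travel as a plain data frame with columns
#   chain (character), resno (integer), resid (3-letter code),
#   elety (atom name), x, y, z (Angstrom), model (integer, >1 only for
#   ensemble members).

#' @keywords internal
atom_frame <- function(chain, resno, resid, elety, x, y, z, model = 1L) {
  data.frame(chain = as.character(chain), resno = as.integer(resno),
             resid = as.character(resid), elety = as.character(elety),
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             model = as.integer(rep_len(model, length(chain))),
             stringsAsFactors = FALSE)
}

#' Create a template chain entry
#'
#' One chain of a template structure: its sequence, Calpha trace,
#' crystallographic resolution and (optionally) the full atom records
#' needed for side-chain editing.
#'
#' @param entry_id source identifier, conventionally `<structure>_<chain>`
#'   (e.g. `"1n9w_A"`)
#' @param sequence an [new_sequence()] record
#' @param ca n x 3 matrix of Calpha coordinates, one row per residue
#' @param resolution resolution in Angstrom, or `NA` when the header does
#'   not state one
#' @param resno residue numbers for the Calpha rows (source numbering);
#'   defaults to 1..n
#' @param atoms optional full atom data frame (see [atom_frame()])
#' @return object of class `chain_entry`
#' @export
chain_entry <- function(entry_id, sequence, ca, resolution = NA_real_,
                        resno = NULL, atoms = NULL) {
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 3L)
  n <- nchar(sequence$residues)
  if (nrow(ca) != n) {
    stop("entry '", entry_id, "': ", n, " residues but ", nrow(ca),
         " Calpha coordinates")
  }
  if (is.null(resno)) resno <- seq_len(n)
  stopifnot(length(resno) == n)
  if (!is.na(resolution) && resolution <= 0) {
    stop("entry '", entry_id, "': resolution must be positive")
  }
  structure(list(entry_id = entry_id, sequence = sequence, ca = ca,
                 resolution = as.numeric(resolution),
                 resno = as.integer(resno), atoms = atoms,
                 length = n),
            class = "chain_entry")
}

#' @export
print.chain_entry <- function(x, ...) {
  cat("<chain>", x$entry_id, paste0("(", x$length, " res, "),
      if (is.na(x$resolution)) "resolution unknown)" else
        paste0(format(x$resolution, nsmall = 1), " A)"), "\n")
  invisible(x)
}

#' @keywords internal
structure_of <- function(entry_id) sub("_.*$", "", entry_id)

# ---- reading ---------------------------------------------------------------

#' Read polymer chains from a PDB or mmCIF file
#'
#' Returns one [chain_entry()] per polymer chain.  Only standard
#' amino-acid ATOM records are kept (waters and heteroatoms are dropped),
#' the first alternate location is retained, and the resolution is taken
#' from the header when present (`NA` otherwise).  Chains without a
#' single Calpha are skipped with a warning.
#'
#' @param path structure file
#' @param dialect `"pdb"` or `"mmcif"`; guessed from the file extension
#'   by default
#' @return list of `chain_entry`
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- switch(dialect,
                   pdb = read_pdb_atoms(path),
                   mmcif = read_mmcif_atoms(path))
  atoms <- parsed$atoms
  atoms <- atoms[atoms$resid %in% setdiff(names(SIDECHAIN_ATOMS), "UNK"), ,
                 drop = FALSE]
  out <- list()
  base <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
              ignore.case = TRUE)
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    ca <- a[a$elety == "CA", , drop = FALSE]
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
    if (nrow(ca) < 1L) {
      warning("chain ", ch, " in ", basename(path),
              " has no Calpha atoms; skipped")
      next
    }
    ca <- ca[order(ca$resno), , drop = FALSE]
    seq1 <- paste(aa3to1(ca$resid), collapse = "")
    entry <- chain_entry(paste0(base, "_", ch),
                         new_sequence(paste0(base, "_", ch), seq1),
                         as.matrix(ca[, c("x", "y", "z")]),
                         resolution = parsed$resolution,
                         resno = ca$resno,
                         atoms = a[a$resno %in% ca$resno, , drop = FALSE])
    out[[entry$entry_id]] <- entry
  }
  out
}

#' @keywords internal
read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  # keep the first altloc per (chain, resno, elety)
  if (any(nzchar(a$alt) & !is.na(a$alt))) {
    key <- paste(a$chain, a$resno, a$elety)
    a <- a[!duplicated(key), , drop = FALSE]
  }
  res <- NA_real_
  hdr <- grep("^REMARK   2 RESOLUTION", readLines(path, warn = FALSE),
              value = TRUE)
  if (length(hdr) > 0L) {
    m <- regmatches(hdr[1], regexpr("[0-9]+\\.[0-9]+", hdr[1]))
    if (length(m) == 1L) res <- as.numeric(m)
  }
  list(atoms = atom_frame(a$chain, a$resno, a$resid, a$elety,
                          a$x, a$y, a$z),
       resolution = res)
}

# Minimal mmCIF reader: the atom_site loop plus the resolution item.  No
# installed R package parses mmCIF, so only the records this package
# consumes are handled; quoted values containing whitespace are not
# supported in atom_site rows (they do not occur there).
#' @keywords internal
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  res <- NA_real_
  for (key in c("_refine.ls_d_res_high", "_reflns.d_resolution_high")) {
    hit <- grep(key, lines, fixed = TRUE, value = TRUE)
    if (length(hit) > 0L) {
      val <- suppressWarnings(as.numeric(strsplit(trimws(hit[1]),
                                                  "\\s+")[[1]][2]))
      if (!is.na(val)) { res <- val; break }
    }
  }
  loop_starts <- grep("^\\s*loop_", lines)
  for (ls in loop_starts) {
    i <- ls + 1L
    fields <- character(0)
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      fields <- c(fields, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(startsWith(fields, "_atom_site."))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || startsWith(ln, "_") || startsWith(ln, "loop_") ||
          startsWith(ln, "#")) break
      rows[[length(rows) + 1L]] <- strsplit(ln, "\\s+")[[1]]
      i <- i + 1L
    }
    if (length(rows) == 0L) stop("cannot parse mmCIF file ", path,
                                 ": empty atom_site loop")
    bad <- which(vapply(rows, length, 0L) != length(fields))
    if (length(bad) > 0L) stop("cannot parse mmCIF file ", path,
                               ": malformed atom_site row ", bad[1])
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- fields
    need <- function(nm, alt = NULL) {
      if (nm %in% names(tab)) return(tab[[nm]])
      if (!is.null(alt) && alt %in% names(tab)) return(tab[[alt]])
      stop("cannot parse mmCIF file ", path, ": missing atom_site.", nm)
    }
    grp <- if ("group_PDB" %in% names(tab)) tab$group_PDB else "ATOM"
    alt <- if ("label_alt_id" %in% names(tab)) tab$label_alt_id else "."
    a <- atom_frame(chain = need("auth_asym_id", "label_asym_id"),
                    resno = need("auth_seq_id", "label_seq_id"),
                    resid = need("auth_comp_id", "label_comp_id"),
                    elety = gsub("\"", "", need("auth_atom_id",
                                                "label_atom_id")),
                    x = as.numeric(need("Cartn_x")),
                    y = as.numeric(need("Cartn_y")),
                    z = as.numeric(need("Cartn_z")))
    keep <- grp == "ATOM" & alt %in% c(".", "?", "A", "1", "")
    a <- a[keep, , drop = FALSE]
    return(list(atoms = a, resolution = res))
  }
  stop("cannot parse mmCIF file ", path, ": no atom_site loop found")
}

# ---- writing ---------------------------------------------------------------

#' @keywords internal
format_atom_name <- function(n) {
  ifelse(nchar(n) >= 4L, substr(n, 1, 4), sprintf(" %-3s", n))
}

#' @keywords internal
pdb_atom_lines <- function(a, serial_start = 1L) {
  serial <- serial_start + seq_len(nrow(a)) - 1L
  elem <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, format_atom_name(a$elety), a$resid,
          substr(a$chain, 1, 1), a$resno, a$x, a$y, a$z, 1, 0, elem)
}

#' Write a search model as a PDB file
#'
#' Standard fixed-column PDB output: coordinates at 3-decimal precision,
#' residue numbering preserved from the source, one TER record per chain.
#' Ensembles (atom records with several `model` values) are written as a
#' multi-MODEL file.  Output round-trips through [read_structure()].
#'
#' @param model a `search_model` (see [make_mixed_model()]) or any object
#'   with an `atoms` data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  a <- if (is.data.frame(model)) model else model$atoms
  if (is.null(a) || nrow(a) == 0L) stop("model has no atoms")
  if (nrow(a) > 99999L) stop("model exceeds the PDB format limit of ",
                             "99999 atoms")
  con <- file(path, "w")
  on.exit(close(con))
  models <- sort(unique(a$model))
  multi <- length(models) > 1L
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    am <- a[a$model == m, , drop = FALSE]
    serial <- 1L
    for (ch in unique(am$chain)) {
      ac <- am[am$chain == ch, , drop = FALSE]
      writeLines(pdb_atom_lines(ac, serial), con)
      serial <- serial + nrow(ac)
      last <- ac[nrow(ac), ]
      writeLines(sprintf("TER   %5d      %3s %1s%4d", serial %% 100000L,
                         last$resid, substr(last$chain, 1, 1), last$resno),
                 con)
      serial <- serial + 1L
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
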