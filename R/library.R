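# Template-library curation: resolution/length filtering, redundancy
# reduction, hierarchical organisation, domain decomposition and the
# serialisable library index.

#' Domain record
#'
#' @param parent entry id of the parent chain
#' @param domain_index ordinal within the parent
#' @param residue_ranges k x 2 matrix of inclusive source-numbering
#'   spans, non-overlapping and sorted
#' @return object of class `domain_entry`
#' @export
domain_entry <- function(parent, domain_index, residue_ranges) {
  residue_ranges <- matrix(as.integer(residue_ranges), ncol = 2)
  if (nrow(residue_ranges) > 1L) {
    o <- order(residue_ranges[, 1])
    residue_ranges <- residue_ranges[o, , drop = FALSE]
    if (any(residue_ranges[-1L, 1] <= residue_ranges[-nrow(residue_ranges), 2]))
      stop("domain ranges overlap")
  }
  if (any(residue_ranges[, 2] < residue_ranges[, 1]))
    stop("domain range end precedes start")
  structure(list(parent = parent, domain_index = as.integer(domain_index),
                 residue_ranges = residue_ranges),
            class = "domain_entry")
}

#' Assembly operators for a chain
#'
#' @param entry_id parent chain id
#' @param operators list of `list(rotation = 3x3, translation = length-3)`;
#'   each rotation must be orthogonal with determinant +1 (tolerance
#'   1e-6)
#' @return object of class `assembly_record`
#' @export
assembly_record <- function(entry_id, operators) {
  for (op in operators) {
    r <- op$rotation
    if (max(abs(crossprod(r) - diag(3))) > 1e-6 || abs(det(r) - 1) > 1e-6)
      stop("assembly operator for ", entry_id,
           " is not a proper rotation")
  }
  structure(list(entry_id = entry_id, operators = operators,
                 multimer_size = length(operators)),
            class = "assembly_record")
}

#' Identity rotation-translation operator
#' @return operator list usable in [assembly_record()]
#' @export
identity_operator <- function() list(rotation = diag(3),
                                     translation = c(0, 0, 0))

#' Library curation thresholds
#'
#' Defaults follow the classic database rules: chains longer than 15
#' residues, refined to 3.5 Angstrom or better, and deduplication of
#' pairs with identity above 80% and Calpha RMSD below 1 Angstrom
#' (conformational variants - high identity but RMSD >= 1 - are kept).
#'
#' @param min_length minimum chain length in residues (`> 15` read as
#'   `>= 16`)
#' @param max_resolution worst admissible resolution in Angstrom
#'   (inclusive)
#' @param dedup_identity identity above which a pair is a duplication
#'   candidate (strict `>`)
#' @param dedup_rmsd RMSD below which a candidate pair is redundant
#'   (strict `<`)
#' @return object of class `curation_config`
#' @export
curation_config <- function(min_length = 16, max_resolution = 3.5,
                            dedup_identity = 0.80, dedup_rmsd = 1.0) {
  stopifnot(dedup_identity > 0, dedup_identity <= 1,
            min_length > 0, max_resolution > 0, dedup_rmsd > 0)
  structure(list(min_length = min_length, max_resolution = max_resolution,
                 dedup_identity = dedup_identity, dedup_rmsd = dedup_rmsd),
            class = "curation_config")
}

#' Filter chains on length and resolution
#'
#' Retains exactly the entries with length >= `min_length` and a known
#' resolution <= `max_resolution`; entries with unknown resolution fail
#' the filter (conservative).  Order is preserved; removals are
#' reported in the `removed` attribute with a reason each.  Idempotent.
#'
#' @param entries list of [chain_entry()]
#' @param config a [curation_config()]
#' @return the retained sublist
#' @export
filter_entries <- function(entries, config = curation_config()) {
  reasons <- character(0)
  keep <- vapply(entries, function(e) {
    if (e$length < config$min_length) {
      reasons[[e$entry_id]] <<- "too short"
      return(FALSE)
    }
    if (is.na(e$resolution)) {
      reasons[[e$entry_id]] <<- "resolution unknown"
      return(FALSE)
    }
    if (e$resolution > config$max_resolution) {
      reasons[[e$entry_id]] <<- "resolution too low"
      return(FALSE)
    }
    TRUE
  }, TRUE)
  out <- entries[keep]
  attr(out, "removed") <- reasons
  out
}

#' Remove redundant chains
#'
#' Deterministic greedy reduction: entries are visited in order of
#' resolution ascending (entry id breaking ties) and retained unless
#' some already-retained entry has pairwise identity above
#' `dedup_identity` *and* aligned-Calpha RMSD below `dedup_rmsd`.  The
#' representative therefore always has resolution at least as good as
#' anything it displaces, and conformational variants (high identity,
#' RMSD at or above the threshold) are all kept.  Entries with fewer
#' than 3 aligned pairs to a retained entry are never considered
#' redundant against it (superposition undefined).
#'
#' @param entries list of [chain_entry()] that passed [filter_entries()]
#' @param config a [curation_config()]
#' @param aligner pairwise alignment function
#' @return retained sublist (resolution order); the `displaced`
#'   attribute maps each removed id to its representative
#' @export
redundancy_reduce <- function(entries, config = curation_config(),
                              aligner = align_pair) {
  if (length(entries) <= 1L) return(entries)
  res <- vapply(entries, function(e) e$resolution, 0)
  ids <- vapply(entries, function(e) e$entry_id, "")
  ord <- order(res, ids)
  entries <- entries[ord]
  retained <- list()
  displaced <- character(0)
  for (e in entries) {
    dup_of <- NULL
    for (r in retained) {
      al <- aligner(e$sequence, r$sequence)
      if (al$identity <= config$dedup_identity) next
      rmsd <- aligned_ca_rmsd(e, r, al)
      if (!is.na(rmsd) && rmsd < config$dedup_rmsd) { dup_of <- r; break }
    }
    if (is.null(dup_of)) retained[[length(retained) + 1L]] <- e
    else displaced[[e$entry_id]] <- dup_of$entry_id
  }
  attr(retained, "displaced") <- displaced
  retained
}

#' Hierarchical organisation of chains by sequence identity
#'
#' Agglomerative (average-linkage) tree over the pairwise identity
#' matrix; merge heights are `1 - identity`, so heights are monotone
#' non-increasing in identity.
#'
#' @param entries list of >= 1 [chain_entry()]
#' @param aligner pairwise alignment function
#' @return object of class `mrp_hierarchy`: fields `labels`, `merge`,
#'   `height`, `order` (the [stats::hclust()] encoding) and the
#'   `identity` matrix
#' @export
cluster_chains <- function(entries, aligner = align_pair) {
  stopifnot(length(entries) >= 1L)
  ids <- vapply(entries, function(e) e$entry_id, "")
  n <- length(entries)
  if (n == 1L) {
    return(structure(list(labels = ids, merge = matrix(0L, 0, 2),
                          height = numeric(0), order = 1L,
                          identity = matrix(1, 1, 1,
                                            dimnames = list(ids, ids))),
                     class = "mrp_hierarchy"))
  }
  idm <- diag(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      idm[i, j] <- idm[j, i] <- aligner(entries[[i]]$sequence,
                                        entries[[j]]$sequence)$identity
    }
  }
  dimnames(idm) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(1 - idm), method = "average")
  structure(list(labels = ids, merge = hc$merge, height = hc$height,
                 order = hc$order, identity = idm),
            class = "mrp_hierarchy")
}

#' @keywords internal
as_hclust <- function(h) {
  structure(list(merge = h$merge, height = h$height, order = h$order,
                 labels = h$labels, method = "average",
                 call = quote(cluster_chains()), dist.method = "1-identity"),
            class = "hclust")
}

#' Decompose a chain into compact domains
#'
#' Recursive contiguous bipartition on the Calpha contact map: at each
#' level every cut point (respecting `min_domain_len`) is scored by the
#' number of contacts it severs, and the best cut is accepted when the
#' severed contacts are at most `split_frac` of the contacts in the
#' segment - a separation criterion for spatial compactness.  Chains
#' shorter than `2 * min_domain_len` come back as one whole-chain
#' domain.  The returned ranges always partition the chain exactly.
#'
#' @param entry a [chain_entry()]
#' @param min_domain_len minimum domain length in residues
#' @param contact_dist Calpha-Calpha contact cutoff in Angstrom
#' @param min_seq_sep contacts closer than this in sequence are ignored
#' @param split_frac maximum severed-contact fraction for an accepted cut
#' @return list of [domain_entry()] (ranges in source numbering)
#' @export
decompose_domains <- function(entry, min_domain_len = 40,
                              contact_dist = 8, min_seq_sep = 3,
                              split_frac = 0.05) {
  n <- entry$length
  d <- as.matrix(stats::dist(entry$ca))
  contact <- d <= contact_dist
  contact[abs(row(contact) - col(contact)) < min_seq_sep] <- FALSE
  ij <- which(contact & upper.tri(contact), arr.ind = TRUE)

  cuts <- integer(0)
  recurse <- function(i0, i1) {
    len <- i1 - i0 + 1L
    if (len < 2L * min_domain_len) return(invisible())
    inseg <- ij[, 1] >= i0 & ij[, 2] <= i1
    total <- sum(inseg)
    if (total == 0L) return(invisible())
    ks <- seq(i0 + min_domain_len - 1L, i1 - min_domain_len)
    sever <- vapply(ks, function(k)
      sum(inseg & ij[, 1] <= k & ij[, 2] > k), 0L)
    best <- which.min(sever)
    if (sever[best] <= split_frac * total) {
      k <- ks[best]
      cuts <<- c(cuts, k)
      recurse(i0, k)
      recurse(k + 1L, i1)
    }
    invisible()
  }
  recurse(1L, n)

  bounds <- sort(unique(c(0L, cuts, n)))
  out <- vector("list", length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    i0 <- bounds[k] + 1L; i1 <- bounds[k + 1L]
    out[[k]] <- domain_entry(entry$entry_id, k,
                             cbind(entry$resno[i0], entry$resno[i1]))
  }
  out
}

# ---- index -----------------------------------------------------------------

#' Assemble the library index
#'
#' Cross-references are validated (a dangling domain or assembly
#' reference errors, naming the reference) and both hierarchies are
#' built: chains clustered by sequence identity, domains by the
#' identity of their subsequences.
#'
#' @param chains curated list of [chain_entry()]
#' @param domains list of [domain_entry()]
#' @param assemblies list of [assembly_record()]
#' @param aligner pairwise alignment function
#' @return object of class `library_index`
#' @export
build_index <- function(chains, domains = list(), assemblies = list(),
                        aligner = align_pair) {
  ids <- vapply(chains, function(e) e$entry_id, "")
  names(chains) <- ids
  for (d in domains) {
    if (!d$parent %in% ids) stop("domain references unknown chain '",
                                 d$parent, "'")
  }
  for (a in assemblies) {
    if (!a$entry_id %in% ids) stop("assembly references unknown chain '",
                                   a$entry_id, "'")
  }
  chain_tree <- if (length(chains) > 0L) cluster_chains(chains, aligner)
                else NULL
  domain_tree <- if (length(domains) > 0L) {
    pseudo <- lapply(domains, function(d) domain_subchain(chains[[d$parent]], d))
    cluster_chains(pseudo, aligner)
  } else NULL
  structure(list(chains = chains, domains = domains,
                 assemblies = assemblies, chain_tree = chain_tree,
                 domain_tree = domain_tree),
            class = "library_index")
}

#' @keywords internal
domain_subchain <- function(parent, d) {
  keep <- rep(FALSE, parent$length)
  for (k in seq_len(nrow(d$residue_ranges))) {
    keep <- keep | (parent$resno >= d$residue_ranges[k, 1] &
                      parent$resno <= d$residue_ranges[k, 2])
  }
  idx <- which(keep)
  chain_entry(paste0(parent$entry_id, "_d", d$domain_index),
              new_sequence(paste0(parent$entry_id, "_d", d$domain_index),
                           paste(strsplit(parent$sequence$residues,
                                          "")[[1]][idx], collapse = "")),
              parent$ca[idx, , drop = FALSE],
              resolution = parent$resolution,
              resno = parent$resno[idx])
}

#' @export
print.library_index <- function(x, ...) {
  cat(sprintf("<library index> %d chains, %d domains, %d assemblies\n",
              length(x$chains), length(x$domains), length(x$assemblies)))
  invisible(x)
}

#' Serialise a library index to JSON
#'
#' Coordinates are stored at the PDB's 3-decimal precision, so a
#' save/load cycle reproduces the index exactly.
#'
#' @param index a [build_index()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
save_index <- function(index, path) {
  # adding zero collapses IEEE negative zeros so that a save/load/save
  # cycle is byte-identical
  round0 <- function(x, digits) round(x, digits) + 0
  ser_chain <- function(e) list(
    entry_id = e$entry_id, residues = e$sequence$residues,
    ca = round0(unname(e$ca), 3), resolution = e$resolution,
    resno = e$resno,
    atoms = if (is.null(e$atoms)) NULL else {
      a <- e$atoms   # column-oriented for compact, reload-stable JSON
      list(chain = a$chain, resno = a$resno, resid = a$resid,
           elety = a$elety, x = round0(a$x, 3), y = round0(a$y, 3),
           z = round0(a$z, 3), model = a$model)
    })
  ser_tree <- function(h) if (is.null(h)) NULL else
    list(labels = h$labels, merge = unname(h$merge), height = h$height,
         order = h$order, identity = unname(round0(h$identity, 10)))
  obj <- list(
    chains = lapply(unname(index$chains), ser_chain),
    domains = lapply(index$domains, function(d) list(
      parent = d$parent, domain_index = d$domain_index,
      residue_ranges = unname(d$residue_ranges))),
    assemblies = lapply(index$assemblies, function(a) list(
      entry_id = a$entry_id,
      operators = lapply(a$operators, function(op) list(
        rotation = unname(round0(op$rotation, 12)),
        translation = round0(op$translation, 6))))),
    chain_tree = ser_tree(index$chain_tree),
    domain_tree = ser_tree(index$domain_tree))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a library index written by [save_index()]
#'
#' @param path JSON file
#' @return a `library_index`
#' @export
load_index <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  chains <- lapply(obj$chains, function(c0) {
    atoms <- if (is.null(c0$atoms)) NULL else
      atom_frame(c0$atoms$chain, c0$atoms$resno, c0$atoms$resid,
                 c0$atoms$elety, c0$atoms$x, c0$atoms$y, c0$atoms$z,
                 c0$atoms$model)
    chain_entry(c0$entry_id, new_sequence(c0$entry_id, c0$residues),
                matrix(unlist(c0$ca), ncol = 3, byrow = is.list(c0$ca)),
                resolution = if (is.null(c0$resolution)) NA_real_
                             else c0$resolution,
                resno = c0$resno, atoms = atoms)
  })
  domains <- lapply(obj$domains, function(d)
    domain_entry(d$parent, d$domain_index,
                 matrix(unlist(d$residue_ranges), ncol = 2,
                        byrow = is.list(d$residue_ranges))))
  assemblies <- lapply(obj$assemblies, function(a)
    assembly_record(a$entry_id, lapply(a$operators, function(op)
      list(rotation = matrix(unlist(op$rotation), 3, 3,
                             byrow = is.list(op$rotation)),
           translation = as.numeric(op$translation)))))
  des_tree <- function(t0) if (is.null(t0)) NULL else {
    idm <- if (is.matrix(t0$identity)) t0$identity else
      matrix(unlist(t0$identity), length(t0$labels), byrow = TRUE)
    dimnames(idm) <- list(t0$labels, t0$labels)
    structure(list(labels = t0$labels,
                   merge = matrix(as.integer(unlist(t0$merge)), ncol = 2,
                                  byrow = is.list(t0$merge)),
                   height = as.numeric(t0$height),
                   order = as.integer(t0$order), identity = idm),
              class = "mrp_hierarchy")
  }
  structure(list(chains = stats::setNames(
    chains, vapply(chains, function(e) e$entry_id, "")),
    domains = domains, assemblies = assemblies,
    chain_tree = des_tree(obj$chain_tree),
    domain_tree = des_tree(obj$domain_tree)),
    class = "library_index")
}
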