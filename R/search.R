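# Homologue search over the library index: hierarchical hit grouping
# (assemblies, per-sequence structures, cross-structure domains), model
# indexing and the Matthews-style copy-number estimate.

#' Target crystal metadata
#'
#' Only metadata is consumed by the decision layer; reflection data stay
#' an opaque path forwarded to external engine adapters.
#'
#' @param sequences list of [new_sequence()] records
#' @param cell six numbers: a, b, c (Angstrom), alpha, beta, gamma
#'   (degrees)
#' @param space_group Hermann-Mauguin symbol (e.g. `"P 21 21 21"`)
#' @param resolution high-resolution limit in Angstrom
#' @param reflections optional opaque path to a reflection file
#' @return object of class `target_data`
#' @export
target_data <- function(sequences, cell, space_group = "P 1",
                        resolution = 2.0, reflections = NULL) {
  if (inherits(sequences, "mrp_sequence")) sequences <- list(sequences)
  cell <- as.numeric(cell)
  stopifnot(length(cell) == 6L, all(cell[1:3] > 0),
            all(cell[4:6] > 0), all(cell[4:6] < 180),
            resolution > 0)
  structure(list(sequences = sequences, cell = cell,
                 space_group = space_group, resolution = resolution,
                 reflections = reflections),
            class = "target_data")
}

#' Write/read a target descriptor (YAML)
#'
#' @param target a [target_data()]
#' @param path descriptor file
#' @return `path` / a `target_data`
#' @export
write_target <- function(target, path) {
  obj <- list(
    sequences = lapply(target$sequences, function(s)
      list(id = s$id, residues = s$residues)),
    cell = target$cell, space_group = target$space_group,
    resolution = target$resolution,
    reflections = target$reflections)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_target
#' @export
read_target <- function(path) {
  obj <- yaml::read_yaml(path)
  target_data(lapply(obj$sequences, function(s)
    new_sequence(s$id, s$residues)),
    cell = unlist(obj$cell), space_group = obj$space_group,
    resolution = obj$resolution, reflections = obj$reflections)
}

#' Search configuration
#'
#' @param max_structures_per_sequence structure (PDB-file) groups kept
#'   per target sequence (default 5)
#' @param max_whole_chain_models cap on whole-chain models per sequence
#'   (default 15)
#' @param include_list optional entry ids restricting the search
#' @param batch_size optional batch size for [batch_runner()]
#' @param user_models optional user-supplied `search_model`s appended to
#'   the hit list
#' @param identity_floor minimal identity for reporting a chain hit
#' @param domain_identity_floor separate (lower) floor for domain hits
#' @return object of class `search_config`
#' @export
search_config <- function(max_structures_per_sequence = 5,
                          max_whole_chain_models = 15,
                          include_list = NULL, batch_size = NULL,
                          user_models = NULL, identity_floor = 0.20,
                          domain_identity_floor = 0.10) {
  stopifnot(max_structures_per_sequence >= 1,
            max_whole_chain_models >= 1,
            is.null(batch_size) || batch_size >= 1)
  structure(list(max_structures_per_sequence = max_structures_per_sequence,
                 max_whole_chain_models = max_whole_chain_models,
                 include_list = include_list, batch_size = batch_size,
                 user_models = user_models,
                 identity_floor = identity_floor,
                 domain_identity_floor = domain_identity_floor),
            class = "search_config")
}

#' @keywords internal
template_hit <- function(template, template_id, kind, group, sequence_ids,
                         alignment, prescore, model_index,
                         ensemble_ok = FALSE) {
  structure(list(template = template, template_id = template_id,
                 kind = kind, group = group, sequence_ids = sequence_ids,
                 alignment = alignment, prescore = prescore,
                 model_index = model_index, ensemble_ok = ensemble_ok),
            class = "template_hit")
}

#' Hierarchical template search
#'
#' Emits hits in the canonical order: (1) assembly hits for all target
#' sequences and every subset of at least two (larger subsets first);
#' (2) per-sequence hits grouped by source structure - at most
#' `max_structures_per_sequence` structures per sequence, each
#' contributing its monomer(s), domains and multimer; (3)
#' cross-structure domain hits from structures outside the per-sequence
#' groups.  Model indices follow the `as<g>m<k>` / `sq<i>st<j>m<k>`
#' scheme (cross-structure domains use `sq<i>dm<k>`).  Chain and domain
#' hits with at least one same-sequence companion are flagged
#' ensemble-eligible so flows can try ensembles before single chains.
#'
#' @param targets list of target [new_sequence()] records
#' @param library a [build_index()] result
#' @param config a [search_config()]
#' @param aligner pairwise alignment function
#' @param scorer ranking function of an alignment (default [prescore()])
#' @return list of `template_hit` (possibly empty, with a `notice`
#'   attribute when nothing clears the identity floor)
#' @export
search_hierarchy <- function(targets, library, config = search_config(),
                             aligner = align_pair, scorer = prescore) {
  if (inherits(targets, "mrp_sequence")) targets <- list(targets)
  stopifnot(length(targets) >= 1L)
  chains <- library$chains
  if (!is.null(config$include_list)) {
    chains <- chains[names(chains) %in% config$include_list]
  }
  nt <- length(targets)
  # alignment cache: target i vs chain id
  aln <- lapply(seq_len(nt), function(i)
    lapply(chains, function(ch) aligner(targets[[i]], ch$sequence)))
  hits <- list()
  emit <- function(h) hits[[length(hits) + 1L]] <<- h

  # -- (1) assembly hits -----------------------------------------------------
  if (nt >= 2L && length(library$assemblies) > 0L) {
    subsets <- list()
    for (size in seq(nt, 2L)) {
      cmb <- utils::combn(nt, size)
      for (c0 in seq_len(ncol(cmb))) {
        subsets[[length(subsets) + 1L]] <- cmb[, c0]
      }
    }
    g <- 0L
    for (s in subsets) {
      cand <- list()
      for (a in library$assemblies) {
        if (!a$entry_id %in% names(chains)) next
        als <- lapply(s, function(i) aln[[i]][[a$entry_id]])
        if (any(vapply(als, function(x) x$identity, 0) <
                config$identity_floor)) next
        cand[[length(cand) + 1L]] <-
          list(a = a, als = als,
               score = mean(vapply(als, scorer, 0)))
      }
      if (length(cand) == 0L) next
      g <- g + 1L
      cand <- cand[order(-vapply(cand, `[[`, 0, "score"),
                         vapply(cand, function(x) x$a$entry_id, ""))]
      for (m in seq_along(cand)) {
        emit(template_hit(cand[[m]]$a, cand[[m]]$a$entry_id, "assembly",
                          sprintf("assembly_%d", g), s,
                          cand[[m]]$als, cand[[m]]$score,
                          sprintf("as%dm%d", g, m)))
      }
    }
  }

  # -- (2) per-sequence structure groups ---------------------------------
  top_structs <- vector("list", nt)
  for (i in seq_len(nt)) {
    sc <- vapply(names(chains), function(id) {
      al <- aln[[i]][[id]]
      if (al$identity < config$identity_floor) -1 else scorer(al)
    }, 0)
    ok <- names(sc)[sc >= 0]
    if (length(ok) == 0L) next
    st <- vapply(ok, structure_of, "")
    best_by_struct <- tapply(sc[ok], st, max)
    structs <- names(sort(best_by_struct, decreasing = TRUE))
    structs <- utils::head(structs, config$max_structures_per_sequence)
    top_structs[[i]] <- structs
    n_chain_models <- 0L
    for (j in seq_along(structs)) {
      members <- ok[st == structs[j]]
      members <- members[order(-sc[members], members)]
      m <- 0L
      many <- length(ok) > 1L
      for (id in members) {       # monomers
        if (n_chain_models >= config$max_whole_chain_models) break
        m <- m + 1L
        n_chain_models <- n_chain_models + 1L
        emit(template_hit(chains[[id]], id, "monomer",
                          sprintf("sq%d_%s", i, structs[j]), i,
                          aln[[i]][[id]], sc[[id]],
                          sprintf("sq%dst%dm%d", i, j, m),
                          ensemble_ok = many))
      }
      for (d in library$domains) {     # domains of this structure
        if (!d$parent %in% members) next
        ral <- restrict_alignment(aln[[i]][[d$parent]], chains[[d$parent]],
                                  d$residue_ranges, targets[[i]])
        if (ral$identity < config$domain_identity_floor ||
            nrow(ral$pairs) < 3L) next
        m <- m + 1L
        emit(template_hit(d, sprintf("%s_d%d", d$parent, d$domain_index),
                          "domain", sprintf("sq%d_%s", i, structs[j]), i,
                          ral, scorer(ral),
                          sprintf("sq%dst%dm%d", i, j, m),
                          ensemble_ok = many))
      }
      for (a in library$assemblies) {  # multimer of this structure
        if (!a$entry_id %in% members || a$multimer_size < 2L) next
        m <- m + 1L
        emit(template_hit(a, a$entry_id, "multimer",
                          sprintf("sq%d_%s", i, structs[j]), i,
                          aln[[i]][[a$entry_id]], sc[[a$entry_id]],
                          sprintf("sq%dst%dm%d", i, j, m)))
      }
    }
  }

  # -- (3) cross-structure domain hits -----------------------------------
  for (i in seq_len(nt)) {
    k <- 0L
    cand <- list()
    for (d in library$domains) {
      if (!d$parent %in% names(chains)) next
      if (structure_of(d$parent) %in% top_structs[[i]]) next
      ral <- restrict_alignment(aln[[i]][[d$parent]], chains[[d$parent]],
                                d$residue_ranges, targets[[i]])
      if (ral$identity < config$domain_identity_floor ||
          nrow(ral$pairs) < 3L) next
      cand[[length(cand) + 1L]] <-
        list(d = d, ral = ral, score = scorer(ral))
    }
    if (length(cand) == 0L) next
    cand <- cand[order(-vapply(cand, `[[`, 0, "score"),
                       vapply(cand, function(x) x$d$parent, ""))]
    for (c0 in cand) {
      k <- k + 1L
      emit(template_hit(c0$d,
                        sprintf("%s_d%d", c0$d$parent, c0$d$domain_index),
                        "domain", sprintf("sq%d_domains", i), i,
                        c0$ral, c0$score, sprintf("sq%ddm%d", i, k),
                        ensemble_ok = length(cand) > 1L))
    }
  }

  if (length(hits) == 0L) {
    attr(hits, "notice") <- "no homologues above the identity floor"
  }
  hits
}

#' Tabular view of a hit list
#'
#' Mirrors the classic report columns: model index, group, template,
#' similarity, residues, multimer/domain flags.
#'
#' @param hits a [search_hierarchy()] result
#' @return data frame, one row per hit
#' @export
hit_table <- function(hits) {
  if (length(hits) == 0L) {
    return(data.frame(model_index = character(0), group = character(0),
                      template = character(0), similarity = numeric(0),
                      residues = integer(0), multimer = logical(0),
                      domain = logical(0), prescore = numeric(0)))
  }
  one_al <- function(h) if (inherits(h$alignment, "alignment_result"))
    h$alignment else h$alignment[[1L]]
  data.frame(
    model_index = vapply(hits, `[[`, "", "model_index"),
    group = vapply(hits, `[[`, "", "group"),
    template = vapply(hits, `[[`, "", "template_id"),
    similarity = vapply(hits, function(h) one_al(h)$identity, 0),
    residues = vapply(hits, function(h) nrow(one_al(h)$pairs), 0L),
    multimer = vapply(hits, function(h) h$kind %in%
                        c("assembly", "multimer"), TRUE),
    domain = vapply(hits, function(h) h$kind == "domain", TRUE),
    prescore = vapply(hits, `[[`, 0, "prescore"),
    stringsAsFactors = FALSE)
}

# ---- copy-number estimation ------------------------------------------------

# Symmetry-operator counts for common Hermann-Mauguin space-group
# symbols (standard settings; rhombohedral groups in the hexagonal
# setting include the centring).
#' @keywords internal
SG_OPERATORS <- c(
  "P 1" = 1, "P -1" = 2,
  "P 2" = 2, "P 21" = 2, "C 2" = 4,
  "P 2 2 2" = 4, "P 2 2 21" = 4, "P 21 21 2" = 4, "P 21 21 21" = 4,
  "C 2 2 21" = 8, "C 2 2 2" = 8, "F 2 2 2" = 16, "I 2 2 2" = 8,
  "I 21 21 21" = 8,
  "P 4" = 4, "P 41" = 4, "P 42" = 4, "P 43" = 4, "I 4" = 8, "I 41" = 8,
  "P 4 2 2" = 8, "P 4 21 2" = 8, "P 41 2 2" = 8, "P 41 21 2" = 8,
  "P 42 2 2" = 8, "P 42 21 2" = 8, "P 43 2 2" = 8, "P 43 21 2" = 8,
  "I 4 2 2" = 16, "I 41 2 2" = 16,
  "P 3" = 3, "P 31" = 3, "P 32" = 3, "R 3" = 9,
  "P 3 1 2" = 6, "P 3 2 1" = 6, "P 31 1 2" = 6, "P 31 2 1" = 6,
  "P 32 1 2" = 6, "P 32 2 1" = 6, "R 3 2" = 18,
  "P 6" = 6, "P 61" = 6, "P 65" = 6, "P 62" = 6, "P 64" = 6, "P 63" = 6,
  "P 6 2 2" = 12, "P 61 2 2" = 12, "P 65 2 2" = 12, "P 62 2 2" = 12,
  "P 64 2 2" = 12, "P 63 2 2" = 12,
  "P 2 3" = 12, "F 2 3" = 48, "I 2 3" = 24, "P 21 3" = 12, "I 21 3" = 24,
  "P 4 3 2" = 24, "P 42 3 2" = 24, "F 4 3 2" = 96, "F 41 3 2" = 96,
  "I 4 3 2" = 48, "P 43 3 2" = 24, "P 41 3 2" = 24, "I 41 3 2" = 48)

#' @keywords internal
sg_operator_count <- function(symbol) {
  key <- toupper(trimws(symbol))
  hit <- match(key, toupper(names(SG_OPERATORS)))
  if (is.na(hit)) {
    # tolerate compact symbols like "P212121"
    compact <- gsub(" ", "", toupper(names(SG_OPERATORS)))
    hit <- match(gsub(" ", "", key), compact)
  }
  if (is.na(hit)) stop("unknown space-group symbol: ", symbol)
  unname(SG_OPERATORS[hit])
}

#' Unit-cell volume from cell parameters
#'
#' @param cell six numbers a, b, c (Angstrom), alpha, beta, gamma
#'   (degrees)
#' @return volume in cubic Angstrom
#' @export
cell_volume <- function(cell) {
  ang <- cell[4:6] * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3])
  prod(cell[1:3]) * sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
}

#' Expected copies of a model in the asymmetric unit
#'
#' Matthews-style estimate: for each candidate copy number the solvent
#' fraction implied by the cell volume, symmetry-operator count and the
#' model weight is computed (protein volume fraction `1.345/Vm`, i.e.
#' 50% solvent at the conventional Vm = 2.69 A^3/Da); the copy number
#' whose solvent fraction is closest to 50% is returned, considering
#' only counts whose fraction lies in `[0.25, 0.75]`.  When no count is
#' feasible the estimate is 0, with a warning.
#'
#' @param target a [target_data()]
#' @param model_weight model molecular weight in Dalton
#' @param solvent_range admissible solvent-fraction window
#' @param max_copies largest copy number considered
#' @return integer copy count (0 when infeasible)
#' @export
estimate_copy_number <- function(target, model_weight,
                                 solvent_range = c(0.25, 0.75),
                                 max_copies = 20) {
  stopifnot(model_weight > 0)
  v <- cell_volume(target$cell)
  z <- sg_operator_count(target$space_group)
  n <- seq_len(max_copies)
  vm <- v / (z * n * model_weight)
  solvent <- 1 - 1.345 / vm
  feasible <- solvent >= solvent_range[1] & solvent <= solvent_range[2]
  if (!any(feasible)) {
    warning("no copy number gives a plausible solvent fraction")
    return(0L)
  }
  n[feasible][which.min(abs(solvent[feasible] - 0.5))]
}

#' Approximate protein weight from sequence length
#'
#' @param sequence an [new_sequence()] or residue count
#' @return weight in Dalton (mean residue mass 110 Da)
#' @export
sequence_weight <- function(sequence) {
  n <- if (inherits(sequence, "mrp_sequence")) nchar(sequence$residues)
       else as.numeric(sequence)
  110 * n
}
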