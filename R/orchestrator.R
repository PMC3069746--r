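# End-to-end flows over an engine: the database-driven flow (assemblies
# first, then per-sequence models, then combination) and the exhaustive
# flow (every prepared model in prescore order, early exit on the first
# good solution), plus local batching.

#' Run configuration
#'
#' @param flow `"balbes"` (assemblies -> per-sequence -> combination) or
#'   `"mrbump"` (exhaustive, ranked by prescore)
#' @param try_all process every model even after a good solution
#'   (default off: early exit)
#' @param n_refine_cycles restrained-refinement cycles per placement
#' @param engine an [mr_engine()], or `"simulated"` to build one from
#'   the problem under study
#' @param job_id optional job identifier; with `workdir`, a
#'   [make_job_tree()] is created and models/reports are written
#' @param workdir optional parent directory for the job tree
#' @param seed master seed; every engine call derives its own stream
#' @param search a [search_config()]
#' @param scoring a [scoring_config()]
#' @param model_types model types prepared per whole-chain template hit
#' @param parallel_workers reserved for local parallelism (1 = serial)
#' @param space_groups optional alternative space groups, forwarded to
#'   engines that understand them (the simulated engine ignores them)
#' @return object of class `run_config`
#' @export
run_config <- function(flow = c("mrbump", "balbes"), try_all = FALSE,
                       n_refine_cycles = 30L, engine = "simulated",
                       job_id = NULL, workdir = NULL, seed = 1L,
                       search = search_config(),
                       scoring = scoring_config(),
                       model_types = c("unmodified", "mixed",
                                       "mixed_msa", "polyalanine"),
                       parallel_workers = 1L, space_groups = NULL) {
  stopifnot(n_refine_cycles >= 1L)
  structure(list(flow = match.arg(flow), try_all = try_all,
                 n_refine_cycles = as.integer(n_refine_cycles),
                 engine = engine, job_id = job_id, workdir = workdir,
                 seed = seed, search = search, scoring = scoring,
                 model_types = model_types,
                 parallel_workers = parallel_workers,
                 space_groups = space_groups),
            class = "run_config")
}

# `best_index` overrides the rank-1 entry as the reported best: the
# staged flow's final answer is its combined solution even when a
# constituent's refinement noise landed marginally lower.
#' @keywords internal
run_result <- function(solutions, combined_index = NULL,
                       notice = NULL, best_index = NULL) {
  solutions <- rank_solutions(solutions)
  best <- if (length(solutions) == 0L) NULL else solutions[[1L]]
  if (!is.null(best_index)) {
    hit <- which(vapply(solutions, `[[`, "", "model_index") == best_index)
    if (length(hit) > 0L) best <- solutions[[hit[1L]]]
  }
  structure(list(solutions = solutions, best = best,
                 combined_index = combined_index, notice = notice),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<run result> no solution\n")
  } else {
    cat(sprintf(
      "<run result> %d scored models; best %s (class %s, Rfree %.3f, Q %.3f)\n",
      length(x$solutions), x$best$model_index,
      x$best$score$mrbump_class,
      x$best$trace$rfree[x$best$trace$n_cycles], x$best$score$q))
  }
  invisible(x)
}

# ---- model preparation for a hit -------------------------------------------

#' Prepare the concrete search models for a template hit
#'
#' Whole-chain hits expand into the configured model types (unmodified,
#' the two mixed variants, polyalanine); domain hits into the extracted
#' domain; assembly/multimer hits into the operator-expanded multimer.
#'
#' @param hit a `template_hit` from [search_hierarchy()]
#' @param library the [build_index()] result the hit came from
#' @param targets list of target sequences
#' @param config a [run_config()]
#' @param msa_maps optional precomputed consensus maps for the
#'   `mixed_msa` variant (see [consensus_alignment()])
#' @return named list of `search_model`s (suffixes appended to the
#'   hit's model index)
#' @export
prepare_hit_models <- function(hit, library, targets, config,
                               msa_maps = NULL) {
  out <- list()
  tgt <- targets[[hit$sequence_ids[1L]]]
  add <- function(m, suffix) {
    m$model_index <- paste0(hit$model_index, suffix)
    out[[m$model_index]] <<- m
  }
  if (hit$kind == "monomer") {
    tpl <- library$chains[[hit$template_id]]
    for (ty in config$model_types) {
      m <- switch(ty,
        unmodified = chain_as_model(tpl),
        polyalanine = make_polyalanine(tpl),
        mixed = try_model(make_mixed_model(tpl, hit$alignment, tgt)),
        mixed_msa = {
          al <- if (is.null(msa_maps)) hit$alignment
                else consensus_restrict(hit$alignment,
                                        msa_maps[[hit$template_id]])
          try_model(make_mixed_model(tpl, al, tgt,
                                     model_type = "mixed_msa"))
        })
      # short type tag; "_" is reserved for combination-stage indices
      tag <- c(unmodified = "un", mixed = "mi", mixed_msa = "mm",
               polyalanine = "po")[[ty]]
      if (!is.null(m)) add(m, tag)
    }
  } else if (hit$kind == "domain") {
    tpl <- library$chains[[hit$template$parent]]
    add(extract_domain(tpl, hit$template), "")
  } else if (hit$kind %in% c("assembly", "multimer")) {
    tpl <- library$chains[[hit$template$entry_id]]
    add(apply_assembly(chain_as_model(tpl), hit$template), "")
  }
  out
}

#' @keywords internal
try_model <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

#' Target-anchored consensus of template alignments
#'
#' The second mixed-model variant is informed by a multiple alignment.
#' This builds it progressively from the pairwise target alignments of
#' the top templates: for each target position the fraction of
#' templates aligning to it is recorded, and [consensus_restrict()]
#' then masks a template's pairwise map down to positions supported by
#' at least `min_support` of the templates - a conservative pairing
#' that mirrors how multiple alignment firms up low-identity regions.
#'
#' @param alignments named list of [align_pair()] results (one per
#'   template, target as pattern)
#' @param target_length target sequence length
#' @param min_support minimal supporting fraction
#' @return named list of logical vectors over target positions
#' @export
consensus_alignment <- function(alignments, target_length,
                                min_support = 0.5) {
  occ <- rep(0, target_length)
  for (al in alignments) {
    occ[al$pairs[, "target"]] <- occ[al$pairs[, "target"]] + 1
  }
  supported <- occ / max(1L, length(alignments)) >= min_support
  lapply(alignments, function(al) supported)
}

#' @keywords internal
consensus_restrict <- function(alignment, supported) {
  if (is.null(supported)) return(alignment)
  keep <- supported[alignment$pairs[, "target"]]
  out <- alignment
  out$pairs <- alignment$pairs[keep, , drop = FALSE]
  out
}

# ---- shared processing core ------------------------------------------------

#' @keywords internal
process_model <- function(model, engine, config, fixed = list(),
                          counter, tree = NULL, template_id = NULL) {
  seed_p <- derive_seed(config$seed, 2L * counter)
  seed_r <- derive_seed(config$seed, 2L * counter + 1L)
  placement <- engine$place(NULL, model, fixed, seed = seed_p)
  trace <- engine$refine(placement, n_cycles = config$n_refine_cycles,
                         seed = seed_r)
  q <- q_factor(trace, config$scoring)
  sc <- solution_score(q, p_solution(q, config$scoring),
                       classify_mrbump(trace, config$scoring))
  files <- character(0)
  if (!is.null(tree) && !is.null(template_id)) {
    d <- model_dir(tree, template_id, model$model_type)
    f <- file.path(d, paste0(model$model_index, ".pdb"))
    write_model(model, f)
    files <- f
  }
  list(model = model, model_index = model$model_index,
       model_type = model$model_type, placement = placement,
       trace = trace, score = sc, files = files)
}

#' @keywords internal
maybe_job_tree <- function(config) {
  if (is.null(config$job_id) || is.null(config$workdir)) return(NULL)
  make_job_tree(config$job_id, config$workdir, overwrite = TRUE)
}

#' @keywords internal
finish_run <- function(solutions, config, tree, combined_index = NULL,
                       notice = NULL, best_index = NULL) {
  res <- run_result(solutions, combined_index = combined_index,
                    notice = notice, best_index = best_index)
  if (!is.null(tree)) {
    write_report(res, file.path(tree$results_dir, "report.txt"),
                 config$scoring)
    utils::write.table(solution_table(res$solutions),
                       file.path(tree$results_dir, "solutions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    res$job_tree <- tree
  }
  res
}

# ---- the exhaustive flow ---------------------------------------------------

#' Run the exhaustive (bulk model preparation) flow
#'
#' Template hits are ranked by prescore; for each, all configured model
#' types are prepared and submitted in rank order.  Every successful
#' placement is refined for `n_refine_cycles` cycles and classified;
#' unless `try_all` is set the flow exits at the first *good*
#' classification.  The final list is ranked by final Rfree, and each
#' solution records the pre-MR rank of its template so rank
#' displacement between the sequence-based and refinement-based
#' orderings can be examined.
#'
#' @param targets target sequence(s) (list of [new_sequence()] or a
#'   [target_data()])
#' @param library a [build_index()] result
#' @param engine an [mr_engine()]
#' @param config a [run_config()]
#' @return a `run_result`
#' @export
run_mrbump_flow <- function(targets, library, engine,
                            config = run_config(flow = "mrbump")) {
  targets <- as_target_list(targets)
  tree <- maybe_job_tree(config)
  hits <- search_hierarchy(targets, library, config$search)
  hits <- hits[order(-vapply(hits, `[[`, 0, "prescore"),
                     vapply(hits, `[[`, "", "model_index"))]
  # consensus maps for the MSA-informed mixed variant, per sequence
  msa_maps <- list()
  for (i in seq_along(targets)) {
    als <- list()
    for (h in hits) {
      if (h$kind == "monomer" && identical(h$sequence_ids, i)) {
        als[[h$template_id]] <- h$alignment
      }
    }
    if (length(als) > 0L) {
      msa_maps <- c(msa_maps,
                    consensus_alignment(als, nchar(targets[[i]]$residues)))
    }
  }
  solutions <- list()
  counter <- 0L
  stop_now <- FALSE
  for (rank0 in seq_along(hits)) {
    h <- hits[[rank0]]
    models <- prepare_hit_models(h, library, targets, config, msa_maps)
    for (m in models) {
      counter <- counter + 1L
      sol <- process_model(m, engine, config, counter = counter,
                           tree = tree, template_id = h$template_id)
      sol$prescore_rank <- rank0
      solutions[[length(solutions) + 1L]] <- sol
      if (!config$try_all && sol$score$mrbump_class == "good") {
        stop_now <- TRUE
        break
      }
    }
    if (stop_now) break
  }
  # user-supplied models are appended after the automatic set
  for (um in config$search$user_models) {
    counter <- counter + 1L
    if (is.na(um$model_index)) um$model_index <- sprintf("user%d", counter)
    sol <- process_model(um, engine, config, counter = counter,
                         tree = tree, template_id = "user")
    sol$prescore_rank <- NA_integer_
    solutions[[length(solutions) + 1L]] <- sol
  }
  finish_run(solutions, config, tree,
             notice = attr(hits, "notice"))
}

# ---- the database-driven flow ----------------------------------------------

#' Run the staged assembly-first flow
#'
#' Stage 1 places and refines assembly models (all-sequence subsets
#' first); if any Q exceeds `q_definite` the flow stops there.  Stage 2
#' processes per-sequence models - ensembles before single chains -
#' keeping the best solution per sequence.  Stage 3 combines the
#' per-sequence best solutions: the best of one sequence is fixed and
#' each remaining best is placed in turn, the result indexed by
#' concatenating the constituent indices with underscores; the final
#' Q/P is computed on the combined solution's trace.
#'
#' @inheritParams run_mrbump_flow
#' @return a `run_result`
#' @export
run_balbes_flow <- function(targets, library, engine,
                            config = run_config(flow = "balbes")) {
  targets <- as_target_list(targets)
  tree <- maybe_job_tree(config)
  hits <- search_hierarchy(targets, library, config$search)
  if (length(hits) == 0L) {
    return(finish_run(list(), config, tree, notice = attr(hits, "notice")))
  }
  scoring <- config$scoring
  solutions <- list()
  counter <- 0L

  run_one <- function(model, template_id, fixed = list()) {
    counter <<- counter + 1L
    sol <- process_model(model, engine, config, fixed = fixed,
                         counter = counter, tree = tree,
                         template_id = template_id)
    solutions[[length(solutions) + 1L]] <<- sol
    sol
  }

  # stage 1: assemblies
  best_q <- -Inf
  for (h in hits) {
    if (h$kind != "assembly") next
    for (m in prepare_hit_models(h, library, targets, config)) {
      sol <- run_one(m, h$template_id)
      best_q <- max(best_q, sol$score$q)
    }
    if (best_q > scoring$q_definite) break
  }
  if (best_q > scoring$q_definite) {
    return(finish_run(solutions, config, tree))
  }

  # stage 2: per-sequence models, ensembles before single chains
  per_seq_best <- list()
  for (i in seq_along(targets)) {
    seq_hits <- Filter(function(h)
      h$kind != "assembly" && identical(h$sequence_ids, i), hits)
    if (length(seq_hits) == 0L) next
    candidates <- list()
    ens_members <- Filter(function(h)
      h$kind == "monomer" && h$ensemble_ok, seq_hits)
    if (length(ens_members) >= 2L) {
      ens <- try_model(build_ensemble(
        lapply(ens_members, function(h) library$chains[[h$template_id]]),
        prescores = vapply(ens_members, `[[`, 0, "prescore")))
      if (!is.null(ens)) {
        ens$model_index <- sprintf("sq%dens1", i)
        sol <- run_one(ens, paste0("sq", i, "_ensemble"))
        candidates[[length(candidates) + 1L]] <- sol
      }
    }
    found <- any(vapply(candidates, function(s)
      s$score$q > scoring$q_definite, TRUE))
    if (!found) {
      for (h in seq_hits) {
        for (m in prepare_hit_models(h, library, targets, config)) {
          sol <- run_one(m, h$template_id)
          candidates[[length(candidates) + 1L]] <- sol
          if (sol$score$q > scoring$q_definite) { found <- TRUE; break }
        }
        if (found && !config$try_all) break
      }
    }
    if (length(candidates) > 0L) {
      qs <- vapply(candidates, function(s) s$score$q, 0)
      per_seq_best[[length(per_seq_best) + 1L]] <-
        c(candidates[[which.max(qs)]], list(sequence_id = i))
    }
  }

  if (length(per_seq_best) <= 1L) {
    return(finish_run(solutions, config, tree))
  }

  # stage 3: combination, best solutions first; each constituent
  # contributes its placed single-member coordinates
  member_atoms <- function(model) {
    a <- model$atoms[model$atoms$model == 1L, , drop = FALSE]
    a$model <- 1L
    a
  }
  ord <- order(-vapply(per_seq_best, function(s) s$score$q, 0))
  per_seq_best <- per_seq_best[ord]
  combined_atoms <- member_atoms(per_seq_best[[1L]]$model)
  fixed <- list(per_seq_best[[1L]]$model)
  indices <- per_seq_best[[1L]]$model_index
  last_sol <- per_seq_best[[1L]]
  for (k in seq_along(per_seq_best)[-1L]) {
    nxt <- per_seq_best[[k]]
    a <- member_atoms(nxt$model)
    used <- unique(combined_atoms$chain)
    a$chain <- LETTERS[(match(a$chain, unique(a$chain)) +
                          length(used) - 1L) %% 26L + 1L]
    model <- search_model(nxt$model$model_type, a, nxt$model$source,
                          model_index = nxt$model_index)
    sol <- run_one(model, "combined", fixed = fixed)
    indices <- c(indices, nxt$model_index)
    combined_atoms <- rbind(combined_atoms, a)
    combined <- search_model("multimer", combined_atoms,
                             source = "combined",
                             model_index = paste(indices, collapse = "_"))
    fixed <- list(combined)
    last_sol <- sol
  }
  combined_index <- paste(indices, collapse = "_")
  combined_sol <- last_sol
  combined_sol$model_index <- combined_index
  combined_sol$model <- fixed[[1L]]
  combined_sol$files <- character(0)
  solutions[[length(solutions) + 1L]] <- combined_sol
  finish_run(solutions, config, tree, combined_index = combined_index,
             best_index = combined_index)
}

#' @keywords internal
as_target_list <- function(targets) {
  if (inherits(targets, "target_data")) return(targets$sequences)
  if (inherits(targets, "mrp_sequence")) return(list(targets))
  targets
}

# ---- batching --------------------------------------------------------------

#' Run a search in consecutive batches of template entries
#'
#' Partitions the entry ids into consecutive batches of `batch_size`,
#' runs `runner` on each (a function taking an include list and
#' returning a `run_result`) and merges the ranked lists.  Up to
#' ranking ties the merged result equals an unbatched run - the local
#' equivalent of feeding a cluster INCLUDE lists of limited size.
#'
#' @param entry_ids template entry ids to process
#' @param batch_size entries per batch (>= 1)
#' @param runner function `(ids) -> run_result`
#' @return merged `run_result`; the `batches` attribute records the
#'   partition
#' @export
batch_runner <- function(entry_ids, batch_size, runner) {
  stopifnot(batch_size >= 1L)
  n <- length(entry_ids)
  batches <- split(entry_ids, ceiling(seq_len(n) / batch_size))
  solutions <- list()
  combined <- NULL
  for (b in batches) {
    res <- runner(b)
    solutions <- c(solutions, res$solutions)
    if (!is.null(res$combined_index)) combined <- res$combined_index
  }
  out <- run_result(solutions, combined_index = combined)
  attr(out, "batches") <- unname(lapply(batches, identity))
  out
}
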