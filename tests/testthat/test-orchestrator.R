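# End-to-end flows over the simulated engine: staging, early exit,
# combination, include lists and batching.

test_that("a near-perfect planted assembly stops the staged flow at stage 1", {
  p <- make_synthetic_problem(21, n_residues = 60, n_targets = 3,
                              n_decoys = 3)
  res <- run_balbes_flow(p$target$sequences, p$library,
                         simulated_engine(p),
                         run_config(flow = "balbes", seed = 21))
  expect_match(res$best$model_index, "^as1m1")
  expect_gt(res$best$score$q, 0.75)
  # stage 1 stopped the flow: nothing but assembly models were processed
  expect_true(all(grepl("^as", vapply(res$solutions, `[[`, "",
                                      "model_index"))))
})

test_that("without assemblies the flow combines per-sequence best solutions", {
  p <- make_synthetic_problem(22, n_residues = 60, n_targets = 3,
                              n_decoys = 3, with_assembly = FALSE)
  res <- run_balbes_flow(p$target$sequences, p$library,
                         simulated_engine(p),
                         run_config(flow = "balbes", seed = 22))
  expect_match(res$combined_index,
               "^sq[0-9]+[a-z0-9_]+(_sq[0-9]+[a-z0-9_]+){2}")
  expect_setequal(unique(regmatches(res$combined_index,
    gregexpr("sq[0-9]+", res$combined_index))[[1]]),
    c("sq1", "sq2", "sq3"))
  # the combined model carries every constituent's residues
  expect_equal(res$best$model_index, res$combined_index)
})

test_that("the combined solution concatenates constituent residues exactly", {
  p <- make_synthetic_problem(23, n_residues = 50, n_targets = 2,
                              n_decoys = 2, with_assembly = FALSE)
  res <- run_balbes_flow(p$target$sequences, p$library,
                         simulated_engine(p),
                         run_config(flow = "balbes", seed = 23))
  expect_false(is.null(res$combined_index))
  expect_equal(res$best$model_index, res$combined_index)
  idx <- vapply(res$solutions, `[[`, "", "model_index")
  comb <- res$solutions[[which(idx == res$combined_index)[1]]]
  n_comb <- sum(comb$model$atoms$elety == "CA")
  parts <- strsplit(res$combined_index, "_")[[1]]
  n_parts <- vapply(parts, function(pi) {
    s <- res$solutions[[which(idx == pi)[1]]]
    a <- s$model$atoms
    sum(a$elety == "CA" & a$model == 1L)
  }, 0)
  expect_equal(n_comb, sum(n_parts))
})

test_that("zero homologues produce an honest empty result", {
  res <- run_balbes_flow(list(new_sequence("t", random_seq_string(40, 24))),
                         build_index(list()),
                         mr_engine(function(...) stop("unused"),
                                   function(...) stop("unused"), "none"),
                         run_config(flow = "balbes", seed = 24))
  expect_null(res$best)
  expect_match(write_report(res), "No solution")
})

test_that("the exhaustive flow early-exits on good and try_all never does worse", {
  p <- make_synthetic_problem(25, n_residues = 60, n_decoys = 6)
  eng <- simulated_engine(p)
  early <- run_mrbump_flow(p$target$sequences, p$library, eng,
                           run_config(flow = "mrbump", seed = 25))
  full <- run_mrbump_flow(p$target$sequences, p$library, eng,
                          run_config(flow = "mrbump", seed = 25,
                                     try_all = TRUE))
  expect_equal(early$best$score$mrbump_class, "good")
  expect_lt(length(early$solutions), length(full$solutions))
  rf <- function(res) res$best$trace$rfree[res$best$trace$n_cycles]
  expect_lte(rf(full), rf(early))
})

test_that("pre-MR rank is recorded and can disagree with the final rank", {
  # seven homologous structures; the seventh by sequence ranking is the
  # only one accurate enough to succeed
  n <- 60
  truth_seq <- random_aa_sequence(n, 2601, id = "truth")
  truth_ca <- make_globule(n, 2602)
  truth <- chain_entry("truth_A", truth_seq, truth_ca)
  chains <- list()
  for (k in 1:7) {
    id <- sprintf("st%02d_A", k)
    idk <- c(0.95, 0.92, 0.89, 0.86, 0.83, 0.80, 0.62)[k]
    sgk <- c(rep(3.0, 6), 0.15)[k]
    sq <- mutate_sequence(truth_seq, idk, 2610 + k, id = id)
    chains[[id]] <- chain_entry(id, sq,
                                perturb_coords(truth_ca, sgk, 2620 + k),
                                resolution = 2.0,
                                atoms = backbone_atoms(
                                  perturb_coords(truth_ca, sgk, 2620 + k),
                                  sq))
  }
  lib <- build_index(chains)
  problem <- list(truth = list(chains = list(truth)))
  cfg <- run_config(flow = "mrbump", seed = 26, try_all = TRUE,
                    search = search_config(max_structures_per_sequence = 10),
                    model_types = "unmodified")
  res <- run_mrbump_flow(list(new_sequence("t", truth_seq$residues)),
                         lib, simulated_engine(problem), cfg)
  expect_equal(res$best$model_type, "unmodified")
  expect_equal(res$best$prescore_rank, 7L)
  expect_match(res$best$model_index, "^sq1st7")
})

test_that("include lists restrict processing to the named templates", {
  p <- make_synthetic_problem(27, n_residues = 50,
                              homologue_identities = c(0.9, 0.85),
                              homologue_sigmas = c(0.3, 0.4),
                              n_decoys = 4)
  cfg <- run_config(flow = "mrbump", seed = 27, try_all = TRUE,
                    search = search_config(include_list = "hom2_A"))
  res <- run_mrbump_flow(p$target$sequences, p$library,
                         simulated_engine(p), cfg)
  srcs <- unique(unlist(lapply(res$solutions, function(s) s$model$source)))
  expect_setequal(srcs, "hom2_A")
})

test_that("batching partitions ids and merges to the unbatched ranking", {
  p <- make_synthetic_problem(28, n_residues = 50,
                              homologue_identities = c(0.9, 0.8),
                              homologue_sigmas = c(0.3, 0.5),
                              n_decoys = 8)
  eng <- simulated_engine(p)
  ids <- names(p$library$chains)
  runner <- function(include) {
    run_mrbump_flow(p$target$sequences, p$library, eng,
                    run_config(flow = "mrbump", seed = 28, try_all = TRUE,
                               search = search_config(
                                 include_list = include,
                                 max_structures_per_sequence = 10)))
  }
  merged <- batch_runner(ids, 3, runner)
  sizes <- vapply(attr(merged, "batches"), length, 0L)
  expect_equal(sizes, c(3L, 3L, 3L, 1L))
  unbatched <- runner(ids)
  expect_equal(vapply(merged$solutions, `[[`, "", "model_index"),
               vapply(unbatched$solutions, `[[`, "", "model_index"))
  single <- batch_runner(ids[1:2], 1, runner)
  expect_length(attr(single, "batches"), 2L)
})

test_that("a job tree captures models, report and summary", {
  wd <- withr_local_tempdir()
  p <- make_synthetic_problem(29, n_residues = 50, n_decoys = 2)
  cfg <- run_config(flow = "mrbump", seed = 29, job_id = "29",
                    workdir = wd)
  res <- run_mrbump_flow(p$target$sequences, p$library,
                         simulated_engine(p), cfg)
  root <- file.path(wd, "search_29")
  expect_true(dir.exists(file.path(root, "data")))
  expect_true(file.exists(file.path(root, "results", "report.txt")))
  expect_true(file.exists(file.path(root, "results", "solutions.tsv")))
  expect_gt(length(list.files(file.path(root, "data"), recursive = TRUE,
                              pattern = "[.]pdb$")), 0L)
  tab <- utils::read.delim(file.path(root, "results", "solutions.tsv"))
  expect_equal(nrow(tab), length(res$solutions))
})

test_that("the CLI runs end to end on serialised problems", {
  wd <- withr_local_tempdir()
  p <- make_synthetic_problem(30, n_residues = 40, n_decoys = 2)
  pd <- file.path(wd, "problem")
  write_problem(p, pd)
  idx <- file.path(wd, "index.json")
  out <- utils::capture.output(
    mrp_cli(c("library", "build", "--pdb-dir", pd, "--meta",
              file.path(pd, "templates.tsv"), "--out", idx)),
    type = "message")
  expect_true(file.exists(idx))
  tsv <- utils::capture.output(
    mrp_cli(c("search", "--seqin", file.path(pd, "target.fasta"),
              "--library", idx)))
  expect_gt(length(tsv), 1L)
  expect_match(tsv[1], "model_index")
  rep <- utils::capture.output(
    mrp_cli(c("run", "--flow", "mrbump",
              "-s", file.path(pd, "target.fasta"),
              "--target", file.path(pd, "target.yaml"),
              "--library", idx, "--truth", file.path(pd, "truth.pdb"),
              "--seed", "3")))
  expect_match(paste(rep, collapse = "\n"), "Ranked solutions")
})
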