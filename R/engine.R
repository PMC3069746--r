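# The MR/refinement engine contract and the seeded simulated engine.
#
# An engine is a pair of functions behind a fixed signature; the
# orchestration layer never sees anything else.  The simulated engine's
# dynamics are an invention of this package, calibrated only so that
# every decision path (good/marginal/poor classes, all Q bands) is
# exercisable; they model no crystallography.

#' Evaluate code under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded engine calls never
#' disturb the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %%
               .Machine$integer.max)
}

#' Construct an engine
#'
#' @param place function `(target, model, fixed, seed)` returning a
#'   placement (see [simulated_engine()]); failure is a signalled
#'   outcome (`success = FALSE`), never an exception
#' @param refine function `(placement, n_cycles, seed)` returning a
#'   [refinement_trace()] with exactly `n_cycles` entries
#' @param name engine label
#' @return object of class `mr_engine`
#' @export
mr_engine <- function(place, refine, name) {
  stopifnot(is.function(place), is.function(refine))
  structure(list(place = place, refine = refine, name = name),
            class = "mr_engine")
}

#' Simulated-engine constants
#'
#' All simulator constants live here.  `Rfree` starts near `start`,
#' decays with time constant `tau` towards an asymptote
#' `asym_base - asym_gain * sqrt(q*)` that falls with model quality
#' `q* = identity x coverage x exp(-rmsd)`, plus seeded Gaussian noise
#' `noise`; `R` tracks `Rfree` minus a gap `gap_base + gap_gain *
#' (1 - q*)` that grows with overfitting at low quality.  Placements
#' with `q*` below `success_floor` fail and refine to a flat trace
#' (noise `flat_noise`).  Each fixed model eases the floor by
#' `fixed_relief` (placing into a partial solution shrinks the search
#' problem and never lowers the success chance).
#'
#' @param start,tau,noise,flat_noise,asym_base,asym_gain,gap_base,gap_gain,success_floor,fixed_relief
#'   see description
#' @return object of class `sim_config`
#' @export
sim_config <- function(start = 0.55, tau = 4, noise = 0.005,
                       flat_noise = 0.002, asym_base = 0.55,
                       asym_gain = 0.35, gap_base = 0.02, gap_gain = 0.08,
                       success_floor = 0.2, fixed_relief = 0.15) {
  structure(list(start = start, tau = tau, noise = noise,
                 flat_noise = flat_noise, asym_base = asym_base,
                 asym_gain = asym_gain, gap_base = gap_base,
                 gap_gain = gap_gain, success_floor = success_floor,
                 fixed_relief = fixed_relief),
            class = "sim_config")
}

#' Model quality of a search model against the ground truth
#'
#' `q* = identity x coverage x exp(-rmsd)`, computed from a pairwise
#' alignment of the model's (first-member, first-chain) sequence to the
#' truth chain and the aligned-Calpha RMSD after superposition.  The
#' truth itself scores 1; unrelated decoys score essentially 0 because
#' their post-fit RMSD is large.
#'
#' @param model a `search_model` or [chain_entry()]
#' @param truth the ground-truth [chain_entry()]
#' @param aligner pairwise alignment function
#' @return q* in \[0, 1\]
#' @export
model_quality <- function(model, truth, aligner = align_pair) {
  ch <- if (inherits(model, "chain_entry")) model else model_as_chain(model)
  al <- aligner(truth$sequence, ch$sequence)
  if (nrow(al$pairs) < 3L) return(0)
  rmsd <- aligned_ca_rmsd(truth, ch, al)
  if (is.na(rmsd)) return(0)
  al$identity * al$coverage * exp(-rmsd)
}

#' Seeded simulated MR/refinement engine
#'
#' Implements the engine contract against a synthetic problem's ground
#' truth (see [make_synthetic_problem()]).  `place` succeeds when the
#' model quality `q*` (plus a little seeded noise) clears the
#' configured floor, returning an `mr_placement` whose `mr_score`
#' increases with `q*`; `refine` produces a [refinement_trace()] of
#' exactly `n_cycles` values following the dynamics documented in
#' [sim_config()].  Fully deterministic under fixed seeds.
#'
#' @param problem a `synthetic_problem`
#' @param config a [sim_config()]
#' @param aligner pairwise alignment function used for model quality
#' @return an [mr_engine()]
#' @export
simulated_engine <- function(problem, config = sim_config(),
                             aligner = align_pair) {
  truths <- problem$truth$chains
  place <- function(target, model, fixed = list(), seed = 1L) {
    stopifnot(nrow(model$atoms) > 0L)
    qstar <- max(vapply(truths, function(tr)
      model_quality(model, tr, aligner), 0))
    floor_eff <- config$success_floor *
      (1 - config$fixed_relief * min(length(fixed), 3L))
    with_seed(seed, {
      jitter <- stats::rnorm(1, 0, 0.01)
      success <- (qstar + jitter) > floor_eff
      mr_score <- max(0, 100 * qstar + stats::rnorm(1, 0, 1))
    })
    structure(list(model = model, transform = NULL,
                   mr_score = mr_score, success = success,
                   qstar = qstar),
              class = "mr_placement")
  }
  refine <- function(placement, n_cycles = 30L, seed = 1L) {
    stopifnot(n_cycles >= 1L)
    q <- placement$qstar
    with_seed(seed, {
      if (!placement$success) {
        rfree <- config$start + stats::rnorm(n_cycles, 0, config$flat_noise)
        r <- rfree - config$gap_base +
          stats::rnorm(n_cycles, 0, config$flat_noise)
      } else {
        asym <- config$asym_base - config$asym_gain * sqrt(q)
        t <- seq_len(n_cycles) - 1L
        rfree <- asym + (config$start - asym) * exp(-t / config$tau) +
          stats::rnorm(n_cycles, 0, config$noise)
        gap <- (config$gap_base + config$gap_gain * (1 - q)) *
          (1 - exp(-t / config$tau))
        r <- rfree - gap + stats::rnorm(n_cycles, 0, config$noise / 2)
      }
    })
    refinement_trace(pmin(pmax(r, 0), 1), pmin(pmax(rfree, 0), 1))
  }
  mr_engine(place, refine, "simulated")
}

# ---- external-engine adapter stubs ----------------------------------------

#' Command-line builders for external MR/refinement programs
#'
#' Structural parity with the real pipelines: the adapters honour the
#' same contract as the simulated engine but only construct the command
#' lines; invoking them requires the corresponding crystallographic
#' programs, which this package does not ship.  `place`/`refine` raise
#' an informative error when the executable is absent.
#'
#' @param program `"molrep"`, `"phaser"` or `"refmac5"`
#' @param hklin,seqin,xyzin,xyzout,hklout file arguments
#' @return character vector: the program followed by its arguments
#' @export
external_engine_command <- function(program = c("molrep", "phaser",
                                                "refmac5"),
                                    hklin = NULL, seqin = NULL,
                                    xyzin = NULL, xyzout = NULL,
                                    hklout = NULL) {
  program <- match.arg(program)
  args <- switch(program,
    molrep = c("-f", hklin, "-s", seqin, "-m", xyzin),
    phaser = c("HKLIN", hklin, "SEQIN", seqin, "XYZIN", xyzin),
    refmac5 = c("HKLIN", hklin, "XYZIN", xyzin, "XYZOUT", xyzout,
                "HKLOUT", hklout))
  c(program, args[!vapply(args, is.null, TRUE)])
}

#' @rdname external_engine_command
#' @param name engine name (`"molrep"` or `"phaser"`)
#' @export
external_engine <- function(name = c("molrep", "phaser")) {
  name <- match.arg(name)
  fail <- function(...) stop("external engine '", name,
                             "' is not available in this installation; ",
                             "use engine = \"simulated\"")
  mr_engine(place = fail, refine = fail, name = name)
}
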