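# Refinement-trace scoring: Q factor, solution probability, the
# good/marginal/poor classification and final ranking.

#' Per-cycle refinement statistics
#'
#' @param r R values per cycle (fractions in \[0, 1\])
#' @param rfree Rfree values per cycle, same length
#' @return object of class `refinement_trace` with fields `r`, `rfree`,
#'   `n_cycles` and a `flagged` attribute when any value exceeds 0.75
#' @export
refinement_trace <- function(r, rfree) {
  r <- as.numeric(r); rfree <- as.numeric(rfree)
  if (length(r) < 1L || length(r) != length(rfree)) {
    stop("r and rfree must have equal length >= 1")
  }
  if (any(r < 0 | r > 1) || any(rfree < 0 | rfree > 1)) {
    stop("R values must lie in [0, 1]")
  }
  out <- structure(list(r = r, rfree = rfree, n_cycles = length(r)),
                   class = "refinement_trace")
  attr(out, "flagged") <- any(c(r, rfree) > 0.75)
  out
}

#' @export
print.refinement_trace <- function(x, ...) {
  cat(sprintf("<trace> %d cycles  R %.4f -> %.4f  Rfree %.4f -> %.4f\n",
              x$n_cycles, x$r[1], x$r[x$n_cycles],
              x$rfree[1], x$rfree[x$n_cycles]))
  invisible(x)
}

#' Scoring configuration
#'
#' All constants of the empirical quality curve, the probability map and
#' the good/marginal/poor rule live here so none is buried in code.
#'
#' The Q factor is an empirical function of the weighted final R
#' statistics, `Rw = w * Rfree_final + (1 - w) * R_final`:
#' \deqn{Q = 1 / (1 + Rw/q0 + (Rw/r_random)^gamma)}
#' The rational term calibrates the high-quality regime; the steep
#' high-power term (negligible for well-refined solutions) drives Q
#' towards 0 as Rw approaches the random-model plateau near 0.55.
#' `Q > 0.75` marks a definite solution, `Q < 0.25` a very unlikely one.
#'
#' The solution probability is a logistic map centred mid-band:
#' `P = plogis((Q - p_mid) / p_scale)`.
#'
#' The class rule uses the final Rfree and its change over the
#' refinement: *good* requires `Rfree_final <= good_rfree` and a drop of
#' at least `good_drop`; *marginal* requires `Rfree_final <=
#' marginal_rfree` and a drop of at least `marginal_drop`; anything else
#' is *poor*.  All boundaries are inclusive.
#'
#' @param w weight of Rfree against R in `Rw` (default 0.75)
#' @param q0 linear calibration constant of the quality curve
#' @param r_random R level of a random model (onset of the steep penalty)
#' @param gamma exponent of the steep penalty term
#' @param q_definite,q_unlikely the 0.75/0.25 band edges
#' @param p_mid,p_scale centre and scale of the logistic probability map
#' @param good_rfree,good_drop,marginal_rfree,marginal_drop class rule
#'   thresholds
#' @param report_prob_cap cap applied to *displayed* probabilities
#' @return object of class `scoring_config`
#' @export
scoring_config <- function(w = 0.75, q0 = 1.58, r_random = 0.5,
                           gamma = 16, q_definite = 0.75,
                           q_unlikely = 0.25, p_mid = 0.5, p_scale = 0.05,
                           good_rfree = 0.45, good_drop = 0.05,
                           marginal_rfree = 0.50, marginal_drop = 0.02,
                           report_prob_cap = 0.990) {
  stopifnot(w >= 0, w <= 1, q_unlikely < q_definite, q0 > 0, p_scale > 0)
  structure(list(w = w, q0 = q0, r_random = r_random, gamma = gamma,
                 q_definite = q_definite, q_unlikely = q_unlikely,
                 p_mid = p_mid, p_scale = p_scale,
                 good_rfree = good_rfree, good_drop = good_drop,
                 marginal_rfree = marginal_rfree,
                 marginal_drop = marginal_drop,
                 report_prob_cap = report_prob_cap),
            class = "scoring_config")
}

#' Q factor of a refined solution
#'
#' Empirical quality score computed from the final R and Rfree of a
#' refinement trace (see [scoring_config()] for the curve and its
#' constants).  Strictly decreasing in both final statistics; values
#' above `q_definite` mark solutions that are definitely correct, values
#' below `q_unlikely` solutions that are very unlikely to be correct.
#'
#' @param trace a [refinement_trace()]
#' @param config a [scoring_config()]
#' @return Q in \[0, 1\]
#' @export
#' @examples
#' tr <- refinement_trace(r = c(0.3730, 0.2520), rfree = c(0.4070, 0.3100))
#' round(q_factor(tr), 3)  # 0.842
q_factor <- function(trace, config = scoring_config()) {
  if (is.null(trace$rfree)) stop("Rfree required")
  rw <- config$w * trace$rfree[trace$n_cycles] +
    (1 - config$w) * trace$r[trace$n_cycles]
  1 / (1 + rw / config$q0 + (rw / config$r_random)^config$gamma)
}

#' Probability that a scored solution is correct
#'
#' Monotone logistic map from the Q factor to a probability; the
#' presentation cap (99.0%) is applied only when rendering reports,
#' never here.
#'
#' @param q Q factor in \[0, 1\]
#' @param config a [scoring_config()]
#' @return probability in (0, 1)
#' @export
p_solution <- function(q, config = scoring_config()) {
  stopifnot(q >= 0, q <= 1)
  stats::plogis((q - config$p_mid) / config$p_scale)
}

#' Q band of a solution
#'
#' @param q Q factor
#' @param config a [scoring_config()]
#' @return `"definite"` (`q > 0.75`), `"unlikely"` (`q < 0.25`) or
#'   `"intermediate"`
#' @export
q_band <- function(q, config = scoring_config()) {
  if (q > config$q_definite) "definite"
  else if (q < config$q_unlikely) "unlikely"
  else "intermediate"
}

#' Classify a refinement trace as good, marginal or poor
#'
#' Deterministic rule on the final Rfree and its change over the
#' refinement (thresholds in [scoring_config()]; boundaries inclusive).
#' A flat high trace never classifies good.
#'
#' @param trace a [refinement_trace()] with at least 2 cycles
#' @param config a [scoring_config()]
#' @return `"good"`, `"marginal"` or `"poor"`
#' @export
classify_mrbump <- function(trace, config = scoring_config()) {
  if (trace$n_cycles < 2L) stop("classification needs >= 2 cycles")
  final <- trace$rfree[trace$n_cycles]
  drop <- trace$rfree[1L] - final
  eps <- 1e-9   # inclusive boundaries, robust to float representation
  if (final <= config$good_rfree + eps && drop >= config$good_drop - eps)
    "good"
  else if (final <= config$marginal_rfree + eps &&
             drop >= config$marginal_drop - eps) "marginal"
  else "poor"
}

#' @keywords internal
solution_score <- function(q, p, mrbump_class, rank = NA_integer_) {
  structure(list(q = q, p = p, mrbump_class = mrbump_class,
                 rank = as.integer(rank)),
            class = "solution_score")
}

#' Rank scored solutions
#'
#' Solutions are ranked by ascending final Rfree; ties are broken by Q
#' descending, then model index lexicographically.  Ranks 1..n are
#' written into each solution's score.
#'
#' @param solutions list of solutions, each carrying `model_index`,
#'   `trace` and `score`
#' @return the list, reordered, with ranks assigned
#' @export
rank_solutions <- function(solutions) {
  if (length(solutions) == 0L) return(solutions)
  rfree <- vapply(solutions, function(s) s$trace$rfree[s$trace$n_cycles], 0)
  q <- vapply(solutions, function(s) s$score$q, 0)
  idx <- vapply(solutions, function(s) s$model_index, "")
  ord <- order(rfree, -q, idx)
  out <- solutions[ord]
  for (i in seq_along(out)) out[[i]]$score$rank <- i
  out
}

#' Tabular summary of ranked solutions
#'
#' @param solutions a ranked solution list (see [rank_solutions()])
#' @return data frame with one row per solution
#' @export
solution_table <- function(solutions) {
  if (length(solutions) == 0L) {
    return(data.frame(rank = integer(0), model_index = character(0),
                      model_type = character(0), class = character(0),
                      rfree_final = numeric(0), r_final = numeric(0),
                      q = numeric(0), p = numeric(0),
                      prescore_rank = integer(0)))
  }
  data.frame(
    rank = vapply(solutions, function(s) s$score$rank, 0L),
    model_index = vapply(solutions, function(s) s$model_index, ""),
    model_type = vapply(solutions, function(s)
      if (is.null(s$model_type)) NA_character_ else s$model_type, ""),
    class = vapply(solutions, function(s) s$score$mrbump_class, ""),
    rfree_final = vapply(solutions, function(s)
      s$trace$rfree[s$trace$n_cycles], 0),
    r_final = vapply(solutions, function(s) s$trace$r[s$trace$n_cycles], 0),
    q = vapply(solutions, function(s) s$score$q, 0),
    p = vapply(solutions, function(s) s$score$p, 0),
    prescore_rank = vapply(solutions, function(s)
      if (is.null(s$prescore_rank)) NA_integer_ else
        as.integer(s$prescore_rank), 0L),
    stringsAsFactors = FALSE)
}
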