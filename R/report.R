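# Plain-text run report: best-solution summary plus the full ranked
# model list.

#' @keywords internal
format_prob_percent <- function(p, cap = 0.990) {
  sprintf("%.1f%%", min(p, cap) * 100)
}

#' Render the final run report
#'
#' For the best solution the report shows the model index, output file
#' paths, initial/final R and Rfree, the Q factor to 3 decimals and the
#' sentence `"Its probability of being a solution is NN.N%"`, with the
#' displayed probability capped at 99.0% (the internal value is never
#' capped).  The full ranked model list with class labels and final
#' Rfree follows.  An empty solution list renders a no-solution notice
#' and no Q line.
#'
#' @param result a `run_result` (see [run_mrbump_flow()]) or any list
#'   with a `solutions` element; each solution carries `model_index`,
#'   `trace`, `score` and optionally `files`
#' @param path optional file to write the report to
#' @param config scoring/report configuration, see [scoring_config()]
#' @return the report as a single character string, invisibly when
#'   `path` is given
#' @export
write_report <- function(result, path = NULL, config = scoring_config()) {
  sols <- result$solutions
  lines <- character(0)
  if (length(sols) == 0L) {
    lines <- c(lines, "No solution was found.")
  } else {
    best <- sols[[1L]]
    tr <- best$trace
    sc <- best$score
    lines <- c(lines,
      "A structure is suggested.",
      sprintf("Its probability of being a solution is %s.",
              format_prob_percent(sc$p, config$report_prob_cap)),
      "",
      sprintf("Model index                %s", best$model_index),
      sprintf("PDB file                   %s",
              if (length(best$files) > 0L) best$files[[1L]] else "-"),
      sprintf("R_initial/R_final          %.4f/%.4f",
              tr$r[1L], tr$r[tr$n_cycles]),
      sprintf("Rfree_initial/Rfree_final  %.4f/%.4f",
              tr$rfree[1L], tr$rfree[tr$n_cycles]),
      sprintf("Q factor                   %.3f", sc$q),
      "",
      "Ranked solutions (by final Rfree):",
      sprintf("%-4s %-28s %-8s %-11s %-6s",
              "rank", "model_index", "class", "Rfree_final", "Q"))
    for (s in sols) {
      lines <- c(lines,
        sprintf("%-4d %-28s %-8s %-11.4f %-6.3f",
                s$score$rank, s$model_index, s$score$mrbump_class,
                s$trace$rfree[s$trace$n_cycles], s$score$q))
    }
  }
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
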