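# Job directory layout: search_<JobID>/ with data/, results/ and logs/
# subtrees; one directory per template search model under data/, one
# subdirectory per model type.

#' Create the job directory tree
#'
#' Lays out `search_<job_id>/` with `data/`, `results/` and `logs/`
#' subdirectories.  Per-template subtrees under `data/` are created
#' lazily *via* [model_dir()] as models are processed.
#'
#' @param job_id job identifier (appended to `search_`)
#' @param workdir writable parent directory
#' @param overwrite remove an existing tree first (default errors on
#'   collision)
#' @return object of class `mrp_job_tree`
#' @export
make_job_tree <- function(job_id, workdir, overwrite = FALSE) {
  stopifnot(length(job_id) == 1L, dir.exists(workdir))
  root <- file.path(workdir, paste0("search_", job_id))
  if (dir.exists(root)) {
    if (!overwrite) stop("job tree already exists: ", root)
    unlink(root, recursive = TRUE)
  }
  dirs <- file.path(root, c("data", "results", "logs"))
  for (d in dirs) dir.create(d, recursive = TRUE)
  structure(list(root = root, data_dir = dirs[1], results_dir = dirs[2],
                 logs_dir = dirs[3], job_id = as.character(job_id)),
            class = "mrp_job_tree")
}

#' Per-model working directory inside a job tree
#'
#' @param tree an [make_job_tree()] result
#' @param template_id template search-model identifier (e.g. `"1abc_A"`)
#' @param model_type one of the prepared model types
#' @return the directory path, created if needed
#' @export
model_dir <- function(tree, template_id, model_type) {
  stopifnot(inherits(tree, "mrp_job_tree"))
  d <- file.path(tree$data_dir, template_id, model_type)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}
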