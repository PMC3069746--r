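# Pairwise sequence alignment and the pre-MR ranking score.
#
# Alignment is delegated to Biostrings::pairwiseAlignment (BLOSUM62,
# affine gaps); this module derives the residue-pair map, identity and
# coverage that the rest of the pipeline consumes.

#' Alignment parameters
#'
#' @param matrix substitution matrix name (a matrix object shipped with
#'   Biostrings, default `"BLOSUM62"`)
#' @param gap_open,gap_extend affine gap penalties (positive costs)
#' @param type `"global"` (Needleman-Wunsch, used for ranking) or
#'   `"local"`
#' @param identity_mode denominator of the identity fraction:
#'   `"aligned"` (identical pairs / aligned non-gap columns, the default
#'   used throughout) or `"shorter"` (identical pairs / shorter sequence
#'   length)
#' @return object of class `align_params`
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 1, type = c("global", "local"),
                         identity_mode = c("aligned", "shorter")) {
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, type = match.arg(type),
                 identity_mode = match.arg(identity_mode)),
            class = "align_params")
}

#' @keywords internal
get_sub_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Align two sequences
#'
#' Optimal pairwise alignment under affine gap scoring.  The result
#' carries the residue-pair map (strictly increasing in both
#' coordinates), the identity and the coverage (aligned fraction of
#' `a`), which downstream ranking and model editing consume.
#'
#' @param a target sequence (an [new_sequence()] record)
#' @param b template sequence
#' @param params an [align_params()]
#' @return object of class `alignment_result` with fields `pairs`
#'   (m x 2 matrix, columns `target`/`template`, 1-based residue
#'   indices), `identity`, `coverage` and `score`
#' @export
align_pair <- function(a, b, params = align_params()) {
  stopifnot(nchar(a$residues) > 0L, nchar(b$residues) > 0L)
  al <- Biostrings::pairwiseAlignment(
    a$residues, b$residues,
    substitutionMatrix = get_sub_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = params$type)
  pat <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  # local alignments start mid-sequence
  off_a <- Biostrings::start(Biostrings::pattern(al)) - 1L
  off_b <- Biostrings::start(Biostrings::subject(al)) - 1L
  ia <- off_a + cumsum(pat != "-")
  ib <- off_b + cumsum(sub != "-")
  both <- pat != "-" & sub != "-"
  pairs <- cbind(target = ia[both], template = ib[both])
  ident_pairs <- sum(pat[both] == sub[both])
  denom <- switch(params$identity_mode,
                  aligned = max(1L, nrow(pairs)),
                  shorter = min(nchar(a$residues), nchar(b$residues)))
  structure(list(pairs = pairs,
                 identity = ident_pairs / denom,
                 coverage = nrow(pairs) / nchar(a$residues),
                 score = Biostrings::score(al)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> %d pairs  identity %.3f  coverage %.3f  score %.1f\n",
              nrow(x$pairs), x$identity, x$coverage, x$score))
  invisible(x)
}

#' Pre-MR ranking score of a template hit
#'
#' The product of alignment identity and target coverage: a scoring
#' function built from the sequence alignment and its completeness,
#' monotone increasing in each factor.  Exposed as the default ranking
#' strategy; flows accept any function with this signature.
#'
#' @param hit_alignment an [align_pair()] result
#' @return score in \[0, 1\]
#' @export
prescore <- function(hit_alignment) {
  hit_alignment$identity * hit_alignment$coverage
}

#' Restrict an alignment to template residues inside domain ranges
#'
#' Used when a domain of a template chain is scored against the target:
#' the parent-chain alignment is cut down to pairs whose template
#' residue (source numbering) lies in the domain, and identity/coverage
#' are recomputed on the restriction.
#'
#' @param alignment parent-chain [align_pair()] result
#' @param template parent [chain_entry()]
#' @param ranges k x 2 matrix of inclusive source-numbering spans
#' @param target target sequence (for the coverage denominator)
#' @return an `alignment_result`
#' @keywords internal
restrict_alignment <- function(alignment, template, ranges, target) {
  resno <- template$resno[alignment$pairs[, "template"]]
  keep <- rep(FALSE, length(resno))
  for (k in seq_len(nrow(ranges))) {
    keep <- keep | (resno >= ranges[k, 1] & resno <= ranges[k, 2])
  }
  pairs <- alignment$pairs[keep, , drop = FALSE]
  ta <- strsplit(target$residues, "")[[1]]
  tb <- strsplit(template$sequence$residues, "")[[1]]
  ident <- if (nrow(pairs) > 0L)
    sum(ta[pairs[, "target"]] == tb[pairs[, "template"]]) / nrow(pairs)
  else 0
  structure(list(pairs = pairs, identity = ident,
                 coverage = nrow(pairs) / nchar(target$residues),
                 score = NA_real_),
            class = "alignment_result")
}
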