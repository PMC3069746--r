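# Sequence container and FASTA input/output.

#' Create a sequence record
#'
#' @param id text label (FASTA header without the leading `>`)
#' @param residues one-letter amino-acid string; the 20 standard letters
#'   plus `X` are accepted, lower case is folded to upper
#' @return an object of class `mrp_sequence`
#' @export
#' @examples
#' new_sequence("t", "MKV")
new_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L)
  residues <- toupper(as.character(residues))
  if (nchar(residues) < 1L) stop("sequence '", id, "' is empty")
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters), AA_LETTERS)
  if (length(bad) > 0L) {
    stop("sequence '", id, "' contains non amino-acid letters: ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, residues = residues), class = "mrp_sequence")
}

#' @export
print.mrp_sequence <- function(x, ...) {
  cat("<sequence>", x$id, paste0("(", nchar(x$residues), " aa)"), "\n")
  invisible(x)
}

#' @export
length.mrp_sequence <- function(x) nchar(x$residues)

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; a light
#' pre-scan reports malformed records with the offending line number,
#' which the Biostrings parser does not do.
#'
#' @param path FASTA file
#' @return list of [new_sequence()] records, in file order, headers kept
#'   as ids
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("no sequences in ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA record at line ", nonblank[1],
         ": expected a '>' header")
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty) > 0L) {
    hdr <- which(startsWith(trimws(lines), ">"))[empty[1]]
    stop("malformed FASTA record at line ", hdr, ": header without sequence")
  }
  lapply(seq_along(set), function(i) {
    new_sequence(names(set)[i], as.character(set[[i]]))
  })
}

#' Write sequences to a FASTA file
#'
#' @param sequences list of `mrp_sequence` records
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "mrp_sequence")) sequences <- list(sequences)
  set <- Biostrings::AAStringSet(vapply(sequences, `[[`, "", "residues"))
  names(set) <- vapply(sequences, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
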