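#' Parse protein tail sequences from a FASTA file
#'
#' Reads cytosolic-tail sequences (e.g. the ADAM tails used as biopanning
#' baits) from FASTA. A single trailing stop marker \code{"*"} on a record is
#' stripped at parse time and never stored; any other character outside the
#' 20 standard amino-acid codes is an error naming the record and position.
#'
#' @param path path to a FASTA file; records may end in \code{"*"}.
#' @param source free-text provenance note attached to every tail.
#' @return a named list of \code{protein_tail} objects, each with fields
#'   \code{id} (first token of the FASTA header), \code{sequence} and
#'   \code{source}.
#' @export
parse_tails <- function(path, source = basename(path)) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  tails <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    s <- sub("\\*$", "", s)
    protein_tail(ids[i], s, source = source)
  })
  names(tails) <- ids
  tails
}

#' Construct a protein tail record
#'
#' @param id short label, e.g. \code{"ADAM8"}.
#' @param sequence one-letter amino-acid string (no stop marker).
#' @param source free-text provenance note.
#' @export
protein_tail <- function(id, sequence, source = "") {
  if (!nzchar(sequence)) stop("tail '", id, "': sequence is empty")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_STANDARD)
  if (length(bad)) {
    stop("tail '", id, "': non-standard residue '", chars[bad[1]],
         "' at position ", bad[1])
  }
  structure(list(id = id, sequence = sequence, source = source),
            class = "protein_tail")
}

#' @export
print.protein_tail <- function(x, ...) {
  cat("<protein_tail>", x$id, paste0("(", nchar(x$sequence), " aa)"), "\n")
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' The printed ADAM cytosolic tails shipped with the package
#'
#' Returns the six ADAM cytosolic-tail bait sequences (ADAM8, 9, 10, 12, 15,
#' 17) bundled as a plain-text FASTA fixture. The ADAM19 tail sequence is not
#' available and is deliberately absent; downstream reports mark it
#' \code{"sequence unavailable"}.
#'
#' @return named list of \code{protein_tail} objects.
#' @export
adam_tails <- function() {
  parse_tails(system.file("extdata", "adam_tails.fasta", package = "adamsh3",
                          mustWork = TRUE),
              source = "packaged ADAM tail fixture")
}
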