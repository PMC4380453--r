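# Shared constants and small helpers.

#' The 20 standard amino-acid one-letter codes
#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default hydrophobic residue set for the motif symbol "h" (Phi)
#'
#' A deliberately inclusive superset of common hydrophobicity definitions;
#' sensitivity is preferred over precision when flagging candidate SH3 sites.
#' @export
DEFAULT_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y", "P")

roman_numeral <- function(i) as.character(utils::as.roman(i))

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Full-precision numeric formatting so TSV round-trips are bit-exact.
fmt_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.17g", v)
    # prefer the shortest representation that still round-trips
    for (d in 1:16) {
      c_ <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(c_) == v) return(c_)
    }
    s
  }, character(1))
}

#' Write a data.frame as TSV with optional provenance header lines
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param header character vector written as \code{#}-prefixed comment lines
#'   before the table (configuration hash, seed, coordinate conventions).
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsv}} (comment lines skipped)
#'
#' @param path TSV path.
#' @param ... passed to \code{utils::read.delim}.
#' @return data.frame.
#' @export
read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
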