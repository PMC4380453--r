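# SH3 target-motif grammar: compilation, scanning, cluster merging, tiling.

#' Compile a motif specification string into a position-set pattern
#'
#' The grammar mirrors the established SH3 target-motif notation: a literal
#' residue letter matches itself; \code{"+"} matches K or R; \code{"h"} (or
#' the Greek Phi, its typographic original) matches the configured
#' hydrophobic set; \code{"x"} matches any of the 20 standard residues.
#' The canonical class I consensus is \code{"+hPxxP"}, class II is
#' \code{"PxhPx+"}, and \code{"PxxDY"} is the atypical Eps8-family motif.
#'
#' @param spec motif specification string, length >= 4 symbols.
#' @param name label for the pattern; defaults to the spec string.
#' @param class_tag one of \code{"classI"}, \code{"classII"},
#'   \code{"atypical"}, \code{"custom"}.
#' @param hydrophobic residue set substituted for \code{"h"}.
#' @return a \code{motif_pattern}: name, spec, class tag, and the ordered
#'   list of allowed-residue sets.
#' @export
compile_pattern <- function(spec, name = spec, class_tag = "custom",
                            hydrophobic = DEFAULT_HYDROPHOBIC) {
  class_tag <- match.arg(class_tag, c("classI", "classII", "atypical", "custom"))
  stopifnot(all(hydrophobic %in% AA_STANDARD))
  symbols <- strsplit(spec, "")[[1]]
  if (length(symbols) < 4L) {
    stop("pattern '", name, "': specification must have at least 4 positions")
  }
  positions <- lapply(seq_along(symbols), function(i) {
    sym <- symbols[i]
    if (sym == "x") AA_STANDARD
    else if (sym == "+") c("K", "R")
    else if (sym == "h" || sym == "\u03a6") hydrophobic
    else if (sym %in% AA_STANDARD) sym
    else stop("pattern '", name, "': unknown symbol '", sym,
              "' at position ", i)
  })
  structure(list(name = name, spec = spec, class_tag = class_tag,
                 positions = positions),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", x$name, paste0("[", x$class_tag, "]"),
      "spec:", x$spec, paste0("(", length(x$positions), " positions)"), "\n")
  invisible(x)
}

#' Load a named set of motif patterns from a YAML file
#'
#' Each YAML entry maps a pattern name to a list with fields \code{spec}
#' (the grammar string) and optional \code{class}. With no argument, the
#' shipped default pattern file is loaded: class I \code{"+hPxxP"}, class II
#' \code{"PxhPx+"}, atypical \code{"PxxDY"}, and the named high-affinity
#' specials \code{RxAPxxP}, \code{RxLPxxP}, \code{RxIPxxP}.
#'
#' @param path YAML pattern file; default is the packaged grammar.
#' @param hydrophobic residue set substituted for \code{"h"}.
#' @return named list of \code{motif_pattern} objects.
#' @export
load_patterns <- function(path = NULL, hydrophobic = DEFAULT_HYDROPHOBIC) {
  if (is.null(path)) {
    path <- system.file("extdata", "sh3_patterns.yaml", package = "adamsh3",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  pats <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    compile_pattern(entry$spec, name = nm,
                    class_tag = if (is.null(entry$class)) "custom" else entry$class,
                    hydrophobic = hydrophobic)
  })
  names(pats) <- names(raw)
  pats
}

pattern_regex <- function(pattern) {
  paste0(vapply(pattern$positions, function(set) {
    if (length(set) == length(AA_STANDARD)) "."
    else if (length(set) == 1L) set
    else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a tail sequence for motif hits
#'
#' Every window of the sequence is tested against every pattern; all matches
#' are reported, including mutually overlapping ones (overlap between motifs
#' within one proline cluster is the norm, not an artifact). Duplicates on
#' identical (start, pattern) pairs are dropped.
#'
#' @param tail a \code{protein_tail}.
#' @param patterns list of compiled \code{motif_pattern}s.
#' @return data.frame with columns \code{tail_id}, \code{pattern},
#'   \code{start}, \code{end} (1-based, inclusive, relative to the tail's
#'   first residue) and \code{matched}, sorted by (start, pattern).
#' @export
scan_motifs <- function(tail, patterns) {
  stopifnot(inherits(tail, "protein_tail"))
  if (length(patterns) == 0L) return(empty_hits())
  hits <- lapply(patterns, function(p) {
    stopifnot(inherits(p, "motif_pattern"))
    L <- length(p$positions)
    # lookahead regex yields overlapping match starts
    m <- gregexpr(paste0("(?=", pattern_regex(p), ")"), tail$sequence,
                  perl = TRUE)[[1]]
    starts <- as.integer(m)
    starts <- starts[starts > 0 & starts + L - 1L <= nchar(tail$sequence)]
    if (length(starts) == 0L) return(empty_hits())
    data.frame(tail_id = tail$id, pattern = p$name, start = starts,
               end = starts + L - 1L,
               matched = substring(tail$sequence, starts, starts + L - 1L),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[!duplicated(hits[, c("start", "pattern")]), , drop = FALSE]
  hits <- hits[order(hits$start, hits$pattern), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(tail_id = character(), pattern = character(),
             start = integer(), end = integer(), matched = character(),
             stringsAsFactors = FALSE)
}

#' Merge motif hits into proline clusters
#'
#' Hits whose spans lie within \code{gap_merge} residues of each other are
#' merged into a single cluster; clusters are indexed with Roman numerals
#' from the membrane-proximal (N-terminal) end of the tail, matching the
#' field's convention for numbering candidate SH3-binding proline clusters.
#'
#' @param hits data.frame from \code{\link{scan_motifs}}, all on one tail.
#' @param tail the \code{protein_tail} the hits belong to.
#' @param gap_merge maximum residue gap between hit spans merged into one
#'   cluster (default 8).
#' @return data.frame with columns \code{tail_id}, \code{index} (Roman
#'   numeral), \code{start}, \code{end}, \code{hit_count}; clusters are
#'   non-overlapping and ordered N- to C-terminus.
#' @export
find_clusters <- function(hits, tail, gap_merge = 8) {
  stopifnot(inherits(tail, "protein_tail"))
  empty <- data.frame(tail_id = character(), index = character(),
                      start = integer(), end = integer(),
                      hit_count = integer(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  if (any(hits$tail_id != tail$id)) {
    stop("hits reference tail '", setdiff(hits$tail_id, tail$id)[1],
         "' but clustering was requested on '", tail$id, "'")
  }
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  cl_start <- hits$start[1]
  cl_end <- hits$end[1]
  cl_n <- 1L
  out <- list()
  if (nrow(hits) > 1L) for (i in 2:nrow(hits)) {
    gap <- hits$start[i] - cl_end - 1L
    if (gap <= gap_merge) {
      cl_end <- max(cl_end, hits$end[i])
      cl_n <- cl_n + 1L
    } else {
      out[[length(out) + 1L]] <- c(cl_start, cl_end, cl_n)
      cl_start <- hits$start[i]
      cl_end <- hits$end[i]
      cl_n <- 1L
    }
  }
  out[[length(out) + 1L]] <- c(cl_start, cl_end, cl_n)
  m <- do.call(rbind, out)
  data.frame(tail_id = tail$id,
             index = roman_numeral(seq_len(nrow(m))),
             start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             hit_count = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

short_tail_label <- function(tail_id) sub("^ADAM", "A", tail_id)

#' Tile a proline cluster into array peptides
#'
#' Emits synthesizable peptides of 14-17 residues covering a cluster, with
#' a flanking context of \code{flank} residues on each side (clipped at the
#' tail termini). A cluster short enough to fit one window yields a single
#' centered peptide; longer clusters are tiled left-to-right with an overlap
#' of at least \code{min_overlap} residues so that no motif (up to
#' \code{min_overlap} long) is split without appearing whole in some tile.
#' Multiple tiles from one cluster get suffix letters a, b, c, mirroring
#' array peptide names such as \code{"A12-IIIb"}.
#'
#' @param cluster one row of a \code{\link{find_clusters}} result.
#' @param tail the \code{protein_tail} the cluster lies on.
#' @param min_len,max_len peptide length bounds (default 14 and 17).
#' @param flank context residues added each side before clipping (default 4).
#' @param min_overlap minimum overlap between adjacent tiles (default 7).
#' @param hits optional hit table; when given, peptides that do not contain
#'   at least one full motif hit are flagged \code{context_only}.
#' @return data.frame with columns \code{name}, \code{tail_id}, \code{start},
#'   \code{end}, \code{sequence}, \code{short} (tail shorter than
#'   \code{min_len}), \code{context_only}.
#' @export
tile_peptides <- function(cluster, tail, min_len = 14, max_len = 17,
                          flank = 4, min_overlap = 7, hits = NULL) {
  stopifnot(inherits(tail, "protein_tail"))
  len <- nchar(tail$sequence)
  if (cluster$start < 1 || cluster$end > len || cluster$start > cluster$end) {
    stop("cluster [", cluster$start, ",", cluster$end,
         "] is not a valid span on tail '", tail$id, "' (", len, " aa)")
  }
  base_name <- paste0(short_tail_label(tail$id), "-", cluster$index)
  short_flag <- len < min_len

  if (short_flag) {
    windows <- matrix(c(1L, len), ncol = 2)
  } else {
    rs <- max(1L, cluster$start - flank)
    re <- min(len, cluster$end + flank)
    region_len <- re - rs + 1L
    if (region_len <= max_len) {
      # single peptide centered on the cluster; grow to min_len if clipping
      # at a terminus left it short
      while (re - rs + 1L < min_len) {
        if (re < len) re <- re + 1L else rs <- rs - 1L
      }
      windows <- matrix(c(rs, re), ncol = 2)
    } else {
      step <- max_len - min_overlap
      starts <- seq.int(rs, re - max_len + 1L, by = step)
      if (starts[length(starts)] + max_len - 1L < re) {
        starts <- c(starts, re - max_len + 1L)
      }
      windows <- cbind(as.integer(starts), as.integer(starts) + max_len - 1L)
    }
  }

  n <- nrow(windows)
  suffix <- if (n > 1L) letters[seq_len(n)] else ""
  pep <- data.frame(
    name = paste0(base_name, suffix),
    tail_id = tail$id,
    start = as.integer(windows[, 1]),
    end = as.integer(windows[, 2]),
    sequence = substring(tail$sequence, windows[, 1], windows[, 2]),
    short = short_flag,
    stringsAsFactors = FALSE
  )
  pep$context_only <- if (is.null(hits) || nrow(hits) == 0L) NA else
    vapply(seq_len(n), function(i) {
      !any(hits$start >= pep$start[i] & hits$end <= pep$end[i])
    }, logical(1))
  pep
}

#' Scan, cluster and tile a set of tails in one pass
#'
#' Convenience wrapper running \code{\link{scan_motifs}},
#' \code{\link{find_clusters}} and \code{\link{tile_peptides}} over a list
#' of tails with one pattern set and configuration.
#'
#' @inheritParams find_clusters
#' @inheritParams tile_peptides
#' @param tails named list of \code{protein_tail}s.
#' @param patterns list of compiled patterns (default: shipped grammar).
#' @return list with data.frames \code{hits}, \code{clusters},
#'   \code{peptides}.
#' @export
scan_tail_set <- function(tails, patterns = load_patterns(), gap_merge = 8,
                          min_len = 14, max_len = 17, flank = 4,
                          min_overlap = 7) {
  hits <- do.call(rbind, lapply(tails, scan_motifs, patterns = patterns))
  if (is.null(hits)) hits <- empty_hits()
  clusters <- do.call(rbind, lapply(tails, function(tl) {
    find_clusters(hits[hits$tail_id == tl$id, , drop = FALSE], tl,
                  gap_merge = gap_merge)
  }))
  peptides <- do.call(rbind, lapply(tails, function(tl) {
    cl <- clusters[clusters$tail_id == tl$id, , drop = FALSE]
    if (nrow(cl) == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
      tile_peptides(cl[i, ], tl, min_len = min_len, max_len = max_len,
                    flank = flank, min_overlap = min_overlap,
                    hits = hits[hits$tail_id == tl$id, , drop = FALSE])
    }))
  }))
  rownames(hits) <- rownames(clusters) <- NULL
  if (!is.null(peptides)) rownames(peptides) <- NULL
  list(hits = hits, clusters = clusters,
       peptides = if (is.null(peptides)) NULL else peptides)
}
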