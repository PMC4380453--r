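# CelluSpot peptide-array quantification: background model, triplicate
# averaging, per-probe normalization, clustering, TreeView export.

#' Construct one probed array slide
#'
#' One slide corresponds to one SH3-domain probing: every peptide is spotted
#' in triplicate, and a set of empty spots (33 in the study design) carries
#' the slide-specific background.
#'
#' @param slide_id slide label.
#' @param probe_id SH3 domain used as probe.
#' @param spots data.frame with columns \code{peptide}, \code{replicate}
#'   (1-3) and \code{signal} (raw, >= 0).
#' @param empty_signals numeric vector of raw signals from empty spots.
#' @param probe_concentration probe concentration in micrograms/ml
#'   (metadata only; concentrations are chosen empirically per probe and no
#'   correction is applied).
#' @param control flag for GST-only control probings, which can be excluded
#'   from clustering.
#' @return an \code{array_slide}.
#' @export
array_slide <- function(slide_id, probe_id, spots, empty_signals,
                        probe_concentration = NA_real_, control = FALSE) {
  stopifnot(all(c("peptide", "replicate", "signal") %in% names(spots)))
  if (any(spots$signal < 0)) stop("slide '", slide_id, "': negative raw signal")
  reps <- table(spots$peptide)
  bad <- names(reps)[reps != 3L]
  if (length(bad)) {
    stop("slide '", slide_id, "': peptide '", bad[1],
         "' has ", reps[bad[1]], " replicate spots (3 required)")
  }
  if (any(empty_signals < 0)) stop("slide '", slide_id, "': negative empty-spot signal")
  # keep the slide's peptide panel in spotting order (not alphabetical)
  panel <- unique(spots$peptide)
  structure(list(slide_id = slide_id, probe_id = probe_id,
                 probe_concentration = probe_concentration,
                 spots = spots[order(match(spots$peptide, panel),
                                     spots$replicate), , drop = FALSE],
                 empty_signals = as.numeric(empty_signals),
                 control = isTRUE(control)),
            class = "array_slide")
}

#' @export
print.array_slide <- function(x, ...) {
  cat("<array_slide>", x$slide_id, "probe", x$probe_id,
      paste0("(", length(unique(x$spots$peptide)), " peptides x3, ",
             length(x$empty_signals), " empties)"), "\n")
  invisible(x)
}

#' Load array slides from spot and empty-spot TSV tables
#'
#' @param spot_path TSV with columns \code{slide_id}, \code{probe_id},
#'   \code{probe_conc}, \code{peptide}, \code{replicate}, \code{signal} and
#'   optional \code{control}.
#' @param empty_path TSV with columns \code{slide_id}, \code{signal}.
#' @return list of \code{array_slide} objects.
#' @export
load_array_slides <- function(spot_path, empty_path) {
  spots <- read_tsv(spot_path)
  empties <- read_tsv(empty_path)
  lapply(split(spots, spots$slide_id), function(g) {
    array_slide(g$slide_id[1], g$probe_id[1],
                g[, c("peptide", "replicate", "signal")],
                empties$signal[empties$slide_id == g$slide_id[1]],
                probe_concentration = if ("probe_conc" %in% names(g)) g$probe_conc[1] else NA_real_,
                control = if ("control" %in% names(g)) isTRUE(as.logical(g$control[1])) else FALSE)
  })
}

#' Estimate the slide-specific background level
#'
#' Background is the mean empty-spot signal plus \code{n_sd} (default 2)
#' sample standard deviations of the empty spots, so that only signals
#' clearly above the empty-spot distribution survive subtraction.
#'
#' @param slide an \code{array_slide} with at least 2 empty spots.
#' @param n_sd number of standard deviations added to the mean.
#' @return background scalar.
#' @export
estimate_background <- function(slide, n_sd = 2) {
  e <- slide$empty_signals
  if (length(e) < 2L) {
    stop("slide '", slide$slide_id,
         "': need >= 2 empty spots to estimate background (SD undefined)")
  }
  mean(e) + n_sd * stats::sd(e)
}

#' A signal matrix with a processing-stage tag
#'
#' @param values numeric matrix, peptides in rows, SH3 probes in columns.
#' @param stage one of \code{"raw_mean"}, \code{"bg_subtracted"},
#'   \code{"normalized"}.
#' @param flagged ids of all-background (all-zero) columns.
#' @return a \code{signal_matrix}.
#' @export
signal_matrix <- function(values, stage = c("raw_mean", "bg_subtracted", "normalized"),
                          flagged = character()) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(list(values = values, stage = stage, flagged = flagged),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix>", nrow(x$values), "peptides x", ncol(x$values),
      "probes, stage:", x$stage,
      if (length(x$flagged)) paste0("(", length(x$flagged), " all-background columns)") else "",
      "\n")
  invisible(x)
}

#' Average triplicates and subtract the slide background
#'
#' Per peptide, the triplicate spot signals are averaged and the slide
#' background subtracted; negative results are clipped to 0 (background
#' level) and the clip count is reported via a message and the
#' \code{"n_clipped"} attribute.
#'
#' @param slide an \code{array_slide} with complete triplicates.
#' @param background scalar from \code{\link{estimate_background}}.
#' @return one-column \code{signal_matrix} at stage \code{bg_subtracted}.
#' @export
average_and_subtract <- function(slide, background = estimate_background(slide)) {
  panel <- unique(slide$spots$peptide)
  m <- tapply(slide$spots$signal, factor(slide$spots$peptide, levels = panel),
              function(v) {
    if (length(v) != 3L || anyNA(v)) stop("incomplete triplicate")
    mean(v)
  })
  vals <- as.numeric(m) - background
  n_clipped <- sum(vals < 0)
  if (n_clipped > 0) {
    message("slide ", slide$slide_id, ": clipped ", n_clipped,
            " sub-background value(s) to 0")
  }
  vals <- pmax(vals, 0)
  out <- matrix(vals, ncol = 1,
                dimnames = list(names(m), slide$probe_id))
  structure(signal_matrix(out, "bg_subtracted"), n_clipped = n_clipped)
}

#' Quantify a slide set into a combined background-subtracted matrix
#'
#' @param slides list of \code{array_slide}s sharing one peptide panel.
#' @return \code{signal_matrix} (peptides x probes) at stage
#'   \code{bg_subtracted}; column order follows the slide list.
#' @export
quantify_slides <- function(slides) {
  cols <- lapply(slides, function(s) average_and_subtract(s))
  peps <- rownames(cols[[1]]$values)
  vals <- do.call(cbind, lapply(cols, function(c_) {
    if (!identical(rownames(c_$values), peps)) {
      stop("slides carry different peptide panels")
    }
    c_$values
  }))
  signal_matrix(vals, "bg_subtracted")
}

#' Normalize each probe column to a maximum of 2
#'
#' Each SH3-domain probing is scaled so that the peptide giving the
#' strongest signal in that column sits at exactly \code{target} (default
#' 2); background-level binding stays at 0. Columns with no above-background
#' signal are left all-zero and flagged. Normalizing an already-normalized
#' matrix is a no-op.
#'
#' @param m \code{signal_matrix} at stage \code{bg_subtracted} (or
#'   \code{normalized}, for idempotence).
#' @param target column maximum after scaling.
#' @return \code{signal_matrix} at stage \code{normalized}; all values lie
#'   in [0, target].
#' @export
normalize_columns <- function(m, target = 2.0) {
  stopifnot(inherits(m, "signal_matrix"))
  if (!m$stage %in% c("bg_subtracted", "normalized")) {
    stop("normalize_columns expects a background-subtracted matrix, got stage '",
         m$stage, "'")
  }
  v <- m$values
  if (any(v < 0)) stop("negative values in input; background clipping must happen upstream")
  maxes <- apply(v, 2, max)
  flagged <- colnames(v)[maxes == 0]
  pos <- maxes > 0
  v[, pos] <- sweep(v[, pos, drop = FALSE], 2, maxes[pos] / target, "/")
  signal_matrix(v, "normalized", flagged = flagged)
}

# Centered-Pearson distance matrix over rows of x; zero-variance rows get
# the maximum distance 2 to every other row and are reported.
pearson_distance <- function(x) {
  sds <- apply(x, 1, stats::sd)
  flat <- rownames(x)[sds == 0]
  cm <- suppressWarnings(stats::cor(t(x)))
  d <- 1 - cm
  d[is.na(d)] <- 2
  diag(d) <- 0
  list(d = d, flat = flat)
}

#' Hierarchically cluster a normalized signal matrix
#'
#' Agglomerative clustering with distance one minus the centered Pearson
#' correlation and average linkage -- the common configuration of the
#' Cluster 3 tool whose output feeds Java TreeView. Constant (zero-variance)
#' rows are assigned the maximum distance 2 to everything and flagged.
#' Tie-breaking is deterministic in input order.
#'
#' @param m \code{signal_matrix} at stage \code{normalized}.
#' @param axis \code{"rows"} (peptides) or \code{"cols"} (probes).
#' @param exclude leaf ids (e.g. GST-only control probes) dropped before
#'   clustering.
#' @return list with \code{tree} (an \code{hclust}), \code{order} (leaf ids
#'   in dendrogram order) and \code{flagged} (zero-variance leaf ids).
#' @export
cluster_matrix <- function(m, axis = c("rows", "cols"), exclude = character()) {
  stopifnot(inherits(m, "signal_matrix"))
  if (m$stage != "normalized") {
    stop("cluster_matrix expects a normalized matrix, got stage '", m$stage, "'")
  }
  axis <- match.arg(axis)
  x <- if (axis == "rows") m$values else t(m$values)
  if (length(exclude)) x <- x[!rownames(x) %in% exclude, , drop = FALSE]
  if (nrow(x) < 2L) stop("need >= 2 leaves on axis '", axis, "' to cluster")
  pd <- pearson_distance(x)
  tree <- stats::hclust(stats::as.dist(pd$d), method = "average")
  list(tree = tree, order = rownames(x)[tree$order], flagged = pd$flat)
}

tree_node_lines <- function(tree, leaf_prefix) {
  n <- nrow(tree$merge)
  lines <- character(n)
  for (i in seq_len(n)) {
    ch <- vapply(tree$merge[i, ], function(j) {
      if (j < 0) paste0(leaf_prefix, -j, "X") else paste0("NODE", j, "X")
    }, character(1))
    lines[i] <- paste(paste0("NODE", i, "X"), ch[1], ch[2],
                      fmt_full(1 - tree$height[i]), sep = "\t")
  }
  lines
}

#' Export a normalized matrix as TSV or TreeView-compatible CDT/GTR/ATR
#'
#' The TSV export round-trips bit-exactly through \code{\link{read_signal_tsv}}.
#' The CDT export writes the clustered data table with rows and columns in
#' dendrogram leaf order plus GTR/ATR tree files (node similarity = 1 -
#' merge height) loadable by Java TreeView; the grayscale convention is
#' 0 = white (background-level binding) to 2 = black (strongest binding per
#' probe).
#'
#' @param m \code{signal_matrix} at stage \code{normalized}.
#' @param path output path without extension.
#' @param format \code{"tsv"} or \code{"cdt"}.
#' @param trees optional list with entries \code{rows} and/or \code{cols}
#'   from \code{\link{cluster_matrix}}; required for GTR/ATR emission.
#' @param header provenance lines prepended as \code{#} comments to TSV
#'   output (never to CDT, which TreeView parses line-positionally).
#' @return character vector of files written.
#' @export
export_heatmap <- function(m, path, format = c("tsv", "cdt"), trees = NULL,
                           header = character()) {
  stopifnot(inherits(m, "signal_matrix"))
  format <- match.arg(format)
  v <- m$values
  if (format == "tsv") {
    file <- paste0(path, ".tsv")
    df <- data.frame(peptide = rownames(v), stringsAsFactors = FALSE)
    for (j in seq_len(ncol(v))) df[[colnames(v)[j]]] <- fmt_full(v[, j])
    write_tsv(df, file, header = header)
    return(file)
  }
  row_order <- if (!is.null(trees$rows)) trees$rows$order else rownames(v)
  col_order <- if (!is.null(trees$cols)) trees$cols$order else colnames(v)
  v <- v[row_order, col_order, drop = FALSE]
  files <- character()
  # GENE/ARRY ids refer to the leaf indices used inside the GTR/ATR trees
  # (input order of the clustered matrix), not to the display order
  gid_idx <- if (!is.null(trees$rows)) match(rownames(v), trees$rows$tree$labels)
             else seq_len(nrow(v))
  aid_idx <- if (!is.null(trees$cols)) match(colnames(v), trees$cols$tree$labels)
             else seq_len(ncol(v))
  gid <- paste0("GENE", gid_idx, "X")
  aid <- paste0("ARRY", aid_idx, "X")
  cdt <- paste0(path, ".cdt")
  con <- file(cdt, "wt")
  writeLines(paste(c("GID", "NAME", "GWEIGHT", colnames(v)), collapse = "\t"), con)
  if (!is.null(trees$cols)) {
    writeLines(paste(c("AID", "", "", aid), collapse = "\t"), con)
  }
  writeLines(paste(c("EWEIGHT", "", "", rep("1", ncol(v))), collapse = "\t"), con)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(c(gid[i], rownames(v)[i], "1", fmt_full(v[i, ])),
                     collapse = "\t"), con)
  }
  close(con)
  files <- c(files, cdt)
  if (!is.null(trees$rows)) {
    gtr <- paste0(path, ".gtr")
    # GENE ids in the GTR refer to input order of the clustered leaves
    tr <- trees$rows$tree
    writeLines(tree_node_lines(tr, "GENE"), gtr)
    files <- c(files, gtr)
  }
  if (!is.null(trees$cols)) {
    atr <- paste0(path, ".atr")
    writeLines(tree_node_lines(trees$cols$tree, "ARRY"), atr)
    files <- c(files, atr)
  }
  files
}

#' Re-read a TSV signal matrix written by \code{\link{export_heatmap}}
#'
#' @param path the \code{.tsv} file.
#' @param stage stage tag to attach.
#' @return a \code{signal_matrix}.
#' @export
read_signal_tsv <- function(path, stage = "normalized") {
  df <- read_tsv(path)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  storage.mode(v) <- "double"
  maxes <- apply(v, 2, max)
  signal_matrix(v, stage, flagged = colnames(v)[maxes == 0])
}

#' Parse a CDT file back into matrix structure
#'
#' Used to verify that exports are structurally loadable: returns the data
#' matrix plus the GID/AID scaffolding TreeView needs.
#'
#' @param path the \code{.cdt} file.
#' @return list with \code{values}, \code{gids}, \code{aids} (NULL without
#'   an AID line).
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "GID") stop("not a CDT file: ", path)
  probes <- header[-(1:3)]
  i <- 2
  aids <- NULL
  if (fields[[i]][1] == "AID") {
    aids <- fields[[i]][-(1:3)]
    i <- i + 1
  }
  if (fields[[i]][1] != "EWEIGHT") stop("malformed CDT: missing EWEIGHT line")
  rows <- fields[(i + 1):length(fields)]
  v <- t(vapply(rows, function(f) as.numeric(f[-(1:3)]), numeric(length(probes))))
  rownames(v) <- vapply(rows, `[[`, character(1), 2)
  colnames(v) <- probes
  list(values = v, gids = vapply(rows, `[[`, character(1), 1), aids = aids)
}
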