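# Phage-display selection analysis: libraries, screens, dominance, tiers,
# reduction-library design.

#' Construct an SH3 phage display library
#'
#' @param ids SH3 domain identifiers, or a named numeric vector of relative
#'   abundances.
#' @param library_id library label.
#' @param excluded SH3 ids whose phages were removed from the library; their
#'   abundance is forced to exactly 0.
#' @return an \code{sh3_library} with abundances normalized to sum 1 over
#'   the included domains.
#' @export
sh3_library <- function(ids, library_id = "lib", excluded = character()) {
  if (is.numeric(ids)) {
    if (is.null(names(ids))) stop("abundance vector must be named by SH3 id")
    abundance <- ids
  } else {
    abundance <- stats::setNames(rep(1, length(ids)), ids)
  }
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (anyDuplicated(names(abundance))) stop("duplicated SH3 ids in library")
  abundance[names(abundance) %in% excluded] <- 0
  total <- sum(abundance)
  if (total <= 0) stop("library '", library_id, "' has no included SH3 domains")
  structure(list(library_id = library_id,
                 abundance = abundance / total,
                 excluded = sort(unique(excluded))),
            class = "sh3_library")
}

#' @export
print.sh3_library <- function(x, ...) {
  cat("<sh3_library>", x$library_id, "-", sum(x$abundance > 0),
      "included SH3 domains,", length(x$excluded), "excluded\n")
  invisible(x)
}

#' The default complete SH3 phage library
#'
#' A uniform-abundance library over the SH3 domains named in the screening
#' and array work, always lacking the Crk(II) and CrkL(II) SH3 phages: those
#' atypical domains are prone to affinity-independent selection and cause
#' false positives, so every library in this design excludes them.
#'
#' @return an \code{sh3_library}.
#' @export
default_sh3_library <- function() {
  path <- system.file("extdata", "sh3_library.tsv", package = "adamsh3",
                      mustWork = TRUE)
  df <- read_tsv(path)
  sh3_library(stats::setNames(df$abundance, df$sh3_id),
              library_id = "complete",
              excluded = df$sh3_id[df$excluded])
}

#' Parse a reported enrichment factor
#'
#' Enrichment factors are reported as plain numbers or as lower bounds with
#' a leading \code{">"} (e.g. \code{">10,000"}); the bound flag is preserved,
#' never silently dropped. Thousands separators are tolerated.
#'
#' @param x character scalar (or numeric, passed through).
#' @return list with \code{value} (numeric) and \code{lower_bound} (logical).
#' @export
parse_enrichment <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) {
    return(list(value = NA_real_, lower_bound = FALSE))
  }
  if (is.numeric(x)) return(list(value = as.numeric(x), lower_bound = FALSE))
  s <- trimws(as.character(x))
  lb <- startsWith(s, ">")
  v <- suppressWarnings(as.numeric(gsub(",", "", sub("^>", "", s))))
  if (is.na(v)) stop("cannot parse enrichment factor: '", x, "'")
  if (v <= 0) stop("enrichment factor must be positive: '", x, "'")
  list(value = v, lower_bound = lb)
}

#' Construct the result of one panning screen
#'
#' @param screen_id unique screen label.
#' @param adam_id bait identifier.
#' @param library_id id of the library panned.
#' @param counts named integer vector of sequenced clone counts per SH3.
#' @param enrichment optional retained-phage enrichment factor (number or
#'   \code{">N"} string).
#' @param full_library whether the screen used a complete (non-reduction)
#'   library; dominance-tier calls are restricted to full-library screens.
#' @return a \code{screen_result}; \code{total_clones} is the count sum.
#' @export
screen_result <- function(screen_id, adam_id, library_id, counts,
                          enrichment = NULL, full_library = TRUE) {
  if (is.null(names(counts)) || !all(nzchar(names(counts)))) {
    stop("screen '", screen_id, "': counts must be named by SH3 id")
  }
  if (any(counts < 0)) {
    bad <- names(counts)[which(counts < 0)[1]]
    stop("screen '", screen_id, "': negative clone count for ", bad)
  }
  structure(list(screen_id = screen_id, adam_id = adam_id,
                 library_id = library_id,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 total_clones = as.integer(sum(counts)),
                 enrichment = parse_enrichment(enrichment),
                 full_library = isTRUE(full_library)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", x$screen_id, paste0("(", x$adam_id, " vs ",
      x$library_id, "):"), x$total_clones, "clones,",
      sum(x$counts > 0), "distinct SH3s\n")
  invisible(x)
}

#' Load phage screen clone counts from a TSV file
#'
#' Expected columns: \code{screen_id}, \code{adam_id}, \code{library_id},
#' \code{sh3_id}, \code{clones}; optional \code{enrichment} and
#' \code{full_library}. Rows are grouped per screen and totals computed.
#' A clone of an SH3 marked excluded in the referenced library is a
#' contamination signal and raises an error.
#'
#' @param path TSV file path.
#' @param libraries optional named list of \code{sh3_library} objects keyed
#'   by \code{library_id}, used to police exclusion lists.
#' @return list of \code{screen_result} objects.
#' @export
load_screen_counts <- function(path, libraries = NULL) {
  df <- read_tsv(path)
  need <- c("screen_id", "adam_id", "library_id", "sh3_id", "clones")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  screens <- lapply(split(df, df$screen_id), function(g) {
    lib_id <- unique(g$library_id)
    adam <- unique(g$adam_id)
    if (length(lib_id) != 1L || length(adam) != 1L) {
      stop("screen '", g$screen_id[1],
           "' mixes multiple adam_id or library_id values")
    }
    counts <- stats::setNames(g$clones, g$sh3_id)
    if (!is.null(libraries) && lib_id %in% names(libraries)) {
      lib <- libraries[[lib_id]]
      contam <- intersect(names(counts)[counts > 0], lib$excluded)
      if (length(contam)) {
        stop("screen '", g$screen_id[1], "': clones of excluded SH3 ",
             contam[1], " in library '", lib_id, "' (contamination signal)")
      }
    }
    enr <- if ("enrichment" %in% names(g)) g$enrichment[1] else NULL
    full <- if ("full_library" %in% names(g)) isTRUE(as.logical(g$full_library[1])) else TRUE
    screen_result(g$screen_id[1], adam, lib_id, counts,
                  enrichment = enr, full_library = full)
  })
  screens[order(names(screens))]
}

#' Fraction of clones contributed by the top-k SH3 domains
#'
#' The published screens summarize selectivity by the share of sequenced
#' clones taken by the most frequently selected domains (e.g. the top two
#' SH3s accounted for 94\% of clones in the strongest screens).
#'
#' @param screen a \code{screen_result} with \code{total_clones > 0}.
#' @param k number of top domains (>= 1).
#' @return fraction in [0, 1]; attribute \code{"top_ids"} carries the top-k
#'   SH3 ids (ties broken lexicographically for reporting; the fraction is
#'   unaffected by tie order).
#' @export
dominance_fraction <- function(screen, k) {
  stopifnot(inherits(screen, "screen_result"), k >= 1)
  if (screen$total_clones == 0L) {
    stop("screen '", screen$screen_id, "' has no sequenced clones")
  }
  ord <- order(-screen$counts, names(screen$counts))
  top <- ord[seq_len(min(k, length(ord)))]
  structure(sum(screen$counts[top]) / screen$total_clones,
            top_ids = names(screen$counts)[top])
}

#' Tier thresholds for selection classification
#'
#' The published tier labels (dominant / strongly selected / significantly
#' enriched) are qualitative; these numeric defaults operationalize them and
#' are echoed in every report. Dominant: clone fraction >= 0.40 in at least
#' one full-library screen. Strongly selected: fraction >= 0.10 in >= 2
#' independent screens (any library). Significantly enriched: >= 2 clones in
#' each of >= 2 independent screens.
#'
#' @param dominant_fraction,strong_fraction clone-fraction thresholds.
#' @param strong_screens,enriched_screens minimum independent screens.
#' @param enriched_clones minimum clones per screen for the enriched tier.
#' @return named list of thresholds.
#' @export
tier_thresholds <- function(dominant_fraction = 0.40,
                            strong_fraction = 0.10, strong_screens = 2,
                            enriched_clones = 2, enriched_screens = 2) {
  list(dominant_fraction = dominant_fraction,
       strong_fraction = strong_fraction,
       strong_screens = as.integer(strong_screens),
       enriched_clones = as.integer(enriched_clones),
       enriched_screens = as.integer(enriched_screens))
}

TIER_LEVELS <- c("dominant", "strongly_selected", "significantly_enriched", "none")

#' Classify SH3 partners of one ADAM into selection tiers
#'
#' Pools all screens performed with one ADAM bait and assigns each observed
#' SH3 domain the highest tier whose evidence threshold it satisfies
#' (see \code{\link{tier_thresholds}}).
#'
#' @param screens list of \code{screen_result}s, all for the same ADAM.
#' @param thresholds a \code{\link{tier_thresholds}} configuration.
#' @return a \code{selection_profile}: \code{adam_id}, \code{tier} (named
#'   character vector over observed SH3s), \code{evidence} data.frame
#'   (max fraction overall and in full-library screens, screens observed,
#'   screens passing the strong/enriched thresholds), and the thresholds
#'   used.
#' @export
classify_selection <- function(screens, thresholds = tier_thresholds()) {
  stopifnot(length(screens) >= 1L)
  adams <- unique(vapply(screens, `[[`, character(1), "adam_id"))
  if (length(adams) != 1L) {
    stop("screens span multiple ADAM baits: ", paste(adams, collapse = ", "))
  }
  per_screen <- lapply(screens, function(s) {
    obs <- s$counts[s$counts > 0]
    data.frame(sh3_id = names(obs), count = as.integer(obs),
               fraction = as.numeric(obs) / s$total_clones,
               full_library = s$full_library, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, per_screen)
  if (is.null(long) || nrow(long) == 0L) {
    stop("no SH3 clones observed in any screen for ", adams)
  }
  ids <- sort(unique(long$sh3_id))
  ev <- do.call(rbind, lapply(ids, function(id) {
    g <- long[long$sh3_id == id, , drop = FALSE]
    data.frame(
      sh3_id = id,
      max_fraction = max(g$fraction),
      max_fraction_full = if (any(g$full_library)) max(g$fraction[g$full_library]) else 0,
      screens_observed = nrow(g),
      screens_strong = sum(g$fraction >= thresholds$strong_fraction),
      screens_enriched = sum(g$count >= thresholds$enriched_clones),
      total_clones = sum(g$count),
      stringsAsFactors = FALSE)
  }))
  tier <- vapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    if (e$max_fraction_full >= thresholds$dominant_fraction) "dominant"
    else if (e$screens_strong >= thresholds$strong_screens) "strongly_selected"
    else if (e$screens_enriched >= thresholds$enriched_screens) "significantly_enriched"
    else "none"
  }, character(1))
  structure(list(adam_id = adams,
                 tier = stats::setNames(tier, ev$sh3_id),
                 evidence = ev, thresholds = thresholds),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat("<selection_profile>", x$adam_id, "\n")
  for (lv in setdiff(TIER_LEVELS, "none")) {
    ids <- names(x$tier)[x$tier == lv]
    if (length(ids)) cat(" ", lv, ":", paste(ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Design a reduction library by excluding dominant binders
#'
#' Mirrors the sequential screening strategy: SH3 phages that dominated the
#' clones selected in prior experiments are removed from the library so that
#' lower-affinity partners become visible in the next panning round.
#'
#' @param base the \code{sh3_library} screened so far.
#' @param profile a \code{selection_profile} computed from screens on the
#'   base (or an ancestor) library.
#' @param include_strong also exclude strongly-selected SH3s.
#' @param library_id id for the new library; default appends \code{"-red"}.
#' @return a new \code{sh3_library} with the tiered domains excluded and the
#'   remaining abundances renormalized.
#' @export
design_reduction_library <- function(base, profile, include_strong = FALSE,
                                     library_id = paste0(base$library_id, "-red")) {
  stopifnot(inherits(base, "sh3_library"), inherits(profile, "selection_profile"))
  tiers <- "dominant"
  if (include_strong) tiers <- c(tiers, "strongly_selected")
  drop <- names(profile$tier)[profile$tier %in% tiers]
  excluded <- union(base$excluded, drop)
  if (all(names(base$abundance) %in% excluded)) {
    stop("excluding ", paste(drop, collapse = ", "),
         " would empty library '", base$library_id, "'")
  }
  sh3_library(base$abundance, library_id = library_id, excluded = excluded)
}

#' Diversity of a negative-control screen
#'
#' Background retention without a specific bait should look unbiased: many
#' distinct SH3 identities spread over few clones (the control benchmark is
#' 79 different SH3s among 119 phages).
#'
#' @param screen a \code{screen_result} with \code{total_clones > 0}.
#' @return named integer vector \code{c(distinct_sh3, total_clones)}.
#' @export
negative_control_diversity <- function(screen) {
  stopifnot(inherits(screen, "screen_result"))
  if (screen$total_clones == 0L) {
    stop("screen '", screen$screen_id, "' has no sequenced clones")
  }
  c(distinct_sh3 = sum(screen$counts > 0),
    total_clones = screen$total_clones)
}
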