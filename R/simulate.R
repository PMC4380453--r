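# Seeded synthetic-data generators: affinity-weighted biopanning with clone
# sequencing, peptide-array slides with known ground truth, and motif-planted
# tail sequences. Every generator is a pure function of (parameters, seed).

#' Relative capture affinities of SH3 domains for one bait
#'
#' @param adam_id bait identifier.
#' @param weights named non-negative numeric vector; 1.0 means
#'   background-level (nonspecific) capture. SH3 domains absent from the
#'   vector default to weight 1. Weights are relative, not probabilities.
#' @return an \code{affinity_profile}.
#' @export
affinity_profile <- function(adam_id, weights = numeric()) {
  if (length(weights)) {
    stopifnot(!is.null(names(weights)), all(weights >= 0))
  }
  if (!any(c(weights, 1) > 0)) stop("at least one weight must be positive")
  structure(list(adam_id = adam_id, weights = weights),
            class = "affinity_profile")
}

#' Panning configuration
#'
#' @param rounds capture/amplification rounds per screen (>= 1; default 2,
#'   the standard biopanning depth, which reproduces the high top-2
#'   dominance regime seen in strong screens).
#' @param clones_sequenced clones picked for sequencing after the last
#'   round (default 150, the mid-range of the study's 47-384 clones per
#'   bait).
#' @param seed RNG seed.
#' @param background_capture positive weight floor modelling low-level
#'   nonspecific phage retention (default 0.01).
#' @return a \code{panning_config}.
#' @export
panning_config <- function(rounds = 2, clones_sequenced = 150, seed = 1,
                           background_capture = 0.01) {
  stopifnot(rounds >= 1, clones_sequenced >= 1, background_capture > 0)
  structure(list(rounds = as.integer(rounds),
                 clones_sequenced = as.integer(clones_sequenced),
                 seed = as.integer(seed),
                 background_capture = background_capture),
            class = "panning_config")
}

#' Simulate one biopanning screen
#'
#' Capture is modelled as single-hit binding proportional to
#' abundance x affinity with a background floor: after each round the
#' post-capture frequency of SH3 i is
#' \code{a_i * max(w_i, floor) / sum_j a_j * max(w_j, floor)}, and the next
#' round starts from those frequencies. Sequencing draws a multinomial
#' sample of \code{clones_sequenced} clones from the final frequencies.
#' Excluded SH3s have abundance 0 and therefore count exactly 0.
#'
#' @param library an \code{sh3_library} (normalized).
#' @param profile an \code{affinity_profile} for the bait.
#' @param config a \code{panning_config}.
#' @param screen_id screen label.
#' @param full_library whether this is a complete-library screen.
#' @return a \code{screen_result}; attributes \code{"frequencies"} (the
#'   pre-sampling post-capture frequencies) and the simulated enrichment
#'   factor \code{sum(a w) / sum(a * floor)} stored in the result.
#' @export
simulate_panning <- function(library, profile, config,
                             screen_id = paste0(profile$adam_id, "-", library$library_id),
                             full_library = TRUE) {
  stopifnot(inherits(library, "sh3_library"),
            inherits(profile, "affinity_profile"),
            inherits(config, "panning_config"))
  a <- library$abundance
  ids <- names(a)
  w <- rep(1, length(ids))
  names(w) <- ids
  known <- intersect(ids, names(profile$weights))
  w[known] <- profile$weights[known]
  eff <- pmax(w, config$background_capture)
  if (sum(a * eff) <= 0) stop("all effective capture weights are zero")
  enrichment <- sum(a * w) / sum(a * config$background_capture)
  f <- a
  for (r in seq_len(config$rounds)) {
    f <- f * eff
    f <- f / sum(f)
  }
  counts <- with_seed(config$seed, {
    as.integer(stats::rmultinom(1, config$clones_sequenced, f))
  })
  names(counts) <- ids
  res <- screen_result(screen_id, profile$adam_id, library$library_id,
                       counts, enrichment = enrichment,
                       full_library = full_library)
  attr(res, "frequencies") <- f
  res
}

#' Closed-form post-capture frequencies
#'
#' The expectation the sampler draws from:
#' \code{a_i * e_i^rounds / sum_j a_j * e_j^rounds} with
#' \code{e = max(w, floor)}.
#'
#' @inheritParams simulate_panning
#' @return named frequency vector over the library's SH3 ids.
#' @export
expected_capture_frequencies <- function(library, profile, config) {
  a <- library$abundance
  w <- rep(1, length(a))
  names(w) <- names(a)
  known <- intersect(names(a), names(profile$weights))
  w[known] <- profile$weights[known]
  eff <- pmax(w, config$background_capture)
  f <- a * eff^config$rounds
  f / sum(f)
}

#' Simulate a sequential screening series with reduction libraries
#'
#' Emulates the sequential strategy: screen the current library
#' \code{screens_per_stage} times, classify all screens so far, exclude the
#' newly tiered binders (dominant tier by default, optionally also strongly
#' selected) into a reduction library, and repeat until no SH3 is newly
#' excludable or exclusion would empty the library.
#'
#' @inheritParams simulate_panning
#' @param reduction_policy \code{"dominant"} or \code{"dominant_strong"}.
#' @param screens_per_stage independent screens per library stage
#'   (default 2; every bait was screened at least twice per library).
#' @param thresholds \code{\link{tier_thresholds}} used for classification.
#' @return list with \code{screens} (all \code{screen_result}s in order),
#'   \code{profile} (final \code{selection_profile}), \code{libraries}
#'   (per-stage \code{sh3_library}s).
#' @export
simulate_screen_series <- function(library, profile, config,
                                   reduction_policy = c("dominant", "dominant_strong"),
                                   screens_per_stage = 2,
                                   thresholds = tier_thresholds()) {
  reduction_policy <- match.arg(reduction_policy)
  tiers <- if (reduction_policy == "dominant") "dominant"
           else c("dominant", "strongly_selected")
  screens <- list()
  libraries <- list(library)
  lib <- library
  max_stages <- length(lib$abundance) + 1L
  for (stage in seq_len(max_stages)) {
    for (j in seq_len(screens_per_stage)) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * stage + j
      screens[[length(screens) + 1L]] <-
        simulate_panning(lib, profile, cfg,
                         screen_id = sprintf("%s-s%02d-%d", profile$adam_id, stage, j),
                         full_library = stage == 1L)
    }
    prof <- classify_selection(screens, thresholds)
    newly <- setdiff(names(prof$tier)[prof$tier %in% tiers], lib$excluded)
    if (length(newly) == 0L) break
    if (all(names(lib$abundance) %in% union(lib$excluded, newly))) break
    lib <- design_reduction_library(lib, prof,
                                    include_strong = reduction_policy == "dominant_strong",
                                    library_id = sprintf("%s-red%d", library$library_id, stage))
    libraries[[length(libraries) + 1L]] <- lib
  }
  list(screens = screens, profile = prof, libraries = libraries)
}

#' Simulate a probed peptide-array slide set with known ground truth
#'
#' One slide per probe column of \code{truth}. Raw spot signal is
#' \code{background + truth * lognormal multiplicative noise} with the
#' requested coefficient of variation (noise factor has mean 1); each
#' peptide gets 3 replicate spots. Empty spots (\code{n_empty}, default 33)
#' are drawn from a Normal(\code{background_mean}, \code{background_sd})
#' truncated at 0, as is the per-spot background.
#'
#' @param truth non-negative peptide x probe matrix with dimnames; column
#'   units are arbitrary fluorescence.
#' @param noise_cv multiplicative spot noise CV (default 0.2).
#' @param background_mean,background_sd empty-spot signal model (defaults
#'   100 and 10 arbitrary units).
#' @param n_empty empty spots per slide (default 33, the study layout).
#' @param seed RNG seed.
#' @return named list of \code{array_slide}s, one per probe.
#' @export
simulate_array <- function(truth, noise_cv = 0.2, background_mean = 100,
                           background_sd = 10, n_empty = 33, seed = 1) {
  stopifnot(is.matrix(truth), all(truth >= 0), noise_cv >= 0,
            !is.null(rownames(truth)), !is.null(colnames(truth)))
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    slides <- lapply(seq_len(ncol(truth)), function(j) {
      npep <- nrow(truth)
      bg <- pmax(stats::rnorm(3 * npep, background_mean, background_sd), 0)
      noise <- if (noise_cv > 0) {
        stats::rlnorm(3 * npep, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, 3 * npep)
      sig <- bg + rep(truth[, j], each = 3) * noise
      spots <- data.frame(peptide = rep(rownames(truth), each = 3),
                          replicate = rep(1:3, npep),
                          signal = sig, stringsAsFactors = FALSE)
      empties <- pmax(stats::rnorm(n_empty, background_mean, background_sd), 0)
      array_slide(paste0("slide-", colnames(truth)[j]), colnames(truth)[j],
                  spots, empties)
    })
    names(slides) <- colnames(truth)
    slides
  })
}

#' Generate a random tail with planted motif instances
#'
#' Background residues are drawn uniformly from the 20 standard amino
#' acids; the planted motif instances are then written over the recorded
#' positions. Chance background hits are possible and intended -- the
#' brute-force oracle counts them.
#'
#' @param length tail length.
#' @param planted data.frame with columns \code{sequence} (literal motif
#'   instance) and \code{start} (1-based position), or NULL to plant
#'   nothing.
#' @param seed RNG seed.
#' @param id tail id.
#' @return a \code{protein_tail}; attribute \code{"planted"} records the
#'   planted spans.
#' @export
plant_motif_tail <- function(length, planted = NULL, seed = 1,
                             id = sprintf("synthetic-%d", seed)) {
  stopifnot(length >= 1)
  if (!is.null(planted) && nrow(planted)) {
    ends <- planted$start + nchar(planted$sequence) - 1L
    if (any(planted$start < 1) || any(ends > length)) {
      stop("planted motif does not fit within tail of length ", length)
    }
    spans <- lapply(seq_len(nrow(planted)),
                    function(i) planted$start[i]:ends[i])
    if (anyDuplicated(unlist(spans))) {
      stop("planted motifs overlap each other (position collision)")
    }
  }
  seq <- with_seed(seed, {
    paste(sample(AA_STANDARD, length, replace = TRUE), collapse = "")
  })
  if (!is.null(planted) && nrow(planted)) {
    chars <- strsplit(seq, "")[[1]]
    for (i in seq_len(nrow(planted))) {
      ins <- strsplit(planted$sequence[i], "")[[1]]
      chars[planted$start[i] + seq_along(ins) - 1L] <- ins
    }
    seq <- paste(chars, collapse = "")
  }
  tl <- protein_tail(id, seq, source = "synthetic planted-motif tail")
  attr(tl, "planted") <- planted
  tl
}
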