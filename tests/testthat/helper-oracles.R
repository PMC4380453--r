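# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they verify: the motif oracle is a
# character-by-character window matcher (no regex), and the clustering
# oracle is a naive O(n^3) agglomeration (no hclust).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Brute-force scan: tests every window of the sequence against the
# pattern's position sets, one position at a time.
oracle_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(pattern$positions)
  n <- length(chars)
  if (n < L) return(integer())
  starts <- seq_len(n - L + 1L)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(L)) {
    ok <- ok & chars[starts + j - 1L] %in% pattern$positions[[j]]
  }
  starts[ok]
}

# Naive average-linkage agglomeration over a precomputed distance matrix:
# repeatedly merge the closest pair of clusters, with the inter-cluster
# distance the arithmetic mean of all member pairs. Returns merge heights.
naive_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        ia <- clusters[[active[a]]]
        ib <- clusters[[active[b]]]
        dd <- mean(d[ia, ib])
        if (dd < best_d) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    ia <- active[best[1]]
    ib <- active[best[2]]
    clusters[[length(clusters) + 1L]] <- c(clusters[[ia]], clusters[[ib]])
    active <- c(setdiff(active, c(ia, ib)), length(clusters))
    heights <- c(heights, best_d)
  }
  heights
}

# Small uniform test library of n synthetic SH3 ids.
toy_library <- function(n = 40, id = "toy") {
  sh3_library(sprintf("SH3_%02d", seq_len(n)), library_id = id)
}

# A minimal valid array slide built from a vector of per-peptide means.
toy_slide <- function(means, background = 0, probe = "probeA",
                      empties = c(0, 0)) {
  spots <- data.frame(peptide = rep(names(means), each = 3),
                      replicate = rep(1:3, length(means)),
                      signal = rep(means, each = 3) + background)
  array_slide(paste0("slide-", probe), probe, spots, empties)
}
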