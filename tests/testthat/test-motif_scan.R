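# Motif grammar compilation, tail parsing, scanning, clustering, tiling.

test_that("FASTA parsing stores stop-stripped, alphabet-checked tails", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1 demo", "ACDG*", ">t2", "PPKPLP"), fa)
  tails <- parse_tails(fa)
  expect_named(tails, c("t1", "t2"))
  expect_equal(tails$t1$sequence, "ACDG")
  expect_equal(tails$t2$sequence, "PPKPLP")

  writeLines(c(">bad", "ACBDG"), fa)
  expect_error(parse_tails(fa), "position 3")
  expect_error(protein_tail("x", ""), "empty")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(parse_tails(empty))
})

test_that("the printed ADAM10 tail is 52 residues long", {
  tails <- adam_tails()
  expect_equal(nchar(tails$ADAM10$sequence), 52L)
  expect_setequal(names(tails),
                  c("ADAM8", "ADAM9", "ADAM10", "ADAM12", "ADAM15", "ADAM17"))
})

test_that("pattern compilation expands grammar symbols left to right", {
  p <- compile_pattern("+hPxxP", name = "classI", class_tag = "classI")
  expect_length(p$positions, 6)
  expect_setequal(p$positions[[1]], c("K", "R"))
  expect_setequal(p$positions[[2]], DEFAULT_HYDROPHOBIC)
  expect_equal(p$positions[[3]], "P")
  expect_setequal(p$positions[[4]], AA20)   # wildcard = full alphabet
  expect_equal(p$positions[[6]], "P")

  p2 <- compile_pattern("RxAPxxP")
  expect_equal(vapply(p2$positions, function(s) if (length(s) == 1) s else ".",
                      character(1)),
               c("R", ".", "A", "P", ".", ".", "P"))
  p3 <- compile_pattern("PxxDY", class_tag = "atypical")
  expect_equal(vapply(p3$positions, function(s) if (length(s) == 1) s else ".",
                      character(1)),
               c("P", ".", ".", "D", "Y"))
  # the Greek Phi is accepted as an alias for "h"
  expect_equal(compile_pattern("P\u03a6xP")$positions,
               compile_pattern("PhxP")$positions)
  expect_error(compile_pattern("PxZ!"), "unknown symbol")
  expect_error(compile_pattern("PxP"), "at least 4")
})

test_that("scanning the printed tails reproduces the discussed motif content", {
  tails <- adam_tails()
  rxap <- compile_pattern("RxAPxxP")
  rxlp <- compile_pattern("RxLPxxP")
  # the ADAM8 tail lacks the high-affinity SNX9 motif entirely
  expect_equal(nrow(scan_motifs(tails$ADAM8, list(rxap))), 0L)
  # positions verified against the character-by-character oracle
  for (tl in tails) {
    for (p in list(rxap, rxlp)) {
      hits <- scan_motifs(tl, list(p))
      expect_equal(hits$start, oracle_scan(tl$sequence, p),
                   info = paste(tl$id, p$name))
    }
  }
  expect_gte(nrow(scan_motifs(tails$ADAM9, list(rxap))), 1L)
  expect_gte(nrow(scan_motifs(tails$ADAM15, list(rxap))), 1L)
  expect_gte(nrow(scan_motifs(tails$ADAM12, list(rxlp))), 1L)
  expect_gte(nrow(scan_motifs(tails$ADAM15, list(rxlp))), 1L)
  expect_equal(nrow(scan_motifs(tails$ADAM15, list())), 0L)
})

test_that("overlapping matches are all reported and sorted", {
  tl <- protein_tail("t", "KPPPPPPPR")
  p <- compile_pattern("PxxP")
  hits <- scan_motifs(tl, list(p))
  expect_equal(hits$start, oracle_scan(tl$sequence, p))
  expect_true(nrow(hits) > 1)        # overlapping windows present
  expect_equal(hits$matched, substring(tl$sequence, hits$start, hits$end))
  expect_true(!is.unsorted(hits$start))
})

test_that("shift equivariance: prepending k residues shifts retained hits by k", {
  pats <- load_patterns()
  set.seed(71)
  for (rep in 1:20) {
    s <- random_aa_seq(sample(40:120, 1))
    k <- sample(3:15, 1)
    prefix <- random_aa_seq(k)
    h0 <- scan_motifs(protein_tail("a", s), pats)
    h1 <- scan_motifs(protein_tail("a", paste0(prefix, s)), pats)
    h1 <- h1[h1$start > k, , drop = FALSE]
    # junction-spanning new matches are excluded by construction; every
    # original hit must reappear shifted by exactly k
    expect_true(all(paste(h0$start + k, h0$pattern) %in%
                    paste(h1$start, h1$pattern)))
  }
})

test_that("scan output is byte-identical across repeated runs", {
  tails <- adam_tails()
  pats <- load_patterns()
  r1 <- scan_tail_set(tails, pats)
  r2 <- scan_tail_set(tails, pats)
  expect_identical(r1, r2)
})

test_that("cluster merging follows the gap rule and Roman numbering", {
  tl <- protein_tail("t", paste(rep("A", 60), collapse = ""))
  mk <- function(s, e) data.frame(tail_id = "t", pattern = "p", start = s,
                                  end = e, matched = "x")
  one <- find_clusters(rbind(mk(5, 10), mk(12, 18)), tl, gap_merge = 8)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(5L, 18L))
  expect_equal(one$hit_count, 2L)

  two <- find_clusters(rbind(mk(5, 10), mk(40, 46)), tl, gap_merge = 8)
  expect_equal(two$index, c("I", "II"))
  expect_true(all(two$end[-nrow(two)] < two$start[-1]))   # non-overlapping

  foreign <- mk(5, 10)
  foreign$tail_id <- "other"
  expect_error(find_clusters(foreign, tl), "other")
})

test_that("ADAM15 cluster structure matches a brute-force scan-and-merge", {
  tl <- adam_tails()$ADAM15
  pats <- load_patterns()[c("classI", "classII")]
  hits <- scan_motifs(tl, pats)
  # oracle: pool per-pattern oracle hits, sort, merge spans with gap <= 8
  spans <- do.call(rbind, lapply(pats, function(p) {
    st <- oracle_scan(tl$sequence, p)
    if (!length(st)) return(NULL)
    cbind(st, st + length(p$positions) - 1L)
  }))
  spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
  merged <- list(spans[1, ])
  for (i in seq_len(nrow(spans))[-1]) {
    last <- merged[[length(merged)]]
    if (spans[i, 1] - last[2] - 1L <= 8) {
      merged[[length(merged)]] <- c(last[1], max(last[2], spans[i, 2]))
    } else merged[[length(merged) + 1L]] <- spans[i, ]
  }
  cl <- find_clusters(hits, tl, gap_merge = 8)
  expect_equal(nrow(cl), length(merged))
  expect_equal(cl$start, vapply(merged, `[[`, numeric(1), 1))
  expect_equal(cl$end, vapply(merged, `[[`, numeric(1), 2))
  # every hit lies inside exactly one cluster
  for (i in seq_len(nrow(hits))) {
    inside <- sum(hits$start[i] >= cl$start & hits$end[i] <= cl$end)
    expect_equal(inside, 1L)
  }
})

test_that("peptide tiling respects length bounds, overlap and coverage", {
  tl <- protein_tail("ADAM99", paste(rep("A", 60), collapse = ""))
  cl <- data.frame(tail_id = "ADAM99", index = "I", start = 10, end = 16,
                   hit_count = 1)
  pep <- tile_peptides(cl, tl)
  expect_equal(nrow(pep), 1L)
  expect_equal(c(pep$start, pep$end), c(6L, 20L))   # 15-mer centered
  expect_equal(pep$name, "A99-I")

  cl2 <- data.frame(tail_id = "ADAM99", index = "II", start = 15, end = 44,
                    hit_count = 3)
  pep2 <- tile_peptides(cl2, tl)
  expect_gte(nrow(pep2), 2L)
  expect_true(all(nchar(pep2$sequence) >= 14 & nchar(pep2$sequence) <= 17))
  expect_true(grepl("a$", pep2$name[1]) && grepl("b$", pep2$name[2]))
  # union of tiles covers the cluster, adjacent tiles overlap >= 7
  covered <- unique(unlist(Map(seq, pep2$start, pep2$end)))
  expect_true(all(cl2$start:cl2$end %in% covered))
  if (nrow(pep2) > 1) {
    ov <- pep2$end[-nrow(pep2)] - pep2$start[-1] + 1
    expect_true(all(ov >= 7))
  }
  # every peptide is a verbatim substring of the tail
  expect_true(all(pep2$sequence ==
                  substring(tl$sequence, pep2$start, pep2$end)))

  short_tail <- protein_tail("s", "PPKPLPAKP")
  ps <- tile_peptides(data.frame(tail_id = "s", index = "I", start = 3,
                                 end = 9, hit_count = 1), short_tail)
  expect_true(ps$short)
  expect_equal(ps$sequence, short_tail$sequence)

  expect_error(tile_peptides(data.frame(tail_id = "s", index = "I",
                                        start = 5, end = 99, hit_count = 1),
                             short_tail), "valid span")
})

test_that("all peptides tiled from the printed tails are 14-17 long with a whole hit", {
  res <- scan_tail_set(adam_tails())
  lens <- nchar(res$peptides$sequence)
  expect_true(all(lens >= 14 & lens <= 17))
  # containment: each peptide holds >= 1 full hit or is flagged context-only
  expect_true(all(res$peptides$context_only %in% c(TRUE, FALSE)))
  with_hit <- !res$peptides$context_only
  expect_true(any(with_hit))
  for (i in which(with_hit)) {
    p <- res$peptides[i, ]
    h <- res$hits[res$hits$tail_id == p$tail_id, ]
    expect_true(any(h$start >= p$start & h$end <= p$end))
  }
})
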