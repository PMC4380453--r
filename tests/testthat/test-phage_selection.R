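# Phage-screen quantification: loading, dominance, tier classification,
# reduction-library design, negative controls.

test_that("screen counts load, group and total correctly", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("screen_id\tadam_id\tlibrary_id\tsh3_id\tclones",
               "s1\tADAM8\tcomplete\tA\t10",
               "s1\tADAM8\tcomplete\tB\t5",
               "s1\tADAM8\tcomplete\tC\t5",
               "s2\tADAM8\tcomplete\tA\t7"), tsv)
  screens <- load_screen_counts(tsv)
  expect_length(screens, 2)
  expect_equal(screens$s1$total_clones, 20L)
  expect_equal(sort(names(screens$s1$counts)), c("A", "B", "C"))

  writeLines(c("screen_id\tadam_id\tlibrary_id\tsh3_id\tclones",
               "s1\tADAM8\tcomplete\tA\t-1"), tsv)
  expect_error(load_screen_counts(tsv), "negative")

  # a clone of an excluded SH3 is a contamination signal
  writeLines(c("screen_id\tadam_id\tlibrary_id\tsh3_id\tclones",
               "s1\tADAM8\tred\tA\t3"), tsv)
  lib <- sh3_library(c("A", "B", "C"), "red", excluded = "A")
  expect_error(load_screen_counts(tsv, libraries = list(red = lib)),
               "contamination")
})

test_that("the packaged screening-statistics fixture carries the published totals", {
  fx <- load_paper_fixture()
  expect_equal(fx$table1$total_clones, c(332L, 142L, 190L, 384L, 172L, 47L, 203L))
  expect_equal(fx$table1$selected_domains, c(8L, 7L, 0L, 8L, 14L, 0L, 14L))
  # ">10,000" parses as a flagged lower bound, never silently dropped
  i <- match("ADAM9", fx$table1$adam_id)
  expect_equal(fx$table1$enrichment_value[i], 10000)
  expect_true(fx$table1$enrichment_lower_bound[i])
  expect_false(any(fx$table1$enrichment_lower_bound[-i]))
})

test_that("dominance fraction reproduces the top-k clone share arithmetic", {
  s <- screen_result("s", "ADAM9", "complete", c(A = 47, B = 47, C = 6))
  expect_equal(as.numeric(dominance_fraction(s, 2)), 0.94)
  expect_equal(attr(dominance_fraction(s, 2), "top_ids"), c("A", "B"))
  expect_equal(as.numeric(dominance_fraction(screen_result("s", "a", "l", c(A = 10)), 2)), 1)
  u <- screen_result("s", "a", "l", stats::setNames(rep(5, 10), LETTERS[1:10]))
  expect_equal(as.numeric(dominance_fraction(u, 2)), 0.2)
  # non-decreasing in k, reaching 1 at the number of distinct SH3s
  fr <- vapply(1:5, function(k) as.numeric(dominance_fraction(s, k)), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[3], 1)
  expect_error(dominance_fraction(screen_result("e", "a", "l", c(A = 0)), 1),
               "no sequenced clones")
})

test_that("tier classification applies the threshold hierarchy", {
  th <- tier_thresholds()
  s1 <- screen_result("s1", "ADAM8", "complete", c(A = 90, B = 10))
  prof <- classify_selection(list(s1), th)
  expect_equal(unname(prof$tier["A"]), "dominant")   # 0.90 >= 0.40
  expect_equal(unname(prof$tier["B"]), "none")       # single screen only

  # one clone in one screen -> none
  s2 <- screen_result("s2", "ADAM8", "complete", c(A = 90, C = 1))
  prof2 <- classify_selection(list(s1, s2), th)
  expect_equal(unname(prof2$tier["C"]), "none")
  # >= 2 clones in each of >= 2 screens -> significantly enriched
  s3 <- screen_result("s3", "ADAM8", "red", c(C = 2, D = 30), full_library = FALSE)
  s4 <- screen_result("s4", "ADAM8", "red", c(C = 2, D = 40), full_library = FALSE)
  prof3 <- classify_selection(list(s1, s3, s4), th)
  expect_equal(unname(prof3$tier["C"]), "significantly_enriched")
  # fraction >= 0.10 in >= 2 screens (any library) -> strongly selected
  expect_equal(unname(prof3$tier["D"]), "strongly_selected")
  # 0.40+ fraction in a reduction screen alone never yields dominant
  expect_false("dominant" %in% prof3$tier[c("C", "D")])

  expect_error(classify_selection(list(
    s1, screen_result("x", "ADAM9", "complete", c(A = 1)))),
    "multiple ADAM baits")
})

test_that("classification is invariant to screen order and id relabeling", {
  set.seed(5)
  screens <- lapply(1:4, function(i) {
    screen_result(paste0("s", i), "A", "lib",
                  stats::setNames(rpois(6, c(60, 20, 5, 2, 1, 1)), LETTERS[1:6]),
                  full_library = i <= 2)
  })
  p1 <- classify_selection(screens)
  p2 <- classify_selection(rev(screens))
  expect_equal(p1$tier, p2$tier)
  # relabel ids: tiers follow the relabeling
  relab <- stats::setNames(paste0("z", LETTERS[1:6]), LETTERS[1:6])
  screens_r <- lapply(screens, function(s) {
    screen_result(s$screen_id, s$adam_id, s$library_id,
                  stats::setNames(s$counts, relab[names(s$counts)]),
                  full_library = s$full_library)
  })
  p3 <- classify_selection(screens_r)
  expect_equal(unname(p3$tier[relab[names(p1$tier)]]), unname(p1$tier))
})

test_that("tier never drops when clones are added (monotonicity)", {
  rank_of <- function(t) match(t, c("none", "significantly_enriched",
                                    "strongly_selected", "dominant"))
  set.seed(11)
  for (rep in 1:25) {
    counts <- stats::setNames(rpois(5, 10), LETTERS[1:5])
    s1 <- screen_result("s1", "A", "l", counts)
    s2 <- screen_result("s2", "A", "l", rev(counts), full_library = FALSE)
    base <- classify_selection(list(s1, s2))
    add <- sample(5, 1)
    counts2 <- counts
    counts2[add] <- counts2[add] + sample(1:80, 1)
    bumped <- classify_selection(list(
      screen_result("s1", "A", "l", counts2),
      screen_result("s2", "A", "l", rev(counts2), full_library = FALSE)))
    id <- names(counts)[add]
    expect_gte(rank_of(bumped$tier[id]), rank_of(base$tier[id]))
  }
})

test_that("reduction libraries exclude dominant binders and renormalize", {
  lib <- toy_library(40)
  s <- screen_result("s1", "A", "toy",
                     c(SH3_01 = 70, SH3_02 = 62, SH3_03 = 18))
  prof <- classify_selection(list(s))
  red <- design_reduction_library(lib, prof)
  expect_setequal(red$excluded, c("SH3_01", "SH3_02"))
  expect_equal(sum(red$abundance > 0), 38)
  expect_equal(sum(red$abundance), 1)
  expect_equal(unname(red$abundance[c("SH3_01", "SH3_02")]), c(0, 0))

  # no dominant binder: identical membership up to renormalization
  prof_none <- classify_selection(list(
    screen_result("s2", "A", "toy", c(SH3_05 = 30, SH3_06 = 40, SH3_07 = 40))))
  same <- design_reduction_library(lib, prof_none)
  expect_equal(same$abundance, lib$abundance)

  # exclusion can never empty the library
  small <- sh3_library(c("A", "B"), "small")
  prof_all <- classify_selection(list(
    screen_result("s3", "X", "small", c(A = 50, B = 50))))
  expect_error(design_reduction_library(small, prof_all), "empty")

  # iterated exclusion terminates within the number of SH3 domains
  cur <- toy_library(6)
  for (i in 1:6) {
    ids <- names(cur$abundance)[cur$abundance > 0]
    if (length(ids) <= 1) break
    pr <- classify_selection(list(screen_result(paste0("it", i), "A", cur$library_id,
                                                stats::setNames(100, ids[1]))))
    cur <- tryCatch(design_reduction_library(cur, pr), error = function(e) cur)
  }
  expect_lte(i, 6)
})

test_that("negative-control diversity counts distinct SH3 identities", {
  set.seed(3)
  # 79 distinct ids among 119 clones, the control benchmark shape
  extra <- table(sample(79, 40, replace = TRUE))
  counts <- rep(1L, 79)
  names(counts) <- paste0("sh3_", 1:79)
  counts[as.integer(names(extra))] <- counts[as.integer(names(extra))] + as.integer(extra)
  s <- screen_result("neg", "control", "complete", counts)
  expect_equal(unname(negative_control_diversity(s)), c(79L, 119L))
  one <- screen_result("one", "c", "l", c(A = 12))
  expect_equal(unname(negative_control_diversity(one)), c(1L, 12L))
  singletons <- screen_result("all", "c", "l",
                              stats::setNames(rep(1L, 7), letters[1:7]))
  expect_equal(unname(negative_control_diversity(singletons)), c(7L, 7L))
})

test_that("the default library lacks the false-positive-prone Crk SH3 phages", {
  lib <- default_sh3_library()
  expect_true(all(c("Crk(II)", "CrkL(II)") %in% lib$excluded))
  expect_equal(unname(lib$abundance[c("Crk(II)", "CrkL(II)")]), c(0, 0))
  expect_equal(sum(lib$abundance), 1)
})
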