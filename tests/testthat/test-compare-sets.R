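test_that("unique counts and percentages follow the printed convention", {
  g <- generate_library(library_spec(3, list(c("salt", "tautomer")), seed = 2))
  kt <- key_table(g$release1)
  u <- unique_stats(kt, "uuuuu", length(g$release1))
  expect_equal(u$unique_count, 3)  # K scaffolds
  # n identical records -> one key, 100/n percent
  ident <- key_table(lapply(1:4, function(i) example_mol("water", paste0("w", i))))
  expect_equal(unique_stats(ident, "ficts", 4),
               list(unique_count = 1, percentage = 25.0))
  expect_error(unique_stats(kt, "nope", 10), "absent")
})

test_that("overlap matrix and coverage reproduce per-pair intersections", {
  p <- plant_keyed_sets(c("A", "B", "C"),
                        c("A" = 30, "B" = 10, "C" = 5, "A&B" = 12,
                          "A&C" = 7, "B&C" = 3, "A&B&C" = 2))
  m <- overlap_matrix(p$sets)
  expect_equal(m["A", "A"], 30 + 12 + 7 + 2)
  expect_equal(m["A", "B"], 12 + 2)
  expect_equal(m["B", "C"], 3 + 2)
  expect_true(isSymmetric(m))
  # disjoint sets: off-diagonal zeros
  d <- plant_keyed_sets(c("X", "Y"), c("X" = 5, "Y" = 8))
  expect_equal(overlap_matrix(d$sets)["X", "Y"], 0)
  # mixed levels refuse
  bad <- p$sets
  bad[[2]]$level <- "uuuuu"
  expect_error(overlap_matrix(bad), "different levels")
})

test_that("venn cells equal a brute-force membership scan on random sets", {
  set.seed(404)
  for (rep in 1:5) {
    n_sets <- sample(2:4, 1)
    universe <- sprintf("K%04d", 1:400)
    sets <- lapply(seq_len(n_sets), function(i)
      keyed_set(LETTERS[i], sample(universe, 200), "ficts"))
    vp <- venn(sets)
    oracle <- venn_oracle(sets)
    for (m in names(oracle))
      expect_equal(vp$cells[[m]]$count, unname(oracle[m]), info = m)
    # conservation: cells partition the union
    expect_equal(sum(vapply(vp$cells, `[[`, 0L, "count")), vp$union_size)
    for (i in seq_len(n_sets)) {
      in_i <- vapply(names(vp$cells), function(m)
        substr(m, i, i) == "1", logical(1))
      expect_equal(sum(vapply(vp$cells[in_i], `[[`, 0L, "count")),
                   length(sets[[i]]$keys))
    }
    # overlap(i,j) equals the sum of venn cells containing both
    om <- overlap_matrix(sets)
    for (i in seq_len(n_sets)) for (j in seq_len(n_sets)) {
      if (i == j) next
      both <- vapply(names(vp$cells), function(m)
        substr(m, i, i) == "1" && substr(m, j, j) == "1", logical(1))
      expect_equal(om[i, j], sum(vapply(vp$cells[both], `[[`, 0L, "count")))
    }
  }
})

test_that("degenerate and planted venn configurations behave", {
  a <- keyed_set("A", sprintf("k%d", 1:20), "ficts")
  b <- keyed_set("B", sprintf("k%d", 1:20), "ficts")
  vp <- venn(list(a, b))
  expect_equal(venn_cell(vp, c("A", "B")), 20)
  expect_equal(venn_cell(vp, "A"), 0)
  # engineered 4-way center
  p <- plant_keyed_sets(c("A", "B", "C", "D"),
                        c("A" = 3, "B" = 4, "C" = 5, "D" = 6,
                          "A&B&C&D" = 7))
  expect_equal(venn_cell(venn(p$sets), c("A", "B", "C", "D")), 7)
  expect_error(venn(list(a)), "between 2 and 4")
})

test_that("release diff matches generator bookkeeping", {
  spec <- library_spec(7, list(c("salt", "tautomer"), character()),
                       curation = list(remove = 1L, add_stereo = 1L,
                                       redraw_tautomer = 1L, new_records = 2L),
                       seed = 21)
  g <- generate_library(spec)
  old <- key_table(g$release1); new <- key_table(g$release2)
  d <- release_diff(old, new)
  expect_equal(unlist(d$levels$ficts),
               unclass(g$truth$diff$sensitive))
  expect_equal(unlist(d$levels$uuuuu),
               unclass(g$truth$diff$skeleton))
  expect_equal(d$skeleton_links, g$truth$diff$skeleton_links)
  # identical releases: nothing removed or added at any level
  d0 <- release_diff(old, old)
  expect_equal(d0$levels$ficts$removed, 0)
  expect_equal(d0$levels$ficts$added, 0)
  expect_equal(d0$levels$uuuuu$removed, 0)
  expect_equal(d0$skeleton_links, 0)
  # conservation: maintained + removed = old uniques, + added = new uniques
  expect_equal(d$levels$ficts$maintained + d$levels$ficts$removed,
               length(unique(old$keys$ficts)))
  expect_equal(d$levels$ficts$maintained + d$levels$ficts$added,
               length(unique(new$keys$ficts)))
})

test_that("category profiles count keys, with partial maps allowed", {
  s <- keyed_set("S", sprintf("k%d", 1:10), "ficts")
  cats <- stats::setNames(lapply(1:10, function(i) "C"), sprintf("k%d", 1:10))
  expect_equal(unname(category_profile(s, cats)["C"]), 100)
  # missing keys are in no category
  half <- cats[1:5]
  expect_equal(unname(category_profile(s, half)["C"]), 50)
  expect_error(category_profile(keyed_set("E", character(), "ficts"), cats),
               "empty set")
  # random flags at rate p land within binomial noise of 100 p
  set.seed(5150)
  p <- 0.3; n <- 1000
  keys <- sprintf("k%05d", 1:n)
  flagged <- keys[stats::runif(n) < p]
  prof <- category_profile(keyed_set("R", keys, "ficts"),
                           stats::setNames(rep(list("hit"), length(flagged)),
                                           flagged))
  expect_lt(abs(prof[["hit"]] - 100 * p), 3 * 100 * sqrt(p * (1 - p) / n))
})
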