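test_that("the trivial library is fully degenerate", {
  g <- generate_library(library_spec(5, seed = 1))
  kt <- key_table(g$release1)
  for (lv in c("ficts", "ficus", "uuuuu"))
    expect_equal(length(unique(kt$keys[[lv]])), 5, info = lv)
  d <- release_diff(kt, key_table(g$release2))
  expect_equal(d$levels$ficts$removed, 0)
  expect_equal(d$levels$ficts$added, 0)
  expect_equal(d$levels$ficts$maintained, 5)
})

test_that("the worked variant plan enumerates as designed", {
  # 3 scaffolds x {salt, tautomer, stereo_invert}: 12 sensitive forms,
  # 9 tautomer-invariant, 3 skeletons
  g <- generate_library(library_spec(
    3, list(c("salt", "tautomer", "stereo_invert")), seed = 4))
  kt <- key_table(g$release1)
  expect_equal(length(unique(kt$keys$ficts)), 12)
  expect_equal(length(unique(kt$keys$ficus)), 9)
  expect_equal(length(unique(kt$keys$uuuuu)), 3)
  expect_equal(unname(g$truth$unique$r1), c(12L, 9L, 3L))
})

test_that("identical spec and seed give byte-identical output", {
  spec <- library_spec(4, list(c("salt", "isotope"), character()),
                       curation = list(remove = 1L, new_records = 1L),
                       seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_library(spec, out_dir = d1)
  generate_library(spec, out_dir = d2)
  for (f in c("release1.sdf", "release2.sdf", "ground_truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # a different seed permutes atoms differently but keys are unchanged
  spec2 <- library_spec(4, list(c("salt", "isotope"), character()),
                        curation = list(remove = 1L, new_records = 1L),
                        seed = 78)
  g1 <- generate_library(spec)
  g2 <- generate_library(spec2)
  k1 <- key_table(g1$release1)$keys
  k2 <- key_table(g2$release1)$keys
  expect_equal(k1[order(k1$source_id), ], k2[order(k2$source_id), ],
               ignore_attr = TRUE)
})

test_that("infeasible plans fail at generation time, never silently", {
  expect_error(library_spec(2, variant_plan = list("grow_wings")),
               "unknown variant")
  # curation demands more single-record scaffolds than exist
  expect_error(library_spec(2, list(c("salt"), c("isotope")),
                            curation = list(add_stereo = 1L)),
               "single-record scaffolds")
  expect_error(library_spec(0), "n_scaffolds")
})

test_that("master integration: every ground-truth field is recovered", {
  specs <- list(
    library_spec(4, list(c("exact_duplicate", "charge"), character()),
                 curation = list(remove = 1L, redraw_tautomer = 1L),
                 seed = 101),
    library_spec(5, list(c("salt", "tautomer", "stereo_invert",
                           "stereo_strip", "isotope"), character()),
                 curation = list(add_stereo = 1L, new_records = 2L),
                 seed = 102),
    library_spec(3, list(character()),
                 curation = list(remove = 1L, add_stereo = 1L,
                                 redraw_tautomer = 1L), seed = 103))
  for (spec in specs) {
    g <- generate_library(spec)
    k1 <- key_table(g$release1); k2 <- key_table(g$release2)
    expect_equal(nrow(k1$rejected), 0)
    expect_equal(length(g$release1), unname(g$truth$n_records["r1"]))
    expect_equal(length(g$release2), unname(g$truth$n_records["r2"]))
    for (rel in c("r1", "r2")) {
      kt <- if (rel == "r1") k1 else k2
      for (lv in c("ficts", "ficus", "uuuuu"))
        expect_equal(length(unique(kt$keys[[lv]])),
                     unname(g$truth$unique[[rel]][lv]),
                     info = paste(spec$seed, rel, lv))
    }
    d <- release_diff(k1, k2)
    expect_equal(unlist(d$levels$ficts), unclass(g$truth$diff$sensitive))
    expect_equal(unlist(d$levels$uuuuu), unclass(g$truth$diff$skeleton))
    expect_equal(d$skeleton_links, g$truth$diff$skeleton_links)
    # planted release-pair venn cells
    vs <- venn(list(keyed_set("old", k1$keys$ficts, "ficts"),
                    keyed_set("new", k2$keys$ficts, "ficts")))
    expect_equal(venn_cell(vs, c("old", "new")),
                 unname(g$truth$venn_sensitive["both"]))
    expect_equal(venn_cell(vs, "old"),
                 unname(g$truth$venn_sensitive["old_only"]))
    expect_equal(venn_cell(vs, "new"),
                 unname(g$truth$venn_sensitive["new_only"]))
    # stereo classes
    expect_equal(unclass(summarize_stereo(g$release1)$counts),
                 unclass(g$truth$stereo$r1))
    expect_equal(unclass(summarize_stereo(g$release2)$counts),
                 unclass(g$truth$stereo$r2))
  }
})

test_that("protein input plants are internally consistent", {
  gp <- generate_protein_inputs(c(A = 10, B = 8, "A&B" = 5),
                                reviewed_fraction = 1.0, seed = 6)
  expect_equal(sum(gp$annotations$reviewed == "TR"), 0)
  expect_equal(length(gp$ids$A), 15)
  expect_error(generate_protein_inputs(c(A = 5)))
})
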