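test_that("ID loading de-duplicates and rejects malformed accessions", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("P12345", "Q9XYZ1", "P12345", "not_an_id", "A0A0B4J2F0",
               "", "P12345"), f)
  ids <- load_ids(f)
  expect_setequal(ids$accessions, c("P12345", "Q9XYZ1", "A0A0B4J2F0"))
  expect_equal(ids$n_duplicates, 2)
  expect_equal(ids$malformed, "not_an_id")
  expect_error(load_ids(file.path(tempdir(), "gone.txt")), "not found")
})

test_that("planted duplicates in generated dumps are recovered", {
  out <- withr::local_tempdir()
  gp <- generate_protein_inputs(c(A = 40, B = 25, "A&B" = 15),
                                n_duplicates = 7, n_malformed = 3,
                                out_dir = out, seed = 12)
  ids <- load_ids(gp$files$A)
  expect_equal(length(ids$accessions), 40 + 15)
  expect_equal(ids$n_duplicates, 7)
  expect_length(ids$malformed, 3)
})

test_that("species split and SP:TR ratios are exact partitions", {
  gp <- generate_protein_inputs(c(A = 60, B = 30, "A&B" = 10),
                                target_fraction = 0.45,
                                reviewed_fraction = 0.8, seed = 3)
  entries <- protein_entries(gp$ids$A, gp$annotations)
  sp <- species_split(entries, "human")
  tr_a <- gp$truth$per_source$A
  expect_equal(sp$total, tr_a$total)
  expect_equal(sp$target_count, tr_a$target)
  expect_equal(sp$sp_count, tr_a$sp)
  expect_equal(sp$tr_count, tr_a$tr)
  expect_equal(sp$target_tr_only, tr_a$target_tr)
  expect_equal(sp$sp_count + sp$tr_count, sp$total)
  expect_equal(sum(unlist(sp$per_species)), sp$total)
  # deterministic species counts over the universe
  ann <- gp$annotations
  expect_equal(sum(ann$species == "human"), round(0.45 * nrow(ann)))
  # all-reviewed target set: TR count 0
  all_sp <- data.frame(accession = c("P11111", "P22222"),
                       species = "human", reviewed = "SP", go = "enzyme")
  s2 <- species_split(protein_entries(all_sp$accession, all_sp))
  expect_equal(s2$tr_count, 0)
})

test_that("missing annotations degrade loudly to unknown/unreviewed", {
  ann <- data.frame(accession = "P11111", species = "human",
                    reviewed = "SP", go = "enzyme")
  expect_warning(e <- protein_entries(c("P11111", "P99999"), ann), "missing")
  expect_equal(e$species[2], "unknown")
  expect_equal(e$reviewed[2], "TR")
})

test_that("consensus inherits the exact Venn partition", {
  gp <- generate_protein_inputs(c(A = 50, B = 40, C = 30, "A&B" = 12,
                                  "A&C" = 9, "B&C" = 6, "A&B&C" = 220),
                                seed = 8)
  vp <- consensus(gp$ids)
  expect_equal(venn_cell(vp, c("A", "B", "C")), 220)
  expect_equal(venn_cell(vp, "A"), 50)
  expect_equal(venn_cell(vp, c("A", "B")), 12)
  # two identical sets: consensus is either set
  vp2 <- consensus(list(X = gp$ids$A, Y = gp$ids$A))
  expect_equal(venn_cell(vp2, c("X", "Y")), length(gp$ids$A))
})

test_that("GO distributions handle forked assignments and sum to one", {
  ann <- data.frame(
    accession = sprintf("P%05d", 1:11),
    species = "human", reviewed = "SP",
    go = c(rep("enzyme", 10), "receptor;transporter"))
  e <- protein_entries(ann$accession, ann)
  gd <- go_distribution(e)
  expect_equal(gd$n_assignments, 12)
  expect_equal(sum(gd$distribution$fraction), 1, tolerance = 1e-12)
  expect_equal(gd$distribution$count[gd$distribution$category == "enzyme"], 10)
  # single-category degenerate case
  one <- protein_entries(ann$accession[1:3], ann)
  gd1 <- go_distribution(one)
  expect_equal(gd1$distribution$fraction, 1)
  # planted biases rank-order as planted
  gp <- generate_protein_inputs(c(A = 120, B = 100, "A&B" = 20),
                                go_categories = c("enzyme", "receptor"),
                                fork_fraction = 0.1, seed = 99)
  eA <- protein_entries(gp$ids$A, gp$annotations)
  gdA <- go_distribution(eA)
  truthA <- gp$truth$per_source$A$go_counts
  for (cc in names(truthA))
    expect_equal(gdA$distribution$count[gdA$distribution$category == cc],
                 truthA[[cc]], info = cc)
  # all-empty annotations warn and return an empty distribution
  none <- protein_entries("P12345",
                          data.frame(accession = "P12345", species = "human",
                                     reviewed = "SP", go = ""))
  expect_warning(g0 <- go_distribution(none), "no GO annotations")
  expect_equal(g0$n_unannotated, 1)
})
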