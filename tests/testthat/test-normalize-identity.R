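keys_of <- function(name) compute_keys(example_mol(name))$keys

test_that("normalization operators are idempotent", {
  for (nm in c("benzene", "acetate_na", "nitrobenzene_neutral", "tma",
               "alanine_wedge")) {
    rec <- example_mol(nm)
    n1 <- normalize_base(rec)
    expect_equal(canonical_serialization(normalize_base(n1)),
                 canonical_serialization(n1), info = nm)
    for (op in list(neutralize, clear_isotopes, strip_stereo)) {
      o1 <- op(n1)
      expect_equal(canonical_serialization(op(o1)),
                   canonical_serialization(o1), info = nm)
    }
    t1 <- canonical_tautomer(select_parent(n1))
    expect_equal(canonical_serialization(canonical_tautomer(t1)),
                 canonical_serialization(t1), info = nm)
  }
})

test_that("alternate nitro drawings normalize to one key", {
  k1 <- keys_of("nitrobenzene_neutral")
  k2 <- keys_of("nitrobenzene_charged")
  expect_equal(k1[["ficts"]], k2[["ficts"]])
  expect_equal(k1[["uuuuu"]], k2[["uuuuu"]])
})

test_that("parent selection keeps the largest fragment deterministically", {
  # single fragment: unchanged
  b <- normalize_base(example_mol("benzene"))
  expect_equal(canonical_serialization(select_parent(b)),
               canonical_serialization(b))
  # acetate + Na: the 4-heavy-atom acid fragment wins over the bare cation
  p <- select_parent(normalize_base(example_mol("acetate_na")))
  expect_equal(fragment_count(p), 1)
  expect_false("Na" %in% p$atoms$elem)
  # true tie (two identical fragments): deterministic single copy
  two <- example_mol("acetone")
  shift <- example_mol("acetone")
  shift$atoms$x <- shift$atoms$x + 10
  tie <- mol_record("tie", rbind(two$atoms, shift$atoms),
                    rbind(two$bonds,
                          transform(shift$bonds, a1 = a1 + 4, a2 = a2 + 4)))
  p1 <- select_parent(normalize_base(tie))
  p2 <- select_parent(normalize_base(permute_atoms(tie, rev(seq_len(8)))))
  expect_equal(canonical_serialization(p1), canonical_serialization(p2))
})

test_that("neutralization follows hydrogen arithmetic", {
  # deprotonated carboxylate regains its H
  ac <- neutralize(normalize_base(example_mol("acetate")))
  expect_true(all(ac$atoms$charge == 0))
  expect_equal(canonical_serialization(ac),
               canonical_serialization(normalize_base(example_mol("acetic_acid"))))
  # quaternary N has no H to shed: charge retained
  tma <- neutralize(normalize_base(example_mol("tma")))
  expect_true(any(tma$atoms$charge == 1))
  # neutral achiral molecule is a fixed point of all three strippers
  w <- normalize_base(example_mol("water"))
  for (op in list(neutralize, clear_isotopes, strip_stereo))
    expect_equal(canonical_serialization(op(w)), canonical_serialization(w))
})

test_that("tautomer pairs share the tautomer-invariant key only", {
  ka <- keys_of("acetone"); kp <- keys_of("propen2ol")
  expect_false(ka[["ficts"]] == kp[["ficts"]])
  expect_equal(ka[["ficus"]], kp[["ficus"]])
  expect_equal(ka[["uuuuu"]], kp[["uuuuu"]])
  kh <- keys_of("hydroxypyridine"); ko <- keys_of("pyridone")
  expect_false(kh[["ficts"]] == ko[["ficts"]])
  expect_equal(kh[["ficus"]], ko[["ficus"]])
  # no mobile hydrogen: benzene is its own representative
  b <- normalize_base(example_mol("benzene"))
  expect_equal(canonical_serialization(canonical_tautomer(b)),
               canonical_serialization(b))
})

test_that("enantiomer drawings differ sensitively, share the skeleton key", {
  ku <- keys_of("alanine_wedge"); kd <- keys_of("alanine_down")
  kf <- keys_of("alanine_flat")
  expect_false(ku[["ficts"]] == kd[["ficts"]])
  expect_false(ku[["ficts"]] == kf[["ficts"]])
  expect_equal(ku[["uuuuu"]], kd[["uuuuu"]])
  expect_equal(ku[["uuuuu"]], kf[["uuuuu"]])
  # stereo is kept at the tautomer-invariant level
  expect_false(ku[["ficus"]] == kd[["ficus"]])
})

test_that("keys are invariant under atom-order permutation", {
  set.seed(202)
  mols <- c("benzene", "acetone", "alanine_wedge", "nitrobenzene_neutral",
            "acetate_na", "trans2butene", "hydroxypyridine")
  for (nm in mols) {
    k0 <- keys_of(nm)
    for (i in 1:15) {
      ki <- compute_keys(permute_atoms(example_mol(nm)))$keys
      expect_equal(ki, k0, info = sprintf("%s shuffle %d", nm, i))
    }
  }
})

test_that("exact duplicates agree at every level; planted variants split as designed", {
  g <- generate_library(library_spec(
    1, list(c("exact_duplicate", "salt", "isotope", "tautomer",
              "stereo_invert")), seed = 5))
  kt <- key_table(g$release1)
  expect_equal(nrow(kt$rejected), 0)
  # base + duplicate collapse; salt/isotope/tautomer/stereo each split
  expect_equal(length(unique(kt$keys$ficts)), 5)
  expect_equal(length(unique(kt$keys$ficus)), 4)  # tautomer folds in
  expect_equal(length(unique(kt$keys$uuuuu)), 1)  # one scaffold
  base <- kt$keys[kt$keys$source_id == "S001R0", ]
  dup <- kt$keys[kt$keys$source_id == "S001R1", ]
  expect_equal(unlist(base[-1]), unlist(dup[-1]))
})

test_that("key-equality classes match a graph-isomorphism oracle", {
  skip_if_not_installed("igraph")
  set.seed(77)
  mols <- lapply(c("benzene", "acetone", "propen2ol", "acetic_acid",
                   "ethanol", "hydroxypyridine", "pyridone", "trans2butene",
                   "water", "tma"), example_mol)
  mols <- c(mols, lapply(mols, function(m)
    permute_atoms(m, sample(nrow(m$atoms)))))
  norm <- lapply(mols, normalize_base)
  ser <- vapply(norm, canonical_serialization, character(1),
                with_stereo = FALSE)
  for (i in seq_along(norm)) for (j in seq_along(norm)) {
    expect_equal(ser[i] == ser[j], iso_oracle(norm[[i]], norm[[j]]),
                 info = sprintf("pair %d/%d", i, j))
  }
})

test_that("rejected records yield no key bundle and are tallied", {
  # carbon with five explicit bonds: uncorrectable valence
  bad <- mol_record("bad5",
    data.frame(elem = rep("C", 6), charge = 0L, isotope = NA_integer_,
               hcount = NA_integer_, x = 0, y = 0),
    data.frame(a1 = 1L, a2 = 2:6, order = 1L, wedge = "none"))
  bad <- complete_hydrogens(bad)
  expect_null(compute_keys(bad))
  kt <- key_table(list(bad, example_mol("water")))
  expect_equal(nrow(kt$keys), 1)
  expect_equal(kt$rejected$source_id, "bad5")
})

test_that("external providers attach keys verbatim", {
  bdl <- compute_keys(example_mol("water"),
                      providers = list(stdkey = function(r) "EXTERNAL-KEY"))
  expect_equal(bdl$keys[["stdkey"]], "EXTERNAL-KEY")
})
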