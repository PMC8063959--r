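test_that("terminality follows the iterative removal verdict", {
  # trisaccharide chain of ratio-marginal sugars peels completely
  recs <- classify_terminality(parse_one("diginatin_like"))
  circ <- Filter(function(r) r$moiety_type == "circular", recs)
  expect_length(circ, 3L)
  expect_true(all(vapply(circ, function(r) r$terminal, logical(1))))

  # two bridging sugars never become removable
  recs <- classify_terminality(parse_one("cucurbitoside_like"))
  circ <- Filter(function(r) r$moiety_type == "circular", recs)
  expect_length(circ, 2L)
  expect_false(any(vapply(circ, function(r) r$terminal, logical(1))))

  recs <- classify_terminality(parse_one("phenyl_glucoside"))
  expect_length(recs, 1L)
  expect_true(recs[[1]]$terminal)
})

test_that("removal yields connected aglycones and sugar-only verdicts", {
  fr <- remove_sugars(parse_one("fructose"))
  expect_null(fr$aglycone)
  expect_true(fr$consists_only_of_sugars)
  expect_length(fr$removed, 1L)

  iso <- remove_sugars(parse_one("isomaltose_open"))
  expect_true(iso$consists_only_of_sugars)
  types <- sort(vapply(iso$removed, function(r) r$moiety_type, character(1)))
  expect_equal(types, c("circular", "linear"))

  tol <- remove_sugars(parse_one("toluene"))
  expect_false(tol$consists_only_of_sugars)
  expect_length(tol$removed, 0L)
  expect_equal(as_smiles(tol$aglycone), as_smiles(tol$input))

  ph <- remove_sugars(parse_one("phenyl_glucoside"))
  expect_equal(as_smiles(ph$aglycone), "c1ccccc1")
})

test_that("atom conservation holds across removal", {
  mols <- parse_fx(c("glucose", "phenyl_glucoside", "maltose", "diginatin_like",
                     "cucurbitoside_like", "lndfh_like", "isomaltose_open",
                     "lavaudioside_like", "toluene"))
  g <- generate_glycosides(generator_spec(n_molecules = 30, seed = 5,
                                          fraction_glycosylated = 0.7))
  for (m in c(unclass(mols), unclass(g$collection))) {
    r <- remove_sugars(m)
    n_out <- (if (is.null(r$aglycone)) 0L else length(r$aglycone$atoms)) +
      sum(vapply(r$removed, function(x) length(x$atoms), integer(1))) +
      sum(vapply(r$discarded_fragments, length, integer(1)))
    expect_equal(n_out, length(m$atoms), info = m$id)
    # default-mode aglycone stays connected
    if (!is.null(r$aglycone)) {
      expect_lte(glycoscan:::n_fragments(r$aglycone), 1L)
    }
  }
})

test_that("removal is idempotent on its own aglycone", {
  mols <- parse_fx(c("phenyl_glucoside", "diginatin_like", "lavaudioside_like"))
  for (m in mols) {
    r <- remove_sugars(m)
    if (is.null(r$aglycone)) next
    agl <- r$aglycone
    agl2 <- parse_smiles(as_smiles(agl), m$id)[[1]]
    r2 <- remove_sugars(agl2)
    expect_length(r2$removed, 0L)
  }
})

test_that("terminal flags and aglycone are invariant under atom permutation", {
  set.seed(99)
  for (name in c("diginatin_like", "cucurbitoside_like", "lavaudioside_like")) {
    m <- parse_one(name)
    ref <- remove_sugars(m)
    ref_agl <- if (is.null(ref$aglycone)) "" else glycoscan:::mol_to_smiles(ref$aglycone)
    for (i in 1:5) {
      pm <- permute_molecule(m, sample(length(m$atoms)))
      r <- remove_sugars(pm)
      expect_equal(length(r$removed), length(ref$removed))
      expect_equal(length(r$retained), length(ref$retained))
      agl <- if (is.null(r$aglycone)) "" else glycoscan:::mol_to_smiles(r$aglycone)
      expect_equal(agl, ref_agl)
    }
  }
})

test_that("synthetic sugar chains peel fully; bridges are retained", {
  for (k in 1:5) {
    spec <- generator_spec(n_molecules = 1, seed = 100 + k,
                           fraction_glycosylated = 1, bridging_fraction = 0,
                           circular_fraction = 1,
                           sugar_count_distribution = c(rep(0, k - 1), 1, rep(0, 14 - k)))
    g <- generate_glycosides(spec)
    r <- remove_sugars(g$collection[[1]])
    expect_length(r$removed, k)
    expect_length(r$retained, 0L)
  }
  spec <- generator_spec(n_molecules = 5, seed = 200, fraction_glycosylated = 1,
                         bridging_fraction = 1, circular_fraction = 1,
                         sugar_count_distribution = c(1, rep(0, 13)))
  g <- generate_glycosides(spec)
  for (m in g$collection) {
    r <- remove_sugars(m)
    expect_length(r$retained, 1L)
    expect_false(r$retained[[1]]$terminal)
  }
})

test_that("moiety extraction exports standalone hydrogen-saturated sugars", {
  ph <- remove_sugars(parse_one("phenyl_glucoside"))
  ext <- extract_moieties(ph)
  expect_length(ext, 1L)
  # pyranose ring plus its four exocyclic oxygens
  expect_equal(length(ext[[1]]$atoms), 10L)
  expect_equal(sum(ext[[1]]$atoms == "O"), 5L)
  smi <- as_smiles(ext[[1]])
  expect_false(is.na(smi))

  dig <- extract_moieties(remove_sugars(parse_one("diginatin_like")))
  expect_length(dig, 3L)

  expect_length(extract_moieties(remove_sugars(parse_one("toluene"))), 0L)
})

test_that("remove-all mode excises non-terminal sugars into a multi-fragment remainder", {
  m <- parse_one("cucurbitoside_like")
  r <- remove_sugars(m, removal_settings(remove_only_terminal = FALSE))
  expect_length(r$removed, 2L)
  expect_length(r$retained, 0L)
  expect_gt(glycoscan:::n_fragments(r$aglycone), 1L)
})
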