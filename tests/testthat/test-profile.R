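test_that("single-molecule profiles capture the canonical cases", {
  p <- profile_molecule(parse_one("lavaudioside_like"))
  expect_true(p$has_both)
  expect_true(p$has_circular && p$has_linear)
  expect_false(p$has_only_circular || p$has_only_linear)

  p <- profile_molecule(parse_one("lndfh_like"))
  expect_true(p$consists_only_of_sugars)
  expect_equal(p$n_circular, 5L)
  expect_equal(p$n_linear, 1L)
  expect_true(p$is_sugar_polymer)
  expect_false(p$is_sugar_monomer)

  p <- profile_molecule(parse_one("benzene"))
  expect_false(any(unlist(p[glycoscan:::profile_fields])))
  expect_equal(p$n_total, 0L)

  p <- profile_molecule(parse_one("fructose"))
  expect_true(p$is_circular_monomer)
})

test_that("profile invariants hold over generator output", {
  g <- generate_glycosides(generator_spec(n_molecules = 60, seed = 21,
                                          fraction_glycosylated = 0.5,
                                          bridging_fraction = 0.3,
                                          circular_fraction = 0.8))
  profs <- profile_collection(g$collection)
  expect_equal(profs$has_sugars, profs$has_circular | profs$has_linear)
  expect_equal(profs$has_both, profs$has_circular & profs$has_linear)
  expect_equal(profs$has_only_circular, profs$has_circular & !profs$has_linear)
  expect_equal(profs$has_only_linear, profs$has_linear & !profs$has_circular)
  expect_equal(profs$n_total, profs$n_circular + profs$n_linear)
  expect_true(all(profs$has_sugars[profs$consists_only_of_sugars]))
  expect_equal(profs$is_sugar_monomer,
               profs$consists_only_of_sugars & profs$n_total == 1L)
  expect_equal(profs$is_sugar_polymer,
               profs$consists_only_of_sugars & profs$n_total >= 2L)
})

test_that("aggregation satisfies every partition identity exactly", {
  g <- generate_glycosides(generator_spec(n_molecules = 80, seed = 31,
                                          fraction_glycosylated = 0.6,
                                          bridging_fraction = 0.25,
                                          circular_fraction = 0.85))
  profs <- profile_collection(g$collection)
  st <- aggregate_stats(profs)
  ms <- st$molecule_stats; cnt <- function(f) ms$count[ms$field == f]
  expect_equal(cnt("has_only_circular") + cnt("has_only_linear") + cnt("has_both"),
               cnt("has_sugars"))
  for (x in c("circular", "linear")) {
    expect_equal(cnt(paste0("has_only_terminal_", x)) +
                   cnt(paste0("has_only_nonterminal_", x)) +
                   cnt(paste0("has_both_terminal_kinds_", x)),
                 cnt(paste0("has_", x)))
  }
  expect_equal(cnt("is_sugar_monomer") + cnt("is_sugar_polymer"),
               cnt("consists_only_of_sugars"))
  mo <- st$moiety_stats; mcnt <- function(f) mo$count[mo$field == f]
  expect_equal(mcnt("circular") + mcnt("linear"), mcnt("total"))
  expect_equal(mcnt("terminal") + mcnt("nonterminal"), mcnt("total"))
  expect_equal(mcnt("circular_furanose") + mcnt("circular_pyranose") +
                 mcnt("circular_heptose"), mcnt("circular"))
  expect_equal(mcnt("linear_tetrose") + mcnt("linear_pentose") +
                 mcnt("linear_hexose") + mcnt("linear_heptose"), mcnt("linear"))
  # percentages recompute from counts
  expect_equal(ms$percent, round(100 * ms$count / st$n_molecules, 2))

  empty <- aggregate_stats(profile_collection(parse_fx("toluene")))
  expect_equal(empty$n_moieties, 0L)
})

test_that("moiety-count histogram sums to the glycoside count", {
  g <- generate_glycosides(generator_spec(n_molecules = 50, seed = 41,
                                          fraction_glycosylated = 0.5))
  profs <- profile_collection(g$collection)
  h <- moiety_count_histogram(profs)
  expect_equal(sum(h$molecules), sum(profs$has_sugars))

  spec2 <- generator_spec(n_molecules = 10, seed = 43, fraction_glycosylated = 1,
                          sugar_count_distribution = c(0, 1, rep(0, 12)))
  profs2 <- profile_collection(generate_glycosides(spec2)$collection)
  h2 <- moiety_count_histogram(profs2)
  expect_equal(h2$n_total[h2$molecules > 0], 2L)

  h0 <- moiety_count_histogram(profile_collection(parse_fx("toluene")))
  expect_equal(nrow(h0), 0L)
})

test_that("ratio histogram uses half-open bins split at the threshold", {
  # 4 exocyclic oxygens on a pyranose: bin [0.6, 0.7)
  mols <- parse_fx(c("phenyl_glucoside", "low_oxy_pyranose"))
  h <- ratio_histogram(mols)
  expect_equal(h$pass[h$lower == 0.6], 1L)
  expect_equal(h$fail[h$lower == 0.3], 1L)
  expect_equal(sum(h$pass), 1L)

  # eight oxygens on a pyranose: 8/6 lands in [1.3, 1.4)
  octa <- parse_smiles(decorated_ring_smiles(5, c(2L, 2L, 2L, 1L, 1L)), "octa")
  h8 <- ratio_histogram(octa)
  expect_equal(h8$pass[h8$lower == 1.3], 1L)

  h0 <- ratio_histogram(structure(list(), class = "mol_collection"))
  expect_true(all(h0$pass == 0L) && all(h0$fail == 0L))

  # pass bins sum to the accepted circular count on a mixed batch
  g <- generate_glycosides(generator_spec(n_molecules = 30, seed = 51,
                                          fraction_glycosylated = 0.6))
  hg <- ratio_histogram(g$collection)
  n_acc <- sum(vapply(g$collection, function(m)
    length(detect_circular_sugars(m)), integer(1)))
  expect_equal(sum(hg$pass), n_acc)
})
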