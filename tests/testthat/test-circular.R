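test_that("candidate ring perception handles the canonical special cases", {
  glc <- find_candidate_rings(parse_one("glucose"))
  expect_length(glc, 1L)
  expect_equal(glc[[1]]$ring_class, "pyranose")
  # C6's hydroxyl oxygen hangs off an exocyclic carbon, so n_exo is 4 not 5
  expect_equal(glc[[1]]$n_exo, 4L)
  expect_equal(glc[[1]]$r_exo, 4 / 6)

  # cyclic double bond disqualifies the lactone ring
  expect_length(find_candidate_rings(parse_one("vitamin_c")), 0L)
  # pseudosugar: no ring oxygen
  expect_length(find_candidate_rings(parse_one("inositol")), 0L)

  thp <- find_candidate_rings(parse_one("tetrahydropyran"))
  expect_length(thp, 1L)
  expect_equal(thp[[1]]$n_exo, 0L)
  expect_equal(thp[[1]]$r_exo, 0)
})

test_that("glycosidic bond detection distinguishes bridges from hydroxyls", {
  ph <- find_candidate_rings(parse_one("phenyl_glucoside"))[[1]]
  expect_true(ph$has_glycosidic_bond)
  me <- find_candidate_rings(parse_one("methyl_glucoside"))[[1]]
  expect_true(me$has_glycosidic_bond)
  free <- find_candidate_rings(parse_one("glucose"))[[1]]
  expect_false(free$has_glycosidic_bond)
})

test_that("detection filters respond to threshold, spiro and keto options", {
  ph <- parse_one("phenyl_glucoside")
  expect_length(detect_circular_sugars(ph), 1L)

  low <- parse_one("low_oxy_pyranose")  # 2 exocyclic oxygens, ratio 1/3
  expect_length(detect_circular_sugars(low), 0L)
  expect_length(detect_circular_sugars(low, circular_settings(ratio_threshold = 0.3)), 1L)

  sp <- parse_one("spiro_sugar")
  expect_length(detect_circular_sugars(sp), 0L)
  expect_length(detect_circular_sugars(sp, circular_settings(allow_spiro = TRUE)), 1L)

  ke <- parse_one("keto_sugar")
  expect_length(detect_circular_sugars(ke), 0L)
  acc <- detect_circular_sugars(ke, circular_settings(allow_keto = TRUE))
  expect_length(acc, 1L)
  # the keto oxygen still counts toward n_exo
  expect_gte(acc[[1]]$n_exo, 4L)

  expect_length(detect_circular_sugars(ph, circular_settings(require_glycosidic_bond = TRUE)), 1L)
  expect_length(detect_circular_sugars(parse_one("glucose"),
                                       circular_settings(require_glycosidic_bond = TRUE)), 0L)
})

test_that("exhaustive decorated rings obey the ratio interval arithmetic", {
  cases <- list()
  for (nc in 4:6) {
    grid <- expand.grid(rep(list(0:2), nc))
    for (r in seq_len(nrow(grid))) {
      subs <- as.integer(grid[r, ])
      cases[[length(cases) + 1L]] <- list(nc = nc, subs = subs,
                                          smi = decorated_ring_smiles(nc, subs))
    }
  }
  mols <- parse_smiles(vapply(cases, function(x) x$smi, character(1)))
  expect_length(mols, length(cases))
  n_inc_all <- integer(); r_exo_all <- numeric(); cls_all <- character()
  for (k in seq_along(mols)) {
    cand <- find_candidate_rings(mols[[k]])
    expect_length(cand, 1L)
    c1 <- cand[[1]]
    expect_equal(c1$n_inc, cases[[k]]$nc + 1L)
    expect_equal(c1$n_exo, sum(cases[[k]]$subs))
    expect_equal(c1$r_exo, sum(cases[[k]]$subs) / (cases[[k]]$nc + 1L))
    expect_lt(c1$r_exo, 2)
    n_inc_all <- c(n_inc_all, c1$n_inc)
    r_exo_all <- c(r_exo_all, c1$r_exo)
    cls_all <- c(cls_all, c1$ring_class)
  }
  # no furanose can land in [0.5, 0.6)
  expect_false(any(cls_all == "furanose" & r_exo_all >= 0.5 & r_exo_all < 0.6))
  # [0.3, 0.4) holds pyranoses only
  expect_true(all(cls_all[r_exo_all >= 0.3 & r_exo_all < 0.4] == "pyranose"))
  # [0.7, 0.8) holds heptoses only (five exocyclic oxygens)
  sel <- r_exo_all >= 0.7 & r_exo_all < 0.8
  expect_true(all(cls_all[sel] == "heptose"))
  expect_true(all(round(r_exo_all[sel] * 7) == 5))
  # reaching the 0.5 threshold needs three exocyclic oxygens on 5/6-rings
  small <- n_inc_all %in% c(5L, 6L)
  expect_true(all((r_exo_all[small] >= 0.5) == (r_exo_all[small] * n_inc_all[small] >= 3)))
  # ratio >= 1 implies a doubly-oxygenated ring carbon
  for (k in seq_along(cases)) {
    if (r_exo_all[k] >= 1) expect_true(any(cases[[k]]$subs == 2L))
  }
})

test_that("lowering the ratio threshold never loses accepted candidates", {
  mols <- parse_fx(c("glucose", "phenyl_glucoside", "low_oxy_pyranose",
                     "maltose", "diginatin_like", "tetrahydropyran"))
  thresholds <- seq(0, 1, by = 0.1)
  for (m in mols) {
    counts <- vapply(thresholds, function(t)
      length(detect_circular_sugars(m, circular_settings(ratio_threshold = t))),
      integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("ring detection matches the brute-force cycle oracle", {
  mols <- parse_fx(c("glucose", "phenyl_glucoside", "methyl_glucoside",
                     "fructose", "vitamin_c", "inositol", "tetrahydropyran",
                     "maltose", "spiro_sugar", "keto_sugar", "low_oxy_pyranose"))
  configs <- list(circular_settings(),
                  circular_settings(allow_spiro = TRUE),
                  circular_settings(allow_keto = TRUE),
                  circular_settings(ratio_threshold = 0.3))
  for (m in mols) {
    expect_lte(length(m$atoms), 30L)
    for (cs in configs) {
      got <- lapply(detect_circular_sugars(m, cs),
                    function(x) sort(x$ring_atoms))
      want <- bf_detect_circular(m, cs)
      expect_equal(got[order(vapply(got, min, integer(1)))],
                   want[order(vapply(want, min, integer(1)))],
                   info = paste(m$id, cs$ratio_threshold))
    }
  }
})
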