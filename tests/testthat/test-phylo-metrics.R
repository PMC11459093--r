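test_that("Newick reading validates structure and branch lengths", {
  tr <- toy_tree()
  expect_equal(length(tr$tip.label), 3)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(sum(tr$edge.length), 5)

  single <- read_newick(text = "(A:1);")
  expect_equal(length(single$tip.label), 1)
  expect_equal(sum(single$edge.length), 1)

  expect_error(read_newick(text = "((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_newick(text = "((A,B),C);"), "branch length")
  expect_error(read_newick("/nonexistent/file.nwk"), "not found")
})

test_that("pruning keeps exactly the requested taxa and their distances", {
  tr <- toy_tree()
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(patristic_distances(pr)["A", "C"], 4)
  pr2 <- prune_to_taxa(tr, c("A", "B"))
  expect_equal(patristic_distances(pr2)["A", "B"], 2)

  all_t <- prune_to_taxa(tr, c("A", "B", "C"))
  expect_equal(patristic_distances(all_t), patristic_distances(tr))

  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")
})

test_that("pruning preserves patristic distances on random trees", {
  for (seed in 1:10) {
    tr <- random_tree(12, seed)
    set.seed(seed + 100)
    keep <- sample(tr$tip.label, 5)
    d_full <- patristic_distances(tr)[keep, keep]
    d_pruned <- patristic_distances(prune_to_taxa(tr, keep))[keep, keep]
    expect_equal(d_pruned, d_full, tolerance = 1e-12)
  }
})

test_that("patristic distances are path sums, symmetric, zero-diagonal", {
  d <- patristic_distances(toy_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))
  expect_equal(d, t(d))

  ds <- patristic_distances(star_tree(5))
  expect_true(all(ds[upper.tri(ds)] == 2))
})

test_that("Faith's PD follows the root-inclusive convention", {
  tr <- toy_tree()
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5)
  expect_equal(faith_pd(tr, "C"), 2)
  expect_error(faith_pd(tr, character(0)), "at least 1")
  # MRCA-spanning variant drops the stem branch
  expect_equal(faith_pd(tr, c("A", "B"), include_root = FALSE), 2)
})

test_that("PD equals total branch length for all tips and is monotone", {
  for (seed in 1:5) {
    tr <- random_tree(10, seed)
    expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length),
                 tolerance = 1e-12)
    set.seed(seed)
    base <- sample(tr$tip.label, 4)
    extra <- sample(setdiff(tr$tip.label, base), 1)
    expect_gte(faith_pd(tr, c(base, extra)), faith_pd(tr, base))
  }
})

test_that("PSV and PSR match hand computation and closed forms", {
  tr <- toy_tree()
  expect_equal(psv(tr, c("A", "B", "C")), 5 / 6)
  expect_equal(psr(tr, c("A", "B", "C")), 2.5)
  # star phylogeny: C = identity
  st <- star_tree(7)
  expect_equal(psv(st, st$tip.label), 1)
  expect_equal(psr(st, st$tip.label), 7)
  # two tips: PSV = 1 - C12; for the toy tree A,B share half their depth
  expect_equal(psv(tr, c("A", "B")), 0.5)
  expect_equal(psr(tr, c("A", "B")), 1)
  expect_true(is.na(psv(tr, "A")))
})

test_that("PSE matches hand arithmetic, its bounds, and picante", {
  tr <- toy_tree()
  expect_equal(pse(tr, c(A = 1, B = 1, C = 2)), 27 / 32)
  # star + equal abundances attains the stated maximum of 1
  st <- star_tree(10)
  expect_equal(pse(st, setNames(rep(5, 10), st$tip.label)), 1)
  expect_true(is.na(pse(tr, c(A = 3))))
  # all-ones abundances stay within [0, 1]
  for (seed in 1:5) {
    tr2 <- random_tree(10, seed)
    ab <- setNames(rep(1, 6), sample(tr2$tip.label, 6))
    v <- pse(tr2, ab)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # reference implementation agreement on random ultrametric trees (the
  # scale on which the metric's defining reference is stated)
  skip_if_not_installed("picante")
  for (seed in 1:5) {
    set.seed(seed)
    tr2 <- ape::rcoal(12)
    tr2$tip.label <- sprintf("t%02d", 1:12)
    spp <- sample(tr2$tip.label, 7)
    ab <- setNames(sample(1:9, 7, replace = TRUE), spp)
    ref <- picante::pse(comm_matrix(spp, tr2$tip.label, ab), tr2)[1, "PSEs"]
    expect_equal(pse(tr2, ab), ref, tolerance = 1e-10)
  }
})

test_that("PSE is invariant under scaling all abundances by a constant", {
  tr <- random_tree(10, 3)
  ab <- setNames(c(1, 2, 5, 3, 8), tr$tip.label[1:5])
  expect_equal(pse(tr, ab * 7), pse(tr, ab), tolerance = 1e-12)
})

test_that("MPD and MNTD match hand values and the path-walking oracle", {
  tr <- toy_tree()
  d <- patristic_distances(tr)
  expect_equal(mpd_obs(d, c("A", "B", "C")), 10 / 3)
  expect_equal(mntd_obs(d, c("A", "B", "C")), 8 / 3)
  expect_equal(mpd_obs(d, c("A", "C")), 4)
  expect_equal(mntd_obs(d, c("A", "C")), 4)
  expect_true(is.na(mpd_obs(d, "A")))
  ds <- patristic_distances(star_tree(6))
  expect_equal(mpd_obs(ds, LETTERS[1:6]), mntd_obs(ds, LETTERS[1:6]))

  for (seed in 1:8) {
    tr2 <- random_tree(10, seed)
    set.seed(seed)
    spp <- sample(tr2$tip.label, 5)
    d2 <- patristic_distances(tr2)
    expect_equal(mpd_obs(d2, spp), oracle_mpd(tr2, spp), tolerance = 1e-10)
    expect_equal(mntd_obs(d2, spp), oracle_mntd(tr2, spp), tolerance = 1e-10)
  }
})

test_that("metrics agree with picante on random trees", {
  skip_if_not_installed("picante")
  for (seed in 1:5) {
    tr <- random_tree(15, seed)
    set.seed(seed)
    spp <- sample(tr$tip.label, 8)
    cm <- comm_matrix(spp, tr$tip.label)
    expect_equal(faith_pd(tr, spp),
                 picante::pd(cm, tr, include.root = TRUE)[1, "PD"],
                 tolerance = 1e-10)
    expect_equal(psv(tr, spp), picante::psv(cm, tr)[1, "PSVs"],
                 tolerance = 1e-10)
    d <- patristic_distances(tr)
    expect_equal(mpd_obs(d, spp), picante::mpd(cm, d)[1], tolerance = 1e-10)
    expect_equal(mntd_obs(d, spp), picante::mntd(cm, d)[1], tolerance = 1e-10)
  }
})

test_that("diversity_table flags undefined metrics and obeys PSR = k PSV", {
  study <- simulate_study(default_scenario(3))
  dv <- diversity_table(study$tree, study$survey)
  expect_true(all(c("total", "herb", "woody") %in% dv$level))
  ok <- dv$richness >= 2
  expect_equal(dv$PSR[ok], dv$richness[ok] * dv$PSV[ok], tolerance = 1e-12)
  expect_true(all(dv$PD[dv$richness >= 1] > 0))
  expect_true(all(is.na(dv$MPD[dv$richness < 2])))
  # woody level absent in farmland/grassland stages -> zero-richness rows
  expect_true(any(dv$richness[dv$level == "woody"] == 0))
})
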