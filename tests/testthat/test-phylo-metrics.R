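test_that("cophenetic distances match hand path sums and the pairwise oracle", {
  d <- cophenetic_distances(abc_tree())
  expect_equal(unname(d["A", "B"]), 2)
  expect_equal(unname(d["A", "C"]), 4)
  expect_equal(unname(d["B", "C"]), 4)
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))
  expect_equal(d, t(d))

  # ultrametric depth-1 trees: every distance <= 2
  tr <- simulate_phylogeny(25, seed = 4)
  expect_lte(max(cophenetic_distances(tr)), 2 + 1e-9)

  # random trees: equals per-pair path summation via tree traversal
  for (seed in 1:5) {
    rt <- withr::with_seed(seed, ape::rtree(8))
    d <- cophenetic_distances(rt)
    for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
      a <- rt$tip.label[pair[1]]; b <- rt$tip.label[pair[2]]
      path <- ape::nodepath(rt, pair[1], pair[2])
      len <- sum(vapply(seq_len(length(path) - 1), function(k) {
        e <- which((rt$edge[, 1] == path[k] & rt$edge[, 2] == path[k + 1]) |
                   (rt$edge[, 2] == path[k] & rt$edge[, 1] == path[k + 1]))
        rt$edge.length[e]
      }, numeric(1)))
      expect_equal(unname(d[a, b]), len, tolerance = 1e-10)
    }
  }
})

test_that("Faith's PD is root-inclusive and matches oracles and picante", {
  star <- star_tree(3)
  expect_equal(faith_pd(c("A", "B"), star), 2.0)
  expect_equal(faith_pd(c("A", "B", "C"), star), 3.0)

  tr <- abc_tree()
  expect_equal(faith_pd(c("A", "B"), tr), 3.0)   # two tip branches + stem
  expect_equal(faith_pd(c("A", "B", "C"), tr), sum(tr$edge.length))
  expect_equal(faith_pd(character(0), tr), 0)

  # oracle + cross-check on random trees and random communities
  for (seed in 1:5) {
    rt <- withr::with_seed(seed, ape::rtree(8))
    comm <- withr::with_seed(seed + 100,
      sample(rt$tip.label, sample(2:7, 1)))
    expect_equal(faith_pd(comm, rt), oracle_pd(comm, rt), tolerance = 1e-10)
    samp <- matrix(as.integer(rt$tip.label %in% comm), nrow = 1,
                   dimnames = list("q", rt$tip.label))
    expect_equal(faith_pd(comm, rt),
                 picante::pd(samp, rt, include.root = TRUE)$PD,
                 tolerance = 1e-10)
  }
})

test_that("PD never decreases when a species is added", {
  tr <- simulate_phylogeny(20, seed = 9)
  withr::with_seed(10, for (i in 1:20) {
    comm <- sample(tr$tip.label, sample(1:15, 1))
    extra <- sample(setdiff(tr$tip.label, comm), 1)
    expect_gte(faith_pd(c(comm, extra), tr), faith_pd(comm, tr) - 1e-12)
  })
})

test_that("MPD and MNTD match hand values, brute-force oracles and picante", {
  d <- cophenetic_distances(abc_tree())
  expect_equal(mpd(c("A", "C"), d), 4)
  expect_equal(mntd(c("A", "C"), d), 4)
  expect_equal(mpd(c("A", "B", "C"), d), 10 / 3)
  expect_equal(mntd(c("A", "B", "C"), d), 8 / 3)
  expect_true(is.na(mpd("A", d)))
  expect_true(is.na(mntd("A", d)))

  for (seed in 1:10) {
    rt <- withr::with_seed(seed, ape::rtree(8))
    dm <- cophenetic_distances(rt)
    comm <- withr::with_seed(seed + 50, sample(rt$tip.label, sample(2:8, 1)))
    expect_equal(mpd(comm, dm), oracle_mpd(comm, dm), tolerance = 1e-12)
    expect_equal(mntd(comm, dm), oracle_mntd(comm, dm), tolerance = 1e-12)
    expect_lte(mntd(comm, dm), max(dm) + 1e-12)   # bounded by the tree diameter
    samp <- matrix(as.integer(rt$tip.label %in% comm), nrow = 1,
                   dimnames = list("q", colnames(dm)))
    expect_equal(mpd(comm, dm),
                 picante::mpd(samp, dm, abundance.weighted = FALSE),
                 tolerance = 1e-12)
    expect_equal(mntd(comm, dm),
                 picante::mntd(samp, dm, abundance.weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("SES metrics are reproducible, label-invariant and flag degenerate nulls", {
  tr <- simulate_phylogeny(12, seed = 2)
  st <- random_stems(300, side = 30, n_species = 12, seed = 3)
  st$species <- sprintf("sp%03d", as.integer(sub("sp", "", st$species)))
  g <- quadrat_grid(30, 5)
  cm <- build_community_matrix(st, g)
  cfg <- null_model_config(n_rand = 199, seed = 7)
  a <- ses_metrics(cm, tr, cfg)
  b <- ses_metrics(cm, tr, cfg)
  expect_identical(a, b)   # same seed => identical to the last bit

  # branch-length scale invariance: NRI/NTI unchanged under c * lengths
  tr3 <- tr; tr3$edge.length <- tr3$edge.length * 3
  s3 <- ses_metrics(cm, tr3, cfg)
  expect_equal(s3$nri, a$nri, tolerance = 1e-9)
  expect_equal(s3$nti, a$nti, tolerance = 1e-9)
  expect_equal(s3$pd, 3 * a$pd, tolerance = 1e-9)

  # a community equal to the whole pool has a degenerate (sd 0) null
  full <- matrix(1L, 1, 12, dimnames = list("0", tr$tip.label))
  sf <- ses_metrics(full, tr, cfg)
  expect_false(sf$valid)
  expect_true(is.na(sf$nri))

  # SR < 2 rows are flagged invalid but keep SR and PD
  expect_true(all(!a$valid[a$sr < 2]))
  expect_true(all(is.finite(a$pd)))
})

test_that("SES null moments agree with picante's taxa-label null", {
  tr <- simulate_phylogeny(15, seed = 5)
  st <- random_stems(400, side = 30, n_species = 15, seed = 6)
  st$species <- sprintf("sp%03d", as.integer(sub("sp", "", st$species)))
  g <- quadrat_grid(30, 10)
  cm <- build_community_matrix(st, g)
  mine <- ses_metrics(cm, tr, null_model_config(n_rand = 999, seed = 8))
  dm <- cophenetic_distances(tr)[colnames(cm), colnames(cm)]
  ref <- withr::with_seed(9,
    picante::ses.mpd(cm, dm, null.model = "taxa.labels", runs = 999,
                     abundance.weighted = FALSE))
  ok <- mine$valid
  expect_equal(mine$mpd_obs[ok], ref$mpd.obs[ok], tolerance = 1e-10)
  # two independent 999-draw Monte-Carlo estimates of the same null moments
  expect_lt(max(abs(mine$mpd_null_mean[ok] - ref$mpd.rand.mean[ok])), 0.08)
  expect_lt(max(abs(mine$nri[ok] - (-ref$mpd.obs.z[ok]))), 0.5)
  expect_gt(cor(mine$nri[ok], -ref$mpd.obs.z[ok]), 0.97)
})

test_that("stage summaries test mean NRI/NTI against zero per scale and stage", {
  # identically-zero SES: mean 0, non-significant
  rows <- data.frame(scale = 5, stage = "all", nri = rep(0, 50), nti = rep(0, 50))
  rows$nri <- rows$nri + rep(c(-1e-9, 1e-9), 25)
  rows$nti <- rows$nri
  s0 <- stage_summary(rows)
  expect_equal(s0$nri_mean, 0, tolerance = 1e-8)
  expect_gt(s0$nri_p, 0.5)

  # a +0.5 shift at n = 200 is detected
  shifted <- withr::with_seed(11, data.frame(
    scale = 5, stage = "sapling", nri = rnorm(200, 0.5, 1), nti = rnorm(200, 0.5, 1)))
  s1 <- stage_summary(shifted)
  expect_gt(s1$nri_mean, 0)
  expect_lt(s1$nri_p, 0.001)

  # 3 scales x 4 stage groupings = 12 rows
  grid_rows <- expand.grid(scale = c(2.5, 5, 10),
                           stage = c("all", "sapling", "juvenile", "adult"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  many <- do.call(rbind, lapply(seq_len(nrow(grid_rows)), function(i) {
    withr::with_seed(i, data.frame(scale = grid_rows$scale[i],
                                   stage = grid_rows$stage[i],
                                   nri = rnorm(20), nti = rnorm(20)))
  }))
  expect_equal(nrow(stage_summary(many)), 12L)

  # too few valid quadrats: flagged NA
  tiny <- data.frame(scale = 5, stage = "adult", nri = c(0.1, NA), nti = c(0.2, NA))
  expect_true(is.na(stage_summary(tiny)$nri_p))
})
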