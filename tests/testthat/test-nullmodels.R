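test_that("mpd, mntd and betaMNTD match naive oracles on small trees", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    tr <- randomTestTree(n)
    d <- patristicDistances(tr)
    ab1 <- rpois(n, 2); ab2 <- rpois(n, 2)
    for (mask in 1:(2^n - 1)) {
      keep <- as.integer(intToBits(mask)[1:n])
      a <- ab1 * keep + keep  # ensure positive where kept
      for (w in c(TRUE, FALSE)) {
        expect_equal(mpd(a, d, weighted = w), naiveMPD(a, d, weighted = w),
                     tolerance = 1e-12)
        expect_equal(mntd(a, d, weighted = w), naiveMNTD(a, d, weighted = w),
                     tolerance = 1e-12)
      }
    }
    # directional-average betaMNTD on a handful of subset pairs
    for (k in 1:10) {
      a <- rpois(n, 2); b <- rpois(n, 2)
      if (!sum(a) || !sum(b)) next
      for (w in c(TRUE, FALSE))
        expect_equal(betaMNTD(a, b, d, weighted = w),
                     naiveBetaMNTD(a, b, d, weighted = w), tolerance = 1e-12)
    }
  }
})

test_that("toy-tree hand values hold", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- patristicDistances(tr)
  all4 <- c(A = 1, B = 1, C = 1, D = 1)
  expect_equal(mpd(all4, d, weighted = FALSE), 10 / 3)
  expect_equal(mntd(all4, d, weighted = FALSE), 2)
  expect_equal(mpd(c(A = 1, B = 1, C = 0, D = 0), d), 2)
  expect_equal(mpd(c(A = 3, B = 1, C = 0, D = 0), d), 2) # single pair
  expect_equal(mntd(c(A = 3, B = 1, C = 0, D = 0), d), 2)
  expect_true(is.na(mpd(c(A = 1, B = 0, C = 0, D = 0), d)))
  expect_equal(betaMNTD(all4, all4, d), 0)
  expect_equal(betaMNTD(c(A = 1, B = 1, C = 0, D = 0),
                        c(A = 0, B = 0, C = 1, D = 1), d), 4)
  expect_equal(betaMNTD(c(A = 1, B = 0, C = 0, D = 0),
                        c(A = 1, B = 1, C = 0, D = 0), d), 0.5)
})

test_that("statistics agree with picante on random communities", {
  skip_if_not_installed("picante")
  set.seed(12)
  tr <- randomTestTree(15)
  d <- patristicDistances(tr)
  comm <- randomCommunity(6, tr, nIndividuals = 60)
  # weighted MPD: package excludes self-pairs, picante includes them;
  # the two differ exactly by the factor (1 - sum f^2)
  f <- comm / rowSums(comm)
  scale <- 1 - rowSums(f * f)
  mpdMine <- vapply(1:6, function(i) mpd(comm[i, ], d), numeric(1))
  expect_equal(unname(mpdMine * scale),
               picante::mpd(comm, d, abundance.weighted = TRUE),
               tolerance = 1e-10)
  expect_equal(vapply(1:6, function(i) mpd(comm[i, ], d, weighted = FALSE),
                      numeric(1)),
               picante::mpd(comm, d, abundance.weighted = FALSE),
               tolerance = 1e-10)
  for (w in c(TRUE, FALSE))
    expect_equal(vapply(1:6, function(i) mntd(comm[i, ], d, weighted = w),
                        numeric(1)),
                 picante::mntd(comm, d, abundance.weighted = w),
                 tolerance = 1e-10)
  # abundance-weighted beta-MNTD coincides with comdistnt
  expect_equal(unname(betaMNTDMatrix(comm, d)),
               unname(as.matrix(picante::comdistnt(comm, d,
                                                   abundance.weighted = TRUE))),
               tolerance = 1e-10)
  # comdist variant
  for (w in c(TRUE, FALSE))
    expect_equal(unname(betaMNTDMatrix(comm, d, weighted = w,
                                       metric = "bmpd")),
                 unname(as.matrix(picante::comdist(comm, d,
                                                   abundance.weighted = w))),
                 tolerance = 1e-10)
})

test_that("taxaShuffle permutes labels and preserves the distance multiset", {
  tr <- randomTestTree(8)
  d <- patristicDistances(tr)
  expect_equal(taxaShuffle(d, perm = 1:8), d)
  set.seed(13)
  ds <- taxaShuffle(d)
  expect_equal(sort(rownames(ds)), sort(rownames(d)))
  expect_equal(sort(ds[lower.tri(ds)]), sort(d[lower.tri(d)]))
  expect_true(isSymmetric(ds))
  # 2-taxon swap leaves the single distance unchanged
  d2 <- patristicDistances(ape::read.tree(text = "(A:1,B:2);"))
  expect_equal(unname(taxaShuffle(d2, perm = c(2, 1))["A", "B"]),
               unname(d2["A", "B"]))
})

test_that("sesMetric equals a naive same-stream oracle and handles degenerate nulls", {
  set.seed(14)
  tr <- randomTestTree(5)
  d <- patristicDistances(tr)
  ab <- c(3, 0, 2, 5, 1)
  nIter <- 49
  for (metric in c("mpd", "mntd")) {
    set.seed(77)
    res <- sesMetric(ab, d, metric = metric, nIter = nIter)
    # oracle: identical permutation stream, naive metric on the shuffled
    # matrix
    fun <- if (metric == "mpd") naiveMPD else naiveMNTD
    set.seed(77)
    nulls <- vapply(seq_len(nIter), function(i) {
      p <- sample.int(5)
      fun(ab, d[p, p], weighted = TRUE)
    }, numeric(1))
    expect_equal(res$observed, fun(ab, d, weighted = TRUE), tolerance = 1e-12)
    expect_equal(res$null_mean, mean(nulls), tolerance = 1e-12)
    expect_equal(res$null_sd, sd(nulls), tolerance = 1e-12)
    expect_equal(res$ses, (res$observed - mean(nulls)) / sd(nulls),
                 tolerance = 1e-12)
    expect_equal(res$index, -res$ses)
  }
  # star tree: all distances equal, null sd = 0, ses undefined not infinite
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  dstar <- patristicDistances(star)
  expect_warning(res <- sesMetric(c(1, 2, 3, 0), dstar, nIter = 19),
                 "degenerate null")
  expect_true(is.na(res$ses))
})

test_that("betaNTI is symmetric, seed-reproducible and oracle-consistent", {
  set.seed(15)
  tr <- randomTestTree(12)
  d <- patristicDistances(tr)
  comm <- randomCommunity(4, tr, nIndividuals = 40)
  set.seed(99); r1 <- suppressWarnings(betaNTI(comm, d, nIter = 59))
  set.seed(99); r2 <- suppressWarnings(betaNTI(comm, d, nIter = 59))
  expect_identical(r1, r2)
  expect_equal(r1$beta_nti, t(r1$beta_nti))
  expect_true(all(is.na(diag(r1$beta_nti))))

  # naive same-stream oracle for one pair
  set.seed(99)
  nulls <- vapply(seq_len(59), function(i) {
    p <- sample.int(12)
    naiveBetaMNTD(comm[2, ], comm[1, ], d[p, p], weighted = TRUE)
  }, numeric(1))
  expect_equal(r1$beta_mntd_obs[2, 1],
               naiveBetaMNTD(comm[2, ], comm[1, ], d), tolerance = 1e-12)
  expect_equal(r1$null_mean[2, 1], mean(nulls), tolerance = 1e-12)
  expect_equal(r1$null_sd[2, 1], sd(nulls), tolerance = 1e-12)
  expect_equal(r1$beta_nti[2, 1],
               (r1$beta_mntd_obs[2, 1] - mean(nulls)) / sd(nulls),
               tolerance = 1e-12)
})

test_that("a pool of identical samples has zero beta-MNTD and a degenerate null", {
  # identical communities stay identical under any joint relabeling, so
  # the null distribution collapses at zero and beta-NTI is undefined
  tr <- randomTestTree(10)
  d <- patristicDistances(tr)
  ab <- c(5, 3, 0, 2, 0, 0, 1, 0, 4, 0)
  comm <- rbind(s1 = ab, s2 = ab, s3 = ab)
  colnames(comm) <- tr$tip.label
  set.seed(16)
  expect_warning(res <- betaNTI(comm, d, nIter = 29), "degenerate null")
  expect_true(all(res$beta_mntd_obs[lower.tri(res$beta_mntd_obs)] == 0))
  expect_true(all(is.na(res$beta_nti[lower.tri(res$beta_nti)])))
})

test_that("Bray-Curtis follows the min-sum formula and vegan agrees", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 1, 0, 0), c(0, 0, 2, 2)), 1)
  expect_equal(brayCurtis(c(2, 2, 0), c(0, 2, 2)), 0.5)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "empty")
  set.seed(17)
  for (i in 1:10) {
    a <- rpois(8, 3); b <- rpois(8, 3)
    if (!sum(a) || !sum(b)) next
    expect_equal(brayCurtis(a, b), brayCurtis(a * 7.3, b * 7.3))
    expect_equal(brayCurtis(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b), "bray")))
  }
  comm <- matrix(rpois(40, 4), 5, 8)
  expect_equal(unname(brayCurtisMatrix(comm)),
               unname(as.matrix(vegan::vegdist(comm, "bray"))))
})

test_that("RC-bray stays in bounds and resolves the constructed tails", {
  set.seed(18)
  tr <- randomTestTree(20)
  comm <- randomCommunity(6, tr, nIndividuals = 100)
  comm <- comm[rowSums(comm) > 0, ]
  rc <- raupCrickBray(comm, nIter = 199)
  v <- rc$rc_bray[lower.tri(rc$rc_bray)]
  expect_true(all(v >= -1 & v <= 1))

  # identical pair inside a diverse pool: less dissimilar than any null
  commId <- rbind(comm, dup = comm[1, ])
  set.seed(19)
  rcId <- raupCrickBray(commId, nIter = 199)
  expect_lte(rcId$rc_bray["dup", rownames(comm)[1]], -0.9)

  # determinism under a fixed seed
  set.seed(20); a <- raupCrickBray(comm, nIter = 99)
  set.seed(20); b <- raupCrickBray(comm, nIter = 99)
  expect_identical(a, b)

  # degenerate single-taxon pool is refused
  one <- matrix(c(3, 5), 2, 1, dimnames = list(c("s1", "s2"), "t1"))
  expect_error(raupCrickBray(one), "degenerate pool")

  # non-integer tables are rescaled to the abundance floor with richness
  # preserved
  spiked <- comm / 7.77
  set.seed(21)
  rcS <- raupCrickBray(spiked, nIter = 49, abundanceFloor = 500)
  expect_true(all(rcS$rc_bray[lower.tri(rcS$rc_bray)] >= -1))
})

test_that("pools partition samples and sub-seeds are deterministic 32-bit", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   compartment = rep(c("leaf", "root"), each = 3),
                   week = rep(c(3, 4, 3), 2))
  pools <- makePools(md)
  expect_equal(sort(unlist(pools, use.names = FALSE)), paste0("s", 1:6))
  expect_length(pools, 4L)
  expect_error(makePools(md, groupBy = "plot"), "missing grouping")

  s1 <- poolSeed(42, "leaf.3"); s2 <- poolSeed(42, "leaf.4")
  expect_identical(s1, poolSeed(42, "leaf.3"))
  expect_false(s1 == s2)
  expect_true(s1 > 0 && s1 < 2^31)
})

test_that("assemblyNullModels ties pools, metrics and classification together", {
  set.seed(22)
  tr <- randomTestTree(30)
  comm <- randomCommunity(8, tr, nIndividuals = 150)
  md <- data.frame(sample_id = rownames(comm),
                   compartment = rep(c("leaf", "root"), each = 4),
                   week = 3L)
  pce <- PhyloCommunityExperiment(t(comm), tr, sampleData = md)
  res <- assemblyNullModels(pce, nIter = 59, seed = 5)
  expect_setequal(unique(res$ses$metric), c("mpd", "mntd"))
  expect_equal(nrow(res$ses), 8 * 2)
  # within-pool pairs only: 2 pools of 4 samples -> 2 * choose(4,2)
  expect_equal(nrow(res$pairs), 12L)
  expect_true(all(res$pairs$sample_a != res$pairs$sample_b))
  expect_true(all(table(res$pairs$compartment) == 6L))
  expect_s3_class(res$pairs$process, "factor")
  # reproducible independent of pool order: rerun equals first run
  res2 <- assemblyNullModels(pce, nIter = 59, seed = 5)
  expect_identical(res, res2)
})
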