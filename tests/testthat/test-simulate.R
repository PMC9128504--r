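test_that("Yule tree simulation is reproducible with the right shape", {
  tr <- simulateTree(2, seed = 1)
  expect_length(tr$tip.label, 2L)
  expect_true(all(tr$edge.length > 0))

  t1 <- simulateTree(20, seed = 7)
  t2 <- simulateTree(20, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  t64 <- simulateTree(64, seed = 3)
  expect_equal(t64$Nnode, 63L)  # fully bifurcating pure-birth topology
  expect_true(ape::is.rooted(t64))
  expect_error(simulateTree(1), "at least 2")
})

test_that("Brownian traits have the closed-form cherry variance", {
  tr <- ape::read.tree(text = "(A:2,B:2);")
  expect_equal(unname(evolveTraitBM(tr, traitSigma = 0)), c(0, 0))
  set.seed(41)
  diffs <- replicate(4000, {
    x <- evolveTraitBM(tr, traitSigma = 1.5)
    x[["A"]] - x[["B"]]
  })
  # difference of two independent BM endpoints: Normal(0, 2 * sigma^2 * t)
  expect_equal(var(diffs), 2 * 1.5^2 * 2, tolerance = 0.1)
  expect_equal(mean(diffs), 0, tolerance = 0.2)
})

test_that("community assembly responds to filter and migration limits", {
  set.seed(42)
  tr <- simulateTree(50)
  traits <- evolveTraitBM(tr, 1)
  meta <- stats::setNames(runif(50), names(traits))
  meta <- meta / sum(meta)

  out <- assembleCommunity(traits, 0, Inf, 5000, 0, meta)
  expect_equal(sum(out), 5000)  # multinomial conservation
  expect_equal(names(out), names(traits))
  # filter off, m = 0 -> uniform expectation
  expect_lt(max(abs(out / 5000 - 1 / 50)), 0.05)

  # m = 1 follows the metacommunity regardless of traits
  set.seed(43)
  big <- assembleCommunity(traits, 99, 0.01, 50000, 1, meta)
  expect_gt(cor(big / 50000, meta), 0.99)

  # a tight filter concentrates the sample near the optimum
  set.seed(44)
  sel <- assembleCommunity(traits, traits[[1]], 0.1 * sd(traits), 1000, 0,
                           meta)
  expect_gt(sel[[1]], 0)
  got <- traits[sel > 0]
  expect_lt(max(abs(got - traits[[1]])), sd(traits))

  expect_error(assembleCommunity(traits, 1e6, 1e-4, 10, 0, meta),
               "weights are zero")
  expect_error(assembleCommunity(traits, 0, -1, 10, 0, meta), "positive")
})

test_that("scenarioSpec validates and fills calibrated defaults", {
  sp <- scenarioSpec("neutral_drift")
  expect_equal(sp$regime, "drift_diversification")
  expect_true(is.infinite(sp$filterStrength))
  sp2 <- scenarioSpec("homogeneous_selection", nTaxa = 50, seed = 9)
  expect_equal(sp2$nTaxa, 50L)
  expect_true(sp2$filterStrength > 0)
  expect_error(scenarioSpec("homogeneous_selection", nSamples = 1), "at least 2")
  expect_error(scenarioSpec("neutral_drift", migrationRate = 2), "migration")
  expect_error(scenarioSpec("flying"), "'arg' should be one of")
})

test_that("simulateScenario builds a coherent, reproducible dataset", {
  sp <- scenarioSpec("dispersal_limitation", nTaxa = 60, nSamples = 6,
                     nIndividuals = 300, seed = 5)
  ds <- simulateScenario(sp)
  expect_s3_class(ds$tree, "phylo")
  expect_true(all(rownames(ds$table) %in% ds$tree$tip.label))
  expect_equal(unname(colSums(ds$table)), rep(300, 6))
  expect_equal(ds$truth$regime, "dispersal_limitation")
  expect_equal(nrow(ds$metadata), 6L)
  expect_s4_class(ds$experiment, "PhyloCommunityExperiment")

  ds2 <- simulateScenario(sp)
  expect_identical(ds$table, ds2$table)
  expect_identical(ape::write.tree(ds$tree), ape::write.tree(ds2$tree))
})

test_that("simulateStudy produces the study-shaped design with a spike", {
  sched <- expand.grid(compartment = c("leaf", "root", "rhizosphere"),
                       week = 3:4, stringsAsFactors = FALSE)
  sched$regime <- "drift_diversification"
  ds <- simulateStudy(schedule = sched, nTaxa = 40, samplesPerPool = 6,
                      nIndividuals = 200, seed = 11)
  md <- ds$metadata
  expect_equal(nrow(md), 3 * 2 * 6)
  expect_setequal(unique(md$compartment), c("leaf", "root", "rhizosphere"))
  expect_true(all(c("nam_line", "bbch", "block") %in% names(md)))
  expect_equal(sort(unique(md$block)), 1:3)

  spike <- ds$table[ds$spike_taxon, ]
  rootish <- md$sample_id[md$compartment %in% c("root", "rhizosphere")]
  leafy <- md$sample_id[md$compartment == "leaf"]
  expect_true(all(spike[rootish] > 0))
  expect_true(all(spike[leafy] == 0))
  expect_false(ds$spike_taxon %in% ds$tree$tip.label)

  # missing pool in the schedule is an error
  expect_error(simulateStudy(schedule = sched[-1, ], nTaxa = 40,
                             samplesPerPool = 4), "missing pool")

  # per-pool sub-seeding makes the dataset a pure function of the seed
  ds2 <- simulateStudy(schedule = sched, nTaxa = 40, samplesPerPool = 6,
                       nIndividuals = 200, seed = 11)
  expect_identical(ds$table, ds2$table)
})

test_that("synthetic datasets round-trip through the plain-text writers", {
  sp <- scenarioSpec("neutral_drift", nTaxa = 30, nSamples = 4,
                     nIndividuals = 150, seed = 2)
  ds <- simulateScenario(sp)
  dir <- withr::local_tempdir()
  paths <- writeSyntheticDataset(ds, dir, seed = 2)
  expect_true(all(file.exists(paths)))
  tr <- readNewickTree(paths[["tree"]])
  tab <- readFeatureTable(paths[["table"]])
  md <- readSampleMetadata(paths[["metadata"]])
  expect_setequal(tr$tip.label, ds$tree$tip.label)
  expect_equal(tab[rownames(ds$table), ], ds$table)
  expect_equal(md$sample_id, ds$metadata$sample_id)
})
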