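test_that("composite LD formula matches its closed form and bounds", {
  # fully linked, maximally divergent founders: |Delta| at its 0.25 cap
  expect_equal(expectedCompositeLD(0, 1, 0, 1, 0), 0.25)
  expect_equal(expectedCompositeLD(0, 0, 1, 1, 0), -0.25)  # repulsion
  # equal parental frequencies kill the LD regardless of distance
  expect_equal(expectedCompositeLD(0.1, 0.4, 0.4, 0.9, 0.1), 0)
  # free recombination kills it too
  expect_equal(expectedCompositeLD(0.5, 1, 0, 1, 0), 0)
  expect_error(expectedCompositeLD(0.7, 0.5, 0.5, 0.5, 0.5), "theta")
  expect_error(expectedCompositeLD(0.1, 1.5, 0.5, 0.5, 0.5), "frequencies")
})

test_that("marker-capture proportions reproduce the design values", {
  expect_equal(round(markerCaptureRatio(2000, 100), 2), 0.95)
  expect_equal(round(markerCaptureRatio(2000, 2 * 39.22 * 2), 2), 0.93)
  expect_equal(markerCaptureRatio(500, 0), 1)
  expect_equal(round(markerCaptureFromSpacing(39.22, 0.001), 2), 0.86)
  expect_equal(markerCaptureFromSpacing(100, 0), 1)
  expect_equal(markerCaptureFromSpacing(250, 0.001), 0.5)
  expect_error(markerCaptureRatio(0, 10), "positive")
})

test_that("gamete dropping reproduces the map's recombination fractions", {
  ## two chromosomes, two loci each, 10 cM apart within a chromosome
  map <- new("GenomeMap", chromosome = c(1L, 1L, 2L, 2L),
             position_cM = c(0, 10, 0, 10), qtl = 1L)
  hapA <- matrix(1L, 1, 4)
  hapB <- matrix(0L, 1, 4)
  pop <- popFromHaps(hapA, hapB, map)
  set.seed(42)
  g <- sampleGamete(pop, 1, n = 20000)
  rec_within <- mean(g[, 1] != g[, 2])
  rec_across <- mean(g[, 2] != g[, 3])
  expect_equal(rec_within, 0.5 * (1 - exp(-0.2)), tolerance = 0.08)
  expect_equal(rec_across, 0.5, tolerance = 0.03)

  ## coincident loci never recombine
  map0 <- new("GenomeMap", chromosome = c(1L, 1L),
              position_cM = c(3, 3), qtl = 1L)
  pop0 <- popFromHaps(matrix(1L, 1, 2), matrix(0L, 1, 2), map0)
  g0 <- sampleGamete(pop0, 1, n = 5000)
  expect_true(all(g0[, 1] == g0[, 2]))

  ## 0.1 cM: Monte-Carlo recombination fraction matches Haldane
  map1 <- new("GenomeMap", chromosome = c(1L, 1L),
              position_cM = c(0, 0.1), qtl = 1L)
  pop1 <- popFromHaps(matrix(1L, 1, 2), matrix(0L, 1, 2), map1)
  set.seed(7)
  g1 <- sampleGamete(pop1, 1, n = 1e6)
  c_expected <- (1 - exp(-0.002)) / 2
  expect_equal(mean(g1[, 1] != g1[, 2]), c_expected,
               tolerance = 0.15)
})

test_that("composite population carries the expected LD and decays with distance", {
  map <- smallMap(spacing = 0.5)
  n <- nLoci(map)
  founders <- new("FounderSpec", p1 = rep(0.95, n), p2 = rep(0.05, n),
                  ne_target = 40)
  comp <- simulateComposite(founders, map, n_generations = 1,
                            pop_size = 4000, seed = 5)
  ## compare estimated LD with the closed form at three distances
  theta_of <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))
  for (gap in c(1L, 8L, 20L)) {
    pairs_a <- seq(1, 40 - gap)
    pairs_b <- pairs_a + gap
    d_hat <- mean(estimateLD(comp, pairs_a, pairs_b))
    d_exp <- expectedCompositeLD(theta_of(0.5 * gap), 0.95, 0.05, 0.95,
                                 0.05)
    expect_equal(d_hat, d_exp, tolerance = 0.08)
  }
  ## monotone decay of |LD| with map distance
  mean_abs <- sapply(c(1L, 8L, 20L), function(gap)
    mean(abs(estimateLD(comp, seq(1, 40 - gap), seq(1, 40 - gap) + gap))))
  expect_true(all(diff(mean_abs) < 0))

  ## identical founder frequencies: no LD beyond sampling noise
  f0 <- new("FounderSpec", p1 = rep(0.5, n), p2 = rep(0.5, n),
            ne_target = 40)
  comp0 <- simulateComposite(f0, map, n_generations = 1,
                             pop_size = 4000, seed = 6)
  expect_lt(abs(mean(estimateLD(comp0, 1:39, 2:40))), 0.02)
})

test_that("composite is in Hardy-Weinberg proportions at most loci", {
  map <- smallMap()
  comp <- simulateComposite(founderSpec(map, seed = 8), map,
                            n_generations = 5, pop_size = 1000, seed = 9)
  dos <- dosages(comp)
  p <- colMeans(dos) / 2
  n <- nrow(dos)
  pvals <- sapply(seq_len(ncol(dos)), function(j) {
    obs <- tabulate(dos[, j] + 1L, 3L)
    expd <- n * c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
    suppressWarnings(chisq.test(obs, p = expd / n)$p.value)
  })
  expect_gt(mean(pvals > 0.01), 0.9)
})

test_that("family cohort has the requested structure and relationships", {
  rep <- smallReplicate()
  pop <- rep$pop
  expect_equal(nIndividuals(pop), 100)
  expect_equal(as.integer(table(familyId(pop))), rep(20L, 5))
  ped <- pedigree(pop)
  ## full sibs share both parents; different families share none
  expect_equal(ped$sire[1], ped$sire[20])
  expect_equal(ped$dam[1], ped$dam[20])
  expect_false(ped$sire[1] == ped$sire[21])
  ## dosages decompose into the two haplotypes
  expect_true(all(dosages(pop) %in% 0:2))
  expect_identical(dosages(pop), pop@hapA + pop@hapB)
  ## pedigree expectation: within-family additive relationship 0.5
  A <- pedigreeA(ped, ids = ped$id)
  fam <- familyId(pop)
  within <- A[fam == 1, fam == 1]
  expect_equal(mean(within[upper.tri(within)]), 0.5, tolerance = 1e-12)
  ## minimal case: two full sibs
  comp <- simulateComposite(founderSpec(smallMap(), seed = 2), smallMap(),
                            n_generations = 1, pop_size = 50, seed = 3)
  two <- makeFamilies(comp, n_families = 1, family_size = 2, seed = 4)
  expect_equal(nIndividuals(two), 2)
  expect_equal(pedigree(two)$sire[1], pedigree(two)$sire[2])
  expect_error(makeFamilies(comp, n_families = 100, family_size = 2),
               "not enough parents")
})

test_that("MAF screening excludes rare loci and the pipeline keeps all markers", {
  map <- new("GenomeMap", chromosome = c(1L, 1L), position_cM = c(0, 1),
             qtl = 1L)
  hapA <- cbind(rep(0L, 50), rep(1L, 50))
  hapA[1:4, 1] <- 1L   # p = 0.04 at locus 1
  hapB <- matrix(0L, 50, 2)
  hapB[, 2] <- 1L      # locus 2 fixed heterozygous, p = 1 -> drop too
  hapB[1:25, 2] <- 0L  # p = 0.75
  pop <- popFromHaps(hapA, hapB, map)
  expect_equal(enforceMAF(pop, 0.05), 2L)
  expect_equal(enforceMAF(pop, 0), c(1L, 2L))
  expect_error(enforceMAF(pop, 0.7), "threshold")
  ## the default pipeline retains the full marker panel
  rep <- smallReplicate()
  expect_equal(length(enforceMAF(rep$pop, 0.05)), nLoci(rep$pop))
})

test_that("simulation is deterministic given the seed", {
  map <- smallMap()
  r1 <- simulateReplicate(map = map, n_families = 3, family_size = 10,
                          pop_size = 150, seed = 21)
  r2 <- simulateReplicate(map = map, n_families = 3, family_size = 10,
                          pop_size = 150, seed = 21)
  expect_identical(r1$pop@hapA, r2$pop@hapA)
  expect_identical(r1$y, r2$y)
  expect_identical(r1$trait@a, r2$trait@a)
})

test_that("trait calibration hits heritability targets and architecture shares", {
  map <- smallMap()
  for (s in c(31, 32, 33)) {
    rep <- simulateReplicate(map = map, n_families = 4, family_size = 15,
                             pop_size = 200, seed = s)
    h2 <- realizedHeritability(rep$trait)
    expect_equal(unname(h2["h2_broad"]), 0.30, tolerance = 0.02)
    expect_equal(unname(h2["h2_narrow"]), 0.20, tolerance = 0.02)
  }
  ## major-gene architecture: 5 loci carry half the genetic variance
  rep2 <- simulateReplicate(map = map, architecture = "major_genes",
                            n_families = 4, family_size = 15,
                            pop_size = 200, seed = 41)
  tr <- rep2$trait
  dos <- (rep2$pop@hapA + rep2$pop@hapB)[, tr@qtl]
  p <- colMeans(dos) / 2
  q <- 1 - p
  alpha <- tr@a + (q - p) * tr@d
  contrib <- 2 * p * q * alpha^2 + (2 * p * q * tr@d)^2
  share <- sum(contrib[tr@major_idx]) / sum(contrib)
  expect_equal(share, 0.5, tolerance = 0.05)
  ## mean degree of dominance is around 1 (complete dominance)
  expect_gt(median(abs(rep2$trait@d / rep2$trait@a)), 0.3)
  expect_error(assignTrait(rep2$pop, h2_broad = 0.2, h2_narrow = 0.3),
               "h2")
})

test_that("phenotypes are genotypic values plus calibrated residual noise", {
  rep <- smallReplicate()
  tr <- rep$trait
  ## var(y) should approximate var(g) / h2_broad
  set.seed(99)
  y_big <- replicate(40, simulatePhenotypes(rep$pop, tr))
  expect_equal(mean(apply(y_big, 2, var)), var(rep$truth$g) / 0.30,
               tolerance = 0.1)
  ## complete homozygote stays within the genotypic-value envelope
  b <- genotypicBounds(tr)
  n_qtl <- length(tr@a)
  all_M <- matrix(2L, 1, n_qtl)
  all_m <- matrix(0L, 1, n_qtl)
  g_hi <- AddDomGS:::genotypicValues(all_M, tr@a, tr@d, tr@mean_m)
  g_lo <- AddDomGS:::genotypicValues(all_m, tr@a, tr@d, tr@mean_m)
  expect_lte(g_hi, b["gmax"] + 1e-9)
  expect_gte(g_lo, b["gmin"] - 1e-9)
})
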