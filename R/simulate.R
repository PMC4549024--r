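## Forward simulation of the composite breeding population.
##
## Default parameters reproduce the study design: 10 chromosomes of
## 20 cM, 2,000 equidistant SNPs (0.1 cM spacing) of which 100 are QTL, a
## composite of two maximally divergent founder populations advanced by
## five generations of random mating (no mutation, selection or
## migration), and a genotyped cohort of 20 full-sib families of 50 bred
## from a limited parent pool (40 parents, Ne close to 40).

#' Construct a genome map
#'
#' @param n_chromosomes number of equally sized chromosomes.
#' @param chrom_length_cM chromosome length in centimorgans.
#' @param spacing_cM distance between adjacent loci.
#' @param n_qtl number of loci designated as QTL.
#' @param qtl `"even"` to space the QTL evenly across the genome,
#'   `"random"` to draw them uniformly without replacement (uses the
#'   current RNG state), or an explicit integer vector of locus indices.
#' @return a [GenomeMap-class].
#' @examples
#' genomeMap()  # the default 10 x 20 cM, 2000-locus, 100-QTL genome
#' @export
genomeMap <- function(n_chromosomes = 10, chrom_length_cM = 20,
                      spacing_cM = 0.1, n_qtl = 100, qtl = "even") {
  per_chrom <- round(chrom_length_cM / spacing_cM)
  if (per_chrom < 1) stop("degenerate map: no loci")
  n <- n_chromosomes * per_chrom
  chromosome <- rep(seq_len(n_chromosomes), each = per_chrom)
  position <- rep(seq(0, by = spacing_cM, length.out = per_chrom),
                  times = n_chromosomes)
  qtl_idx <- if (is.numeric(qtl)) {
    as.integer(qtl)
  } else if (identical(qtl, "even")) {
    as.integer(round(seq(per_chrom / (2 * n_qtl / n_chromosomes), n,
                         length.out = n_qtl)))
  } else if (identical(qtl, "random")) {
    sort(sample.int(n, n_qtl))
  } else stop("qtl must be 'even', 'random' or an index vector")
  new("GenomeMap", chromosome = chromosome, position_cM = position,
      qtl = qtl_idx)
}

#' Specify the founder populations of the composite
#'
#' The two parental populations are in linkage equilibrium; LD in the
#' composite arises from their allele-frequency divergence.  The default
#' `"maximal"` scheme draws `p1 ~ U(0.05, 0.95)` and mirrors it
#' (`p2 = 1 - p1`), which reproduces a large-LD regime; `"independent"`
#' draws both uniformly, giving milder divergence.
#'
#' @param map a [GenomeMap-class].
#' @param divergence `"maximal"` or `"independent"`.
#' @param ne_target intended effective size of the cohort parent pool
#'   (reported downstream, not enforced here).
#' @param seed RNG seed for the frequency draws.
#' @return a [FounderSpec-class].
#' @export
founderSpec <- function(map, divergence = c("maximal", "independent"),
                        ne_target = 40, seed = NULL) {
  divergence <- match.arg(divergence)
  if (!is.null(seed)) set.seed(seed)
  n <- nLoci(map)
  p1 <- runif(n, 0.05, 0.95)
  p2 <- if (divergence == "maximal") 1 - p1 else runif(n, 0.05, 0.95)
  new("FounderSpec", p1 = p1, p2 = p2, ne_target = as.numeric(ne_target))
}

## Haldane switch probabilities between adjacent loci; 0.5 across
## chromosome boundaries (and for the arbitrary first locus).
recombinationFractions <- function(map) {
  n <- nLoci(map)
  rec <- numeric(n)
  rec[1] <- 0.5
  if (n > 1) {
    d_morgan <- diff(map@position_cM) / 100
    same <- diff(map@chromosome) == 0L
    rec[-1] <- ifelse(same, 0.5 * (1 - exp(-2 * d_morgan)), 0.5)
  }
  rec
}

emptyPedigree <- function(n) {
  data.frame(id = seq_len(n), sire = 0L, dam = 0L)
}

newPop <- function(hapA, hapB, map, pedigree = emptyPedigree(nrow(hapA)),
                   family = integer(nrow(hapA)), generation = 0L) {
  storage.mode(hapA) <- "integer"
  storage.mode(hapB) <- "integer"
  new("BreedingPop", hapA = hapA, hapB = hapB, map = map,
      pedigree = pedigree, family = as.integer(family),
      generation = as.integer(generation))
}

#' Sample one recombinant gamete from a parent
#'
#' Draws a gamete from the two phased haplotypes of a parent by gamete
#' dropping under the Haldane map function (no interference): the copied
#' haplotype switches between adjacent loci with probability equal to the
#' recombination fraction implied by their map distance, and segregates
#' independently across chromosomes.
#'
#' @param pop a [BreedingPop-class].
#' @param parent index of the parent individual.
#' @param n number of gametes to draw.
#' @return integer matrix (`n` x loci) of 0/1 gametes.
#' @export
sampleGamete <- function(pop, parent, n = 1) {
  rec <- recombinationFractions(pop@map)
  cpp_drop_gametes(pop@hapA, pop@hapB, rep(as.integer(parent), n), rec)
}

#' Simulate the advanced-generation composite population
#'
#' Crosses two founder populations in linkage equilibrium (each gamete of
#' the F1 is drawn locus-wise from one parental frequency vector) and
#' advances the cross by random mating - random union of gametes with
#' recombination, without mutation, selection or migration.  The
#' resulting composite is in Hardy-Weinberg proportions but retains the
#' LD generated by the founder divergence.
#'
#' @param founders a [FounderSpec-class].
#' @param map a [GenomeMap-class].
#' @param n_generations generations of random mating after the cross.
#' @param pop_size population size maintained each generation.
#' @param seed RNG seed.
#' @return a [BreedingPop-class] (the advanced generation).
#' @export
simulateComposite <- function(founders, map, n_generations = 5,
                              pop_size = 5000, seed = NULL) {
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (pop_size <= 1) stop("pop_size must exceed 1")
  if (nLoci(map) != length(founders@p1))
    stop("founder frequencies do not match the map")
  if (!is.null(seed)) set.seed(seed)
  n <- nLoci(map)
  ## F1: one gamete from each parental population, loci independent (LE)
  hapA <- matrix(rbinom(pop_size * n, 1L, rep(founders@p1, each = pop_size)),
                 pop_size, n)
  hapB <- matrix(rbinom(pop_size * n, 1L, rep(founders@p2, each = pop_size)),
                 pop_size, n)
  rec <- recombinationFractions(map)
  for (g in seq_len(n_generations)) {
    sires <- sample.int(pop_size, pop_size, replace = TRUE)
    dams <- sample.int(pop_size, pop_size, replace = TRUE)
    newA <- cpp_drop_gametes(hapA, hapB, sires, rec)
    newB <- cpp_drop_gametes(hapA, hapB, dams, rec)
    hapA <- newA
    hapB <- newB
  }
  newPop(hapA, hapB, map, generation = n_generations)
}

#' Breed the genotyped full-sib cohort
#'
#' Samples a limited pool of `2 * n_families` parents from the composite,
#' mates them in disjoint pairs and produces `family_size` full sibs per
#' pair.  Parents are recorded in the pedigree as founders (ids
#' `1..2*n_families`); the cohort carries ids following them.
#'
#' @param composite a [BreedingPop-class] composite population.
#' @param n_families number of full-sib families.
#' @param family_size individuals per family.
#' @param seed RNG seed.
#' @param parents optional indices of the `2 * n_families` parents in
#'   the composite; their pairing is shuffled. By default parents are
#'   sampled at random.
#' @return a [BreedingPop-class] of `n_families * family_size` genotyped
#'   individuals with pedigree and family labels.
#' @export
makeFamilies <- function(composite, n_families = 20, family_size = 50,
                         seed = NULL, parents = NULL) {
  n_parents <- 2L * n_families
  if (n_parents > nIndividuals(composite))
    stop("not enough parents in the composite population")
  if (!is.null(seed)) set.seed(seed)
  parents <- if (is.null(parents))
    sample.int(nIndividuals(composite), n_parents)
  else {
    if (length(parents) != n_parents)
      stop("parents must supply 2 * n_families individuals")
    sample(parents)
  }
  rec <- recombinationFractions(composite@map)
  n_off <- n_families * family_size
  sires <- rep(parents[seq(1, n_parents, by = 2)], each = family_size)
  dams <- rep(parents[seq(2, n_parents, by = 2)], each = family_size)
  hapA <- cpp_drop_gametes(composite@hapA, composite@hapB, sires, rec)
  hapB <- cpp_drop_gametes(composite@hapA, composite@hapB, dams, rec)
  ## pedigree ids: parents 1..n_parents (founders), offspring follow
  sire_id <- rep(seq(1L, n_parents, by = 2L), each = family_size)
  dam_id <- rep(seq(2L, n_parents, by = 2L), each = family_size)
  ped <- data.frame(id = n_parents + seq_len(n_off), sire = sire_id,
                    dam = dam_id)
  fam <- rep(seq_len(n_families), each = family_size)
  newPop(hapA, hapB, composite@map, pedigree = ped, family = fam,
         generation = composite@generation + 1L)
}

#' Filter loci on minor allele frequency
#'
#' @param pop a [BreedingPop-class].
#' @param threshold loci are kept when `min(p, 1 - p) > threshold`.
#' @return integer indices of passing loci.
#' @export
enforceMAF <- function(pop, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5)
    stop("threshold must lie in [0, 0.5]")
  p <- alleleFreq(pop)
  which(pmin(p, 1 - p) > threshold)
}

#' Estimate pairwise LD from phased haplotypes
#'
#' Gametic-phase disequilibrium `Delta = P(AB) - pA * pB`, pooling both
#' gametes of every individual.
#'
#' @param pop a [BreedingPop-class].
#' @param loci_a,loci_b equal-length locus index vectors; the i-th pair
#'   is evaluated together.
#' @return numeric vector of LD estimates.
#' @export
estimateLD <- function(pop, loci_a, loci_b) {
  stopifnot(length(loci_a) == length(loci_b))
  ha <- pop@hapA
  hb <- pop@hapB
  vapply(seq_along(loci_a), function(k) {
    i <- loci_a[k]; j <- loci_b[k]
    gam_i <- c(ha[, i], hb[, i])
    gam_j <- c(ha[, j], hb[, j])
    mean(gam_i * gam_j) - mean(gam_i) * mean(gam_j)
  }, numeric(1))
}

#' Simulate replicate cohorts of one conceptual breeding population
#'
#' Builds the conceptual population once - founder draw, composite
#' advance, a common breeding-parent pool, trait architecture calibrated
#' on the first genotyped cohort - and then samples `n_replicates`
#' full-sib cohorts, each re-pairing the shared parents into new
#' families with fresh meioses and phenotypic residuals.  Because every
#' cohort shares the founders, the composite LD phase, the parent pool
#' and the QTL effects, the cohorts are samples of one conceptual
#' breeding population: marker effects estimated in one replicate are
#' transferable to another (different families, same population), which
#' is what the training/validation protocol requires.  The MAF screen
#' redraws the
#' founder frequencies (with a shifted seed) until all markers pass in
#' every cohort, so the default design yields exactly `n_loci` markers.
#'
#' @param map a [GenomeMap-class].
#' @param architecture `"infinitesimal"` or `"major_genes"`.
#' @param h2_broad,h2_narrow heritability targets.
#' @param n_replicates number of cohorts to sample.
#' @param n_families,family_size cohort design.
#' @param pop_size composite population size.
#' @param n_generations generations of random mating.
#' @param divergence founder divergence scheme (see [founderSpec()]).
#' @param maf minor-allele-frequency threshold in the cohorts.
#' @param seed RNG seed.
#' @param max_tries redraw attempts for the MAF screen.
#' @return list of `n_replicates` replicates; each is a list with `pop`
#'   (cohort), `trait` ([TraitArchitecture-class], shared), `y`
#'   (phenotypes), `truth` (list `u_a`, `u_d`, `g`), `coding`
#'   ([MarkerCoding-class] of the cohort markers), `founders` and `ne`
#'   (effective size of the parent pool).
#' @export
simulateStudy <- function(map = genomeMap(),
                          architecture = "infinitesimal",
                          h2_broad = 0.30, h2_narrow = 0.20,
                          n_replicates = 10, n_families = 20,
                          family_size = 50, pop_size = 5000,
                          n_generations = 5, divergence = "maximal",
                          maf = 0.05, seed = 1, max_tries = 10) {
  for (try in seq_len(max_tries)) {
    s <- seed + (try - 1L) * 1000003L
    founders <- founderSpec(map, divergence = divergence, seed = s)
    comp <- simulateComposite(founders, map,
                              n_generations = n_generations,
                              pop_size = pop_size)
    set.seed(s + 13L)
    parent_pool <- sample.int(nIndividuals(comp),
                              min(2L * n_families, nIndividuals(comp)))
    cohorts <- lapply(seq_len(n_replicates), function(r)
      makeFamilies(comp, n_families = n_families,
                   family_size = family_size, seed = s + 101L * r,
                   parents = parent_pool))
    ok <- all(vapply(cohorts, function(co)
      length(enforceMAF(co, maf)) == nLoci(map), logical(1)))
    if (ok) break
    if (try == max_tries)
      stop("MAF screen failed after ", max_tries, " founder redraws")
  }
  trait <- assignTrait(cohorts[[1]], architecture = architecture,
                       h2_broad = h2_broad, h2_narrow = h2_narrow,
                       seed = seed + 7L)
  ne <- effectiveSize(n_families, n_families)
  lapply(seq_along(cohorts), function(r) {
    cohort <- cohorts[[r]]
    y <- simulatePhenotypes(cohort, trait, seed = seed + 211L * r)
    list(pop = cohort, trait = trait, y = y,
         truth = trueValues(cohort, trait),
         coding = markerCoding(dosages(cohort)), founders = founders,
         ne = ne)
  })
}

#' Simulate one complete replicate of the study design
#'
#' Convenience wrapper around [simulateStudy()] returning a single
#' cohort.
#'
#' @inheritParams simulateStudy
#' @return a single replicate (see [simulateStudy()]).
#' @export
simulateReplicate <- function(map = genomeMap(),
                              architecture = "infinitesimal",
                              h2_broad = 0.30, h2_narrow = 0.20,
                              n_families = 20, family_size = 50,
                              pop_size = 5000, n_generations = 5,
                              divergence = "maximal", maf = 0.05,
                              seed = 1, max_tries = 10) {
  simulateStudy(map = map, architecture = architecture,
                h2_broad = h2_broad, h2_narrow = h2_narrow,
                n_replicates = 1, n_families = n_families,
                family_size = family_size, pop_size = pop_size,
                n_generations = n_generations, divergence = divergence,
                maf = maf, seed = seed, max_tries = max_tries)[[1]]
}
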