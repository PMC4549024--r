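## Accessors and show() methods.

#' Number of loci / individuals
#'
#' @param x a [GenomeMap-class] or [BreedingPop-class].
#' @return integer count.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname nLoci
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname nLoci
setMethod("nLoci", "GenomeMap", function(x) length(x@chromosome))

#' @rdname nLoci
setMethod("nLoci", "BreedingPop", function(x) ncol(x@hapA))

#' @rdname nLoci
setMethod("nIndividuals", "BreedingPop", function(x) nrow(x@hapA))

#' QTL indices of a genome map
#' @param x a [GenomeMap-class].
#' @return integer vector of locus indices.
#' @export
qtlIndices <- function(x) {
  stopifnot(is(x, "GenomeMap"))
  x@qtl
}

#' Genotype dosages of a population
#'
#' @param x a [BreedingPop-class].
#' @return integer matrix (individuals x loci) of 0/1/2 dosages of
#'   allele M.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
setMethod("dosages", "BreedingPop", function(x) x@hapA + x@hapB)

#' Pedigree, family labels and map of a population
#' @param x a [BreedingPop-class].
#' @return `pedigree()`: data.frame with id/sire/dam; `familyId()`:
#'   integer labels; `genomeMapOf()`: the [GenomeMap-class].
#' @export
pedigree <- function(x) {
  stopifnot(is(x, "BreedingPop"))
  x@pedigree
}

#' @rdname pedigree
#' @export
familyId <- function(x) {
  stopifnot(is(x, "BreedingPop"))
  x@family
}

#' @rdname pedigree
#' @export
genomeMapOf <- function(x) {
  stopifnot(is(x, "BreedingPop"))
  x@map
}

#' Observed allele frequencies (of allele M) in a population
#' @param x a [BreedingPop-class].
#' @return numeric vector, one frequency per locus.
#' @export
alleleFreq <- function(x) {
  stopifnot(is(x, "BreedingPop"))
  colMeans(x@hapA + x@hapB) / 2
}

#' Retained samples of an MCMC chain
#' @param x an [MCMCChain-class].
#' @return data.frame of retained scalar samples.
#' @export
chainSamples <- function(x) {
  stopifnot(is(x, "MCMCChain"))
  x@samples
}

#' Posterior-mean marker effects of a chain
#' @param x an [MCMCChain-class].
#' @return list with elements `ma` and `md`.
#' @export
markerEffects <- function(x) {
  stopifnot(is(x, "MCMCChain"))
  list(ma = x@post_mean_ma, md = x@post_mean_md)
}

setMethod("show", "GenomeMap", function(object) {
  cat(sprintf(
    "GenomeMap: %d loci on %d chromosomes (%.1f cM total), %d QTL\n",
    nLoci(object), length(unique(object@chromosome)),
    sum(tapply(object@position_cM, object@chromosome, max)),
    length(object@qtl)))
})

setMethod("show", "BreedingPop", function(object) {
  nf <- length(unique(object@family[object@family > 0L]))
  cat(sprintf(
    "BreedingPop: %d individuals x %d loci (generation %d%s)\n",
    nIndividuals(object), nLoci(object), object@generation,
    if (nf > 0) sprintf(", %d families", nf) else ""))
})

setMethod("show", "TraitArchitecture", function(object) {
  cat(sprintf(
    "TraitArchitecture (%s): %d QTL, h2 broad %.2f / narrow %.2f, sigma2_e %.3g\n",
    object@architecture, length(object@a), object@h2_broad,
    object@h2_narrow, object@sigma_e2))
})

setMethod("show", "MarkerCoding", function(object) {
  cat(sprintf(
    "MarkerCoding: %d individuals x %d loci; sum 2pq = %.3f, sum (2pq)^2 = %.3f\n",
    nrow(object@W), ncol(object@W), object@sum2pq, object@sum2pq_sq))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %s [%s], df1 = %g, df2 = %g, %d iterations (burn-in %d, thin %d)\n",
    object@method, object@prior_family, object@df1, object@df2,
    object@n_iter, object@burn_in, object@thin))
})

setMethod("show", "MCMCChain", function(object) {
  s <- object@samples
  cat(sprintf(
    "MCMCChain (%s): %d retained samples\n  posterior means: h2a %.3f, h2d %.3f, Vd/Va %.3f\n",
    object@config@method, nrow(s), mean(s$h2a), mean(s$h2d),
    mean(s$vd_va)))
})
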