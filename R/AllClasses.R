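## Central S4 containers.  Haplotypes are stored as two binary matrices
## (one per gamete) so that dosages, gamete sampling and LD estimation are
## all plain matrix operations.

#' GenomeMap: chromosome layout and QTL assignment
#'
#' Describes a diploid genome as a set of equally sized chromosomes
#' carrying equidistant biallelic loci, a subset of which are causal
#' (QTL).  Distances are in centimorgans.
#'
#' @slot chromosome integer vector, chromosome index per locus.
#' @slot position_cM numeric vector, map position of each locus within its
#'   chromosome (cM).
#' @slot qtl integer indices of the causal loci.
#'
#' @exportClass GenomeMap
setClass("GenomeMap",
  representation(
    chromosome = "integer",
    position_cM = "numeric",
    qtl = "integer"
  )
)

setValidity("GenomeMap", function(object) {
  n <- length(object@chromosome)
  if (n == 0L) return("map has no loci")
  if (length(object@position_cM) != n)
    return("chromosome and position_cM lengths differ")
  if (any(object@qtl < 1L | object@qtl > n))
    return("qtl indices out of range")
  if (anyDuplicated(object@qtl)) return("duplicated qtl indices")
  ## positions must be non-decreasing within chromosome
  for (ch in unique(object@chromosome)) {
    pos <- object@position_cM[object@chromosome == ch]
    if (is.unsorted(pos)) return("positions not sorted within chromosome")
  }
  TRUE
})

#' FounderSpec: allele frequencies of the two parental populations
#'
#' The two founder populations are each in linkage equilibrium; linkage
#' disequilibrium in the composite arises solely from their allele
#' frequency divergence.
#'
#' @slot p1 numeric, frequency of allele M per locus in parental
#'   population 1.
#' @slot p2 numeric, frequency of allele M per locus in parental
#'   population 2.
#' @slot ne_target numeric(1), intended effective population size of the
#'   genotyped cohort's parent pool (reported, not enforced).
#'
#' @exportClass FounderSpec
setClass("FounderSpec",
  representation(p1 = "numeric", p2 = "numeric", ne_target = "numeric")
)

setValidity("FounderSpec", function(object) {
  if (length(object@p1) != length(object@p2))
    return("p1 and p2 lengths differ")
  if (any(object@p1 <= 0 | object@p1 >= 1) ||
      any(object@p2 <= 0 | object@p2 >= 1))
    return("founder frequencies must lie strictly in (0, 1)")
  TRUE
})

#' BreedingPop: a diploid population with phased haplotypes
#'
#' @slot hapA,hapB integer matrices (individuals x loci) of 0/1 allele
#'   codes; the dosage of allele M is `hapA + hapB`.
#' @slot map the [GenomeMap-class] the haplotypes are defined over.
#' @slot pedigree data.frame with columns `id`, `sire`, `dam` (0 denotes
#'   an unknown/founder parent).
#' @slot family integer family label per individual (0 when unstructured).
#' @slot generation integer(1), generation index of the population.
#'
#' @exportClass BreedingPop
setClass("BreedingPop",
  representation(
    hapA = "matrix",
    hapB = "matrix",
    map = "GenomeMap",
    pedigree = "data.frame",
    family = "integer",
    generation = "integer"
  )
)

setValidity("BreedingPop", function(object) {
  n <- nrow(object@hapA)
  if (!identical(dim(object@hapA), dim(object@hapB)))
    return("hapA and hapB dimensions differ")
  if (ncol(object@hapA) != length(object@map@chromosome))
    return("haplotype loci do not match the genome map")
  if (!all(object@hapA %in% c(0L, 1L)) || !all(object@hapB %in% c(0L, 1L)))
    return("haplotype entries must be 0/1")
  if (length(object@family) != n)
    return("family labels do not match individuals")
  if (nrow(object@pedigree) != n)
    return("pedigree rows do not match individuals")
  TRUE
})

#' TraitArchitecture: QTL effects and trait design parameters
#'
#' Holds the per-QTL homozygote effects `a` and heterozygote effects `d`
#' (classical genotypic-value scale: MM -> +a, Mm -> d, mm -> -a), the
#' population mean, the residual variance chosen to hit the broad-sense
#' heritability target, and bookkeeping about the architecture.
#'
#' @slot architecture character(1), "infinitesimal" or "major_genes".
#' @slot a,d numeric per-QTL effects.
#' @slot mean_m numeric(1), trait mean parameter.
#' @slot sigma_e2 numeric(1), residual variance.
#' @slot h2_broad,h2_narrow numeric(1) heritability targets.
#' @slot var_a,var_d,var_g numeric(1) realized additive, dominance and
#'   total genetic variances in the calibration cohort.
#' @slot major_idx integer indices (into the QTL set) of major genes.
#' @slot qtl integer locus indices of the QTL (copied from the map).
#'
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(
    architecture = "character",
    a = "numeric",
    d = "numeric",
    mean_m = "numeric",
    sigma_e2 = "numeric",
    h2_broad = "numeric",
    h2_narrow = "numeric",
    var_a = "numeric",
    var_d = "numeric",
    var_g = "numeric",
    major_idx = "integer",
    qtl = "integer"
  )
)

setValidity("TraitArchitecture", function(object) {
  if (!object@architecture %in% c("infinitesimal", "major_genes"))
    return("unknown architecture")
  if (length(object@a) != length(object@d))
    return("a and d lengths differ")
  if (length(object@qtl) != length(object@a))
    return("qtl indices do not match effects")
  if (object@sigma_e2 < 0) return("sigma_e2 must be non-negative")
  TRUE
})

#' MarkerCoding: W/S incidence matrices and allele frequencies
#'
#' Additive codes per locus are MM -> 2q, Mm -> q - p, mm -> -2p and
#' dominance codes MM -> -2q^2, Mm -> 2pq, mm -> -2p^2, where p is the
#' frequency of allele M and q = 1 - p.
#'
#' @slot W numeric matrix of additive codes (individuals x loci).
#' @slot S numeric matrix of dominance codes.
#' @slot p numeric allele frequencies used for the coding.
#' @slot sum2pq numeric(1), the additive scaling constant sum(2 p q).
#' @slot sum2pq_sq numeric(1), the dominance scaling constant
#'   sum((2 p q)^2).
#'
#' @exportClass MarkerCoding
setClass("MarkerCoding",
  representation(
    W = "matrix",
    S = "matrix",
    p = "numeric",
    sum2pq = "numeric",
    sum2pq_sq = "numeric"
  )
)

setValidity("MarkerCoding", function(object) {
  if (!identical(dim(object@W), dim(object@S)))
    return("W and S dimensions differ")
  if (ncol(object@W) != length(object@p))
    return("frequency vector does not match loci")
  if (any(object@p <= 0 | object@p >= 1))
    return("allele frequencies must lie strictly in (0, 1)")
  TRUE
})

#' ModelConfig: estimation method and MCMC controls
#'
#' @slot method character(1), one of the names in [gsMethods()].
#' @slot df1 numeric(1), prior degrees of freedom of the scaled inverse
#'   chi-square for the residual variance (-2 = flat).
#' @slot df2 numeric(1), prior degrees of freedom for the marker-variance
#'   / shrinkage hyperparameter (-2 = flat).
#' @slot prior_family character(1): "normal-homogeneous", "laplace",
#'   "student-t" or "fixed-heterogeneous".
#' @slot n_iter,burn_in,thin integer MCMC controls.
#' @slot h2a0,h2d0 numeric(1) prior guesses used to anchor the prior
#'   scales from the phenotypic variance.
#'
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    method = "character",
    df1 = "numeric",
    df2 = "numeric",
    prior_family = "character",
    n_iter = "integer",
    burn_in = "integer",
    thin = "integer",
    h2a0 = "numeric",
    h2d0 = "numeric"
  )
)

setValidity("ModelConfig", function(object) {
  if (object@n_iter <= object@burn_in)
    return("n_iter must exceed burn_in")
  if (object@thin < 1L) return("thin must be >= 1")
  if (!object@prior_family %in%
      c("normal-homogeneous", "laplace", "student-t", "fixed-heterogeneous"))
    return("unknown prior_family")
  TRUE
})

#' MCMCChain: retained Gibbs samples and posterior-mean effects
#'
#' @slot samples data.frame of retained scalar samples per kept iteration:
#'   `mu`, `sigma2_e`, `sigma2_a`, `sigma2_d`, `h2a`, `h2d`, `vd_va`.
#' @slot post_mean_ma,post_mean_md numeric posterior-mean marker effects.
#' @slot post_mean_tau2a,post_mean_tau2d numeric posterior means of the
#'   per-locus (or common) marker-effect variances.
#' @slot config the [ModelConfig-class] used.
#' @slot effects optional matrix of retained additive-effect samples
#'   (kept only when requested; columns = loci).
#'
#' @exportClass MCMCChain
setClass("MCMCChain",
  representation(
    samples = "data.frame",
    post_mean_ma = "numeric",
    post_mean_md = "numeric",
    post_mean_tau2a = "numeric",
    post_mean_tau2d = "numeric",
    config = "ModelConfig",
    effects = "matrix"
  )
)

setValidity("MCMCChain", function(object) {
  need <- c("mu", "sigma2_e", "sigma2_a", "sigma2_d", "h2a", "h2d", "vd_va")
  if (!all(need %in% names(object@samples)))
    return("samples is missing required columns")
  if (nrow(object@samples) < 1L) return("empty chain")
  TRUE
})
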