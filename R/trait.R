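## Trait architectures, genotypic values and phenotypes.
##
## Genotypic-value scale per QTL: MM -> +a, Mm -> d, mm -> -a, plus a
## per-locus mean m.  Breeding values use the allele-substitution effect
## alpha = a + (q - p) d and the additive codes; dominance deviations use
## the dominance codes, both evaluated at the cohort allele frequencies.

qtlDosages <- function(pop, qtl) (pop@hapA + pop@hapB)[, qtl, drop = FALSE]

## per-individual genotypic values given dosages (0/1/2) and effects
genotypicValues <- function(dos, a, d, mean_m) {
  ## value = m + a*(dos - 1) for homozygotes, m + d for heterozygotes
  het <- dos == 1L
  v <- sweep(sweep(dos - 1, 2, a, "*"), 2, mean_m, "+")
  v[het] <- (rep(d, each = nrow(dos)) + mean_m)[het]
  rowSums(v)
}

#' True genetic values of a cohort under a trait architecture
#'
#' Computes per-individual genotypic values `g`, breeding values `u_a`
#' (additive codes times allele-substitution effects
#' `alpha = a + (q - p) d`) and dominance deviations `u_d` (dominance
#' codes times `d`), using the observed cohort allele frequencies at the
#' QTL.
#'
#' @param pop a [BreedingPop-class].
#' @param trait a [TraitArchitecture-class].
#' @return list with numeric vectors `u_a`, `u_d`, `g` and the
#'   substitution effects `alpha`.
#' @export
trueValues <- function(pop, trait) {
  dos <- qtlDosages(pop, trait@qtl)
  p <- colMeans(dos) / 2
  ## QTL fixed in this cohort contribute nothing to the deviations
  seg <- p > 0 & p < 1
  q <- 1 - p
  alpha <- (trait@a + (q - p) * trait@d)[seg]
  Wq <- codeAdditive(dos[, seg, drop = FALSE], p[seg])
  Sq <- codeDominance(dos[, seg, drop = FALSE], p[seg])
  list(u_a = drop(Wq %*% alpha),
       u_d = drop(Sq %*% trait@d[seg]),
       g = genotypicValues(dos, trait@a, trait@d, trait@mean_m),
       alpha = alpha)
}

#' Assign QTL effects calibrated to heritability targets
#'
#' Draws additive QTL effects from a zero-mean normal and dominance
#' effects from the same distribution (with a configurable fraction of
#' positive dominance directions), then calibrates on the realized
#' cohort:
#' * for the `"major_genes"` architecture, five designated QTL are
#'   rescaled until they account for 50% of the genetic variance;
#' * the dominance effects are globally rescaled until the ratio of
#'   total genetic to additive variance matches `h2_broad / h2_narrow`;
#' * the residual variance is set from the realized genetic variance so
#'   that the broad-sense heritability hits its target exactly.
#'
#' Because additive effects have magnitude comparable to dominance
#' effects, the mean degree of dominance |d/a| is about 1 (complete
#' dominance on average).
#'
#' @param pop the genotyped [BreedingPop-class] used for calibration.
#' @param architecture `"infinitesimal"` or `"major_genes"`.
#' @param h2_broad,h2_narrow target heritabilities
#'   (`0 < h2_narrow < h2_broad < 1`).
#' @param dominance_positive fraction of QTL with positive dominance
#'   direction.
#' @param mean_m per-QTL mean on the genotypic-value scale.
#' @param n_major number of major genes (architecture `"major_genes"`).
#' @param major_share genetic-variance share of the major genes.
#' @param seed RNG seed for the effect draws.
#' @return a [TraitArchitecture-class].
#' @export
assignTrait <- function(pop, architecture = c("infinitesimal", "major_genes"),
                        h2_broad = 0.30, h2_narrow = 0.20,
                        dominance_positive = 0.7, mean_m = 1,
                        n_major = 5, major_share = 0.5, seed = NULL) {
  architecture <- match.arg(architecture)
  if (!(h2_narrow > 0 && h2_broad > h2_narrow && h2_broad < 1))
    stop("need 0 < h2_narrow < h2_broad < 1")
  if (!is.null(seed)) set.seed(seed)
  qtl <- qtlIndices(pop@map)
  n_qtl <- length(qtl)
  a <- rnorm(n_qtl)
  d <- abs(rnorm(n_qtl)) * ifelse(runif(n_qtl) < dominance_positive, 1, -1)
  dos <- qtlDosages(pop, qtl)
  p <- colMeans(dos) / 2
  major_idx <- integer(0)
  if (architecture == "major_genes")
    major_idx <- sort(sample.int(n_qtl, n_major))

  varParts <- function(a, d) {
    q <- 1 - p
    alpha <- a + (q - p) * d
    u_a <- drop(codeAdditive(dos, p) %*% alpha)
    u_d <- drop(codeDominance(dos, p) %*% d)
    g <- genotypicValues(dos, a, d, mean_m)
    c(va = var(u_a), vg = var(g))
  }

  scale_d <- function(a, d) {
    target <- h2_broad / h2_narrow
    f <- function(logk) {
      v <- varParts(a, d * exp(logk))
      v["vg"] / v["va"] - target
    }
    exp(uniroot(f, c(-8, 8), tol = 1e-10)$root)
  }

  for (pass in 1:4) {
    if (length(major_idx)) {
      ## per-locus genetic-variance contributions (HWE approximation)
      q <- 1 - p
      alpha <- a + (q - p) * d
      contrib <- 2 * p * q * alpha^2 + (2 * p * q * d)^2
      share <- sum(contrib[major_idx]) / sum(contrib)
      ratio <- (major_share / (1 - major_share)) *
        (sum(contrib[-major_idx]) / sum(contrib[major_idx]))
      f <- sqrt(ratio)
      a[major_idx] <- a[major_idx] * f
      d[major_idx] <- d[major_idx] * f
    }
    k <- scale_d(a, d)
    d <- d * k
    if (!length(major_idx)) break
  }

  v <- varParts(a, d)
  sigma_e2 <- unname(v["vg"] * (1 - h2_broad) / h2_broad)
  new("TraitArchitecture", architecture = architecture, a = a, d = d,
      mean_m = mean_m, sigma_e2 = sigma_e2, h2_broad = h2_broad,
      h2_narrow = h2_narrow, var_a = unname(v["va"]),
      var_d = unname(v["vg"] - v["va"]), var_g = unname(v["vg"]),
      major_idx = major_idx, qtl = qtl)
}

#' Simulate phenotypes from a trait architecture
#'
#' Adds an independent normal residual with variance `sigma_e2` to each
#' individual's genotypic value.
#'
#' @param pop a [BreedingPop-class].
#' @param trait a [TraitArchitecture-class].
#' @param seed RNG seed for the residual draws.
#' @return numeric phenotype vector.
#' @export
simulatePhenotypes <- function(pop, trait, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genotypicValues(qtlDosages(pop, trait@qtl), trait@a, trait@d,
                       trait@mean_m)
  g + rnorm(length(g), 0, sqrt(trait@sigma_e2))
}

#' Genotypic-value bounds of an architecture
#'
#' The extreme complete homozygotes span
#' `[sum(m - |a|), sum(m + |a|)]`; with `n_qtl` loci of common mean `m`
#' this is the classical `n_qtl * (m -/+ a)` envelope.
#'
#' @param trait a [TraitArchitecture-class].
#' @return named numeric vector `c(gmin, gmax)`.
#' @export
genotypicBounds <- function(trait) {
  n <- length(trait@a)
  c(gmin = n * trait@mean_m - sum(abs(trait@a)),
    gmax = n * trait@mean_m + sum(abs(trait@a)))
}

#' Realized heritabilities of a simulated trait
#'
#' Parametric (calibration-cohort) heritabilities implied by the realized
#' genetic variances and the residual variance.
#'
#' @param trait a [TraitArchitecture-class].
#' @return named vector with `h2_broad`, `h2_narrow`, `vd_va`.
#' @export
realizedHeritability <- function(trait) {
  vp <- trait@var_g + trait@sigma_e2
  c(h2_broad = trait@var_g / vp, h2_narrow = trait@var_a / vp,
    vd_va = trait@var_d / trait@var_a)
}
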