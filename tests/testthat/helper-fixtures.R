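# Shared fixtures, generated in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## a small two-chromosome genome
smallMap <- function(spacing = 0.5, n_qtl = 8)
  genomeMap(n_chromosomes = 2, chrom_length_cM = 20,
            spacing_cM = spacing, n_qtl = n_qtl)

## a small but complete replicate: 5 families x 20, 80 markers, 8 QTL
smallReplicate <- function() {
  cached("small_rep",
    simulateReplicate(map = smallMap(), n_families = 5, family_size = 20,
                      pop_size = 400, seed = 11))
}

## construct a BreedingPop directly from haplotype matrices
popFromHaps <- function(hapA, hapB, map) {
  storage.mode(hapA) <- "integer"
  storage.mode(hapB) <- "integer"
  new("BreedingPop", hapA = hapA, hapB = hapB, map = map,
      pedigree = data.frame(id = seq_len(nrow(hapA)), sire = 0L,
                            dam = 0L),
      family = integer(nrow(hapA)), generation = 0L)
}

## independent REML log-likelihood used as a brute-force oracle
oracleLogLik <- function(y, X, Klist, sigma2) {
  n <- length(y)
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(Klist)) V <- V + sigma2[k] * Klist[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V)$modulus +
                     determinant(XtViX)$modulus + t(r) %*% Vi %*% r))
}

## printed scenario-1 comparison table used for criteria-scoring checks
## (methods x h2a, h2d, cor_a, by_a, cor_d, by_d, vd_va)
scenario1PrintedReport <- function() {
  data.frame(
    method = c("BRR(-2,-2)", "IBLASSO(4,-2)", "IBLASSO(4,2)",
               "BAYESA*B*(-2,6)", "BAYESA*B*(4,6)", "BAYESA*B*(-2,8)",
               "RR-HET(-2,-2)", "BLASSO(4,2)", "G-BLUP",
               "Pedigree-BLUP"),
    h2a = c(0.15, 0.12, 0.14, 0.15, 0.15, 0.15, 0.11, 0.17, 0.15, 0.16),
    h2d = c(0.12, 0.14, 0.10, 0.10, 0.10, 0.09, 0.14, 0.13, 0.13, 0.07),
    cor_a = c(0.63, 0.62, 0.63, 0.63, 0.63, 0.63, 0.62, 0.63, 0.63,
              0.53),
    by_a = c(1.40, 2.41, 1.86, 1.51, 1.49, 1.44, 2.43, 1.44, 1.25,
             0.96),
    cor_d = c(0.31, 0.28, 0.29, 0.29, 0.29, 0.29, 0.28, 0.29, 0.31,
              0.05),
    by_d = c(0.57, 0.46, 0.63, 0.69, 0.71, 0.72, 0.44, 3.20, 0.70,
             0.20),
    vd_va = c(0.77, 1.19, 0.81, 0.67, 0.65, 0.61, 1.24, 0.74, 0.83, NA)
  )
}

scenario1Parametric <- function() list(h2a = 0.21, h2d = 0.10, vd_va = 0.48)
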