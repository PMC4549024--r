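## Unified MCMC machinery for the eight Bayesian shrinkage methods plus
## the registry of all ten fitted methods.

.METHOD_TABLE <- data.frame(
  method = c("BRR(-2,-2)", "IBLASSO(4,-2)", "IBLASSO(4,2)",
             "BAYESA*B*(-2,6)", "BAYESA*B*(4,6)", "BAYESA*B*(-2,8)",
             "RR-HET(-2,-2)", "BLASSO(4,2)", "G-BLUP", "Pedigree-BLUP"),
  class = c("mcmc", "mcmc", "mcmc", "mcmc", "mcmc", "mcmc", "mcmc",
            "mcmc", "reml", "reml"),
  prior_family = c("normal-homogeneous", "laplace", "laplace",
                   "student-t", "student-t", "student-t",
                   "fixed-heterogeneous", "laplace", NA, NA),
  df1 = c(-2, 4, 4, -2, 4, -2, -2, 4, NA, NA),
  df2 = c(-2, -2, 2, 6, 6, 8, -2, 2, NA, NA),
  stringsAsFactors = FALSE
)

#' Registry of fitted methods
#'
#' The ten estimation methods: Bayesian Ridge Regression, two improved
#' Bayesian Lasso variants, three Student-t Lasso (BayesA*B*) variants,
#' ridge regression with fixed heterogeneous marker variances, the
#' classical Bayesian Lasso, G-BLUP via REML, and pedigree BLUP.  The
#' two numbers in an MCMC method's name are the prior degrees of freedom
#' (df1 for the residual variance, df2 for the marker-variance /
#' shrinkage hyperparameter); -2 makes the scaled inverse chi-square
#' flat.
#'
#' @return data.frame with columns `method`, `class`, `prior_family`,
#'   `df1`, `df2`.
#' @export
gsMethods <- function() .METHOD_TABLE

#' Effective marker-effect prior of a method
#'
#' @param method a method name from [gsMethods()].
#' @return list with `prior_family`, `df1`, `df2`, `class` and a short
#'   `description` of the marginal prior on marker effects.
#' @export
priorFor <- function(method) {
  row <- .METHOD_TABLE[.METHOD_TABLE$method == method, ]
  if (nrow(row) == 0)
    stop("unknown method '", method, "'; see gsMethods()")
  desc <- switch(row$class,
    reml = "normal (relationship-matrix BLUP)",
    switch(row$prior_family,
      "normal-homogeneous" = "normal with a common marker variance",
      "laplace" = "double exponential via an exponential scale mixture",
      "student-t" = sprintf(
        "Student-t with %g degrees of freedom (scaled-inv-chi2 locus variances)",
        row$df2),
      "fixed-heterogeneous" =
        "normal with fixed per-locus variances supplied externally"))
  list(method = row$method, class = row$class,
       prior_family = row$prior_family, df1 = row$df1, df2 = row$df2,
       description = desc)
}

#' Construct a model configuration
#'
#' @param method method name (see [gsMethods()]).
#' @param n_iter,burn_in,thin MCMC controls (defaults 120000 / 20000 /
#'   10, retaining 10,000 samples).
#' @param h2a0,h2d0 optional fixed heritability splits anchoring the
#'   prior scales; the default `NA` estimates the genetic variances from
#'   the data by Haseman-Elston regression on the genomic relationships.
#' @return a [ModelConfig-class].
#' @export
modelConfig <- function(method = "BAYESA*B*(-2,8)", n_iter = 120000,
                        burn_in = 20000, thin = 10, h2a0 = NA_real_,
                        h2d0 = NA_real_) {
  pf <- priorFor(method)
  if (pf$class != "mcmc")
    stop("'", method, "' is not an MCMC method")
  new("ModelConfig", method = pf$method, df1 = pf$df1, df2 = pf$df2,
      prior_family = pf$prior_family, n_iter = as.integer(n_iter),
      burn_in = as.integer(burn_in), thin = as.integer(thin),
      h2a0 = h2a0, h2d0 = h2d0)
}

familyCode <- function(fam) {
  match(fam, c("normal-homogeneous", "laplace", "student-t",
               "fixed-heterogeneous")) - 1L
}

## Prior scales: anchor the prior mean of the locus variance at a
## method-of-moments estimate of the genetic variances divided by the
## coding constants (sigma2_a / sum(2pq), dominance analogue).  The
## default estimate is a Haseman-Elston regression of phenotype
## cross-products on the genomic relationships, floored at a small
## fraction of var(y); fixed heritability splits h2a0/h2d0 can override
## it.  For a scaled-inv-chi2(nu, S2) the prior mean is nu*S2/(nu-2),
## hence the (nu-2)/nu correction for nu > 2.
priorScales <- function(y, coding, config) {
  vy <- var(y)
  if (is.na(config@h2a0) || is.na(config@h2d0)) {
    Ga <- buildGa(coding)
    Gd <- buildGd(coding)
    yc <- y - mean(y)
    cp <- tcrossprod(yc)
    off <- upper.tri(Ga)
    Xhe <- cbind(Ga[off], Gd[off])
    b <- tryCatch(drop(solve(crossprod(Xhe), crossprod(Xhe, cp[off]))),
                  error = function(e) c(NA_real_, NA_real_))
    s2a_mom <- if (is.na(config@h2a0))
      min(max(b[1], 0.02 * vy, na.rm = TRUE), 0.9 * vy)
    else config@h2a0 * vy
    s2d_mom <- if (is.na(config@h2d0))
      min(max(b[2], 0.01 * vy, na.rm = TRUE), 0.9 * vy)
    else config@h2d0 * vy
  } else {
    s2a_mom <- config@h2a0 * vy
    s2d_mom <- config@h2d0 * vy
  }
  s2ma <- s2a_mom / max(coding@sum2pq, 1e-12)
  s2md <- s2d_mom / max(coding@sum2pq_sq, 1e-12)
  adj <- if (config@df2 > 2) (config@df2 - 2) / config@df2 else 1
  s2e <- max(vy - s2a_mom - s2d_mom, 0.05 * vy)
  list(S2ma = s2ma * adj, S2md = s2md * adj, S2e = s2e)
}

#' Run the Gibbs sampler for an MCMC method
#'
#' Fits the additive-dominance marker model
#' `y = 1 mu + W m_a + S m_d + e` by site-by-site Gibbs sampling (fixed
#' locus order), with the marker-effect prior implied by the method (see
#' [priorFor()]).  Reproducible through `seed`.
#'
#' @param y phenotype vector.
#' @param coding a [MarkerCoding-class] aligned with `y`.
#' @param config a [ModelConfig-class].
#' @param tau2a,tau2d fixed per-locus variances, required for the
#'   `fixed-heterogeneous` family (see [rrHetVariances()]).
#' @param use_dominance fit the dominance term (default TRUE).
#' @param keep_effects retain per-iteration additive-effect samples
#'   (memory-heavy; only for small problems).
#' @param seed RNG seed.
#' @return an [MCMCChain-class].
#' @export
gibbsRun <- function(y, coding, config = modelConfig(), tau2a = NULL,
                     tau2d = NULL, use_dominance = TRUE,
                     keep_effects = FALSE, seed = NULL) {
  stopifnot(is(coding, "MarkerCoding"))
  if (length(y) != nrow(coding@W))
    stop("phenotypes and coding have different numbers of individuals")
  fam <- familyCode(config@prior_family)
  m <- ncol(coding@W)
  if (config@prior_family == "fixed-heterogeneous") {
    if (is.null(tau2a) || is.null(tau2d))
      stop("fixed-heterogeneous prior requires tau2a and tau2d")
    if (length(tau2a) != m || length(tau2d) != m)
      stop("fixed variance vectors do not match the number of loci")
  } else {
    tau2a <- tau2d <- numeric(m)
  }
  if (!is.null(seed)) set.seed(seed)
  sc <- priorScales(y, coding, config)
  twopq <- 2 * coding@p * (1 - coding@p)
  res <- cpp_gibbs(y, coding@W, coding@S, fam, fam, config@df1,
                   config@df2, sc$S2e, sc$S2ma, sc$S2md, tau2a, tau2d,
                   twopq, twopq^2, config@n_iter, config@burn_in,
                   config@thin, use_dominance, keep_effects)
  samples <- as.data.frame(res$samples)
  names(samples) <- c("mu", "sigma2_e", "sigma2_a", "sigma2_d", "h2a",
                      "h2d", "vd_va")
  new("MCMCChain", samples = samples, post_mean_ma = res$post_mean_ma,
      post_mean_md = res$post_mean_md,
      post_mean_tau2a = res$post_mean_tau2a,
      post_mean_tau2d = res$post_mean_tau2d, config = config,
      effects = res$effects)
}

#' Per-locus variances for the fixed-heterogeneity ridge
#'
#' The RR-HET method runs ridge regression with marker-specific
#' variances taken as the posterior means of the per-locus variances of
#' a previous IBLASSO(4,-2) fit on the same data.
#'
#' @param source_chain an [MCMCChain-class] from `IBLASSO(4,-2)`.
#' @param n_loci expected locus count (for a consistency check).
#' @return list with `tau2a` and `tau2d` vectors.
#' @export
rrHetVariances <- function(source_chain, n_loci = NULL) {
  stopifnot(is(source_chain, "MCMCChain"))
  t2a <- source_chain@post_mean_tau2a
  t2d <- source_chain@post_mean_tau2d
  if (!is.null(n_loci) && length(t2a) != n_loci)
    stop("locus count of the source chain does not match")
  list(tau2a = t2a, tau2d = t2d)
}

#' Geweke convergence diagnostic
#'
#' Compares the means of an early and a late chain segment with a
#' spectral-density estimate of the variance at frequency zero (AR-fit
#' estimator), returning a standard normal z-score per parameter.
#'
#' @param chain an [MCMCChain-class], data.frame or numeric vector.
#' @param first,last fractions of the chain used for the early and late
#'   segments.
#' @return named numeric vector of z-scores.
#' @export
geweke <- function(chain, first = 0.1, last = 0.5) {
  x <- if (is(chain, "MCMCChain")) chain@samples
       else if (is.numeric(chain)) data.frame(x = chain)
       else as.data.frame(chain)
  n <- nrow(x)
  if (n < 100) stop("chain too short for the diagnostic")
  i1 <- seq_len(floor(first * n))
  i2 <- seq(n - floor(last * n) + 1L, n)
  spec0 <- function(v) {
    if (sd(v) == 0) stop("degenerate (constant) chain segment")
    fit <- ar(v, aic = TRUE, order.max = min(20, length(v) - 1))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  vapply(names(x), function(nm) {
    v <- x[[nm]]
    if (sd(v) == 0) stop("degenerate (constant) chain for '", nm, "'")
    (mean(v[i1]) - mean(v[i2])) /
      sqrt(spec0(v[i1]) / length(i1) + spec0(v[i2]) / length(i2))
  }, numeric(1))
}

#' Posterior summary of a chain
#'
#' Posterior means and standard deviations of the variance components
#' and heritabilities, plus point predictions from the posterior-mean
#' marker effects.
#'
#' @param chain an [MCMCChain-class].
#' @param coding optional [MarkerCoding-class]; when supplied the fitted
#'   genetic values `ua = W m_a`, `ud = S m_d` are returned.
#' @return list with `mean` and `sd` (named vectors over the scalar
#'   samples) and, when `coding` is given, `ua`, `ud`, `ghat`.
#' @export
posteriorSummary <- function(chain, coding = NULL) {
  s <- chain@samples
  out <- list(mean = vapply(s, mean, numeric(1)),
              sd = vapply(s, sd, numeric(1)))
  if (!is.null(coding)) {
    out$ua <- drop(coding@W %*% chain@post_mean_ma)
    out$ud <- if (length(chain@post_mean_md))
      drop(coding@S %*% chain@post_mean_md) else numeric(nrow(coding@W))
    out$ghat <- out$ua + out$ud
  }
  out
}
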