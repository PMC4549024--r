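## Deterministic accuracy formulas, empirical accuracy/bias, the
## training/validation protocol and criteria scoring.

#' Deterministic (parametric) prediction accuracies
#'
#' Expected accuracy of genomic prediction given the training size `N`,
#' the number of QTL, the proportion `r2_mq` of genetic variance
#' captured by markers and the heritabilities:
#' \deqn{r_{a\hat a} = \sqrt{\frac{r^2_{mq} (N r^2_{mq} h^2_a / n_{QTL})}
#'   {1 + N r^2_{mq} h^2_g / n_{QTL}}}}
#' with the dominance version substituting \eqn{h^2_d} in the numerator,
#' and the genotypic accuracy combining both in quadrature.
#'
#' @param N training population size.
#' @param n_qtl number of QTL (> 0).
#' @param r2_mq marker-capture proportion (see [markerCaptureRatio()]).
#' @param h2a,h2d,h2g additive, dominance and total heritability.
#' @return the expected accuracy.
#' @examples
#' parametricAccuracyAdditive(1000, 100, 0.93, 0.20, 0.30)   # ~0.68
#' parametricAccuracyDominance(1000, 100, 0.93, 0.10, 0.30)  # ~0.48
#' @export
parametricAccuracyAdditive <- function(N, n_qtl, r2_mq, h2a, h2g) {
  if (n_qtl <= 0) stop("n_qtl must be positive")
  sqrt(r2_mq * (N * r2_mq * h2a / n_qtl) / (1 + N * r2_mq * h2g / n_qtl))
}

#' @rdname parametricAccuracyAdditive
#' @export
parametricAccuracyDominance <- function(N, n_qtl, r2_mq, h2d, h2g) {
  if (n_qtl <= 0) stop("n_qtl must be positive")
  sqrt(r2_mq * (N * r2_mq * h2d / n_qtl) / (1 + N * r2_mq * h2g / n_qtl))
}

#' @rdname parametricAccuracyAdditive
#' @param ra,rd additive and dominance accuracies in `[0, 1]` with
#'   `ra^2 + rd^2 <= 1`.
#' @export
parametricAccuracyGenotypic <- function(ra, rd) {
  if (any(ra < 0 | ra > 1 | rd < 0 | rd > 1))
    stop("accuracies must lie in [0, 1]")
  if (any(ra^2 + rd^2 > 1 + 1e-12))
    stop("ra^2 + rd^2 exceeds 1")
  sqrt(ra^2 + rd^2)
}

#' Empirical accuracy and bias
#'
#' Pearson correlation between predicted and true genetic values
#' (accuracy) and the ordinary least-squares slope of true on predicted
#' (bias; 1 = unbiased prediction).
#'
#' @param predicted,true equal-length numeric vectors with non-zero
#'   variance.
#' @return named vector `c(cor, by)`.
#' @export
empiricalAccuracyBias <- function(predicted, true) {
  if (length(predicted) != length(true))
    stop("vectors must have equal length")
  if (sd(predicted) == 0 || sd(true) == 0)
    stop("zero-variance input")
  c(cor = cor(predicted, true),
    by = unname(coef(lm(true ~ predicted))[2]))
}

## Fit one method on a training replicate and return marker effects plus
## heritability estimates.  REML methods back out marker effects through
## the equivalent marker-level ridge model.
fitMethodOnReplicate <- function(rep, method, n_iter = 120000,
                                 burn_in = 20000, thin = 10, seed = 1) {
  pf <- priorFor(method)
  coding <- rep$coding
  y <- rep$y
  if (pf$class == "reml") {
    if (method == "Pedigree-BLUP") {
      A <- pedigreeA(pedigree(rep$pop), ids = pedigree(rep$pop)$id)
      D <- pedigreeD(pedigree(rep$pop), ids = pedigree(rep$pop)$id)
      fit <- fitREML(y, list(a = A, d = D))
      sol <- solveMME(y, list(a = A, d = D), fit$sigma2)
      return(list(method = method, class = "pedigree", h2a = fit$h2[["a"]],
                  h2d = fit$h2[["d"]], vd_va = fit$vd_va,
                  ua = sol$u$a, ud = sol$u$d,
                  ma = NULL, md = NULL, fit = fit))
    }
    Ga <- buildGa(coding)
    Gd <- buildGd(coding)
    fit <- fitREML(y, list(a = Ga, d = Gd))
    s2ma <- fit$sigma2[["a"]] / coding@sum2pq
    s2md <- fit$sigma2[["d"]] / coding@sum2pq_sq
    mr <- markerRidge(y, coding@W, coding@S, s2ma, s2md,
                      fit$sigma2[["e"]])
    return(list(method = method, class = "gblup", h2a = fit$h2[["a"]],
                h2d = fit$h2[["d"]], vd_va = fit$vd_va, ua = mr$ua,
                ud = mr$ud, ma = mr$ma, md = mr$md, fit = fit))
  }
  config <- modelConfig(method, n_iter = n_iter, burn_in = burn_in,
                        thin = thin)
  tau <- NULL
  if (pf$prior_family == "fixed-heterogeneous") {
    src_cfg <- modelConfig("IBLASSO(4,-2)", n_iter = n_iter,
                           burn_in = burn_in, thin = thin)
    src <- gibbsRun(y, coding, src_cfg, seed = seed)
    tau <- rrHetVariances(src, ncol(coding@W))
  }
  chain <- gibbsRun(y, coding, config, tau2a = tau$tau2a,
                    tau2d = tau$tau2d, seed = seed + 1)
  ps <- posteriorSummary(chain, coding)
  eff <- markerEffects(chain)
  gz <- tryCatch(max(abs(geweke(chain))), error = function(e) NA_real_)
  list(method = method, class = "mcmc", h2a = ps$mean[["h2a"]],
       h2d = ps$mean[["h2d"]], vd_va = ps$mean[["vd_va"]], ua = ps$ua,
       ud = ps$ud, ma = eff$ma, md = eff$md, chain = chain,
       geweke_max_z = gz)
}

#' Training/validation evaluation of prediction methods
#'
#' Implements the replicate-based protocol: every replicate but one is
#' used in turn as a training population; marker effects estimated there
#' are applied to the validation replicate's marker codes and correlated
#' with its true breeding values and dominance deviations.  Pedigree
#' BLUP, which carries no marker effects across populations, is
#' evaluated within each training replicate instead (its accuracy is the
#' in-population correlation between BLUPs and true values).
#'
#' @param replicates list of replicates from [simulateReplicate()]
#'   (>= 2); all must share the same marker panel size.
#' @param methods character vector of method names (see [gsMethods()]).
#' @param validation index of the validation replicate (default: last).
#' @param n_iter,burn_in,thin MCMC controls passed to the samplers.
#' @param seed base seed for the stochastic fits.
#' @return data.frame with one row per method: mean `h2a`, `h2d`,
#'   `cor_a`, `by_a`, `cor_d`, `by_d`, `vd_va` across training
#'   replicates, their standard deviations (`*_sd`), the wall time
#'   spent on the method (`seconds`) and the largest Geweke |z| across
#'   its chains (informational).
#' @export
runValidation <- function(replicates, methods = gsMethods()$method,
                          validation = length(replicates),
                          n_iter = 120000, burn_in = 20000, thin = 10,
                          seed = 1) {
  if (length(replicates) < 2) stop("need at least 2 replicates")
  m_panel <- vapply(replicates, function(r) ncol(r$coding@W), numeric(1))
  if (length(unique(m_panel)) != 1)
    stop("marker panels differ across replicates")
  val <- replicates[[validation]]
  train_idx <- setdiff(seq_along(replicates), validation)
  metric_names <- c("h2a", "h2d", "cor_a", "by_a", "cor_d", "by_d",
                    "vd_va")
  ## a fully shrunk (constant) prediction carries no information:
  ## accuracy 0, bias slope undefined
  safe_ab <- function(predicted, true) {
    if (sd(predicted) == 0 || sd(true) == 0)
      return(c(cor = 0, by = NA_real_))
    empiricalAccuracyBias(predicted, true)
  }
  rows <- lapply(methods, function(method) {
    t0 <- proc.time()[["elapsed"]]
    gz_all <- c()
    per_rep <- sapply(train_idx, function(i) {
      fit <- fitMethodOnReplicate(replicates[[i]], method,
                                  n_iter = n_iter, burn_in = burn_in,
                                  thin = thin, seed = seed + 97 * i)
      if (fit$class == "pedigree") {
        pred_a <- fit$ua
        pred_d <- fit$ud
        tr <- replicates[[i]]$truth
        aa <- safe_ab(pred_a, tr$u_a)
        dd <- safe_ab(pred_d, tr$u_d)
      } else {
        pred_a <- drop(val$coding@W %*% fit$ma)
        pred_d <- drop(val$coding@S %*% fit$md)
        aa <- safe_ab(pred_a, val$truth$u_a)
        dd <- safe_ab(pred_d, val$truth$u_d)
      }
      gz_all <<- c(gz_all, fit$geweke_max_z)
      c(h2a = fit$h2a, h2d = fit$h2d, cor_a = unname(aa["cor"]),
        by_a = unname(aa["by"]), cor_d = unname(dd["cor"]),
        by_d = unname(dd["by"]), vd_va = fit$vd_va)
    })
    means <- rowMeans(per_rep)
    sds <- apply(per_rep, 1, sd)
    out <- c(means, setNames(sds, paste0(metric_names, "_sd")))
    c(list(method = method), as.list(out),
      list(seconds = round(proc.time()[["elapsed"]] - t0, 2),
           geweke_max_z = if (length(gz_all)) max(gz_all) else NA_real_))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Score methods on the "number of best criteria" rule
#'
#' Applies the comparison rule used to rank methods across seven
#' criteria: heritabilities and the Vd/Va ratio are "best" when within
#' 0.02 of the method closest to the parametric value; accuracies when
#' within 0.02 of the highest; bias slopes when inside `[0.5, 1.5]`.
#' Missing entries never score.
#'
#' @param report data.frame with columns `method`, `h2a`, `h2d`,
#'   `cor_a`, `by_a`, `cor_d`, `by_d`, `vd_va` (as from
#'   [runValidation()]).
#' @param parametric named list/vector with the parametric `h2a`, `h2d`
#'   and `vd_va`.
#' @param tol closeness tolerance (default 0.02).
#' @param slope_range admissible bias-slope interval.
#' @return named integer vector of per-method criterion counts.
#' @export
scoreBestCriteria <- function(report, parametric, tol = 0.02,
                              slope_range = c(0.5, 1.5)) {
  parametric <- as.list(parametric)
  eps <- 1e-9  # guard against binary representation noise at 2 dp
  closest <- function(vals, target) {
    d <- abs(vals - target)
    ifelse(is.na(d), FALSE, d <= min(d, na.rm = TRUE) + tol + eps)
  }
  highest <- function(vals)
    ifelse(is.na(vals), FALSE, vals >= max(vals, na.rm = TRUE) - tol - eps)
  in_range <- function(vals)
    ifelse(is.na(vals), FALSE,
           vals >= slope_range[1] & vals <= slope_range[2])
  score <- closest(report$h2a, parametric$h2a) +
    closest(report$h2d, parametric$h2d) +
    highest(report$cor_a) + in_range(report$by_a) +
    highest(report$cor_d) + in_range(report$by_d) +
    closest(report$vd_va, parametric$vd_va)
  setNames(as.integer(score), report$method)
}
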