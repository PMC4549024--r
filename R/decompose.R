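## Decomposition of genomic heritability and accuracy into linkage
## disequilibrium (LD), co-segregation (CS) and pedigree-relationship
## information, via three phenotype datasets:
##   raw  - uncorrected phenotypes, all families together
##          (captures CS + LD + family IBD relationships);
##   AWF  - within-family deviations analysed across families
##          (captures CS + LD);
##   DMS  - within-family deviations analysed one family at a time with
##          posterior averaging (captures LD only);
## plus a pedigree fit of the raw data (CS + individual IBD
## relationships).  Heritability components separate by subtraction,
## accuracy components by quadrature.

#' Within-family phenotype deviations
#'
#' Subtracts each family's mean phenotype.  Deviations of a singleton
#' family are zero (flagged with a warning).
#'
#' @param y phenotype vector.
#' @param family_id family label per individual (>= 2 families).
#' @return numeric vector of family-corrected phenotypes.
#' @export
withinFamilyDeviations <- function(y, family_id) {
  if (length(unique(family_id)) < 2) stop("need at least 2 families")
  sizes <- table(family_id)
  if (any(sizes == 1))
    warning("singleton families have zero deviations")
  y - ave(y, family_id)
}

#' Per-family fit with posterior averaging
#'
#' Fits the model separately within each family on family-corrected
#' phenotypes and averages the resulting in-family accuracies of the
#' additive predictions (unweighted mean; family sizes are equal by
#' design).  Families smaller than `min_size` are skipped with a
#' warning.
#'
#' @param rep a replicate from [simulateReplicate()].
#' @param method method name; any entry of [gsMethods()] except
#'   Pedigree-BLUP.
#' @param min_size smallest family that is still fitted.
#' @param n_iter,burn_in,thin MCMC controls.
#' @param seed base RNG seed.
#' @return list with `accuracy` (mean over families), `h2a` (mean
#'   estimated additive heritability), `per_family` data.frame.
#' @export
perFamilyFitAverage <- function(rep, method = "BAYESA*B*(-2,8)",
                                min_size = 10, n_iter = 6000,
                                burn_in = 1000, thin = 5, seed = 1) {
  fam <- familyId(rep$pop)
  ydev <- withinFamilyDeviations(rep$y, fam)
  fams <- sort(unique(fam))
  out <- lapply(fams, function(f) {
    idx <- which(fam == f)
    if (length(idx) < min_size) {
      warning("family ", f, " smaller than ", min_size, "; skipped")
      return(NULL)
    }
    sub <- subsetReplicate(rep, idx, y = ydev[idx])
    fit <- fitMethodOnReplicate(sub, method, n_iter = n_iter,
                                burn_in = burn_in, thin = thin,
                                seed = seed + f)
    ua_true <- sub$truth$u_a
    acc <- if (sd(fit$ua) == 0 || sd(ua_true) == 0) 0 else
      cor(fit$ua, ua_true)
    data.frame(family = f, accuracy = acc, h2a = fit$h2a)
  })
  per_family <- do.call(rbind, out)
  list(accuracy = mean(per_family$accuracy),
       h2a = mean(per_family$h2a), per_family = per_family)
}

## Restrict a replicate to a subset of individuals (recoding markers at
## the subset's own frequencies; monomorphic loci are dropped).
subsetReplicate <- function(rep, idx, y = rep$y[idx]) {
  pop <- rep$pop
  hapA <- pop@hapA[idx, , drop = FALSE]
  hapB <- pop@hapB[idx, , drop = FALSE]
  dos <- hapA + hapB
  p <- colMeans(dos) / 2
  keep <- p > 0 & p < 1
  sub_pop <- newPop(hapA, hapB, pop@map,
                    pedigree = pop@pedigree[idx, , drop = FALSE],
                    family = pop@family[idx],
                    generation = pop@generation)
  coding <- markerCoding(dos[, keep, drop = FALSE])
  truth <- trueValues(sub_pop, rep$trait)
  list(pop = sub_pop, trait = rep$trait, y = y, truth = truth,
       coding = coding, keep = which(keep))
}

#' Quadrature difference of accuracies
#'
#' `sqrt(x^2 - y^2)`: the accuracy attributable to an information source
#' after removing a nested source.
#'
#' @param x,y accuracies with `x >= y >= 0`.
#' @return the component accuracy.
#' @examples
#' quadratureDifference(0.53, 0.52)  # ~0.10
#' @export
quadratureDifference <- function(x, y) {
  if (any(y < 0) || any(x < y))
    stop("need x >= y >= 0")
  sqrt(x^2 - y^2)
}

#' Accuracy of related individuals from pedigree and unrelated accuracy
#'
#' `r_related = r_ped + (1 - r_ped) * r_unrelated`.
#'
#' @param r_ped accuracy due to pedigree.
#' @param r_unrelated accuracy for unrelated individuals.
#' @return composed accuracy.
#' @examples
#' combineRelatedAccuracy(0.45, 0.52)  # 0.736
#' @export
combineRelatedAccuracy <- function(r_ped, r_unrelated) {
  if (any(r_ped < 0 | r_ped > 1 | r_unrelated < 0 | r_unrelated > 1))
    stop("accuracies must lie in [0, 1]")
  r_ped + (1 - r_ped) * r_unrelated
}

#' Assemble the information-decomposition table
#'
#' Derives the component rows from the four fitted analyses:
#' co-segregation CS = AWF - DMS, family IBD relationships
#' F-IBD-R = raw - AWF and individual IBD relationships
#' I-IBD-R = pedigree - CS, using linear differences for heritability
#' and quadrature differences for accuracy.  A negative derived
#' component is reported as 0 with a warning.  The fraction of
#' pedigree-captured information relative to LD is reported as
#' `I-IBD-R / LD` on the heritability scale.
#'
#' @param raw,awf,dms,ped lists with elements `h2a` and `accuracy` for
#'   the raw, across-family-deviation, within-family-averaged and
#'   pedigree analyses of the same cohort.
#' @param parametric_h2a the parametric additive heritability.
#' @return list with `table` (data.frame of rows: raw, AWF, DMS, CS,
#'   F-IBD-R, pedigree, I-IBD-R, parametric), `ld_fraction`
#'   (I-IBD-R h2 / LD h2) and `related_accuracy` (composed from the
#'   pedigree and DMS accuracies).
#' @export
buildDecomposition <- function(raw, awf, dms, ped, parametric_h2a) {
  clamp <- function(v, what) {
    if (v < 0) {
      warning(what, " component negative (", signif(v, 3),
              "); reported as 0")
      0
    } else v
  }
  cs_h2 <- clamp(awf$h2a - dms$h2a, "CS heritability")
  fibd_h2 <- clamp(raw$h2a - awf$h2a, "F-IBD-R heritability")
  iibd_h2 <- clamp(ped$h2a - cs_h2, "I-IBD-R heritability")
  cs_acc <- if (awf$accuracy >= dms$accuracy)
    quadratureDifference(awf$accuracy, dms$accuracy)
  else {
    warning("CS accuracy component negative; reported as 0")
    0
  }
  iibd_acc <- if (ped$accuracy >= cs_acc)
    quadratureDifference(ped$accuracy, cs_acc)
  else {
    warning("I-IBD-R accuracy component negative; reported as 0")
    0
  }
  tab <- data.frame(
    information = c("raw", "AWF", "DMS", "CS", "F-IBD-R", "pedigree",
                    "I-IBD-R", "parametric"),
    composition = c("COSEG + IBD-LD + F-IBD-R", "COSEG + LD", "LD",
                    "AWF - DMS", "raw - AWF", "COSEG + I-IBD-R",
                    "pedigree - CS", "ALL"),
    h2a = c(raw$h2a, awf$h2a, dms$h2a, cs_h2, fibd_h2, ped$h2a,
            iibd_h2, parametric_h2a),
    accuracy = c(raw$accuracy, awf$accuracy, dms$accuracy, cs_acc, NA,
                 ped$accuracy, iibd_acc, NA))
  list(table = tab,
       ld_fraction = if (dms$h2a > 0) iibd_h2 / dms$h2a else NA_real_,
       related_accuracy = combineRelatedAccuracy(ped$accuracy,
                                                 dms$accuracy))
}

#' Run the full three-dataset decomposition on a replicate
#'
#' Performs the four analyses (raw, across-family deviations, per-family
#' averaging, pedigree) with the requested method and assembles the
#' decomposition table.  In-sample accuracies (correlation of fitted
#' additive values with the true breeding values) are used throughout,
#' matching the "calculated from data" entries of the partition.
#'
#' @param rep a replicate from [simulateReplicate()].
#' @param method method used for the genomic fits.
#' @param n_iter,burn_in,thin MCMC controls.
#' @param seed base RNG seed.
#' @return see [buildDecomposition()].
#' @export
decomposeInformation <- function(rep, method = "BAYESA*B*(-2,8)",
                                 n_iter = 20000, burn_in = 4000,
                                 thin = 8, seed = 1) {
  fam <- familyId(rep$pop)
  truth <- rep$truth
  fit_acc <- function(y, tag_seed) {
    fit <- fitMethodOnReplicate(
      modifyList(rep, list(y = y)), method, n_iter = n_iter,
      burn_in = burn_in, thin = thin, seed = seed + tag_seed)
    list(h2a = fit$h2a, accuracy = cor(fit$ua, truth$u_a))
  }
  raw <- fit_acc(rep$y, 0)
  awf <- fit_acc(withinFamilyDeviations(rep$y, fam), 1)
  dms <- perFamilyFitAverage(rep, method, n_iter = max(2000, n_iter %/% 4),
                             burn_in = max(500, burn_in %/% 4),
                             thin = thin, seed = seed + 2)
  ped_fit <- fitMethodOnReplicate(rep, "Pedigree-BLUP")
  ped <- list(h2a = ped_fit$h2a,
              accuracy = cor(ped_fit$ua, truth$u_a))
  par_h2a <- realizedHeritability(rep$trait)[["h2_narrow"]]
  buildDecomposition(raw, awf, dms, ped, par_h2a)
}
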