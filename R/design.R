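## Closed-form design calculators for the composite-population setting.

#' Expected linkage disequilibrium in a composite population
#'
#' When two random-mating populations in linkage equilibrium are crossed,
#' the expected LD between two loci in the composite is
#' \deqn{\Delta_{ab} = \frac{1 - 2\theta_{ab}}{4}
#'   (p^1_a - p^2_a)(p^1_b - p^2_b),}
#' where \eqn{\theta} is the recombination fraction between the loci and
#' \eqn{p^1, p^2} are allele frequencies in the two parental populations.
#' The LD is maximal (|Delta| = 0.25) for fully linked loci with fixed
#' alternative alleles in the two parents; it vanishes whenever the
#' parental frequencies coincide at either locus or theta = 0.5.
#'
#' @param theta recombination fraction in `[0, 0.5]`.
#' @param pa1,pa2 allele frequencies at locus a in parental populations
#'   1 and 2.
#' @param pb1,pb2 allele frequencies at locus b.
#' @return the expected LD value (covariance scale); positive for
#'   coupling, negative for repulsion.
#' @examples
#' expectedCompositeLD(0, 1, 0, 1, 0)  # 0.25, the maximum
#' @export
expectedCompositeLD <- function(theta, pa1, pa2, pb1, pb2) {
  if (any(theta < 0 | theta > 0.5))
    stop("theta must lie in [0, 0.5]")
  freqs <- c(pa1, pa2, pb1, pb2)
  if (any(freqs < 0 | freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  ((1 - 2 * theta) / 4) * (pa1 - pa2) * (pb1 - pb2)
}

#' Proportion of genetic variance captured by markers
#'
#' `markerCaptureRatio()` computes \eqn{r^2_{mq} = n / (n + n_{QTL})}
#' from the marker and QTL counts.  `markerCaptureFromSpacing()` uses the
#' alternative expression \eqn{1 / (1 + 4 N_e S)} based on effective
#' population size and marker spacing.
#'
#' @param n number of markers (> 0).
#' @param n_qtl number of QTL (>= 0); may be an effective number such as
#'   `2 * Ne * L`.
#' @return the capture proportion in `(0, 1]`.
#' @examples
#' markerCaptureRatio(2000, 100)           # 0.95
#' markerCaptureRatio(2000, 2 * 39.22 * 2) # 0.93
#' markerCaptureFromSpacing(39.22, 0.001)  # 0.86
#' @export
markerCaptureRatio <- function(n, n_qtl) {
  if (any(n <= 0)) stop("marker count n must be positive")
  if (any(n_qtl < 0)) stop("n_qtl must be non-negative")
  n / (n + n_qtl)
}

#' @rdname markerCaptureRatio
#' @param Ne effective population size (> 0).
#' @param S marker spacing in Morgans (>= 0).
#' @export
markerCaptureFromSpacing <- function(Ne, S) {
  if (any(Ne <= 0)) stop("Ne must be positive")
  if (any(S < 0)) stop("spacing S must be non-negative")
  1 / (1 + 4 * Ne * S)
}

#' Effective population size of a balanced mating design
#'
#' Standard sex-ratio formula `4 Ns Nd / (Ns + Nd)` for the number of
#' sires and dams contributing to the genotyped cohort.
#'
#' @param n_sires,n_dams parent counts.
#' @return effective size.
#' @export
effectiveSize <- function(n_sires, n_dams) {
  4 * n_sires * n_dams / (n_sires + n_dams)
}
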