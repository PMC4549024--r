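## Marker incidence coding and relationship matrices.

#' Additive and dominance marker codes
#'
#' `codeAdditive()` maps dosages of allele M to the classical
#' substitution-effect codes (MM -> 2q, Mm -> q - p, mm -> -2p) and
#' `codeDominance()` to the dominance-deviation codes (MM -> -2q^2,
#' Mm -> 2pq, mm -> -2p^2).  With `p` equal to the observed cohort
#' frequency every column of the additive code matrix sums to zero
#' exactly.
#'
#' @param dosages integer matrix (individuals x loci) of 0/1/2 dosages.
#' @param p per-locus frequency of allele M, strictly inside (0, 1);
#'   monomorphic loci must be filtered beforehand.
#' @return numeric matrix of codes, same shape as `dosages`.
#' @examples
#' codeAdditive(matrix(c(0L, 1L, 2L)), 0.5)   #  -1, 0, 1
#' codeDominance(matrix(c(0L, 1L, 2L)), 0.5)  #  -0.5, 0.5, -0.5
#' @export
codeAdditive <- function(dosages, p) {
  checkCodingArgs(dosages, p)
  sweep(dosages, 2, 2 * p, "-")
}

#' @rdname codeAdditive
#' @export
codeDominance <- function(dosages, p) {
  checkCodingArgs(dosages, p)
  q <- 1 - p
  n <- nrow(dosages)
  S <- matrix(0, n, ncol(dosages))
  S[dosages == 2L] <- rep(-2 * q^2, each = n)[dosages == 2L]
  S[dosages == 1L] <- rep(2 * p * q, each = n)[dosages == 1L]
  S[dosages == 0L] <- rep(-2 * p^2, each = n)[dosages == 0L]
  S
}

checkCodingArgs <- function(dosages, p) {
  if (length(p) == 1L) p <- rep(p, ncol(dosages))
  if (length(p) != ncol(dosages))
    stop("frequency vector does not match the number of loci")
  if (any(p <= 0 | p >= 1))
    stop("allele frequencies must lie strictly in (0, 1); ",
         "filter monomorphic loci first")
  invisible(p)
}

#' Build the W/S coding of a genotype matrix
#'
#' @param dosages integer matrix of 0/1/2 dosages.
#' @param p allele frequencies; by default estimated from the genotyped
#'   cohort itself.
#' @return a [MarkerCoding-class].
#' @export
markerCoding <- function(dosages, p = colMeans(dosages) / 2) {
  p <- checkCodingArgs(dosages, p)
  W <- codeAdditive(dosages, p)
  S <- codeDominance(dosages, p)
  twopq <- 2 * p * (1 - p)
  new("MarkerCoding", W = W, S = S, p = p, sum2pq = sum(twopq),
      sum2pq_sq = sum(twopq^2))
}

#' Genomic relationship matrices
#'
#' `buildGa()` forms the additive genomic relationship
#' `G_a = W W' / sum(2 p q)` and `buildGd()` the dominance counterpart
#' `G_d = S S' / sum((2 p q)^2)`; the denominators are the identities
#' that convert marker-effect variances into genetic variances
#' (`sigma2_a = sum(2pq) * sigma2_ma`,
#' `sigma2_d = sum((2pq)^2) * sigma2_md`).
#'
#' @param coding a [MarkerCoding-class], or a raw code matrix together
#'   with `p`.
#' @param p allele frequencies (only when passing a raw matrix).
#' @return symmetric relationship matrix.
#' @export
buildGa <- function(coding, p = NULL) {
  if (is(coding, "MarkerCoding"))
    return(tcrossprod(coding@W) / coding@sum2pq)
  p <- checkCodingArgs(coding, p)
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("sum(2pq) must be positive")
  tcrossprod(coding) / denom
}

#' @rdname buildGa
#' @export
buildGd <- function(coding, p = NULL) {
  if (is(coding, "MarkerCoding"))
    return(tcrossprod(coding@S) / coding@sum2pq_sq)
  p <- checkCodingArgs(coding, p)
  denom <- sum((2 * p * (1 - p))^2)
  if (denom <= 0) stop("sum((2pq)^2) must be positive")
  tcrossprod(coding) / denom
}

orderPedigree <- function(ped) {
  ## topological order, parents before offspring; detects cycles
  ids <- ped$id
  extra <- setdiff(c(ped$sire, ped$dam), c(0L, ids))
  if (length(extra))  # unseen parents become founders
    ped <- rbind(data.frame(id = extra, sire = 0L, dam = 0L), ped)
  ped <- ped[!duplicated(ped$id), ]
  n <- nrow(ped)
  placed <- logical(n)
  order <- integer(0)
  known <- c(0L)
  for (pass in seq_len(n)) {
    ready <- !placed & ped$sire %in% known & ped$dam %in% known
    if (!any(ready)) break
    order <- c(order, which(ready))
    known <- c(known, ped$id[ready])
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree contains a cycle or unresolvable parents")
  ped[order, , drop = FALSE]
}

#' Pedigree relationship matrices
#'
#' `pedigreeA()` builds the numerator relationship matrix by the tabular
#' method; `pedigreeD()` derives the dominance relationship for a
#' non-inbred pedigree as
#' `D_jk = (A_sj,sk * A_dj,dk + A_sj,dk * A_dj,sk) / 4` with unit
#' diagonal.  Parents referenced but absent from the table are treated as
#' unrelated founders, as is the conventional id 0.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @param ids optional subset/order of individuals for the returned
#'   matrix (default: all pedigree members in pedigree order).
#' @return symmetric relationship matrix with `ids` as dimnames.
#' @export
pedigreeA <- function(ped, ids = NULL) {
  ped <- orderPedigree(ped)
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    si <- if (s == 0L) 0L else pos[[as.character(s)]]
    di <- if (d == 0L) 0L else pos[[as.character(d)]]
    f <- if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
    A[i, i] <- 1 + f
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (si > 0L) A[j, si] else 0) +
                    (if (di > 0L) A[j, di] else 0))
      A[i, j] <- A[j, i] <- aij
    }
  }
  if (!is.null(ids)) A[as.character(ids), as.character(ids)] else A
}

#' @rdname pedigreeA
#' @export
pedigreeD <- function(ped, ids = NULL) {
  ped <- orderPedigree(ped)
  A <- pedigreeA(ped)
  n <- nrow(ped)
  ## augment with a zero row/column standing in for unknown parents
  Az <- rbind(cbind(A, 0), 0)
  pos <- setNames(seq_len(n), ped$id)
  idx <- function(par) ifelse(par == 0L, n + 1L, pos[as.character(par)])
  si <- idx(ped$sire)
  di <- idx(ped$dam)
  D <- 0.25 * (Az[si, si] * Az[di, di] + Az[si, di] * Az[di, si])
  diag(D) <- 1
  dimnames(D) <- dimnames(A)
  if (!is.null(ids)) D[as.character(ids), as.character(ids)] else D
}
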