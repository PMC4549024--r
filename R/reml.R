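## REML estimation and BLUP for the additive-dominance mixed model
##   y = X b + u_a + u_d + e,   u_a ~ N(0, Ka * sigma2_a),
##   u_d ~ N(0, Kd * sigma2_d), e ~ N(0, I * sigma2_e),
## where Ka/Kd are genomic (Ga/Gd) or pedigree (A/D) relationship
## matrices over the phenotyped individuals.

RIDGE_JITTER <- 1e-8

#' REML log-likelihood of a variance-component model
#'
#' Restricted log-likelihood
#' `-0.5 * (log|V| + log|X'V^-1 X| + y' P y)` for
#' `V = sum_k sigma2_k K_k + sigma2_e I`.
#'
#' @param y phenotype vector.
#' @param X fixed-effects design matrix.
#' @param K list of relationship matrices, one per genetic component.
#' @param sigma2 variances, ordered as `c(components, residual)`.
#' @return the restricted log-likelihood (constant terms dropped).
#' @export
remlLogLik <- function(y, X, K, sigma2) {
  n <- length(y)
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(K)) V <- V + sigma2[k] * K[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  chx <- chol(XtViX)
  logdetX <- 2 * sum(log(diag(chx)))
  beta <- backsolve(chx, forwardsolve(t(chx), XtVi %*% y))
  r <- y - X %*% beta
  quad <- drop(crossprod(r, Vi %*% r))
  -0.5 * (logdetV + logdetX + quad)
}

#' Fit variance components by REML
#'
#' Average-information REML with EM fall-back steps (an AI update that
#' would push a variance negative is replaced by its EM counterpart, and
#' variances are floored at `1e-8 * var(y)` so boundary solutions are
#' reported as effectively zero rather than failing).  Deterministic
#' given the inputs.
#'
#' @param y phenotype vector.
#' @param K list of relationship matrices (e.g.
#'   `list(a = Ga, d = Gd)`); symmetric positive semidefinite.
#' @param X fixed-effects design (default intercept only).
#' @param start optional starting variances (components then residual).
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; exceeding it flags `converged = FALSE`.
#' @return list with `sigma2` (named variances incl. `e`), `h2` (per
#'   component plus `h2g`), `vd_va` when both `a` and `d` are present,
#'   `loglik`, `converged`, `iterations`.
#' @export
fitREML <- function(y, K, X = matrix(1, length(y), 1), start = NULL,
                    tol = 1e-8, max_iter = 500) {
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effects design")
  K <- lapply(K, function(k) (k + t(k)) / 2)
  vy <- var(y)
  if (vy <= 0) {
    sig <- c(rep(0, length(K)), 0)
    names(sig) <- c(names(K), "e")
    return(list(sigma2 = sig, h2 = rep(0, length(K)), vd_va = NA_real_,
                loglik = NA_real_, converged = TRUE, iterations = 0L))
  }
  nk <- length(K)
  floor_v <- RIDGE_JITTER * vy
  sigma2 <- if (is.null(start)) rep(vy / (nk + 1), nk + 1) else start
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    V <- diag(sigma2[nk + 1], n)
    for (k in seq_len(nk)) V <- V + sigma2[k] * K[[k]]
    Vi <- chol2inv(chol(V + diag(vy * 1e-10, n)))
    XtVi <- crossprod(X, Vi)
    XtViX_inv <- solve(XtVi %*% X)
    P <- Vi - t(XtVi) %*% XtViX_inv %*% XtVi
    Py <- P %*% y
    Vk <- c(K, list(diag(1, n)))
    score <- numeric(nk + 1)
    VkPy <- vector("list", nk + 1)
    for (k in seq_len(nk + 1)) {
      VkPy[[k]] <- Vk[[k]] %*% Py
      score[k] <- -0.5 * (sum(P * Vk[[k]]) -
                          drop(crossprod(Py, VkPy[[k]])))
    }
    AI <- matrix(0, nk + 1, nk + 1)
    for (k in seq_len(nk + 1)) for (l in k:(nk + 1)) {
      AI[k, l] <- AI[l, k] <-
        0.5 * drop(crossprod(VkPy[[k]], P %*% VkPy[[l]]))
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    prop <- if (is.null(step)) rep(-1, nk + 1) else sigma2 + step
    if (any(prop < 0)) {
      ## EM update, guaranteed non-negative
      prop <- sigma2
      for (k in seq_len(nk + 1)) {
        trPV <- sum(P * Vk[[k]])
        yPVPy <- drop(crossprod(Py, VkPy[[k]]))
        prop[k] <- sigma2[k] + (sigma2[k]^2 / n) * (yPVPy - trPV)
      }
    }
    prop <- pmax(prop, floor_v)
    rel <- max(abs(prop - sigma2) / (abs(sigma2) + vy * 1e-3))
    sigma2 <- prop
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  ## derivative-free polish on the log scale when the AI/EM iteration
  ## stalls: the steps can crawl along a flat likelihood ridge (small n,
  ## highly correlated relationship matrices)
  if (!converged) {
    polish <- stats::optim(log(pmax(sigma2, floor_v)), function(ls)
      -remlLogLik(y, X, K, exp(ls)), method = "Nelder-Mead",
      control = list(maxit = 1000, reltol = 1e-13))
    if (-polish$value > remlLogLik(y, X, K, sigma2)) {
      sigma2 <- pmax(exp(polish$par), floor_v)
      converged <- polish$convergence == 0
    }
  }
  loglik <- remlLogLik(y, X, K, sigma2)
  total <- sum(sigma2)
  h2 <- sigma2[seq_len(nk)] / total
  names(sigma2) <- c(names(K), "e")
  names(h2) <- names(K)
  vd_va <- if (all(c("a", "d") %in% names(K)))
    unname(sigma2["d"] / sigma2["a"]) else NA_real_
  list(sigma2 = sigma2, h2 = h2, h2g = sum(h2), vd_va = vd_va,
       loglik = loglik, converged = converged, iterations = it)
}

#' Solve the mixed model equations for BLUP
#'
#' Henderson's equations with shrinkage ratios
#' `lambda_k = sigma2_e / sigma2_k`; relationship matrices receive a
#' small diagonal jitter before inversion.  A component whose variance is
#' at (or below) the numerical floor is shrunk entirely to zero.
#'
#' @param y phenotype vector.
#' @param K list of relationship matrices (same names as in the fit).
#' @param sigma2 named variances as returned by [fitREML()] (must
#'   include `e`).
#' @param X fixed-effects design.
#' @return list with `b` (fixed effects), `u` (list of BLUP vectors per
#'   component), `ghat` (sum of the genetic BLUPs) and `residual_norm`
#'   (relative residual of the solved system).
#' @export
solveMME <- function(y, K, sigma2, X = matrix(1, length(y), 1)) {
  n <- length(y)
  s2e <- sigma2[["e"]]
  if (s2e <= 0) stop("residual variance must be positive")
  if (var(y) == 0) {
    u <- lapply(K, function(k) numeric(n))
    return(list(b = mean(y), u = u, ghat = numeric(n), residual_norm = 0))
  }
  active <- names(K)[vapply(names(K), function(nm)
    sigma2[[nm]] > RIDGE_JITTER * var(y) * 10, logical(1))]
  Kact <- K[active]
  nk <- length(Kact)
  p <- ncol(X)
  dim_tot <- p + nk * n
  M <- matrix(0, dim_tot, dim_tot)
  rhs <- numeric(dim_tot)
  M[seq_len(p), seq_len(p)] <- crossprod(X)
  rhs[seq_len(p)] <- crossprod(X, y)
  blocks <- lapply(seq_len(nk), function(k) p + (k - 1L) * n + seq_len(n))
  for (k in seq_len(nk)) {
    bk <- blocks[[k]]
    M[seq_len(p), bk] <- t(X)
    M[bk, seq_len(p)] <- X
    Kinv <- chol2inv(chol(Kact[[k]] + diag(RIDGE_JITTER, n)))
    lam <- s2e / sigma2[[active[k]]]
    M[bk, bk] <- diag(1, n) + lam * Kinv
    rhs[bk] <- y
    for (l in seq_len(nk)) if (l != k)
      M[bk, blocks[[l]]] <- diag(1, n)
  }
  sol <- tryCatch(solve(M, rhs), error = function(e)
    stop("mixed model equations are singular"))
  resid <- sqrt(sum((M %*% sol - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-12)
  b <- sol[seq_len(p)]
  u <- setNames(vector("list", length(K)), names(K))
  for (nm in names(K)) u[[nm]] <- numeric(n)
  for (k in seq_len(nk)) u[[active[k]]] <- sol[blocks[[k]]]
  ghat <- Reduce(`+`, u, numeric(n))
  list(b = b, u = u, ghat = ghat, residual_norm = resid)
}

#' BLUP of marker effects under the equivalent marker-level model
#'
#' For the marker model `y = X b + W m_a + S m_d + e` with
#' `m_a ~ N(0, I sigma2_ma)` and `m_d ~ N(0, I sigma2_md)`, the BLUPs
#' are `m_hat = sigma2_m M' V^-1 (y - X b_hat)` with
#' `V = sigma2_ma W W' + sigma2_md S S' + sigma2_e I`, which is
#' algebraically identical to the relationship-matrix BLUP through
#' `u_a = W m_a`.
#'
#' @param y phenotypes.
#' @param W,S marker code matrices (pass `S = NULL` for additive-only).
#' @param sigma2_ma,sigma2_md,sigma2_e variance components on the
#'   marker-effect scale.
#' @param X fixed-effects design.
#' @return list with `b`, `ma`, `md` and fitted genetic values `ua`,
#'   `ud`.
#' @export
markerRidge <- function(y, W, S = NULL, sigma2_ma, sigma2_md = 0,
                        sigma2_e, X = matrix(1, length(y), 1)) {
  n <- length(y)
  V <- diag(sigma2_e, n) + sigma2_ma * tcrossprod(W)
  if (!is.null(S) && sigma2_md > 0) V <- V + sigma2_md * tcrossprod(S)
  Vi <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vi)
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- Vi %*% (y - X %*% b)
  ma <- sigma2_ma * drop(crossprod(W, r))
  md <- if (!is.null(S) && sigma2_md > 0)
    sigma2_md * drop(crossprod(S, r)) else numeric(if (is.null(S)) 0 else ncol(S))
  list(b = drop(b), ma = ma, md = md, ua = drop(W %*% ma),
       ud = if (length(md)) drop(S %*% md) else numeric(n))
}
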