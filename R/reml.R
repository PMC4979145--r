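#' REML variance components for the animal model
#'
#' Fits y = Xb + a + e with a ~ N(0, sigma_a2 * Phi) and
#' e ~ N(0, sigma_e2 * I) by restricted maximum likelihood. The kinship
#' matrix is eigen-decomposed once (after adding a small ridge), which
#' reduces the REML profile likelihood to a one-dimensional optimization
#' over the variance ratio delta = sigma_e2/sigma_a2. The standard error
#' of h2 comes from the curvature of the profile likelihood.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (default: intercept only).
#' @param K `kinship_matrix` (or plain symmetric matrix).
#' @param ridge small value added to the diagonal before decomposition.
#' @param interval search interval for log(delta).
#' @return object of class `reml_fit`: sigma_a2, sigma_e2, h2, se_h2,
#'   loglik, converged, beta, plus the eigen-rotation (U, d) and rotated
#'   data for reuse by the association scan and BLUP.
#' @export
reml_univariate <- function(y, X = NULL, K, ridge = 1e-8,
                            interval = c(-25, 25)) {
  phi <- if (inherits(K, "kinship_matrix")) K$phi else as.matrix(K)
  n <- length(y)
  if (n < 30) warning("REML with fewer than 30 observations is fragile")
  stopifnot(nrow(phi) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  eig <- eigen(phi + diag(ridge, n), symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 1e-10)
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  prof <- function(log_delta) {
    v <- d + exp(log_delta)
    w <- 1 / v
    A <- crossprod(Xt * w, Xt)
    b <- solve(A, crossprod(Xt * w, yt))
    r <- yt - drop(Xt %*% b)
    R <- sum(r^2 * w)
    s2 <- R / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(v)) +
                    determinant(A, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), b = b, s2 = s2, r = r, w = w)
  }
  opt <- optimize(function(ld) prof(ld)$ll, interval = interval,
                  maximum = TRUE, tol = 1e-10)
  ld <- opt$maximum
  at_boundary <- ld <= interval[1] + 1e-3 || ld >= interval[2] - 1e-3
  fit <- prof(ld)
  delta <- exp(ld)
  sigma_a2 <- fit$s2
  sigma_e2 <- delta * sigma_a2
  h2 <- 1 / (1 + delta)
  if (at_boundary) h2 <- round(h2)  # report boundary estimates at 0 or 1

  # SE of h2 from numerical curvature of the profile loglik in h2
  se_h2 <- NA_real_
  if (!at_boundary) {
    ll_h2 <- function(h) prof(log((1 - h) / h))$ll
    eps <- min(1e-4, h2 / 2, (1 - h2) / 2)
    d2 <- (ll_h2(h2 + eps) - 2 * opt$objective + ll_h2(h2 - eps)) / eps^2
    if (is.finite(d2) && d2 < 0) se_h2 <- sqrt(-1 / d2)
  }
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, h2 = h2,
                 se_h2 = se_h2, loglik = opt$objective,
                 converged = !at_boundary, beta = drop(fit$b),
                 delta = delta, U = U, d = d, yt = yt, Xt = Xt, X = X,
                 y = y, n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML animal model: sigma_a2 = %.4g, sigma_e2 = %.4g\n",
              x$sigma_a2, x$sigma_e2))
  cat(sprintf("  h2 = %.4f (SE %.4f), REML loglik = %.3f%s\n",
              x$h2, x$se_h2, x$loglik,
              if (x$converged) "" else " [boundary]"))
  invisible(x)
}

#' Breeding values (BLUP) from a univariate REML fit
#'
#' @param object a `reml_fit`.
#' @param ... unused.
#' @return numeric vector of estimated breeding values, one per
#'   individual in input order.
#' @export
ebv <- function(object, ...) UseMethod("ebv")

#' @export
ebv.reml_fit <- function(object, ...) {
  v <- object$d + object$delta
  r <- object$yt - drop(object$Xt %*% object$beta)
  drop(object$U %*% (object$d / v * r))
}

#' Bivariate REML: genetic and residual covariance of two traits
#'
#' Both traits share the kinship eigen-rotation, which reduces the
#' restricted likelihood to n independent 2x2 blocks
#' V_i = G d_i + R. G and R are parameterized by log-Cholesky factors and
#' maximized with derivative-free then quasi-Newton steps, starting from
#' the univariate fits. The genetic correlation is
#' r_g = G12 / sqrt(G11 G22), with a delta-method standard error from the
#' numerical Hessian.
#'
#' @param y1,y2 trait vectors on the same individuals, same order.
#' @param X shared fixed-effect design (default intercept).
#' @param K `kinship_matrix`.
#' @param ridge diagonal ridge for the eigen-decomposition.
#' @return object of class `reml_biv_fit`: g_cov, r_cov (2x2), r_g, se_rg,
#'   loglik, converged.
#' @export
reml_bivariate <- function(y1, y2, X = NULL, K, ridge = 1e-8) {
  n <- length(y1)
  stopifnot(length(y2) == n)
  phi <- if (inherits(K, "kinship_matrix")) K$phi else as.matrix(K)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  eig <- eigen(phi + diag(ridge, n), symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 1e-10)
  y1t <- drop(crossprod(U, y1))
  y2t <- drop(crossprod(U, y2))
  Xt <- crossprod(U, X)

  unpack <- function(th) {
    Lg <- matrix(c(exp(th[1]), th[3], 0, exp(th[2])), 2, 2)
    Lr <- matrix(c(exp(th[4]), th[6], 0, exp(th[5])), 2, 2)
    list(G = tcrossprod(Lg), R = tcrossprod(Lr))
  }
  negll <- function(th) {
    gr <- unpack(th)
    G <- gr$G; R <- gr$R
    v11 <- G[1, 1] * d + R[1, 1]
    v22 <- G[2, 2] * d + R[2, 2]
    v12 <- G[1, 2] * d + R[1, 2]
    det_i <- v11 * v22 - v12^2
    if (any(det_i <= 0) || any(v11 <= 0) || any(v22 <= 0)) return(1e10)
    i11 <- v22 / det_i; i22 <- v11 / det_i; i12 <- -v12 / det_i
    # GLS for block-diagonal fixed effects (same X per trait)
    A11 <- crossprod(Xt * i11, Xt); A22 <- crossprod(Xt * i22, Xt)
    A12 <- crossprod(Xt * i12, Xt)
    A <- rbind(cbind(A11, A12), cbind(A12, A22))
    rhs <- c(crossprod(Xt, i11 * y1t + i12 * y2t),
             crossprod(Xt, i12 * y1t + i22 * y2t))
    b <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(b)) return(1e10)
    r1 <- y1t - drop(Xt %*% b[seq_len(p)])
    r2 <- y2t - drop(Xt %*% b[p + seq_len(p)])
    Q <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
    ldetA <- determinant(A, logarithm = TRUE)$modulus
    0.5 * (Q + sum(log(det_i)) + as.numeric(ldetA))
  }

  f1 <- reml_univariate(y1, X, K, ridge)
  f2 <- reml_univariate(y2, X, K, ridge)
  st <- c(0.5 * log(max(f1$sigma_a2, 1e-8)),
          0.5 * log(max(f2$sigma_a2, 1e-8)), 0,
          0.5 * log(max(f1$sigma_e2, 1e-8)),
          0.5 * log(max(f2$sigma_e2, 1e-8)), 0)
  o1 <- optim(st, negll, method = "Nelder-Mead",
              control = list(maxit = 4000, reltol = 1e-12))
  o2 <- optim(o1$par, negll, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12))
  best <- if (o2$value <= o1$value) o2 else o1
  gr <- unpack(best$par)
  G <- gr$G; R <- gr$R
  r_g <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])

  se_rg <- NA_real_
  near_singular <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) <
    1e-8 * max(diag(G))
  H <- tryCatch(optimHess(best$par, negll), error = function(e) NULL)
  if (!is.null(H)) {
    Vth <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vth)) {
      grad <- numeric(6)
      for (k in 1:6) {
        thp <- best$par; thp[k] <- thp[k] + 1e-5
        thm <- best$par; thm[k] <- thm[k] - 1e-5
        rgp <- with(unpack(thp), G[1, 2] / sqrt(G[1, 1] * G[2, 2]))
        rgm <- with(unpack(thm), G[1, 2] / sqrt(G[1, 1] * G[2, 2]))
        grad[k] <- (rgp - rgm) / 2e-5
      }
      v <- drop(t(grad) %*% Vth %*% grad)
      if (is.finite(v) && v >= 0) se_rg <- sqrt(v)
    }
  }
  if (near_singular) {
    warning("near-singular genetic covariance: r_g has a wide SE")
    if (is.na(se_rg)) se_rg <- 1
  }
  structure(list(g_cov = G, r_cov = R, r_g = r_g, se_rg = se_rg,
                 loglik = -best$value, converged = best$convergence == 0,
                 h2 = c(G[1, 1] / (G[1, 1] + R[1, 1]),
                        G[2, 2] / (G[2, 2] + R[2, 2]))),
            class = "reml_biv_fit")
}

#' @export
print.reml_biv_fit <- function(x, ...) {
  cat(sprintf("Bivariate REML: r_g = %.4f (SE %.4f)\n", x$r_g, x$se_rg))
  cat(sprintf("  h2: %.3f / %.3f; REML loglik = %.3f\n",
              x$h2[1], x$h2[2], x$loglik))
  invisible(x)
}
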