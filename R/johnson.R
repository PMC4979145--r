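#' Anderson-Darling normality test
#'
#' Computes the Anderson-Darling statistic for composite normality (mean
#' and standard deviation estimated from the sample), applies the
#' small-sample correction A2* = A2 (1 + 0.75/n + 2.25/n^2), and returns a
#' p-value from the standard piecewise approximation for the
#' estimated-parameters case.
#'
#' @param x numeric vector, n >= 8, with positive variance.
#' @return list(A2 = uncorrected statistic, A2_star, p_value, n).
#' @export
anderson_darling_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("Anderson-Darling test needs n >= 8")
  s <- sd(x)
  if (s == 0) stop("degenerate sample: zero variance")
  w <- sort((x - mean(x)) / s)
  logp <- pnorm(w, log.p = TRUE)
  logq <- pnorm(w, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (logp + rev(logq)))
  A2s <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (A2s >= 0.6) exp(1.2937 - 5.709 * A2s + 0.0186 * A2s^2)
  else if (A2s >= 0.34) exp(0.9177 - 4.279 * A2s - 1.38 * A2s^2)
  else if (A2s > 0.2) 1 - exp(-8.318 + 42.796 * A2s - 59.938 * A2s^2)
  else 1 - exp(-13.436 + 101.14 * A2s - 223.73 * A2s^2)
  list(A2 = A2, A2_star = A2s, p_value = min(max(p, 0), 1), n = n)
}

# ---- Johnson system, percentile (quantile-ratio) fitting -------------------

johnson_su_fit <- function(q, z) {
  # q = sample quantiles at normal scores (-3z, -z, z, 3z)
  m <- q[4] - q[3]; n <- q[2] - q[1]; p <- q[3] - q[2]
  if (p <= 0 || m <= 0 || n <= 0) return(NULL)
  ratio <- m * n / p^2
  if (ratio <= 1) return(NULL)
  mp <- m / p; np <- n / p
  eta <- 2 * z / acosh(0.5 * (mp + np))
  gamma <- eta * asinh((np - mp) / (2 * sqrt(ratio - 1)))
  lambda <- 2 * p * sqrt(ratio - 1) /
    ((mp + np - 2) * sqrt(mp + np + 2))
  eps <- (q[3] + q[2]) / 2 + p * (np - mp) / (2 * (mp + np - 2))
  if (!is.finite(eta) || !is.finite(lambda) || eta <= 0 || lambda <= 0)
    return(NULL)
  list(family = "SU",
       params = c(gamma = gamma, eta = eta, eps = eps, lambda = lambda),
       transform = function(x) gamma + eta * asinh((x - eps) / lambda))
}

johnson_sb_fit <- function(q, z) {
  m <- q[4] - q[3]; n <- q[2] - q[1]; p <- q[3] - q[2]
  if (p <= 0 || m <= 0 || n <= 0) return(NULL)
  ratio <- p^2 / (m * n)
  if (ratio <= 1) return(NULL)
  pm <- p / m; pn <- p / n
  arg <- 0.5 * sqrt((1 + pm) * (1 + pn))
  if (arg <= 1) return(NULL)
  eta <- z / acosh(arg)
  inner <- (1 + pm) * (1 + pn) - 4
  if (inner < 0) return(NULL)
  gamma <- eta * asinh((pn - pm) * sqrt(inner) / (2 * (ratio - 1)))
  lam_in <- ((1 + pm) * (1 + pn) - 2)^2 - 4
  if (lam_in < 0) return(NULL)
  lambda <- p * sqrt(lam_in) / (ratio - 1)
  eps <- (q[3] + q[2]) / 2 - lambda / 2 + p * (pn - pm) / (2 * (ratio - 1))
  if (!is.finite(eta) || !is.finite(lambda) || eta <= 0 || lambda <= 0)
    return(NULL)
  list(family = "SB",
       params = c(gamma = gamma, eta = eta, eps = eps, lambda = lambda),
       transform = function(x) gamma + eta * log((x - eps) / (lambda + eps - x)))
}

johnson_sl_fit <- function(q, z) {
  m <- q[4] - q[3]; n <- q[2] - q[1]; p <- q[3] - q[2]
  if (p <= 0 || m <= 0 || n <= 0) return(NULL)
  mp <- m / p
  if (mp <= 1) return(NULL)
  eta <- 2 * z / log(mp)
  gamma <- eta * log((mp - 1) / (p * sqrt(mp)))
  eps <- (q[3] + q[2]) / 2 - (p / 2) * (mp + 1) / (mp - 1)
  if (!is.finite(eta) || eta <= 0) return(NULL)
  list(family = "SL",
       params = c(gamma = gamma, eta = eta, eps = eps, lambda = 1),
       transform = function(x) gamma + eta * log(x - eps))
}

#' Johnson transformation toward normality
#'
#' Fits Johnson SB, SL and SU candidates by the percentile method over a
#' grid of selection constants z (sample quantiles at normal scores -3z,
#' -z, z, 3z), keeps every candidate that is finite and strictly monotone
#' on the sample range, and returns the transform whose transformed values
#' have the largest Anderson-Darling p-value. Falls back to the identity
#' transform (with a warning) when no candidate achieves a finite fit.
#'
#' @param x numeric sample, n >= 20.
#' @param z_grid grid of selection constants (default 0.25 to 1.25 in
#'   steps of 0.01).
#' @param quantile_type passed to [stats::quantile()].
#' @return object of class `johnson_fit`: list(z = transformed values,
#'   family, params, sel_z, ad_before, ad_after, transform).
#' @export
johnson_transform <- function(x, z_grid = seq(0.25, 1.25, by = 0.01),
                              quantile_type = 6) {
  x <- x[!is.na(x)]
  if (length(x) < 20) stop("Johnson transformation needs n >= 20")
  ad_before <- anderson_darling_test(x)$p_value
  best <- NULL; best_p <- -Inf
  rng <- range(x)
  for (zc in z_grid) {
    probs <- pnorm(c(-3, -1, 1, 3) * zc)
    q <- unname(quantile(x, probs, type = quantile_type))
    for (fit in list(johnson_su_fit(q, zc), johnson_sb_fit(q, zc),
                     johnson_sl_fit(q, zc))) {
      if (is.null(fit)) next
      # domain / monotonicity checks on the sample range
      if (fit$family == "SL" && fit$params[["eps"]] >= rng[1]) next
      if (fit$family == "SB" &&
          (fit$params[["eps"]] >= rng[1] ||
           fit$params[["eps"]] + fit$params[["lambda"]] <= rng[2])) next
      zz <- fit$transform(x)
      if (any(!is.finite(zz)) || sd(zz) == 0) next
      p <- tryCatch(anderson_darling_test(zz)$p_value,
                    error = function(e) -Inf)
      if (p > best_p) {
        best_p <- p
        best <- c(fit, list(sel_z = zc, zvals = zz))
      }
    }
  }
  if (is.null(best)) {
    warning("no Johnson candidate achieved a finite fit; identity returned")
    return(structure(list(z = x, family = "identity",
                          params = c(gamma = 0, eta = 1, eps = 0, lambda = 1),
                          sel_z = NA_real_, ad_before = ad_before,
                          ad_after = ad_before, transform = identity),
                     class = "johnson_fit"))
  }
  structure(list(z = best$zvals, family = best$family, params = best$params,
                 sel_z = best$sel_z, ad_before = ad_before,
                 ad_after = best_p, transform = best$transform),
            class = "johnson_fit")
}

#' @export
print.johnson_fit <- function(x, ...) {
  cat(sprintf("Johnson %s transform (selection constant z = %.2f)\n",
              x$family, x$sel_z))
  cat(sprintf("  AD p-value: %.4g before -> %.4g after\n",
              x$ad_before, x$ad_after))
  invisible(x)
}
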