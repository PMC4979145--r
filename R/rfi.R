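#' Fit the Koch intake model and compute RFI
#'
#' Ordinary least squares of average daily feed intake on metabolic
#' mid-test body weight and average daily gain,
#' ADFI = b0 + b1*MMBW + b2*ADG + RFI,
#' where the residual RFI is the bird's residual feed intake. By
#' construction the residuals have zero mean and are orthogonal to both
#' regressors.
#'
#' @param traits data.frame with columns `adfi`, `mmbw`, `adg` (and
#'   usually `bird_id`).
#' @return object of class `koch_fit`: coefficients b0/b1/b2, model R2,
#'   the per-bird `rfi` vector (in input row order), and the input traits
#'   with an `rfi` column appended.
#' @export
fit_koch_rfi <- function(traits) {
  stopifnot(all(c("adfi", "mmbw", "adg") %in% names(traits)))
  if (nrow(traits) < 4) stop("need at least 4 birds to fit the Koch model")
  if (abs(cor(traits$mmbw, traits$adg)) > 1 - 1e-10)
    stop("singular fit: MMBW and ADG are collinear")
  fit <- lm(adfi ~ mmbw + adg, data = traits)
  rfi <- unname(residuals(fit))
  b <- coef(fit)
  sst <- sum((traits$adfi - mean(traits$adfi))^2)
  out <- traits
  out$rfi <- rfi
  structure(list(b0 = unname(b[1]), b1 = unname(b[2]), b2 = unname(b[3]),
                 r2_model = if (sst > 0) 1 - sum(rfi^2) / sst else 1,
                 rfi = rfi, traits = out),
            class = "koch_fit")
}

#' @export
print.koch_fit <- function(x, ...) {
  cat(sprintf("Koch intake model: ADFI = %.3f + %.4f*MMBW + %.4f*ADG + RFI\n",
              x$b0, x$b1, x$b2))
  cat(sprintf("  model R2 = %.3f; RFI sd = %.3f g/day (n = %d)\n",
              x$r2_model, sd(x$rfi), length(x$rfi)))
  invisible(x)
}

#' @export
coef.koch_fit <- function(object, ...) {
  c(b0 = object$b0, b1 = object$b1, b2 = object$b2)
}

#' @export
residuals.koch_fit <- function(object, ...) object$rfi

#' Test sex and pen fixed effects on RFI and adjust when significant
#'
#' One-way F-tests of RFI on sex and on pen. Each factor found significant
#' at `alpha` has its level means subtracted (the adjusted values are
#' re-centered to overall mean zero); sex is adjusted before pen. The
#' adjustment is idempotent.
#'
#' @param rfi numeric RFI vector.
#' @param sex,pen factors (coerced) with >= 2 levels each; a single-level
#'   factor's test is skipped with a warning.
#' @param alpha significance level for adjusting (default 0.01).
#' @return list(p_sex, p_pen, adjusted_for, rfi_adjusted).
#' @export
test_fixed_effects_and_adjust <- function(rfi, sex, pen, alpha = 0.01) {
  sex <- factor(sex); pen <- factor(pen)
  one_way_p <- function(y, f) {
    if (nlevels(f) < 2) {
      warning("factor has a single level; test skipped")
      return(NA_real_)
    }
    tab <- anova(lm(y ~ f))
    p <- tab[["Pr(>F)"]][1]
    if (is.na(p) && tab[["F value"]][1] == 0) p <- 1
    p
  }
  subtract_means <- function(y, f) {
    y <- y - ave(y, f)
    y - mean(y)
  }
  p_sex <- one_way_p(rfi, sex)
  p_pen <- one_way_p(rfi, pen)
  adj <- rfi
  adjusted_for <- character(0)
  if (!is.na(p_sex) && p_sex < alpha) {
    adj <- subtract_means(adj, sex)
    adjusted_for <- c(adjusted_for, "sex")
  }
  if (!is.na(p_pen) && p_pen < alpha) {
    adj <- subtract_means(adj, pen)
    adjusted_for <- c(adjusted_for, "pen")
  }
  list(p_sex = p_sex, p_pen = p_pen, adjusted_for = adjusted_for,
       rfi_adjusted = adj)
}

#' Contrast the RFI-divergent tails of the cohort
#'
#' Selects the floor(fraction*n) birds with the lowest and the highest RFI
#' (ties broken by bird_id for determinism) and reports, per trait, the
#' group means with standard errors and a Welch two-sample t-test p-value.
#'
#' @param traits data.frame containing `bird_id`, `rfi` and the trait
#'   columns to contrast.
#' @param fraction tail fraction in (0, 0.5).
#' @param trait_cols character vector of trait columns to contrast.
#' @return list with `table` (data.frame: trait, mean_low, se_low,
#'   mean_high, se_high, p_value) and the selected `low_ids`/`high_ids`.
#' @export
divergent_group_contrast <- function(traits, fraction = 0.10,
                                     trait_cols = intersect(
                                       c("rfi", "adfi", "adg", "mbw", "fcr"),
                                       names(traits))) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must lie in (0, 0.5)")
  n <- nrow(traits)
  if (n < 20) stop("cohort too small for a tail contrast (need >= 20)")
  k <- floor(fraction * n)
  ord <- order(traits$rfi, traits$bird_id)
  low <- traits[ord[seq_len(k)], ]
  high <- traits[rev(ord)[seq_len(k)], ]
  se <- function(x) sd(x) / sqrt(length(x))
  rows <- lapply(trait_cols, function(tc) {
    xl <- low[[tc]]; xh <- high[[tc]]
    p <- if (sd(xl) == 0 && sd(xh) == 0) NA_real_
         else t.test(xl, xh)$p.value
    data.frame(trait = tc, mean_low = mean(xl), se_low = se(xl),
               mean_high = mean(xh), se_high = se(xh), p_value = p,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       low_ids = low$bird_id, high_ids = high$bird_id)
}
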