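#' Fit a bird's linear growth curve
#'
#' Ordinary least squares of body weight on day of test (DOT),
#' BW = mu + a*DOT + e, where the slope a is the average daily gain (ADG).
#' Mid-test body weight (MBW) is the predicted weight at `mid_day`
#' (day 21 of a 40-day test), and metabolic mid-test body weight (MMBW) is
#' MBW^0.75. Birds whose regression R2 falls below `r2_flag_threshold` are
#' flagged but retained.
#'
#' @param records data.frame with columns `DOT` and `body_weight_g` (one
#'   bird's series; DOT values must be distinct).
#' @param mid_day day index at which MBW is predicted.
#' @param r2_flag_threshold R2 below which `low_fit_flag` is set.
#' @return object of class `growth_fit`: list(intercept, adg, r2, mbw,
#'   mmbw, low_fit_flag, n_days).
#' @export
fit_growth_curve <- function(records, mid_day = 21, r2_flag_threshold = 0.80) {
  dot <- records$DOT
  bw <- records$body_weight_g
  keep <- complete.cases(dot, bw)
  dot <- dot[keep]; bw <- bw[keep]
  if (anyDuplicated(dot)) stop("DOT values must be unique within a bird")
  if (length(dot) < 3 || length(unique(dot)) < 3)
    stop("unfittable bird: need at least 3 distinct DOT values")
  fit <- lm(bw ~ dot)
  b <- coef(fit)
  sst <- sum((bw - mean(bw))^2)
  r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else 1
  mbw <- unname(b[1] + b[2] * mid_day)
  if (mbw <= 0) stop("negative predicted mid-test body weight")
  structure(list(intercept = unname(b[1]), adg = unname(b[2]), r2 = r2,
                 mbw = mbw, mmbw = mbw^0.75,
                 low_fit_flag = r2 < r2_flag_threshold,
                 n_days = length(dot)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit: intercept %.1f g, ADG %.2f g/day, R2 %.3f%s\n",
              x$intercept, x$adg, x$r2,
              if (x$low_fit_flag) " [low-fit flag]" else ""))
  cat(sprintf("  MBW %.1f g, MMBW %.2f g^0.75 (%d days)\n",
              x$mbw, x$mmbw, x$n_days))
  invisible(x)
}

#' Derive per-bird feeding traits
#'
#' ADFI is the mean of the recorded daily feed intakes (missing days are
#' tolerated: the mean of available days is used and their count reported).
#' FCR is defined per bird as ADFI/ADG; it is undefined (NA, with a
#' warning) when ADG <= 0.
#'
#' @param feed data.frame with columns `DOT` and `feed_g` for one bird.
#' @param fit the bird's [fit_growth_curve()] result.
#' @return list with adfi, fcr, n_feed_days, and the carried-forward adg,
#'   mbw, mmbw, r2, low_fit_flag.
#' @export
derive_feeding_traits <- function(feed, fit) {
  fg <- feed$feed_g[!is.na(feed$feed_g)]
  if (length(fg) == 0) stop("feed series is empty")
  adfi <- mean(fg)
  if (fit$adg <= 0) {
    warning("ADG <= 0: FCR undefined for this bird")
    fcr <- NA_real_
  } else fcr <- adfi / fit$adg
  list(adfi = adfi, fcr = fcr, n_feed_days = length(fg),
       adg = fit$adg, mbw = fit$mbw, mmbw = fit$mmbw,
       r2 = fit$r2, low_fit_flag = fit$low_fit_flag)
}

#' Derive feeding traits for a whole cohort
#'
#' Applies [fit_growth_curve()] and [derive_feeding_traits()] per bird over
#' a long-format record table.
#'
#' @param records long data.frame (bird_id, sex, pen, DOT, body_weight_g,
#'   feed_g) as produced by [simulate_growth_and_intake()] or read from the
#'   phenotype CSV.
#' @param mid_day,r2_flag_threshold passed to [fit_growth_curve()].
#' @return data.frame with one row per bird: bird_id, sex, pen, intercept,
#'   adg, r2, mbw, mmbw, adfi, fcr, n_feed_days, low_fit_flag.
#' @export
derive_cohort_traits <- function(records, mid_day = 21,
                                 r2_flag_threshold = 0.80) {
  sp <- split(records, records$bird_id)
  rows <- lapply(sp, function(df) {
    fit <- fit_growth_curve(df, mid_day, r2_flag_threshold)
    tr <- derive_feeding_traits(df[, c("DOT", "feed_g")], fit)
    data.frame(bird_id = df$bird_id[1], sex = df$sex[1], pen = df$pen[1],
               intercept = fit$intercept, adg = tr$adg, r2 = tr$r2,
               mbw = tr$mbw, mmbw = tr$mmbw, adfi = tr$adfi, fcr = tr$fcr,
               n_feed_days = tr$n_feed_days,
               low_fit_flag = tr$low_fit_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bird_id), ]
  rownames(out) <- NULL
  out
}
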