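#' Survival curve of the unfolded population
#'
#' `Pu(t)` is the fraction of trajectories whose first passage time exceeds
#' `t`, evaluated on a logarithmically spaced time grid spanning the
#' observed first passage times.  `Pu(0) = 1` and the curve is
#' non-increasing.  Censored trajectories (never folded) are excluded from
#' the curve but their count is carried along.
#'
#' @param fpts An `fpt_ensemble` from [run_kinetics()], or any data frame
#'   with columns `fpt` and `reached`, or a bare numeric vector of first
#'   passage times.
#' @param n_points Number of grid points.
#' @param min_events Minimum number of uncensored folding events.
#' @return A `survival_curve` tibble with columns `time`, `pu`, `n_at_risk`;
#'   attributes `n`, `n_censored`.
#' @export
survival_curve <- function(fpts, n_points = 60L, min_events = 50L) {
  x <- extract_fpts(fpts)
  if (length(x$fpt) < min_events)
    rlang::abort(sprintf("too few uncensored folding events: %d < %d",
                         length(x$fpt), min_events))
  tmax <- max(x$fpt)
  tmin <- max(min(x$fpt), 1)
  grid <- unique(c(0, exp(seq(log(tmin), log(tmax), length.out = n_points))))
  n <- length(x$fpt)
  pu <- vapply(grid, function(t) sum(x$fpt > t) / n, numeric(1))
  out <- tibble::tibble(time = grid, pu = pu, n_at_risk = round(pu * n))
  attr(out, "n") <- n
  attr(out, "n_censored") <- x$n_censored
  class(out) <- c("survival_curve", class(out))
  out
}

extract_fpts <- function(fpts) {
  if (is.numeric(fpts))
    return(list(fpt = fpts[is.finite(fpts)],
                n_censored = sum(!is.finite(fpts))))
  if (!all(c("fpt", "reached") %in% names(fpts)))
    rlang::abort("fpts must have columns fpt and reached")
  list(fpt = fpts$fpt[fpts$reached], n_censored = sum(!fpts$reached))
}

#' Single-exponential fit of the unfolded-population decay
#'
#' Two-state folding gives `Pu(t) = exp(-k t)`; the rate constant is the
#' negative slope of a weighted linear regression of `ln Pu(t)` on `t` over
#' the window `Pu` in `[p_lo, p_hi]` (trimming the short-time transient and
#' the noisy tail).  Weights are the inverse variances of `ln Pu` under
#' binomial sampling, `n Pu / (1 - Pu)`.  A residual diagnostic (weighted
#' root-mean-square deviation of `ln Pu`) flags non-exponential decay.
#'
#' @param curve A [survival_curve()] (or an `fpt_ensemble`, which is
#'   converted first).
#' @param p_lo,p_hi Fit window on `Pu`.
#' @param resid_threshold Residual level above which the fit is flagged
#'   non-exponential.
#' @return A `rate_fit` object: list with `k`, `ln_k`, `intercept`,
#'   `resid_rms`, `flagged`, `n_points`, `n`, `n_censored`,
#'   `censored_fraction`, `unreliable` (censoring above 5 percent).
#' @export
fit_single_exponential <- function(curve, p_lo = 0.05, p_hi = 0.95,
                                   resid_threshold = 0.1) {
  if (!inherits(curve, "survival_curve")) curve <- survival_curve(curve)
  n <- attr(curve, "n")
  n_cens <- attr(curve, "n_censored") %||% 0L
  use <- curve$pu >= p_lo & curve$pu <= p_hi & curve$pu > 0 & curve$time > 0
  pts <- curve[use, ]
  if (nrow(pts) < 5L)
    rlang::abort(sprintf("only %d usable points in the fit window", nrow(pts)))
  w <- n * pts$pu / (1 - pts$pu)
  fit <- stats::lm(log(pts$pu) ~ pts$time, weights = w)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    rlang::abort("non-positive decay rate; survival curve is not decaying")
  resid_rms <- sqrt(stats::weighted.mean(stats::resid(fit)^2, w))
  cens_frac <- n_cens / (n + n_cens)
  structure(list(k = -slope, ln_k = log(-slope),
                 intercept = unname(stats::coef(fit)[1L]),
                 resid_rms = resid_rms,
                 flagged = resid_rms > resid_threshold,
                 n_points = nrow(pts), n = n, n_censored = n_cens,
                 censored_fraction = cens_frac,
                 unreliable = cens_frac > 0.05),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k = %.4g per MC step (ln k = %.3f), %d points, resid %.3g%s%s\n",
              x$k, x$ln_k, x$n_points, x$resid_rms,
              if (x$flagged) " [non-exponential]" else "",
              if (x$unreliable) " [censoring > 5%]" else ""))
  invisible(x)
}

#' Folding rate from a kinetic ensemble
#'
#' Convenience wrapper: survival curve plus single-exponential fit.
#'
#' @param fpts An `fpt_ensemble`.
#' @param ... Passed to [fit_single_exponential()].
#' @return A `rate_fit`.
#' @export
folding_rate <- function(fpts, ...) {
  fit_single_exponential(survival_curve(fpts), ...)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "ln_k"), estimate = c(x$k, x$ln_k))
}

#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(k = x$k, ln_k = x$ln_k, resid_rms = x$resid_rms,
                 flagged = x$flagged, n = x$n, n_censored = x$n_censored,
                 censored_fraction = x$censored_fraction,
                 unreliable = x$unreliable)
}
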