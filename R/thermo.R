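#' Heat capacity from equilibrium energy samples
#'
#' The fluctuation formula `Cv(T) = (<E^2> - <E>^2) / T^2` (with `kB = 1`)
#' applied to the per-temperature samples of a parallel-tempering run.  The
#' melting temperature is the heat-capacity peak, refined by parabolic
#' interpolation through the peak and its two neighbours.
#'
#' @param pt A `pt_samples` object from [parallel_tempering()], or any
#'   tibble with columns `temperature` and `samples` (list of numeric
#'   vectors).
#' @param min_samples Minimum decorrelated samples required per temperature.
#' @return A `heat_capacity_curve` tibble with columns `temperature`,
#'   `mean_energy`, `cv`, `n`; the melting temperature is in
#'   `attr(, "tm")`.
#' @export
heat_capacity <- function(pt, min_samples = 1000L) {
  if (nrow(pt) < 2L) rlang::abort("need samples at >= 2 temperatures")
  counts <- vapply(pt$samples, length, integer(1))
  if (any(counts < min_samples))
    rlang::abort(paste0(
      "insufficient samples per temperature: ",
      paste(sprintf("T=%.4g: %d", pt$temperature[counts < min_samples],
                    counts[counts < min_samples]), collapse = ", ")))
  out <- tibble::tibble(
    temperature = pt$temperature,
    mean_energy = vapply(pt$samples, mean, numeric(1)),
    cv = purrr::map2_dbl(pt$samples, pt$temperature,
                         function(e, t) stats::var(e) * (length(e) - 1) /
                           length(e) / t^2),
    n = counts)
  out <- dplyr::arrange(out, .data$temperature)
  attr(out, "tm") <- peak_parabolic(out$temperature, out$cv)
  class(out) <- c("heat_capacity_curve", class(out))
  out
}

#' Melting temperature of a heat-capacity curve
#'
#' @param curve A [heat_capacity()] result.
#' @return The peak temperature.
#' @export
melting_temperature <- function(curve) attr(curve, "tm")

peak_parabolic <- function(x, y) {
  p <- which.max(y)
  if (p == 1L || p == length(y)) return(x[p])
  xs <- x[(p - 1L):(p + 1L)]
  ys <- y[(p - 1L):(p + 1L)]
  fit <- stats::lm(ys ~ xs + I(xs^2))
  a <- stats::coef(fit)
  if (!is.finite(a[3L]) || a[3L] >= 0) return(x[p])
  vertex <- -a[2L] / (2 * a[3L])
  if (vertex < xs[1L] || vertex > xs[3L]) x[p] else unname(vertex)
}

#' Multi-histogram (WHAM) density-of-states estimate
#'
#' Combines integer-energy histograms collected at several temperatures
#' into one density-of-states estimate by the standard self-consistent
#' iteration, run in log space.  Under the Go potential energies are exact
#' integers, so the histogram bin width is one reduced unit and there is no
#' binning ambiguity.
#'
#' @param pt A `pt_samples` object (or tibble with `temperature`,
#'   `samples`).
#' @param tol Convergence threshold on the maximum absolute change of the
#'   per-temperature free-energy shifts.
#' @param max_iter Iteration cap.
#' @param min_total Minimum total sample count.
#' @return A `wham_fit`: list with `dos` (tibble `energy`, `ln_omega`, up
#'   to an additive constant), `shifts`, `temperatures`, `iterations`,
#'   `residual`.
#' @export
wham <- function(pt, tol = 1e-7, max_iter = 1e5, min_total = 1e4) {
  eps <- attr(pt, "epsilon") %||% 1
  temps <- pt$temperature
  ord <- order(temps)
  temps <- temps[ord]
  samples <- pt$samples[ord]
  counts <- vapply(samples, length, integer(1))
  if (sum(counts) < min_total)
    rlang::abort(sprintf("WHAM needs >= %g total samples, got %d",
                         min_total, sum(counts)))
  all_e <- round(unlist(samples) / eps)
  grid <- seq(min(all_e), max(all_e))
  H <- vapply(samples, function(s)
    tabulate(round(s / eps) - grid[1L] + 1L, nbins = length(grid)),
    numeric(length(grid)))
  check_histogram_overlap(H, temps, grid)
  nt <- length(temps)
  lw <- outer(grid * eps, 1 / temps, function(e, b) -e * b)  # -E/T
  lnN <- log(counts)
  lnH <- log(rowSums(H))
  sampled <- rowSums(H) > 0
  f <- rep(0, nt)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # ln Omega(E) = ln sum_t H_t(E) - logsumexp_t(ln N_t + f_t - E/T_t)
    m <- sweep(lw, 2L, lnN + f, `+`)
    rmax <- apply(m, 1L, max)
    ln_omega <- lnH - (rmax + log(rowSums(exp(m - rmax))))
    # f_t = -logsumexp_E(ln Omega(E) - E/T_t)
    m2 <- lw[sampled, , drop = FALSE] + ln_omega[sampled]
    cmax <- apply(m2, 2L, max)
    fnew <- -(cmax + log(colSums(exp(sweep(m2, 2L, cmax, `-`)))))
    fnew <- fnew - fnew[1L]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol || iter >= max_iter) break
  }
  dos <- tibble::tibble(energy = grid[sampled] * eps,
                        ln_omega = ln_omega[sampled])
  structure(list(dos = dos, shifts = f, temperatures = temps,
                 iterations = iter, residual = delta, epsilon = eps),
            class = "wham_fit")
}

check_histogram_overlap <- function(H, temps, grid) {
  nt <- ncol(H)
  for (t in seq_len(nt - 1L)) {
    if (!any(H[, t] > 0 & H[, t + 1L] > 0))
      rlang::abort(sprintf(
        "histograms at T = %.4g and T = %.4g share no energy level; ladder too sparse",
        temps[t], temps[t + 1L]))
  }
  invisible(TRUE)
}

#' @export
print.wham_fit <- function(x, ...) {
  cat(sprintf("<wham_fit> %d temperatures, %d energy levels, %d iterations (residual %.2g)\n",
              length(x$temperatures), nrow(x$dos), x$iterations, x$residual))
  invisible(x)
}

#' Free-energy profile over the energy coordinate
#'
#' `F(E; T) = E - T ln Omega(E)` up to an additive constant, reweighted to
#' any requested temperature from a WHAM density-of-states estimate.  The
#' energy of the system is used as the reaction coordinate; under the Go
#' potential it is proportional to the fraction of native contacts.
#'
#' @param fit A [wham()] fit.
#' @param temperature Target temperature.
#' @return An `fe_profile` tibble with columns `energy`, `free_energy`
#'   (minimum shifted to zero), with the temperature in
#'   `attr(, "temperature")`.
#' @export
free_energy_profile <- function(fit, temperature) {
  check_temperature(temperature)
  f <- fit$dos$energy - temperature * fit$dos$ln_omega
  out <- tibble::tibble(energy = fit$dos$energy, free_energy = f - min(f))
  attr(out, "temperature") <- temperature
  class(out) <- c("fe_profile", class(out))
  out
}

#' Reweighted mean energy at an arbitrary temperature
#'
#' @param fit A [wham()] fit.
#' @param temperature Target temperature(s).
#' @return Mean energy under the WHAM density of states.
#' @export
wham_mean_energy <- function(fit, temperature) {
  vapply(temperature, function(tt) {
    lw <- fit$dos$ln_omega - fit$dos$energy / tt
    m <- max(lw)
    w <- exp(lw - m)
    sum(fit$dos$energy * w) / sum(w)
  }, numeric(1))
}

#' Heat capacity reweighted from a WHAM fit
#'
#' @param fit A [wham()] fit.
#' @param temperature Target temperature(s).
#' @return `Cv` from the reweighted energy fluctuations.
#' @export
wham_heat_capacity <- function(fit, temperature) {
  vapply(temperature, function(tt) {
    lw <- fit$dos$ln_omega - fit$dos$energy / tt
    m <- max(lw)
    w <- exp(lw - m)
    w <- w / sum(w)
    e1 <- sum(fit$dos$energy * w)
    (sum(fit$dos$energy^2 * w) - e1^2) / tt^2
  }, numeric(1))
}

#' Barrier analysis of a free-energy profile
#'
#' Locates the folded minimum (lowest-energy basin), the unfolded minimum
#' (global minimum above the barrier, near `E = 0` for a denatured chain)
#' and the global barrier between them.  The activation free energy is
#' `F(barrier) - F(unfolded)`.  Any additional local minimum between the
#' barrier and the folded minimum whose own flanking maxima exceed
#' `depth_threshold` marks a post-transition-state intermediate and the
#' profile is classified as non-two-state.
#'
#' All outputs are invariant under an additive shift of the profile.
#'
#' @param profile An `fe_profile` from [free_energy_profile()].
#' @param depth_threshold Minimum basin depth (reduced units) for an
#'   intermediate to count.
#' @return A `barrier_summary` one-row tibble: `temperature`, `e_folded`,
#'   `e_unfolded`, `e_barrier`, `dg_fold`, `dg_act`, `dg_act_thermal`
#'   (units of the profile temperature), `two_state`,
#'   `intermediate_energy`, `barrierless`.
#' @export
barrier_analysis <- function(profile, depth_threshold = 0.2) {
  e <- profile$energy
  f <- profile$free_energy
  tt <- attr(profile, "temperature")
  ord <- order(e)
  e <- e[ord]
  f <- f[ord]
  n <- length(e)
  if (n < 3L) rlang::abort("profile spans too few energy levels")
  is_min <- local_extrema(f, "min")
  is_max <- local_extrema(f, "max")
  mins <- which(is_min)
  if (length(mins) < 2L) {
    out <- tibble::tibble(temperature = tt, e_folded = e[which.min(f)],
                          e_unfolded = NA_real_, e_barrier = NA_real_,
                          dg_fold = NA_real_, dg_act = NA_real_,
                          dg_act_thermal = NA_real_, two_state = NA,
                          intermediate_energy = NA_real_, barrierless = TRUE)
    class(out) <- c("barrier_summary", class(out))
    return(out)
  }
  i_fold <- mins[1L]                 # lowest-energy basin
  i_unf0 <- mins[length(mins)]       # highest-energy basin
  seg <- (i_fold):(i_unf0)
  i_bar <- seg[which.max(f[seg])]
  above <- which(e > e[i_bar])
  i_unf <- above[which.min(f[above])]
  dg_act <- f[i_bar] - f[i_unf]
  dg_fold <- f[i_fold] - f[i_unf]
  # intermediates strictly between the folded minimum and the barrier
  inter <- NA_real_
  two_state <- TRUE
  inner <- mins[mins > i_fold & mins < i_bar]
  for (m in inner) {
    left_max <- max(f[(i_fold):(m)])
    right_max <- max(f[(m):(i_bar)])
    depth <- min(left_max, right_max) - f[m]
    if (depth >= depth_threshold) {
      two_state <- FALSE
      if (is.na(inter)) inter <- e[m]
    }
  }
  out <- tibble::tibble(temperature = tt, e_folded = e[i_fold],
                        e_unfolded = e[i_unf], e_barrier = e[i_bar],
                        dg_fold = dg_fold, dg_act = dg_act,
                        dg_act_thermal = dg_act / tt, two_state = two_state,
                        intermediate_energy = inter, barrierless = FALSE)
  class(out) <- c("barrier_summary", class(out))
  out
}

# Local extrema on a finite sequence; plateaus count at their first point,
# endpoints count when the interior neighbour is on the appropriate side.
local_extrema <- function(f, what = c("min", "max")) {
  what <- match.arg(what)
  g <- if (what == "min") -f else f
  n <- length(g)
  out <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) g[i] > g[i - 1L] else TRUE
    right <- if (i < n) g[i] > g[i + 1L] else TRUE
    # tolerate flat plateaus: strictly greater on at least one side,
    # not smaller on the other
    left_ge <- if (i > 1L) g[i] >= g[i - 1L] else TRUE
    right_ge <- if (i < n) g[i] >= g[i + 1L] else TRUE
    out[i] <- (left && right_ge) || (left_ge && right)
  }
  out
}
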