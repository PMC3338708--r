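fake_pt <- function(temps, samples, eps = 1) {
  out <- tibble::tibble(temperature = temps, samples = samples)
  attr(out, "epsilon") <- eps
  class(out) <- c("pt_samples", class(out))
  out
}

test_that("heat capacity: zero variance gives zero Cv; Schottky matches closed form", {
  temps <- seq(0.3, 1.2, length.out = 8)
  flat <- fake_pt(temps, purrr::map(temps, ~rep(-3, 2000)))
  cv <- heat_capacity(flat)
  expect_equal(cv$cv, rep(0, 8))

  # two-level system, gap delta, degeneracies (1, g): exact Schottky curve
  delta <- 2
  g <- 30
  set.seed(101)
  n <- 4e4
  samp <- purrr::map(temps, function(tt) {
    p0 <- 1 / (1 + g * exp(-delta / tt))  # ground E = 0, excited E = delta
    delta * stats::rbinom(n, 1, 1 - p0)
  })
  cv <- heat_capacity(fake_pt(temps, samp))
  p1 <- 1 - 1 / (1 + g * exp(-delta / temps))
  schottky <- delta^2 * p1 * (1 - p1) / temps^2
  se <- 4 * delta^2 / temps^2 / sqrt(n)  # generous SE on the variance
  expect_true(all(abs(cv$cv - schottky) < se + 0.02))

  expect_error(heat_capacity(fake_pt(temps, purrr::map(temps, ~rep(0, 10)))),
               "insufficient")
})

test_that("Tm sits at the heat-capacity peak, refined parabolically", {
  temps <- seq(0.4, 1.0, by = 0.05)
  cvs <- 5 - 40 * (temps - 0.63)^2
  pt <- fake_pt(temps, purrr::map(seq_along(temps), ~rnorm(1500)))
  curve <- heat_capacity(pt)
  curve$cv <- cvs  # inject an exact parabola
  attr(curve, "tm") <- latticefold:::peak_parabolic(curve$temperature,
                                                    curve$cv)
  expect_equal(melting_temperature(curve), 0.63, tolerance = 1e-8)
})

test_that("single-temperature WHAM reduces to the reweighting identity", {
  set.seed(7)
  e <- sample(-5:0, 2e4, replace = TRUE, prob = c(1, 2, 4, 8, 12, 20))
  fit <- wham(fake_pt(0.8, list(e)), min_total = 1e4)
  prof <- free_energy_profile(fit, 0.8)
  h <- table(factor(e, levels = -5:0))
  expected <- -0.8 * log(as.numeric(h))
  expect_equal(prof$free_energy, expected - min(expected), tolerance = 1e-6)
})

test_that("WHAM recovers two-level degeneracy ratios and is order-invariant", {
  delta <- 2
  g <- 30
  temps <- c(0.5, 0.8, 1.2)
  set.seed(11)
  samples <- purrr::map(temps, function(tt) {
    p1 <- g * exp(-delta / tt) / (1 + g * exp(-delta / tt))
    delta * stats::rbinom(2e4, 1, p1)
  })
  fit <- wham(fake_pt(temps, samples), min_total = 1e4)
  dos <- fit$dos
  expect_equal(nrow(dos), 2L)
  lng <- dos$ln_omega[dos$energy == delta] - dos$ln_omega[dos$energy == 0]
  expect_equal(lng, log(g), tolerance = 0.1)

  fit2 <- wham(fake_pt(rev(temps), rev(samples)), min_total = 1e4)
  d1 <- fit$dos$ln_omega - fit$dos$ln_omega[1]
  d2 <- fit2$dos$ln_omega - fit2$dos$ln_omega[1]
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("WHAM density of states matches exact enumeration on the 8-mer", {
  m <- toy8_model()
  ladder <- temperature_ladder(10, center = 0.55, span = c(0.5, 2.5))
  pt <- parallel_tempering(m, ladder, steps_per_round = 200,
                           n_rounds = 4000, burnin_rounds = 500, seed = 5)
  fit <- wham(pt, min_total = 1e4)
  cnt <- toy8_dos()
  exact <- log(cnt[-fit$dos$energy + 1])
  rel <- (fit$dos$ln_omega - fit$dos$ln_omega[1]) - (exact - exact[1])
  expect_true(all(abs(rel) < 0.15))

  # non-overlapping histograms are rejected with the gap named
  bad <- fake_pt(c(0.3, 2), list(rep(-5, 6000), rep(0, 6000)))
  expect_error(wham(bad, min_total = 1e4), "share no energy level")
})

test_that("Cv equals the temperature derivative of the reweighted mean energy", {
  fit <- wham(toy24()$pt, min_total = 1e4)
  tt <- seq(0.55, 0.72, by = 0.01)
  me <- wham_mean_energy(fit, tt)
  cv <- wham_heat_capacity(fit, tt)
  dnum <- diff(me) / diff(tt)
  mid <- (cv[-1] + cv[-length(cv)]) / 2
  expect_equal(dnum, mid, tolerance = 0.02)
})

test_that("barrier analysis annotates minima, barrier and intermediates", {
  # two-state V-shape: folded at -16, barrier at -8, unfolded at -2
  e <- -16:0
  f <- c(0, 3, 4.5, 5.5, 6.2, 6.8, 7.3, 7.7, 8, 7.5, 6.8, 6, 5.2, 4.5, 4,
         3.8, 4.2)
  bar <- barrier_analysis(make_profile(e, f, temperature = 0.6))
  expect_true(bar$two_state)
  expect_equal(bar$e_folded, -16)
  expect_equal(bar$e_barrier, -8)
  expect_equal(bar$e_unfolded, -1)
  expect_equal(bar$dg_act, 8 - 3.8)
  expect_equal(bar$dg_act_thermal, (8 - 3.8) / 0.6)
  expect_equal(bar$dg_fold, 0 - 3.8)

  # additive shifts leave the summary unchanged (gauge invariance)
  bar2 <- barrier_analysis(make_profile(e, f + 11.3, temperature = 0.6))
  expect_equal(as.data.frame(bar2), as.data.frame(bar))

  # an extra dip on the folded side marks a post-barrier intermediate
  f3 <- f
  f3[e == -13] <- f3[e == -13] - 2.5  # local minimum at E = -13
  bar3 <- barrier_analysis(make_profile(e, f3, temperature = 0.6))
  expect_false(bar3$two_state)
  expect_equal(bar3$intermediate_energy, -13)

  # shallow dips below the depth threshold do not break two-state
  f4 <- f
  f4[e == -13] <- f4[e == -13] - 0.05
  expect_true(barrier_analysis(make_profile(e, f4, 0.6),
                               depth_threshold = 0.2)$two_state)

  # monotone profile: flagged barrierless, not silently processed
  mono <- barrier_analysis(make_profile(-5:0, seq(0, 5, 1), 0.6))
  expect_true(mono$barrierless)
  expect_true(is.na(mono$dg_act))
})

test_that("the activation barrier peaks at the melting temperature", {
  t24 <- toy24()
  fit <- wham(t24$pt, min_total = 1e4)
  at_tm <- barrier_analysis(free_energy_profile(fit, t24$tm))$dg_act
  below <- barrier_analysis(free_energy_profile(fit, 0.95 * t24$tm))$dg_act
  expect_gte(at_tm, below - 0.05)
})

test_that("the toy free-energy profile has its folded minimum at -epsilon*n_contacts", {
  t24 <- toy24()
  fit <- wham(t24$pt, min_total = 1e4)
  bar <- barrier_analysis(free_energy_profile(fit, t24$tm))
  expect_equal(bar$e_folded, -t24$model$n_contacts)
})
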