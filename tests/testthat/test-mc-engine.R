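test_that("random coils are valid, diverse and seed-deterministic", {
  coils <- lapply(1:200, function(s) random_coil(48, seed = s))
  expect_true(all(vapply(coils, function(cc)
    validate_conformation(cc$coords)$ok, logical(1))))
  sigs <- vapply(coils, function(cc) paste(t(cc$coords), collapse = ","),
                 character(1))
  expect_gt(length(unique(sigs)), 190)
  expect_identical(random_coil(48, seed = 5)$coords,
                   random_coil(48, seed = 5)$coords)
})

test_that("move candidates match the geometric enumeration oracle", {
  # rod: no interior moves, four end-moves at each terminus
  rod <- cbind(0:5, 0L, 0L)
  expect_equal(nrow(move_candidates(rod, 2)), 0L)
  ends <- move_candidates(rod, 0)
  expect_equal(nrow(ends), 4L)
  expect_setequal(move_set_signature(oracle_moves(rod, 0)),
                  move_set_signature(purrr::transpose(ends[-1])))

  # L-shaped 3-mer: exactly one corner flip to the opposite corner
  ell <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  mc <- move_candidates(ell, 1)
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$kind, "corner-flip")
  expect_equal(as.vector(mc$new_coords[[1]]), c(0, 1, 0))

  # U-shaped 4-mer: three crankshaft rotations of the middle pair
  u4 <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0))
  mc <- move_candidates(u4, 1)
  expect_equal(sort(table(mc$kind), decreasing = TRUE),
               sort(c(crankshaft = 3L)), ignore_attr = TRUE)

  # property: engine enumeration equals the oracle at every bead of coils
  for (s in 1:15) {
    conf <- random_coil(12, seed = 3000 + s)
    for (b in 0:11) {
      got <- move_candidates(conf, b)
      got_l <- if (nrow(got)) purrr::transpose(got[-1]) else list()
      expect_setequal(move_set_signature(got_l),
                      move_set_signature(oracle_moves(conf$coords, b)))
    }
  }
})

test_that("propose_move draws from the fixed slot space", {
  conf <- random_coil(10, seed = 77)
  seen_null <- FALSE
  seen_move <- FALSE
  for (s in 1:60) {
    pr <- propose_move(conf, seed = s)
    if (is.null(pr)) {
      seen_null <- TRUE
    } else {
      seen_move <- TRUE
      expect_true(pr$kind %in% c("end-move", "corner-flip", "crankshaft"))
    }
  }
  expect_true(seen_null && seen_move)
})

test_that("downhill moves are always accepted and uphill moves frozen out at low T", {
  m <- toy8_model()
  conf <- random_coil(8, seed = 4)
  r <- run_mc(conf, m, temperature = 1e-3, n_steps = 2e4, seed = 1,
              sample_stride = 10)
  expect_true(all(diff(r$energies) <= 0))
  # the native state is absorbing at low temperature
  r2 <- run_mc(m$native, m, temperature = 1e-3, n_steps = 5e3, seed = 2)
  expect_equal(r2$energy, -5)
})

test_that("Metropolis sampling matches exact Boltzmann enumeration on the 8-mer", {
  m <- toy8_model()
  temp <- 0.7
  cnt <- toy8_dos()
  p_exact <- cnt * exp((0:5) / temp)
  p_exact <- p_exact / sum(p_exact)
  r <- run_mc(random_coil(8, 3), m, temp, n_steps = 2e6, seed = 42,
              sample_stride = 20, burnin = 2e4)
  lev <- -r$energies
  for (e in 0:5) {
    if (cnt[e + 1] == 0) {
      expect_equal(sum(lev == e), 0)
      next
    }
    ind <- as.numeric(lev == e)
    se <- max(batch_se(ind), 1e-4)
    expect_lt(abs(mean(ind) - p_exact[e + 1]), 3 * se + 0.004)
  }
})

test_that("energies stay integer multiples of epsilon within the native range", {
  m <- toy8_model()
  r <- run_mc(random_coil(8, 9), m, 0.8, n_steps = 1e5, seed = 3,
              sample_stride = 7)
  expect_true(all(r$energies == round(r$energies)))
  expect_true(all(r$energies <= 0 & r$energies >= -5))
})

test_that("folding trajectories detect first passage and are reproducible", {
  m <- go_model(compact_cuboid_path(c(2, 3, 3)))
  t0 <- run_folding_trajectory(m, 0.6, seed = 1, start = m$native)
  expect_equal(t0$fpt, 0)
  expect_true(t0$reached)

  a <- run_folding_trajectory(m, 0.6, seed = 11, max_steps = 1e7,
                              energy_stride = 500)
  b <- run_folding_trajectory(m, 0.6, seed = 11, max_steps = 1e7,
                              energy_stride = 500)
  expect_identical(a$fpt, b$fpt)
  expect_identical(a$energies, b$energies)
  expect_identical(a$final$coords, b$final$coords)
  expect_true(fraction_native(a$final, m) == 1 || !a$reached)

  censored <- run_folding_trajectory(m, 0.6, seed = 12, max_steps = 100)
  expect_false(censored$reached)
  expect_true(is.na(censored$fpt))
})

test_that("first passage times are roughly exponential beyond a transient", {
  m <- go_model(compact_cuboid_path(c(2, 3, 3)))
  kin <- run_kinetics(m, 0.62, n_trajectories = 400, seed = 5,
                      max_steps = 1e7)
  expect_true(all(kin$reached))
  fit <- folding_rate(kin)
  expect_false(fit$flagged)
  expect_gt(fit$k, 0)
})

test_that("replica exchange: equal temperatures always swap, means rise with T", {
  m <- toy8_model()
  # equal-temperature pair: the swap exponent vanishes identically
  res <- latticefold:::cpp_parallel_tempering(
    m$native$coords, as.matrix(m$contacts), c(0.7, 0.7 + 1e-12),
    50, 200, 50, 1)
  expect_equal(as.numeric(res$swap_acceptance), 1)

  ladder <- temperature_ladder(8, center = 0.55, span = c(0.5, 2.5))
  pt <- parallel_tempering(m, ladder, steps_per_round = 200,
                           n_rounds = 3000, burnin_rounds = 500, seed = 6)
  means <- vapply(pt$samples, mean, numeric(1))
  expect_true(all(diff(means) > -0.05))

  # per-temperature means match independent single-temperature chains
  for (idx in c(2, 5, 8)) {
    ref <- run_mc(m$native, m, ladder[idx], n_steps = 3e5, seed = 60 + idx,
                  sample_stride = 20, burnin = 2e4)
    se <- sqrt(batch_se(ref$energies)^2 + batch_se(pt$samples[[idx]])^2)
    expect_lt(abs(mean(ref$energies) - means[idx]), 4 * se + 0.02)
  }
})
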