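test_that("candidate harvesting equals a direct energy filter with deduplication", {
  m <- go_model(compact_cuboid_path(c(2, 3, 3)))
  confs <- lapply(1:30, function(s) random_coil(18, seed = 400 + s))
  energies <- vapply(confs, go_energy, numeric(1), model = m)
  snaps <- tibble::tibble(step = seq_along(confs) * 100,
                          energy = energies, conf = confs, traj = 1L)
  bar_e <- stats::median(energies)
  got <- harvest_candidates(snaps, bar_e, window = 1)
  keep <- abs(energies - bar_e) <= 1
  sigs <- vapply(confs[keep], latticefold:::conf_signature, character(1))
  expect_equal(nrow(got), length(unique(sigs)))
  expect_true(all(abs(got$energy - bar_e) <= 1))

  # a translated duplicate is removed
  shifted <- confs[[1]]
  shifted$coords <- shifted$coords + 5L
  snaps2 <- tibble::tibble(step = c(1, 2),
                           energy = rep(energies[1], 2),
                           conf = list(confs[[1]], shifted), traj = 1L)
  expect_equal(nrow(harvest_candidates(snaps2, energies[1], window = 0)), 1L)

  expect_error(harvest_candidates(snaps, max(energies) + 10, window = 0.5),
               "denser snapshot stride")
})

test_that("pfold is 1 from the native state and 0 below the unfold threshold", {
  m <- go_model(compact_cuboid_path(c(2, 3, 3)))
  pf <- pfold(m$native, m, temperature = 0.6, n_trials = 50, seed = 1)
  expect_equal(pf$pfold, 1)
  coil <- random_coil(18, seed = 2)  # Q = 0 at the start
  pf0 <- pfold(coil, m, temperature = 0.6, n_trials = 50, seed = 1)
  expect_equal(pf0$pfold, 0)
})

test_that("pfold estimates agree between M and 10M trials within 3 binomial SE", {
  t24 <- toy24()
  m <- t24$model
  kin <- run_kinetics(m, t24$tm, n_trajectories = 20, seed = 31,
                      max_steps = 1e8, snapshot_stride = 200,
                      snapshot_window = c(-17, -15))
  snaps <- attr(kin, "snapshots")
  conf <- snaps$conf[[which.min(abs(snaps$energy + 16))]]
  p1 <- pfold(conf, m, t24$tm, n_trials = 100, seed = 7)
  p2 <- pfold(conf, m, t24$tm, n_trials = 1000, seed = 8)
  se <- sqrt(p1$se^2 + p2$se^2)
  expect_lt(abs(p1$pfold - p2$pfold), 3 * se + 0.01)
})

test_that("TSE selection equals a direct band filter", {
  confs <- lapply(1:12, function(s) random_coil(18, seed = 600 + s))
  cand <- tibble::tibble(
    conf = confs, energy = rep(-8, 12),
    pfold = c(0.5, 0.52, 0.61, 0.9, 0.12, 0.45, 0.40, 0.58, 0.71, 0.50,
              0.39, 0.05),
    se = c(rep(0.049, 11), 0.2))
  tse <- select_tse(cand, band = 0.1, se_max = 0.05, min_size = 2)
  manual <- abs(cand$pfold - 0.5) <= 0.1 & cand$se <= 0.05
  expect_equal(nrow(tse), sum(manual))
  expect_true(all(abs(tse$pfold - 0.5) <= 0.1))

  cand_far <- dplyr::mutate(cand, pfold = 0.95, se = 0.02)
  expect_error(select_tse(cand_far, band = 0.1), "empty transition-state")
  expect_warning(select_tse(cand, band = 0.1, min_size = 50),
                 "only .* members")
})

test_that("CO of the transition-state ensemble averages member contact orders", {
  m <- go_model(compact_cuboid_path(c(2, 3, 3)))
  # single-member ensemble = native: CO_TSE equals the native CO
  tse1 <- tibble::tibble(conf = list(m$native), energy = -16,
                         pfold = 0.5, se = 0.04)
  class(tse1) <- c("tse_record", class(tse1))
  expect_equal(co_tse(tse1, m), contact_order(m$contacts))

  # hand-built three-member ensemble: manual average over formed contacts
  members <- lapply(c(21, 33, 47), function(s) random_coil(18, seed = s))
  per <- vapply(members, function(cc) {
    formed <- latticefold:::formed_native_contacts(cc, m)
    if (nrow(formed) == 0) NA_real_ else mean(formed$j - formed$i)
  }, numeric(1))
  tse3 <- tibble::tibble(conf = members, energy = -8, pfold = 0.5, se = 0.04)
  class(tse3) <- c("tse_record", class(tse3))
  if (anyNA(per)) {
    expect_warning(got <- co_tse(tse3, m), "zero native contacts")
  } else {
    got <- co_tse(tse3, m)
  }
  expect_equal(got, mean(per, na.rm = TRUE))
})

test_that("optimal-superposition RMSD is a proper congruence metric", {
  a <- random_coil(10, seed = 1)
  expect_equal(rmsd_to_native(a, a), 0, tolerance = 1e-9)

  shifted <- a$coords + matrix(c(5L, 5L, 5L), 10, 3, byrow = TRUE)
  expect_equal(rmsd_to_native(shifted, a), 0, tolerance = 1e-9)

  rot90z <- a$coords %*% matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(rmsd_to_native(rot90z, a), 0, tolerance = 1e-9)

  b <- random_coil(10, seed = 2)
  expect_equal(rmsd_to_native(a, b), rmsd_to_native(b, a), tolerance = 1e-9)
  expect_gt(rmsd_to_native(a, b), 0)
  expect_error(rmsd_to_native(a, random_coil(12, seed = 3)), "mismatch")
})

test_that("RMSD never exceeds the 24-rotation brute-force oracle", {
  for (s in 1:10) {
    a <- random_coil(6, seed = 700 + s)
    b <- random_coil(6, seed = 800 + s)
    k <- rmsd_to_native(a, b)
    o <- oracle_rmsd_24(a$coords, b$coords)
    expect_lte(k, o + 1e-9)
  }
  # congruent chains: the optimum is attained at a lattice rotation
  a <- random_coil(8, seed = 19)
  rot <- a$coords %*% matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3)
  expect_equal(rmsd_to_native(rot, a), oracle_rmsd_24(rot, a$coords),
               tolerance = 1e-9)
})

test_that("the transition-state network equals the counting oracle and is monotone", {
  m <- go_model(compact_cuboid_path(c(2, 3, 3)))
  members <- lapply(c(5, 9, 13, 21), function(s) random_coil(18, seed = s))
  tse <- tibble::tibble(conf = members, energy = -8, pfold = 0.5, se = 0.04)
  class(tse) <- c("tse_record", class(tse))

  # counting oracle
  freq <- sapply(seq_len(nrow(m$contacts)), function(r) {
    pair <- c(m$contacts$i[r], m$contacts$j[r])
    mean(vapply(members, function(cc) {
      fc <- oracle_contacts(cc$coords)
      nrow(fc) > 0 && any(fc[, 1] == pair[1] & fc[, 2] == pair[2])
    }, logical(1)))
  })
  tsn <- transition_state_network(tse, m, p_star = 0.25)
  expect_equal(attr(tsn, "frequencies")$frequency, freq)
  expect_equal(nrow(tsn), sum(freq >= 0.25))
  expect_equal(attr(tsn, "co_tsn"),
               mean((m$contacts$j - m$contacts$i)[freq >= 0.25]))

  # monotone in the threshold; p* > 1 empty; p* = 0 the full native map
  sizes <- vapply(c(0, 0.25, 0.5, 0.75, 1.01), function(p)
    nrow(transition_state_network(tse, m, p_star = p)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], m$n_contacts)
  expect_equal(sizes[5], 0L)
  empty <- transition_state_network(tse, m, p_star = 1.01)
  expect_true(is.na(attr(empty, "co_tsn")))

  # invariant under member relabeling
  tse_rev <- tse[rev(seq_len(nrow(tse))), ]
  class(tse_rev) <- c("tse_record", class(tse_rev))
  expect_equal(attr(transition_state_network(tse_rev, m, 0.25), "co_tsn"),
               attr(tsn, "co_tsn"))
})
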