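#' Random-coil starting conformation
#'
#' Uniform-attempt self-avoiding walk: each bond direction is drawn
#' uniformly from the six lattice directions and the walk is restarted on
#' any collision, so accepted walks are uniform over all N-bead
#' self-avoiding walks.  Deterministic given the seed.
#'
#' @param n Chain length (>= 4).
#' @param seed Integer seed.
#' @param max_tries Restart budget.
#' @return A `lattice_conf`.
#' @export
random_coil <- function(n, seed, max_tries = 1e7) {
  if (n < 4L) rlang::abort("n must be >= 4")
  lattice_conformation(cpp_random_coil(n, seed, max_tries))
}

#' Enumerate the legal elementary moves at one bead
#'
#' The local move set comprises end-moves (terminal bead re-placed at a free
#' neighbour of its bonded neighbour), corner flips (a right-angle bead
#' moved across the square diagonal) and crankshafts (a U-shaped pair of
#' beads rotated by 90/180/270 degrees about the axis through its flanking
#' beads).  Each bead has a fixed slot space (6 slots at the termini, 7 in
#' the interior), so the proposal distribution of [propose_move()] is
#' symmetric and Metropolis acceptance preserves detailed balance.
#'
#' @param conf A `lattice_conf` or coordinate matrix.
#' @param bead 0-based bead index.
#' @return Tibble with columns `slot`, `kind`, `beads` (list of 0-based
#'   indices) and `new_coords` (list of candidate coordinate rows); zero
#'   rows when no legal move exists at the bead.
#' @export
move_candidates <- function(conf, bead) {
  coords <- as_coord_matrix(conf)
  res <- cpp_move_candidates(coords, as.integer(bead))
  if (!length(res))
    return(tibble::tibble(slot = integer(), kind = character(),
                          beads = list(), new_coords = list()))
  purrr::map_dfr(res, function(m)
    tibble::tibble(slot = m$slot, kind = m$kind, beads = list(m$beads),
                   new_coords = list(m$new_coords)))
}

#' Propose one elementary move
#'
#' Picks a bead uniformly, then one of its move slots uniformly; returns
#' `NULL` when the drawn slot holds no legal, self-avoiding candidate (a
#' null proposal, which still consumes one MC time unit in the sampler).
#'
#' @param conf A `lattice_conf`.
#' @param seed Integer seed.
#' @return A list with `kind`, `beads` (0-based) and `new_coords`, or
#'   `NULL`.
#' @export
propose_move <- function(conf, seed) {
  coords <- as_coord_matrix(conf)
  n <- nrow(coords)
  rng <- splitmix_pair(seed)
  bead <- rng[1L] %% n
  k <- if (bead == 0L || bead == n - 1L) 6L else 7L
  slot <- rng[2L] %% k
  cand <- move_candidates(coords, bead)
  hit <- which(cand$slot == slot)
  if (!length(hit)) return(NULL)
  list(kind = cand$kind[hit], beads = cand$beads[[hit]],
       new_coords = cand$new_coords[[hit]])
}

splitmix_pair <- function(seed) {
  x <- (as.numeric(seed) * 69069 + 1) %% 2147483647
  y <- (x * 69069 + 1) %% 2147483647
  as.integer(c(x %% 1e9, y %% 1e9))
}

#' Fixed-temperature Metropolis run
#'
#' Standard Metropolis MC with the local move set; one attempted elementary
#' move is one MC step, and null or rejected proposals advance time without
#' changing the chain.  Acceptance probability is
#' `min(1, exp(-dE / T))` with `kB = 1`.
#'
#' @param conf Starting `lattice_conf`.
#' @param model A [go_model()].
#' @param temperature Temperature in reduced units (> 0).
#' @param n_steps Number of MC steps.
#' @param seed Integer seed.
#' @param sample_stride Record the energy every this many steps (0 = none).
#' @param burnin Steps to discard before sampling.
#' @return A list with `energies` (reduced units), `final` (the final
#'   `lattice_conf`), `acceptance` and `energy` (final energy).
#' @export
run_mc <- function(conf, model, temperature, n_steps, seed,
                   sample_stride = 0, burnin = 0) {
  check_temperature(temperature)
  if (conf$n != model$n) rlang::abort("chain length mismatch")
  res <- cpp_run_mc(conf$coords, as.matrix(model$contacts), FALSE,
                    temperature / model$epsilon, n_steps, sample_stride,
                    burnin, seed)
  list(energies = res$energies * model$epsilon,
       final = lattice_conformation(res$final),
       acceptance = res$acceptance, energy = res$energy * model$epsilon)
}

#' Single Metropolis step
#'
#' @inheritParams run_mc
#' @return The (possibly unchanged) `lattice_conf` after one attempted move.
#' @export
metropolis_step <- function(conf, model, temperature, seed) {
  run_mc(conf, model, temperature, n_steps = 1, seed = seed)$final
}

check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    rlang::abort("temperature must be a single positive number")
}

#' Single folding trajectory
#'
#' Starts from a random coil (or a supplied conformation) and runs until all
#' native contacts are formed; the first passage time is the index of the
#' first step at which the fraction of native contacts reaches 1.
#' Trajectories that do not fold within `max_steps` are returned flagged,
#' not dropped.
#'
#' @param model A [go_model()].
#' @param temperature Simulation temperature (reduced units).
#' @param seed Integer seed (also seeds the random coil).
#' @param max_steps Step budget.
#' @param snapshot_stride Record a conformation snapshot every this many
#'   steps (0 disables snapshots).
#' @param snapshot_window Optional numeric `c(lo, hi)`: record only
#'   snapshots whose energy lies in the window (reduced units).
#' @param energy_stride Record the energy every this many steps (0 = none).
#' @param start Optional starting `lattice_conf` (default: random coil).
#' @param max_snapshots Snapshot storage cap.
#' @return A `folding_traj`: list with `fpt`, `reached`, `energies`,
#'   `snapshots` (tibble `step`, `energy`, `conf`), `temperature`, `seed`.
#' @export
run_folding_trajectory <- function(model, temperature, seed,
                                   max_steps = 1e9, snapshot_stride = 1000,
                                   snapshot_window = NULL,
                                   energy_stride = 0, start = NULL,
                                   max_snapshots = 1e5) {
  check_temperature(temperature)
  if (is.null(start)) start <- random_coil(model$n, child_seed(seed, 777))
  if (start$n != model$n) rlang::abort("chain length mismatch")
  win <- snapshot_window_int(snapshot_window, model)
  res <- cpp_folding_traj(start$coords, as.matrix(model$contacts),
                          temperature / model$epsilon, max_steps, seed,
                          snapshot_stride, win[1L], win[2L], energy_stride,
                          max_snapshots)
  snaps <- snapshot_tibble(res, model)
  structure(list(fpt = res$fpt, reached = res$reached,
                 energies = res$energies * model$epsilon, snapshots = snaps,
                 final = lattice_conformation(res$final),
                 temperature = temperature, seed = seed,
                 max_steps = max_steps),
            class = "folding_traj")
}

snapshot_window_int <- function(snapshot_window, model) {
  if (is.null(snapshot_window))
    return(c(-model$n_contacts, 0L))
  w <- sort(round(snapshot_window / model$epsilon))
  c(as.integer(w[1L]), as.integer(w[2L]))
}

snapshot_tibble <- function(res, model) {
  nsnap <- length(res$snap_step)
  confs <- purrr::map(seq_len(nsnap), function(r) {
    m <- matrix(res$snapshots[r, ], ncol = 3L, byrow = TRUE)
    lattice_conformation(m, validate = FALSE)
  })
  tibble::tibble(step = as.numeric(res$snap_step),
                 energy = as.numeric(res$snap_energy) * model$epsilon,
                 conf = confs)
}

#' @export
print.folding_traj <- function(x, ...) {
  cat(sprintf("<folding_traj> T = %g, %s, %d snapshots\n", x$temperature,
              if (x$reached) sprintf("FPT = %.0f", x$fpt) else
                sprintf("not reached within %.3g steps", x$max_steps),
              nrow(x$snapshots)))
  invisible(x)
}

#' Kinetic ensemble of independent folding trajectories
#'
#' Each trajectory starts from a different random coil and stops when the
#' native structure is reached (or at `max_steps`, in which case it is
#' counted as censored).
#'
#' @inheritParams run_folding_trajectory
#' @param n_trajectories Number of independent trajectories (500 in the
#'   reference study conditions).
#' @param seed Master seed; trajectory `i` uses a derived seed.
#' @param snapshot_stride,snapshot_window Passed to each trajectory; leave
#'   `snapshot_stride = 0` unless snapshots are needed for transition-state
#'   harvesting.
#' @return An `fpt_ensemble`: tibble with columns `traj`, `seed`, `fpt`,
#'   `reached`, with attributes `temperature`, `label`, `max_steps` and
#'   (when requested) `snapshots`.
#' @export
run_kinetics <- function(model, temperature, n_trajectories = 500L, seed = 1L,
                         max_steps = 1e9, snapshot_stride = 0,
                         snapshot_window = NULL, max_snapshots = 2e4) {
  check_temperature(temperature)
  runs <- purrr::map(seq_len(n_trajectories), function(i) {
    run_folding_trajectory(model, temperature, seed = child_seed(seed, i),
                           max_steps = max_steps,
                           snapshot_stride = snapshot_stride,
                           snapshot_window = snapshot_window,
                           max_snapshots = max_snapshots)
  })
  out <- tibble::tibble(
    traj = seq_len(n_trajectories),
    seed = vapply(runs, function(r) r$seed, numeric(1)),
    fpt = vapply(runs, function(r) if (r$reached) r$fpt else NA_real_,
                 numeric(1)),
    reached = vapply(runs, function(r) r$reached, logical(1)))
  attr(out, "temperature") <- temperature
  attr(out, "label") <- model$label
  attr(out, "max_steps") <- max_steps
  if (snapshot_stride > 0) {
    snaps <- purrr::imap_dfr(runs, function(r, i)
      dplyr::mutate(r$snapshots, traj = i))
    attr(out, "snapshots") <- snaps
  }
  class(out) <- c("fpt_ensemble", class(out))
  out
}

#' Geometric temperature ladder
#'
#' About 50 geometrically spaced temperatures bracketing the folding
#' transition (default span one half to twice the centre temperature) give
#' replica exchange a representative sweep from the native to the thermally
#' denatured state.
#'
#' @param n Number of temperatures.
#' @param center Centre temperature, typically a pilot estimate of the
#'   melting temperature.
#' @param span Multiplicative range around `center`.
#' @return Strictly increasing numeric vector.
#' @export
temperature_ladder <- function(n = 50L, center = 0.75, span = c(0.5, 2)) {
  exp(seq(log(center * span[1L]), log(center * span[2L]), length.out = n))
}

#' Parallel-tempering (replica-exchange) equilibrium sampling
#'
#' Each replica advances independently between swap attempts; adjacent-pair
#' swaps are accepted with probability
#' `min(1, exp((1/T_i - 1/T_j) (E_i - E_j)))`, alternating pair parity
#' between rounds.  One energy sample per temperature is recorded each round
#' after burn-in.
#'
#' @param model A [go_model()].
#' @param temperatures Strictly increasing ladder (>= 2 values), e.g. from
#'   [temperature_ladder()].
#' @param steps_per_round MC steps per replica between swap attempts.
#' @param n_rounds Total swap rounds.
#' @param burnin_rounds Rounds discarded before sampling.
#' @param seed Integer seed.
#' @param start Starting `lattice_conf` for every replica (default: the
#'   native structure, which low-temperature replicas equilibrate in place
#'   and high-temperature replicas melt).
#' @return A `pt_samples` tibble with columns `temperature` and `samples`
#'   (list of energy vectors, reduced units), and attribute
#'   `swap_acceptance`.
#' @export
parallel_tempering <- function(model, temperatures, steps_per_round = 2000,
                               n_rounds = 1500L, burnin_rounds = 300L,
                               seed = 1L, start = NULL) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 2L || any(diff(temperatures) <= 0))
    rlang::abort("temperatures must be a strictly increasing ladder of >= 2 values")
  if (is.null(start)) start <- model$native
  res <- cpp_parallel_tempering(start$coords, as.matrix(model$contacts),
                                temperatures / model$epsilon, steps_per_round,
                                n_rounds, burnin_rounds, seed)
  out <- tibble::tibble(
    temperature = temperatures,
    samples = purrr::map(seq_along(temperatures),
                         function(t) res$samples[, t] * model$epsilon))
  attr(out, "swap_acceptance") <- res$swap_acceptance
  attr(out, "label") <- model$label
  attr(out, "epsilon") <- model$epsilon
  class(out) <- c("pt_samples", class(out))
  out
}
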