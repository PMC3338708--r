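#' Ordinary least-squares line with Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3 points; `x` must not be
#'   constant).
#' @return A one-row tibble: `slope`, `intercept`, `r` (Pearson), `n`.
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) rlang::abort("need at least 3 finite points")
  if (stats::sd(x) == 0) rlang::abort("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  tibble::tibble(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = stats::cor(x, y), n = length(x))
}

#' Study configuration
#'
#' Bundle of the tunable parameters of a family study.  The defaults are
#' the reference study conditions: a ladder of about 50 replica
#' temperatures spanning half to twice the pilot melting-temperature
#' estimate, 500 folding trajectories per permutant simulated at its own
#' melting temperature, and the transition-state parameters (Pfold band
#' 0.1 with 100 trials, unfold threshold Q = 0.2, harvest window of one
#' reduced unit, network threshold 0.5).  Every value is config-exposed;
#' desk-scale runs shrink the sampling parameters, never the physics.
#'
#' @param n_replicas Number of parallel-tempering replicas.
#' @param ladder Optional explicit temperature ladder (overrides
#'   `n_replicas`/`ladder_span` and the pilot estimate).
#' @param ladder_span Multiplicative span of the ladder around the pilot
#'   melting-temperature estimate.
#' @param steps_per_round,pt_rounds,pt_burnin Parallel-tempering sampling
#'   effort.
#' @param n_trajectories Folding trajectories per permutant.
#' @param max_steps Per-trajectory step cap (censoring boundary).
#' @param min_samples Minimum equilibrium samples per temperature.
#' @param depth_threshold Intermediate-detection depth (reduced units).
#' @param pfold_trials,pfold_band,pfold_se_max,q_unfold Pfold trial count,
#'   acceptance band, maximum standard error and unfold threshold.
#' @param harvest_window,p_star,tse_min_size,tse_max_candidates
#'   Transition-state harvest window, network threshold and ensemble-size
#'   controls.
#' @param co_split Contact-order threshold for the split correlation
#'   analysis.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_replicas = 50L, ladder = NULL,
                         ladder_span = c(0.5, 2), steps_per_round = 3000,
                         pt_rounds = 2500L, pt_burnin = 500L,
                         n_trajectories = 500L, max_steps = 1e9,
                         min_samples = 1000L, depth_threshold = 0.2,
                         pfold_trials = 100L, pfold_band = 0.1,
                         pfold_se_max = 0.05, q_unfold = 0.2,
                         harvest_window = 1, p_star = 0.5,
                         tse_min_size = 50L, tse_max_candidates = 400L,
                         co_split = 18.5) {
  structure(as.list(environment()), class = "study_config")
}

#' Pilot estimate of the melting temperature
#'
#' A short, coarse parallel-tempering run whose heat-capacity peak centres
#' the production ladder.
#'
#' @param model A [go_model()].
#' @param seed Integer seed.
#' @param span Coarse ladder range (reduced units).
#' @param n_temps,steps_per_round,n_rounds,burnin_rounds Pilot effort.
#' @return Estimated melting temperature.
#' @export
estimate_tm_pilot <- function(model, seed = 1L, span = c(0.3, 1.6),
                              n_temps = 16L, steps_per_round = 1500,
                              n_rounds = 1500L, burnin_rounds = 300L) {
  ladder <- exp(seq(log(span[1L]), log(span[2L]), length.out = n_temps))
  pt <- parallel_tempering(model, ladder, steps_per_round = steps_per_round,
                           n_rounds = n_rounds,
                           burnin_rounds = burnin_rounds, seed = seed)
  melting_temperature(heat_capacity(pt, min_samples = 100L))
}

#' Run the full thermodynamic/kinetic study of a permutant family
#'
#' For every circular permutant of the parent: replica-exchange equilibrium
#' sampling, heat capacity and melting temperature, WHAM free-energy
#' profile at the melting temperature, barrier analysis with two-state
#' classification, and first-passage-time kinetics at the melting
#' temperature with a single-exponential rate fit.  Optionally the
#' transition-state ensemble and network.  A single master seed spawns
#' deterministic per-permutant, per-stage streams.
#'
#' @param parent A `parent_structure`.
#' @param config A [study_config()].
#' @param seed Master seed.
#' @param epsilon Interaction energy.
#' @param do_tse Also run the Pfold/transition-state analysis per
#'   permutant.
#' @param keep Optional integer vector of permutant cut indices `k` to
#'   analyze (default: all).
#' @param verbose Print per-permutant progress.
#' @return A `family_study`: tibble with one row per analyzed permutant
#'   (`label`, `k`, `co`, `n_contacts`, `tm`, `dg_fold`, `dg_act`,
#'   `dg_act_thermal`, `ln_k`, `k_rate`, `fit_resid`, `n_censored`,
#'   `two_state`, `intermediate_energy`, plus transition-state columns when
#'   requested), with the parent, config and free-energy profiles in
#'   attributes.
#' @export
run_family_study <- function(parent, config = study_config(), seed = 1L,
                             epsilon = 1, do_tse = FALSE, keep = NULL,
                             verbose = FALSE) {
  family <- cp_family(parent, epsilon = epsilon)
  if (!is.null(keep)) family <- family[family$k %in% keep, ]
  ladder <- config$ladder
  if (is.null(ladder)) {
    tm0 <- estimate_tm_pilot(family$model[[1L]], seed = child_seed(seed, 1))
    ladder <- temperature_ladder(config$n_replicas, center = tm0,
                                 span = config$ladder_span)
  }
  profiles <- vector("list", nrow(family))
  rows <- vector("list", nrow(family))
  for (idx in seq_len(nrow(family))) {
    model <- family$model[[idx]]
    kk <- family$k[idx]
    if (verbose)
      message(sprintf("permutant k = %d (%s)", kk, family$label[idx]))
    pt <- parallel_tempering(model, ladder,
                             steps_per_round = config$steps_per_round,
                             n_rounds = config$pt_rounds,
                             burnin_rounds = config$pt_burnin,
                             seed = child_seed(seed, kk, 1))
    cv <- heat_capacity(pt, min_samples = config$min_samples)
    tm <- melting_temperature(cv)
    wf <- wham(pt, min_total = min(1e4, sum(vapply(pt$samples, length,
                                                   integer(1)))))
    prof <- free_energy_profile(wf, tm)
    bar <- barrier_analysis(prof, depth_threshold = config$depth_threshold)
    profiles[[idx]] <- prof
    snap_stride <- 0
    snap_window <- NULL
    if (do_tse && !bar$barrierless) {
      snap_stride <- max(10, round(model$n * 10))
      snap_window <- c(bar$e_barrier - config$harvest_window,
                       bar$e_barrier + config$harvest_window)
    }
    kin <- run_kinetics(model, tm, n_trajectories = config$n_trajectories,
                        seed = child_seed(seed, kk, 2),
                        max_steps = config$max_steps,
                        snapshot_stride = snap_stride,
                        snapshot_window = snap_window)
    rate <- tryCatch(folding_rate(kin), error = function(e) NULL)
    row <- tibble::tibble(
      label = family$label[idx], k = kk, co = family$co[idx],
      n_contacts = family$n_contacts[idx], tm = tm,
      e_folded = bar$e_folded, e_barrier = bar$e_barrier,
      dg_fold = bar$dg_fold, dg_act = bar$dg_act,
      dg_act_thermal = bar$dg_act_thermal,
      k_rate = if (is.null(rate)) NA_real_ else rate$k,
      ln_k = if (is.null(rate)) NA_real_ else rate$ln_k,
      fit_resid = if (is.null(rate)) NA_real_ else rate$resid_rms,
      n_censored = sum(!kin$reached),
      two_state = bar$two_state,
      intermediate_energy = bar$intermediate_energy,
      barrierless = bar$barrierless)
    if (do_tse && !bar$barrierless) {
      tse_res <- tryCatch(
        analyze_tse(attr(kin, "snapshots"), model, bar, tm,
                    seed = child_seed(seed, kk, 3),
                    window = config$harvest_window,
                    n_trials = config$pfold_trials,
                    q_unfold = config$q_unfold, band = config$pfold_band,
                    se_max = config$pfold_se_max,
                    min_size = config$tse_min_size, p_star = config$p_star,
                    max_candidates = config$tse_max_candidates),
        error = function(e) NULL)
      if (!is.null(tse_res)) row <- dplyr::bind_cols(row, tse_res$summary)
    }
    rows[[idx]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "parent") <- parent
  attr(out, "config") <- config
  attr(out, "ladder") <- ladder
  attr(out, "profiles") <- profiles
  attr(out, "seed") <- seed
  class(out) <- c("family_study", class(out))
  out
}

#' Family-level correlation report
#'
#' Joins the per-permutant results into the family table, drops permutants
#' that are not strict two-state folders (they keep their rows, flagged,
#' but are excluded from all regressions) and computes the correlation
#' battery: `ln k` against the activation free energy in thermal units
#' (transition-state-theory check, expected slope near -1), `ln k` against
#' contact order, and - when transition-state columns are present - the
#' `CO_TSE`/`CO_TSN` relations, each also recomputed after removing
#' permutants with contact order above `co_split`.
#'
#' @param study A `family_study` (or an equivalently shaped data frame).
#' @param co_split Contact-order threshold for the split variants.
#' @return A `family_report`: list with `table` (per-permutant tibble with
#'   an `excluded` flag), `correlations` (tibble `pair`, `subset`,
#'   `slope`, `intercept`, `r`, `n`), `n_excluded`, `co_split`.
#' @export
build_family_report <- function(study, co_split = NULL) {
  co_split <- co_split %||% attr(study, "config")$co_split %||% 18.5
  tab <- tibble::as_tibble(study)
  tab$excluded <- !tab$two_state %in% TRUE |
    !is.finite(tab$ln_k) | !is.finite(tab$dg_act_thermal)
  use <- tab[!tab$excluded, ]
  pairs <- list(
    c("ln_k", "dg_act_thermal"),
    c("ln_k", "co"),
    c("ln_k", "co_tse"),
    c("co_tse", "co"),
    c("co_tsn", "co"),
    c("n_tsn", "co"))
  cors <- purrr::map_dfr(pairs, function(p) {
    yv <- p[1L]
    xv <- p[2L]
    if (!all(c(xv, yv) %in% names(use))) return(NULL)
    full <- try_fit(use[[xv]], use[[yv]])
    below <- use[use$co <= co_split, ]
    split_fit <- try_fit(below[[xv]], below[[yv]])
    dplyr::bind_rows(
      if (!is.null(full))
        dplyr::mutate(full, pair = paste(yv, "~", xv), subset = "all"),
      if (!is.null(split_fit))
        dplyr::mutate(split_fit, pair = paste(yv, "~", xv),
                      subset = sprintf("co <= %.3g", co_split)))
  })
  if (!nrow(cors) || !"pair" %in% names(cors)) {
    cors <- tibble::tibble(pair = character(), subset = character(),
                           slope = numeric(), intercept = numeric(),
                           r = numeric(), n = integer())
  }
  structure(list(table = tab,
                 correlations = dplyr::relocate(cors, "pair", "subset"),
                 n_excluded = sum(tab$excluded), co_split = co_split),
            class = "family_report")
}

try_fit <- function(x, y) {
  tryCatch(linear_fit(x, y), error = function(e) NULL)
}

#' @export
print.family_report <- function(x, ...) {
  cat(sprintf("<family_report> %d permutants (%d excluded from fits)\n",
              nrow(x$table), x$n_excluded))
  print(x$correlations)
  invisible(x)
}

#' @export
tidy.family_report <- function(x, ...) x$correlations

#' @export
glance.family_report <- function(x, ...) {
  tst <- x$correlations[x$correlations$pair == "ln_k ~ dg_act_thermal" &
                          x$correlations$subset == "all", ]
  tibble::tibble(n_permutants = nrow(x$table), n_excluded = x$n_excluded,
                 tst_slope = if (nrow(tst)) tst$slope else NA_real_,
                 tst_r = if (nrow(tst)) tst$r else NA_real_,
                 co_split = x$co_split)
}

#' Toy fixture systems
#'
#' Deterministic compact parents on small cuboids with their expected
#' contact counts from the lattice edge-count formula: `N = 8` (2x2x2, 5
#' contacts), `N = 18` (2x3x3, 16 contacts) and, for `"medium"`, `N = 27`
#' (3x3x3, 28 contacts).  Even-volume fixtures carry their full
#' circular-permutant families; the 27-mer cannot have adjacent termini on
#' a bipartite lattice (odd site count) and is emitted as a compact
#' structure only.
#'
#' @param size `"small"` (N = 8 only) or `"medium"` (all three).
#' @param seed Stored for bookkeeping (the constructions are
#'   deterministic).
#' @return A named list of fixtures; each has `parent`, `expected_contacts`
#'   and (when defined) `family`.
#' @export
generate_fixtures <- function(size = c("small", "medium"), seed = 1L) {
  size <- match.arg(size)
  mk <- function(box, with_family) {
    parent <- compact_cuboid_path(box, label = sprintf("toy%d", prod(box)))
    out <- list(parent = parent,
                expected_contacts = cuboid_contact_count(box), seed = seed)
    if (with_family) out$family <- cp_family(parent)
    out
  }
  out <- list(n8 = mk(c(2L, 2L, 2L), TRUE))
  if (size == "medium") {
    out$n18 <- mk(c(2L, 3L, 3L), TRUE)
    out$n27 <- mk(c(3L, 3L, 3L), FALSE)
  }
  out
}
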