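#' Harvest transition-state candidates from trajectory snapshots
#'
#' Collects trajectory snapshots whose energy lies in a window around the
#' barrier peak of the free-energy profile (default one reduced unit either
#' side), deduplicated by coordinates up to translation, keeping provenance
#' (trajectory, step).
#'
#' @param snapshots A snapshot tibble (columns `step`, `energy`, `conf`,
#'   optionally `traj`), e.g. `attr(run_kinetics(...), "snapshots")` or the
#'   `snapshots` element of a `folding_traj`.
#' @param barrier A [barrier_analysis()] summary (or a single energy value).
#' @param window Half-width of the energy window (reduced units).
#' @return A tibble of candidates: `traj`, `step`, `energy`, `conf`.
#' @export
harvest_candidates <- function(snapshots, barrier, window = 1) {
  e_bar <- if (is.numeric(barrier)) barrier else barrier$e_barrier
  if (!is.finite(e_bar)) rlang::abort("barrier energy is undefined")
  if (!nrow(snapshots))
    rlang::abort("no snapshots supplied; record snapshots with a finer stride")
  keep <- abs(snapshots$energy - e_bar) <= window + 1e-9
  out <- snapshots[keep, , drop = FALSE]
  if (!nrow(out))
    rlang::abort(sprintf(
      "no snapshot within %.3g of the barrier energy %.3g; use a denser snapshot stride",
      window, e_bar))
  if (!"traj" %in% names(out)) out$traj <- 1L
  key <- vapply(out$conf, conf_signature, character(1))
  out <- out[!duplicated(key), c("traj", "step", "energy", "conf")]
  out
}

conf_signature <- function(conf) {
  xyz <- sweep(conf$coords, 2L, apply(conf$coords, 2L, min))
  paste(t(xyz), collapse = ",")
}

#' Folding commitment probability (Pfold)
#'
#' Runs `n_trials` independent trajectories from a conformation at the
#' given temperature; each terminates "fold" on reaching the native state
#' (all native contacts) or "unfold" on dropping to a fraction of native
#' contacts at or below `q_unfold`.  The fold fraction estimates the
#' commitment probability; its binomial standard error is
#' `sqrt(p (1 - p) / n)`.  With 100 trials the standard error at
#' `p = 0.5` is 0.05, matching a five-percent error requirement.
#'
#' @param conf Starting `lattice_conf`.
#' @param model A [go_model()].
#' @param temperature Trial temperature.
#' @param n_trials Number of trials (>= 100 recommended).
#' @param q_unfold Unfolding threshold on the fraction of native contacts
#'   (trial ends "unfold" at `Q <= q_unfold`).
#' @param max_steps Per-trial step cap; capped trials count as
#'   indeterminate and the estimate is flagged when they exceed 10 percent.
#' @param seed Integer seed.
#' @return A one-row tibble: `pfold`, `se`, `n_fold`, `n_unfold`,
#'   `n_indeterminate`, `flagged`.
#' @export
pfold <- function(conf, model, temperature, n_trials = 100L, q_unfold = 0.2,
                  max_steps = 1e7, seed = 1L) {
  check_temperature(temperature)
  if (conf$n != model$n) rlang::abort("chain length mismatch")
  if (q_unfold <= 0 || q_unfold >= 1)
    rlang::abort("q_unfold must be in (0, 1)")
  unfold_contacts <- floor(q_unfold * model$n_contacts)
  res <- cpp_pfold(conf$coords, as.matrix(model$contacts),
                   temperature / model$epsilon, n_trials, unfold_contacts,
                   max_steps, seed)
  n_det <- res[1L] + res[2L]
  p <- if (n_det > 0) res[1L] / n_det else NA_real_
  tibble::tibble(pfold = p,
                 se = if (n_det > 0) sqrt(p * (1 - p) / n_det) else NA_real_,
                 n_fold = res[1L], n_unfold = res[2L],
                 n_indeterminate = res[3L],
                 flagged = res[3L] > 0.1 * n_trials)
}

#' Select the transition-state ensemble
#'
#' Members are candidates whose commitment probability lies within `band`
#' of one half with standard error at most `se_max` (and no indeterminacy
#' flag), i.e. barrier-top conformations equally likely to fold or unfold.
#'
#' @param candidates Candidate tibble (from [harvest_candidates()]) with
#'   Pfold columns joined, i.e. columns `conf`, `energy`, `pfold`, `se`
#'   (and optionally `flagged`).
#' @param band Half-width of the acceptance band around 0.5.
#' @param se_max Maximum binomial standard error.
#' @param min_size Warn when the ensemble is smaller than this.
#' @return A `tse_record` tibble of members, with ensemble metadata in
#'   attributes.
#' @export
select_tse <- function(candidates, band = 0.1, se_max = 0.05, min_size = 50L) {
  need <- c("conf", "energy", "pfold", "se")
  if (!all(need %in% names(candidates)))
    rlang::abort("candidates must carry columns conf, energy, pfold, se")
  ok <- abs(candidates$pfold - 0.5) <= band & candidates$se <= se_max
  if ("flagged" %in% names(candidates)) ok <- ok & !candidates$flagged
  ok[is.na(ok)] <- FALSE
  out <- candidates[ok, , drop = FALSE]
  if (!nrow(out)) {
    qs <- stats::quantile(candidates$pfold, c(0, .25, .5, .75, 1), na.rm = TRUE)
    rlang::abort(paste0(
      "empty transition-state ensemble; Pfold quantiles of the candidates: ",
      paste(sprintf("%.2f", qs), collapse = ", ")))
  }
  if (nrow(out) < min_size)
    rlang::warn(sprintf("transition-state ensemble has only %d members (< %d)",
                        nrow(out), min_size))
  attr(out, "band") <- band
  attr(out, "se_max") <- se_max
  class(out) <- c("tse_record", class(out))
  out
}

#' Contact order of the transition-state ensemble
#'
#' For each member the contact order is computed over its formed native
#' contacts (non-native adjacencies carry no energy and are ignored); the
#' ensemble value is the mean over members.  Members with no formed native
#' contact are excluded with a warning.
#'
#' @param tse A `tse_record`.
#' @param model The permutant's [go_model()].
#' @return The ensemble-average contact order.
#' @export
co_tse <- function(tse, model) {
  vals <- purrr::map_dbl(tse$conf, function(conf) {
    formed <- formed_native_contacts(conf, model)
    if (nrow(formed) == 0L) return(NA_real_)
    contact_order(formed)
  })
  if (anyNA(vals)) {
    rlang::warn(sprintf("%d members with zero native contacts excluded",
                        sum(is.na(vals))))
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) rlang::abort("no member has a formed native contact")
  mean(vals)
}

formed_native_contacts <- function(conf, model) {
  formed <- compute_contacts(conf)
  keep <- contact_key(formed) %in% contact_key(model$contacts)
  contact_map(as.matrix(formed[keep, c("i", "j")]), model$n)
}

#' Optimal-superposition RMSD between two conformations
#'
#' Least-squares rigid-body superposition (centroid alignment plus the
#' singular-value-decomposition rotation solution, reflections excluded):
#' the minimum root-mean-square deviation over translations and proper
#' rotations, in lattice units.
#'
#' @param conf,native Two `lattice_conf`s (or coordinate matrices) of equal
#'   length.
#' @return RMSD in lattice units (zero iff the chains are congruent under a
#'   proper isometry).
#' @export
rmsd_to_native <- function(conf, native) {
  a <- as_coord_matrix(conf)
  b <- as_coord_matrix(native)
  if (nrow(a) != nrow(b)) rlang::abort("length mismatch between conformations")
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- a %*% t(rot) - b
  sqrt(sum(diff^2) / nrow(a))
}

#' Ensemble-average RMSD to the native structure
#'
#' @param tse A `tse_record`.
#' @param model The permutant's [go_model()].
#' @return Mean optimal-superposition RMSD of the members to the native
#'   conformation, in lattice units.
#' @export
rmsd_tse <- function(tse, model) {
  mean(purrr::map_dbl(tse$conf, rmsd_to_native, native = model$native))
}

#' Transition-state network
#'
#' The set of native contacts present in the transition-state ensemble with
#' occurrence frequency at least `p_star`.  The network is a superset of
#' the folding nucleus and characterises the portion of native structure
#' significantly formed at the barrier top; its mean sequence separation
#' (`CO_TSN`) and the multiset of contact ranges `|i - j|` are reported.
#'
#' @param tse A `tse_record`.
#' @param model The permutant's [go_model()].
#' @param p_star Frequency threshold.
#' @return A `tsn` tibble of the retained contacts (`i`, `j`, `frequency`,
#'   `separation`) with attributes `n`, `co_tsn` (NA when empty),
#'   `p_star`, `spectrum` (tibble `separation`, `count`) and `frequencies`
#'   (all native contacts with their TSE frequencies).
#' @export
transition_state_network <- function(tse, model, p_star = 0.5) {
  if (!nrow(tse)) rlang::abort("empty transition-state ensemble")
  nat_keys <- contact_key(model$contacts)
  counts <- integer(length(nat_keys))
  for (conf in tse$conf) {
    formed <- compute_contacts(conf)
    counts <- counts + (nat_keys %in% contact_key(formed))
  }
  freq <- counts / nrow(tse)
  all_freq <- tibble::tibble(i = model$contacts$i, j = model$contacts$j,
                             frequency = freq,
                             separation = model$contacts$j - model$contacts$i)
  keep <- all_freq$frequency >= p_star
  out <- all_freq[keep, , drop = FALSE]
  attr(out, "n") <- nrow(out)
  attr(out, "co_tsn") <- if (nrow(out)) mean(out$separation) else NA_real_
  attr(out, "p_star") <- p_star
  attr(out, "spectrum") <- dplyr::count(out, .data$separation,
                                        name = "count")
  attr(out, "frequencies") <- all_freq
  class(out) <- c("tsn", class(out))
  out
}

#' Full transition-state analysis of one permutant
#'
#' Harvest, Pfold, selection, and the ensemble metrics in one call.
#'
#' @param snapshots Snapshot tibble (see [harvest_candidates()]).
#' @param model The permutant's [go_model()].
#' @param barrier Its [barrier_analysis()] summary.
#' @param temperature Pfold trial temperature (normally the melting
#'   temperature).
#' @param seed Integer seed.
#' @param window Harvest window (reduced units).
#' @param n_trials,q_unfold,max_steps Passed to [pfold()].
#' @param band,se_max,min_size Passed to [select_tse()].
#' @param p_star Passed to [transition_state_network()].
#' @param max_candidates Cap on the number of candidates scored with Pfold.
#' @return A list with `tse`, `tsn`, and a one-row `summary` tibble
#'   (`tse_size`, `co_tse`, `rmsd_tse`, `n_tsn`, `co_tsn`,
#'   `max_contact_range`, `p_star`, `q_unfold`, `window`).
#' @export
analyze_tse <- function(snapshots, model, barrier, temperature, seed = 1L,
                        window = 1, n_trials = 100L, q_unfold = 0.2,
                        max_steps = 1e7, band = 0.1, se_max = 0.05,
                        min_size = 50L, p_star = 0.5,
                        max_candidates = 400L) {
  cand <- harvest_candidates(snapshots, barrier, window = window)
  if (nrow(cand) > max_candidates) {
    set.seed(child_seed(seed, 31))
    cand <- cand[sample.int(nrow(cand), max_candidates), ]
  }
  pf <- purrr::imap_dfr(cand$conf, function(conf, i)
    pfold(conf, model, temperature, n_trials = n_trials,
          q_unfold = q_unfold, max_steps = max_steps,
          seed = child_seed(seed, 100 + i)))
  cand <- dplyr::bind_cols(cand, pf)
  tse <- select_tse(cand, band = band, se_max = se_max, min_size = min_size)
  tsn <- transition_state_network(tse, model, p_star = p_star)
  summary <- tibble::tibble(
    tse_size = nrow(tse), co_tse = co_tse(tse, model),
    rmsd_tse = rmsd_tse(tse, model), n_tsn = attr(tsn, "n"),
    co_tsn = attr(tsn, "co_tsn"),
    max_contact_range = if (nrow(tsn)) max(tsn$separation) else NA_real_,
    p_star = p_star, q_unfold = q_unfold, window = window)
  list(tse = tse, tsn = tsn, summary = summary)
}
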