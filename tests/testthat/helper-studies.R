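# Desk-scale circular-permutant family studies shared by the acceptance
# tests: a pool of collapsed 24-mer parents, the high- and low-contact-order
# extremes, and the full thermodynamic/kinetic study of both families.
# Computed once per test run; every seed is fixed, so results are
# reproducible bit for bit.
family_studies <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pool <- generate_parent_pool(12, 24, c(2, 3, 4), seed = 42)
      ph <- select_parents_by_co(pool, "high")
      pl <- select_parents_by_co(pool, "low")
      cfg <- study_config(n_replicas = 14, ladder_span = c(0.75, 1.35),
                          steps_per_round = 1000, pt_rounds = 8000,
                          pt_burnin = 1000, n_trajectories = 300,
                          max_steps = 1e8)
      sh <- run_family_study(ph, cfg, seed = 7)
      sl <- run_family_study(pl, cfg, seed = 8)
      cache <<- list(pool = pool, parent_high = ph, parent_low = pl,
                     study_high = sh, study_low = sl,
                     report_high = build_family_report(sh),
                     report_low = build_family_report(sl))
    }
    cache
  }
})
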