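# Shared simulated cohorts, built once per test run and cached.

.cohorts <- new.env(parent = emptyenv())

sim_cohort <- function(key, n_flies, duration_s, seeds = seq_len(n_flies),
                       params = drift_params(), chamber = chamber_spec()) {
  if (!is.null(.cohorts[[key]])) return(.cohorts[[key]])
  out <- lapply(seeds, function(s)
    simulate_session(params, chamber, duration_s, seed = s))
  assign(key, out, envir = .cohorts)
  out
}

default_cohort <- function() sim_cohort("default20", 20, 7200)

cohort_eggs <- function(sessions) {
  do.call(rbind, lapply(seq_along(sessions), function(i) {
    e <- sessions[[i]]$egg_events
    if (!nrow(e)) return(NULL)
    cbind(fly = i, e)
  }))
}
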