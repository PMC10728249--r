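# Shared fixtures, all built in code.

# Printed group-level parameter estimates, used as simulation ground truth.
truth_params <- function() {
  observer_params(wf_s = 0.18, wf_p = 0.35, alpha = 0.195,
                  k = c(AS = 2, DS = 2.4, RS = 2.13))
}

# A minimal valid trial table: `n` trials for one participant/condition, each
# with 4 positions; reproduced values given per trial (recycled per position)
# or per row.
toy_trials <- function(per_trial_reproduced, condition = "DS", set_id = 1,
                       participant = "p1", sample = interval_set(set_id)) {
  n <- length(per_trial_reproduced)
  data.frame(
    participant_id = participant,
    block = 1L,
    trial = rep(seq_len(n), each = 4L),
    condition = condition,
    set_id = set_id,
    position = rep(1:4, times = n),
    sample_ms = rep(sample, times = n),
    reproduced_ms = rep(per_trial_reproduced, each = 4L),
    stringsAsFactors = FALSE
  )
}

# Small simulated dataset cached per session for cheap reuse.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(simulation_config(n_participants = 3,
                                                   master_seed = 20260922,
                                                   n_trials = 132))
    }
    cache
  }
})
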