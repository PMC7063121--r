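# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# One clean noise-free session with pulsatile PPG, used by several files.
clean_session <- function() {
  memo("clean_session", function() {
    cfg <- sim_config(participant_count = 1, between_subject_cv = 0,
                      rng_seed = 42)
    simulate_session(cfg, 1, "rapid_supine_to_stand", 1)
  })
}

clean_prepared <- function() {
  memo("clean_prepared", function() prepare_repeat(clean_session()))
}

get_channel <- function(session, name) {
  j <- which(session$channels$channel == name)
  list(x = session$channels$samples[[j[1]]],
       fs = session$channels$fs[j[1]])
}
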