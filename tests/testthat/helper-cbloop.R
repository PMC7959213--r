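# Shared small fixtures, built in code.  Heavy objects are memoized so the
# suite pays for them once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# silence cbl_log messages inside tests that don't assert on them
quietly_cbl <- function(expr) {
  withCallingHandlers(expr, cbl_log = function(c) invokeRestart("muffleMessage"))
}

# a small, fast participant: 16 channels, low noise, short lead-in
small_gen <- function(noise_sd = 4, switch_prob = 0.3, mixing_seed = 11,
                      ...) {
  eeg_gen_params(n_channels = 16, noise_sd = noise_sd,
                 switch_prob = switch_prob, lead_in_s = 1.5,
                 mixing_seed = mixing_seed, ...)
}

small_templates <- function() memo("tmpl256", make_templates(1.875, 256, 5))

# trained small model + its training set (cached)
small_trained <- function() {
  memo("small_trained", {
    gen <- small_gen()
    ts <- simulate_training_set(gen, small_templates(), n_trials = 10,
                                seed = 101)
    list(gen = gen, trials = ts$trials, templates = ts$templates,
         model = train_backward_model(ts$trials, ts$templates))
  })
}

# deterministic synthetic score stream (not from EEG)
fake_stream <- function(c_face, c_spiral, hop = 0.25, window = 3) {
  n <- length(c_face)
  structure(data.frame(window_end = window + hop * (seq_len(n) - 1),
                       c_face = c_face, c_spiral = c_spiral),
            class = c("cbl_scorestream", "data.frame"),
            hop = hop, window = window, fs = 256)
}

# tiny schedule config that divides evenly into 3 blocks
tiny_schedule <- function(n = 24, seed = 5)
  schedule_config(n_main_trials = n, n_control_trials = 8, seed = seed)
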