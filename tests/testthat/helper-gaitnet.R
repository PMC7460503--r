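# Shared fixtures, all generated in code.

# A scaled-down architecture for gradient checks and equivalence tests;
# same topology, small enough for finite differences.
tiny_config <- function(variant = "fmsnet", ...) {
  cfg <- model_config(map_rows = 5, map_cols = 5, n_sub = 3,
                      conv_filters = c(4L, 3L, 1L), lstm_units = 5,
                      fc_units = c(7L, 6L), ...)
  fl <- gaitphase:::variant_flags(variant)
  cfg$use_skip <- fl$use_skip
  cfg$use_bn <- fl$use_bn
  cfg
}

# Windowed examples from one short noise-controlled recording.
quick_examples <- function(duration_s = 20, speed = 1.0, noise_sd = 0.05,
                           seed = 1, spec = windowing_spec()) {
  rec <- synthesize_recording(
    gait_profile(speed = speed, noise_sd = noise_sd, seed = seed),
    duration_s = duration_s
  )
  build_examples(rec, spec)
}

# Independent pairwise-counting AUC oracle (equivalent to exhaustive
# threshold enumeration with trapezoid interpolation at ties).
auc_pairwise <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) {
    for (n in neg_scores) {
      wins <- wins + (p > n) + 0.5 * (p == n)
    }
  }
  wins / (length(pos_scores) * length(neg_scores))
}
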