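# Shared fixtures, generated once per test run.

# small separable two-class Gaussian table in the pipeline's table format
make_separable_table <- function(n_per_class = 30, n_features = 10, shift = 4,
                                 seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per_class * n_features), n_per_class),
               matrix(stats::rnorm(n_per_class * n_features, mean = shift), n_per_class))
    colnames(x) <- paste0("f", seq_len(n_features))
    list(x = x, y = rep(c("HC", "PD"), each = n_per_class))
  })
}

# short synthetic cohort for audio pipeline tests (low rate keeps tests fast)
make_cohort <- function(n_per_class = 4, duration_s = 10, rate = 4000, seed = 7) {
  c(
    lapply(seq_len(n_per_class), function(i) {
      make_synthetic_audio(duration_s, rate = rate, profile = hc_voice_profile(),
                           label = "HC", record_id = sprintf("HC_%02d", i),
                           seed = derive_test_seed(seed, i))
    }),
    lapply(seq_len(n_per_class), function(i) {
      make_synthetic_audio(duration_s, rate = rate, profile = pd_voice_profile(),
                           label = "PD", record_id = sprintf("PD_%02d", i),
                           seed = derive_test_seed(seed, 100 + i))
    })
  )
}

derive_test_seed <- function(seed, i) as.integer((seed * 7919 + i * 104729) %% 2147483587)

# three-image handwriting set for the fusion tests
make_drawing_triplet <- function(tremor, seed = 11) {
  list(make_synthetic_drawing("spiral", tremor, class_label = "x", seed = seed),
       make_synthetic_drawing("meander", tremor, class_label = "x", seed = seed + 1),
       make_synthetic_drawing("circle", tremor, class_label = "x", seed = seed + 2))
}
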