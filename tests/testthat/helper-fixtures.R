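# Small fixtures shared across test files; everything is generated in code.

# Tiny two-group survival dataset with a single informative feature.
toy_survival <- function(n = 60, hr = 4, seed = 1) {
  withr::with_seed(seed, {
    g <- rep(0:1, length.out = n)
    x <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("signal", "noise1", "noise2")))
    x[, "signal"] <- x[, "signal"] + 3 * g
    time <- rexp(n, rate = 0.01 * hr^g)
    cens <- rexp(n, rate = 0.005)
    list(x = x, time = pmin(time, cens),
         event = as.integer(time <= cens), group = g)
  })
}

# Raw clinical table covering every category at least once.
toy_raw_clinical <- function() {
  data.frame(
    sex = c("Male", "Female", "Male", "Male"),
    age = c(55, 62, 48, 71),
    hpv_status = c("Positive", "Negative", "Unknown", "Positive"),
    smoking_status = c("Never", "Former", "Current", "Never"),
    t_category = c("T1", "T2", "T3", "T4"),
    n_category = c("N0", "N1", "N2", "N3"),
    therapeutic_combination = c("CC", "IC+CC", "IC+RT", "RT"),
    ajcc_stage = c("I", "II", "III", "IV"),
    stringsAsFactors = FALSE)
}

# Small fitted forest reused by proximity tests.
small_forest <- function(n = 10, n_trees = 20, seed = 7) {
  d <- toy_survival(n = n, seed = seed)
  fit_survival_forest(d$x, d$time, d$event, n_trees = n_trees,
                      min_node_size = 2, seed = seed)
}
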