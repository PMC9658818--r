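# Programmatic fixtures shared across test files.

# 8 class-mean rows over 5 informative features: each feature is the sole
# separator of one class pair (dropping feature j merges classes 1 and
# j+1), so every informative feature carries necessary information.
planted_class_means <- rbind(
  c( 1,  1,  1,  1,  1),
  c(-1,  1,  1,  1,  1),
  c( 1, -1,  1,  1,  1),
  c( 1,  1, -1,  1,  1),
  c( 1,  1,  1, -1,  1),
  c( 1,  1,  1,  1, -1),
  c(-1, -1,  1,  1,  1),
  c(-1,  1, -1,  1,  1))

# 5 necessary informative features + n_noise pure-noise features,
# 8 balanced classes. Column names are valid composed feature names over 5
# channels so channel-grouping code can run on this fixture too.
make_planted_data <- function(seed, n_per_class = 20, n_noise = 20,
                              noise_sd = 0.3) {
  stopifnot(n_noise <= 20)
  y <- rep(1:8, each = n_per_class)
  n <- length(y)
  withr::with_seed(seed, {
    Xi <- planted_class_means[y, ] + matrix(rnorm(n * 5, sd = noise_sd), n)
    Xn <- matrix(rnorm(n * n_noise), n)
    X <- cbind(Xi, Xn)
    chans <- c("rt_av", "rt_v", "lt_av", "ls_v", "lf_av")
    labs <- c("mean", "rms", "variance", "skewness", "kurtosis")
    noise_names <- as.vector(outer(chans, labs[-1], paste, sep = "."))
    colnames(X) <- c(paste0(chans, ".mean"),
                     noise_names[seq_len(n_noise)])
    list(X = X, y = y, informative = 1:5)
  })
}

# Small synthetic gait dataset + features, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_gait_features <- function() {
  if (is.null(.fixture_env$fm)) {
    cfg <- synth_config(n_per_class = 12, seed = 401)
    .fixture_env$ds <- generate_dataset(cfg)
    .fixture_env$fm <- feature_matrix(.fixture_env$ds)
  }
  .fixture_env$fm
}

small_gait_dataset <- function() {
  invisible(small_gait_features())
  .fixture_env$ds
}
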