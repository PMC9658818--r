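# Independent brute-force oracles. These re-derive every quantity from its
# definition with explicit loops / exhaustive enumeration and never share a
# code path with the implementation they check.

naive_time_features <- function(x) {
  n <- length(x)
  s <- 0; s_abs <- 0; s_sqrt <- 0; s_sq <- 0
  for (v in x) {
    s <- s + v; s_abs <- s_abs + abs(v)
    s_sqrt <- s_sqrt + sqrt(abs(v)); s_sq <- s_sq + v * v
  }
  mu <- s / n; avg_amp <- s_abs / n
  root_amp <- (s_sqrt / n)^2; rms <- sqrt(s_sq / n)
  m2 <- 0; m3 <- 0; m4 <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  sdv <- sqrt(m2)
  peak <- max(abs(x))
  c(max(x), min(x), peak, max(x) - min(x), mu, avg_amp, root_amp, m2, sdv,
    rms, m4 / sdv^4, m3 / sdv^3, rms / avg_amp, peak / rms, peak / avg_amp,
    peak / root_amp, peak / avg_amp^2)
}

naive_freq_features <- function(x, fs) {
  n <- length(x)
  kk <- seq_len(n %/% 2)
  s <- numeric(length(kk)); f <- numeric(length(kk))
  for (k in kk) {
    re <- 0; im <- 0
    for (t in 0:(n - 1)) {
      re <- re + x[t + 1] * cos(2 * pi * k * t / n)
      im <- im - x[t + 1] * sin(2 * pi * k * t / n)
    }
    s[k] <- sqrt(re^2 + im^2)
    f[k] <- k * fs / n
  }
  tot <- sum(s)
  fc <- sum(f * s) / tot
  c(mean(s), fc, sqrt(sum(f^2 * s) / tot), sqrt(sum((f - fc)^2 * s) / tot))
}

# Dempster combination of n discounted score rows by exhaustive enumeration
# of all focal-set products (focal sets: m singletons + the frame).
bf_ds_fuse <- function(Z, alpha) {
  n <- nrow(Z); m <- ncol(Z)
  masses <- lapply(seq_len(n), function(i)
    list(singleton = alpha * Z[i, ], theta = 1 - alpha))
  focal <- c(seq_len(m), 0L)           # 0 encodes the frame
  grid <- as.matrix(expand.grid(rep(list(focal), n)))
  sing_tot <- numeric(m); theta_tot <- 0; conflict <- 0
  for (r in seq_len(nrow(grid))) {
    sets <- grid[r, ]
    w <- 1
    for (i in seq_len(n)) {
      w <- w * if (sets[i] == 0L) masses[[i]]$theta
               else masses[[i]]$singleton[sets[i]]
    }
    named <- unique(sets[sets != 0L])
    if (length(named) == 0L) theta_tot <- theta_tot + w
    else if (length(named) == 1L) sing_tot[named] <- sing_tot[named] + w
    else conflict <- conflict + w
  }
  sing <- sing_tot / (1 - conflict)
  list(decision = which.max(sing), singleton = sing,
       theta = theta_tot / (1 - conflict))
}

bf_algebraic <- function(Z, rule) {
  m <- ncol(Z)
  e <- numeric(m)
  for (j in seq_len(m)) {
    col <- Z[, j]
    e[j] <- switch(rule,
      sum = sum(col), average = sum(col) / length(col),
      max = max(col), min = min(col),
      product = prod(pmax(col, 1e-12)))
  }
  which.max(e)
}

bf_dt_predict <- function(templates, Z) {
  d <- vapply(templates, function(tpl) {
    tot <- 0
    for (i in seq_len(nrow(Z))) for (j in seq_len(ncol(Z))) {
      tot <- tot + (Z[i, j] - tpl[i, j])^2
    }
    tot
  }, numeric(1))
  which.min(d)
}

# Exhaustive greedy MRMR (difference criterion) recomputing every relevance
# and redundancy term from scratch at each step.
oracle_mi_codes <- function(a, b) {
  tab <- table(a, b) / length(a)
  out <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j]
    if (p > 0) out <- out + p * log(p / (sum(tab[i, ]) * sum(tab[, j])))
  }
  max(0, out)
}

exhaustive_mrmr <- function(X, y, k, bins = ceiling(sqrt(length(y)))) {
  codes <- apply(as.matrix(X), 2, gaitfuse:::discretize_ef, bins = bins)
  sel <- integer(0)
  rem <- seq_len(ncol(codes))
  for (step in seq_len(k)) {
    best <- -Inf; best_j <- NA_integer_
    for (j in rem) {
      rel <- oracle_mi_codes(codes[, j], y)
      red <- if (length(sel) == 0L) 0 else
        mean(vapply(sel, function(s2)
          oracle_mi_codes(codes[, j], codes[, s2]), numeric(1)))
      sc <- rel - red
      if (sc > best + 1e-12) { best <- sc; best_j <- j }
    }
    sel <- c(sel, best_j)
    rem <- setdiff(rem, best_j)
  }
  sel
}

random_simplex <- function(m) {
  x <- stats::runif(m, 0.01, 1)
  x / sum(x)
}
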