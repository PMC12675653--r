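# Independent naive (loop-based) oracles for the quality metrics and the
# statistics. These deliberately avoid the package's vectorized code paths.

oracle_accuracy <- function(x, y, tx, ty) {
  tot <- 0; n <- 0
  for (i in seq_along(x)) {
    if (is.finite(x[i]) && is.finite(y[i])) {
      tot <- tot + sqrt((x[i] - tx)^2 + (y[i] - ty)^2)
      n <- n + 1
    }
  }
  tot / n
}

oracle_std <- function(x, y) {
  xs <- c(); ys <- c()
  for (i in seq_along(x)) {
    if (is.finite(x[i]) && is.finite(y[i])) { xs <- c(xs, x[i]); ys <- c(ys, y[i]) }
  }
  mx <- sum(xs) / length(xs); my <- sum(ys) / length(ys)
  acc <- 0
  for (i in seq_along(xs)) acc <- acc + (xs[i] - mx)^2 + (ys[i] - my)^2
  sqrt(acc / length(xs))
}

# pair-enumeration oracle: adjacency by original sample index
oracle_rms <- function(x, y, idx) {
  acc <- 0; n <- 0
  for (i in seq_along(x)[-1]) {
    for (j in seq_len(i - 1)) {
      if (idx[i] - idx[j] == 1 &&
          is.finite(x[i]) && is.finite(y[i]) &&
          is.finite(x[j]) && is.finite(y[j])) {
        acc <- acc + (x[i] - x[j])^2 + (y[i] - y[j])^2
        n <- n + 1
      }
    }
  }
  if (n == 0) return(NA_real_)
  sqrt(acc / n)
}

oracle_data_loss <- function(valid) 100 * sum(!valid) / length(valid)

oracle_shift <- function(pairs) {
  per <- c()
  for (p in pairs) {
    bx <- mean(p$bright$x[p$bright$valid]); by <- mean(p$bright$y[p$bright$valid])
    dx <- mean(p$dark$x[p$dark$valid]); dy <- mean(p$dark$y[p$dark$valid])
    per <- c(per, sqrt((bx - dx)^2 + (by - dy)^2))
  }
  list(per = per, mean = mean(per))
}

# textbook paired/one-sample t via difference scores
oracle_t <- function(d) {
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# brute-force single-pass SD filter (population sd)
oracle_sd_filter <- function(x, y, k = 3) {
  ok <- is.finite(x) & is.finite(y)
  mx <- mean(x[ok]); my <- mean(y[ok])
  sx <- sqrt(mean((x[ok] - mx)^2)); sy <- sqrt(mean((y[ok] - my)^2))
  drop <- rep(FALSE, length(x))
  for (i in seq_along(x)) {
    if (ok[i]) {
      if ((sx > 0 && abs(x[i] - mx) > k * sx) ||
          (sy > 0 && abs(y[i] - my) > k * sy)) drop[i] <- TRUE
    }
  }
  drop
}

# random degree-space recording with optional NaN gaps
random_recording <- function(n, nan_frac = 0.1, condition = "bright",
                             trial = 1L) {
  x <- rnorm(n); y <- rnorm(n)
  bad <- runif(n) < nan_frac
  x[bad] <- NaN; y[bad] <- NaN
  gaze_recording(seq_len(n) / 100, x, y, valid = !bad,
                 condition = condition, trial_index = trial)
}

make_rec <- function(x, y, ...) {
  gaze_recording(seq_along(x) / 100, x, y, ...)
}
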