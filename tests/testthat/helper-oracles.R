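# shared fixtures and independent oracles, built in code

study_schedule <- c(-15, 30, 60, 90, 120, 150, 180, 210, 240, 300)
post_schedule <- study_schedule[study_schedule > 0]

# deterministic random Bateman parameter sets on physiologic scales
random_bateman_params <- function(n, seed = 404) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ke <- exp(stats::runif(1, log(0.003), log(0.03)))
    rho <- exp(stats::runif(1, log(2), log(25)))
    list(A = exp(stats::runif(1, log(0.05), log(5))),
         ka = rho * ke, ke = ke,
         t0 = stats::runif(1, 0, 30))
  })
}

# quadrature oracle for any family value function; `kink` marks a point of
# non-smoothness (the lag t0) where the integral is split so the adaptive
# rule reaches full precision
quadrature_auc <- function(value_fn, window = c(0, 300), kink = NULL) {
  pts <- sort(unique(c(window, kink[kink > window[1] & kink < window[2]])))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    total <- total + stats::integrate(value_fn, pts[i], pts[i + 1L],
                                      rel.tol = 1e-12, abs.tol = 1e-14,
                                      subdivisions = 2000L)$value
  }
  total
}

# Monte-Carlo power oracle: balanced 2x2 ANOVA, main effect of a two-level
# factor with Cohen's f, unit error SD; vectorized over replicates
mc_power_2x2 <- function(f, n_per_group, alpha = 0.05, reps = 20000, seed = 99) {
  set.seed(seed)
  N <- 4 * n_per_group
  # cell means: factor B shifts +/- f (SD of the two level means = f)
  mu <- rep(c(-f, f, -f, f), each = n_per_group)  # cells A1B1 A1B2 A2B1 A2B2
  cell <- rep(1:4, each = n_per_group)
  b_level <- rep(c(1, 2, 1, 2), each = n_per_group)
  rej <- logical(reps)
  crit <- stats::qf(1 - alpha, 1, N - 4)
  for (r in seq_len(reps)) {
    y <- mu + stats::rnorm(N)
    cm <- tapply(y, cell, mean)
    bm <- tapply(y, b_level, mean)
    gm <- mean(y)
    ss_b <- 2 * n_per_group * sum((bm - gm)^2)
    sse <- sum((y - cm[cell])^2)
    rej[r] <- (ss_b / 1) / (sse / (N - 4)) > crit
  }
  mean(rej)
}
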