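# shared fixtures and small oracles, built in code at test time

# absolute circular difference in [0, pi]
circ_diff <- function(a, b) {
  abs(((a - b + pi) %% (2 * pi)) - pi)
}

# direct term-by-term KL summation oracle (independent of kl_to_uniform)
kl_oracle <- function(p) {
  n <- length(p)
  s <- 0
  for (j in seq_len(n)) {
    if (p[j] > 0) s <- s + p[j] * log(p[j] / (1 / n))
  }
  s
}

# random point on the simplex
rsimplex <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# one coupled window (10 s + 2 s context at `rate`) with a single component
coupled_window <- function(f_low = 2.5, f_high = 100, d = 0.8, phase = 0,
                           noise_sd = 0.3, rate = 1000, duration = 10,
                           seed = NULL) {
  generate_coupled_signal(
    data.frame(f_low = f_low, f_high = f_high, strength = d, phase = phase),
    duration_s = duration, rate = rate, noise_sd = noise_sd, pad_s = 2,
    seed = seed)
}

# brute-force complex convolution oracle: per-pixel loops with R complex
# arithmetic, valid cross-correlation, no padding
conv_oracle <- function(xc, wc) {
  dx <- dim(xc); dw <- dim(wc)
  ho <- dx[1] - dw[1] + 1; wo <- dx[2] - dw[2] + 1
  out <- array(0 + 0i, c(ho, wo, dw[4], dx[4]))
  for (n in seq_len(dx[4])) for (co in seq_len(dw[4])) {
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- 0 + 0i
      for (ci in seq_len(dx[3])) for (u in seq_len(dw[1])) {
        for (v in seq_len(dw[2])) {
          acc <- acc + xc[i + u - 1, j + v - 1, ci, n] * wc[u, v, ci, co]
        }
      }
      out[i, j, co, n] <- acc
    }
  }
  out
}

# central-difference numerical gradient
numgrad <- function(f, x, eps = 1e-6) {
  g <- array(0, if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# pairwise-comparison (Mann-Whitney) AUC oracle
auc_rank_oracle <- function(x, truth) {
  pos <- x[truth]
  neg <- x[!truth]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# tiny two-patient image dataset for evaluation plumbing tests; images are
# computed from simulated windows at a modest rate to keep tests fast
tiny_dataset <- function(n_per_class = 8, windows_per_channel = 4,
                         patients = c("A", "B"), seed = 42, rate = 400,
                         profile = "clinical") {
  specs <- default_class_specs(profile)
  out <- purrr::map2_dfr(patients, seed + seq_along(patients), function(p, s) {
    d <- generate_labeled_dataset(specs, n_per_class = n_per_class,
                                  windows_per_channel = windows_per_channel,
                                  rate = rate, patient = p, seed = s)
    d$channel <- paste0(p, "_", d$channel)
    d
  })
  out$window_id <- seq_len(nrow(out))
  out
}
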