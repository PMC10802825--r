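# Shared fixtures and straight-line brute-force re-implementations of every
# feature formula, kept deliberately independent of the package's code paths
# (loops and stats::lm instead of vectorised closed forms).

fig1_window <- c(373, 375, 360, 373)

make_episode <- function(cl, id = "E1", pid = "P1", label = "unknown") {
  episode(id, pid, label, cl)
}

# random plausible CL window
rand_window <- function(n = 10, mean = 340, sd = 25) {
  pmin(pmax(rnorm(n, mean, sd), 150), 900)
}

o_mean <- function(x) sum(x) / length(x)

o_sd <- function(x) {
  m <- o_mean(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  sqrt(acc / (length(x) - 1))
}

o_rmssd <- function(x) {
  acc <- 0
  for (i in seq_len(length(x) - 1)) acc <- acc + (x[i + 1] - x[i])^2
  sqrt(acc / (length(x) - 1))
}

o_nn50 <- function(x, thr = 50) {
  cnt <- 0
  for (i in seq_len(length(x) - 1)) if (abs(x[i + 1] - x[i]) > thr) cnt <- cnt + 1
  cnt
}

o_sd1 <- function(x) {
  d <- numeric(0)
  for (i in seq_len(length(x) - 1)) d <- c(d, (x[i + 1] - x[i]) / sqrt(2))
  o_sd(d)
}

o_sd2 <- function(x) {
  s <- numeric(0)
  for (i in seq_len(length(x) - 1)) s <- c(s, (x[i + 1] + x[i]) / sqrt(2))
  o_sd(s)
}

# AR(1) by stats::lm — a different route than the package's closed form
o_ar1 <- function(x) {
  n <- length(x)
  fit <- stats::lm(lead ~ lag, data = data.frame(lag = x[-n], lead = x[-1]))
  list(phi = unname(stats::coef(fit)[2]), c = unname(stats::coef(fit)[1]),
       resid_sd = if (n - 1 > 2) sqrt(sum(stats::resid(fit)^2) / (n - 3))
                  else sqrt(sum(stats::resid(fit)^2)))
}

o_init_to_shortest <- function(x) {
  idx <- which(x == min(x))[1]
  list(time_to_min_s = sum(x[1:idx]) / 1000,
       pct_beats_to_min = 100 * idx / length(x),
       pct_change_first_to_min = 100 * (x[1] - x[idx]) / x[1])
}

# TINN by exhaustive double loop over edge pairs, histogram built with cut()
o_tinn <- function(x, bw = 7.8125) {
  edges <- seq(floor(min(x) / bw) * bw, (floor(max(x) / bw) + 1) * bw, by = bw)
  counts <- as.vector(table(cut(x, breaks = edges, right = FALSE)))
  centers <- edges[-length(edges)] + bw / 2
  peak <- which.max(counts)
  X <- centers[peak]; DX <- counts[peak]
  best <- c(err = Inf, width = NA)
  for (N in edges[edges < X]) {
    for (M in edges[edges > X]) {
      err <- 0
      for (j in seq_along(centers)) {
        cc <- centers[j]
        h <- if (cc >= N && cc <= X) DX * (cc - N) / (X - N)
             else if (cc > X && cc <= M) DX * (M - cc) / (M - X)
             else 0
        err <- err + (counts[j] - h)^2
      }
      if (err < best["err"] - 1e-12 ||
          (abs(err - best["err"]) <= 1e-12 && (M - N) < best["width"]))
        best <- c(err = err, width = M - N)
    }
  }
  unname(best["width"])
}

# small labelled feature table for classifier/group tests
toy_features <- function(n_per = 20, sep = 2, seed = 99) {
  withr::with_seed(seed, {
    data.frame(
      episode_id = sprintf("E%02d", seq_len(2 * n_per)),
      patient_id = sprintf("P%02d", rep(seq_len(10), length.out = 2 * n_per)),
      label = rep(c("terminating", "sustained"), each = n_per),
      signal = c(rnorm(n_per, sep), rnorm(n_per, 0)),
      noise1 = rnorm(2 * n_per), noise2 = rnorm(2 * n_per),
      noise3 = rnorm(2 * n_per),
      stringsAsFactors = FALSE)
  })
}

write_cohort_csv <- function(ch, path = tempfile(fileext = ".csv")) {
  write_cohort(ch, path)
  path
}
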