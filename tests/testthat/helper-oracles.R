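# Shared test utilities and independent oracles.

# deterministic random unit quaternion(s)
random_quats <- function(n) {
  M <- matrix(rnorm(4L * n), n, 4L)
  M / sqrt(rowSums(M * M))
}

# rotation angle (deg) between two rotation matrices via the trace identity
# (matrix-logarithm magnitude) - independent of the quaternion path
rotmat_angle <- function(R0, R1) {
  Rd <- t(R0) %*% R1
  acos(min(1, max(-1, (sum(diag(Rd)) - 1) / 2))) * 180 / pi
}

# brute-force one-way sums of squares, written as explicit loops so it shares
# nothing with the implementation
brute_force_ss <- function(groups) {
  all_vals <- c()
  for (g in groups) all_vals <- c(all_vals, g)
  gm <- sum(all_vals) / length(all_vals)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    m <- sum(g) / length(g)
    ssb <- ssb + length(g) * (m - gm)^2
    for (x in g) ssw <- ssw + (x - m)^2
  }
  k <- length(groups)
  N <- length(all_vals)
  list(ss_between = ssb, ss_within = ssw,
       ms_between = ssb / (k - 1), ms_within = ssw / (N - k),
       df_between = k - 1, df_within = N - k, grand_mean = gm)
}

# random unbalanced difference-set fixture
random_diffset <- function(k = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(k)) k <- sample(2:12, 1)
  ni <- sample(2:30, k, replace = TRUE)
  diffs <- lapply(ni, function(n) rnorm(n, rnorm(1, 0, 3), runif(1, 0.5, 4)))
  names(diffs) <- sprintf("P%02d", seq_len(k))
  difference_set(diffs, method = "CF", placement = "frontal",
                 movement = "test", angle_set = "test")
}

# zero-noise spec (nothing stochastic, no latency, identity frame offsets)
exact_noise <- function() {
  noise_spec(keypoint_sd = 0, orientation_sd = 0, latency = 0,
             misdetection_prob = 0, misdetection_sd = 0,
             frame_offsets = NULL, depth_axis_mult = 1, seed = 1L)
}

# digital magnitude response |H(f)| of a Butterworth design evaluated
# directly from the transfer-function coefficients at e^{i 2 pi f / fs};
# independent of the time-domain filtering code path
butter_gain <- function(order, cutoff, rate, f) {
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  z <- exp(1i * 2 * pi * f / rate)
  num <- sum(bf$b * z^(-(seq_along(bf$b) - 1)))
  den <- sum(bf$a * z^(-(seq_along(bf$a) - 1)))
  Mod(num / den)
}
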