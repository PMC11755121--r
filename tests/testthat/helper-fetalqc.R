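# brute-force oracles and small generators shared across tests

# per-window Pearson correlation, computed naively window by window
brute_sliding_fc <- function(x, y, win) {
  w <- win$width_tr
  starts <- seq.int(1L, length(x) - w + 1L, by = win$stride)
  vapply(starts, function(s) {
    xs <- x[s:(s + w - 1L)]
    ys <- y[s:(s + w - 1L)]
    if (sd(xs) == 0 || sd(ys) == 0) NA_real_ else cor(xs, ys)
  }, numeric(1))
}

brute_sliding_mean <- function(v, win) {
  w <- win$width_tr
  starts <- seq.int(1L, length(v) - w + 1L, by = win$stride)
  vapply(starts, function(s) mean(v[s:(s + w - 1L)]), numeric(1))
}

# a smooth, non-degenerate rigid motion trace
random_motion <- function(n, tr = 3, scale_t = 0.5, scale_r = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sm <- function(s) as.vector(stats::filter(rnorm(n + 8, sd = s), rep(1 / 5, 5),
                                            sides = 2))[5:(n + 4)]
  motion_trace(cbind(sm(scale_t), sm(scale_t), sm(scale_t),
                     sm(scale_r), sm(scale_r), sm(scale_r)), tr = tr)
}

# region signals with a planted contaminated subset sharing one episodic
# noise process; returns the parcel series, the FD proxy, and the planted
# edge indicator aligned with combn(n_regions, 2) ordering
make_planted_subject <- function(n_regions = 12, n_corrupt = 6,
                                 params = sim_params(snr_phys = 0.5,
                                                     snr_scan = 3,
                                                     env_model = "burst"),
                                 seed = 1) {
  set.seed(seed)
  kernel <- hrf_kernel(hrf_params(), dt = 1 / params$nu_g)
  pn <- phys_noise(params$n_latent, params) / params$snr_phys
  fd <- abs(colMeans(matrix(pn, nrow = params$d)))
  sig <- matrix(0, n_regions, params$n_obs)
  for (i in seq_len(n_regions)) {
    b <- fetalqc:::.convolve_events(generate_neural_events(params), kernel)
    b <- (b - mean(b)) / max(sd(b), 1e-12)
    lat <- if (i <= n_corrupt) b + pn else b
    x <- colMeans(matrix(lat, nrow = params$d))
    x <- x + rnorm(params$n_obs, sd = sqrt(mean(x^2)) / params$snr_scan)
    sig[i, ] <- x
  }
  pairs <- combn(n_regions, 2)
  list(ts = parcel_ts(sig, tr = 1 / params$nu_o), fd = fd,
       noise_obs = colMeans(matrix(pn, nrow = params$d)),
       planted = pairs[1, ] <= n_corrupt & pairs[2, ] <= n_corrupt)
}
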