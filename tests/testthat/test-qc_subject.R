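test_that("windowed FC matches the brute-force per-window oracle", {
  set.seed(1)
  for (case in list(list(n = 96, w = 45, s = 1), list(n = 96, w = 46, s = 1),
                    list(n = 120, w = 20, s = 3))) {
    win <- window_spec(case$w, case$s)
    x <- rnorm(case$n); y <- rnorm(case$n)
    cc <- sliding_fc(x, y, win)
    expect_equal(cc, brute_sliding_fc(x, y, win), tolerance = 1e-12,
                 ignore_attr = TRUE)
    fd <- abs(rnorm(case$n))
    expect_equal(sliding_fd(fd, win), brute_sliding_mean(fd, win),
                 tolerance = 1e-12)
  }
})

test_that("windowed FC degenerate cases behave", {
  x <- rnorm(60)
  win <- window_spec(10)
  expect_equal(as.numeric(sliding_fc(x, x, win)), rep(1, 51), tolerance = 1e-12)
  # full-length window reduces to the plain Pearson correlation
  y <- rnorm(60)
  expect_equal(as.numeric(sliding_fc(x, y, window_spec(60))), cor(x, y),
               tolerance = 1e-12)
  # zero-variance windows are flagged undefined, not silently zeroed
  z <- c(rep(0, 20), rnorm(40))
  cc <- sliding_fc(z, y, window_spec(10))
  expect_true(anyNA(cc))
  expect_identical(attr(cc, "n_undefined"), sum(is.na(cc)))
})

test_that("window bookkeeping matches the stated identities", {
  expect_identical(n_windows(96, window_spec(46)), 51L)
  expect_error(window_spec(2), "width_tr")
  expect_error(sliding_fd(rnorm(10), window_spec(11)), "longer than the series")
})

test_that("windowed FD of simple inputs is exact", {
  win <- window_spec(5)
  expect_equal(sliding_fd(rep(0.3, 20), win), rep(0.3, 16), tolerance = 1e-14)
  spike <- c(rep(0, 9), 1, rep(0, 10))
  fdw <- sliding_fd(spike, win)
  inside <- vapply(1:16, function(s) s <= 10 && 10 <= s + 4, logical(1))
  expect_equal(fdw, ifelse(inside, 1 / 5, 0), tolerance = 1e-14)
})

test_that("the t statistic follows its closed form", {
  # independent oracle: cor.test on the same data
  set.seed(2)
  x <- rnorm(51)
  y <- 0.5 * x + rnorm(51)
  ft <- fcfd_test(x, y)
  ct <- cor.test(x, y)
  expect_equal(ft$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(ft$t_stat, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(ft$p_param, ct$p.value, tolerance = 1e-12)
  expect_identical(ft$df, 49L)
  # closed-form check at r exactly 0.5 with 51 windows:
  # t = 0.5 * sqrt(49) / sqrt(1 - 0.25)
  expect_equal(0.5 * sqrt(49) / sqrt(0.75), 4.04145188432738, tolerance = 1e-12)
  # perfectly collinear series: infinite t, zero p
  ft1 <- fcfd_test(seq_len(51), 0.5 * seq_len(51))
  expect_identical(ft1$t_stat, Inf)
  expect_identical(ft1$p_param, 0)
})

test_that("uncorrelated series give a centered test", {
  # perfectly orthogonal pair: r = 0 -> t = 0, p = 1
  x <- c(1, -1, 1, -1, 1, -1)
  y <- c(1, 1, -1, -1, 1, 1)
  ft <- fcfd_test(x - mean(x), y - mean(y))
  expect_equal(ft$t_stat, 0, tolerance = 1e-12)
  expect_equal(ft$p_param, 1, tolerance = 1e-12)
})

test_that("the parametric test is calibrated for serially independent inputs", {
  set.seed(3)
  n_rep <- 10000; L <- 51
  tcrit <- qt(0.975, L - 2)
  rcrit <- sqrt(tcrit^2 / (tcrit^2 + L - 2))
  X <- matrix(rnorm(n_rep * L), L)
  Y <- matrix(rnorm(n_rep * L), L)
  r <- vapply(seq_len(n_rep), function(i) cor(X[, i], Y[, i]), numeric(1))
  rate <- mean(abs(r) > rcrit)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("surrogates preserve the FD amplitude spectrum exactly", {
  set.seed(4)
  fd <- abs(rnorm(96))
  S <- fetalqc:::.phase_surrogates(fd, 50)
  A0 <- Mod(fft(fd))
  for (j in c(1, 25, 50))
    expect_equal(Mod(fft(S[, j])), A0, tolerance = 1e-10)
})

test_that("a one-component spectrum yields phase-shifted sinusoids", {
  t <- 0:95
  fd <- 2 + sin(2 * pi * 4 * t / 96)
  set.seed(5)
  S <- fetalqc:::.phase_surrogates(fd, 20)
  for (j in c(3, 17)) {
    s <- S[, j]
    expect_equal(mean(s), 2, tolerance = 1e-10)
    # fitting a sinusoid of the same frequency explains the surrogate
    fit <- lm(s ~ sin(2 * pi * 4 * t / 96) + cos(2 * pi * 4 * t / 96))
    expect_gt(suppressWarnings(summary(fit))$r.squared, 1 - 1e-10)
    expect_equal(sqrt(sum(coef(fit)[2:3]^2)), 1, tolerance = 1e-8)
  }
})

test_that("the surrogate null is centered at zero", {
  set.seed(6)
  fd <- abs(fetalqc:::.fft_lowpass(rnorm(96), 1 / 3, 0.05))
  cc <- sliding_fc(rnorm(96), rnorm(96))
  means <- vapply(1:10, function(s) {
    mean(surrogate_null(fd, cc, n_surrogates = 300, seed = s)$r_null)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 2 * se + 0.02)
})

test_that("surrogate testing stays calibrated under autocorrelated FD where the parametric test is not", {
  set.seed(7)
  n_rep <- 300; n <- 96
  win <- window_spec(46)
  p_surr <- p_par <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    # independent smooth FD and signal pair: null is true by construction
    fd <- abs(fetalqc:::.fft_lowpass(rnorm(n), 1 / 3, 0.02)) + 0.05
    cc <- sliding_fc(rnorm(n), rnorm(n), win)
    fdw <- sliding_fd(fd, win)
    p_par[i] <- fcfd_test(cc, fdw)$p_param
    p_surr[i] <- surrogate_null(fd, cc, win, n_surrogates = 100)$p_surr
  }
  rate_surr <- mean(p_surr < 0.05)
  rate_par <- mean(p_par < 0.05)
  expect_gt(rate_par, 0.15)        # parametric test badly anticonservative
  expect_gt(rate_surr, 0.01)
  expect_lt(rate_surr, 0.10)       # surrogate test near nominal
})

test_that("subject assessment enumerates all region pairs and reports structure", {
  set.seed(8)
  ts <- parcel_ts(matrix(rnorm(8 * 96), 8), centroids = matrix(rnorm(24, sd = 20), 8),
                  tr = 3)
  fd <- abs(rnorm(96, sd = 0.3))
  rep <- assess_subject(ts, fd, null_mode = "parametric")
  expect_identical(nrow(rep$edges), 28L)
  expect_identical(rep$n_windows, 51L)
  expect_true(all(abs(rep$edges$r) <= 1, na.rm = TRUE))
  expect_length(rep$region_counts, 8L)
  expect_true(is.finite(rep$distance_dependence$rho))
})

test_that("degenerate inputs are flagged, not crashed", {
  set.seed(9)
  dat <- matrix(rnorm(5 * 96), 5)
  dat[3, ] <- 2  # constant region
  ts <- parcel_ts(dat, tr = 3)
  rep <- assess_subject(ts, abs(rnorm(96)), null_mode = "parametric")
  expect_identical(rep$excluded_regions, "3")
  expect_identical(nrow(rep$edges), 6L)  # 4 usable regions
  rep0 <- assess_subject(ts, rep(0, 96), null_mode = "parametric")
  expect_true(rep0$fd_degenerate)
  expect_true(all(is.na(rep0$edges$r)))
})

test_that("neural synchrony is not mistaken for motion corruption", {
  # strongly correlated pairs at low contamination: the corrupted count
  # stays near the alpha baseline
  p <- sim_params(seed = 17, snr_phys = 12, snr_scan = 18)
  ds <- simulate_dataset(150, p, rho = 0.9)
  hits <- vapply(seq_along(ds), function(i) {
    o <- ds[[i]]
    cc <- sliding_fc(o$observed_x, o$observed_y)
    surrogate_null(o$fd_true, cc, n_surrogates = 199, seed = i)$p_surr < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.12)
})

test_that("the corrupted count grows with contamination on matched seeds", {
  count_at <- function(snr_p, snr_s, n = 150) {
    p <- sim_params(seed = 23, snr_phys = snr_p, snr_scan = snr_s)
    ds <- simulate_dataset(n, p, rho = 0)
    sum(vapply(seq_along(ds), function(i) {
      o <- ds[[i]]
      cc <- sliding_fc(o$observed_x, o$observed_y)
      surrogate_null(o$fd_true, cc, n_surrogates = 199, seed = i)$p_surr < 0.05
    }, logical(1)))
  }
  low <- count_at(12, 18)
  high <- count_at(2, 3)
  expect_lte(low, high)
})

test_that("planted motion-coupled edges dominate the corrupted set", {
  sub <- make_planted_subject(params = sim_params(n_obs = 192, snr_phys = 0.5,
                                                  snr_scan = 3,
                                                  env_model = "burst"),
                              seed = 1)
  rep <- assess_subject(sub$ts, sub$fd, n_surrogates = 400, seed = 12)
  sens <- mean(rep$edges$corrupted[sub$planted])
  clean_fpr <- mean(rep$edges$corrupted[!sub$planted &
    !(rep$edges$region_i %in% as.character(1:6)) &
    !(rep$edges$region_j %in% as.character(1:6))])
  expect_gt(sens, 0.6)
  expect_lt(clean_fpr, 0.2)
  # FDR correction can only reduce the flagged set
  rep_fdr <- assess_subject(sub$ts, sub$fd, n_surrogates = 400, seed = 12,
                            correction = "fdr")
  expect_lte(sum(rep_fdr$edges$corrupted), sum(rep$edges$corrupted))
})
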