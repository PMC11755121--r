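#' Simulation parameters for the generative BOLD model
#'
#' Bundles the parameters of the parametric model of corrupted resting-state
#' BOLD signal pairs. Latent neural events are generated at rate
#' \code{nu_g} Hz, observed volumes at rate \code{nu_o} Hz (TR =
#' \code{1/nu_o} seconds), so each observed timepoint integrates
#' \code{d = nu_g/nu_o} latent bins, which must be a whole number.
#'
#' @param nu_g latent (neural) sampling frequency in Hz.
#' @param nu_o observation frequency in Hz; the repetition time is
#'   \code{1/nu_o} seconds.
#' @param n_obs number of observed timepoints.
#' @param activity_rate stationary fraction of active latent bins, in
#'   \code{[0, 1]}.
#' @param snr_phys physiological signal-to-noise ratio: RMS amplitude of
#'   the (standardized) ideal BOLD signal divided by the RMS amplitude of
#'   the added shared physiological noise. \code{Inf} disables the noise.
#' @param snr_scan thermal (scanner) signal-to-noise ratio, an RMS
#'   amplitude ratio evaluated on the downsampled signal. \code{Inf}
#'   disables the noise.
#' @param prune_rate probability that an active latent bin is deleted in
#'   the observed branch before hemodynamic convolution (observation-side
#'   event loss; the ideal branch keeps all events).
#' @param active_self_p self-transition probability of the active state of
#'   the two-state neural Markov chain; 0.5 makes events short bursts.
#' @param noise_cutoff low-pass cutoff (Hz) of the physiological noise
#'   carrier.
#' @param env_cutoff low-pass cutoff (Hz) of the slow nonnegative envelope
#'   that modulates the carrier. The envelope gives the noise the episodic,
#'   minute-scale character of fetal movement; without it the noise
#'   amplitude is essentially constant at the sliding-window scale and
#'   window-averaged FD carries no information.
#' @param env_model \code{"lowpass"} (default: envelope is the absolute
#'   value of Gaussian noise low-passed at \code{env_cutoff}) or
#'   \code{"burst"} (a small number of discrete movement episodes --
#'   Gaussian bumps of width \code{burst_width} seconds over a quiescent
#'   baseline -- emulating the alternation of fetal quiescence and
#'   movement).
#' @param burst_count,burst_width,burst_baseline burst-envelope shape:
#'   number of episodes per acquisition, episode width (s), and relative
#'   quiescent-baseline amplitude.
#' @param shared_noise logical; if \code{TRUE} (default) both signals of a
#'   pair receive the same physiological noise realization, which is what
#'   couples spurious FC to FD.
#' @param downsample \code{"mean"} (block average over each window of
#'   \code{d} latent samples, mimicking volume-integrating acquisition) or
#'   \code{"decimate"} (take every \code{d}-th sample).
#' @param seed optional integer master seed; used by the generator
#'   functions when supplied.
#'
#' @return an object of class \code{fetalqc_sim_params}.
#' @examples
#' p <- sim_params(n_obs = 96, snr_phys = 6, snr_scan = 9)
#' p$d  # 60 latent bins per volume
#' @export
sim_params <- function(nu_g = 20, nu_o = 1 / 3, n_obs = 96,
                       activity_rate = 0.05, snr_phys = 6, snr_scan = 9,
                       prune_rate = 0.1, active_self_p = 0.5,
                       noise_cutoff = 0.3, env_cutoff = 0.01,
                       env_model = c("lowpass", "burst"),
                       burst_count = 3L, burst_width = 15,
                       burst_baseline = 0.05, shared_noise = TRUE,
                       downsample = c("mean", "decimate"), seed = NULL) {
  downsample <- match.arg(downsample)
  env_model <- match.arg(env_model)
  if (!(nu_g > nu_o && nu_o > 0))
    stop("need nu_g > nu_o > 0 (latent rate faster than observation rate)")
  d <- nu_g / nu_o
  if (abs(d - round(d)) > 1e-8)
    stop(sprintf("downsampling rate d = nu_g/nu_o = %.6f is not a whole number", d))
  d <- as.integer(round(d))
  if (!.is_count(n_obs)) stop("n_obs must be a positive integer")
  if (activity_rate < 0 || activity_rate > 1)
    stop("activity_rate must lie in [0, 1]")
  if (!(snr_phys > 0)) stop("snr_phys must be > 0")
  if (!(snr_scan > 0)) stop("snr_scan must be > 0")
  if (prune_rate < 0 || prune_rate > 1) stop("prune_rate must lie in [0, 1]")
  if (active_self_p < 0 || active_self_p >= 1)
    stop("active_self_p must lie in [0, 1)")
  # rest -> active probability implied by the stationary distribution
  if (activity_rate < 1) {
    p_ra <- activity_rate * (1 - active_self_p) / (1 - activity_rate)
    if (p_ra > 1)
      stop("activity_rate/active_self_p combination has no stationary 2-state chain")
  }
  structure(list(
    nu_g = nu_g, nu_o = nu_o, n_obs = as.integer(n_obs), d = d,
    n_latent = as.integer(n_obs * d),
    activity_rate = activity_rate, snr_phys = snr_phys, snr_scan = snr_scan,
    prune_rate = prune_rate, active_self_p = active_self_p,
    noise_cutoff = noise_cutoff, env_cutoff = env_cutoff,
    env_model = env_model, burst_count = as.integer(burst_count),
    burst_width = burst_width, burst_baseline = burst_baseline,
    shared_noise = shared_noise, downsample = downsample, seed = seed
  ), class = "fetalqc_sim_params")
}

#' @export
print.fetalqc_sim_params <- function(x, ...) {
  cat("fetalqc simulation parameters\n")
  cat(sprintf("  nu_g = %g Hz, nu_o = %g Hz (TR = %.3g s), d = %d, n_obs = %d\n",
              x$nu_g, x$nu_o, 1 / x$nu_o, x$d, x$n_obs))
  cat(sprintf("  activity_rate = %g, active_self_p = %g, prune_rate = %g\n",
              x$activity_rate, x$active_self_p, x$prune_rate))
  cat(sprintf("  snr_phys = %g, snr_scan = %g (RMS ratios), noise cutoff %g Hz, envelope cutoff %g Hz\n",
              x$snr_phys, x$snr_scan, x$noise_cutoff, x$env_cutoff))
  invisible(x)
}

#' Generate a latent neural event train
#'
#' Simulates the binary neural activity sequence of one signal: a two-state
#' first-order Markov chain at rate \code{nu_g} whose stationary probability
#' of the active state equals \code{activity_rate} and whose active-state
#' self-transition probability is \code{active_self_p}. The chain is drawn
#' by alternating geometrically distributed sojourns, which is exact and
#' fast.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return integer vector of 0/1 of length \code{params$n_latent}.
#' @examples
#' set.seed(1)
#' ev <- generate_neural_events(sim_params())
#' mean(ev)  # close to 0.05
#' @export
generate_neural_events <- function(params) {
  stopifnot(inherits(params, "fetalqc_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_latent
  a <- params$activity_rate
  if (a == 0) return(integer(n))
  if (a == 1) return(rep(1L, n))
  p_aa <- params$active_self_p
  p_ra <- a * (1 - p_aa) / (1 - a)
  state <- stats::rbinom(1L, 1L, a)
  # expected sojourn lengths 1/(1-p_aa) (active) and 1/p_ra (rest)
  per_cycle <- 1 / (1 - p_aa) + 1 / p_ra
  out <- integer(0)
  while (length(out) < n) {
    k <- max(8L, ceiling(2 * (n - length(out)) / per_cycle))
    states <- rep_len(c(state, 1L - state), 2L * k)  # alternating sojourn states
    lens <- integer(2L * k)
    act <- states == 1L
    lens[act] <- stats::rgeom(sum(act), 1 - p_aa) + 1L
    lens[!act] <- stats::rgeom(sum(!act), p_ra) + 1L
    out <- c(out, rep(states, lens))
    state <- 1L - states[length(states)]
  }
  out[seq_len(n)]
}

#' Hemodynamic response parameters
#'
#' The canonical HRF is a difference of two gamma densities: a positive
#' response peaking at \code{peak_delay} seconds and a later undershoot
#' peaking at \code{undershoot_delay} seconds, weighted by
#' \code{undershoot_ratio}. Gamma shapes are parameterized so that each
#' density's mode sits exactly at its stated delay.
#'
#' @param peak_delay time to peak of the positive response, seconds.
#' @param undershoot_delay time to peak of the undershoot, seconds.
#' @param peak_dispersion,undershoot_dispersion gamma dispersions (scale
#'   parameters), seconds.
#' @param undershoot_ratio weight of the undershoot term.
#' @param duration kernel support, seconds.
#' @return an object of class \code{fetalqc_hrf_params}.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, duration = 32) {
  if (!(peak_delay < undershoot_delay))
    stop("peak_delay must be smaller than undershoot_delay")
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0)
    stop("dispersions must be positive")
  if (duration <= peak_delay)
    stop("duration too short to contain the response peak")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, duration = duration),
            class = "fetalqc_hrf_params")
}

#' Sample the double-gamma HRF kernel
#'
#' @param hrf a \code{\link{hrf_params}} object.
#' @param dt sampling interval in seconds.
#' @return numeric vector sampling the kernel on \code{seq(0, duration, dt)},
#'   normalized so its maximum is 1.
#' @examples
#' k <- hrf_kernel(hrf_params(), dt = 0.05)
#' (which.max(k) - 1) * 0.05  # peak at ~6 s
#' @export
hrf_kernel <- function(hrf = hrf_params(), dt) {
  stopifnot(inherits(hrf, "fetalqc_hrf_params"))
  if (!(dt > 0)) stop("dt must be positive")
  t <- seq(0, hrf$duration, by = dt)
  # shape chosen so the gamma mode (shape-1)*scale equals the stated delay
  pk <- stats::dgamma(t, shape = hrf$peak_delay / hrf$peak_dispersion + 1,
                      scale = hrf$peak_dispersion)
  us <- stats::dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_dispersion + 1,
                      scale = hrf$undershoot_dispersion)
  k <- pk - hrf$undershoot_ratio * us
  k / max(k)
}

# convolve a sparse binary event train with an HRF kernel (causal, same length)
.convolve_events <- function(events, kernel) {
  out <- numeric(length(events))
  idx <- which(events == 1L)
  nk <- length(kernel)
  n <- length(events)
  for (i in idx) {
    j <- i:min(n, i + nk - 1L)
    out[j] <- out[j] + kernel[seq_along(j)]
  }
  out
}

#' Impose a target correlation structure on standardized signals
#'
#' Multiplies the signal matrix by the lower-triangular Cholesky factor of
#' the target correlation matrix \code{R}, so that the rows of the output
#' have correlation matrix approximately \code{R} when the input rows are
#' uncorrelated and standardized.
#'
#' @param signals \code{n_signals x T} matrix; rows are standardized before
#'   mixing.
#' @param R symmetric positive-definite correlation matrix with unit
#'   diagonal.
#' @return matrix of the same dimension as \code{signals}.
#' @export
impose_correlation <- function(signals, R) {
  signals <- as.matrix(signals)
  R <- as.matrix(R)
  if (nrow(R) != nrow(signals) || ncol(R) != nrow(signals))
    stop("R must be n_signals x n_signals")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  U <- tryCatch(chol(R), error = function(e) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf("R is not positive definite; eigenvalues: %s",
                 paste(signif(ev, 4), collapse = ", ")))
  })
  Z <- t(scale(t(signals)))
  Z[is.nan(Z)] <- 0  # constant rows standardize to zero
  t(U) %*% Z
}

# FFT brick-wall low-pass filter (deterministic, zero-phase)
.fft_lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  f <- stats::fft(x)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)
  f[freq > cutoff] <- 0
  Re(stats::fft(f, inverse = TRUE)) / n
}

#' Generate the shared physiological noise process
#'
#' A low-pass-filtered Gaussian carrier (cutoff \code{noise_cutoff}) is
#' amplitude-modulated by a slow nonnegative envelope (the absolute value of
#' Gaussian noise low-passed at \code{env_cutoff}), then scaled to unit RMS.
#' The envelope makes the noise episodic at the minute scale, emulating
#' alternating quiescent and active periods of fetal movement; the local
#' magnitude of this process is the ground-truth displacement proxy.
#'
#' @param n number of latent samples.
#' @param params a \code{\link{sim_params}} object (supplies \code{nu_g},
#'   \code{noise_cutoff} and \code{env_cutoff}).
#' @return numeric vector of length \code{n} with unit RMS.
#' @export
phys_noise <- function(n, params) {
  carrier <- .fft_lowpass(stats::rnorm(n), params$nu_g, params$noise_cutoff)
  if (identical(params$env_model, "burst")) {
    tt <- (seq_len(n) - 1) / params$nu_g
    k <- params$burst_count
    # stratified placement: one episode per segment of the acquisition,
    # jittered, so realizations always contain several separated episodes
    centers <- (seq_len(k) - stats::runif(k)) * max(tt) / k
    amp <- stats::runif(k, 0.8, 1.2)
    env <- rep(params$burst_baseline, n)
    for (b in seq_len(params$burst_count))
      env <- env + amp[b] * exp(-(tt - centers[b])^2 / (2 * params$burst_width^2))
  } else {
    env <- abs(.fft_lowpass(stats::rnorm(n), params$nu_g, params$env_cutoff))
  }
  z <- carrier * env
  s <- .rms(z)
  if (s == 0) return(z)
  z / s
}

.block_downsample <- function(x, d, mode) {
  if (mode == "mean") {
    colMeans(matrix(x, nrow = d))
  } else {
    x[seq(d, length(x), by = d)]
  }
}

#' Apply the observation process to an ideal latent-rate signal pair
#'
#' Maps a pair of noiseless latent-rate BOLD signals to observed scanner
#' signals: (1) optional observation-side event pruning (when the latent
#' event trains are supplied, a \code{prune_rate} fraction of active bins is
#' deleted and the observed branch is re-convolved, while the ideal branch
#' keeps all events), (2) addition of shared episodic physiological noise at
#' amplitude ratio \code{snr_phys}, (3) block-downsampling by
#' \code{d = nu_g/nu_o} to \code{n_obs} points, (4) addition of white
#' thermal noise at amplitude ratio \code{snr_scan}, (5) per-signal
#' z-scoring. The ground-truth displacement proxy \code{fd_true} is the
#' absolute value of the downsampled physiological noise.
#'
#' @param ideal \code{2 x n_latent} matrix: the noiseless pair at the latent
#'   rate (rows are standardized internally).
#' @param params a \code{\link{sim_params}} object.
#' @param events optional list of two binary event trains; enables pruning.
#' @param kernel HRF kernel at the latent rate, required when \code{events}
#'   is supplied.
#' @param mix optional \code{2 x 2} lower-triangular mixing matrix (from the
#'   Cholesky factor of a target correlation matrix) applied to the
#'   re-convolved pruned branch so that it matches the correlation imposed
#'   on the ideal branch.
#' @param rho_true the neural correlation imposed on the pair, recorded in
#'   the output.
#' @return an object of class \code{fetalqc_bold_obs} with elements
#'   \code{observed_x}, \code{observed_y} (zero-mean, unit-variance, length
#'   \code{n_obs}), \code{ideal_x}, \code{ideal_y} (latent rate),
#'   \code{fd_true} (nonnegative, length \code{n_obs}) and \code{rho_true}.
#' @export
observe <- function(ideal, params, events = NULL, kernel = NULL,
                    mix = NULL, rho_true = NA_real_) {
  stopifnot(inherits(params, "fetalqc_sim_params"))
  ideal <- as.matrix(ideal)
  if (nrow(ideal) != 2L || ncol(ideal) != params$n_latent)
    stop("ideal must be a 2 x n_latent matrix")
  branch <- ideal
  if (!is.null(events) && params$prune_rate > 0) {
    if (is.null(kernel)) stop("kernel is required when events are supplied")
    branch <- matrix(0, 2L, params$n_latent)
    for (s in 1:2) {
      ev <- events[[s]]
      keep <- stats::runif(length(ev)) >= params$prune_rate
      pruned <- as.integer(ev == 1L & keep)
      branch[s, ] <- .convolve_events(pruned, kernel)
    }
  }
  branch <- t(scale(t(branch)))
  branch[is.nan(branch)] <- 0
  if (!is.null(mix)) branch <- mix %*% branch
  # shared physiological noise at RMS ratio snr_phys (signal rows have RMS ~1)
  if (is.finite(params$snr_phys)) {
    pn <- phys_noise(params$n_latent, params) / params$snr_phys
    if (params$shared_noise) {
      branch <- branch + rep(1, 2) %o% pn
    } else {
      branch <- branch + rbind(pn, phys_noise(params$n_latent, params) / params$snr_phys)
    }
    fd_true <- abs(.block_downsample(pn, params$d, params$downsample))
  } else {
    fd_true <- numeric(params$n_obs)
  }
  xo <- .block_downsample(branch[1, ], params$d, params$downsample)
  yo <- .block_downsample(branch[2, ], params$d, params$downsample)
  if (is.finite(params$snr_scan)) {
    xo <- xo + stats::rnorm(params$n_obs, sd = .rms(xo) / params$snr_scan)
    yo <- yo + stats::rnorm(params$n_obs, sd = .rms(yo) / params$snr_scan)
  }
  zscore <- function(v) {
    v <- v - mean(v)
    s <- stats::sd(v)
    if (s > 0) v / s else v
  }
  structure(list(observed_x = zscore(xo), observed_y = zscore(yo),
                 ideal_x = ideal[1, ], ideal_y = ideal[2, ],
                 fd_true = fd_true, rho_true = rho_true),
            class = "fetalqc_bold_obs")
}

#' Simulate one corrupted BOLD signal pair
#'
#' Runs the full generative pipeline for a pair of signals: latent neural
#' event trains, hemodynamic convolution, Cholesky imposition of the target
#' neural correlation \code{rho}, and the observation process of
#' \code{\link{observe}}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param rho target neural correlation between the two signals.
#' @param hrf a \code{\link{hrf_params}} object.
#' @return a \code{fetalqc_bold_obs} object (see \code{\link{observe}}).
#' @export
simulate_pair <- function(params, rho = 0, hrf = hrf_params()) {
  stopifnot(inherits(params, "fetalqc_sim_params"))
  if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)")
  if (!is.null(params$seed)) set.seed(params$seed)
  params_noseed <- params
  params_noseed$seed <- NULL
  kernel <- hrf_kernel(hrf, dt = 1 / params$nu_g)
  ev <- list(generate_neural_events(params_noseed),
             generate_neural_events(params_noseed))
  ideal <- rbind(.convolve_events(ev[[1]], kernel),
                 .convolve_events(ev[[2]], kernel))
  R <- matrix(c(1, rho, rho, 1), 2, 2)
  mixed <- impose_correlation(ideal, R)
  mix <- t(chol(R))
  observe(mixed, params_noseed, events = ev, kernel = kernel, mix = mix,
          rho_true = rho)
}

#' Simulate a dataset of independent corrupted BOLD signal pairs
#'
#' Each pair is generated from its own seed derived deterministically from
#' the master seed, so datasets are reproducible and independent of
#' \code{n_pairs}.
#'
#' @param n_pairs number of signal pairs.
#' @param params a \code{\link{sim_params}} object; its \code{seed} is the
#'   master seed (defaults to 1 when unset).
#' @param rho target neural correlation within each pair.
#' @param hrf a \code{\link{hrf_params}} object.
#' @return list of \code{fetalqc_bold_obs} objects, with \code{params}
#'   attached as an attribute.
#' @export
simulate_dataset <- function(n_pairs, params, rho = 0, hrf = hrf_params()) {
  if (!.is_count(n_pairs)) stop("n_pairs must be a positive integer")
  stopifnot(inherits(params, "fetalqc_sim_params"))
  master <- if (is.null(params$seed)) 1L else as.integer(params$seed)
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    p_i <- params
    p_i$seed <- (master + 104729L * (i - 1L)) %% 2147483647L
    out[[i]] <- simulate_pair(p_i, rho = rho, hrf = hrf)
  }
  attr(out, "params") <- params
  attr(out, "rho") <- rho
  class(out) <- "fetalqc_sim_dataset"
  out
}

#' @export
print.fetalqc_sim_dataset <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("fetalqc simulated dataset: %d pairs, rho_true = %g, snr_phys = %g, snr_scan = %g\n",
              length(x), attr(x, "rho"), p$snr_phys, p$snr_scan))
  invisible(x)
}
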