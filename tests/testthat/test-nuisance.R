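# small synthetic 4D scene shared by the design tests
make_scene <- function(seed = 1, nt = 60) {
  set.seed(seed)
  d <- c(8, 8, 4)
  brain <- array(TRUE, d)
  wm <- array(FALSE, d); wm[1:2, , ] <- TRUE
  csf <- array(FALSE, d); csf[3, , ] <- TRUE
  s <- sin(2 * pi * (1:nt) / 17)
  bold <- array(rnorm(prod(d) * nt, sd = 1), c(d, nt))
  # WM voxels carry a strong common signal for the aCompCor test
  wm_idx <- which(array(wm, d))
  bm <- matrix(bold, ncol = nt)
  bm[wm_idx, ] <- matrix(s, length(wm_idx), nt, byrow = TRUE) +
    0.05 * bm[wm_idx, ]
  list(bold = array(bm, c(d, nt)), masks = list(brain = brain, wm = wm, csf = csf),
       s = s, nt = nt)
}

test_that("strategy registry covers the benchmark families and rejects unknowns", {
  expect_true(all(c("none", "6HMP", "24HMP", "2Phys", "8Phys", "GSR", "2GSR",
                    "4GSR", "aCompCor", "aCompCor+6HMP", "tCompCor", "localWM",
                    "4GSR+8Phys+24HMP") %in% list_strategies()))
  expect_error(build_design("notastrategy"), "registered strategies")
})

test_that("head-motion designs have the definitional column counts", {
  mot <- random_motion(60, seed = 3)
  expect_identical(ncol(build_design("6HMP", motion = mot)$regressors), 6L)
  expect_identical(ncol(build_design("24HMP", motion = mot)$regressors), 24L)
  sc <- make_scene()
  expect_identical(ncol(build_design("GSR", bold = sc$bold, masks = sc$masks)$regressors), 1L)
  expect_identical(ncol(build_design("4GSR", bold = sc$bold, masks = sc$masks)$regressors), 4L)
  expect_identical(ncol(build_design("8Phys", bold = sc$bold, masks = sc$masks)$regressors), 8L)
  big <- build_design("4GSR+8Phys+24HMP", motion = mot, bold = sc$bold, masks = sc$masks)
  expect_identical(ncol(big$regressors), 36L)
})

test_that("aCompCor's leading component recovers a planted dominant signal", {
  sc <- make_scene(seed = 7)
  dsg <- build_design("aCompCor", bold = sc$bold, masks = sc$masks)
  expect_identical(ncol(dsg$regressors), 5L)
  expect_gt(abs(cor(dsg$regressors[, 1], sc$s)), 0.99)
})

test_that("tCompCor selects high-variance voxels and returns the requested PCs", {
  sc <- make_scene(seed = 8)
  # make a small voxel subset dominate the temporal variance
  bm <- matrix(sc$bold, ncol = sc$nt)
  bm[1:5, ] <- matrix(10 * cos(2 * pi * (1:sc$nt) / 9), 5, sc$nt, byrow = TRUE)
  bold <- array(bm, dim(sc$bold))
  dsg <- build_design("tCompCor", bold = bold, masks = sc$masks, n_compcor = 3)
  expect_identical(ncol(dsg$regressors), 3L)
  expect_gt(abs(cor(dsg$regressors[, 1], cos(2 * pi * (1:sc$nt) / 9))), 0.99)
})

test_that("missing tissue masks are rejected with a clear message", {
  sc <- make_scene()
  expect_error(build_design("aCompCor", bold = sc$bold,
                            masks = list(wm = sc$masks$wm,
                                         csf = array(FALSE, dim(sc$masks$csf)))),
               "csf")
})

test_that("regression residuals are orthogonal to the design", {
  set.seed(5)
  nt <- 80
  X <- cbind(rnorm(nt), rnorm(nt), rnorm(nt))
  y <- rnorm(nt)
  r <- regress_out(y, X)
  expect_lt(max(abs(cor(as.numeric(r), X))), 1e-10)
})

test_that("a constant design demeans and a spanned input is annihilated", {
  set.seed(6)
  y <- rnorm(50) + 3
  r <- regress_out(y, matrix(1, 50, 1))
  expect_equal(as.numeric(r), y - mean(y), tolerance = 1e-12)
  X <- cbind(rnorm(50), rnorm(50))
  y2 <- X %*% c(2, -1)
  r2 <- regress_out(as.numeric(y2), X)
  expect_lt(sqrt(sum(r2^2)) / sqrt(sum(y2^2)), 1e-10)
})

test_that("regression is idempotent", {
  set.seed(7)
  X <- cbind(rnorm(60), rnorm(60))
  y <- rnorm(60)
  r1 <- as.numeric(regress_out(y, X))
  r2 <- as.numeric(regress_out(r1, X))
  expect_lt(sqrt(sum((r1 - r2)^2)) / sqrt(sum(r1^2)), 1e-10)
})

test_that("censored frames are excluded from fit and output", {
  set.seed(8)
  nt <- 40
  y <- rnorm(nt)
  X <- matrix(rnorm(nt), nt, 1)
  cm <- censor_mask(rep(c(TRUE, FALSE), c(30, 10)))
  r <- regress_out(y, X, censor = cm)
  expect_length(as.numeric(r), 30)
  expect_identical(attr(r, "frames"), 1:30)
  # fitting only on the retained frames: orthogonality holds there
  expect_lt(abs(cor(as.numeric(r), X[1:30, 1])), 1e-10)
})

test_that("overparameterized and rank-deficient designs are handled", {
  set.seed(9)
  y <- rnorm(10)
  expect_error(regress_out(y, matrix(rnorm(100), 10, 10)), "more regressors")
  X <- cbind(rnorm(30), 0)
  X <- cbind(X, X[, 1])  # duplicated column
  expect_warning(r <- regress_out(rnorm(30), X), "rank-deficient")
  expect_length(as.numeric(r), 30)
})

test_that("localWM augments each region with its own local regressor", {
  sc <- make_scene(seed = 10)
  d3 <- dim(sc$bold)[1:3]
  parc <- array(0L, d3)
  parc[5:6, , ] <- 1L
  parc[7:8, , ] <- 2L
  dsg <- build_design("localWM", bold = sc$bold, masks = sc$masks,
                      parcellation = parc, affine = diag(4), localwm_radius = 50)
  expect_identical(dim(dsg$per_region), c(as.integer(sc$nt), 2L))
  # local regressor tracks the planted WM signal
  expect_gt(abs(cor(dsg$per_region[, 1], sc$s)), 0.9)
  ts <- matrix(rnorm(2 * sc$nt), 2)
  r <- regress_out(ts, dsg)
  expect_lt(abs(cor(r[1, ], dsg$per_region[, 1])), 1e-10)
})

test_that("high-pass filter removes drift and passes fluctuations", {
  tr <- 3; nt <- 96; tt <- (0:(nt - 1)) * tr
  slow <- sin(2 * pi * 0.002 * tt)
  fast <- sin(2 * pi * 0.05 * tt)
  expect_lt(sum(highpass(slow, 0.008, tr)^2) / sum(slow^2), 0.05)
  expect_gt(sum(highpass(fast, 0.008, tr)^2) / sum(fast^2), 0.90)
  expect_equal(highpass(rep(2, nt), 0.008, tr), numeric(nt), tolerance = 1e-12)
  expect_error(highpass(c(1, 2), 0.008, tr), "at least 3")
  expect_error(highpass(rnorm(50), cutoff = 0.4, tr = 3), "Nyquist")
})
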