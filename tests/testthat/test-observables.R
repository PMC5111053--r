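test_that("MSD handles degenerate and ballistic trajectories exactly", {
  nf <- 50
  # constant centre of mass
  tr <- fake_traj(com = matrix(5, nf, 3))
  m <- msd_com(tr, "xy", lags = 1:10)
  expect_true(all(m$msd == 0))
  expect_equal(m$n_origin, nf - 1:10)
  # ballistic motion (1, 0, 0) per frame: msd(tau) = tau^2
  tr <- fake_traj(com = cbind(0:(nf - 1), 0, 0))
  m <- msd_com(tr, "xy", lags = c(1, 2, 5, 10))
  expect_equal(m$msd, c(1, 4, 25, 100))
  # xy component ignores z displacement
  tr <- fake_traj(com = cbind(0, 0, 0:(nf - 1)))
  expect_true(all(msd_com(tr, "xy", lags = 1:5)$msd == 0))
  expect_equal(msd_com(tr, "xyz", lags = 2)$msd, 4)
  expect_error(msd_com(tr, "xy", lags = nf), "lags")
})

test_that("MSD is symmetric under time reversal of the trajectory", {
  set.seed(3)
  com <- apply(matrix(rnorm(60 * 3), 60, 3), 2, cumsum)
  a <- msd_com(fake_traj(com = com), lags = c(1, 3, 7, 15))
  b <- msd_com(fake_traj(com = com[60:1, ]), lags = c(1, 3, 7, 15))
  expect_equal(a$msd, b$msd)
})

test_that("end-to-end ACF matches closed forms", {
  nf <- 40
  # frozen vector: rho = 1 at all lags
  a <- end_to_end_acf(fake_traj(ree = matrix(rep(c(2L, 1L, 0L), each = nf),
                                             nf, 3)), lags = 1:5)
  expect_equal(a$rho, rep(1, 6))
  # alternating vector: rho(tau) = (-1)^tau
  ree <- cbind(rep(c(1L, -1L), nf / 2), 0L, 0L)
  a <- end_to_end_acf(fake_traj(ree = ree), lags = 1:4)
  expect_equal(a$rho, c(1, -1, 1, -1, 1))
  expect_error(end_to_end_acf(fake_traj(ree = matrix(0L, nf, 3))),
               "degenerate")
})

test_that("D_xy estimator recovers exact slopes", {
  msd <- structure(data.frame(lag_frames = 1:100, lag_mcs = 1:100,
                              msd = as.numeric(1:100), n_origin = 200 - 1:100),
                   class = c("polylat_msd", "data.frame"))
  est <- estimate_dxy(msd)
  expect_equal(est$d_xy, 0.25)
  expect_true(est$ok)
  msd$msd <- rep(0, 100)
  expect_equal(estimate_dxy(msd)$d_xy, 0)
  # window restriction: slope taken from the last decade only
  msd$msd <- c(sqrt(1:50), 0.2 * (51:100))  # curved head, linear tail
  est <- estimate_dxy(msd, window = c(60, 100))
  expect_equal(est$d_xy, 0.05)
  expect_warning(estimate_dxy(msd, window = c(1, 60), min_r_squared = 0.999),
                 "linearity")
})

test_that("tau_R estimator fits the 0.06-0.30 window of ln rho", {
  mk_acf <- function(lag, rho)
    structure(data.frame(lag_frames = lag, lag_mcs = lag, rho = rho,
                         n_origin = max(lag) + 1 - lag),
              class = c("polylat_acf", "data.frame"))
  lag <- 0:1000
  est <- estimate_tau_r(mk_acf(lag, exp(-lag / 100)))
  expect_equal(est$tau_r, 100, tolerance = 1e-8)
  expect_true(all(exp(-est$window_used / 100) > 0.06 - 1e-12) &&
              all(exp(-est$window_used / 100) < 0.30 + 1e-12))
  # sampling too sparse: no points inside the window
  expect_error(estimate_tau_r(mk_acf(c(0, 50, 100), exp(-c(0, 50, 100)))),
               "window")
  # amplitude prefactor does not bias the window fit: 0.5 exp(-t/200)
  rho <- ifelse(lag == 0, 1, 0.5 * exp(-lag / 200))
  expect_equal(estimate_tau_r(mk_acf(lag, rho))$tau_r, 200, tolerance = 1e-8)
  # non-decaying curve
  expect_error(estimate_tau_r(mk_acf(lag, rep(0.1, length(lag)))))
})

test_that("tau_R and 1/D scale linearly under time rescaling", {
  lag <- 0:2000
  acf <- structure(data.frame(lag_frames = lag, lag_mcs = lag,
                              rho = exp(-lag / 300),
                              n_origin = max(lag) + 1 - lag),
                   class = c("polylat_acf", "data.frame"))
  t1 <- estimate_tau_r(acf)$tau_r
  acf$lag_mcs <- acf$lag_mcs * 10
  expect_equal(estimate_tau_r(acf)$tau_r, 10 * t1, tolerance = 1e-8)
  msd <- structure(data.frame(lag_frames = 1:50, lag_mcs = 1:50,
                              msd = 0.4 * (1:50), n_origin = 51 - 1:50),
                   class = c("polylat_msd", "data.frame"))
  d1 <- estimate_dxy(msd)$d_xy
  msd$lag_mcs <- msd$lag_mcs * 10
  expect_equal(estimate_dxy(msd)$d_xy, d1 / 10, tolerance = 1e-12)
})

test_that("scaling-exponent fits recover exact power laws", {
  nv <- c(8, 16, 32, 64)
  fit <- fit_scaling_exponent(nv, 3 * nv^-1.5, decreasing = TRUE)
  expect_equal(fit$exponent, 1.5, tolerance = 1e-10)
  expect_equal(fit$prefactor, 3, tolerance = 1e-10)
  expect_equal(fit_scaling_exponent(nv, 0.7 * nv^2.2)$exponent, 2.2,
               tolerance = 1e-10)
  expect_equal(fit_scaling_exponent(nv, rep(4, 4))$exponent, 0)
  expect_error(fit_scaling_exponent(c(8, 16), c(1, 2)), "at least 3")
  expect_error(fit_scaling_exponent(nv, c(1, -1, 1, 1)), "positive")
})

test_that("coil-globule locator finds the steepest drop of <R_G^2>", {
  e <- seq(0, 1, by = 0.1)
  sig <- 30 - 20 / (1 + exp(-(e - 0.5) / 0.08))
  loc <- locate_coil_globule(e, sig)
  expect_equal(loc$e_pp_transition, 0.5, tolerance = 0.1)
  expect_equal(loc$resolution, 0.1)
  expect_error(locate_coil_globule(e, 10 - 5 * e), "linear")
  expect_error(locate_coil_globule(e, 10 + 5 * e), "decrease")
})
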