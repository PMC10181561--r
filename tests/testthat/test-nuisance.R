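test_that("frame censoring flags per-TR displacement above threshold", {
  mot <- matrix(0.5, 50, 6)
  expect_identical(censor_frames(mot)$n_censored, 0L)
  mot2 <- mot
  mot2[20:50, 1] <- mot2[20:50, 1] + 0.5       # persistent 0.5 mm step
  cens <- censor_frames(mot2)
  expect_identical(cens$n_censored, 1L)
  expect_false(cens$keep[20])
  expect_error(censor_frames(mot[1, , drop = FALSE]), "2 frames")
  expect_error(censor_frames(mot[, 1:5]), "6 columns")
  # idempotence on the generator's default (spike-free) motion
  truth <- small_truth()
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 200,
                            seed = 1)
  c1 <- censor_frames(sim$motion)
  c2 <- censor_frames(sim$motion[c1$keep, , drop = FALSE])
  expect_identical(c2$n_censored, 0L)
})

test_that("physiological regressors have the conventional 13 columns", {
  tt <- 80
  trace <- list(cardiac_phase = runif(tt, 0, 2 * pi),
                respiratory_phase = runif(tt, 0, 2 * pi),
                rvt = rnorm(tt))
  x <- build_physio_regressors(trace)
  expect_identical(ncol(x), 13L)
  expect_identical(sum(grepl("^card|^resp", colnames(x))), 8L)
  expect_identical(sum(grepl("^rvt", colnames(x))), 5L)
  # lag-k columns are shifted copies
  expect_equal(x[, "rvt_lag2"][3:tt], trace$rvt[1:(tt - 2)])
  const <- list(cardiac_phase = rep(1, tt),
                respiratory_phase = rep(1, tt), rvt = rnorm(tt))
  expect_warning(build_physio_regressors(const), "collinear")
})

test_that("motion regressors are parameters plus first derivatives", {
  tt <- 30
  mot <- matrix(rnorm(tt * 6), tt, 6)
  x <- build_motion_regressors(mot)
  expect_identical(ncol(x), 12L)
  expect_equal(x[, 7:12], rbind(0, diff(mot)), ignore_attr = TRUE)
  const <- build_motion_regressors(matrix(2, tt, 6))
  expect_true(all(const[, 7:12] == 0))
  ramp <- build_motion_regressors(matrix(rep(seq_len(tt), 6), tt, 6))
  expect_true(all(abs(ramp[-1, 7:12] - 1) < 1e-12))
})

test_that("CSF principal components capture a planted common waveform", {
  set.seed(5)
  d <- c(6, 6, 4, 120)
  wave <- sin(seq_len(d[4]) / 4)
  csf_mask <- array(FALSE, d[1:3]); csf_mask[2:4, 2:4, 2] <- TRUE
  a <- array(0, dim = d)
  m <- matrix(rnorm(sum(csf_mask) * d[4], 0, 0.3), sum(csf_mask), d[4])
  m <- m + outer(runif(sum(csf_mask), 0.5, 2), wave)
  a_full <- matrix(0, prod(d[1:3]), d[4]); a_full[as.vector(csf_mask), ] <- m
  a[] <- a_full
  pcs <- build_csf_regressors(a, csf_mask)
  expect_identical(ncol(pcs), 3L)
  expect_gt(abs(cor(pcs[, 1], wave)), 0.95)
  # exact rank-1 input: components beyond the first carry ~no variance
  a1 <- array(0, dim = d)
  a_full1 <- matrix(0, prod(d[1:3]), d[4])
  a_full1[as.vector(csf_mask), ] <- outer(seq_len(sum(csf_mask)), wave)
  a1[] <- a_full1
  expect_warning(p1 <- build_csf_regressors(a1, csf_mask), "rank")
  expect_lt(ncol(p1), 3L)
})

test_that("local-WM regressor averages the neighbourhood or falls back", {
  d <- c(10, 10, 6, 40)
  wave <- cos(seq_len(d[4]) / 3)
  wm_mask <- array(FALSE, d[1:3]); wm_mask[3:8, 3:8, 2:5] <- TRUE
  a <- array(rep(wave, each = prod(d[1:3])), dim = d)
  targets <- array(FALSE, d[1:3]); targets[5, 5, 3] <- TRUE; targets[1, 1, 1] <- TRUE
  lw <- build_local_wm_regressor(a, wm_mask, targets, radius_mm = 8,
                                 voxel_mm = c(2.4, 2.4, 2.7))
  expect_equal(lw[1, ], wave, tolerance = 1e-12)   # pure common waveform
  fb <- attr(lw, "fallback")
  expect_true(any(fb))                              # corner target falls back
  expect_equal(lw[which(fb)[1], ], wave, tolerance = 1e-12)
  # adjacent targets share most of the neighbourhood -> high correlation
  truth <- small_truth()
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 80,
                            seed = 3)
  gm <- phantom_mask(truth, "gm")
  lw2 <- build_local_wm_regressor(echo_data(sim$series),
                                  phantom_mask(truth, "wm"), gm,
                                  voxel_mm = truth$voxel_mm)
  ap <- meepi:::adjacent_pairs(gm)
  rr <- meepi:::rowwise_cor(lw2[ap[, 1], ], lw2[ap[, 2], ])
  expect_gt(mean(abs(rr)), 0.8)
})

test_that("nuisance GLM removes the design space and keeps the mean", {
  set.seed(9)
  tt <- 60
  d3 <- c(5, 5, 4)
  nv <- prod(d3)
  mot <- matrix(rnorm(tt * 6), tt, 6)
  x <- build_motion_regressors(mot)
  beta <- matrix(rnorm(nv * ncol(x)), nv, ncol(x))
  y <- beta %*% t(x) + 50
  a <- array(0, dim = c(d3, tt)); a[] <- y
  des <- build_nuisance_design(tt, 940, motion = x, polort = 0)
  mask <- array(TRUE, d3)
  fit <- fit_nuisance_glm(a, des, mask)
  expect_lt(max(apply(fit$residuals, 1, var)), 1e-18)
  expect_equal(rowMeans(fit$residuals), rowMeans(y), tolerance = 1e-8)
  # intercept-only design: residual is the original series (mean kept)
  des0 <- build_nuisance_design(tt, 940, polort = 0)
  fit0 <- fit_nuisance_glm(a, des0, mask)
  expect_equal(fit0$residuals, y, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("RSS of nested designs is monotone and marginal R2 is in [0,1]", {
  set.seed(10)
  tt <- 20
  d3 <- c(4, 4, 2)
  a <- array(rnorm(prod(d3) * tt), dim = c(d3, tt))
  mask <- array(TRUE, d3)
  trace <- list(cardiac_phase = runif(tt, 0, 2 * pi),
                respiratory_phase = runif(tt, 0, 2 * pi), rvt = rnorm(tt))
  des <- build_nuisance_design(tt, 940,
                               physio = build_physio_regressors(trace)[, 1:4],
                               motion = build_motion_regressors(
                                 matrix(rnorm(tt * 6), tt, 6)),
                               polort = 1)
  full <- fit_nuisance_glm(a, des, mask)
  for (step in c("physio", "motion", "polort")) {
    vp <- marginal_r2(a, des, step, mask)
    r2 <- vp$r2[mask]
    expect_true(all(r2 >= -1e-12 & r2 <= 1))
    expect_true(all(vp$ss_total <= vp$ss_step + 1e-9))
    expect_equal(vp$ss_total, full$rss, tolerance = 1e-9)
  }
  expect_error(marginal_r2(a, des, "nonsense", mask), "unknown step")
  expect_error(marginal_r2(a, des, "combine", mask), "reference")
})

test_that("combination-removed noise is independent of the regressors", {
  truth <- generate_phantom(shape = c(14, 14, 10), n_networks = 2, seed = 2,
                            noise_fractions = pure_fractions("thermal"))
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 300,
                            seed = 4)
  gm <- phantom_mask(truth, "gm")
  head <- phantom_mask(truth, "head")
  lw <- build_local_wm_regressor(echo_data(sim$series),
                                 phantom_mask(truth, "wm"), gm,
                                 voxel_mm = truth$voxel_mm)
  des <- build_nuisance_design(
    300, 940, physio = build_physio_regressors(sim$physio),
    motion = build_motion_regressors(sim$motion),
    local_wm = lw, local_wm_mask = gm)
  cmb <- combine_echoes(sim$series, oc_weights(fit_t2star(sim$series)))
  tab <- removed_noise_correlations(sim$series, cmb, des, gm)
  rms_reg <- tab$rms_r[grepl("^removed_vs_", tab$quantity)]
  expect_true(all(rms_reg < 0.1))
  # removed noise decorrelates across neighbours, unlike the local-WM set
  expect_lt(tab$rms_r[tab$quantity == "removed_adjacent"],
            tab$rms_r[tab$quantity == "local_wm_adjacent"])
})
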