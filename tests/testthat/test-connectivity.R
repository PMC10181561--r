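make_4d <- function(nv3, tt, fill) array(fill, dim = c(nv3, tt))

test_that("bandpass keeps in-band and rejects out-of-band oscillations", {
  tr <- 0.94
  tt <- 500                      # 0.3 Hz falls exactly on Fourier bin 141
  t_s <- (seq_len(tt) - 1) * tr
  d3 <- c(4, 4, 2)
  inband <- sin(2 * pi * 0.05 * t_s)
  outband <- sin(2 * pi * 0.3 * t_s)
  a_in <- array(rep(inband, each = prod(d3)), dim = c(d3, tt))
  a_out <- array(rep(outband, each = prod(d3)), dim = c(d3, tt))
  f_in <- bandpass_and_smooth(a_in, tr, fwhm_mm = 0)
  f_out <- bandpass_and_smooth(a_out, tr, fwhm_mm = 0)
  expect_gt(sd(f_in[1, 1, 1, ]) / sd(inband), 0.99)
  expect_lt(sd(f_out[1, 1, 1, ]) / sd(outband), 0.01)
  expect_error(bandpass_and_smooth(a_in, tr, band = c(0.009, 0.6)),
               "Nyquist")
})

test_that("bandpass retains the white-noise variance fraction of the band", {
  set.seed(31)
  tr <- 0.94
  tt <- 2000
  x <- rnorm(tt)
  a <- array(x, dim = c(1, 1, 1, tt))
  f <- bandpass_and_smooth(a, tr, fwhm_mm = 0)
  retained <- var(f[1, 1, 1, ]) / var(x)
  # FFT oracle: exact fraction of Fourier bins kept (excluding DC)
  fr <- seq(0, tt - 1) / (tt * tr)
  fr <- pmin(fr, 1 / tr - fr)
  frac_bins <- sum(fr >= 0.009 & fr <= 0.1) / (tt - 1)
  expect_equal(retained, frac_bins, tolerance = 0.1)
  expect_equal(frac_bins, (0.1 - 0.009) / (0.5 / tr), tolerance = 0.02)
})

test_that("smoothing is mean-preserving for spatially uniform frames", {
  a <- make_4d(c(8, 8, 6), 3, 7)
  s <- bandpass_and_smooth(a, 2, band = c(0.0, 0.2), fwhm_mm = 4,
                           voxel_mm = c(2.4, 2.4, 2.7))
  expect_equal(s, a, tolerance = 1e-9)
})

test_that("run concatenation z-scores per run", {
  set.seed(12)
  d3 <- c(5, 5, 3)
  r1 <- array(rnorm(prod(d3) * 160, 100, 10), dim = c(d3, 160))
  one <- concat_runs(list(r1))
  m <- matrix(one, prod(d3), 160)
  expect_lt(max(abs(rowMeans(m))), 1e-10)
  expect_equal(apply(m, 1, sd), rep(1, prod(d3)), tolerance = 1e-10)
  two <- concat_runs(list(r1, r1))
  expect_identical(dim(two)[4], 320L)
  expect_lt(max(abs(rowMeans(matrix(two, prod(d3), 320)))), 1e-10)
  r2 <- array(rnorm(prod(c(4, 4, 3)) * 20), dim = c(4, 4, 3, 20))
  expect_error(concat_runs(list(r1, r2)), "grid")
})

test_that("ROI FC matrix is symmetric Fisher-z with clipped extremes", {
  set.seed(13)
  d3 <- c(6, 6, 2)
  tt <- 500
  parcels <- array(0L, d3)
  parcels[1:2, , 1] <- 1L; parcels[3:4, , 1] <- 2L; parcels[5:6, , 1] <- 3L
  # parcels 1 and 2 share one waveform exactly; parcel 3 independent
  wave <- rnorm(tt)
  a <- array(0, dim = c(d3, tt))
  m <- matrix(0, prod(d3), tt)
  m[as.vector(parcels == 1L), ] <- rep(wave, each = sum(parcels == 1L))
  m[as.vector(parcels == 2L), ] <- rep(wave, each = sum(parcels == 2L))
  m[as.vector(parcels == 3L), ] <- rnorm(sum(parcels == 3L) * tt)
  a[] <- m
  fc <- roi_fc_matrix(a, parcels)
  expect_equal(fc$z, t(fc$z), tolerance = 1e-12)
  expect_true(all(diag(fc$z) == 0))
  expect_true(fc$clipped[1, 2])
  expect_equal(fc$z[1, 2], atanh(1 - 1e-7))
  expect_lt(abs(fc$z[1, 3]), 0.15)
  expect_equal(fisher_z(0.3), atanh(0.3))
  expect_equal(round(fisher_z(0.3), 4), 0.3095)
  # independent white-noise parcels stay near zero on average
  b <- array(rnorm(prod(d3) * tt), dim = c(d3, tt))
  fcb <- roi_fc_matrix(b, parcels)
  expect_lt(mean(abs(fcb$z[upper.tri(fcb$z)])), 0.1)
  # constant parcel
  cst <- a; cm <- matrix(cst, prod(d3), tt)
  cm[as.vector(parcels == 3L), ] <- 5
  cst[] <- cm
  expect_warning(fcc <- roi_fc_matrix(cst, parcels), "constant")
  expect_true(all(is.na(fcc$z[3, 1:2])))
})

test_that("paired edge screening needs both significance and magnitude", {
  set.seed(14)
  n <- 18
  base <- matrix(0, 4, 4)
  mk <- function(z12, noise) {
    m <- base
    m[1, 2] <- m[2, 1] <- z12 + rnorm(1, 0, noise)
    m + matrix(rnorm(16, 0, 0.01), 4, 4) * (1 - diag(4))
  }
  a <- replicate(n, mk(0.5, 0.1), simplify = FALSE)
  b <- replicate(n, mk(0.0, 0.1), simplify = FALSE)
  cmp <- compare_fc_groups(a, b)
  expect_true(cmp$edges[1, 2])
  expect_equal(sum(cmp$per_roi$n_edges), sum(cmp$edges))
  # identical groups: zero-variance differences get p = 1, no edges
  same <- compare_fc_groups(a, a)
  expect_identical(sum(same$edges), 0L)
  expect_true(all(same$p == 1))
  # strong significance but |z| below threshold in both groups: no edges
  a2 <- replicate(n, mk(0.15, 0.005), simplify = FALSE)
  b2 <- replicate(n, mk(0.05, 0.005), simplify = FALSE)
  cmp2 <- compare_fc_groups(a2, b2)
  expect_identical(sum(cmp2$edges), 0L)
  expect_error(compare_fc_groups(a[1:3], b[1:4]), "paired")
})

test_that("seed maps and the group seed-FC threshold behave", {
  set.seed(15)
  d3 <- c(8, 8, 4)
  tt <- 200
  mask <- array(TRUE, d3)
  seedm <- array(FALSE, d3); seedm[4, 4, 2] <- TRUE
  a <- array(rnorm(prod(d3) * tt), dim = c(d3, tt))
  z <- seed_fc_map(a, seedm, mask)
  expect_equal(z[4, 4, 2], atanh(1 - 1e-7))    # self-correlation clipped
  expect_error(seed_fc_map(a, array(FALSE, d3)), "empty seed")
  # null maps survive nowhere at FDR 0.001 + |z| > 0.3
  maps <- replicate(6, array(rnorm(prod(d3), 0, 0.05), dim = d3),
                    simplify = FALSE)
  g <- group_seed_fc(maps, gcor_covariate = runif(6, 0, 0.1), mask)
  expect_identical(g$extent, 0L)
  # strong consistent connectivity survives
  maps2 <- lapply(1:6, function(i) {
    m <- array(0.05, dim = d3); m[1:4, , ] <- 0.6 + rnorm(1, 0, 0.02); m
  })
  g2 <- group_seed_fc(maps2, gcor_covariate = runif(6, 0, 0.1), mask)
  expect_gte(g2$extent, sum(rep(TRUE, 4 * 8 * 4)) * 0.8)
})

test_that("fast GCOR identity matches the all-pairs mean", {
  set.seed(16)
  d3 <- c(3, 3, 1)
  tt <- 40
  a <- array(rnorm(prod(d3) * tt), dim = c(d3, tt))
  mask <- array(TRUE, d3)
  g <- gcor(a, mask)
  cmat <- cor(t(matrix(a, prod(d3), tt)))
  expect_equal(g, mean(cmat), tolerance = 1e-12)
  # toy 3-series hand check
  m3 <- array(0, dim = c(3, 1, 1, tt))
  m3[1, 1, 1, ] <- sin(1:tt); m3[2, 1, 1, ] <- cos(1:tt)
  m3[3, 1, 1, ] <- sin(1:tt) + 0.5 * rnorm(tt)
  g3 <- gcor(m3, array(TRUE, c(3, 1, 1)))
  expect_equal(g3, mean(cor(t(matrix(m3, 3, tt)))), tolerance = 1e-12)
  # identical waveforms give 1; many independent series approach 0
  same <- array(rep(sin(1:tt), each = 9), dim = c(3, 3, 1, tt))
  expect_equal(gcor(same, mask), 1, tolerance = 1e-12)
  big <- array(rnorm(500 * tt), dim = c(500, 1, 1, tt))
  expect_lt(gcor(big, array(TRUE, c(500, 1, 1))), 0.05)
  expect_error(gcor(a, array(FALSE, d3)), "2 voxels")
})
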