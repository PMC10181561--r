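test_that("phantom generation and simulation are deterministic in the seed", {
  a <- generate_phantom(shape = c(12, 12, 10), seed = 4)
  b <- generate_phantom(shape = c(12, 12, 10), seed = 4)
  expect_identical(a, b)
  p <- reference_protocol("multi")
  sa <- simulate_multiecho(a, p, n_frames = 20, seed = 9)
  sb <- simulate_multiecho(b, p, n_frames = 20, seed = 9)
  expect_identical(sa, sb)
  sc <- simulate_multiecho(a, p, n_frames = 20, seed = 10)
  expect_false(identical(sa$series$data[[1]], sc$series$data[[1]]))
})

test_that("invalid noise fractions are rejected naming the tissue", {
  nf <- default_noise_fractions()
  nf$wm["thermal"] <- 0.99
  expect_error(generate_phantom(shape = c(8, 8, 8), noise_fractions = nf),
               "wm")
  nf2 <- default_noise_fractions()
  nf2$gm["physio"] <- -0.1
  expect_error(generate_phantom(shape = c(8, 8, 8), noise_fractions = nf2),
               "nonnegative.*gm")
})

test_that("grey-matter T2* averages to the 3T cortical value", {
  truth <- generate_phantom(seed = 2)
  normal_gm <- phantom_mask(truth, "gm") & !truth$dropout_mask
  expect_equal(mean(truth$t2star_map[normal_gm]), 66, tolerance = 0.02)
  expect_true(all(truth$t2star_map[phantom_mask(truth, "head")] > 0))
  # networks live inside grey matter
  gm <- phantom_mask(truth, "gm")
  for (m in truth$network_maps) expect_true(all(m[!gm] == 0))
})

test_that("noise-free signal follows the mono-exponential closed form", {
  truth <- flat_truth(t2 = 40, s0 = 1000)
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 5,
                            seed = 1)
  head <- phantom_mask(truth, "head")
  mu <- vapply(sim$series$data,
               function(a) mean(rowMeans(vox_mat_test(a, head))), numeric(1))
  expect_equal(round(mu, 1), c(742.7, 474.7, 302.7))
  # zero temporal variance everywhere
  v <- max(vapply(sim$series$data, function(a) {
    max(apply(vox_mat_test(a, head), 1, var))
  }, numeric(1)))
  expect_equal(v, 0)
  # ln(signal) exactly linear in TE: residual from the 3-point line is 0
  te <- sim$series$echo_times
  lnS <- log(vapply(sim$series$data,
                    function(a) rowMeans(vox_mat_test(a, head)),
                    numeric(sum(head))))
  fit <- lm.fit(cbind(1, te), t(lnS))
  expect_lt(max(abs(fit$residuals)), 1e-12)
  expect_equal(unname(-1 / fit$coefficients[2, ]),
               rep(40, sum(head)), tolerance = 1e-9)
})

test_that("fractional BOLD amplitude grows with echo time", {
  truth <- flat_truth(t2 = 50, fractions = pure_fractions("bold", 0.3,
                                                          thermal_rest = FALSE))
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 200,
                            seed = 3)
  net <- truth$network_maps[[1]] > 0
  frac_sd <- vapply(sim$series$data, function(a) {
    m <- vox_mat_test(a, net)
    mean(apply(m, 1, sd) / rowMeans(m))
  }, numeric(1))
  expect_true(all(diff(frac_sd) > 0))
})

test_that("injected component variance fractions are recovered", {
  truth <- generate_phantom(shape = c(12, 12, 10), n_networks = 2, seed = 1)
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 2000,
                            seed = 6)
  comp <- sim$components
  gm <- (truth$tissue == 1L)[comp$mask]
  for (nm in names(comp$matrices)) {
    sel <- gm & comp$target_sd[[nm]] > 0
    if (!any(sel)) next
    emp <- mean((apply(comp$matrices[[nm]][sel, , drop = FALSE], 1, sd) /
                   comp$total_sd[sel])^2)
    target <- mean((comp$target_sd[[nm]][sel] / comp$total_sd[sel])^2)
    tol <- if (nm == "bold") 0.01 else 0.003    # bold is nonlinear in T2*
    expect_equal(emp, target, tolerance = tol / max(target, 1e-6))
  }
})

test_that("generated motion matches the quiet-subject displacement scale", {
  truth <- small_truth()
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 300,
                            seed = 11)
  cens <- censor_frames(sim$motion)
  expect_equal(mean(cens$enorm[-1]), 0.028, tolerance = 0.25)
  expect_identical(cens$n_censored, 0L)
  # injected spikes exceed the censoring threshold
  sim_sp <- simulate_multiecho(truth, reference_protocol("multi"),
                               n_frames = 100, seed = 12, motion_spikes = 2)
  expect_identical(censor_frames(sim_sp$motion)$n_censored, 2L)
})

test_that("late echoes relative to T2* trigger a warning", {
  truth <- flat_truth(t2 = 10)
  expect_warning(simulate_multiecho(truth, reference_protocol("multi"),
                                    n_frames = 4, seed = 1),
                 "3x")
})

test_that("datasets round-trip through NIfTI/TSV/JSON", {
  truth <- small_truth(shape = c(10, 10, 8))
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 12,
                            seed = 5)
  dir <- file.path(tempdir(), "meepi-roundtrip")
  manifest <- write_dataset(sim, dir)
  expect_identical(manifest$echo_times_ms, sim$series$echo_times)
  expect_identical(length(manifest$echo_files), 3L)
  expect_true(all(file.exists(file.path(dir, manifest$echo_files))))
  back <- read_dataset(dir)
  for (e in 1:3) {
    expect_equal(back$series$data[[e]],
                 unclass(sim$series$data[[e]]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  expect_equal(back$series$echo_times, sim$series$echo_times)
  expect_equal(back$series$tr, sim$series$tr)
  expect_equal(back$motion, sim$motion, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$physio$rvt, sim$physio$rvt, tolerance = 1e-6)
  expect_equal(back$truth_maps$t2star, unclass(truth$t2star_map),
               tolerance = 1e-6, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
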