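test_that("dual regression exactly inverts a noiseless mixture", {
  set.seed(21)
  d3 <- c(8, 8, 4)
  tt <- 50
  mask <- array(TRUE, d3)
  k <- 3
  maps <- lapply(1:k, function(i) array(rnorm(prod(d3)), dim = d3))
  names(maps) <- paste0("net", 1:k)
  tcs <- matrix(rnorm(k * tt), k, tt)
  A <- vapply(maps, function(m) m[mask], numeric(prod(d3)))
  y <- A %*% tcs
  a <- array(0, dim = c(d3, tt)); a[] <- y
  dr <- dual_regression(maps, a, mask)
  expect_equal(dr$timecourses, tcs, tolerance = 1e-8, ignore_attr = TRUE)
  for (i in 1:k) {
    expect_equal(dr$subject_maps[[i]], maps[[i]], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # K = 1 zero-mean unit-norm map: stage-1 equals the map-weighted mean
  m1 <- maps[[1]] - mean(maps[[1]])
  m1 <- m1 / sqrt(sum(m1^2))
  tc1 <- rnorm(tt)
  y1 <- outer(as.vector(m1), tc1)
  a1 <- array(0, dim = c(d3, tt)); a1[] <- y1
  dr1 <- dual_regression(list(n = m1), a1, mask)
  expect_equal(as.vector(dr1$timecourses),
               as.vector(t(y1) %*% as.vector(m1)), tolerance = 1e-8)
  # collinear maps are rejected
  expect_error(dual_regression(list(a = maps[[1]], b = maps[[1]] * 2),
                               a, mask), "collinear")
})

test_that("detection metrics follow the confusion-matrix identities", {
  d3 <- c(10, 10, 1)
  mask <- array(TRUE, d3)
  truth <- array(FALSE, d3); truth[1:2, 1:5, 1] <- TRUE   # 10 positives
  # hand counts: TP=8, FN=2, FP=1, TN=89
  test <- array(FALSE, d3)
  test[1:2, 1:4, 1] <- TRUE                                # 8 true hits
  test[5, 5, 1] <- TRUE                                    # 1 false alarm
  m <- detection_metrics(truth, test, mask)
  expect_identical(c(m$tp, m$fn, m$fp, m$tn), c(8L, 2L, 1L, 89L))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$fpr, 1 - 89 / 90)
  expect_equal(m$accuracy, 0.97)
  expect_identical(m$tp + m$tn + m$fp + m$fn, as.integer(sum(mask)))
  # perfect and complementary detections
  p <- detection_metrics(truth, truth, mask)
  expect_equal(c(p$sensitivity, p$fpr, p$accuracy), c(1, 0, 1))
  q <- detection_metrics(truth, !truth, mask)
  expect_equal(c(q$sensitivity, q$accuracy), c(0, 0))
  expect_error(detection_metrics(array(FALSE, d3), test, mask),
               "empty truth")
})

test_that("group network mask controls the null and finds strong effects", {
  set.seed(22)
  d3 <- c(8, 8, 3)
  mask <- array(TRUE, d3)
  null_maps <- replicate(6, array(rnorm(prod(d3)), dim = d3),
                         simplify = FALSE)
  det0 <- group_network_mask(null_maps, mask)
  expect_lt(sum(det0), 3)
  sig_maps <- lapply(1:6, function(i) {
    m <- array(rnorm(prod(d3), 0, 0.05), dim = d3)
    m[1:3, 1:3, ] <- m[1:3, 1:3, ] + 1
    m
  })
  det1 <- group_network_mask(sig_maps, mask)
  expect_gt(sum(det1[1:3, 1:3, ]), 0.8 * 27)
})

test_that("EPI coverage masks expose dropout recovery by combination", {
  truth <- generate_phantom(seed = 6)
  sim <- simulate_multiecho(truth, reference_protocol("multi"), n_frames = 80,
                            seed = 7)
  head <- phantom_mask(truth, "head")
  gm <- phantom_mask(truth, "gm")
  dropout <- phantom_mask(truth, "dropout")
  cmb <- combine_echoes(sim$series, oc_weights(fit_t2star(sim$series)))
  m_me <- epi_mask(cmb, ref_mask = head)
  m_oe <- epi_mask(echo_data(sim$series), ref_mask = head)
  cov_me <- coverage_ratio(list(m_me), gm)
  cov_oe <- coverage_ratio(list(m_oe), gm)
  drop_sel <- dropout[gm]
  expect_gt(mean(cov_me$map[gm][drop_sel]), mean(cov_oe$map[gm][drop_sel]))
  expect_gte(cov_me$ratio, cov_oe$ratio)
  # coverage-ratio arithmetic
  full <- array(TRUE, dim = dim(gm))
  expect_equal(coverage_ratio(list(full, full), gm)$ratio, 1)
  cr <- coverage_ratio(list(full, array(FALSE, dim(gm))), gm)
  expect_equal(cr$ratio, 0.5)
  expect_true(all(cr$map[gm] == 0.5))
  expect_error(coverage_ratio(list(full), array(FALSE, dim(gm))), "empty")
})

test_that("scan-length curve validates lengths and returns one row per cell", {
  set.seed(23)
  d3 <- c(6, 6, 3)
  mask <- array(TRUE, d3)
  map <- array(0, d3); map[1:3, 1:3, ] <- 1
  tcs_len <- 160
  subj <- lapply(1:3, function(i) {
    tc <- rnorm(tcs_len)
    y <- outer(as.vector(map), tc) + rnorm(prod(d3) * tcs_len, 0, 0.2)
    array(y, dim = c(d3, tcs_len))
  })
  cv <- scan_length_curve(subj, list(net = map), list(map > 0), tr_ms = 940,
                          mask, lengths_min = c(1, 2))
  expect_identical(nrow(cv), 2L)
  expect_true(all(cv$sensitivity >= 0 & cv$sensitivity <= 1))
  expect_error(scan_length_curve(subj, list(net = map), list(map > 0),
                                 940, mask, lengths_min = 0),
               "positive")
  expect_error(scan_length_curve(subj, list(net = map), list(map > 0),
                                 940, mask, lengths_min = 60),
               "available")
})
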