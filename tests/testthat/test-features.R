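test_that("Burg recovers known AR(2) coefficients from simulation", {
  x <- generate_ar_process(c(0.75, -0.5), 1, 10000, seed = 7)
  m <- fit_ar(x, 2)
  expect_lt(max(abs(m$coeffs - c(0.75, -0.5))), 0.05)
  expect_lt(abs(m$noise_var - 1), 0.1)
})

test_that("zero-noise AR recursion is recovered exactly by least squares", {
  x <- generate_ar_process(c(0.75, -0.5), 0, 60, seed = 1,
                           init = c(0.3, 1))
  m <- fit_ar(x, 2, method = "least_squares", demean = FALSE)
  expect_lt(max(abs(m$coeffs - c(0.75, -0.5))), 1e-6)
  expect_lt(m$noise_var, 1e-12)
  # Burg's joint forward/backward criterion lands nearby but not exactly
  mb <- fit_ar(generate_ar_process(c(0.75, -0.5), 1e-8, 5000, seed = 2),
               2)
  expect_lt(max(abs(mb$coeffs - c(0.75, -0.5))), 0.05)
})

test_that("white noise fits to near-zero coefficients", {
  w <- generate_ar_process(numeric(0), 1, 10000, seed = 3)
  m <- fit_ar(w, 2)
  expect_lt(max(abs(m$coeffs)), 0.05)
})

test_that("all three estimators agree on well-conditioned data", {
  x <- generate_ar_process(c(0.6, -0.3), 1, 5000, seed = 11)
  for (meth in c("burg", "yule_walker", "least_squares")) {
    m <- fit_ar(x, 2, meth)
    expect_lt(max(abs(m$coeffs - c(0.6, -0.3))), 0.08)
  }
  expect_error(fit_ar(rep(1, 100), 2), "constant")
  expect_error(fit_ar(rnorm(5), 2), "too short")
})

test_that("Burg coefficient error averages below 0.02 over 50 replicates", {
  err <- vapply(1:50, function(s) {
    x <- generate_ar_process(c(0.75, -0.5), 1, 10000, seed = s)
    mean(abs(fit_ar(x, 2)$coeffs - c(0.75, -0.5)))
  }, numeric(1))
  expect_lt(mean(err), 0.02)
})

test_that("Burg fits are always stationary and amplitude-invariant", {
  set.seed(13)
  for (i in 1:10) {
    x <- cumsum(rnorm(500))      # awkward, near-unit-root input
    m <- fit_ar(x, 4)
    expect_true(all(Mod(polyroot(c(1, -m$coeffs))) > 1))
  }
  x <- generate_ar_process(c(0.5), 1, 2000, seed = 2)
  m1 <- fit_ar(x, 3); m2 <- fit_ar(100 * x, 3)
  expect_equal(m1$coeffs, m2$coeffs, tolerance = 1e-10)
  expect_equal(m2$noise_var / m1$noise_var, 1e4, tolerance = 1e-6)
})

test_that("prediction-error curve drops at the true order then flattens", {
  x <- generate_ar_process(c(0.75, -0.5), 1, 8000, seed = 21)
  curve <- prediction_error_curve(x, 8)
  expect_gt(curve[1] - curve[2], 0.1)
  expect_lt(max(abs(diff(curve[2:8]))), 0.02)
  expect_true(all(diff(curve) <= 1e-9))     # Burg is non-increasing
  w <- generate_ar_process(numeric(0), 1, 8000, seed = 22)
  cw <- prediction_error_curve(w, 8)
  expect_lt(diff(range(cw)), 0.02)
})

test_that("knee selection follows the chord-distance rule", {
  expect_equal(select_order_knee(c(10, 2, 1.9, 1.85, 1.84)), 2L)
  expect_equal(select_order_knee(seq(10, 2, length.out = 6)), 1L)
  expect_equal(select_order_knee(rep(3, 5)), 1L)
  # oracle: brute-force perpendicular distance on random convex curves
  set.seed(31)
  for (i in 1:20) {
    cv <- sort(rexp(8), decreasing = TRUE)
    m <- length(cv)
    dist <- abs((cv[m] - cv[1]) * (1:m - 1) - (m - 1) * (cv - cv[1])) /
      sqrt((cv[m] - cv[1])^2 + (m - 1)^2)
    expect_equal(select_order_knee(cv), which.max(dist))
  }
})

test_that("beat grouping floors to complete groups", {
  expect_length(beat_groups(1:7 * 100, 2), 3)
  expect_length(beat_groups(100, 2), 0)
  g <- beat_groups(1:9 * 50, 3)
  expect_equal(unlist(g), 1:9)
  expect_error(beat_groups(1:5, 0), "group_size")
})

test_that("feature extraction produces AR + interval rows per group", {
  sim <- generate_ecg(clean_config(duration_s = 20))
  pk <- peak_set(r = sim$truth$r_indices, p = sim$truth$p_indices,
                 t = sim$truth$t_indices)
  f <- extract_features(sim$record, pk, ar_order = 2,
                        labels = sim$truth$beat_labels)
  expect_named(f, c("ar1", "ar2", "rr", "pr", "rt", "label"))
  expect_equal(nrow(f), 10)
  expect_true(all(abs(f$rr - 1.0) <= 1 / 360))
  tpl <- beat_template("regular")
  expect_true(all(abs(f$pr - tpl$pr_interval / 1000) <= 2 / 360))
  # missing P propagates as NA in the interval slot
  simv <- generate_ecg(clean_config(duration_s = 20,
                                    beat_classes = "PVC"))
  pkv <- peak_set(r = simv$truth$r_indices, p = simv$truth$p_indices,
                  t = simv$truth$t_indices)
  fv <- extract_features(simv$record, pkv, ar_order = 2)
  expect_true(all(is.na(fv$pr)))
  expect_error(extract_features(sim$record, peak_set(r = 100)),
               "at least")
})

test_that("morphology mode flattens 65-sample beats with RR features", {
  sim <- generate_ecg(clean_config(duration_s = 20, fs = 360))
  rc <- resample_record(sim$record, 260)
  r_rs <- round((sim$truth$r_indices - 1) * 260 / 360) + 1
  f <- extract_features(rc, peak_set(r = r_rs), type = "morphology",
                        labels = sim$truth$beat_labels)
  expect_equal(ncol(f), 65 + 3 + 1)  # 65 samples + 3 RR features + label
  expect_true(all(apply(f[, 1:65], 1, min) == -1))
  expect_true(all(apply(f[, 1:65], 1, max) == 1))
})
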