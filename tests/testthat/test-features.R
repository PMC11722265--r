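test_that("spike detection is empty on flat traces and exact on crafted ones", {
  pr <- step_protocol(noise = FALSE)
  flat <- voltage_trace(seq(0, 800, by = 0.025), rep(-70, 32001), pr)
  expect_identical(nrow(detect_spikes(flat)), 0L)

  tr <- make_triangle_trace(c(200, 300, 410), c(30, 26, 22))
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$t_threshold, c(200, 300, 410))
  expect_equal(sp$v_threshold, rep(-70, 3))
  expect_equal(sp$v_peak, c(30, 26, 22))
  expect_equal(sp$amplitude, c(100, 96, 92))
  # triangle at 80 mV/ms: width at half height = amplitude / 80
  expect_equal(sp$width, c(100, 96, 92) / 80, tolerance = 1e-10)
  expect_equal(sp$ahp, rep(0, 3))
})

test_that("upstroke-based detection is direction-sensitive", {
  # asymmetric spikes: slow ramp (16 mV/ms, below threshold) to -40, fast
  # upstroke (80 mV/ms) to +30, uniform fast fall back to baseline
  pr <- step_protocol(noise = FALSE)
  dt <- pr$dt
  vm <- rep(-70, 32001)
  for (t0 in c(200, 300, 410)) {
    i0 <- round(t0 / dt) + 1
    vm[i0 + 1:75] <- -70 + 0.4 * (1:75)          # ramp to -40
    vm[i0 + 75 + 1:35] <- -40 + 2 * (1:35)       # upstroke to +30
    vm[i0 + 110 + 1:50] <- 30 - 2 * (1:50)       # fall to -70
  }
  tr <- voltage_trace(seq(0, by = dt, length.out = 32001), vm, pr)
  sp_f <- detect_spikes(tr)
  sp_r <- detect_spikes(voltage_trace(tr$time, rev(tr$vm), pr))
  expect_equal(nrow(sp_f), 3L)
  expect_equal(sp_f$v_threshold, rep(-40, 3))    # past the slow ramp
  expect_equal(nrow(sp_r), 3L)
  expect_equal(sp_r$v_threshold, rep(-70, 3))    # reversed flank is all fast
})

test_that("all 23 features match hand-computed values on a crafted train", {
  tr <- make_triangle_trace(c(200, 300, 410), c(30, 26, 22))
  fv <- extract_features(tr)
  amps <- c(100, 96, 92)
  expect_equal(unname(fv["ap_threshold"]), -70)
  expect_equal(unname(fv["ap_amplitude"]), 100)
  expect_equal(unname(fv["ap_width"]), 100 / 80, tolerance = 1e-10)
  expect_equal(unname(fv["ahp"]), 0)
  expect_equal(unname(fv["ap_threshold_3rd"]), -70)
  expect_equal(unname(fv["ap_amplitude_3rd"]), 92)
  expect_equal(unname(fv["ap_width_3rd"]), 92 / 80, tolerance = 1e-10)
  expect_equal(unname(fv["ahp_3rd"]), 0)
  expect_equal(unname(fv["ap_count"]), 3)
  expect_equal(unname(fv["ap_count_1st_8th"]), 0)   # [100, 175)
  expect_equal(unname(fv["ap_count_1st_quarter"]), 1) # [100, 250)
  expect_equal(unname(fv["ap_count_1st_half"]), 2)  # [100, 400)
  expect_equal(unname(fv["ap_count_2nd_half"]), 1)  # [400, 700)
  expect_equal(unname(fv["ap_amp_adapt"]), 100 / 96)
  expect_equal(unname(fv["ap_average_amp_adapt"]), mean(c(100 / 96, 96 / 92)))
  expect_equal(unname(fv["ap_cv"]), sd(amps) / mean(amps))
  expect_equal(unname(fv["isi_adapt"]), 110 / 100)
  expect_equal(unname(fv["isi_cv"]), sd(c(100, 110)) / mean(c(100, 110)))
  expect_equal(unname(fv["latency"]), 100)
  # voltage moments straight off the crafted samples (independent slicing)
  t <- tr$time; vm <- tr$vm
  w <- vm[t >= 100 & t < 700]
  expect_equal(unname(fv["rest_vm_mean"]), mean(vm[t < 100]))
  expect_equal(unname(fv["vm_mean"]), mean(w))
  expect_equal(unname(fv["vm_std"]), sqrt(mean((w - mean(w))^2)))
  expect_equal(unname(fv["vm_skewness"]),
               mean((w - mean(w))^3) / mean((w - mean(w))^2)^1.5)
  expect_true(is_well_defined(fv))
})

test_that("degenerate and low-spike-count traces flag the right undefineds", {
  pr <- step_protocol(noise = FALSE)
  flat <- voltage_trace(seq(0, 800, by = 0.025), rep(-70, 32001), pr)
  fv <- extract_features(flat)
  expect_equal(unname(fv["rest_vm_mean"]), -70)
  expect_equal(unname(fv["vm_mean"]), -70)
  expect_equal(unname(fv["vm_std"]), 0)
  expect_equal(unname(fv["vm_skewness"]), 0)  # constant-window convention
  expect_equal(unname(fv["ap_count"]), 0)
  expect_true(is.na(fv["latency"]))
  expect_true(is.na(fv["ap_threshold"]))
  expect_false(is_well_defined(fv))

  two <- extract_features(make_triangle_trace(c(200, 300), c(30, 26)))
  expect_equal(unname(two["ap_count"]), 2)
  expect_false(is.na(two["ap_amp_adapt"]))
  expect_true(is.na(two["ap_threshold_3rd"]))
  expect_true(is.na(two["isi_adapt"]))
  expect_false(is_well_defined(two))
})

test_that("feature transforms follow the declared conventions", {
  tr <- make_triangle_trace(c(200, 300, 410), c(30, 26, 22))
  fv <- extract_features(tr)
  tf <- transform_features(fv)
  expect_equal(unname(tf["ap_count"]), log(3 + 1))
  expect_equal(unname(tf["ap_count_1st_8th"]), 0)      # log(0 + 1)
  expect_equal(unname(tf["latency"]), log(100))
  expect_equal(unname(tf["isi_adapt"]), log(1.1))
  expect_equal(unname(tf["ap_average_amp_adapt"]),
               1 / (1 + exp(-mean(c(100 / 96, 96 / 92)))))
  expect_equal(unname(tf["ap_threshold"]), -70)        # untransformed

  # sigmoid at zero is one half
  fv0 <- fv; fv0["ap_average_amp_adapt"] <- 0
  expect_equal(unname(transform_features(fv0)["ap_average_amp_adapt"]), 0.5)
  # zero latency (spike at onset) becomes undefined under log
  fv0["latency"] <- 0
  expect_true(is.na(transform_features(fv0)["latency"]))
})

test_that("voltage shift moves exactly the four voltage-level features", {
  tr <- make_triangle_trace(c(200, 300, 410), c(30, 26, 22))
  shifted <- voltage_trace(tr$time, tr$vm + 5, tr$protocol)
  a <- extract_features(tr); b <- extract_features(shifted)
  volt <- c("ap_threshold", "ap_threshold_3rd", "rest_vm_mean", "vm_mean")
  expect_equal(unname(b[volt] - a[volt]), rep(5, 4))
  rest <- setdiff(feature_names(), volt)
  expect_equal(unname(b[rest]), unname(a[rest]))
})

test_that("feature extraction ignores padding appended after the protocol", {
  tr <- make_triangle_trace(c(200, 300, 410), c(30, 26, 22))
  pad <- voltage_trace(c(tr$time, max(tr$time) + seq_len(2000) * 0.025),
                       c(tr$vm, rep(-55, 2000)), tr$protocol)
  expect_equal(extract_features(pad, tr$protocol)[feature_names()],
               extract_features(tr)[feature_names()])
})

test_that("standardizer gives zero mean unit (population) sd, and errors on zero sd", {
  set.seed(1)
  x <- matrix(rnorm(50 * 23), 50, dimnames = list(NULL, feature_names()))
  std <- fit_standardizer(x)
  z <- apply_standardizer(x, std)
  expect_equal(unname(colMeans(z)), rep(0, 23), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(z^2))), rep(1, 23), tolerance = 1e-12)
  # two-vector set: +/- 1 under the population convention
  two <- x[1:2, ]
  z2 <- apply_standardizer(two, fit_standardizer(two))
  expect_equal(abs(unname(z2)), matrix(1, 2, 23), tolerance = 1e-12)
  bad <- x; bad[, "latency"] <- 1
  expect_error(fit_standardizer(bad), "latency")
})
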