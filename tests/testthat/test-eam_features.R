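test_that("voltage amplitude is the peak-to-peak deflection", {
  expect_identical(voltage_amplitude(c(-0.8, 0.1, 1.2)), 2)
  expect_identical(voltage_amplitude(rep(3, 10)), 0)
  s <- random_signal()
  expect_equal(voltage_amplitude(s + 7.3), voltage_amplitude(s))
  expect_error(voltage_amplitude(numeric(0)), "empty")
})

test_that("triangulated CV recovers analytic planar and radial waves", {
  patch <- make_flat_patch(15, 15, 2)
  # planar wave at 50 cm/s: t(x) = x / 0.5 ms
  act <- patch$points[, 1] / 0.5
  cv <- conduction_velocity_map(patch, act)$cv
  interior <- patch$points[, 1] > 4 & patch$points[, 1] < 24 &
    patch$points[, 2] > 4 & patch$points[, 2] < 24
  expect_true(all(abs(cv[interior] - 50) < 2.5))
  # radial wave at 40 cm/s from the patch centre
  ctr <- c(14, 14, 0)
  r <- sqrt(rowSums(sweep(patch$points, 2, ctr)^2))
  cvr <- conduction_velocity_map(patch, r / 0.4)$cv
  far <- r >= 3 * 2 & patch$points[, 1] > 2 & patch$points[, 1] < 26 &
    patch$points[, 2] > 2 & patch$points[, 2] < 26
  expect_true(all(abs(cvr[far] - 40) / 40 < 0.10))
})

test_that("degenerate activation yields masked CV", {
  patch <- make_flat_patch(6, 6, 2)
  cv <- conduction_velocity_map(patch, rep(5, nrow(patch$points)))$cv
  expect_true(all(is.na(cv)))
})

test_that("CV error on a planar wave shrinks with mesh refinement", {
  err <- vapply(c(4, 2, 1), function(h) {
    patch <- make_flat_patch(round(28 / h) + 1, round(28 / h) + 1, h)
    act <- patch$points[, 1] / 0.5
    cv <- conduction_velocity_map(patch, act, radius = 2.5 * h)$cv
    interior <- patch$points[, 1] > 6 & patch$points[, 1] < 22 &
      patch$points[, 2] > 6 & patch$points[, 2] < 22
    mean(abs(cv[interior] - 50))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-9))
})

test_that("isochronal crowding matches exhaustive counting and its bounds", {
  patch <- make_flat_patch(12, 12, 2)
  expect_true(all(isochronal_crowding(
    patch, rep(1, nrow(patch$points)), geodesic = FALSE) == 1))
  # brute-force oracle over 20 random activation maps (euclidean discs)
  set.seed(11)
  for (k in 1:20) {
    act <- runif(nrow(patch$points), 0, 100)
    ic <- isochronal_crowding(patch, act, radius = 6, geodesic = FALSE)
    rng <- range(act)
    bins <- pmin(floor((act - rng[1]) / diff(rng) * 16) + 1L, 16L)
    for (i in sample(nrow(patch$points), 8)) {
      d <- sqrt(rowSums(sweep(patch$points, 2, patch$points[i, ])^2))
      expect_identical(ic[i], length(unique(bins[d <= 6])))
    }
    expect_lte(max(ic), 16L)
  }
  # linear ramp where the disc spans exactly 2/16 of the time range:
  # interior crowding is 2 or 3 (oracle: direct bin counting)
  wide <- make_flat_patch(41, 9, 2)          # x range 0..80
  act <- wide$points[, 1]                    # disc x-extent 10 = 2/16 * 80
  icr <- isochronal_crowding(wide, act, radius = 5, geodesic = FALSE)
  interior <- wide$points[, 1] >= 20 & wide$points[, 1] <= 60 &
    wide$points[, 2] >= 6 & wide$points[, 2] <= 10
  expect_true(all(icr[interior] %in% 2:3))
})

test_that("fractionation counts injected deflections and honours invariances", {
  tt <- seq(0, 0.5, by = 1 / 400)
  spike <- function(center, amp = 5) {
    g <- exp(-((tt - center) / 0.004)^2)
    c(diff(g), 0) * amp
  }
  expect_identical(fractionation_index(rep(0, 201)), 0L)
  expect_identical(fractionation_index(spike(0.2)), 1L)
  tri <- spike(0.1) + spike(0.25) + spike(0.4)
  expect_identical(fractionation_index(tri), 3L)
  # baseline shift and amplitude scaling above threshold do not change FI
  expect_identical(fractionation_index(tri + 4.2), fractionation_index(tri))
  expect_identical(fractionation_index(tri * 10), fractionation_index(tri))
})

test_that("electrogram duration matches the exhaustive sliding-window oracle", {
  dur_oracle <- function(x, fs = 400, wms = 27.5, frac = 0.10) {
    w <- round(wms * fs / 1000)
    sds <- vapply(seq_len(length(x) - w + 1L),
                  function(i) sd(x[i:(i + w - 1L)]), numeric(1))
    if (max(sds) <= 0) return(0)
    act <- which(sds > frac * max(sds))
    (max(act) - min(act)) / fs * 1000
  }
  expect_identical(egm_duration(rep(2, 160)), 0)
  # compact 40 ms deflection in a quiet 400 ms trace
  sig <- rep(0, 160); sig[60:76] <- sin(seq(0, 2 * pi, length.out = 17))
  expect_equal(egm_duration(sig), dur_oracle(sig))
  expect_gte(egm_duration(sig), 40 - 27.5)
  expect_lte(egm_duration(sig), 40 + 27.5)
  # two deflections 100 ms apart span both
  sig2 <- rep(0, 200); sig2[41:57] <- 1; sig2[81:97] <- -1
  expect_equal(egm_duration(sig2), dur_oracle(sig2))
  expect_gt(egm_duration(sig2), 100)
  # 100 random signals, exact agreement
  for (k in 1:100) {
    x <- random_signal(120 + (k %% 60), seed = k)
    expect_equal(egm_duration(x), dur_oracle(x), tolerance = 1e-12)
  }
  expect_error(egm_duration(rnorm(5)), "shorter")
})

test_that("frequency power obeys Parseval and quadratic scaling", {
  expect_identical(frequency_power(rep(1.5, 100)), 0)
  for (k in 1:25) {
    x <- random_signal(100 + 3 * k, seed = 100 + k)
    fp <- frequency_power(x)
    # time-domain oracle: population variance times sampling rate in kHz
    expect_equal(fp, mean((x - mean(x))^2) * 0.4, tolerance = 1e-9)
    expect_equal(frequency_power(2 * x), 4 * fp, tolerance = 1e-9)
  }
})

test_that("feature extraction fills all six features on captured maps", {
  f <- one_map()
  fm <- f$fm
  anat <- !f$s$lid
  for (feat in c("v_amp", "egm_dur", "fi", "fp")) {
    expect_gte(mean(!is.na(fm[[feat]][anat])), 0.95)
  }
  expect_gte(mean(!is.na(fm$cv[anat])), 0.5)    # masked where activation absent
  expect_true(all(fm$v_amp >= 0, na.rm = TRUE))
  expect_true(all(fm$egm_dur >= 0, na.rm = TRUE))
  expect_true(all(fm$fp >= 0, na.rm = TRUE))
  expect_true(all(fm$ic >= 1 & fm$ic <= 16, na.rm = TRUE))
  # deterministic
  fm2 <- extract_features(f$em, f$s, neighbors = coarse_neighbors())
  expect_identical(fm, fm2)
})
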