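test_that("intensity distance matches hand-computed cases and is a
           symmetric per-pixel mean", {
  I <- array(c(1, 0, 0, 1), c(2, 2, 1))
  J <- array(c(0, 0, 0, 1), c(2, 2, 1))
  expect_equal(distance_I(I, I), 0)
  expect_equal(distance_I(I, J), 0.25)
  set.seed(8)
  A <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  B <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  expect_equal(distance_I(A, B), distance_I(B, A))
  expect_error(distance_I(A, array(0, c(2, 2, 2))), "mismatch")
})

test_that("plan distances are exact for a perfect reconstruction and scale
           quadratically with dose", {
  tn <- fake_tensor(K = 2, dose = 3)
  perfect <- structure(list(
    aperture_prob = pmin(pmax(tn$apertures, 1e-7), 1 - 1e-7),
    dose_hat = tn$doses,
    intensity_hat = tn$intensities), class = "vmat_reconstruction")
  sc <- plan_distances(tn, perfect)
  expect_equal(sc$d_I, 0)
  expect_equal(sc$d_D, 0)
  expect_lte(sc$d_A, 1e-5)

  # imperfect reconstruction: doubling doses in input and reconstruction
  # quadruples the quadratic metrics and leaves the aperture BCE unchanged
  rec <- perfect
  rec$dose_hat <- tn$doses * 0.8
  rec$intensity_hat <- tn$intensities * 0.8
  rec$aperture_prob <- pmin(pmax(tn$apertures, 0.2), 0.8)
  s1 <- plan_distances(tn, rec)
  tn2 <- tn; tn2$doses <- tn$doses * 2; tn2$intensities <- tn$intensities * 2
  rec2 <- rec; rec2$dose_hat <- rec$dose_hat * 2
  rec2$intensity_hat <- rec$intensity_hat * 2
  s2 <- plan_distances(tn2, rec2)
  expect_equal(s2$d_I, 4 * s1$d_I, tolerance = 1e-12)
  expect_equal(s2$d_D, 4 * s1$d_D, tolerance = 1e-12)
  expect_equal(s2$d_A, s1$d_A, tolerance = 1e-12)

  # internal consistency with distance_I on the assembled stacks
  expect_equal(s1$d_I, distance_I(tn$intensities, rec$intensity_hat))
})

test_that("plan distances are invariant to CP ordering", {
  tn <- fake_tensor(K = 4)
  set.seed(1)
  rec <- structure(list(aperture_prob = array(runif(16 * 16 * 4, 0.1, 0.9),
                                              c(16, 16, 4)),
                        dose_hat = runif(4, 1, 3),
                        intensity_hat = array(runif(16 * 16 * 4),
                                              c(16, 16, 4))),
                   class = "vmat_reconstruction")
  perm <- c(3, 1, 4, 2)
  tnp <- tn
  tnp$apertures <- tn$apertures[, , perm]
  tnp$intensities <- tn$intensities[, , perm]
  tnp$doses <- tn$doses[perm]
  recp <- rec
  recp$aperture_prob <- rec$aperture_prob[, , perm]
  recp$dose_hat <- rec$dose_hat[perm]
  recp$intensity_hat <- rec$intensity_hat[, , perm]
  expect_equal(plan_distances(tn, rec)[, c("d_I", "d_A", "d_D")],
               plan_distances(tnp, recp)[, c("d_I", "d_A", "d_D")])
})

test_that("zero-FNR threshold calibration matches the exhaustive sweep", {
  pol <- threshold_policy("oracle_fnr0")
  scores <- c(1, 2, 3, 5, 7)
  labels <- c("regular", "regular", "regular", "anomalous", "anomalous")
  a <- calibrate_threshold(scores, labels, pol)
  expect_equal(a, 3)
  expect_equal(a, oracle_fnr0_threshold(scores, labels))
  # the rule is strict: FNR is zero at alpha, positive above min anomaly
  expect_true(all(classify(c(5, 7), a) == "anomalous"))

  set.seed(11)
  for (i in 1:25) {
    s <- round(runif(20, 0, 10), 1)
    l <- sample(c("regular", "anomalous"), 20, replace = TRUE,
                prob = c(0.8, 0.2))
    if (!any(l == "anomalous")) l[1] <- "anomalous"
    a <- calibrate_threshold(s, l, pol)
    sweep_a <- oracle_fnr0_threshold(s, l)
    if (is.na(sweep_a)) {
      expect_lt(a, min(s[l == "anomalous"]))
    } else {
      expect_equal(a, sweep_a)
    }
    # invariant: zero false negatives on calibration data
    expect_equal(sum(l == "anomalous" & s <= a), 0L)
  }
})

test_that("degenerate overlap falls back to a threshold below every
           anomaly", {
  a <- calibrate_threshold(c(2, 3, 1), c("regular", "regular", "anomalous"),
                           threshold_policy("oracle_fnr0"))
  expect_lt(a, 1)
  pred <- classify(c(2, 3, 1), a)
  expect_equal(sum(pred == "anomalous"), 3L)  # FNR 0, FPR 1
  expect_error(calibrate_threshold(c(1, 2), c("regular", "regular"),
                                   threshold_policy("oracle_fnr0")),
               "anomal")
})

test_that("quantile calibration uses the nearest rank and is monotone in
           q", {
  expect_equal(calibrate_threshold(1:100,
                                   policy = threshold_policy("quantile",
                                                             0.95)), 95)
  set.seed(3)
  s <- runif(57)
  alphas <- vapply(c(0.5, 0.8, 0.9, 0.99), function(q)
    calibrate_threshold(s, policy = threshold_policy("quantile", q)),
    numeric(1))
  expect_true(all(diff(alphas) >= 0))
  expect_error(threshold_policy("quantile", 1.5), "quantile_q")
})

test_that("classification is strict at the threshold", {
  expect_identical(classify(5, 3), "anomalous")
  expect_identical(classify(3, 3), "regular")
  expect_identical(classify(2, 3), "regular")
  expect_identical(classify(c(1, 4), 3), c("regular", "anomalous"))
})

test_that("score_plan equals distances of the model's own reconstruction", {
  tn <- fake_tensor(K = 3)
  m <- vmat_ae(tn, kind = "multitask", input_shape = c(16, 16),
               latent_dim = 4, channels = c(2, 3, 4, 5), epochs = 1,
               batch_size = 4, seed = 1)
  sc <- score_plan(m, tn)
  rec <- predict(m, tn)
  expect_equal(sc$d_I, distance_I(tn$intensities, rec$intensity_hat))
  expect_equal(sc$d_A, loss_aperture(tn$apertures, rec$aperture_prob))
  expect_equal(sc$d_D, loss_dose(tn$doses, rec$dose_hat))

  mb <- vmat_ae(tn, kind = "vanilla", input_shape = c(16, 16),
                latent_dim = 4, channels = c(2, 3, 4, 5), epochs = 1,
                batch_size = 4, seed = 1)
  scb <- score_plan(mb, tn)
  expect_true(is.na(scb$d_A) && is.na(scb$d_D))
  expect_gte(scb$d_I, 0)
})
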