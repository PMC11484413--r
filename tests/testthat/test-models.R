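test_that("loss functions reproduce hand-computed values", {
  # BCE: perfect reconstruction is (numerically) zero
  A <- c(1, 0, 1, 1)
  expect_lte(loss_aperture(A, pmin(pmax(A, 1e-7), 1 - 1e-7)), 1e-5)
  # uninformative probabilities give ln 2
  expect_equal(loss_aperture(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-9)
  # single-term closed form: all-ones target at p = 0.9
  expect_equal(loss_aperture(1, 0.9), -log(0.9), tolerance = 1e-9)
  expect_error(loss_aperture(c(1, 0), c(0.5, 0.5, 0.5)), "mismatch")

  expect_equal(loss_dose(c(1, 3), c(1, 3)), 0)
  expect_equal(loss_dose(c(1, 3), c(2, 2)), 1, tolerance = 1e-9)
  # quadratic homogeneity
  expect_equal(loss_dose(c(0, 0), 2 * c(1, 2)),
               4 * loss_dose(c(0, 0), c(1, 2)), tolerance = 1e-12)
  expect_error(loss_dose(1:3, 1:2), "length")

  expect_equal(loss_total(0.5, 0.25, 0), 0.25)
  expect_equal(loss_total(0.5, 0.25, 1), 0.75)
  expect_equal(loss_total(0.1, 0.3, 2), 0.5)
  expect_error(loss_total(0.1, 0.3, -1), ">= 0")
})

test_that("total loss is monotone in its components and weight", {
  set.seed(1)
  for (i in 1:20) {
    la <- runif(1); ld <- runif(1); lam <- runif(1, 0, 3)
    expect_gte(loss_total(la + 0.1, ld, lam), loss_total(la, ld, lam))
    expect_gte(loss_total(la, ld + 0.1, lam), loss_total(la, ld, lam))
    expect_gte(loss_total(la, ld, lam + 0.1) - loss_total(la, ld, lam), 0)
  }
})

test_that("variational KL term matches the closed form", {
  expect_equal(kl_gaussian(0, 0), 0)
  expect_equal(kl_gaussian(1, 0), 0.5, tolerance = 1e-12)
  # batch of two samples averages per-sample KL
  mu <- cbind(c(1, 0), c(0, 0)); lv <- cbind(c(0, 0), c(0, 0))
  expect_equal(kl_gaussian(mu, lv), 0.25, tolerance = 1e-12)
  expect_gte(kl_gaussian(rnorm(5), rnorm(5)), 0)
})

test_that("architecture dimensions follow the config", {
  tn <- fake_tensor(M = 64, N = 64, K = 2)
  m <- vmat_ae(tn, kind = "multitask", input_shape = c(64, 64),
               latent_dim = 32, epochs = 0, seed = 1)
  enc <- m$segments$enc
  lin <- enc[[length(enc) - 1]]
  # spatial size before the linear block is 4x4
  expect_equal(lin$nin, 32L * 4L * 4L)
  expect_equal(lin$nout, 32L)

  # latent echo through the forward pass
  X <- matrix(tn$intensities, 4096, 2) / m$dose_norm
  h <- vmatqa:::seq_fwd(enc, X, train = FALSE)$out
  expect_equal(nrow(h), 32L)

  mv <- vmat_ae(fake_tensor(M = 16, N = 16), kind = "variational",
                input_shape = c(16, 16), latent_dim = 5, epochs = 0,
                seed = 1)
  encv <- mv$segments$enc
  expect_equal(encv[[length(encv)]]$nout, 10L)  # (mu, log sigma^2)

  expect_error(ae_config(input_shape = c(60, 60)), "divisible by 16")
})

test_that("training refuses anomalous plans and epochs = 0 keeps the
           initial weights", {
  tn <- fake_tensor()
  bad <- fake_tensor(label = "anomalous")
  expect_error(vmat_ae(list(tn, bad), kind = "vanilla",
                       input_shape = c(16, 16), epochs = 1),
               "regular plans only")
  m0a <- vmat_ae(tn, kind = "vanilla", input_shape = c(16, 16),
                 epochs = 0, seed = 9)
  m0b <- vmat_ae(tn, kind = "vanilla", input_shape = c(16, 16),
                 epochs = 0, seed = 9)
  expect_identical(m0a$checksum, m0b$checksum)
  expect_equal(nrow(m0a$history), 0L)
  expect_true(is.finite(m0a$baseline_loss[["L_R"]]))
})

test_that("a single repeated control point is overfit to a fraction of the
           initial loss", {
  tl <- lapply(1:64, function(i) fake_tensor(K = 1))
  m <- vmat_ae(tl, kind = "multitask", input_shape = c(16, 16),
               latent_dim = 8, channels = c(2, 4, 6, 8), epochs = 200,
               batch_size = 16, seed = 5)
  expect_lt(tail(m$history$L_R, 1), 0.1 * m$history$L_R[1])
})

test_that("training is bit-reproducible under a fixed seed", {
  tl <- lapply(1:8, function(i) fake_tensor(K = 2))
  for (kind in c("multitask", "contractive", "variational")) {
    m1 <- vmat_ae(tl, kind = kind, input_shape = c(16, 16), latent_dim = 4,
                  channels = c(2, 3, 4, 5), epochs = 3, batch_size = 8,
                  seed = 7)
    m2 <- vmat_ae(tl, kind = kind, input_shape = c(16, 16), latent_dim = 4,
                  channels = c(2, 3, 4, 5), epochs = 3, batch_size = 8,
                  seed = 7)
    expect_identical(m1$history, m2$history)
    expect_identical(m1$checksum, m2$checksum)
  }
})

test_that("contractive training with zero penalty weight is loss-identical
           to the vanilla objective", {
  tl <- lapply(1:8, function(i) fake_tensor(K = 2))
  mv <- vmat_ae(tl, kind = "vanilla", input_shape = c(16, 16),
                latent_dim = 4, channels = c(2, 3, 4, 5), epochs = 3,
                batch_size = 8, seed = 3)
  mc <- vmat_ae(tl, kind = "contractive", contractive_gamma = 0,
                input_shape = c(16, 16), latent_dim = 4,
                channels = c(2, 3, 4, 5), epochs = 3, batch_size = 8,
                seed = 3)
  expect_equal(mv$history$L_R, mc$history$L_R, tolerance = 1e-12)
})

test_that("the contractive penalty vanishes for a constant encoder and
           matches a finite-difference Jacobian", {
  tn <- fake_tensor()
  m <- vmat_ae(tn, kind = "contractive", input_shape = c(16, 16),
               latent_dim = 4, channels = c(2, 3, 4, 5), epochs = 0,
               seed = 3)
  X <- matrix(rnorm(256 * 3), 256, 3)
  # zero out every weight -> zero Jacobian -> zero penalty
  m0 <- m
  m0$segments$enc <- lapply(m0$segments$enc, function(l) {
    for (p in vmatqa:::param_names(l)) l[[p]] <- l[[p]] * 0
    l
  })
  expect_equal(contractive_penalty(m0, X, mode = "exact"), 0)

  pen <- contractive_penalty(m, X, mode = "exact")
  enc_eval <- function(Z) vmatqa:::seq_fwd(m$segments$enc, Z,
                                           train = FALSE)$out
  eps <- 1e-5; tot <- 0
  for (i in 1:256) {
    Xp <- X; Xp[i, ] <- Xp[i, ] + eps
    Xm <- X; Xm[i, ] <- Xm[i, ] - eps
    tot <- tot + sum(((enc_eval(Xp) - enc_eval(Xm)) / (2 * eps))^2)
  }
  expect_equal(pen, tot / ncol(X), tolerance = 0.05)
})

test_that("reconstructions have the right ranges, shapes and dose scale", {
  tl <- lapply(1:6, function(i) fake_tensor(K = 4, dose = 2 + i / 3))
  m <- vmat_ae(tl, kind = "multitask", input_shape = c(16, 16),
               latent_dim = 8, channels = c(2, 4, 6, 8), epochs = 30,
               batch_size = 8, seed = 2)
  rec <- predict(m, tl[[1]])
  expect_s3_class(rec, "vmat_reconstruction")
  expect_true(all(rec$aperture_prob > 0 & rec$aperture_prob < 1))
  expect_equal(dim(rec$intensity_hat), c(16, 16, 4))
  expect_equal(length(rec$dose_hat), 4L)
  # intensity is assembled from the two heads
  expect_equal(rec$intensity_hat[, , 2],
               rec$dose_hat[2] * rec$aperture_prob[, , 2],
               tolerance = 1e-12)

  mb <- vmat_ae(tl, kind = "vanilla", input_shape = c(16, 16),
                latent_dim = 8, channels = c(2, 4, 6, 8), epochs = 1,
                batch_size = 8, seed = 2)
  recb <- predict(mb, tl[[1]])
  expect_null(recb$aperture_prob)
  expect_equal(dim(recb$intensity_hat), c(16, 16, 4))

  # shape metadata guard
  expect_error(predict(m, fake_tensor(M = 32, N = 32)), "shape")
})

test_that("checkpoints round-trip through save and load", {
  tn <- fake_tensor()
  m <- vmat_ae(tn, kind = "multitask", input_shape = c(16, 16),
               latent_dim = 4, channels = c(2, 3, 4, 5), epochs = 1,
               batch_size = 4, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_vmat_ae(m, path)
  m2 <- load_vmat_ae(path)
  expect_identical(m2$checksum, m$checksum)
  expect_equal(score_plan(m2, tn), score_plan(m, tn))
  saveRDS(list(a = 1), path)
  expect_error(load_vmat_ae(path), "checkpoint")
})
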