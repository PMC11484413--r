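#' Autoencoder configuration
#'
#' @param kind model family: `"multitask"` (aperture + dose decoders),
#'   `"vanilla"`, `"contractive"` or `"variational"` (single intensity
#'   decoder).
#' @param input_shape `c(M, N)` feature-map size; both must be divisible by
#'   16 (four stride-2 halvings).
#' @param latent_dim bottleneck width h.
#' @param channels widths of the four conv blocks.
#' @param lambda_weight weight of the aperture term in the multi-task loss
#'   `L_R = lambda * L_A + L_D`.
#' @param contractive_gamma weight of the contractive (Jacobian Frobenius)
#'   penalty.
#' @param vae_beta weight of the variational KL term.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size (individual CPs are the sample unit).
#' @param seed RNG seed for initialization, shuffling and any sampling.
#' @return an object of class `ae_config`.
#' @export
ae_config <- function(kind = c("multitask", "vanilla", "contractive",
                               "variational"),
                      input_shape = c(64L, 64L), latent_dim = 32L,
                      channels = c(4L, 8L, 16L, 32L), lambda_weight = 1,
                      contractive_gamma = 1e-4, vae_beta = 1e-3,
                      learning_rate = 1e-3, epochs = 5L, batch_size = 128L,
                      seed = 1L) {
  kind <- match.arg(kind)
  input_shape <- as.integer(input_shape)
  if (any(input_shape %% 16L != 0L))
    stop("input_shape must be divisible by 16")
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  if (length(channels) != 4L) stop("channels must give four block widths")
  if (lambda_weight < 0 || contractive_gamma < 0 || vae_beta < 0)
    stop("loss weights must be >= 0")
  structure(list(kind = kind, input_shape = input_shape,
                 latent_dim = as.integer(latent_dim),
                 channels = as.integer(channels),
                 lambda_weight = lambda_weight,
                 contractive_gamma = contractive_gamma, vae_beta = vae_beta,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "ae_config")
}

# encoder: four down blocks (stride-2 conv + stride-1 conv, each BN+ReLU)
# then one linear block to the bottleneck. The variational encoder ends in
# a plain linear layer emitting (mu, log sigma^2).
build_encoder <- function(cfg) {
  M <- cfg$input_shape[1]; N <- cfg$input_shape[2]
  ch <- c(1L, cfg$channels)
  layers <- list()
  for (b in 1:4) {
    hi <- M / 2^(b - 1); wi <- N / 2^(b - 1)
    ho <- hi / 2; wo <- wi / 2
    layers <- c(layers, list(
      nn_conv(ch[b], ch[b + 1], hi, wi, 2L), nn_bn(ch[b + 1], ho * wo),
      nn_relu(),
      nn_conv(ch[b + 1], ch[b + 1], ho, wo, 1L), nn_bn(ch[b + 1], ho * wo),
      nn_relu()))
  }
  flat <- cfg$channels[4] * (M / 16) * (N / 16)
  if (cfg$kind == "variational")
    c(layers, list(nn_linear(flat, 2L * cfg$latent_dim)))
  else
    c(layers, list(nn_linear(flat, cfg$latent_dim), nn_relu()))
}

# spatial decoder: linear block then four up blocks (stride-2 transposed
# conv + stride-1 conv, BN+ReLU) and a pointwise 1-channel head emitting
# logits (multitask aperture) or intensities (baselines). The full-
# resolution block is kept narrow: it dominates CPU cost.
build_spatial_decoder <- function(cfg) {
  M <- cfg$input_shape[1]; N <- cfg$input_shape[2]
  ch <- cfg$channels
  flat <- ch[4] * (M / 16) * (N / 16)
  layers <- list(nn_linear(cfg$latent_dim, flat), nn_relu())
  half <- max(2L, ch[1] %/% 2L)
  upch <- c(ch[3], ch[2], ch[1], ch[1])   # transposed-conv widths
  s1ch <- c(ch[3], ch[2], ch[1], half)    # stride-1 conv widths
  for (b in 1:4) {
    hi <- (M / 16) * 2^(b - 1); wi <- (N / 16) * 2^(b - 1)
    cin <- if (b == 1) ch[4] else s1ch[b - 1]
    layers <- c(layers, list(
      nn_convt(cin, upch[b], hi, wi),
      nn_bn(upch[b], 4 * hi * wi), nn_relu(),
      nn_conv(upch[b], s1ch[b], 2 * hi, 2 * wi, 1L),
      nn_bn(s1ch[b], 4 * hi * wi), nn_relu()))
  }
  c(layers, list(nn_conv(half, 1L, M, N, 1L)))
}

build_dose_decoder <- function(cfg) {
  list(nn_linear(cfg$latent_dim, 64L), nn_relu(),
       nn_linear(64L, 32L), nn_relu(),
       nn_linear(32L, 16L), nn_relu(),
       nn_linear(16L, 1L))
}

build_segments <- function(cfg) {
  segs <- list(enc = nn_init(build_encoder(cfg)))
  if (cfg$kind == "multitask") {
    segs$dec_a <- nn_init(build_spatial_decoder(cfg))
    segs$dec_d <- nn_init(build_dose_decoder(cfg))
  } else {
    segs$dec_i <- nn_init(build_spatial_decoder(cfg))
  }
  segs
}

# ---- losses --------------------------------------------------------------

#' Aperture reconstruction loss (binary cross-entropy)
#'
#' `L_A = -(1/(K*M*N)) sum [A log A' + (1-A) log(1-A')]`, with the
#' reconstructed probabilities clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param A binary aperture stack (any numeric array/matrix).
#' @param A_prob reconstructed probabilities, same shape.
#' @return non-negative scalar.
#' @export
loss_aperture <- function(A, A_prob) {
  if (!identical(dim(A) %||% length(A), dim(A_prob) %||% length(A_prob)))
    stop("shape mismatch between A and A_prob")
  p <- pmin(pmax(A_prob, 1e-7), 1 - 1e-7)
  -mean(A * log(p) + (1 - A) * log(1 - p))
}

#' Dose reconstruction loss (mean squared error)
#'
#' `L_D = (1/K) sum (D_k - D'_k)^2`.
#'
#' @param D,D_hat dose vectors of equal length.
#' @return non-negative scalar, zero iff equal.
#' @export
loss_dose <- function(D, D_hat) {
  if (length(D) != length(D_hat)) stop("dose vectors differ in length")
  mean((D - D_hat)^2)
}

#' Combined multi-task loss
#'
#' `L_R = lambda * L_A + L_D`.
#'
#' @param L_A,L_D component losses.
#' @param lambda_weight non-negative weighting factor.
#' @return scalar.
#' @export
loss_total <- function(L_A, L_D, lambda_weight) {
  if (!is.finite(L_A) || !is.finite(L_D)) stop("losses must be finite")
  if (lambda_weight < 0) stop("lambda_weight must be >= 0")
  lambda_weight * L_A + L_D
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `-0.5 * sum(1 + log sigma^2 - mu^2 - sigma^2)` per sample,
#' averaged over samples (columns).
#'
#' @param mu,logvar latent mean and log-variance (vectors, or
#'   `latent x batch` matrices).
#' @return mean per-sample KL (>= 0).
#' @export
kl_gaussian <- function(mu, logvar) {
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  if (!identical(dim(mu), dim(logvar))) stop("shape mismatch")
  mean(colSums(-0.5 * (1 + logvar - mu^2 - exp(logvar))))
}

#' Contractive penalty of a fitted encoder
#'
#' Squared Frobenius norm of the Jacobian of the latent code with respect to
#' the input, averaged over samples. `mode = "exact"` sums `|J e_i|^2` over
#' all input directions (use on small inputs only); `"hutchinson"` is the
#' unbiased Rademacher-probe estimate used during training. Evaluated at the
#' encoder's inference point (batch-norm running statistics).
#'
#' @param object a fitted [vmat_ae()].
#' @param X input matrix (`prod(input_shape) x n` samples).
#' @param mode `"exact"` or `"hutchinson"`.
#' @param n_probes probes for the Hutchinson estimate.
#' @param seed RNG seed for probe draws.
#' @return scalar penalty (without the `contractive_gamma` factor).
#' @export
contractive_penalty <- function(object, X, mode = c("exact", "hutchinson"),
                                n_probes = 1L, seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  f <- seq_fwd(object$segments$enc, X, train = FALSE)
  if (mode == "exact") {
    tot <- 0
    for (i in seq_len(nrow(X))) {
      T_ <- matrix(0, nrow(X), ncol(X)); T_[i, ] <- 1
      tot <- tot + sum(seq_jvp(f$layers, f$caches, T_)$tout^2)
    }
    tot / ncol(X)
  } else {
    with_seed(seed, {
      tot <- 0
      for (j in seq_len(n_probes)) {
        T_ <- matrix(sample(c(-1, 1), length(X), replace = TRUE), nrow(X))
        tot <- tot + sum(seq_jvp(f$layers, f$caches, T_)$tout^2)
      }
      tot / (n_probes * ncol(X))
    })
  }
}

# ---- training ------------------------------------------------------------

bce_mean <- function(A, P) {
  p <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  -mean(A * log(p) + (1 - A) * log(1 - p))
}

#' Fit a plan autoencoder
#'
#' Trains an autoencoder on the feature maps of regular plans only; the
#' sample unit is the individual control point. Inputs are the intensity
#' maps scaled by the training-set maximum dose (the factor is stored with
#' the model). The multi-task model reconstructs the binary aperture (via a
#' sigmoid head trained with binary cross-entropy) and the normalized dose
#' (mean squared error), combined as `L_R = lambda * L_A + L_D`; baseline
#' models reconstruct the intensity map itself under mean squared error,
#' optionally with a contractive or variational regularizer. Optimization
#' is Adam with learning rate `1e-3` by default; training is fully seeded
#' and reproducible on a fixed thread count.
#'
#' @param x a `feature_tensor` or list of them (the training set; labels
#'   must not be `"anomalous"`).
#' @param kind,... model family and any [ae_config()] argument.
#' @param config an [ae_config()]; overrides `kind`/`...` when given.
#' @return an object of class `vmat_ae`: the fitted model, with `history`
#'   (per-epoch mean losses), `baseline_loss` (pre-training loss on a
#'   sample), `dose_norm`, `checksum` and `seed`.
#' @seealso [predict.vmat_ae()], [score_plan()], [save_vmat_ae()]
#' @export
vmat_ae <- function(x, kind = "multitask", ..., config = NULL) {
  if (inherits(x, "feature_tensor")) x <- list(x)
  if (!length(x) || !all(vapply(x, inherits, TRUE, "feature_tensor")))
    stop("x must be a feature_tensor or a non-empty list of them")
  labs <- vapply(x, function(t) t$label, character(1))
  if (any(labs == "anomalous"))
    stop("training set must contain regular plans only")
  cfg <- config %||% ae_config(kind = kind, ...)
  sh <- dim(x[[1]]$apertures)[1:2]
  if (!identical(as.integer(sh), cfg$input_shape))
    stop("feature-map shape ", paste(sh, collapse = "x"),
         " does not match config input_shape")
  npix <- prod(cfg$input_shape)
  dose_norm <- max(unlist(lapply(x, `[[`, "doses")), 0)
  if (dose_norm <= 0) dose_norm <- 1
  # control points are addressed lazily through a (plan, cp) index so the
  # full training matrix is never materialized
  K_i <- vapply(x, function(t) dim(t$intensities)[3], integer(1))
  plan_of <- rep(seq_along(x), K_i)
  cp_of <- sequence(K_i)
  n <- sum(K_i)
  dn <- unlist(lapply(x, `[[`, "doses")) / dose_norm
  gather <- function(idx) {
    Xb <- matrix(0, npix, length(idx))
    Ab <- if (cfg$kind == "multitask") matrix(0L, npix, length(idx))
    for (j in seq_along(idx)) {
      t <- x[[plan_of[idx[j]]]]
      k <- cp_of[idx[j]]
      Xb[, j] <- t$intensities[, , k]
      if (!is.null(Ab)) Ab[, j] <- t$apertures[, , k]
    }
    list(X = Xb / dose_norm, A = Ab, d = dn[idx])
  }

  with_seed(cfg$seed, {
    segs <- build_segments(cfg)
    state <- adam_init(segs)
    # pre-training loss on a subsample, for reference and for epochs = 0
    g0 <- gather(seq_len(min(n, 512L)))
    baseline <- eval_loss(segs, cfg, g0$X, g0$A, g0$d)
    hist <- list()
    tstep <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      acc <- c(L_A = 0, L_D = 0, L_R = 0, KL = 0, contractive = 0)
      nb <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
        B <- length(idx)
        g <- gather(idx)
        r <- train_step(segs, cfg, g$X, g$A, g$d)
        tstep <- tstep + 1L
        upd <- adam_step(r$segments, r$grads, state, cfg$learning_rate,
                         tstep)
        segs <- upd$segments; state <- upd$state
        lv <- unlist(r$losses)
        if (any(is.nan(lv) | is.infinite(lv)))
          stop("non-finite loss at epoch ", ep, "; aborting training")
        acc <- acc + unlist(r$losses)[names(acc)] * B
        nb <- nb + B
      }
      hist[[ep]] <- as.list(acc / nb)
    }
    hist <- do.call(rbind, lapply(hist, as.data.frame))
    if (is.null(hist)) hist <- data.frame(L_A = numeric(0), L_D = numeric(0),
                                          L_R = numeric(0), KL = numeric(0),
                                          contractive = numeric(0))
    hist$epoch <- seq_len(nrow(hist))
    model <- structure(list(
      kind = cfg$kind, config = cfg, segments = segs,
      dose_norm = dose_norm, history = hist, baseline_loss = baseline,
      checksum = model_checksum(segs), seed = cfg$seed,
      n_train_cps = n), class = "vmat_ae")
    model
  })
}

model_checksum <- function(segs) {
  s <- 0
  for (layers in segs) for (l in layers)
    for (p in param_names(l)) s <- s + sum(abs(l[[p]]))
  signif(s, 12)
}

# one optimization step; returns updated (BN stats) segments, grads, losses
train_step <- function(segs, cfg, Xb, Ab, db) {
  B <- ncol(Xb)
  fe <- seq_fwd(segs$enc, Xb, train = TRUE)
  losses <- list(L_A = NA_real_, L_D = NA_real_, L_R = NA_real_,
                 KL = NA_real_, contractive = NA_real_)
  grads <- list()
  if (cfg$kind == "multitask") {
    h <- fe$out
    fa <- seq_fwd(segs$dec_a, h, train = TRUE)
    fd <- seq_fwd(segs$dec_d, h, train = TRUE)
    P <- sigmoid(fa$out)
    L_A <- bce_mean(Ab, P)
    L_D <- mean((db - fd$out)^2)
    losses$L_A <- L_A; losses$L_D <- L_D
    losses$L_R <- cfg$lambda_weight * L_A + L_D
    dlogits <- cfg$lambda_weight * (P - Ab) / length(P)
    ddose <- 2 * (fd$out - matrix(db, 1)) / B
    ba <- seq_bwd(fa$layers, fa$caches, dlogits)
    bd <- seq_bwd(fd$layers, fd$caches, ddose)
    be <- seq_bwd(fe$layers, fe$caches, ba$dX + bd$dX)
    segs <- list(enc = fe$layers, dec_a = fa$layers, dec_d = fd$layers)
    grads <- list(enc = be$grads, dec_a = ba$grads, dec_d = bd$grads)
  } else if (cfg$kind == "variational") {
    L <- cfg$latent_dim
    mu <- fe$out[seq_len(L), , drop = FALSE]
    lv <- pmin(pmax(fe$out[L + seq_len(L), , drop = FALSE], -10), 10)
    epsm <- matrix(rnorm(L * B), L, B)
    z <- mu + exp(0.5 * lv) * epsm
    fi <- seq_fwd(segs$dec_i, z, train = TRUE)
    L_I <- mean((Xb - fi$out)^2)
    KL <- mean(colSums(-0.5 * (1 + lv - mu^2 - exp(lv))))
    losses$KL <- KL
    losses$L_R <- L_I + cfg$vae_beta * KL
    dout <- 2 * (fi$out - Xb) / length(Xb)
    bi <- seq_bwd(fi$layers, fi$caches, dout)
    dz <- bi$dX
    dmu <- dz + cfg$vae_beta * mu / B
    dlv <- dz * epsm * 0.5 * exp(0.5 * lv) +
      cfg$vae_beta * 0.5 * (exp(lv) - 1) / B
    be <- seq_bwd(fe$layers, fe$caches, rbind(dmu, dlv))
    segs <- list(enc = fe$layers, dec_i = fi$layers)
    grads <- list(enc = be$grads, dec_i = bi$grads)
  } else { # vanilla / contractive share the plain MSE objective
    h <- fe$out
    fi <- seq_fwd(segs$dec_i, h, train = TRUE)
    L_I <- mean((Xb - fi$out)^2)
    losses$L_R <- L_I
    dout <- 2 * (fi$out - Xb) / length(Xb)
    bi <- seq_bwd(fi$layers, fi$caches, dout)
    be <- seq_bwd(fe$layers, fe$caches, bi$dX)
    enc_grads <- be$grads
    if (cfg$kind == "contractive" && cfg$contractive_gamma > 0) {
      T_ <- matrix(sample(c(-1, 1), length(Xb), replace = TRUE), nrow(Xb))
      jv <- seq_jvp(fe$layers, fe$caches, T_)
      pen <- sum(jv$tout^2) / B
      losses$contractive <- cfg$contractive_gamma * pen
      losses$L_R <- L_I + cfg$contractive_gamma * pen
      tb <- seq_tan_bwd(fe$layers, fe$caches, jv$tcaches,
                        2 * cfg$contractive_gamma * jv$tout / B)
      enc_grads <- grads_add(enc_grads, tb$grads)
    }
    segs <- list(enc = fe$layers, dec_i = fi$layers)
    grads <- list(enc = enc_grads, dec_i = bi$grads)
  }
  list(segments = segs, grads = grads, losses = losses)
}

# loss evaluation without weight updates (inference-mode batch norm)
eval_loss <- function(segs, cfg, Xb, Ab, db) {
  fe <- seq_fwd(segs$enc, Xb, train = FALSE)
  if (cfg$kind == "multitask") {
    h <- fe$out
    P <- sigmoid(seq_fwd(segs$dec_a, h, train = FALSE)$out)
    dhat <- seq_fwd(segs$dec_d, h, train = FALSE)$out
    L_A <- bce_mean(Ab, P); L_D <- mean((db - dhat)^2)
    c(L_R = cfg$lambda_weight * L_A + L_D, L_A = L_A, L_D = L_D)
  } else {
    h <- if (cfg$kind == "variational")
      fe$out[seq_len(cfg$latent_dim), , drop = FALSE] else fe$out
    out <- seq_fwd(segs$dec_i, h, train = FALSE)$out
    c(L_R = mean((Xb - out)^2))
  }
}

# ---- prediction and methods ---------------------------------------------

#' Reconstruct feature maps with a fitted autoencoder
#'
#' For the multi-task model the reconstruction holds the aperture
#' probabilities `A'` (sigmoid outputs, strictly inside (0, 1)), the
#' denormalized dose `D'`, and the intensity `I' = D' * A'` assembled from
#' the two heads on the MU scale of the input. Baseline models return the
#' reconstructed intensity only. `type = "scores"` returns the plan-level
#' reconstruction distances instead (see [plan_distances()]).
#'
#' @param object a fitted [vmat_ae()].
#' @param newdata a `feature_tensor` (or list of them).
#' @param type `"reconstruction"` or `"scores"`.
#' @param ... unused.
#' @return a `vmat_reconstruction` (list with `aperture_prob`, `dose_hat`,
#'   `intensity_hat`), a list of them, or a score data.frame.
#' @export
predict.vmat_ae <- function(object, newdata,
                            type = c("reconstruction", "scores"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_tensor")) {
    if (type == "scores") return(score_plan(object, newdata))
    return(reconstruct_tensor(object, newdata))
  }
  if (type == "scores")
    return(do.call(rbind, lapply(newdata, function(t)
      score_plan(object, t))))
  lapply(newdata, function(t) reconstruct_tensor(object, t))
}

reconstruct_tensor <- function(model, tensor, chunk = 256L) {
  cfg <- model$config
  if (!identical(as.integer(tensor$target_shape), cfg$input_shape))
    stop("tensor shape metadata (", paste(tensor$target_shape,
         collapse = "x"), ") does not match the model input shape")
  npix <- prod(cfg$input_shape)
  K <- dim(tensor$intensities)[3]
  X <- matrix(tensor$intensities, npix, K) / model$dose_norm
  segs <- model$segments
  aprob <- dhat <- ihat <- NULL
  if (model$kind == "multitask") {
    aprob <- matrix(NA_real_, npix, K); dhat <- numeric(K)
  }
  ihat <- matrix(NA_real_, npix, K)
  for (start in seq(1L, K, by = chunk)) {
    ii <- start:min(K, start + chunk - 1L)
    fe <- seq_fwd(segs$enc, X[, ii, drop = FALSE], train = FALSE)
    if (model$kind == "multitask") {
      P <- sigmoid(seq_fwd(segs$dec_a, fe$out, train = FALSE)$out)
      dn <- as.numeric(seq_fwd(segs$dec_d, fe$out, train = FALSE)$out)
      aprob[, ii] <- P
      dhat[ii] <- dn * model$dose_norm
      ihat[, ii] <- sweep(P, 2, dhat[ii], `*`)
    } else {
      h <- if (model$kind == "variational")
        fe$out[seq_len(cfg$latent_dim), , drop = FALSE] else fe$out
      out <- seq_fwd(segs$dec_i, h, train = FALSE)$out
      ihat[, ii] <- out * model$dose_norm
    }
  }
  M <- cfg$input_shape[1]; N <- cfg$input_shape[2]
  structure(list(
    aperture_prob = if (!is.null(aprob)) array(aprob, c(M, N, K)),
    dose_hat = dhat,
    intensity_hat = array(ihat, c(M, N, K)),
    plan_id = tensor$plan_id), class = "vmat_reconstruction")
}

#' @export
print.vmat_ae <- function(x, ...) {
  cat(sprintf("%s autoencoder: input %dx%d, latent %d, %d training CPs\n",
              x$kind, x$config$input_shape[1], x$config$input_shape[2],
              x$config$latent_dim, x$n_train_cps))
  if (nrow(x$history))
    cat(sprintf("  trained %d epoch(s); final L_R = %.5g\n",
                nrow(x$history), tail(x$history$L_R, 1)))
  else
    cat(sprintf("  untrained (epochs = 0); baseline L_R = %.5g\n",
                x$baseline_loss[["L_R"]]))
  invisible(x)
}

#' @export
summary.vmat_ae <- function(object, ...) {
  print(object)
  npar <- 0L
  for (layers in object$segments) for (l in layers)
    for (p in param_names(l)) npar <- npar + length(l[[p]])
  cat(sprintf("  parameters: %d; dose normalization: %.4g MU; seed %d\n",
              npar, object$dose_norm, object$seed))
  if (nrow(object$history)) {
    cat("  loss history (per-epoch means):\n")
    print(object$history[, colSums(!is.na(object$history)) > 0])
  }
  invisible(object)
}

#' @export
plot.vmat_ae <- function(x, ...) {
  if (!nrow(x$history)) stop("no training history to plot")
  h <- x$history
  cols <- intersect(c("L_R", "L_A", "L_D"), names(h)[colSums(!is.na(h)) > 0])
  graphics::matplot(h$epoch, h[, cols, drop = FALSE], type = "b", pch = 1,
                    xlab = "epoch", ylab = "loss", lty = 1, ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols), lty = 1)
  invisible(x)
}

#' Per-control-point reconstruction residuals
#'
#' Mean squared intensity residual of each control point, on the MU scale —
#' the per-CP contributions to the plan-level distance `d_I`.
#'
#' @param object a fitted [vmat_ae()].
#' @param newdata a `feature_tensor`.
#' @param ... unused.
#' @return numeric vector of length K.
#' @export
residuals.vmat_ae <- function(object, newdata, ...) {
  rec <- reconstruct_tensor(object, newdata)
  d <- (newdata$intensities - rec$intensity_hat)^2
  apply(d, 3, mean)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the weights, configuration,
#' dose-normalization factor and input-shape metadata. Loading restores a
#' model that refuses to score tensors whose shape metadata differs.
#'
#' @param object a fitted [vmat_ae()].
#' @param path file path.
#' @return `load_vmat_ae` returns the restored model.
#' @export
save_vmat_ae <- function(object, path) {
  stopifnot(inherits(object, "vmat_ae"))
  saveRDS(list(format = "vmatqa-checkpoint-1", model = object,
               package_version = as.character(packageVersion("vmatqa"))),
          path)
  invisible(path)
}

#' @rdname save_vmat_ae
#' @export
load_vmat_ae <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "vmatqa-checkpoint-1"))
    stop("not a vmatqa model checkpoint: ", path)
  x$model
}
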