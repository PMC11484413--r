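# Minimal feed-forward neural-network engine.
#
# Activations are stored one sample per column; conv feature maps are
# flattened with the row index fastest and the channel slowest (an R array
# of dim c(H, W, C) flattened by as.vector()), matching the layout of the
# compiled conv primitives. Layers are plain lists; the forward pass returns
# updated layers (batch-norm running statistics) plus per-layer caches for
# the backward pass. A JVP (tangent) pass supports the contractive penalty.

nn_linear <- function(nin, nout) list(type = "linear", nin = nin, nout = nout)
nn_conv <- function(cin, cout, h, w, stride)
  list(type = "conv", cin = cin, cout = cout, h = h, w = w, stride = stride)
nn_conv1 <- function(cin, cout, p)      # pointwise 1x1 conv
  list(type = "conv1", cin = cin, cout = cout, p = p)
nn_convt <- function(cin, cout, h, w)   # input h x w, output 2h x 2w
  list(type = "convt", cin = cin, cout = cout, h = h, w = w)
nn_bn <- function(c, p) list(type = "bn", c = c, p = p, momentum = 0.9,
                             eps = 1e-5)
nn_relu <- function() list(type = "relu")

nn_init <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      linear = {
        l$W <- matrix(rnorm(l$nout * l$nin, 0, sqrt(2 / l$nin)),
                      l$nout, l$nin)
        # small positive bias keeps narrow ReLU bottlenecks alive at init
        l$b <- rep(0.1, l$nout)
      },
      conv = {
        l$W <- matrix(rnorm(l$cout * l$cin * 9, 0, sqrt(2 / (l$cin * 9))),
                      l$cout, l$cin * 9)
        l$b <- numeric(l$cout)
      },
      conv1 = {
        l$W <- matrix(rnorm(l$cout * l$cin, 0, sqrt(2 / l$cin)),
                      l$cout, l$cin)
        l$b <- numeric(l$cout)
      },
      convt = {
        l$W <- matrix(rnorm(l$cin * l$cout * 9, 0, sqrt(2 / (l$cin * 9))),
                      l$cin, l$cout * 9)
        l$b <- numeric(l$cout)
      },
      bn = {
        l$gamma <- rep(1, l$c); l$beta <- numeric(l$c)
        l$running_mean <- numeric(l$c); l$running_var <- rep(1, l$c)
      })
    l
  })
}

# per-channel mean over batch and space; x is (P*C) x B
bn_channel_mean <- function(x, P, C) {
  rowMeans(matrix(.colMeans(x, P, C * ncol(x)), C))
}

nn_fwd_layer <- function(l, X, train) {
  switch(l$type,
    linear = list(out = l$W %*% X + l$b, cache = list(X = X), layer = l),
    conv = list(out = cpp_conv_fwd(X, l$W, l$b, l$cin, l$h, l$w, l$stride),
                cache = list(X = X), layer = l),
    conv1 = list(out = cpp_conv1_fwd(X, l$W, l$b, l$cin, l$p),
                 cache = list(X = X), layer = l),
    convt = list(out = cpp_convt_fwd(X, l$W, l$b, l$cin, l$cout, l$h, l$w),
                 cache = list(X = X), layer = l),
    relu = {
      out <- cpp_relu_fwd(X)
      list(out = out, cache = list(out = out), layer = l)
    },
    bn = {
      P <- l$p
      if (train) {
        st <- cpp_channel_stats(X, P)
        mu <- as.numeric(st$mean); v <- as.numeric(st$var)
        l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * mu
        l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * v
      } else {
        mu <- l$running_mean; v <- l$running_var
      }
      inv_std <- 1 / sqrt(v + l$eps)
      r <- cpp_bn_apply(X, mu, inv_std, l$gamma, l$beta, P)
      list(out = r$out,
           cache = list(xhat = r$xhat, inv_std = inv_std, train = train),
           layer = l)
    })
}

nn_bwd_layer <- function(l, cache, dY) {
  switch(l$type,
    linear = list(dX = crossprod(l$W, dY),
                  grads = list(W = tcrossprod(dY, cache$X),
                               b = rowSums(dY))),
    conv = {
      r <- cpp_conv_bwd(cache$X, l$W, dY, l$cin, l$h, l$w, l$stride)
      list(dX = r$dX, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    conv1 = {
      r <- cpp_conv1_bwd(cache$X, l$W, dY, l$cin, l$p)
      list(dX = r$dX, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    convt = {
      r <- cpp_convt_bwd(cache$X, l$W, dY, l$cin, l$cout, l$h, l$w)
      list(dX = r$dX, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    relu = list(dX = cpp_relu_bwd(dY, cache$out), grads = NULL),
    bn = {
      r <- cpp_bn_bwd(dY, cache$xhat, cache$inv_std, l$gamma, l$p,
                      cache$train)
      list(dX = r$dX, grads = list(gamma = as.numeric(r$dgamma),
                                   beta = as.numeric(r$dbeta)))
    })
}

# tangent (JVP) pass: propagate a direction T through the linearization of
# the layer at the cached primal point; ReLU masks and batch-norm statistics
# are treated as locally constant.
nn_jvp_layer <- function(l, cache, T_) {
  switch(l$type,
    linear = list(tout = l$W %*% T_, tcache = list(Tin = T_)),
    conv = list(tout = cpp_conv_fwd(T_, l$W, numeric(l$cout), l$cin, l$h,
                                    l$w, l$stride),
                tcache = list(Tin = T_)),
    conv1 = list(tout = cpp_conv1_fwd(T_, l$W, numeric(l$cout), l$cin, l$p),
                 tcache = list(Tin = T_)),
    convt = list(tout = cpp_convt_fwd(T_, l$W, numeric(l$cout), l$cin,
                                      l$cout, l$h, l$w),
                 tcache = list(Tin = T_)),
    relu = list(tout = cpp_relu_bwd(T_, cache$out), tcache = NULL),
    bn = {
      scale <- rep(l$gamma * cache$inv_std, each = l$p)
      list(tout = T_ * scale, tcache = list(Tin = T_))
    })
}

# backward through the tangent pass (for gradients of a function of the JVP
# output w.r.t. the weights); bias gradients do not arise here.
nn_tan_bwd_layer <- function(l, cache, tcache, dT) {
  switch(l$type,
    linear = list(dX = crossprod(l$W, dT),
                  grads = list(W = tcrossprod(dT, tcache$Tin), b = 0)),
    conv = {
      r <- cpp_conv_bwd(tcache$Tin, l$W, dT, l$cin, l$h, l$w, l$stride)
      list(dX = r$dX, grads = list(W = r$dW, b = 0))
    },
    conv1 = {
      r <- cpp_conv1_bwd(tcache$Tin, l$W, dT, l$cin, l$p)
      list(dX = r$dX, grads = list(W = r$dW, b = 0))
    },
    convt = {
      r <- cpp_convt_bwd(tcache$Tin, l$W, dT, l$cin, l$cout, l$h, l$w)
      list(dX = r$dX, grads = list(W = r$dW, b = 0))
    },
    relu = list(dX = cpp_relu_bwd(dT, cache$out), grads = NULL),
    bn = {
      P <- l$p
      isrow <- rep(cache$inv_std, each = P)
      dgamma <- bn_channel_mean(dT * tcache$Tin * isrow, P, l$c) *
        (P * ncol(dT))
      list(dX = dT * rep(l$gamma, each = P) * isrow,
           grads = list(gamma = dgamma, beta = 0))
    })
}

seq_fwd <- function(layers, X, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_fwd_layer(layers[[i]], X, train)
    X <- r$out; caches[[i]] <- r$cache; layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, layers = layers)
}

seq_bwd <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_bwd_layer(layers[[i]], caches[[i]], dY)
    dY <- r$dX; grads[i] <- list(r$grads)
  }
  list(dX = dY, grads = grads)
}

seq_jvp <- function(layers, caches, T_) {
  tcaches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_jvp_layer(layers[[i]], caches[[i]], T_)
    T_ <- r$tout; tcaches[i] <- list(r$tcache)
  }
  list(tout = T_, tcaches = tcaches)
}

seq_tan_bwd <- function(layers, caches, tcaches, dT) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_tan_bwd_layer(layers[[i]], caches[[i]], tcaches[[i]], dT)
    dT <- r$dX; grads[i] <- list(r$grads)
  }
  list(dX = dT, grads = grads)
}

# ---- Adam ----------------------------------------------------------------

param_names <- function(l) switch(l$type,
  linear = , conv = , conv1 = , convt = c("W", "b"),
  bn = c("gamma", "beta"), character(0))

adam_init <- function(segments) {
  lapply(segments, function(layers) lapply(layers, function(l) {
    ps <- param_names(l)
    st <- lapply(ps, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- ps
    st
  }))
}

# grads_by_seg mirrors the segment/layer structure; entries may be NULL
adam_step <- function(segments, grads_by_seg, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (s in names(segments)) {
    layers <- segments[[s]]
    for (i in seq_along(layers)) {
      g <- grads_by_seg[[s]][[i]]
      if (is.null(g)) next
      for (p in names(g)) {
        if (is.null(g[[p]]) || (length(g[[p]]) == 1 && identical(g[[p]], 0)))
          next
        st <- state[[s]][[i]][[p]]
        st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
        st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
        layers[[i]][[p]] <- layers[[i]][[p]] -
          lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
        state[[s]][[i]][[p]] <- st
      }
    }
    segments[[s]] <- layers
  }
  list(segments = segments, state = state)
}

# sum two grad lists with identical structure (NULLs allowed)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) { a[[i]] <- b[[i]]; next }
    for (p in names(b[[i]]))
      a[[i]][[p]] <- (a[[i]][[p]] %||% 0) + b[[i]][[p]]
  }
  a
}

sigmoid <- function(x) 1 / (1 + exp(-x))
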