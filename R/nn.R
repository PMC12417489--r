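# Minimal neural-network primitives with hand-derived gradients.
#
# No deep-learning runtime is assumed: every layer is an environment holding
# its parameters and a cache from the last forward pass, with `forward(x,
# training)` and `backward(dy)` closures. Convolutions are im2col + BLAS
# matrix products. Activations for the convolutional stack use the layout
# (channels C, time T, batch N); dense layers use (N x features) matrices.
# Layers are stateful across one forward/backward cycle and not re-entrant.

new_param <- function(val, decay = TRUE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- array(0, dim = if (is.null(dim(val))) length(val) else dim(val))
  if (is.null(dim(val))) e$grad <- as.numeric(e$grad)
  e$decay <- decay
  e$name <- name
  class(e) <- "nn_param"
  e
}

zero_grads <- function(params) {
  for (p in params) p$grad <- p$grad * 0
  invisible(NULL)
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- dense layer: x is (N x d_in) ------------------------------------------

nn_linear <- function(d_in, d_out, name = "linear") {
  self <- new.env()
  self$kind <- "linear"
  self$W <- new_param(glorot(d_in, d_out, c(d_in, d_out)),
                      name = paste0(name, ".W"))
  self$b <- new_param(numeric(d_out), decay = FALSE,
                      name = paste0(name, ".b"))
  self$params <- list(self$W, self$b)
  self$forward <- function(x, training = TRUE) {
    self$x <- x
    sweep(x %*% self$W$val, 2, self$b$val, "+")
  }
  self$backward <- function(dy) {
    self$W$grad <- self$W$grad + crossprod(self$x, dy)
    self$b$grad <- self$b$grad + colSums(dy)
    dy %*% t(self$W$val)
  }
  class(self) <- "nn_layer"
  self
}

nn_relu_mat <- function() {
  self <- new.env()
  self$params <- list()
  self$forward <- function(x, training = TRUE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$backward <- function(dy) dy * self$mask
  class(self) <- "nn_layer"
  self
}

# ---- conv-stack layers: x is (C, T, N) -------------------------------------

nn_conv1d <- function(c_in, c_out, kernel, name = "conv") {
  self <- new.env()
  self$k <- kernel
  self$c_in <- c_in
  self$c_out <- c_out
  self$W <- new_param(glorot(c_in * kernel, c_out, c(c_out, c_in * kernel)),
                      name = paste0(name, ".W"))
  self$b <- new_param(numeric(c_out), decay = FALSE,
                      name = paste0(name, ".b"))
  self$params <- list(self$W, self$b)
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    k <- self$k
    Tout <- d[2] - k + 1L
    if (Tout < 1L) stop("conv input too short: T=", d[2], " kernel=", k)
    if (d[1] != self$c_in) stop("conv expected ", self$c_in,
                                " input channels, got ", d[1])
    if (k == 1L) {
      M <- x
      dim(M) <- c(d[1], d[2] * d[3])
    } else {
      M <- cpp_im2col(x, d[1], d[2], d[3], k)
    }
    self$M <- M
    self$dims_in <- d
    y <- self$W$val %*% M + self$b$val
    dim(y) <- c(self$c_out, Tout, d[3])
    y
  }
  self$backward <- function(dy, need_dx = TRUE) {
    d <- dim(dy)                       # (c_out, Tout, N)
    k <- self$k
    din <- self$dims_in
    dim(dy) <- c(d[1], d[2] * d[3])
    self$W$grad <- self$W$grad + tcrossprod(dy, self$M)
    self$b$grad <- self$b$grad + rowSums(dy)
    if (!need_dx) return(NULL)
    dM <- crossprod(self$W$val, dy)    # (c_in*k, Tout*N)
    if (k == 1L) {
      dim(dM) <- din
      return(dM)
    }
    dx <- cpp_col2im(dM, din[1], din[2], din[3], k)
    dim(dx) <- din
    dx
  }
  class(self) <- "nn_layer"
  self
}

nn_batchnorm <- function(C, momentum = 0.1, eps = 1e-5, name = "bn") {
  self <- new.env()
  self$kind <- "batchnorm"
  self$gamma <- new_param(rep(1, C), decay = FALSE, name = paste0(name, ".gamma"))
  self$beta <- new_param(numeric(C), decay = FALSE, name = paste0(name, ".beta"))
  self$params <- list(self$gamma, self$beta)
  self$running_mean <- numeric(C)
  self$running_var <- rep(1, C)
  self$eps <- eps
  self$momentum <- momentum
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    self$dims <- d
    dim(x) <- c(d[1], prod(d[-1]))
    self$training_mode <- training
    if (training) {
      mu <- rowMeans(x)
      v <- rowMeans(x * x) - mu * mu
      v[v < 0] <- 0
      istd <- 1 / sqrt(v + self$eps)
      xhat <- (x - mu) * istd
      self$running_mean <- (1 - self$momentum) * self$running_mean + self$momentum * mu
      self$running_var <- (1 - self$momentum) * self$running_var + self$momentum * v
      self$xhat <- xhat
      self$istd <- istd
    } else {
      istd <- 1 / sqrt(self$running_var + self$eps)
      xhat <- (x - self$running_mean) * istd
      self$xhat <- xhat
      self$istd <- istd
    }
    y <- xhat * self$gamma$val + self$beta$val
    dim(y) <- d
    y
  }
  self$backward <- function(dy) {
    d <- self$dims
    dim(dy) <- c(d[1], prod(d[-1]))
    if (!self$training_mode) {
      self$gamma$grad <- self$gamma$grad + rowSums(dy * self$xhat)
      self$beta$grad <- self$beta$grad + rowSums(dy)
      dx <- dy * (self$gamma$val * self$istd)
      dim(dx) <- d
      return(dx)
    }
    m <- ncol(dy)
    xhat <- self$xhat
    self$gamma$grad <- self$gamma$grad + rowSums(dy * xhat)
    self$beta$grad <- self$beta$grad + rowSums(dy)
    dxhat <- dy * self$gamma$val
    dx <- (self$istd / m) *
      (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
    dim(dx) <- d
    dx
  }
  class(self) <- "nn_layer"
  self
}

nn_elu <- function(alpha = 1) {
  self <- new.env()
  self$params <- list()
  self$forward <- function(x, training = TRUE) {
    pos <- x > 0
    y <- x
    y[!pos] <- alpha * expm1(x[!pos])
    self$pos <- pos
    self$y <- y
    y
  }
  self$backward <- function(dy) {
    g <- self$y + alpha
    g[self$pos] <- 1
    dy * g
  }
  class(self) <- "nn_layer"
  self
}

nn_maxpool <- function(width = 3) {
  self <- new.env()
  self$params <- list()
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    Tout <- d[2] %/% width
    xt <- x[, seq_len(width * Tout), , drop = FALSE]
    dim(xt) <- c(d[1], width, Tout, d[3])
    slices <- vector("list", width)
    for (v in seq_len(width)) {
      sl <- xt[, v, , , drop = FALSE]
      dim(sl) <- c(d[1], Tout, d[3])
      slices[[v]] <- sl
    }
    y <- slices[[1]]
    for (v in 2:width) y <- pmax(y, slices[[v]])
    taken <- array(FALSE, dim(y))
    masks <- vector("list", width)
    for (v in seq_len(width)) {
      mv <- !taken & (slices[[v]] == y)
      taken <- taken | mv
      masks[[v]] <- mv
    }
    self$masks <- masks
    self$dims_in <- d
    self$Tout <- Tout
    y
  }
  self$backward <- function(dy) {
    d <- self$dims_in
    Tout <- self$Tout
    dxt <- array(0, dim = c(d[1], width, Tout, d[3]))
    for (v in seq_len(width)) dxt[, v, , ] <- dy * self$masks[[v]]
    dim(dxt) <- c(d[1], width * Tout, d[3])
    if (width * Tout < d[2]) {
      dx <- array(0, dim = d)
      dx[, seq_len(width * Tout), ] <- dxt
      dx
    } else dxt
  }
  class(self) <- "nn_layer"
  self
}

nn_dropout <- function(p = 0.5) {
  self <- new.env()
  self$kind <- "dropout"
  self$params <- list()
  self$p <- p
  self$forward <- function(x, training = TRUE) {
    if (!training || self$p <= 0) {
      self$mask <- NULL
      return(x)
    }
    m <- (stats::runif(length(x)) >= self$p) / (1 - self$p)
    dim(m) <- dim(x)
    self$mask <- m
    x * m
  }
  self$backward <- function(dy) {
    if (is.null(self$mask)) dy else dy * self$mask
  }
  class(self) <- "nn_layer"
  self
}

# batch normalization over the rows of an (n x d) matrix (per-feature
# statistics across the batch); the dense-layer counterpart of nn_batchnorm.
nn_batchnorm_mat <- function(d, momentum = 0.1, eps = 1e-5, name = "bnm") {
  inner <- nn_batchnorm(d, momentum = momentum, eps = eps, name = name)
  self <- new.env()
  self$kind <- "batchnorm_mat"
  self$params <- inner$params
  self$inner <- inner
  self$forward <- function(x, training = TRUE) {
    t(inner$forward(t(x), training))
  }
  self$backward <- function(dy) t(inner$backward(t(dy)))
  class(self) <- "nn_layer"
  self
}

nn_sequential <- function(layers) {
  self <- new.env()
  self$layers <- layers
  self$params <- do.call(c, c(lapply(layers, function(l) l$params), list(list())))
  self$forward <- function(x, training = TRUE) {
    for (l in self$layers) x <- l$forward(x, training)
    x
  }
  self$backward <- function(dy) {
    for (l in rev(self$layers)) dy <- l$backward(dy)
    dy
  }
  class(self) <- "nn_layer"
  self
}

# ---- row-wise L2 normalization ---------------------------------------------

# Projections live on the unit sphere (cosine similarity space). All-zero
# rows cannot be normalized; they map to the zero vector with a warning
# (degenerate but defined), and receive zero gradient.
l2_normalize_rows <- function(x, warn = TRUE) {
  nrm <- sqrt(rowSums(x * x))
  zero <- nrm < 1e-12
  if (any(zero) && warn) {
    warning(sum(zero), " zero-norm row(s) mapped to the zero vector")
  }
  nrm_safe <- ifelse(zero, 1, nrm)
  y <- x / nrm_safe
  list(y = y, norm = nrm_safe, zero = zero)
}

l2_normalize_backward <- function(dy, cache) {
  y <- cache$y
  dx <- (dy - y * rowSums(dy * y)) / cache$norm
  dx[cache$zero, ] <- 0
  dx
}

# ---- Adam ------------------------------------------------------------------

# Parameter-group Adam with decoupled-from-groups L2 weight decay added to
# the gradient (classic Adam + weight_decay). Bias parameters and
# normalization scales are created with decay = FALSE and are skipped.
nn_adam <- function(groups, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  self <- new.env()
  self$groups <- groups   # list of list(params=, lr=, weight_decay=)
  self$t <- 0L
  for (g in groups) {
    for (p in g$params) {
      if (is.null(p$m)) {
        p$m <- p$grad * 0
        p$v <- p$grad * 0
      }
    }
  }
  self$step <- function() {
    self$t <- self$t + 1L
    bc1 <- 1 - beta1^self$t
    bc2 <- 1 - beta2^self$t
    for (g in self$groups) {
      if (g$lr == 0) next
      for (p in g$params) {
        grad <- p$grad
        if (isTRUE(p$decay) && g$weight_decay > 0) {
          grad <- grad + g$weight_decay * p$val
        }
        p$m <- beta1 * p$m + (1 - beta1) * grad
        p$v <- beta2 * p$v + (1 - beta2) * grad * grad
        p$val <- p$val - g$lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
      }
    }
    invisible(NULL)
  }
  self$zero <- function() {
    for (g in self$groups) zero_grads(g$params)
  }
  self
}

# Flatten parameter values to a single numeric vector (and back): used for
# checkpoints and finite-difference tests.
params_to_vector <- function(params) {
  unlist(lapply(params, function(p) as.numeric(p$val)), use.names = FALSE)
}

vector_to_params <- function(vec, params) {
  off <- 0L
  for (p in params) {
    n <- length(p$val)
    v <- vec[(off + 1L):(off + n)]
    dim(v) <- dim(p$val)
    p$val <- if (is.null(dim(p$val))) as.numeric(v) else v
    off <- off + n
  }
  invisible(NULL)
}


# all batch-norm layer environments reachable from a model (trunk + heads)
collect_bn_layers <- function(model) {
  out <- list()
  grab <- function(l) {
    if (identical(l$kind, "batchnorm")) out[[length(out) + 1L]] <<- l
    if (identical(l$kind, "batchnorm_mat")) out[[length(out) + 1L]] <<- l$inner
    if (!is.null(l$layers)) for (s in l$layers) grab(s)
  }
  grab(model$eeg_encoder$trunk)
  grab(model$head_x)
  grab(model$head_y)
  out
}

collect_dropout_layers <- function(model) {
  Filter(function(l) identical(l$kind, "dropout"),
         model$eeg_encoder$trunk$layers)
}
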