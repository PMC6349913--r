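# Internal minimal neural-net layer toolkit.
#
# Activations are numeric arrays dim c(N, W, C) (batch, width, channel) or
# N x D matrices after flattening. R's column-major order makes the
# (N, W, C) -> (N*W) x C reshape free, so 1-D convolutions are im2col
# matrix products on BLAS. Each layer is a list: type, hyp (hyperparameters),
# par (trainable arrays), buf (non-trainable state, e.g. batch-norm running
# moments). Forward returns list(out, cache, layer); backward returns
# list(dx, grads) with grads shaped like par.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

he_init <- function(fan_in, n) {
  rnorm(n, sd = sqrt(2 / fan_in))
}

add_bias <- function(m, b) {
  m + rep(b, each = nrow(m))
}

pad_width <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * p, d[3]))
  xp[, (p + 1L):(p + d[2]), ] <- x
  xp
}

# (N, W, C) -> (N*W') x (k*C) patch matrix, W' = W - k + 1; rows ordered
# batch-fastest then position, column blocks ordered by tap offset.
im2col <- function(x, k) {
  d <- dim(x)
  n <- d[1]; w <- d[2]; c <- d[3]
  wp <- w - k + 1L
  cols <- vector("list", k)
  for (t in seq_len(k) - 1L) {
    xi <- x[, (1L + t):(wp + t), , drop = FALSE]
    dim(xi) <- c(n * wp, c)
    cols[[t + 1L]] <- xi
  }
  do.call(cbind, cols)
}

# adjoint of im2col: scatter-add patch gradients back to input positions
col2im <- function(dp, dim_x, k) {
  n <- dim_x[1]; w <- dim_x[2]; c <- dim_x[3]
  wp <- w - k + 1L
  dx <- array(0, dim_x)
  for (t in seq_len(k) - 1L) {
    block <- dp[, (t * c + 1L):((t + 1L) * c), drop = FALSE]
    dim(block) <- c(n, wp, c)
    dx[, (1L + t):(wp + t), ] <- dx[, (1L + t):(wp + t), , drop = FALSE] + block
  }
  dx
}

## ---- layer constructors (call inside withr::with_seed) ----

# bias = FALSE is the standard choice when the conv feeds a batch-norm layer
# (the norm's shift makes a conv bias redundant)
layer_conv <- function(k, c_in, c_out, pad = c("same", "valid"), bias = TRUE) {
  pad <- match.arg(pad)
  p <- if (pad == "same") (k - 1L) %/% 2L else 0L
  par <- list(W = matrix(he_init(k * c_in, k * c_in * c_out), k * c_in, c_out))
  if (bias) par$b <- numeric(c_out)
  list(type = "conv", hyp = list(k = k, p = p), par = par)
}

layer_bn <- function(c) {
  list(type = "bn",
       hyp = list(),
       par = list(gamma = rep(1, c), beta = numeric(c)),
       buf = list(mean = numeric(c), var = rep(1, c)))
}

layer_lrelu <- function(slope = 0.3) {
  list(type = "lrelu", hyp = list(slope = slope), par = NULL)
}

layer_maxpool <- function() {
  list(type = "maxpool", hyp = list(), par = NULL)
}

layer_adapool <- function(out_w) {
  list(type = "adapool", hyp = list(out_w = out_w), par = NULL)
}

# locally connected, valid padding: one (k*C_in) x C_out kernel per output
# position, no weight sharing across width
layer_local <- function(k, w_in, c_in, c_out) {
  wp <- w_in - k + 1L
  if (wp < 1L) abort("locally connected kernel wider than input", class = "panbinder_shape_error")
  list(type = "local",
       hyp = list(k = k, w_in = w_in),
       par = list(W = array(he_init(k * c_in, k * c_in * c_out * wp),
                            c(k * c_in, c_out, wp)),
                  b = matrix(0, wp, c_out)))
}

layer_dense <- function(d_in, d_out) {
  list(type = "dense",
       hyp = list(),
       par = list(W = matrix(he_init(d_in, d_in * d_out), d_in, d_out),
                  b = numeric(d_out)))
}

layer_flatten <- function() {
  list(type = "flatten", hyp = list(), par = NULL)
}

## ---- forward ----

lay_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      k <- layer$hyp$k
      xp <- pad_width(x, layer$hyp$p)
      p_mat <- im2col(xp, k)
      y <- p_mat %*% layer$par$W
      if (!is.null(layer$par$b)) y <- add_bias(y, layer$par$b)
      wp <- dim(xp)[2] - k + 1L
      dim(y) <- c(dim(x)[1], wp, ncol(layer$par$W))
      list(out = y, cache = list(p_mat = p_mat, dim_xp = dim(xp), dim_x = dim(x)),
           layer = layer)
    },
    bn = {
      d <- dim(x)
      m <- prod(d[-length(d)])
      xm <- x
      dim(xm) <- c(m, d[length(d)])
      if (training) {
        mu <- colMeans(xm)
        xc <- xm - rep(mu, each = m)
        v <- colSums(xc * xc) / m
        inv <- 1 / sqrt(v + BN_EPS)
        xhat <- xc * rep(inv, each = m)
        layer$buf$mean <- BN_MOMENTUM * layer$buf$mean + (1 - BN_MOMENTUM) * mu
        layer$buf$var <- BN_MOMENTUM * layer$buf$var + (1 - BN_MOMENTUM) * v
      } else {
        inv <- 1 / sqrt(layer$buf$var + BN_EPS)
        xhat <- (xm - rep(layer$buf$mean, each = m)) * rep(inv, each = m)
      }
      y <- xhat * rep(layer$par$gamma, each = m) + rep(layer$par$beta, each = m)
      dim(y) <- d
      list(out = y, cache = list(xhat = xhat, inv = inv, m = m, d = d), layer = layer)
    },
    lrelu = {
      # per-element slope mask: 1 where x > 0, `slope` elsewhere; reused in
      # the backward pass (dy * w)
      w <- layer$hyp$slope + (1 - layer$hyp$slope) * (x > 0)
      list(out = x * w, cache = list(w = w), layer = layer)
    },
    maxpool = {
      d <- dim(x)
      i1 <- seq.int(1L, d[2], by = 2L)
      i2 <- pmin(i1 + 1L, d[2])
      x1 <- x[, i1, , drop = FALSE]
      x2 <- x[, i2, , drop = FALSE]
      m1 <- x1 >= x2
      y <- x2
      y[m1] <- x1[m1]
      list(out = y, cache = list(m1 = m1, i1 = i1, i2 = i2, dim_x = d), layer = layer)
    },
    adapool = {
      d <- dim(x)
      ow <- layer$hyp$out_w
      if (d[2] < ow) abort("adaptive pool input narrower than output", class = "panbinder_shape_error")
      y <- array(0, c(d[1], ow, d[3]))
      bins <- vector("list", ow)
      for (b in seq_len(ow)) {
        s <- floor((b - 1L) * d[2] / ow) + 1L
        e <- floor(b * d[2] / ow)
        bins[[b]] <- s:e
        acc <- matrix(0, d[1], d[3])
        for (j in s:e) acc <- acc + x[, j, ]
        y[, b, ] <- acc / (e - s + 1L)
      }
      list(out = y, cache = list(bins = bins, dim_x = d), layer = layer)
    },
    local = {
      k <- layer$hyp$k
      d <- dim(x)
      if (d[2] != layer$hyp$w_in) abort("locally connected width mismatch", class = "panbinder_shape_error")
      wp <- d[2] - k + 1L
      n <- d[1]
      p_mat <- im2col(x, k)
      c_out <- dim(layer$par$W)[2]
      y <- array(0, c(n, wp, c_out))
      for (i in seq_len(wp)) {
        rows <- (n * (i - 1L) + 1L):(n * i)
        y[, i, ] <- add_bias(p_mat[rows, , drop = FALSE] %*% layer$par$W[, , i],
                             layer$par$b[i, ])
      }
      list(out = y, cache = list(p_mat = p_mat, dim_x = d), layer = layer)
    },
    dense = {
      y <- add_bias(x %*% layer$par$W, layer$par$b)
      list(out = y, cache = list(x = x), layer = layer)
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(d[1], prod(d[-1]))
      list(out = y, cache = list(dim_x = d), layer = layer)
    },
    abort(paste("unknown layer type", layer$type))
  )
}

## ---- backward ----

lay_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      k <- layer$hyp$k
      c_out <- ncol(layer$par$W)
      dym <- dy
      dim(dym) <- c(prod(dim(dy)[1:2]), c_out)
      grads <- list(W = crossprod(cache$p_mat, dym))
      if (!is.null(layer$par$b)) grads$b <- colSums(dym)
      dx <- NULL
      if (need_dx) {
        dp <- tcrossprod(dym, layer$par$W)
        dxp <- col2im(dp, cache$dim_xp, k)
        p <- layer$hyp$p
        dx <- if (p > 0L) dxp[, (p + 1L):(p + cache$dim_x[2]), , drop = FALSE] else dxp
      }
      list(dx = dx, grads = grads)
    },
    bn = {
      m <- cache$m
      dym <- dy
      dim(dym) <- c(m, length(layer$par$gamma))
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- dym * rep(layer$par$gamma, each = m)
      dx <- rep(cache$inv / m, each = m) *
        (m * dxhat - rep(colSums(dxhat), each = m) -
           cache$xhat * rep(colSums(dxhat * cache$xhat), each = m))
      dim(dx) <- cache$d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    lrelu = {
      list(dx = dy * cache$w, grads = NULL)
    },
    maxpool = {
      dx <- array(0, cache$dim_x)
      a1 <- dy
      a1[!cache$m1] <- 0
      a2 <- dy
      a2[cache$m1] <- 0
      dx[, cache$i1, ] <- dx[, cache$i1, , drop = FALSE] + a1
      dx[, cache$i2, ] <- dx[, cache$i2, , drop = FALSE] + a2
      list(dx = dx, grads = NULL)
    },
    adapool = {
      dx <- array(0, cache$dim_x)
      for (b in seq_along(cache$bins)) {
        bin <- cache$bins[[b]]
        share <- dy[, b, ] / length(bin)
        for (j in bin) dx[, j, ] <- share
      }
      list(dx = dx, grads = NULL)
    },
    local = {
      k <- layer$hyp$k
      d <- cache$dim_x
      n <- d[1]
      wp <- d[2] - k + 1L
      c_out <- dim(layer$par$W)[2]
      dW <- array(0, dim(layer$par$W))
      db <- matrix(0, wp, c_out)
      dp <- if (need_dx) matrix(0, nrow(cache$p_mat), ncol(cache$p_mat))
      for (i in seq_len(wp)) {
        rows <- (n * (i - 1L) + 1L):(n * i)
        dyi <- matrix(dy[, i, ], n, c_out)
        dW[, , i] <- crossprod(cache$p_mat[rows, , drop = FALSE], dyi)
        db[i, ] <- colSums(dyi)
        if (need_dx) dp[rows, ] <- tcrossprod(dyi, layer$par$W[, , i])
      }
      list(dx = if (need_dx) col2im(dp, d, k), grads = list(W = dW, b = db))
    },
    dense = {
      grads <- list(W = crossprod(cache$x, dy), b = colSums(dy))
      list(dx = tcrossprod(dy, layer$par$W), grads = grads)
    },
    flatten = {
      dx <- dy
      dim(dx) <- cache$dim_x
      list(dx = dx, grads = NULL)
    },
    abort(paste("unknown layer type", layer$type))
  )
}

## ---- sequential stacks ----

stack_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- lay_forward(layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
    layers[[i]] <- fw$layer
  }
  list(out = x, caches = caches, layers = layers)
}

stack_backward <- function(layers, caches, dy, need_dx = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- lay_backward(layers[[i]], caches[[i]], dy,
                       need_dx = need_dx || i > 1L)
    dy <- bw$dx
    grads[i] <- list(bw$grads)  # keep NULL slots for parameterless layers
  }
  list(dx = dy, grads = grads)
}

# SGD with momentum on one stack; returns updated layers and velocities
stack_update <- function(layers, grads, vel, lr, momentum) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      v <- momentum * vel[[i]][[nm]] - lr * g[[nm]]
      vel[[i]][[nm]] <- v
      layers[[i]]$par[[nm]] <- layers[[i]]$par[[nm]] + v
    }
  }
  list(layers = layers, vel = vel)
}

stack_zero_vel <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$par)) NULL else lapply(l$par, function(p) {
      z <- p
      z[] <- 0
      z
    })
  })
}

stack_n_params <- function(layers) {
  sum(vapply(layers, function(l) {
    if (is.null(l$par)) 0L else sum(vapply(l$par, length, integer(1)))
  }, integer(1)))
}
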