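# Minimal reverse-mode neural-network layers on BLAS-backed matrix ops.
#
# Feature maps are stored as [H, W, N, C] arrays (batch N third, channels
# last) so that `matrix(x, ncol = C)` exposes channels as columns without a
# copy of the permuted data, and flattening [H, W] to a token axis is a pure
# `dim<-` change. Every layer provides a forward returning `list(out, cache)`
# and a backward returning `list(dx, grads)` with gradients named like the
# parameters. Parameters live in one flat named list, `"<prefix>.W"` style.

nn_rnorm <- function(n, sd) rnorm(n, sd = sd)

# ---- dense ----------------------------------------------------------------

linear_init <- function(fan_in, fan_out, prefix) {
  p <- list()
  p[[paste0(prefix, ".W")]] <- matrix(nn_rnorm(fan_in * fan_out,
                                               sqrt(2 / fan_in)),
                                      fan_in, fan_out)
  p[[paste0(prefix, ".b")]] <- numeric(fan_out)
  p
}

linear_fwd <- function(params, prefix, X) {
  W <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  out <- X %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = list(X = X))
}

linear_bwd <- function(params, prefix, cache, dY) {
  W <- params[[paste0(prefix, ".W")]]
  grads <- list()
  grads[[paste0(prefix, ".W")]] <- crossprod(cache$X, dY)
  grads[[paste0(prefix, ".b")]] <- colSums(dY)
  list(dx = dY %*% t(W), grads = grads)
}

# ---- pointwise (1x1) convolution: a dense map over channels ---------------

pw_fwd <- function(params, prefix, X) {
  d <- dim(X)
  r <- linear_fwd(params, prefix, matrix(X, ncol = d[4]))
  dim(r$out) <- c(d[1:3], ncol(params[[paste0(prefix, ".W")]]))
  r
}

pw_bwd <- function(params, prefix, cache, dY) {
  d <- dim(dY)
  r <- linear_bwd(params, prefix, cache, matrix(dY, ncol = d[4]))
  dim(r$dx) <- c(d[1:3], nrow(params[[paste0(prefix, ".W")]]))
  r
}

# ---- full 3x3 convolution (stride s, pad 1) via im2col --------------------

conv3_init <- function(cin, cout, prefix) {
  p <- list()
  p[[paste0(prefix, ".W")]] <- matrix(nn_rnorm(9 * cin * cout,
                                               sqrt(2 / (9 * cin))),
                                      9 * cin, cout)
  p[[paste0(prefix, ".b")]] <- numeric(cout)
  p
}

conv3_fwd <- function(params, prefix, X, stride = 1) {
  W <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  d <- dim(X)
  cols <- im2col3(X, as.integer(d), as.integer(stride))
  out <- cols %*% W
  out <- out + rep(b, each = nrow(out))
  Ho <- (d[1] - 1) %/% stride + 1
  Wo <- (d[2] - 1) %/% stride + 1
  dim(out) <- c(Ho, Wo, d[3], ncol(W))
  list(out = out, cache = list(cols = cols, dimX = d, stride = stride))
}

conv3_bwd <- function(params, prefix, cache, dY) {
  W <- params[[paste0(prefix, ".W")]]
  dYm <- matrix(dY, ncol = ncol(W))
  grads <- list()
  grads[[paste0(prefix, ".W")]] <- crossprod(cache$cols, dYm)
  grads[[paste0(prefix, ".b")]] <- colSums(dYm)
  dcols <- dYm %*% t(W)
  list(dx = col2im3(dcols, as.integer(cache$dimX),
                    as.integer(cache$stride)),
       grads = grads)
}

# ---- depthwise 3x3 convolution (stride 1, pad 1) --------------------------

dw3_init <- function(c, prefix) {
  p <- list()
  p[[paste0(prefix, ".W")]] <- matrix(nn_rnorm(9 * c, sqrt(2 / 9)), 9, c)
  p[[paste0(prefix, ".b")]] <- numeric(c)
  p
}

dw3_fwd <- function(params, prefix, X) {
  out <- dw3_forward(X, as.integer(dim(X)), params[[paste0(prefix, ".W")]],
                     params[[paste0(prefix, ".b")]])
  list(out = out, cache = list(X = X))
}

dw3_bwd <- function(params, prefix, cache, dY) {
  r <- dw3_backward(cache$X, as.integer(dim(cache$X)),
                    params[[paste0(prefix, ".W")]], dY)
  grads <- list()
  grads[[paste0(prefix, ".W")]] <- r$dW
  grads[[paste0(prefix, ".b")]] <- r$db
  list(dx = r$dx, grads = grads)
}

# ---- batch normalization (per channel over H, W, N) -----------------------

bn_init <- function(c, prefix) {
  p <- list()
  p[[paste0(prefix, ".gamma")]] <- rep(1, c)
  p[[paste0(prefix, ".beta")]] <- numeric(c)
  p
}

# `run_stats` is an environment holding per-layer running moments so that
# evaluation-mode forward passes are batch-independent.
rs_get <- function(env, nm) {
  if (!is.null(env) && exists(nm, envir = env, inherits = FALSE)) {
    get(nm, envir = env)
  } else {
    NULL
  }
}

bn_fwd <- function(params, prefix, X, training, run_stats, eps = 1e-5,
                   momentum = 0.9) {
  g <- params[[paste0(prefix, ".gamma")]]
  be <- params[[paste0(prefix, ".beta")]]
  d <- dim(X); C <- d[4]
  M <- length(X) %/% C
  if (training) {
    mu <- .colMeans(X, M, C)
    va <- .colMeans(X * X, M, C) - mu^2
    rs <- rs_get(run_stats, prefix)
    new_rs <- if (is.null(rs)) {
      list(mu = mu, va = va)
    } else {
      list(mu = momentum * rs$mu + (1 - momentum) * mu,
           va = momentum * rs$va + (1 - momentum) * va)
    }
    if (!is.null(run_stats)) assign(prefix, new_rs, envir = run_stats)
  } else {
    rs <- rs_get(run_stats, prefix)
    if (is.null(rs)) {
      mu <- .colMeans(X, M, C)
      va <- .colMeans(X * X, M, C) - mu^2
    } else {
      mu <- rs$mu
      va <- rs$va
    }
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- channel_affine(X, C, inv, -mu * inv)
  out <- channel_affine(xhat, C, g, be)
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv = inv, dimX = d))
}

bn_bwd <- function(params, prefix, cache, dY) {
  g <- params[[paste0(prefix, ".gamma")]]
  d <- cache$dimX; C <- d[4]
  M <- length(dY) %/% C
  xhat <- cache$xhat
  gxh <- dY * xhat
  grads <- list()
  grads[[paste0(prefix, ".gamma")]] <- .colSums(gxh, M, C)
  grads[[paste0(prefix, ".beta")]] <- .colSums(dY, M, C)
  dxh <- channel_affine(dY, C, g, numeric(C))
  m1 <- .colMeans(dxh, M, C)
  m2 <- .colMeans(dxh * xhat, M, C)
  dx <- bn_backward_core(dxh, xhat, C, cache$inv, m1, m2)
  dim(dx) <- d
  list(dx = dx, grads = grads)
}

# ---- GELU (exact) ---------------------------------------------------------

gelu_fwd <- function(X) {
  list(out = gelu_forward_cpp(X), cache = list(X = X))
}

gelu_bwd <- function(cache, dY) {
  gelu_backward_cpp(cache$X, dY)
}

# ---- global average pool over (H, W) --------------------------------------

gap_fwd <- function(X) {
  d <- dim(X)
  m <- matrix(X, nrow = d[1] * d[2])          # (H*W) x (N*C)
  out <- matrix(colMeans(m), d[3], d[4])
  list(out = out, cache = list(dimX = d))
}

gap_bwd <- function(cache, dY) {
  d <- cache$dimX
  hw <- d[1] * d[2]
  dx <- array(rep(as.vector(dY / hw), each = hw), d)
  dx
}
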