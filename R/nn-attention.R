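#' Rotary positional embedding (RoPE)
#'
#' Encodes token position by rotating adjacent coordinate pairs of each
#' feature vector. Pair `i` (0-based) of a `D`-dimensional token at position
#' `m` is rotated by the angle `m * theta_i` with
#' `theta_i = base^(-2 i / D)`. Rotations are isometries, and the inner
#' product of two rotated tokens depends only on their relative position —
#' the property that makes RoPE a relative positional encoding.
#'
#' @param x Numeric matrix, one token per row, an even number of columns.
#' @param positions Integer position per token (default `0:(N-1)`).
#' @param base Wavelength base of the rotation frequencies (default 10000).
#' @return Matrix of rotated tokens, same shape as `x`.
#' @examples
#' q <- matrix(rnorm(8), 2, 4)
#' all.equal(rope_rotate(q, positions = c(0, 0)), q)  # position 0: identity
#' @export
rope_rotate <- function(x, positions = seq_len(nrow(x)) - 1, base = 10000) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  D <- ncol(x)
  if (D %% 2 != 0) {
    stop_sawoce("RoPE requires an even feature dimension", "sawoce_config")
  }
  stopifnot(length(positions) == nrow(x))
  theta <- base^(-2 * (seq_len(D / 2) - 1) / D)
  ang <- outer(positions, theta)              # N x D/2
  rope_apply(x, cos(ang), sin(ang))
}

# Apply a precomputed rotation (cos/sin of per-row, per-pair angles).
rope_apply <- function(x, co, si) {
  storage.mode(x) <- "double"
  rope_apply_cpp(x, co, si)
}

# Rotation tables for T tokens of dimension D.
rope_tables <- function(T_, D, base) {
  theta <- base^(-2 * (seq_len(D / 2) - 1) / D)
  ang <- outer(0:(T_ - 1), theta)
  list(co = cos(ang), si = sin(ang))
}

#' Efficient additive attention (EAA)
#'
#' Linear-complexity attention: token scores `alpha = softmax(Q w_a /
#' sqrt(D))` pool the queries into one global query `q = sum_i alpha_i Q_i`,
#' which is broadcast and multiplied element-wise into the keys; a linear
#' projection of that interaction plus a query residual gives the output:
#' `Linear(K * q) + Q`. Cost grows linearly in the number of tokens `N`
#' (a standard attention matrix would be quadratic).
#'
#' @param Q,K `N x D` query/key matrices (after any positional encoding).
#' @param w_a Learned attention vector, length `D`.
#' @param W_out,b_out Projection of the key-query interaction (defaults:
#'   identity, zero).
#' @return `N x D` output matrix. The multiply-accumulate count of the
#'   computation is attached as attribute `"ops"`.
#' @seealso [eaa_ops()] for the closed-form operation count.
#' @export
eaa <- function(Q, K, w_a, W_out = diag(ncol(Q)), b_out = numeric(ncol(Q))) {
  if (!all(dim(Q) == dim(K))) {
    stop_sawoce("Q and K must have identical shapes", "sawoce_config")
  }
  D <- ncol(Q)
  if (length(w_a) != D || nrow(W_out) != D) {
    stop_sawoce("w_a / W_out dimensions must match ncol(Q)", "sawoce_config")
  }
  s <- as.vector(Q %*% w_a) / sqrt(D)
  a <- exp(s - max(s))
  a <- a / sum(a)
  q <- as.vector(crossprod(Q, a))             # global query, length D
  G <- K * rep(q, each = nrow(K))
  out <- G %*% W_out + rep(b_out, each = nrow(K)) + Q
  attr(out, "ops") <- eaa_ops(nrow(Q), D)
  out
}

#' Multiply-accumulate count of [eaa()]
#'
#' Closed-form operation count of the additive-attention computation:
#' scoring (`N D`), global-query pooling (`N D`), key modulation (`N D`)
#' and the output projection (`N D^2`) — every term linear in `N`.
#'
#' @param N Token count.
#' @param D Feature dimension.
#' @return Number of multiply-accumulates.
#' @export
eaa_ops <- function(N, D) {
  N * D + N * D + N * D + N * D * D
}

# Batched EAA over samples stacked row-wise: X rows are ordered token-major
# within sample ((t, n) pairs, t fastest). RoPE rotation tables are applied
# to Q and K before attention. Returns output tokens plus a cache for the
# backward pass.
eaa_fwd <- function(params, prefix, Xm, T_, B, rope) {
  D <- ncol(Xm)
  Wq <- params[[paste0(prefix, ".Wq")]]
  Wk <- params[[paste0(prefix, ".Wk")]]
  wa <- params[[paste0(prefix, ".wa")]]
  Q0 <- Xm %*% Wq
  K0 <- Xm %*% Wk
  idx <- rep(seq_len(T_), B)
  co <- rope$co[idx, , drop = FALSE]
  si <- rope$si[idx, , drop = FALSE]
  Q <- rope_apply(Q0, co, si)
  K <- rope_apply(K0, co, si)
  s <- matrix(as.vector(Q %*% wa) / sqrt(D), T_, B)
  s <- s - rep(apply(s, 2, max), each = T_)
  e <- exp(s)
  alpha <- e / rep(colSums(e), each = T_)     # T x B, sums to 1 per sample
  av <- as.vector(alpha)
  grp <- rep(seq_len(B), each = T_)
  q <- rowsum(Q * av, grp, reorder = FALSE)   # B x D global queries
  q_exp <- q[grp, , drop = FALSE]
  G <- K * q_exp
  lin <- linear_fwd(params, paste0(prefix, ".proj"), G)
  out <- lin$out + Q
  list(out = out,
       cache = list(Xm = Xm, Q = Q, K = K, alpha = alpha, q_exp = q_exp,
                    lin = lin$cache, co = co, si = si, grp = grp, T_ = T_,
                    B = B))
}

eaa_bwd <- function(params, prefix, cache, dOut) {
  D <- ncol(dOut)
  T_ <- cache$T_; B <- cache$B; grp <- cache$grp
  wa <- params[[paste0(prefix, ".wa")]]
  Wq <- params[[paste0(prefix, ".Wq")]]
  Wk <- params[[paste0(prefix, ".Wk")]]
  lb <- linear_bwd(params, paste0(prefix, ".proj"), cache$lin, dOut)
  grads <- lb$grads
  dG <- lb$dx
  dQ <- dOut                                   # residual branch
  dK <- dG * cache$q_exp
  dq <- rowsum(dG * cache$K, grp, reorder = FALSE)   # B x D
  dq_exp <- dq[grp, , drop = FALSE]
  av <- as.vector(cache$alpha)
  # q = sum_i alpha_i Q_i
  dQ <- dQ + dq_exp * av
  dalpha <- matrix(rowSums(cache$Q * dq_exp), T_, B)
  # softmax backward per sample
  dot <- colSums(cache$alpha * dalpha)
  ds <- cache$alpha * (dalpha - rep(dot, each = T_))
  dsv <- as.vector(ds) / sqrt(D)
  dQ <- dQ + outer(dsv, wa)
  grads[[paste0(prefix, ".wa")]] <- as.vector(crossprod(cache$Q, dsv))
  # undo RoPE (rotate gradients by the negative angle)
  dQ0 <- rope_apply(dQ, cache$co, -cache$si)
  dK0 <- rope_apply(dK, cache$co, -cache$si)
  grads[[paste0(prefix, ".Wq")]] <- crossprod(cache$Xm, dQ0)
  grads[[paste0(prefix, ".Wk")]] <- crossprod(cache$Xm, dK0)
  dX <- dQ0 %*% t(Wq) + dK0 %*% t(Wk)
  list(dx = dX, grads = grads)
}

eaa_init <- function(D, prefix) {
  p <- list()
  p[[paste0(prefix, ".Wq")]] <- matrix(nn_rnorm(D * D, sqrt(1 / D)), D, D)
  p[[paste0(prefix, ".Wk")]] <- matrix(nn_rnorm(D * D, sqrt(1 / D)), D, D)
  p[[paste0(prefix, ".wa")]] <- nn_rnorm(D, sqrt(1 / D))
  c(p, linear_init(D, D, paste0(prefix, ".proj")))
}
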