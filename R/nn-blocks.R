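# PVNet building blocks: each block couples an `_init` (parameters), a
# `_fwd` (output + cache) and a `_bwd` (input gradient + parameter grads).

merge_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# ---- ConvEncoder: X + Conv1x1(GELU(Conv1x1(BN(DWConv3x3(X))))) ------------

conv_encoder_init <- function(channels, expansion = 4, prefix = "ce") {
  hidden <- channels * expansion
  c(dw3_init(channels, paste0(prefix, ".dw")),
    bn_init(channels, paste0(prefix, ".bn")),
    linear_init(channels, hidden, paste0(prefix, ".pw1")),
    linear_init(hidden, channels, paste0(prefix, ".pw2")))
}

conv_encoder_fwd <- function(params, prefix, X, training, run_stats) {
  dw <- dw3_fwd(params, paste0(prefix, ".dw"), X)
  bn <- bn_fwd(params, paste0(prefix, ".bn"), dw$out, training, run_stats)
  p1 <- pw_fwd(params, paste0(prefix, ".pw1"), bn$out)
  ge <- gelu_fwd(p1$out)
  p2 <- pw_fwd(params, paste0(prefix, ".pw2"), ge$out)
  list(out = p2$out + X,
       cache = list(dw = dw$cache, bn = bn$cache, p1 = p1$cache,
                    ge = ge$cache, p2 = p2$cache))
}

conv_encoder_bwd <- function(params, prefix, cache, dY) {
  g <- list()
  b2 <- pw_bwd(params, paste0(prefix, ".pw2"), cache$p2, dY)
  g <- merge_grads(g, b2$grads)
  dge <- gelu_bwd(cache$ge, b2$dx)
  b1 <- pw_bwd(params, paste0(prefix, ".pw1"), cache$p1, dge)
  g <- merge_grads(g, b1$grads)
  bb <- bn_bwd(params, paste0(prefix, ".bn"), cache$bn, b1$dx)
  g <- merge_grads(g, bb$grads)
  bd <- dw3_bwd(params, paste0(prefix, ".dw"), cache$dw, bb$dx)
  g <- merge_grads(g, bd$grads)
  list(dx = bd$dx + dY, grads = g)
}

#' ConvEncoder block (single forward pass)
#'
#' The local feature-extraction unit of PVNet: a depthwise 3x3 convolution
#' (per-channel spatial filtering), batch normalization, a pointwise
#' expansion convolution, GELU, and a pointwise projection back to the
#' block width, wrapped in a residual connection:
#' `X + Conv1x1(GELU(Conv1x1(BN(DWConv3x3(X)))))`. Shape-preserving.
#'
#' @param x Feature map: `[H, W, C]` or `[H, W, N, C]` array.
#' @param params Parameters from [conv_encoder_init()] (prefix `"ce"`).
#' @return Array of the same shape as `x`.
#' @export
conv_encoder <- function(x, params) {
  squeeze <- length(dim(x)) == 3
  if (squeeze) dim(x) <- c(dim(x)[1:2], 1, dim(x)[3])
  C <- dim(x)[4]
  if (length(params[["ce.dw.b"]]) != C) {
    stop_sawoce("channel mismatch between input and parameters",
                "sawoce_config")
  }
  out <- conv_encoder_fwd(params, "ce", x, training = FALSE,
                          run_stats = NULL)$out
  if (squeeze) dim(out) <- dim(out)[-3]
  out
}

# ---- SwiftFormer encoder block --------------------------------------------
# X1 = Conv1x1(DWConv3x3(X)); Xattn = EAA(RoPE(X1)); out =
# Conv1x1(BN(DWConv3x3(Xattn))). The EAA itself carries a query residual.

swiftformer_init <- function(channels, prefix = "sf") {
  c(dw3_init(channels, paste0(prefix, ".dwa")),
    linear_init(channels, channels, paste0(prefix, ".pwa")),
    eaa_init(channels, paste0(prefix, ".att")),
    dw3_init(channels, paste0(prefix, ".dwb")),
    bn_init(channels, paste0(prefix, ".bnb")),
    linear_init(channels, channels, paste0(prefix, ".pwb")))
}

swiftformer_fwd <- function(params, prefix, X, training, run_stats,
                            rope_base = 10000) {
  d <- dim(X)
  T_ <- d[1] * d[2]; B <- d[3]; C <- d[4]
  da <- dw3_fwd(params, paste0(prefix, ".dwa"), X)
  pa <- pw_fwd(params, paste0(prefix, ".pwa"), da$out)
  Xm <- matrix(pa$out, ncol = C)              # tokens, t-major within sample
  rope <- rope_tables(T_, C, rope_base)
  at <- eaa_fwd(params, paste0(prefix, ".att"), Xm, T_, B, rope)
  Xattn <- at$out
  dim(Xattn) <- d
  db <- dw3_fwd(params, paste0(prefix, ".dwb"), Xattn)
  bb <- bn_fwd(params, paste0(prefix, ".bnb"), db$out, training, run_stats)
  pb <- pw_fwd(params, paste0(prefix, ".pwb"), bb$out)
  list(out = pb$out,
       cache = list(da = da$cache, pa = pa$cache, at = at$cache,
                    db = db$cache, bb = bb$cache, pb = pb$cache, d = d))
}

swiftformer_bwd <- function(params, prefix, cache, dY) {
  g <- list()
  bpb <- pw_bwd(params, paste0(prefix, ".pwb"), cache$pb, dY)
  g <- merge_grads(g, bpb$grads)
  bbb <- bn_bwd(params, paste0(prefix, ".bnb"), cache$bb, bpb$dx)
  g <- merge_grads(g, bbb$grads)
  bdb <- dw3_bwd(params, paste0(prefix, ".dwb"), cache$db, bbb$dx)
  g <- merge_grads(g, bdb$grads)
  dAttn <- matrix(bdb$dx, ncol = cache$d[4])
  bat <- eaa_bwd(params, paste0(prefix, ".att"), cache$at, dAttn)
  g <- merge_grads(g, bat$grads)
  dPa <- bat$dx
  dim(dPa) <- cache$d
  bpa <- pw_bwd(params, paste0(prefix, ".pwa"), cache$pa, dPa)
  g <- merge_grads(g, bpa$grads)
  bda <- dw3_bwd(params, paste0(prefix, ".dwa"), cache$da, bpa$dx)
  g <- merge_grads(g, bda$grads)
  list(dx = bda$dx, grads = g)
}

#' SwiftFormer encoder block (single forward pass)
#'
#' Local mixing (depthwise 3x3 then pointwise convolution), flattening of
#' the spatial grid into a token sequence, efficient additive attention
#' over RoPE-rotated query/key projections, and a linear block (depthwise
#' convolution, batch normalization, pointwise projection) back in the
#' spatial domain. Shape-preserving; position-sensitive through RoPE.
#'
#' @param x Feature map: `[H, W, C]` or `[H, W, N, C]` array with even `C`.
#' @param params Parameters from [swiftformer_init()] (prefix `"sf"`).
#' @param rope_base RoPE wavelength base.
#' @return Array of the same shape as `x`.
#' @export
swiftformer_block <- function(x, params, rope_base = 10000) {
  squeeze <- length(dim(x)) == 3
  if (squeeze) dim(x) <- c(dim(x)[1:2], 1, dim(x)[3])
  C <- dim(x)[4]
  if (length(params[["sf.dwa.b"]]) != C) {
    stop_sawoce("channel mismatch between input and parameters",
                "sawoce_config")
  }
  out <- swiftformer_fwd(params, "sf", x, training = FALSE, run_stats = NULL,
                         rope_base = rope_base)$out
  if (squeeze) dim(out) <- dim(out)[-3]
  out
}

#' @rdname conv_encoder
#' @param channels Block width (channel count).
#' @param expansion Hidden expansion ratio of the pointwise MLP.
#' @param seed Seed for the random initialization.
#' @export
conv_encoder_init_seeded <- function(channels, expansion = 4, seed = 0) {
  with_seed(seed, conv_encoder_init(channels, expansion))
}

#' @rdname swiftformer_block
#' @param channels Block width (must be even for RoPE).
#' @param seed Seed for the random initialization.
#' @export
swiftformer_init_seeded <- function(channels, seed = 0) {
  if (channels %% 2 != 0) {
    stop_sawoce("swiftformer channels must be even (RoPE pairs elements)",
                "sawoce_config")
  }
  with_seed(seed, swiftformer_init(channels))
}
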