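#' PVNet configuration
#'
#' Architecture hyper-parameters of the phase-velocity regression network:
#' a two-convolution patch-embedding stem (4x spatial reduction), four
#' hierarchical encoder stages (ConvEncoder blocks capped by a SwiftFormer
#' attention block, 2x downsampling between stages), and a pooled
#' regression head emitting one velocity in m/s.
#'
#' Variants define desk-scale presets: `tiny` (dims 16/32/48/64, one block
#' per stage, 64 x 64 input) is sized so a CPU forward pass is
#' sub-second and training on simulated data takes minutes; `S`, `base`
#' and `L` scale dims/depths up at the instrument's 320 x 320 input.
#' Parameter counts of these presets are package choices and are not
#' comparable to any published model size.
#'
#' @param variant One of `"tiny"`, `"S"`, `"base"`, `"L"`; presets may be
#'   overridden by the other arguments.
#' @param input_size `(H, W)` of the input phase image.
#' @param stage_dims Four even channel widths.
#' @param stage_depths Four block counts per stage.
#' @param rope_base RoPE wavelength base (default 10000).
#' @param head_hidden Regression-head width.
#' @param expansion ConvEncoder pointwise expansion ratio.
#' @return A list of class `pvnet_config`.
#' @export
pvnet_config <- function(variant = c("tiny", "S", "base", "L"),
                         input_size = NULL, stage_dims = NULL,
                         stage_depths = NULL, rope_base = 10000,
                         head_hidden = NULL, expansion = 4) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    tiny = list(input_size = c(64, 64), stage_dims = c(16, 32, 48, 64),
                stage_depths = c(1, 1, 1, 1), head_hidden = 32),
    S = list(input_size = c(320, 320), stage_dims = c(32, 64, 96, 128),
             stage_depths = c(2, 2, 4, 2), head_hidden = 64),
    base = list(input_size = c(320, 320), stage_dims = c(48, 96, 160, 224),
                stage_depths = c(3, 3, 6, 3), head_hidden = 128),
    L = list(input_size = c(320, 320), stage_dims = c(64, 128, 224, 320),
             stage_depths = c(3, 3, 9, 3), head_hidden = 160))
  cfg <- list(variant = variant,
              input_size = input_size %||% preset$input_size,
              stage_dims = stage_dims %||% preset$stage_dims,
              stage_depths = stage_depths %||% preset$stage_depths,
              rope_base = rope_base,
              head_hidden = head_hidden %||% preset$head_hidden,
              expansion = expansion)
  stopifnot(length(cfg$stage_dims) == 4, length(cfg$stage_depths) == 4,
            all(cfg$stage_depths >= 1), length(cfg$input_size) == 2)
  if (any(cfg$stage_dims %% 2 != 0)) {
    stop_sawoce("stage dims must be even (RoPE pairs elements)",
                "sawoce_config")
  }
  if (any(cfg$input_size %% 32 != 0)) {
    stop_sawoce("input size must be divisible by 32 (stem + 3 downsamples)",
                "sawoce_config")
  }
  structure(cfg, class = "pvnet_config")
}

#' Construct a PVNet model
#'
#' Randomly initializes all parameters of the network described by a
#' [pvnet_config()]. The returned model carries its parameters, the batch
#' normalization running statistics, and the target normalization (set
#' during training).
#'
#' @param config A [pvnet_config()].
#' @param seed Initialization seed.
#' @return An object of class `pvnet`.
#' @export
pvnet <- function(config = pvnet_config(), seed = 0) {
  stopifnot(inherits(config, "pvnet_config"))
  dims <- config$stage_dims
  params <- with_seed(seed, {
    p <- c(conv3_init(1, dims[1] %/% 2, "stem.c1"),
           bn_init(dims[1] %/% 2, "stem.n1"),
           conv3_init(dims[1] %/% 2, dims[1], "stem.c2"),
           bn_init(dims[1], "stem.n2"))
    for (s in 1:4) {
      for (b in seq_len(config$stage_depths[s] - 1)) {
        p <- c(p, conv_encoder_init(dims[s], config$expansion,
                                    sprintf("s%d.ce%d", s, b)))
      }
      p <- c(p, swiftformer_init(dims[s], sprintf("s%d.sf", s)))
      if (s < 4) {
        p <- c(p, conv3_init(dims[s], dims[s + 1], sprintf("down%d.c", s)),
               bn_init(dims[s + 1], sprintf("down%d.n", s)))
      }
    }
    c(p, linear_init(dims[4], config$head_hidden, "head.fc1"),
      linear_init(config$head_hidden, 1, "head.fc2"))
  })
  # Running batch-norm moments start at (0, 1) so evaluation-mode forward
  # passes are sample-independent even before any training.
  run_stats <- new.env(parent = emptyenv())
  for (nm in grep("\\.gamma$", names(params), value = TRUE)) {
    pre <- sub("\\.gamma$", "", nm)
    C <- length(params[[nm]])
    assign(pre, list(mu = numeric(C), va = rep(1, C)), envir = run_stats)
  }
  structure(list(config = config, params = params, run_stats = run_stats,
                 target_center = 0, target_scale = 1, seed = seed),
            class = "pvnet")
}

#' @export
print.pvnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pvnet %s> input %dx%d, dims %s, depths %s, %d parameters\n",
    cfg$variant, cfg$input_size[1], cfg$input_size[2],
    paste(cfg$stage_dims, collapse = "/"),
    paste(cfg$stage_depths, collapse = "/"),
    n_parameters(x)))
  invisible(x)
}

#' Total trainable parameter count of a PVNet
#'
#' @param model A [pvnet()].
#' @return Integer: sum of lengths of all parameter tensors.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Full network forward. `x` is [H, W, N, 1]; returns normalized-scale
# predictions (length N) and, when `keep_cache`, everything backward needs.
pvnet_fwd <- function(model, x, training = FALSE, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  rs <- model$run_stats
  cache <- list()
  c1 <- conv3_fwd(p, "stem.c1", x, stride = 2)
  n1 <- bn_fwd(p, "stem.n1", c1$out, training, rs)
  g1 <- gelu_fwd(n1$out)
  c2 <- conv3_fwd(p, "stem.c2", g1$out, stride = 2)
  n2 <- bn_fwd(p, "stem.n2", c2$out, training, rs)
  g2 <- gelu_fwd(n2$out)
  h <- g2$out
  if (keep_cache) cache$stem <- list(c1 = c1$cache, n1 = n1$cache,
                                     g1 = g1$cache, c2 = c2$cache,
                                     n2 = n2$cache, g2 = g2$cache)
  for (s in 1:4) {
    for (b in seq_len(cfg$stage_depths[s] - 1)) {
      ce <- conv_encoder_fwd(p, sprintf("s%d.ce%d", s, b), h, training, rs)
      h <- ce$out
      if (keep_cache) cache[[sprintf("s%d.ce%d", s, b)]] <- ce$cache
    }
    sf <- swiftformer_fwd(p, sprintf("s%d.sf", s), h, training, rs,
                          cfg$rope_base)
    h <- sf$out
    if (keep_cache) cache[[sprintf("s%d.sf", s)]] <- sf$cache
    if (s < 4) {
      dc <- conv3_fwd(p, sprintf("down%d.c", s), h, stride = 2)
      dn <- bn_fwd(p, sprintf("down%d.n", s), dc$out, training, rs)
      h <- dn$out
      if (keep_cache) cache[[sprintf("down%d", s)]] <- list(c = dc$cache,
                                                            n = dn$cache)
    }
  }
  gp <- gap_fwd(h)
  f1 <- linear_fwd(p, "head.fc1", gp$out)
  hg <- gelu_fwd(f1$out)
  f2 <- linear_fwd(p, "head.fc2", hg$out)
  if (keep_cache) cache$head <- list(gp = gp$cache, f1 = f1$cache,
                                     hg = hg$cache, f2 = f2$cache)
  list(pred = as.vector(f2$out), cache = cache)
}

pvnet_bwd <- function(model, cache, dpred) {
  p <- model$params
  cfg <- model$config
  g <- list()
  b2 <- linear_bwd(p, "head.fc2", cache$head$f2, matrix(dpred, ncol = 1))
  g <- merge_grads(g, b2$grads)
  dhg <- gelu_bwd(cache$head$hg, b2$dx)
  b1 <- linear_bwd(p, "head.fc1", cache$head$f1, dhg)
  g <- merge_grads(g, b1$grads)
  dh <- gap_bwd(cache$head$gp, b1$dx)
  for (s in 4:1) {
    if (s < 4) {
      dn <- bn_bwd(p, sprintf("down%d.n", s), cache[[sprintf("down%d", s)]]$n,
                   dh)
      g <- merge_grads(g, dn$grads)
      dc <- conv3_bwd(p, sprintf("down%d.c", s),
                      cache[[sprintf("down%d", s)]]$c, dn$dx)
      g <- merge_grads(g, dc$grads)
      dh <- dc$dx
    }
    sf <- swiftformer_bwd(p, sprintf("s%d.sf", s),
                          cache[[sprintf("s%d.sf", s)]], dh)
    g <- merge_grads(g, sf$grads)
    dh <- sf$dx
    for (b in rev(seq_len(cfg$stage_depths[s] - 1))) {
      ce <- conv_encoder_bwd(p, sprintf("s%d.ce%d", s, b),
                             cache[[sprintf("s%d.ce%d", s, b)]], dh)
      g <- merge_grads(g, ce$grads)
      dh <- ce$dx
    }
  }
  dg2 <- gelu_bwd(cache$stem$g2, dh)
  bn2 <- bn_bwd(p, "stem.n2", cache$stem$n2, dg2)
  g <- merge_grads(g, bn2$grads)
  bc2 <- conv3_bwd(p, "stem.c2", cache$stem$c2, bn2$dx)
  g <- merge_grads(g, bc2$grads)
  dg1 <- gelu_bwd(cache$stem$g1, bc2$dx)
  bn1 <- bn_bwd(p, "stem.n1", cache$stem$n1, dg1)
  g <- merge_grads(g, bn1$grads)
  bc1 <- conv3_bwd(p, "stem.c1", cache$stem$c1, bn1$dx)
  g <- merge_grads(g, bc1$grads)
  g
}

# Stack a list of [H, W] phase images into the [H, W, N, 1] input tensor,
# wrapping to [-pi, pi) and scaling by 1/pi.
pvnet_input <- function(images, input_size) {
  H <- input_size[1]; W <- input_size[2]
  n <- length(images)
  x <- array(0, c(H, W, n, 1))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!all(dim(img) == input_size)) {
      stop_sawoce(sprintf(
        "image %d is %dx%d; expected %dx%d (resize explicitly before predict)",
        i, nrow(img), ncol(img), H, W), "sawoce_config")
    }
    if (any(!is.finite(img))) {
      stop_sawoce(sprintf("image %d contains non-finite values", i),
                  "sawoce_invariant")
    }
    x[, , i, 1] <- wrap_phase(img) / pi
  }
  x
}

#' Predict phase velocities from phase images
#'
#' Runs the network in evaluation mode (frozen batch statistics). Images
#' must already match the configured input size — there is no silent
#' resizing; use [resize_phase_image()] first if needed.
#'
#' @param object A trained [pvnet()].
#' @param images A single `[H, W]` matrix or list of them (radians).
#' @param batch_size Forward batch size.
#' @param ... Unused.
#' @return Numeric vector of phase velocities, m/s.
#' @export
predict.pvnet <- function(object, images, batch_size = 128, ...) {
  if (is.matrix(images)) images <- list(images)
  n <- length(images)
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- pvnet_input(images[idx], object$config$input_size)
    out[idx] <- pvnet_fwd(object, x, training = FALSE)$pred
  }
  out * object$target_scale + object$target_center
}

#' Resize a phase image to the network input size
#'
#' Bilinear resampling of a lateral-temporal phase image onto the model's
#' input grid (the acquisition geometry rarely matches it exactly).
#'
#' @param img Numeric matrix (radians).
#' @param size Target `(H, W)`.
#' @return Resized matrix.
#' @export
resize_phase_image <- function(img, size) {
  resize_bilinear(img, size[1], size[2])
}
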