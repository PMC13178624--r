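# Internal helpers shared across modules.

# Run `expr` under a private RNG stream without disturbing the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Symmetric Hann window. signal::hanning() is used for n >= 2; the n == 1
# degenerate case (0/0 in the cosine argument) is pinned to 1.
hann_window <- function(n) {
  if (n < 1) stop("window length must be >= 1")
  if (n == 1) return(1)
  as.numeric(signal::hanning(n))
}

next_pow2 <- function(n) {
  2L^as.integer(ceiling(log2(n)))
}

# FFT bin frequencies for an n-point transform at sample spacing d,
# in cycles per unit of d. Bins above n/2 map to negative frequencies.
fft_freqs <- function(n, d) {
  j <- 0:(n - 1L)
  j[j > n / 2] <- j[j > n / 2] - n
  j / (n * d)
}

# Bilinear resampling of a matrix onto an `out_h` x `out_w` grid
# (align-corners convention; both axes treated as uniformly sampled).
resize_bilinear <- function(mat, out_h, out_w) {
  stopifnot(is.matrix(mat), out_h >= 1, out_w >= 1)
  h <- nrow(mat)
  w <- ncol(mat)
  src_r <- if (out_h == 1) (h + 1) / 2 else seq(1, h, length.out = out_h)
  src_c <- if (out_w == 1) (w + 1) / 2 else seq(1, w, length.out = out_w)
  r0 <- pmax(pmin(floor(src_r), h - 1L), 1L)
  c0 <- pmax(pmin(floor(src_c), w - 1L), 1L)
  fr <- src_r - r0
  fc <- src_c - c0
  r1 <- pmin(r0 + 1L, h)
  c1 <- pmin(c0 + 1L, w)
  top <- mat[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    mat[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  bot <- mat[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    mat[r1, c1, drop = FALSE] * outer(fr, fc)
  top + bot
}

# Wrap angles to [-pi, pi).
wrap_phase <- function(x) {
  y <- ((x + pi) %% (2 * pi)) - pi
  y[y >= pi] <- y[y >= pi] - 2 * pi
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sawoce <- function(msg, class) {
  abort(msg, class = c(class, "sawoce_error"))
}
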