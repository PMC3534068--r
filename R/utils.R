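# Internal numeric helpers shared across model stages.

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Seeds the session RNG, evaluates `expr`, and restores the previous RNG
#' state, so generators are reproducible without clobbering the caller's
#' random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Circular (wrapped) absolute difference between angles in degrees.
circ_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Cyclically shift a matrix (or the first two dims of an array) by integer
# (dy, dx): positive dy moves content down, positive dx moves it right.
roll2 <- function(x, dy, dx) {
  d <- dim(x)
  iy <- ((seq_len(d[1]) - 1 - dy) %% d[1]) + 1
  ix <- ((seq_len(d[2]) - 1 - dx) %% d[2]) + 1
  if (length(d) == 2) x[iy, ix, drop = FALSE] else x[iy, ix, , drop = FALSE]
}

# Sample a field (matrix or H x W x K array, complex allowed) at positions
# displaced by the constant offset (dx, dy), with wrap-around, using bilinear
# interpolation between the four neighbouring integer shifts. Returns the
# field "pulled back": out(y, x) = field(y + dy, x + dx).
shift_bilinear <- function(field, dx, dy) {
  x0 <- floor(dx); y0 <- floor(dy)
  fx <- dx - x0;   fy <- dy - y0
  # out(y,x) = f(y+dy, x+dx); roll2 with negative offsets pulls content.
  w00 <- (1 - fx) * (1 - fy)
  w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy
  w11 <- fx * fy
  out <- w00 * roll2(field, -y0, -x0)
  if (w10 > 0) out <- out + w10 * roll2(field, -y0, -(x0 + 1))
  if (w01 > 0) out <- out + w01 * roll2(field, -(y0 + 1), -x0)
  if (w11 > 0) out <- out + w11 * roll2(field, -(y0 + 1), -(x0 + 1))
  out
}

# Unit-sum circular Gaussian kernel over `n` evenly spaced direction bins
# (spacing `step` degrees) with standard deviation `sigma` degrees.
dir_kernel <- function(n, step, sigma) {
  offs <- (seq_len(n) - 1) * step
  w <- exp(-circ_diff_deg(offs, 0)^2 / (2 * sigma^2))
  w / sum(w)
}

# Row-normalized Gaussian interaction matrix over an arbitrary (possibly
# non-uniform) speed axis; the row normalization conserves mass at the axis
# ends, the discrete analogue of a reflecting (Neumann) boundary.
speed_kernel_matrix <- function(speeds, sigma) {
  m <- outer(speeds, speeds, function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
  sweep(m, 1, rowSums(m), "/")
}

# Circulant direction-convolution matrix from dir_kernel (columns index
# input bins, rows output bins).
dir_kernel_matrix <- function(n, step, sigma) {
  k <- dir_kernel(n, step, sigma)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) m[i, ] <- k[((seq_len(n) - i) %% n) + 1]
  m
}

# Apply speed (S) and direction (D) interaction matrices to the last two axes
# of an (ny, nx, n_speed, n_dir) array.
vel_smooth <- function(a, S, D) {
  d <- dim(a)
  m <- matrix(a, nrow = d[1] * d[2] * d[3], ncol = d[4])
  m <- m %*% t(D)
  a <- array(m, d)
  a <- aperm(a, c(1, 2, 4, 3))
  m <- matrix(a, nrow = d[1] * d[2] * d[4], ncol = d[3])
  m <- m %*% t(S)
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

# 2-D FFT helpers (R's fft handles n-dimensional arrays natively).
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Unit-sum periodic 2-D Gaussian kernel (origin at [1,1]) and its FFT,
# for circular spatial convolution.
periodic_gaussian_fft <- function(H, W, sigma) {
  dy <- pmin(0:(H - 1), H - (0:(H - 1)))
  dx <- pmin(0:(W - 1), W - (0:(W - 1)))
  k <- outer(exp(-dy^2 / (2 * sigma^2)), exp(-dx^2 / (2 * sigma^2)))
  k <- k / sum(k)
  stats::fft(k)
}

# Circular convolution of a matrix with a precomputed kernel FFT.
conv2_circ <- function(x, kernel_fft) {
  Re(ifft2(stats::fft(x) * kernel_fft))
}

# Tiny stable string hash (FNV-1a, 32 bit) for run manifests. Arithmetic is
# done in doubles below 2^53 so the 32-bit product stays exact.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32, split as h*(2^24 + 403) to stay exact
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
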