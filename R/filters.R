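# Visual front-end: recursive (Deriche) Gaussian filtering, the
# difference-of-Gaussians receptive field, and the prosthesis pixel-averaging
# encoder.

# Deriche's 4th-order sum-of-exponentials approximation of the Gaussian:
# h(x) ~ (a0 cos(w0 x/s) + a1 sin(w0 x/s)) e^(-b0 x/s)
#      + (c0 cos(w1 x/s) + c1 sin(w1 x/s)) e^(-b1 x/s),  x >= 0.
.deriche_const <- list(a0 = 1.68, a1 = 3.735, b0 = 1.783, w0 = 0.6318,
                       c0 = -0.6803, c1 = -0.2598, b1 = 1.723, w1 = 1.997)

# 2nd-order causal section for e^(-l n) (a cos(o n) + c sin(o n)) u(n):
# H(z) = (a + e^-l (c sin o - a cos o) z^-1) /
#        (1 - 2 e^-l cos o z^-1 + e^-2l z^-2)
.deriche_section <- function(a, c, l, o) {
  list(num = c(a, exp(-l) * (c * sin(o) - a * cos(o))),
       den = c(1, -2 * exp(-l) * cos(o), exp(-2 * l)))
}

.polymul <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  }
  out
}

# causal numerator n0..n3, common denominator 1,d1..d4, anticausal numerator
# m1..m4 (m_k = n_k - d_k n0), all normalized to exact unit DC gain
deriche_coefficients <- function(sigma) {
  stopifnot(sigma > 0)
  k <- .deriche_const
  s1 <- .deriche_section(k$a0, k$a1, k$b0 / sigma, k$w0 / sigma)
  s2 <- .deriche_section(k$c0, k$c1, k$b1 / sigma, k$w1 / sigma)
  den <- .polymul(s1$den, s2$den)                      # degree 4
  num <- .polymul(s1$num, s2$den) + c(.polymul(s2$num, s1$den))
  num <- c(num, 0)                                     # pad to degree 4
  m <- num[2:5] - den[2:5] * num[1]                    # anticausal, lags 1..4
  gain <- (sum(num) + sum(m)) / sum(den)
  list(num = num / gain, den = den, m = m / gain)
}

# one-dimensional pass along the columns of a matrix, replicate boundaries;
# recursions are initialized at their steady state so a constant signal is
# reproduced exactly (DC gain 1 to float precision)
.deriche_cols <- function(x, co, pad) {
  x <- as.matrix(x)
  n <- nrow(x)
  xp <- rbind(x[rep(1L, pad), , drop = FALSE], x,
              x[rep(n, pad), , drop = FALSE])
  den_tail <- co$den[2:5]
  run <- function(u, first_row) {
    # recursive part: y[i] = u[i] - sum(den_tail * y[i-k]); steady-state init
    y_ss <- first_row / sum(co$den)
    stats::filter(u, -den_tail, method = "recursive",
                  init = matrix(rep(y_ss, each = 4L), nrow = 4L))
  }
  # causal: FIR lags 0..4, then recursion (forward)
  u1 <- stats::filter(xp, co$num, method = "convolution", sides = 1)
  u1[seq_len(4L), ] <- matrix(rep(colSums(matrix(co$num)) *
                                    xp[1L, ], each = 4L), nrow = 4L)
  u1[is.na(u1)] <- 0
  yplus <- run(u1, sum(co$num) * xp[1L, ])
  # anticausal: FIR lags 1..4 on the reversed signal, recursion, reverse back
  xr <- xp[nrow(xp):1L, , drop = FALSE]
  u2 <- stats::filter(xr, c(0, co$m), method = "convolution", sides = 1)
  u2[seq_len(5L), ] <- matrix(rep(sum(co$m) * xr[1L, ], each = 5L),
                              nrow = 5L)
  u2[is.na(u2)] <- 0
  yminus <- run(u2, sum(co$m) * xr[1L, ])
  yminus <- yminus[nrow(yminus):1L, , drop = FALSE]
  y <- unclass(yplus + yminus)
  y[(pad + 1L):(pad + n), , drop = FALSE]
}

#' Fast recursive Gaussian smoothing
#'
#' O(pixels) approximation of Gaussian convolution using Deriche's 4th-order
#' recursive filter (a causal + anticausal IIR pair per axis), separable over
#' rows and columns, with replicate boundary handling and exact unit DC gain.
#' The impulse response matches the normalized Gaussian to about 1e-4 of the
#' peak; a constant image passes through unchanged.
#'
#' @param frame numeric matrix (H x W) or vector.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return filtered matrix of the same size.
#' @export
recursive_gaussian <- function(frame, sigma) {
  stopifnot(sigma > 0)
  co <- deriche_coefficients(sigma)
  pad <- max(ceiling(4 * sigma) + 4L, 8L)
  vec <- is.null(dim(frame))
  x <- if (vec) matrix(frame, ncol = 1L) else frame
  y <- .deriche_cols(x, co, pad)                 # along columns
  if (!vec) y <- t(.deriche_cols(t(y), co, pad)) # along rows
  if (vec) drop(y) else y
}

#' Direct FIR Gaussian convolution (reference)
#'
#' Truncated (6 sigma) discrete Gaussian kernel applied separably with
#' replicate boundaries; the brute-force oracle for
#' [recursive_gaussian()].
#'
#' @inheritParams recursive_gaussian
#' @return filtered matrix.
#' @export
fir_gaussian <- function(frame, sigma) {
  r <- ceiling(6 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x) { # columns, replicate boundary
    n <- nrow(x)
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x, x[rep(n, r), , drop = FALSE])
    out <- stats::filter(xp, k, method = "convolution", sides = 2)
    out[(r + 1L):(r + n), , drop = FALSE]
  }
  vec <- is.null(dim(frame))
  x <- if (vec) matrix(frame, ncol = 1L) else frame
  y <- conv1(x)
  if (!vec) y <- t(conv1(t(y)))
  y <- unclass(y)
  if (vec) drop(y) else y
}

#' Difference-of-Gaussians receptive field
#'
#' Circularly symmetric center-surround spatial kernel
#' \code{w_c G(sigma_c) - w_s G(sigma_s)} (normalized Gaussians, so a
#' uniform frame of level I responds \code{(w_c - w_s) I}), followed by a
#' causal exponential-cascade temporal filter of order \code{n_rf} with time
#' constant \code{tau_rf} (unit DC gain).
#'
#' @param sigma_c,sigma_s center/surround widths, in the stimulus spatial
#'   modality (requires \code{sigma_s > sigma_c > 0}).
#' @param w_c,w_s center/surround weights.
#' @param tau_rf temporal time constant, s.
#' @param n_rf temporal cascade order (>= 1).
#' @return object of class \code{"receptive_field"}.
#' @export
receptive_field <- function(sigma_c, sigma_s, w_c = 1, w_s = 0.5,
                            tau_rf = 0.02, n_rf = 1) {
  if (!(sigma_s > sigma_c && sigma_c > 0)) {
    stop(validation_error("receptive field needs sigma_s > sigma_c > 0"))
  }
  stopifnot(n_rf >= 1, tau_rf > 0)
  structure(
    list(sigma_c = sigma_c, sigma_s = sigma_s, w_c = w_c, w_s = w_s,
         tau_rf = tau_rf, n_rf = as.integer(n_rf)),
    class = "receptive_field"
  )
}

#' Spatial DoG response of one frame
#' @param frame H x W gray-level matrix.
#' @param rf a [receptive_field()].
#' @param px_size stimulus calibration (length per pixel); receptive-field
#'   sigmas are divided by it to get pixel units.
#' @return filtered frame.
#' @export
dog_spatial <- function(frame, rf, px_size = 1) {
  sc <- rf$sigma_c / px_size
  ss <- rf$sigma_s / px_size
  if (sc < 0.5) {
    warning("center sigma is below half a pixel; the DoG is under-resolved")
  }
  rf$w_c * recursive_gaussian(frame, sc) -
    rf$w_s * recursive_gaussian(frame, ss)
}

# exact ZOH discretization of n_rf cascaded first-order low-passes
.temporal_cascade <- function(u, dt, tau, n_ord) {
  a <- exp(-dt / tau)
  y <- u
  for (stage in seq_len(n_ord)) {
    y <- stats::filter(y * (1 - a), a, method = "recursive")
    y <- unclass(y)
  }
  y
}

#' Receptive-field drive of a movie at cell positions
#'
#' Each frame is spatially DoG-filtered, sampled at the cell positions
#' (nearest pixel; positions share the stimulus spatial frame, pixel centers
#' at \code{(j - 0.5) px_size}), held constant between frames (zero-order
#' hold on the \code{dt} grid), and passed through the causal temporal
#' cascade. The result feeds a cell's external slot (times a scenario gain).
#'
#' @param stim a [stimulus()].
#' @param rf a [receptive_field()].
#' @param positions two-column matrix of cell (x, y) positions in the
#'   stimulus modality units.
#' @param dt output sampling step, s.
#' @param t_end output duration, s (default the movie duration).
#' @return list with \code{time} (vector, 0 to t_end) and \code{drive}
#'   (matrix, length(time) x n_cells).
#' @export
dog_response <- function(stim, rf, positions, dt, t_end = stim_duration(stim)) {
  positions <- rbind(positions)
  if (nrow(positions) == 0L) {
    stop(validation_error("dog_response: no positions supplied"))
  }
  d <- dim(stim$frames)
  px <- stim$px_size
  col <- pmin(pmax(ceiling(positions[, 1] / px), 1L), d[3])
  row <- pmin(pmax(ceiling(positions[, 2] / px), 1L), d[2])
  nt <- d[1]
  spat <- matrix(0, nt, nrow(positions))
  for (k in seq_len(nt)) {
    fr <- dog_spatial(stim$frames[k, , ], rf, px)
    spat[k, ] <- fr[cbind(row, col)]
  }
  time <- seq(0, t_end, by = dt)
  frame_idx <- pmin(floor(time * stim$fps) + 1L, nt)  # zero-order hold
  u <- spat[frame_idx, , drop = FALSE]
  drive <- .temporal_cascade(u, dt, rf$tau_rf, rf$n_rf)
  list(time = time, drive = drive)
}

#' Prosthesis pixel-averaging input
#'
#' Partitions each frame into \code{nx} by \code{ny} tiles (one per
#' electrode of the layer; the tile grid is the image size divided by the
#' electrode counts, every pixel counted exactly once) and delivers the mean
#' gray level of an electrode's tile, scaled by \code{gain}, as its external
#' current (pA), zero-order held on the \code{dt} grid.
#'
#' @param stim a [stimulus()].
#' @param electrode_layer a [layer_spec()] (row-major electrode indexing:
#'   x across columns, y across rows, matching the tile grid).
#' @param gain pA per gray level (default 1).
#' @param dt output step, s.
#' @param t_end output duration, s.
#' @return list with \code{time} and \code{drive} (length(time) x
#'   n_electrodes).
#' @export
prosthesis_input <- function(stim, electrode_layer, gain = 1, dt,
                             t_end = stim_duration(stim)) {
  d <- dim(stim$frames)
  nx <- electrode_layer$nx
  ny <- electrode_layer$ny
  if (nx > d[3] || ny > d[2]) {
    stop(validation_error("more electrodes than pixels along an axis"))
  }
  xb <- round(seq(0, d[3], length.out = nx + 1))
  yb <- round(seq(0, d[2], length.out = ny + 1))
  nt <- d[1]
  means <- matrix(0, nt, nx * ny)
  for (k in seq_len(nt)) {
    fr <- stim$frames[k, , ]
    for (ey in seq_len(ny)) {
      for (ex in seq_len(nx)) {
        tile <- fr[(yb[ey] + 1):yb[ey + 1], (xb[ex] + 1):xb[ex + 1]]
        means[k, (ey - 1L) * nx + ex] <- mean(tile)
      }
    }
  }
  time <- seq(0, t_end, by = dt)
  frame_idx <- pmin(floor(time * stim$fps) + 1L, nt)
  list(time = time, drive = gain * means[frame_idx, , drop = FALSE])
}
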