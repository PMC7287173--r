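# Savitzky-Golay least-squares smoothing with full handling of the
# input-on / input-off transients, used to estimate the baseline of the
# dermo-epidermal junction signal.

#' Savitzky-Golay smoothing (projection) matrix
#'
#' For an odd window of length `window` = 2M + 1 and polynomial order
#' `order` = d, builds the basis matrix S with columns `s_i(m) = m^i`
#' (m = -M..M, i = 0..d) and the projection matrix
#' `B = S (S'S)^-1 S'`. Applying B to a window of samples returns the
#' least-squares degree-d polynomial fit evaluated at every window
#' position; the center column/row `b0` is the steady-state FIR response
#' and is symmetric, `b0(-m) = b0(m)`.
#'
#' @param window odd window length N = 2M + 1.
#' @param order polynomial order d with 0 <= d <= M.
#' @return List with `B` (N x N projection matrix), `b0` (center
#'   response), `M` and the inputs.
#' @examples
#' sgSmoothingMatrix(5, 0)$b0  # moving average: rep(1/5, 5)
#' @export
sgSmoothingMatrix <- function(window, order) {
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and positive")
  M <- (window - 1L) %/% 2L
  if (order < 0L || order > M) stop("order must satisfy 0 <= order <= M")
  m <- seq(-M, M)
  S <- outer(m, 0:order, "^")
  G <- solve(crossprod(S))          # (S'S) is nonsingular for distinct m
  B <- S %*% G %*% t(S)
  list(B = B, b0 = B[, M + 1L], M = M, window = as.integer(window),
       order = as.integer(order))
}

#' Savitzky-Golay filtering of a signal
#'
#' Smooths a signal with a symmetric least-squares polynomial window. In
#' steady state each output sample is the centered response
#' `y(n) = sum_m b0(-m) x(n - m)`. In the input-on transient (first M
#' samples) and input-off transient (last M samples), where the moving
#' window would leave the signal, the output takes the least-squares fit
#' of the first (respectively last) full window evaluated at the boundary
#' positions, i.e. the correspondingly shifted rows of the projection
#' matrix. Every output sample therefore equals the value at its position
#' of the degree-d least-squares fit over its window, and polynomials of
#' degree <= d are reproduced exactly, transients included.
#'
#' @param x numeric signal of length L >= window.
#' @param window odd window length.
#' @param order polynomial order.
#' @return Smoothed signal of length L.
#' @examples
#' savitzkyGolay(3 * (1:50) + 2, window = 11, order = 1)  # the ramp itself
#' @export
savitzkyGolay <- function(x, window = 449L, order = 1L) {
  L <- length(x)
  if (L < window)
    stop(sprintf("signal length %d shorter than window %d", L, window))
  sg <- sgSmoothingMatrix(window, order)
  M <- sg$M; N <- sg$window
  y <- numeric(L)
  # steady state via centered convolution (b0 is symmetric)
  y <- stats::filter(x, sg$b0, method = "convolution", sides = 2)
  y <- as.numeric(y)
  if (M > 0) {
    y[seq_len(M)] <- as.numeric(sg$B[seq_len(M), , drop = FALSE] %*% x[seq_len(N)])
    y[(L - M + 1L):L] <-
      as.numeric(sg$B[(M + 2L):N, , drop = FALSE] %*% x[(L - N + 1L):L])
  }
  y
}
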