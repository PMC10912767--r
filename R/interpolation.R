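#' Trainable input interpolation layer
#'
#' Elementwise contrast/interpolation transform applied to an image batch
#' before the convolutional stem:
#' \deqn{\hat X = -2 e^{-2X^2}\left[\cos(90\omega_1) + X \sin(90\omega_2)\right]}
#' with the angles \eqn{90\omega} read in degrees, so that
#' \eqn{\omega \in [-1, 1]} spans a quarter period. The two weights are
#' trainable scalars learned jointly with the network; at
#' \eqn{\omega = (0, 0)} the transform reduces to \eqn{-2 e^{-2X^2}}.
#'
#' @param batch numeric array of pixel values in `[0, 1]` (any shape; the
#'   canonical layout is `(batch, height, width, channel)`).
#' @param omega1,omega2 interpolation weights in `[-1, 1]`.
#' @return array of the same shape; finite for finite input.
#' @seealso [minmaxRescale()] which maps the result onto `[-1, 1]`.
#' @examples
#' interpolateInput(0, 0, 0)      # -2
#' interpolateInput(1, 0, 0)      # -2 * exp(-2)
#' @export
interpolateInput <- function(batch, omega1 = 0, omega2 = 0) {
  if (!all(is.finite(batch)))
    stop("interpolateInput: batch contains non-finite values")
  if (abs(omega1) > 1 || abs(omega2) > 1)
    stop("interpolateInput: omega weights must lie in [-1, 1]")
  deg <- pi / 180
  out <- -2 * exp(-2 * batch^2) *
    (cos(90 * omega1 * deg) + batch * sin(90 * omega2 * deg))
  out
}

#' Min-max feature scaling to [-1, 1]
#'
#' Rescales a batch linearly so its minimum maps to -1 and its maximum to
#' +1, using the global batch minimum and maximum:
#' \deqn{\tilde X = 2 (\hat X - \min \hat X) / (\max \hat X - \min \hat X) - 1.}
#' A constant batch (max equals min) is returned as all zeros with a
#' warning rather than producing NaN.
#'
#' @param batch finite numeric array.
#' @return array of the same shape with range exactly `[-1, 1]` for any
#'   non-constant input.
#' @export
minmaxRescale <- function(batch) {
  if (!all(is.finite(batch)))
    stop("minmaxRescale: batch contains non-finite values")
  lo <- min(batch); hi <- max(batch)
  if (hi == lo) {
    warning("minmaxRescale: constant batch; returning zeros")
    return(batch * 0)
  }
  2 * (batch - lo) / (hi - lo) - 1
}

## gradient of Eq. 1 w.r.t. the omega weights (used by the trainer);
## min/max of the rescale step are treated as constants (stop-gradient).
interpGrad <- function(batch, omega1, omega2, upstream, scale) {
  deg <- pi / 180
  e <- -2 * exp(-2 * batch^2)
  d1 <- sum(upstream * e * (-sin(90 * omega1 * deg)) * 90 * deg) * scale
  d2 <- sum(upstream * e * batch * cos(90 * omega2 * deg) * 90 * deg) * scale
  c(d1, d2)
}
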