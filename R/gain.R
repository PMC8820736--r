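#' Rectified power-law gain
#'
#' The supralinear input-output function `[z]_+^alpha`: zero for
#' non-positive input current, `z^alpha` otherwise. Vectorized over `z`.
#'
#' @param z Input current (any real).
#' @param alpha Exponent (> 0).
#' @return Firing rate(s), same length as `z`.
#' @examples
#' powerlaw_gain(-3, 2)   # 0 (rectified)
#' powerlaw_gain(2, 2)    # 4
#' @export
powerlaw_gain <- function(z, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  ifelse(z > 0, z^alpha, 0)
}

# Derivative of the power-law gain expressed through the rate:
# d[z]_+^alpha/dz = alpha * [z]_+^(alpha-1) = alpha * r^((alpha-1)/alpha).
# At r = 0 the factor vanishes for alpha > 1 (one-sided convention at the
# rectification corner), equals one for alpha = 1.
gain_slope <- function(r, alpha) {
  out <- numeric(length(r))
  pos <- r > 0
  out[pos] <- alpha * r[pos]^((alpha - 1) / alpha)
  if (any(!pos)) out[!pos] <- if (alpha > 1) 0 else if (alpha == 1) 1 else Inf
  out
}
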