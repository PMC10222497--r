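#' Pearson correlation between observed and calculated endpoints
#'
#' Thin wrapper over the product-moment coefficient that turns the
#' degenerate case (either series constant) into an explicit error, so the
#' optimizer can treat it as an always-rejected move.
#'
#' @param observed,calculated Numeric vectors of equal length (>= 2).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(observed, calculated) {
  x <- as.numeric(observed); y <- as.numeric(calculated)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 points")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: constant series")
  stats::cor(x, y)
}

#' Sign-split mean absolute errors of the residuals
#'
#' Residuals are Delta_k = observed_k - calculated_k.  Strictly negative
#' residuals feed the "-" subset, non-negative ones (including exact zeros)
#' the "+" subset; each subset's mean absolute error is reported together
#' with its count.  An empty subset has MAE 0 and count 0.
#'
#' @param observed Binary endpoint values (0/1).
#' @param calculated Fitted values on the same compounds.
#' @return List of class \code{"residual_split"} with \code{mae_neg},
#'   \code{mae_pos}, \code{n_neg}, \code{n_pos}.
#' @export
residual_split <- function(observed, calculated) {
  d <- as.numeric(observed) - as.numeric(calculated)
  if (length(d) < 1L) stop("need at least 1 residual")
  neg <- d < 0
  structure(list(
    mae_neg = if (any(neg)) mean(abs(d[neg])) else 0,
    mae_pos = if (any(!neg)) mean(d[!neg]) else 0,
    n_neg = sum(neg),
    n_pos = sum(!neg)), class = "residual_split")
}

#' Index of ideality of correlation (IIC)
#'
#' Pearson r between observed and calculated, scaled by the ratio of the
#' smaller to the larger of the two sign-split mean absolute errors.  The
#' ratio lies in \[0, 1\], so |IIC| <= |r| always; it rewards fits whose
#' positive and negative residuals are balanced in magnitude ("ideal"
#' correlations).  A perfect fit (both MAEs 0) returns r itself; if exactly
#' one residual subset is empty the ratio is 0 and IIC is 0.
#'
#' @inheritParams residual_split
#' @return IIC value in \[-1, 1\].
#' @export
iic <- function(observed, calculated) {
  r <- pearson_r(observed, calculated)
  rs <- residual_split(observed, calculated)
  lo <- min(rs$mae_neg, rs$mae_pos)
  hi <- max(rs$mae_neg, rs$mae_pos)
  if (hi == 0) return(r)
  r * lo / hi
}

#' Target function TF0 (training-set correlation balance)
#'
#' Sum of the active- and passive-training correlation coefficients minus a
#' small penalty on their gap: \code{r_at + r_pt - |r_at - r_pt| * penalty}.
#' The penalty discourages weights that fit the active training set at the
#' passive set's expense.
#'
#' @param r_at,r_pt Correlation coefficients for the active and passive
#'   training sets.
#' @param penalty Gap penalty factor, default 0.1.
#' @return TF0 value.
#' @export
tf0 <- function(r_at, r_pt, penalty = 0.1) {
  r_at + r_pt - abs(r_at - r_pt) * penalty
}

#' Target function TF1 (TF0 plus calibration IIC)
#'
#' \code{tf0_value + weight * iic_c}: augments TF0 with the index of
#' ideality of correlation computed on the calibration set, steering the
#' optimization toward models that generalise past the training sets.
#'
#' @param tf0_value A TF0 value.
#' @param iic_c Calibration-set IIC.
#' @param weight IIC weight, default 0.5.
#' @return TF1 value.
#' @export
tf1 <- function(tf0_value, iic_c, weight = 0.5) {
  tf0_value + weight * iic_c
}
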