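#' Average absolute relative deviation (AARD)
#'
#' AARD (%) = 100/NDP * sum |D12_calc - D12_exp| / D12_exp.
#' The standard figure of merit for diffusion-coefficient correlations and
#' the fitting objective of this package.
#'
#' @param calc Calculated D12 values, cm^2/s.
#' @param exp_ Experimental D12 values, cm^2/s, all > 0.
#' @return AARD in percent.
#' @export
#' @examples
#' aard(c(1.1, 0.9), c(1, 1))  # 10
aard <- function(calc, exp_) {
  if (length(calc) == 0L) stop("empty input: AARD undefined", call. = FALSE)
  if (length(calc) != length(exp_)) stop("calc and exp_ lengths differ", call. = FALSE)
  if (any(exp_ <= 0)) stop("experimental D12 must be > 0", call. = FALSE)
  100 * mean(abs(calc - exp_) / exp_)
}

#' Average relative deviation (ARD, signed)
#'
#' ARD (%) = 100/NDP * sum (D12_calc - D12_exp) / D12_exp. The sign is kept,
#' so ARD measures bias: a negative value means systematic underprediction.
#' Always |ARD| <= AARD.
#'
#' @inheritParams aard
#' @return ARD in percent (signed).
#' @export
#' @examples
#' ard(c(1.1, 0.9), c(1, 1))  # 0
ard <- function(calc, exp_) {
  if (length(calc) == 0L) stop("empty input: ARD undefined", call. = FALSE)
  if (length(calc) != length(exp_)) stop("calc and exp_ lengths differ", call. = FALSE)
  if (any(exp_ <= 0)) stop("experimental D12 must be > 0", call. = FALSE)
  100 * mean((calc - exp_) / exp_)
}
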