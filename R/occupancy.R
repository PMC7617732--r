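#' Equilibrium Langmuir occupancy
#'
#' Fraction of a displayed clone bound by a bait at equilibrium under the
#' single-site Langmuir law, `conc / (conc + kd)`. This is the binding law
#' the selection simulator uses to convert a latent dissociation constant
#' into a per-round retention probability: occupancy rises with bait
#' concentration and falls with Kd, so lowering the bait concentration in
#' successive sorts increases stringency for affinity.
#'
#' @param kd Dissociation constant in molar. Must be strictly positive.
#'   Vectorised; recycled against `conc`.
#' @param conc Free bait concentration in molar, `>= 0`. `Inf` is allowed and
#'   returns 1, the saturation limit (useful for modelling certain capture or
#'   certain depletion).
#'
#' @return Numeric vector of bound fractions in `[0, 1]`.
#'
#' @examples
#' occupancy(kd = 1e-9, conc = 1e-9) # half saturation, 0.5
#' occupancy(kd = 1e-9, conc = 9e-9) # 0.9
#' occupancy(kd = 1e-9, conc = 0)    # 0
#' @export
occupancy <- function(kd, conc) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    abort("`kd` must be finite and strictly positive (molar).")
  }
  if (any(is.na(conc)) || any(conc < 0)) {
    abort("`conc` must be nonnegative (molar).")
  }
  theta <- conc / (conc + kd)
  theta[is.infinite(conc)] <- 1
  theta
}
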