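# Network Auto-Reduction: the compound (depth x width x resolution)
# reduction transform and the input-reduction baseline.

#' Compound scaling coefficients
#'
#' Holds the per-dimension bases `alpha` (depth), `beta` (width), `gamma`
#' (resolution) and the shared exponent `phi`. Reduction factors are their
#' negative powers: `d = alpha^-phi`, `w = beta^-phi`, `r = gamma^-phi`.
#' Balanced coefficients keep `alpha * beta^2 * gamma^2` close to 2 so that
#' one unit of `phi` roughly halves the FLOPs of the network. The defaults
#' are the grid-searched values for the lymphocyte-classification task.
#'
#' @param alpha,beta,gamma Scaling bases, each > 1 (or exactly 1).
#' @param phi Non-negative exponent; integers 0-6 in practice, any
#'   non-negative real accepted.
#' @return A `nar_scaling` object.
#' @examples
#' scaling_coefficients(phi = 2)
#' @export
scaling_coefficients <- function(alpha = 1.2, beta = 1.1, gamma = 1.15, phi = 0) {
  if (any(c(alpha, beta, gamma) < 1)) stop("alpha, beta, gamma must be >= 1")
  if (phi < 0) stop("phi must be non-negative")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), phi = as.numeric(phi),
                 constraint = as.numeric(alpha * beta^2 * gamma^2)),
            class = "nar_scaling")
}

#' @export
print.nar_scaling <- function(x, ...) {
  f <- reduction_factors(x)
  cat(sprintf("<nar_scaling> alpha=%g beta=%g gamma=%g phi=%g  (d=%.4f w=%.4f r=%.4f, alpha*beta^2*gamma^2=%.4f)\n",
              x$alpha, x$beta, x$gamma, x$phi, f["d"], f["w"], f["r"], x$constraint))
  invisible(x)
}

#' Reduction factors
#'
#' @param coefficients A [scaling_coefficients()] object.
#' @return Named numeric vector `c(d, w, r)` with `d = alpha^-phi`,
#'   `w = beta^-phi`, `r = gamma^-phi`.
#' @examples
#' reduction_factors(scaling_coefficients(phi = 1))
#' @export
reduction_factors <- function(coefficients) {
  c(d = coefficients$alpha^-coefficients$phi,
    w = coefficients$beta^-coefficients$phi,
    r = coefficients$gamma^-coefficients$phi)
}

#' Scale an integer count
#'
#' Multiplies `n` by `factor` and rounds to the nearest integer with
#' ties-to-even, clamping the result to a minimum of 1. This rounding rule
#' reproduces every unambiguous repeat/width/input-size cell of the
#' published reduced-architecture tables (e.g. `3 * 1.2^-1 = 2.5 -> 2`,
#' `256 * 1.1^-2 = 211.6 -> 212`, `240 * 1.15^-3 = 157.8 -> 158`).
#'
#' @param n Count(s) >= 1.
#' @param factor Scaling factor in (0, 1].
#' @return Scaled count(s), each >= 1.
#' @examples
#' scale_count(256, 1.1^-2)  # 212
#' scale_count(3, 1.2^-1)    # 2.5 rounds to even: 2
#' @export
scale_count <- function(n, factor) {
  if (any(n < 1)) stop("n must be >= 1")
  if (factor <= 0 || factor > 1) stop("factor must be in (0, 1]")
  pmax(1, round_half_even(n * factor))
}

#' Compound reduction of a network
#'
#' Applies the depth factor to every depth-scalable stage's repeat count,
#' the width factor to every stage's base width (per-layer ratios
#' preserved, so a 1:1:4 bottleneck stays 1:1:4), and the resolution factor
#' to the input height and width. Stems, transitions, heads, fixed-width
#' convolutions, input channels and the number of classes are untouched.
#' The original network is not modified.
#'
#' @param net A `nar_network`.
#' @param coefficients A [scaling_coefficients()] object.
#' @return The reduced `nar_network`.
#' @examples
#' red <- compound_reduce(resnet50v2_template(240, 2), scaling_coefficients(phi = 1))
#' vapply(red$stages, function(s) s$repeats, numeric(1))  # 2 3 5 2
#' @export
compound_reduce <- function(net, coefficients) {
  issues <- validate_network(net)
  if (length(issues))
    stop("invalid network: ", paste(issues, collapse = "; "))
  if (coefficients$phi > 3 && identical(net$name, "resnet50v2"))
    warning("phi > 3 reduces this template to a nearly sequential network ",
            "with single-repeat stages")
  f <- reduction_factors(coefficients)
  out <- net
  for (k in seq_along(out$stages)) {
    st <- out$stages[[k]]
    if (st$depth_scalable) st$repeats <- scale_count(st$repeats, f[["d"]])
    st$base_width <- scale_count(st$base_width, f[["w"]])
    out$stages[[k]] <- st
  }
  if (coefficients$phi > 0) {
    out$input[1] <- max(net$min_input, scale_count(net$input[1], f[["r"]]))
    out$input[2] <- max(net$min_input, scale_count(net$input[2], f[["r"]]))
    out$name <- sprintf("%s_nar_phi%g", net$name, coefficients$phi)
  }
  out
}

#' Input-reduction baseline
#'
#' Shrinks only the input resolution by the factor `r = gamma^-phi`; the
#' architecture itself stays exactly the original.
#'
#' @param net A `nar_network`.
#' @param coefficients A [scaling_coefficients()] object.
#' @return A `nar_network` with reduced input.
#' @examples
#' ir <- input_reduce(resnet50v2_template(240, 2), scaling_coefficients(phi = 1))
#' ir$input  # 209 209 3
#' @export
input_reduce <- function(net, coefficients) {
  issues <- validate_network(net)
  if (length(issues))
    stop("invalid network: ", paste(issues, collapse = "; "))
  f <- reduction_factors(coefficients)
  side <- scale_count(net$input[1:2], f[["r"]])
  if (any(side < net$min_input))
    stop("reduced input ", side[1], "x", side[2],
         " is below the network minimum of ", net$min_input)
  out <- net
  out$input[1:2] <- side
  if (coefficients$phi > 0) out$name <- sprintf("%s_ir_phi%g", net$name, coefficients$phi)
  out
}

#' Check the balance constraint on scaling coefficients
#'
#' Balanced coefficients satisfy `alpha * beta^2 * gamma^2` approximately
#' equal to 2. The check warns rather than rejects: the default triple
#' (1.2, 1.1, 1.15) itself gives 1.9203.
#'
#' @param coefficients A [scaling_coefficients()] object.
#' @param tol Acceptable deviation from 2 (default 0.1).
#' @return List with `value` (`alpha * beta^2 * gamma^2`) and `ok`.
#' @examples
#' check_constraint(scaling_coefficients())  # value 1.9203, ok
#' @export
check_constraint <- function(coefficients, tol = 0.1) {
  value <- coefficients$alpha * coefficients$beta^2 * coefficients$gamma^2
  list(value = value, ok = abs(value - 2) <= tol)
}

#' Theoretical FLOPs reduction ratio
#'
#' Under exactly balanced coefficients the FLOPs of the reduced network
#' shrink by `2^-phi` before integer rounding.
#'
#' @param phi Non-negative exponent.
#' @return `2^-phi`.
#' @export
theoretical_ratio <- function(phi) {
  if (any(phi < 0)) stop("phi must be non-negative")
  2^-phi
}

#' Smallest phi meeting a FLOPs budget
#'
#' Enumerates integer `phi = 0, 1, ..., phi_max` and returns the smallest
#' exponent whose compound-reduced network costs at most `flops_budget`
#' total FLOPs.
#'
#' @param net A `nar_network`.
#' @param coefficients A [scaling_coefficients()] object (its `phi` is
#'   ignored).
#' @param flops_budget Positive FLOPs budget.
#' @param phi_max Largest exponent to try (default 6).
#' @return The selected integer `phi`.
#' @export
choose_phi_for_budget <- function(net, coefficients, flops_budget, phi_max = 6) {
  if (flops_budget <= 0) stop("flops_budget must be positive")
  last <- NA
  for (phi in 0:phi_max) {
    c_phi <- scaling_coefficients(coefficients$alpha, coefficients$beta,
                                  coefficients$gamma, phi)
    last <- cost_report(compound_reduce(net, c_phi))$total_flops
    if (last <= flops_budget) return(phi)
  }
  stop("budget of ", flops_budget, " FLOPs unattainable: cost at phi_max = ",
       phi_max, " is still ", last, " FLOPs")
}
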