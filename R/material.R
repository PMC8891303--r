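# Physical description of the releasing slab.

#' Slab material description
#'
#' The archetype setup: a homogeneous planar slab with constant diffusion
#' coefficient `D`, thickness `b` (possibly infinite), contact area `A`,
#' and a uniform initial volumetric concentration `c0` of the chemical
#' species. All internal computations use SI units.
#'
#' @param D Diffusion coefficient, m^2/s, > 0. Typical values: ~1e-10 for
#'   viscous liquid-like phases (gels), ~1e-12 to 1e-14 for plastics.
#' @param b Slab thickness, m, > 0; `Inf` for a semi-infinite medium.
#' @param A Contact area, m^2, > 0.
#' @param c0 Initial volumetric concentration, amount/m^3, >= 0. Released
#'   masses are often reported normalized by `A * c0` (units of length), so
#'   the defaults `A = 1`, `c0 = 1` give normalized output directly.
#' @return An object of class `slab_material`.
#' @examples
#' material(D = 1e-13, b = 1e-4)   # a 0.1 mm plastic slab
#' @export
material <- function(D, b = Inf, A = 1, c0 = 1) {
  if (!is.finite(D) || D <= 0) stop("D must be finite and > 0", call. = FALSE)
  if (is.na(b) || b <= 0) stop("b must be > 0 (Inf allowed)", call. = FALSE)
  if (!is.finite(A) || A <= 0) stop("A must be finite and > 0", call. = FALSE)
  if (!is.finite(c0) || c0 < 0) stop("c0 must be finite and >= 0", call. = FALSE)
  structure(list(D = D, b = b, A = A, c0 = c0), class = "slab_material")
}

#' @export
print.slab_material <- function(x, ...) {
  cat(sprintf("Slab material: D = %g m^2/s, b = %s, A = %g m^2, c0 = %g\n",
              x$D, if (is.infinite(x$b)) "infinite" else sprintf("%g m", x$b),
              x$A, x$c0))
  invisible(x)
}
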