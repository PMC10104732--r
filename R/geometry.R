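#' Idealised stenosed-vessel geometry
#'
#' Defines a straight cylindrical vessel of length `L` and baseline radius
#' `R0` carrying a single smooth focal stenosis. The radius profile along the
#' centerline arclength `s` is
#' \deqn{r(s) = R_0 \, (1 - d \, g(s)), \qquad
#'       g(s) = \exp\{-(s - s_0)^2 / (2 w^2)\},}
#' so the throat radius at `s = s0` is `R0 * (1 - d)` and the profile relaxes
#' to `R0` away from the lesion. `d` is the fractional diameter reduction
#' ("percent diameter stenosis" / 100) conventional in coronary angiography.
#'
#' @param L Vessel length in mm (> 0).
#' @param R0 Baseline lumen radius in mm (> 0). Clinically relevant vessels
#'   have diameters above 1.5 mm, i.e. `R0 > 0.75`.
#' @param d Stenosis severity, fractional diameter reduction at the throat,
#'   in `[0, 1)`. `d = 0` is a uniform tube.
#' @param s0 Stenosis center along the centerline in mm (default `L / 2`).
#' @param w Gaussian width (standard deviation) of the stenotic bump in mm.
#' @return An object of class `vessel_geometry`: a list with fields `L`,
#'   `R0`, `d`, `s0`, `w` and a `centerline` matrix (n x 3, mm) of points
#'   along the vessel axis (the z axis in phantom space).
#' @examples
#' geom <- vessel_geometry(L = 40, R0 = 2, d = 0.5)
#' vessel_radius(geom, c(0, geom$s0)) # R0 at inlet, R0/2 at the throat
#' @export
vessel_geometry <- function(L, R0, d = 0, s0 = L / 2, w = L / 10) {
  check_scalar(L, "L", positive = TRUE)
  check_scalar(R0, "R0", positive = TRUE)
  check_scalar(w, "w", positive = TRUE)
  check_scalar(s0, "s0")
  check_scalar(d, "d")
  if (d < 0 || d >= 1) abort("`d` must lie in [0, 1): a fractional diameter reduction.")
  s <- seq(0, L, length.out = max(2L, ceiling(L) + 1L))
  structure(
    list(
      L = L, R0 = R0, d = d, s0 = s0, w = w,
      centerline = cbind(x = 0, y = 0, z = s)
    ),
    class = "vessel_geometry"
  )
}

#' Evaluate the lumen radius profile of a vessel geometry
#'
#' @param geometry A [vessel_geometry()].
#' @param s Arclength positions along the centerline, mm.
#' @return Numeric vector of radii (mm), `R0 * (1 - d * g(s))`.
#' @export
vessel_radius <- function(geometry, s) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  g <- exp(-(s - geometry$s0)^2 / (2 * geometry$w^2))
  geometry$R0 * (1 - geometry$d * g)
}

#' Sample a vessel geometry into a radius-profile table
#'
#' @param geometry A [vessel_geometry()].
#' @param ds Station spacing along the centerline, mm.
#' @return A tibble with columns `s` (mm) and `r` (mm), suitable for
#'   [solve_steady_flow()].
#' @export
lumen_profile <- function(geometry, ds = 0.5) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  check_scalar(ds, "ds", positive = TRUE)
  s <- seq(0, geometry$L, by = ds)
  if (s[length(s)] < geometry$L) s <- c(s, geometry$L)
  tibble(s = s, r = vessel_radius(geometry, s))
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> L = %g mm, R0 = %g mm, d = %g (throat r = %g mm at s0 = %g mm, w = %g mm)\n",
    x$L, x$R0, x$d, x$R0 * (1 - x$d), x$s0, x$w
  ))
  invisible(x)
}
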