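#' The hinge angle (degrees)
#'
#' View zenith angle of 57.5 degrees, at which the projection coefficient of
#' the Campbell ellipsoidal leaf angle distribution is nearly independent of
#' leaf orientation, so the inversion coefficient for plant area index is
#' close to 1.1 regardless of canopy type.
#'
#' @export
HINGE_ANGLE <- 57.5

#' Ellipsoidal leaf angle distribution
#'
#' Campbell's one-parameter family of leaf-normal angle distributions. Leaf
#' normals are distributed like the surface normals of an oblate or prolate
#' spheroid with horizontal-to-vertical semi-axis ratio `x`. `x = 1` is the
#' spherical (isotropic) distribution; `x > 1` tends towards horizontal
#' leaves (planophile), `x < 1` towards vertical leaves (erectophile).
#'
#' The mean leaf-normal zenith angle is derived from `x` via Campbell's
#' approximation \eqn{\bar\alpha \approx 9.65 (3 + x)^{-1.65}} (radians) and
#' reported in degrees; it decreases strictly as `x` increases.
#'
#' @param x Ratio of horizontal to vertical semi-axes of the leaf-normal
#'   ellipsoid. Must be a single value greater than 0.
#' @return An object of class `ellipsoidal_lad`: a list with elements `x`
#'   and `mean_leaf_normal_zenith` (degrees).
#' @seealso [lad_from_mean_zenith()] for the inverse parameterization,
#'   [extinction_coefficient()], [projection_coefficient()].
#' @examples
#' ellipsoidal_lad(1)    # spherical
#' ellipsoidal_lad(3)$mean_leaf_normal_zenith  # more horizontal leaves
#' @export
ellipsoidal_lad <- function(x = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`x` must be a single finite number > 0", call. = FALSE)
  }
  structure(
    list(x = x, mean_leaf_normal_zenith = mean_leaf_zenith(x)),
    class = "ellipsoidal_lad"
  )
}

#' @export
print.ellipsoidal_lad <- function(x, ...) {
  cat(sprintf(
    "<ellipsoidal_lad> x = %.4g (mean leaf-normal zenith %.1f deg)\n",
    x$x, x$mean_leaf_normal_zenith
  ))
  invisible(x)
}

# Campbell (1990) approximation, radians in, degrees out
mean_leaf_zenith <- function(x) {
  9.65 * (3 + x)^(-1.65) * 180 / pi
}

#' Ellipsoidal LAD from a mean leaf-normal zenith angle
#'
#' Inverts the approximation \eqn{\bar\alpha \approx 9.65 (3+x)^{-1.65}}
#' to recover the axis ratio `x` from a mean leaf-normal zenith angle, the
#' parameterization used when distributions are described by their mean leaf
#' inclination.
#'
#' @param alpha_deg Mean leaf-normal zenith angle in degrees, in (0, 90).
#' @return An `ellipsoidal_lad` object.
#' @export
lad_from_mean_zenith <- function(alpha_deg) {
  if (!is.numeric(alpha_deg) || length(alpha_deg) != 1L ||
      alpha_deg <= 0 || alpha_deg >= 90) {
    stop("`alpha_deg` must be a single angle in (0, 90) degrees", call. = FALSE)
  }
  alpha <- alpha_deg * pi / 180
  x <- (alpha / 9.65)^(-1 / 1.65) - 3
  if (x <= 0) {
    stop("mean zenith angle too large for the ellipsoidal approximation",
         call. = FALSE)
  }
  ellipsoidal_lad(x)
}

lad_x <- function(lad) {
  if (inherits(lad, "ellipsoidal_lad")) return(lad$x)
  if (is.numeric(lad) && all(is.finite(lad)) && all(lad > 0)) return(lad)
  stop("`lad` must be an ellipsoidal_lad object or a positive numeric x",
       call. = FALSE)
}

check_zenith <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta < 0) || any(theta >= 90)) {
    stop("view zenith angle must be in [0, 90) degrees", call. = FALSE)
  }
  theta
}

#' Campbell extinction coefficient K
#'
#' Extinction coefficient of the ellipsoidal leaf angle distribution for a
#' beam at view zenith angle `theta`:
#' \deqn{K(\theta, x) = \frac{\sqrt{x^2 + \tan^2\theta}}
#'                          {x + 1.702\,(x + 1.12)^{-0.708}}}
#' K is the attenuation per unit cumulative plant area along the slant path;
#' the projection coefficient onto the horizontal is `G = K cos(theta)`.
#' Both arguments are vectorized (recycled).
#'
#' @param theta View zenith angle in degrees, in \[0, 90).
#' @param lad An [ellipsoidal_lad()] object, or the numeric axis ratio `x`.
#' @return Numeric K > 0.
#' @examples
#' extinction_coefficient(0, 1)              # ~0.5 at nadir, spherical
#' extinction_coefficient(HINGE_ANGLE, 1)    # ~0.93 at the hinge angle
#' @export
extinction_coefficient <- function(theta, lad = ellipsoidal_lad(1)) {
  theta <- check_zenith(theta)
  x <- lad_x(lad)
  t <- theta * pi / 180
  sqrt(x^2 + tan(t)^2) / (x + 1.702 * (x + 1.12)^(-0.708))
}

#' Projection coefficient G (the G-function)
#'
#' Mean projection of unit plant area onto a plane perpendicular to the view
#' direction, `G = K cos(theta)`, for the Campbell ellipsoidal leaf angle
#' distribution. G lies in (0, 1\] and, for the spherical distribution
#' (`x = 1`), is approximately 0.5 at every view angle. Curves of G against
#' `theta` for different `x` cross near the hinge angle of 57.5 degrees.
#'
#' @inheritParams extinction_coefficient
#' @return Numeric G in (0, 1\].
#' @examples
#' projection_coefficient(HINGE_ANGLE, 1)  # ~0.5
#' @export
projection_coefficient <- function(theta, lad = ellipsoidal_lad(1)) {
  extinction_coefficient(theta, lad) * cos(check_zenith(theta) * pi / 180)
}

#' Hinge-angle inversion coefficient
#'
#' The coefficient that converts log gap probability measured at the hinge
#' angle (57.5 degrees) into cumulative plant area index:
#' `cos(57.5)/G(57.5, x) = 1/K(57.5, x)`. For the spherical distribution it
#' evaluates to about 1.07, which rounds to the conventional 1.1; its spread
#' across realistic leaf angle distributions is small, which is what makes
#' the hinge angle attractive for inversion.
#'
#' @inheritParams extinction_coefficient
#' @return Numeric coefficient (dimensionless).
#' @examples
#' hinge_inverse_coefficient(1)  # 1.0745, rounds to 1.1
#' @export
hinge_inverse_coefficient <- function(lad = ellipsoidal_lad(1)) {
  1 / extinction_coefficient(HINGE_ANGLE, lad)
}

#' Family of projection-coefficient curves
#'
#' Evaluates G over a grid of view zenith angles and leaf angle distribution
#' axis ratios, ready for plotting the classic crossing of the curve family
#' near the hinge angle.
#'
#' @param theta View zenith angles in degrees (default 0 to 85 by 1).
#' @param x Axis ratios of the ellipsoidal LAD.
#' @return A tibble with columns `theta`, `x`, `mean_leaf_normal_zenith`,
#'   `G`.
#' @examples
#' curves <- lad_curve_family(x = c(0.5, 1, 2, 4))
#' @export
lad_curve_family <- function(theta = seq(0, 85, by = 1),
                             x = c(0.2, 0.5, 1, 2, 5)) {
  check_zenith(theta)
  lad_x(x)
  grid <- tidyr::expand_grid(theta = theta, x = x)
  dplyr::mutate(
    grid,
    mean_leaf_normal_zenith = mean_leaf_zenith(.data$x),
    G = projection_coefficient(.data$theta, .data$x)
  )
}

#' Plot the projection-coefficient curve family
#'
#' @param data A tibble from [lad_curve_family()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_lad_curves <- function(data, ...) {
  ggplot2::ggplot(
    data,
    ggplot2::aes(.data$theta, .data$G,
                 colour = factor(round(.data$mean_leaf_normal_zenith, 1)),
                 group = .data$x)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = HINGE_ANGLE, linetype = "dashed") +
    ggplot2::labs(
      x = "view zenith angle (deg)",
      y = "projection coefficient G",
      colour = "mean leaf-normal\nzenith (deg)"
    )
}
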