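#' Spherical-cap shape from volume and contact area
#'
#' A spreading cell is approximated as a spherical cap standing on its
#' contact disk. Given the cap volume V and the contact area Ac = pi a^2,
#' the cap height h is the unique positive root of the monotone cubic
#' h^3 + 3 a^2 h - 6 V / pi = 0, solved in closed form (hyperbolic-sine
#' solution of the depressed cubic; the discriminant is always positive so
#' exactly one real root exists). The total surface area is
#' Atot = Ac + pi (a^2 + h^2).
#'
#' @param V Cap volume(s), um^3, positive. Vectorised.
#' @param Ac Contact area(s), um^2, positive.
#' @return A list of class `cap_shape` with fields `V`, `Ac`, `a` (contact
#'   radius, um), `h` (cap height, um) and `Atot` (um^2).
#' @export
cap_from_volume_contact <- function(V, Ac) {
  if (any(V <= 0)) stop("cap_from_volume_contact: V must be positive",
                        call. = FALSE)
  if (any(Ac <= 0)) {
    stop("cap_from_volume_contact: Ac must be positive; use ",
         "sphere_area_from_volume() for the detached-sphere limit",
         call. = FALSE)
  }
  a <- sqrt(Ac / pi)
  pp <- 3 * a^2                       # cubic h^3 + pp*h - qq = 0, pp, qq > 0
  qq <- 6 * V / pi
  m <- 2 * sqrt(pp / 3)
  h <- m * sinh(asinh(3 * qq / (pp * m)) / 3)
  resid <- h^3 + pp * h - qq
  bad <- abs(resid) > 1e-12 * pmax(1, qq)
  if (any(bad)) {
    # bisection fallback; the closed form is accurate in practice but the
    # residual tolerance is part of the contract
    for (i in which(bad)) {
      h[i] <- stats::uniroot(function(x) x^3 + pp[i] * x - qq[i],
                             lower = 0, upper = qq[i]^(1 / 3) + 1,
                             tol = 1e-14)$root
    }
  }
  structure(list(V = V, Ac = Ac, a = a, h = h,
                 Atot = Ac + pi * (a^2 + h^2)),
            class = "cap_shape")
}

#' Volume of a spherical cap from contact radius and height
#'
#' @param a Contact radius (um).
#' @param h Cap height (um).
#' @return Volume (pi h / 6) (3 a^2 + h^2), um^3.
#' @export
cap_volume <- function(a, h) pi * h / 6 * (3 * a^2 + h^2)

#' Normalised area derivatives of the spherical cap
#'
#' The viscoelastic volume model needs how fast the total membrane area
#' changes when volume or contact area change. At fixed contact area,
#' dAtot/dV = 4 h / (a^2 + h^2); at fixed volume, dAtot/dAc =
#' 2 a^2 / (a^2 + h^2). Both are returned normalised by Atot:
#' f1 = (1/Atot) dAtot/dV (um^-3), so that xi * V_iso * f1 is dimensionless,
#' and f2 = (1/Atot) dAtot/dAc (um^-2).
#'
#' @param shape A `cap_shape` from [cap_from_volume_contact()].
#' @return List with `f1`, `f2` and the raw derivatives `dAtot_dV`,
#'   `dAtot_dAc`.
#' @export
cap_area_derivatives <- function(shape) {
  stopifnot(inherits(shape, "cap_shape"))
  denom <- shape$a^2 + shape$h^2
  if (any(shape$h <= 1e-9 * shape$a)) {
    stop("cap_area_derivatives: degenerate flat cap (h -> 0); derivatives ",
         "diverge", call. = FALSE)
  }
  dAtot_dV <- 4 * shape$h / denom
  dAtot_dAc <- 2 * shape$a^2 / denom
  list(f1 = dAtot_dV / shape$Atot,
       f2 = dAtot_dAc / shape$Atot,
       dAtot_dV = dAtot_dV,
       dAtot_dAc = dAtot_dAc)
}

#' Surface area of a sphere of given volume
#'
#' Used for non-adherent (detached) cells.
#'
#' @param V Volume (um^3), >= 0. Vectorised.
#' @return Area (36 pi)^(1/3) V^(2/3), um^2.
#' @export
sphere_area_from_volume <- function(V) {
  if (any(V < 0)) stop("sphere_area_from_volume: V must be >= 0",
                       call. = FALSE)
  (36 * pi)^(1 / 3) * V^(2 / 3)
}

#' Surface area of a cylinder of given volume and height
#'
#' Used for cells flattened under a confiner of known height.
#'
#' @param V Volume (um^3), positive.
#' @param height Cylinder height (um), positive.
#' @return Total area 2 pi r^2 + 2 pi r height with r = sqrt(V / (pi height)).
#' @export
cylinder_area_from_volume <- function(V, height) {
  if (any(V <= 0)) stop("cylinder_area_from_volume: V must be positive",
                        call. = FALSE)
  if (any(height <= 0)) {
    stop("cylinder_area_from_volume: height must be positive", call. = FALSE)
  }
  r <- sqrt(V / (pi * height))
  2 * pi * r^2 + 2 * pi * r * height
}

# Lean scalar kernel for the integrator hot loop: cap height, total area and
# normalised derivatives without validation or S3 allocation. Same closed
# form as cap_from_volume_contact()/cap_area_derivatives().
cap_coefs_fast <- function(V, Ac) {
  a2 <- Ac / pi
  pp <- 3 * a2
  qq <- 6 * V / pi
  m <- 2 * sqrt(a2)                      # 2*sqrt(pp/3)
  h <- m * sinh(asinh(3 * qq / (pp * m)) / 3)
  denom <- a2 + h * h
  Atot <- Ac + pi * denom
  c(h = h, Atot = Atot,
    f1 = 4 * h / (denom * Atot),
    f2 = 2 * a2 / (denom * Atot))
}

#' Membrane area excess at a given volume ratio, spherical assumption
#'
#' A swollen spherical cell that reaches `volume_ratio` times its initial
#' volume has unfolded volume_ratio^(2/3) times its initial apparent
#' surface area; applied to the rupture point of water-exposed cells.
#'
#' @param volume_ratio V_max / V_init, >= 1.
#' @return Area ratio volume_ratio^(2/3).
#' @export
rupture_area_ratio <- function(volume_ratio) {
  if (any(volume_ratio < 1)) {
    stop("rupture_area_ratio: volume_ratio must be >= 1", call. = FALSE)
  }
  volume_ratio^(2 / 3)
}
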