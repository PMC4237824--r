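#' Carotid vessel-wall phantom with an eccentric plaque
#'
#' Constructs a 2D digital phantom of a carotid artery cross-section: a
#' circular lumen, an annular vessel wall, and an eccentric plaque bulge on
#' the outer boundary. Per-pixel ground-truth Patlak parameters are assigned
#' (`ktrans_wall`, `vp_wall` in the wall; Ktrans = 0, vp = 1 in the lumen,
#' which therefore carries plasma concentration directly), along with
#' baseline T1 and signal-scale values used by the SPGR forward model.
#'
#' Geometry is defined in mm with the image origin at the grid corner and
#' pixel centers at \eqn{(j - 0.5, i - 0.5) \times} `pixel_size`; the vessel
#' is centered on the grid. Boundary polygons are returned in the same
#' coordinates and are consistent with the rasterized masks to within half a
#' pixel.
#'
#' @param protocol An [acq_protocol()]; supplies the pixel size.
#' @param lumen_radius Lumen radius in mm (> 0).
#' @param wall_thickness Baseline (plaque-free) wall thickness in mm (> 0).
#' @param plaque_bulge Additional outward wall thickness at the plaque apex,
#'   mm (>= 0).
#' @param ktrans_wall True transfer constant in the wall, 1/min.
#' @param vp_wall True fractional plasma volume in the wall (0..1).
#' @param grid_size Phantom grid side length in pixels; the grid is a
#'   vessel-centered crop of the full field of view.
#' @param plaque_angle Direction of the plaque apex, radians.
#' @param plaque_halfwidth Angular half-width of the plaque bulge, radians.
#' @param t10_wall,t10_blood Baseline longitudinal relaxation times, ms.
#' @param m0 Equilibrium signal scale (arbitrary units).
#' @param r1 Contrast agent relaxivity, L/(mmol s).
#' @param n_vertices Number of polygon vertices per contour.
#'
#' @return An object of class `vessel_phantom`: masks (`lumen_mask`,
#'   `wall_mask`), contour polygons in mm (`lumen_contour`,
#'   `outer_contour`), true parameter maps (`ktrans_true`, `vp_true`),
#'   relaxation maps (`t10`, scalar `m0`, `r1`), `pixel_size`, `grid_size`
#'   and `max_wall_thickness` (mm).
#' @export
#' @examples
#' ph <- build_phantom(acq_protocol("GE"), lumen_radius = 3,
#'                     wall_thickness = 1.5, plaque_bulge = 2)
#' ph$max_wall_thickness
build_phantom <- function(protocol,
                          lumen_radius = 3,
                          wall_thickness = 1.5,
                          plaque_bulge = 2,
                          ktrans_wall = 0.062,
                          vp_wall = 0.067,
                          grid_size = 48L,
                          plaque_angle = 0,
                          plaque_halfwidth = pi / 2,
                          t10_wall = 1000,
                          t10_blood = 1650,
                          m0 = 1000,
                          r1 = 4.5,
                          n_vertices = 180L) {
  validate_protocol(protocol)
  if (lumen_radius <= 0) stop("'lumen_radius' must be > 0")
  if (wall_thickness <= 0) stop("'wall_thickness' must be > 0")
  if (plaque_bulge < 0) stop("'plaque_bulge' must be >= 0")
  if (ktrans_wall < 0) stop("'ktrans_wall' must be >= 0")
  if (vp_wall < 0 || vp_wall > 1) stop("'vp_wall' must be in [0, 1]")

  px <- protocol$pixel_size
  half_extent <- grid_size * px / 2
  r_max <- lumen_radius + wall_thickness + plaque_bulge
  if (r_max >= half_extent)
    stop("vessel geometry (outer radius ", signif(r_max, 3),
         " mm) exceeds the field of view of the phantom grid")

  # Outward bump: raised cosine in angle, max 1 at plaque_angle.
  bump <- function(theta) {
    d <- atan2(sin(theta - plaque_angle), cos(theta - plaque_angle))
    ifelse(abs(d) < plaque_halfwidth, 0.5 * (1 + cos(pi * d / plaque_halfwidth)), 0)
  }
  outer_radius <- function(theta) lumen_radius + wall_thickness + plaque_bulge * bump(theta)

  ctr <- pixel_centers(grid_size, grid_size, px)
  cx <- half_extent
  cy <- half_extent
  dx <- ctr$x - cx
  dy <- ctr$y - cy
  r_pix <- sqrt(dx^2 + dy^2)
  th_pix <- atan2(dy, dx)
  lumen_mask <- r_pix <= lumen_radius
  wall_mask <- !lumen_mask & r_pix <= outer_radius(th_pix)

  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  lumen_contour <- cbind(x = cx + lumen_radius * cos(theta),
                         y = cy + lumen_radius * sin(theta))
  ro <- outer_radius(theta)
  outer_contour <- cbind(x = cx + ro * cos(theta), y = cy + ro * sin(theta))

  ktrans_true <- matrix(0, grid_size, grid_size)
  vp_true <- matrix(0, grid_size, grid_size)
  ktrans_true[wall_mask] <- ktrans_wall
  vp_true[wall_mask] <- vp_wall
  vp_true[lumen_mask] <- 1

  t10 <- matrix(t10_wall, grid_size, grid_size)
  t10[lumen_mask] <- t10_blood

  th_fine <- seq(0, 2 * pi, length.out = 2048L)
  max_wt <- max(outer_radius(th_fine) - lumen_radius)

  structure(list(
    lumen_mask = lumen_mask,
    wall_mask = wall_mask,
    lumen_contour = lumen_contour,
    outer_contour = outer_contour,
    ktrans_true = ktrans_true,
    vp_true = vp_true,
    t10 = t10,
    m0 = m0,
    r1 = r1,
    pixel_size = px,
    grid_size = as.integer(grid_size),
    lumen_radius = lumen_radius,
    max_wall_thickness = max_wt
  ), class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("Vessel phantom: %dx%d px (%.3f mm), lumen %d px, wall %d px, max wall thickness %.2f mm\n",
              x$grid_size, x$grid_size, x$pixel_size,
              sum(x$lumen_mask), sum(x$wall_mask), x$max_wall_thickness))
  invisible(x)
}
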