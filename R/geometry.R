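#' Mass-weighted centroid of a molecule
#'
#' The binding-cavity centre is defined as the weighted centre of mass of
#' all ligand atoms (hydrogens included when present):
#' \deqn{c = \left(\frac{\sum_i x_i m_i}{\sum_i m_i},
#'                \frac{\sum_i y_i m_i}{\sum_i m_i},
#'                \frac{\sum_i z_i m_i}{\sum_i m_i}\right)}
#'
#' @param mol a [molecule()].
#' @return named numeric vector `c(x =, y =, z =)` in Angstrom.
#' @export
centroid <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  m <- mol$atoms$mass
  total <- sum(m)
  if (!(total > 0)) stop("zero total mass", call. = FALSE)
  c(x = sum(mol$atoms$x * m),
    y = sum(mol$atoms$y * m),
    z = sum(mol$atoms$z * m)) / total
}

#' Cube side matching the volume of an inclusion sphere
#'
#' Docking engines that describe the binding site with a box rather than a
#' sphere need a comparable search volume; the cube side is scaled so the
#' cube's volume equals that of the sphere of radius `r`:
#' \eqn{l = (4\pi/3)^{1/3} r}, i.e. \eqn{l^3 = \frac{4}{3}\pi r^3}.
#'
#' @param r sphere radius in Angstrom, > 0.
#' @return cube side in Angstrom.
#' @examples
#' cube_side(20) # ~32.24 A for the default 20 A cavity radius
#' @export
cube_side <- function(r) {
  if (!is.numeric(r) || any(r <= 0) || anyNA(r))
    stop("radius must be positive", call. = FALSE)
  (4 * pi / 3)^(1 / 3) * r
}

#' Heavy-atom RMSD between two poses
#'
#' Root-mean-square deviation over heavy atoms paired by position:
#' \deqn{RMSD(a,b) = \sqrt{\frac{1}{n}\sum_{i=1}^{n}
#'   \left((a_{ix}-b_{ix})^2 + (a_{iy}-b_{iy})^2 +
#'   (a_{iz}-b_{iz})^2\right)}}
#'
#' No superposition is performed before the comparison (reference proteins
#' are assumed pre-aligned, so the pose and the crystallographic ligand
#' share a frame) and no graph-automorphism symmetry correction is applied:
#' atom i of `a` is compared with atom i of `b`. Hydrogens are excluded on
#' both sides. A pre-flight check requires the two heavy-atom element
#' sequences to be identical, since positional correspondence is otherwise
#' meaningless.
#'
#' @param a,b [molecule()]s with identical heavy-atom ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  stopifnot(inherits(a, "molecule"), inherits(b, "molecule"))
  ea <- a$atoms$element[a$atoms$is_heavy]
  eb <- b$atoms$element[b$atoms$is_heavy]
  if (length(ea) != length(eb))
    stop("correspondence error: heavy-atom counts differ (",
         length(ea), " vs ", length(eb), ")", call. = FALSE)
  if (!all(ea == eb))
    stop("correspondence error: heavy-atom element sequences differ",
         call. = FALSE)
  d <- coords(a, heavy_only = TRUE) - coords(b, heavy_only = TRUE)
  sqrt(mean(rowSums(d * d)))
}

#' Binding-cavity definition from a reference ligand
#'
#' Centres the search cavity on the ligand's mass-weighted centroid and
#' carries the sphere radius, the volume-matched cube side for box-based
#' engines, and the grid spacing for grid-based ones.
#'
#' @param ligand the reference [molecule()].
#' @param r inclusion-sphere radius in Angstrom (default 20).
#' @param grid_spacing grid spacing in Angstrom for grid-based engines
#'   (default 0.375).
#' @return object of class `cavity_definition` with fields `centroid`,
#'   `radius`, `cube_side`, `grid_spacing`.
#' @export
build_cavity <- function(ligand, r = 20, grid_spacing = 0.375) {
  if (!is.numeric(grid_spacing) || grid_spacing <= 0)
    stop("grid_spacing must be positive", call. = FALSE)
  structure(
    list(centroid = centroid(ligand), radius = r, cube_side = cube_side(r),
         grid_spacing = grid_spacing),
    class = "cavity_definition"
  )
}

#' @export
print.cavity_definition <- function(x, ...) {
  cat(sprintf(
    "<cavity> centre (%.3f, %.3f, %.3f) A, r = %g A, cube side = %.4f A, grid %g A\n",
    x$centroid[["x"]], x$centroid[["y"]], x$centroid[["z"]],
    x$radius, x$cube_side, x$grid_spacing))
  invisible(x)
}
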