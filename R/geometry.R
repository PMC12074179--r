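#' Build a triangulated biplanar coil surface pair
#'
#' Constructs two square planar triangle meshes of side \code{plane_size},
#' centered on the z-axis at z = +/- \code{separation}/2.  The z-axis is
#' normal to the coil planes, y is vertical and x in-plane.  Each plane is a
#' regular \code{resolution} x \code{resolution} vertex grid, every grid cell
#' split into two triangles; all faces are oriented counter-clockwise when
#' viewed from +z so the surface normal convention is +z for both planes.
#'
#' @param plane_size side length of each square plane (m).
#' @param separation distance between the two planes (m).
#' @param resolution number of vertices per edge (>= 4).  The default 33
#'   gives 2 x 32^2 = 2048 triangles per plane; the center-field computation
#'   changes by well under 1\% on refinement to 41 (see the package vignette).
#' @return an object of class \code{biplanar_mesh} with elements
#'   \code{vertices} (m x 3), \code{faces} (t x 3 vertex indices),
#'   \code{plane_side} (per-vertex +1 / -1), \code{boundary} (per-vertex
#'   logical), \code{plane_size}, \code{separation}, \code{resolution}.
#' @examples
#' mesh <- build_biplanar_mesh(1.4, 1.4, resolution = 9)
#' mesh_area(mesh)  # ~ 2 * 1.4^2
#' @export
build_biplanar_mesh <- function(plane_size, separation, resolution = 33) {
  if (!is.numeric(plane_size) || length(plane_size) != 1 || plane_size <= 0)
    .stop_geometry("plane_size must be a positive number")
  if (!is.numeric(separation) || length(separation) != 1 || separation <= 0)
    .stop_geometry("separation must be a positive number")
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 4)
    .stop_geometry("resolution must be an integer >= 4")

  n <- resolution
  xs <- seq(-plane_size / 2, plane_size / 2, length.out = n)
  grid <- expand.grid(x = xs, y = xs, KEEP.OUT.ATTRS = FALSE)  # x fastest
  nv <- n * n

  # Faces for one plane (CCW viewed from +z).
  ix <- rep(seq_len(n - 1), n - 1)
  iy <- rep(seq_len(n - 1), each = n - 1)
  v00 <- (iy - 1L) * n + ix
  v10 <- v00 + 1L
  v01 <- v00 + n
  v11 <- v01 + 1L
  faces1 <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  vertices <- rbind(
    cbind(grid$x, grid$y, rep(separation / 2, nv)),
    cbind(grid$x, grid$y, rep(-separation / 2, nv))
  )
  faces <- rbind(faces1, faces1 + nv)
  dimnames(faces) <- NULL

  on_edge <- grid$x %in% xs[c(1, n)] | grid$y %in% xs[c(1, n)]
  structure(
    list(
      vertices = vertices,
      faces = faces,
      plane_side = rep(c(1L, -1L), each = nv),
      boundary = rep(on_edge, 2L),
      plane_size = plane_size,
      separation = separation,
      resolution = n
    ),
    class = "biplanar_mesh"
  )
}

#' @export
print.biplanar_mesh <- function(x, ...) {
  cat(sprintf(
    "Biplanar coil mesh: %.3g x %.3g m planes at z = +/- %.3g m\n",
    x$plane_size, x$plane_size, x$separation / 2
  ))
  cat(sprintf(
    "  %d vertices, %d triangles (%d per plane), resolution %d\n",
    nrow(x$vertices), nrow(x$faces), nrow(x$faces) / 2L, x$resolution
  ))
  invisible(x)
}

#' Total surface area of a triangle mesh
#'
#' @param mesh a \code{biplanar_mesh} or any list with \code{vertices} and
#'   \code{faces}.
#' @return total area (m^2).
#' @export
mesh_area <- function(mesh) {
  sum(triangle_areas(mesh$vertices, mesh$faces))
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangle_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  n / sqrt(rowSums(n^2))
}

#' Sample points inside a spherical target region
#'
#' Draws points uniformly inside a sphere; the first point is always the
#' center.  Deterministic for a fixed seed; the caller's random-number state
#' is left untouched.
#'
#' @param n_points number of points (>= 1).
#' @param radius sphere radius (m); default 0.25 m (the 50 cm diameter
#'   target sphere between the coil planes).
#' @param center sphere center, length-3 (m).
#' @param seed integer seed.
#' @return an \code{n_points} x 3 matrix of coordinates.
#' @export
sample_target_sphere <- function(n_points, radius = 0.25,
                                 center = c(0, 0, 0), seed = 0L) {
  if (n_points < 1) .stop_geometry("n_points must be >= 1")
  if (radius < 0) .stop_geometry("radius must be >= 0")
  pts <- matrix(rep(center, each = n_points), n_points, 3)
  if (n_points > 1) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    m <- n_points - 1
    dir <- matrix(stats::rnorm(3 * m), m, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- radius * stats::runif(m)^(1 / 3)
    pts[-1, ] <- pts[-1, , drop = FALSE] + dir * r
  }
  pts
}

#' Quasi-uniform points on a sphere surface (Fibonacci spiral)
#'
#' Deterministic point set used to place target-field constraints on the
#' surface of the target sphere.
#'
#' @param n number of surface points.
#' @inheritParams sample_target_sphere
#' @return an \code{n} x 3 matrix.
#' @export
sphere_surface_points <- function(n, radius = 0.25, center = c(0, 0, 0)) {
  if (n < 1) .stop_geometry("n must be >= 1")
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  p <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  sweep(p, 2, center, "+")
}

#' Probe points along a coordinate axis through the coil center
#'
#' Reproduces the measurement grid used for gradient-coil efficiency:
#' points spaced \code{step} apart between \code{start} and \code{stop}
#' along one axis, the other two coordinates zero.
#'
#' @param axis one of \code{"x"}, \code{"y"}, \code{"z"}.
#' @param start,stop range along the axis (m), \code{stop > start}.
#' @param step spacing (m), > 0.
#' @return an ordered k x 3 matrix of points.
#' @examples
#' axis_probe_line("z", -0.15, 0.15, 0.05)  # the 7-point z line
#' @export
axis_probe_line <- function(axis = c("z", "x", "y"), start = -0.15,
                            stop = 0.15, step = 0.05) {
  axis <- match.arg(axis)
  if (!(stop > start)) .stop_geometry("empty probe range: stop must be > start")
  if (step <= 0) .stop_geometry("step must be > 0")
  s <- seq(start, stop, by = step)
  pts <- matrix(0, length(s), 3)
  pts[, match(axis, c("x", "y", "z"))] <- s
  pts
}

#' Export a mesh as Wavefront OBJ (vertices and faces only)
#'
#' @param mesh a mesh with \code{vertices} and \code{faces}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_obj <- function(mesh, path) {
  v <- sprintf("v %.9g %.9g %.9g",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d",
               mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c("# opmnull mesh", v, f), path)
  invisible(path)
}

#' Read a Wavefront OBJ mesh (vertices and triangular faces only)
#'
#' @param path file path.
#' @return a list with \code{vertices} and \code{faces}.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(tok)
    as.integer(sub("/.*", "", tok[2:4]))))
  list(vertices = vertices, faces = faces)
}
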