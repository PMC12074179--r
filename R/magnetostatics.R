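# Magnetostatic kernels for piecewise-linear stream functions on triangle
# meshes and for polyline current loops.  Conventions: the stream function s
# (amperes, one value per vertex) is equivalent to a magnetic dipole sheet of
# surface density s * n_hat, i.e. surface current density K = grad(s) x n_hat.
# With n_hat = +z the current runs anticlockwise (viewed from +z) around
# maxima of s.  The scalar potential U is the H-field potential (B = -mu0
# grad U in current-free regions); a closed loop of current I subtends
# U = I * Omega / (4 pi) with Omega the solid angle.

# Biot-Savart contributions of line segments (p1 -> p2, unit current) at a
# single point.  Returns an S x 3 matrix.  Well-conditioned two-endpoint
# formula; segments closer than `clearance` raise a singular-evaluation
# error.
segment_fields_at <- function(p, p1, p2, clearance = 1e-9) {
  ax <- p1[, 1] - p[1]; ay <- p1[, 2] - p[2]; az <- p1[, 3] - p[3]
  bx <- p2[, 1] - p[1]; by <- p2[, 2] - p[2]; bz <- p2[, 3] - p[3]
  na <- sqrt(ax^2 + ay^2 + az^2)
  nb <- sqrt(bx^2 + by^2 + bz^2)
  cx <- ay * bz - az * by
  cy <- az * bx - ax * bz
  cz <- ax * by - ay * bx
  dot <- ax * bx + ay * by + az * bz
  denom <- na * nb * (na * nb + dot)
  # distance from p to each segment (for the singularity guard)
  lx <- p2[, 1] - p1[, 1]; ly <- p2[, 2] - p1[, 2]; lz <- p2[, 3] - p1[, 3]
  ll <- lx^2 + ly^2 + lz^2
  t <- pmin(1, pmax(0, -(ax * lx + ay * ly + az * lz) / pmax(ll, 1e-300)))
  dx <- ax + t * lx; dy <- ay + t * ly; dz <- az + t * lz
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(dist < clearance))
    stop("singular evaluation: observation point lies on (or within ",
         clearance, " m of) a current segment", call. = FALSE)
  f <- 1e-7 * (na + nb) / denom  # mu0 / 4pi = 1e-7
  f[ll == 0] <- 0                # degenerate zero-length segments
  cbind(cx * f, cy * f, cz * f)
}

face_edge_endpoints <- function(vertices, faces) {
  list(
    p1 = rbind(vertices[faces[, 1], , drop = FALSE],
               vertices[faces[, 2], , drop = FALSE],
               vertices[faces[, 3], , drop = FALSE]),
    p2 = rbind(vertices[faces[, 2], , drop = FALSE],
               vertices[faces[, 3], , drop = FALSE],
               vertices[faces[, 1], , drop = FALSE])
  )
}

# Sparse map from vertex values to per-triangle mean values (T x V).
triangle_mean_map <- function(faces, n_vertices) {
  t_ <- nrow(faces)
  Matrix::sparseMatrix(
    i = rep(seq_len(t_), 3L),
    j = as.vector(faces),
    x = rep(1 / 3, 3L * t_),
    dims = c(t_, n_vertices)
  )
}

#' Magnetic-field coupling matrix of a stream-function surface
#'
#' Builds the linear map A from per-vertex stream-function values s (amperes)
#' to the magnetic field B (teslas, three components) at a set of evaluation
#' points.  The piecewise-linear stream function is represented by its
#' per-triangle mean value, i.e. each triangle carries a closed boundary line
#' current equal to that mean; summing the exact segment Biot-Savart fields
#' of these triangle loops gives the field.  Edge currents of neighbouring
#' triangles largely cancel, leaving the discrete rotated-gradient current.
#'
#' @param mesh a \code{biplanar_mesh} (or any mesh list with \code{vertices}
#'   and \code{faces}).
#' @param points k x 3 matrix of evaluation points (m); must keep at least
#'   \code{clearance} distance from the surface.
#' @param clearance minimum allowed point-to-surface distance (m).
#' @return object of class \code{coupling_matrix}: list with \code{matrix}
#'   ((3k) x V, units T/A, rows interleaved x,y,z per point), \code{points},
#'   \code{layout = "xyz"}, \code{units}.
#' @export
field_coupling <- function(mesh, points, clearance = 1e-3) {
  points <- as_points(points)
  ep <- face_edge_endpoints(mesh$vertices, mesh$faces)
  t_ <- nrow(mesh$faces)
  k <- nrow(points)
  tri <- matrix(0, 3L * k, t_)
  for (i in seq_len(k)) {
    bf <- segment_fields_at(points[i, ], ep$p1, ep$p2, clearance)
    rows <- (3L * (i - 1L) + 1L):(3L * i)
    # the three edge blocks of each triangle are stacked; sum them
    tri[rows, ] <- t(bf[seq_len(t_), ] +
                     bf[t_ + seq_len(t_), ] +
                     bf[2L * t_ + seq_len(t_), ])
  }
  m <- as.matrix(tri %*% triangle_mean_map(mesh$faces, nrow(mesh$vertices)))
  structure(
    list(matrix = m, points = points, layout = "xyz", units = "T/A"),
    class = "coupling_matrix"
  )
}

#' Apply a field coupling matrix to stream-function values
#'
#' @param coupling a \code{coupling_matrix} from \code{\link{field_coupling}}.
#' @param s per-vertex stream-function values (A) or a
#'   \code{stream_function}.
#' @return k x 3 matrix of B (T) at the coupling's points.
#' @export
field_of_stream <- function(coupling, s) {
  b <- coupling$matrix %*% as.numeric(unclass(s))
  matrix(b, ncol = 3, byrow = TRUE, dimnames = list(NULL, c("Bx", "By", "Bz")))
}

#' Magnetic scalar-potential coupling matrix of a stream-function surface
#'
#' Returns the map from per-vertex stream-function values (A) to the magnetic
#' scalar potential U (A) at evaluation points, using the dipole-sheet
#' representation U(p) = (1/4pi) int s n.(p-r)/|p-r|^3 dA with a three-point
#' (edge midpoint) quadrature per triangle, exact for quadratic integrands.
#' In current-free regions B = -mu0 grad U.
#'
#' @inheritParams field_coupling
#' @return object of class \code{coupling_matrix} with \code{matrix} (k x V,
#'   units A per A of stream function).
#' @export
potential_coupling <- function(mesh, points, clearance = 1e-3) {
  points <- as_points(points)
  v <- mesh$vertices
  f <- mesh$faces
  t_ <- nrow(f)
  areas <- triangle_areas(v, f)
  normals <- triangle_normals(v, f)
  # quadrature nodes: the three edge midpoints of each triangle
  mids <- rbind(
    (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE]) / 2,
    (v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 2,
    (v[f[, 3], , drop = FALSE] + v[f[, 1], , drop = FALSE]) / 2
  )
  w <- rep(areas / 3, 3L)            # quadrature weight per node
  nq <- rbind(normals, normals, normals)
  # node values: mean of the two edge vertices
  q <- 3L * t_
  mmap <- Matrix::sparseMatrix(
    i = rep(seq_len(q), 2L),
    j = c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1]),
    x = rep(0.5, 2L * q),
    dims = c(q, nrow(v))
  )
  k <- nrow(points)
  out <- matrix(0, k, nrow(v))
  chunk <- max(1L, floor(2e6 / q))
  for (start in seq(1L, k, by = chunk)) {
    idx <- start:min(k, start + chunk - 1L)
    coeff <- matrix(0, length(idx), q)
    for (jj in seq_along(idx)) {
      p <- points[idx[jj], ]
      rx <- p[1] - mids[, 1]; ry <- p[2] - mids[, 2]; rz <- p[3] - mids[, 3]
      r2 <- rx^2 + ry^2 + rz^2
      if (min(r2) < clearance^2)
        stop("singular evaluation: point within ", clearance,
             " m of the surface", call. = FALSE)
      ndr <- nq[, 1] * rx + nq[, 2] * ry + nq[, 3] * rz
      coeff[jj, ] <- w * ndr / (4 * pi * r2^1.5)
    }
    out[idx, ] <- as.matrix(coeff %*% mmap)
  }
  structure(
    list(matrix = out, points = points, layout = "scalar", units = "A/A"),
    class = "coupling_matrix"
  )
}

#' Resistance matrix of a conducting surface
#'
#' Quadratic form R such that t(s) %*% R %*% s equals the ohmic power
#' dissipated by the surface current of stream function s at unit drive,
#' P = (rho/t) * integral |grad s|^2 dA.  This is the finite-element
#' stiffness matrix scaled by the sheet resistance rho/thickness: symmetric,
#' positive semi-definite, with per-plane constant vectors in its null space.
#'
#' @param mesh a \code{biplanar_mesh}.
#' @param resistivity conductor resistivity (Ohm m); default annealed copper.
#' @param thickness conductor thickness (m); default 70 um (2 oz copper).
#' @return object of class \code{resistance_matrix}: list with \code{matrix}
#'   (V x V, ohms), \code{sheet_resistance} (Ohm/square).
#' @export
resistance_matrix <- function(mesh, resistivity = 1.72e-8, thickness = 70e-6) {
  if (resistivity <= 0 || thickness <= 0)
    stop("resistivity and thickness must be > 0", call. = FALSE)
  v <- mesh$vertices
  f <- mesh$faces
  t_ <- nrow(f)
  areas <- triangle_areas(v, f)
  normals <- triangle_normals(v, f)
  nv <- nrow(v)
  # hat-function gradients: grad psi_i = n x (v_k - v_j) / (2A)
  grads <- vector("list", 3L)
  for (i in 1:3) {
    j <- i %% 3L + 1L
    k <- j %% 3L + 1L
    e <- v[f[, k], , drop = FALSE] - v[f[, j], , drop = FALSE]
    g <- cbind(
      normals[, 2] * e[, 3] - normals[, 3] * e[, 2],
      normals[, 3] * e[, 1] - normals[, 1] * e[, 3],
      normals[, 1] * e[, 2] - normals[, 2] * e[, 1]
    ) / (2 * areas)
    grads[[i]] <- g
  }
  ii <- jj <- xx <- vector("list", 9L)
  idx <- 1L
  for (i in 1:3) for (j in 1:3) {
    ii[[idx]] <- f[, i]
    jj[[idx]] <- f[, j]
    xx[[idx]] <- areas * rowSums(grads[[i]] * grads[[j]])
    idx <- idx + 1L
  }
  K <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(nv, nv)
  )
  sheet <- resistivity / thickness
  structure(
    list(matrix = as.matrix(K) * sheet, sheet_resistance = sheet,
         resistivity = resistivity, thickness = thickness),
    class = "resistance_matrix"
  )
}

#' Power dissipated by a stream function
#'
#' @param R a \code{resistance_matrix}.
#' @param s per-vertex stream-function values (A).
#' @return dissipated power (W) at unit drive.
#' @export
dissipated_power <- function(R, s) {
  s <- as.numeric(unclass(s))
  drop(crossprod(s, R$matrix %*% s))
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

close_loop <- function(loop, tol = 1e-9) {
  if (sqrt(sum((loop[1, ] - loop[nrow(loop), ])^2)) > tol)
    stop("loop is not closed (first and last points differ by more than ",
         tol, " m)", call. = FALSE)
  loop
}

#' Magnetic field of polyline current loops
#'
#' Exact line-segment Biot-Savart sum over a set of closed polyline loops
#' all carrying the same (series) current.  Loop traversal order defines the
#' current direction.
#'
#' @param loops a \code{discrete_coil} (see \code{\link{discretize}}) or a
#'   list of closed k x 3 polylines (first point equal to last within 1e-9 m).
#' @param current drive current (A).
#' @param points evaluation points (k x 3, m).
#' @param clearance singular-evaluation guard distance (m).
#' @return k x 3 matrix of B (T).
#' @export
polyline_field <- function(loops, current, points, clearance = 1e-9) {
  points <- as_points(points)
  loops <- coil_loop_list(loops)
  out <- matrix(0, nrow(points), 3,
                dimnames = list(NULL, c("Bx", "By", "Bz")))
  if (current == 0 || length(loops) == 0) return(out)
  p1 <- do.call(rbind, lapply(loops, function(l) {
    l <- close_loop(as_points(l))
    l[-nrow(l), , drop = FALSE]
  }))
  p2 <- do.call(rbind, lapply(loops, function(l) {
    l <- close_loop(as_points(l))
    l[-1, , drop = FALSE]
  }))
  for (i in seq_len(nrow(points))) {
    bf <- segment_fields_at(points[i, ], p1, p2, clearance)
    out[i, ] <- current * colSums(bf)
  }
  out
}

#' Magnetic scalar potential of polyline current loops
#'
#' Computes U(p) = I * Omega(p) / (4 pi) where Omega is the signed solid
#' angle subtended by each closed loop, evaluated by fan-triangulating the
#' loop about its centroid and summing Van Oosterom-Strackee triangle solid
#' angles.  Exact for planar loops; consistent with the dipole-sheet
#' convention of \code{\link{potential_coupling}}.
#'
#' @inheritParams polyline_field
#' @return length-k vector of U (A).
#' @export
polyline_potential <- function(loops, current, points, clearance = 1e-9) {
  points <- as_points(points)
  loops <- coil_loop_list(loops)
  total <- numeric(nrow(points))
  if (current == 0 || length(loops) == 0) return(total)
  for (l in loops) {
    l <- close_loop(as_points(l))
    cen <- colMeans(l[-nrow(l), , drop = FALSE])
    a <- l[-nrow(l), , drop = FALSE]
    b <- l[-1, , drop = FALSE]
    for (i in seq_len(nrow(points))) {
      p <- points[i, ]
      A <- sweep(a, 2, p)
      B <- sweep(b, 2, p)
      C <- matrix(cen - p, nrow(A), 3, byrow = TRUE)
      la <- sqrt(rowSums(A^2)); lb <- sqrt(rowSums(B^2))
      lc <- sqrt(sum((cen - p)^2))
      if (min(la, lb, lc) < clearance)
        stop("singular evaluation: point on loop", call. = FALSE)
      det3 <- A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) -
              A[, 2] * (B[, 1] * C[, 3] - B[, 3] * C[, 1]) +
              A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])
      den <- la * lb * lc + rowSums(A * B) * lc +
             rowSums(A * C) * lb + rowSums(B * C) * la
      total[i] <- total[i] - sum(2 * atan2(det3, den))
    }
  }
  current * total / (4 * pi)
}

#' Persist a coupling or resistance matrix to a binary container
#'
#' Simple versioned binary layout: magic "OPMNMTX1", format version, matrix
#' dimensions, a units string and the column-major doubles.
#'
#' @param m a matrix, \code{coupling_matrix} or \code{resistance_matrix}.
#' @param path output path.
#' @param units units tag stored with the matrix.
#' @return \code{path}, invisibly.
#' @export
write_matrix_bin <- function(m, path, units = NULL) {
  if (inherits(m, c("coupling_matrix", "resistance_matrix"))) {
    if (is.null(units)) units <- if (!is.null(m$units)) m$units else "Ohm"
    m <- m$matrix
  }
  if (is.null(units)) units <- ""
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("OPMNMTX1"), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(nrow(m), ncol(m)), con, size = 4, endian = "little")
  u <- charToRaw(units)
  writeBin(length(u), con, size = 4, endian = "little")
  writeBin(u, con)
  writeBin(as.numeric(m), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_matrix_bin
#' @return for \code{read_matrix_bin}: a list with \code{matrix} and
#'   \code{units}.
#' @export
read_matrix_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (magic != "OPMNMTX1") stop("not an opmnull matrix container", call. = FALSE)
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ver != 1L) stop("unsupported matrix container version: ", ver,
                      call. = FALSE)
  d <- readBin(con, "integer", 2, size = 4, endian = "little")
  ulen <- readBin(con, "integer", 1, size = 4, endian = "little")
  units <- if (ulen > 0) rawToChar(readBin(con, "raw", ulen)) else ""
  x <- readBin(con, "numeric", d[1] * d[2], size = 8, endian = "little")
  list(matrix = matrix(x, d[1], d[2]), units = units)
}
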