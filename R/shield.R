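# Field distortion by high-permeability (mu-metal) surfaces.  The shield is
# modeled as an infinite-permeability material: its inner surface is an
# equipotential of the magnetic scalar potential, enforced by an equivalent
# stream function s_shield on the shield mesh satisfying
#   C_U^coil s_coil = - C_U^shield s_shield
# at collocation points on the shield, after which the total field is
#   B = C_B^coil s_coil + C_B^shield s_shield.

#' Build a flat rectangular shield panel mesh
#'
#' @param center panel center (length-3, m).
#' @param normal panel normal (length-3); should point toward the coil
#'   region, i.e. toward the side on which the equipotential condition is
#'   collocated.
#' @param half_extent half side length (m), scalar (square) or length-2.
#' @param resolution vertices per edge.
#' @return a mesh list (\code{vertices}, \code{faces}, \code{normal}) of
#'   class \code{shield_panel}; faces are oriented so triangle normals equal
#'   \code{normal}.
#' @export
shield_panel <- function(center, normal, half_extent, resolution = 33) {
  if (length(half_extent) == 1) half_extent <- rep(half_extent, 2)
  resolution <- as.integer(resolution)
  if (resolution < 4) .stop_geometry("resolution must be >= 4")
  n <- normal / sqrt(sum(normal^2))
  # in-plane frame with u x v = n
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  m <- resolution
  us <- seq(-half_extent[1], half_extent[1], length.out = m)
  vs <- seq(-half_extent[2], half_extent[2], length.out = m)
  grid <- expand.grid(a = us, b = vs, KEEP.OUT.ATTRS = FALSE)
  vertices <- matrix(center, nrow(grid), 3, byrow = TRUE) +
    outer(grid$a, u) + outer(grid$b, v)
  ix <- rep(seq_len(m - 1), m - 1)
  iy <- rep(seq_len(m - 1), each = m - 1)
  v00 <- (iy - 1L) * m + ix
  v10 <- v00 + 1L
  v01 <- v00 + m
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, normal = n,
                 center = center, half_extent = half_extent,
                 resolution = m),
            class = "shield_panel")
}

combine_panels <- function(panels) {
  offs <- 0L
  vs <- list(); fs <- list()
  for (p in panels) {
    vs[[length(vs) + 1L]] <- p$vertices
    fs[[length(fs) + 1L]] <- p$faces + offs
    offs <- offs + nrow(p$vertices)
  }
  list(vertices = do.call(rbind, vs), faces = do.call(rbind, fs))
}

#' Assemble a shielded coil system
#'
#' Precomputes the scalar-potential coupling matrices and the shield
#' response operator.  The equipotential condition is collocated at the
#' shield mesh vertices, on the side each panel's normal points to; because
#' each panel is flat, the panel's own dipole sheet contributes exactly
#' s/2 there (the in-plane principal value vanishes), giving a
#' well-conditioned diagonal self-term.  The shield solve uses a truncated
#' pseudo-inverse with relative singular-value cutoff \code{sv_cutoff}.
#'
#' @param coil_mesh the \code{biplanar_mesh} carrying the coil stream
#'   function (used for stream-function sources; discrete coils supply
#'   their own potentials at solve time).
#' @param panels a list of \code{\link{shield_panel}}s (mu-metal surfaces).
#' @param sv_cutoff relative singular-value cutoff for the shield solve.
#' @return object of class \code{shield_system} with the coupling matrices,
#'   the response operator mapping coil-vertex stream values to shield
#'   stream values, and the shield operator's \code{condition} number.
#' @export
shield_system <- function(coil_mesh, panels, sv_cutoff = 1e-8) {
  if (inherits(panels, "shield_panel")) panels <- list(panels)
  if (length(panels) == 0) stop("no shield panels given", call. = FALSE)
  nvert <- vapply(panels, function(p) nrow(p$vertices), 0L)
  total <- sum(nvert)
  CUs <- matrix(0, total, total)
  starts <- cumsum(c(0L, nvert))
  for (i in seq_along(panels)) {
    ri <- starts[i] + seq_len(nvert[i])
    for (j in seq_along(panels)) {
      cj <- starts[j] + seq_len(nvert[j])
      if (i == j) {
        CUs[ri, cj] <- diag(0.5, nvert[i])
      } else {
        CUs[ri, cj] <- potential_coupling(panels[[j]],
                                          panels[[i]]$vertices,
                                          clearance = 1e-6)$matrix
      }
    }
  }
  sv <- svd(CUs)
  keep <- sv$d > sv_cutoff * sv$d[1]
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  shield_points <- do.call(rbind, lapply(panels, `[[`, "vertices"))
  CU_coil <- potential_coupling(coil_mesh, shield_points)$matrix
  structure(
    list(
      coil_mesh = coil_mesh,
      panels = panels,
      shield_mesh = combine_panels(panels),
      shield_points = shield_points,
      CU_shield = CUs,
      CU_shield_pinv = pinv,
      CU_coil = CU_coil,
      response = -pinv %*% CU_coil,
      condition = sv$d[1] / min(sv$d[sv$d > 0]),
      sv_cutoff = sv_cutoff
    ),
    class = "shield_system"
  )
}

#' @export
print.shield_system <- function(x, ...) {
  cat(sprintf(
    "Infinite-permeability shield: %d panel(s), %d collocation points\n",
    length(x$panels), nrow(x$shield_points)))
  cat(sprintf("  equipotential operator condition number %.3g (cutoff %.1g)\n",
              x$condition, x$sv_cutoff))
  invisible(x)
}

#' Equivalent shield stream function induced by a coil
#'
#' Solves the equipotential boundary condition
#' C_U^coil s_coil = -C_U^shield s_shield for the shield's equivalent
#' stream function.
#'
#' @param system a \code{\link{shield_system}}.
#' @param s_coil coil source: a \code{stream_function} on the system's coil
#'   mesh, or a \code{discrete_coil} / list of closed loops (then
#'   \code{current} applies).
#' @param current drive current (A) when \code{s_coil} is a discrete coil.
#' @return numeric vector of shield stream values (A), one per shield mesh
#'   vertex.
#' @export
solve_shield_response <- function(system, s_coil, current = 1) {
  u_coil <- shield_source_potential(system, s_coil, current)
  drop(-system$CU_shield_pinv %*% u_coil)
}

shield_source_potential <- function(system, s_coil, current = 1) {
  if (inherits(s_coil, "stream_function")) {
    drop(system$CU_coil %*% as.numeric(s_coil))
  } else {
    polyline_potential(s_coil, current, system$shield_points)
  }
}

shield_source_field <- function(system, s_coil, current, points) {
  if (inherits(s_coil, "stream_function")) {
    field_of_stream(field_coupling(system$coil_mesh, points),
                    as.numeric(s_coil))
  } else {
    polyline_field(s_coil, current, points)
  }
}

#' Total magnetic field with the shield present
#'
#' B = C_B^coil s_coil + C_B^shield s_shield: the free-space field of the
#' source plus the field of the shield's equivalent stream function.
#'
#' @inheritParams solve_shield_response
#' @param points evaluation points (k x 3, m).
#' @return k x 3 matrix of B (T).
#' @export
shielded_field <- function(system, s_coil, points, current = 1) {
  points <- as_points(points)
  direct <- shield_source_field(system, s_coil, current, points)
  s_sh <- solve_shield_response(system, s_coil, current)
  CBs <- field_coupling(system$shield_mesh, points)
  direct + field_of_stream(CBs, s_sh)
}

#' Coil efficiency in the presence of a shield
#'
#' Same definition as \code{\link{coil_efficiency}} but evaluated with
#' \code{\link{shielded_field}}; reported beside the free-space value in
#' coil property tables.  Passing \code{system = NULL} returns the
#' free-space efficiency.
#'
#' @param coil a \code{discrete_coil} (or list of closed loops).
#' @param system a \code{\link{shield_system}}, or \code{NULL} for free
#'   space.
#' @inheritParams coil_efficiency
#' @return efficiency in nT/mA (uniform kinds) or nT/m/mA (gradient kinds).
#' @export
shielded_efficiency <- function(coil, system, kind, probe = NULL,
                                mode = c("direct", "sweep"),
                                currents = NULL) {
  kind <- match.arg(kind, COIL_KINDS)
  mode <- match.arg(mode)
  if (is.null(system)) return(coil_efficiency(coil, kind, probe, mode, currents))
  gradient <- kind_is_gradient(kind)
  if (is.null(probe)) {
    probe <- if (gradient) axis_probe_line("z", -0.15, 0.15, 0.05)
             else matrix(0, 1, 3)
  }
  probe <- as_points(probe)
  # the shield response is linear in the drive: precompute per unit current
  s_sh_unit <- solve_shield_response(system, coil, current = 1)
  CBs <- field_coupling(system$shield_mesh, probe)
  b_sh_unit <- field_of_stream(CBs, s_sh_unit)
  field_at <- function(current)
    polyline_field(coil, current, probe) + current * b_sh_unit
  efficiency_engine(field_at, kind, probe, mode, currents)
}
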