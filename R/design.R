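# Target-field specification, stream-function optimization, contour
# discretization into N turns, and coil efficiency.

COIL_KINDS <- c("Bx", "By", "Bz", "Gxz", "Gyz", "Gzz")

kind_component <- function(kind) {
  switch(kind, Bx = 1L, Gxz = 1L, By = 2L, Gyz = 2L, Bz = 3L, Gzz = 3L,
         stop("unknown coil kind: ", kind, call. = FALSE))
}

kind_is_gradient <- function(kind) startsWith(kind, "G")

#' Construct a target-field specification
#'
#' Uniform kinds (Bx, By, Bz) ask for a constant field in the named
#' component and zero in the others at every target point.  Gradient kinds
#' (Gxz = dBx/dz, Gyz = dBy/dz, Gzz = dBz/dz) ask for the named component to
#' vary linearly along z with the given slope, zero at the target center,
#' and zero in the other components.
#'
#' @param kind one of \code{"Bx"}, \code{"By"}, \code{"Bz"}, \code{"Gxz"},
#'   \code{"Gyz"}, \code{"Gzz"}.
#' @param amplitude target amplitude: T for uniform kinds, T/m for gradient
#'   kinds; must be nonzero.
#' @param points k x 3 matrix of target points (m).
#' @param center target-region center (m); gradients are zero there.
#' @return object of class \code{target_spec} with the desired field matrix
#'   \code{b} (k x 3, T).
#' @export
make_target <- function(kind, amplitude, points, center = c(0, 0, 0)) {
  kind <- match.arg(kind, COIL_KINDS)
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude == 0)
    stop("amplitude must be a single nonzero number", call. = FALSE)
  points <- as_points(points)
  b <- matrix(0, nrow(points), 3, dimnames = list(NULL, c("Bx", "By", "Bz")))
  comp <- kind_component(kind)
  if (kind_is_gradient(kind)) {
    b[, comp] <- amplitude * (points[, 3] - center[3])
  } else {
    b[, comp] <- amplitude
  }
  structure(
    list(kind = kind, amplitude = amplitude, points = points, b = b,
         center = center),
    class = "target_spec"
  )
}

#' Stream function on a biplanar mesh
#'
#' A per-vertex scalar current function (amperes).  Boundary vertices must
#' carry value zero: the surface current K = grad(s) x n is then confined to
#' the planes and no current crosses the plane edges.
#'
#' @param values numeric vector, one value per mesh vertex.
#' @param mesh the \code{biplanar_mesh} the values live on.
#' @param tol tolerance for the boundary-zero check (A).
#' @return a \code{stream_function} (numeric vector with the mesh attached).
#' @export
stream_function <- function(values, mesh, tol = 1e-12) {
  if (length(values) != nrow(mesh$vertices))
    stop("stream function needs one value per vertex", call. = FALSE)
  if (any(abs(values[mesh$boundary]) > tol))
    stop("stream function must vanish on boundary vertices", call. = FALSE)
  structure(as.numeric(values), mesh = mesh, class = "stream_function")
}

#' @export
print.stream_function <- function(x, ...) {
  cat(sprintf("Stream function on %d vertices; range [%.4g, %.4g] A\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Minimum-dissipation stream function for a target field
#'
#' Solves the regularized quadratic program
#' \deqn{\hat s = \arg\min_s \tfrac12 s^T R s + \lambda \|b - A s\|^2}
#' over interior vertices (boundary vertices are eliminated at zero), i.e.
#' the normal equations (R + 2 lambda A^T A) s = 2 lambda A^T b, where the
#' misfit term runs over the coil's named field component at the target
#' points (see the note in the implementation: constraining the other
#' components to zero is unphysical for gradient coils and redundant for
#' uniform ones).  The implementation factorizes R once (Cholesky), takes
#' the SVD of A R^{-1/2}, and then obtains the solution and the relative
#' residual in closed form for any lambda; when \code{lambda} is
#' \code{NULL} the value achieving relative residual \code{residual} on the
#' named component is found by a monotone root search (the residual is
#' strictly decreasing in lambda).
#'
#' @param R a \code{resistance_matrix} for the mesh.
#' @param A a \code{coupling_matrix} from \code{\link{field_coupling}} whose
#'   points carry the target.
#' @param target a \code{target_spec}; its points must match \code{A}.
#' @param lambda fixed regularization parameter, or \code{NULL} to choose it
#'   from \code{residual}.
#' @param residual target relative L2 residual on the target points
#'   (default 2\%), used when \code{lambda} is \code{NULL}.
#' @param mesh the \code{biplanar_mesh} (for the boundary pattern).
#' @return object of class \code{design_solution}: \code{s}
#'   (\code{stream_function}), \code{lambda}, \code{residual} (achieved,
#'   relative), \code{objective}, \code{achieved} (k x 3 fields, T).
#' @export
optimize_stream_function <- function(R, A, target, lambda = NULL,
                                     residual = 0.02, mesh) {
  if (is.null(lambda) && (residual <= 0 || residual >= 1))
    stop("residual must be in (0, 1)", call. = FALSE)
  interior <- !mesh$boundary
  Ai <- A$matrix[, interior, drop = FALSE]
  Ri <- R$matrix[interior, interior]
  bvec_full <- as.numeric(t(target$b))  # matches the xyz row interleaving
  # The fit constrains only the coil's named component.  For gradient coils
  # anything else is unphysical (div B = 0 forces transverse fields on a
  # dBz/dz coil, so zero off-target components are unattainable and only
  # drive lambda to a wild interpolating solution); for uniform coils the
  # transverse components vanish by symmetry anyway.  The residual is the
  # relative L2 misfit of that component over the target points.
  keep <- rep(1:3, nrow(target$b)) == kind_component(target$kind)
  Ai_fit <- Ai[keep, , drop = FALSE]
  bvec <- bvec_full[keep]
  bnorm <- sqrt(sum(bvec^2))

  U <- tryCatch(chol(Ri), error = function(e)
    stop("numerical conditioning error: resistance matrix not positive ",
         "definite after boundary elimination (", conditionMessage(e), ")",
         call. = FALSE))
  if (bnorm == 0) {
    s <- stream_function(numeric(nrow(mesh$vertices)), mesh)
    return(structure(
      list(s = s, lambda = if (is.null(lambda)) 0 else lambda, residual = 0,
           objective = 0, achieved = matrix(0, nrow(target$b), 3)),
      class = "design_solution"
    ))
  }
  # Z = A R^{-1/2}: solve t(U) %*% X = t(Ai)
  Z <- t(forwardsolve(t(U), t(Ai_fit)))
  sv <- svd(Z)
  bt <- drop(crossprod(sv$u, bvec))
  bperp2 <- max(0, sum(bvec^2) - sum(bt^2))
  d2 <- sv$d^2

  rel_res <- function(lam)
    sqrt((sum(bt^2 / (1 + 2 * lam * d2)^2) + bperp2)) / bnorm

  if (is.null(lambda)) {
    res_inf <- sqrt(sum(bt[d2 < max(d2) * 1e-28]^2) + bperp2) / bnorm
    if (res_inf >= residual)
      stop("numerical conditioning error: requested residual ",
           residual, " unreachable (limit ", signif(res_inf, 3), ")",
           call. = FALSE)
    f <- function(t) rel_res(10^t) - residual
    lo <- -20; hi <- 30
    while (f(hi) > 0 && hi < 60) hi <- hi + 10
    while (f(lo) < 0 && lo > -60) lo <- lo - 10
    lambda <- 10^stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  shrink <- 2 * lambda * sv$d / (1 + 2 * lambda * d2)
  u_t <- sv$v %*% (shrink * bt)
  s_int <- backsolve(U, u_t)
  values <- numeric(nrow(mesh$vertices))
  values[interior] <- s_int
  s <- stream_function(values, mesh)
  achieved <- matrix(Ai %*% s_int, ncol = 3, byrow = TRUE,
                     dimnames = list(NULL, c("Bx", "By", "Bz")))
  res_vec <- bvec - (Ai_fit %*% s_int)
  structure(
    list(
      s = s,
      lambda = lambda,
      residual = sqrt(sum(res_vec^2)) / bnorm,
      objective = 0.5 * sum(u_t^2) + lambda * sum(res_vec^2),
      achieved = achieved
    ),
    class = "design_solution"
  )
}

#' @export
print.design_solution <- function(x, ...) {
  cat(sprintf(
    "Stream-function design: lambda = %.4g, relative residual = %.3g%%\n",
    x$lambda, 100 * x$residual
  ))
  invisible(x)
}

# bilinear interpolation of per-plane grid values at (x, y)
grid_interp <- function(xs, z, x, y) {
  n <- length(xs)
  ix <- pmin(pmax(findInterval(x, xs), 1L), n - 1L)
  iy <- pmin(pmax(findInterval(y, xs), 1L), n - 1L)
  tx <- (x - xs[ix]) / (xs[ix + 1L] - xs[ix])
  ty <- (y - xs[iy]) / (xs[iy + 1L] - xs[iy])
  z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    z[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    z[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    z[cbind(ix + 1L, iy + 1L)] * tx * ty
}

polygon_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Discretize a stream function into N current loops
#'
#' Extracts iso-contours of the stream function at N levels placed by the
#' midpoint rule over the signed symmetric range [-max|s|, +max|s|] of the
#' joint (two-plane) stream function: levels at -max|s| + (k - 1/2) *
#' 2 max|s| / N, so no contour sits at an extremum or at zero (for even N).
#' Each contour level carries the same current increment 2 max|s| / N;
#' levels falling outside a plane's local range simply produce no loop
#' there, which is what makes the turn count of symmetric uniform-field
#' pairs come out right.  Each contour becomes a closed planar loop,
#' oriented along the physical current direction (higher stream function to
#' the left of travel); polarity +1 marks anticlockwise loops viewed from
#' +z.  Loops are sorted outermost first (by enclosed area, ties by
#' centroid).
#'
#' @param solution a \code{design_solution} or \code{stream_function}.
#' @param N number of contour levels (turns), >= 2.
#' @return object of class \code{discrete_coil}: \code{loops} (each with
#'   \code{vertices} closed k x 3, \code{polarity}, \code{level},
#'   \code{plane} (+1/-1), \code{area}), \code{turns}, and the
#'   \code{level_step} (A): driving the discrete coil with current
#'   \code{level_step} reproduces the continuous solution's field.
#' @export
discretize <- function(solution, N = 30) {
  N <- as.integer(N)
  if (is.na(N) || N < 2) stop("N must be an integer >= 2", call. = FALSE)
  s <- if (inherits(solution, "design_solution")) solution$s else solution
  if (!inherits(s, "stream_function"))
    stop("solution must be a design_solution or stream_function",
         call. = FALSE)
  mesh <- attr(s, "mesh")
  n <- mesh$resolution
  nv <- n * n
  xs <- seq(-mesh$plane_size / 2, mesh$plane_size / 2, length.out = n)
  values <- as.numeric(s)
  smax <- max(abs(values))
  if (smax == 0 || diff(range(values)) <= smax * 1e-9)
    stop("degenerate stream function: constant values cannot be discretized",
         call. = FALSE)
  step <- 2 * smax / N
  all_levels <- -smax + (seq_len(N) - 0.5) * step

  loops <- list()
  eps <- 0.05 * min(diff(xs))
  for (side in c(1L, -1L)) {
    idx <- if (side == 1L) seq_len(nv) else nv + seq_len(nv)
    z <- matrix(values[idx], n, n)   # z[ix, iy]
    rng <- range(z)
    levels <- all_levels[all_levels > rng[1] & all_levels < rng[2]]
    if (length(levels) == 0) next  # inert plane
    cl <- grDevices::contourLines(xs, xs, z, levels = levels)
    zpos <- side * mesh$separation / 2
    for (cont in cl) {
      cx <- cont$x; cy <- cont$y
      closed <- abs(cx[1] - cx[length(cx)]) < 1e-12 &&
                abs(cy[1] - cy[length(cy)]) < 1e-12
      if (!closed) {
        on_edge <- function(v) min(abs(v - xs[1]), abs(v - xs[n])) < 1e-9
        if ((on_edge(cx[1]) || on_edge(cy[1])) &&
            (on_edge(cx[length(cx)]) || on_edge(cy[length(cy)])))
          stop("contour level ", signif(cont$level, 6),
               " intersects the mesh boundary; stream function does not ",
               "vanish there", call. = FALSE)
        cx <- c(cx, cx[1]); cy <- c(cy, cy[1])
      }
      # orient along the current: higher s on the left of travel
      mx <- (cx[1] + cx[2]) / 2; my <- (cy[1] + cy[2]) / 2
      dx <- cx[2] - cx[1]; dy <- cy[2] - cy[1]
      dl <- sqrt(dx^2 + dy^2)
      lx <- -dy / dl; ly <- dx / dl   # left normal
      s_left <- grid_interp(xs, z, mx + eps * lx, my + eps * ly)
      s_right <- grid_interp(xs, z, mx - eps * lx, my - eps * ly)
      if (s_left < s_right) {
        cx <- rev(cx); cy <- rev(cy)
      }
      area <- polygon_signed_area(cx[-length(cx)], cy[-length(cy)])
      loops[[length(loops) + 1L]] <- list(
        vertices = cbind(cx, cy, rep(zpos, length(cx)), deparse.level = 0),
        polarity = if (area > 0) 1L else -1L,
        level = cont$level,
        plane = side,
        area = abs(area)
      )
    }
  }
  if (length(loops) == 0)
    stop("degenerate stream function: no contours found", call. = FALSE)
  ord <- order(
    -vapply(loops, `[[`, 0, "area"),
    vapply(loops, function(l) mean(l$vertices[, 1]), 0),
    vapply(loops, function(l) mean(l$vertices[, 2]), 0)
  )
  structure(
    list(loops = loops[ord], turns = N, level_step = step,
         plane_size = mesh$plane_size, separation = mesh$separation),
    class = "discrete_coil"
  )
}

coil_loop_list <- function(x) {
  if (inherits(x, "discrete_coil")) lapply(x$loops, `[[`, "vertices")
  else if (is.list(x)) x
  else stop("expected a discrete_coil or list of loops", call. = FALSE)
}

#' @export
print.discrete_coil <- function(x, ...) {
  pol <- vapply(x$loops, `[[`, 0L, "polarity")
  pl <- vapply(x$loops, `[[`, 0L, "plane")
  cat(sprintf("Discrete coil: %d loops (%d contour levels)\n",
              length(x$loops), x$turns))
  for (side in c(1L, -1L)) {
    sel <- pl == side
    if (!any(sel)) next
    cat(sprintf("  plane z = %+0.3g m: %d loops (%d CCW, %d CW)\n",
                side * x$separation / 2, sum(sel),
                sum(pol[sel] == 1L), sum(pol[sel] == -1L)))
  }
  cat(sprintf("  total conductor length %.1f m\n", loops_length(x)))
  invisible(x)
}

#' Total length of the discretized current loops
#'
#' @param coil a \code{discrete_coil}.
#' @return summed loop perimeter (m), excluding any connection segments.
#' @export
loops_length <- function(coil) {
  sum(vapply(coil_loop_list(coil), function(l) {
    sum(sqrt(rowSums((l[-1, , drop = FALSE] - l[-nrow(l), , drop = FALSE])^2)))
  }, 0))
}

#' Coil efficiency: field (or gradient) per unit current
#'
#' Uniform coils: the named field component at the target center per mA of
#' drive current (nT/mA).  Gradient coils: the least-squares slope of the
#' named component along z over the probe line, per mA (nT/m/mA).  The
#' \code{"sweep"} mode emulates the bench measurement protocol: fields are
#' computed for a ramp of currents (0-60 mA for uniform coils, 0-24 mA for
#' gradient coils) and the efficiency is the slope of the best-fitting line;
#' for these exactly linear kernels it coincides with \code{"direct"}.
#'
#' @param coil a \code{discrete_coil} (or list of closed loops).
#' @param kind coil kind, see \code{\link{make_target}}.
#' @param probe probe points: the target center (uniform kinds) or the
#'   z-axis line (gradient kinds, default -15..15 cm step 5 cm).
#' @param mode \code{"direct"} (single unit-current evaluation) or
#'   \code{"sweep"} (current ramp + line fit).
#' @param currents optional current ramp (A) for \code{"sweep"}.
#' @return efficiency in nT/mA (uniform) or nT/m/mA (gradient); the
#'   magnitude of the signed slope, with the sign in attribute
#'   \code{"sign"}.
#' @export
coil_efficiency <- function(coil, kind, probe = NULL,
                            mode = c("direct", "sweep"), currents = NULL) {
  kind <- match.arg(kind, COIL_KINDS)
  mode <- match.arg(mode)
  comp <- kind_component(kind)
  gradient <- kind_is_gradient(kind)
  if (is.null(probe)) {
    probe <- if (gradient) axis_probe_line("z", -0.15, 0.15, 0.05)
             else matrix(0, 1, 3)
  }
  probe <- as_points(probe)
  if (gradient && nrow(probe) < 2)
    stop("gradient efficiency needs a probe line of at least 2 points",
         call. = FALSE)
  if (!gradient && nrow(probe) < 1)
    stop("uniform efficiency needs at least the center probe point",
         call. = FALSE)
  efficiency_engine(function(current) polyline_field(coil, current, probe),
                    kind, probe, mode, currents)
}

# shared slope logic: field_at(current) -> fields at the probe points
efficiency_engine <- function(field_at, kind, probe, mode, currents) {
  comp <- kind_component(kind)
  gradient <- kind_is_gradient(kind)
  measure <- function(current) {
    b <- field_at(current)[, comp]
    if (gradient) unname(stats::coef(stats::lm(b ~ probe[, 3]))[2])
    else b[1]
  }
  if (mode == "direct") {
    slope <- measure(1)
  } else {
    if (is.null(currents))
      currents <- seq(0, if (gradient) 24e-3 else 60e-3, length.out = 7)
    y <- vapply(currents, measure, 0)
    slope <- unname(stats::coef(stats::lm(y ~ currents))[2])
  }
  structure(abs(slope) * 1e6, sign = sign(slope),
            units = if (gradient) "nT/m/mA" else "nT/mA")
}

#' Design a biplanar nulling coil
#'
#' The central fitting function: builds the biplanar mesh and target-point
#' set, assembles the resistance and field-coupling matrices, solves the
#' minimum-dissipation stream-function problem (regularization chosen so the
#' relative target residual equals \code{residual}), discretizes the stream
#' function into \code{turns} loops per plane, and evaluates the coil
#' efficiency.
#'
#' @param kind coil kind: \code{"Bx"}, \code{"By"}, \code{"Bz"} (uniform) or
#'   \code{"Gxz"}, \code{"Gyz"}, \code{"Gzz"} (z-gradients).
#' @param plane_size,separation coil-plane geometry (m); defaults 1.4 m
#'   square planes separated by 1.4 m.
#' @param target_radius radius of the spherical target region (m);
#'   default 0.25 m.
#' @param n_target number of target constraint points on the sphere surface
#'   (a deterministic Fibonacci set; the center is added for uniform kinds).
#' @param resolution mesh vertices per plane edge.
#' @param turns contour levels (turns) per plane, N.
#' @param residual relative target-field residual used to pick lambda.
#' @param lambda optional fixed regularization (overrides \code{residual}).
#' @param amplitude target amplitude (T or T/m); the design is linear, so
#'   this only fixes the scale of the stream function, never the efficiency.
#' @param trace_width_mm,copper_oz PCB trace parameters used for the
#'   resistance matrix and reports.
#' @return object of class \code{coil_design}; see
#'   \code{\link{print.coil_design}}, \code{\link{summary.coil_design}},
#'   \code{\link{predict.coil_design}}, \code{\link{plot.coil_design}}.
#' @examples
#' \donttest{
#' d <- design_coil("Bz", resolution = 17, n_target = 40)
#' d$efficiency
#' }
#' @export
design_coil <- function(kind, plane_size = 1.4, separation = 1.4,
                        target_radius = 0.25, n_target = 128,
                        resolution = 33, turns = 30, residual = 0.02,
                        lambda = NULL, amplitude = NULL,
                        trace_width_mm = 5, copper_oz = 2) {
  kind <- match.arg(kind, COIL_KINDS)
  spec <- trace_spec(width_mm = trace_width_mm, copper_oz = copper_oz)
  if (is.null(amplitude)) amplitude <- 1e-9  # 1 nT or 1 nT/m; scale only
  mesh <- build_biplanar_mesh(plane_size, separation, resolution)
  pts <- sphere_surface_points(n_target, radius = target_radius)
  if (!kind_is_gradient(kind)) pts <- rbind(c(0, 0, 0), pts)
  target <- make_target(kind, amplitude, pts)
  R <- resistance_matrix(mesh, resistivity = spec$resistivity,
                         thickness = spec$thickness_um * 1e-6)
  A <- field_coupling(mesh, pts)
  sol <- optimize_stream_function(R, A, target, lambda = lambda,
                                  residual = residual, mesh = mesh)
  coil <- discretize(sol, N = turns)
  eff <- coil_efficiency(coil, kind)
  structure(
    list(
      kind = kind, mesh = mesh, target = target, solution = sol,
      coil = coil, efficiency = eff, trace = spec,
      call = match.call()
    ),
    class = "coil_design"
  )
}

#' @describeIn design_coil print a short description of the fitted design.
#' @param x,object a \code{coil_design}.
#' @param ... unused.
#' @export
print.coil_design <- function(x, ...) {
  cat(sprintf("Biplanar %s nulling-coil design\n", x$kind))
  cat(sprintf("  planes: %.3g x %.3g m at z = +/- %.3g m; target sphere r = %.3g m\n",
              x$mesh$plane_size, x$mesh$plane_size, x$mesh$separation / 2,
              attr(x$target$points, "radius") %||% max(sqrt(rowSums(
                sweep(x$target$points, 2, x$target$center)^2)))))
  cat(sprintf("  lambda = %.4g, relative residual = %.3g%%\n",
              x$solution$lambda, 100 * x$solution$residual))
  cat(sprintf("  N = %d contour levels -> %d loops; efficiency %.3g %s\n",
              x$coil$turns, length(x$coil$loops), x$efficiency,
              attr(x$efficiency, "units")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn design_coil stream-function coefficients (A per vertex).
#' @export
coef.coil_design <- function(object, ...) as.numeric(object$solution$s)

#' @describeIn design_coil target-field residuals (achieved minus desired,
#'   k x 3, T).
#' @export
residuals.coil_design <- function(object, ...) {
  object$solution$achieved - object$target$b
}

#' Predict the magnetic field of a designed coil
#'
#' @param object a \code{coil_design}.
#' @param points evaluation points (k x 3, m); default the target points.
#' @param current drive current (A); default 1 mA.
#' @param type \code{"loops"}: exact Biot-Savart field of the discretized
#'   loops at the given series current.  \code{"stream"}: field of the
#'   continuous stream function scaled to the equivalent drive (the stream
#'   function divided by the contour level step equals the coil at unit
#'   current).
#' @param ... unused.
#' @return k x 3 matrix of B (T).
#' @export
predict.coil_design <- function(object, points = NULL, current = 1e-3,
                                type = c("loops", "stream"), ...) {
  type <- match.arg(type)
  if (is.null(points)) points <- object$target$points
  points <- as_points(points)
  if (type == "loops") {
    polyline_field(object$coil, current, points)
  } else {
    A <- field_coupling(object$mesh, points)
    step <- mean(object$coil$level_step, na.rm = TRUE)
    field_of_stream(A, as.numeric(object$solution$s)) * (current / step)
  }
}

#' @describeIn design_coil summary with loop statistics, conductor length,
#'   predicted resistance and efficiency.
#' @export
summary.coil_design <- function(object, ...) {
  len <- loops_length(object$coil)
  res <- trace_resistance(len, object$trace)
  pol <- vapply(object$coil$loops, `[[`, 0L, "polarity")
  out <- list(
    kind = object$kind,
    lambda = object$solution$lambda,
    residual = object$solution$residual,
    turns = object$coil$turns,
    n_loops = length(object$coil$loops),
    n_ccw = sum(pol == 1L), n_cw = sum(pol == -1L),
    length_m = len,
    resistance_ohm = res,
    efficiency = object$efficiency
  )
  class(out) <- "summary.coil_design"
  out
}

#' @export
print.summary.coil_design <- function(x, ...) {
  cat(sprintf("%s coil: %d loops (%d CCW / %d CW), %d contour levels\n",
              x$kind, x$n_loops, x$n_ccw, x$n_cw, x$turns))
  cat(sprintf("  lambda %.4g, residual %.3g%%\n", x$lambda, 100 * x$residual))
  cat(sprintf("  loop length %.1f m, loop resistance %.2f Ohm\n",
              x$length_m, x$resistance_ohm))
  cat(sprintf("  efficiency %.3g %s\n", x$efficiency,
              attr(x$efficiency, "units")))
  invisible(x)
}

#' Plot a coil design
#'
#' Draws, for each plane, the stream-function contours and the discretized
#' loops (anticlockwise loops in red, clockwise in blue).
#'
#' @param x a \code{coil_design}.
#' @param ... passed to \code{\link[graphics]{plot.default}}.
#' @export
plot.coil_design <- function(x, ...) {
  mesh <- x$mesh
  n <- mesh$resolution
  xs <- seq(-mesh$plane_size / 2, mesh$plane_size / 2, length.out = n)
  values <- as.numeric(x$solution$s)
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (side in c(1L, -1L)) {
    idx <- if (side == 1L) seq_len(n * n) else n * n + seq_len(n * n)
    z <- matrix(values[idx], n, n)
    graphics::contour(xs, xs, z, nlevels = 12, col = "grey60",
                      drawlabels = FALSE, asp = 1,
                      xlab = "x (m)", ylab = "y (m)",
                      main = sprintf("%s, z = %+0.2f m", x$kind,
                                     side * mesh$separation / 2), ...)
    for (l in x$coil$loops) {
      if (l$plane != side) next
      graphics::lines(l$vertices[, 1], l$vertices[, 2],
                      col = if (l$polarity > 0) "firebrick" else "navy")
    }
  }
  invisible(x)
}
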