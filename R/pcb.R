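# Turn disconnected discrete current loops into a continuous two-layer PCB
# conducting path.
#
# Scheme (per plane): loops are grouped into "nests" (chains of mutually
# nested rings).  A deterministic cut ray runs from the innermost loop's
# centroid outward; every ring is opened where it crosses a corridor of
# half-width W around the ray.  The front layer carries the opened rings
# plus short diagonal bridges joining consecutive rings into a spiral
# (entering at the outermost ring).  The back layer carries the return
# path from the innermost ring back out: it retraces every front bridge
# with an identical, oppositely-traversed copy, hopping across each ring's
# gap with short stubs, so the connection segments' stray fields cancel
# layer against layer.  Nests, and the feed terminals, are joined by
# jumper segments present identically on both layers with vias at their
# ends.

new_trace <- function(id, layer, role, xy, nest = NA_integer_,
                      loop_id = NA_integer_, polarity = NA_integer_,
                      partner_of = NA_integer_) {
  list(id = id, layer = layer, role = role, xy = xy, nest = nest,
       loop_id = loop_id, polarity = polarity, partner_of = partner_of)
}

trace_length <- function(tr) {
  xy <- tr$xy
  sum(sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2)))
}

point_in_polygon <- function(px, py, poly) {
  # even-odd rule; poly is k x 2 (closed or open)
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Cut-plan for a coil kind
#'
#' Board split orientation by coil: vertical cuts (left/right halves) for
#' Bx, Gxz, Bz, Gzz; horizontal cuts for By, Gyz.  The x/y coils need only
#' two solder joints (one per copper layer); the z coils' rings straddle
#' the symmetry axis and need one joint pair per severed ring.
#'
#' @param kind coil kind.
#' @return object of class \code{cut_plan} with \code{axis}
#'   (\code{"vertical"} or \code{"horizontal"}) and the expected solder
#'   joint count (\code{2} or \code{NA} for "multiple").
#' @export
cut_plan <- function(kind) {
  kind <- match.arg(kind, COIL_KINDS)
  axis <- if (kind %in% c("Bx", "Gxz", "Bz", "Gzz")) "vertical" else "horizontal"
  joints <- if (kind %in% c("Bx", "By", "Gxz", "Gyz")) 2L else NA_integer_
  structure(list(kind = kind, axis = axis, expected_joints = joints),
            class = "cut_plan")
}

# ---- nest analysis ---------------------------------------------------------

# containment analysis: returns per-loop areas, the containment matrix and
# each loop's root (outermost container); nests are root + descendants,
# ordered deterministically by centroid
find_nests <- function(loops2d) {
  nl <- length(loops2d)
  if (nl == 0) return(list())
  areas <- vapply(loops2d, function(l)
    abs(polygon_signed_area(l$xy[, 1], l$xy[, 2])), 0)
  contains <- matrix(FALSE, nl, nl)
  for (i in seq_len(nl)) for (j in seq_len(nl)) {
    if (i != j && areas[i] > areas[j])
      contains[i, j] <- point_in_polygon(loops2d[[j]]$xy[1, 1],
                                         loops2d[[j]]$xy[1, 2],
                                         loops2d[[i]]$xy)
  }
  root <- integer(nl)
  for (j in seq_len(nl)) {
    anc <- which(contains[, j])
    root[j] <- if (length(anc) == 0) j else anc[which.max(areas[anc])]
  }
  nests <- lapply(unique(root), function(r) {
    members <- which(root == r | seq_len(nl) == r)
    members <- unique(c(r, members[order(-areas[members])]))
    list(members = members, areas = areas[members],
         contains = contains[members, members, drop = FALSE])
  })
  cent <- t(vapply(nests, function(n) {
    colMeans(do.call(rbind, lapply(loops2d[n$members],
                                   function(l) l$xy)))
  }, numeric(2)))
  nests[order(cent[, 1], cent[, 2])]
}

# ---- obstacle-grid routing -------------------------------------------------
# Jumpers and pod channels are routed deterministically on a raster of the
# board: every existing trace is stamped as an obstacle (inflated by a
# clearance radius) and a breadth-first search finds the shortest free
# rectilinear path.

make_route_grid <- function(plane_size, h = 3e-3) {
  n <- 2L * ceiling(plane_size / 2 / h) + 1L
  xs <- seq(-plane_size / 2, plane_size / 2, length.out = n)
  env <- new.env(parent = emptyenv())
  env$blocked <- matrix(FALSE, n, n)  # clearance-inflated obstacles
  env$hard <- matrix(FALSE, n, n)     # bare trace centerlines
  env$xs <- xs
  env$h <- xs[2] - xs[1]
  env$n <- n
  env
}

grid_cell <- function(grid, p) {
  c(pmin(pmax(round((p[1] - grid$xs[1]) / grid$h) + 1L, 1L), grid$n),
    pmin(pmax(round((p[2] - grid$xs[1]) / grid$h) + 1L, 1L), grid$n))
}

grid_stamp <- function(grid, xy, inflate = 3e-3, hard_inflate = 0) {
  # sample the polyline densely and block a disk around every sample
  if (nrow(xy) < 2) return(invisible())
  pts <- list()
  for (j in seq_len(nrow(xy) - 1L)) {
    a <- xy[j, ]; b <- xy[j + 1L, ]
    len <- sqrt(sum((b - a)^2))
    m <- max(2L, ceiling(len / (grid$h / 2)))
    t <- seq(0, 1, length.out = m)
    pts[[j]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  pts <- do.call(rbind, pts)
  ci <- round((pts[, 1] - grid$xs[1]) / grid$h) + 1L
  cj <- round((pts[, 2] - grid$xs[1]) / grid$h) + 1L
  stamp <- function(field, infl) {
    r <- ceiling(infl / grid$h)
    off <- expand.grid(di = -r:r, dj = -r:r)
    off <- off[off$di^2 + off$dj^2 <= (r + 0.5)^2, ]
    for (k in seq_len(nrow(off))) {
      ii <- ci + off$di[k]; jj <- cj + off$dj[k]
      ok <- ii >= 1L & ii <= grid$n & jj >= 1L & jj <= grid$n
      grid[[field]][cbind(ii[ok], jj[ok])] <- TRUE
    }
  }
  stamp("blocked", inflate)
  stamp("hard", hard_inflate)
  invisible()
}

# route a path confined to a narrow sleeve around an existing polyline:
# used for the return leg of a canceling pair, which must hug its partner
# without touching it
route_alongside <- function(grid, along_xy, p1, p2, sleeve = 12e-3) {
  n <- grid$n
  for (s in c(sleeve, 2 * sleeve)) {
    allowed <- matrix(FALSE, n, n)
    for (j in seq_len(nrow(along_xy) - 1L)) {
      a <- along_xy[j, ]; b <- along_xy[j + 1L, ]
      len <- sqrt(sum((b - a)^2))
      m <- max(2L, ceiling(len / grid$h))
      t <- seq(0, 1, length.out = m)
      ci <- round((a[1] + t * (b[1] - a[1]) - grid$xs[1]) / grid$h) + 1L
      cj <- round((a[2] + t * (b[2] - a[2]) - grid$xs[1]) / grid$h) + 1L
      r <- ceiling(s / grid$h)
      for (di in -r:r) for (dj in -r:r) {
        if (di^2 + dj^2 > (r + 0.5)^2) next
        ii <- ci + di; jj <- cj + dj
        ok <- ii >= 1L & ii <= n & jj >= 1L & jj <= n
        allowed[cbind(ii[ok], jj[ok])] <- TRUE
      }
    }
    blocked <- grid$hard | !allowed
    c1 <- grid_cell(grid, p1); c2 <- grid_cell(grid, p2)
    cells <- grid_bfs(blocked, n, c1, c2, 2L)
    if (!is.null(cells)) {
      ij <- cbind((cells - 1L) %% n + 1L, (cells - 1L) %/% n + 1L)
      xy <- cbind(grid$xs[ij[, 1]], grid$xs[ij[, 2]])
      if (nrow(xy) > 2) {
        keep <- c(TRUE, diff(diff(xy[, 1])) != 0 | diff(diff(xy[, 2])) != 0,
                  TRUE)
        xy <- xy[keep, , drop = FALSE]
      }
      return(rbind(p1, xy, p2))
    }
  }
  # last resort: the plain back-layer route
  route_between(grid, p1, p2)
}

# parallel copy of a polyline, offset to the left of travel
offset_polyline <- function(xy, off) {
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 1e-12)
  xy <- xy[keep, , drop = FALSE]
  k <- nrow(xy)
  if (k < 2) return(xy)
  segs <- diff(xy)
  len <- sqrt(rowSums(segs^2))
  nx <- -segs[, 2] / len; ny <- segs[, 1] / len
  if (k == 2) {
    vnx <- rep(nx, 2); vny <- rep(ny, 2)
  } else {
    vnx <- c(nx[1], (nx[-1] + nx[-(k - 1)]) / 2, nx[k - 1])
    vny <- c(ny[1], (ny[-1] + ny[-(k - 1)]) / 2, ny[k - 1])
  }
  nn <- sqrt(vnx^2 + vny^2); nn[nn < 1e-9] <- 1
  cbind(xy[, 1] + off * vnx / nn, xy[, 2] + off * vny / nn)
}

grid_bfs <- function(blocked, n, c1, c2, fr) {
  clear_disk <- function(c0) {
    ii <- pmax(1L, c0[1] - fr):pmin(n, c0[1] + fr)
    jj <- pmax(1L, c0[2] - fr):pmin(n, c0[2] + fr)
    blocked[ii, jj] <<- FALSE
  }
  clear_disk(c1); clear_disk(c2)
  start <- (c1[2] - 1L) * n + c1[1]
  goal <- (c2[2] - 1L) * n + c2[1]
  parent <- integer(n * n)
  parent[start] <- -1L
  frontier <- start
  found <- start == goal
  bl <- as.vector(blocked)
  while (!found && length(frontier) > 0) {
    cand <- c(frontier + 1L, frontier - 1L, frontier + n, frontier - n)
    src <- rep(frontier, 4L)
    row <- (frontier - 1L) %% n + 1L   # forbid wrapping across rows
    okm <- c(row < n, row > 1L, frontier + n <= n * n, frontier - n >= 1L)
    cand <- cand[okm]; src <- src[okm]
    keep <- !bl[cand] & parent[cand] == 0L & cand != start
    cand <- cand[keep]; src <- src[keep]
    if (length(cand) == 0) break
    dup <- !duplicated(cand)
    cand <- cand[dup]; src <- src[dup]
    parent[cand] <- src
    if (parent[goal] != 0L) { found <- TRUE; break }
    frontier <- cand
  }
  if (!found && parent[goal] == 0L) return(NULL)
  cells <- goal
  cur <- goal
  while (parent[cur] != -1L) { cur <- parent[cur]; cells <- c(cur, cells) }
  cells
}

# breadth-first shortest rectilinear path between two points; tries the
# clearance-inflated obstacle map first, then falls back to the bare
# centerline map (tight squeeze through a pinched channel: still
# non-crossing as line geometry, clearance left to the fab review).
# Endpoint neighbourhoods are treated as free so paths may leave/enter the
# immediate vicinity of the traces they connect to.
route_between <- function(grid, p1, p2, free_radius = 3.9e-3) {
  n <- grid$n
  fr <- ceiling(free_radius / grid$h)
  c1 <- grid_cell(grid, p1); c2 <- grid_cell(grid, p2)
  cells <- grid_bfs(grid$blocked, n, c1, c2, fr)
  if (is.null(cells)) cells <- grid_bfs(grid$hard, n, c1, c2, max(1L, fr %/% 2L))
  if (is.null(cells))
    stop("routing failed: no clear path between (",
         signif(p1[1], 3), ",", signif(p1[2], 3), ") and (",
         signif(p2[1], 3), ",", signif(p2[2], 3), ")", call. = FALSE)
  ij <- cbind((cells - 1L) %% n + 1L, (cells - 1L) %/% n + 1L)
  xy <- cbind(grid$xs[ij[, 1]], grid$xs[ij[, 2]])
  if (nrow(xy) > 2) {
    keep <- c(TRUE, diff(diff(xy[, 1])) != 0 | diff(diff(xy[, 2])) != 0, TRUE)
    xy <- xy[keep, , drop = FALSE]
  }
  rbind(p1, xy, p2)
}

# open one ring where it crosses the corridor |v| < W around ray (o, d)
open_ring <- function(xy, o, d, W, loop_name) {
  nvec <- c(-d[2], d[1])
  k <- nrow(xy)
  if (all(abs(xy[1, ] - xy[k, ]) < 1e-12)) xy <- xy[-k, , drop = FALSE]
  k <- nrow(xy)
  u <- (xy[, 1] - o[1]) * d[1] + (xy[, 2] - o[2]) * d[2]
  v <- (xy[, 1] - o[1]) * nvec[1] + (xy[, 2] - o[2]) * nvec[2]
  # clamp the corridor so small rings still stick out of it on both sides
  W <- min(W, 0.45 * max(abs(v)))
  nxt <- c(seq_len(k)[-1], 1L)
  cross <- which(v * v[nxt] <= 0 & (v != v[nxt]))
  if (length(cross) == 0)
    stop("unconnectable loop: cut segment misses loop ", loop_name,
         call. = FALSE)
  alpha <- -v[cross] / (v[nxt[cross]] - v[cross])
  ucross <- u[cross] + alpha * (u[nxt[cross]] - u[cross])
  pos <- which(ucross > 0)
  if (length(pos) == 0)
    stop("unconnectable loop: cut segment misses loop ", loop_name,
         call. = FALSE)
  sel <- pos[which.min(ucross[pos])]
  j0 <- cross[sel]
  t_i <- ucross[sel]

  interp <- function(j, jn, target_v) {
    a <- (target_v - v[j]) / (v[jn] - v[j])
    xy[j, ] + a * (xy[jn, ] - xy[j, ])
  }
  # forward walk (traversal direction) until |v| >= W
  idx <- nxt[j0]
  steps <- 0L
  while (abs(v[idx]) < W && steps < k) { idx <- nxt[idx]; steps <- steps + 1L }
  if (steps >= k)
    stop("corridor too wide: loop ", loop_name,
         " lies entirely within the cut corridor", call. = FALSE)
  prev_idx <- which(nxt == idx)
  p_fwd <- interp(prev_idx, idx, sign(v[idx]) * W)
  side_fwd <- sign(v[idx])
  # backward walk
  prv <- c(k, seq_len(k - 1L))
  idb <- j0
  steps <- 0L
  while (abs(v[idb]) < W && steps < k) { idb <- prv[idb]; steps <- steps + 1L }
  if (steps >= k)
    stop("corridor too wide: loop ", loop_name,
         " lies entirely within the cut corridor", call. = FALSE)
  # boundary crossing on segment (idb -> next(idb)) at |v| = W
  p_bwd <- interp(idb, nxt[idb], sign(v[idb]) * W)
  side_bwd <- sign(v[idb])
  # remaining polyline: p_fwd, then vertices idx .. idb, then p_bwd
  if (idx <= idb) ord <- idx:idb else ord <- c(idx:k, 1:idb)
  opened <- rbind(p_fwd, xy[ord, , drop = FALSE], p_bwd)
  list(opened = opened, t = t_i, p_fwd = p_fwd, p_bwd = p_bwd,
       side_fwd = side_fwd, side_bwd = side_bwd)
}

# ---- connect_loops ---------------------------------------------------------

#' Connect discrete loops into a continuous two-layer board layout
#'
#' Deterministically joins the loops of each coil plane into a single
#' conducting path from terminal to terminal (see the scheme described in
#' the package vignette): rings are opened along a cut ray per nest,
#' spiral-bridged on the front layer, returned on the back layer with
#' geometrically identical, oppositely-traversed copies of every front
#' connection segment, and nests/terminals are joined by two-layer jumpers
#' with vias at both ends.
#'
#' @param coil a \code{discrete_coil}.
#' @param kind coil kind (sets the cut plan and terminal placement);
#'   optional.
#' @param cut_segments optional list (one entry per plane, each a list per
#'   nest) of 2 x 2 matrices (rows: ray origin, second point) overriding
#'   the default cut rays.
#' @param trace_width_mm copper trace width (mm).
#' @param corridor_factor corridor half-width in units of the trace width.
#' @param margin clearance (m) between a nest's outermost ring and its
#'   entry point.
#' @return object of class \code{board_set}: a named list of
#'   \code{board_layout} objects (one per plane: \code{plane_pos},
#'   \code{plane_neg}), each with traces, vias, terminals, the traversal
#'   path and annotations.
#' @export
connect_loops <- function(coil, kind = NULL, cut_segments = NULL,
                          trace_width_mm = 5, corridor_factor = 1.5,
                          margin = 0.01) {
  loops <- coil$loops
  if (length(loops) == 0) stop("coil has no loops", call. = FALSE)
  planes <- unique(vapply(loops, `[[`, 0L, "plane"))
  out <- list()
  for (side in sort(planes, decreasing = TRUE)) {
    pl <- loops[vapply(loops, `[[`, 0L, "plane") == side]
    loops2d <- lapply(seq_along(pl), function(i) {
      list(xy = pl[[i]]$vertices[, 1:2, drop = FALSE],
           polarity = pl[[i]]$polarity, id = i)
    })
    segs <- if (!is.null(cut_segments))
      cut_segments[[if (side == 1L) "plane_pos" else "plane_neg"]] else NULL
    out[[if (side == 1L) "plane_pos" else "plane_neg"]] <-
      connect_plane(loops2d, side, coil$separation, coil$plane_size,
                    kind, segs, trace_width_mm, corridor_factor, margin)
  }
  structure(out, class = "board_set",
            kind = kind, plane_size = coil$plane_size,
            separation = coil$separation)
}

# centroid of the innermost ring along the largest-area branch of a subtree
main_leaf_centroid <- function(loops2d, sub) {
  cur <- 1L
  repeat {
    kids <- which(sub$contains[cur, ])
    if (length(kids) == 0) break
    direct <- kids[!vapply(kids, function(kk)
      any(sub$contains[setdiff(kids, kk), kk, drop = FALSE]), TRUE)]
    if (length(direct) == 0) break
    cur <- direct[which.max(sub$areas[direct])]
  }
  xy <- loops2d[[sub$members[cur]]]$xy
  colMeans(xy[-nrow(xy), , drop = FALSE])
}

# sub-structure rooted at local index l of `sub`, restricted to the given
# candidate members (a pod may only absorb loops that are not already part
# of the enclosing chain)
nest_subtree <- function(sub, l, allowed = seq_along(sub$members)) {
  mem <- c(l, intersect(which(sub$contains[l, ]), allowed))
  mem <- unique(mem[order(-sub$areas[mem])])
  list(members = sub$members[mem], areas = sub$areas[mem],
       contains = sub$contains[mem, mem, drop = FALSE])
}

connect_plane <- function(loops2d, side, separation, plane_size, kind,
                          cut_segments, trace_width_mm, corridor_factor,
                          margin) {
  W <- corridor_factor * trace_width_mm * 1e-3
  nests <- find_nests(loops2d)
  g <- length(nests)
  cents <- t(vapply(nests, function(n) {
    # ray origin: centroid of the deepest main-branch leaf
    cur <- 1L  # local index of the root (largest area)
    repeat {
      kids <- which(n$contains[cur, ])
      direct <- kids[!vapply(kids, function(kk)
        any(n$contains[kids[kids != kk], kk]), TRUE)]
      if (length(direct) == 0) break
      cur <- direct[which.max(n$areas[direct])]
    }
    xy <- loops2d[[n$members[cur]]]$xy
    colMeans(xy[-nrow(xy), , drop = FALSE])
  }, numeric(2)))
  # nest bounding boxes and row orientation
  bboxes <- lapply(nests, function(n) {
    xy <- do.call(rbind, lapply(loops2d[n$members], `[[`, "xy"))
    rbind(apply(xy, 2, min), apply(xy, 2, max))
  })
  row_along_x <- g < 2 ||
    diff(range(cents[, 1])) >= diff(range(cents[, 2]))
  # visit nests in order along the row so consecutive jumpers are short
  ord <- order(cents[, if (row_along_x) 1L else 2L])
  nests <- nests[ord]
  cents <- cents[ord, , drop = FALSE]
  bboxes <- bboxes[ord]
  # every nest is entered from the same side of the row
  dirs <- matrix(0, g, 2)
  for (i in seq_len(g)) dirs[i, ] <- if (row_along_x) c(0, -1) else c(-1, 0)
  if (!is.null(cut_segments)) {
    for (i in seq_along(cut_segments)) {
      cs <- cut_segments[[i]]
      if (is.null(cs)) next
      cents[i, ] <- cs[1, ]
      dd <- cs[2, ] - cs[1, ]
      dirs[i, ] <- dd / sqrt(sum(dd^2))
    }
  }

  traces <- list()
  vias <- data.frame(x = numeric(), y = numeric(), drill_mm = numeric())
  path <- data.frame(id = integer(), rev = logical())
  grid <- make_route_grid(plane_size)   # both-layer obstacle map
  bgrid <- make_route_grid(plane_size)  # back-layer map (for pod spurs)
  idc <- 0L
  nid <- function() { idc <<- idc + 1L; idc }
  add <- function(tr) {
    traces[[tr$id]] <<- tr
    grid_stamp(grid, tr$xy)
    if (tr$layer == "B") grid_stamp(bgrid, tr$xy)
    tr$id
  }
  addpath <- function(id, rev = FALSE)
    path <<- rbind(path, data.frame(id = id, rev = rev))
  addvia <- function(p) {
    vias <<- rbind(vias, data.frame(x = p[1], y = p[2], drill_mm = 2))
    grid_stamp(grid, rbind(p, p))
    grid_stamp(bgrid, rbind(p, p))
  }

  entry_pts <- matrix(NA_real_, g, 2)
  nest_records <- vector("list", g)
  nest_paths <- vector("list", g)

  open_or_null <- function(xy, o, d, name) tryCatch(
    open_ring(xy, o, d, W, loop_name = name),
    error = function(e)
      if (grepl("corridor too wide", conditionMessage(e))) stop(e) else NULL)

  # entry point of a (sub)nest: just beyond the outermost ring on the ray,
  # offset to the corridor side the current leaves from; kept inside the
  # board area
  nest_entry <- function(sub, o, d) {
    op <- open_ring(loops2d[[sub$members[1]]]$xy, o, d, W,
                    loop_name = sub$members[1])
    E <- o + (op$t + margin) * d + W * op$side_fwd * c(-d[2], d[1])
    bound <- plane_size / 2 - 1.5 * trace_width_mm * 1e-3
    pmin(pmax(E, -bound), bound)
  }

  # keep via positions clear of the future symmetry-axis cut
  cut_ci <- if (is.null(kind)) NULL
            else if (cut_plan(kind)$axis == "vertical") 1L else 2L
  cut_ok <- function(p) is.null(cut_ci) || abs(p[cut_ci]) > 5e-3

  # pods may be elongated and walled in on some sides: consider eight
  # opening directions and use the free one that crosses the pod nearest
  # to its centroid (the thin side)
  pod_direction <- function(sub, o, d0) {
    best <- NULL
    for (strict in c(2L, 1L, 0L)) {
      for (rot in (0:7) * pi / 4) {
        cs <- cos(rot); sn <- sin(rot)
        d <- c(cs * d0[1] - sn * d0[2], sn * d0[1] + cs * d0[2])
        op <- tryCatch(open_ring(loops2d[[sub$members[1]]]$xy, o, d, W,
                                 loop_name = sub$members[1]),
                       error = function(e) NULL)
        if (is.null(op)) next
        E <- tryCatch(nest_entry(sub, o, d), error = function(e) NULL)
        if (is.null(E) || !cut_ok(E)) next
        cc <- grid_cell(grid, E)
        if (strict >= 1L && grid$blocked[cc[1], cc[2]]) next
        if (strict >= 2L && bgrid$blocked[cc[1], cc[2]]) next
        if (is.null(best) || op$t < best$t)
          best <- list(d = d, E = E, t = op$t)
      }
      if (!is.null(best)) break
    }
    if (is.null(best))
      stop("unconnectable loop: no free entry found for nested loop group",
           call. = FALSE)
    best
  }

  # recursively emit one nest: entry segment, opened rings spiral-bridged
  # along the ray, off-ray subtrees as self-contained "pods" visited by a
  # channel path circling the annulus between their enclosing rings, then
  # the back-layer return retracing every front connection segment
  emit_nest <- function(sub, o, d, E, tag, depth = 1L) {
    if (depth > 5L)
      stop("loop nesting too deep to route", call. = FALSE)
    nm <- length(sub$members)
    opened <- lapply(seq_len(nm), function(k)
      open_or_null(loops2d[[sub$members[k]]]$xy, o, d, sub$members[k]))
    on_ray <- !vapply(opened, is.null, TRUE)
    if (!any(on_ray))
      stop("unconnectable loop: cut segment misses every loop of nest ",
           tag, call. = FALSE)
    chain <- which(on_ray)
    chain <- chain[order(-vapply(opened[chain], `[[`, 0, "t"))]
    leftovers <- which(!on_ray)
    pod_roots <- leftovers[!vapply(leftovers, function(l)
      any(sub$contains[leftovers, l]), TRUE)]
    # all pods hang off the tail segment inside the innermost ring (the
    # hub): their back-layer spurs fan out like spokes and never cross
    # the cut corridor or each other
    n_chain <- length(chain)
    slot <- rep(n_chain, length(pod_roots))

    theta0 <- atan2(d[2], d[1])
    # make all of this nest's geometry visible to the router up front
    for (k in chain) grid_stamp(grid, opened[[k]]$opened)
    for (l in leftovers) grid_stamp(grid, loops2d[[sub$members[l]]]$xy)
    # reserve the cut corridor on the back layer (stubs and bridge return
    # copies will live there); the hub inside the innermost ring and the
    # space beyond the outermost ring stay open
    t_ch <- vapply(chain, function(cc) opened[[cc]]$t, 0)
    grid_stamp(bgrid,
               rbind(o + max(0, min(t_ch) - W) * d,
                     o + (max(t_ch) - W) * d),
               inflate = W + 3e-3, hard_inflate = W + 3e-3)

    n <- length(chain)
    ring_ids <- integer(n)
    stubs <- vector("list", n)
    bridge_ids <- vector("list", n)   # bridge_ids[[k]]: legs after ring k
    entry_id <- add(new_trace(nid(), "F", "entry",
                              rbind(E, opened[[chain[1]]]$p_fwd),
                              nest = tag))
    addpath(entry_id)
    terminus <- NULL
    for (ci in seq_len(n)) {
      k <- chain[ci]
      m_global <- sub$members[k]
      ring_ids[ci] <- add(new_trace(nid(), "F", "loop", opened[[k]]$opened,
                                    nest = tag, loop_id = m_global,
                                    polarity = loops2d[[m_global]]$polarity))
      addpath(ring_ids[ci])
      stubs[[ci]] <- rbind(opened[[k]]$p_bwd, opened[[k]]$p_fwd)
      pods <- pod_roots[slot == ci]
      last_ring <- ci == n
      if (length(pods) == 0 && last_ring) {
        terminus <- opened[[k]]$p_bwd
        next
      }
      # the bridge after ring k: straight to the next ring, or (after the
      # last ring) a short tail into the free interior.  Pods in this slot
      # hang off the bridge as back-layer out-and-back spurs.
      b_start <- opened[[k]]$p_bwd
      npod <- length(pods)
      voff <- 1.5 * trace_width_mm * 1e-3   # along-tail via separation
      tl <- 2 * W + npod * 3 * voff + 0.02  # tail length into the hub
      b_end <- if (last_ring) b_start - tl * d
               else opened[[chain[ci + 1L]]]$p_fwd
      if (npod == 0) {
        bid <- add(new_trace(nid(), "F", "bridge", rbind(b_start, b_end),
                             nest = tag))
        addpath(bid)
        bridge_ids[[ci]] <- bid
        if (last_ring) terminus <- b_end
        next
      }
      pod_subs <- lapply(pods, function(l)
        nest_subtree(sub, l, allowed = leftovers))
      pod_o <- t(vapply(pod_subs, function(ps)
        main_leaf_centroid(loops2d, ps), numeric(2)))
      thl <- atan2(pod_o[, 2] - o[2], pod_o[, 1] - o[1])
      thl <- theta0 + (thl - theta0) %% (2 * pi)
      ordl <- order(thl)
      pods <- pods[ordl]; pod_subs <- pod_subs[ordl]
      pod_o <- pod_o[ordl, , drop = FALSE]; thl <- thl[ordl]
      # attachment points on the hub part of the tail, beyond the reserved
      # corridor band; spur vias step off the tail toward the pod's side
      vv <- c(-d[2], d[1])
      u_start <- sum((b_start - o) * d)
      legs <- integer(0)
      prev <- b_start
      for (j in seq_len(npod)) {
        # pods are preferably opened toward the hub
        d0 <- (o - pod_o[j, ])
        d0 <- d0 / max(sqrt(sum(d0^2)), 1e-9)
        de <- pod_direction(pod_subs[[j]], pod_o[j, ], d0)
        side_v <- sign(sum((pod_o[j, ] - o) * vv))
        if (side_v == 0) side_v <- 1
        u_A <- u_start - 2 * W - 0.008 - (j - 1L) * 3 * voff
        for (try in 1:10) {
          A <- b_start - (u_start - u_A) * d
          A_dn <- A - voff * d + side_v * 2 * voff * vv
          A_up <- A + voff * d + side_v * 2 * voff * vv
          if (cut_ok(A_dn) && cut_ok(A_up)) break
          u_A <- u_A - 2 * voff
        }
        bid <- add(new_trace(nid(), "F", "bridge", rbind(prev, A),
                             nest = tag))
        addpath(bid)
        legs <- c(legs, bid)
        prev <- A
        # prestamp the pod's own corridor so the spurs avoid its stubs
        grid_stamp(bgrid,
                   rbind(pod_o[j, ], pod_o[j, ] + max(0, de$t - W) * de$d),
                   inflate = W + 3e-3, hard_inflate = W + 3e-3)
        sd_id <- add(new_trace(nid(), "F", "spur_stub", rbind(A, A_dn),
                               nest = tag))
        addpath(sd_id)
        addvia(A_dn)
        sin_xy <- route_between(bgrid, A_dn, de$E)
        sin_id <- add(new_trace(nid(), "B", "spur", sin_xy, nest = tag))
        addpath(sin_id)
        emit_nest(pod_subs[[j]], pod_o[j, ], de$d, de$E, tag, depth + 1L)
        # the outgoing spur hugs the incoming one (a tight canceling pair)
        sout_xy <- route_alongside(bgrid, sin_xy, de$E, A_up)
        sout_id <- add(new_trace(nid(), "B", "spur", sout_xy, nest = tag,
                                 partner_of = sin_id))
        addpath(sout_id)
        addvia(A_up)
        su_id <- add(new_trace(nid(), "F", "spur_stub", rbind(A_up, A),
                               nest = tag))
        addpath(su_id)
      }
      bid <- add(new_trace(nid(), "F", "bridge", rbind(prev, b_end),
                           nest = tag))
      addpath(bid)
      bridge_ids[[ci]] <- c(legs, bid)
      if (last_ring) terminus <- b_end
    }
    # inner terminus via, then the back return: identical reversed copies
    # of every front connection segment, hopping ring gaps with stubs
    addvia(terminus)
    for (ci in rev(seq_len(n))) {
      for (bid in rev(bridge_ids[[ci]])) {
        add_id <- add(new_trace(nid(), "B", "bridge_ret",
                                traces[[bid]]$xy, nest = tag,
                                partner_of = bid))
        addpath(add_id, rev = TRUE)
      }
      stub_id <- add(new_trace(nid(), "B", "stub", stubs[[ci]], nest = tag))
      addpath(stub_id)
    }
    eret <- add(new_trace(nid(), "B", "entry_ret", traces[[entry_id]]$xy,
                          nest = tag, partner_of = entry_id))
    addpath(eret, rev = TRUE)
    addvia(E)
    invisible(vapply(seq_len(n), function(ci) sub$members[chain[ci]], 0L))
  }

  for (i in seq_len(g)) {
    path <- data.frame(id = integer(), rev = logical())
    o <- cents[i, ]; d <- dirs[i, ]
    E <- nest_entry(nests[[i]], o, d)
    entry_pts[i, ] <- E
    emit_nest(nests[[i]], o, d, E, i)
    nest_records[[i]] <- list(members = nests[[i]]$members,
                              centroid = o, dir = d, entry = E)
    nest_paths[[i]] <- path
  }

  # terminals and jumpers, routed on the obstacle grid so they thread the
  # free space between nests without touching any ring
  edge <- plane_size / 2 * 0.995
  ax <- if (row_along_x) 1L else 2L   # coordinate along the nest row
  ay <- 3L - ax
  mk <- function(a, b) { p <- numeric(2); p[ax] <- a; p[ay] <- b; p }
  w_off <- 2 * trace_width_mm * 1e-3
  term_xy <- mk(entry_pts[1, ax], -edge)
  # jumpers should cross the symmetry-axis cut exactly once where they
  # must, and not at all otherwise: the cut line is blocked during
  # routing, and a crossing jumper is routed through one chosen free
  # point on the line
  with_cut_blocked <- function(gr) {
    if (is.null(cut_ci)) return(gr)
    g2 <- new.env(parent = emptyenv())
    g2$xs <- gr$xs; g2$h <- gr$h; g2$n <- gr$n
    g2$blocked <- gr$blocked; g2$hard <- gr$hard
    cc <- round((0 - gr$xs[1]) / gr$h) + 1L
    idx <- pmax(1L, cc - 1L):pmin(gr$n, cc + 1L)
    if (cut_ci == 1L) {
      g2$blocked[idx, ] <- TRUE; g2$hard[idx, ] <- TRUE
    } else {
      g2$blocked[, idx] <- TRUE; g2$hard[, idx] <- TRUE
    }
    g2
  }
  route_cut_aware <- function(gr, a, b) {
    if (is.null(cut_ci) || (a[cut_ci]) * (b[cut_ci]) > 0) {
      gb <- with_cut_blocked(gr)
      p <- tryCatch(route_between(gb, a, b), error = function(e) NULL)
      if (!is.null(p)) return(p)
      return(route_between(gr, a, b))
    }
    # must cross once: pick the free point on the cut line nearest the
    # straight connection
    cc <- round((0 - gr$xs[1]) / gr$h) + 1L
    other <- (a[3L - cut_ci] + b[3L - cut_ci]) / 2
    free <- if (cut_ci == 1L) !gr$blocked[cc, ] else !gr$blocked[, cc]
    cand <- which(free)
    if (length(cand) == 0)
      cand <- which(if (cut_ci == 1L) !gr$hard[cc, ] else !gr$hard[, cc])
    P <- numeric(2)
    P[cut_ci] <- gr$xs[cc]
    P[3L - cut_ci] <- gr$xs[cand[which.min(abs(gr$xs[cand] - other))]]
    gb <- with_cut_blocked(gr)
    p1 <- tryCatch(route_between(gb, a, P), error = function(e) NULL)
    p2 <- tryCatch(route_between(gb, P, b), error = function(e) NULL)
    if (is.null(p1) || is.null(p2)) return(route_between(gr, a, b))
    rbind(p1, p2[-1, , drop = FALSE])
  }
  # the feed and inter-nest jumpers run on the front; the whole return
  # current retraces them on the back layer, ending at a back-layer
  # terminal pad directly under the front one (a tight two-layer feed
  # pair, so the jumper chain's stray field cancels).  When a nest entry
  # is pocketed behind another nest's rings the forward leg falls back to
  # the back layer with a parallel return alongside it.
  make_jumper <- function(a, b) {
    fp <- tryCatch(route_cut_aware(grid, a, b), error = function(e) NULL)
    if (!is.null(fp)) {
      idf <- add(new_trace(nid(), "F", "jumper", fp))
      idb <- add(new_trace(nid(), "B", "jumper_ret", fp, partner_of = idf))
    } else {
      bp <- route_cut_aware(bgrid, a, b)
      idf <- add(new_trace(nid(), "B", "jumper", bp))
      ret <- route_alongside(bgrid, bp, a, b)
      idb <- add(new_trace(nid(), "B", "jumper_ret", ret, partner_of = idf))
    }
    addvia(a); addvia(b)
    c(idf, idb)
  }
  ends <- rbind(term_xy, entry_pts)
  jp <- matrix(0L, g, 2)
  full_path <- data.frame(id = integer(), rev = logical())
  for (j in seq_len(g)) {
    jp[j, ] <- make_jumper(ends[j, ], ends[j + 1L, ])
    full_path <- rbind(full_path, data.frame(id = jp[j, 1], rev = FALSE),
                       nest_paths[[j]])
  }
  for (j in rev(seq_len(g)))
    full_path <- rbind(full_path, data.frame(id = jp[j, 2], rev = TRUE))
  term_plus <- term_xy
  term_minus <- term_xy

  ann <- data.frame(text = character(), x = numeric(), y = numeric(),
                    layer = character(), stringsAsFactors = FALSE)
  for (i in seq_len(g)) {
    pol <- vapply(nest_records[[i]]$members,
                  function(m) loops2d[[m]]$polarity, 0L)
    ann <- rbind(ann, data.frame(
      text = sprintf("nest %d: %d CCW / %d CW", i, sum(pol == 1), sum(pol == -1)),
      x = cents[i, 1], y = cents[i, 2], layer = "F",
      stringsAsFactors = FALSE))
  }
  ann <- rbind(ann,
               data.frame(text = "+", x = term_plus[1], y = term_plus[2],
                          layer = "F", stringsAsFactors = FALSE),
               data.frame(text = "-", x = term_minus[1], y = term_minus[2],
                          layer = "F", stringsAsFactors = FALSE))
  if (!is.null(kind))
    ann <- rbind(ann, data.frame(text = kind, x = 0, y = plane_size / 2 * 0.97,
                                 layer = "F", stringsAsFactors = FALSE))

  structure(
    list(plane = side, z = side * separation / 2,
         plane_size = plane_size,
         trace_width_mm = trace_width_mm,
         traces = traces,
         vias = unique(round(vias, 9)),
         terminals = data.frame(x = c(term_plus[1], term_minus[1]),
                                y = c(term_plus[2], term_minus[2]),
                                layer = c("F", "B"),
                                name = c("+", "-")),
         path = full_path,
         pads = data.frame(x = numeric(), y = numeric(),
                           layer = character(), pair = integer()),
         cut_axis = NULL,
         annotations = ann,
         nests = nest_records),
    class = "board_layout"
  )
}

#' @export
print.board_layout <- function(x, ...) {
  nf <- sum(vapply(x$traces, function(t) t$layer == "F", TRUE))
  nb <- length(x$traces) - nf
  cat(sprintf("Board layout (plane z = %+0.3g m): %d front / %d back traces, %d vias\n",
              x$z, nf, nb, nrow(x$vias)))
  cat(sprintf("  conducting length %.2f m, trace width %g mm\n",
              layout_length(x), x$trace_width_mm))
  if (!is.null(x$cut_axis))
    cat(sprintf("  cut: %s, %d solder pad(s)\n", x$cut_axis, nrow(x$pads)))
  invisible(x)
}

#' @export
print.board_set <- function(x, ...) {
  cat(sprintf("Board set (%s): %d plane(s)\n",
              attr(x, "kind") %||% "coil", length(x)))
  for (b in x) print(b)
  invisible(x)
}

#' Total conducting length of a board layout
#'
#' Sum of all trace polyline lengths on both copper layers, including the
#' canceling return segments.
#'
#' @param layout a \code{board_layout}, \code{board_set}, or a list of
#'   board halves from \code{\link{split_board}}.
#' @return length (m).
#' @export
layout_length <- function(layout) {
  if (inherits(layout, "board_set"))
    return(sum(vapply(layout, layout_length, 0)))
  if (!inherits(layout, "board_layout") && is.list(layout) &&
      all(vapply(layout, inherits, TRUE, "board_layout")))
    return(sum(vapply(layout, layout_length, 0)))
  sum(vapply(layout$traces, trace_length, 0))
}

board_set_length <- function(set) layout_length(set)

# ---- connectivity / crossing checks ---------------------------------------

snap_key <- function(x, y, tol = 1e-6) {
  paste(round(x / tol), round(y / tol))
}

#' Check electrical connectivity of a board layout
#'
#' Builds the node graph of trace endpoints (per layer), vias (joining the
#' layers) and solder-pad pairs, with 1e-6 m coordinate snapping, and
#' checks that every trace belongs to the single component containing the
#' terminals.
#'
#' @param layout a \code{board_layout} or a list of halves (merged first).
#' @param join_pads treat matching solder-pad pairs as connected (used when
#'   checking that re-soldered halves restore the original path).
#' @return \code{TRUE} if connected (invisibly \code{FALSE} otherwise, with
#'   attribute \code{"components"}).
#' @export
board_connected <- function(layout, join_pads = FALSE) {
  nodes <- character(0)
  parent <- integer(0)
  nodeid <- function(key) {
    i <- match(key, nodes)
    if (is.na(i)) {
      nodes <<- c(nodes, key)
      parent <<- c(parent, length(nodes))
      i <- length(nodes)
    }
    i
  }
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- findp(i); rj <- findp(j)
    if (ri != rj) parent[ri] <<- rj
  }
  trace_nodes <- list()
  for (tr in layout$traces) {
    k1 <- nodeid(paste(tr$layer, snap_key(tr$xy[1, 1], tr$xy[1, 2])))
    k2 <- nodeid(paste(tr$layer, snap_key(tr$xy[nrow(tr$xy), 1],
                                          tr$xy[nrow(tr$xy), 2])))
    unite(k1, k2)
    trace_nodes[[length(trace_nodes) + 1L]] <- k1
  }
  if (nrow(layout$vias) > 0)
    for (r in seq_len(nrow(layout$vias))) {
      kf <- nodeid(paste("F", snap_key(layout$vias$x[r], layout$vias$y[r])))
      kb <- nodeid(paste("B", snap_key(layout$vias$x[r], layout$vias$y[r])))
      unite(kf, kb)
    }
  if (join_pads && nrow(layout$pads) > 0) {
    for (p in unique(layout$pads$pair)) {
      sel <- layout$pads[layout$pads$pair == p, ]
      ks <- vapply(seq_len(nrow(sel)), function(r)
        nodeid(paste(sel$layer[r], snap_key(sel$x[r], sel$y[r]))), 0L)
      for (k in ks[-1]) unite(ks[1], k)
    }
  }
  tl <- if (!is.null(layout$terminals$layer)) layout$terminals$layer[1] else "F"
  term <- nodeid(paste(tl, snap_key(layout$terminals$x[1],
                                    layout$terminals$y[1])))
  roots <- vapply(trace_nodes, findp, 0L)
  ok <- all(roots == findp(term))
  structure(ok, components = length(unique(roots)))
}

segments_of <- function(tr) {
  xy <- tr$xy
  cbind(xy[-nrow(xy), , drop = FALSE], xy[-1, , drop = FALSE])
}

seg_cross <- function(a, b, tol = 1e-9) {
  # proper intersection of segments a=(x1,y1,x2,y2), b likewise, excluding
  # shared endpoints
  d1x <- a[3] - a[1]; d1y <- a[4] - a[2]
  d2x <- b[3] - b[1]; d2y <- b[4] - b[2]
  den <- d1x * d2y - d1y * d2x
  if (abs(den) < 1e-15) return(FALSE)
  t <- ((b[1] - a[1]) * d2y - (b[2] - a[2]) * d2x) / den
  u <- ((b[1] - a[1]) * d1y - (b[2] - a[2]) * d1x) / den
  ep <- 1e-7
  t > ep && t < 1 - ep && u > ep && u < 1 - ep
}

#' Count same-layer trace crossings involving connection segments
#'
#' Checks every connection segment (entries, bridges, jumpers, stubs and
#' their return copies) against all traces on its layer; ring traces are
#' iso-contours of one scalar function at distinct levels and cannot cross
#' each other.  Shared endpoints do not count.
#'
#' @param layout a \code{board_layout}.
#' @return number of crossings (0 for a valid layout).
#' @export
board_crossings <- function(layout) {
  count <- 0L
  for (layer in c("F", "B")) {
    lt <- layout$traces[vapply(layout$traces,
                               function(t) t$layer == layer, TRUE)]
    if (length(lt) < 2) next
    segs <- lapply(lt, segments_of)
    conn <- vapply(lt, function(t) t$role != "loop", TRUE)
    for (i in seq_along(lt)[-length(lt)]) {
      for (j in (i + 1L):length(lt)) {
        if (!conn[i] && !conn[j]) next  # ring/ring: distinct iso-levels
        A <- segs[[i]]; B <- segs[[j]]
        for (ia in seq_len(nrow(A))) for (ib in seq_len(nrow(B))) {
          if (seg_cross(A[ia, ], B[ib, ])) count <- count + 1L
        }
      }
    }
  }
  count
}

# ---- stray field of the connection segments --------------------------------

#' Magnetic field of a board layout's complete conducting path
#'
#' Computes the exact segment Biot-Savart field of the layout as built:
#' every trace is traversed along the conducting path (back-layer return
#' copies in the opposite direction to their front partners).  Because the
#' gap left in each opened ring is re-crossed by the back return, and every
#' front connection segment is cancelled by its back copy, this field
#' differs from the ideal closed-loop field only at the level of the
#' trace-offset geometry; the comparison against
#' \code{\link{polyline_field}} of the ideal loops is the layout
#' perturbation check.  Setting \code{include_partners = FALSE} drops the
#' back-layer copies, which demonstrably worsens the perturbation.
#'
#' @param layout a \code{board_layout} from \code{\link{connect_loops}}.
#' @param current drive current (A).
#' @param points evaluation points (k x 3, m).
#' @param include_partners include the back-layer canceling copies.
#' @return k x 3 matrix of B (T).
#' @export
layout_field <- function(layout, current, points, include_partners = TRUE) {
  points <- as_points(points)
  p1 <- matrix(0, 0, 3); p2 <- matrix(0, 0, 3)
  for (r in seq_len(nrow(layout$path))) {
    tr <- layout$traces[[layout$path$id[r]]]
    if (!include_partners && tr$layer == "B" && !is.na(tr$partner_of)) next
    xy <- tr$xy
    if (layout$path$rev[r]) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    z3 <- cbind(xy, layout$z)
    p1 <- rbind(p1, z3[-nrow(z3), , drop = FALSE])
    p2 <- rbind(p2, z3[-1, , drop = FALSE])
  }
  out <- matrix(0, nrow(points), 3, dimnames = list(NULL, c("Bx","By","Bz")))
  if (nrow(p1) == 0 || current == 0) return(out)
  for (i in seq_len(nrow(points))) {
    out[i, ] <- current * colSums(segment_fields_at(points[i, ], p1, p2))
  }
  out
}

#' Polarity bookkeeping along the conducting path
#'
#' Traverses the board's path and reports, for every ring visited, the
#' orientation implied by the traversal (sign of the enclosed area of the
#' closed-up ring) against the loop's assigned polarity.
#'
#' @param layout a \code{board_layout}.
#' @return data.frame with \code{loop_id}, \code{polarity},
#'   \code{traversed} (+1 anticlockwise / -1 clockwise).
#' @export
path_polarities <- function(layout) {
  rows <- list()
  for (r in seq_len(nrow(layout$path))) {
    tr <- layout$traces[[layout$path$id[r]]]
    if (tr$role != "loop") next
    xy <- tr$xy
    a <- polygon_signed_area(xy[, 1], xy[, 2])
    rows[[length(rows) + 1L]] <- data.frame(
      loop_id = tr$loop_id, polarity = tr$polarity,
      traversed = if (a > 0) 1L else -1L)
  }
  do.call(rbind, rows)
}

# ---- split / merge ---------------------------------------------------------

#' Split a board along its symmetry axis into two halves
#'
#' Severs every trace crossing the cut line (vertical or horizontal
#' through the bounding-box center), terminating the severed ends with
#' paired solder pads at matching coordinates on both halves.
#'
#' @param layout a \code{board_layout}.
#' @param plan a \code{\link{cut_plan}} or axis string (\code{"vertical"} /
#'   \code{"horizontal"}).
#' @return object of class \code{board_pair}: list with the two half
#'   layouts \code{a} and \code{b}, \code{axis}, \code{cut_value} and
#'   \code{n_pad_pairs}.
#' @export
split_board <- function(layout, plan) {
  axis <- if (inherits(plan, "cut_plan")) plan$axis else match.arg(
    plan, c("vertical", "horizontal"))
  coord <- if (axis == "vertical") 1L else 2L
  allxy <- do.call(rbind, lapply(layout$traces, `[[`, "xy"))
  # the cut runs along the board's symmetry axis (through the center of a
  # symmetric layout's bounding box)
  cutv <- 0
  tol <- 1e-9

  if (all(allxy[, coord] > cutv - tol) || all(allxy[, coord] < cutv + tol))
    stop("degenerate cut: all traces lie on one side of the axis",
         call. = FALSE)
  pad_clear <- 2e-3
  if (nrow(layout$vias) > 0) {
    vc <- if (coord == 1L) layout$vias$x else layout$vias$y
    if (any(abs(vc - cutv) < pad_clear))
      stop("via lies on the cut line and must be relocated before splitting",
           call. = FALSE)
  }

  half <- function(which_side) {
    l <- layout
    l$traces <- list(); l$pads <- data.frame(x = numeric(), y = numeric(),
                                             layer = character(),
                                             pair = integer())
    l$cut_axis <- axis
    l
  }
  a <- half(+1); b <- half(-1)
  pair_count <- 0L

  for (tr in layout$traces) {
    xy <- tr$xy
    # vertices exactly on the cut line would defeat the sign-change test;
    # nudge them by a nanometer
    on_line <- abs(xy[, coord] - cutv) < tol
    xy[on_line, coord] <- cutv + 1e-9
    cc <- xy[, coord]
    pieces <- list(); cur <- xy[1, , drop = FALSE]
    cur_side <- sign(cc[1] - cutv); if (cur_side == 0) cur_side <- 1
    for (j in seq_len(nrow(xy) - 1L)) {
      s1 <- cc[j] - cutv; s2 <- cc[j + 1L] - cutv
      if (s1 * s2 < 0) {
        al <- s1 / (s1 - s2)
        pcut <- xy[j, ] + al * (xy[j + 1L, ] - xy[j, ])
        cur <- rbind(cur, pcut)
        pieces[[length(pieces) + 1L]] <- list(xy = cur, side = cur_side,
                                              cut_end = TRUE)
        cur <- matrix(pcut, 1, 2)
        cur_side <- sign(s2)
      }
      cur <- rbind(cur, xy[j + 1L, ])
    }
    pieces[[length(pieces) + 1L]] <- list(xy = cur, side = cur_side,
                                          cut_end = FALSE)
    for (pi in seq_along(pieces)) {
      p <- pieces[[pi]]
      if (nrow(p$xy) < 2) next
      tgt <- if (p$side >= 0) "a" else "b"
      newtr <- tr; newtr$xy <- p$xy
      if (tgt == "a") { newtr$id <- length(a$traces) + 1L
                        a$traces[[newtr$id]] <- newtr }
      else { newtr$id <- length(b$traces) + 1L
             b$traces[[newtr$id]] <- newtr }
      if (p$cut_end) {
        pair_count <- pair_count + 1L
        pcut <- p$xy[nrow(p$xy), ]
        pad <- data.frame(x = pcut[1], y = pcut[2], layer = tr$layer,
                          pair = pair_count)
        a$pads <- rbind(a$pads, pad)
        b$pads <- rbind(b$pads, pad)
      }
    }
  }
  vside <- if (coord == 1L) layout$vias$x else layout$vias$y
  a$vias <- layout$vias[vside >= cutv, , drop = FALSE]
  b$vias <- layout$vias[vside < cutv, , drop = FALSE]
  tside <- if (coord == 1L) layout$terminals$x else layout$terminals$y
  a$terminals <- layout$terminals[tside >= cutv, , drop = FALSE]
  b$terminals <- layout$terminals[tside < cutv, , drop = FALSE]
  aside <- if (coord == 1L) layout$annotations$x else layout$annotations$y
  a$annotations <- layout$annotations[aside >= cutv, , drop = FALSE]
  b$annotations <- layout$annotations[aside < cutv, , drop = FALSE]
  cutlab <- data.frame(text = "CUT", layer = "F",
                       x = if (coord == 1L) cutv else range(allxy[, 1]),
                       y = if (coord == 1L) range(allxy[, 2]) else cutv,
                       stringsAsFactors = FALSE)
  a$annotations <- rbind(a$annotations, cutlab)
  b$annotations <- rbind(b$annotations, cutlab)
  a$path <- NULL; b$path <- NULL
  structure(list(a = a, b = b, axis = axis, cut_value = cutv,
                 n_pad_pairs = pair_count),
            class = "board_pair")
}

#' Re-merge two board halves (solder the pads back together)
#'
#' @param pair a \code{board_pair} from \code{\link{split_board}}.
#' @return a \code{board_layout} whose connectivity graph (with pads
#'   joined) matches the original board's.
#' @export
merge_boards <- function(pair) {
  l <- pair$a
  off <- length(l$traces)
  for (tr in pair$b$traces) {
    tr$id <- tr$id + off
    l$traces[[tr$id]] <- tr
  }
  l$vias <- rbind(pair$a$vias, pair$b$vias)
  l$terminals <- unique(rbind(pair$a$terminals, pair$b$terminals))
  l$pads <- rbind(pair$a$pads, pair$b$pads)
  l$annotations <- unique(rbind(pair$a$annotations, pair$b$annotations))
  l$cut_axis <- pair$axis
  l
}
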