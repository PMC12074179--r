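# shared fixtures: closed-form loops and cached coil designs (module tests
# use a coarse mesh; the acceptance tests build the full-resolution designs
# themselves)

circle_loop <- function(radius, z = 0, n = 181, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), z)
}

square_loop <- function(side, z = 0) {
  h <- side / 2
  cbind(c(-h, h, h, -h, -h), c(-h, -h, h, h, -h), z)
}

# stream function approximating a single circular loop of current I:
# indicator of r < radius on the +z plane
disk_stream <- function(mesh, radius, current = 1) {
  r <- sqrt(mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2)
  v <- ifelse(mesh$plane_side == 1 & r < radius, current, 0)
  v[mesh$boundary] <- 0
  stream_function(v, mesh)
}

# equivalent loop radius of a staircase disk stream function (same total
# dipole moment); the comparison loop for the field/potential oracles
disk_equiv_radius <- function(mesh, s) {
  w <- as.numeric(s)
  tri_mean <- (w[mesh$faces[, 1]] + w[mesh$faces[, 2]] +
               w[mesh$faces[, 3]]) / 3
  areas <- opmnull:::triangle_areas(mesh$vertices, mesh$faces)
  sqrt(sum(tri_mean * areas) / pi)
}

# synthetic concentric-ring coil (clean topology for layout tests)
concentric_coil <- function(radii, z = 0.5, polarity = 1L,
                            plane_size = 1.4, separation = 2 * z) {
  loops <- lapply(radii, function(r) {
    xy <- circle_loop(r, z)
    if (polarity < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
    list(vertices = xy, polarity = as.integer(polarity), level = r,
         plane = 1L, area = pi * r^2)
  })
  structure(list(loops = loops, turns = length(radii), level_step = 1,
                 plane_size = plane_size, separation = separation),
            class = "discrete_coil")
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_design <- function(kind) {
  cached(paste0("design-", kind),
         design_coil(kind, resolution = 21, n_target = 64))
}

small_board_set <- function(kind) {
  cached(paste0("board-", kind),
         connect_loops(small_design(kind)$coil, kind = kind))
}
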