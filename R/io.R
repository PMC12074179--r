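# Manufacturing exports: Gerber RS-274X copper and silkscreen layers,
# Excellon drill files, SVG previews and a schema-versioned layout-JSON
# round trip.  All coordinates are emitted in millimeters at 1 um
# resolution; outputs carry no timestamps, so identical inputs give
# byte-identical files.

LAYOUT_SCHEMA <- "opmnull-layout"
LAYOUT_VERSION <- 1L

mm <- function(m) round(m * 1e3, 3)  # meters -> mm at 1 um resolution

#' Write a board layout as Gerber RS-274X plus an Excellon drill file
#'
#' Emits five files: front/back copper (traces drawn with a circular
#' aperture equal to the trace width), front/back silkscreen (annotation
#' markers; the text itself travels in G04 comments), and the plated
#' through-hole drill file (2 mm tool).  Metric units, 4.6 coordinate
#' format, leading zeros omitted.
#'
#' @param layout a \code{board_layout} (see \code{\link{connect_loops}},
#'   \code{\link{split_board}}); must pass \code{\link{board_connected}}.
#' @param outdir output directory (created if missing).
#' @param name file-name stem.
#' @return object of class \code{gerber_set}: named file paths.
#' @export
write_gerber <- function(layout, outdir, name = "coil") {
  if (!isTRUE(as.logical(board_connected(layout, join_pads = TRUE))))
    stop("refusing to export: layout is not a single connected path",
         call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt_coord <- function(v) {
    # 4.6 metric: integer micrometer-and-tenths units (1e-6 mm)
    sprintf("%d", round(v * 1e6))
  }
  copper <- function(layer, path) {
    con <- file(path, "wb")  # binary: fixed LF line endings
    wl <- function(s) writeLines(s, con, sep = "\n")
    wl("G04 opmnull Gerber RS-274X*")
    wl(sprintf("G04 layer %s copper*", layer))
    wl("%FSLAX46Y46*%")
    wl("%MOMM*%")
    wl(sprintf("%%ADD10C,%.6f*%%", layout$trace_width_mm))
    wl("D10*")
    for (tr in layout$traces) {
      if (tr$layer != layer) next
      xy <- mm(tr$xy)
      wl(sprintf("X%sY%sD02*", fmt_coord(xy[1, 1]), fmt_coord(xy[1, 2])))
      for (r in 2:nrow(xy))
        wl(sprintf("X%sY%sD01*", fmt_coord(xy[r, 1]), fmt_coord(xy[r, 2])))
    }
    pads <- layout$pads[layout$pads$layer == layer, , drop = FALSE]
    if (nrow(pads) > 0) {
      wl(sprintf("%%ADD11C,%.6f*%%", 1.5 * layout$trace_width_mm))
      wl("D11*")
      for (r in seq_len(nrow(pads)))
        wl(sprintf("X%sY%sD03*", fmt_coord(mm(pads$x[r])),
                   fmt_coord(mm(pads$y[r]))))
    }
    wl("M02*")
    close(con)
    path
  }
  silk <- function(layer, path) {
    con <- file(path, "wb")
    wl <- function(s) writeLines(s, con, sep = "\n")
    wl("G04 opmnull Gerber RS-274X silkscreen*")
    wl("%FSLAX46Y46*%")
    wl("%MOMM*%")
    wl("%ADD12C,0.300000*%")
    wl("D12*")
    ann <- layout$annotations[layout$annotations$layer == layer, ,
                              drop = FALSE]
    for (r in seq_len(nrow(ann))) {
      wl(sprintf("G04 text %s*", gsub("\\*", "", ann$text[r])))
      wl(sprintf("X%sY%sD03*", fmt_coord(mm(ann$x[r])),
                 fmt_coord(mm(ann$y[r]))))
    }
    wl("M02*")
    close(con)
    path
  }
  drill <- function(path) {
    con <- file(path, "wb")
    wl <- function(s) writeLines(s, con, sep = "\n")
    wl("M48")
    wl("; opmnull Excellon drill, plated through holes")
    wl("METRIC,TZ")
    wl("T1C2.000")
    wl("%")
    wl("T1")
    for (r in seq_len(nrow(layout$vias)))
      wl(sprintf("X%.3fY%.3f", mm(layout$vias$x[r]), mm(layout$vias$y[r])))
    wl("M30")
    close(con)
    path
  }
  files <- c(
    front_copper = copper("F", file.path(outdir, paste0(name, "-F_Cu.gtl"))),
    back_copper = copper("B", file.path(outdir, paste0(name, "-B_Cu.gbl"))),
    front_silk = silk("F", file.path(outdir, paste0(name, "-F_Silk.gto"))),
    back_silk = silk("B", file.path(outdir, paste0(name, "-B_Silk.gbo"))),
    drill = drill(file.path(outdir, paste0(name, ".drl")))
  )
  structure(as.list(files), class = "gerber_set")
}

#' Parse back a Gerber copper layer written by \code{\link{write_gerber}}
#'
#' Round-trip reader used to verify the export: returns the draw
#' polylines (mm) and the aperture diameter.
#'
#' @param path a Gerber file.
#' @return list with \code{polylines} (list of k x 2 matrices, mm),
#'   \code{aperture_mm}, \code{flashes} (pad positions, mm).
#' @export
read_gerber <- function(path) {
  lines <- readLines(path)
  ap <- regmatches(lines, regexec("^%ADD10C,([0-9.]+)\\*%$", lines))
  ap <- as.numeric(unlist(lapply(ap, `[`, 2)))
  ap <- ap[!is.na(ap)][1]
  polylines <- list()
  flashes <- matrix(numeric(0), 0, 2)
  cur <- NULL
  for (ln in lines) {
    m <- regexec("^X(-?[0-9]+)Y(-?[0-9]+)D0([123])\\*$", ln)[[1]]
    if (m[1] == -1) next
    parts <- regmatches(ln, regexec("^X(-?[0-9]+)Y(-?[0-9]+)D0([123])\\*$",
                                    ln))[[1]]
    x <- as.numeric(parts[2]) / 1e6
    y <- as.numeric(parts[3]) / 1e6
    op <- parts[4]
    if (op == "2") {
      if (!is.null(cur) && nrow(cur) > 1)
        polylines[[length(polylines) + 1L]] <- cur
      cur <- matrix(c(x, y), 1, 2)
    } else if (op == "1") {
      cur <- rbind(cur, c(x, y))
    } else {
      flashes <- rbind(flashes, c(x, y))
    }
  }
  if (!is.null(cur) && nrow(cur) > 1)
    polylines[[length(polylines) + 1L]] <- cur
  list(polylines = polylines, aperture_mm = ap, flashes = flashes)
}

#' @rdname read_gerber
#' @return for \code{read_drill}: list with \code{tool_mm} and
#'   \code{holes} (k x 2 matrix, mm).
#' @export
read_drill <- function(path) {
  lines <- readLines(path)
  tool <- regmatches(lines, regexec("^T1C([0-9.]+)$", lines))
  tool <- as.numeric(unlist(lapply(tool, `[`, 2)))
  tool <- tool[!is.na(tool)][1]
  hm <- regmatches(lines, regexec("^X(-?[0-9.]+)Y(-?[0-9.]+)$", lines))
  holes <- do.call(rbind, lapply(hm, function(p)
    if (length(p) == 3) as.numeric(p[2:3]) else NULL))
  list(tool_mm = tool, holes = holes)
}

#' Write an SVG preview of a board layout
#'
#' Front copper in red, back copper in blue, vias as filled circles,
#' solder pads as squares, annotations as text.  Deterministic output.
#'
#' @param layout a \code{board_layout}.
#' @param path output file.
#' @param width_px image width in pixels.
#' @return \code{path}, invisibly.
#' @export
write_board_svg <- function(layout, path, width_px = 800) {
  allxy <- do.call(rbind, lapply(layout$traces, `[[`, "xy"))
  lim <- range(allxy) + c(-0.02, 0.02)
  span <- diff(lim)
  sc <- width_px / span
  px <- function(v) sprintf("%.2f", (v - lim[1]) * sc)
  py <- function(v) sprintf("%.2f", (lim[2] - v) * sc)
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width_px, width_px, width_px, width_px),
    '<rect width="100%" height="100%" fill="white"/>')
  wmm <- max(1, layout$trace_width_mm * 1e-3 * sc)
  for (lay in c("B", "F")) {
    col <- if (lay == "F") "#c0392b" else "#2980b9"
    for (tr in layout$traces) {
      if (tr$layer != lay) next
      pts <- paste(px(tr$xy[, 1]), py(tr$xy[, 2]), sep = ",",
                   collapse = " ")
      out <- c(out, sprintf(
        '<polyline points="%s" fill="none" stroke="%s" stroke-width="%.2f" stroke-opacity="0.8"/>',
        pts, col, wmm))
    }
  }
  for (r in seq_len(nrow(layout$vias)))
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%.2f" fill="#2c3e50"/>',
      px(layout$vias$x[r]), py(layout$vias$y[r]),
      max(1.5, 1e-3 * sc)))
  if (nrow(layout$pads) > 0)
    for (r in seq_len(nrow(layout$pads)))
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%.2f" height="%.2f" fill="#f39c12"/>',
        px(layout$pads$x[r] - 2e-3), py(layout$pads$y[r] + 2e-3),
        4e-3 * sc, 4e-3 * sc))
  for (r in seq_len(nrow(layout$annotations)))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="12" fill="#333">%s</text>',
      px(layout$annotations$x[r]), py(layout$annotations$y[r]),
      layout$annotations$text[r]))
  out <- c(out, "</svg>")
  con <- file(path, "wb")
  writeLines(out, con, sep = "\n")
  close(con)
  invisible(path)
}

trace_to_json <- function(tr) {
  list(id = tr$id, layer = tr$layer, role = tr$role,
       xy_mm = unname(apply(mm(tr$xy), 1, as.numeric, simplify = FALSE)),
       nest = tr$nest, loop_id = tr$loop_id, polarity = tr$polarity,
       partner_of = tr$partner_of)
}

#' Layout-JSON round trip
#'
#' Serializes a \code{board_layout} to a schema-versioned JSON document
#' (coordinates in mm at 1 um resolution) and reads it back losslessly.
#' Unknown top-level fields and unsupported schema versions are rejected.
#'
#' @param layout a \code{board_layout}.
#' @param path file path.
#' @return \code{write_layout}: \code{path} invisibly;
#'   \code{read_layout}: the \code{board_layout}.
#' @export
write_layout <- function(layout, path) {
  doc <- list(
    schema = LAYOUT_SCHEMA,
    version = LAYOUT_VERSION,
    units = "mm",
    plane = layout$plane,
    z_mm = mm(layout$z),
    plane_size_mm = mm(layout$plane_size),
    trace_width_mm = layout$trace_width_mm,
    cut_axis = layout$cut_axis,
    traces = lapply(layout$traces, trace_to_json),
    vias = list(x_mm = mm(layout$vias$x), y_mm = mm(layout$vias$y),
                drill_mm = layout$vias$drill_mm),
    pads = list(x_mm = mm(layout$pads$x), y_mm = mm(layout$pads$y),
                layer = layout$pads$layer, pair = layout$pads$pair),
    terminals = list(x_mm = mm(layout$terminals$x),
                     y_mm = mm(layout$terminals$y),
                     layer = layout$terminals$layer,
                     name = layout$terminals$name),
    path = list(id = layout$path$id, rev = layout$path$rev),
    annotations = list(text = layout$annotations$text,
                       x_mm = mm(layout$annotations$x),
                       y_mm = mm(layout$annotations$y),
                       layer = layout$annotations$layer)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("layout-JSON parse error: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (!identical(doc$schema, LAYOUT_SCHEMA))
    stop("not a layout-JSON document (schema field missing or wrong)",
         call. = FALSE)
  if (!identical(as.integer(doc$version), LAYOUT_VERSION))
    stop("unsupported layout-JSON schema version: ", doc$version,
         call. = FALSE)
  known <- c("schema", "version", "units", "plane", "z_mm", "plane_size_mm",
             "trace_width_mm", "cut_axis", "traces", "vias", "pads",
             "terminals", "path", "annotations")
  extra <- setdiff(names(doc), known)
  if (length(extra) > 0)
    stop("unknown field(s) in layout-JSON: ", paste(extra, collapse = ", "),
         call. = FALSE)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  traces <- lapply(doc$traces, function(tr) {
    xy <- do.call(rbind, lapply(tr$xy_mm, num)) / 1e3
    new_trace(as.integer(tr$id), tr$layer, tr$role, xy,
              nest = tr$nest %||% NA_integer_,
              loop_id = tr$loop_id %||% NA_integer_,
              polarity = tr$polarity %||% NA_integer_,
              partner_of = tr$partner_of %||% NA_integer_)
  })
  structure(
    list(
      plane = doc$plane,
      z = doc$z_mm / 1e3,
      plane_size = doc$plane_size_mm / 1e3,
      trace_width_mm = doc$trace_width_mm,
      traces = traces,
      vias = data.frame(x = num(doc$vias$x_mm) / 1e3,
                        y = num(doc$vias$y_mm) / 1e3,
                        drill_mm = num(doc$vias$drill_mm)),
      terminals = data.frame(x = num(doc$terminals$x_mm) / 1e3,
                             y = num(doc$terminals$y_mm) / 1e3,
                             layer = chr(doc$terminals$layer),
                             name = chr(doc$terminals$name)),
      path = data.frame(id = as.integer(unlist(doc$path$id)),
                        rev = as.logical(unlist(doc$path$rev))),
      pads = if (length(doc$pads$x_mm) > 0)
        data.frame(x = num(doc$pads$x_mm) / 1e3,
                   y = num(doc$pads$y_mm) / 1e3,
                   layer = chr(doc$pads$layer),
                   pair = as.integer(unlist(doc$pads$pair)))
      else data.frame(x = numeric(), y = numeric(),
                      layer = character(), pair = integer()),
      cut_axis = doc$cut_axis,
      annotations = if (length(doc$annotations$text) > 0)
        data.frame(text = chr(doc$annotations$text),
                   x = num(doc$annotations$x_mm) / 1e3,
                   y = num(doc$annotations$y_mm) / 1e3,
                   layer = chr(doc$annotations$layer),
                   stringsAsFactors = FALSE)
      else data.frame(text = character(), x = numeric(), y = numeric(),
                      layer = character(), stringsAsFactors = FALSE)
    ),
    class = "board_layout"
  )
}

#' Write and read a design/shield configuration as YAML
#'
#' The configuration mirrors \code{\link{design_coil}}'s arguments plus an
#' optional list of shield panels (center, normal, half-extent,
#' resolution).
#'
#' @param config a named list.
#' @param path file path.
#' @return \code{read_config}: the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Design report as YAML
#'
#' Records the design's operating point: kind, geometry, turns, the
#' regularization that the residual rule selected, the achieved residual
#' and the efficiency.
#'
#' @param design a \code{coil_design}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_design_report <- function(design, path) {
  yaml::write_yaml(list(
    kind = design$kind,
    plane_size_m = design$mesh$plane_size,
    separation_m = design$mesh$separation,
    resolution = design$mesh$resolution,
    turns = design$coil$turns,
    n_loops = length(design$coil$loops),
    lambda = design$solution$lambda,
    relative_residual = design$solution$residual,
    level_step_A = design$coil$level_step,
    loops_length_m = loops_length(design$coil),
    efficiency = as.numeric(design$efficiency),
    efficiency_units = attr(design$efficiency, "units")
  ), path)
  invisible(path)
}
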