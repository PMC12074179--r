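# Physical coil properties: copper-weight conversion, trace resistance and
# the six-coil report table.

#' Copper weight to layer thickness
#'
#' PCB copper is specified in oz/ft^2.  The industry nominal conversion is
#' 35 um per oz (the value manufacturers quote; 2 oz = 70 um), which is the
#' default here.  \code{convention = "density"} instead derives the
#' thickness from the copper density (8.96 g/cm^3, 1 oz = 28.3495 g spread
#' over 1 ft^2 = 929.0304 cm^2), giving 34.06 um/oz.
#'
#' @param weight_oz copper weight (oz/ft^2), > 0.
#' @param convention \code{"nominal"} (35 um/oz) or \code{"density"}.
#' @return thickness in micrometers.
#' @examples
#' copper_thickness(1)  # 35
#' copper_thickness(2)  # 70
#' copper_thickness(1, "density")  # 34.06
#' @export
copper_thickness <- function(weight_oz, convention = c("nominal", "density")) {
  convention <- match.arg(convention)
  if (any(weight_oz <= 0)) stop("weight must be > 0", call. = FALSE)
  per_oz <- if (convention == "nominal") 35
            else 28.3495 / (8.96 * 929.0304) * 1e4  # cm -> um
  weight_oz * per_oz
}

#' PCB trace specification
#'
#' @param width_mm trace width (mm), > 0; 5 mm is the widest width typical
#'   manufacturers etch without extra cost.
#' @param copper_oz copper weight (oz/ft^2).
#' @param resistivity conductor resistivity (Ohm m); default annealed copper
#'   1.72e-8.
#' @return object of class \code{trace_spec} with the derived
#'   \code{thickness_um}.
#' @export
trace_spec <- function(width_mm = 5, copper_oz = 2, resistivity = 1.72e-8) {
  if (width_mm <= 0) stop("trace width must be > 0", call. = FALSE)
  structure(
    list(width_mm = width_mm, copper_oz = copper_oz,
         thickness_um = copper_thickness(copper_oz),
         resistivity = resistivity),
    class = "trace_spec"
  )
}

#' @export
print.trace_spec <- function(x, ...) {
  cat(sprintf("PCB trace: %.3g mm wide, %g oz Cu (%.3g um), rho = %.3g Ohm m\n",
              x$width_mm, x$copper_oz, x$thickness_um, x$resistivity))
  invisible(x)
}

#' DC resistance of a PCB trace
#'
#' R = rho L / (w t).
#'
#' @param length_m trace length (m), >= 0.
#' @param spec a \code{\link{trace_spec}}.
#' @return resistance (Ohm).
#' @examples
#' trace_resistance(170.6, trace_spec(5, 2))  # ~8.4 Ohm
#' @export
trace_resistance <- function(length_m, spec = trace_spec()) {
  if (any(length_m < 0)) stop("length must be >= 0", call. = FALSE)
  spec$resistivity * length_m /
    (spec$width_mm * 1e-3 * spec$thickness_um * 1e-6)
}

#' Coil property report (lengths, resistances, efficiencies)
#'
#' Builds the per-coil summary table: loops-only conductor length, connected
#' (PCB path) length, the corresponding resistances, and the free-space and
#' shielded efficiencies where available.
#'
#' @param designs named list of \code{coil_design} objects (names are coil
#'   kinds).
#' @param layouts optional named list of board sets from
#'   \code{\link{connect_loops}} (same names); supplies connected lengths.
#' @param shielded_eff optional named numeric vector of shielded
#'   efficiencies.
#' @param measured optional named numeric vector of measured efficiencies
#'   (reported for comparison only).
#' @param spec a \code{\link{trace_spec}}.
#' @return a data.frame, one row per coil.
#' @export
properties_report <- function(designs, layouts = NULL, shielded_eff = NULL,
                              measured = NULL, spec = trace_spec()) {
  if (length(designs) == 0) {
    return(data.frame(
      coil = character(), length_loops_m = numeric(),
      length_connected_m = numeric(), resistance_loops_ohm = numeric(),
      resistance_connected_ohm = numeric(), efficiency = numeric(),
      efficiency_shielded = numeric(), efficiency_measured = numeric(),
      units = character(), stringsAsFactors = FALSE
    ))
  }
  if (!all(COIL_KINDS %in% names(designs)))
    warning("partial report: missing coil(s) ",
            paste(setdiff(COIL_KINDS, names(designs)), collapse = ", "),
            call. = FALSE)
  rows <- lapply(names(designs), function(k) {
    d <- designs[[k]]
    llen <- loops_length(d$coil)
    clen <- if (!is.null(layouts[[k]])) board_set_length(layouts[[k]])
            else NA_real_
    data.frame(
      coil = k,
      length_loops_m = llen,
      length_connected_m = clen,
      resistance_loops_ohm = trace_resistance(llen, spec),
      resistance_connected_ohm = if (is.na(clen)) NA_real_
                                 else trace_resistance(clen, spec),
      efficiency = as.numeric(d$efficiency),
      efficiency_shielded = if (!is.null(shielded_eff[[k]]))
        as.numeric(shielded_eff[[k]]) else NA_real_,
      efficiency_measured = if (!is.null(measured[[k]]))
        as.numeric(measured[[k]]) else NA_real_,
      units = attr(d$efficiency, "units") %||% "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a property report as CSV (rounded) and YAML (full precision)
#'
#' The CSV mirrors the familiar published table layout with values rounded
#' to one decimal; the YAML file keeps machine precision.
#'
#' @param report data.frame from \code{\link{properties_report}}.
#' @param csv_path,yaml_path output paths (either may be \code{NULL}).
#' @return the report, invisibly.
#' @export
write_properties <- function(report, csv_path = NULL, yaml_path = NULL) {
  if (!is.null(csv_path)) {
    rounded <- report
    num <- vapply(rounded, is.numeric, TRUE)
    rounded[num] <- lapply(rounded[num], round, 1)
    utils::write.csv(rounded, csv_path, row.names = FALSE)
  }
  if (!is.null(yaml_path)) {
    yaml::write_yaml(lapply(split(report, report$coil), as.list), yaml_path)
  }
  invisible(report)
}
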