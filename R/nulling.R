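# Background-field nulling: estimate the sensor-by-coil coupling matrix
# from per-coil activations, solve for the drive currents that null a
# measured background, and simulate the whole procedure against the actual
# coil layouts.

#' Estimate the sensor-by-coil coupling matrix
#'
#' Each nulling coil is driven one at a time with a known current while
#' every sensor is read; with an all-coils-off baseline subtracted, column
#' k of the coupling matrix M is the field change per unit current of coil
#' k (nT/mA), so that sensor readings obey b = M I.
#'
#' @param readings a data.frame with columns \code{sensor}, \code{coil},
#'   \code{current_mA} and \code{field_nT}: one row per sensor per
#'   activation.  Rows with \code{coil == "baseline"} (any current) give
#'   the all-coils-off reading per sensor.  Repeated activations of a coil
#'   are averaged (least squares through the origin).
#' @param coils optional character vector fixing the coil order; must not
#'   contain duplicates.
#' @return object of class \code{nulling_model}: \code{M} (sensors x
#'   coils, nT/mA), \code{sensors}, \code{coils}, \code{condition} (2-norm
#'   condition number).
#' @export
estimate_coupling <- function(readings, coils = NULL) {
  need <- c("sensor", "coil", "current_mA", "field_nT")
  if (!all(need %in% names(readings)))
    stop("readings must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(coils) && anyDuplicated(coils))
    stop("duplicate coil labels", call. = FALSE)
  act <- readings[readings$coil != "baseline", , drop = FALSE]
  if (any(act$current_mA == 0))
    stop("zero activation current for coil ",
         act$coil[act$current_mA == 0][1], call. = FALSE)
  sensors <- sort(unique(readings$sensor))
  if (is.null(coils)) coils <- unique(act$coil)
  base <- readings[readings$coil == "baseline", , drop = FALSE]
  baseline <- setNames(rep(0, length(sensors)), sensors)
  if (nrow(base) > 0) {
    bb <- tapply(base$field_nT, base$sensor, mean)
    baseline[names(bb)] <- bb
  }
  M <- matrix(0, length(sensors), length(coils),
              dimnames = list(sensors, coils))
  for (k in seq_along(coils)) {
    rows <- act[act$coil == coils[k], , drop = FALSE]
    if (nrow(rows) == 0)
      stop("no activation readings for coil ", coils[k], call. = FALSE)
    for (s in seq_along(sensors)) {
      rs <- rows[rows$sensor == sensors[s], , drop = FALSE]
      if (nrow(rs) == 0) next
      db <- rs$field_nT - baseline[s]
      # least-squares slope through the origin over repeats
      M[s, k] <- sum(db * rs$current_mA) / sum(rs$current_mA^2)
    }
  }
  sv <- svd(M)$d
  structure(
    list(M = M, sensors = sensors, coils = coils,
         condition = if (min(sv) > 0) max(sv) / min(sv) else Inf),
    class = "nulling_model"
  )
}

#' @export
print.nulling_model <- function(x, ...) {
  cat(sprintf("Nulling model: %d sensors x %d coils, condition number %.3g\n",
              nrow(x$M), ncol(x$M), x$condition))
  invisible(x)
}

#' Coil currents that null a measured background field
#'
#' Solves b = M I for the drive currents: an exact inverse for square M, a
#' least-squares solution when there are more sensors than coils.  Applying
#' minus these currents cancels the background at the sensors (to the
#' residual reported).
#'
#' @param model a \code{\link{nulling_model}}.
#' @param background measured field per sensor (nT), in the model's sensor
#'   order.
#' @param cond_limit warn (not fail) when the model's condition number
#'   exceeds this; default 100.
#' @return object of class \code{nulling_currents}: \code{currents} (mA,
#'   named by coil), \code{residual} (nT per sensor), \code{residual_norm}.
#' @export
nulling_currents <- function(model, background, cond_limit = 100) {
  b <- as.numeric(background)
  if (length(b) != nrow(model$M))
    stop("background length must match the sensor count", call. = FALSE)
  if (model$condition > cond_limit)
    warning(sprintf(
      "coupling matrix condition number %.3g exceeds %.3g; currents may be unreliable",
      model$condition, cond_limit), call. = FALSE)
  M <- model$M
  I <- if (nrow(M) == ncol(M)) solve(M, b) else qr.solve(M, b)
  res <- b - drop(M %*% I)
  structure(
    list(currents = setNames(drop(I), model$coils), residual = res,
         residual_norm = sqrt(sum(res^2))),
    class = "nulling_currents"
  )
}

#' @export
print.nulling_currents <- function(x, ...) {
  cat("Nulling currents (mA):\n")
  print(round(x$currents, 4))
  cat(sprintf("predicted residual norm %.4g nT\n", x$residual_norm))
  invisible(x)
}

#' Sensor bias correction by flipping
#'
#' A sensor's offset can be separated from the field by taking one reading
#' in the original orientation and one with the sensor flipped along its
#' sensitive axis: the bias is the mean of the two (the field term changes
#' sign), and the corrected field is half their difference.
#'
#' @param reading,flipped readings (nT) in the original and flipped
#'   orientations.
#' @return list with \code{bias} and \code{corrected} (both nT).
#' @export
flip_bias_correct <- function(reading, flipped) {
  list(bias = (reading + flipped) / 2, corrected = (reading - flipped) / 2)
}

#' Helmet-like sensor layout
#'
#' Places sensors quasi-uniformly on the upper hemisphere of a sphere
#' (a stand-in for an OPM helmet) with radially-outward sensitive axes,
#' optionally jittered so the sensors point in genuinely different
#' directions, which keeps the coupling matrix well conditioned.
#'
#' @param n number of sensors.
#' @param radius helmet radius (m).
#' @param center helmet center (m).
#' @param jitter orientation jitter (radians, sd of a random tilt).
#' @param seed integer seed.
#' @return list with \code{positions} (n x 3) and unit \code{orientations}
#'   (n x 3).
#' @export
helmet_sensors <- function(n = 16, radius = 0.1, center = c(0, 0, 0),
                           jitter = 0.2, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- i / n                     # upper hemisphere only
  rho <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), z)
  if (jitter > 0) {
    dirs <- dirs + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
  }
  list(positions = sweep(radius * dirs, 2, center, "+"),
       orientations = dirs)
}

#' Simulate a background-field nulling session
#'
#' End-to-end simulation of the nulling procedure against the actual
#' discretized coils: a background field (uniform vector, optional uniform
#' gradient, optional slow linear drift) is observed by helmet sensors
#' along their sensitive axes; each coil is activated in turn at a probe
#' current to build the coupling matrix via \code{\link{estimate_coupling}};
#' \code{\link{nulling_currents}} is solved once at time zero and the
#' (frozen) compensation currents are applied while the background
#' continues to drift.
#'
#' @param coils named list of \code{discrete_coil} objects (or closed-loop
#'   lists), one per nulling coil.
#' @param sensors a \code{\link{helmet_sensors}} layout.
#' @param background list with \code{uniform} (length-3, nT), optional
#'   \code{gradient} (3 x 3 tensor, nT/m, applied as G %*% r) and optional
#'   \code{drift} (length-3, nT per unit time, added as t * drift).
#' @param probe_current_mA per-coil activation current for building M.
#' @param times time points at which the residual is evaluated (the
#'   currents are set at the first one).
#' @param noise_sd sensor noise (nT) added to every reading.
#' @param seed integer seed (noise only).
#' @return object of class \code{nulling_session}: the model, currents and
#'   a data.frame \code{trace} with max absolute residual per time point,
#'   plus \code{before} (max |background| reading at t = 0).
#' @export
simulate_nulling_session <- function(coils, sensors,
                                     background = list(uniform = c(0, 0, 21)),
                                     probe_current_mA = 10,
                                     times = 0,
                                     noise_sd = 0,
                                     seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  pos <- sensors$positions
  ori <- sensors$orientations
  ns <- nrow(pos)
  if (is.null(names(coils))) names(coils) <- paste0("coil", seq_along(coils))
  bg_at <- function(t) {
    b <- matrix(background$uniform %||% c(0, 0, 0), ns, 3, byrow = TRUE)
    if (!is.null(background$gradient))
      b <- b + t(background$gradient %*% t(pos))
    if (!is.null(background$drift))
      b <- b + t * matrix(background$drift, ns, 3, byrow = TRUE)
    b
  }
  proj <- function(B3) rowSums(B3 * ori)
  noise <- function() if (noise_sd > 0) stats::rnorm(ns, sd = noise_sd) else 0
  # coil fields per mA, projected on the sensor axes (nT/mA)
  coil_proj <- vapply(coils, function(cl)
    proj(polyline_field(cl, 1e-3, pos)) * 1e9, numeric(ns))
  t0 <- times[1]
  baseline <- proj(bg_at(t0)) + noise()
  rows <- data.frame(sensor = seq_len(ns), coil = "baseline",
                     current_mA = 0, field_nT = baseline)
  for (k in seq_along(coils)) {
    reading <- proj(bg_at(t0)) + probe_current_mA * coil_proj[, k] + noise()
    rows <- rbind(rows, data.frame(sensor = seq_len(ns),
                                   coil = names(coils)[k],
                                   current_mA = probe_current_mA,
                                   field_nT = reading))
  }
  model <- estimate_coupling(rows, coils = names(coils))
  sol <- nulling_currents(model, baseline)
  trace <- do.call(rbind, lapply(times, function(t) {
    resid <- proj(bg_at(t)) - drop(coil_proj %*% sol$currents)
    data.frame(time = t, max_residual_nT = max(abs(resid)))
  }))
  structure(
    list(model = model, currents = sol, trace = trace,
         before = max(abs(baseline))),
    class = "nulling_session"
  )
}

#' @export
print.nulling_session <- function(x, ...) {
  cat(sprintf(
    "Nulling session: max |field| %.3g nT before, %.3g nT after (t = %g)\n",
    x$before, x$trace$max_residual_nT[1], x$trace$time[1]))
  if (nrow(x$trace) > 1)
    cat(sprintf("  residual at t = %g: %.3g nT\n",
                x$trace$time[nrow(x$trace)],
                x$trace$max_residual_nT[nrow(x$trace)]))
  invisible(x)
}

#' Read and write activation tables and solved currents
#'
#' Activation readings travel as delimited text with columns
#' \code{sensor}, \code{coil}, \code{current_mA}, \code{field_nT};
#' solved currents as two-column text and as YAML.
#'
#' @param path file path.
#' @param sep field separator.
#' @return \code{read_readings}: the readings data.frame.
#' @export
read_readings <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}

#' @rdname read_readings
#' @param readings readings data.frame to write.
#' @export
write_readings <- function(readings, path, sep = "\t") {
  utils::write.table(readings, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname read_readings
#' @param currents a \code{nulling_currents} object.
#' @param yaml_path optional YAML output with full metadata.
#' @export
write_currents <- function(currents, path, yaml_path = NULL, sep = "\t") {
  df <- data.frame(coil = names(currents$currents),
                   current_mA = as.numeric(currents$currents))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(yaml_path))
    yaml::write_yaml(list(currents_mA = as.list(currents$currents),
                          residual_norm_nT = currents$residual_norm),
                     yaml_path)
  invisible(path)
}
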