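# Plain-text readers/writers for the measurement formats the analysis
# consumes. All formats are comma-separated columns with `# key=value`
# header lines carrying the scalar metadata.

.read_header_keys <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*([-0-9.eE+]+)", l))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
  }
  kv
}

#' Read a permeation measurement from columnar text
#'
#' Expects columns `time_s,mass_g` and header lines
#' `# clot_length_m=...`, `# tube_diameter_m=...`, `# pressure_drop_pa=...`,
#' `# viscosity_pa_s=...`.
#'
#' @param path File path.
#' @return A [permeation_measurement()].
#' @export
read_permeation <- function(path) {
  kv <- .read_header_keys(path)
  need <- c("clot_length_m", "tube_diameter_m", "pressure_drop_pa",
            "viscosity_pa_s")
  if (!all(need %in% names(kv)))
    stop("missing header keys: ", paste(setdiff(need, names(kv)), collapse = ", "))
  df <- utils::read.csv(path, comment.char = "#")
  permeation_measurement(
    clot_length = kv$clot_length_m,
    tube_area = pi * kv$tube_diameter_m^2 / 4,
    pressure_drop = kv$pressure_drop_pa,
    viscosity = kv$viscosity_pa_s,
    flow_series = df[, c("time_s", "mass_g")])
}

#' Write a permeation measurement to columnar text
#'
#' @param m A [permeation_measurement()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_permeation <- function(m, path) {
  stopifnot(inherits(m, "permeation_measurement"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# clot_length_m=%.10g", m$clot_length),
    sprintf("# tube_diameter_m=%.10g", sqrt(4 * m$tube_area / pi)),
    sprintf("# pressure_drop_pa=%.10g", m$pressure_drop),
    sprintf("# viscosity_pa_s=%.10g", m$viscosity)), con)
  utils::write.csv(m$flow_series, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FRAP trace from columnar text
#'
#' Expects columns `time_s,intensity` and a `# roi_radius_um=...` header;
#' optional `# I_pre=`, `# I_0=`, `# I_inf=` anchors (estimated from the
#' trace when absent).
#'
#' @param path File path.
#' @return A [frap_trace()].
#' @export
read_frap_trace <- function(path) {
  kv <- .read_header_keys(path)
  if (is.null(kv$roi_radius_um)) stop("missing header key roi_radius_um")
  df <- utils::read.csv(path, comment.char = "#")
  frap_trace(df$time_s, df$intensity, roi_radius = kv$roi_radius_um,
             I_pre = kv$I_pre, I_0 = kv$I_0, I_inf = kv$I_inf)
}

#' Write a FRAP trace to columnar text
#'
#' @param trace A [frap_trace()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# roi_radius_um=%.10g", trace$roi_radius),
    sprintf("# I_pre=%.10g", trace$I_pre),
    sprintf("# I_0=%.10g", trace$I_0),
    sprintf("# I_inf=%.10g", trace$I_inf)), con)
  utils::write.csv(data.frame(time_s = trace$times,
                              intensity = trace$intensities),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gel sample table
#'
#' Columnar text `c_fg_mg_ml,phi,r_f_nm,k_um2`; empty fields are allowed for
#' quantities not yet derived.
#'
#' @param path File path.
#' @return A `data.frame` of class `gel_panel` with columns `c_fg`, `phi`,
#'   `r_f`, `k_s`.
#' @export
read_gel_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("c_fg_mg_ml", "phi", "r_f_nm", "k_um2")
  if (!all(need %in% names(df)))
    stop("gel table must have columns ", paste(need, collapse = ", "))
  out <- data.frame(c_fg = df$c_fg_mg_ml, phi = df$phi,
                    r_f = df$r_f_nm, k_s = df$k_um2)
  structure(out, class = c("gel_panel", "data.frame"))
}

#' Write a gel sample table
#'
#' @param panel A `gel_panel` (or data.frame with columns `c_fg`, `phi`,
#'   `r_f`, `k_s`).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_gel_table <- function(panel, path) {
  utils::write.csv(
    data.frame(c_fg_mg_ml = panel$c_fg, phi = panel$phi,
               r_f_nm = panel$r_f, k_um2 = panel$k_s),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a concentration field as columnar text
#'
#' Writes `r,theta,c` (nondimensional radius in units of R1) for every cell.
#'
#' @param field A `concentration_field`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_concentration_field <- function(field, path) {
  stopifnot(inherits(field, "concentration_field"))
  df <- data.frame(r = rep(field$r_centers, length(field$th_centers)),
                   theta = rep(field$th_centers, each = length(field$r_centers)),
                   c = as.vector(field$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a velocity field on a user grid as columnar text
#'
#' Writes `r_um,theta_rad,u_r,u_theta` over the outer product of `r` and
#' `theta`.
#'
#' @param sol A [solve_composite_sphere()] solution.
#' @param r Radii, um.
#' @param theta Polar angles, rad.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(sol, r, theta, path) {
  rr <- rep(r, length(theta))
  tt <- rep(theta, each = length(r))
  u <- flow_velocity(sol, rr, tt)
  utils::write.csv(data.frame(r_um = rr, theta_rad = tt,
                              u_r = u[, "u_r"], u_theta = u[, "u_theta"]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
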