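#' Two-regime pressure transduction
#'
#' Converts a lumen diameter series at a catheter port into pressure. While
#' the lumen is wider than the contact threshold the port sees intrabolus
#' hydrodynamic pressure, rising gently (`hydro_gain`) with luminal narrowing;
#' once the wall closes onto the port the reading switches to mucosal contact
#' pressure, rising steeply (`contact_gain`) with further narrowing. The two
#' branches meet continuously at the threshold.
#'
#' @param d_mm Lumen diameter at the port, mm (vector).
#' @param baseline_d_mm Resting lumen diameter at the port, mm.
#' @param mano A [manometry_config()].
#' @return Pressure in mmHg (same length as `d_mm`).
#' @export
#' @examples
#' transduce_pressure(c(20, 10, 5, 0), 20, manometry_config())
transduce_pressure <- function(d_mm, baseline_d_mm, mano) {
  thr <- mano$occlusion_threshold_mm
  hydro <- mano$baseline_mmHg + mano$hydro_gain_mmHg_per_mm * (baseline_d_mm - d_mm)
  contact <- mano$baseline_mmHg +
    mano$hydro_gain_mmHg_per_mm * (baseline_d_mm - thr) +
    mano$contact_gain_mmHg_per_mm * (thr - d_mm)
  ifelse(d_mm > thr, hydro, contact)
}

#' Arc-length positions of the catheter ports on the modelled axis
#'
#' Ports are numbered from the distal end (port 1 most distal); ports whose
#' position falls outside the modelled antral segment are marked out-of-antrum
#' and emit baseline plus noise only.
#'
#' @param mano A [manometry_config()].
#' @param axis_length_mm Length of the modelled axis, mm.
#' @return Tibble: `port`, `s_mm`, `in_antrum`.
#' @export
port_positions <- function(mano, axis_length_mm) {
  s <- axis_length_mm - mano$distal_offset_mm -
    (seq_len(mano$n_ports) - 1) * mano$port_spacing_mm
  tibble(port = seq_len(mano$n_ports), s_mm = s,
         in_antrum = s >= 0 & s <= axis_length_mm)
}

#' Simulate the perfused-manometry record of one acquisition block
#'
#' Interpolates the ground-truth diameter series at each in-antrum port
#' position up to the manometry sampling rate, transduces it through the
#' two-regime pressure model, and adds a respiration-band sinusoidal artifact
#' plus Gaussian sensor noise. Out-of-antrum ports record baseline + noise
#' and are flagged in the port metadata.
#'
#' @param wave The [wave_config()] used for the block (recorded in metadata).
#' @param mano A [manometry_config()].
#' @param truth A `ground_truth` from [generate_cine()].
#' @param seed Integer seed.
#' @param phantom The [phantom_config()] of the block (for the baseline
#'   diameter profile).
#' @param resp Optional [respiration_config()] driving the artifact phase.
#' @return A `pressure_traces` object: tibble (`time_s`, `port_01`, ...) with
#'   port metadata, sampling rate, and the analytic noise-free block AUC per
#'   in-antrum port (`true_port_auc`) and their mean (`true_block_auc_mano`)
#'   as attributes.
#' @export
generate_pressure <- function(wave, mano, truth, seed = 1L,
                              phantom = NULL, resp = respiration_config()) {
  stopifnot(inherits(mano, "manometry_config"), inherits(truth, "ground_truth"))
  set.seed(seed + 1L)
  s_nodes <- truth$node_s_mm
  L <- max(s_nodes)
  ports <- port_positions(mano, L)
  t_frames <- truth$frame_times_s
  duration <- max(t_frames)
  tt <- seq(0, duration, by = 1 / mano$fs_hz)
  quiet <- wave_config(freq_cpm = max(wave$freq_cpm, 1), occlusion_frac = 0,
                       active = FALSE)
  traces <- matrix(mano$baseline_mmHg, length(tt), mano$n_ports)
  true_auc <- rep(NA_real_, mano$n_ports)
  for (p in seq_len(mano$n_ports)) {
    if (!ports$in_antrum[p]) next
    # baseline calibre at the port from the truth's widest state
    d_frames <- approx(s_nodes, rep(1, length(s_nodes)), ports$s_mm[p])$y  # in-range check
    if (is.na(d_frames)) { ports$in_antrum[p] <- FALSE; next }
    d_t <- apply(truth$true_diameter_map, 2,
                 function(col) approx(s_nodes, col, ports$s_mm[p])$y)
    d_fine <- approx(t_frames, d_t, tt)$y
    base_d <- max(d_t)
    p_clean <- transduce_pressure(d_fine, base_d, mano)
    traces[, p] <- p_clean
    true_auc[p] <- trapz_uniform(p_clean - mano$baseline_mmHg, 1 / mano$fs_hz)
  }
  if (mano$resp_artifact_mmHg > 0)
    traces <- traces + mano$resp_artifact_mmHg *
      sin(2 * pi * tt / resp$period_s + resp$phase)
  if (mano$noise_sd_mmHg > 0)
    traces <- traces + matrix(rnorm(length(traces), sd = mano$noise_sd_mmHg),
                              nrow(traces))
  tb <- as_tibble(setNames(as.data.frame(traces),
                           sprintf("port_%02d", seq_len(mano$n_ports))))
  tb <- dplyr::bind_cols(tibble(time_s = tt), tb)
  new_pressure_traces(tb, fs_hz = mano$fs_hz, ports = ports,
                      meta = list(seed = seed, wave = wave, mano = mano,
                                  true_port_auc = true_auc,
                                  true_block_auc_mano = mean(true_auc, na.rm = TRUE)))
}

#' Construct a pressure trace set
#'
#' @param tb Tibble with a `time_s` column and one `port_XX` column per
#'   channel (mmHg).
#' @param fs_hz Sampling rate, Hz.
#' @param ports Port metadata tibble (`port`, `s_mm`, `in_antrum`); defaults
#'   to all ports in-antrum at unknown positions.
#' @param events Named numeric vector of event times (e.g. `drink`), seconds.
#' @param meta Free-form metadata list.
#' @return A `pressure_traces` object.
#' @export
new_pressure_traces <- function(tb, fs_hz, ports = NULL, events = NULL,
                                meta = list()) {
  stopifnot("time_s" %in% names(tb), fs_hz > 0)
  pcols <- grep("^port_", names(tb), value = TRUE)
  if (!length(pcols)) abort("No port_XX columns present.")
  dt <- diff(tb$time_s)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6))
    abort("Time axis must be uniformly increasing.")
  if (is.null(ports))
    ports <- tibble(port = seq_along(pcols), s_mm = NA_real_, in_antrum = TRUE)
  structure(list(data = tb, fs_hz = fs_hz, ports = ports,
                 events = events %||% c(), meta = meta),
            class = "pressure_traces")
}

#' @export
print.pressure_traces <- function(x, ...) {
  cat(sprintf("<pressure_traces> %d ports (%d in antrum), %.0f s @ %g Hz\n",
              nrow(x$ports), sum(x$ports$in_antrum),
              max(x$data$time_s), x$fs_hz))
  invisible(x)
}

#' @describeIn new_pressure_traces Long-format view of the traces.
#' @param x A `pressure_traces` object.
#' @param ... Unused.
#' @method tidy pressure_traces
#' @export
tidy.pressure_traces <- function(x, ...) {
  tidyr::pivot_longer(x$data, -"time_s", names_to = "port",
                      names_prefix = "port_", names_transform = as.integer,
                      values_to = "pressure_mmHg")
}
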