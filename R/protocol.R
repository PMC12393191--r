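#' Acquisition protocol for an ES-mGRE sequence
#'
#' Bundles the complete timing, geometry and gradient description of one
#' echo-shifted multi-echo gradient-echo acquisition. Defaults correspond to
#' the phantom-style protocol (TR 1200 ms, flip 75 deg, 64 echoes of which
#' one third are shifted, K = 10); use [es_preset()] for the bundled
#' presets.
#'
#' @param TR repetition time in ms.
#' @param n_slices number of interleaved slices, or `"auto"` to use the
#'   maximum number whose sub-TR interval still accommodates one full
#'   readout block (see [max_slices()]). Echo shifting requires at least 2.
#' @param n_echoes total number of echoes `p + q`.
#' @param n_shifted number of echoes `q` shifted into the next sub-TR
#'   interval.
#' @param TE1 first echo time in ms.
#' @param dTE echo spacing in ms.
#' @param dPE time for the navigator phase rewinding + winding gradients, ms.
#' @param K area of the first echo-shifting ("additional") gradient as a
#'   multiple of the slice-rephasing gradient area; the diffusion-sensitivity
#'   knob. `K = 0` reduces the sequence to a conventional bipolar mGRE.
#' @param flip_angle excitation flip angle in degrees.
#' @param slice_thickness slice thickness in mm.
#' @param readout_bandwidth readout bandwidth in Hz/pixel.
#' @param matrix integer vector `c(read, phase)` matrix size.
#' @param fov field of view `c(read, phase)` in mm.
#' @param navigator_slots integer positions of the navigator echoes within
#'   the slot sequence (echoes + navigators), or `NULL` to place one
#'   navigator in the middle of each echo block automatically.
#' @param gradient_raster gradient raster time in ms; all lobe durations and
#'   areas are rounded to it.
#' @param gamma gyromagnetic ratio in rad/s/T.
#' @param max_grad maximum gradient amplitude in mT/m.
#' @param slew_rate gradient slew rate in mT/m/ms.
#' @param rf_dur excitation RF pulse duration in ms.
#' @param rf_tbw RF time-bandwidth product; together with the slice
#'   thickness it fixes the slice-rephasing area that `K` scales.
#' @param addgrad_axis axis carrying the echo-shifting gradients, one of
#'   `"slice"`, `"read"`, `"phase"`.
#'
#' @return An object of class `es_protocol` (a validated list).
#' @seealso [build_echo_train()], [build_gradient_waveform()], [es_preset()]
#' @export
#' @examples
#' cfg <- es_protocol(TR = 3000, n_slices = 23, n_echoes = 64,
#'                    n_shifted = 21, K = 10, flip_angle = 60)
#' compute_sub_tr(cfg)
es_protocol <- function(TR = 1200, n_slices = "auto", n_echoes = 64,
                        n_shifted = 21, TE1 = 3, dTE = 1.47, dPE = 0.8,
                        K = 10, flip_angle = 75, slice_thickness = 2,
                        readout_bandwidth = 800, matrix = c(64, 64),
                        fov = c(240, 216), navigator_slots = NULL,
                        gradient_raster = 0.01, gamma = 267.52218744e6,
                        max_grad = 30, slew_rate = 200, rf_dur = 2.56,
                        rf_tbw = 2.7, addgrad_axis = "slice") {
  cfg <- list(TR = TR, n_slices = n_slices, n_echoes = n_echoes,
              n_shifted = n_shifted, TE1 = TE1, dTE = dTE, dPE = dPE,
              K = K, flip_angle = flip_angle,
              slice_thickness = slice_thickness,
              readout_bandwidth = readout_bandwidth,
              matrix = as.integer(matrix), fov = fov,
              navigator_slots = navigator_slots,
              gradient_raster = gradient_raster, gamma = gamma,
              max_grad = max_grad, slew_rate = slew_rate,
              rf_dur = rf_dur, rf_tbw = rf_tbw, addgrad_axis = addgrad_axis)
  class(cfg) <- "es_protocol"
  auto <- identical(n_slices, "auto")
  if (auto) cfg$n_slices <- 1L    # placeholder so validation of others runs
  validate_protocol(cfg, check_slices = FALSE)
  if (is.null(navigator_slots)) cfg$navigator_slots <- default_navigator_slots(cfg)
  if (auto) cfg$n_slices <- max_slices(cfg)
  validate_protocol(cfg)
  cfg
}

# one navigator in the middle of each non-empty echo block
default_navigator_slots <- function(cfg) {
  p <- cfg$n_echoes - cfg$n_shifted
  q <- cfg$n_shifted
  slots <- integer(0)
  if (p > 1) slots <- c(slots, ceiling(p / 2) + 1L)  # mid-prompt slot
  n_prompt_slots <- p + length(slots)
  if (q > 1) slots <- c(slots, n_prompt_slots + ceiling(q / 2) + 1L)
  as.integer(slots)
}

#' Validate an ES-mGRE protocol
#'
#' Checks the invariants of an [es_protocol()] object and raises a classed
#' validation error (`es_validation_error`) naming the offending field.
#'
#' @param cfg an `es_protocol` object.
#' @param check_slices validate the slice count (disabled internally while
#'   the automatic slice count is being resolved).
#' @return `cfg`, invisibly.
#' @export
validate_protocol <- function(cfg, check_slices = TRUE) {
  chk <- function(ok, field, what) {
    if (!ok) stop_validation(sprintf("invalid protocol: field '%s' %s", field, what))
  }
  chk(is.numeric(cfg$TR) && cfg$TR > 0, "TR", "must be > 0")
  chk(is.numeric(cfg$n_echoes) && cfg$n_echoes >= 1, "n_echoes", "must be >= 1")
  chk(cfg$n_shifted >= 0, "n_shifted", "must be >= 0")
  chk(cfg$n_shifted < cfg$n_echoes, "n_shifted", "must be < n_echoes")
  chk(cfg$K >= 0, "K", "must be >= 0")
  chk(cfg$TE1 > 0, "TE1", "must be > 0")
  chk(cfg$dTE > 0, "dTE", "must be > 0")
  chk(cfg$gradient_raster > 0, "gradient_raster", "must be > 0")
  chk(cfg$slice_thickness > 0, "slice_thickness", "must be > 0")
  chk(cfg$readout_bandwidth > 0, "readout_bandwidth", "must be > 0")
  chk(length(cfg$matrix) == 2 && all(cfg$matrix >= 4), "matrix",
      "must be two counts >= 4")
  chk(cfg$flip_angle > 0 && cfg$flip_angle <= 90, "flip_angle",
      "must be in (0, 90] degrees")
  if (check_slices) {
    chk(is.numeric(cfg$n_slices) && cfg$n_slices >= 1, "n_slices",
        "must be a positive count")
    if (cfg$n_shifted > 0 && cfg$n_slices < 2)
      stop_validation(paste("invalid protocol: field 'n_slices' must be >= 2",
                            "for echo shifting (a next sub-TR interval is needed)"))
    blk <- block_duration(cfg)
    if (blk > cfg$TR / cfg$n_slices)
      stop_validation(sprintf(paste(
        "invalid protocol: readout block (%.2f ms) exceeds sub-TR (%.2f ms);",
        "reduce echoes/slices or K"), blk, cfg$TR / cfg$n_slices),
        class = "es_timing_overflow")
  }
  ns <- cfg$navigator_slots
  if (length(ns)) {
    total <- cfg$n_echoes + length(ns)
    chk(all(ns >= 2 & ns <= total), "navigator_slots",
        "must lie inside the slot sequence (not first)")
    chk(!anyDuplicated(ns), "navigator_slots", "must be distinct")
  }
  invisible(cfg)
}

#' Sub-TR interval of a multislice acquisition
#'
#' The per-slice acquisition window, TR divided by the number of interleaved
#' slices. Shifted echoes are refocused one sub-TR after their excitation.
#'
#' @param cfg an [es_protocol()] object.
#' @return Duration in ms.
#' @export
#' @examples
#' compute_sub_tr(es_protocol(TR = 3000, n_slices = 23, n_shifted = 21, K = 10))
compute_sub_tr <- function(cfg) {
  if (!is.numeric(cfg$n_slices) || cfg$n_slices < 1)
    stop_validation("invalid protocol: field 'n_slices' must be a positive count")
  if (cfg$n_slices == 1)
    warning("single-slice protocol: echo shifting is impossible (no next sub-TR interval)")
  cfg$TR / cfg$n_slices
}

#' Maximum number of slices fitting one readout block per sub-TR
#'
#' @param cfg an [es_protocol()] object (slice count ignored).
#' @return Integer slice count `floor(TR / block duration)`.
#' @export
max_slices <- function(cfg) {
  max(1L, as.integer(floor(cfg$TR / block_duration(cfg))))
}

#' Bundled protocol presets
#'
#' `"table1_invivo"` reproduces the in vivo acquisition (TR 3000 ms, 23
#' slices, 64 echoes / 21 shifted, navigators at slots 16 and 49, K = 10,
#' flip 60 deg, 1 mm in-plane). `"phantom_64echo_K10"` is the phantom-style
#' protocol (TR 1200 ms, flip 75 deg, one third of 64 echoes shifted,
#' K = 10) at a 64 x 64 desk-scale matrix.
#'
#' @param name preset name.
#' @param ... overrides passed on to [es_protocol()].
#' @return An `es_protocol` object.
#' @export
es_preset <- function(name = c("table1_invivo", "phantom_64echo_K10"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "esmgre")
  if (!nzchar(path))
    stop_runtime(sprintf("preset file for '%s' not found", name))
  read_protocol(path, ...)
}

#' Read / write protocol configuration files
#'
#' Protocols are stored as human-editable YAML key/value files whose keys
#' match the arguments of [es_protocol()] (schema version field
#' `config_version: 1`).
#'
#' @param path file path.
#' @param ... overrides applied after reading.
#' @return `read_protocol()` returns an `es_protocol`; `write_protocol()`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path, ...) {
  if (!file.exists(path)) stop_validation(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  raw$config_version <- NULL
  known <- names(formals(es_protocol))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_validation(sprintf("unknown config field(s): %s",
                            paste(unknown, collapse = ", ")))
  raw <- modifyList(raw, list(...))
  do.call(es_protocol, raw)
}

#' @rdname read_protocol
#' @param cfg an `es_protocol` object to write.
#' @export
write_protocol <- function(cfg, path) {
  out <- unclass(cfg)
  out <- c(list(config_version = 1L), out)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.es_protocol <- function(x, ...) {
  p <- x$n_echoes - x$n_shifted
  cat(sprintf("ES-mGRE protocol: TR %g ms / %d slices (sub-TR %.2f ms)\n",
              x$TR, x$n_slices, x$TR / x$n_slices))
  cat(sprintf("  echoes: %d prompt + %d shifted, TE1 %g ms, dTE %g ms, K = %g\n",
              p, x$n_shifted, x$TE1, x$dTE, x$K))
  cat(sprintf("  flip %g deg, matrix %d x %d, %g mm slice, %g Hz/px\n",
              x$flip_angle, x$matrix[1], x$matrix[2], x$slice_thickness,
              x$readout_bandwidth))
  invisible(x)
}
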