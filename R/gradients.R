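# Gradient waveform construction and moment/b-value integration.
#
# All lobes are laid out on the gradient raster (default 0.01 ms): a lobe is
# a symmetric trapezoid sampled at raster-bin centers, so its discrete area
# is exactly amp * raster * (ramp_bins + flat_bins) and splits exactly in
# half at the lobe center. Echo centers are placed on bin edges, which makes
# the zeroth-moment cancellation at echo centers exact in the discrete
# integral as well.

gamma_bar <- function(cfg) cfg$gamma / (2 * pi)  # Hz/T

# slice-rephasing gradient area A_s in mT*ms/m, defined as half the discrete
# slice-select lobe area (ramps included); K scales this area
slice_rephase_area <- function(cfg) {
  sel <- select_lobe_spec(cfg)
  sel$amp * cfg$gradient_raster * (sel$ramp_n + sel$flat_n) / 2
}

#' Spoiling threshold
#'
#' Gradient area producing 2*pi phase dispersion across one slice
#' thickness (the standard crusher criterion); spins whose zeroth moment
#' exceeds it are considered dephased.
#'
#' @param cfg an [es_protocol()] object.
#' @return Area in mT*ms/m.
#' @export
spoiling_threshold <- function(cfg) {
  2 * pi / (cfg$gamma * cfg$slice_thickness * 1e-3) * 1e6
}

even_bins <- function(n) { n <- as.integer(round(n)); n + (n %% 2L) }

# symmetric trapezoid with exact discrete area; amplitude solved so that
# sum(samples) * raster == area
trap_lobe_spec <- function(area, max_amp, slew, raster) {
  if (abs(area) < 1e-12) return(NULL)
  ramp_n <- max(1L, as.integer(ceiling(max_amp / slew / raster)))
  flat_n <- max(0, ceiling(abs(area) / (max_amp * raster) - ramp_n))
  flat_n <- even_bins(flat_n)
  amp <- area / ((ramp_n + flat_n) * raster)
  while (abs(amp) > max_amp * (1 + 1e-9)) {
    flat_n <- flat_n + 2L
    amp <- area / ((ramp_n + flat_n) * raster)
  }
  list(amp = amp, ramp_n = ramp_n, flat_n = as.integer(flat_n),
       n_bins = 2L * ramp_n + as.integer(flat_n),
       area = amp * raster * (ramp_n + flat_n))
}

lobe_samples <- function(spec) {
  up <- spec$amp * (seq_len(spec$ramp_n) - 0.5) / spec$ramp_n
  c(up, rep(spec$amp, spec$flat_n), rev(up))
}

select_lobe_spec <- function(cfg) {
  r <- cfg$gradient_raster
  flat_n <- even_bins(cfg$rf_dur / r)
  bw_rf <- cfg$rf_tbw / (cfg$rf_dur * 1e-3)                   # Hz
  amp <- bw_rf / (gamma_bar(cfg) * cfg$slice_thickness * 1e-3) * 1e3  # mT/m
  if (amp > cfg$max_grad)
    stop_validation("invalid protocol: slice-select amplitude exceeds max_grad; increase rf_dur or slice_thickness")
  ramp_n <- max(1L, as.integer(ceiling(amp / cfg$slew_rate / r)))
  list(amp = amp, ramp_n = ramp_n, flat_n = flat_n,
       n_bins = 2L * ramp_n + flat_n,
       area = amp * r * (ramp_n + flat_n))
}

readout_lobe_spec <- function(cfg) {
  r <- cfg$gradient_raster
  flat_n <- even_bins((1000 / cfg$readout_bandwidth) / r)      # ADC window
  amp <- (cfg$matrix[1] * cfg$readout_bandwidth) /
    (gamma_bar(cfg) * cfg$fov[1] * 1e-3) * 1e3                 # mT/m
  ramp_n <- max(1L, as.integer(ceiling(amp / cfg$slew_rate / r)))
  n_bins <- 2L * ramp_n + flat_n
  if (n_bins * r > cfg$dTE)
    stop_validation(sprintf(paste(
      "invalid protocol: readout lobe (%.3f ms) does not fit the echo",
      "spacing dTE = %g ms"), n_bins * r, cfg$dTE),
      class = "es_timing_overflow")
  list(amp = amp, ramp_n = ramp_n, flat_n = flat_n, n_bins = n_bins,
       area = amp * r * (ramp_n + flat_n))
}

# phase-encode area per k-space line step, mT*ms/m
pe_step_area <- function(cfg) 1 / (gamma_bar(cfg) * cfg$fov[2] * 1e-3) * 1e6

# Full symbolic layout of one sub-TR interval: slot timing, lobe placement
# (start bin, spec, axis, role) and the additional-gradient block duration.
# Everything downstream (block duration, waveform sampling, echo-train TEs)
# derives from this single plan.
interval_plan <- function(cfg) {
  r <- cfg$gradient_raster
  p <- cfg$n_echoes - cfg$n_shifted
  q <- cfg$n_shifted
  nav <- sort(as.integer(cfg$navigator_slots))
  n_slots <- cfg$n_echoes + length(nav)
  dTE_n <- as.integer(round(cfg$dTE / r))

  sel <- select_lobe_spec(cfg)
  ro <- readout_lobe_spec(cfg)
  A_s <- sel$amp * r * (sel$ramp_n + sel$flat_n) / 2

  rf_edge <- sel$ramp_n + sel$flat_n %/% 2L    # RF center (bin edge)
  t_rf <- rf_edge * r
  te1_n <- as.integer(round(cfg$TE1 / r))

  # slot bookkeeping: which slots are echoes, which are navigators; the
  # prompt block ends with the slot of the p-th echo
  is_nav <- rep(FALSE, n_slots)
  if (length(nav)) is_nav[nav] <- TRUE
  echo_of_slot <- cumsum(!is_nav)
  if (p > 0) {
    n_prompt_slots <- which(!is_nav & echo_of_slot == p)[1]
  } else n_prompt_slots <- 0L

  # additional (echo-shifting) gradients: -A' then +2A'; the -A' lobe sits
  # between the prompt and shifted readout blocks and sets the extra delay
  add_on <- q > 0 && cfg$K > 0
  add1 <- if (add_on) trap_lobe_spec(-cfg$K * A_s, cfg$max_grad, cfg$slew_rate, r)
  add2 <- if (add_on) trap_lobe_spec(2 * cfg$K * A_s, cfg$max_grad, cfg$slew_rate, r)
  t_add_n <- if (add_on) add1$n_bins else 0L

  half_ro <- ro$ramp_n + ro$flat_n %/% 2L
  slot_center <- rf_edge + te1_n + (seq_len(n_slots) - 1L) * dTE_n
  if (n_prompt_slots < n_slots)
    slot_center[(n_prompt_slots + 1L):n_slots] <-
      slot_center[(n_prompt_slots + 1L):n_slots] + t_add_n
  polarity <- ifelse(seq_len(n_slots) %% 2L == 1L, 1, -1)

  lobes <- list()
  addl <- function(axis, role, start, spec) {
    if (is.null(spec)) return()
    lobes[[length(lobes) + 1L]] <<- list(axis = axis, role = role,
                                         start = as.integer(start), spec = spec)
  }
  addl("slice", "slice_select", 0L, sel)
  reph <- trap_lobe_spec(-A_s, cfg$max_grad, cfg$slew_rate, r)
  addl("slice", "slice_rephase", sel$n_bins, reph)
  deph <- trap_lobe_spec(-ro$area / 2, cfg$max_grad, cfg$slew_rate, r)
  addl("read", "read_dephase", sel$n_bins, deph)
  if (sel$n_bins + deph$n_bins > slot_center[1] - half_ro)
    stop_validation("invalid protocol: TE1 too short for slice-select and readout dephasing",
                    class = "es_timing_overflow")

  for (s in seq_len(n_slots)) {
    spec_s <- ro
    spec_s$amp <- ro$amp * polarity[s]
    spec_s$area <- ro$area * polarity[s]
    addl("read", if (is_nav[s]) "navigator_readout" else "readout",
         slot_center[s] - half_ro, spec_s)
  }
  if (add_on) {
    first_shift_start <- slot_center[n_prompt_slots + 1L] - half_ro
    addl("slice", "addgrad1", first_shift_start - add1$n_bins, add1)
  }
  last_end <- slot_center[n_slots] + half_ro
  if (add_on) addl("slice", "addgrad2", last_end + 1L, add2)
  # duplicated readout dephasing lobe balances the interval's read moment;
  # for an even slot count it has polarity opposite to the initial dephaser
  dup_area <- -(deph$area + ro$area * (n_slots %% 2L))
  dup <- trap_lobe_spec(dup_area, cfg$max_grad, cfg$slew_rate, r)
  addl("read", "read_dephase_dup", last_end + 1L, dup)
  if (add_on) {
    refoc <- trap_lobe_spec(-A_s, cfg$max_grad, cfg$slew_rate, r)
    addl("slice", "slice_refocus_dup", last_end + 1L + add2$n_bins, refoc)
  }

  ends <- vapply(lobes, function(l) l$start + l$spec$n_bins, 1)
  block_end <- max(ends) + 1L

  list(raster = r, p = p, q = q, n_slots = n_slots, is_nav = is_nav,
       echo_of_slot = echo_of_slot, n_prompt_slots = n_prompt_slots,
       slot_center = slot_center, polarity = polarity, rf_edge = rf_edge,
       t_rf = t_rf, t_add = t_add_n * r, A_s = A_s, lobes = lobes,
       select = sel, readout = ro, block_end = block_end,
       block_end_ms = block_end * r)
}

block_duration <- function(cfg) interval_plan(cfg)$block_end_ms

#' Build the ES-mGRE gradient waveform
#'
#' Samples the full per-sub-TR gradient waveform (slice select + rephase,
#' bipolar readout train with navigator slots, the echo-shifting gradient
#' pair with area ratio -1:+2, duplicated dephasing/refocusing lobes, and
#' the phase-encoding lobes) on the gradient raster, repeated over
#' `n_intervals` sub-TR intervals.
#'
#' @param cfg an [es_protocol()] object.
#' @param axis `"all"` (default) or one of `"read"`, `"slice"`, `"phase"`
#'   to retain a single axis in `$axes`.
#' @param n_intervals number of sub-TR intervals to sample; shifted-echo
#'   moments and b-values need at least 2.
#' @param pe_line k-space line index (1-based) whose phase-encoding
#'   amplitude is sampled on the phase axis; `NULL` uses the zero-encode
#'   (center) line.
#' @return An `es_waveform` object: raster-sampled amplitudes per axis
#'   (mT/m), a lobe annotation table, slot timing and the sub-TR length.
#' @export
build_gradient_waveform <- function(cfg, axis = "all", n_intervals = 2,
                                    pe_line = NULL) {
  validate_protocol(cfg)
  plan <- interval_plan(cfg)
  r <- plan$raster
  sub_tr_n <- as.integer(round(cfg$TR / cfg$n_slices / r))
  if (plan$block_end > sub_tr_n)
    stop_validation(sprintf(
      "timing overflow: readout block (%.2f ms) exceeds sub-TR (%.2f ms)",
      plan$block_end_ms, sub_tr_n * r), class = "es_timing_overflow")

  lobes <- plan$lobes
  # phase axis: per-line encode, navigator rewind/wind, final rewinder
  pe_area <- 0
  if (!is.null(pe_line)) {
    offset <- pe_line - (cfg$matrix[2] %/% 2L + 1L)
    pe_area <- offset * pe_step_area(cfg)
  }
  if (abs(pe_area) > 0) {
    pe <- trap_lobe_spec(pe_area, cfg$max_grad, cfg$slew_rate, r)
    lobes[[length(lobes) + 1L]] <- list(axis = "phase", role = "pe_encode",
                                        start = plan$select$n_bins, spec = pe)
    half_ro <- plan$readout$ramp_n + plan$readout$flat_n %/% 2L
    for (s in which(plan$is_nav)) {
      rw <- trap_lobe_spec(-pe_area, cfg$max_grad, cfg$slew_rate, r)
      wd <- trap_lobe_spec(pe_area, cfg$max_grad, cfg$slew_rate, r)
      lobes[[length(lobes) + 1L]] <- list(axis = "phase", role = "pe_rewind",
        start = plan$slot_center[s] - half_ro - rw$n_bins, spec = rw)
      lobes[[length(lobes) + 1L]] <- list(axis = "phase", role = "pe_wind",
        start = plan$slot_center[s] + half_ro, spec = wd)
    }
    rw_end <- trap_lobe_spec(-pe_area, cfg$max_grad, cfg$slew_rate, r)
    lobes[[length(lobes) + 1L]] <- list(axis = "phase", role = "pe_rewinder",
      start = plan$slot_center[plan$n_slots] + half_ro + 1L, spec = rw_end)
  }

  n_bins <- sub_tr_n * n_intervals
  axes <- list(read = numeric(n_bins), slice = numeric(n_bins),
               phase = numeric(n_bins))
  ann <- vector("list", length(lobes) * n_intervals)
  k <- 0L
  for (i in seq_len(n_intervals)) {
    off <- (i - 1L) * sub_tr_n
    for (l in lobes) {
      idx <- off + l$start + seq_len(l$spec$n_bins)
      axes[[l$axis]][idx] <- axes[[l$axis]][idx] + lobe_samples(l$spec)
      k <- k + 1L
      ann[[k]] <- data.frame(interval = i, axis = l$axis, role = l$role,
                             start_ms = (off + l$start) * r,
                             end_ms = (off + l$start + l$spec$n_bins) * r,
                             area = l$spec$area)
    }
  }
  if (!identical(axis, "all")) {
    axis <- match.arg(axis, c("read", "slice", "phase"))
    axes <- axes[axis]
  }
  structure(list(
    raster = r, n_intervals = n_intervals, sub_tr = sub_tr_n * r,
    sub_tr_bins = sub_tr_n, n_bins = n_bins, axes = axes,
    lobes = do.call(rbind, ann[seq_len(k)]), plan = plan, config = cfg
  ), class = "es_waveform")
}

#' @export
print.es_waveform <- function(x, ...) {
  cat(sprintf("ES-mGRE gradient waveform: %d sub-TR interval(s) of %.2f ms (%d bins @ %g ms)\n",
              x$n_intervals, x$sub_tr, x$n_bins, x$raster))
  cat(sprintf("  axes: %s; %d lobes; additional-gradient block %.2f ms\n",
              paste(names(x$axes), collapse = ", "), nrow(x$lobes), x$plan$t_add))
  invisible(x)
}

# RF-center time (ms from waveform start) for the pulse of interval i
rf_time <- function(wf, interval = 1L) {
  (interval - 1L) * wf$sub_tr + wf$plan$t_rf
}

# absolute echo/navigator center times (ms) for the slice excited in
# `origin` interval: prompt slots in the same interval, shifted in the next
slot_times_abs <- function(wf, origin = 1L) {
  plan <- wf$plan
  centers <- plan$slot_center * wf$raster
  shifted <- seq_len(plan$n_slots) > plan$n_prompt_slots
  (origin - 1L) * wf$sub_tr + centers + ifelse(shifted, wf$sub_tr, 0)
}

#' Absolute echo-center times on a sampled waveform
#'
#' Times (ms from the waveform start) at which the echoes of the slice
#' excited in interval `origin` are read out: prompt echoes within the same
#' sub-TR interval, shifted echoes one interval later. Useful together with
#' [zeroth_moment()] to verify echo formation and spoiling.
#'
#' @param wf an [build_gradient_waveform()] object.
#' @param origin excitation interval (1-based).
#' @param navigators include navigator slots.
#' @return Numeric vector of center times in ms.
#' @export
echo_center_times <- function(wf, origin = 1L, navigators = FALSE) {
  t <- slot_times_abs(wf, origin)
  if (navigators) t else t[!wf$plan$is_nav]
}

#' Zeroth gradient moment experienced by a spin
#'
#' Cumulative gradient-area integral from the RF pulse that excited the spin
#' up to time `t`. At every echo center the moment of the spins being read
#' out is zero (echo formation); for the next slice's spins it exceeds the
#' spoiling threshold at every shifted echo whenever `K > 0`.
#'
#' @param wf an [build_gradient_waveform()] object (all axes present).
#' @param spin_origin `"this_slice"` (excited in interval 1) or
#'   `"next_slice"` (interval 2).
#' @param t absolute time(s) in ms from the start of the waveform; must lie
#'   within the sampled window and after the originating RF pulse.
#' @param axes which axes to report.
#' @return A matrix `length(t) x length(axes)` of moments in mT*ms/m.
#' @export
zeroth_moment <- function(wf, spin_origin = c("this_slice", "next_slice"),
                          t, axes = c("read", "slice")) {
  spin_origin <- match.arg(spin_origin)
  origin <- if (spin_origin == "this_slice") 1L else 2L
  if (origin == 2L && wf$n_intervals < 2)
    stop_runtime("waveform has a single interval; next_slice spins need >= 2")
  r <- wf$raster
  rf_bin <- as.integer(round(rf_time(wf, origin) / r))
  jt <- as.integer(round(t / r))
  if (any(jt < rf_bin) || any(jt > wf$n_bins))
    stop_runtime("time outside the simulated window for this spin origin")
  axes <- intersect(axes, names(wf$axes))
  out <- sapply(axes, function(a) {
    cs <- c(0, cumsum(wf$axes[[a]]) * r)
    cs[jt + 1L] - cs[rf_bin + 1L]
  })
  out <- matrix(out, nrow = length(jt), dimnames = list(NULL, axes))
  out
}

#' Per-echo diffusion b-values from the gradient waveform
#'
#' Numerically integrates `b(TE_n) = gamma^2 * int_0^TEn [int_0^t G dt']^2 dt`
#' over the read and slice axes (phase encoding excluded), starting at the
#' exciting RF pulse. For shifted echoes the integral spans both sub-TR
#' intervals the spins traverse.
#'
#' @param wf an [build_gradient_waveform()] object with `n_intervals >= 2`
#'   when shifted echoes are present.
#' @param echo_train an [build_echo_train()] table (TEs and shifted flags).
#' @return Numeric vector of b-values in s/mm^2, one per echo.
#' @export
compute_b_values <- function(wf, echo_train) {
  cfg <- wf$config
  r <- wf$raster
  if (any(echo_train$shifted) && wf$n_intervals < 2)
    stop_runtime("shifted echoes need a waveform with at least 2 intervals")
  rf_bin <- as.integer(round(rf_time(wf, 1L) / r))
  ax <- intersect(c("read", "slice"), names(wf$axes))
  cs <- lapply(ax, function(a) c(0, cumsum(wf$axes[[a]]) * r))
  m2 <- numeric(wf$n_bins - rf_bin)           # summed squared moment per bin
  for (csa in cs) {
    m <- csa[(rf_bin + 1L):wf$n_bins + 1L] - csa[rf_bin + 1L]
    m2 <- m2 + m^2
  }
  cum_m2 <- c(0, cumsum(m2))
  bfac <- cfg$gamma^2 * r * 1e-21             # (mT*ms/m)^2 * ms -> s/mm^2
  te_bins <- as.integer(round((rf_time(wf, 1L) + echo_train$te) / r))
  if (any(te_bins > wf$n_bins))
    stop_runtime("echo time beyond the sampled waveform window")
  bfac * cum_m2[te_bins - rf_bin + 1L]
}

#' b-value of an arbitrary sampled gradient waveform
#'
#' Same moment-squared integrator as [compute_b_values()], exposed for
#' auditing arbitrary waveforms (e.g. a rectangular pulsed-gradient pair,
#' whose closed form is `gamma^2 G^2 delta^2 (Delta - delta/3)`).
#'
#' @param G gradient samples in mT/m on the raster (one axis), or a list of
#'   per-axis sample vectors whose contributions are summed.
#' @param raster sample spacing in ms.
#' @param t end time(s) of the integral in ms (from the first sample).
#' @param gamma gyromagnetic ratio in rad/s/T.
#' @return b-value(s) in s/mm^2.
#' @export
b_value_from_samples <- function(G, raster, t, gamma = 267.52218744e6) {
  if (!is.list(G)) G <- list(G)
  n <- length(G[[1]])
  m2 <- numeric(n)
  for (g in G) m2 <- m2 + (cumsum(g) * raster)^2
  cum <- c(0, cumsum(m2))
  jt <- as.integer(round(t / raster))
  if (any(jt < 0 | jt > n)) stop_runtime("integration end outside the waveform")
  gamma^2 * raster * 1e-21 * cum[jt + 1L]
}

#' Build the echo-train timing table
#'
#' Computes per-echo TE, shifted flag, bipolar readout polarity and (by
#' default) the diffusion b-value for one protocol. Prompt echoes sit at
#' `TE1 + (slot-1)*dTE` with each navigator occupying one extra
#' echo-spacing slot; shifted echoes are additionally offset by one sub-TR
#' interval plus the echo-shifting gradient lobe duration. All times are on
#' the gradient raster.
#'
#' @param cfg an [es_protocol()] object.
#' @param with_b compute per-echo b-values (builds a two-interval waveform).
#' @return An `es_echo_train` data frame with columns `echo`, `slot`, `te`
#'   (ms), `shifted`, `polarity`, `b` (s/mm^2), and attributes `navigators`
#'   (slot/TE/block table), `sub_tr`, `t_add` and `config`.
#' @export
#' @examples
#' tr <- build_echo_train(es_preset("phantom_64echo_K10"), with_b = FALSE)
#' head(tr)
build_echo_train <- function(cfg, with_b = TRUE) {
  validate_protocol(cfg)
  plan <- interval_plan(cfg)
  r <- plan$raster
  sub_tr <- round(cfg$TR / cfg$n_slices / r) * r
  if (plan$block_end_ms > sub_tr)
    stop_validation(sprintf(
      "timing overflow: readout block (%.2f ms) exceeds sub-TR (%.2f ms)",
      plan$block_end_ms, sub_tr), class = "es_timing_overflow")

  slots <- seq_len(plan$n_slots)
  shifted_slot <- slots > plan$n_prompt_slots
  te_slot <- cfg$TE1 + (slots - 1L) * cfg$dTE +
    ifelse(shifted_slot, sub_tr + plan$t_add, 0)
  te_slot <- round(te_slot / r) * r

  esl <- slots[!plan$is_nav]
  train <- data.frame(echo = seq_len(cfg$n_echoes), slot = esl,
                      te = te_slot[esl], shifted = shifted_slot[esl],
                      polarity = plan$polarity[esl], b = 0)
  navs <- data.frame(nav = seq_along(which(plan$is_nav)),
                     slot = slots[plan$is_nav],
                     te = te_slot[plan$is_nav],
                     block = ifelse(shifted_slot[plan$is_nav],
                                    "shifted", "prompt"))
  if (with_b) {
    wf <- build_gradient_waveform(cfg, n_intervals = 2)
    train$b <- compute_b_values(wf, train)
  }
  structure(train, navigators = navs, sub_tr = sub_tr, t_add = plan$t_add,
            config = cfg, class = c("es_echo_train", "data.frame"))
}

#' Navigator slots and times of an echo train
#' @param train an [build_echo_train()] object.
#' @return Data frame with columns `nav`, `slot`, `te`, `block`.
#' @export
navigators <- function(train) attr(train, "navigators")

#' Export an echo-train table
#'
#' Writes the per-echo timing/b-value table together with the navigator
#' entries and sub-TR either as tab-separated text or JSON.
#'
#' @param train an [build_echo_train()] object.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_echo_train <- function(train, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(as.data.frame(train), path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  } else {
    jsonlite::write_json(list(
      sub_tr_ms = attr(train, "sub_tr"), t_add_ms = attr(train, "t_add"),
      echoes = as.data.frame(train), navigators = navigators(train)
    ), path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an echo-train table written by [write_echo_train()]
#' @param path JSON file path.
#' @return An `es_echo_train` data frame (without the protocol attribute).
#' @export
read_echo_train <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x$echoes, navigators = x$navigators, sub_tr = x$sub_tr_ms,
            t_add = x$t_add_ms, class = c("es_echo_train", "data.frame"))
}

#' Export a gradient waveform as tab-separated text
#' @param wf an [build_gradient_waveform()] object.
#' @param path output file; lobe annotations go to `<path>.lobes.tsv`.
#' @return `path`, invisibly.
#' @export
write_waveform_tsv <- function(wf, path) {
  df <- data.frame(time_ms = (seq_len(wf$n_bins) - 0.5) * wf$raster)
  for (a in names(wf$axes)) df[[a]] <- wf$axes[[a]]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(wf$lobes, paste0(path, ".lobes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
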