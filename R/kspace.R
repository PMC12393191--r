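# Per-line k-space acquisition under physiological field fluctuations and
# the two-step navigator-echo phase correction.
#
# Phase-encode lines are acquired in linear (bottom-to-top) order; line 1 is
# the phase reference of the correction. The fluctuation is a spatially
# uniform per-shot frequency offset, which multiplies the acquired line by a
# global phase 2*pi*df0(p)*TE_n; that is exactly the term the two-step
# correction removes.

#' Physiological field-fluctuation model
#'
#' Per-phase-encode-line resonance-frequency offset composed of a sinusoid,
#' a linear drift and optional Gaussian jitter; an optional extra sinusoid
#' acts only during the shifted-echo block (and its navigator), emulating a
#' slow component that the first navigator cannot see.
#'
#' @param amplitude_hz sinusoid amplitude in Hz.
#' @param period_lines sinusoid period in phase-encode lines.
#' @param phase sinusoid phase offset, rad.
#' @param drift_hz_per_line linear drift in Hz per line.
#' @param jitter_hz standard deviation of per-line Gaussian jitter, Hz.
#' @param shifted_extra_hz amplitude of the shifted-block-only sinusoid, Hz.
#' @param shifted_extra_period period of that component, lines.
#' @param seed seed for the jitter.
#' @return An `es_fluctuation` object.
#' @export
fluctuation_model <- function(amplitude_hz = 5, period_lines = 24, phase = 0,
                              drift_hz_per_line = 0, jitter_hz = 0,
                              shifted_extra_hz = 0, shifted_extra_period = 32,
                              seed = NULL) {
  structure(list(amplitude_hz = amplitude_hz, period_lines = period_lines,
                 phase = phase, drift_hz_per_line = drift_hz_per_line,
                 jitter_hz = jitter_hz, shifted_extra_hz = shifted_extra_hz,
                 shifted_extra_period = shifted_extra_period, seed = seed),
            class = "es_fluctuation")
}

# per-line offsets: list(base, extra) in Hz, deterministic given seed
fluct_offsets <- function(fl, n_lines) {
  p <- seq_len(n_lines)
  if (is.null(fl)) return(list(base = numeric(n_lines), extra = numeric(n_lines)))
  base <- fl$amplitude_hz * sin(2 * pi * p / fl$period_lines + fl$phase) +
    fl$drift_hz_per_line * (p - 1)
  if (fl$jitter_hz > 0) {
    if (!is.null(fl$seed)) set.seed(fl$seed)
    base <- base + rnorm(n_lines, 0, fl$jitter_hz)
  }
  extra <- if (fl$shifted_extra_hz != 0)
    fl$shifted_extra_hz * sin(2 * pi * p / fl$shifted_extra_period) else
      numeric(n_lines)
  list(base = base, extra = extra)
}

#' Simulate the multi-echo k-space acquisition
#'
#' Acquires every phase-encode line of every echo from the noiseless
#' phantom images, applying the per-line fluctuation phase
#' `2 pi df0(p) TE_n` (plus the shifted-block-only component for shifted
#' echoes), and acquires the navigator echoes at their slots with zero
#' phase encoding. Complex Gaussian noise is added per k-space sample.
#'
#' @param phantom an [build_figure2_phantom()] object.
#' @param train an [build_echo_train()] object.
#' @param cfg an [es_protocol()] object; matrix must match the phantom.
#' @param fluctuation an [fluctuation_model()] object or `NULL`.
#' @param noise an [es_noise()] object (image-domain sigma) or `NULL`.
#' @return An `es_kspace` object: `$echoes` (complex `read x line x echo`),
#'   `$navs` (`read x line x navigator`), the train, the applied
#'   fluctuation record and the noise level.
#' @export
acquire_kspace <- function(phantom, train, cfg = phantom$config,
                           fluctuation = NULL, noise = NULL) {
  nr <- cfg$matrix[1]; np <- cfg$matrix[2]
  if (!all(dim(phantom$labels) == c(nr, np)))
    stop_runtime("phantom grid does not match the protocol matrix")
  navs <- navigators(train)
  fo <- fluct_offsets(fluctuation, np)

  images <- phantom_echo_images(phantom, train)
  ne <- nrow(train)
  kspace <- array(0i, dim = c(nr, np, ne))
  for (n in seq_len(ne)) {
    K <- fft(images[, , n])
    ph <- 2 * pi * (fo$base + if (train$shifted[n]) fo$extra else 0) *
      train$te[n] * 1e-3
    kspace[, , n] <- K * matrix(exp(1i * ph), nr, np, byrow = TRUE)
  }

  # navigators: zero phase encoding = the ky = 0 k-space line of the object
  # at the navigator TE, acquired once per excitation (per line p)
  nav_b <- numeric(nrow(navs))
  if (nrow(navs)) {
    wf_b <- train$b        # navigator b interpolated from neighbours
    nav_b <- vapply(navs$te, function(te) {
      i <- which.min(abs(train$te - te)); wf_b[i]
    }, 1)
  }
  nav_stack <- phantom_image_stack(phantom, navs$te, nav_b)
  knav <- array(0i, dim = c(nr, np, nrow(navs)))
  for (j in seq_len(nrow(navs))) {
    K <- fft(nav_stack[, , j])
    ph <- 2 * pi * (fo$base + if (navs$block[j] == "shifted") fo$extra else 0) *
      navs$te[j] * 1e-3
    knav[, , j] <- outer(K[, 1], exp(1i * ph))
  }

  sigma <- if (is.null(noise)) 0 else noise$sigma
  if (sigma > 0) {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    sk <- sigma * sqrt(nr * np)
    kspace <- kspace + complex(real = rnorm(length(kspace), 0, sk),
                               imaginary = rnorm(length(kspace), 0, sk))
    knav <- knav + complex(real = rnorm(length(knav), 0, sk),
                           imaginary = rnorm(length(knav), 0, sk))
  }

  structure(list(
    echoes = kspace, navs = knav, train = train, config = cfg,
    fluct = data.frame(line = seq_len(np), df0_hz = fo$base,
                       df0_shifted_extra_hz = fo$extra),
    sigma = sigma, support = phantom$labels > 0,
    step1_applied = FALSE, step2_applied = FALSE
  ), class = "es_kspace")
}

#' @export
print.es_kspace <- function(x, ...) {
  d <- dim(x$echoes)
  cat(sprintf("ES-mGRE k-space: %d x %d, %d echoes, %d navigators; sigma = %g\n",
              d[1], d[2], d[3], dim(x$navs)[3], x$sigma))
  cat(sprintf("  corrections applied: step1 %s, step2 %s\n",
              x$step1_applied, x$step2_applied))
  invisible(x)
}

hybrid <- function(k) mvfft(k, inverse = TRUE) / nrow(k)   # (x, ky) space
unhybrid <- function(h) mvfft(h)

#' Replace low-SNR phase estimates by the high-SNR median
#'
#' Positions whose navigator SNR falls below the mean SNR get their
#' estimated phase replaced by the median phase over the above-mean
#' positions; above-mean positions are never altered. With uniform SNR no
#' position is strictly below the mean and nothing is replaced.
#'
#' @param phase_map numeric vector of per-position phase estimates, rad.
#' @param snr_map numeric vector of per-position SNR values.
#' @return Phase vector with low-SNR entries replaced.
#' @export
low_snr_fallback <- function(phase_map, snr_map) {
  low <- snr_map < mean(snr_map)
  if (!any(low)) return(phase_map)
  if (all(low)) {
    warning("no above-mean SNR positions; using the global median phase")
    phase_map[] <- median(phase_map)
    return(phase_map)
  }
  phase_map[low] <- median(phase_map[!low])
  phase_map
}

# per-line phase difference maps from one navigator (hybrid space), with
# optional low-SNR fallback; returns matrix [x, line]
navigator_phase_map <- function(nav_h, sigma_h, robust) {
  phase <- Arg(nav_h * Conj(nav_h[, 1]))
  if (robust && sigma_h > 0) {
    snr <- Mod(nav_h[, 1]) / sigma_h
    for (p in seq_len(ncol(phase)))
      phase[, p] <- low_snr_fallback(phase[, p], snr)
  }
  phase
}

#' Navigator correction, step 1
#'
#' Transforms every readout to hybrid (x, ky) space, computes the per-line
#' phase of the first (prompt-block) navigator relative to line 1, and
#' removes it from every echo (prompt and shifted) and every later
#' navigator after scaling by `TE_n / TE_nav1`.
#'
#' @param ks an [acquire_kspace()] object.
#' @param robust apply the low-SNR median fallback to the phase estimates
#'   when the noise level is known.
#' @return The corrected `es_kspace`; a `CorrectionReport` is attached as
#'   attribute `report` (step-1 phase map, fallback usage).
#' @export
correct_step1 <- function(ks, robust = TRUE) {
  navs <- navigators(ks$train)
  i1 <- which(navs$block == "prompt")[1]
  if (is.na(i1)) i1 <- 1L
  if (dim(ks$navs)[3] < 1) stop_runtime("no navigator echoes present")
  nr <- dim(ks$echoes)[1]
  sigma_h <- ks$sigma * sqrt(dim(ks$echoes)[2])
  nav_h <- hybrid(ks$navs[, , i1])
  phase <- navigator_phase_map(nav_h, sigma_h, robust)
  te1 <- navs$te[i1]

  for (n in seq_len(dim(ks$echoes)[3])) {
    h <- hybrid(ks$echoes[, , n])
    ks$echoes[, , n] <- unhybrid(h * exp(-1i * phase * ks$train$te[n] / te1))
  }
  # every navigator is itself a readout: the first one is corrected too
  # (scale factor TE_nav1/TE_nav1 = 1), which zeroes its line-to-line phase
  # and makes the step idempotent
  for (j in seq_len(dim(ks$navs)[3])) {
    h <- hybrid(ks$navs[, , j])
    ks$navs[, , j] <- unhybrid(h * exp(-1i * phase * navs$te[j] / te1))
  }
  ks$step1_applied <- TRUE
  attr(ks, "report") <- list(step1_phase = phase,
                             fallback_used = robust && ks$sigma > 0,
                             reference_nav = i1)
  ks
}

#' Navigator correction, step 2
#'
#' Estimates the residual per-line phase from the shifted-block navigator
#' (itself already corrected by step 1), scales it by `TE_n / TE_nav2` and
#' removes it from the shifted echoes only; prompt echoes are returned
#' bit-identical.
#'
#' @param ks an `es_kspace` after [correct_step1()].
#' @param robust apply the low-SNR median fallback.
#' @return The corrected `es_kspace` (report extended with the step-2 map).
#' @export
correct_step2 <- function(ks, robust = TRUE) {
  if (!isTRUE(ks$step1_applied))
    stop_runtime("correct_step2 requires correct_step1 first")
  navs <- navigators(ks$train)
  i2 <- which(navs$block == "shifted")[1]
  if (is.na(i2)) {
    warning("no shifted-block navigator present; step 2 is a no-op")
    return(ks)
  }
  sigma_h <- ks$sigma * sqrt(dim(ks$echoes)[2])
  nav_h <- hybrid(ks$navs[, , i2])
  phase <- navigator_phase_map(nav_h, sigma_h, robust)
  te2 <- navs$te[i2]
  for (n in which(ks$train$shifted)) {
    h <- hybrid(ks$echoes[, , n])
    ks$echoes[, , n] <- unhybrid(h * exp(-1i * phase * ks$train$te[n] / te2))
  }
  ks$step2_applied <- TRUE
  rep <- attr(ks, "report")
  rep$step2_phase <- phase
  attr(ks, "report") <- rep
  ks
}

#' Navigator-to-echo assignment for long multi-navigator trains
#'
#' For an N-echo train with m navigators, echoes are split into m contiguous
#' equal blocks: block 1 is corrected by the first navigator only, block k
#' (k >= 2) by the first and the k-th navigator. A 128-echo train with 4
#' navigators yields blocks 1-32 (first only), 33-64 (first + second),
#' 65-96 (first + third) and 97-128 (first + fourth).
#'
#' @param n_echoes total number of echoes.
#' @param n_navigators number of navigators (>= 1).
#' @return Data frame with columns `echo`, `step1_nav` (always 1) and
#'   `step2_nav` (`NA` for the first block).
#' @export
assign_navigators_qute <- function(n_echoes, n_navigators) {
  if (n_navigators < 1) stop_validation("at least one navigator is required")
  block <- ceiling(seq_len(n_echoes) / (n_echoes / n_navigators))
  block <- pmin(block, n_navigators)
  data.frame(echo = seq_len(n_echoes), step1_nav = 1L,
             step2_nav = ifelse(block >= 2, block, NA_integer_))
}

#' Reconstruct per-echo magnitude images
#' @param ks an `es_kspace` object.
#' @return Numeric array `read x phase x echo` of magnitudes.
#' @export
reconstruct_magnitude <- function(ks) {
  d <- dim(ks$echoes)
  out <- array(0, dim = d)
  for (n in seq_len(d[3]))
    out[, , n] <- Mod(fft(ks$echoes[, , n], inverse = TRUE)) / (d[1] * d[2])
  out
}

#' Ghost-energy metric
#'
#' Fraction of image energy lying outside the object support; phase-encode
#' ghosting from shot-to-shot phase inconsistency raises it.
#'
#' @param mag magnitude image (matrix) or stack (3-d array; averaged).
#' @param support logical matrix of the object support.
#' @return Scalar in `[0, 1]`.
#' @export
ghost_energy <- function(mag, support) {
  if (length(dim(mag)) == 3) {
    e <- apply(mag, 3, function(m) sum(m[!support]^2) / sum(m^2))
    return(mean(e))
  }
  sum(mag[!support]^2) / sum(mag^2)
}
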