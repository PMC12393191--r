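# Voxelwise estimation of M0, T2* and D from multi-echo magnitude data.
#
# The signal model is s(TE_n) = M0 exp(-TE_n/T2*) exp(-b(TE_n) D)
# exp((-1)^n delta), with the (-1)^n sign taken from each echo's bipolar
# readout polarity. Magnitude data are Rician distributed; the likelihood
# uses the exponentially scaled Bessel I0 for stability and holds sigma
# fixed at the background estimate.

#' Fit-model settings
#'
#' @param include_diffusion estimate the diffusivity `D` (otherwise `D = 0`).
#' @param include_delta estimate the bipolar modulation `delta` as a free
#'   parameter of the voxel fit (the iterative correction in
#'   [iterative_delta_correction()] is the default route; simulation fits
#'   exclude delta).
#' @param noise_model `"rician"` (magnitude likelihood) or `"gaussian"`
#'   (least squares).
#' @param t2_bounds,d_bounds,delta_bound parameter bounds: T2* in ms,
#'   D in um^2/ms, |delta| dimensionless.
#' @param multi_start number of T2* starting points (1 disables the
#'   multi-start; 3 brackets the log-linear initial value by x1/3 and x3).
#' @param maxit optimizer iteration cap.
#' @param reltol relative convergence tolerance on the objective.
#' @return An `es_fit_model` list.
#' @export
fit_model <- function(include_diffusion = TRUE, include_delta = FALSE,
                      noise_model = c("rician", "gaussian"),
                      t2_bounds = c(1, 5000), d_bounds = c(0, 10),
                      delta_bound = 1, multi_start = 3, maxit = 200,
                      reltol = 1e-10) {
  structure(list(include_diffusion = include_diffusion,
                 include_delta = include_delta,
                 noise_model = match.arg(noise_model),
                 t2_bounds = t2_bounds, d_bounds = d_bounds,
                 delta_bound = delta_bound, multi_start = multi_start,
                 maxit = maxit, reltol = reltol),
            class = "es_fit_model")
}

#' Evaluate the magnitude signal model
#'
#' @param params named list/vector with `M0`, `T2star` (ms) and optionally
#'   `D` (um^2/ms) and `delta`.
#' @param train an [build_echo_train()] object (TEs, b-values, polarities).
#' @return Noiseless magnitude per echo.
#' @export
model_signal <- function(params, train) {
  D <- if (is.null(params$D)) 0 else params$D
  delta <- if (is.null(params$delta)) 0 else params$delta
  params$M0 * exp(-train$te / params$T2star - train$b * D * 1e-3 +
                    train$polarity * delta)
}

#' Estimate the magnitude-noise level from background corners
#'
#' Pools four square ROIs at the image corners (default 20 x 20 = 400
#' voxels each) and converts the pooled mean under Rayleigh background
#' statistics: `sigma = mean / sqrt(pi/2)`. `method = "second_moment"` uses
#' `sigma = sqrt(mean(x^2)/2)` instead.
#'
#' @param mag magnitude image (matrix) or stack (first echo is used).
#' @param corner_size side length of each corner ROI in voxels.
#' @param method `"rayleigh_mean"` (default) or `"second_moment"`.
#' @return List with `sigma`, `n_voxels` and the per-corner means.
#' @export
estimate_noise_sigma <- function(mag, corner_size = 20,
                                 method = c("rayleigh_mean", "second_moment")) {
  method <- match.arg(method)
  if (length(dim(mag)) == 3) mag <- mag[, , 1]
  nr <- nrow(mag); np <- ncol(mag); cs <- corner_size
  if (nr < 2 * cs || np < 2 * cs)
    stop_validation("image smaller than twice the corner ROI size")
  corners <- list(mag[1:cs, 1:cs], mag[1:cs, (np - cs + 1):np],
                  mag[(nr - cs + 1):nr, 1:cs],
                  mag[(nr - cs + 1):nr, (np - cs + 1):np])
  means <- vapply(corners, mean, 1)
  vals <- unlist(corners)
  if (all(vals == 0)) {
    warning("all-zero background corners; sigma = 0")
    return(list(sigma = 0, n_voxels = length(vals), corner_means = means))
  }
  if (max(means) > 3 * median(means) + 1e-12)
    warning("one background corner is much brighter than the others; it may overlap the object")
  sigma <- switch(method,
    rayleigh_mean = mean(vals) / sqrt(pi / 2),
    second_moment = sqrt(mean(vals^2) / 2))
  list(sigma = sigma, n_voxels = length(vals), corner_means = means)
}

# log I0 and the ratio I1/I0, switching to the large-argument asymptotic
# series where besselI becomes slow; the series is accurate to ~1e-10 at
# the switch point z = 50
log_bessel_i0 <- function(z) {
  out <- numeric(length(z))
  small <- z < 50
  if (any(small))
    out[small] <- z[small] + log(besselI(z[small], 0, expon.scaled = TRUE))
  if (any(!small)) {
    zi <- 1 / z[!small]
    out[!small] <- z[!small] - 0.5 * log(2 * pi * z[!small]) +
      log1p(zi / 8 + 9 * zi^2 / 128 + 225 * zi^3 / 3072)
  }
  out
}

bessel_ratio_i1i0 <- function(z) {
  out <- numeric(length(z))
  small <- z < 50
  if (any(small))
    out[small] <- besselI(z[small], 1, expon.scaled = TRUE) /
      besselI(z[small], 0, expon.scaled = TRUE)
  if (any(!small)) {
    zi <- 1 / z[!small]
    out[!small] <- (1 - 3 * zi / 8 - 15 * zi^2 / 128 - 105 * zi^3 / 3072) /
      (1 + zi / 8 + 9 * zi^2 / 128 + 225 * zi^3 / 3072)
  }
  out
}

# negative log-likelihoods (vectorized over echoes) and their gradients
# with respect to the predicted amplitudes nu
rician_nll <- function(s, nu, sigma) {
  z <- s * nu / sigma^2
  -sum(log(s / sigma^2) - (s^2 + nu^2) / (2 * sigma^2) + log_bessel_i0(z))
}

rician_dnll_dnu <- function(s, nu, sigma) {
  z <- s * nu / sigma^2
  nu / sigma^2 - (s / sigma^2) * bessel_ratio_i1i0(z)
}

gaussian_nll <- function(s, nu, sigma) {
  sum((s - nu)^2) / (2 * sigma^2) + length(s) * log(sigma * sqrt(2 * pi))
}

gaussian_dnll_dnu <- function(s, nu, sigma) -(s - nu) / sigma^2

# log-linear initializer: (M0, T2*) from the prompt echoes, D from the
# shifted/prompt block log-ratio
init_params <- function(s, train, model) {
  pos <- s > 0
  prompt <- !train$shifted & pos
  if (sum(prompt) < 2) prompt <- pos
  x <- train$te[prompt]; y <- log(s[prompt])
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- max(-fit$coefficients[2], 1 / 5000)
  t2 <- min(max(1 / r2, model$t2_bounds[1]), model$t2_bounds[2])
  m0 <- exp(fit$coefficients[1])
  d0 <- 0
  if (model$include_diffusion && any(train$shifted & pos)) {
    sh <- train$shifted & pos
    pred <- m0 * exp(-train$te[sh] / t2)
    lr <- log(pmax(s[sh], 1e-12) / pred)
    bsh <- train$b[sh] * 1e-3
    d0 <- -sum(lr * bsh) / max(sum(bsh^2), 1e-12)
    d0 <- min(max(d0, model$d_bounds[1]), model$d_bounds[2])
  }
  list(M0 = max(m0, 1e-9), T2star = t2, D = d0)
}

#' Fit one voxel's echo-train magnitudes
#'
#' Maximum-likelihood estimation of `M0`, `T2*` and optionally `D` (and
#' `delta`) under the Rician magnitude likelihood (or Gaussian least
#' squares), by bounded quasi-Newton optimization with analytic gradients,
#' a log-linear initializer and a fixed multi-start grid on T2*. The result
#' is deterministic given the data and settings.
#'
#' @param s magnitude signal per echo.
#' @param train an [build_echo_train()] object.
#' @param model an [fit_model()] object.
#' @param sigma magnitude-noise standard deviation (required for the Rician
#'   model; see [estimate_noise_sigma()]).
#' @return An `es_fit` list: estimates, `logLik`, `k` (free parameters),
#'   `n`, `caic`, convergence flag and iteration count.
#' @export
fit_voxel <- function(s, train, model = fit_model(), sigma = NULL) {
  n <- length(s)
  if (n != nrow(train)) stop_runtime("signal length does not match the train")
  if (model$noise_model == "rician" && (is.null(sigma) || sigma <= 0))
    stop_validation("the Rician noise model requires a positive sigma")
  k_free <- 2L + model$include_diffusion + model$include_delta
  if (n < k_free) stop_runtime("fewer echoes than free parameters")
  sigma_fixed <- sigma
  profile_sigma <- model$noise_model == "gaussian" && is.null(sigma)

  pe <- pmax(s, 1e-12)
  nll_fun <- if (model$noise_model == "rician") rician_nll else gaussian_nll
  dnll_fun <- if (model$noise_model == "rician") rician_dnll_dnu else
    gaussian_dnll_dnu

  unpack <- function(th) {
    i <- 3L
    D <- if (model$include_diffusion) th[i] else 0
    if (model$include_diffusion) i <- i + 1L
    delta <- if (model$include_delta) th[i] else 0
    list(M0 = th[1], T2star = th[2], D = D, delta = delta)
  }
  predict_nu <- function(pl) {
    pl$M0 * exp(-train$te / pl$T2star - train$b * pl$D * 1e-3 +
                  train$polarity * pl$delta)
  }
  obj <- function(th) {
    pl <- unpack(th)
    nu <- predict_nu(pl)
    if (profile_sigma) {
      rss <- sum((pe - nu)^2)
      return(n / 2 * log(max(rss, 1e-300) / n))
    }
    nll_fun(pe, nu, sigma_fixed)
  }
  grad <- function(th) {
    pl <- unpack(th)
    nu <- predict_nu(pl)
    dn <- if (profile_sigma) {
      rss <- sum((pe - nu)^2)
      -(pe - nu) * n / max(rss, 1e-300)
    } else dnll_fun(pe, nu, sigma_fixed)
    g <- c(sum(dn * nu / pl$M0), sum(dn * nu * train$te / pl$T2star^2))
    if (model$include_diffusion) g <- c(g, sum(dn * nu * (-train$b * 1e-3)))
    if (model$include_delta) g <- c(g, sum(dn * nu * train$polarity))
    g
  }

  ini <- init_params(pe, train, model)
  lower <- c(1e-12, model$t2_bounds[1])
  upper <- c(Inf, model$t2_bounds[2])
  th0 <- c(ini$M0, ini$T2star)
  if (model$include_diffusion) {
    lower <- c(lower, model$d_bounds[1]); upper <- c(upper, model$d_bounds[2])
    th0 <- c(th0, ini$D)
  }
  if (model$include_delta) {
    lower <- c(lower, -model$delta_bound); upper <- c(upper, model$delta_bound)
    th0 <- c(th0, 0)
  }
  starts <- list(th0)
  if (model$multi_start > 1) {
    for (f in c(1 / 3, 3)[seq_len(model$multi_start - 1)]) {
      th <- th0
      th[2] <- min(max(th0[2] * f, model$t2_bounds[1]), model$t2_bounds[2])
      starts[[length(starts) + 1L]] <- th
    }
  }
  best <- NULL
  for (th in starts) {
    ps <- pmax(abs(th), c(1e-6, 1, if (model$include_diffusion) 0.5,
                          if (model$include_delta) 0.05))
    res <- tryCatch(
      optim(th, obj, grad, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = model$maxit, factr = model$reltol / 1e-15,
                           parscale = ps)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(M0 = ini$M0, T2star = ini$T2star, D = ini$D,
                          delta = 0, logLik = NA_real_, k = k_free, n = n,
                          caic = NA_real_, converged = FALSE, iterations = 0L,
                          model = model), class = "es_fit"))
  pl <- unpack(best$par)
  k_tot <- k_free + profile_sigma          # profiled sigma counts as a parameter
  ll <- if (profile_sigma) {
    rss <- sum((pe - predict_nu(pl))^2)
    -n / 2 * (log(2 * pi * rss / n) + 1)
  } else -best$value
  structure(list(M0 = pl$M0, T2star = pl$T2star, D = pl$D, delta = pl$delta,
                 logLik = ll, k = as.integer(k_tot), n = n,
                 caic = caic(ll, k_tot, n),
                 converged = best$convergence == 0,
                 iterations = best$counts[1], model = model),
            class = "es_fit")
}

#' @export
print.es_fit <- function(x, ...) {
  cat(sprintf("es_fit: M0 = %.4g, T2* = %.4g ms, D = %.4g um^2/ms, delta = %.4g\n",
              x$M0, x$T2star, x$D, x$delta))
  cat(sprintf("  logLik %.4g, k = %d, n = %d, cAIC %.4g, converged: %s\n",
              x$logLik, x$k, x$n, x$caic, x$converged))
  invisible(x)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `cAIC = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; undefined (NA) when
#' `n - k - 1 <= 0`.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations.
#' @return Scalar cAIC.
#' @export
caic <- function(logLik, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare two fits by corrected AIC
#'
#' Works on single `es_fit` objects or on [fit_map()] outputs; the fit (or
#' map) with the lower cAIC is preferred, the simpler model winning ties.
#'
#' @param fit_with_D fit including the diffusion term.
#' @param fit_without_D fit excluding it.
#' @return For single fits, a list with both cAICs and
#'   `prefers_diffusion`; for maps, a list with the cAIC difference matrix
#'   and a logical preference matrix (NA outside the mask).
#' @export
caic_compare <- function(fit_with_D, fit_without_D) {
  if (inherits(fit_with_D, "es_fit")) {
    cw <- fit_with_D$caic; co <- fit_without_D$caic
    return(list(caic_with = cw, caic_without = co,
                prefers_diffusion = isTRUE(cw < co)))
  }
  cw <- caic_map(fit_with_D); co <- caic_map(fit_without_D)
  list(caic_with = cw, caic_without = co, delta_caic = cw - co,
       prefers_diffusion = cw < co)
}

caic_map <- function(map) {
  k <- attr(map, "k")
  out <- map$logLik
  out[] <- mapply(function(ll, n) if (is.na(ll)) NA_real_ else
    caic(ll, k, n), map$logLik, map$n)
  out
}

#' Iterative bipolar-modulation (delta) correction
#'
#' Alternates between (a) fitting the delta-free signal model, (b)
#' synthesizing delta-free images from the fit, and (c) choosing the delta
#' that minimizes the discrepancy between the demodulated data and the
#' synthesis; the data are demodulated with the accumulated delta and the
#' loop repeats until the increment falls below `tol`. By default delta is
#' a single global scalar estimated over all supplied voxels (the
#' per-voxel variant returns one delta per voxel).
#'
#' @param signals matrix `voxels x echoes` of magnitudes (a vector is
#'   treated as one voxel).
#' @param train an [build_echo_train()] object.
#' @param model an [fit_model()] object; its `include_delta` flag is
#'   ignored (the delta-free model is fitted).
#' @param sigma noise level for the fits.
#' @param per_voxel estimate one delta per voxel instead of a global one.
#' @param tol convergence tolerance on the delta increment.
#' @param max_iter iteration cap (a non-converged loop returns the last
#'   iterate, flagged).
#' @return List with `delta` (scalar or per-voxel), `corrected` (demodulated
#'   signals), `iterations`, `converged` and the increment `history`.
#' @export
iterative_delta_correction <- function(signals, train, model = fit_model(),
                                       sigma = NULL, per_voxel = FALSE,
                                       tol = 1e-4, max_iter = 10) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  model$include_delta <- FALSE
  nv <- nrow(signals)
  pol <- train$polarity
  est_one <- function(S) {     # S: voxels x echoes block sharing one delta
    d_tot <- 0; hist <- numeric(0); converged <- FALSE
    for (it in seq_len(max_iter)) {
      dem <- sweep(S, 2, exp(-pol * d_tot), `*`)
      synth <- t(apply(dem, 1, function(v)
        model_signal(fit_voxel(v, train, model, sigma), train)))
      f <- function(d) sum((sweep(S, 2, exp(-pol * (d_tot + d)), `*`) - synth)^2)
      d_inc <- optimize(f, c(-0.5, 0.5))$minimum
      d_tot <- d_tot + d_inc
      hist <- c(hist, d_inc)
      if (abs(d_inc) < tol) { converged <- TRUE; break }
    }
    list(delta = d_tot, iterations = it, converged = converged, history = hist)
  }
  if (per_voxel) {
    res <- lapply(seq_len(nv), function(i) est_one(signals[i, , drop = FALSE]))
    delta <- vapply(res, `[[`, 1, "delta")
    corrected <- signals * exp(-outer(delta, pol))
    list(delta = delta, corrected = corrected,
         iterations = max(vapply(res, `[[`, 1L, "iterations")),
         converged = all(vapply(res, `[[`, TRUE, "converged")),
         history = lapply(res, `[[`, "history"))
  } else {
    res <- est_one(signals)
    corrected <- sweep(signals, 2, exp(-pol * res$delta), `*`)
    c(res[c("delta", "iterations", "converged", "history")],
      list(corrected = corrected))
  }
}

#' Fit every voxel of a multi-echo image stack
#'
#' @param stack numeric array `read x phase x echo` of magnitudes.
#' @param train an [build_echo_train()] object.
#' @param model an [fit_model()] object.
#' @param sigma noise level; if `NULL` it is estimated with
#'   [estimate_noise_sigma()].
#' @param mask logical matrix of voxels to fit; default: first-echo
#'   magnitude above `3 sigma`.
#' @return An `es_fit_map` list of matrices (`M0`, `T2star`, `D`, `delta`,
#'   `logLik`, `n`, `converged`, `mask`) with the model and `k` attached.
#' @export
fit_map <- function(stack, train, model = fit_model(), sigma = NULL,
                    mask = NULL) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] != nrow(train))
    stop_runtime("stack dimensions do not match the echo train")
  if (is.null(sigma)) sigma <- estimate_noise_sigma(stack,
      corner_size = min(20, d[1] %/% 4))$sigma
  if (is.null(mask)) mask <- stack[, , 1] > 3 * sigma
  mk <- function() matrix(NA_real_, d[1], d[2])
  out <- list(M0 = mk(), T2star = mk(), D = mk(), delta = mk(),
              logLik = mk(), n = mk(), converged = matrix(NA, d[1], d[2]),
              mask = mask)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    f <- fit_voxel(stack[i, j, ], train, model, sigma)
    out$M0[i, j] <- f$M0; out$T2star[i, j] <- f$T2star
    out$D[i, j] <- f$D; out$delta[i, j] <- f$delta
    out$logLik[i, j] <- f$logLik; out$n[i, j] <- f$n
    out$converged[i, j] <- f$converged
  }
  structure(out, k = 2L + model$include_diffusion + model$include_delta,
            model = model, sigma = sigma, class = "es_fit_map")
}

#' @export
print.es_fit_map <- function(x, ...) {
  cat(sprintf("es_fit_map: %d x %d, %d fitted voxels (k = %d)\n",
              nrow(x$T2star), ncol(x$T2star), sum(x$mask), attr(x, "k")))
  invisible(x)
}
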