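#' Default component mapping for the global fit
#'
#' Region SB is described by the cross-correlation Gaussian; A by the S2
#' population plus the hot-ground-state step; C and D by S1 plus triplet;
#' E by S1 plus the high-energy sideband that overlaps it; F by S1 (the
#' shakeup band follows the dark-state depopulation). Every region carries a
#' free constant baseline. For N 1s, A is the excited-state gain and B the
#' depletion plus sideband.
#'
#' @param regions Character vector of region names.
#' @return Named list mapping region to component names among
#'   `"sideband"`, `"s2"`, `"s1"`, `"t"`, `"hgs"`, `"depletion"`,
#'   `"baseline"`.
#' @export
default_fit_components <- function(regions) {
  comp <- list(
    SB = c("sideband", "baseline"),
    A = c("s2", "hgs", "baseline"),
    B = c("depletion", "sideband", "baseline"),
    C = c("s1", "t", "baseline"),
    D = c("s1", "t", "baseline"),
    E = c("s1", "sideband", "baseline"),
    F = c("s1", "baseline")
  )
  out <- comp[regions]
  if (any(vapply(out, is.null, logical(1)))) {
    abort("no default components for some regions; supply `components`.",
          class = "trxps_fit_setup_error")
  }
  out
}

# component shapes on a delay grid for shared parameters
component_shapes <- function(t, t0, sigma, tau_ic, tau_isc) {
  C <- pnorm(t, mean = t0, sd = sigma)
  e_ic <- emg(t, t0, sigma, tau_ic)
  rel <- abs(tau_isc - tau_ic) / max(tau_ic, tau_isc)
  s1 <- if (rel < 1e-9) {
    emg_degenerate(t, t0, sigma, tau_ic)
  } else {
    tau_isc / (tau_isc - tau_ic) *
      (emg(t, t0, sigma, tau_isc) - e_ic)
  }
  list(
    sideband = exp(-(t - t0)^2 / (2 * sigma^2)),
    s2 = e_ic,
    s1 = s1,
    t = pmax(C - e_ic - s1, 0),
    hgs = C,
    depletion = -C,
    baseline = rep(1, length(t))
  )
}

# weighted NNLS amplitude solve for one region; baseline is unconstrained
# (split into +/- columns). Returns list(amps, fitted, ssr).
solve_amplitudes <- function(y, w, shapes, comps) {
  has_base <- "baseline" %in% comps
  nn <- setdiff(comps, "baseline")
  X <- do.call(cbind, shapes[nn])
  colnames(X) <- nn
  if (all(abs(y) < .Machine$double.eps) || any(!is.finite(X))) {
    abort("degenerate trace or design in amplitude solve.",
          class = "trxps_fit_setup_error")
  }
  Xw <- X * w
  yw <- y * w
  if (has_base) {
    # unconstrained baseline projected out before the NNLS step
    bw <- shapes$baseline * w
    bn2 <- sum(bw^2)
    proj <- function(v) v - bw * (sum(bw * v) / bn2)
    Xp <- apply(Xw, 2, proj)
    yp <- proj(yw)
  } else {
    Xp <- Xw
    yp <- yw
  }
  keep <- colSums(Xp^2) > 1e-300
  a <- setNames(numeric(length(nn)), nn)
  if (any(keep)) {
    sol <- tryCatch(pracma::lsqnonneg(Xp[, keep, drop = FALSE], yp),
                    error = function(e) {
                      abort(paste0("amplitude solve failed: ",
                                   conditionMessage(e)),
                            class = "trxps_fit_setup_error")
                    })
    a[keep] <- sol$x
  }
  if (has_base) {
    c_base <- sum(bw * (yw - Xw %*% a)) / bn2
    fitted <- as.vector(X %*% a) + c_base * shapes$baseline
    amps <- c(a, baseline = c_base)
  } else {
    fitted <- as.vector(X %*% a)
    amps <- a
  }
  list(amps = amps, fitted = fitted,
       ssr = sum((yw - fitted * w)^2))
}

#' Gaussian fit of a sideband time trace
#'
#' Fits `a * exp(-(t - t0)^2 / (2 sigma^2)) + b` to a region-integrated
#' sideband trace; its width measures the pump-probe cross-correlation.
#'
#' @param trace Tibble `delay`, `value` (optionally `sigma`).
#' @return One-row tibble `t0`, `sigma`, `fwhm`, `amplitude`, `baseline`.
#' @export
fit_sideband_gaussian <- function(trace) {
  t <- trace$delay; y <- trace$value
  dense <- abs(t) < 500
  t0g <- t[dense][which.max(y[dense])]
  fit <- suppressWarnings(
    nls(y ~ a * exp(-(t - t0)^2 / (2 * s^2)) + b,
        start = list(a = max(y) - median(y), t0 = t0g, s = 40,
                     b = median(y)),
        control = list(maxiter = 500, warnOnly = TRUE)))
  cf <- coef(fit)
  tibble::tibble(t0 = unname(cf["t0"]), sigma = abs(unname(cf["s"])),
                 fwhm = sigma_to_fwhm(abs(unname(cf["s"]))),
                 amplitude = unname(cf["a"]), baseline = unname(cf["b"]))
}

#' Global fit of region-integrated time traces
#'
#' Fits all regions simultaneously with shared nonlinear parameters (time
#' zero, Gaussian IRF sigma, internal-conversion and intersystem-crossing
#' constants) and per-region non-negative component amplitudes (baseline
#' unconstrained), by weighted least squares (weights 1/sigma^2). Amplitudes
#' are solved by constrained linear least squares inside the nonlinear
#' search (variable projection), which keeps the very short tau_ic << IRF
#' regime well conditioned.
#'
#' Initialization: t0 and sigma from a Gaussian pre-fit of the SB trace when
#' present; tau_ic 50 fs, tau_isc 1 ps. Bounds: tau_ic in \[1, 500\] fs,
#' tau_isc in \[0.1, 100\] ps. Time constants are searched on a log scale.
#'
#' @param traces A `trxps_traces` tibble (`region`, `delay`, `value`,
#'   `sigma`).
#' @param components Named list region -> component names; default
#'   [default_fit_components()].
#' @param init Optional named list overriding initial values (`t0`, `sigma`,
#'   `tau_ic`, `tau_isc`).
#' @param bounds Optional named list of `c(lo, hi)` bounds per parameter.
#' @param fixed Optional named list of parameters to hold fixed.
#' @return A `trxps_fit` object; see [tidy.trxps_fit()] and
#'   [glance.trxps_fit()].
#' @export
fit_global <- function(traces, components = NULL, init = list(),
                       bounds = list(), fixed = list()) {
  regions <- unique(traces$region)
  if (length(regions) < 2 && length(fixed) == 0) {
    abort("global fit needs at least two regions.",
          class = "trxps_fit_setup_error")
  }
  components <- components %||% default_fit_components(regions)
  tr <- split(traces, traces$region)[regions]
  for (r in regions) {
    if (all(tr[[r]]$value == 0)) {
      abort(paste0("region ", r, " has an all-zero trace."),
            class = "trxps_fit_setup_error")
    }
  }
  w <- purrr::map(tr, ~ {
    s <- .x$sigma
    if (all(is.na(s)) || all(s == 0)) rep(1, nrow(.x))
    else 1 / pmax(s, max(s[s > 0], na.rm = TRUE) * 1e-3)
  })

  defaults <- list(t0 = 0, sigma = fwhm_to_sigma(80.5), tau_ic = 50,
                   tau_isc = 1000)
  if ("SB" %in% regions && is.null(init$t0) && is.null(init$sigma)) {
    pre <- tryCatch(fit_sideband_gaussian(tr[["SB"]]),
                    error = function(e) NULL)
    if (!is.null(pre) && is.finite(pre$sigma) && pre$sigma > 5 &&
        pre$sigma < 200) {
      defaults$t0 <- pre$t0
      defaults$sigma <- pre$sigma
    }
  }
  start <- modifyList(defaults, init)
  bnd <- modifyList(list(t0 = c(-100, 100), sigma = c(5, 200),
                         tau_ic = c(1, 500), tau_isc = c(100, 1e5)),
                    bounds)

  free <- setdiff(c("t0", "sigma", "tau_ic", "tau_isc"), names(fixed))
  to_internal <- function(p) {
    vapply(free, function(nm) {
      if (nm == "t0") p[[nm]] else log(p[[nm]])
    }, numeric(1))
  }
  from_internal <- function(x) {
    p <- fixed
    for (i in seq_along(free)) {
      nm <- free[i]
      p[[nm]] <- if (nm == "t0") x[i] else exp(x[i])
    }
    p[c("t0", "sigma", "tau_ic", "tau_isc")]
  }
  objective <- function(x) {
    p <- from_internal(x)
    ssr <- 0
    for (r in regions) {
      sh <- component_shapes(tr[[r]]$delay, p$t0, p$sigma, p$tau_ic,
                             p$tau_isc)
      ssr <- ssr + solve_amplitudes(tr[[r]]$value, w[[r]], sh,
                                    components[[r]])$ssr
    }
    ssr
  }
  lower <- vapply(free, function(nm)
    if (nm == "t0") bnd[[nm]][1] else log(bnd[[nm]][1]), numeric(1))
  upper <- vapply(free, function(nm)
    if (nm == "t0") bnd[[nm]][2] else log(bnd[[nm]][2]), numeric(1))
  x0 <- pmin(pmax(to_internal(start), lower), upper)

  opt <- optim(x0, objective, method = "L-BFGS-B", lower = lower,
               upper = upper, hessian = TRUE,
               control = list(maxit = 500, factr = 1e7))
  p_hat <- from_internal(opt$par)

  # curvature-based 1-sigma uncertainties: cov = 2 H^-1 on the internal
  # scale (objective is the weighted SSR ~ chi-square), delta method back.
  se_int <- rep(NA_real_, length(free))
  covm <- tryCatch(solve(opt$hessian / 2), error = function(e) NULL)
  if (!is.null(covm)) {
    d <- diag(covm)
    se_int <- ifelse(d > 0, sqrt(d), NA_real_)
  }
  se <- setNames(rep(NA_real_, 4), c("t0", "sigma", "tau_ic", "tau_isc"))
  for (i in seq_along(free)) {
    nm <- free[i]
    se[nm] <- if (nm == "t0") se_int[i] else se_int[i] * p_hat[[nm]]
  }

  amps <- list(); fitted <- list(); npar_amp <- 0
  for (r in regions) {
    sh <- component_shapes(tr[[r]]$delay, p_hat$t0, p_hat$sigma,
                           p_hat$tau_ic, p_hat$tau_isc)
    sol <- solve_amplitudes(tr[[r]]$value, w[[r]], sh, components[[r]])
    amps[[r]] <- tibble::tibble(region = r, component = names(sol$amps),
                                amplitude = unname(sol$amps))
    fitted[[r]] <- tibble::tibble(region = r, delay = tr[[r]]$delay,
                                  value = tr[[r]]$value,
                                  sigma = tr[[r]]$sigma,
                                  fitted = sol$fitted)
    npar_amp <- npar_amp + length(sol$amps)
  }
  chisq <- opt$value
  dof <- nrow(traces) - length(free) - npar_amp
  params <- tibble::tibble(
    term = c("t0", "sigma_irf", "tau_ic", "tau_isc", "cc_fwhm"),
    estimate = c(p_hat$t0, p_hat$sigma, p_hat$tau_ic, p_hat$tau_isc,
                 sigma_to_fwhm(p_hat$sigma)),
    std_error = c(se["t0"], se["sigma"], se["tau_ic"], se["tau_isc"],
                  se["sigma"] * 2 * sqrt(2 * log(2))),
    fixed = c("t0", "sigma", "tau_ic", "tau_isc", "sigma") %in% names(fixed)
  )
  structure(list(
    params = params,
    amplitudes = dplyr::bind_rows(amps),
    fitted = dplyr::bind_rows(fitted),
    chisq = chisq, dof = dof,
    redchi = chisq / max(dof, 1),
    convergence = opt$convergence,
    message = opt$message %||% "",
    components = components,
    irf_convention = "fwhm",
    traces = traces
  ), class = "trxps_fit")
}

#' @export
print.trxps_fit <- function(x, ...) {
  cat("Global TR-XPS kinetic fit\n")
  cat(sprintf("  regions: %s\n",
              paste(unique(x$amplitudes$region), collapse = ", ")))
  p <- x$params
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-9s %10.3f +/- %.3f%s\n", p$term[i], p$estimate[i],
                p$std_error[i], if (p$fixed[i]) " (fixed)" else ""))
  }
  cat(sprintf("  reduced chi-square: %.3f (dof %d)\n", x$redchi, x$dof))
  invisible(x)
}

#' Tidy a global fit
#'
#' @param x A `trxps_fit`.
#' @param ... Unused.
#' @return Tibble of parameter estimates with 1-sigma uncertainties.
#' @export
tidy.trxps_fit <- function(x, ...) x$params

#' One-row fit summary
#'
#' @param x A `trxps_fit`.
#' @param ... Unused.
#' @return Tibble with chi-square, degrees of freedom, reduced chi-square
#'   and convergence code.
#' @export
glance.trxps_fit <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, dof = x$dof, redchi = x$redchi,
                 convergence = x$convergence)
}

#' Residual-resampling bootstrap for fit uncertainties
#'
#' Resamples standardized residuals with replacement, rebuilds synthetic
#' traces around the fitted curves, refits (warm-started at the point
#' estimate) and summarises percentile intervals. Aborts when more than 10%
#' of replicates fail.
#'
#' @param fit A `trxps_fit`.
#' @param n_boot Number of replicates (>= 100).
#' @param seed Integer seed.
#' @param level Interval level (default 0.68, ~1 sigma).
#' @return Tibble `term`, `median`, `lo`, `hi` with attribute `draws`.
#' @export
bootstrap_uncertainty <- function(fit, n_boot = 200, seed = 1,
                                  level = 0.68) {
  if (n_boot < 100) {
    abort("`n_boot` must be at least 100.", class = "trxps_domain_error")
  }
  fd <- fit$fitted
  res <- fd$value - fd$fitted
  p0 <- setNames(fit$params$estimate[1:4],
                 c("t0", "sigma", "tau_ic", "tau_isc"))
  set.seed(seed)
  draws <- vector("list", n_boot)
  failures <- 0
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(res), replace = TRUE)
    tr_b <- tibble::tibble(region = fd$region, delay = fd$delay,
                           value = fd$fitted + res[idx], sigma = fd$sigma)
    fb <- tryCatch(
      fit_global(tr_b, components = fit$components,
                 init = as.list(p0)),
      error = function(e) NULL)
    if (is.null(fb) || fb$convergence != 0) {
      failures <- failures + 1
      next
    }
    draws[[b]] <- setNames(fb$params$estimate, fit$params$term)
  }
  if (failures > 0.1 * n_boot) {
    abort(paste0(failures, " of ", n_boot, " bootstrap refits failed."),
          class = "trxps_fit_setup_error")
  }
  dm <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  a <- (1 - level) / 2
  out <- tibble::tibble(
    term = colnames(dm),
    median = apply(dm, 2, median),
    lo = apply(dm, 2, quantile, probs = a),
    hi = apply(dm, 2, quantile, probs = 1 - a)
  )
  attr(out, "draws") <- dm
  out
}
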