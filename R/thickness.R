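#' Dynamic TM-window phosphate selection by protein proximity
#'
#' Selects, independently in every frame, the phosphate beads whose minimum
#' Euclidean distance to any protein bead is at most `cutoff` (default 6 A).
#' Phosphates exchange in and out of the window, so the selection is
#' per frame (dynamic).
#'
#' @param system An [md_ensemble()].
#' @param protein_selection Protein beads (`bead_selection` or 0-based
#'   indices), non-empty.
#' @param phosphate_selection Candidate phosphate beads, non-empty.
#' @param cutoff Distance cutoff in angstrom (> 0).
#' @return A `frame_selection`: list with `frames` (per-frame integer vectors
#'   of 0-based bead indices) and `descriptor`.
#' @export
tm_window_selection <- function(system, protein_selection,
                                phosphate_selection, cutoff = 6) {
  stopifnot(inherits(system, "md_ensemble"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  p_idx <- as.integer(protein_selection)
  l_idx <- as.integer(phosphate_selection)
  if (length(p_idx) == 0L) stop("empty protein selection")
  if (length(l_idx) == 0L) stop("empty phosphate selection")
  nf <- n_frames(system)
  cut2 <- cutoff^2
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    P <- matrix(system$coords[f, p_idx + 1L, ], ncol = 3)
    L <- matrix(system$coords[f, l_idx + 1L, ], ncol = 3)
    # squared distances via the expansion |l - p|^2 = |l|^2 + |p|^2 - 2 l.p
    d2 <- outer(rowSums(L^2), rowSums(P^2), `+`) - 2 * L %*% t(P)
    frames[[f]] <- l_idx[matrixStats_rowMins(d2) <= cut2 + 1e-9]
  }
  structure(list(frames = frames,
                 descriptor = sprintf("tm_window(cutoff=%g)", cutoff)),
            class = "frame_selection")
}

matrixStats_rowMins <- function(m) {
  do.call(pmin, c(as.data.frame(m), list(na.rm = FALSE)))
}

#' @export
print.frame_selection <- function(x, ...) {
  cat("<frame_selection> ", length(x$frames), " frame(s), ",
      "mean ", round(mean(lengths(x$frames)), 1), " beads/frame: ",
      x$descriptor, "\n", sep = "")
  invisible(x)
}

#' Fit a sum of Gaussians to a leaflet density profile
#'
#' Nonlinear least squares of `sum_k A_k exp(-(z - mu_k)^2 / (2 sigma_k^2))`
#' to a phosphate number-density profile, with K = 2 for a protein-free bulk
#' membrane (one Gaussian per leaflet) or K = 3 when a mid-plane phosphate
#' population is present inside a TM window. Initial means come from the two
#' outermost local maxima of the profile (plus their midpoint for K = 3);
#' fitting uses bounded Levenberg-Marquardt ([minpack.lm::nls.lm()] with an
#' analytic Jacobian) under `A >= 0` and
#' `sigma > 0` bounds.
#'
#' @param profile A `density_profile` (or data frame with `z` and `density`).
#' @param n_components 2 or 3.
#' @param weighted If `TRUE`, bins are weighted by their density (Poisson-like
#'   weighting); default unweighted.
#' @return A `gaussian_fit`: list with `components` (tibble of `amplitude`,
#'   `mean`, `sigma` sorted by mean, plus standard errors), `r_squared`,
#'   `residual_norm`, `converged`, `n_components`. Non-convergence is
#'   reported via `converged = FALSE`, never silently.
#' @export
fit_leaflet_gaussians <- function(profile, n_components = 2,
                                  weighted = FALSE) {
  if (!n_components %in% c(2, 3)) stop("n_components must be 2 or 3")
  z <- profile$z
  y_raw <- profile$density
  # fit on a unit-peak scale for numerical conditioning; amplitudes are
  # rescaled afterwards (thickness only depends on the means anyway)
  y_scale <- max(y_raw)
  y <- if (y_scale > 0) y_raw / y_scale else y_raw
  if (length(z) < 2 * n_components + 1) {
    stop("profile too short for a ", n_components, "-component fit")
  }
  nz <- sum(y > 0)
  if (nz < 2 * n_components + 1) {
    stop("initialization failed for profile '",
         attr(profile, "selection_descriptor") %||% "profile",
         "': only ", nz, " nonzero bins")
  }
  peaks <- find_outer_peaks(z, y)
  if (length(peaks$z) < 2) {
    stop("initialization failed for profile '",
         attr(profile, "selection_descriptor") %||% "profile",
         "': fewer than 2 detectable peaks")
  }
  bin_w <- if (length(z) > 1) z[2] - z[1] else 1
  sigma0 <- max(2 * bin_w, (peaks$z[2] - peaks$z[1]) / 20)
  start <- list(A1 = peaks$y[1], mu1 = peaks$z[1], s1 = sigma0,
                A2 = peaks$y[2], mu2 = peaks$z[2], s2 = sigma0)
  lower <- c(0, min(z), bin_w / 4, 0, min(z), bin_w / 4)
  upper <- c(Inf, max(z), diff(range(z)), Inf, max(z), diff(range(z)))
  if (n_components == 3) {
    # The mid component models deep-lying phosphates near the mid-plane, so
    # it is constrained to the central half of the inter-peak region with at
    # least a bin width of spread; otherwise, with little or no mid-plane
    # density, it drifts onto single-bin counting noise in the leaflets.
    mid_z <- (peaks$z[1] + peaks$z[2]) / 2
    sep0 <- peaks$z[2] - peaks$z[1]
    mid_y <- max(y[which.min(abs(z - mid_z))], 0.05 * max(y))
    start <- c(start, list(A3 = mid_y, mu3 = mid_z,
                           s3 = max(sep0 / 6, 2 * sigma0)))
    lower <- c(lower, 0, mid_z - sep0 / 4, bin_w)
    upper <- c(upper, Inf, mid_z + sep0 / 4, sep0 / 2)
  }
  attempt <- lm_fit_attempt(z, y, start, lower, upper,
                            weights = if (weighted) pmax(y, max(y) * 1e-6))

  null_mid <- NULL
  if (n_components == 3 && !attempt$converged) {
    # With no detectable mid-plane density the third component is
    # unidentifiable: its maximum-likelihood amplitude is 0 and its mean and
    # width are arbitrary, so Levenberg-Marquardt drifts without formally
    # stopping. Recognize that case, fit the two leaflet components alone,
    # and report the mid component explicitly as null (amplitude 0).
    a3 <- if (!is.null(attempt$par)) unname(attempt$par["A3"]) else 0
    if (is.na(a3) || a3 <= 1e-3) {
      attempt2 <- lm_fit_attempt(z, y, start[1:6], lower[1:6], upper[1:6],
                                 weights = if (weighted) pmax(y, max(y) * 1e-6))
      if (attempt2$converged) {
        attempt <- attempt2
        est2 <- attempt2$par
        null_mid <- tibble::tibble(
          amplitude = 0,
          mean = unname((est2["mu1"] + est2["mu2"]) / 2),
          sigma = sigma0,
          se_amplitude = NA_real_, se_mean = NA_real_, se_sigma = NA_real_)
      }
    }
  }
  if (is.null(attempt$par)) {
    return(new_gaussian_fit(NULL, n_components, converged = FALSE,
                            message = attempt$message))
  }
  est <- attempt$par
  se <- attempt$se
  k_fit <- length(est) / 3
  comp <- tibble::tibble(
    amplitude = unname(est[paste0("A", 1:k_fit)]) * y_scale,
    mean = unname(est[paste0("mu", 1:k_fit)]),
    sigma = abs(unname(est[paste0("s", 1:k_fit)])),
    se_amplitude = unname(se[paste0("A", 1:k_fit)]) * y_scale,
    se_mean = unname(se[paste0("mu", 1:k_fit)]),
    se_sigma = unname(se[paste0("s", 1:k_fit)])
  )
  if (!is.null(null_mid)) comp <- dplyr::bind_rows(comp, null_mid)
  comp <- comp[order(comp$mean), ]
  rss <- attempt$rss
  tss <- sum((y - mean(y))^2)
  new_gaussian_fit(comp, n_components, converged = attempt$converged,
                   residual_norm = sqrt(rss) * y_scale,
                   r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                   message = if (!is.null(null_mid)) "mid-plane component empty (amplitude 0)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian-mixture model and its analytic Jacobian (K inferred from length)
gauss_mix_eval <- function(p, z) {
  k <- length(p) / 3
  out <- numeric(length(z))
  for (j in seq_len(k)) {
    A <- p[3 * j - 2]; mu <- p[3 * j - 1]; s <- p[3 * j]
    out <- out + A * exp(-(z - mu)^2 / (2 * s^2))
  }
  out
}

gauss_mix_jac <- function(p, z) {
  k <- length(p) / 3
  J <- matrix(0, length(z), length(p))
  for (j in seq_len(k)) {
    A <- p[3 * j - 2]; mu <- p[3 * j - 1]; s <- p[3 * j]
    E <- exp(-(z - mu)^2 / (2 * s^2))
    J[, 3 * j - 2] <- E
    J[, 3 * j - 1] <- A * E * (z - mu) / s^2
    J[, 3 * j] <- A * E * (z - mu)^2 / s^3
  }
  J
}

# Bounded Levenberg-Marquardt on the mixture with the analytic Jacobian
# (minpack.lm::nls.lm), with up to two warm restarts; converged when the
# optimizer reports convergence or the RSS is stationary across restarts.
# Parameter standard errors come from the Gauss-Newton covariance
# sigma^2 (J'J)^-1 at the solution.
lm_fit_attempt <- function(z, y, start, lower, upper, weights = NULL) {
  p <- unlist(start)
  pn <- names(p) <- names(start)
  sw <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  fn <- function(par, z, y) sw * (y - gauss_mix_eval(par, z))
  jac <- function(par, z, y) -sw * gauss_mix_jac(par, z)
  out <- NULL
  rss_prev <- Inf
  converged <- FALSE
  for (round in 1:3) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p, lower = lower, upper = upper, fn = fn,
                         jac = jac, z = z, y = y,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(list(par = NULL, se = NULL, rss = NA_real_,
                  converged = FALSE, message = conditionMessage(res)))
    }
    out <- res
    rss <- sum(out$fvec^2)
    if (out$info %in% 1:4 ||
        abs(rss_prev - rss) <= 1e-6 * max(rss, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
    p <- stats::setNames(pmin(pmax(unlist(out$par), lower + 1e-9),
                              ifelse(is.finite(upper), upper - 1e-9, upper)),
                         pn)
  }
  par <- stats::setNames(unlist(out$par), pn)
  rss <- sum(out$fvec^2)
  dof <- length(y) - length(par)
  se <- rep(NA_real_, length(par))
  J <- jac(par, z, y)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * rss / max(dof, 1), error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  names(se) <- pn
  list(par = par, se = se, rss = rss, converged = converged,
       message = if (!converged) "iteration limit reached without a stationary fit")
}

# outermost two local maxima of a binned profile; a bin counts as a peak if
# it is interior, >= both neighbours, and above 20% of the global maximum
# (leaflet peaks are of comparable height; the threshold rejects single-bin
# counting noise in the tails)
find_outer_peaks <- function(z, y) {
  n <- length(y)
  if (n < 3) return(list(z = numeric(0), y = numeric(0)))
  thr <- 0.2 * max(y)
  is_peak <- vapply(seq_len(n), function(i) {
    if (i == 1L || i == n) return(FALSE)
    y[i] >= y[i - 1] && y[i] >= y[i + 1] && y[i] > thr
  }, logical(1))
  idx <- which(is_peak)
  if (length(idx) < 2) return(list(z = z[idx], y = y[idx]))
  pick <- c(idx[1], idx[length(idx)])
  list(z = z[pick], y = y[pick])
}

new_gaussian_fit <- function(components, n_components, converged,
                             residual_norm = NA_real_, r_squared = NA_real_,
                             message = NULL) {
  structure(list(components = components, n_components = n_components,
                 converged = converged, residual_norm = residual_norm,
                 r_squared = r_squared, message = message),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("<gaussian_fit> K=", x$n_components,
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  if (!is.null(x$components)) {
    print(as.data.frame(x$components[, c("amplitude", "mean", "sigma")]),
          digits = 4)
    cat("R^2 =", format(x$r_squared, digits = 5), "\n")
  } else if (!is.null(x$message)) cat("  ", x$message, "\n")
  invisible(x)
}

#' Peak-separation thickness from a Gaussian fit
#'
#' The bilayer thickness is the separation of the two outermost Gaussian
#' means; in a triple fit the middle component absorbs deep-lying mid-plane
#' phosphates and does not enter the thickness. Invariant to amplitudes and
#' to any rigid shift along z.
#'
#' @param fit A converged `gaussian_fit`.
#' @return Thickness in angstrom.
#' @export
thickness_from_fit <- function(fit) {
  stopifnot(inherits(fit, "gaussian_fit"))
  if (!isTRUE(fit$converged)) stop("cannot read thickness off an unconverged fit")
  max(fit$components$mean) - min(fit$components$mean)
}

#' Thickness pipeline across replicate ensembles
#'
#' Per replicate: select phosphates (all of them for `region = "bulk"`, or
#' the dynamic 6-A proximity window for `region = "tm_window"`), build the
#' number-density profile, fit K = 2 (bulk) or K = 3 (tm_window) Gaussians,
#' and read the peak-separation thickness. Replicates whose fit does not
#' converge are excluded with a warning and `n_replicates` is decremented.
#'
#' @param replicate_ensembles List of [md_ensemble()] objects (one per
#'   replicate) or a single ensemble.
#' @param region `"bulk"` or `"tm_window"`.
#' @param protein_role Role used for the protein selection in window mode.
#' @param cutoff Window cutoff in angstrom (default 6).
#' @param bin_width Profile bin width in angstrom (default 1).
#' @param n_components Number of Gaussian components; default 2 for bulk,
#'   3 for tm_window ("auto").
#' @param weighted Passed to [fit_leaflet_gaussians()].
#' @return A `thickness_result`: list with `region`, `method`,
#'   `per_replicate` (tibble: replicate, thickness, r_squared, converged),
#'   `mean`, `sem` (sd/sqrt(n) across replicates), `n_replicates`, `fits`.
#'   With a single converged replicate the SEM is reported as 0 with a
#'   warning.
#' @export
thickness_pipeline <- function(replicate_ensembles,
                               region = c("bulk", "tm_window"),
                               protein_role = "protein_backbone",
                               cutoff = 6, bin_width = 1,
                               n_components = c("auto", "2", "3"),
                               weighted = FALSE) {
  region <- match.arg(region)
  if (inherits(replicate_ensembles, "md_ensemble")) {
    replicate_ensembles <- list(replicate_ensembles)
  }
  n_components <- match.arg(as.character(n_components[1]),
                            c("auto", "2", "3"))
  k <- switch(n_components, auto = if (region == "bulk") 2L else 3L,
              `2` = 2L, `3` = 3L)
  method <- if (k == 2L) "double" else "triple"

  rows <- list()
  fits <- list()
  for (r in seq_along(replicate_ensembles)) {
    sys <- replicate_ensembles[[r]]
    po4 <- select_beads(sys, role = "lipid_phosphate")
    sel <- if (region == "bulk") {
      po4
    } else {
      prot <- select_beads(sys, role = protein_role)
      if (length(prot) == 0L) {
        stop("tm_window region requires protein beads (role ", protein_role,
             ") in replicate ", r)
      }
      tm_window_selection(sys, prot, po4, cutoff = cutoff)
    }
    prof <- density_profile(sys, sel, bin_width = bin_width)
    fit <- tryCatch(fit_leaflet_gaussians(prof, n_components = k),
                    error = function(e) {
                      new_gaussian_fit(NULL, k, converged = FALSE,
                                       message = conditionMessage(e))
                    })
    fits[[r]] <- fit
    if (isTRUE(fit$converged)) {
      rows[[r]] <- tibble::tibble(replicate = r,
                                  thickness = thickness_from_fit(fit),
                                  r_squared = fit$r_squared,
                                  converged = TRUE)
    } else {
      warning("replicate ", r, " excluded: fit did not converge (",
              fit$message %||% "no message", ")")
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  n_ok <- nrow(per_rep)
  if (n_ok == 0L) stop("no replicate produced a converged fit")
  if (n_ok == 1L) {
    warning("single converged replicate; SEM reported as 0")
    sem <- 0
  } else {
    sem <- stats::sd(per_rep$thickness) / sqrt(n_ok)
  }
  structure(list(region = region, method = method, per_replicate = per_rep,
                 mean = mean(per_rep$thickness), sem = sem,
                 n_replicates = n_ok, fits = fits),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat("<thickness_result> region=", x$region, ", method=", x$method,
      ", n=", x$n_replicates, "\n", sep = "")
  cat(sprintf("  thickness = %.2f +/- %.2f A (mean +/- SEM)\n", x$mean, x$sem))
  invisible(x)
}

#' Relative thinning of a membrane region
#'
#' `(bulk - window) / bulk * 100`, in percent. Negative values (thickening)
#' are allowed but flagged with a warning.
#'
#' @param bulk Bulk thickness in angstrom (> 0).
#' @param window Window thickness in angstrom.
#' @return Percent thinning.
#' @examples
#' relative_thinning(38.1, 20.1)  # 47.24, i.e. ~47% thinner
#' @export
relative_thinning <- function(bulk, window) {
  if (any(bulk <= 0)) stop("bulk thickness must be > 0")
  out <- (bulk - window) / bulk * 100
  if (any(out < 0)) warning("window thicker than bulk: negative thinning")
  out
}

#' Difference between two thickness results with propagated error
#'
#' `a - b` with the SEMs combined in quadrature,
#' `sqrt(sem_a^2 + sem_b^2)`.
#'
#' @param a,b `thickness_result` objects, or bare numeric means (in which
#'   case `sem_a`/`sem_b` supply the errors).
#' @param sem_a,sem_b SEMs when `a`/`b` are numeric (default 0).
#' @return A tibble with `difference` and `propagated_error` (angstrom).
#' @export
thickness_difference <- function(a, b, sem_a = 0, sem_b = 0) {
  if (inherits(a, "thickness_result")) { sem_a <- a$sem; a <- a$mean }
  if (inherits(b, "thickness_result")) { sem_b <- b$sem; b <- b$mean }
  tibble::tibble(difference = a - b,
                 propagated_error = sqrt(sem_a^2 + sem_b^2))
}
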