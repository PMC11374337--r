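#' Bound fraction under the ligand-depletion one-site isotherm
#'
#' Exact single-site bound fraction of the labelled protein when the
#' ligand is not in large excess (the quadratic, ligand-depletion
#' solution):
#' \deqn{f_B = \frac{(P+L+K_D) - \sqrt{(P+L+K_D)^2 - 4PL}}{2P}}
#' Evaluated in the numerically stable form
#' \eqn{f_B = 2L / (b + \sqrt{b^2 - 4PL})} with \eqn{b = P+L+K_D},
#' which avoids catastrophic cancellation when \eqn{4PL \ll b^2}
#' (weak binding / low ligand).
#'
#' @param P labelled protein concentration (uM), > 0.
#' @param L titrant concentration (uM), >= 0.
#' @param kd dissociation constant (uM), > 0. All arguments recycle.
#' @return bound fraction in `[0, min(L/P, 1)]`.
#' @examples
#' fraction_bound(300, 0, 528)    # 0
#' fraction_bound(300, 900, 528)  # ~0.579
#' @export
fraction_bound <- function(P, L, kd) {
  if (any(P <= 0)) stop("P must be > 0", call. = FALSE)
  if (any(L < 0)) stop("L must be >= 0", call. = FALSE)
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  b <- P + L + kd
  disc <- b^2 - 4 * P * L
  disc[disc < 0] <- 0  # guard against roundoff for near-stoichiometric cases
  2 * L / (b + sqrt(disc))
}

#' Predicted CSP under the binding model
#'
#' Fast-exchange two-state binding: the observed combined CSP is the
#' saturation shift scaled by the bound fraction,
#' \eqn{\Delta\delta = \Delta\delta_{max} f_B(P, L, K_D)}.
#'
#' @param kd dissociation constant (uM).
#' @param dmax saturation CSP (ppm), >= 0.
#' @param P,L concentrations (uM) as in [fraction_bound()].
#' @return predicted CSP (ppm); 0 at L = 0, nondecreasing in L, bounded
#'   by `dmax`.
#' @export
eval_binding_model <- function(kd, dmax, P, L) {
  dmax * fraction_bound(P, L, kd)
}

#' Select residues for the global fit
#'
#' Default rule: a residue qualifies when it has at least `min_points`
#' valid non-reference points and its endpoint CSP strictly exceeds the
#' mean + `sd_mult` s.d. of all endpoint CSPs. Two free quantities per
#' residue trajectory (its share of the shared K_D plus its own
#' saturation shift) need at least three points for a meaningful
#' residual. An explicit residue list overrides the rule.
#'
#' @param profiles a `csp_profiles` data.frame.
#' @param residues optional explicit residue numbers; returned verbatim
#'   (after checking they exist) when supplied.
#' @param min_points minimum valid non-reference points, default 3.
#' @param sd_mult endpoint-CSP threshold multiplier, default 1.
#' @return integer vector of selected residue numbers.
#' @export
select_fit_residues <- function(profiles, residues = NULL,
                                min_points = 3, sd_mult = 1) {
  ep <- endpoint_csp(profiles)
  if (!is.null(residues)) {
    missing <- setdiff(as.integer(residues), as.integer(names(ep)))
    if (length(missing) > 0) {
      stop("residue(s) not present in profiles: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(as.integer(residues))
  }
  nv <- n_valid_points(profiles)
  thr <- mean(ep) + sd_mult * stats::sd(ep)
  eligible <- as.integer(names(ep))[ep > thr &
                                    nv[names(ep)] >= min_points]
  if (length(eligible) == 0) {
    stop("no residues selected: ", length(ep), " residues, endpoint CSP ",
         "threshold ", signif(thr, 4),
         " ppm exceeded by none with >= ", min_points, " valid points; ",
         "supply an explicit residue list or lower sd_mult",
         call. = FALSE)
  }
  sort(eligible)
}

# stack selected residues' valid non-reference observations
fit_data <- function(profiles, residues) {
  d <- profiles[profiles$residue_number %in% residues &
                profiles$valid & profiles$L_conc > 0, ]
  if (nrow(d) == 0) stop("no valid observations for the fit", call. = FALSE)
  npts <- table(d$residue_number)
  if (any(npts < 3)) {
    stop("residue(s) with < 3 valid points: ",
         paste(names(npts)[npts < 3], collapse = ", "), call. = FALSE)
  }
  d
}

# heuristic initial K_D: ligand concentration at which the strongest
# responder reaches half its endpoint CSP (linear interpolation)
init_kd_halfmax <- function(d) {
  ep <- tapply(d$csp_ppm, d$residue_number, function(x) x[length(x)])
  r <- names(ep)[which.max(ep)]
  dr <- d[d$residue_number == as.integer(r), ]
  dr <- dr[order(dr$L_conc), ]
  half <- ep[[r]] / 2
  i <- which(dr$csp_ppm >= half)[1]
  if (is.na(i) || i == 1) return(max(dr$L_conc[1], 1))
  x0 <- dr$L_conc[i - 1]; y0 <- dr$csp_ppm[i - 1]
  x1 <- dr$L_conc[i];     y1 <- dr$csp_ppm[i]
  if (y1 == y0) return(x1)
  max(x0 + (half - y0) / (y1 - y0) * (x1 - x0), 1)
}

#' Global fit of a shared dissociation constant across residues
#'
#' Simultaneous least-squares fit of the ligand-depletion isotherm to
#' the CSP trajectories of several residues: one saturation shift
#' `dmax` per residue, one K_D shared by all, minimising
#' \eqn{\sum_r \sum_i (\Delta\delta_{obs,r,i} -
#' \Delta\delta_{max,r} f_B(P_i, L_i, K_D))^2} with a trust-region
#' Levenberg-Marquardt optimiser. K_D is parameterised on a log10
#' scale within `bounds`; residuals are unweighted (an optional
#' per-point `sigma` column in `profiles` is honoured when present).
#' Missing points are dropped per residue, never imputed.
#'
#' @param profiles a `csp_profiles` data.frame.
#' @param residues residue numbers to fit (e.g. from
#'   [select_fit_residues()]); each needs >= 3 valid points.
#' @param init optional list with `kd` (uM) and/or `dmax` (named vector)
#'   starting values; defaults are the half-maximal-CSP ligand
#'   concentration of the strongest responder and each residue's
#'   endpoint CSP.
#' @param bounds K_D bounds in uM, default `c(1e-3, 1e6)`.
#' @return A `binding_fit` list: `kd`, `kd_stderr` (uM, covariance
#'   based), `dmax` and `dmax_stderr` (named per residue),
#'   `residues_used`, `residuals` (one per fitted observation),
#'   `converged`, `kd_at_bound`, `endpoint_fraction_bound` (bound
#'   fraction at the final manifest concentrations under the fitted
#'   K_D), `n_obs`, `message`.
#' @export
fit_global_kd <- function(profiles, residues, init = NULL,
                          bounds = c(1e-3, 1e6)) {
  d <- fit_data(profiles, residues)
  residues <- sort(unique(d$residue_number))
  r_index <- match(d$residue_number, residues)
  w <- if ("sigma" %in% names(d) && all(is.finite(d$sigma)) &&
           all(d$sigma > 0)) 1 / d$sigma else rep(1, nrow(d))

  ep <- endpoint_csp(profiles)
  dmax0 <- unname(ep[as.character(residues)])
  dmax0[!is.finite(dmax0) | dmax0 <= 0] <- max(d$csp_ppm, 1e-3)
  kd0 <- init_kd_halfmax(d)
  if (!is.null(init$kd)) kd0 <- init$kd
  if (!is.null(init$dmax)) {
    dmax0 <- unname(init$dmax[as.character(residues)])
  }
  kd0 <- min(max(kd0, bounds[1] * 1.01), bounds[2] * 0.99)

  resid_fun <- function(par) {
    kd <- 10^par[1]
    dmax <- par[-1]
    w * (d$csp_ppm - dmax[r_index] * fraction_bound(d$P_conc, d$L_conc, kd))
  }
  fit <- minpack.lm::nls.lm(
    par = c(log10(kd0), dmax0),
    lower = c(log10(bounds[1]), rep(0, length(residues))),
    upper = c(log10(bounds[2]), rep(Inf, length(residues))),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  converged <- fit$info %in% 1:4
  kd <- 10^fit$par[1]
  dmax <- fit$par[-1]
  names(dmax) <- residues

  # covariance-based standard errors; delta method back from log10(K_D)
  np <- length(fit$par)
  dof <- max(length(fit$fvec) - np, 1)
  s2 <- sum(fit$fvec^2) / dof
  cov <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
    se <- sqrt(diag(cov))
    kd_stderr <- kd * log(10) * se[1]
    dmax_stderr <- se[-1]
  } else {
    kd_stderr <- NA_real_
    dmax_stderr <- rep(NA_real_, length(residues))
  }
  names(dmax_stderr) <- residues

  at_bound <- kd <= bounds[1] * 1.001 || kd >= bounds[2] * 0.999
  if (at_bound) {
    warning("fitted K_D is pinned at a bound (", signif(kd, 4),
            " uM); treat the estimate as a limit, not a value",
            call. = FALSE)
  }
  if (!converged) {
    warning("global K_D fit did not converge: ", fit$message,
            call. = FALSE)
  }

  last <- which.max(d$L_conc)
  res <- list(
    kd = kd,
    kd_stderr = kd_stderr,
    dmax = dmax,
    dmax_stderr = dmax_stderr,
    residues_used = residues,
    residuals = as.numeric(fit$fvec),
    n_obs = nrow(d),
    converged = converged,
    kd_at_bound = at_bound,
    endpoint_fraction_bound = fraction_bound(d$P_conc[last],
                                             d$L_conc[last], kd),
    bounds = bounds,
    message = fit$message
  )
  class(res) <- "binding_fit"
  res
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> K_D = %.4g +/- %.3g uM (%d residues, %d points)\n",
              x$kd, x$kd_stderr, length(x$residues_used), x$n_obs))
  cat(sprintf("  endpoint fraction bound %.3f; converged: %s%s\n",
              x$endpoint_fraction_bound, x$converged,
              if (x$kd_at_bound) "; K_D AT BOUND" else ""))
  invisible(x)
}

#' Profile-likelihood grid estimate of the shared K_D
#'
#' Independent route to the same optimum exploited for validation: at
#' fixed K_D the model is linear in each residue's saturation shift, so
#' the conditional optimum is closed form,
#' \eqn{\hat{\Delta\delta}_{max,r}(K_D) = \sum_i f_i y_i / \sum_i f_i^2},
#' and the profiled RSS only needs a 1-D search over a log-spaced K_D
#' grid. Slower but free of optimiser failure modes.
#'
#' @param profiles a `csp_profiles` data.frame.
#' @param residues residues to fit.
#' @param grid K_D grid (uM); default 2000 log-spaced points over
#'   `bounds`.
#' @param bounds grid range when `grid` is NULL.
#' @return list with `kd` (grid minimiser of the profiled RSS), `rss`,
#'   `dmax` (conditional saturation shifts at `kd`), `grid`, `rss_grid`.
#' @export
profile_kd_grid <- function(profiles, residues, grid = NULL,
                            bounds = c(1e-3, 1e6)) {
  d <- fit_data(profiles, residues)
  residues <- sort(unique(d$residue_number))
  if (is.null(grid)) {
    grid <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = 2000)
  }
  sp <- split(d, d$residue_number)
  rss_for <- function(kd) {
    sum(vapply(sp, function(dr) {
      f <- fraction_bound(dr$P_conc, dr$L_conc, kd)
      dmax <- sum(f * dr$csp_ppm) / sum(f^2)
      sum((dr$csp_ppm - dmax * f)^2)
    }, numeric(1)))
  }
  rss_grid <- vapply(grid, rss_for, numeric(1))
  i <- which.min(rss_grid)
  # golden-section polish between the neighbouring grid points
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(lk) rss_for(10^lk),
                         interval = log10(c(lo, hi)), tol = 1e-10)
  kd <- 10^opt$minimum
  dmax <- vapply(sp, function(dr) {
    f <- fraction_bound(dr$P_conc, dr$L_conc, kd)
    sum(f * dr$csp_ppm) / sum(f^2)
  }, numeric(1))
  list(kd = kd, rss = opt$objective, dmax = dmax,
       grid = grid, rss_grid = rss_grid)
}

#' Bootstrap interval for the shared K_D
#'
#' Case-resampling bootstrap: residues (default) or observations are
#' resampled with replacement and the global fit repeated; the interval
#' is the percentile interval of the resampled K_D estimates. This is
#' reported alongside, and labelled distinctly from, the
#' covariance-based standard error of [fit_global_kd()].
#'
#' @param profiles a `csp_profiles` data.frame.
#' @param residues residues used by the primary fit.
#' @param n_boot number of resamples, >= 10; default 200.
#' @param seed RNG seed (required, for reproducibility).
#' @param level interval level, default 0.95.
#' @param resample `"residues"` (default) or `"points"`.
#' @param bounds passed to [fit_global_kd()].
#' @return list with `interval` (named lower/upper, uM), `kd_boot`
#'   (successful resample estimates), `n_failed`, `level`, `seed`.
#' @export
bootstrap_kd <- function(profiles, residues, n_boot = 200, seed,
                         level = 0.95, resample = c("residues", "points"),
                         bounds = c(1e-3, 1e6)) {
  resample <- match.arg(resample)
  if (n_boot < 10) stop("n_boot must be >= 10", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  d <- fit_data(profiles, residues)
  residues <- sort(unique(d$residue_number))
  rng <- local({ set.seed(seed); function(n, k) sample(n, k, replace = TRUE) })

  kd_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    if (resample == "residues") {
      pick <- residues[rng(length(residues), length(residues))]
      db <- do.call(rbind, lapply(seq_along(pick), function(j) {
        dj <- d[d$residue_number == pick[j], ]
        dj$residue_number <- j  # duplicated residues become distinct units
        dj
      }))
    } else {
      db <- d[rng(nrow(d), nrow(d)), ]
      keep <- names(which(table(db$residue_number) >= 3))
      db <- db[db$residue_number %in% as.integer(keep), ]
      if (length(unique(db$residue_number)) == 0) next
    }
    pb <- db
    class(pb) <- c("csp_profiles", "data.frame")
    kd_boot[b] <- tryCatch(
      suppressWarnings(
        fit_global_kd(pb, unique(pb$residue_number), bounds = bounds)$kd),
      error = function(e) NA_real_)
  }
  ok <- kd_boot[is.finite(kd_boot)]
  if (length(ok) < 10) {
    stop("bootstrap produced too few successful fits (",
         length(ok), ")", call. = FALSE)
  }
  a <- (1 - level) / 2
  interval <- stats::quantile(ok, c(a, 1 - a), names = FALSE)
  list(interval = c(lower = interval[1], upper = interval[2]),
       kd_boot = ok, n_failed = n_boot - length(ok),
       level = level, seed = seed)
}

#' Per-residue fitted titration curves
#'
#' Tabulates observed and fitted CSPs (plus a dense fitted curve) for
#' plotting titration insets.
#'
#' @param fit a `binding_fit`.
#' @param profiles the `csp_profiles` the fit was computed from.
#' @param n_dense points in the dense curve per residue, default 50.
#' @return data.frame with columns `residue_number`, `L_conc`,
#'   `csp_obs` (`NA` on dense-grid rows), `csp_fit`.
#' @export
fitted_curves <- function(fit, profiles, n_dense = 50) {
  d <- fit_data(profiles, fit$residues_used)
  out <- lapply(fit$residues_used, function(r) {
    dr <- d[d$residue_number == r, ]
    P <- dr$P_conc[1]
    dense_L <- seq(0, max(dr$L_conc), length.out = n_dense)
    rbind(
      data.frame(residue_number = r, L_conc = dr$L_conc,
                 csp_obs = dr$csp_ppm,
                 csp_fit = eval_binding_model(fit$kd,
                                              fit$dmax[[as.character(r)]],
                                              dr$P_conc, dr$L_conc)),
      data.frame(residue_number = r, L_conc = dense_L,
                 csp_obs = NA_real_,
                 csp_fit = eval_binding_model(fit$kd,
                                              fit$dmax[[as.character(r)]],
                                              P, dense_L))
    )
  })
  do.call(rbind, out)
}
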