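# independent equilibrium oracle: solve Kd = (P-B)(L-B)/B for the bound
# complex B by root bracketing, then f_B = B/P
fb_oracle <- function(P, L, kd) {
  if (L == 0) return(0)
  f <- function(B) (P - B) * (L - B) / B - kd
  B <- stats::uniroot(f, c(1e-12, min(P, L) * (1 - 1e-12)),
                      tol = 1e-14)$root
  B / P
}

test_that("fraction_bound matches the equilibrium root-finding oracle", {
  expect_equal(fraction_bound(300, 0, 528), 0)
  # stoichiometric limit: K_D -> 0 with L >= P saturates the protein
  expect_equal(fraction_bound(300, 900, 1e-9), 1, tolerance = 1e-9)
  expect_equal(fraction_bound(300, 900, 528), fb_oracle(300, 900, 528),
               tolerance = 1e-10)
  expect_equal(fraction_bound(300, 900, 528), 0.5790, tolerance = 1e-4)

  set.seed(42)
  for (i in 1:25) {
    P <- stats::runif(1, 1, 1000)
    L <- stats::runif(1, 0.1, 5000)
    kd <- 10^stats::runif(1, -2, 4)
    expect_equal(fraction_bound(P, L, kd), fb_oracle(P, L, kd),
                 tolerance = 1e-9)
  }
  expect_error(fraction_bound(0, 10, 1), "P must be")
  expect_error(fraction_bound(-1, 10, 1), "P must be")
})

test_that("fraction_bound is numerically stable when 4PL << (P+L+K_D)^2", {
  # naive evaluation loses all precision here; the rearranged form must not
  P <- 300; L <- 1e-6; kd <- 1e6
  expect_equal(fraction_bound(P, L, kd), fb_oracle(P, L, kd),
               tolerance = 1e-9)
  expect_gt(fraction_bound(P, L, kd), 0)
})

test_that("bound complex is symmetric under protein/ligand exchange", {
  set.seed(7)
  for (i in 1:25) {
    P <- stats::runif(1, 1, 2000)
    L <- stats::runif(1, 1, 2000)
    kd <- 10^stats::runif(1, -1, 4)
    expect_equal(P * fraction_bound(P, L, kd),
                 L * fraction_bound(L, P, kd), tolerance = 1e-10)
  }
})

test_that("closed-form limits and monotonicity hold grid-wide", {
  P_grid <- c(50, 250, 300, 1000)
  L_grid <- c(0, 10, 150, 300, 900, 2420)
  # convergence in K_D is ~sqrt(K_D) at the stoichiometric point L = P,
  # so the K_D -> 0 limit is checked at 1e-5
  for (P in P_grid) for (L in L_grid) {
    expect_equal(fraction_bound(P, L, 1e-9), min(L / P, 1),
                 tolerance = 1e-5)
    expect_lt(fraction_bound(P, L, 1e9), 1e-5)
    fb <- fraction_bound(P, L, 100)
    expect_gte(fb, 0)
    expect_lte(fb, min(L / P, 1) + 1e-12)
  }
  # nondecreasing in L, nonincreasing in K_D
  L_seq <- seq(0, 3000, by = 50)
  kd_seq <- 10^seq(-2, 5, by = 0.25)
  for (P in P_grid) {
    expect_true(all(diff(fraction_bound(P, L_seq, 200)) >= 0))
    expect_true(all(diff(fraction_bound(P, 500, kd_seq)) <= 0))
  }
})

test_that("eval_binding_model scales fraction_bound by the saturation shift", {
  expect_equal(eval_binding_model(528, 0.2, 300, 0), 0)
  # weak-binding limit: f_B ~ L/K_D -> 0
  expect_lt(eval_binding_model(1e9, 0.2, 300, 900), 1e-6)
  expect_equal(eval_binding_model(528, 0.1, 300, 900),
               0.1 * fraction_bound(300, 900, 528))
  expect_equal(eval_binding_model(528, 0.1, 300, 900), 0.05790,
               tolerance = 1e-4)
})

test_that("default residue selection applies the mean + 1 s.d. endpoint rule", {
  sim <- small_sim(seed = 9, noise_H = 0.002, noise_N = 0.01)
  prof <- build_csp_profiles(sim$series)
  sel <- select_fit_residues(prof)
  # recompute the rule by hand
  ep <- endpoint_csp(prof)
  thr <- mean(ep) + stats::sd(ep)
  expect_setequal(sel, as.integer(names(ep))[ep > thr])
  # the strong binders clear the rule; the weakest may sit at the threshold
  expect_gte(length(intersect(sim$ground_truth$binders$residue_number,
                              sel)), 3)

  # explicit list overrides the rule verbatim
  expect_equal(select_fit_residues(prof, residues = c(15L, 17L)),
               c(15L, 17L))
  expect_error(select_fit_residues(prof, residues = 999L), "not present")
})

test_that("all-flat profiles give an informative empty-selection error", {
  ref <- make_free_reference(10, seed = 2)
  man <- titration_manifest("x", "y", data.frame(
    point_label = c("a", "b", "c", "d"), P_conc = 300,
    L_conc = c(0, 100, 200, 400)))
  s <- titration_series(man, list(ref, ref, ref, ref))
  prof <- build_csp_profiles(s)
  expect_error(select_fit_residues(prof), "no residues selected")
})

test_that("noiseless global fit recovers K_D and all saturation shifts exactly", {
  sim <- small_sim(seed = 3, kd = 100)
  prof <- build_csp_profiles(sim$series)
  tr <- sim$ground_truth$binders
  fit <- fit_global_kd(prof, tr$residue_number)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd - 100) / 100, 1e-6)
  rel <- abs(fit$dmax[as.character(tr$residue_number)] -
             tr$dmax_combined) / tr$dmax_combined
  expect_lt(max(rel), 1e-6)
  expect_equal(length(fit$residuals), fit$n_obs)
  # near-zero noise-free stderr
  expect_lt(fit$kd_stderr, 1e-4)
})

test_that("a single noiseless residue identifies (K_D, dmax) exactly", {
  sim <- small_sim(seed = 4, kd = 250, binder_res = 10L)
  prof <- build_csp_profiles(sim$series)
  fit <- fit_global_kd(prof, 10L)
  expect_lt(abs(fit$kd - 250) / 250, 1e-6)
  expect_lt(abs(fit$dmax[["10"]] -
                sim$ground_truth$binders$dmax_combined[1]) /
            sim$ground_truth$binders$dmax_combined[1], 1e-6)
})

test_that("fit is deterministic and endpoint fraction bound uses fitted K_D", {
  sim <- small_sim(seed = 8, noise_H = 0.002, noise_N = 0.01)
  prof <- build_csp_profiles(sim$series)
  r <- sim$ground_truth$binders$residue_number
  f1 <- fit_global_kd(prof, r)
  f2 <- fit_global_kd(prof, r)
  expect_identical(f1$kd, f2$kd)
  expect_identical(f1$dmax, f2$dmax)
  expect_equal(f1$endpoint_fraction_bound,
               fraction_bound(300, 800, f1$kd))
})

test_that("optimizer agrees with the profile-likelihood grid oracle", {
  set.seed(123)
  for (i in 1:8) {
    kd_true <- 10^stats::runif(1, 1, 3)
    sim <- small_sim(seed = 100 + i, kd = kd_true,
                     noise_H = 0.002, noise_N = 0.01)
    prof <- build_csp_profiles(sim$series)
    r <- sim$ground_truth$binders$residue_number
    fit <- suppressWarnings(fit_global_kd(prof, r))
    oracle <- profile_kd_grid(prof, r)
    expect_lt(abs(fit$kd - oracle$kd) / oracle$kd, 0.005)
  }
})

test_that("residues with fewer than 3 valid points are rejected from fitting", {
  sim <- small_sim(seed = 6, L = c(0, 100, 400))  # 2 non-reference points
  prof <- build_csp_profiles(sim$series)
  expect_error(fit_global_kd(prof, 15L), "< 3 valid points")
})

test_that("bootstrap intervals are seeded, reproducible, and tight at zero noise", {
  sim <- small_sim(seed = 12, noise_H = 0.002, noise_N = 0.01)
  prof <- build_csp_profiles(sim$series)
  r <- sim$ground_truth$binders$residue_number
  b1 <- bootstrap_kd(prof, r, n_boot = 30, seed = 99)
  b2 <- bootstrap_kd(prof, r, n_boot = 30, seed = 99)
  expect_identical(b1$interval, b2$interval)
  expect_identical(b1$kd_boot, b2$kd_boot)

  expect_error(bootstrap_kd(prof, r, n_boot = 5, seed = 1), ">= 10")
  expect_error(bootstrap_kd(prof, r, n_boot = 30), "seed")

  sim0 <- small_sim(seed = 12)  # zero noise
  prof0 <- build_csp_profiles(sim0$series)
  b0 <- bootstrap_kd(prof0, r, n_boot = 30, seed = 99)
  width <- diff(unname(b0$interval))
  expect_lt(width / 100, 1e-5)

  # point resampling is also available and seeded
  bp <- bootstrap_kd(prof, r, n_boot = 30, seed = 5, resample = "points")
  expect_length(bp$interval, 2)
})

test_that("fitted_curves tabulates observed and model CSPs per residue", {
  sim <- small_sim(seed = 13)
  prof <- build_csp_profiles(sim$series)
  r <- sim$ground_truth$binders$residue_number
  fit <- fit_global_kd(prof, r)
  fc <- fitted_curves(fit, prof, n_dense = 10)
  expect_setequal(unique(fc$residue_number), r)
  obs <- fc[!is.na(fc$csp_obs), ]
  # zero noise: observed equals fitted on the observation rows
  expect_equal(obs$csp_obs, obs$csp_fit, tolerance = 1e-6)
})
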