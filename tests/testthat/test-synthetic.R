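test_that("make_free_reference: counts, ranges, proline omission, seeding", {
  st <- make_free_reference(1, seed = 1)
  expect_equal(nrow(st), 2L)
  expect_setequal(st$atom, c("H", "N"))

  st2 <- make_free_reference(120, seed = 2, prolines = c(5, 20, 40, 80, 100))
  expect_equal(nrow(st2), 230L)   # (120 - 5) residues x 2 atoms
  h <- st2$shift_ppm[st2$atom == "H"]
  n <- st2$shift_ppm[st2$atom == "N"]
  expect_true(all(h >= 7.5 & h <= 9.5))
  expect_true(all(n >= 105 & n <= 130))

  expect_identical(make_free_reference(30, seed = 7),
                   make_free_reference(30, seed = 7))
})

test_that("titration_spec validates its invariants", {
  b <- data.frame(residue_number = 3L, dmax_H = 0.1, dmax_N = 0.4)
  ok <- titration_spec(10, b, kd = 100, P_conc = 300,
                       L_schedule = c(0, 100), seed = 1)
  expect_s3_class(ok, "titration_spec")
  expect_error(titration_spec(10, b, 100, 300, c(50, 100), seed = 1),
               "start at 0")
  expect_error(titration_spec(10, b, 100, 300, c(0, 200, 100), seed = 1),
               "nondecreasing")
  expect_error(titration_spec(10, b, -1, 300, c(0, 100), seed = 1),
               "kd")
  expect_error(titration_spec(10, b, 100, 300, c(0, 100),
                              noise_sd_H = -1, seed = 1), "noise")
  expect_error(titration_spec(10, b, 100, 300, c(0, 100),
                              peak_loss_prob = 1, seed = 1),
               "peak_loss_prob")
  expect_error(titration_spec(2, b, 100, 300, c(0, 100), seed = 1),
               "binder")
  expect_error(titration_spec(10, b, 100, 300, c(0, 100)), "seed")
  # binder sitting on a proline position is rejected
  expect_error(titration_spec(10, b, 100, 300, c(0, 100), prolines = 3,
                              seed = 1), "binder")
})

test_that("identical seeds reproduce the simulation exactly", {
  s1 <- simulate_titration(titration_preset("beta3", seed = 5))
  s2 <- simulate_titration(titration_preset("beta3", seed = 5))
  expect_identical(s1$ground_truth, s2$ground_truth)
  for (i in seq_along(s1$series$tables)) {
    expect_identical(as.data.frame(s1$series$tables[[i]]),
                     as.data.frame(s2$series$tables[[i]]))
  }
  s3 <- simulate_titration(titration_preset("beta3", seed = 6))
  expect_false(identical(s1$series$tables[[2]]$shift_ppm,
                         s3$series$tables[[2]]$shift_ppm))
})

test_that("noiseless simulation round-trips through the CSP pipeline exactly", {
  sim <- small_sim(seed = 21, kd = 150)
  prof <- build_csp_profiles(sim$series)
  tr <- sim$ground_truth$binders
  for (j in seq_len(nrow(tr))) {
    r <- tr$residue_number[j]
    pr <- prof[prof$residue_number == r, ]
    expected <- eval_binding_model(150, tr$dmax_combined[j], pr$P_conc,
                                  pr$L_conc)
    expect_equal(pr$csp_ppm, expected, tolerance = 1e-12)
  }
  # non-binders stay at exactly zero CSP without noise
  nb <- setdiff(unique(prof$residue_number), tr$residue_number)
  expect_true(all(prof$csp_ppm[prof$residue_number %in% nb] == 0))
})

test_that("presets encode the printed concentration schedules", {
  b3 <- titration_preset("beta3", seed = 1)
  expect_length(b3$L_schedule, 7)
  expect_equal(b3$P_conc, 300)
  expect_equal(max(b3$L_schedule), 900)
  expect_equal(b3$kd, 528)

  b1 <- titration_preset("beta1", seed = 1)
  expect_equal(b1$L_schedule, c(0, 150, 300, 650))
  expect_equal(b1$kd, 52)

  rv <- titration_preset("reverse", seed = 1)
  expect_equal(rv$P_conc, 250)
  expect_equal(max(rv$L_schedule), 2420)
  expect_equal(rv$kd, 532)

  # overrides pass through
  expect_equal(titration_preset("beta3", seed = 1, kd = 10)$kd, 10)
})

test_that("peak loss removes whole crosspeaks and is honoured downstream", {
  sim <- small_sim(seed = 30, loss = 0.15)
  for (tb in sim$series$tables) {
    per_res <- table(tb$residue_number)
    expect_true(all(per_res == 2))  # H and N vanish together
  }
  prof <- build_csp_profiles(sim$series)
  expect_true(any(!prof$valid))
})

test_that("recovered-K_D spread grows with shift noise", {
  spread <- sapply(c(0.001, 0.004, 0.016), function(ns) {
    kds <- sapply(1:20, function(s) {
      sim <- small_sim(seed = 400 + s, noise_H = ns, noise_N = 5 * ns)
      prof <- build_csp_profiles(sim$series)
      suppressWarnings(
        fit_global_kd(prof, 15:18)$kd)
    })
    stats::mad(kds)
  })
  expect_true(all(diff(spread) > 0))
})

test_that("bootstrap intervals are calibrated at the forward titration design", {
  # 100 seeded replicates at the weak-affinity forward design; nominal
  # 95% observation-resampling intervals should cover the generating
  # K_D close to their nominal rate, and the replicate median must be
  # consistent with a single experiment's interval
  kds <- rep(NA_real_, 100)
  cover <- rep(NA, 100)
  first_int <- NULL
  for (s in 1:100) {
    sim <- simulate_titration(titration_preset("beta3", seed = 5000 + s))
    prof <- build_csp_profiles(sim$series)
    r <- tryCatch(select_fit_residues(prof), error = function(e) NULL)
    if (is.null(r)) next
    kds[s] <- suppressWarnings(fit_global_kd(prof, r)$kd)
    b <- tryCatch(bootstrap_kd(prof, r, n_boot = 100, seed = s,
                               resample = "points"),
                  error = function(e) NULL)
    if (is.null(b)) next
    cover[s] <- b$interval[["lower"]] <= 528 &&
      528 <= b$interval[["upper"]]
    if (is.null(first_int)) first_int <- b$interval
  }
  expect_lt(mean(is.na(cover)), 0.05)
  cov_rate <- mean(cover, na.rm = TRUE)
  expect_gte(cov_rate, 0.90)
  expect_lte(cov_rate, 0.99)
  med <- stats::median(kds, na.rm = TRUE)
  expect_gte(med, first_int[["lower"]])
  expect_lte(med, first_int[["upper"]])
})

test_that("bundle write + load round-trips the series", {
  dir <- withr::local_tempdir()
  sim <- small_sim(seed = 44, noise_H = 0.002, noise_N = 0.01)
  write_titration_bundle(sim, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  series <- load_titration_series(file.path(dir, "manifest.json"))
  p1 <- build_csp_profiles(sim$series)
  p2 <- build_csp_profiles(series)
  expect_equal(p1$csp_ppm, p2$csp_ppm, tolerance = 1e-8)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$kd, 100)
})
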