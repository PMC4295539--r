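# Synthetic study generator and toy imaging modules.

test_that("degenerate settings give identical volumes; same seed, identical bytes", {
  cfg <- small_config(noise_sd = 0, amplitude = 0, motion_prob = 0,
                      root = tempfile())
  study <- generate_synthetic_study(cfg)
  arr <- as.array(RNifti::readNifti(study$input_locations[["S1/movie"]]))
  base <- arr[, , , cfg$numdummies + 1]
  for (t in (cfg$numdummies + 1):dim(arr)[4]) {
    expect_equal(arr[, , , t], base)
  }
  cfg2 <- small_config(noise_sd = 0, amplitude = 0, motion_prob = 0,
                       root = tempfile())
  study2 <- generate_synthetic_study(cfg2)
  expect_equal(unname(tools::md5sum(study$input_locations[["S1/movie"]])),
               unname(tools::md5sum(study2$input_locations[["S1/movie"]])))
})

test_that("an injected shift translates the whole volume (zero-noise case)", {
  cfg <- small_config(noise_sd = 0, motion_prob = 1, max_shift = 1,
                      root = tempfile())
  study <- generate_synthetic_study(cfg)
  truth <- read_ground_truth(study, "S1", "movie")
  arr <- as.array(RNifti::readNifti(study$input_locations[["S1/movie"]]))
  shifts <- do.call(rbind, lapply(truth$shifts, unlist))
  # find a scan in the middle of an off-block whose predecessor is also off
  # and unshifted, so the volumes differ by translation only
  act <- numeric(dim(arr)[4])
  post <- (cfg$numdummies + 1):dim(arr)[4]
  tc <- aqueduct:::activation_timecourse(length(post), cfg$block_on,
                                         cfg$block_off)$course
  act[post] <- tc
  cand <- which(act == 0 & c(0, act[-length(act)]) == 0 &
                  rowSums(abs(shifts)) > 0 &
                  c(TRUE, rowSums(abs(shifts))[-nrow(shifts)] == 0))
  cand <- cand[cand > cfg$numdummies + 1]
  skip_if(length(cand) == 0, "no isolated moved off-block scan in this draw")
  t <- cand[[1]]
  expect_equal(arr[, , , t],
               aqueduct:::shift_volume(arr[, , , t - 1], shifts[t, ]))
})

test_that("dummy discard arithmetic and boundaries", {
  series <- array(seq_len(4 * 4 * 3 * 20), c(4, 4, 3, 20))
  expect_equal(dim(discard_dummies(series, 3))[4], 17L)
  expect_equal(discard_dummies(series, 3), series[, , , 4:20])
  expect_identical(discard_dummies(series, 0), series)
  expect_error(discard_dummies(series, 20), class = "aqueduct_spec_error")
  expect_error(discard_dummies(series, 25), class = "aqueduct_spec_error")
})

test_that("toy realignment recovers injected shifts exactly at zero noise", {
  cfg <- small_config(noise_sd = 0, motion_prob = 0.8, max_shift = 2,
                      n_subjects = 1, root = tempfile())
  study <- generate_synthetic_study(cfg)
  truth <- read_ground_truth(study, "S1", "movie")
  arr <- as.array(RNifti::readNifti(study$input_locations[["S1/movie"]]))
  post <- discard_dummies(arr, cfg$numdummies)
  res <- toy_realign(post, max_shift = 3)
  injected <- do.call(rbind, lapply(truth$shifts, unlist))[
    -(seq_len(cfg$numdummies)), , drop = FALSE]
  expect_equal(unname(res$motion[, 1:3]), unname(injected))
  expect_true(all(res$motion[, 4:6] == 0))
  # the corrected mean is the meanepi content by definition
  expect_equal(res$mean, apply(res$corrected, 1:3, mean))
})

test_that("an already-aligned series yields an all-zero motion table", {
  cfg <- small_config(noise_sd = 0.5, motion_prob = 0, n_subjects = 1,
                      root = tempfile())
  study <- generate_synthetic_study(cfg)
  arr <- discard_dummies(
    as.array(RNifti::readNifti(study$input_locations[["S1/movie"]])), 3)
  res <- toy_realign(arr)
  expect_true(all(res$motion == 0))
  expect_equal(res$corrected, unclass(arr))
})

test_that("a constant series warns and assumes zero motion", {
  flat <- array(1, c(4, 4, 3, 3))
  expect_warning(res <- toy_realign(flat), "constant")
  expect_true(all(res$motion == 0))
})

test_that("smoothing: identity at 0, measured FWHM matches, intensity conserved", {
  expect_error(gaussian_smooth(array(0, c(3, 3, 3)), -1),
               class = "aqueduct_spec_error")
  vol <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  expect_identical(gaussian_smooth(vol, 0), vol)
  # unit impulse, 8 mm kernel on 2 mm voxels -> measured FWHM ~ 4 voxels
  imp <- array(0, c(17, 17, 17)); imp[9, 9, 9] <- 1
  sm <- gaussian_smooth(imp, 8, c(2, 2, 2))
  profile <- sm[, 9, 9]
  half <- max(profile) / 2
  above <- which(profile >= half)
  # linear interpolation of the half-maximum crossings
  lo <- min(above); hi <- max(above)
  x_lo <- lo - 1 + (half - profile[lo - 1]) / (profile[lo] - profile[lo - 1])
  x_hi <- hi + (profile[hi] - half) / (profile[hi] - profile[hi + 1])
  expect_equal(x_hi - x_lo, 4, tolerance = 0.1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)  # interior impulse conserved
})

test_that("time-series difference metrics: zeros, corruption locality, scale invariance", {
  flat <- array(5, c(6, 6, 4, 8))
  rep0 <- tsdiffana_metrics(flat)
  expect_equal(rep0$metrics, rep(0, 7))
  expect_length(rep0$outliers, 0L)
  expect_length(rep0$metrics, dim(flat)[4] - 1L)

  set.seed(7)
  series <- array(100 + rnorm(6 * 6 * 4 * 10), c(6, 6, 4, 10))
  corrupted <- series
  corrupted[, , , 5] <- corrupted[, , , 5] + rnorm(6 * 6 * 4, sd = 25)
  rep1 <- tsdiffana_metrics(corrupted, outlier_mult = 10)
  expect_setequal(rep1$outliers, c(4L, 5L))  # the two adjacent pairs
  rep_scaled <- tsdiffana_metrics(corrupted * 10, outlier_mult = 10)
  expect_equal(rep_scaled$metrics, rep1$metrics)
})

test_that("voxelwise OLS: null contrasts, permutation invariance, rank handling", {
  set.seed(11)
  n <- 24
  X <- cbind(task = rep(c(0, 1), each = n / 2), constant = 1)
  series <- array(rnorm(8 * n), c(2, 2, 2, n))
  fit <- fit_first_level(series, X, list(c(0, 0)))
  expect_true(all(fit$tstat[[1]] == 0))
  perm <- sample(n)
  fit1 <- fit_first_level(series, X, list(c(1, 0)))
  fit2 <- fit_first_level(series[, , , perm, drop = FALSE],
                          X[perm, , drop = FALSE], list(c(1, 0)))
  expect_equal(fit2$beta, fit1$beta)
  expect_equal(fit1$df, n - 2L)
  # duplicated column: pseudoinverse path with reduced df
  Xd <- cbind(X, X[, 1])
  expect_warning(fitd <- fit_first_level(series, Xd, list(c(1, 0, 0))),
                 "rank")
  expect_equal(fitd$df, n - 2L)
})

test_that("group t-test: degeneracy, antisymmetry, single-subject error", {
  maps <- replicate(4, array(2, c(3, 3, 2)), simplify = FALSE)
  res <- second_level_ttest(maps)
  expect_true(all(is.infinite(res$tstat)))
  expect_true(all(res$degenerate))
  expect_equal(res$df, 3L)
  set.seed(3)
  maps2 <- replicate(5, array(rnorm(18), c(3, 3, 2)), simplify = FALSE)
  res_pos <- second_level_ttest(maps2)
  res_neg <- second_level_ttest(lapply(maps2, function(m) -m))
  expect_equal(res_neg$tstat, -res_pos$tstat)
  expect_error(second_level_ttest(maps2[1]), class = "aqueduct_spec_error")
})

test_that("group t-test type-I error is near nominal under the null", {
  set.seed(19)
  n_sim <- 400  # a quick check; the acceptance run uses 2000
  n_sub <- 8
  crit <- qt(0.975, df = n_sub - 1)
  rejections <- 0L; trials <- 0L
  for (i in seq_len(n_sim)) {
    maps <- replicate(n_sub, array(rnorm(4, mean = 0, sd = 2), c(2, 2, 1)),
                      simplify = FALSE)
    res <- second_level_ttest(maps)
    rejections <- rejections + sum(abs(res$tstat) > crit)
    trials <- trials + length(res$tstat)
  }
  rate <- rejections / trials
  ci <- qbinom(c(0.005, 0.995), trials, 0.05) / trials
  expect_gte(rate, ci[[1]])
  expect_lte(rate, ci[[2]])
})

test_that("the full toy pipeline localizes the injected activation at default conditions", {
  # default generator conditions: 2 subjects, 12x12x10 at 3 mm, 27 scans
  # (3 dummies), blocks 6 on / 6 off, amplitude 8 on baseline 100, noise
  # sd 1, movements within +/-2 voxels; 8 mm smoothing kernel
  cfg <- synthetic_study_config(root = tempfile())
  study <- generate_synthetic_study(cfg)
  an <- new_analysis(tasklist = toy_tasklist(), study = study)
  an <- set_parameter(an, "acq_details.numdummies", cfg$numdummies)
  an <- set_tasksetting(an, "smooth", "FWHM", 8)
  tr <- read_ground_truth(study, "S1", "movie")
  an <- add_event(an, "first_level", "*", "*", "blocks",
                  unlist(tr$onsets), tr$duration)
  an <- add_contrast(an, "first_level", "*", "sameforallsessions", 1)
  prov <- quiet_run(an)
  expect_equal(prov$n_failed, 0L)
  trunk <- analysis_trunk_dir_of(study)
  gt <- as.array(RNifti::readNifti(file.path(
    trunk, "second_level_00001", "group_t_001.nii.gz")))
  cons <- lapply(study$subjects, function(s) as.array(RNifti::readNifti(
    file.path(trunk, "first_level_00001", s, "con_001.nii.gz"))))
  gmean <- Reduce(`+`, cons) / length(cons)
  core <- array(FALSE, dim(gt))
  core[(cfg$mask_lo[1] + 1):(cfg$mask_hi[1] - 1),
       (cfg$mask_lo[2] + 1):(cfg$mask_hi[2] - 1),
       (cfg$mask_lo[3] + 1):(cfg$mask_hi[3] - 1)] <- TRUE
  # outside = beyond the mask dilated by 2 voxels (the smoothing kernel
  # spreads signal into a ring around the region)
  dil <- array(FALSE, dim(gt))
  dil[(cfg$mask_lo[1] - 2):(cfg$mask_hi[1] + 2),
      (cfg$mask_lo[2] - 2):(cfg$mask_hi[2] + 2),
      (cfg$mask_lo[3] - 2):(cfg$mask_hi[3] + 2)] <- TRUE
  thr <- cfg$amplitude / 4  # amplitude-dependent effect threshold
  expect_true(all(gmean[core] > thr))
  expect_true(all(abs(gmean[!dil]) < thr))
  expect_true(all(gt[core] > 10))
})

test_that("modules read and write only inside their instance directories", {
  study <- generate_synthetic_study(small_config(n_subjects = 1L))
  an <- toy_analysis(study)
  plan <- build_plan(an)
  quiet_run(plan)
  root <- normalizePath(analysis_trunk_dir_of(study))
  for (inst in plan$map$instance_index) {
    recs <- read_output_records(inst$dir)
    for (stream in names(recs %||% list())) {
      for (f in recs[[stream]]$files) {
        p <- normalizePath(file.path(inst$dir, f$path))
        expect_true(startsWith(p, normalizePath(inst$dir)))
        expect_true(startsWith(p, root))
      }
    }
  }
})

test_that("a module writing outside its directory fails the instance", {
  study <- generate_synthetic_study(small_config(n_subjects = 1L))
  tl <- parse_tasklist("main: [{name: import_epi}, {name: passthrough}]")
  reg <- default_registry()
  register_module_impl(reg, "passthrough", function(ctx) {
    stray <- file.path(dirname(ctx$dir), "..", "stray.nii.gz")
    writeLines("x", stray)
    list(epi = stray)
  })
  an <- new_analysis(tasklist = tl, study = study, registry = reg)
  an <- set_parameter(an, "acq_details.numdummies", 3)
  prov <- quiet_run(an)
  expect_equal(prov$n_failed, 1L)
  expect_match(unlist(prov$errors), "outside its own directory")
})
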