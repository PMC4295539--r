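# Event and contrast specification, design assembly, contrast expansion.

test_that("the block-design example yields 6 events of duration 7.5 scans everywhere", {
  m <- add_event(fmri_model(), "first_level", "*", "*",
                 "VisualStimulus", seq(0, 75, by = 15), 7.5)
  for (sub in c("S1", "S2")) {
    for (sess in c("movie", "rest")) {
      evs <- aqueduct:::events_for(m, "first_level", sub, sess)
      expect_length(evs, 1L)
      expect_length(evs[[1]]$onsets, 6L)
      expect_equal(evs[[1]]$durations, 7.5)
    }
  }
  d <- build_design(aqueduct:::events_for(m, "first_level", "S1", "movie"),
                    n_scans = 90, hrf_mode = "boxcar")
  # boxcar mass integrates to 6 events x 7.5 scans
  expect_equal(sum(d$X[, 1]), 45)
})

test_that("onset order does not matter and scalar durations broadcast", {
  sorted <- build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", c(0, 15, 30), 5, NULL)), 40)
  shuffled <- build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", c(30, 0, 15), 5, NULL)), 40)
  expect_equal(shuffled$X, sorted$X)
  listed <- build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", c(30, 0, 15), c(5, 5, 5), NULL)), 40)
  expect_equal(listed$X, shuffled$X)
})

test_that("per-coordinate specificity overrides the wildcard spec", {
  m <- fmri_model()
  m <- add_event(m, "fl", "*", "*", "ev", c(0, 10), 2)
  m <- add_event(m, "fl", "S2", "movie", "ev", 5, 1)
  evs_s1 <- aqueduct:::events_for(m, "fl", "S1", "movie")
  expect_equal(evs_s1[[1]]$onsets, c(0, 10))
  evs_s2 <- aqueduct:::events_for(m, "fl", "S2", "movie")
  expect_length(evs_s2, 1L)
  expect_equal(evs_s2[[1]]$onsets, 5)
})

test_that("event specification errors are caught", {
  expect_error(add_event(fmri_model(), "fl", "*", "*", "ev",
                         c(0, 5, 10), c(1, 2)),
               class = "aqueduct_spec_error")
  expect_error(add_event(fmri_model(), "fl", "*", "*", "ev", -1, 1),
               class = "aqueduct_spec_error")
  expect_error(build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", 18, 5, NULL)), n_scans = 20),
    class = "aqueduct_spec_error")
})

test_that("contrast defaults and format tokens behave as documented", {
  m <- add_contrast(fmri_model(), "fl", "*", "sameforallsessions", c(1, -1))
  expect_equal(m$contrasts[[1]]$contype, "T")
  expect_error(add_contrast(fmri_model(), "fl", "*", "everysession", 1),
               class = "aqueduct_spec_error")
  expect_error(add_contrast(fmri_model(), "fl", "*", "singlesession:", 1),
               class = "aqueduct_spec_error")
})

two_session_design <- function() {
  m <- fmri_model()
  m <- add_event(m, "fl", "*", "*", "evA", c(0, 10), 3)
  m <- add_event(m, "fl", "*", "*", "evB", c(5, 15), 3)
  motion <- lapply(stats::setNames(nm = c("sess1", "sess2")), function(s) {
    set.seed(nchar(s))
    cbind(matrix(rnorm(60), 20, 3), matrix(0, 20, 3))
  })
  build_first_level_design(m, "fl", "S1", c("sess1", "sess2"),
                           list(sess1 = 20, sess2 = 20), motion)
}

test_that("sameforallsessions tiles task columns and zeros the nuisance block", {
  design <- two_session_design()
  # per session: 2 task + 3 varying motion + 1 constant = 6 columns
  expect_equal(ncol(design$X), 12L)
  spec <- aqueduct:::new_contrast_spec("fl", "*", "sameforallsessions",
                                       c(1, -1), "T", TRUE)
  row <- expand_contrast(spec, design)
  expect_equal(as.numeric(row),
               c(1, -1, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0))
})

test_that("singlesession places the vector in one block, zeros elsewhere", {
  design <- two_session_design()
  spec <- aqueduct:::new_contrast_spec("fl", "*", "singlesession:sess2",
                                       c(1, 0), "T", TRUE)
  row <- expand_contrast(spec, design)
  expect_equal(as.numeric(row),
               c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  bad <- aqueduct:::new_contrast_spec("fl", "*", "singlesession:ghost",
                                      c(1, 0), "T", TRUE)
  expect_error(expand_contrast(bad, design),
               class = "aqueduct_contrast_error")
})

test_that("uniquebysession consumes the whole task width exactly", {
  design <- two_session_design()
  spec <- aqueduct:::new_contrast_spec("fl", "*", "uniquebysession",
                                       c(1, 0, 0, -1), "T", TRUE)
  row <- expand_contrast(spec, design)
  expect_equal(as.numeric(row),
               c(1, 0, 0, 0, 0, 0, 0, -1, 0, 0, 0, 0))
  short <- aqueduct:::new_contrast_spec("fl", "*", "uniquebysession",
                                        c(1, 0, 0), "T", TRUE)
  expect_error(expand_contrast(short, design),
               class = "aqueduct_contrast_error")
})

test_that("expanded contrasts always match the design width; zero vectors are valid", {
  design <- two_session_design()
  for (fmt in c("sameforallsessions", "singlesession:sess1")) {
    spec <- aqueduct:::new_contrast_spec("fl", "*", fmt, c(0, 0), "T", TRUE)
    row <- expand_contrast(spec, design)
    expect_equal(ncol(row), ncol(design$X))
    expect_true(all(row == 0))
  }
  # without auto nuisance padding the vector must cover every column
  full <- aqueduct:::new_contrast_spec("fl", "*", "sameforallsessions",
                                       rep(0, 12), "T", FALSE)
  expect_equal(ncol(expand_contrast(full, design)), 12L)
  part <- aqueduct:::new_contrast_spec("fl", "*", "sameforallsessions",
                                       rep(0, 11), "T", FALSE)
  expect_error(expand_contrast(part, design),
               class = "aqueduct_contrast_error")
})

test_that("a whole-session event is collinear with the session mean", {
  d <- build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", 0, 30, NULL)), 30)
  expect_equal(d$X[, 1], d$X[, 2])  # event column == constant column
})

test_that("an all-equal parametric modulator vanishes after mean-centering", {
  d <- build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", c(0, 10, 20), 2, c(3, 3, 3))), 30)
  expect_equal(d$names[1:2], c("ev", "ev_x_param"))
  expect_true(all(d$X[, 2] == 0))
  # a varying modulator produces a nonzero, centered column
  d2 <- build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", c(0, 10, 20), 2, c(1, 2, 6))), 30)
  expect_gt(max(abs(d2$X[, 2])), 0)
  expect_equal(sum(d2$X[, 2]), 0)
})

test_that("the canonical response peaks at the gamma mode with a later undershoot", {
  h <- canonical_hrf(tr = 0.5)
  t <- seq(0, 32, by = 0.5)
  # positive lobe gamma(shape 6, rate 1): mode at (6 - 1)/1 = 5 s
  expect_equal(t[which.max(h)], 5, tolerance = 1e-12)
  expect_equal(max(h), 1)
  expect_lt(min(h[t > 10 & t < 25]), 0)  # undershoot
  d <- build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", 0, 1, NULL)), 40, hrf_mode = "canonical", tr = 0.5)
  expect_equal(which.max(d$X[, 1]), which.max(h))
})

test_that("the GLM recovers injected amplitudes with error vanishing as noise does", {
  set.seed(42)
  n <- 40
  d <- build_design(list(aqueduct:::new_event_spec(
    "m", "*", "*", "ev", c(5, 20), 6, NULL)), n)
  amp <- 3.7
  signal <- amp * d$X[, 1] + 10
  errs <- vapply(c(1, 0.1, 0), function(sd) {
    series <- array(rep(signal, each = 8) +
                      rnorm(8 * n, sd = sd), c(2, 2, 2, n))
    fit <- fit_first_level(series, d$X, list(c(1, 0)))
    max(abs(fit$effects[[1]] - amp))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[[3]], 1e-10)
})
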