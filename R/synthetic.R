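# Synthetic 4D study generator: stands in for the output of DICOM
# conversion, so the engine can run end to end with no scanner data. Each
# session is a 4D EPI series with a structured baseline image, injected
# block activation in a cuboid region, injected per-scan integer motion,
# leading dummy scans with elevated intensity, and Gaussian noise; each
# subject also gets a 3D structural volume. A ground-truth sidecar (shifts,
# amplitude, mask, timing) is written next to every series for recovery
# tests.

#' Configuration of a synthetic study
#'
#' Defaults describe a small two-subject block-design study: 12 x 12 x 10
#' voxels at 3 mm, 27 scans of which 3 are dummies, activation blocks of 6
#' scans on / 6 off at amplitude 8 on a baseline of 100, noise sd 1, and
#' integer head movements within +/-2 voxels.
#'
#' @param n_subjects number of subjects (ids `S1`, `S2`, ...).
#' @param sessions session names, identical for every subject.
#' @param n_scans volumes per series, dummies included.
#' @param shape volume dimensions in voxels.
#' @param voxel_mm voxel size in millimeters.
#' @param tr repetition time in seconds.
#' @param numdummies leading non-steady-state volumes (elevated intensity,
#'   no activation, no motion).
#' @param block_on,block_off activation block timing in scans, on the
#'   post-dummy grid.
#' @param amplitude activation amplitude added inside the region.
#' @param baseline mean intensity of the baseline image.
#' @param noise_sd Gaussian noise standard deviation.
#' @param max_shift motion shifts drawn uniformly from
#'   `-max_shift:max_shift` per axis (|shift| <= 3 required by the toy
#'   realigner's search radius).
#' @param motion_prob probability that a scan moves at all.
#' @param mask_lo,mask_hi inclusive voxel index corners of the activated
#'   cuboid.
#' @param seed RNG seed; a fixed seed makes the output bitwise
#'   reproducible.
#' @param root directory to write the study under.
#' @param analysis_id analysis id of the resulting study description.
#' @return list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_subjects = 2L, sessions = "movie",
                                   n_scans = 27L, shape = c(12L, 12L, 10L),
                                   voxel_mm = c(3, 3, 3), tr = 2,
                                   numdummies = 3L, block_on = 6L,
                                   block_off = 6L, amplitude = 8,
                                   baseline = 100, noise_sd = 1,
                                   max_shift = 2L, motion_prob = 0.5,
                                   mask_lo = c(5L, 5L, 4L),
                                   mask_hi = c(8L, 8L, 7L),
                                   seed = 1L, root = tempfile("synthstudy"),
                                   analysis_id = "analysis") {
  stopifnot(max_shift <= 3L, amplitude >= 0, numdummies >= 0,
            numdummies < n_scans)
  structure(as.list(environment()), class = "synthetic_study_config")
}

# integer-block activation time course on the post-dummy grid
activation_timecourse <- function(n_post, block_on, block_off) {
  tc <- numeric(n_post)
  onsets <- seq.int(block_off, n_post - 1L, by = block_on + block_off)
  onsets <- onsets[onsets + block_on <= n_post]
  for (o in onsets) tc[(o + 1L):(o + block_on)] <- 1
  list(course = tc, onsets = onsets, duration = block_on)
}

subject_baseline <- function(shape, baseline, subject_idx) {
  # structured, subject-specific image: offset Gaussian bump plus gradients,
  # so correlation-based realignment has something to lock onto
  cx <- shape / 2 + c(subject_idx %% 3 - 1, subject_idx %% 2, 0)
  ax <- lapply(1:3, function(a) seq_len(shape[a]))
  bump <- outer(outer(exp(-(ax[[1]] - cx[1])^2 / (0.12 * shape[1]^2)),
                      exp(-(ax[[2]] - cx[2])^2 / (0.12 * shape[2]^2))),
                exp(-(ax[[3]] - cx[3])^2 / (0.2 * shape[3]^2)))
  grad <- outer(outer(ax[[1]] / shape[1], ax[[2]] / shape[2] * 0.5, "+"),
                ax[[3]] / shape[3] * 0.25, "+")
  baseline * (0.4 + 0.5 * bump + 0.1 * grad / max(grad))
}

#' Generate a synthetic study tree
#'
#' Writes, under `config$root`, one 4D NIfTI EPI series per (subject,
#' session), one 3D structural per subject, and a `truth.json` sidecar per
#' series recording the injected shifts, activation timing, amplitude and
#' region mask. With `noise_sd = 0`, `amplitude = 0` and no motion every
#' volume is identical; the same seed always reproduces identical bytes.
#'
#' @param config a [synthetic_study_config()].
#' @return a [study_description()] for the generated tree (the config is
#'   attached as attribute `config`).
#' @export
generate_synthetic_study <- function(config = synthetic_study_config()) {
  stopifnot(inherits(config, "synthetic_study_config"))
  subjects <- paste0("S", seq_len(config$n_subjects))
  raw <- file.path(config$root, "raw")
  locations <- list()
  act <- activation_timecourse(config$n_scans - config$numdummies,
                               config$block_on, config$block_off)
  mask <- array(FALSE, config$shape)
  mask[config$mask_lo[1]:config$mask_hi[1],
       config$mask_lo[2]:config$mask_hi[2],
       config$mask_lo[3]:config$mask_hi[3]] <- TRUE
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    base <- subject_baseline(config$shape, config$baseline, si)
    sdir <- file.path(raw, sub)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    struct_path <- file.path(sdir, "structural.nii.gz")
    write_nifti_array(base, struct_path, config$voxel_mm)
    locations[[sub]] <- struct_path
    for (zi in seq_along(config$sessions)) {
      sess <- config$sessions[[zi]]
      set.seed(config$seed + 1009L * si + zi)
      n <- config$n_scans
      shifts <- matrix(0L, n, 3L)
      movable <- seq_len(n) > config$numdummies + 1L
      for (t in which(movable)) {
        if (stats::runif(1) < config$motion_prob) {
          shifts[t, ] <- sample(seq.int(-config$max_shift, config$max_shift),
                                3L, replace = TRUE)
        }
      }
      series <- array(0, c(config$shape, n))
      for (t in seq_len(n)) {
        vol <- base
        if (t <= config$numdummies) {
          vol <- vol * 1.15  # pre-steady-state saturation
        } else {
          a <- act$course[[t - config$numdummies]]
          if (a > 0) vol <- vol + config$amplitude * a * mask
        }
        vol <- shift_volume(vol, shifts[t, ])
        if (config$noise_sd > 0) {
          vol <- vol + stats::rnorm(length(vol), sd = config$noise_sd)
        }
        series[, , , t] <- vol
      }
      zdir <- file.path(sdir, sess)
      dir.create(zdir, recursive = TRUE, showWarnings = FALSE)
      epi_path <- file.path(zdir, "epi.nii.gz")
      write_nifti_array(series, epi_path, config$voxel_mm, config$tr)
      truth <- list(
        subject = sub, session = sess,
        shifts = apply(shifts, 1L, function(r) as.list(r), simplify = FALSE),
        onsets = as.list(act$onsets), duration = act$duration,
        amplitude = config$amplitude, baseline = config$baseline,
        noise_sd = config$noise_sd, numdummies = config$numdummies,
        mask_lo = as.list(config$mask_lo), mask_hi = as.list(config$mask_hi))
      write_json_atomic(truth, file.path(zdir, "truth.json"))
      locations[[paste(sub, sess, sep = "/")]] <- epi_path
    }
  }
  study <- study_description(list(
    analysis_root = config$root, analysis_id = config$analysis_id,
    subjects = subjects,
    sessions_per_subject = stats::setNames(
      rep(list(as.character(config$sessions)), length(subjects)), subjects),
    input_locations = locations, numdummies = config$numdummies))
  attr(study, "config") <- config
  study
}

#' Read the ground-truth sidecar of a synthetic session
#'
#' @param study a study from [generate_synthetic_study()].
#' @param subject,session identifiers.
#' @return the sidecar list (shifts, onsets, duration, amplitude, mask).
#' @export
read_ground_truth <- function(study, subject, session) {
  epi <- study$input_locations[[paste(subject, session, sep = "/")]]
  read_json_file(file.path(dirname(epi), "truth.json"))
}
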