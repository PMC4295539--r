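# First-level model specification: events and contrasts, accumulated on the
# analysis and expanded into per-session design matrices at run time.
#
# Onsets and durations are in scans (conversion from seconds is the
# caller's job). "Moves and means" nuisance regressors are the 6 motion
# parameters (3 translations + 3 rotations) plus one constant per session.

N_MOTION_COLS <- 6L

#' Create an empty fMRI model specification
#'
#' @return object of class `fmri_model` holding event and contrast specs.
#' @export
fmri_model <- function() {
  structure(list(events = list(), contrasts = list()), class = "fmri_model")
}

#' Add an event regressor to a first-level model
#'
#' Repeated calls accumulate. Wildcards (`"*"`) for subject and/or session
#' expand at design-build time to all applicable coordinates; a spec given
#' for a specific subject/session overrides a wildcard spec of the same
#' event name for that coordinate.
#'
#' @param x an `fmri_model` or an `analysis_spec`.
#' @param module stage name of the first-level model stage this event
#'   applies to.
#' @param subject subject id or `"*"`.
#' @param session session id or `"*"`.
#' @param event_name name of the stimulus or response event.
#' @param onsets event onset times in scans; need not be sorted.
#' @param durations a single duration (applied to every onset) or one per
#'   onset, in scans.
#' @param parametric optional parametric modulator values, one per onset
#'   (mean-centered before entering the design).
#' @return `x` with the spec appended.
#' @examples
#' m <- add_event(fmri_model(), "first_level", "*", "*",
#'                "VisualStimulus", seq(0, 75, by = 15), 7.5)
#' @export
add_event <- function(x, module, subject, session, event_name, onsets,
                      durations, parametric = NULL) {
  UseMethod("add_event")
}

new_event_spec <- function(module, subject, session, event_name, onsets,
                           durations, parametric) {
  onsets <- as.numeric(onsets)
  if (any(!is.finite(onsets)) || any(onsets < 0)) {
    abort_aq("event onsets must be finite and >= 0", "aqueduct_spec_error")
  }
  durations <- as.numeric(durations)
  if (length(durations) != 1L && length(durations) != length(onsets)) {
    abort_aq(sprintf(
      "durations must be length 1 or match the %d onsets (got %d)",
      length(onsets), length(durations)), "aqueduct_spec_error")
  }
  if (!is.null(parametric) && length(parametric) != length(onsets)) {
    abort_aq("parametric modulator length must match onsets",
             "aqueduct_spec_error")
  }
  list(module = module, subject = subject, session = session,
       event_name = event_name, onsets = onsets, durations = durations,
       parametric = parametric)
}

#' @export
add_event.fmri_model <- function(x, module, subject, session, event_name,
                                 onsets, durations, parametric = NULL) {
  x$events[[length(x$events) + 1L]] <-
    new_event_spec(module, subject, session, event_name, onsets, durations,
                   parametric)
  x
}

#' @export
add_event.analysis_spec <- function(x, module, subject, session, event_name,
                                    onsets, durations, parametric = NULL) {
  x$model <- add_event(x$model, module, subject, session, event_name,
                       onsets, durations, parametric)
  x
}

CONTRAST_FORMATS <- c("sameforallsessions", "uniquebysession")

#' Add a contrast to a first-level model
#'
#' @param x an `fmri_model` or an `analysis_spec`.
#' @param module stage name of the contrast/model stage.
#' @param subject subject id or `"*"`.
#' @param format `"sameforallsessions"` (vector applied to every session),
#'   `"singlesession:<name>"` (vector for one session, zeros elsewhere), or
#'   `"uniquebysession"` (one long vector covering every session's task
#'   columns in order).
#' @param vector numeric contrast vector (a matrix for F contrasts).
#' @param contype `"T"` or `"F"`; defaults to `"T"`.
#' @param auto_movesandmeans add zeros for the motion and session-mean
#'   nuisance columns automatically (default `TRUE`); when `FALSE` the
#'   vector must already cover all columns.
#' @return `x` with the spec appended.
#' @export
add_contrast <- function(x, module, subject, format, vector, contype = "T",
                         auto_movesandmeans = TRUE) {
  UseMethod("add_contrast")
}

new_contrast_spec <- function(module, subject, format, vector, contype,
                              auto_movesandmeans) {
  base_fmt <- sub(":.*$", "", format)
  if (!base_fmt %in% c(CONTRAST_FORMATS, "singlesession")) {
    abort_aq(sprintf("unknown contrast format '%s'", format),
             "aqueduct_spec_error")
  }
  if (base_fmt == "singlesession" && !grepl("^singlesession:.+$", format)) {
    abort_aq("singlesession format must name a session: 'singlesession:<name>'",
             "aqueduct_spec_error")
  }
  if (length(vector) == 0L) {
    abort_aq("contrast vector must be nonempty", "aqueduct_spec_error")
  }
  if (!contype %in% c("T", "F")) {
    abort_aq("contype must be 'T' or 'F'", "aqueduct_spec_error")
  }
  list(module = module, subject = subject, format = format,
       vector = vector, contype = contype,
       auto_movesandmeans = isTRUE(auto_movesandmeans))
}

#' @export
add_contrast.fmri_model <- function(x, module, subject, format, vector,
                                    contype = "T", auto_movesandmeans = TRUE) {
  x$contrasts[[length(x$contrasts) + 1L]] <-
    new_contrast_spec(module, subject, format, vector, contype,
                      auto_movesandmeans)
  x
}

#' @export
add_contrast.analysis_spec <- function(x, module, subject, format, vector,
                                       contype = "T",
                                       auto_movesandmeans = TRUE) {
  x$model <- add_contrast(x$model, module, subject, format, vector, contype,
                          auto_movesandmeans)
  x
}

# events applicable to (module, subject, session); per event name the most
# specific matching specs win (exact subject/session beats wildcard).
events_for <- function(model, module, subject, session) {
  specs <- Filter(function(e) {
    e$module == module &&
      (e$subject == "*" || e$subject == subject) &&
      (e$session == "*" || e$session == session)
  }, model$events)
  if (length(specs) == 0L) return(list())
  score <- vapply(specs, function(e)
    (e$subject != "*") + (e$session != "*"), 0)
  names_ <- vapply(specs, function(e) e$event_name, "")
  keep <- logical(length(specs))
  for (nm in unique(names_)) {
    idx <- which(names_ == nm)
    keep[idx[score[idx] == max(score[idx])]] <- TRUE
  }
  specs[keep]
}

contrasts_for <- function(model, module, subject) {
  Filter(function(cn) {
    cn$module == module && (cn$subject == "*" || cn$subject == subject)
  }, model$contrasts)
}

# fractional boxcar of one event spec on the scan grid: scan t (interval
# [t, t+1)) accumulates the overlap of each occurrence [onset, onset+dur).
event_boxcar <- function(onsets, durations, n_scans, weights = NULL) {
  if (length(durations) == 1L) durations <- rep(durations, length(onsets))
  if (is.null(weights)) weights <- rep(1, length(onsets))
  if (any(onsets + durations > n_scans + 1e-9)) {
    abort_aq(sprintf(
      "event extends past the series end (%g scans): onset %g + duration %g",
      n_scans, onsets[which.max(onsets + durations)],
      durations[which.max(onsets + durations)]), "aqueduct_spec_error")
  }
  col <- numeric(n_scans)
  for (i in seq_along(onsets)) {
    a <- onsets[[i]]; b <- onsets[[i]] + durations[[i]]
    t0 <- floor(a); t1 <- min(ceiling(b), n_scans)
    if (t1 <= t0) next
    for (t in seq.int(t0, t1 - 1L)) {
      col[t + 1L] <- col[t + 1L] +
        weights[[i]] * max(0, min(b, t + 1) - max(a, t))
    }
  }
  col
}

#' Canonical haemodynamic response kernel
#'
#' Double-gamma response (peak at 6 s, undershoot at 16 s, undershoot ratio
#' 1/6), sampled on the scan grid given a nominal repetition time, scaled
#' to unit peak.
#'
#' @param tr repetition time in seconds per scan.
#' @param length_s kernel support in seconds.
#' @return numeric kernel sampled at scan resolution.
#' @export
canonical_hrf <- function(tr = 2, length_s = 32) {
  t <- seq(0, length_s, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

convolve_design <- function(col, kernel) {
  n <- length(col)
  out <- stats::convolve(c(col, numeric(length(kernel))),
                         rev(kernel), type = "open")
  out[seq_len(n)]
}

#' Build a single-session first-level design matrix
#'
#' Each event yields a boxcar regressor on the scan grid (fractional onsets
#' and durations accumulate proportionally into the scans they overlap),
#' optionally convolved with the canonical double-gamma response;
#' parametric modulators add a mean-centered, occurrence-weighted copy.
#' Motion parameters and a session-mean constant are appended as nuisance
#' columns.
#'
#' @param events list of event specs (see [add_event()]); order defines the
#'   task-column order.
#' @param n_scans scans in the session (after dummy discard).
#' @param hrf_mode `"boxcar"` (no convolution) or `"canonical"`.
#' @param tr repetition time in seconds, used by the canonical kernel.
#' @param motion optional scans x 6 motion-parameter matrix.
#' @param include_constant append the session-mean column.
#' @return list: `X` (scans x columns), `names`, `task_cols`,
#'   `nuisance_cols`.
#' @export
build_design <- function(events, n_scans, hrf_mode = c("boxcar", "canonical"),
                         tr = 2, motion = NULL, include_constant = TRUE) {
  hrf_mode <- match.arg(hrf_mode)
  cols <- list()
  for (ev in events) {
    cols[[ev$event_name]] <- event_boxcar(ev$onsets, ev$durations, n_scans)
    if (!is.null(ev$parametric)) {
      w <- ev$parametric - mean(ev$parametric)
      cols[[paste0(ev$event_name, "_x_param")]] <-
        event_boxcar(ev$onsets, ev$durations, n_scans, weights = w)
    }
  }
  if (hrf_mode == "canonical" && length(cols)) {
    kernel <- canonical_hrf(tr = tr)
    cols <- lapply(cols, convolve_design, kernel = kernel)
  }
  task_names <- names(cols)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans || ncol(motion) != N_MOTION_COLS) {
      abort_aq(sprintf("motion parameters must be %d x %d", n_scans,
                       N_MOTION_COLS), "aqueduct_spec_error")
    }
    for (j in seq_len(N_MOTION_COLS)) {
      # constant motion columns (e.g. the zero rotation columns of the toy
      # realigner) are collinear with the session mean; drop them
      if (stats::sd(motion[, j]) > 0) {
        cols[[paste0("motion_", j)]] <- motion[, j]
      }
    }
  }
  if (include_constant) cols[["constant"]] <- rep(1, n_scans)
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(0, n_scans, 0)
  list(X = X, names = names(cols),
       task_cols = seq_along(task_names),
       nuisance_cols = setdiff(seq_along(cols), seq_along(task_names)))
}

#' Assemble a subject's first-level design across sessions
#'
#' Builds one design per session (wildcard event specs expand here) and a
#' session block layout for contrast expansion. The full design is block
#' diagonal: rows are concatenated scans, columns concatenated per-session
#' columns.
#'
#' @param model an `fmri_model`.
#' @param module first-level stage name the specs address.
#' @param subject subject id.
#' @param sessions character vector of session names, in order.
#' @param n_scans named (by session) scan counts.
#' @param motion optional named list of motion matrices.
#' @param hrf_mode,tr see [build_design()].
#' @return object of class `first_level_design`: `sessions` (per-session
#'   design lists), `layout` (per-session column offsets and widths), `X`
#'   (full block-diagonal matrix), `names`.
#' @export
build_first_level_design <- function(model, module, subject, sessions,
                                     n_scans, motion = NULL,
                                     hrf_mode = "boxcar", tr = 2) {
  designs <- list()
  for (sess in sessions) {
    evs <- events_for(model, module, subject, sess)
    designs[[sess]] <- build_design(
      evs, n_scans[[sess]], hrf_mode = hrf_mode, tr = tr,
      motion = motion[[sess]])
  }
  widths <- vapply(designs, function(d) ncol(d$X), 0L)
  rows <- vapply(designs, function(d) nrow(d$X), 0L)
  total_cols <- sum(widths)
  X <- matrix(0, sum(rows), total_cols)
  names_full <- character(total_cols)
  layout <- list()
  roff <- 0L; coff <- 0L
  for (sess in sessions) {
    d <- designs[[sess]]
    if (ncol(d$X) > 0) {
      X[roff + seq_len(nrow(d$X)), coff + seq_len(ncol(d$X))] <- d$X
      names_full[coff + seq_along(d$names)] <- paste(sess, d$names, sep = ":")
    }
    layout[[sess]] <- list(col_offset = coff, n_cols = ncol(d$X),
                           task_cols = d$task_cols,
                           nuisance_cols = d$nuisance_cols,
                           row_offset = roff, n_rows = nrow(d$X))
    roff <- roff + nrow(d$X); coff <- coff + ncol(d$X)
  }
  structure(list(sessions = designs, layout = layout, X = X,
                 names = names_full, session_order = sessions),
            class = "first_level_design")
}

#' Expand a contrast specification to full design width
#'
#' `sameforallsessions` tiles the vector over every session's task columns;
#' `singlesession:<name>` places it in the named session block with zeros
#' elsewhere; `uniquebysession` consumes the vector block by block and must
#' match the total task-column count. With `auto_movesandmeans` the
#' nuisance columns (motion and session means) receive zeros automatically;
#' otherwise the given vector must already cover all columns of the full
#' design.
#'
#' @param spec a contrast spec from [add_contrast()].
#' @param design a [build_first_level_design()] result.
#' @return numeric row vector (or matrix for F contrasts) whose width
#'   equals `ncol(design$X)`.
#' @export
expand_contrast <- function(spec, design) {
  vec <- spec$vector
  if (is.matrix(vec) && spec$contype == "T" && nrow(vec) == 1L) {
    vec <- drop(vec)
  }
  rows <- if (is.matrix(vec)) nrow(vec) else 1L
  as_mat <- function(v) if (is.matrix(v)) v else matrix(v, nrow = 1L)
  vec <- as_mat(vec)
  total_cols <- ncol(design$X)
  if (!spec$auto_movesandmeans) {
    if (ncol(vec) != total_cols) {
      abort_aq(sprintf("contrast width %d != design width %d (auto_movesandmeans disabled)",
                       ncol(vec), total_cols), "aqueduct_contrast_error")
    }
    return(vec)
  }
  out <- matrix(0, rows, total_cols)
  fmt <- sub(":.*$", "", spec$format)
  sessions <- design$session_order
  if (fmt == "sameforallsessions") {
    for (sess in sessions) {
      lay <- design$layout[[sess]]
      if (ncol(vec) != length(lay$task_cols)) {
        abort_aq(sprintf(
          "contrast width %d != %d task columns of session '%s'",
          ncol(vec), length(lay$task_cols), sess), "aqueduct_contrast_error")
      }
      out[, lay$col_offset + lay$task_cols] <- vec
    }
  } else if (fmt == "singlesession") {
    target <- sub("^singlesession:", "", spec$format)
    if (!target %in% sessions) {
      abort_aq(sprintf("singlesession contrast names unknown session '%s'",
                       target), "aqueduct_contrast_error")
    }
    lay <- design$layout[[target]]
    if (ncol(vec) != length(lay$task_cols)) {
      abort_aq(sprintf("contrast width %d != %d task columns of session '%s'",
                       ncol(vec), length(lay$task_cols), target),
               "aqueduct_contrast_error")
    }
    out[, lay$col_offset + lay$task_cols] <- vec
  } else if (fmt == "uniquebysession") {
    total_task <- sum(vapply(sessions, function(s)
      length(design$layout[[s]]$task_cols), 0L))
    if (ncol(vec) != total_task) {
      abort_aq(sprintf("uniquebysession contrast width %d != total task columns %d",
                       ncol(vec), total_task), "aqueduct_contrast_error")
    }
    pos <- 0L
    for (sess in sessions) {
      lay <- design$layout[[sess]]
      k <- length(lay$task_cols)
      if (k > 0) {
        out[, lay$col_offset + lay$task_cols] <- vec[, pos + seq_len(k),
                                                     drop = FALSE]
      }
      pos <- pos + k
    }
  }
  if (rows == 1L && spec$contype == "T") out else out
}
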