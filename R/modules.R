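# Module implementation registry and the bundled toy implementations.
#
# An implementation is a function(ctx) returning a named list mapping each
# declared output stream to the files it wrote (inside ctx$dir). The
# context carries the bound settings, the general parameters, the study,
# the instance coordinate, the placed inputs (ctx$inputs: stream -> file
# paths; ctx$inputs_by_source groups fan-in sources), and the model specs.

#' Create an empty module-implementation registry
#'
#' @return an environment mapping implementation names to functions.
#' @export
module_registry <- function() new.env(parent = emptyenv())

#' Register a module implementation
#'
#' The engine resolves the implementation under the interface's
#' `impl_alias` when present, else under the module name, so several
#' interfaces can share one implementation.
#'
#' @param registry a [module_registry()].
#' @param name implementation name.
#' @param fn `function(ctx)` returning a named list: output stream to file
#'   paths.
#' @return the registry, invisibly.
#' @export
register_module_impl <- function(registry, name, fn) {
  stopifnot(is.environment(registry), is.function(fn))
  assign(name, fn, envir = registry)
  invisible(registry)
}

get_module_impl <- function(registry, name) {
  fn <- get0(name, envir = registry)
  if (is.null(fn)) {
    abort_aq(sprintf("no implementation registered under '%s'", name),
             "aqueduct_schema_error")
  }
  fn
}

session_input <- function(ctx, stream, file) {
  hits <- ctx$inputs[[stream]]
  hits <- hits[basename(hits) == file]
  if (length(hits) == 0L) {
    abort_aq(sprintf("expected input file '%s' on stream '%s' not placed",
                     file, stream), "aqueduct_dependency_error")
  }
  hits[[1]]
}

# ---- toy implementations --------------------------------------------------

impl_check_parameters <- function(ctx) {
  study <- ctx$study
  if (length(study$subjects) == 0L) {
    abort_aq("study lists no subjects", "aqueduct_study_error")
  }
  for (sub in study$subjects) {
    for (sess in study$sessions_per_subject[[sub]]) {
      loc <- study$input_locations[[paste(sub, sess, sep = "/")]]
      if (is.null(loc) || !file.exists(loc)) {
        abort_aq(sprintf("missing input series for %s/%s", sub, sess),
                 "aqueduct_study_error")
      }
    }
  }
  invisible(NULL)
}

impl_import_epi <- function(ctx) {
  co <- ctx$coordinate
  loc <- ctx$study$input_locations[[paste(co[["subject"]], co[["session"]],
                                          sep = "/")]]
  series <- read_nifti_array(loc)
  nd <- as.integer(get_nested(ctx$global, "acq_details.numdummies") %||%
                     ctx$settings$numdummies %||% ctx$study$numdummies %||% 0L)
  if (nd > 0L) series <- discard_dummies(series, nd)
  pd <- attr(series, "pixdim") %||% c(3, 3, 3, 2)
  out <- file.path(ctx$dir, "epi.nii.gz")
  write_nifti_array(unclass(series), out, pd[1:3], pd[4] %||% 2)
  list(epi = out)
}

impl_import_structural <- function(ctx) {
  loc <- ctx$study$input_locations[[ctx$coordinate[["subject"]]]]
  out <- file.path(ctx$dir, "structural.nii.gz")
  file.copy(loc, out, overwrite = TRUE)
  list(structural = out)
}

impl_realign <- function(ctx) {
  path <- session_input(ctx, "epi", "epi.nii.gz")
  series <- read_nifti_array(path)
  pd <- attr(series, "pixdim") %||% c(3, 3, 3, 2)
  res <- toy_realign(unclass(series),
                     max_shift = as.integer(ctx$settings$max_shift %||% 3L))
  epi_out <- file.path(ctx$dir, "epi.nii.gz")
  write_nifti_array(res$corrected, epi_out, pd[1:3], pd[4] %||% 2)
  mot_out <- file.path(ctx$dir, "motion.txt")
  utils::write.table(res$motion, mot_out, row.names = FALSE,
                     col.names = FALSE)
  mean_out <- file.path(ctx$dir, "meanepi.nii.gz")
  write_nifti_array(res$mean, mean_out, pd[1:3])
  list(epi = epi_out, realignment_parameter = mot_out, meanepi = mean_out)
}

impl_tsdiff <- function(ctx) {
  path <- session_input(ctx, "epi", "epi.nii.gz")
  series <- unclass(read_nifti_array(path))
  report <- tsdiffana_metrics(series,
                              outlier_mult = ctx$settings$outlier_mult %||% 10)
  tsv <- file.path(ctx$dir, "tsdiff_metrics.tsv")
  utils::write.table(
    data.frame(volume_pair = seq_along(report$metrics),
               metric = report$metrics),
    tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- file.path(ctx$dir, "tsdiff.json")
  write_json_atomic(list(metrics = report$metrics,
                         mean_intensity = report$mean_intensity,
                         outliers = as.list(report$outliers),
                         threshold = report$threshold), js)
  files <- c(tsv, js)
  plot_file <- file.path(ctx$dir, "tsdiff.png")
  ok <- tryCatch({
    grDevices::png(plot_file, width = 480, height = 320)
    graphics::plot(report$metrics, type = "b", xlab = "volume pair",
                   ylab = "scaled squared difference",
                   main = "time-series diagnostics")
    graphics::abline(h = report$threshold, lty = 2)
    grDevices::dev.off()
    TRUE
  }, error = function(e) FALSE)
  if (ok && file.exists(plot_file)) files <- c(files, plot_file)
  list(qc_timediff = files)
}

impl_smooth <- function(ctx) {
  path <- session_input(ctx, "epi", "epi.nii.gz")
  series <- read_nifti_array(path)
  pd <- attr(series, "pixdim") %||% c(3, 3, 3, 2)
  fwhm <- as.numeric(ctx$settings$FWHM %||% 10)
  series <- unclass(series)
  for (t in seq_len(dim(series)[4])) {
    series[, , , t] <- gaussian_smooth(series[, , , t], fwhm, pd[1:3])
  }
  out <- file.path(ctx$dir, "epi.nii.gz")
  write_nifti_array(series, out, pd[1:3], pd[4] %||% 2)
  list(epi = out)
}

impl_first_level <- function(ctx) {
  sub <- ctx$coordinate[["subject"]]
  sessions <- ctx$study$sessions_per_subject[[sub]]
  stage_name <- ctx$instance$stage$name
  series_list <- list(); n_scans <- list(); motion <- list()
  for (sess in sessions) {
    sd <- file.path(ctx$dir, paste0("src_", sess))
    epi <- unclass(read_nifti_array(file.path(sd, "epi.nii.gz")))
    series_list[[sess]] <- epi
    n_scans[[sess]] <- dim(epi)[4]
    mot_path <- file.path(sd, "motion.txt")
    if (file.exists(mot_path)) {
      motion[[sess]] <- as.matrix(utils::read.table(mot_path))
    }
  }
  design <- build_first_level_design(
    ctx$model, stage_name, sub, sessions, n_scans, motion,
    hrf_mode = ctx$settings$hrf %||% "boxcar",
    tr = as.numeric(ctx$settings$tr %||% 2))
  specs <- contrasts_for(ctx$model, stage_name, sub)
  cons <- lapply(specs, expand_contrast, design = design)
  series <- array(0, c(dim(series_list[[1]])[1:3],
                       sum(unlist(n_scans))))
  off <- 0L
  for (sess in sessions) {
    nt <- n_scans[[sess]]
    series[, , , off + seq_len(nt)] <- series_list[[sess]]
    off <- off + nt
  }
  fit <- fit_first_level(series, design$X,
                         lapply(cons, function(m) as.numeric(m[1, ])))
  pd <- c(3, 3, 3)
  con_files <- character(0); t_files <- character(0)
  for (k in seq_along(cons)) {
    cf <- file.path(ctx$dir, sprintf("con_%03d.nii.gz", k))
    write_nifti_array(fit$effects[[k]], cf, pd)
    tf <- file.path(ctx$dir, sprintf("tstat_%03d.nii.gz", k))
    write_nifti_array(fit$tstat[[k]], tf, pd)
    con_files <- c(con_files, cf); t_files <- c(t_files, tf)
  }
  beta_file <- file.path(ctx$dir, "beta.nii.gz")
  write_nifti_array(fit$beta, beta_file, pd)
  stats_file <- file.path(ctx$dir, "firstlevel_stats.json")
  write_json_atomic(list(df = fit$df, n_contrasts = length(cons),
                         columns = design$names,
                         sessions = as.list(sessions)), stats_file)
  list(con = con_files, beta = beta_file,
       firstlevel_stats = c(stats_file, t_files))
}

impl_second_level <- function(ctx) {
  groups <- ctx$inputs_by_source$con %||% list()
  if (length(groups) < 2L) {
    abort_aq("second-level t-test needs contrast maps from >= 2 subjects",
             "aqueduct_spec_error")
  }
  by_contrast <- list()
  for (g in groups) {
    for (f in g$files) {
      key <- basename(f)
      by_contrast[[key]] <- c(by_contrast[[key]], f)
    }
  }
  out_files <- character(0)
  summaries <- list()
  for (key in sort(names(by_contrast))) {
    maps <- lapply(by_contrast[[key]], function(f)
      unclass(read_nifti_array(f)))
    res <- second_level_ttest(maps)
    out <- file.path(ctx$dir, sub("^con", "group_t", key))
    write_nifti_array(res$tstat, out, c(3, 3, 3))
    out_files <- c(out_files, out)
    summaries[[key]] <- list(df = res$df, n_subjects = length(maps),
                             n_degenerate = sum(res$degenerate))
  }
  js <- file.path(ctx$dir, "group_stats.json")
  write_json_atomic(summaries, js)
  list(group_stats = c(out_files, js))
}

impl_passthrough <- function(ctx) {
  if (isTRUE(ctx$settings$fail)) {
    stop("passthrough module instructed to fail")
  }
  path <- session_input(ctx, "epi", "epi.nii.gz")
  out <- file.path(ctx$dir, "epi.nii.gz")
  tmp <- tempfile(tmpdir = ctx$dir, fileext = ".nii.gz")
  file.copy(path, tmp)
  file.rename(tmp, out)
  list(epi = out)
}

#' The bundled toy implementation registry
#'
#' Implementations for the bundled toy interfaces: `check_parameters`,
#' `import_epi`, `import_structural`, `realign`, `tsdiff`, `smooth`,
#' `first_level`, `second_level`, and `passthrough` (an epi copier with a
#' `fail` switch, useful for failure-policy experiments).
#'
#' @return a populated [module_registry()].
#' @export
default_registry <- function() {
  reg <- module_registry()
  register_module_impl(reg, "check_parameters", impl_check_parameters)
  register_module_impl(reg, "import_epi", impl_import_epi)
  register_module_impl(reg, "import_structural", impl_import_structural)
  register_module_impl(reg, "realign", impl_realign)
  register_module_impl(reg, "tsdiff", impl_tsdiff)
  register_module_impl(reg, "smooth", impl_smooth)
  register_module_impl(reg, "first_level", impl_first_level)
  register_module_impl(reg, "second_level", impl_second_level)
  register_module_impl(reg, "passthrough", impl_passthrough)
  reg
}

#' Bundled toy module interfaces
#'
#' Parses the XML interface documents shipped with the package.
#'
#' @param tree a [domain_tree()].
#' @return named list of `module_interface` objects.
#' @export
toy_interfaces <- function(tree = domain_tree()) {
  load_interfaces(system.file("extdata", "modules", package = "aqueduct"),
                  tree = tree)
}

#' Bundled toy tasklists
#'
#' `toy_tasklist()` is a linear EPI pipeline (import, realign, time-series
#' diagnostics, smooth, first-level GLM, second-level t-test);
#' `toy_branch_tasklist()` shares the trunk up to realignment and then
#' forks into two smoothing-kernel branches.
#'
#' @return a `tasklist`.
#' @export
toy_tasklist <- function() {
  parse_tasklist(system.file("extdata", "tasklists", "toy_fmri.xml",
                             package = "aqueduct"))
}

#' @rdname toy_tasklist
#' @export
toy_branch_tasklist <- function() {
  parse_tasklist(system.file("extdata", "tasklists", "toy_fmri_branched.xml",
                             package = "aqueduct"))
}
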