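# Diagnostics aggregation and permanence-ranked garbage collection.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# diagnostics-like assets inside an instance directory
diagnostic_assets <- function(dir) {
  list.files(dir, pattern = "\\.(png|tsv|json|txt)$", full.names = FALSE)
}

#' Collect diagnostics into a multi-level report
#'
#' Builds, under `<analysis_root>/report/`, one index page linking the
#' per-stage / per-subject / per-session assets of every instance, so the
#' analysis can be browsed vertically (within subject) and horizontally
#' (between subjects). With two or more subjects, a between-subject motion
#' summary table (maximum absolute translation per subject, from the
#' realignment-parameter tables) is added. Generation is read-only over
#' the instance directories; missing assets are noted, not fatal.
#'
#' @param analysis_root the analysis directory (`<root>/<analysisid>`)
#'   holding a provenance record.
#' @return (invisibly) list: `index` (path to index.html), `motion_summary`
#'   (data.frame or NULL).
#' @export
collect_diagnostics <- function(analysis_root) {
  prov <- tryCatch(load_provenance(analysis_root), error = function(e) NULL)
  report_dir <- file.path(analysis_root, "report")
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c("<html><head><title>analysis diagnostics</title></head><body>",
             sprintf("<h1>Diagnostics: %s</h1>", html_escape(analysis_root)))
  motion <- list()
  instances <- prov$instances %||% list()
  stages <- unique(vapply(instances, function(i) i$stage, ""))
  lines <- c(lines, sprintf("<p>%d stage(s), %d instance(s)</p>",
                            length(stages), length(instances)))
  for (stage in stages) {
    lines <- c(lines, sprintf("<h2>%s</h2><ul>", html_escape(stage)))
    for (inst in instances) {
      if (inst$stage != stage) next
      coord <- coordinate_key(unlist(inst$coordinate) %||% character(0))
      assets <- if (dir.exists(inst$dir)) diagnostic_assets(inst$dir) else
        character(0)
      items <- if (length(assets)) {
        paste(sprintf('<a href="%s">%s</a>',
                      html_escape(file.path(inst$dir, assets)),
                      html_escape(assets)), collapse = " | ")
      } else "<em>no assets</em>"
      lines <- c(lines, sprintf("<li>%s [%s]: %s</li>", html_escape(coord),
                                html_escape(inst$status %||% "?"), items))
      mot <- file.path(inst$dir, "motion.txt")
      if (file.exists(mot)) {
        sub <- unlist(inst$coordinate)[["subject"]] %||% NA_character_
        if (!is.na(sub)) {
          m <- as.matrix(utils::read.table(mot))
          motion[[sub]] <- max(c(motion[[sub]] %||% 0,
                                 abs(m[, 1:3, drop = FALSE])))
        }
      }
    }
    lines <- c(lines, "</ul>")
  }
  motion_summary <- NULL
  n_subjects <- length(unique(names(motion)))
  if (n_subjects >= 2L) {
    motion_summary <- data.frame(subject = names(motion),
                                 max_abs_translation_vox = unlist(motion),
                                 row.names = NULL)
    motion_summary <- motion_summary[
      order(-motion_summary$max_abs_translation_vox), , drop = FALSE]
    utils::write.table(motion_summary,
                       file.path(report_dir, "motion_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    lines <- c(lines, "<h2>Between-subject motion summary</h2><table border='1'>",
               "<tr><th>subject</th><th>max |translation| (vox)</th></tr>",
               sprintf("<tr><td>%s</td><td>%g</td></tr>",
                       html_escape(motion_summary$subject),
                       motion_summary$max_abs_translation_vox),
               "</table>")
  }
  lines <- c(lines, "</body></html>")
  index <- file.path(report_dir, "index.html")
  writeLines(lines, index)
  invisible(list(index = index, motion_summary = motion_summary))
}

#' Garbage-collect low-permanence stream payloads
#'
#' Deletes the registered stream files of every instance whose producing
#' stage has `permanenceofoutput` below `keep_threshold` (higher ranks
#' mark more important data). Completion flags, stream manifests, logs and
#' the provenance record are always retained, and the digests stay in the
#' manifests, so completed downstream results remain done while the
#' deleted payloads are regenerable: a later run re-executes exactly the
#' producers of deleted streams that pending work needs.
#'
#' @param analysis_root the analysis directory holding a provenance record.
#' @param keep_threshold integer rank; streams of stages with
#'   `permanence_of_output < keep_threshold` are deleted (so 0 deletes
#'   nothing).
#' @param dry_run list candidates without deleting.
#' @return data.frame deletion manifest: `stage`, `instance`, `stream`,
#'   `path`, `deleted`.
#' @export
garbage_collect <- function(analysis_root, keep_threshold, dry_run = FALSE) {
  stopifnot(keep_threshold >= 0)
  prov <- load_provenance(analysis_root)
  rank <- list()
  for (s in prov$stages) rank[[s$dirname]] <- s$permanence_of_output
  ranks_present <- unlist(rank)
  rows <- list()
  for (inst in prov$instances) {
    if (isTRUE(inst$status == "external")) next
    r <- rank[[inst$stage]]
    if (is.null(r) || r >= keep_threshold) next
    recs <- read_output_records(inst$dir)
    for (stream in names(recs %||% list())) {
      for (f in recs[[stream]]$files) {
        path <- file.path(inst$dir, f$path)
        deleted <- FALSE
        if (!dry_run && file.exists(path)) deleted <- unlink(path) == 0L
        rows[[length(rows) + 1L]] <- data.frame(
          stage = inst$stage, instance = inst$label, stream = stream,
          path = path, deleted = deleted, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L && length(ranks_present) &&
      keep_threshold <= min(ranks_present)) {
    warning("keep_threshold is at or below the minimum permanence rank present; nothing deleted")
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(0), instance = character(0),
               stream = character(0), path = character(0),
               deleted = logical(0), stringsAsFactors = FALSE)
}
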