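# Shared fixtures: tiny interface/tasklist builders, abstract studies, and
# independent brute-force oracles used to cross-check the engine.

`%||%` <- function(x, y) if (is.null(x)) y else x

iface_xml <- function(name, domain, ins = character(0), outs = character(0),
                      settings = list(), permanence = 1L, alias = NULL) {
  set_xml <- paste(vapply(names(settings), function(nm)
    sprintf("<%s>%s</%s>", nm, settings[[nm]], nm), ""), collapse = "")
  alias_attr <- if (is.null(alias)) "" else
    sprintf(' mfile_alias="%s"', alias)
  sprintf(
    '<interface><currenttask name="%s" domain="%s" desc="%s" modality="MRI"%s>
       <permanenceofoutput>%d</permanenceofoutput>%s
       <inputstreams>%s</inputstreams>
       <outputstreams>%s</outputstreams>
     </currenttask></interface>',
    name, domain, name, alias_attr, permanence, set_xml,
    paste(sprintf("<stream>%s</stream>", ins), collapse = ""),
    paste(sprintf("<stream>%s</stream>", outs), collapse = ""))
}

make_iface <- function(name, domain, ins = character(0),
                       outs = character(0), settings = list(),
                       permanence = 1L, alias = NULL) {
  parse_module_interface(iface_xml(name, domain, ins, outs, settings,
                                   permanence, alias))
}

linear_tasklist <- function(names) {
  parse_tasklist(paste0("main:\n",
                        paste(sprintf("  - name: %s", names),
                              collapse = "\n")))
}

abstract_study <- function(subjects = c("S1", "S2"),
                           sessions = c("sess1", "sess2"),
                           root = tempfile("study"), id = "myanalysis") {
  study_description(list(
    analysis_root = root, analysis_id = id, subjects = subjects,
    sessions_per_subject = stats::setNames(
      rep(list(sessions), length(subjects)), subjects)))
}

# ---- independent brute-force oracle for the dependency map ----------------
# Works directly from the stage declarations and the study lists; shares no
# code with resolve_stream_source / build_dependency_map.

oracle_coords <- function(domain, subjects, sessions_per_subject) {
  if (domain == "study") return(list(list(subject = NA, session = NA)))
  if (domain == "subject") {
    return(lapply(subjects, function(s) list(subject = s, session = NA)))
  }
  out <- list()
  for (s in subjects) {
    for (z in sessions_per_subject[[s]]) {
      out[[length(out) + 1L]] <- list(subject = s, session = z)
    }
  }
  out
}

oracle_compatible <- function(a, b) {
  # one coordinate must lie on the path of the other (no sideways link)
  if (!is.na(a$subject) && !is.na(b$subject) && a$subject != b$subject) {
    return(FALSE)
  }
  if (!is.na(a$session) && !is.na(b$session) &&
      (a$session != b$session || a$subject != b$subject)) {
    return(FALSE)
  }
  TRUE
}

oracle_label <- function(name, index, coord) {
  key <- if (is.na(coord$subject)) "study" else if (is.na(coord$session)) {
    coord$subject
  } else paste(coord$subject, coord$session, sep = "/")
  sprintf("%s_%05d@%s", name, index, key)
}

# stages: list of list(name, index, domain, ins, outs); already in order
oracle_dependency_edges <- function(stages, subjects, sessions_per_subject) {
  edges <- character(0)
  for (ti in seq_along(stages)) {
    tgt <- stages[[ti]]
    for (stream in tgt$ins) {
      src <- NULL
      for (si in rev(seq_len(ti - 1L))) {
        if (stream %in% stages[[si]]$outs) { src <- stages[[si]]; break }
      }
      if (is.null(src)) next
      for (tc in oracle_coords(tgt$domain, subjects, sessions_per_subject)) {
        for (sc in oracle_coords(src$domain, subjects,
                                 sessions_per_subject)) {
          if (!oracle_compatible(sc, tc)) next
          edges <- c(edges, paste(
            oracle_label(src$name, src$index, sc),
            oracle_label(tgt$name, tgt$index, tc), stream, sep = " -> "))
        }
      }
    }
  }
  sort(edges)
}

engine_edge_strings <- function(map) {
  sort(vapply(map$edges, function(e)
    paste(e$source, e$target, e$stream, sep = " -> "), ""))
}

# random pipeline whose inputs are always satisfiable
random_pipeline_case <- function(rng_case) {
  set.seed(rng_case)
  n_stages <- sample(2:6, 1)
  pool <- c("a", "b", "c")
  domains <- c("study", "subject", "session")
  stages <- list()
  produced <- character(0)
  counts <- integer(0)
  for (i in seq_len(n_stages)) {
    outs <- sample(pool, sample(1:2, 1))
    ins <- if (length(produced)) {
      unique(sample(produced, sample(0:min(2, length(produced)), 1)))
    } else character(0)
    nm <- paste0("mod", sample(1:4, 1))
    counts[nm] <- (if (nm %in% names(counts)) counts[[nm]] else 0L) + 1L
    stages[[i]] <- list(name = nm, index = unname(counts[nm]),
                        domain = sample(domains, 1),
                        ins = ins, outs = unique(outs))
    produced <- unique(c(produced, outs))
  }
  n_sub <- sample(1:3, 1); n_sess <- sample(1:3, 1)
  subjects <- paste0("S", seq_len(n_sub))
  sessions <- stats::setNames(
    rep(list(paste0("sess", seq_len(n_sess))), n_sub), subjects)
  list(stages = stages, subjects = subjects, sessions = sessions)
}

case_to_engine <- function(case) {
  ifaces <- list()
  invocations <- character(0)
  seen <- character(0)
  for (s in case$stages) {
    if (!s$name %in% seen) {
      seen <- c(seen, s$name)
    }
  }
  # interface per module name: use the declarations of its first occurrence?
  # interfaces are per-name, so give each occurrence a distinct name when
  # declarations differ
  by_occurrence <- list()
  for (i in seq_along(case$stages)) {
    s <- case$stages[[i]]
    key <- sprintf("%s_o%d", s$name, s$index)
    by_occurrence[[key]] <- s
  }
  # rename each occurrence to a unique module id so ins/outs can differ,
  # then map oracle labels accordingly
  stages2 <- list()
  ifaces <- list()
  for (i in seq_along(case$stages)) {
    s <- case$stages[[i]]
    uid <- sprintf("%s_o%d", s$name, s$index)
    ifaces[[uid]] <- make_iface(uid, s$domain, s$ins, s$outs)
    stages2[[i]] <- list(name = uid, index = 1L, domain = s$domain,
                         ins = s$ins, outs = s$outs)
  }
  tl <- linear_tasklist(vapply(stages2, function(s) s$name, ""))
  study <- study_description(list(
    analysis_root = tempfile(), analysis_id = "x",
    subjects = case$subjects, sessions_per_subject = case$sessions))
  list(tasklist = tl, interfaces = ifaces, study = study, stages = stages2)
}

# ---- toy-study helpers ----------------------------------------------------

quiet_run <- function(...) suppressWarnings(run_pipeline(...))

small_config <- function(..., root = tempfile("synth")) {
  args <- list(
    n_subjects = 2L, sessions = "movie", n_scans = 15L,
    shape = c(8L, 8L, 6L), numdummies = 3L, block_on = 3L, block_off = 3L,
    amplitude = 8, noise_sd = 0.5, max_shift = 1L,
    mask_lo = c(4L, 4L, 3L), mask_hi = c(5L, 5L, 4L), root = root)
  args[names(list(...))] <- list(...)
  do.call(synthetic_study_config, args)
}

toy_analysis <- function(study, tasklist = toy_tasklist(), fwhm = 6) {
  an <- new_analysis(tasklist = tasklist, study = study)
  an <- set_parameter(an, "acq_details.numdummies",
                      attr(study, "config")$numdummies)
  if (!is.null(fwhm)) an <- set_tasksetting(an, "smooth", "FWHM", fwhm)
  tr <- read_ground_truth(study, study$subjects[[1]],
                          study$sessions_per_subject[[1]][[1]])
  an <- add_event(an, "first_level", "*", "*", "blocks",
                  unlist(tr$onsets), tr$duration)
  an <- add_contrast(an, "first_level", "*", "sameforallsessions", 1)
  an
}

analysis_trunk_dir_of <- function(study) {
  file.path(study$analysis_root, study$analysis_id)
}

# digest map of the payload files of an analysis tree (volumes, tables,
# text), keyed by path relative to the root; bookkeeping files with
# embedded timestamps and plot bitmaps are excluded
payload_digests <- function(root) {
  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  keep <- grepl("\\.(nii\\.gz|txt|tsv)$", files) & !grepl("^report/", files) &
    !grepl("log_", files)
  files <- files[keep]
  stats::setNames(unname(tools::md5sum(file.path(root, files))), files)
}
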