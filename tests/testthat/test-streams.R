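# Stream resolution and the instance-level dependency map.

fmri_ifaces <- function() {
  list(
    realign = make_iface("realign", "session", ins = "epi",
                         outs = c("realignment_parameter", "meanepi", "epi")),
    tsdiff = make_iface("tsdiff", "session", ins = "epi",
                        outs = "qc_timediff"),
    slicetiming = make_iface("slicetiming", "session", ins = "epi",
                             outs = "epi"),
    import = make_iface("import", "session", outs = "epi"),
    import_structural = make_iface("import_structural", "subject",
                                   outs = "structural"),
    coreg = make_iface("coreg", "session",
                       ins = c("epi", "structural"), outs = "epi"),
    first_level = make_iface("first_level", "subject", ins = "epi",
                             outs = "con"),
    second_level = make_iface("second_level", "study", ins = "con",
                              outs = "group_stats"))
}

test_that("a QC stage that outputs no epi is skipped by the backward search", {
  pipe <- expand_tasklist(linear_tasklist(c("import", "realign", "tsdiff",
                                            "slicetiming")),
                          fmri_ifaces())
  st <- pipe$stages[[4]]
  src <- resolve_stream_source(pipe, st, "epi")
  expect_equal(src$name, "realign")
  expect_equal(attr(src, "source_stream"), "epi")
})

test_that("a fully qualified reference overrides the last producer", {
  tl <- parse_tasklist('
main:
  - name: import
  - name: realign
  - name: slicetiming
    inputs: {epi: import.epi}
')
  pipe <- expand_tasklist(tl, fmri_ifaces())
  src <- resolve_stream_source(pipe, pipe$stages[[3]], "epi")
  expect_equal(src$name, "import")
})

test_that("an unproduced stream is an unconnected-stream error at build time", {
  pipe <- expand_tasklist(linear_tasklist("tsdiff"), fmri_ifaces())
  expect_error(resolve_stream_source(pipe, pipe$stages[[1]], "epi"),
               "tsdiff.*epi", class = "aqueduct_unconnected_stream_error")
  study <- abstract_study()
  expect_error(build_dependency_map(pipe, study),
               class = "aqueduct_unconnected_stream_error")
})

test_that("equal-domain streams connect matching coordinates only", {
  study <- abstract_study(subjects = paste0("S", 1:4),
                          sessions = c("sess1", "sess2"))
  pipe <- expand_tasklist(linear_tasklist(c("import", "realign")),
                          fmri_ifaces())
  map <- build_dependency_map(pipe, study)
  to_realign <- Filter(function(e) grepl("^realign", e$target), map$edges)
  expect_length(to_realign, 8L)  # one per (subject, session)
  tgt <- "realign_00001@S4/sess2"
  in_edges <- Filter(function(e) e$target == tgt, to_realign)
  expect_length(in_edges, 1L)
  expect_equal(in_edges[[1]]$source, "import_00001@S4/sess2")
})

test_that("session-level contrasts fan in to a study-level test (2x2 -> 4 edges)", {
  study <- abstract_study(subjects = c("S1", "S2"),
                          sessions = c("sess1", "sess2"))
  ifaces <- list(
    contrasts = make_iface("contrasts", "session", outs = "con"),
    second_level = make_iface("second_level", "study", ins = "con",
                              outs = "group_stats"))
  pipe <- expand_tasklist(linear_tasklist(c("contrasts", "second_level")),
                          ifaces)
  map <- build_dependency_map(pipe, study)
  fanin <- Filter(function(e) grepl("^second_level", e$target), map$edges)
  expect_length(fanin, 4L)
  expect_equal(length(unique(vapply(fanin, function(e) e$target, ""))), 1L)
})

test_that("a subject-level structural feeds every session of that subject", {
  study <- abstract_study(subjects = "S1", sessions = c("sess1", "sess2"))
  pipe <- expand_tasklist(linear_tasklist(c("import_structural", "import",
                                            "coreg")), fmri_ifaces())
  map <- build_dependency_map(pipe, study)
  struct_edges <- Filter(function(e) e$stream == "structural", map$edges)
  expect_length(struct_edges, 2L)
  expect_equal(unique(vapply(struct_edges, function(e) e$source, "")),
               "import_structural_00001@S1")
})

test_that("no edge ever connects disjoint coordinates", {
  for (seed in 1:40) {
    case <- random_pipeline_case(seed)
    eng <- case_to_engine(case)
    pipe <- expand_tasklist(eng$tasklist, eng$interfaces)
    map <- build_dependency_map(pipe, eng$study)
    for (e in map$edges) {
      a <- map$instance_index[[e$source]]$coordinate
      b <- map$instance_index[[e$target]]$coordinate
      expect_false(coordinate_relation(a, b) == "disjoint")
    }
  }
})

test_that("the engine dependency map equals brute-force enumeration", {
  for (seed in 1:60) {
    case <- random_pipeline_case(seed)
    eng <- case_to_engine(case)
    pipe <- expand_tasklist(eng$tasklist, eng$interfaces)
    map <- build_dependency_map(pipe, eng$study)
    oracle <- oracle_dependency_edges(eng$stages, eng$study$subjects,
                                      eng$study$sessions_per_subject)
    expect_equal(engine_edge_strings(map), oracle, info = seed)
  }
})

test_that("within a branch, resolution uses own stages then the trunk, never a sibling", {
  tl <- parse_tasklist('
main:
  - name: import
  - name: realign
  - branch:
      - analysisid_suffix: _a
        modules: [{name: slicetiming}, {name: tsdiff}]
      - analysisid_suffix: _b
        modules: [{name: tsdiff}]
')
  pipe <- expand_tasklist(tl, fmri_ifaces())
  # branch A's tsdiff sees its own slicetiming
  tsd_a <- pipe$stages[[4]]
  expect_equal(resolve_stream_source(pipe, tsd_a, "epi")$name, "slicetiming")
  # branch B's tsdiff must NOT see branch A's slicetiming: trunk realign wins
  tsd_b <- pipe$stages[[5]]
  expect_equal(tsd_b$name, "tsdiff")
  expect_equal(tsd_b$index, 2L)
  expect_equal(resolve_stream_source(pipe, tsd_b, "epi")$name, "realign")
})

test_that("sideways domain reads are rejected at build time", {
  tree <- domain_tree("diffusion_session")
  ifaces <- list(
    import = parse_module_interface(iface_xml("import", "session",
                                              outs = "epi"), tree = tree),
    dwi_stage = parse_module_interface(
      iface_xml("dwi_stage", "diffusion_session", ins = "epi", outs = "fa"),
      tree = tree))
  pipe <- expand_tasklist(linear_tasklist(c("import", "dwi_stage")), ifaces)
  study <- study_description(list(
    analysis_root = tempfile(), analysis_id = "x", subjects = "S1",
    sessions_per_subject = list(S1 = "movie"),
    extra_sessions = list(diffusion_session = list(S1 = "dwi"))))
  expect_error(build_dependency_map(pipe, study, tree),
               class = "aqueduct_illegal_read_error")
})

test_that("outputs register with digests and inputs place them unchanged", {
  study <- abstract_study(subjects = "S1", sessions = "movie")
  ifaces <- fmri_ifaces()
  pipe <- expand_tasklist(linear_tasklist(c("import", "slicetiming")),
                          ifaces)
  map <- build_dependency_map(pipe, study)
  src_inst <- map$instances[[1]][[1]]
  tgt_inst <- map$instances[[2]][[1]]
  dir.create(src_inst$dir, recursive = TRUE)
  f <- file.path(src_inst$dir, "epi.nii.gz")
  writeLines("payload-bytes", f)
  recs <- register_outputs(src_inst, list(epi = f), "epi")
  expect_named(recs, "epi")
  expect_equal(recs$epi$files[[1]]$digest, unname(tools::md5sum(f)))
  # scratch files not in any stream are not registered
  writeLines("scratch", file.path(src_inst$dir, "scratch.txt"))
  recs2 <- register_outputs(src_inst, list(epi = f), "epi")
  expect_named(recs2, "epi")
  # placement preserves digests end-to-end
  edges_in <- Filter(function(e) e$target == instance_label(tgt_inst),
                     map$edges)
  manifest <- place_inputs(tgt_inst, edges_in,
                           stats::setNames(list(recs),
                                           instance_label(src_inst)),
                           map$instance_index)
  placed <- file.path(tgt_inst$dir, manifest$epi[[1]]$files[[1]]$path)
  expect_equal(unname(tools::md5sum(placed)), unname(tools::md5sum(f)))
  # an instance requesting nothing gets an empty manifest but a directory
  lone <- map$instances[[1]][[1]]
  lone$dir <- file.path(tempfile(), "lone")
  m0 <- place_inputs(lone, list(), list(), map$instance_index)
  expect_length(m0, 0L)
  expect_true(dir.exists(lone$dir))
})

test_that("declared-but-missing outputs and out-of-directory writes are errors", {
  study <- abstract_study(subjects = "S1", sessions = "movie")
  pipe <- expand_tasklist(linear_tasklist("import"), fmri_ifaces())
  map <- build_dependency_map(pipe, study)
  inst <- map$instances[[1]][[1]]
  dir.create(inst$dir, recursive = TRUE)
  expect_error(register_outputs(inst, list(), "epi"),
               class = "aqueduct_missing_output_error")
  stray <- tempfile()
  writeLines("outside", stray)
  expect_error(register_outputs(inst, list(epi = stray), "epi"),
               class = "aqueduct_illegal_write_error")
})

test_that("fan-in inputs are placed in per-source subfolders with full provenance", {
  study <- abstract_study(subjects = c("S1", "S2"),
                          sessions = c("sess1", "sess2"))
  ifaces <- list(
    contrasts = make_iface("contrasts", "session", outs = "con"),
    second_level = make_iface("second_level", "study", ins = "con",
                              outs = "group_stats"))
  pipe <- expand_tasklist(linear_tasklist(c("contrasts", "second_level")),
                          ifaces)
  map <- build_dependency_map(pipe, study)
  records <- list()
  for (inst in map$instances[[1]]) {
    dir.create(inst$dir, recursive = TRUE)
    f <- file.path(inst$dir, "con.nii.gz")
    writeLines(paste("con for", instance_label(inst)), f)
    records[[instance_label(inst)]] <-
      register_outputs(inst, list(con = f), "con")
  }
  tgt <- map$instances[[2]][[1]]
  edges_in <- Filter(function(e) e$target == instance_label(tgt), map$edges)
  manifest <- place_inputs(tgt, edges_in, records, map$instance_index)
  expect_length(manifest$con, 4L)
  placed <- vapply(manifest$con, function(s) s$files[[1]]$path, "")
  expect_setequal(dirname(placed),
                  c("src_S1_sess1", "src_S1_sess2", "src_S2_sess1",
                    "src_S2_sess2"))
  expect_true(all(file.exists(file.path(tgt$dir, placed))))
})
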