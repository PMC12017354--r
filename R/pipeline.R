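# End-to-end orchestration: simulate -> preprocess -> features ->
# event-lock -> stats -> report, plus dataset I/O and validation.

#' Analyze one subject end to end
#'
#' Generates (or accepts) the subject's modalities and returns language
#' and prosody features, per-channel activation, and the target-channel
#' event window set.
#'
#' @param subject One row of [generate_cohort()].
#' @param spec The [cohort_spec()].
#' @param lexicon Word -> category map used for tagging.
#' @param window_s Event window length (s).
#' @return List with `language`, `prosody`, `activation` (named vector),
#'   `windows` (target-channel `event_window_set`), `excluded` flag.
#' @export
analyze_subject <- function(subject, spec, lexicon = default_lexicon(),
                            window_s = 10) {
  transcript <- generate_transcript(subject, spec)
  # the analysis path relies on lexicon tags, not generator labels
  labelled <- tag_tokens_lexicon(
    transcript[, c("token", "onset_s", "offset_s")], lexicon)
  lang <- language_features(labelled)
  pros <- prosody_features(generate_prosody(subject, spec))
  rec <- generate_fnirs(subject, transcript, spec)
  hemo <- preprocess_recording(rec)
  onsets <- rec$segments$narration[1] +
    labelled$onset_s[labelled$category == "negative"]
  out <- list(language = lang, prosody = pros, excluded = FALSE)
  act <- try(subject_activation(hemo, onsets, window_s = window_s),
             silent = TRUE)
  if (inherits(act, "try-error")) {
    out$excluded <- TRUE
    out$activation <- rep(NA_real_, spec$session$n_channels)
    out$windows <- NULL
  } else {
    out$activation <- act
    out$windows <- suppressMessages(
      extract_windows(hemo, spec$session$target_channel, onsets, window_s))
  }
  out
}

#' Run the full cohort analysis
#'
#' Simulates the cohort, preprocesses every recording, extracts
#' language/prosody features, event-locks the target channel, tests all
#' channels with Mann-Whitney + BH-FDR, characterizes the group-average
#' time courses, and runs the normality-gated group comparisons.
#'
#' @param spec A [cohort_spec()].
#' @param lexicon Word -> category map (default the packaged lexicon).
#' @param window_s Event window length in seconds.
#' @return List of class `cohort_analysis` with elements `subjects`,
#'   `features`, `activation_table`, `channel_tests`, `grand_average`
#'   (per group), `profiles` (per group [characterize_timecourse()]),
#'   `group_comparisons`, `capsD_correlation`, `excluded_subjects`.
#' @export
run_cohort_analysis <- function(spec, lexicon = default_lexicon(),
                                window_s = 10) {
  subjects <- generate_cohort(spec)
  nch <- spec$session$n_channels
  feat <- list(); act_rows <- list()
  wsets <- list(PTSD = list(), TEC = list())
  excluded <- character(0)
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    res <- analyze_subject(s, spec, lexicon, window_s)
    feat[[i]] <- cbind(s[, c("id", "group")], res$language, res$prosody)
    if (res$excluded) {
      excluded <- c(excluded, s$id)
      next
    }
    act_rows[[length(act_rows) + 1L]] <-
      data.frame(subject = s$id, group = s$group, channel = seq_len(nch),
                 activation = unname(res$activation))
    wsets[[s$group]][[length(wsets[[s$group]]) + 1L]] <- res$windows
  }
  features <- do.call(rbind, feat)
  activation_table <- do.call(rbind, act_rows)
  channel_tests <- group_channel_test(activation_table)
  ga <- lapply(wsets, grand_average)
  profiles <- lapply(ga, characterize_timecourse, fs_hz = spec$session$fs_hz)
  comparisons <- group_feature_comparisons(subjects, features)
  pts <- merge(subjects[subjects$group == "PTSD", c("id", "capsD")],
               features[features$group == "PTSD", c("id", "neg_pct")])
  capsD_cor <- tryCatch(gated_correlation(pts$neg_pct, pts$capsD),
                        error = function(e)
                          list(method = NA_character_, r = NA_real_,
                               p = NA_real_))
  structure(list(spec = spec, subjects = subjects, features = features,
                 activation_table = activation_table,
                 channel_tests = channel_tests, grand_average = ga,
                 profiles = profiles, group_comparisons = comparisons,
                 capsD_correlation = capsD_cor,
                 excluded_subjects = excluded),
            class = "cohort_analysis")
}

#' Normality-gated comparisons of demographic and feature variables
#'
#' @param subjects [generate_cohort()] output.
#' @param features Per-subject feature table (columns `id`, `group`,
#'   numeric features).
#' @return data.frame of [auto_compare()] rows.
#' @export
group_feature_comparisons <- function(subjects, features) {
  px <- subjects$group == "PTSD"
  rows <- list(
    auto_compare(subjects$age[px], subjects$age[!px], "continuous",
                 variable = "age"),
    auto_compare(subjects$sex[px], subjects$sex[!px], "categorical",
                 variable = "sex"),
    auto_compare(subjects$education[px], subjects$education[!px],
                 "continuous", variable = "education"))
  fx <- features$group == "PTSD"
  for (v in c("honore_r", "neg_pct", "pos_pct", "factual_pct",
              "mean_pitch_hz", "semitone_change", "n_pauses")) {
    a <- features[[v]][fx]; b <- features[[v]][!fx]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    rows[[length(rows) + 1L]] <- auto_compare(a, b, "continuous",
                                              variable = v)
  }
  do.call(rbind, rows)
}

# ---- dataset I/O ---------------------------------------------------------

#' Write a synthetic dataset to disk
#'
#' Emits the generator's plain-text interchange formats: `subjects.tsv`,
#' `transcript_<id>.tsv`, `prosody_<id>.csv`, `od_<id>.csv` (long
#' format), `session.json` and `lexicon.tsv`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param ids Subject ids to write (default: first PTSD and first TEC
#'   subject; optical CSVs are large).
#' @param write_od Write optical-density CSVs (default `TRUE`).
#' @return Invisibly, the list of files written.
#' @export
write_dataset <- function(spec, dir, ids = NULL, write_od = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- generate_cohort(spec)
  if (is.null(ids)) ids <- subjects$id[c(1, spec$n_ptsd + 1)]
  files <- character(0)
  p <- function(...) file.path(dir, sprintf(...))
  utils::write.table(subjects, p("subjects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c(files, p("subjects.tsv"))
  lex <- default_lexicon()
  utils::write.table(data.frame(word = names(lex), category = unname(lex)),
                     p("lexicon.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files <- c(files, p("lexicon.tsv"))
  ses <- spec$session
  geo <- .rec_geometry(ses)
  jsonlite::write_json(
    list(fs_hz = ses$fs_hz, n_channels = ses$n_channels,
         target_channel = ses$target_channel,
         wavelengths_nm = ses$wavelengths_nm,
         sd_separation_cm = ses$sd_separation_cm,
         edge_buffer_s = ses$edge_buffer_s,
         segments = geo$segments),
    p("session.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, p("session.json"))
  for (id in ids) {
    s <- subjects[subjects$id == id, ]
    tr <- generate_transcript(s, spec)
    write_transcript(tr, p("transcript_%s.tsv", id))
    pr <- generate_prosody(s, spec)
    utils::write.csv(pr, p("prosody_%s.csv", id), row.names = FALSE)
    files <- c(files, p("transcript_%s.tsv", id), p("prosody_%s.csv", id))
    if (write_od) {
      rec <- generate_fnirs(s, tr, spec)
      n <- dim(rec$od)[1]
      t_s <- rep((seq_len(n) - 1) / ses$fs_hz, times = 2 * ses$n_channels)
      long <- data.frame(
        t_s = t_s,
        channel = rep(rep(seq_len(ses$n_channels), each = n), times = 2),
        wavelength_nm = rep(ses$wavelengths_nm, each = n * ses$n_channels),
        delta_od = c(rec$od))
      utils::write.csv(long, p("od_%s.csv", id), row.names = FALSE)
      files <- c(files, p("od_%s.csv", id))
    }
  }
  invisible(files)
}

#' Read an optical recording written by [write_dataset()]
#'
#' @param od_path Long-format OD CSV.
#' @param session_path `session.json` sidecar.
#' @return An `optical_recording` list usable by
#'   [preprocess_recording()].
#' @export
read_optical_csv <- function(od_path, session_path) {
  ses <- jsonlite::read_json(session_path, simplifyVector = TRUE)
  long <- utils::read.csv(od_path)
  n <- length(unique(long$t_s))
  od <- array(NA_real_, c(n, ses$n_channels, 2))
  for (w in 1:2) {
    sub <- long[long$wavelength_nm == ses$wavelengths_nm[w], ]
    od[, , w] <- matrix(sub$delta_od, n, ses$n_channels)
  }
  structure(list(od = od, fs_hz = ses$fs_hz,
                 segments = lapply(ses$segments, as.numeric),
                 wavelengths_nm = ses$wavelengths_nm,
                 sd_separation_cm = ses$sd_separation_cm,
                 target_channel = ses$target_channel),
            class = "optical_recording")
}

#' Validate a dataset directory
#'
#' Schema checks for the interchange formats: required columns,
#' strictly increasing transcript onsets, uniform prosody frame
#' spacing, consistent OD series lengths, contiguous session segments.
#'
#' @param dir Dataset directory.
#' @return data.frame of violations (zero rows when valid) with columns
#'   `file`, `check`, `detail`.
#' @export
validate_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  bad <- list()
  note <- function(file, check, detail)
    bad[[length(bad) + 1L]] <<- data.frame(file = file, check = check,
                                           detail = detail)
  safe <- function(f, file, expr) {
    tryCatch(expr, error = function(e) note(file, "io_error",
                                            conditionMessage(e)))
  }
  sj <- file.path(dir, "session.json")
  if (file.exists(sj)) {
    safe("session", sj, {
      ses <- jsonlite::read_json(sj, simplifyVector = TRUE)
      segs <- ses$segments
      ord <- c("rest", "digits1", "narration", "digits2")
      if (!all(ord %in% names(segs))) {
        note(sj, "segments", "missing segment labels")
      } else {
        b <- vapply(segs[ord], function(s) as.numeric(s),
                    numeric(2))
        if (any(abs(b[2, -4] - b[1, -1]) > 1e-9))
          note(sj, "segments", "segments not contiguous")
      }
    })
  } else note(sj, "missing", "session.json not found")
  for (f in list.files(dir, "^transcript_.*\\.tsv$", full.names = TRUE)) {
    safe("transcript", f, {
      tr <- utils::read.delim(f)
      if (!all(c("token", "onset_s", "offset_s") %in% names(tr)))
        note(f, "schema", "missing transcript columns")
      else if (any(diff(tr$onset_s) <= 0))
        note(f, "onsets", sprintf("non-increasing onset at row %d",
                                  which(diff(tr$onset_s) <= 0)[1] + 1L))
    })
  }
  for (f in list.files(dir, "^prosody_.*\\.csv$", full.names = TRUE)) {
    safe("prosody", f, {
      pr <- utils::read.csv(f)
      if (!all(c("t_s", "f0_hz", "voiced") %in% names(pr)))
        note(f, "schema", "missing prosody columns")
      else {
        dt <- diff(pr$t_s)
        if (max(abs(dt - stats::median(dt))) > 1e-6)
          note(f, "frames", "non-uniform frame spacing")
      }
    })
  }
  for (f in list.files(dir, "^od_.*\\.csv$", full.names = TRUE)) {
    safe("od", f, {
      od <- utils::read.csv(f)
      if (!all(c("t_s", "channel", "wavelength_nm", "delta_od") %in%
               names(od))) {
        note(f, "schema", "missing OD columns")
      } else {
        lens <- table(paste(od$channel, od$wavelength_nm))
        if (length(unique(as.integer(lens))) != 1)
          note(f, "length", "per-channel series lengths differ")
      }
    })
  }
  if (length(bad) == 0)
    data.frame(file = character(0), check = character(0),
               detail = character(0))
  else do.call(rbind, bad)
}

# ---- configuration and pipeline runner ----------------------------------

#' Default run configuration
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return Nested list serializable to YAML with [write_config()].
#' @export
default_config <- function(seed = 1, outdir = "narrafnirs_out") {
  list(seed = seed, outdir = outdir,
       cohort = list(n_ptsd = 35, n_tec = 37),
       analysis = list(window_s = 10),
       report = list(digits = 3))
}

#' Read / write a YAML run configuration
#' @param path YAML file path.
#' @param config Configuration list (for writing).
#' @return `read_config` returns the configuration list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the pipeline from a configuration
#'
#' Executes simulate -> preprocess -> features -> event-lock -> stats,
#' writes the report tables, and returns a manifest with per-file
#' checksums. Outputs are pure functions of (config, seed).
#'
#' @param config Configuration list (see [default_config()]) or path to
#'   a YAML file.
#' @return The manifest (invisibly): file list with md5 checksums, the
#'   seed, and per-stage log.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  spec <- cohort_spec(n_ptsd = config$cohort$n_ptsd,
                      n_tec = config$cohort$n_tec,
                      seed = config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stamp <- function(stage, note) log[[stage]] <<- note
  stamp("simulate", sprintf("cohort %d + %d, seed %d", spec$n_ptsd,
                            spec$n_tec, spec$seed))
  res <- run_cohort_analysis(spec, window_s = config$analysis$window_s)
  stamp("analyze", sprintf("%d subjects analyzed, %d excluded",
                           nrow(res$subjects),
                           length(res$excluded_subjects)))
  p <- function(f) file.path(config$outdir, f)
  utils::write.table(res$features, p("language_features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$activation_table, p("activation_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$channel_tests, p("channel_tests.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$group_comparisons, p("group_comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(profiles = lapply(res$profiles, unclass),
         capsD_correlation = res$capsD_correlation,
         grand_average = res$grand_average),
    p("timecourse_profiles.json"), auto_unbox = TRUE, digits = NA)
  files <- c("language_features.tsv", "activation_table.tsv",
             "channel_tests.tsv", "group_comparisons.tsv",
             "timecourse_profiles.json")
  stamp("report", sprintf("%d files written", length(files)))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("narrafnirs")),
    files = data.frame(file = files,
                       md5 = unname(tools::md5sum(vapply(files, p, "")))),
    log = log)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
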