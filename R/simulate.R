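#' Configuration for synthetic surface decoding datasets
#'
#' Generates multi-subject, multi-run surface time series with
#' condition-specific multivariate patterns confined to a known geodesic
#' patch, plus matching paradigm files. Defaults give the desk-scale study
#' conditions used throughout the test suite: a 2,562-vertex pattern sphere
#' (`high_div = 16`) decoded on a 162-vertex searchlight sphere
#' (`low_div = 4`), 8 subjects, 3 runs, 2 conditions, 10 trials per condition
#' per run, TR 1 s, trial patterns sampled 7 s after onset, and an
#' information patch of 0.25 rad around a fixed downsampled vertex with
#' pattern-to-noise amplitude ratio 1.5. The full-resolution scale
#' (`high_div = 128`, `low_div = 40`) is available by overriding the
#' divisions.
#'
#' @param high_div,low_div icosahedron edge divisions of the pattern and
#'   searchlight spheres.
#' @param n_subjects,n_runs,trials_per_condition_per_run design sizes.
#' @param conditions non-zero condition codes (>= 2).
#' @param tr repetition time, seconds.
#' @param timepoint trial sampling latency after onset, seconds.
#' @param patch_center downsampled vertex index at the patch center.
#' @param patch_radius patch angular radius, radians.
#' @param effect_size condition-pattern amplitude as a multiple of
#'   `noise_sd` (when `noise_sd = 0` the pattern sd is `effect_size`
#'   itself, giving noise-free separable data).
#' @param noise_sd i.i.d. Gaussian noise sd.
#' @param baseline constant added to every vertex value.
#' @param iti onset-to-onset interval, seconds.
#' @param first_onset first trial onset, seconds.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(high_div = 16L, low_div = 4L, n_subjects = 8L,
                       n_runs = 3L, trials_per_condition_per_run = 10L,
                       conditions = c(1L, 2L), tr = 1, timepoint = 7,
                       patch_center = 1L, patch_radius = 0.25,
                       effect_size = 1.5, noise_sd = 1, baseline = 0,
                       iti = 12, first_onset = 8, seed = 1L) {
  if (length(conditions) < 2L || any(conditions == 0L))
    sl_stop("need >= 2 non-zero condition codes", "surflight_invalid_parameter")
  if (any(c(high_div, low_div, n_subjects, n_runs,
            trials_per_condition_per_run) < 1) || patch_radius <= 0)
    sl_stop("counts must be positive and patch_radius > 0",
            "surflight_invalid_parameter")
  structure(list(high_div = as.integer(high_div), low_div = as.integer(low_div),
                 n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
                 trials_per_condition_per_run = as.integer(trials_per_condition_per_run),
                 conditions = as.integer(conditions), tr = tr,
                 timepoint = timepoint, patch_center = as.integer(patch_center),
                 patch_radius = patch_radius, effect_size = effect_size,
                 noise_sd = noise_sd, baseline = baseline, iti = iti,
                 first_onset = first_onset, seed = as.integer(seed)),
            class = "sim_config")
}

# high-res vertices within the ground-truth patch
patch_vertices <- function(config, high, low) {
  ctr <- low$vertices[config$patch_center, ]
  which(angular_distance(high$vertices, ctr) <= config$patch_radius)
}

#' Simulate one subject's runs
#'
#' Per run: a paradigm with a randomized condition order (balanced trial
#' counts), and a vertex-wise time series of i.i.d. Gaussian noise. At each
#' trial's sampled volume (`round((onset + timepoint)/tr)`, the volume
#' [extract_trials()] will read) the patch vertices additionally carry that
#' condition's spatial pattern. Per-condition patterns are drawn once per
#' subject — fine-grained patterns are subject-specific while decodability
#' is shared, the usual MVPA assumption.
#'
#' @param config a [sim_config()].
#' @param subject_seed RNG seed for this subject.
#' @param high,low sphere meshes; built from the config when omitted
#'   (pass them in when simulating several subjects).
#' @return List with `runs` (list of [run_series()]), `paradigms` (list of
#'   event data frames), and `truth`
#'   (`list(patch_vertices, patterns)` where `patterns` is a
#'   `conditions x patch` matrix).
#' @export
simulate_subject <- function(config, subject_seed, high = NULL, low = NULL) {
  if (is.null(high)) high <- subdivide(base_icosahedron(), config$high_div)
  if (is.null(low)) low <- subdivide(base_icosahedron(), config$low_div)
  vh <- nrow(high$vertices)
  patch <- patch_vertices(config, high, low)
  set.seed(subject_seed)
  pat_sd <- if (config$noise_sd > 0) config$effect_size * config$noise_sd
            else config$effect_size
  k <- length(config$conditions)
  patterns <- matrix(rnorm(k * length(patch), sd = pat_sd), k)

  n_trials <- config$trials_per_condition_per_run * k
  onsets <- config$first_onset + (seq_len(n_trials) - 1L) * config$iti
  idx0 <- round((onsets + config$timepoint) / config$tr)
  n_vol <- max(idx0) + 6L
  runs <- vector("list", config$n_runs)
  paradigms <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    codes <- sample(rep(config$conditions, config$trials_per_condition_per_run))
    data <- matrix(rnorm(n_vol * vh, sd = config$noise_sd), n_vol, vh) +
      config$baseline
    for (t in seq_len(n_trials)) {
      ci <- match(codes[t], config$conditions)
      data[idx0[t] + 1L, patch] <- data[idx0[t] + 1L, patch] + patterns[ci, ]
    }
    paradigms[[r]] <- data.frame(onset = onsets, code = codes,
                                 duration = 2, weight = 1)
    runs[[r]] <- run_series(data, tr = config$tr,
                            run_id = sprintf("%03d", r))
  }
  list(runs = runs, paradigms = paradigms,
       truth = list(patch_vertices = patch, patterns = patterns))
}

#' Simulate a full multi-subject dataset
#'
#' Subject seeds are `config$seed * 1000 + subject index`, so the dataset is
#' reproducible from the master seed and any subject can be regenerated
#' independently.
#'
#' @param config a [sim_config()].
#' @param high,low sphere meshes; built from the config when omitted.
#' @return List of per-subject [simulate_subject()] results, with the
#'   config as attribute `config`.
#' @export
simulate_dataset <- function(config, high = NULL, low = NULL) {
  if (is.null(high)) high <- subdivide(base_icosahedron(), config$high_div)
  if (is.null(low)) low <- subdivide(base_icosahedron(), config$low_div)
  subjects <- lapply(seq_len(config$n_subjects), function(s)
    simulate_subject(config, subject_seed = config$seed * 1000L + s,
                     high = high, low = low))
  attr(subjects, "config") <- config
  subjects
}

#' Write a simulated dataset as a subjects directory tree
#'
#' Emulates the conventional study layout: per-subject folders sharing a
#' prefix, each with `bold/<run>/` subfolders holding the surface-encoded
#' NIfTI series and the paradigm file, readable by [read_surface_series()]
#' and [read_paradigm()].
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir target directory.
#' @param prefix subject folder prefix (default `"Sub"`).
#' @param force overwrite a non-empty target?
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "Sub", force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    sl_stop(sprintf("'%s' exists and is not empty (use force = TRUE)", dir),
            "surflight_io_error")
  for (s in seq_along(dataset)) {
    sub <- dataset[[s]]
    for (r in seq_along(sub$runs)) {
      rdir <- file.path(dir, sprintf("%s%02d", prefix, s), "bold",
                        sprintf("%03d", r))
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      write_surface_series(sub$runs[[r]],
                           file.path(rdir, "series.fsaverage.lh.nii.gz"))
      write_paradigm(sub$paradigms[[r]], file.path(rdir, "paradigm.par"))
    }
  }
  invisible(dir)
}

#' Read a subjects directory tree back into trial sets
#'
#' Discovers subject folders by prefix and run folders under `bold/`, reads
#' each run's series and paradigm, and extracts trial patterns at the given
#' latency.
#'
#' @param dir subjects directory ([write_dataset()] layout).
#' @param prefix subject folder prefix.
#' @param timepoint sampling latency after onset, seconds.
#' @param expected_vertices template vertex count check (optional).
#' @param tr repetition-time override (optional; default from file headers).
#' @return List (one element per subject) of combined `trial_set`s.
#' @export
read_dataset <- function(dir, prefix = "Sub", timepoint = 7,
                         expected_vertices = NULL, tr = NULL) {
  subs <- sort(list.files(dir, pattern = paste0("^", prefix)))
  if (length(subs) == 0L)
    sl_stop(sprintf("no '%s*' subject folders under '%s'", prefix, dir),
            "surflight_io_error")
  lapply(subs, function(sd) {
    rdirs <- sort(list.dirs(file.path(dir, sd, "bold"), recursive = FALSE))
    sets <- lapply(rdirs, function(rd) {
      series <- list.files(rd, pattern = "\\.nii(\\.gz)?$|\\.func\\.gii$",
                           full.names = TRUE)[1]
      par <- list.files(rd, pattern = "\\.par$", full.names = TRUE)[1]
      if (is.na(series) || is.na(par))
        sl_stop(sprintf("run folder '%s' lacks a series or paradigm file", rd),
                "surflight_io_error")
      run <- read_surface_series(series, expected_vertices, tr = tr,
                                 run_id = basename(rd))
      extract_trials(run, read_paradigm(par), timepoint)
    })
    bind_trials(sets)
  })
}
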