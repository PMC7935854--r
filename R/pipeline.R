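#' Read a pipeline configuration
#'
#' Configurations are plain named lists, storable as YAML or JSON. Values are
#' validated by the stage that consumes them.
#'
#' @param config A named list, or a path to a `.yaml`/`.yml`/`.json` file.
#' @return A named list.
#' @export
read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop("unsupported config format: ", ext))
  }
  stopifnot(is.list(config))
  config
}

#' Validate a trial table against the pipeline schema
#'
#' Checks the columns and invariants the analysis stages rely on and returns
#' an itemized report; `error = TRUE` (default) raises the report instead.
#'
#' @param trials Trial tibble.
#' @param error Raise on violations?
#' @return Character vector of violations (empty if valid), invisibly when
#'   erroring is enabled.
#' @export
validate_trials <- function(trials, error = TRUE) {
  problems <- character()
  need <- c("trial_id", "condition", "stream_mean", paste0("diff_", 1:6))
  miss <- setdiff(need, names(trials))
  if (length(miss))
    problems <- c(problems, paste("missing columns:",
                                  paste(miss, collapse = ", ")))
  if ("condition" %in% names(trials)) {
    if (!all(trials$condition %in% c("WM", "control1", "control2")))
      problems <- c(problems, "condition outside {WM, control1, control2}")
    wm <- trials$condition == "WM"
    if ("wm_color" %in% names(trials)) {
      if (any(wm & is.na(trials$wm_color)))
        problems <- c(problems, "WM trials lack a wm_color")
      if (any(trials$condition == "control1" & !is.na(trials$wm_color)))
        problems <- c(problems, "control1 trials carry a wm_color")
    }
  }
  if ("choice" %in% names(trials) &&
      !all(trials$choice %in% c("blue", "red", NA)))
    problems <- c(problems, "choice outside {blue, red}")
  if (error && length(problems))
    stop("trial table validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  if (error) invisible(problems) else problems
}

stage_names <- c("simulate", "fit-maps", "null-map", "group-test", "align",
                 "tune", "stability", "psychometrics", "crosstalk", "report")

write_manifest <- function(out_dir, stage, config, seed, inputs, outputs) {
  man <- list(
    stage = stage,
    config = config,
    seed = seed,
    package_version = as.character(packageVersion("wmstream")),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs))
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

read_run_trials <- function(dir) {
  f <- file.path(dir, "trials.csv")
  if (!file.exists(f)) stop("missing upstream artifact: ", f)
  tr <- tibble::as_tibble(read.csv(f))
  validate_trials(tr)
  tr
}

read_run_dots <- function(dir) {
  f <- file.path(dir, "dots.csv")
  if (!file.exists(f)) stop("missing upstream artifact: ", f)
  tibble::as_tibble(read.csv(f))
}

read_run_maps <- function(dir, pattern = "^maps_") {
  fs <- list.files(dir, pattern, full.names = TRUE)
  if (!length(fs)) stop("missing upstream artifact: weight maps in ", dir)
  lapply(fs, readRDS)
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis stages with file interfaces and a JSON manifest
#' (md5 content hashes of inputs and outputs, configuration, seed, package
#' version). Trial tables travel as CSV, fitted map objects as RDS
#' containers, statistics as tidy CSV. Rerunning a stage with identical
#' inputs and seed reproduces its outputs.
#'
#' Stages: `simulate` (cohort generation), `fit-maps` (per-subject weight
#' maps M), `null-map` (per-subject unbiased maps M* and difference maps),
#' `group-test` (FDR-masked group map over difference maps), `align`
#' (rotational alignment; writes aligned trial table and exclusion log),
#' `tune` (angular tuning), `stability` (inter-display correlations),
#' `psychometrics` (per-subject choice-model coefficients and weighting
#' functions), `crosstalk` (recall regressions, residual correlation,
#' precision), `report` (aggregate the run's tidy outputs).
#'
#' @param stage One of the stage names above.
#' @param config Configuration list or YAML/JSON path; fields with package
#'   defaults may be omitted.
#' @param input Directory holding the upstream artifacts (defaults to
#'   `out_dir`).
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of written file paths (including the manifest).
#' @export
run_stage <- function(stage, config = list(), input = out_dir,
                      out_dir = ".") {
  stage <- match.arg(stage, stage_names)
  config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- function(name, default) config[[name]] %||% default
  seed <- cfg("seed", NULL)
  grid_size <- cfg("grid_size", 61L)
  ridge <- cfg("ridge", 1e-3)
  inputs <- character()
  outputs <- character()

  if (stage == "simulate") {
    obs_cfg <- cfg("observer", list())
    obs <- do.call(observer_params, obs_cfg)
    coh <- simulate_cohort(
      n_subjects = cfg("n_subjects", 1L),
      n_trials = cfg("n_trials", 240L),
      observer = obs,
      condition = cfg("condition", "WM"),
      group = cfg("group", "averaging"),
      stream_means = cfg("stream_means", c(-4, 4)),
      shift = cfg("shift", 0),
      include_dots = cfg("include_dots", TRUE),
      seed = seed
    )
    f1 <- file.path(out_dir, "trials.csv")
    write.csv(coh$trials, f1, row.names = FALSE)
    outputs <- f1
    if (!is.null(coh$dots)) {
      f2 <- file.path(out_dir, "dots.csv")
      write.csv(coh$dots, f2, row.names = FALSE)
      outputs <- c(outputs, f2)
    }
  } else if (stage %in% c("fit-maps", "null-map")) {
    trials <- read_run_trials(input)
    dots <- read_run_dots(input)
    inputs <- file.path(input, c("trials.csv", "dots.csv"))
    aligned <- cfg("aligned", FALSE)
    if (aligned) {
      fa <- file.path(input, "trials_aligned.csv")
      if (!file.exists(fa)) stop("missing upstream artifact: ", fa)
      trials <- tibble::as_tibble(read.csv(fa))
      inputs <- c(inputs, fa)
    }
    prefix <- if (stage == "fit-maps") "maps_" else "nullmaps_"
    for (s in unique(trials$subject)) {
      tr <- trials[trials$subject == s, ]
      dt <- dots[dots$subject == s & dots$trial_id %in% tr$trial_id, ]
      rot <- if (aligned) tr$rotation else NULL
      m <- if (stage == "fit-maps") {
        fit_weight_maps(tr, dt, grid_size, cfg("kernel_width", NULL),
                        ridge, rotation = rot, subject = s)
      } else {
        pf <- fit_choice_model(tr)
        fit_null_maps(tr, dt, pf, grid_size, cfg("kernel_width", NULL),
                      ridge, rotation = rot, subject = s)
      }
      f <- file.path(out_dir, sprintf("%ssubject%03d.rds", prefix, s))
      saveRDS(m, f)
      outputs <- c(outputs, f)
    }
  } else if (stage == "group-test") {
    Ms <- read_run_maps(input, "^maps_subject")
    Ns <- read_run_maps(input, "^nullmaps_subject")
    inputs <- c(list.files(input, "^maps_subject", full.names = TRUE),
                list.files(input, "^nullmaps_subject", full.names = TRUE))
    stopifnot(length(Ms) == length(Ns))
    deltas <- Map(map_difference, Ms, Ns)
    gt <- group_map_test(deltas, alpha = cfg("alpha", 0.05),
                         collapse = cfg("collapse", TRUE))
    f1 <- file.path(out_dir, "group_test.rds")
    saveRDS(gt, f1)
    f2 <- file.path(out_dir, "group_test.csv")
    write.csv(tidy(gt), f2, row.names = FALSE)
    outputs <- c(f1, f2)
  } else if (stage == "align") {
    trials <- read_run_trials(input)
    inputs <- file.path(input, "trials.csv")
    out_t <- list(); out_e <- list()
    for (s in unique(trials$subject)) {
      al <- align_trials(trials[trials$subject == s, ],
                         reference = cfg("reference", 45),
                         exclusion_px = cfg("exclusion_px", 40))
      out_t[[length(out_t) + 1]] <- al$trials
      out_e[[length(out_e) + 1]] <- al$excluded
    }
    f1 <- file.path(out_dir, "trials_aligned.csv")
    write.csv(dplyr::bind_rows(out_t), f1, row.names = FALSE)
    f2 <- file.path(out_dir, "exclusions.csv")
    write.csv(dplyr::bind_rows(out_e), f2, row.names = FALSE)
    outputs <- c(f1, f2)
    message(sprintf("align: excluded %d of %d trials",
                    nrow(dplyr::bind_rows(out_e)), nrow(trials)))
  } else if (stage == "tune") {
    Ms <- read_run_maps(input, "^deltamaps_|^maps_subject")
    inputs <- list.files(input, "^deltamaps_|^maps_subject",
                         full.names = TRUE)
    tu <- angular_tuning(Ms, n_segments = cfg("n_segments", 11L),
                         reference = cfg("reference", 45))
    f1 <- file.path(out_dir, "tuning_profile.csv")
    write.csv(tu$profile, f1, row.names = FALSE)
    outputs <- f1
    if (!is.null(tu$test)) {
      f2 <- file.path(out_dir, "tuning_test.csv")
      write.csv(tu$test, f2, row.names = FALSE)
      outputs <- c(outputs, f2)
    }
  } else if (stage == "stability") {
    Ms <- read_run_maps(input, "^maps_subject")
    inputs <- list.files(input, "^maps_subject", full.names = TRUE)
    if (!is.null(seed)) set.seed(seed)
    st <- purrr::imap_dfr(Ms, function(m, i) {
      out <- map_stability(m, n_rotations = cfg("n_rotations", 1000L))
      out$subject <- if (!is.null(m$subject)) m$subject else i
      out
    })
    f <- file.path(out_dir, "stability.csv")
    write.csv(st, f, row.names = FALSE)
    outputs <- f
  } else if (stage == "psychometrics") {
    trials <- read_run_trials(input)
    inputs <- file.path(input, "trials.csv")
    coefs <- list(); wfs <- list()
    for (s in unique(trials$subject)) {
      tr <- trials[trials$subject == s, ]
      ft <- fit_choice_model(tr)
      td <- tidy(ft)
      if (nrow(td)) { td$subject <- s; coefs[[length(coefs) + 1]] <- td }
      wf <- weighting_function(tr)
      wf$subject <- s
      wfs[[length(wfs) + 1]] <- wf
    }
    f1 <- file.path(out_dir, "psychometric_fits.csv")
    write.csv(dplyr::bind_rows(coefs), f1, row.names = FALSE)
    f2 <- file.path(out_dir, "weighting_functions.csv")
    write.csv(dplyr::bind_rows(wfs), f2, row.names = FALSE)
    outputs <- c(f1, f2)
  } else if (stage == "crosstalk") {
    trials <- read_run_trials(input)
    inputs <- file.path(input, "trials.csv")
    wm <- trials[trials$condition == "WM", ]
    rb <- recall_color_regression(wm)
    rc <- residual_correlation(wm)
    f1 <- file.path(out_dir, "recall_bias.csv")
    write.csv(rb$pooled, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "residual_correlation.csv")
    write.csv(rc$correlations, f2, row.names = FALSE)
    outputs <- c(f1, f2)
    message(sprintf("crosstalk: %d flagged recall fits, %d flagged residual fits",
                    rb$n_flagged, rc$n_flagged))
  } else if (stage == "report") {
    fs <- list.files(input, "\\.csv$", full.names = TRUE)
    if (!length(fs)) stop("missing upstream artifact: no tidy CSVs in ", input)
    inputs <- fs
    summary <- purrr::map_dfr(fs, function(f) {
      d <- read.csv(f)
      tibble::tibble(artifact = basename(f), rows = nrow(d),
                     columns = ncol(d))
    })
    f <- file.path(out_dir, "report.csv")
    write.csv(summary, f, row.names = FALSE)
    outputs <- f
  }

  man <- write_manifest(out_dir, stage, config, seed, inputs, outputs)
  invisible(c(outputs, man))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
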