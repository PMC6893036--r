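# Session container on disk and the pipeline orchestrator.
#
# A session is stored as a directory of plain-text files: one CSV per
# time-series channel, per-wavelength reflectance CSVs, a JSON metadata
# sidecar (rates, units, start times) and a JSON ground-truth sidecar for
# synthetic sessions.

#' Write a session to a directory container
#'
#' @param session An `ox_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(channels = list())
  for (ch in setdiff(names(session), c("truth", "reflectance"))) {
    ts <- session[[ch]]
    ts_write_csv(ts, file.path(path, paste0(ch, ".csv")))
    meta$channels[[ch]] <- list(
      rate = ts_rate(ts), t0 = ts$time[1],
      units = attr(ts, "units") %||% "a.u.", n = nrow(ts)
    )
  }
  if (!is.null(session$reflectance)) {
    st <- session$reflectance
    for (wl in names(st$frames)) {
      utils::write.csv(st$frames[[wl]],
        file.path(path, paste0("reflectance_", wl, ".csv")),
        row.names = FALSE
      )
    }
    meta$reflectance <- list(
      wavelengths = names(st$frames), rate = st$rate, t0 = st$t0,
      roi_masks = st$roi_masks
    )
  }
  if (!is.null(session$truth)) {
    truth <- session$truth
    truth$config <- truth$config[!vapply(truth$config, is.function, logical(1))]
    jsonlite::write_json(truth, file.path(path, "truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a session container
#'
#' @param path Session directory written by [write_session()].
#' @return An `ox_session` (without the generator's function-valued config).
#' @export
read_session <- function(path) {
  meta_f <- file.path(path, "meta.json")
  if (!file.exists(meta_f)) stop("not a session container: missing meta.json", call. = FALSE)
  meta <- tryCatch(jsonlite::read_json(meta_f, simplifyVector = TRUE),
    error = function(e) stop("unreadable session metadata: ", conditionMessage(e), call. = FALSE)
  )
  out <- list()
  for (ch in names(meta$channels)) {
    df <- utils::read.csv(file.path(path, paste0(ch, ".csv")))
    ts <- tibble::as_tibble(df)
    attr(ts, "units") <- meta$channels[[ch]]$units
    out[[ch]] <- ts
  }
  if (!is.null(meta$reflectance)) {
    frames <- lapply(meta$reflectance$wavelengths, function(wl) {
      as.matrix(utils::read.csv(file.path(path, paste0("reflectance_", wl, ".csv"))))
    })
    names(frames) <- meta$reflectance$wavelengths
    out$reflectance <- reflectance_stack(frames,
      rate = meta$reflectance$rate,
      t0 = meta$reflectance$t0,
      roi_masks = lapply(meta$reflectance$roi_masks, as.integer)
    )
  }
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    out$truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  }
  structure(out, class = "ox_session")
}

#' Validate a session container or in-memory session
#'
#' Checks the container schema, channel rates, time monotonicity and value
#' finiteness, returning a machine-readable report rather than erroring on
#' content problems (I/O failures still error).
#'
#' @param x Session directory path or an `ox_session`.
#' @return Tibble with columns `check`, `channel`, `ok`, `detail`.
#' @export
validate_session <- function(x) {
  session <- if (is.character(x)) read_session(x) else x
  rows <- list()
  note <- function(check, channel, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, channel = channel, ok = ok, detail = detail
    )
  }
  chans <- setdiff(names(session), c("truth", "reflectance"))
  if (length(chans) == 0L) note("has_channels", "-", FALSE, "no channels present")
  for (ch in chans) {
    ts <- session[[ch]]
    ok_cols <- is.data.frame(ts) && all(c("time", "value") %in% names(ts))
    note("schema", ch, ok_cols, if (!ok_cols) "missing time/value columns" else "")
    if (!ok_cols) next
    dt <- diff(ts$time)
    note("monotone_time", ch, all(dt > 0), "")
    rate_ok <- length(dt) > 0 && all(dt > 0) &&
      (max(dt) - min(dt)) <= 1e-6 * stats::median(dt)
    note(
      "uniform_positive_rate", ch, rate_ok,
      if (rate_ok) sprintf("rate %.6g Hz", 1 / stats::median(dt)) else "non-uniform or zero rate"
    )
    note("finite_values", ch, all(is.finite(ts$value)), "")
  }
  if (!is.null(session$reflectance)) {
    st <- session$reflectance
    note("reflectance_rate", "reflectance", st$rate > 0, sprintf("rate %.6g Hz", st$rate))
    note(
      "reflectance_positive", "reflectance",
      all(vapply(st$frames, function(f) all(f > 0), logical(1))), ""
    )
  }
  dplyr::bind_rows(rows)
}

stage_order <- c(
  "generate", "behavior", "preprocess", "neural", "kernel",
  "coupling", "respphase", "o2model"
)

stage_deps <- list(
  generate = character(),
  behavior = "generate",
  preprocess = "generate",
  neural = "generate",
  kernel = c("behavior", "preprocess"),
  coupling = c("neural", "preprocess"),
  respphase = "generate",
  o2model = character()
)

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in order on a synthetic session and writes
#' every product as CSV/JSON under `out_dir`, together with a manifest
#' (parameters, seed, package version, file hashes). Identical configs and
#' seeds give identical manifests for deterministic stages.
#'
#' @param config Named list (or path to a YAML file) with elements `seed`
#'   (required), `stages` (subset of
#'   `generate, behavior, preprocess, neural, kernel, coupling, respphase,
#'   o2model`), `out_dir`, optional `session` (generator overrides, passed
#'   to [session_config()]) and per-stage parameter lists.
#' @return The manifest, invisibly (list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) {
    stop("config must set an explicit seed for stochastic stages", call. = FALSE)
  }
  stages <- config$stages %||% stage_order
  bad <- setdiff(stages, stage_order)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stages <- stage_order[stage_order %in% stages]
  for (s in stages) {
    missing_dep <- setdiff(stage_deps[[s]], stages)
    if (length(missing_dep) > 0) {
      stop(sprintf(
        "stage '%s' requires upstream stage(s): %s",
        s, paste(missing_dep, collapse = ", ")
      ), call. = FALSE)
    }
  }
  out_dir <- config$out_dir %||% tempfile("respox_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  products <- character()
  emit_csv <- function(df, name) {
    f <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), f, row.names = FALSE)
    products <<- c(products, f)
  }
  emit_json <- function(x, name) {
    f <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
    products <<- c(products, f)
  }
  env <- new.env(parent = emptyenv())
  if ("generate" %in% stages) {
    cfg <- do.call(session_config, config$session %||% list())
    env$session <- generate_session(cfg, seed = config$seed)
    write_session(env$session, file.path(out_dir, "session"))
  }
  if ("behavior" %in% stages) {
    env$delta <- binarize_locomotion(env$session$velocity)
    env$events <- segment_events(env$delta)
    env$rests <- rest_periods(env$delta)
    emit_csv(env$events, "events")
    emit_csv(env$rests, "rest_periods")
  }
  if ("preprocess" %in% stages) {
    env$pto2_30 <- lowpass_downsample(env$session$pto2, cutoff = 1, order = 5, out_rate = 30)
    emit_csv(env$pto2_30, "pto2_30hz")
  }
  if ("neural" %in% stages) {
    spec <- multitaper_spectrogram(env$session$lfp, window = 1, step = 0.5)
    env$gamma <- gamma_power(spec)
    emit_csv(env$gamma, "gamma_power")
  }
  if ("kernel" %in% stages) {
    kpar <- config$kernel %||% list()
    k_sec <- kpar$k_seconds %||% 15
    d30 <- tibble::tibble(
      time = env$pto2_30$time,
      delta = env$session$truth$delta_pto2$delta[
        round((env$pto2_30$time - env$session$pto2$time[1]) *
          ts_rate(env$session$pto2)) + 1L
      ]
    )
    L <- build_design(d30, k = round(k_sec * 30))
    env$kernel <- deconvolve(env$pto2_30, L)
    emit_csv(tidy(env$kernel), "kernel")
    emit_json(as.list(glance(env$kernel)), "kernel_metrics")
  }
  if ("coupling" %in% stages) {
    g30 <- tibble::tibble(
      time = env$gamma$time,
      value = env$gamma$value
    )
    o2i <- stats::approx(env$pto2_30$time, env$pto2_30$value, g30$time, rule = 2)$y
    lp_x <- min(1, 0.45 * ts_rate(g30))
    xc <- xcorr(g30, tibble::tibble(time = g30$time, value = o2i),
      max_lag = 5, lp = lp_x
    )
    emit_csv(xc, "xcorr_gamma_pto2")
  }
  if ("respphase" %in% stages) {
    resp <- detect_expiratory_peaks(
      bandpass(env$session$thermocouple, 0, 15)
    )
    prof <- phase_align(
      generate_decays(
        ts_new(rep(
          env$session$truth$config$pao2_baseline,
          10 * 1000
        ), 1000),
        resp_peaks = env$session$truth$resp_peaks,
        modulation_depth = config$respphase$modulation_depth %||% 5,
        seed = config$seed + 1
      ),
      env$session$truth$resp_peaks
    )
    emit_csv(tibble::as_tibble(prof), "cycle_profile")
  }
  if ("o2model" %in% stages) {
    par <- do.call(o2_params, config$o2model %||% list())
    tc <- o2_simulate(par, scenario_flhl(), t_end = config$o2model_t_end %||% 30)
    emit_csv(tc, "o2_timecourse_flhl")
  }
  manifest <- list(
    package = "respox",
    version = as.character(utils::packageVersion("respox")),
    seed = config$seed,
    stages = stages,
    config = config[setdiff(names(config), "out_dir")],
    products = lapply(
      stats::setNames(products, basename(products)),
      function(f) unname(tools::md5sum(f))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest$out_dir <- out_dir
  invisible(manifest)
}
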