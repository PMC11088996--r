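#' Write a session to a directory
#'
#' Serializes a [session()] to a plain-text container: `session.yaml`
#' (config and provenance), `trials.csv`, optional `eyelid.csv`
#' (long-format traces), `video/trial_<id>.tif` (multi-page 8-bit
#' grayscale TIFF per trial), `voltage.csv` plus its sampling metadata in
#' the YAML, and a `ground_truth/` directory of CSV tables for synthetic
#' sessions. The layout is deterministic for fixed input.
#'
#' @param sess a valid [session()].
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(sess, path) {
  stopifnot(inherits(sess, "session"))
  if (nrow(sess$trials) < 1L) stop("session contains no trials")
  validate_trials(sess$trials, isi = sess$config$isi)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  meta <- list(config = unclass(sess$config),
               provenance = sess$provenance)
  if (!is.null(sess$voltage))
    meta$voltage <- list(rate = sess$voltage$rate,
                         t0 = sess$voltage$t0 %||% 0)
  yaml::write_yaml(meta, file.path(path, "session.yaml"))
  fwrite(sess$trials, file.path(path, "trials.csv"))
  if (!is.null(sess$traces))
    fwrite(sess$traces, file.path(path, "eyelid.csv"))
  if (!is.null(sess$video)) {
    vd <- file.path(path, "video")
    dir.create(vd, showWarnings = FALSE)
    for (nm in names(sess$video)) {
      v <- sess$video[[nm]]
      pages <- lapply(seq_len(dim(v$frames)[3]),
                      function(i) v$frames[, , i] / 255)
      tiff::writeTIFF(pages, file.path(vd, paste0(nm, ".tif")),
                      bits.per.sample = 8L)
    }
  }
  if (!is.null(sess$voltage))
    fwrite(data.frame(voltage = sess$voltage$samples),
           file.path(path, "voltage.csv"))
  if (!is.null(sess$ground_truth)) {
    gd <- file.path(path, "ground_truth")
    dir.create(gd, showWarnings = FALSE)
    for (nm in names(sess$ground_truth)) {
      obj <- sess$ground_truth[[nm]]
      if (is.data.frame(obj))
        fwrite(obj, file.path(gd, paste0(nm, ".csv")))
      else if (is.numeric(obj))
        fwrite(data.frame(value = obj), file.path(gd, paste0(nm, ".csv")))
    }
  }
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]. Missing optional assets (traces, video,
#' voltage, ground truth) yield absent fields, not errors; a malformed
#' trial table raises a schema error naming the offending row and column.
#'
#' @param path session directory.
#' @return a [session()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no such session directory: ", path)
  meta_file <- file.path(path, "session.yaml")
  trials_file <- file.path(path, "trials.csv")
  if (!file.exists(trials_file)) stop("missing trials.csv in ", path)
  meta <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()
  cfg_args <- meta$config %||% list()
  cfg_args <- cfg_args[names(cfg_args) %in% names(formals(session_config))]
  config <- do.call(session_config, cfg_args)
  trials <- setDF(fread(trials_file))
  for (col in c("cs_onset", "cs_duration", "us_onset", "us_duration",
                "laser_onset", "laser_duration", "iti_before"))
    if (is.logical(trials[[col]])) trials[[col]] <- as.numeric(trials[[col]])
  traces <- NULL
  if (file.exists(file.path(path, "eyelid.csv")))
    traces <- setDF(fread(file.path(path, "eyelid.csv")))
  video <- NULL
  vd <- file.path(path, "video")
  if (dir.exists(vd)) {
    files <- sort(list.files(vd, pattern = "^trial_\\d+\\.tif$"))
    video <- lapply(files, function(f) {
      id <- as.integer(sub("^trial_(\\d+)\\.tif$", "\\1", f))
      pages <- tiff::readTIFF(file.path(vd, f), all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
      for (i in seq_along(pages)) frames[, , i] <- round(pages[[i]] * 255)
      t0 <- if (!is.null(traces)) min(traces$t[traces$trial_id == id])
            else 0
      structure(list(frames = frames, rate = config$video_rate,
                     trial_id = id, t0 = t0), class = "video_stack")
    })
    names(video) <- sub("\\.tif$", "", files)
  }
  voltage <- NULL
  if (file.exists(file.path(path, "voltage.csv"))) {
    v <- fread(file.path(path, "voltage.csv"))
    vm <- meta$voltage %||% list()
    if (!is.null(vm$rate) && !is.null(config$ephys_rate) &&
        abs(vm$rate - config$ephys_rate) > 1e-9)
      stop("consistency error: voltage rate ", vm$rate,
           " Hz does not match config ephys_rate ", config$ephys_rate)
    voltage <- structure(list(samples = v$voltage,
                              rate = vm$rate %||% config$ephys_rate,
                              t0 = vm$t0 %||% 0),
                         class = "voltage_trace")
  }
  ground_truth <- NULL
  gd <- file.path(path, "ground_truth")
  if (dir.exists(gd)) {
    files <- sort(list.files(gd, pattern = "\\.csv$"))
    ground_truth <- lapply(files, function(f) setDF(fread(file.path(gd, f))))
    names(ground_truth) <- sub("\\.csv$", "", files)
    # single-column value tables round-trip back to bare vectors
    ground_truth <- lapply(ground_truth, function(d)
      if (identical(names(d), "value")) d$value else d)
  }
  session(config, trials, traces = traces, video = video,
          voltage = voltage, ground_truth = ground_truth,
          provenance = meta$provenance %||% list())
}
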