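# Readers and writers for the artifacts the pipeline exchanges: multi-page
# grayscale TIFF stacks in; trace/cycle/summary/treatment CSVs and a JSON
# run manifest out. CSV dialect: comma separator, "." decimal, UTF-8, LF.
# Frame rate and um/pixel always come from configuration, never silently
# from TIFF tags.

#' Read a multi-page grayscale TIFF stack
#'
#' @param path TIFF file path.
#' @return A list with \code{stack} (numeric array \code{[row, col, frame]},
#'   raw integer intensities for 8/16-bit input), \code{pages} and
#'   \code{bitDepth} (when reported by the file).
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stopInvalid(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (j in seq_along(pages)) {
    if (length(dim(pages[[j]])) != 2)
      stopInvalid(sprintf(
        "page %d is not single-channel grayscale (RGB input is not supported)",
        j))
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  stack <- array(unlist(pages, use.names = FALSE),
                 dim = c(dim(pages[[1]]), length(pages)))
  list(stack = stack, pages = length(pages),
       bitDepth = if (is.null(bits)) NA_integer_ else as.integer(bits))
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit unsigned integers; values are clamped to
#' \[0, 65535\]. Deterministic: identical input gives identical bytes.
#'
#' @param stack numeric array \code{[row, col, frame]}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeStack <- function(stack, path) {
  if (length(dim(stack)) != 3) stopInvalid("stack must be [row, col, frame]")
  frames <- lapply(seq_len(dim(stack)[3]), function(j) {
    m <- round(stack[, , j])
    pmin(pmax(m, 0), 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a trace from CSV
#'
#' Expects a header \code{time_s,value}. The sample rate is inferred from
#' the median spacing; spacing must be uniform to within 1e-6 relative
#' tolerance and times strictly increasing.
#'
#' @param path CSV path.
#' @return A [Trace-class].
#' @export
readTraceCSV <- function(path) {
  if (!file.exists(path)) stopInvalid(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stopInvalid("trace CSV must have columns time_s,value")
  t <- df$time_s; v <- df$value
  bad <- which(!is.finite(t) | !is.finite(v))
  if (length(bad))
    stopInvalid(sprintf("non-numeric trace row at line %d", bad[1] + 1L))
  if (length(t) < 10) stopInvalid("trace has fewer than 10 samples")
  dt <- diff(t)
  if (any(dt <= 0))
    stopInvalid(sprintf("times not strictly increasing at line %d",
                        which(dt <= 0)[1] + 2L))
  step <- stats::median(dt)
  if (any(abs(dt - step) > 1e-6 * max(step, 1)))
    stopInvalid("trace sampling is not uniform")
  Trace(v, sampleRate = 1 / step, t0 = t[1])
}

#' Write a trace to CSV
#'
#' Full-precision repr round-trip: reading the file back reproduces the
#' values exactly as printed.
#'
#' @param trace a [Trace-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeTraceCSV <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  df <- data.frame(time_s = format(traceTimes(trace), digits = 17,
                                   scientific = FALSE, trim = TRUE),
                   value = format(traceValues(trace), digits = 17,
                                  trim = TRUE))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(paste(df$time_s, df$value, sep = ","), con)
  invisible(path)
}

#' Read an analysis configuration (JSON or YAML)
#'
#' Configuration block for a tracking/quantification run: stack path,
#' \code{frame_rate}, \code{scale} (um/px), geometry (\code{center_x},
#' \code{center_y}, \code{normal_deg}, \code{r}), analysis windows
#' (\code{baseline}, \code{post}; seconds) and an output directory.
#' Numeric fields are validated; windows must not overlap.
#'
#' @param path path to a .json, .yaml or .yml file.
#' @return A named list with a [VesselGeometry-class] under
#'   \code{$geometry} when geometry fields are present.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stopInvalid(sprintf("no such file: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  num <- function(x) !is.null(x) && is.numeric(x) && all(is.finite(x))
  if (!is.null(cfg$frame_rate) && (!num(cfg$frame_rate) || cfg$frame_rate <= 0))
    stopInvalid("frame_rate must be positive")
  if (!is.null(cfg$scale) && (!num(cfg$scale) || cfg$scale <= 0))
    stopInvalid("scale must be positive")
  if (!is.null(cfg$baseline) && !is.null(cfg$post)) {
    b <- as.numeric(cfg$baseline); p <- as.numeric(cfg$post)
    if (length(b) != 2 || length(p) != 2 || b[2] <= b[1] || p[2] <= p[1])
      stopInvalid("windows must be (start, end) with end > start")
    if (max(b[1], p[1]) < min(b[2], p[2]))
      stopInvalid("baseline and post windows must not overlap")
  }
  if (!is.null(cfg$center_x)) {
    cfg$geometry <- vesselGeometry(
      center = c(cfg$center_x, cfg$center_y),
      angle = if (is.null(cfg$normal_deg)) -90 else cfg$normal_deg,
      r = cfg$r, scale = cfg$scale)
  }
  cfg
}

# deterministic CSV writer (LF endings, full precision)
.writeCSV <- function(df, path) {
  fmt <- function(x) {
    if (is.numeric(x)) format(x, digits = 15, scientific = FALSE, trim = TRUE)
    else as.character(x)
  }
  cols <- lapply(df, fmt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Write analysis outputs
#'
#' Writes the per-cycle table (\code{cycles.csv}), the per-trace summary
#' (\code{summary.csv}), the treatment table (\code{treatment.csv}, when a
#' [TreatmentEffect-class] is given) and a JSON run manifest
#' (\code{manifest.json}: configuration echo, package version, seed,
#' timestamp). All CSVs are byte-deterministic for identical inputs; the
#' timestamp lives only in the manifest. An empty cycle table writes a
#' summary row with an undefined-amplitude flag and no cycle rows.
#'
#' @param results a [ContractilitySummary-class] or [TreatmentEffect-class],
#'   or a named list of them (one output row per element).
#' @param dir output directory (created if needed).
#' @param config optional configuration list echoed into the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return Invisible character vector of the files written.
#' @export
writeOutputs <- function(results, dir, config = NULL, seed = NULL) {
  if (is(results, "ContractilitySummary") || is(results, "TreatmentEffect"))
    results <- list(trace = results)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopInvalid(sprintf("cannot create output directory %s", dir))
  files <- character(0)

  summaries <- list(); effects <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    if (is(r, "TreatmentEffect")) {
      effects[[nm]] <- r
      summaries[[paste0(nm, ".baseline")]] <- r@baseline
      summaries[[paste0(nm, ".post")]] <- r@post
    } else summaries[[nm]] <- r
  }

  cyc <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    tab <- s@cycles
    if (nrow(tab) == 0) return(NULL)
    data.frame(trace = nm, cycle = tab$cycle, peak_t = tab$peak_t,
               trough_t = tab$trough_t, peak_val = tab$peak_value,
               trough_val = tab$trough_value, local_mean = tab$local_mean,
               pct_amp = tab$pct_amplitude)
  }))
  if (is.null(cyc))
    cyc <- data.frame(trace = character(0), cycle = integer(0),
                      peak_t = numeric(0), trough_t = numeric(0),
                      peak_val = numeric(0), trough_val = numeric(0),
                      local_mean = numeric(0), pct_amp = numeric(0))
  f <- file.path(dir, "cycles.csv"); .writeCSV(cyc, f); files <- c(files, f)

  sm <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(trace = nm, window_start_s = s@window[1],
               window_end_s = s@window[2],
               frequency_per_min = s@frequency,
               pct_amplitude = s@pctAmplitude,
               amplitude_undefined = !is.finite(s@pctAmplitude),
               pumping_score = s@pumpingScore,
               mean_level = s@meanLevel, n_cycles = s@nCycles)
  }))
  f <- file.path(dir, "summary.csv"); .writeCSV(sm, f); files <- c(files, f)

  if (length(effects)) {
    tr <- do.call(rbind, lapply(names(effects), function(nm) {
      e <- effects[[nm]]
      p <- e@percents
      base <- c(e@baseline@frequency, e@baseline@pctAmplitude,
                e@baseline@pumpingScore, e@baseline@meanLevel)
      post <- c(e@post@frequency, e@post@pctAmplitude,
                e@post@pumpingScore, e@post@meanLevel)
      data.frame(trace = nm,
                 metric = c("frequency_per_min", "pct_amplitude",
                            "pumping_score", "tone_mean_level"),
                 baseline = base, post = post,
                 pct_of_baseline = as.numeric(p[c("frequency", "amplitude",
                                                  "pumping", "tone")]))
    }))
    f <- file.path(dir, "treatment.csv"); .writeCSV(tr, f)
    files <- c(files, f)
  }

  manifest <- list(
    software = "clvtrack",
    version = as.character(utils::packageVersion("clvtrack")),
    seed = seed,
    config = config,
    written = basename(files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  files <- c(files, f)
  invisible(files)
}

#' Export detector scale diagnostics
#'
#' Writes the scalogram row sums as CSV (\code{scale_k,gamma}), for
#' inspecting which rhythm scale the detector locked onto.
#'
#' @param x a [ScaleSelection-class] or a [PeakTroughSet-class] (whose peak
#'   pass is exported).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeScaleDiagnostics <- function(x, path) {
  if (is(x, "PeakTroughSet")) x <- x@scalePeaks
  stopifnot(is(x, "ScaleSelection"))
  .writeCSV(data.frame(scale_k = seq_len(x@L), gamma = x@gamma), path)
}

#' Write a phantom movie artifact set
#'
#' Writes the 16-bit multi-page TIFF, the ground-truth CSV
#' (\code{frame,time_s,true_diameter_um}) and a JSON parameter file
#' embedding the seed.
#'
#' @param movie result of [generateMovie()].
#' @param dir output directory.
#' @param name base name for the files (default "phantom").
#' @return Invisible character vector of the files written.
#' @export
writePhantom <- function(movie, dir, name = "phantom") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopInvalid(sprintf("cannot create output directory %s", dir))
  fTif <- file.path(dir, paste0(name, ".tif"))
  writeStack(movie$stack, fTif)
  fTruth <- file.path(dir, paste0(name, "_truth.csv"))
  .writeCSV(movie$truth, fTruth)
  fPar <- file.path(dir, paste0(name, "_params.json"))
  par <- list(waveform = unclass(movie$waveform$params),
              optics = unclass(movie$optics))
  jsonlite::write_json(par, fPar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(c(fTif, fTruth, fPar))
}
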