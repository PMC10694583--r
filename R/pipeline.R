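#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with the standard
#' defaults: multi-Otsu threshold, 3x3 median filter, 100-bin histogram,
#' 10 frequency levels, ROI/phasor minima of 5000/500 points, 2 GMM
#' clusters. Values can come from a YAML config file, with direct
#' arguments overriding file keys.
#'
#' @param input Character vector of input paths (containers or `.ref`).
#' @param output_dir Directory for all outputs.
#' @param mode `"single"` (one analysis per file) or `"cumulative"`
#'   (files grouped by sample name, replicas pooled into one dataset).
#' @param threshold A [threshold_spec()].
#' @param filter A [filter_spec()].
#' @param bins Histogram bins per dimension. Default 100.
#' @param n_levels Number of contour levels. Default 10.
#' @param min_roi_points,min_phasor_points Contour validity criteria.
#'   Defaults 5000 and 500.
#' @param calibration Optional list `(reference = path, lifetime_ns = )`
#'   or a ready `calibration` object.
#' @param species_table Optional path to a species CSV for unmixing.
#' @param mask Optional path to a TIFF mask.
#' @param clusters GMM cluster count. Default 2.
#' @param seed Integer seed. Default 1.
#' @param config_file Optional YAML file supplying any of the above keys.
#' @param ref_dims,rep_rate Geometry and rep rate used for `.ref` inputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = character(), output_dir = "phasorflim_out",
                       mode = c("single", "cumulative"),
                       threshold = threshold_spec(),
                       filter = filter_spec(),
                       bins = 100L, n_levels = 10L,
                       min_roi_points = 5000L, min_phasor_points = 500L,
                       calibration = NULL, species_table = NULL,
                       mask = NULL, clusters = 2L, seed = 1L,
                       config_file = NULL,
                       ref_dims = c(256L, 256L), rep_rate = 80e6) {
  cfg <- list(
    input = input, output_dir = output_dir, mode = match.arg(mode),
    threshold = threshold, filter = filter,
    bins = as.integer(bins), n_levels = as.integer(n_levels),
    min_roi_points = as.integer(min_roi_points),
    min_phasor_points = as.integer(min_phasor_points),
    calibration = calibration, species_table = species_table,
    mask = mask, clusters = as.integer(clusters), seed = as.integer(seed),
    ref_dims = as.integer(ref_dims), rep_rate = rep_rate
  )
  if (!is.null(config_file)) {
    fromfile <- yaml::read_yaml(config_file)
    if (!is.null(fromfile$threshold)) {
      fromfile$threshold <- do.call(threshold_spec, fromfile$threshold)
    }
    if (!is.null(fromfile$filter)) {
      fromfile$filter <- do.call(filter_spec, fromfile$filter)
    }
    # explicit arguments win over file keys
    supplied <- names(as.list(match.call()))
    keep <- setdiff(names(fromfile), supplied)
    cfg[keep] <- fromfile[keep]
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run config: %d input(s), mode %s, threshold %s, filter %s, %d bins\n",
    length(x$input), x$mode, x$threshold$method, x$filter$kind, x$bins))
  invisible(x)
}

#' Analyse one phasor field (threshold, filter, contours, lifetimes)
#'
#' The single-image core of the pipeline: selects relevant pixels,
#' filters the phasor rasters, builds the 2D histogram, detects ROI
#' perimeters and nested phasors, clusters the retained pixels with a
#' Gaussian mixture, and tabulates per-pixel and per-phasor results.
#'
#' @param field A (calibrated) `phasor_field`.
#' @param config A [run_config()].
#' @param sample,replica Labels carried into the exported tables.
#' @param mask Optional logical mask matrix.
#' @return An object of class `flim_analysis`: list with `field`
#'   (filtered), `selection`, `hist`, `regions`, `gmm`, `df_dataset`
#'   (one row per retained pixel) and `df` (one row per phasor).
#' @export
analyze_field <- function(field, config = run_config(), sample = "sample",
                          replica = 1L, mask = NULL) {
  selection <- select_pixels(field$intensity, config$threshold, mask)
  selection <- selection & field$valid
  if (!any(selection)) {
    stop("no pixels survive thresholding/masking", call. = FALSE)
  }
  field <- smooth_phasors(field, config$filter, selection)
  idx <- which(selection)
  gv <- field$g[idx]; sv <- field$s[idx]
  hist <- build_histogram(gv, sv, bins = config$bins)
  regions <- withCallingHandlers(
    detect_regions(hist, noise_floor_levels(hist, n_levels = config$n_levels),
                   config$min_roi_points, config$min_phasor_points),
    warning = function(w) invokeRestart("muffleWarning")
  )
  assign <- assign_regions(gv, sv, regions)
  gmm <- fit_gmm(cbind(gv, sv), k = min(config$clusters, length(gv)),
                 seed = config$seed)
  rc <- arrayInd(idx, dim(field$g))
  df_dataset <- data.frame(
    sample = sample, replica = as.integer(replica),
    row = rc[, 1] - 1L, col = rc[, 2] - 1L,   # 0-based pixel coordinates
    g = gv, s = sv,
    intensity = field$intensity[idx],
    tau_phase = tau_phase(gv, sv, field$params),
    tau_mod = tau_mod(gv, sv, field$params),
    roi = assign$roi, phasor = assign$phasor,
    cluster = gmm$labels
  )
  df <- phasor_table(df_dataset, regions, field$params, sample)
  structure(
    list(field = field, selection = selection, hist = hist,
         regions = regions, gmm = gmm,
         df_dataset = df_dataset, df = df),
    class = "flim_analysis"
  )
}

phasor_table <- function(df_dataset, regions, params, sample) {
  empty <- data.frame(
    sample = character(0), phasor = integer(0), roi = integer(0),
    n_points = integer(0), g = numeric(0), s = numeric(0),
    g_err = numeric(0), s_err = numeric(0),
    g_weighted = numeric(0), s_weighted = numeric(0),
    tau_phase = numeric(0), sd_phase = numeric(0),
    tau_mod = numeric(0), sd_mod = numeric(0), pca_ratio = numeric(0)
  )
  if (length(regions$phasors) == 0L) return(empty)
  rows <- lapply(seq_along(regions$phasors), function(i) {
    px <- df_dataset[df_dataset$phasor == i, ]
    if (nrow(px) == 0L) return(NULL)
    sm <- summarize_phasor(px$g, px$s, px$intensity, params)
    data.frame(
      sample = sample, phasor = i, roi = regions$phasors[[i]]$parent,
      n_points = sm$n_points,
      g = sm$barycenter$g, s = sm$barycenter$s,
      g_err = sm$g_err, s_err = sm$s_err,
      g_weighted = sm$weighted_barycenter$g,
      s_weighted = sm$weighted_barycenter$s,
      tau_phase = sm$tau_phase, sd_phase = sm$sd_phase,
      tau_mod = sm$tau_mod, sd_mod = sm$sd_mod,
      pca_ratio = sm$pca_ratio
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' @export
print.flim_analysis <- function(x, ...) {
  cat(sprintf("FLIM analysis: %d retained pixels, %d ROI(s), %d phasor(s), %d cluster(s)\n",
              nrow(x$df_dataset), length(x$regions$perimeters),
              length(x$regions$phasors), x$gmm$k))
  invisible(x)
}

#' Write the two analysis tables as CSV
#'
#' Mirrors the pipeline's standard exports: `df_dataset.csv` with one
#' row per retained pixel and `df.csv` with one row per detected phasor.
#' Files are UTF-8, comma-separated, `.` decimal, with a header row;
#' empty analyses produce header-only files.
#'
#' @param analysis A `flim_analysis`, or a list with `df_dataset` and
#'   `df` data frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
export_tables <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "df_dataset.csv")
  p2 <- file.path(dir, "df.csv")
  write.csv(analysis$df_dataset, p1, row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(analysis$df, p2, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(df_dataset = p1, df = p2))
}

#' Run the full FLIM analysis pipeline
#'
#' Reads every input file, applies calibration when configured,
#' analyses each image (or each pooled sample in cumulative mode), and
#' writes `df_dataset.csv`, `df.csv`, region polygon files, lifetime and
#' intensity maps, and a structured log into the output directory. In
#' cumulative mode files are grouped by parsed sample name and replicas
#' are pooled into a single dataset per sample. Unreadable inputs are
#' reported and skipped; the run fails only if every input fails.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of `flim_analysis` objects (one per
#'   sample in cumulative mode, per file otherwise).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("`config` must come from run_config()", call. = FALSE)
  }
  if (length(config$input) == 0L) {
    stop("no input files configured", call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "pipeline.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    message(msg)
  }

  corr <- NULL
  if (!is.null(config$calibration)) {
    if (inherits(config$calibration, "calibration")) {
      corr <- config$calibration
    } else {
      reff <- load_input_field(config$calibration$reference, config)
      sm <- summarize_phasor(reff$g[reff$valid], reff$s[reff$valid],
                             reff$intensity[reff$valid])
      corr <- fit_calibration(sm$barycenter,
                              config$calibration$lifetime_ns, reff$params)
      say("stage=calibration phase_offset=%.6f mod_factor=%.6f",
          corr$phase_offset, corr$mod_factor)
    }
  }
  mask <- if (!is.null(config$mask)) read_mask(config$mask) else NULL

  loaded <- list()
  for (path in config$input) {
    rec <- tryCatch({
      fld <- load_input_field(path, config)
      if (!is.null(corr)) fld <- apply_calibration(fld, corr)
      meta <- tryCatch(parse_sample_name(path), error = function(e) {
        list(date = "", sample_name = tools::file_path_sans_ext(basename(path)),
             replica = 1L)
      })
      list(field = fld, meta = meta, path = path)
    }, error = function(e) {
      say("stage=read file=%s status=error message=%s", path,
          conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) loaded[[length(loaded) + 1L]] <- rec
  }
  if (length(loaded) == 0L) {
    stop("all input files failed to load; see ", logf, call. = FALSE)
  }

  results <- list()
  if (config$mode == "cumulative") {
    samples <- split(loaded,
                     vapply(loaded, function(r) r$meta$sample_name, ""))
    for (nm in names(samples)) {
      grp <- samples[[nm]]
      res <- analyze_pooled(grp, config, nm, mask)
      say("stage=analyze sample=%s replicas=%d pixels=%d rois=%d phasors=%d",
          nm, length(grp), nrow(res$df_dataset),
          length(res$regions$perimeters), length(res$regions$phasors))
      write_sample_outputs(res, config, nm)
      results[[nm]] <- res
    }
  } else {
    for (rec in loaded) {
      nm <- sprintf("%s_%d", rec$meta$sample_name, rec$meta$replica)
      res <- analyze_field(rec$field, config, rec$meta$sample_name,
                           rec$meta$replica, mask)
      say("stage=analyze sample=%s pixels=%d rois=%d phasors=%d",
          nm, nrow(res$df_dataset), length(res$regions$perimeters),
          length(res$regions$phasors))
      write_sample_outputs(res, config, nm)
      results[[nm]] <- res
    }
  }
  save_config(config, file.path(config$output_dir, "config_used.yaml"))
  say("stage=done samples=%d", length(results))
  invisible(results)
}

load_input_field <- function(path, config) {
  obj <- if (tolower(tools::file_ext(path)) == "ref") {
    read_ref(path, dims = config$ref_dims, rep_rate = config$rep_rate)
  } else {
    read_flim_input(path)
  }
  if (inherits(obj, "decay_stack")) obj <- phasor_field(obj)
  obj
}

# pool replicas of one sample: per-replica thresholding/filtering, then
# one combined histogram/region/cluster analysis over all pixels
analyze_pooled <- function(grp, config, sample, mask) {
  pieces <- lapply(grp, function(rec) {
    a <- analyze_field(rec$field, config, sample, rec$meta$replica, mask)
    a$df_dataset
  })
  pooled <- do.call(rbind, pieces)
  hist <- build_histogram(pooled$g, pooled$s, bins = config$bins)
  regions <- withCallingHandlers(
    detect_regions(hist, noise_floor_levels(hist, n_levels = config$n_levels),
                   config$min_roi_points, config$min_phasor_points),
    warning = function(w) invokeRestart("muffleWarning")
  )
  assign <- assign_regions(pooled$g, pooled$s, regions)
  pooled$roi <- assign$roi
  pooled$phasor <- assign$phasor
  gmm <- fit_gmm(cbind(pooled$g, pooled$s),
                 k = min(config$clusters, nrow(pooled)), seed = config$seed)
  pooled$cluster <- gmm$labels
  params <- grp[[1]]$field$params
  structure(
    list(field = grp[[1]]$field, selection = NULL, hist = hist,
         regions = regions, gmm = gmm, df_dataset = pooled,
         df = phasor_table(pooled, regions, params, sample)),
    class = "flim_analysis"
  )
}

write_sample_outputs <- function(res, config, name) {
  dir <- file.path(config$output_dir, gsub("[^A-Za-z0-9_ .-]", "_", name))
  export_tables(res, dir)
  write_regions(res$regions, file.path(dir, "regions.csv"))
  if (!is.null(res$selection)) {
    write_map(lifetime_map(res$field, res$selection),
              file.path(dir, "lifetime_map.tif"))
    write_map(res$field$intensity, file.path(dir, "intensity_map.tif"))
  }
  invisible(dir)
}

save_config <- function(config, path) {
  ser <- unclass(config)
  ser$threshold <- unclass(ser$threshold)
  ser$filter <- unclass(ser$filter)
  if (inherits(ser$calibration, "calibration")) {
    ser$calibration <- unclass(ser$calibration)
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}
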