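#' Pipeline run configuration
#'
#' Assembles and validates the configuration for a full
#' simulate -> preprocess -> map/df run.  Every parameter is checked
#' against its stage's preconditions up front, so a bad band or
#' threshold aborts before any stage runs, naming the offending key.
#'
#' @param scenario one of `"sinus"`, `"paced"`, `"focal"`, `"lesion"`,
#'   `"ischemia"`, `"af"`, or a [propagation_scenario()] object.
#' @param seed integer RNG seed, recorded in every output's provenance.
#' @param out_dir output directory.
#' @param rows,cols,spacing_mm array geometry.
#' @param sample_rate acquisition rate, Hz.
#' @param duration_s rendered duration, s.
#' @param noise_rms additive noise RMS, mV.
#' @param band bandpass edges `c(low, high)`, Hz.
#' @param n_bands isochrone segment count.
#' @param frame_interval_ms time-lapse frame interval, ms.
#' @param ri_threshold regularity-index discard threshold.
#' @param df_band DF search band, Hz.
#' @param farfield `"none"` or `"template"`.
#' @param subtract_farfield subtract the ventricular template when a
#'   reference lead is present.
#' @param adjacency adjacency mode for geometry-aware stages.
#' @param mesh optional mesh path (STL/OBJ/PLY) for the curvature stage;
#'   `"icosphere"` uses a built-in demo shell; `NULL` skips the stage.
#' @param stages character subset of
#'   `c("simulate", "preprocess", "activation", "df", "curvature")`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(scenario = "sinus", seed = 1L, out_dir = tempfile("epimap_"),
                       rows = 16L, cols = 16L, spacing_mm = 3.5,
                       sample_rate = 2048, duration_s = 2,
                       noise_rms = 0.05, band = c(1, 400), n_bands = 15L,
                       frame_interval_ms = 5, ri_threshold = 0.2,
                       df_band = c(3, 15), farfield = "none",
                       subtract_farfield = TRUE,
                       adjacency = "grid8", mesh = NULL,
                       stages = c("simulate", "preprocess", "activation")) {
  if (is.character(scenario))
    scenario <- match.arg(scenario, c("sinus", "paced", "focal",
                                      "lesion", "ischemia", "af"))
  tryCatch(check_band(band[1], band[2], sample_rate),
           error = function(e) stop("bandpass.low/high: ",
                                    conditionMessage(e), call. = FALSE))
  if (n_bands < 1L) stop("n_bands must be >= 1", call. = FALSE)
  if (frame_interval_ms <= 0)
    stop("frame_interval_ms must be > 0", call. = FALSE)
  if (ri_threshold < 0 || ri_threshold > 1)
    stop("ri_threshold must be in [0, 1]", call. = FALSE)
  if (df_band[1] <= 0 || df_band[2] <= df_band[1])
    stop("df_band must satisfy 0 < low < high", call. = FALSE)
  stages <- match.arg(stages, c("simulate", "preprocess", "activation",
                                "df", "curvature"), several.ok = TRUE)
  structure(list(scenario = scenario, seed = as.integer(seed),
                 out_dir = out_dir, rows = rows, cols = cols,
                 spacing_mm = spacing_mm, sample_rate = sample_rate,
                 duration_s = duration_s, noise_rms = noise_rms,
                 band = band, n_bands = n_bands,
                 frame_interval_ms = frame_interval_ms,
                 ri_threshold = ri_threshold, df_band = df_band,
                 farfield = farfield,
                 subtract_farfield = subtract_farfield,
                 adjacency = adjacency, mesh = mesh, stages = stages),
            class = "run_config")
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$scenario <- if (inherits(cfg$scenario, "propagation_scenario"))
    unclass(cfg$scenario) else cfg$scenario
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (simulate -> preprocess ->
#' activation / df / curvature), writes all machine-readable outputs
#' under `config$out_dir`, and returns a run manifest.  Every CSV output
#' carries `#`-prefixed provenance lines (package version, seed, config
#' hash) and every JSON output a `provenance` block; re-running with an
#' identical config and seed reproduces identical checksums.  A stage
#' failure aborts with the stage name prefixed to the error.
#'
#' Outputs (per enabled stage): `recording.{json,csv}`,
#' `ground_truth.json`, `qc.csv`, `activation.csv`, `isochrones.json`,
#' `frames.json`, `cv.csv`, `origin.json`, `df_map.csv`,
#' `curvature.csv`, and `manifest.json`.
#'
#' @param config a [run_config()].
#' @return The manifest (list of class `run_manifest`): config echo,
#'   package version, seed, per-file md5 checksums, warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)),
      warning = note)
  }

  cfg_json <- file.path(config$out_dir, "config.json")
  cfg_echo <- config_echo(config)
  cfg_echo$out_dir <- NULL      # incidental: keep the hash reproducible
  jsonlite::write_json(cfg_echo, cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))
  prov <- list(package = "epimap",
               version = as.character(utils::packageVersion("epimap")),
               seed = config$seed, config_md5 = cfg_hash)
  prov_lines <- sprintf("# epimap %s | seed=%d | config_md5=%s",
                        prov$version, prov$seed, prov$config_md5)
  outp <- function(f) file.path(config$out_dir, f)
  write_prov_csv <- function(df, f) {
    con <- file(outp(f), "w")
    on.exit(close(con))
    writeLines(prov_lines, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  write_prov_json <- function(x, f) {
    x$provenance <- prov
    jsonlite::write_json(x, outp(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", force = TRUE)
  }

  layout <- stage("layout",
                  grid_layout(config$rows, config$cols, config$spacing_mm))
  graph <- stage("adjacency", build_adjacency(layout, config$adjacency))
  rec <- truth <- NULL

  if ("simulate" %in% config$stages) {
    sim <- stage("simulate", {
      if (inherits(config$scenario, "propagation_scenario")) {
        render_recording(layout, config$scenario,
                         sample_rate = config$sample_rate,
                         duration_s = config$duration_s,
                         noise_rms = config$noise_rms,
                         farfield = config$farfield, graph = graph,
                         seed = config$seed)
      } else switch(config$scenario,
        af = af_recording(layout, df_field_patchy(layout,
                                                  band = config$df_band),
                          sample_rate = config$sample_rate,
                          duration_s = max(config$duration_s, 8),
                          noise_rms = config$noise_rms,
                          seed = config$seed),
        sinus = render_recording(layout, scenario_sinus(layout),
                                 sample_rate = config$sample_rate,
                                 duration_s = config$duration_s,
                                 noise_rms = config$noise_rms,
                                 farfield = config$farfield,
                                 graph = graph, seed = config$seed),
        paced = render_recording(layout, scenario_paced(layout),
                                 sample_rate = config$sample_rate,
                                 duration_s = config$duration_s,
                                 noise_rms = config$noise_rms,
                                 farfield = config$farfield,
                                 graph = graph, seed = config$seed),
        focal = render_recording(layout,
                                 scenario_focal(layout,
                                   channel = center_channel(layout)),
                                 sample_rate = config$sample_rate,
                                 duration_s = config$duration_s,
                                 noise_rms = config$noise_rms,
                                 farfield = config$farfield,
                                 graph = graph, seed = config$seed),
        lesion = render_recording(layout,
                                  scenario_lesion(scenario_sinus(layout),
                                    lesion_block(layout)),
                                  sample_rate = config$sample_rate,
                                  duration_s = config$duration_s,
                                  noise_rms = config$noise_rms,
                                  farfield = config$farfield,
                                  graph = graph, seed = config$seed),
        ischemia = render_recording(layout,
                                    scenario_ischemia(scenario_sinus(layout),
                                      lesion_block(layout, half = 3L),
                                      factor = 0.5),
                                    sample_rate = config$sample_rate,
                                    duration_s = config$duration_s,
                                    noise_rms = config$noise_rms,
                                    farfield = config$farfield,
                                    graph = graph, seed = config$seed))
    })
    rec <- sim$recording
    truth <- sim$truth
    stage("simulate", {
      write_recording(rec, outp("recording"), provenance = prov)
      gt <- list(beat_onsets_ms = truth$beat_onsets_ms,
                 cv_mps = truth$cv_mps,
                 source_channels = truth$source_channels,
                 lesions = truth$lesions,
                 farfield_times_ms = truth$farfield_times_ms)
      if (!is.null(truth$offset_ms))
        gt$offset_ms <- as.list(stats::setNames(truth$offset_ms,
                                                layout$channel_id))
      if (!is.null(truth$df_field))
        gt$df_field <- as.list(as.data.frame(truth$df_field))
      write_prov_json(gt, "ground_truth.json")
    })
  } else {
    rec <- stage("load", read_recording(outp("recording")))
  }

  quality <- NULL
  if ("preprocess" %in% config$stages) {
    rec <- stage("preprocess",
                 bandpass(rec, config$band[1], config$band[2]))
    if (config$subtract_farfield && !is.null(rec$reference)) {
      rec <- stage("preprocess", {
        beats <- detect_ventricular_beats(rec)
        subtract_farfield(rec, beats)
      })
    }
    quality <- stage("preprocess", assess_channels(rec))
    stage("preprocess", write_prov_csv(
      data.frame(channel_id = quality$channel_id, flag = quality$flag,
                 rms_mv = quality$rms_mv, clip_frac = quality$clip_frac),
      "qc.csv"))
  }

  if ("activation" %in% config$stages) {
    stage("activation", {
      beats <- segment_beats(rec)
      if (nrow(beats) < 1L) stop("no beats segmented", call. = FALSE)
      amap <- detect_activation(rec, unlist(beats[1L, ]),
                                quality = quality, beat = 1L)
      iso <- build_isochrones(amap, config$n_bands)
      frames <- activation_frames(amap, config$frame_interval_ms)
      cvm <- estimate_cv(amap, layout, graph)
      orig <- localize_origin(amap, layout, graph)
      write_prov_csv(as.data.frame(amap), "activation.csv")
      write_prov_json(list(edges_ms = iso$edges_ms,
                           band = as.list(iso$band),
                           n_bands = iso$n_bands,
                           degenerate = iso$degenerate,
                           color_convention = iso$color_convention),
                      "isochrones.json")
      write_prov_json(list(interval_ms = attr(frames, "interval_ms"),
                           starts_ms = attr(frames, "starts_ms"),
                           frames = lapply(frames, identity)),
                      "frames.json")
      write_prov_csv(as.data.frame(cvm), "cv.csv")
      write_prov_json(list(channel_id = orig$channel_id,
                           position_mm = orig$position_mm,
                           time_ms = orig$time_ms,
                           cv_mean_mps = attr(cvm, "mean_mps"),
                           cv_sd_mps = attr(cvm, "sd_mps")),
                      "origin.json")
    })
  }

  if ("df" %in% config$stages) {
    stage("df", {
      dfm <- df_map(rec, layout, band = config$df_band,
                    threshold = config$ri_threshold, quality = quality)
      write_prov_csv(as.data.frame(dfm), "df_map.csv")
    })
  }

  if ("curvature" %in% config$stages && !is.null(config$mesh)) {
    stage("curvature", {
      mesh <- if (identical(config$mesh, "icosphere"))
        mesh_icosphere(20, 3L) else read_mesh(config$mesh)
      cm <- gaussian_curvature(mesh)
      write_curvature_csv(cm, outp("curvature.csv"),
                          provenance = prov_lines)
    })
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- structure(list(
    config = config_echo(config), provenance = prov,
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))),
    warnings = warnings_seen), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), outp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}

center_channel <- function(layout) {
  layout$channel_id[layout$row == ceiling(max(layout$row) / 2) &
                    layout$col == ceiling(max(layout$col) / 2)][1L]
}

# a 3x3 (or half-array) block of channels in the array middle
lesion_block <- function(layout, half = 1L) {
  rmid <- ceiling(max(layout$row) / 2)
  cmid <- ceiling(max(layout$col) / 2)
  layout$channel_id[abs(layout$row - rmid) <= half &
                    abs(layout$col - cmid) <= half]
}

#' Export a per-channel map onto the 2D probe grid
#'
#' Interpolates/arranges a per-channel scalar map (isochrone band
#' indices, DF values, activation times) onto the 2D reconstruction of
#' the mapping probe: a `rows x cols` matrix indexed by the layout's
#' grid indices, with `NA` marking missing cells, carrying the
#' early = red / late = blue convention tag.
#'
#' @param values named per-channel vector (names = channel ids), e.g.
#'   `isochrone_map$band` or `df_map$interpolated`.
#' @param layout an [electrode_layout()] with grid indices.
#' @return Numeric matrix with attribute `"color_convention"`.
#' @export
export_map_2d <- function(values, layout) {
  if (!has_grid(layout))
    stop("layout has no 2D grid structure; rebuild the layout with ",
         "row/col indices or unroll it with a knn embedding",
         call. = FALSE)
  m <- matrix(NA_real_, max(layout$row), max(layout$col))
  i <- match(as.integer(names(values)), layout$channel_id)
  if (anyNA(i)) stop("values name channels outside the layout",
                     call. = FALSE)
  m[cbind(layout$row[i], layout$col[i])] <- as.numeric(values)
  attr(m, "color_convention") <- "early=red,late=blue"
  m
}
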