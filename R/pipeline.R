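# Pipeline orchestration: simulate -> segment -> features -> cellcycle ->
# spatial, driven by one YAML config with per-stage sections. Each stage
# writes its outputs under `out_dir`; a JSON manifest with config
# snapshot, seeds, per-stage object counts and timestamps is written even
# when a stage fails.

default_config <- function() {
  list(out_dir = "mctsnuclei_run",
       stages = c("simulate", "segment", "features", "cellcycle", "spatial"),
       simulate = list(),                 # phantom_spec() arguments
       segment = list(),                  # segmentation_config() arguments
       features = list(channels = c("dapi", "rfp", "gfp"),
                       spheroid_id = "spheroid"),
       cellcycle = list(mode = "threshold", seed = 1),
       spatial = list(layer_width = 10, max_depth = 60, trend_bin = 5,
                      closing_radius = 10))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the spheroid analysis pipeline
#'
#' Executes the requested stages in order, chaining outputs in memory and
#' writing every artefact (TIFF stacks, label volumes, CSV tables, the
#' resolved config and a JSON run manifest) under `out_dir`. Stages fail
#' fast with stage-named errors; the manifest is written even on failure.
#'
#' @param config a YAML config path or a config list. Top-level keys:
#'   `out_dir`, `stages`, and per-stage sections `simulate`
#'   ([phantom_spec()] arguments), `segment` ([segmentation_config()]
#'   arguments plus optional `input`/`channel`/`spacing` to segment an
#'   existing stack), `features` (`channels`), `cellcycle` (`mode` =
#'   `"threshold"` or `"svm"`, `seed`), `spatial` (`layer_width`,
#'   `max_depth`, `trend_bin`, `closing_radius`).
#' @param stages optional character vector overriding the configured
#'   stage list.
#' @return The run manifest (list), invisibly. Manifest fields: `config`,
#'   `stages_run`, per-stage `counts`, `outputs` (paths) and `timestamps`.
#' @export
run_pipeline <- function(config = list(), stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(stages)) cfg$stages <- stages
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages_run = character(0),
                   counts = list(), outputs = list(), timestamps = list(),
                   version = as.character(utils::packageVersion("mctsnuclei")))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
  }
  on.exit(flush_manifest())
  state <- new.env(parent = emptyenv())
  mark <- function(stage, counts = NULL, outputs = NULL) {
    manifest$stages_run <<- c(manifest$stages_run, stage)
    if (!is.null(counts)) manifest$counts[[stage]] <<- counts
    if (!is.null(outputs)) manifest$outputs[[stage]] <<- outputs
    manifest$timestamps[[stage]] <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      flush_manifest()
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if ("simulate" %in% cfg$stages) run_stage("simulate", function() {
    spec <- do.call(phantom_spec, cfg$simulate)
    ph <- generate_phantom(spec)
    paths <- list()
    for (nm in names(ph$channels)) {
      paths[[nm]] <- file.path(cfg$out_dir, paste0(nm, ".tif"))
      write_stack(ph$channels[[nm]], paths[[nm]])
    }
    paths$truth_labels <- file.path(cfg$out_dir, "truth_labels.tif")
    write_labels(ph$truth_labels, paths$truth_labels)
    paths$truth <- file.path(cfg$out_dir, "truth.csv")
    write_records(ph$truth, paths$truth)
    paths$spec <- file.path(cfg$out_dir, "phantom_spec.yaml")
    write_phantom_spec(spec, paths$spec)
    state$phantom <- ph
    mark("simulate", counts = list(nuclei = nrow(ph$truth)), outputs = paths)
  })

  if ("segment" %in% cfg$stages) run_stage("segment", function() {
    seg_args <- cfg$segment
    input <- seg_args$input; seg_args$input <- NULL
    channel <- if (is.null(seg_args$channel)) "dapi" else seg_args$channel
    seg_args$channel <- NULL
    spacing <- seg_args$spacing; seg_args$spacing <- NULL
    if (!is.null(input)) {
      grid <- read_stack(input, channel, spacing = spacing)
      state$raw_channels <- setNames(list(grid), channel)
    } else if (!is.null(state$phantom)) {
      grid <- state$phantom$channels[[channel]]
      state$raw_channels <- state$phantom$channels
    } else stop("no input stack: run the simulate stage or set segment$input")
    scfg <- do.call(segmentation_config, seg_args)
    seg <- segment_nuclei(grid, scfg, verbose = TRUE)
    state$labels <- seg$labels
    paths <- list(labels = file.path(cfg$out_dir, "labels.tif"),
                  seeds = file.path(cfg$out_dir, "seeds.csv"))
    write_labels(seg$labels, paths$labels)
    write.csv(data.frame(seg$seeds$points, source = seg$seeds$source),
              paths$seeds, row.names = FALSE)
    mark("segment", counts = as.list(seg$log), outputs = paths)
  })

  if ("features" %in% cfg$stages) run_stage("features", function() {
    if (is.null(state$labels)) stop("no label volume: run the segment stage first")
    chans <- list()
    for (nm in cfg$features$channels) {
      g <- state$raw_channels[[nm]]
      if (is.null(g)) next
      chans[[nm]] <- interpolate_isotropic(g)
    }
    if (!length(chans)) stop("no measurable channels")
    rec <- measure_nuclei(state$labels, chans,
                          spheroid_id = cfg$features$spheroid_id)
    gate <- volume_gate(rec)
    state$records <- gate$kept
    paths <- list(features = file.path(cfg$out_dir, "nuclei.csv"),
                  discarded = file.path(cfg$out_dir, "nuclei_discarded.csv"))
    write_records(gate$kept, paths$features)
    if (nrow(gate$discarded)) write_records(gate$discarded, paths$discarded)
    mark("features", counts = list(measured = nrow(rec), gated = nrow(gate$kept)),
         outputs = paths)
  })

  if ("cellcycle" %in% cfg$stages) run_stage("cellcycle", function() {
    rec <- state$records
    if (is.null(rec)) stop("no feature table: run the features stage first")
    rec <- depth_correct(rec, "itg_dapi")
    rec <- normalize_dna(rec, "itg_dapi_corrected")
    has_fucci <- all(c("itg_rfp", "itg_gfp") %in% names(rec))
    if (has_fucci) rec <- classify_fucci(rec)
    mode <- cfg$cellcycle$mode
    counts <- list()
    if (has_fucci && any(rec$fucci_class == "SG2") &&
        any(rec$fucci_class %in% c("G1", "G1S"))) {
      curve <- optimal_threshold(rec$dna_content, rec$fucci_class)
      counts$optimal_threshold <- curve$optimum
      thr <- curve$optimum
    } else thr <- 1.25
    if (identical(mode, "svm") && has_fucci) {
      lab_set <- rec$fucci_class %in% c("G1", "SG2")
      feats <- neighbor_normalize(rec)
      fit <- train_svm(feats[lab_set, , drop = FALSE], rec$fucci_class[lab_set],
                       seed = cfg$cellcycle$seed)
      rec$predicted_class <- predict(fit$model, feats)
      counts$test_balanced_accuracy <- fit$report$balanced_accuracy
    } else {
      rec$predicted_class <- threshold_classify(rec$dna_content, thr)
    }
    state$records <- rec
    paths <- list(calls = file.path(cfg$out_dir, "calls.csv"))
    write_records(rec, paths$calls)
    counts$sg2_called <- sum(rec$predicted_class == "SG2")
    mark("cellcycle", counts = counts, outputs = paths)
  })

  if ("spatial" %in% cfg$stages) run_stage("spatial", function() {
    rec <- state$records
    if (is.null(rec)) stop("no records: run earlier stages first")
    if (is.null(state$labels)) stop("no label volume for surface approximation")
    sp_cfg <- cfg$spatial
    geom <- approximate_surface(state$labels, sp_cfg$closing_radius)
    parts <- filter_detached(rec, geom)
    rec <- parts$kept
    dists <- perimeter_distance(rec, geom)
    rec$perimeter_distance <- dists
    rec$layer <- assign_layers(dists, sp_cfg$layer_width, sp_cfg$max_depth)
    rec$alignment_angle <- record_alignment_angle(rec, geom$center)
    paths <- list(spatial = file.path(cfg$out_dir, "spatial.csv"))
    write_records(rec, paths$spatial)
    if ("predicted_class" %in% names(rec)) {
      ls <- layer_stats(rec$predicted_class, rec$layer, rec$spheroid_id,
                        n_layers = sp_cfg$max_depth / sp_cfg$layer_width)
      paths$layers <- file.path(cfg$out_dir, "layer_summary.csv")
      write.csv(ls$summary, paths$layers, row.names = FALSE)
    }
    state$records <- rec
    mark("spatial", counts = list(kept = nrow(rec), detached = nrow(parts$detached)),
         outputs = paths)
  })

  invisible(manifest)
}
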