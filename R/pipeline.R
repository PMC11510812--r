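# Run configurations, the reduced fixture generator, and stage orchestration.

#' Default run configuration
#'
#' `fixture_run_config()` is the reduced study used throughout the test
#' suite: a 32-channel, 64 x 64, two-material phantom, 360 projections on a
#' 96-cell detector, K = 4 angular subsets, 4 x 16 x 16 blocks with 75%
#' energy / 50% spatial overlap, a base-8 U-Net trained for 20 epochs.
#' `paper_run_config()` is the full-scale configuration: 131 channels,
#' 100 x 100 phantom, 256-cell detector, 75% overlap on all block axes, a
#' base-32 U-Net trained for 100 epochs.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory for pipeline artifacts.
#' @return A `run_config` list.
#' @export
fixture_run_config <- function(seed = 1L, out_dir = tempfile("n2i-run-")) {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    phantom = list(preset = 1L, n_materials = 2L, grid = c(64L, 64L),
                   channels = 32L),
    geometry = list(source_to_object = 57.50, object_to_detector = 58.05,
                    detector_pixels = 96L, detector_pitch = 1.6,
                    n_angles = 360L, beam = "fan"),
    # preserve the full study's per-channel photon budget (60000 photons over
    # 131 channels) so the reduced channel set sees the same noise regime
    total_counts = round(60000 * 32 / 131),
    K = 4L,
    block = list(shape = c(4L, 16L, 16L), overlap = c(0.75, 0.5, 0.5)),
    model = list(base_channels = 8L, lr = 1e-3, epochs = 20L,
                 batch_size = 32L),
    tv = list(alpha = 1, iterations = 100L),
    log_level = "info"
  ), class = "run_config")
}

#' @rdname fixture_run_config
#' @export
paper_run_config <- function(seed = 1L, out_dir = tempfile("n2i-run-")) {
  cfg <- fixture_run_config(seed, out_dir)
  cfg$phantom <- list(preset = 1L, n_materials = 4L, grid = c(100L, 100L),
                      channels = 131L)
  cfg$geometry$detector_pixels <- 256L
  cfg$geometry$detector_pitch <- 0.8
  cfg$block$overlap <- c(0.75, 0.75, 0.75)
  cfg$model <- list(base_channels = 32L, lr = 1e-4, epochs = 100L,
                    batch_size = 32L)
  cfg$total_counts <- 60000
  cfg
}

# channel spectrum for a configuration: the 131 reference channels, cropped
# to a multiple of the grouping factor and block-averaged down to `channels`
.config_spectrum <- function(channels, total_counts) {
  s <- reference_channel_spectrum(total_counts)
  if (channels == 131L) return(s)
  group <- 128L %/% channels
  if (channels * group != 128L) {
    stop("invalid_channels: channel count must divide 128 (or be 131)",
         call. = FALSE)
  }
  s128 <- energy_spectrum(s$bin_centers[1:128], s$fluence[1:128], s$bin_width)
  normalize_total_counts(rebin_average(s128, group), total_counts)
}

.config_geometry <- function(gc) {
  scan_geometry(gc$source_to_object, gc$object_to_detector,
                gc$detector_pixels, gc$detector_pitch,
                seq(0, 360 - 360 / gc$n_angles, by = 360 / gc$n_angles),
                gc$beam)
}

.config_phantom <- function(pc, energies) {
  mats <- phantom_materials(pc$preset, pc$n_materials)
  shapes <- .default_shapes(pc$grid)[seq_len(pc$n_materials)]
  build_phantom(mats, shapes, pc$grid, energies)
}

#' Generate the reduced simulation fixture
#'
#' Builds a scaled-down version of the full synthetic study: a two-material
#' phantom, the matching block-averaged source spectrum normalised to the
#' photon budget, and the Poisson-noisy fan-beam sinogram.  With a fixed seed
#' the bundle is fully reproducible; different seeds change only the noise.
#'
#' @param size `c(channels, height, width)`; `channels >= 8`, square spatial
#'   grid `>= 32`.
#' @param seed Integer noise seed.
#' @param dir Optional directory; when given, the bundle is also written to
#'   disk (`phantom.tif`, `spectrum.csv`, `sinogram.tif`, `manifest.json`).
#' @return List with `phantom`, `spectrum`, `geometry`, `sinogram` (noisy),
#'   `clean_sinogram`, `config`.
#' @export
make_fixture <- function(size = c(32L, 64L, 64L), seed = 1L, dir = NULL) {
  size <- as.integer(size)
  if (size[1] < 8L || size[2] < 32L || size[2] != size[3]) {
    stop("fixture_too_small: need >= 8 channels and square spatial >= 32",
         call. = FALSE)
  }
  cfg <- fixture_run_config(seed)
  cfg$phantom$channels <- size[1]
  cfg$phantom$grid <- size[2:3]
  cfg$total_counts <- round(60000 * size[1] / 131)
  spectrum <- .config_spectrum(cfg$phantom$channels, cfg$total_counts)
  geometry <- .config_geometry(cfg$geometry)
  phantom <- .config_phantom(cfg$phantom, spectrum$bin_centers)
  clean <- project(phantom, geometry,
                   pixel_size_for(geometry, cfg$phantom$grid[2]))
  noisy <- add_poisson_noise(clean, spectrum, seed)
  out <- list(phantom = phantom, spectrum = spectrum, geometry = geometry,
              sinogram = noisy, clean_sinogram = clean, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_phantom(phantom, file.path(dir, "phantom"))
    write_spectrum_csv(spectrum, file.path(dir, "spectrum.csv"))
    write_sinogram(noisy, file.path(dir, "sinogram"))
    jsonlite::write_json(list(seed = seed, size = size,
                              config_hash = config_hash(cfg)),
                         file.path(dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  out
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialisation; identical configurations (and
#' seeds) produce identical hashes, which is what the stage manifests record.
#'
#' @param config A `run_config` (or any JSON-serialisable list).
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(rapply(list(unclass(config)), unclass, how = "replace"),
                       tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

.manifest <- function(cfg, stage, inputs, outputs) {
  list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
       inputs = inputs, outputs = outputs)
}

.write_manifest <- function(cfg, stage, inputs, outputs) {
  path <- file.path(cfg$out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(.manifest(cfg, stage, inputs, outputs), path,
                       digits = NA, auto_unbox = TRUE)
  path
}

.require_artifact <- function(cfg, path, needed_stage) {
  if (!file.exists(file.path(cfg$out_dir, path))) {
    stop("missing_dependency: artifact '", path, "' not found; run stage '",
         needed_stage, "' first", call. = FALSE)
  }
}

#' Run pipeline stages end to end
#'
#' Stages: `simulate` (phantom + spectrum + noisy sinogram), `reconstruct`
#' (K-subset and full-angle FBP), `train` (leave-one-out network),
#' `denoise`, `baseline` (IR-TV and Low2High), `evaluate` (channel-wise
#' metric report for every available stack).  Each stage writes its artifacts
#' plus a manifest carrying the seed and configuration hash, so identical
#' configurations reproduce identical manifests.
#'
#' @param config A `run_config` from [fixture_run_config()] /
#'   [paper_run_config()].
#' @param stages Character vector, subset of
#'   `c("simulate", "reconstruct", "train", "denoise", "baseline",
#'   "evaluate")`.
#' @param verbose Print stage progress.
#' @return Invisibly, a named list of manifest paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "reconstruct", "train",
                                    "denoise", "evaluate"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  known <- c("simulate", "reconstruct", "train", "denoise", "baseline",
             "evaluate")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifests <- list()

  if ("simulate" %in% stages) {
    say("stage simulate")
    spectrum <- .config_spectrum(config$phantom$channels, config$total_counts)
    geometry <- .config_geometry(config$geometry)
    phantom <- .config_phantom(config$phantom, spectrum$bin_centers)
    clean <- project(phantom, geometry,
                     pixel_size_for(geometry, config$phantom$grid[2]))
    noisy <- add_poisson_noise(clean, spectrum, config$seed)
    write_phantom(phantom, file.path(config$out_dir, "phantom"))
    write_spectrum_csv(spectrum, file.path(config$out_dir, "spectrum.csv"))
    write_sinogram(noisy, file.path(config$out_dir, "sinogram"))
    manifests$simulate <- .write_manifest(
      config, "simulate", character(),
      c("phantom.tif", "spectrum.csv", "sinogram.tif"))
  }

  if ("reconstruct" %in% stages) {
    say("stage reconstruct")
    .require_artifact(config, "sinogram.tif", "simulate")
    sino <- read_sinogram(file.path(config$out_dir, "sinogram"))
    grid <- config$phantom$grid
    sp <- split_angles(sino, config$K)
    for (j in seq_len(config$K)) {
      rec <- fbp_channelwise(sp$sinos[[j]], "ram-lak", 1, grid)
      write_stack(rec, file.path(config$out_dir, sprintf("recon_%d", j)))
    }
    full <- fbp_channelwise(sino, "ram-lak", 1, grid)
    write_stack(full, file.path(config$out_dir, "recon_full"))
    manifests$reconstruct <- .write_manifest(
      config, "reconstruct", "sinogram.tif",
      c(sprintf("recon_%d.tif", seq_len(config$K)), "recon_full.tif"))
  }

  if ("train" %in% stages) {
    say("stage train")
    .require_artifact(config, "recon_1.tif", "reconstruct")
    recons <- lapply(seq_len(config$K), function(j) {
      read_stack(file.path(config$out_dir, sprintf("recon_%d", j)))
    })
    pairs <- make_loo_pairs(recons)
    spec <- block_spec(config$block$shape, config$block$overlap)
    mc <- model_config(config$model$base_channels, config$model$lr,
                       config$model$epochs, config$model$batch_size,
                       config$seed)
    model <- train(pairs, spec, mc, verbose = verbose)
    write_model(model, file.path(config$out_dir, "model.json"))
    manifests$train <- .write_manifest(
      config, "train", sprintf("recon_%d.tif", seq_len(config$K)),
      "model.json")
  }

  if ("denoise" %in% stages) {
    say("stage denoise")
    .require_artifact(config, "model.json", "train")
    model <- read_model(file.path(config$out_dir, "model.json"))
    recons <- lapply(seq_len(config$K), function(j) {
      read_stack(file.path(config$out_dir, sprintf("recon_%d", j)))
    })
    den <- denoise(model, recons)
    write_stack(den, file.path(config$out_dir, "denoised"))
    manifests$denoise <- .write_manifest(
      config, "denoise", c("model.json",
                           sprintf("recon_%d.tif", seq_len(config$K))),
      "denoised.tif")
  }

  if ("baseline" %in% stages) {
    say("stage baseline")
    .require_artifact(config, "sinogram.tif", "simulate")
    sino <- read_sinogram(file.path(config$out_dir, "sinogram"))
    grid <- config$phantom$grid
    tv <- tv_reconstruct(sino, tv_config(config$tv$alpha,
                                         config$tv$iterations,
                                         seed = config$seed), grid)
    write_stack(tv, file.path(config$out_dir, "baseline_tv"))
    spec <- block_spec(config$block$shape, config$block$overlap)
    mc <- model_config(config$model$base_channels, config$model$lr,
                       config$model$epochs, config$model$batch_size,
                       config$seed)
    l2h <- low2high_denoise(sino, spec, mc, grid)
    write_stack(l2h$denoised, file.path(config$out_dir, "baseline_low2high"))
    manifests$baseline <- .write_manifest(
      config, "baseline", "sinogram.tif",
      c("baseline_tv.tif", "baseline_low2high.tif"))
  }

  if ("evaluate" %in% stages) {
    say("stage evaluate")
    .require_artifact(config, "phantom.tif", "simulate")
    phantom <- read_phantom(file.path(config$out_dir, "phantom"))
    targets <- c("recon_full", "denoised", "baseline_tv", "baseline_low2high")
    written <- character()
    for (tg in targets) {
      p <- file.path(config$out_dir, paste0(tg, ".tif"))
      if (!file.exists(p)) next
      rep <- evaluate_stack(read_stack(p), phantom)
      write_metric_report(rep,
                          file.path(config$out_dir, paste0("report_", tg, ".csv")),
                          file.path(config$out_dir, paste0("report_", tg, ".json")))
      written <- c(written, paste0("report_", tg, ".csv"))
    }
    if (length(written) == 0) {
      stop("missing_dependency: no reconstructed stacks to evaluate; run ",
           "stage 'reconstruct' first", call. = FALSE)
    }
    manifests$evaluate <- .write_manifest(config, "evaluate", targets, written)
  }

  invisible(manifests)
}
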