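#' Run the full SAW-OCE processing pipeline
#'
#' Orchestrates the stage chain: simulate (or load) a complex volume,
#' detect the surface and flatten, extract the lag-1 phase stack, estimate
#' the depth-resolved NSA velocity profile, smooth it, and fit the bilinear
#' interface model. Optionally trains PVNet on the run's own phase images,
#' labelled with the smoothed NSA profile (the estimation network's
#' supervision protocol), and writes its depth-resolved predictions.
#'
#' All artifacts are written under `out_dir`: `volume.h5` (simulated input,
#' when requested), `surface.csv`, `profile.csv` (+ `profile.csv.fit.json`),
#' `dli_profile.csv` (when PVNet runs), `summary.txt` and `manifest.json`
#' (config hash, seeds, versions). Stages communicate only through these
#' documented formats; reruns of the same configuration are byte-identical.
#'
#' @param config Path to a YAML pipeline configuration, or an equivalent
#'   named list. Top-level keys: `simulate` (passed to [sim_config()];
#'   `preset` selects a [sim_preset()]) or `volume` (path to an HDF5
#'   volume); optional `preprocess`, `nsa`, `interface`, `pvnet` blocks.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer overriding the configured simulation /
#'   training seeds.
#' @return Invisibly, a list with the profile, fit, artifact paths and the
#'   summary lines.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_sawoce(sprintf("[%s] %s", name, conditionMessage(e)),
                  "sawoce_pipeline")
    })
  }

  # --- acquire ------------------------------------------------------------
  sim_cfg <- NULL
  vol <- stage("simulate", {
    if (!is.null(config$volume)) {
      read_volume(config$volume)
    } else {
      sc <- config$simulate %||% list()
      preset <- sc$preset
      sc$preset <- NULL
      sc$write_volume <- NULL
      if (!is.null(sc$layers)) sc$layers <- lapply(sc$layers, unlist)
      if (!is.null(seed)) sc$seed <- seed
      sim_cfg <- if (!is.null(preset)) {
        do.call(sim_preset, c(list(name = preset), sc))
      } else {
        do.call(sim_config, sc)
      }
      simulate_volume(sim_cfg)
    }
  })
  if (!is.null(sim_cfg) && isTRUE(config$simulate$write_volume)) {
    paths$volume <- file.path(out_dir, "volume.h5")
    write_volume(vol, paths$volume)
  }

  # --- preprocess ---------------------------------------------------------
  pp <- config$preprocess %||% list()
  surf <- stage("preprocess",
                detect_surface(vol, k_sigma = pp$k_sigma %||% 5))
  paths$surface <- file.path(out_dir, "surface.csv")
  readr::write_csv(tibble(x_index = seq_along(surf) - 1L,
                          surface_index = surf - 1L),
                   paths$surface)
  flat <- stage("preprocess", flatten_volume(vol, surf))
  n_depths <- pp$n_depths %||% min(100L, dim(vol)[1] - max(surf))
  stack <- stage("preprocess",
                 extract_phase_stack(flat, n_depths = n_depths,
                                     depth_offset = pp$depth_offset %||% 0))

  # --- nsa ----------------------------------------------------------------
  nc <- do.call(nsa_config, config$nsa %||% list())
  prof <- stage("nsa", nsa_profile(stack, nc, smooth = TRUE))
  if (!is.null(sim_cfg)) {
    prof$v_true <- true_profile(sim_cfg, n_depths = nrow(prof))$v_true
  }

  # --- interface ----------------------------------------------------------
  ic <- config$interface %||% list()
  fit <- stage("interface",
               fit_bilinear(prof,
                            min_segment = ic$min_segment %||% 5,
                            jump_threshold = ic$jump_threshold %||% 0.3,
                            ratio_threshold = ic$ratio_threshold %||% 1.05))
  paths$profile <- file.path(out_dir, "profile.csv")
  write_profile(prof, paths$profile, fit = fit)

  # --- optional DLI branch ------------------------------------------------
  dli <- NULL
  if (isTRUE((config$pvnet %||% list())$enabled)) {
    pv <- config$pvnet
    dli <- stage("pvnet", {
      imgs <- lapply(seq_len(n_depths), function(z) stack$phase[z, , ])
      labels <- prof$v_smooth
      ok <- !is.na(labels) & labels > 0
      tc <- training_config(
        lr = pv$lr %||% 1e-3, batch_size = pv$batch_size %||% 32,
        max_epochs = pv$max_epochs %||% 20, patience = pv$patience %||% 15,
        seed = if (!is.null(seed)) seed else pv$seed %||% 0)
      mc <- pvnet_config(pv$variant %||% "tiny")
      fit_nn <- train_pvnet(list(images = imgs[ok], targets = labels[ok]),
                            tc, mc)
      v_dli <- predict(fit_nn, lapply(imgs, resize_phase_image,
                                      size = mc$input_size))
      velocity_profile(prof$depth_index, dz = stack$dz, v_raw = pmax(v_dli,
                                                                     1e-6))
    })
    paths$dli_profile <- file.path(out_dir, "dli_profile.csv")
    write_profile(dli, paths$dli_profile)
  }

  # --- summary + manifest -------------------------------------------------
  dz <- stack$dz
  seg_mean <- function(lo, hi) {
    v <- prof$v_smooth[prof$depth_index >= lo & prof$depth_index < hi]
    mean(v, na.rm = TRUE)
  }
  summary_lines <- c(
    sprintf("depths analysed: %d (dz = %.3g um)", nrow(prof), dz),
    sprintf("mean velocity (smoothed): %.3f m/s",
            mean(prof$v_smooth, na.rm = TRUE)),
    if (fit$has_interface) {
      c(sprintf("interface detected at depth index %g (%.3f mm)",
                fit$z_break, index_to_depth(fit$z_break, dz)),
        sprintf("velocity jump: %.3f m/s", fit$jump),
        sprintf("upper-layer mean: %.3f m/s",
                seg_mean(min(prof$depth_index), fit$z_break)),
        sprintf("lower-layer mean: %.3f m/s",
                seg_mean(fit$z_break, max(prof$depth_index) + 1)))
    } else {
      sprintf("no interface (jump %.3f m/s below threshold or fit not better than single line)",
              fit$jump)
    })
  paths$summary <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, paths$summary)
  manifest <- list(
    package = "sawoce",
    version = as.character(utils::packageVersion("sawoce")),
    config = config,
    seed_override = seed,
    sim_seed = if (!is.null(sim_cfg)) sim_cfg$seed else NULL,
    config_hash = rlang::hash(config))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(list(profile = prof, fit = fit, dli = dli, paths = paths,
                 summary = summary_lines))
}
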