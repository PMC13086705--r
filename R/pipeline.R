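#' Configuration for the synthetic end-to-end pipeline
#'
#' Collects and validates all stage parameters for [run_pipeline()]. One
#' master seed fans out deterministically to per-stage seeds (offsets in
#' the integer seed space), so a single integer reproduces every stage.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master RNG seed.
#' @param stages Character vector of stages to run, in order, from
#'   `c("tiles", "morphometry", "sheath", "velocity", "mle")`.
#' @param n_axons Axons in the synthetic population.
#' @param axon_pixel_nm Rendering resolution for the morphometry stage.
#' @param min_area_px Small-object filter for the mask stage.
#' @param n_sheath Rows in the synthetic sheath dataset.
#' @param sheath_sd_log10 Noise SD of the sheath generator.
#' @param velocities_mps True velocities of the simulated units.
#' @param n_spikes Spikes per simulated unit.
#' @param noise_sd,spike_amplitude_sd Simulator noise and spike amplitude.
#' @param amp_threshold_sd Channel eligibility threshold, SD units.
#' @param n_tiles Tiles in the flat-field stage.
#' @param mle_n Sample size of the unpaired velocity/diameter stage.
#' @param mle_k True exponent of that stage.
#' @param n_boot Bootstrap replicates for the exponent CI (0 disables).
#' @param clip_pct,floor_frac,clahe_kernel_px Tile preprocessing settings.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c("tiles", "morphometry", "sheath",
                                       "velocity", "mle"),
                            n_axons = 800, axon_pixel_nm = 100,
                            min_area_px = 4,
                            n_sheath = 137, sheath_sd_log10 = 0.05,
                            velocities_mps = c(2, -1), n_spikes = 50,
                            noise_sd = 1, spike_amplitude_sd = 5,
                            amp_threshold_sd = 1.5,
                            n_tiles = 8, mle_n = 150, mle_k = 0.64,
                            n_boot = 0, clip_pct = 10, floor_frac = 0.10,
                            clahe_kernel_px = 16) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(n_axons >= 0, n_sheath >= 3, n_tiles >= 2, mle_n >= 5,
            all(velocities_mps != 0), n_spikes >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(master, k) (as.integer(master) * 97L + k * 1009L) %% .Machine$integer.max

#' Run the synthetic study end to end
#'
#' Executes the requested stages in order — tile preprocessing on a
#' synthetic gradient stack, morphometry on a rendered axon population,
#' sheath-scaling fit, conduction-velocity estimation on simulated
#' recordings, and the exponent MLE — writing every table as CSV/JSON into
#' `out_dir` together with a provenance record (package version, seed,
#' full configuration). A stage failure aborts with the stage name;
#' completed outputs are preserved.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_bundle` with per-stage results and
#'   `paths` of everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config, paths = character(0))
  add_path <- function(p) bundle$paths <<- c(bundle$paths, p)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if ("tiles" %in% config$stages) {
    bundle$tiles <- run_stage("tiles", {
      stack <- generate_tile_stack(config$n_tiles, dim = c(64, 64),
                                   content_seed = stage_seed(config$seed, 1L))
      clipped <- lapply(stack$tiles, clip_dark, lower_pct = config$clip_pct,
                        floor_frac = config$floor_frac)
      corrected <- flat_field_correct(clipped)
      equalized <- lapply(corrected$tiles, equalize_clahe,
                          kernel_px = config$clahe_kernel_px)
      list(mean_map = corrected$mean_map, global_mean = corrected$global_mean,
           n_tiles = config$n_tiles, equalized_range = range(unlist(equalized)))
    })
  }

  if ("morphometry" %in% config$stages) {
    bundle$morphometry <- run_stage("morphometry", {
      pop <- generate_axon_population(config$n_axons,
                                      pixel_nm = config$axon_pixel_nm,
                                      seed = stage_seed(config$seed, 2L),
                                      render = TRUE)
      mask <- remove_small(pop$mask != 0, min_area_px = config$min_area_px)
      lab <- label_components(mask)
      tab <- measure_axons(lab, pixel_nm = config$axon_pixel_nm)
      p <- file.path(config$out_dir, "axon_table.csv")
      write.csv(tab, p, row.names = FALSE)
      add_path(p)
      list(table = tab, truth = pop$table,
           summary = summarize_diameters(tab),
           area_fraction = if (nrow(tab) >= 3) area_fraction(tab) else NA,
           total = total_count(nrow(tab)))
    })
  }

  if ("sheath" %in% config$stages) {
    bundle$sheath <- run_stage("sheath", {
      tab <- generate_sheath_dataset(config$n_sheath,
                                     sd_log10 = config$sheath_sd_log10,
                                     seed = stage_seed(config$seed, 3L))
      fit <- fit_scaling(tab)
      p <- file.path(config$out_dir, "sheath_table.csv")
      write.csv(tab, p, row.names = FALSE)
      add_path(p)
      list(table = tab, fit = fit)
    })
  }

  if ("velocity" %in% config$stages) {
    bundle$velocity <- run_stage("velocity", {
      probe <- make_probe()
      rows <- lapply(seq_along(config$velocities_mps), function(i) {
        v <- config$velocities_mps[i]
        cfg <- recording_config(duration_s = max(1, config$n_spikes / 25),
                                noise_sd = config$noise_sd,
                                seed = stage_seed(config$seed, 10L + i))
        rec <- simulate_recording(probe,
                                  unit_spec(v, config$spike_amplitude_sd,
                                            n_spikes = config$n_spikes), cfg)
        proc <- zscore_channels(bandpass(rec))
        wf <- extract_mean_waveforms(proc, rec$spike_times[[1]])
        wf <- correct_round_robin(wf)
        est <- estimate_velocity(wf, probe,
                                 amp_threshold_sd = config$amp_threshold_sd)
        data.frame(unit = i, v_true_mps = v, v_mps = est$v_mps,
                   direction = est$direction, n_pairs = est$n_pairs,
                   flagged = est$flagged,
                   latency_ms_1cm = to_latency(est$v_mps))
      })
      tab <- do.call(rbind, rows)
      p <- file.path(config$out_dir, "velocity_table.csv")
      write.csv(tab, p, row.names = FALSE)
      add_path(p)
      list(table = tab,
           bounds = observational_bounds(probe))
    })
  }

  if ("mle" %in% config$stages) {
    bundle$mle <- run_stage("mle", {
      sim <- generate_velocity_diameter_data(config$mle_n, k = config$mle_k,
                                             seed = stage_seed(config$seed, 4L))
      fit <- fit_exponent(sim$velocities, sim$diameters)
      if (config$n_boot >= 100) {
        ci <- exponent_bca_ci(sim$velocities, sim$diameters,
                              n_boot = config$n_boot,
                              seed = stage_seed(config$seed, 5L))
        fit$ci <- ci$ci
        fit$ci_level <- ci$level
        fit$n_boot <- ci$n_boot
      }
      fit
    })
  }

  prov <- list(package = "neckconn",
               version = as.character(utils::packageVersion("neckconn")),
               seed = config$seed,
               stages = config$stages,
               config = config[setdiff(names(config), c("template"))])
  pp <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, pp, auto_unbox = TRUE, digits = NA, force = TRUE)
  add_path(pp)
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' Summarize a pipeline bundle
#'
#' Collapses a [run_pipeline()] bundle into the study's headline
#' quantities — axon counts and diameter summary, area fraction,
#' sheath-scaling slope, velocity table with latencies and flags, and the
#' exponent fit — as a JSON-serializable list. Every number is taken
#' directly from a stage result. Missing stages are listed rather than
#' silently skipped.
#'
#' @param bundle A `pipeline_bundle`.
#' @param path Optional path to also write the summary as JSON.
#' @return The summary list (invisibly when `path` is given).
#' @export
pipeline_report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  missing <- setdiff(bundle$config$stages,
                     intersect(names(bundle),
                               c("tiles", "morphometry", "sheath",
                                 "velocity", "mle")))
  rep <- list(missing_stages = missing)
  if (!is.null(bundle$morphometry)) {
    m <- bundle$morphometry
    rep$morphometry <- list(
      hemicount = nrow(m$table),
      total_bilateral = as.integer(m$total),
      mean_d_um = m$summary$mean_um, median_d_um = m$summary$median_um,
      count_above = as.list(m$summary$count_above),
      area_fraction = m$area_fraction)
  }
  if (!is.null(bundle$sheath))
    rep$sheath <- list(slope = bundle$sheath$fit$slope,
                       intercept = bundle$sheath$fit$intercept,
                       slope_ci_halfwidth = bundle$sheath$fit$slope_ci_halfwidth,
                       n_used = bundle$sheath$fit$n_used)
  if (!is.null(bundle$velocity)) {
    vt <- bundle$velocity$table
    rep$velocity <- list(
      table = vt,
      mean_abs_v_mps = mean(abs(vt$v_mps)),
      mean_latency_ms_1cm = mean(vt$latency_ms_1cm),
      flagged_units = vt$unit[vt$flagged],
      bounds = bundle$velocity$bounds)
  }
  if (!is.null(bundle$mle)) {
    rep$exponent <- list(k_hat = bundle$mle$k_hat,
                         ci = bundle$mle$ci,
                         d_min_um = bundle$mle$d_min_um)
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, dataframe = "rows")
    return(invisible(rep))
  }
  rep
}
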