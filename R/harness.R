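# Experiment orchestration: deterministic seed derivation, study-level
# drivers for the two case studies, and run manifests.

#' Derive a stage seed from a master seed
#'
#' Deterministic, collision-resistant derivation: a polynomial hash of the
#' stage label is combined with the master seed and a counter, modulo a
#' prime below 2^31.  Distinct counters (up to the modulus) give distinct
#' seeds for a fixed master seed and stage; changing the master seed
#' changes every derived seed.  No stage of the package reads global RNG
#' state: all randomness flows from seeds derived here.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label.
#' @param counter Integer counter (default 1).
#' @return An integer seed in [1, 2^31).
#' @export
derive_seed <- function(master_seed, stage, counter = 1L) {
  p <- 2147483629
  h <- 17
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% p
  s <- (h * 48271) %% p
  s <- (s + (as.numeric(master_seed) %% p) * 69621) %% p
  s <- (s + as.numeric(counter)) %% p
  as.integer(s + 1)
}

#' Configuration for an end-to-end study run
#'
#' @param case "semantic" (hub-and-spoke lesioning) or "action" (SRN
#'   sequential-action lesioning).
#' @param scale "full" reproduces the study-scale replicate counts
#'   (20 networks x 10 lesions per level for the semantic study; 12
#'   networks x 500 episodes per cell for the action study); "desk" is a
#'   reduced preset (5 networks x 5 lesions; 3 networks x 100 episodes)
#'   that preserves every severity grid unchanged.
#' @param profiles Pattern profiles for the semantic study.
#' @param master_seed Master seed.
#' @param out_dir Output directory for CSV results and the manifest.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(case = c("semantic", "action"),
                              scale = c("desk", "full"),
                              profiles = c("P1-like", "P2-like"),
                              master_seed = 1L, out_dir = NULL) {
  case <- match.arg(case)
  scale <- match.arg(scale)
  preset <- if (scale == "full") {
    list(n_networks = 20L, lesions_per_level = 10L,
         n_srn = 12L, episodes_per_cell = 500L)
  } else {
    list(n_networks = 5L, lesions_per_level = 5L,
         n_srn = 3L, episodes_per_cell = 100L)
  }
  structure(c(list(case = case, scale = scale, profiles = profiles,
                   master_seed = as.integer(master_seed), out_dir = out_dir),
              preset),
            class = "experiment_config")
}

write_outputs <- function(out_dir, outputs, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inventory <- list()
  for (nm in names(outputs)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(outputs[[nm]], path, row.names = FALSE)
    inventory[[nm]] <- list(file = basename(path),
                            checksum = file_checksum(path))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("lesionette")),
                   config = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
                   files = inventory)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# order-insensitive content checksum (no external digest dependency)
file_checksum <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  p <- 2147483629
  h <- 5381
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% p
  }
  sprintf("%08x", as.integer(h))
}

#' Run the semantic lesioning study end to end
#'
#' Generates pattern sets, trains a cohort of hub networks per profile,
#' sweeps the requested damage grids, and returns naming-accuracy curves
#' plus per-kind area-between-curves summaries.  With \code{out_dir} set,
#' writes tidy CSVs and a manifest.
#'
#' @param config An \code{experiment_config} with \code{case = "semantic"}.
#' @param kinds Damage kinds to sweep.
#' @param epochs Optional training-epoch override.
#' @return A list: \code{curves} (tidy data.frame), \code{areas}
#'   (data.frame profile, kind, mean, ci_lo, ci_hi, sd, n), \code{nets}
#'   (per-profile list of trained networks), \code{pattern_sets}.
#' @export
run_semantic_study <- function(config = experiment_config("semantic"),
                               kinds = c("sever", "perturb", "ablate", "scale"),
                               epochs = NULL) {
  stopifnot(config$case == "semantic")
  ms <- config$master_seed
  curves <- list(); area_rows <- list()
  nets_by_profile <- list(); ps_by_profile <- list()
  for (prof_id in config$profiles) {
    profile <- build_profile(prof_id)
    ps <- generate_patterns(profile, seed = derive_seed(ms, paste0("ps_", prof_id)))
    nets <- lapply(seq_len(config$n_networks), function(i) {
      net <- init_hub(hub_config(), seed = derive_seed(ms, paste0("hub_", prof_id), i))
      train_hub(net, ps, epochs = epochs)
    })
    nets_by_profile[[prof_id]] <- nets
    ps_by_profile[[prof_id]] <- ps
    for (k in kinds) {
      grid <- damage_grid(k, lesions_per_level = config$lesions_per_level)
      curve <- run_damage_grid(nets, grid, ps,
                               master_seed = derive_seed(ms, paste0(prof_id, "_", k)))
      curve$profile <- prof_id
      curves[[paste0(prof_id, "_", k)]] <- curve
      ar <- area_between_curves(curve)
      area_rows[[paste0(prof_id, "_", k)]] <- data.frame(
        profile = prof_id, kind = k, mean = ar$mean, sd = ar$sd,
        ci_lo = ar$ci[1], ci_hi = ar$ci[2], n = ar$n, stringsAsFactors = FALSE)
    }
  }
  curves <- do.call(rbind, c(curves, make.row.names = FALSE))
  areas <- do.call(rbind, c(area_rows, make.row.names = FALSE))
  write_outputs(config$out_dir, list(naming_curves = curves, areas = areas), config)
  list(curves = curves, areas = areas, nets = nets_by_profile,
       pattern_sets = ps_by_profile)
}

#' Run the sequential-action lesioning study end to end
#'
#' Builds the beverage corpus, trains a cohort of SRNs, verifies intact
#' sequence reproduction, then sweeps the five damage kinds at the printed
#' reference severities, classifying every episode.
#'
#' @param config An \code{experiment_config} with \code{case = "action"}.
#' @param epochs Optional training-epoch override.
#' @param sweep_severities Named list of severity vectors per damage kind
#'   (defaults to \code{\link{action_severity_ladders}}).
#' @return A list: \code{nets}, \code{corpus}, \code{sweep} (tidy error
#'   aggregates), \code{survival} (per-step survival curves at the
#'   reference noise level).
#' @export
run_action_study <- function(config = experiment_config("action"),
                             epochs = NULL, sweep_severities = NULL) {
  stopifnot(config$case == "action")
  ms <- config$master_seed
  corpus <- build_corpus()
  nets <- train_srn_cohort(n = config$n_srn, corpus = corpus,
                           epochs = epochs, master_seed = ms)
  if (is.null(sweep_severities)) sweep_severities <- action_severity_ladders()
  sweep <- damage_sweep(nets, corpus, severities = sweep_severities,
                        episodes_per_cell = config$episodes_per_cell,
                        master_seed = derive_seed(ms, "sweep"))
  episodes <- run_task_episodes(nets, corpus, noise = activation_noise(0.10),
                                tasks = c("coffee", "tea"),
                                episodes_per_net = config$episodes_per_cell,
                                master_seed = derive_seed(ms, "survival"))
  survival <- survival_analysis(episodes, corpus)
  write_outputs(config$out_dir,
                list(error_sweep = sweep$aggregates, survival = survival),
                config)
  list(nets = nets, corpus = corpus, sweep = sweep, survival = survival)
}
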