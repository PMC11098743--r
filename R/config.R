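# Run configuration (YAML) and the end-to-end pipeline runner.

#' Default run configuration
#'
#' All tunable parameters of the scoring and tracer pipelines, each
#' either a published screen/assay parameter or a documented package
#' default.
#'
#' @return nested list (a `run_config`).
#' @export
default_config <- function() {
  structure(list(
    scoring = list(
      min_count = 100, min_count_invivo = 25, pseudocount = 10,
      top_k = 7, min_sgrnas = 5, p_floor = 1e-16,
      untreated_floor = -0.12, resistant_override = 1.5,
      hypersensitive_override = -1.5,
      threshold_per_replicate = TRUE
    ),
    tracer = list(
      n_cells = 0.64e6,
      response_factor = 50,
      internal_standard_level = 1e5,
      initial_volume = 300, per_sample_volume = 15,
      windows = as.list(default_import_windows())
    ),
    simulate = list(
      sigma_abund = 0.5, depth_per_sgrna = 500, doublings = 8,
      n_replicates = 2, effect = -0.5, n_spiked = 20, noise_cv = 0.05
    ),
    seed = 1,
    paths = list(out_dir = ".")
  ), class = "run_config")
}

# Recursively check cfg against the default schema; unknown keys error.
check_config_keys <- function(cfg, schema, prefix = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    sf_stop(paste0("unknown config key(s): ",
                   paste0(prefix, unknown, collapse = ", ")),
            "screenflux_strict_schema")
  }
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]])) &&
        k != "windows" && k != "effects") {
      if (!is.list(cfg[[k]])) {
        sf_stop(sprintf("config key %s%s must be a section", prefix, k),
                "screenflux_strict_schema")
      }
      check_config_keys(cfg[[k]], schema[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(cfg)
}

# Overlay user values onto defaults, depth-first.
merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && k != "windows") {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load a run configuration from YAML
#'
#' Missing keys take package defaults; unknown keys are rejected
#' (strict schema). `load_config(save_config(cfg))` round-trips
#' identically.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    sf_stop(paste("config file not found:", path), "screenflux_path_error")
  }
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  check_config_keys(user, defaults)
  cfg <- merge_config(unclass(defaults), user)
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the synthetic end-to-end pipelines
#'
#' Simulates a screen (spiked depleted genes over the configured
#' doublings), scores it, calls hits, and estimates tracer rates from a
#' simulated import time course; writes gene-score and rate tables plus
#' a provenance sidecar (config hash, seed, package version) under the
#' configured output directory. Deterministic given the config seed.
#'
#' @param config a `run_config` (see [default_config()]).
#' @return invisible list of written paths.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  sim <- config$simulate
  sc <- config$scoring

  spec <- transporter_library_spec()
  manifest <- build_manifest(spec$composition, spec$sgrnas_per_tss,
                             spec$two_tss_genes, spec$n_ntc, seed = seed)
  genes <- unique(manifest$gene[!manifest$is_ntc])
  pseudo <- make_pseudogenes(manifest, length(genes), seed = seed + 1L)
  spiked <- genes[seq_len(sim$n_spiked)]
  truth <- screen_truth(manifest,
                        effects = stats::setNames(rep(sim$effect, sim$n_spiked),
                                                  spiked),
                        sigma_abund = sim$sigma_abund,
                        depth_per_sgrna = sim$depth_per_sgrna)
  design <- two_arm_design(sim$doublings, n_replicates = sim$n_replicates)
  expt <- simulate_screen(manifest, truth, design, seed = seed + 2L)
  tables <- lapply(seq_len(sim$n_replicates), function(r) {
    score_screen(expt, manifest, pseudo,
                 pair = c(paste0("treated_r", r), paste0("T0_r", r)),
                 doublings = sim$doublings, min_count = sc$min_count,
                 pseudocount = sc$pseudocount, top_k = sc$top_k,
                 min_sgrnas = sc$min_sgrnas, p_floor = sc$p_floor)
  })
  avg <- average_replicates(tables)
  hits <- call_hits(avg, pseudogene_thresholds(avg, sc$threshold_per_replicate))
  scores_path <- file.path(out_dir, "gene_scores.tsv")
  write_gene_scores(hits, scores_path)

  tr <- config$tracer
  ttruth <- tracer_truth(J_in = 60, P = 600, noise_cv = sim$noise_cv,
                         amino_acid = "Leu")
  series <- simulate_tracer(ttruth, timepoints = c(0, 5, 10, 20, 30, 40, 100, 250),
                            internal_standard_level = tr$internal_standard_level,
                            seed = seed + 3L, response_factor = tr$response_factor,
                            n_cells = tr$n_cells)
  curve <- fit_standard_curve(simulate_standards(
    "Leu", response_factor = tr$response_factor,
    internal_standard_level = tr$internal_standard_level))
  corrected <- absolute_quantify(
    steady_state_tic_correct(
      internal_standard_correct(natural_abundance_correct(series))),
    curve)
  rate <- import_rate(corrected, window = tr$windows[[ttruth$amino_acid]])
  level <- intracellular_level(corrected)
  rates_path <- file.path(out_dir, "tracer_rates.tsv")
  utils::write.table(
    data.frame(amino_acid = rate$amino_acid, rate = rate$rate, se = rate$se,
               window_lo = rate$window[1], window_hi = rate$window[2],
               n = rate$n, r_squared = rate$r_squared,
               intracellular_level = level,
               turnover_per_min = pool_turnover(rate, level)),
    rates_path, sep = "\t", row.names = FALSE, quote = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_path)
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("screenflux")),
    r_version = R.version.string,
    outputs = c(scores_path, rates_path)
  ), prov_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(gene_scores = scores_path, tracer_rates = rates_path,
                 config = cfg_path, provenance = prov_path))
}
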