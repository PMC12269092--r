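#' Pipeline run configuration
#'
#' Collects every knob of a full simulated run: the seed, the synthetic
#' lake set size and record length, the planted driver couplings, the
#' photochemical constants, the light-field scalars, the coherence bands
#' and the surrogate count. Every constant has a default; the structure
#' round-trips losslessly through [jsonlite::toJSON()] in the run
#' manifest.
#'
#' @param seed Master integer seed (all stage sub-seeds derive from it).
#' @param n_lakes Number of synthetic lakes.
#' @param months Record length in months.
#' @param start Record start date.
#' @param couplings Driver coupling tibble (see [gen_drivers()]).
#'   Defaults plant the canonical phase structure: precipitation lagged
#'   negative at short scales, acid deposition lagged negative and soil
#'   wetness lagged positive at intermediate scales, solar irradiance in
#'   negative antiphase at intermediate scales.
#' @param constants A [photo_constants()] list.
#' @param field A [light_field()].
#' @param bands Coherence bands tibble.
#' @param n_surrogates Surrogates per coherence test.
#' @param n_compounds Screening-set size.
#' @param k_clusters Number of browning clusters (fixed at 3).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_lakes = 37, months = 360,
                       start = "1992-06-01",
                       couplings = default_couplings(),
                       constants = photo_constants(),
                       field = light_field(), bands = coherence_bands(),
                       n_surrogates = 199, n_compounds = 106,
                       k_clusters = 3) {
  if (k_clusters != 3) abort_invalid("`k_clusters` is fixed at 3.")
  structure(list(seed = as.integer(seed), n_lakes = n_lakes,
                 months = months, start = start, couplings = couplings,
                 constants = constants, field = field, bands = bands,
                 n_surrogates = n_surrogates, n_compounds = n_compounds,
                 k_clusters = 3L),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_couplings <- function() {
  tibble(
    driver = c("deposition", "precipitation", "soil_wetness",
               "irradiance"),
    band_lo = c(12, 3, 12, 12),
    band_hi = c(24, 6, 24, 24),
    magnitude = c(0.6, 0.6, 0.6, 0.6),
    phase = c(1.35, 1.91, -1.31, 3.06)
  )
}

#' Run the full simulated analysis pipeline
#'
#' Generates the synthetic lake set and records, runs the trend and
#' browning-classification stage, the driver-coherence stage, the
#' quantum-yield and steady-state photochemistry stage and the
#' contaminant screening stage, and assembles the group comparisons.
#' When `out_dir` is given, every table is written as tidy CSV together
#' with a machine-readable JSON manifest (seed, configuration hash);
#' identical configurations give identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a named list of result tables: `lakes`,
#'   `chemistry`, `trends`, `clusters`, `coherence`, `photochem`,
#'   `screening`, `comparisons`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  seed <- config$seed
  lakes <- gen_lakes(config$n_lakes, seed = seed)

  chem <- purrr::map_dfr(seq_len(nrow(lakes)), function(i) {
    gen_chemistry(lakes[i, ], start = config$start,
                  months = config$months, seed = seed + 1000L * i)
  })

  trends <- trend_table(chem)
  clusters <- classify_browning(trends, seed = seed)

  doc_mat <- vapply(split(chem$doc, chem$lake_id), fill_gaps_linear,
                    numeric(config$months))
  doc_mean <- rowMeans(doc_mat)
  drivers <- gen_drivers(
    tibble(date = unique(chem$date), doc = doc_mean),
    config$couplings, seed = seed)
  coherence <- coherence_table(doc_mat, drivers, bands = config$bands,
                               n_surrogates = config$n_surrogates,
                               seed = seed)

  photo <- purrr::map_dfr(seq_len(nrow(lakes)), function(i) {
    lk <- lakes[i, ]
    spec <- gen_spectrum(0.45 * lk$doc_baseline, 0.016)
    ra <- rate_light_absorption(spec, config$field)
    trace <- gen_kinetics(lk$phi_true, ra = ra, species = "FFA",
                          noise_cv = 0.02, seed = seed + i,
                          constants = config$constants)
    k_obs <- fit_first_order(trace)$k_obs
    qy <- apparent_quantum_yield(k_obs, ra, constants = config$constants)
    ss <- steady_state_1o2(qy, config$field,
                           lake_optical_model(lk$doc_baseline),
                           constants = config$constants)
    dplyr::bind_cols(tibble(lake_id = lk$lake_id), qy, ss)
  })
  photo <- left_join(photo,
                     select(as_tibble(clusters), "lake_id", "cluster"),
                     by = "lake_id") %>%
    left_join(select(lakes, "lake_id", "hydro_class", "till_class",
                     "tau_years"),
              by = "lake_id")

  compounds <- gen_compounds(config$n_compounds, seed = seed)
  screening <- photo %>%
    filter(!is.na(.data$cluster)) %>%
    group_by(.data$cluster) %>%
    summarise(c_med = median(.data$c_euphotic),
              tau_med = median(.data$tau_years), .groups = "drop") %>%
    purrr::pmap_dfr(function(cluster, c_med, tau_med) {
      dplyr::bind_cols(tibble(cluster = cluster),
                       screen_compounds(compounds, c_med, tau_med))
    })

  # group comparisons need >= 2 groups of >= 3 lakes; small simulated
  # sets may not provide them, which is not a pipeline failure
  try_comparison <- function(data, value, group) {
    suppressWarnings(tryCatch(
      compare_groups(data, {{ value }}, {{ group }}),
      error = function(e) NULL))
  }
  comparisons <- list(
    phi_by_hydro = try_comparison(photo, .data$phi_app,
                                  .data$hydro_class),
    c_by_cluster = try_comparison(filter(photo, !is.na(.data$cluster)),
                                  .data$c_euphotic, .data$cluster)
  )

  manifest <- list(seed = seed,
                   config_hash = rlang::hash(unclass(config)),
                   n_lakes = config$n_lakes, months = config$months,
                   package_version =
                     as.character(utils::packageVersion("lakephoto")))

  out <- list(lakes = lakes, chemistry = chem, trends = trends,
              clusters = clusters, coherence = coherence,
              photochem = photo, screening = screening,
              comparisons = comparisons, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(lakes, file.path(out_dir, "lakes.csv"))
    readr::write_csv(chem, file.path(out_dir, "chemistry.csv"))
    readr::write_csv(trends, file.path(out_dir, "trends.csv"))
    readr::write_csv(as_tibble(clusters),
                     file.path(out_dir, "clusters.csv"))
    readr::write_csv(coherence, file.path(out_dir, "coherence.csv"))
    readr::write_csv(photo, file.path(out_dir, "photochem.csv"))
    readr::write_csv(screening, file.path(out_dir, "screening.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Read a tidy chemistry CSV
#'
#' Long format: `lake_id`, `date`, `parameter`, `value`; pivoted to the
#' wide per-parameter layout the trend stage consumes.
#'
#' @param path CSV path.
#' @return Wide chemistry tibble.
#' @export
read_chemistry_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(lake_id = "c", date = "D")) %>%
    tidyr::pivot_wider(names_from = "parameter", values_from = "value") %>%
    arrange(.data$lake_id, .data$date)
}
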