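#' Run the full vulnerability analysis on a synthetic landscape
#'
#' Chains every stage end-to-end on generated data: present climate stack ->
#' clustered occurrences and censuses with planted demographic coupling ->
#' correlation/VIF predictor selection -> pseudo-absence x repetition
#' suitability ensemble -> projection to 5 GCM-like x 2 emission-pathway
#' future stacks -> per-scenario vulnerability surfaces over the present
#' footprint -> per-plant and per-population CCVI (overall, per-pathway and
#' present-scenario averages) -> census summaries -> association models.
#'
#' Future stacks apply a directional shift (in standardized predictor units)
#' to the first predictor — the axis along which populations are planted — and
#' a weaker shift to the remaining predictors, with a per-GCM multiplier and
#' cellwise noise providing between-scenario spread.
#'
#' @param seed integer seed driving every random stage.
#' @param n_rows,n_cols landscape size in cells.
#' @param autocorr_range field smoothness in cells.
#' @param layer_names predictor labels.
#' @param truth a [synthetic_truth()]; defaults to the standard 13-population
#'   study system.
#' @param plants_per_population census sizes.
#' @param n_gcms number of GCM-like future variants per pathway.
#' @param ssp_shifts named shifts (first-predictor, standardized units) for
#'   the two emission pathways.
#' @param secondary_shift_frac fraction of the shift applied to the other
#'   predictors.
#' @param gcm_spread sd of the per-GCM multiplicative spread on the shift.
#' @param noise_sd cellwise future noise sd.
#' @param algorithms,n_pa_scenarios,n_reps,split_ratio,tss_min ensemble
#'   protocol, passed to [fit_sdm_ensemble()].
#' @param center CCVI centering mode, passed to [ccvi_surface()].
#' @return A `vulnerability_analysis` list: `census`, `populations` (planted
#'   truth), `selection`, `model`, `present_map`, `present_binary`,
#'   `per_plant` (census + `ccvi_all`, `ccvi_ssp126`, `ccvi_ssp585`,
#'   `ccvi_present`), `population_ccvi`, `summaries`, `associations`, `seed`.
#' @export
run_vulnerability_pipeline <- function(seed = 1, n_rows = 96, n_cols = 96,
                                       autocorr_range = 4,
                                       layer_names = c("bio03", "bio07", "bio15", "bio19"),
                                       truth = synthetic_truth(seed = seed),
                                       plants_per_population = c(11, 209, 109, 4, 77, 298, 22,
                                                                 283, 181, 89, 251, 33, 48),
                                       n_gcms = 5,
                                       ssp_shifts = c("SSP1-RCP2.6" = 0.3, "SSP5-RCP8.5" = 0.55),
                                       secondary_shift_frac = 0,
                                       gcm_spread = 0.25, noise_sd = 0.05,
                                       algorithms = "glm_quadratic", n_pa_scenarios = 5, n_reps = 15,
                                       split_ratio = 0.7, tss_min = 0.8, n_pa = 1000,
                                       center = "threshold") {
  seed <- as.integer(seed)
  present <- generate_climate_stack(n_rows, n_cols, layer_names,
                                    autocorr_range = autocorr_range, seed = seed)
  syn <- generate_species_occurrences(present, truth,
                                      n_populations = length(truth$v),
                                      plants_per_population = plants_per_population,
                                      seed = seed)
  census <- syn$census

  selection <- select_predictors(present)
  stack_sel <- apply_selection(present, selection)

  occ <- rasterize_occurrences(census, present)
  model <- fit_sdm_ensemble(occ, stack_sel, algorithms = algorithms,
                            n_pa_scenarios = n_pa_scenarios, n_reps = n_reps,
                            split_ratio = split_ratio, tss_min = tss_min,
                            n_pa = n_pa, seed = seed)

  present_map <- project_ensemble(model, stack_sel, scenario = "present")
  present_binary <- binarize(present_map, model$threshold)

  # per-GCM shift multipliers, fixed by the seed
  withr::local_seed(seed)
  gcm_mult <- 1 + stats::rnorm(n_gcms, sd = gcm_spread)
  future_seeds <- sample.int(2^30, n_gcms * length(ssp_shifts))

  per_plant_long <- list()
  surfaces <- list()
  i <- 0
  for (g in seq_len(n_gcms)) {
    for (ssp in names(ssp_shifts)) {
      i <- i + 1
      delta <- ssp_shifts[[ssp]] * gcm_mult[g]
      shift <- stats::setNames(rep(delta * secondary_shift_frac, length(layer_names)),
                               layer_names)
      shift[layer_names[1]] <- delta
      fut <- generate_future_stack(present, shift = shift, noise_sd = noise_sd,
                                   seed = future_seeds[i])
      scen <- sprintf("gcm%d %s", g, ssp)
      fmap <- project_ensemble(model, apply_selection(fut, selection), scenario = scen)
      # a scenario whose footprint suitability is uniform (total loss) carries
      # no relative-vulnerability information; drop it from the averages
      surf <- tryCatch(ccvi_surface(present_binary, fmap, center = center,
                                    threshold = model$threshold, scenario = scen),
                       error = function(e) {
                         message("scenario ", scen, " dropped: ", conditionMessage(e))
                         NULL
                       })
      if (is.null(surf)) next
      surfaces[[scen]] <- surf
      per_plant_long[[scen]] <- suppressWarnings(
        extract_plant_ccvi(surf, census)[c("plant_id", "population", "scenario", "ccvi")])
    }
  }
  # present-scenario index for the no-change reference
  surf_present <- ccvi_surface(present_binary, present_map, center = center,
                               threshold = model$threshold, scenario = "present")
  ccvi_present <- suppressWarnings(
    extract_plant_ccvi(surf_present, census)[c("plant_id", "ccvi")])

  long <- dplyr::bind_rows(per_plant_long)
  n_na <- sum(is.na(long$ccvi))
  if (n_na > 0) {
    message(n_na, " plant-scenario value(s) outside the footprint dropped")
    drop_ids <- unique(long$plant_id[is.na(long$ccvi)])
    long <- long[!long$plant_id %in% drop_ids, ]
  }
  avg <- function(subset) scenario_average(long, subset)
  per_plant <- census |>
    dplyr::left_join(dplyr::rename(avg("all"), ccvi_all = "ccvi"), by = "plant_id") |>
    dplyr::left_join(dplyr::rename(avg("SSP1-RCP2.6"), ccvi_ssp126 = "ccvi"), by = "plant_id") |>
    dplyr::left_join(dplyr::rename(avg("SSP5-RCP8.5"), ccvi_ssp585 = "ccvi"), by = "plant_id") |>
    dplyr::left_join(dplyr::rename(ccvi_present, ccvi_present = "ccvi"), by = "plant_id")

  pop_ccvi <- dplyr::bind_rows(
    population_ccvi(per_plant$ccvi_all, per_plant$population, "all-2055"),
    population_ccvi(per_plant$ccvi_ssp126, per_plant$population, "SSP1-RCP2.6"),
    population_ccvi(per_plant$ccvi_ssp585, per_plant$population, "SSP5-RCP8.5"),
    population_ccvi(per_plant$ccvi_present, per_plant$population, "present"))

  wide <- pop_ccvi |>
    dplyr::select("population", "scenario", "mean_ccvi") |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "mean_ccvi") |>
    dplyr::rename(mean_ccvi = "all-2055", mean_ccvi_ssp126 = "SSP1-RCP2.6",
                  mean_ccvi_ssp585 = "SSP5-RCP8.5", mean_ccvi_present = "present")

  summaries <- summarize_population(census, ccvi = wide)

  assoc_data <- tidyr::drop_na(summaries, "mean_ccvi", "mean_ccvi_ssp585")
  plants_assoc <- tidyr::drop_na(per_plant, "ccvi_all", "ccvi_ssp585")
  associations <- association_table(
    assoc_data,
    scenarios = c("CCVI 2055" = "mean_ccvi", "CCVI 2055 SSP5-RCP8.5" = "mean_ccvi_ssp585"),
    plants = dplyr::rename(plants_assoc, mean_ccvi = "ccvi_all",
                           mean_ccvi_ssp585 = "ccvi_ssp585"))

  structure(list(seed = seed, census = census, populations = syn$populations,
                 truth = truth, selection = selection, model = model,
                 present_map = present_map, present_binary = present_binary,
                 surfaces = surfaces, per_plant = per_plant,
                 population_ccvi = pop_ccvi, summaries = summaries,
                 associations = associations),
            class = "vulnerability_analysis")
}

#' @export
print.vulnerability_analysis <- function(x, ...) {
  cat(sprintf("<vulnerability_analysis> seed %d: %d plants in %d populations\n",
              x$seed, nrow(x$census), length(unique(x$census$population))))
  cat(sprintf("  ensemble: %d members, TSS %.3f, threshold %d/1000\n",
              length(x$model$learners), x$model$tss, x$model$threshold))
  cat("  association models:\n")
  a <- x$associations
  for (i in seq_len(nrow(a)))
    cat(sprintf("   %-34s %-22s %s = %8.3f  p = %.3g\n", a$response[i], a$scenario[i],
                a$statistic_type[i], a$statistic[i], a$p_value[i]))
  invisible(x)
}

#' Replicate the pipeline and summarize planted-effect recovery
#'
#' Repeats [run_vulnerability_pipeline()] under different seeds and records,
#' per replicate, the population-level linear slope of mean stem length on
#' mean CCVI and the binomial slope of the young proportion on mean CCVI,
#' with their p-values. With the default planted coupling (negative stem
#' slope, positive young-fraction slope) this measures how often the full
#' pipeline recovers the planted signs at the 5% level.
#'
#' @param n_replicates number of replicates.
#' @param seed base seed; replicate r uses `seed + 1000 * r`.
#' @param ... passed to [run_vulnerability_pipeline()].
#' @return Tibble: `replicate`, `seed`, `stem_slope`, `stem_p`,
#'   `young_slope`, `young_p`, `ensemble_tss`, `ok` (FALSE when a replicate
#'   failed, e.g. no ensemble member passed the TSS cut).
#' @export
recover_planted_effects <- function(n_replicates = 50, seed = 1, ...) {
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    s <- as.integer(seed + 1000 * r)
    res <- tryCatch(suppressMessages(run_vulnerability_pipeline(seed = s, ...)),
                    error = function(e) e)
    if (inherits(res, "error"))
      return(tibble::tibble(replicate = r, seed = s, stem_slope = NA_real_,
                            stem_p = NA_real_, young_slope = NA_real_,
                            young_p = NA_real_, ensemble_tss = NA_real_, ok = FALSE))
    smry <- tidyr::drop_na(res$summaries, "mean_ccvi")
    lmfit <- linear_fit(smry, "mean_stem_cm", "mean_ccvi")
    d <- dplyr::mutate(smry, total = .data$n_young + .data$n_adult)
    binfit <- binomial_fit(d, "n_young", "total", "mean_ccvi")
    tibble::tibble(replicate = r, seed = s,
                   stem_slope = lmfit$slope, stem_p = lmfit$p_value,
                   young_slope = binfit$slope, young_p = binfit$p_value,
                   ensemble_tss = res$model$tss, ok = TRUE)
  })
}
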