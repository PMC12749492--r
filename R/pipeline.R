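#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed (every stochastic stage derives a named
#'   stream from it).
#' @param stages Named logical vector toggling the stages
#'   (synth, specialise, zeta, markers, rates, power).
#' @param total_reads_per_sample Amplicon depth for the synthetic community.
#' @param n_subsamples Monte-Carlo subsamples for zeta statistics.
#' @return A config list suitable for [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = "foreland_run", seed = 1,
                                    stages = c(synth = TRUE, specialise = TRUE,
                                               zeta = TRUE, markers = TRUE,
                                               rates = TRUE, power = TRUE),
                                    total_reads_per_sample = 1e5,
                                    n_subsamples = 1000) {
  list(out_dir = out_dir, seed = seed, stages = as.list(stages),
       total_reads_per_sample = total_reads_per_sample,
       n_subsamples = n_subsamples)
}

validate_config <- function(config) {
  need <- c("out_dir", "seed", "stages")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  stage_names <- c("synth", "specialise", "zeta", "markers", "rates", "power")
  unknown <- setdiff(names(config$stages), stage_names)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  enabled <- stage_names[vapply(stage_names, function(s)
    isTRUE(config$stages[[s]]), logical(1))]
  downstream <- setdiff(enabled, "synth")
  if (length(downstream) && !"synth" %in% enabled) {
    stop("downstream stages need the synth stage (or precomputed inputs)")
  }
  if (length(enabled) && is.null(config$seed)) stop("seed required")
  config
}

#' Run the foreland analysis pipeline on synthetic data
#'
#' Orchestrates the stages synthesize -> specialise -> zeta -> markers ->
#' rates -> power over one configuration, writing each stage's outputs as
#' TSV/JSON under `out_dir` and a JSON run manifest listing every output.
#' Reruns with an identical config and seed reproduce all stage outputs
#' byte-for-byte.
#'
#' @param config Config list (see [default_pipeline_config()]) or path to a
#'   YAML file with the same fields.
#' @return The manifest (invisibly), a list with per-stage output paths and
#'   headline numbers.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  seed <- config$seed
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(s) isTRUE(config$stages[[s]])
  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   package_version = as.character(utils::packageVersion("forelandr")),
                   outputs = list(), stats = list())
  outfile <- function(name) file.path(out_dir, name)
  message_stage <- function(s) message("[forelandr] stage: ", s)

  community <- NULL
  if (on_stage("synth")) {
    message_stage("synth")
    designs <- default_designs(seed)
    truths <- default_community_truths()
    community <- list(
      antarctic = generate_community(designs$antarctic, truths,
                                     config$total_reads_per_sample,
                                     seed = stream_seed(seed, "antarctic_comm")),
      swiss = generate_community(designs$swiss, truths,
                                 config$total_reads_per_sample,
                                 seed = stream_seed(seed, "swiss_comm"))
    )
    for (g in names(community)) {
      write_abundance_tsv(community[[g]], outfile(paste0(g, "_counts.tsv")),
                          outfile(paste0(g, "_metadata.tsv")))
      manifest$outputs[[paste0(g, "_counts")]] <- outfile(paste0(g, "_counts.tsv"))
      manifest$outputs[[paste0(g, "_metadata")]] <- outfile(paste0(g, "_metadata.tsv"))
    }
    truth_json <- truths
    truth_json$marker_genes <- vapply(truths$marker_genes, paste,
                                      character(1), collapse = ",")
    jsonlite::write_json(truth_json, outfile("truth_registry.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    manifest$outputs$truth_registry <- outfile("truth_registry.json")
  }

  spec_tables <- NULL
  if (on_stage("specialise")) {
    message_stage("specialise")
    if (is.null(community)) stop("stage specialise aborted: no community")
    spec_tables <- lapply(community, function(cm) {
      classify_specialisation(specialisation_index(cm))
    })
    for (g in names(spec_tables)) {
      write_specialisation_tsv(spec_tables[[g]],
                               outfile(paste0(g, "_specialisation.tsv")))
      manifest$outputs[[paste0(g, "_specialisation")]] <-
        outfile(paste0(g, "_specialisation.tsv"))
    }
    props <- class_proportions(community$swiss, spec_tables$swiss, "age_class")
    utils::write.table(props, outfile("swiss_class_proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$swiss_class_proportions <- outfile("swiss_class_proportions.tsv")
  }

  if (on_stage("zeta")) {
    message_stage("zeta")
    if (is.null(community)) stop("stage zeta aborted: no community")
    inc <- incidence_matrix(community$swiss)
    dec <- zeta_decline(inc, i_max = 6, n_subsamples = config$n_subsamples,
                        seed = stream_seed(seed, "zeta"))
    utils::write.table(dec$orders, outfile("zeta_decline.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(dec$fits, outfile("zeta_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    decay2 <- zeta_distance_decay(inc, i = 2,
                                  n_subsamples = config$n_subsamples,
                                  seed = stream_seed(seed, "decay"))
    decay4 <- zeta_distance_decay(inc, i = 4,
                                  n_subsamples = config$n_subsamples,
                                  seed = stream_seed(seed, "decay"))
    utils::write.table(rbind(cbind(order = 2, decay2$records),
                             cbind(order = 4, decay4$records)),
                       outfile("zeta_decay.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs$zeta_decline <- outfile("zeta_decline.tsv")
    manifest$outputs$zeta_fits <- outfile("zeta_fits.json")
    manifest$outputs$zeta_decay <- outfile("zeta_decay.tsv")
    manifest$stats$zeta <- list(selected_model = dec$selected_model,
                                zeta2_jaccard = dec$orders$zeta_jaccard[2],
                                decay_slope_z2 = decay2$slope,
                                decay_slope_z4 = decay4$slope)
  }

  profile <- NULL
  if (on_stage("markers")) {
    message_stage("markers")
    if (is.null(community)) stop("stage markers aborted: no community")
    manifest_tbl <- default_marker_manifest()
    hits <- generate_marker_hits(community$swiss, manifest_tbl,
                                 reads_total = 1e6, fail_fraction = 0.1,
                                 seed = stream_seed(seed, "markers"))
    filtered <- filter_read_hits(hits, manifest_tbl)
    profile <- gene_profile(filtered, manifest_tbl, total_reads = 1e6)
    write_gene_profile_tsv(profile, outfile("gene_profile.tsv"))
    manifest$outputs$gene_profile <- outfile("gene_profile.tsv")
  }

  rates <- NULL
  qpcr <- NULL
  if (on_stage("rates")) {
    message_stage("rates")
    rates <- list()
    for (g in c("h2", "co", "ch4")) {
      sp <- gas_species(g)
      k_true <- c(h2 = 0.2, co = 0.15, ch4 = 0.02)[[g]]
      ts <- generate_gas_timeseries(g, k_true = k_true,
                                    c_atm = sp$c_atm_ppmv, k_abiotic = 0.005,
                                    noise_sd = 0.01,
                                    seed = stream_seed(seed, paste0("gas", g)))
      live <- ts[ts$treatment == "live" & ts$replicate == 1, ]
      killed <- ts[ts$treatment == "heat_killed" & ts$replicate == 1, ]
      rates[[g]] <- fit_first_order(
        live$time_h, live$ppmv,
        control = list(times = killed$time_h, conc = killed$ppmv),
        headspace_volume_l = 0.12, soil_dry_g = 10,
        c_atm_ppmv = sp$c_atm_ppmv)
    }
    nut <- generate_nutrient_series("linear", list(c0 = 50, slope = -2),
                                    times = 0:10, noise_sd = 0.5,
                                    seed = stream_seed(seed, "nutrient"))
    nut_fit <- fit_nutrient_rate(nut$time_days, nut$conc_uM)
    qg <- generate_qpcr(c(site1 = 2e7, site2 = 2e8), noise_sd_cp = 0.1,
                        seed = stream_seed(seed, "qpcr"))
    qpcr <- quantify_qpcr(qg$standards, qg$unknowns, soil_dry_g = 0.5)
    rate_tab <- data.frame(
      gas = names(rates),
      k_per_h = vapply(rates, `[[`, numeric(1), "k_per_h"),
      k_net_per_h = vapply(rates, `[[`, numeric(1), "k_net_per_h"),
      rate_atm_nmol_per_gdw_h = vapply(rates, `[[`, numeric(1),
                                       "rate_atm_nmol_per_gdw_h"),
      model = vapply(rates, `[[`, character(1), "model")
    )
    utils::write.table(rate_tab, outfile("gas_rates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(qpcr$quant, outfile("qpcr_quant.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(nutrient = unclass(nut_fit),
                              qpcr_curve = qpcr$curve),
                         outfile("rate_fits.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$outputs$gas_rates <- outfile("gas_rates.tsv")
    manifest$outputs$qpcr_quant <- outfile("qpcr_quant.tsv")
    manifest$outputs$rate_fits <- outfile("rate_fits.json")
  }

  if (on_stage("power")) {
    message_stage("power")
    if (is.null(rates) || is.null(profile)) {
      stop("stage power aborted: needs rates and markers stages")
    }
    fam_of_gas <- c(h2 = "hhyL", co = "coxL", ch4 = "pmoA")
    cells <- mean(qpcr$quant$copies_per_gdw)
    results <- list()
    for (g in names(rates)) {
      sp <- gas_species(g)
      dg <- gibbs_energy(sp)
      frac <- profile$copies_per_organism[profile$family == fam_of_gas[[g]]]
      frac <- min(max(frac, 1e-6), 1)
      results[[g]] <- power_per_cell(rates[[g]]$rate_atm_nmol_per_gdw_h, dg,
                                     cells_per_gdw = cells,
                                     oxidizer_fraction = frac, gas = g,
                                     site = "swiss")
    }
    psum <- summarize_power(results)
    power_tab <- data.frame(
      gas = names(results),
      dG_kJ_mol = vapply(results, `[[`, numeric(1), "dG_kJ_mol"),
      power_W_per_cell = vapply(results, `[[`, numeric(1), "power_W_per_cell"),
      within_window = vapply(results, `[[`, logical(1),
                             "within_maintenance_window")
    )
    utils::write.table(power_tab, outfile("power_per_cell.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(psum, outfile("power_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs$power_per_cell <- outfile("power_per_cell.tsv")
    manifest$outputs$power_summary <- outfile("power_summary.json")
    manifest$stats$power <- psum
  }

  manifest$completed_utc <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
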