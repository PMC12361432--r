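#' Demonstration ground-truth table
#'
#' A compact variant panel spanning the phenotype classes the pipeline is
#' designed to resolve: a binding-dead mutant, a signaling-dead mutant with
#' partial binding, pathway-biased mutants in both directions, enhanced
#' binders, and constitutively active variants (basal BRET offset, one of
#' them with reduced surface expression).
#'
#' @return A [truth_table].
#' @export
demo_truth_table <- function() {
  truth_table(
    variant_truth("WT"),
    variant_truth("parental", binding_bmax_scale = 0, emax_ca_scale = 0,
                  emax_arr_scale = 0, expression_scale = 1),
    variant_truth("R44A", binding_bmax_scale = 0.02, emax_ca_scale = 0.05,
                  emax_arr_scale = 0.05),
    variant_truth("K211A", binding_bmax_scale = 0.6, emax_ca_scale = 0.1,
                  emax_arr_scale = 0.1),
    variant_truth("T208A", binding_bmax_scale = 1, emax_ca_scale = 1,
                  emax_arr_scale = 0.05),
    variant_truth("N271A", binding_bmax_scale = 1, emax_ca_scale = 0.15,
                  emax_arr_scale = 1.3, basal_bret_offset = 0.04),
    variant_truth("S207A", binding_bmax_scale = 1.5, emax_ca_scale = 1.5,
                  emax_arr_scale = 1.4),
    variant_truth("Y126A", binding_bmax_scale = 2.5, emax_ca_scale = 1.2,
                  emax_arr_scale = 1.2, basal_bret_offset = 0.05,
                  expression_scale = 0.8))
}

#' Run configuration
#'
#' Central parameter record echoed into all outputs for provenance.
#'
#' @param concs molar agonist concentrations (6 by default).
#' @param n_experiments independent experiments.
#' @param n_replicates wells per condition per experiment.
#' @param noise a [noise_model].
#' @param window,baseline_points,horizon kinetics settings.
#' @param top_conc binding readout concentration (molar).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(concs = 10^seq(-10.5, -8, by = 0.5),
                       n_experiments = 3, n_replicates = 3,
                       noise = noise_model(), window = 10L,
                       baseline_points = 10L, horizon = 600,
                       top_conc = 3e-7, seed = 1L) {
  structure(list(concs = concs, n_experiments = n_experiments,
                 n_replicates = n_replicates, noise = noise,
                 window = window, baseline_points = baseline_points,
                 horizon = horizon, top_conc = top_conc, seed = seed),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a [run_config].
#' @param path output YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  cfg$noise <- do.call(noise_model, raw$noise)
  cfg
}

.config_hash <- function(config)
  sprintf("%08x", sum(utf8ToInt(paste(
    utils::capture.output(utils::str(unclass(config))), collapse = ""))))

#' Simulate a complete synthetic dataset
#'
#' Writes, for each experiment: plate map + long-format trace CSVs for the
#' calcium and arrestin assays, a flow-cytometry table (at the
#' concentration-response concentrations plus the top binding
#' concentration), a toy structural ensemble (PDB files), a basal-activity
#' table derived from the truth, the truth table, and the configuration.
#'
#' @param out_dir dataset directory (created).
#' @param truths a [truth_table] (default [demo_truth_table()]).
#' @param config a [run_config].
#' @return `out_dir`, invisibly.
#' @export
simulate_dataset <- function(out_dir, truths = demo_truth_table(),
                             config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, config$n_experiments * 3)
  si <- 0L
  for (e in seq_len(config$n_experiments)) {
    ex <- sprintf("E%d", e)
    for (assay in c("ca", "arrestin")) {
      si <- si + 1L
      nz <- config$noise; nz$seed <- seeds[si]
      pl <- simulate_plate(truths, config$concs, assay = assay,
                           n_replicates = config$n_replicates, noise = nz,
                           experiment_id = ex)
      write_tables(pl$plate,
                   file.path(out_dir, sprintf("plate_%s_%s.csv", assay, ex)))
      write_traces(pl$traces,
                   file.path(out_dir, sprintf("traces_%s_%s.csv", assay, ex)))
    }
    si <- si + 1L
    nz <- config$noise; nz$seed <- seeds[si]
    fl <- simulate_flow_table(truths,
                              sort(unique(c(config$concs, config$top_conc))),
                              noise = nz, experiment_id = ex)
    write_tables(fl, file.path(out_dir, sprintf("flow_%s.csv", ex)))
  }
  # toy structural ensemble + inactive reference
  toy <- generate_toy_ensemble(seed = config$seed)
  for (m in toy$ensemble$models)
    write_structure(m, file.path(out_dir, paste0(m$model_id, ".pdb")))
  write_structure(toy$ensemble$reference_inactive,
                  file.path(out_dir, "inactive_ref.pdb"))
  jsonlite::write_json(toy$truth,
                       file.path(out_dir, "ensemble_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  # basal / expression table from the truth (noiseless bookkeeping values)
  bp <- bret_trace_params()
  basal <- data.frame(
    variant = truths$variant,
    basal_bret = bp$basal_ratio + truths$basal_bret_offset,
    donor_luminescence = bp$donor_level * truths$expression_scale,
    acceptor_level = 1,
    surface_level_eq1 = truths$expression_scale,
    total_level_lum = bp$donor_level)
  write_tables(basal[basal$variant != "parental", ],
               file.path(out_dir, "basal.csv"))
  write_tables(as.data.frame(truths), file.path(out_dir, "truth.csv"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

# per-experiment summary responses for one kinetic assay
.plate_responses <- function(plate, traces, assay, config) {
  buffers <- plate[plate$role %in% c("buffer", "vehicle"), ]
  agonists <- plate[plate$role == "agonist", ]
  rows <- lapply(seq_len(nrow(agonists)), function(i) {
    w <- agonists[i, ]
    bwell <- buffers$well_id[buffers$variant == w$variant &
                               buffers$replicate == w$replicate][1]
    if (is.na(bwell))
      stop("no buffer well for variant ", w$variant, " replicate ",
           w$replicate)
    val <- if (assay == "ca")
      ca_peak_response(traces[[w$well_id]], traces[[bwell]],
                       window = config$window,
                       baseline_points = config$baseline_points)$value
    else
      bret_auc_response(traces[[w$well_id]], traces[[bwell]],
                        horizon = config$horizon, window = config$window,
                        baseline_points = config$baseline_points)$value
    data.frame(variant = w$variant, concentration = w$concentration,
               value = val)
  })
  do.call(rbind, rows)
}

#' Analyze a simulated (or equivalently formatted) dataset
#'
#' Runs the full pipeline: kinetic normalization and per-well responses,
#' per-experiment concentration-response curves and AUCRCs, mutant:WT
#' impact ratios for the calcium and arrestin readouts, 300 nM binding
#' impacts, log-ratio ANOVA with Holm-Sidak correction, radar table and
#' figure, bias indices, basal-activity analysis, and structural-ensemble
#' metrics. Writes CSV/JSON/SVG outputs plus a per-variant JSON summary.
#'
#' @param data_dir dataset directory written by [simulate_dataset()].
#' @param out_dir report directory (created).
#' @param config a [run_config]; default read from the dataset.
#' @return Invisibly, the summary list.
#' @export
analyze_dataset <- function(data_dir, out_dir,
                            config = NULL) {
  if (is.null(config)) {
    cfgp <- file.path(data_dir, "config.yaml")
    config <- if (file.exists(cfgp)) read_run_config(cfgp) else run_config()
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plates <- list.files(data_dir, "^plate_", full.names = TRUE)
  resp <- list(); crc_list <- list()
  for (pf in plates) {
    info <- regmatches(basename(pf),
                       regexec("^plate_([a-z]+)_(E[0-9]+)\\.csv$",
                               basename(pf)))[[1]]
    assay_raw <- info[2]; ex <- info[3]
    assay <- if (assay_raw == "ca") "ca" else "arr3"
    plate <- tryCatch(read_tables(pf, "plate_map"), error = function(e)
      stop("failed reading plate map ", pf, ": ", conditionMessage(e)))
    traces <- read_traces(file.path(data_dir,
                                    sprintf("traces_%s_%s.csv", assay_raw,
                                            ex)))
    pr <- .plate_responses(plate, traces, assay_raw, config)
    for (v in unique(pr$variant)) {
      crc <- assemble_crc(pr, v, assay = assay, experiment_id = ex,
                          resting = if (assay_raw == "ca") 1 else 0)
      crc_list[[paste(assay, v, ex)]] <- crc
      resp[[length(resp) + 1L]] <- data.frame(
        variant = v, assay = assay, experiment_id = ex,
        value = aucrc(crc))
    }
  }
  # binding impacts at the top concentration
  flow_files <- list.files(data_dir, "^flow_", full.names = TRUE)
  flows <- do.call(rbind, lapply(flow_files, function(f)
    as.data.frame(read_tables(f, "flow_table"))))
  flows <- flow_table(flows)
  variants <- setdiff(unique(flows$cell_line), c("parental"))
  for (v in variants) {
    bi <- impact_binding_at_top(flows, v, top_conc = config$top_conc)
    for (ex in names(attr(bi, "per_experiment")))
      resp[[length(resp) + 1L]] <- data.frame(
        variant = v, assay = "binding", experiment_id = ex,
        value = attr(bi, "per_experiment")[[ex]])
  }
  responses <- do.call(rbind, resp)
  impacts <- assemble_impacts(responses)
  write_tables(impacts[, c("variant", "assay", "mean_ratio", "sem", "n")],
               file.path(out_dir, "impact_table.csv"))
  # statistics: one ANOVA per assay
  stats_rows <- list()
  for (a in unique(impacts$assay)) {
    long <- impact_ratios_long(impacts, a)
    an <- tryCatch(
      log_ratio_anova(long, repeated = a != "binding"),
      error = function(e) NULL)
    if (!is.null(an)) {
      cmp <- an$comparisons
      cmp$assay <- a
      stats_rows[[a]] <- cmp
    }
  }
  if (length(stats_rows))
    write_tables(do.call(rbind, stats_rows),
                 file.path(out_dir, "statistics.csv"))
  radar <- radar_table(impacts)
  write_tables(as.data.frame(radar), file.path(out_dir, "radar_table.csv"))
  plot_radar(radar, file.path(out_dir, "radar.svg"))
  # bias indices
  bias <- do.call(rbind, lapply(unique(impacts$variant), function(v) {
    rc <- impacts$mean_ratio[impacts$variant == v & impacts$assay == "ca"]
    ra <- impacts$mean_ratio[impacts$variant == v & impacts$assay == "arr3"]
    if (!length(rc) || !length(ra) || rc <= 0 || ra <= 0) return(NULL)
    data.frame(variant = v, bias_index = as.numeric(bias_index(rc, ra)))
  }))
  if (!is.null(bias)) write_tables(bias, file.path(out_dir, "bias.csv"))
  # basal activity
  basal_path <- file.path(data_dir, "basal.csv")
  basal <- NULL
  if (file.exists(basal_path)) {
    basal <- basal_activity_analysis(read_tables(basal_path))
    write_tables(basal$per_variant, file.path(out_dir, "basal_analysis.csv"))
  }
  # structural metrics on the shipped ensemble
  struct <- NULL
  model_files <- list.files(data_dir, "^model_.*\\.pdb$", full.names = TRUE)
  if (length(model_files)) {
    roles <- c(receptor = "R", chemokine = "C")
    models <- lapply(sort(model_files), read_structure, chain_roles = roles)
    inact <- read_structure(file.path(data_dir, "inactive_ref.pdb"), roles)
    ens <- structure_ensemble(models, "R", "C", reference_inactive = inact)
    cfg_s <- structure_config("R", "C", tm_table = toy_tm_table(),
                              intracellular_markers =
                                as.vector(outer(0:1, toy_tm_table()$from,
                                                "+")))
    rank <- rank_by_activation(ens, cfg_s)
    cmap <- contact_map(ens, config = cfg_s)
    tmres <- unlist(mapply(seq, cfg_s$tm_table$from, cfg_s$tm_table$to))
    sites <- select_mutagenesis_sites(cmap, k = 5, restrict = tmres)
    disp <- tm_displacement(ens$models[[1]], inact,
                            segment = 205:216, config = cfg_s)
    write_tables(rank$ranking, file.path(out_dir, "activation_ranking.csv"))
    write_tables(as.data.frame(cmap), file.path(out_dir, "contacts.csv"))
    write_tables(sites, file.path(out_dir, "mutagenesis_sites.csv"))
    struct <- list(most_active = rank$most_active,
                   tm5_displacement = as.list(disp),
                   selected_sites = sites$resno)
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("ccr9map")),
    config_hash = .config_hash(config),
    variants = lapply(split(impacts, impacts$variant), function(s)
      stats::setNames(as.list(s$mean_ratio), s$assay)),
    bias = if (!is.null(bias))
      stats::setNames(as.list(bias$bias_index), bias$variant),
    structure = struct)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
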