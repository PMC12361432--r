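#' Ground-truth parameters for one receptor variant
#'
#' The synthetic-data generator is driven by an explicit per-variant truth
#' table: multiplicative scales on binding capacity and signaling efficacy,
#' potencies (molar), a basal BRET offset modelling constitutive effector
#' association, and a surface-expression scale. WT is the unit reference
#' (all scales 1, offset 0).
#'
#' @param variant variant name (`"WT"`, `"K40A"`, `"parental"`, ...).
#' @param binding_bmax_scale scale on specific binding capacity (0 = dead
#'   binder; parental cells use 0).
#' @param binding_kd dissociation constant, molar.
#' @param ec50_ca,ec50_arr potencies of the calcium and arrestin responses.
#' @param emax_ca_scale,emax_arr_scale efficacy scales of the two responses.
#' @param basal_bret_offset additive offset on the basal BRET ratio
#'   (constitutive-activity signature).
#' @param expression_scale scale on surface expression / donor level.
#' @return One-row data.frame of class `variant_truth`.
#' @export
variant_truth <- function(variant, binding_bmax_scale = 1, binding_kd = 3e-8,
                          ec50_ca = 3e-9, emax_ca_scale = 1,
                          ec50_arr = 5e-9, emax_arr_scale = 1,
                          basal_bret_offset = 0, expression_scale = 1) {
  stopifnot(binding_bmax_scale >= 0, emax_ca_scale >= 0, emax_arr_scale >= 0,
            expression_scale >= 0, binding_kd > 0, ec50_ca > 0, ec50_arr > 0)
  df <- data.frame(variant = variant, binding_bmax_scale = binding_bmax_scale,
                   binding_kd = binding_kd, ec50_ca = ec50_ca,
                   emax_ca_scale = emax_ca_scale, ec50_arr = ec50_arr,
                   emax_arr_scale = emax_arr_scale,
                   basal_bret_offset = basal_bret_offset,
                   expression_scale = expression_scale,
                   stringsAsFactors = FALSE)
  class(df) <- c("variant_truth", class(df))
  df
}

#' Assemble and validate a truth table
#'
#' @param ... [variant_truth] rows (or data.frames with the same columns).
#' @return data.frame of class `variant_truth`, one row per variant.
#' @export
truth_table <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  if (anyDuplicated(df$variant)) stop("duplicated variants in truth table")
  if ("WT" %in% df$variant) {
    wt <- df[df$variant == "WT", ]
    if (wt$binding_bmax_scale != 1 || wt$emax_ca_scale != 1 ||
        wt$emax_arr_scale != 1 || wt$expression_scale != 1 ||
        wt$basal_bret_offset != 0)
      stop("WT row must have unit scales and zero basal offset")
  }
  class(df) <- c("variant_truth", class(df))
  df
}

#' Noise model for the synthetic generators
#'
#' @param trace_cv per-point multiplicative Gaussian CV on kinetic traces.
#' @param mfi_log_sd lognormal SD (natural-log units) on flow MFIs.
#' @param baseline_drift per-second fractional baseline drift.
#' @param seed RNG seed applied at the top of each generator call; `NULL`
#'   to draw from the current stream (used by plate-level wrappers, which
#'   seed once and let wells draw sequentially).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(trace_cv = 0.03, mfi_log_sd = 0.05,
                        baseline_drift = 0, seed = 1L) {
  stopifnot(trace_cv >= 0, mfi_log_sd >= 0)
  structure(list(trace_cv = trace_cv, mfi_log_sd = mfi_log_sd,
                 baseline_drift = baseline_drift, seed = seed),
            class = "noise_model")
}

.maybe_seed <- function(noise) if (!is.null(noise$seed)) set.seed(noise$seed)

#' Acquisition grid for simulated kinetic traces
#'
#' Default spacing 0.5 s (ten acquisition points per 5 s rolling window).
#'
#' @param duration total seconds recorded.
#' @param dt spacing, seconds.
#' @param injections injection time(s), seconds.
#' @return list of class `trace_grid` with `times` and `injections`.
#' @export
trace_grid <- function(duration = 120, dt = 0.5, injections = 20) {
  times <- seq(0, duration, by = dt)
  structure(list(times = times, injections = injections), class = "trace_grid")
}

#' Kinetic shape and scale defaults for the calcium generator
#'
#' The calcium transient is emulated as a difference of exponentials
#' (rise 3 s, decay 40 s) scaled by a saturating occupancy term; these
#' functional forms describe the generator, not any fitted kinetic model.
#'
#' @param tau_rise,tau_decay transient time constants, seconds.
#' @param amp_max maximal fractional fluorescence increase at full occupancy
#'   for a unit-efficacy variant.
#' @param baseline resting fluorescence, arbitrary units.
#' @param hill Hill coefficient of the occupancy term.
#' @export
ca_trace_params <- function(tau_rise = 3, tau_decay = 40, amp_max = 1.5,
                            baseline = 1000, hill = 1) {
  list(tau_rise = tau_rise, tau_decay = tau_decay, amp_max = amp_max,
       baseline = baseline, hill = hill)
}

.occupancy <- function(conc, ec50, hill) {
  if (conc <= 0) return(0)
  conc^hill / (conc^hill + ec50^hill)
}

# normalized double-exponential transient, peak value 1 at u = u_peak
.transient <- function(u, tau_rise, tau_decay) {
  u_peak <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  smax <- exp(-u_peak / tau_decay) - exp(-u_peak / tau_rise)
  ifelse(u < 0, 0, (exp(-u / tau_decay) - exp(-u / tau_rise)) / smax)
}

#' Closed-form peak amplitude of a simulated calcium response
#'
#' Fractional peak increase over baseline for a variant at a concentration:
#' `emax_ca_scale * amp_max * c^h / (c^h + EC50^h)`. The noiseless peak of
#' the baseline-normalized trace is `1 +` this value.
#'
#' @param truth one-row [variant_truth].
#' @param conc molar concentration.
#' @param params [ca_trace_params()].
#' @export
ca_peak_amplitude <- function(truth, conc, params = ca_trace_params()) {
  truth$emax_ca_scale * params$amp_max *
    .occupancy(conc, truth$ec50_ca, params$hill)
}

#' Simulate a calcium-flux kinetic trace
#'
#' Emulates an FDSS-style fluorescence well: flat (optionally drifting)
#' baseline, then an agonist transient shaped as a difference of
#' exponentials, with per-point multiplicative Gaussian noise. Buffer wells
#' (`conc = 0`) carry no transient.
#'
#' @param truth one-row [variant_truth].
#' @param conc molar agonist concentration (0 for buffer/vehicle).
#' @param noise a [noise_model].
#' @param grid a [trace_grid] with at least 20 pre-injection points.
#' @param well_id well identifier.
#' @param params [ca_trace_params()].
#' @return A [kinetic_trace] with channel `"fluo"`.
#' @export
simulate_ca_trace <- function(truth, conc, noise = noise_model(),
                              grid = trace_grid(), well_id = "A01",
                              params = ca_trace_params()) {
  if (conc < 0) stop("concentration must be >= 0")
  inj <- grid$injections[1]
  if (sum(grid$times < inj) < 20)
    stop("grid must include at least 20 pre-injection points")
  .maybe_seed(noise)
  amp <- ca_peak_amplitude(truth, conc, params)
  base <- params$baseline * (1 + noise$baseline_drift * grid$times)
  sig <- base * (1 + amp * .transient(grid$times - inj,
                                      params$tau_rise, params$tau_decay))
  if (noise$trace_cv > 0)
    sig <- sig * (1 + stats::rnorm(length(sig), 0, noise$trace_cv))
  kinetic_trace(well_id, grid$times, list(fluo = pmax(sig, 1e-6)), inj)
}

#' BRET generator defaults
#'
#' @param basal_ratio acceptor/donor emission ratio with no stimulation.
#' @param donor_level donor (470 nm) luminescence, arbitrary units.
#' @param delta_max maximal ratio change at full occupancy, unit efficacy.
#' @param tau_bret time constant of the saturating ratio change, seconds.
#' @param hill Hill coefficient of the occupancy term.
#' @export
bret_trace_params <- function(basal_ratio = 0.8, donor_level = 30000,
                              delta_max = 0.25, tau_bret = 60, hill = 1) {
  list(basal_ratio = basal_ratio, donor_level = donor_level,
       delta_max = delta_max, tau_bret = tau_bret, hill = hill)
}

#' Closed-form plateau of a simulated BRET ratio change
#'
#' Saturating change in the 540/470 ratio at `t >> tau`: positive for
#' arrestin recruitment, negative for G-protein dissociation.
#'
#' @param truth one-row [variant_truth].
#' @param conc molar concentration.
#' @param mode `"arrestin"` or `"g_dissociation"`.
#' @param params [bret_trace_params()].
#' @export
bret_plateau_delta <- function(truth, conc,
                               mode = c("arrestin", "g_dissociation"),
                               params = bret_trace_params()) {
  mode <- match.arg(mode)
  if (mode == "arrestin")
    truth$emax_arr_scale * params$delta_max *
      .occupancy(conc, truth$ec50_arr, params$hill)
  else
    -truth$emax_ca_scale * params$delta_max *
      .occupancy(conc, truth$ec50_ca, params$hill)
}

#' Simulate a dual-emission BRET kinetic trace
#'
#' The donor channel (`em470`) is constant at `donor_level *
#' expression_scale`; the acceptor channel (`em540`) is the donor times the
#' BRET ratio: basal ratio plus the variant's constitutive offset plus an
#' occupancy-driven saturating change whose sign depends on `mode`
#' (arrestin recruitment raises the ratio; G-protein dissociation lowers
#' it). Per-point multiplicative Gaussian noise on both channels.
#'
#' @inheritParams simulate_ca_trace
#' @param mode `"arrestin"` or `"g_dissociation"`.
#' @param params [bret_trace_params()].
#' @return A [kinetic_trace] with channels `"em540"` and `"em470"`.
#' @export
simulate_bret_trace <- function(truth, conc, noise = noise_model(),
                                grid = trace_grid(duration = 660, dt = 0.5,
                                                  injections = 60),
                                mode = c("arrestin", "g_dissociation"),
                                well_id = "A01",
                                params = bret_trace_params()) {
  mode <- match.arg(mode)
  if (conc < 0) stop("concentration must be >= 0")
  inj <- grid$injections[1]
  if (sum(grid$times < inj) < 20)
    stop("grid must include at least 20 pre-injection points")
  .maybe_seed(noise)
  delta <- bret_plateau_delta(truth, conc, mode, params)
  u <- grid$times - inj
  ratio <- params$basal_ratio + truth$basal_bret_offset +
    delta * ifelse(u < 0, 0, 1 - exp(-u / params$tau_bret))
  em470 <- rep(params$donor_level * truth$expression_scale, length(u))
  em540 <- em470 * ratio
  if (noise$trace_cv > 0) {
    em470 <- em470 * (1 + stats::rnorm(length(u), 0, noise$trace_cv))
    em540 <- em540 * (1 + stats::rnorm(length(u), 0, noise$trace_cv))
  }
  kinetic_trace(well_id, grid$times,
                list(em540 = pmax(em540, 1e-6), em470 = pmax(em470, 1e-6)),
                inj)
}

#' Flow-cytometry generator defaults
#'
#' Two-component binding model: receptor-specific saturable binding plus a
#' linear nonspecific component present in all cell lines (emulating
#' proteoglycan-mediated surface binding).
#'
#' @param af autofluorescence MFI of an unstained line.
#' @param bmax specific-binding MFI span of a unit-scale line.
#' @param k_ns nonspecific slope, MFI per molar.
#' @export
flow_params <- function(af = 120, bmax = 2000, k_ns = 5e8) {
  list(af = af, bmax = bmax, k_ns = k_ns)
}

#' Closed-form noiseless MFI of the flow generator
#'
#' `AF + Bmax * scale * expression * c/(c + Kd) + k_ns * c`.
#'
#' @param truth one-row [variant_truth].
#' @param conc molar ligand concentration.
#' @param params [flow_params()].
#' @export
flow_expected_mfi <- function(truth, conc, params = flow_params()) {
  spec <- params$bmax * truth$binding_bmax_scale * truth$expression_scale *
    ifelse(conc > 0, conc / (conc + truth$binding_kd), 0)
  params$af + spec + params$k_ns * conc
}

#' Simulate a flow-cytometry MFI table
#'
#' One record per cell line and ligand concentration, with the paired
#' autofluorescence (no-ligand) MFI of the same line in the same experiment.
#' Lognormal multiplicative noise on every measured MFI. A `"parental"`
#' truth row (binding scale 0) provides the nonspecific-binding control.
#'
#' @param truths [truth_table] including a `"parental"` row with
#'   `binding_bmax_scale = 0`.
#' @param ligand_concs molar concentrations (> 0).
#' @param noise a [noise_model].
#' @param ligand ligand name.
#' @param experiment_id experiment label.
#' @param events events per sample (bookkeeping only).
#' @param params [flow_params()].
#' @return A [flow_table].
#' @export
simulate_flow_table <- function(truths, ligand_concs, noise = noise_model(),
                                ligand = "CCL25", experiment_id = "E1",
                                events = 10000L, params = flow_params()) {
  if (!"parental" %in% truths$variant)
    stop("truth table must include a 'parental' row")
  if (truths$binding_bmax_scale[truths$variant == "parental"] != 0)
    stop("parental truth must have binding_bmax_scale = 0")
  .maybe_seed(noise)
  rows <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    af <- params$af * exp(stats::rnorm(1, 0, noise$mfi_log_sd))
    for (cc in ligand_concs) {
      mfi <- flow_expected_mfi(tr, cc, params) *
        exp(stats::rnorm(1, 0, noise$mfi_log_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = tr$variant, ligand = ligand, concentration = cc,
        mfi = mfi, autofluorescence_mfi = af, events = events,
        experiment_id = experiment_id, stringsAsFactors = FALSE)
    }
  }
  flow_table(do.call(rbind, rows))
}

#' Simulate a full kinetic plate for one experiment
#'
#' For every variant, one buffer well per replicate plus one agonist well
#' per concentration and replicate. Seeds the RNG once from `noise$seed`;
#' wells then draw sequentially.
#'
#' @param truths [truth_table].
#' @param concs molar agonist concentrations.
#' @param assay `"ca"`, `"arrestin"`, or `"g_dissociation"`.
#' @param n_replicates wells per condition.
#' @param noise a [noise_model].
#' @param grid a [trace_grid]; default depends on assay.
#' @param ligand ligand name.
#' @param experiment_id experiment label.
#' @return list with elements `plate` (a [plate_map]) and `traces`
#'   (named list of [kinetic_trace]).
#' @export
simulate_plate <- function(truths, concs,
                           assay = c("ca", "arrestin", "g_dissociation"),
                           n_replicates = 3, noise = noise_model(),
                           grid = NULL, ligand = "CCL25",
                           experiment_id = "E1") {
  assay <- match.arg(assay)
  if (is.null(grid))
    grid <- if (assay == "ca") trace_grid()
            else trace_grid(duration = 660, dt = 0.5, injections = 60)
  .maybe_seed(noise)
  noise_local <- noise
  noise_local$seed <- NULL
  sim1 <- function(tr, conc, wid) {
    if (assay == "ca") simulate_ca_trace(tr, conc, noise_local, grid, wid)
    else simulate_bret_trace(tr, conc, noise_local, grid,
                             mode = if (assay == "arrestin") "arrestin"
                                    else "g_dissociation", well_id = wid)
  }
  rows <- list(); traces <- list(); w <- 0L
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    if (tr$variant == "parental") next
    for (rep_i in seq_len(n_replicates)) {
      w <- w + 1L; wid <- sprintf("W%03d", w)
      rows[[w]] <- data.frame(well_id = wid, variant = tr$variant,
                              ligand = "buffer", concentration = 0,
                              role = "buffer", replicate = rep_i,
                              experiment_id = experiment_id)
      traces[[wid]] <- sim1(tr, 0, wid)
      for (cc in concs) {
        w <- w + 1L; wid <- sprintf("W%03d", w)
        rows[[w]] <- data.frame(well_id = wid, variant = tr$variant,
                                ligand = ligand, concentration = cc,
                                role = "agonist", replicate = rep_i,
                                experiment_id = experiment_id)
        traces[[wid]] <- sim1(tr, cc, wid)
      }
    }
  }
  list(plate = plate_map(do.call(rbind, rows)), traces = traces)
}
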