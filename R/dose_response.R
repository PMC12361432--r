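#' Concentration-response container
#'
#' Mean response per tested molar concentration for one variant, ligand and
#' assay, within one experiment.
#'
#' @param concentration strictly increasing molar concentrations (> 0).
#' @param response mean responses.
#' @param sem standard errors (optional).
#' @param n replicate counts (optional).
#' @param variant,ligand,assay,experiment_id annotations.
#' @return data.frame of class `concentration_response`.
#' @export
concentration_response <- function(concentration, response, sem = NA_real_,
                                   n = NA_integer_, variant = "WT",
                                   ligand = "CCL25", assay = "ca",
                                   experiment_id = "E1") {
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  if (is.unsorted(concentration, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (length(response) != length(concentration))
    stop("response and concentration lengths differ")
  out <- data.frame(concentration = concentration, response = response,
                    sem = sem, n = n)
  attr(out, "variant") <- variant
  attr(out, "ligand") <- ligand
  attr(out, "assay") <- assay
  attr(out, "experiment_id") <- experiment_id
  class(out) <- c("concentration_response", class(out))
  out
}

#' Area under the concentration-response curve (log-concentration scale)
#'
#' Trapezoidal area of the mean response against log10(concentration)
#' across the tested range; units are response times decades. Shifting the
#' concentration units (a uniform shift of the log grid) does not change
#' the area.
#'
#' @param crc a [concentration_response] with at least 3 points.
#' @param baseline resting response level subtracted before integration
#'   (default 0; peak-ratio responses whose vehicle level is 1 should be
#'   assembled as response - 1, see [assemble_crc()]).
#' @return Numeric area (response x log10(M) units).
#' @export
aucrc <- function(crc, baseline = 0) {
  stopifnot(inherits(crc, "concentration_response"))
  if (nrow(crc) < 3) stop("AUCRC requires at least 3 concentrations")
  pracma::trapz(log10(crc$concentration), crc$response - baseline)
}

#' Mutant:WT AUCRC ratio within one experiment
#'
#' @param mut_crc,wt_crc [concentration_response]s from the same experiment
#'   and assay, on the same concentration grid.
#' @param baseline passed to [aucrc()] for both curves.
#' @return Unitless ratio.
#' @export
aucrc_ratio <- function(mut_crc, wt_crc, baseline = 0) {
  if (!isTRUE(all.equal(mut_crc$concentration, wt_crc$concentration)))
    stop("mutant and WT concentration grids differ")
  if (!identical(attr(mut_crc, "assay"), attr(wt_crc, "assay")))
    stop("mutant and WT assays differ")
  wt_area <- aucrc(wt_crc, baseline)
  if (wt_area <= 0) stop("WT AUCRC is nonpositive; ratio undefined")
  aucrc(mut_crc, baseline) / wt_area
}

.f4pl <- function(logc, floor, ceiling, loge, hill) {
  floor + (ceiling - floor) / (1 + 10^(hill * (loge - logc)))
}

#' Four-parameter logistic fit of a concentration-response curve
#'
#' Least-squares fit of
#' `response = floor + (ceiling - floor) / (1 + 10^(hill (log10 EC50 - log10 c)))`
#' using Levenberg-Marquardt with 8 multi-starts on a log-spaced EC50 grid
#' (best SSE wins, deterministic order). Bounds: `floor >= 0`, `hill` in
#' `[0.3, 5]`. A fit whose EC50 falls outside `[min conc/100, max conc*100]`
#' or that fails to converge is returned with `converged = FALSE` rather
#' than raising.
#'
#' @param crc a [concentration_response] with at least 4 points.
#' @return list of class `fit4pl`: `ec50` (molar), `hill`, `floor`,
#'   `ceiling`, `converged`, `sse`, `se_logec50`.
#' @export
fit_4pl <- function(crc) {
  stopifnot(inherits(crc, "concentration_response"))
  if (nrow(crc) < 4) stop("4PL fit requires at least 4 concentrations")
  logc <- log10(crc$concentration)
  y <- crc$response
  span <- diff(range(y))
  unconverged <- function() structure(
    list(ec50 = NA_real_, hill = NA_real_, floor = NA_real_,
         ceiling = NA_real_, converged = FALSE, sse = NA_real_,
         se_logec50 = NA_real_), class = "fit4pl")
  if (span <= max(1e-12, 1e-6 * max(abs(y)))) return(unconverged())
  starts <- seq(min(logc), max(logc), length.out = 8)
  best <- NULL
  df <- data.frame(logc = logc, y = y)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .f4pl(logc, floor, ceiling, loge, hill), data = df,
        start = list(floor = max(min(y), 1e-9), ceiling = max(y),
                     loge = s, hill = 1),
        lower = c(0, -Inf, min(logc) - 2, 0.3),
        upper = c(Inf, Inf, max(logc) + 2, 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(unconverged())
  cf <- stats::coef(best$fit)
  ec50 <- 10^cf[["loge"]]
  inside <- ec50 >= min(crc$concentration) / 100 &&
    ec50 <= max(crc$concentration) * 100
  se <- tryCatch(summary(best$fit)$coefficients["loge", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(ec50 = ec50, hill = cf[["hill"]], floor = cf[["floor"]],
                 ceiling = cf[["ceiling"]], converged = inside,
                 sse = best$sse, se_logec50 = se),
            class = "fit4pl")
}

#' @export
print.fit4pl <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<fit4pl> EC50 = %.3g M, hill = %.2f, span [%.3g, %.3g]\n",
                x$ec50, x$hill, x$floor, x$ceiling))
  else cat("<fit4pl> not converged\n")
  invisible(x)
}

#' Mutant:WT EC50 ratio
#'
#' Per-experiment potency ratios combined across experiments. Potency
#' ratios are log-normally distributed, so the geometric mean is the
#' default; the arithmetic mean is available via `mean_type`.
#'
#' @param mut_fits,wt_fits [fit_4pl] results (single fits or lists of
#'   per-experiment fits, paired in order).
#' @param mean_type `"geometric"` (default) or `"arithmetic"`.
#' @return Unitless ratio (> 1 means the mutant is less potent).
#' @export
ec50_ratio <- function(mut_fits, wt_fits,
                       mean_type = c("geometric", "arithmetic")) {
  mean_type <- match.arg(mean_type)
  if (inherits(mut_fits, "fit4pl")) mut_fits <- list(mut_fits)
  if (inherits(wt_fits, "fit4pl")) wt_fits <- list(wt_fits)
  if (length(mut_fits) != length(wt_fits))
    stop("need paired per-experiment fits")
  ratios <- mapply(function(m, w) {
    if (!m$converged || !w$converged)
      stop("EC50 ratio requires converged fits")
    m$ec50 / w$ec50
  }, mut_fits, wt_fits)
  if (mean_type == "geometric") exp(mean(log(ratios))) else mean(ratios)
}

#' Assemble a concentration-response curve from per-well responses
#'
#' Aggregates `response_value`s (see [ca_peak_response()] and friends) over
#' replicate wells per concentration, subtracting the assay's resting level
#' so the curve is zero-baselined: peak-ratio assays rest at 1, area-based
#' assays at 0.
#'
#' @param responses data.frame with columns `variant`, `concentration`,
#'   `value` (one row per well).
#' @param variant variant to extract.
#' @param assay assay tag (`"ca"`, `"arrestin"`, `"g_dissociation"`).
#' @param resting resting response level to subtract; default 1 for `"ca"`
#'   (vehicle-normalized peak ratio), 0 otherwise.
#' @param experiment_id annotation.
#' @return A [concentration_response].
#' @export
assemble_crc <- function(responses, variant, assay = "ca", resting = NULL,
                         experiment_id = "E1") {
  if (is.null(resting)) resting <- if (assay == "ca") 1 else 0
  sub <- responses[responses$variant == variant &
                     responses$concentration > 0, ]
  if (!nrow(sub)) stop("no responses for variant ", variant)
  concs <- sort(unique(sub$concentration))
  agg <- lapply(concs, function(cc) {
    v <- sub$value[sub$concentration == cc] - resting
    data.frame(concentration = cc, response = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = length(v))
  })
  agg <- do.call(rbind, agg)
  concentration_response(agg$concentration, agg$response, agg$sem, agg$n,
                         variant = variant, assay = assay,
                         experiment_id = experiment_id)
}
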