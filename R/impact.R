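#' Holm-Sidak step-down adjustment
#'
#' Step-down multiple-comparison adjustment with the Sidak form at each
#' step: for ordered raw p-values `p_(1) <= ... <= p_(m)`, the j-th adjusted
#' value is the running maximum of `1 - (1 - p_(j))^(m - j + 1)`, capped at
#' 1. Adjusted values are monotone nondecreasing along the step-down and
#' never smaller than the raw p.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Assemble mutant:WT impact records from per-experiment responses
#'
#' Within each experiment, every variant's summary response (AUCRC,
#' binding value, ...) is divided by the WT response from the same
#' experiment; ratios are then averaged across experiments with SEM on the
#' ratio scale. Experiments lacking a WT entry are dropped with a warning.
#'
#' @param responses data.frame with columns `variant`, `assay`,
#'   `experiment_id`, `value` (one summary value per variant, assay and
#'   experiment).
#' @param wt reference variant name (default `"WT"`).
#' @return data.frame of class `impact_table` with `variant`, `assay`,
#'   `mean_ratio`, `sem`, `n`; per-experiment ratios in the list column
#'   `ratios`.
#' @export
assemble_impacts <- function(responses, wt = "WT") {
  req <- c("variant", "assay", "experiment_id", "value")
  miss <- setdiff(req, names(responses))
  if (length(miss)) stop("responses missing columns: ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (as_ in unique(responses$assay)) {
    sub <- responses[responses$assay == as_, ]
    ratio_rows <- list()
    for (ex in unique(sub$experiment_id)) {
      se <- sub[sub$experiment_id == ex, ]
      wtv <- se$value[se$variant == wt]
      if (!length(wtv)) {
        warning("assay ", as_, ", experiment ", ex,
                ": no WT response; experiment excluded")
        next
      }
      ratio_rows[[ex]] <- data.frame(variant = se$variant,
                                     experiment_id = ex,
                                     ratio = se$value / mean(wtv))
    }
    rr <- do.call(rbind, ratio_rows)
    if (is.null(rr)) next
    for (v in unique(rr$variant)) {
      r <- rr$ratio[rr$variant == v]
      out[[length(out) + 1L]] <- data.frame(
        variant = v, assay = as_, mean_ratio = mean(r),
        sem = if (length(r) > 1) stats::sd(r) / sqrt(length(r))
              else NA_real_,
        n = length(r), ratios = I(list(r)))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("impact_table", class(res))
  res
}

#' Per-experiment ratio table from an impact table
#'
#' @param impacts an `impact_table` (see [assemble_impacts()]).
#' @param assay assay to extract.
#' @return Long data.frame with `variant`, `ratio`.
#' @export
impact_ratios_long <- function(impacts, assay) {
  sub <- impacts[impacts$assay == assay, ]
  do.call(rbind, lapply(seq_len(nrow(sub)), function(i)
    data.frame(variant = sub$variant[i], ratio = unlist(sub$ratios[i]),
               experiment = seq_along(unlist(sub$ratios[i])))))
}

#' One-way ANOVA on log-ratios with Holm-Sidak post-hoc tests
#'
#' Ratios are log-transformed; the omnibus test is a one-way ANOVA across
#' variants (with experiment as a blocking factor and a single pooled error
#' variance when `repeated = TRUE`, the convention for within-experiment
#' normalized signaling ratios). Post-hoc comparisons of every other
#' variant against `reference` use the pooled residual variance, two-sided,
#' with Holm-Sidak step-down adjustment.
#'
#' @param ratios data.frame with columns `variant`, `ratio`, and (for
#'   `repeated = TRUE`) `experiment`.
#' @param reference comparison reference, default `"WT"`.
#' @param repeated block on experiment (repeated-measures layout).
#' @return list of class `logratio_anova`: `omnibus` (F, df, p),
#'   `comparisons` data.frame (`comparison`, `log10_diff`, `raw_p`,
#'   `adj_p`, `test`).
#' @export
log_ratio_anova <- function(ratios, reference = "WT", repeated = FALSE) {
  stopifnot(all(c("variant", "ratio") %in% names(ratios)))
  if (any(ratios$ratio <= 0))
    stop("nonpositive ratios cannot be log-transformed")
  d <- data.frame(y = log10(ratios$ratio),
                  variant = factor(ratios$variant))
  if (repeated) {
    if (!"experiment" %in% names(ratios))
      stop("repeated-measures layout requires an 'experiment' column")
    d$experiment <- factor(ratios$experiment)
    tab <- table(d$variant, d$experiment)
    if (any(tab != 1))
      stop("repeated-measures ANOVA requires a balanced design ",
           "(one value per variant per experiment)")
    fit <- stats::lm(y ~ variant + experiment, data = d)
  } else {
    ns <- table(d$variant)
    if (any(ns < 2))
      stop("group(s) with fewer than 2 replicates: ",
           paste(names(ns)[ns < 2], collapse = ", "))
    fit <- stats::lm(y ~ variant, data = d)
  }
  an <- stats::anova(fit)
  omnibus <- list(F = an["variant", "F value"],
                  df = c(an["variant", "Df"], an["Residuals", "Df"]),
                  p = an["variant", "Pr(>F)"])
  mse <- an["Residuals", "Mean Sq"]
  dfr <- an["Residuals", "Df"]
  if (dfr < 1) stop("no residual degrees of freedom for post-hoc tests")
  means <- tapply(d$y, d$variant, mean)
  ns <- tapply(d$y, d$variant, length)
  if (!reference %in% names(means))
    stop("reference group '", reference, "' absent")
  others <- setdiff(names(means), reference)
  diffs <- means[others] - means[reference]
  if (mse <= 0) {
    if (any(abs(diffs) > 1e-12))
      stop("degenerate (zero) pooled variance with nonzero differences")
    raw <- rep(1, length(others))
  } else {
    se <- sqrt(mse * (1 / ns[others] + 1 / ns[reference]))
    tstat <- diffs / se
    raw <- 2 * stats::pt(abs(tstat), dfr, lower.tail = FALSE)
  }
  comps <- data.frame(
    comparison = paste(others, "vs", reference),
    log10_diff = as.numeric(diffs), raw_p = as.numeric(raw),
    adj_p = holm_sidak(as.numeric(raw)),
    test = if (repeated)
      "RM one-way ANOVA on log ratios, Holm-Sidak"
    else "one-way ANOVA on log ratios, Holm-Sidak")
  structure(list(omnibus = omnibus, comparisons = comps),
            class = "logratio_anova")
}

#' @export
print.logratio_anova <- function(x, ...) {
  cat(sprintf("Omnibus F(%d, %d) = %.3f, p = %.3g\n", x$omnibus$df[1],
              x$omnibus$df[2], x$omnibus$F, x$omnibus$p))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Radar table of mutation impacts across assays
#'
#' Wide per-variant table of mean mutant:WT ratios and SEMs for the three
#' readouts (binding, calcium, arrestin), with an axis order and optional
#' group brackets. The WT reference sits at 1 on every axis.
#'
#' @param impacts an `impact_table` covering the assays of interest.
#' @param assays assay names in plotting order.
#' @param axis_order variant order around the radar (default: order of
#'   appearance, WT first).
#' @param groups optional named list of variant groupings (brackets).
#' @return data.frame of class `radar_table` with one row per variant and
#'   `<assay>_ratio` / `<assay>_sem` columns.
#' @export
radar_table <- function(impacts, assays = c("binding", "ca", "arr3"),
                        axis_order = NULL, groups = NULL) {
  vs <- unique(impacts$variant)
  if (is.null(axis_order))
    axis_order <- c(intersect("WT", vs), setdiff(vs, "WT"))
  else if (!setequal(axis_order, vs))
    stop("axis_order must be a permutation of the variants")
  rows <- lapply(axis_order, function(v) {
    row <- data.frame(variant = v)
    for (a in assays) {
      hit <- impacts[impacts$variant == v & impacts$assay == a, ]
      row[[paste0(a, "_ratio")]] <-
        if (nrow(hit)) hit$mean_ratio[1] else NA_real_
      row[[paste0(a, "_sem")]] <-
        if (nrow(hit)) hit$sem[1] else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "assays") <- assays
  attr(out, "groups") <- groups
  class(out) <- c("radar_table", class(out))
  out
}

#' Render a radar table to a polar plot
#'
#' One closed contour per assay over the variant axes; ribbon width and
#' transparency encode the SEM. Writes SVG or PNG when `path` is given
#' (chosen by extension), otherwise draws on the current device.
#'
#' @param radar a [radar_table].
#' @param path optional output file (`.svg` or `.png`).
#' @param max_ratio radial limit.
#' @export
plot_radar <- function(radar, path = NULL, max_ratio = NULL) {
  assays <- attr(radar, "assays")
  cols <- grDevices::hcl.colors(max(3L, length(assays)), "Dark 3")
  vals <- as.matrix(radar[, paste0(assays, "_ratio"), drop = FALSE])
  sems <- as.matrix(radar[, paste0(assays, "_sem"), drop = FALSE])
  sems[is.na(sems)] <- 0
  if (is.null(max_ratio))
    max_ratio <- max(1.5, max(vals + sems, na.rm = TRUE)) * 1.05
  n <- nrow(radar)
  th <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  open_dev <- !is.null(path)
  if (open_dev) {
    ext <- tolower(sub(".*\\.", "", path))
    if (ext == "svg") grDevices::svg(path, width = 7, height = 7)
    else grDevices::png(path, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(0, 0, type = "n", xlim = c(-1.3, 1.3) * max_ratio,
                 ylim = c(-1.3, 1.3) * max_ratio, axes = FALSE,
                 xlab = "", ylab = "", asp = 1,
                 main = "Mutation impact (mutant:WT ratio)")
  for (r in pretty(c(0, max_ratio)))
    graphics::lines(r * cos(seq(0, 2 * pi, length.out = 121)),
                    r * sin(seq(0, 2 * pi, length.out = 121)),
                    col = "grey85")
  graphics::polygon(cos(seq(0, 2 * pi, length.out = 121)),
                    sin(seq(0, 2 * pi, length.out = 121)),
                    border = NA, col = grDevices::adjustcolor("palegreen",
                                                              0.35))
  graphics::segments(0, 0, max_ratio * cos(th), max_ratio * sin(th),
                     col = "grey80")
  graphics::text(1.15 * max_ratio * cos(th), 1.15 * max_ratio * sin(th),
                 radar$variant, cex = 0.8)
  for (a in seq_along(assays)) {
    v <- vals[, a]; s <- sems[, a]
    keep <- !is.na(v)
    alpha <- 0.25
    graphics::polygon(c((v + s)[keep] * cos(th[keep]),
                        rev((pmax(v - s, 0))[keep] * cos(th[keep]))),
                      c((v + s)[keep] * sin(th[keep]),
                        rev((pmax(v - s, 0))[keep] * sin(th[keep]))),
                      border = NA,
                      col = grDevices::adjustcolor(cols[a], alpha))
    graphics::polygon(v[keep] * cos(th[keep]), v[keep] * sin(th[keep]),
                      border = cols[a], lwd = 2)
  }
  graphics::legend("topleft", legend = assays, col = cols[seq_along(assays)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(radar)
}

#' Signaling-bias index of one variant
#'
#' Quantifies the "scalene contour" signature of disproportionate pathway
#' impact as the absolute difference of the log10 mutant:WT ratios of the
#' two signaling readouts. 0 means the mutation affected both pathways
#' equally; 1 means a tenfold disproportion. This scalar is a declared
#' surrogate for the visual criterion, recorded in the result's
#' `definition` attribute.
#'
#' @param ratio_ca,ratio_arr positive mutant:WT ratios of the calcium and
#'   arrestin readouts.
#' @return Nonnegative bias index.
#' @export
bias_index <- function(ratio_ca, ratio_arr) {
  if (any(ratio_ca <= 0) || any(ratio_arr <= 0))
    stop("bias index requires positive signaling ratios")
  out <- abs(log10(ratio_ca) - log10(ratio_arr))
  attr(out, "definition") <- "abs(log10(ca ratio) - log10(arr3 ratio))"
  out
}

#' Basal (constitutive) activity analysis
#'
#' Summarizes agonist-independent effector association: per-variant basal
#' BRET fold-change versus WT; correlation of basal BRET with donor
#' luminescence and acceptor level across variants (a confounder check: a
#' genuine constitutive-activity signal should not simply track expression
#' levels); and a surface:total expression ratio flagging predominantly
#' intracellular variants.
#'
#' @param basal_records data.frame with columns `variant`, `basal_bret`,
#'   `donor_luminescence`, `acceptor_level`, `surface_level_eq1` (log-MFI
#'   surface ratio, WT = 1), `total_level_lum` (luminescence total
#'   expression).
#' @param wt reference variant.
#' @param intracellular_threshold surface:total ratio below which a variant
#'   is flagged as predominantly intracellular (default 0.5).
#' @return list of class `basal_analysis` with `per_variant` (fold
#'   changes, surface:total ratios, flags) and `correlations`.
#' @export
basal_activity_analysis <- function(basal_records, wt = "WT",
                                    intracellular_threshold = 0.5) {
  req <- c("variant", "basal_bret", "donor_luminescence", "acceptor_level",
           "surface_level_eq1", "total_level_lum")
  miss <- setdiff(req, names(basal_records))
  if (length(miss)) stop("basal records missing columns: ",
                         paste(miss, collapse = ", "))
  if (!wt %in% basal_records$variant) stop("no paired ", wt, " record")
  b <- basal_records
  wtrow <- b[b$variant == wt, ][1, ]
  total_rel <- b$total_level_lum / wtrow$total_level_lum
  per <- data.frame(
    variant = b$variant,
    basal_fold_vs_wt = b$basal_bret / wtrow$basal_bret,
    surface_total_ratio = b$surface_level_eq1 / total_rel)
  per$intracellular_flag <-
    per$surface_total_ratio < intracellular_threshold
  safe_cor <- function(x, y, method = "pearson") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  cors <- data.frame(
    against = c("donor_luminescence", "acceptor_level"),
    pearson = c(safe_cor(b$basal_bret, b$donor_luminescence),
                safe_cor(b$basal_bret, b$acceptor_level)),
    spearman = c(safe_cor(b$basal_bret, b$donor_luminescence, "spearman"),
                 safe_cor(b$basal_bret, b$acceptor_level, "spearman")))
  structure(list(per_variant = per, correlations = cors,
                 intracellular_threshold = intracellular_threshold),
            class = "basal_analysis")
}
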