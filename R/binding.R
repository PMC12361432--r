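#' Surface-expression ratio from antibody-staining MFIs
#'
#' Antibody binding expressed relative to WT on the log-MFI scale:
#' `(log MFI_mut - log MFI_parental) / (log MFI_WT - log MFI_parental)`.
#' The quotient of logs is base-invariant; base 10 is used internally.
#' 1 means WT-like surface level, 0 means indistinguishable from the
#' untransduced parental line.
#'
#' @param mfi_mut,mfi_parental,mfi_wt positive MFIs from one experiment.
#' @param eps minimal tolerated |log10(MFI_WT) - log10(MFI_parental)|.
#' @return Unitless ratio.
#' @export
surface_ratio <- function(mfi_mut, mfi_parental, mfi_wt, eps = 1e-6) {
  stopifnot(mfi_mut > 0, mfi_parental > 0, mfi_wt > 0)
  den <- log10(mfi_wt) - log10(mfi_parental)
  if (abs(den) < eps)
    stop("WT staining indistinguishable from parental (denominator ~ 0)")
  (log10(mfi_mut) - log10(mfi_parental)) / den
}

#' Chemokine-binding ratio from ligand and autofluorescence MFIs
#'
#' Binding of a labeled chemokine expressed relative to WT on the log-MFI
#' scale: `(log MFI_mut - log AF_mut) / (log MFI_WT - log AF_WT)`, where AF
#' is the MFI of the same cell line, same experiment, without ligand.
#'
#' @param mfi_mut,af_mut mutant-line MFIs with and without ligand.
#' @param mfi_wt,af_wt WT-line MFIs with and without ligand.
#' @return Unitless ratio (1 = WT-like, 0 = autofluorescence-level).
#' @export
binding_ratio <- function(mfi_mut, af_mut, mfi_wt, af_wt) {
  stopifnot(mfi_mut > 0, af_mut > 0, mfi_wt > 0, af_wt > 0)
  den <- log10(mfi_wt) - log10(af_wt)
  if (den <= 0)
    stop("WT signal does not exceed autofluorescence (denominator <= 0)")
  (log10(mfi_mut) - log10(af_mut)) / den
}

#' Receptor-specific binding curve by parental subtraction
#'
#' Specific signal at each concentration is the variant MFI minus the
#' parental-line MFI at the matching concentration (linear scale), with
#' SEMs propagated in quadrature when replicate rows exist. Negative
#' specific signals arising from noise are retained (not clipped) and
#' flagged.
#'
#' @param records a [flow_table] containing the variant and `"parental"`
#'   rows at matching concentrations.
#' @param variant variant cell line to extract.
#' @return data.frame of class `concentration_response` with columns
#'   `concentration`, `response`, `sem`, `n`, `negative_flag` plus
#'   attributes `variant`, `assay`.
#' @export
specific_binding_curve <- function(records, variant) {
  stopifnot(inherits(records, "flow_table"))
  v <- records[records$cell_line == variant, ]
  p <- records[records$cell_line == "parental", ]
  if (!nrow(v)) stop("no records for variant ", variant)
  if (!nrow(p)) stop("no parental records for nonspecific subtraction")
  concs <- sort(unique(v$concentration))
  rows <- lapply(concs, function(cc) {
    vi <- v$mfi[v$concentration == cc]
    pi <- p$mfi[p$concentration == cc]
    if (!length(pi))
      stop("missing parental record at concentration ", cc)
    spec <- mean(vi) - mean(pi)
    sem_v <- if (length(vi) > 1) stats::sd(vi) / sqrt(length(vi)) else 0
    sem_p <- if (length(pi) > 1) stats::sd(pi) / sqrt(length(pi)) else 0
    data.frame(concentration = cc, response = spec,
               sem = sqrt(sem_v^2 + sem_p^2), n = length(vi),
               negative_flag = spec < 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "variant") <- variant
  attr(out, "assay") <- "binding_specific"
  class(out) <- c("concentration_response", class(out))
  out
}

#' Mutant:WT binding impact at the top tested concentration
#'
#' The discrimination between receptor-specific and nonspecific
#' (proteoglycan-mediated) binding is strongest at the highest tested
#' concentration (300 nM by default); the binding impact is the log-MFI
#' binding ratio computed there within each experiment, then averaged
#' across experiments.
#'
#' @param records a [flow_table] spanning one or more experiments.
#' @param variant mutant cell line.
#' @param top_conc molar concentration at which to read out (default 3e-7).
#' @param wt name of the reference line (default `"WT"`).
#' @param tol relative tolerance for concentration matching.
#' @return One-row data.frame of class `binding_impact` with `variant`,
#'   `ligand`, `concentration`, `ratio`, `sem`, `n`, and the
#'   per-experiment ratios in attribute `"per_experiment"`.
#' @export
impact_binding_at_top <- function(records, variant, top_conc = 3e-7,
                                  wt = "WT", tol = 1e-6) {
  stopifnot(inherits(records, "flow_table"))
  near <- function(x) abs(x - top_conc) <= tol * top_conc
  ratios <- c()
  for (ex in unique(records$experiment_id)) {
    sub <- records[records$experiment_id == ex, ]
    vrow <- sub[sub$cell_line == variant & near(sub$concentration), ]
    wrow <- sub[sub$cell_line == wt & near(sub$concentration), ]
    if (!nrow(vrow) || !nrow(wrow))
      stop("experiment ", ex, ": no record at top concentration ",
           top_conc, " for ", if (!nrow(vrow)) variant else wt)
    ratios[ex] <- binding_ratio(mean(vrow$mfi),
                                mean(vrow$autofluorescence_mfi),
                                mean(wrow$mfi),
                                mean(wrow$autofluorescence_mfi))
  }
  out <- data.frame(variant = variant,
                    ligand = records$ligand[1],
                    concentration = top_conc,
                    ratio = mean(ratios),
                    sem = if (length(ratios) > 1)
                            stats::sd(ratios) / sqrt(length(ratios))
                          else NA_real_,
                    n = length(ratios))
  attr(out, "per_experiment") <- ratios
  class(out) <- c("binding_impact", class(out))
  out
}
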