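#' Conventions for structural analysis
#'
#' Bundles the declared conventions the structural metrics rely on: chain
#' roles, the activation-distance residue pair, transmembrane-helix residue
#' ranges (supplied, not computed), the residues marking the intracellular
#' side (used to orient the bundle axis), and geometric cutoffs.
#'
#' @param receptor_chain,chemokine_chain chain ids.
#' @param activation_donor receptor residue carrying the side-chain
#'   hydroxyl (Tyr at BW 3.32 in the CCR9 system: residue 126).
#' @param activation_acceptor receptor residue carrying the side-chain
#'   amide (Asn at BW 6.52: residue 271).
#' @param tm_table data.frame `helix`, `from`, `to` of TM residue ranges.
#' @param intracellular_markers receptor residues on the intracellular
#'   side, orienting the bundle axis sign.
#' @param contact_cutoff heavy-atom contact cutoff, Angstrom.
#' @param hbond_d_a_max donor-acceptor distance cutoff, Angstrom.
#' @param hbond_d_a_min lower distance bound excluding covalent neighbors.
#' @param hbond_dha_min minimal donor-H-acceptor angle, degrees (applied
#'   only when hydrogens are present).
#' @param disulfide_cutoff SG-SG cutoff, Angstrom.
#' @return list of class `structure_config`.
#' @export
structure_config <- function(receptor_chain, chemokine_chain = NULL,
                             activation_donor = 126,
                             activation_acceptor = 271,
                             tm_table = NULL,
                             intracellular_markers = NULL,
                             contact_cutoff = 4.5,
                             hbond_d_a_max = 3.5, hbond_d_a_min = 2.5,
                             hbond_dha_min = 120, disulfide_cutoff = 2.5) {
  structure(list(receptor_chain = receptor_chain,
                 chemokine_chain = chemokine_chain,
                 activation_donor = activation_donor,
                 activation_acceptor = activation_acceptor,
                 tm_table = tm_table,
                 intracellular_markers = intracellular_markers,
                 contact_cutoff = contact_cutoff,
                 hbond_d_a_max = hbond_d_a_max,
                 hbond_d_a_min = hbond_d_a_min,
                 hbond_dha_min = hbond_dha_min,
                 disulfide_cutoff = disulfide_cutoff),
            class = "structure_config")
}

.xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

.select_atoms <- function(model, chain, resnos = NULL, atom_names = NULL) {
  at <- model$atoms
  keep <- at$chain == chain
  if (!is.null(resnos)) keep <- keep & at$resno %in% resnos
  if (!is.null(atom_names)) keep <- keep & at$atom %in% atom_names
  at[keep, , drop = FALSE]
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over a residue
#' selection (C-alpha atoms by default). Returns the rotation/translation
#' (reusable via [apply_transform()]), the selection RMSD, and the fully
#' transformed mobile model.
#'
#' @param mobile,reference [structure_model]s.
#' @param selection residue numbers used for the fit (default: all shared
#'   residues on `chain`).
#' @param chain chain to fit on (default: the mobile receptor chain).
#' @param atom_names atom names used (default `"CA"`).
#' @return list of class `superposition`: `rotation` (3x3), `center_mobile`,
#'   `center_reference`, `rmsd`, `model` (transformed mobile), `n_atoms`.
#' @export
superpose <- function(mobile, reference, selection = NULL, chain = NULL,
                      atom_names = "CA") {
  if (is.null(chain)) chain <- unname(mobile$chain_roles["receptor"])
  if (is.null(selection))
    selection <- intersect(
      unique(.select_atoms(mobile, chain)$resno),
      unique(.select_atoms(reference, chain)$resno))
  m_at <- .select_atoms(mobile, chain, selection, atom_names)
  r_at <- .select_atoms(reference, chain, selection, atom_names)
  key <- function(a) paste(a$resno, a$atom)
  shared <- intersect(key(m_at), key(r_at))
  if (length(shared) < 3)
    stop("superposition needs at least 3 shared atoms (found ",
         length(shared), ")")
  P <- .xyz(m_at[match(shared, key(m_at)), ])
  Q <- .xyz(r_at[match(shared, key(r_at)), ])
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  out <- structure(list(rotation = R, center_mobile = pc,
                        center_reference = qc, rmsd = rmsd,
                        n_atoms = length(shared)),
                   class = "superposition")
  out$model <- apply_transform(mobile, out)
  out
}

#' Apply a superposition transform to a model
#'
#' @param model a [structure_model].
#' @param transform a `superposition` from [superpose()].
#' @return The transformed model.
#' @export
apply_transform <- function(model, transform) {
  X <- sweep(.xyz(model$atoms), 2, transform$center_mobile)
  X <- X %*% t(transform$rotation)
  X <- sweep(X, 2, transform$center_reference, "+")
  model$atoms[, c("x", "y", "z")] <- X
  model
}

#' Per-residue ensemble variability and confidence
#'
#' Superposes all models onto the first on receptor C-alpha atoms and
#' reports the per-residue C-alpha root-mean-square fluctuation about the
#' ensemble mean position, together with the per-residue mean per-atom
#' confidence.
#'
#' @param ensemble a [structure_ensemble] with at least 2 models.
#' @param selection optional residue restriction (receptor chain).
#' @return data.frame `resno`, `rmsf`, `mean_confidence`.
#' @export
ensemble_variability <- function(ensemble, selection = NULL) {
  if (length(ensemble$models) < 2)
    stop("ensemble variability requires at least 2 models")
  ch <- ensemble$receptor_chain
  ref <- ensemble$models[[1]]
  resnos <- unique(.select_atoms(ref, ch, selection, "CA")$resno)
  pos <- array(NA_real_, c(length(resnos), 3, length(ensemble$models)))
  confs <- matrix(NA_real_, length(resnos), length(ensemble$models))
  for (m in seq_along(ensemble$models)) {
    mod <- if (m == 1) ref
           else superpose(ensemble$models[[m]], ref, chain = ch)$model
    ca <- .select_atoms(mod, ch, resnos, "CA")
    pos[, , m] <- .xyz(ca[match(resnos, ca$resno), ])
    rc <- residue_confidence(mod, ch)
    confs[, m] <- rc$confidence[match(resnos, rc$resno)]
  }
  mean_pos <- apply(pos, c(1, 2), mean)
  rmsf <- sqrt(rowMeans(apply(pos, 3, function(X)
    rowSums((X - mean_pos)^2))))
  data.frame(resno = resnos, rmsf = rmsf,
             mean_confidence = rowMeans(confs))
}

#' Activation distance of one model
#'
#' Distance from the donor residue's tyrosine hydroxyl oxygen (`OH`) to
#' the nearest heavy atom of the acceptor residue's asparagine carboxamide
#' (`ND2` or `OD1`; nearest-atom is robust to amide flips). In the CCR9
#' system this is the Y126 (BW 3.32) to N271 (BW 6.52) separation, a
#' marker of the active state.
#'
#' @param model a [structure_model].
#' @param config a [structure_config].
#' @return Distance in Angstrom.
#' @export
activation_distance <- function(model, config) {
  ch <- config$receptor_chain
  don <- .select_atoms(model, ch, config$activation_donor, "OH")
  if (!nrow(don))
    stop("donor residue ", config$activation_donor, " lacks atom OH")
  acc <- .select_atoms(model, ch, config$activation_acceptor,
                       c("ND2", "OD1"))
  if (!nrow(acc))
    stop("acceptor residue ", config$activation_acceptor,
         " lacks atoms ND2/OD1")
  d <- sqrt(rowSums(sweep(.xyz(acc), 2, .xyz(don)[1, ])^2))
  min(d)
}

# first principal axis of the TM C-alpha cloud, oriented so that positive
# values point toward the declared intracellular marker residues
.bundle_axis <- function(model, config, frame_resnos = NULL) {
  ch <- config$receptor_chain
  if (is.null(frame_resnos))
    frame_resnos <- unlist(mapply(seq, config$tm_table$from,
                                  config$tm_table$to))
  ca <- .select_atoms(model, ch, frame_resnos, "CA")
  X <- .xyz(ca)
  ctr <- colMeans(X)
  ax <- svd(sweep(X, 2, ctr))$v[, 1]
  mk <- .select_atoms(model, ch, config$intracellular_markers, "CA")
  if (!nrow(mk)) stop("no intracellular marker residues found")
  if (sum((colMeans(.xyz(mk)) - ctr) * ax) < 0) ax <- -ax
  list(axis = ax, center = ctr)
}

#' Activation metrics for every model of an ensemble
#'
#' Computes, per model: the donor-acceptor activation distance; the
#' outward displacement of the intracellular end of the TM6 helix (radial
#' distance from the bundle axis, minus the same quantity in the inactive
#' reference when available); the cross-pocket C-alpha distance between
#' the donor and acceptor residues (TM3-to-TM6 direction); and the TM5
#' depth (signed projection of the TM5 midpoint C-alpha on the
#' intracellular-positive bundle axis, relative to the frame centroid).
#'
#' @param ensemble a [structure_ensemble].
#' @param config a [structure_config] with `tm_table` and markers.
#' @return data.frame, one row per model.
#' @export
activation_metrics <- function(ensemble, config) {
  ch <- config$receptor_chain
  tm <- config$tm_table
  tm6 <- seq(tm$from[tm$helix == 6], tm$to[tm$helix == 6])
  tm5 <- seq(tm$from[tm$helix == 5], tm$to[tm$helix == 5])
  metric1 <- function(model) {
    bx <- .bundle_axis(model, config)
    ca <- function(resnos) {
      a <- .select_atoms(model, ch, resnos, "CA")
      colMeans(.xyz(a))
    }
    ic6 <- ca(tm6[1:2])  # markers sit at the helix start: IC end
    radial <- function(p) {
      v <- p - bx$center
      sqrt(sum(v^2) - sum(v * bx$axis)^2)
    }
    cp <- sqrt(sum((ca(config$activation_donor) -
                      ca(config$activation_acceptor))^2))
    depth <- sum((ca(tm5[ceiling(length(tm5) / 2)]) - bx$center) * bx$axis)
    c(tm6_ic_radial = radial(ic6), cross_pocket = cp, tm5_depth = depth)
  }
  rows <- lapply(ensemble$models, function(m) {
    v <- metric1(m)
    data.frame(model_id = m$model_id,
               y_donor_acceptor_distance = activation_distance(m, config),
               tm6_ic_outward = v[["tm6_ic_radial"]],
               cross_pocket_distance = v[["cross_pocket"]],
               tm5_depth = v[["tm5_depth"]])
  })
  out <- do.call(rbind, rows)
  if (!is.null(ensemble$reference_inactive)) {
    vref <- metric1(ensemble$reference_inactive)
    out$tm6_ic_outward <- out$tm6_ic_outward - vref[["tm6_ic_radial"]]
  }
  out
}

#' Rank ensemble models by degree of activation
#'
#' Primary key: the donor-acceptor activation distance, descending (the
#' "most active" model has the largest separation); the TM6/cross-pocket/
#' TM5 diagnostics are reported alongside. Ties break by model id, giving
#' a stable total order.
#'
#' @inheritParams activation_metrics
#' @return list: `ranking` (metrics data.frame in rank order),
#'   `most_active` (model id).
#' @export
rank_by_activation <- function(ensemble, config) {
  met <- activation_metrics(ensemble, config)
  ord <- order(-met$y_donor_acceptor_distance, met$model_id)
  ranked <- met[ord, ]
  rownames(ranked) <- NULL
  list(ranking = ranked, most_active = ranked$model_id[1])
}

#' Displacement of a helix segment between two states
#'
#' After superposing `active` onto `inactive` on the frame selection
#' (receptor C-alpha excluding the measured segment, so the moving part
#' does not bias the frame), the displacement vector of the segment's
#' reference C-alpha (the midpoint residue by default) is decomposed into
#' the component along the bundle axis (intracellular-positive) and the
#' perpendicular (outward) component.
#'
#' @param active,inactive [structure_model]s.
#' @param segment residue range of the measured helix.
#' @param config a [structure_config].
#' @param frame residue selection for the superposition frame; default all
#'   TM residues excluding `segment`.
#' @param reference_resno segment residue whose C-alpha is tracked;
#'   default the midpoint residue.
#' @return Named numeric vector `outward`, `along_axis`, `total` (Angstrom).
#' @export
tm_displacement <- function(active, inactive, segment, config,
                            frame = NULL, reference_resno = NULL) {
  ch <- config$receptor_chain
  if (is.null(frame)) {
    tmres <- unlist(mapply(seq, config$tm_table$from, config$tm_table$to))
    frame <- setdiff(tmres, segment)
  }
  if (length(intersect(frame, segment)))
    stop("frame selection must be disjoint from the measured segment")
  sup <- superpose(active, inactive, selection = frame, chain = ch)
  if (is.null(reference_resno)) {
    present <- sort(intersect(segment,
                              .select_atoms(inactive, ch)$resno))
    reference_resno <- present[ceiling(length(present) / 2)]
  }
  get_ca <- function(model) {
    a <- .select_atoms(model, ch, reference_resno, "CA")
    if (!nrow(a)) stop("reference residue ", reference_resno,
                       " has no C-alpha")
    .xyz(a)[1, ]
  }
  disp <- get_ca(sup$model) - get_ca(inactive)
  bx <- .bundle_axis(inactive, config, frame_resnos = frame)
  along <- sum(disp * bx$axis)
  perp <- disp - along * bx$axis
  c(outward = sqrt(sum(perp^2)), along_axis = along,
    total = sqrt(sum(disp^2)))
}

.heavy <- function(atoms) atoms[toupper(atoms$element) != "H", , drop = FALSE]
.backbone_names <- c("N", "CA", "C", "O", "OXT")

.cross_dist <- function(A, B) {
  # |A| x |B| distance matrix
  XA <- .xyz(A); XB <- .xyz(B)
  sqrt(pmax(outer(rowSums(XA^2), rowSums(XB^2), "+") -
              2 * XA %*% t(XB), 0))
}

#' Receptor-chemokine contact map across an ensemble
#'
#' For every receptor/chemokine residue pair: the minimal heavy-atom
#' distance per model, the fraction of models in which the pair is in
#' contact (min distance <= cutoff), and a contact-strength score defined
#' as that fraction times the mean number of atom pairs within the cutoff
#' (averaged over all models). With `sidechain_only`, receptor backbone
#' atoms are excluded, matching selection of residues whose side chains
#' contact the chemokine.
#'
#' @param ensemble a [structure_ensemble] with a chemokine chain.
#' @param cutoff heavy-atom distance cutoff (default from `config`,
#'   4.5 Angstrom).
#' @param sidechain_only restrict receptor atoms to side chains.
#' @param config optional [structure_config] supplying the cutoff.
#' @return data.frame of class `contact_map`: `rec_resno`, `chem_resno`,
#'   `min_distance` (over models), `model_fraction`, `mean_pairs`,
#'   `strength`, sorted by decreasing strength.
#' @export
contact_map <- function(ensemble, cutoff = NULL, sidechain_only = TRUE,
                        config = NULL) {
  if (is.null(cutoff))
    cutoff <- if (!is.null(config)) config$contact_cutoff else 4.5
  rch <- ensemble$receptor_chain
  cch <- ensemble$chemokine_chain
  if (is.null(cch)) stop("ensemble has no chemokine chain")
  acc <- list()
  nm <- length(ensemble$models)
  for (m in ensemble$models) {
    A <- .heavy(m$atoms[m$atoms$chain == rch, ])
    if (sidechain_only) A <- A[!A$atom %in% .backbone_names, ]
    B <- .heavy(m$atoms[m$atoms$chain == cch, ])
    if (!nrow(A) || !nrow(B)) next
    D <- .cross_dist(A, B)
    hit <- which(D <= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    pairs <- data.frame(rec_resno = A$resno[hit[, 1]],
                        chem_resno = B$resno[hit[, 2]],
                        d = D[hit])
    agg <- stats::aggregate(d ~ rec_resno + chem_resno, pairs,
                            function(x) c(min(x), length(x)))
    agg <- data.frame(rec_resno = agg$rec_resno,
                      chem_resno = agg$chem_resno,
                      min_d = agg$d[, 1], npairs = agg$d[, 2])
    acc[[length(acc) + 1L]] <- agg
  }
  if (!length(acc))
    return(structure(data.frame(rec_resno = integer(), chem_resno = integer(),
                                min_distance = numeric(),
                                model_fraction = numeric(),
                                mean_pairs = numeric(), strength = numeric()),
                     class = c("contact_map", "data.frame")))
  all_pairs <- do.call(rbind, acc)
  keys <- paste(all_pairs$rec_resno, all_pairs$chem_resno)
  rows <- lapply(unique(keys), function(k) {
    sub <- all_pairs[keys == k, ]
    frac <- nrow(sub) / nm
    data.frame(rec_resno = sub$rec_resno[1], chem_resno = sub$chem_resno[1],
               min_distance = min(sub$min_d), model_fraction = frac,
               mean_pairs = sum(sub$npairs) / nm,
               strength = frac * sum(sub$npairs) / nm)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$strength, out$rec_resno, out$chem_resno), ]
  rownames(out) <- NULL
  class(out) <- c("contact_map", class(out))
  out
}

#' Select mutagenesis sites from a contact map
#'
#' Ranks receptor residues by their total contact strength against the
#' chemokine (summed over chemokine partners), restricted to a declared
#' residue set (TM domains), and returns the top `k`. Ties break by lower
#' residue number.
#'
#' @param contacts a [contact_map].
#' @param k number of sites (default 10).
#' @param restrict residue set to which candidates are restricted (e.g.
#'   TM residues); `NULL` for no restriction.
#' @return data.frame `resno`, `strength`, ranked.
#' @export
select_mutagenesis_sites <- function(contacts, k = 10, restrict = NULL) {
  if (k == 0) return(data.frame(resno = integer(), strength = numeric()))
  per_res <- stats::aggregate(strength ~ rec_resno, as.data.frame(contacts),
                              sum)
  if (!is.null(restrict))
    per_res <- per_res[per_res$rec_resno %in% restrict, ]
  per_res <- per_res[order(-per_res$strength, per_res$rec_resno), ]
  if (nrow(per_res) < k)
    warning("only ", nrow(per_res), " candidate residues (k = ", k, ")")
  out <- utils::head(per_res, k)
  names(out) <- c("resno", "strength")
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond network around focus residues
#'
#' Geometric criterion on heavy atoms: nitrogen/oxygen pairs with
#' donor-acceptor distance within `(d_a_min, d_a_max]`, excluding
#' same-residue pairs and backbone-backbone pairs of sequence neighbors
#' (covalent vicinity). When hydrogens are present on the putative donor,
#' the D-H-A angle must exceed `dha_min`; without hydrogens the angle
#' criterion is skipped (recorded as `NA`). At least one partner must
#' belong to a focus residue.
#'
#' @param model a [structure_model].
#' @param focus_residues data.frame with columns `chain`, `resno`, or a
#'   numeric vector of receptor residue numbers.
#' @param config a [structure_config] (cutoffs).
#' @return data.frame of class `hbond_set`: donor/acceptor chain, residue,
#'   atom, `d_a_distance`, `dha_angle`, `donor_is_sidechain`,
#'   `acceptor_is_sidechain`.
#' @export
hbond_network <- function(model, focus_residues, config) {
  if (is.numeric(focus_residues))
    focus_residues <- data.frame(chain = config$receptor_chain,
                                 resno = focus_residues)
  at <- model$atoms
  no <- at[toupper(at$element) %in% c("N", "O"), ]
  no$key <- paste(no$chain, no$resno)
  focus_keys <- paste(focus_residues$chain, focus_residues$resno)
  empty <- data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      d_a_distance = numeric(), dha_angle = numeric(),
                      donor_is_sidechain = logical(),
                      acceptor_is_sidechain = logical())
  if (nrow(no) < 2 || !any(no$key %in% focus_keys))
    return(structure(empty, class = c("hbond_set", "data.frame")))
  D <- .cross_dist(no, no)
  hyd <- at[toupper(at$element) == "H", ]
  cand <- which(upper.tri(D) & D > config$hbond_d_a_min &
                  D <= config$hbond_d_a_max, arr.ind = TRUE)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    d <- D[i, j]
    a1 <- no[i, ]; a2 <- no[j, ]
    if (a1$key == a2$key) next
    bb1 <- a1$atom %in% .backbone_names
    bb2 <- a2$atom %in% .backbone_names
    if (bb1 && bb2 && a1$chain == a2$chain &&
        abs(a1$resno - a2$resno) <= 1) next
    if (!(a1$key %in% focus_keys || a2$key %in% focus_keys)) next
    # donor = the nitrogen when the pair is N/O; first atom otherwise
    if (a2$element == "N" && a1$element == "O") { tmp <- a1; a1 <- a2; a2 <- tmp }
    ang <- NA_real_
    if (nrow(hyd)) {
      hs <- hyd[hyd$chain == a1$chain & hyd$resno == a1$resno, ]
      if (nrow(hs)) {
        dv <- .xyz(a1)[1, ]; av <- .xyz(a2)[1, ]
        angs <- apply(.xyz(hs), 1, function(h) {
          v1 <- dv - h; v2 <- av - h
          acos(pmin(pmax(sum(v1 * v2) /
                           sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
        })
        ang <- max(angs)
        if (ang < config$hbond_dha_min) next
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      donor_chain = a1$chain, donor_resno = a1$resno, donor_atom = a1$atom,
      acceptor_chain = a2$chain, acceptor_resno = a2$resno,
      acceptor_atom = a2$atom, d_a_distance = d, dha_angle = ang,
      donor_is_sidechain = !a1$atom %in% .backbone_names,
      acceptor_is_sidechain = !a2$atom %in% .backbone_names)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, class = c("hbond_set", "data.frame"))
}

#' Disulfide bridges within a chain
#'
#' Cysteine SG-SG pairs within the cutoff, paired greedily by increasing
#' distance with each cysteine used at most once.
#'
#' @param model a [structure_model].
#' @param chain chain id.
#' @param cutoff SG-SG distance cutoff, Angstrom (default 2.5).
#' @return data.frame `res_i`, `res_j`, `distance` (res_i < res_j).
#' @export
disulfide_partners <- function(model, chain, cutoff = 2.5) {
  sg <- model$atoms[model$atoms$chain == chain &
                      model$atoms$atom == "SG", ]
  empty <- data.frame(res_i = integer(), res_j = integer(),
                      distance = numeric())
  if (nrow(sg) < 2) return(empty)
  D <- .cross_dist(sg, sg)
  cand <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  cand <- cand[order(D[cand]), , drop = FALSE]
  used <- rep(FALSE, nrow(sg))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      res_i = min(sg$resno[i], sg$resno[j]),
      res_j = max(sg$resno[i], sg$resno[j]),
      distance = D[i, j])
  }
  do.call(rbind, rows)
}

#' Aggregate per-atom scores to residue backbones and side chains
#'
#' Sums externally supplied per-atom scores (e.g. interaction-scoring
#' output) over backbone atoms (N, CA, C, O, OXT) and side-chain atoms of
#' each residue. With a list of models and matching list of score tables,
#' aggregates are averaged across models (e.g. across the top 5).
#'
#' @param model a [structure_model] or list of models.
#' @param scores data.frame `chain`, `resno`, `atom`, `score` (or a list,
#'   one per model).
#' @return data.frame `chain`, `resno`, `backbone_score`,
#'   `sidechain_score`.
#' @export
aggregate_atom_scores <- function(model, scores) {
  if (inherits(model, "structure_model")) {
    model <- list(model)
    scores <- list(scores)
  }
  if (length(model) != length(scores))
    stop("need one score table per model")
  per_model <- mapply(function(m, sc) {
    key_m <- paste(m$atoms$chain, m$atoms$resno, m$atoms$atom)
    key_s <- paste(sc$chain, sc$resno, sc$atom)
    bad <- setdiff(key_s, key_m)
    if (length(bad))
      stop("scored atom(s) not found in model ", m$model_id, ": ",
           paste(utils::head(bad, 5), collapse = "; "))
    sc$is_bb <- sc$atom %in% .backbone_names
    bb <- stats::aggregate(score ~ chain + resno, sc[sc$is_bb, ], sum)
    sch <- stats::aggregate(score ~ chain + resno, sc[!sc$is_bb, ], sum)
    all_res <- unique(sc[, c("chain", "resno")])
    all_res$backbone_score <-
      bb$score[match(paste(all_res$chain, all_res$resno),
                     paste(bb$chain, bb$resno))]
    all_res$sidechain_score <-
      sch$score[match(paste(all_res$chain, all_res$resno),
                      paste(sch$chain, sch$resno))]
    all_res$backbone_score[is.na(all_res$backbone_score)] <- 0
    all_res$sidechain_score[is.na(all_res$sidechain_score)] <- 0
    all_res[order(all_res$chain, all_res$resno), ]
  }, model, scores, SIMPLIFY = FALSE)
  base <- per_model[[1]]
  if (length(per_model) > 1) {
    for (k in 2:length(per_model)) {
      other <- per_model[[k]]
      if (!identical(paste(base$chain, base$resno),
                     paste(other$chain, other$resno)))
        stop("models score different residue sets; cannot average")
      base$backbone_score <- base$backbone_score + other$backbone_score
      base$sidechain_score <- base$sidechain_score + other$sidechain_score
    }
    base$backbone_score <- base$backbone_score / length(per_model)
    base$sidechain_score <- base$sidechain_score / length(per_model)
  }
  rownames(base) <- NULL
  base
}
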