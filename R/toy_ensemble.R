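#' Geometry specification for the toy helical-bundle generator
#'
#' The toy ensemble emulates the geometric features the structural metrics
#' measure, without attempting realistic protein geometry: seven parallel
#' helix analogs on a circle (residue ranges loosely echoing TM1-TM7
#' numbering of a chemokine receptor), a chemokine-analog chain above the
#' bundle, and planted features with exact ground truth: a donor/acceptor
#' atom pair at controlled separation per model (activation-distance
#' analog), receptor-chemokine side-chain contacts, side-chain-to-backbone
#' hydrogen bonds, an axial slide of one helix between active models and
#' the inactive reference, and an SG-SG disulfide in the chemokine chain.
#'
#' @param activation_distances planted donor-acceptor separations, one per
#'   model (recycled); default spreads 3-12 Angstrom.
#' @param contacts data.frame with `rec_resno`, `chem_resno`, `distance`
#'   (planted side-chain separation, Angstrom), `fraction` (fraction of
#'   models carrying the contact).
#' @param hbond_donor_resno receptor residue whose side-chain nitrogen is
#'   hydrogen-bonded to chemokine backbone oxygens.
#' @param hbond_chem_resnos chemokine residues whose backbone O is planted
#'   2.9 Angstrom from the donor.
#' @param helix_shift axial (intracellular-positive) slide of the shifted
#'   helix in active models relative to the inactive reference, Angstrom.
#' @param shift_segment residue range (on the receptor) that is slid.
#' @param tm6_outward_per_A outward shift of the TM6-analog intracellular
#'   end per Angstrom of planted activation distance (couples the
#'   secondary activation diagnostics to the primary one).
#' @param disulfide_resnos two chemokine residue numbers carrying SG atoms
#'   2.05 Angstrom apart.
#' @param jitter_sd per-coordinate Gaussian jitter (Angstrom) applied to
#'   non-planted atoms of each model.
#' @return list of class `toy_ensemble_spec`.
#' @export
toy_ensemble_spec <- function(activation_distances = NULL,
                              contacts = NULL,
                              hbond_donor_resno = 211,
                              hbond_chem_resnos = c(32, 33, 35),
                              helix_shift = 6,
                              shift_segment = 205:216,
                              tm6_outward_per_A = 0.3,
                              disulfide_resnos = c(7, 35),
                              jitter_sd = 0.05) {
  if (is.null(contacts))
    contacts <- data.frame(rec_resno = c(44, 126, 207, 208, 211),
                           chem_resno = c(6, 1, 31, 36, 30),
                           distance = 3.5, fraction = 1)
  structure(list(activation_distances = activation_distances,
                 contacts = contacts,
                 hbond_donor_resno = hbond_donor_resno,
                 hbond_chem_resnos = hbond_chem_resnos,
                 helix_shift = helix_shift,
                 shift_segment = shift_segment,
                 tm6_outward_per_A = tm6_outward_per_A,
                 disulfide_resnos = disulfide_resnos,
                 jitter_sd = jitter_sd),
            class = "toy_ensemble_spec")
}

#' Helix residue ranges of the toy receptor
#'
#' @return data.frame with `helix`, `from`, `to`.
#' @export
toy_tm_table <- function() {
  from <- c(36, 80, 120, 160, 200, 248, 290)
  data.frame(helix = 1:7, from = from, to = from + 23L)
}

# base receptor geometry: 7 parallel helices, extracellular at high z
.toy_receptor_atoms <- function(tm = toy_tm_table()) {
  bundle_r <- 11; ca_r <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  rows <- list()
  for (h in seq_len(nrow(tm))) {
    th <- 2 * pi * (h - 1) / 7
    ctr <- c(bundle_r * cos(th), bundle_r * sin(th))
    resnos <- tm$from[h]:tm$to[h]
    for (k in seq_along(resnos)) {
      phi <- th + twist * (k - 1)
      ca <- c(ctr + ca_r * c(cos(phi), sin(phi)), rise * (k - 1))
      outv <- c(cos(phi), sin(phi), 0)          # radially out of the helix
      inward <- c(-ctr / sqrt(sum(ctr^2)), 0)   # toward the bundle axis
      res <- resnos[k]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "R", resno = res, resid = "ALA",
        atom = c("N", "CA", "C", "O", "CB"),
        element = c("N", "C", "C", "O", "C"),
        x = ca[1] + c(0.5 * outv[1], 0, 0.4 * outv[1], 0.5 * outv[1],
                      1.8 * inward[1]),
        y = ca[2] + c(0.5 * outv[2], 0, 0.4 * outv[2], 0.5 * outv[2],
                      1.8 * inward[2]),
        z = ca[3] + c(-0.5, 0, 0.3, 0.5, 0),
        conf = 90, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.toy_chemokine_atoms <- function(n_res = 40, cys = c(7, 35)) {
  # chain floats above the bundle (receptor tops out near z = 16.5) so that
  # only explicitly planted atoms can come within contact range
  r_ca <- 1.8; rise <- 1.5; step <- 140 * pi / 180; z0 <- 36
  rows <- list()
  for (j in seq_len(n_res)) {
    psi <- step * j
    ca <- c(r_ca * cos(psi), r_ca * sin(psi), z0 + rise * j)
    outv <- c(cos(psi), sin(psi), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "C", resno = j, resid = ifelse(j %in% cys, "CYS", "ALA"),
      atom = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = ca[1] + c(0.5 * outv[1], 0, 0.4 * outv[1], 0.5 * outv[1],
                    1.2 * outv[1]),
      y = ca[2] + c(0.5 * outv[2], 0, 0.4 * outv[2], 0.5 * outv[2],
                    1.2 * outv[2]),
      z = ca[3] + c(-0.5, 0, 0.3, 0.5, 0),
      conf = 85, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.set_atom <- function(atoms, chain, resno, name, xyz, element = NULL,
                      resid = NULL) {
  i <- which(atoms$chain == chain & atoms$resno == resno &
             atoms$atom == name)
  if (length(i) == 0L) {
    j <- max(which(atoms$chain == chain & atoms$resno == resno))
    new <- atoms[j, ]
    new$atom <- name
    if (!is.null(element)) new$element <- element
    atoms <- rbind(atoms[seq_len(j), ], new,
                   if (j < nrow(atoms)) atoms[(j + 1):nrow(atoms), ])
    i <- j + 1L
  }
  atoms[i, c("x", "y", "z")] <- as.list(xyz)
  if (!is.null(resid))
    atoms$resid[atoms$chain == chain & atoms$resno == resno] <- resid
  atoms
}

.atom_xyz <- function(atoms, chain, resno, name) {
  i <- which(atoms$chain == chain & atoms$resno == resno & atoms$atom == name)
  if (!length(i)) stop("atom not found: ", chain, " ", resno, " ", name)
  unlist(atoms[i[1], c("x", "y", "z")], use.names = FALSE)
}

#' Generate a toy helical-bundle ensemble with planted features
#'
#' Builds `n_models` active-state models plus an inactive reference. All
#' planted features are returned as ground truth so that downstream metrics
#' can be validated exactly. Active models slide the `shift_segment` helix
#' by `helix_shift` Angstrom in the intracellular direction relative to the
#' inactive reference, plant the activation-distance atom pair
#' (Tyr126-analog hydroxyl, Asn271-analog amide) at the model's prescribed
#' separation, and move the TM6-analog intracellular end outward in
#' proportion to that separation.
#'
#' @param spec a [toy_ensemble_spec].
#' @param n_models number of active models.
#' @param seed RNG seed for the jitter.
#' @return list with `ensemble` (a [structure_ensemble] with inactive
#'   reference), `truth` (planted feature list), and `config`
#'   (a [structure_config] matching the toy conventions).
#' @export
generate_toy_ensemble <- function(spec = toy_ensemble_spec(), n_models = 5,
                                  seed = 1L) {
  set.seed(seed)
  tm <- toy_tm_table()
  act_d <- spec$activation_distances
  if (is.null(act_d)) act_d <- seq(3, 12, length.out = n_models)
  act_d <- rep_len(act_d, n_models)

  base_r <- .toy_receptor_atoms(tm)
  base_c <- .toy_chemokine_atoms(cys = spec$disulfide_resnos)

  # direction across the pocket from the TM3 analog toward the TM6 analog
  th3 <- 2 * pi * 2 / 7; th6 <- 2 * pi * 5 / 7
  u_pocket <- c(cos(th6) - cos(th3), sin(th6) - sin(th3), 0)
  u_pocket <- u_pocket / sqrt(sum(u_pocket^2))

  plant <- function(atoms_r, atoms_c, d_act, have_contact) {
    # activation pair: OH on residue 126 (TYR analog), amide on 271 (ASN).
    # the pair is placed on an isolated radial spur so the planted
    # separation cannot collide with other planted pocket features
    z126 <- .atom_xyz(atoms_r, "R", 126, "CA")[3]
    oh <- c(30, 0, z126)
    atoms_r <- .set_atom(atoms_r, "R", 126, "OH", oh, "O", resid = "TYR")
    nd2 <- oh + d_act * c(0, 1, 0)
    od1 <- oh + (d_act + 1.3) * c(0, 1, 0)
    atoms_r <- .set_atom(atoms_r, "R", 271, "ND2", nd2, "N", resid = "ASN")
    atoms_r <- .set_atom(atoms_r, "R", 271, "OD1", od1, "O")
    # hydrogen-bond donor: side-chain NZ on the K211 analog
    cb211 <- .atom_xyz(atoms_r, "R", spec$hbond_donor_resno, "CB")
    inw <- c(-cb211[1:2] / sqrt(sum(cb211[1:2]^2)), 0)
    nz <- cb211 + 2.0 * inw
    atoms_r <- .set_atom(atoms_r, "R", spec$hbond_donor_resno, "NZ", nz,
                         "N", resid = "LYS")
    dirs <- rbind(c(1, 0, 0.4), c(-0.5, 0.87, 0.4), c(-0.5, -0.87, 0.4))
    for (i in seq_along(spec$hbond_chem_resnos)) {
      u <- dirs[(i - 1) %% 3 + 1, ]; u <- u / sqrt(sum(u^2))
      atoms_c <- .set_atom(atoms_c, "C", spec$hbond_chem_resnos[i], "O",
                           nz + 2.9 * u, "O")
    }
    # disulfide SG pair
    sg1 <- c(0, 0, 44); sg2 <- sg1 + c(2.05, 0, 0)
    atoms_c <- .set_atom(atoms_c, "C", spec$disulfide_resnos[1], "SG", sg1,
                         "S")
    atoms_c <- .set_atom(atoms_c, "C", spec$disulfide_resnos[2], "SG", sg2,
                         "S")
    # planted receptor-chemokine side-chain contacts: the receptor residue
    # gets a long inward side chain (CG/CD/CE at fixed axis radii) whose
    # tip meets a small chemokine side-chain cluster deep in the pocket,
    # well away from all non-planted residues
    for (i in seq_len(nrow(spec$contacts))) {
      con <- spec$contacts[i, ]
      ca <- .atom_xyz(atoms_r, "R", con$rec_resno, "CA")
      u <- c(ca[1:2] / sqrt(sum(ca[1:2]^2)), 0)  # radial unit at residue
      at_radius <- function(r) c(r * u[1:2], ca[3])
      # receptor side chain present in every model (fixed topology);
      # the chemokine cluster only where the contact is planted
      atoms_r <- .set_atom(atoms_r, "R", con$rec_resno, "CG",
                           at_radius(7.0), "C")
      atoms_r <- .set_atom(atoms_r, "R", con$rec_resno, "CD",
                           at_radius(5.75), "C")
      ce <- at_radius(4.5)
      atoms_r <- .set_atom(atoms_r, "R", con$rec_resno, "CE", ce, "C")
      if (!have_contact[i]) next
      tip <- ce - con$distance * u
      atoms_c <- .set_atom(atoms_c, "C", con$chem_resno, "CB", tip, "C")
      perp <- c(-u[2], u[1], 0)
      offs <- list(CG1 = 0.8 * perp, CG2 = -0.8 * perp,
                   CG3 = c(0, 0, 0.8))
      for (nm in names(offs))
        atoms_c <- .set_atom(atoms_c, "C", con$chem_resno, nm,
                             tip + offs[[nm]], "C")
    }
    list(r = atoms_r, c = atoms_c)
  }

  planted_names <- c("OH", "ND2", "OD1", "NZ", "SG", "CG", "CD", "CE")
  build_model <- function(id, d_act, have_contact, active) {
    ar <- base_r; ac <- base_c
    if (active) {
      seg <- ar$resno %in% spec$shift_segment
      ar$z[seg] <- ar$z[seg] - spec$helix_shift  # intracellular = -z
      ic6 <- ar$resno %in% (tm$from[tm$helix == 6] + 0:3)  # TM6 IC end
      out6 <- c(cos(th6), sin(th6), 0) * spec$tm6_outward_per_A * d_act
      ar$x[ic6] <- ar$x[ic6] + out6[1]
      ar$y[ic6] <- ar$y[ic6] + out6[2]
    }
    pl <- plant(ar, ac, d_act, have_contact)
    at <- rbind(pl$r, pl$c)
    if (spec$jitter_sd > 0) {
      protect <- at$atom %in% planted_names |
        (at$chain == "C" & at$atom == "O" &
           at$resno %in% spec$hbond_chem_resnos) |
        (at$chain == "C" & at$atom %in% c("CB", "CG1", "CG2", "CG3") &
           at$resno %in% spec$contacts$chem_resno)
      n_free <- sum(!protect)
      at[!protect, c("x", "y", "z")] <- at[!protect, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * n_free, 0, spec$jitter_sd), ncol = 3)
    }
    d <- as.matrix(stats::dist(at[, c("x", "y", "z")]))
    same_res <- outer(paste(at$chain, at$resno), paste(at$chain, at$resno),
                      "==")
    d[same_res] <- Inf  # covalently bonded within a residue
    if (min(d) < 0.4) {
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "infeasible toy geometry: %s %d %s and %s %d %s are %.2f Angstrom apart",
        at$chain[ij[1]], at$resno[ij[1]], at$atom[ij[1]],
        at$chain[ij[2]], at$resno[ij[2]], at$atom[ij[2]], min(d)))
    }
    structure_model(id, at, c(receptor = "R", chemokine = "C"))
  }

  n_with <- ceiling(spec$contacts$fraction * n_models)
  models <- lapply(seq_len(n_models), function(i)
    build_model(sprintf("model_%02d", i), act_d[i],
                have_contact = i <= n_with, active = TRUE))
  inactive <- build_model("inactive_ref", act_d[1],
                          have_contact = rep(FALSE, nrow(spec$contacts)),
                          active = FALSE)
  ens <- structure_ensemble(models, receptor_chain = "R",
                            chemokine_chain = "C",
                            reference_inactive = inactive)
  cfg <- structure_config(receptor_chain = "R", chemokine_chain = "C",
                          activation_donor = 126, activation_acceptor = 271,
                          tm_table = tm,
                          intracellular_markers =
                            as.vector(outer(0:1, tm$from, "+")))
  truth <- list(activation_distances = act_d, contacts = spec$contacts,
                hbond_donor_resno = spec$hbond_donor_resno,
                hbond_chem_resnos = spec$hbond_chem_resnos,
                helix_shift = spec$helix_shift,
                shift_segment = spec$shift_segment,
                disulfide_resnos = spec$disulfide_resnos)
  list(ensemble = ens, truth = truth, config = cfg)
}
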