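toy_cfg <- function(toy) toy$config

test_that("superposition recovers rigid transforms and exact RMSD", {
  toy <- generate_toy_ensemble(n_models = 1, seed = 6)
  m <- toy$ensemble$models[[1]]
  self <- superpose(m, m)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  rot <- random_rigid(m, seed = 1)
  sup <- superpose(rot, m)
  expect_equal(sup$rmsd, 0, tolerance = 1e-8)
  expect_equal(as.matrix(sup$model$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate two-atom selection errors
  two <- m$atoms[m$atoms$atom == "CA", ][1:2, ]
  m2 <- make_model(two, chain_roles = c(receptor = "R"))
  expect_error(superpose(m2, m2), "at least 3")
})

test_that("superposition RMSD matches an independent implementation", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    A <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    B <- A + matrix(rnorm(3 * n, sd = 1), ncol = 3)
    mk <- function(X, id) make_model(do.call(rbind, lapply(seq_len(n),
      function(k) atom_row("A", k, "CA", X[k, 1], X[k, 2], X[k, 3], "C"))),
      model_id = id)
    ours <- superpose(mk(A, "a"), mk(B, "b"))$rmsd
    ref <- bio3d::rot.lsq(xx = as.vector(t(A)), yy = as.vector(t(B)))
    rmsd_ref <- sqrt(mean(rowSums(
      (matrix(ref, ncol = 3, byrow = TRUE) - B)^2)))
    expect_equal(ours, rmsd_ref, tolerance = 1e-6)
  }
})

test_that("ensemble RMSF recovers planted per-coordinate jitter", {
  # custom CA-only ensemble with known isotropic jitter
  set.seed(31)
  n_res <- 100; n_mod <- 50; sigma <- 0.3
  base <- matrix(rnorm(3 * n_res, sd = 8), ncol = 3)
  mods <- lapply(seq_len(n_mod), function(m) {
    X <- base + matrix(rnorm(3 * n_res, 0, sigma), ncol = 3)
    make_model(do.call(rbind, lapply(seq_len(n_res), function(k)
      atom_row("A", k, "CA", X[k, 1], X[k, 2], X[k, 3], "C", conf = 90))),
      model_id = sprintf("m%02d", m))
  })
  ens <- structure_ensemble(mods, receptor_chain = "A")
  ev <- ensemble_variability(ens)
  expected <- sigma * sqrt(3 * (n_mod - 1) / n_mod)
  expect_equal(mean(ev$rmsf), expected, tolerance = 0.1)
  expect_equal(ev$mean_confidence, rep(90, n_res))
  # duplicated models have zero fluctuation
  dup <- structure_ensemble(list(mods[[1]], mods[[1]]),
                            receptor_chain = "A")
  expect_equal(ensemble_variability(dup)$rmsf, rep(0, n_res),
               tolerance = 1e-9)
})

test_that("activation distance equals the planted separation and a brute-force oracle", {
  toy <- generate_toy_ensemble(
    toy_ensemble_spec(activation_distances = c(3, 12)), n_models = 2,
    seed = 8)
  cfg <- toy_cfg(toy)
  expect_equal(activation_distance(toy$ensemble$models[[1]], cfg), 3,
               tolerance = 1e-6)
  expect_equal(activation_distance(toy$ensemble$models[[2]], cfg), 12,
               tolerance = 1e-6)
  # randomized side-chain placements vs exhaustive min over amide atoms
  set.seed(17)
  for (i in 1:50) {
    oh <- rnorm(3, sd = 5); nd2 <- rnorm(3, sd = 5); od1 <- rnorm(3, sd = 5)
    at <- rbind(atom_row("A", 126, "CA", 0, 0, 0, "C"),
                atom_row("A", 126, "OH", oh[1], oh[2], oh[3], "O",
                         resid = "TYR"),
                atom_row("A", 271, "CA", 1, 1, 1, "C"),
                atom_row("A", 271, "ND2", nd2[1], nd2[2], nd2[3], "N",
                         resid = "ASN"),
                atom_row("A", 271, "OD1", od1[1], od1[2], od1[3], "O",
                         resid = "ASN"))
    m <- make_model(at)
    cfg2 <- structure_config("A")
    oracle <- min(sqrt(sum((oh - nd2)^2)), sqrt(sum((oh - od1)^2)))
    expect_equal(activation_distance(m, cfg2), oracle, tolerance = 1e-9)
  }
  noatom <- make_model(atom_row("A", 126, "CA", 0, 0, 0, "C"))
  expect_error(activation_distance(noatom, structure_config("A")), "OH")
})

test_that("activation ranking is a stable total order with planted monotone metrics", {
  toy <- generate_toy_ensemble(
    toy_ensemble_spec(activation_distances = c(4, 10, 6, 2, 8)),
    n_models = 5, seed = 12)
  rk <- rank_by_activation(toy$ensemble, toy_cfg(toy))
  expect_equal(rk$ranking$model_id,
               paste0("model_0", c(2, 5, 3, 1, 4)))
  expect_equal(rk$most_active, "model_02")
  # single-model ensemble ranks itself
  one <- generate_toy_ensemble(n_models = 1, seed = 12)
  expect_equal(rank_by_activation(one$ensemble, toy_cfg(one))$most_active,
               "model_01")
  # all-equal metrics: id-ordered
  eq <- generate_toy_ensemble(
    toy_ensemble_spec(activation_distances = 5), n_models = 3, seed = 12)
  expect_equal(rank_by_activation(eq$ensemble, toy_cfg(eq))$ranking$model_id,
               paste0("model_0", 1:3))
})

test_that("helix displacement decomposes planted slides and shifts", {
  toy <- generate_toy_ensemble(n_models = 1, seed = 9)
  cfg <- toy_cfg(toy)
  act <- toy$ensemble$models[[1]]
  inact <- toy$ensemble$reference_inactive
  expect_equal(unname(tm_displacement(inact, inact, 205:216, cfg)),
               c(0, 0, 0), tolerance = 1e-9)
  d <- tm_displacement(act, inact, 205:216, cfg)
  expect_equal(unname(d["along_axis"]), 6, tolerance = 0.1)
  # pure radial shift: outward recovered, axial near zero
  rad <- inact
  seg <- rad$atoms$resno %in% 205:216 & rad$atoms$chain == "R"
  th5 <- 2 * pi * 4 / 7
  rad$atoms$x[seg] <- rad$atoms$x[seg] + 4 * cos(th5)
  rad$atoms$y[seg] <- rad$atoms$y[seg] + 4 * sin(th5)
  d2 <- tm_displacement(rad, inact, 205:216, cfg)
  expect_equal(unname(d2["outward"]), 4, tolerance = 0.1)
  expect_equal(unname(d2["along_axis"]), 0, tolerance = 0.1)
  expect_error(tm_displacement(act, inact, 205:216, cfg, frame = 205:230),
               "disjoint")
})

test_that("contact maps match an exhaustive oracle and recover planted pairs", {
  # planted minimal fixture: far-apart chains except declared pairs
  at_r <- do.call(rbind, lapply(1:6, function(k)
    rbind(atom_row("R", k, "CA", 0, 0, 8 * k, "C"),
          atom_row("R", k, "CB", 1.5, 0, 8 * k, "C"))))
  at_c <- do.call(rbind, lapply(1:4, function(k)
    atom_row("C", k, "CB", 40, 0, 8 * k, "C")))
  # plant contacts (2, 1) and (5, 3) at 3.0 Angstrom from the receptor CB
  at_c[at_c$resno == 1, c("x", "y", "z")] <- c(4.5, 0, 16)
  at_c[at_c$resno == 3, c("x", "y", "z")] <- c(4.5, 0, 40)
  m <- structure_model("f", rbind(at_r, at_c),
                       c(receptor = "R", chemokine = "C"))
  ens <- structure_ensemble(list(m), "R", "C")
  cm <- contact_map(ens, cutoff = 4.5)
  expect_equal(nrow(cm), 2)
  expect_equal(cm$rec_resno, c(2, 5))
  expect_equal(cm$chem_resno, c(1, 3))
  expect_equal(cm$min_distance, c(3, 3))
  expect_equal(cm$model_fraction, c(1, 1))
  expect_equal(nrow(contact_map(ens, cutoff = 0)), 0)
  # chains far apart everywhere: empty map
  far <- structure_model("g", rbind(at_r,
                                    do.call(rbind, lapply(1:4, function(k)
                                      atom_row("C", k, "CB", 40, 40, k, "C")))),
                         c(receptor = "R", chemokine = "C"))
  expect_equal(nrow(contact_map(structure_ensemble(list(far), "R", "C"))), 0)
})

test_that("contact maps agree with the O(n^2) oracle on random fixtures", {
  set.seed(23)
  for (rep_i in 1:25) {
    nr <- sample(3:6, 1); nc <- sample(2:5, 1)
    rows <- list()
    for (k in seq_len(nr)) {
      rows[[length(rows) + 1L]] <- atom_row("R", k, "CA", rnorm(1, 0, 4),
                                            rnorm(1, 0, 4), rnorm(1, 0, 4), "C")
      rows[[length(rows) + 1L]] <- atom_row("R", k, "CB", rnorm(1, 0, 4),
                                            rnorm(1, 0, 4), rnorm(1, 0, 4), "C")
    }
    for (k in seq_len(nc))
      rows[[length(rows) + 1L]] <- atom_row("C", k, "CB", rnorm(1, 0, 4),
                                            rnorm(1, 0, 4), rnorm(1, 0, 4), "C")
    m <- structure_model("r", do.call(rbind, rows),
                         c(receptor = "R", chemokine = "C"))
    ens <- structure_ensemble(list(m), "R", "C")
    got <- as.data.frame(contact_map(ens, cutoff = 4.5))
    want <- contact_oracle(m, "R", "C", 4.5)
    key <- function(d) paste(d$rec_resno, d$chem_resno)
    got <- got[order(key(got)), ]; want <- want[order(key(want)), ]
    expect_equal(key(got), key(want))
    expect_equal(got$min_distance, want$min_d, tolerance = 1e-9)
    expect_equal(got$mean_pairs, as.numeric(want$npairs))
  }
})

test_that("mutagenesis-site selection recovers planted strong contacts", {
  spec <- toy_ensemble_spec(hbond_chem_resnos = integer(0))
  toy <- generate_toy_ensemble(spec, n_models = 5, seed = 10)
  cfg <- toy_cfg(toy)
  cm <- contact_map(toy$ensemble, config = cfg)
  tmres <- unlist(mapply(seq, cfg$tm_table$from, cfg$tm_table$to))
  sel <- select_mutagenesis_sites(cm, k = 5, restrict = tmres)
  expect_setequal(sel$resno, spec$contacts$rec_resno)
  expect_equal(nrow(select_mutagenesis_sites(cm, k = 0)), 0)
  # ties break toward the lower residue number
  tied <- structure(data.frame(rec_resno = c(30, 10), chem_resno = 1,
                               min_distance = 3, model_fraction = 1,
                               mean_pairs = 2, strength = 2),
                    class = c("contact_map", "data.frame"))
  expect_equal(select_mutagenesis_sites(tied, k = 1)$resno, 10)
  expect_warning(select_mutagenesis_sites(tied, k = 5), "candidate")
})

test_that("hydrogen-bond detection applies the declared geometric criteria", {
  cfg <- structure_config("A")
  mk <- function(d) make_model(rbind(
    atom_row("A", 1, "CA", 0, 0, 0, "C"),
    atom_row("A", 1, "NZ", 0, 0, 1, "N"),
    atom_row("A", 5, "CA", 10, 0, 0, "C"),
    atom_row("A", 5, "O", 0, 0, 1 + d, "O")))
  expect_equal(nrow(hbond_network(mk(2.9), 1, cfg)), 1)
  expect_equal(nrow(hbond_network(mk(4.0), 1, cfg)), 0)
  hb <- hbond_network(mk(2.9), 1, cfg)
  expect_equal(hb$donor_atom, "NZ")          # nitrogen end is the donor
  expect_true(hb$donor_is_sidechain)
  expect_false(hb$acceptor_is_sidechain)
  # randomized geometries vs exhaustive pairwise oracle
  set.seed(29)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    rows <- lapply(seq_len(n), function(k)
      atom_row("A", k, sample(c("N", "O", "NZ", "OG"), 1),
               rnorm(1, 0, 3), rnorm(1, 0, 3), rnorm(1, 0, 3)))
    m <- make_model(do.call(rbind, rows))
    got <- hbond_network(m, seq_len(n), cfg)
    X <- as.matrix(m$atoms[, c("x", "y", "z")])
    cnt <- 0L
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      d <- sqrt(sum((X[a, ] - X[b, ])^2))
      bb <- m$atoms$atom[c(a, b)] %in% c("N", "CA", "C", "O", "OXT")
      adj <- all(bb) && abs(m$atoms$resno[a] - m$atoms$resno[b]) <= 1
      if (d > 2.5 && d <= 3.5 && !adj) cnt <- cnt + 1L
    }
    expect_equal(nrow(got), cnt)
  }
})

test_that("disulfide pairing is greedy-nearest with exclusive partners", {
  mk <- function(...) {
    pts <- list(...)
    make_model(do.call(rbind, lapply(seq_along(pts), function(k)
      atom_row("C", k * 7, "SG", pts[[k]][1], pts[[k]][2], pts[[k]][3],
               "S", resid = "CYS"))), chain_roles = c(receptor = "C"))
  }
  one <- disulfide_partners(mk(c(0, 0, 0), c(2.05, 0, 0)), "C")
  expect_equal(nrow(one), 1)
  expect_equal(one$res_i, 7); expect_equal(one$res_j, 14)
  expect_equal(nrow(disulfide_partners(mk(c(0, 0, 0), c(9, 0, 0)), "C")), 0)
  # three cysteines, two within reach of one: nearest wins, no reuse
  three <- disulfide_partners(mk(c(0, 0, 0), c(2.0, 0, 0), c(-2.3, 0, 0)),
                              "C")
  expect_equal(nrow(three), 1)
  expect_equal(three$res_j - three$res_i, 7)  # pairs residues 7 and 14
})

test_that("atom-score aggregation sums backbones and side chains", {
  at <- rbind(atom_row("C", 1, "N", 0, 0, 0, "N"),
              atom_row("C", 1, "CA", 1, 0, 0, "C"),
              atom_row("C", 1, "C", 2, 0, 0, "C"),
              atom_row("C", 1, "O", 3, 0, 0, "O"),
              atom_row("C", 1, "CB", 4, 0, 0, "C"))
  m <- make_model(at, chain_roles = c(receptor = "C"))
  sc <- data.frame(chain = "C", resno = 1, atom = at$atom, score = 1)
  agg <- aggregate_atom_scores(m, sc)
  expect_equal(agg$backbone_score, 4)
  expect_equal(agg$sidechain_score, 1)
  z <- sc; z$score <- 0
  expect_equal(unlist(aggregate_atom_scores(m, z)[, 3:4]),
               c(backbone_score = 0, sidechain_score = 0))
  # two-model averaging
  sc2 <- sc; sc2$score <- 3
  avg <- aggregate_atom_scores(list(m, m), list(sc, sc2))
  expect_equal(avg$backbone_score, (4 + 12) / 2)
  expect_equal(avg$sidechain_score, 2)
  bad <- sc; bad$atom[1] <- "ZZ"
  expect_error(aggregate_atom_scores(m, bad), "not found")
})

test_that("structural metrics are invariant under global rigid transforms", {
  toy <- generate_toy_ensemble(n_models = 2, seed = 14)
  cfg <- toy_cfg(toy)
  m <- toy$ensemble$models[[1]]
  d0 <- activation_distance(m, cfg)
  hb0 <- nrow(hbond_network(m, 211, cfg))
  ds0 <- disulfide_partners(m, "C")
  ens0 <- structure_ensemble(list(m), "R", "C")
  cm0 <- as.data.frame(contact_map(ens0, config = cfg))
  for (s in 1:3) {
    mr <- random_rigid(m, seed = 100 + s)
    expect_equal(activation_distance(mr, cfg), d0, tolerance = 1e-9)
    expect_equal(nrow(hbond_network(mr, 211, cfg)), hb0)
    expect_equal(disulfide_partners(mr, "C")$distance, ds0$distance,
                 tolerance = 1e-9)
    cmr <- as.data.frame(contact_map(structure_ensemble(list(mr), "R", "C"),
                                     config = cfg))
    expect_equal(cmr$min_distance, cm0$min_distance, tolerance = 1e-9)
  }
})
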