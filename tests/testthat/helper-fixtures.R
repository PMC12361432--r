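# shared fixture builders (all generated in code; no stored data)

# a flat kinetic trace with an optional post-injection step or transient
make_trace <- function(well_id = "A01", duration = 120, dt = 0.5,
                       injection = 20, baseline = 100, post = NULL,
                       channel = "fluo") {
  times <- seq(0, duration, by = dt)
  v <- rep(baseline, length(times))
  if (!is.null(post)) v[times >= injection] <- post
  chans <- list(); chans[[channel]] <- v
  kinetic_trace(well_id, times, chans, injection)
}

# dual-channel BRET trace with a prescribed ratio series
make_bret_trace <- function(ratio, well_id = "B01", duration = 660,
                            dt = 0.5, injection = 30, donor = 20000) {
  times <- seq(0, duration, by = dt)
  r <- if (is.function(ratio)) ratio(times) else rep(ratio, length(times))
  kinetic_trace(well_id, times,
                list(em540 = donor * r, em470 = rep(donor, length(times))),
                injection)
}

# a bare structure model from coordinate rows
make_model <- function(coords, model_id = "m1",
                       chain_roles = c(receptor = "A")) {
  structure_model(model_id, coords, chain_roles)
}

atom_row <- function(chain, resno, atom, x, y, z, element = NULL,
                     resid = "ALA", conf = 90) {
  if (is.null(element)) element <- substr(atom, 1, 1)
  data.frame(chain = chain, resno = resno, resid = resid, atom = atom,
             element = element, x = x, y = y, z = z, conf = conf,
             stringsAsFactors = FALSE)
}

# random rigid transform applied to a model (rotation + translation)
random_rigid <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t0 <- rnorm(3, sd = 20)
  X <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, t0, "+")
  model$atoms[, c("x", "y", "z")] <- X
  model
}

# exhaustive heavy-atom contact oracle: per residue pair min distance and
# pair count at cutoff
contact_oracle <- function(model, rch, cch, cutoff, sidechain_only = TRUE) {
  bb <- c("N", "CA", "C", "O", "OXT")
  A <- model$atoms[model$atoms$chain == rch &
                     toupper(model$atoms$element) != "H", ]
  if (sidechain_only) A <- A[!A$atom %in% bb, ]
  B <- model$atoms[model$atoms$chain == cch &
                     toupper(model$atoms$element) != "H", ]
  out <- list()
  for (ri in unique(A$resno)) for (cj in unique(B$resno)) {
    XA <- as.matrix(A[A$resno == ri, c("x", "y", "z")])
    XB <- as.matrix(B[B$resno == cj, c("x", "y", "z")])
    dmin <- Inf; np <- 0L
    for (a in seq_len(nrow(XA))) for (b in seq_len(nrow(XB))) {
      d <- sqrt(sum((XA[a, ] - XB[b, ])^2))
      dmin <- min(dmin, d)
      if (d <= cutoff) np <- np + 1L
    }
    if (np > 0)
      out[[length(out) + 1L]] <- data.frame(rec_resno = ri, chem_resno = cj,
                                            min_d = dmin, npairs = np)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(rec_resno = integer(), chem_resno = integer(),
                  min_d = numeric(), npairs = integer())
}
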