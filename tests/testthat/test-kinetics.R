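test_that("rolling average is a trailing mean with shrinking left edge", {
  tr <- make_trace(baseline = 5)
  expect_equal(rolling_average(tr, 10)$channels$fluo, tr$channels$fluo)
  expect_equal(rolling_average(tr, 1)$channels$fluo, tr$channels$fluo)
  ramp <- kinetic_trace("r", seq(0, 9.5, by = 0.5),
                        list(fluo = 1:20), 5)
  sm <- rolling_average(ramp, 10)$channels$fluo
  expect_equal(sm[20], mean(11:20))  # = 15.5
  expect_equal(sm[1], 1)             # shrunk window at the edge
  expect_equal(sm[5], mean(1:5))
  # oracle equivalence on random series
  set.seed(1)
  v <- runif(50)
  tr2 <- kinetic_trace("x", seq_len(50), list(fluo = v), 10)
  naive <- sapply(seq_len(50), function(i) mean(v[max(1, i - 6):i]))
  expect_equal(rolling_average(tr2, 7)$channels$fluo, naive,
               tolerance = 1e-12)
  expect_error(rolling_average(tr2, 51), "exceeds series length")
})

test_that("baseline normalization divides by the pre-injection window", {
  tr <- make_trace(baseline = 100, post = 250)
  out <- baseline_normalize(tr)
  expect_equal(out$channels$fluo[out$times < 20], rep(1, 40))
  expect_equal(out$channels$fluo[out$times >= 20],
               rep(2.5, sum(tr$times >= 20)))
  neg <- make_trace(baseline = -1)
  expect_error(baseline_normalize(neg), "nonpositive baseline")
  # dual injection: each segment normalized to its own window
  times <- seq(0, 100, by = 0.5)
  v <- ifelse(times < 30, 100, ifelse(times < 60, 200, 500))
  tr2 <- kinetic_trace("d", times, list(fluo = v), c(30, 60))
  out2 <- baseline_normalize(tr2)
  expect_equal(unique(out2$channels$fluo[times < 30]), 1)
  expect_equal(unique(out2$channels$fluo[times >= 30 & times < 60]), 2)
  # second segment normalized by the 200-level window before injection 2
  expect_equal(unique(out2$channels$fluo[times >= 60]), 2.5)
})

test_that("vehicle ratio is pointwise division with grid checks", {
  set.seed(2)
  times <- seq(0, 50, 0.5)
  a <- kinetic_trace("a", times, list(fluo = runif(length(times), 1, 5)), 10)
  b <- kinetic_trace("b", times, list(fluo = runif(length(times), 1, 5)), 10)
  expect_equal(vehicle_ratio(a, b)$channels$fluo,
               a$channels$fluo / b$channels$fluo, tolerance = 1e-12)
  expect_equal(vehicle_ratio(a, a)$channels$fluo,
               rep(1, length(times)))
  short <- kinetic_trace("c", times[-1], list(fluo = rep(1, length(times) - 1)),
                         10)
  expect_error(vehicle_ratio(a, short), "grids")
})

test_that("peak responses behave at the trivial fixed points", {
  ag <- make_trace(baseline = 100, post = 200)
  bu <- make_trace(baseline = 100)
  expect_equal(ca_peak_response(ag, bu, window = 1)$value, 2)
  expect_equal(ca_peak_response(bu, bu)$value, 1)
  # noiseless simulated transient matches the generator's closed-form peak
  wt <- variant_truth("WT")
  nz0 <- noise_model(trace_cv = 0, seed = 1)
  grid <- trace_grid()
  tr <- simulate_ca_trace(wt, 1e-8, nz0, grid)
  b2 <- simulate_ca_trace(wt, 0, nz0, grid)
  peak <- ca_peak_response(tr, b2, window = 1)$value
  # oracle: max over the grid of the analytic transient
  pars <- ca_trace_params()
  u <- grid$times[grid$times >= 20] - 20
  upk <- log(pars$tau_decay / pars$tau_rise) /
    (1 / pars$tau_rise - 1 / pars$tau_decay)
  smax <- exp(-upk / pars$tau_decay) - exp(-upk / pars$tau_rise)
  shape <- (exp(-u / pars$tau_decay) - exp(-u / pars$tau_rise)) / smax
  expect_equal(peak, 1 + ca_peak_amplitude(wt, 1e-8) * max(shape),
               tolerance = 1e-9)
})

test_that("kinetic responses are invariant to rescaling raw traces", {
  wt <- variant_truth("WT")
  nz <- noise_model(trace_cv = 0.02, seed = 8)
  set.seed(8); nzl <- nz; nzl$seed <- NULL
  ag <- simulate_ca_trace(wt, 1e-8, nzl)
  bu <- simulate_ca_trace(wt, 0, nzl)
  base_val <- ca_peak_response(ag, bu)$value
  for (k in c(0.01, 3.7, 1e4)) {
    ag2 <- ag; bu2 <- bu
    ag2$channels$fluo <- k * ag$channels$fluo
    bu2$channels$fluo <- k * bu$channels$fluo
    expect_equal(ca_peak_response(ag2, bu2)$value, base_val,
                 tolerance = 1e-12)
  }
  bt <- simulate_bret_trace(wt, 1e-8, nzl)
  bb <- simulate_bret_trace(wt, 0, nzl)
  v0 <- bret_auc_response(bt, bb)$value
  bt$channels$em540 <- 5 * bt$channels$em540
  bt$channels$em470 <- 5 * bt$channels$em470
  expect_equal(bret_auc_response(bt, bb)$value, v0, tolerance = 1e-9)
})

test_that("BRET ratio and area responses match rectangle closed forms", {
  expect_equal(bret_ratio(make_bret_trace(1))$channels$bret,
               rep(1, 1321))
  expect_equal(bret_ratio(make_bret_trace(2))$channels$bret,
               rep(2, 1321))
  set.seed(3)
  tr <- make_bret_trace(1)
  tr$channels$em540 <- runif(1321, 1, 3)
  expect_equal(bret_ratio(tr)$channels$bret,
               tr$channels$em540 / tr$channels$em470, tolerance = 1e-12)
  one_chan <- make_trace()
  expect_error(bret_ratio(one_chan), "lacks channel")
  # step ratio 1 -> 1 + a: AUC of (normalized ratio - 1) is a * horizon
  a <- 0.2
  ag <- make_bret_trace(function(t) ifelse(t < 30, 1, 1 + a))
  bu <- make_bret_trace(1)
  expect_equal(bret_auc_response(ag, bu, window = 1, horizon = 600)$value,
               a * 600, tolerance = 1e-9)
  expect_equal(bret_auc_response(bu, bu, horizon = 600)$value, 0,
               tolerance = 1e-9)
  # dissociation: ratio 1 -> 1 - a gives AOC a * horizon
  dg <- make_bret_trace(function(t) ifelse(t < 30, 1, 1 - a))
  expect_equal(g_dissoc_aoc(dg, bu, window = 1, horizon = 600)$value,
               a * 600, tolerance = 1e-9)
  expect_equal(g_dissoc_aoc(bu, bu)$value, 0, tolerance = 1e-9)
  expect_warning(bret_auc_response(ag, bu, horizon = 1e5), "truncating")
})

test_that("trapezoid areas are consistent under grid refinement", {
  wt <- variant_truth("WT")
  nz0 <- noise_model(trace_cv = 0, seed = 1)
  g_fine <- trace_grid(duration = 660, dt = 0.25, injections = 60)
  g_half <- trace_grid(duration = 660, dt = 0.5, injections = 60)
  v_f <- bret_auc_response(simulate_bret_trace(wt, 1e-8, nz0, g_fine),
                           simulate_bret_trace(wt, 0, nz0, g_fine),
                           window = 1)$value
  v_h <- bret_auc_response(simulate_bret_trace(wt, 1e-8, nz0, g_half),
                           simulate_bret_trace(wt, 0, nz0, g_half),
                           window = 1)$value
  expect_equal(v_h, v_f, tolerance = 0.01)
})

test_that("antagonist mode reduces to agonist mode under vehicle pretreatment", {
  times <- seq(0, 400, by = 0.5)
  inj <- c(60, 360)
  # vehicle pretreatment: flat through injection 1, probe transient after 2
  resp <- ifelse(times < inj[2], 100, 180)
  tr <- kinetic_trace("w", times, list(fluo = resp), inj)
  bu <- kinetic_trace("b", times, list(fluo = rep(100, length(times))), inj)
  out <- antagonist_response(tr, bu, window = 1)
  expect_equal(out$value, 1.8, tolerance = 1e-9)
  # fully desensitizing pretreatment: flat second segment scores 1
  flat <- kinetic_trace("f", times, list(fluo = rep(100, length(times))), inj)
  expect_equal(antagonist_response(flat, bu)$value, 1)
  single <- kinetic_trace("s", times, list(fluo = resp), inj[1])
  expect_error(antagonist_response(single, bu), "two recorded injections")
  # partial blockade: stronger pretreatment lowers the probe peak
  blocked <- ifelse(times < inj[1], 100,
                    ifelse(times < inj[2], 130, 150))
  trb <- kinetic_trace("p", times, list(fluo = blocked), c(60, 360))
  bub <- kinetic_trace("pb", times,
                       list(fluo = ifelse(times < inj[1], 100, 130)),
                       c(60, 360))
  vb <- antagonist_response(trb, bub, window = 1)$value
  expect_gt(vb, 1)
  expect_lt(vb, out$value)
})
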