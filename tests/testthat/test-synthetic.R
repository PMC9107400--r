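test_that("degenerate diffusion gives constant positions and zero jumps", {
  p <- sim_params(n_molecules = 5, n_frames = 800, D_bound = 0, D_free = 0,
                  loc_error_sigma = 0, bleach_mean = Inf, seed = 4)
  sim <- simulate_switching_tracks(p)
  for (id in unique(sim$localizations$molecule_id)) {
    m <- sim$localizations[sim$localizations$molecule_id == id, ]
    expect_equal(nrow(m), 800)
    expect_equal(diff(range(m$x)), 0)
    expect_equal(diff(range(m$y)), 0)
  }
  j <- compute_jump_lengths(sim_tracks(sim), p$frame_interval, max_lag = 3)
  expect_true(all(unlist(j$jumps) == 0))
})

test_that("symmetric switching reaches a bound fraction of one half", {
  p <- sim_params(n_molecules = 2000, n_frames = 60, frame_interval = 0.05,
                  k_bind = 1, k_unbind = 1, bleach_mean = Inf, seed = 8)
  sim <- simulate_switching_tracks(p)
  gt <- sim$ground_truth
  # states of distinct molecules at the final frame are independent draws
  # from the stationary law
  last <- gt[!duplicated(gt$molecule_id, fromLast = TRUE), ]
  frac <- mean(last$state == "bound")
  se <- sqrt(0.25 / nrow(last))
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("photobleaching lifetimes follow the frame-sampled geometric law", {
  # closed-form oracle: per-frame survival p = exp(-dt/bleach_mean),
  # observed frame count is geometric with mean 1/(1-p)
  p <- sim_params(n_molecules = 10000, n_frames = 400, frame_interval = 0.25,
                  k_bind = 0, k_unbind = 0, D_bound = 0.002, D_free = 0.5,
                  bleach_mean = 5, seed = 2)
  sim <- simulate_switching_tracks(p)
  expect_true(all(sim$ground_truth$state == "bound"))
  lifetimes <- table(sim$ground_truth$molecule_id)
  expected <- 1 / (1 - exp(-0.25 / 5))
  expect_lt(abs(mean(lifetimes) - expected) / expected, 0.05)
})

test_that("a molecule never reappears after bleaching", {
  p <- sim_params(n_molecules = 300, n_frames = 100, bleach_mean = 1, seed = 5)
  sim <- simulate_switching_tracks(p)
  for (rows in split(sim$ground_truth$frame, sim$ground_truth$molecule_id))
    expect_equal(rows, seq(min(rows), length.out = length(rows)))
})

test_that("simulated tracks are reproducible under a fixed seed", {
  p <- sim_params(n_molecules = 20, n_frames = 50, seed = 42)
  expect_identical(simulate_switching_tracks(p), simulate_switching_tracks(p))
})

test_that("pooled MSD matches 4 D k dt + 4 sigma^2 for free diffusion", {
  # single effective population: both states share D, so switching is inert
  # short tracks in a wide field keep boundary reflections negligible
  D <- 0.3; s <- 0.03; dt <- 0.05
  p <- sim_params(n_molecules = 2200, n_frames = 6, frame_interval = dt,
                  D_bound = D, D_free = D, loc_error_sigma = s,
                  fov_size = c(200, 200), bleach_mean = Inf, seed = 9)
  sim <- simulate_switching_tracks(p)
  j <- compute_jump_lengths(sim_tracks(sim), dt, max_lag = 3)
  for (k in 1:3) {
    r2 <- j$jumps[[k]]^2
    want <- 4 * (D * k * dt + s^2)
    se <- sd(r2) / sqrt(length(r2))
    expect_lt(abs(mean(r2) - want), 3 * se)
  }
})

test_that("ground-truth bound dwell times are geometric", {
  # long movies so the finite observation window does not length-bias runs
  dt <- 0.25; ku <- 2
  p <- sim_params(n_molecules = 30, n_frames = 2000, frame_interval = dt,
                  k_bind = 3, k_unbind = ku, bleach_mean = Inf, seed = 10)
  sim <- simulate_switching_tracks(p)
  cont <- exp(-ku * dt)  # per-frame continuation probability
  # interior runs only (bounded by free frames on both sides)
  runs <- integer(0)
  for (st in split(sim$ground_truth$state, sim$ground_truth$molecule_id)) {
    r <- rle(st)
    idx <- which(r$values == "bound")
    idx <- idx[idx > 1 & idx < length(r$values)]
    runs <- c(runs, r$lengths[idx])
  }
  expect_gt(length(runs), 10000)
  kmax <- max(5, stats::qgeom(0.995, 1 - cont) + 1)
  obs <- tabulate(pmin(runs, kmax), nbins = kmax)
  pr <- (1 - cont) * cont^(seq_len(kmax) - 1)
  pr[kmax] <- cont^(kmax - 1)  # collapse the tail
  gof <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(D_free = NA), "finite")
  expect_error(sim_params(frame_interval = 0), "positive")
  expect_error(sim_params(k_bind = 0, k_unbind = 1), "bound fraction")
  expect_error(sim_params(escape_prob_free = 1.5), "probability")
  expect_warning(
    simulate_switching_tracks(sim_params(n_molecules = 2, n_frames = 3,
                                         fov_size = c(1, 1), D_free = 5)),
    "boundary")
})

test_that("residence-event sampler matches exponential-mixture arithmetic", {
  # pure exponential: sample mean -> tau1
  rs <- simulate_residence_events(1, 3, 8, 10000, seed = 1)
  expect_lt(abs(mean(rs$durations) - 3), 3 * 3 / sqrt(10000))
  expect_false(any(rs$censored))
  # mixture mean 0.75*3 + 0.25*8 = 4.25
  rs <- simulate_residence_events(0.75, 3, 8, 10000, seed = 2)
  se <- sd(rs$durations) / sqrt(10000)
  expect_lt(abs(mean(rs$durations) - 4.25), 3 * se)
  # censoring by bleach: min of exponentials, mean 1/(1/3 + 1/6) = 2
  rs <- simulate_residence_events(1, 3, 3, 10000, bleach_mean = 6, seed = 3)
  se <- sd(rs$durations) / sqrt(10000)
  expect_lt(abs(mean(rs$durations) - 2), 3 * se)
  expect_true(any(rs$censored))
})

test_that("residence-event sampler reorders swapped time constants", {
  expect_warning(rs <- simulate_residence_events(0.2, 8, 3, 100, seed = 1),
                 "reordered")
  expect_gt(mean(rs$durations), 0)
})

test_that("discretized durations are whole frames (ceiling)", {
  rs <- simulate_residence_events(1, 3, 3, 500, frame_interval = 0.25, seed = 4)
  expect_true(all(abs(rs$durations / 0.25 - round(rs$durations / 0.25)) < 1e-9))
  expect_true(all(rs$durations >= attr(rs, "true_durations") - 1e-9))
})

test_that("bleach count profiles follow the exponential decay law", {
  expect_equal(simulate_bleach_counts(500, Inf, 0.05, 20), rep(500, 20))
  counts <- simulate_bleach_counts(1000, 10, 1, 20)
  expect_equal(counts[11], 1000 * exp(-1), tolerance = 1e-12)
  counts <- simulate_bleach_counts(1000, 10, 1, 20, noise = "poisson", seed = 6)
  expect_lt(abs(counts[1] - 1000), 4 * sqrt(1000))
})

test_that("deg tables honour prescribed overlap and concordance", {
  tabs <- simulate_deg_tables(1000, 50, 50, concordance_prob = 1,
                              n_overlap = 50, seed = 3)
  cnt <- overlap_counts(tabs$a, tabs$b)
  expect_equal(cnt$m, 50)
  expect_equal(cnt$concordance_percent, 100)
  # determinism contract
  expect_identical(simulate_deg_tables(200, 20, 30, 0.9, seed = 7),
                   simulate_deg_tables(200, 20, 30, 0.9, seed = 7))
})

test_that("independent significant sets overlap at the hypergeometric mean", {
  N <- 400; n1 <- 40; n2 <- 30
  ms <- vapply(1:200, function(s) {
    tabs <- simulate_deg_tables(N, n1, n2, seed = s)
    overlap_counts(tabs$a, tabs$b)$m
  }, numeric(1))
  mu <- n1 * n2 / N
  v <- n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1))
  expect_lt(abs(mean(ms) - mu), 4 * sqrt(v / 200))
})
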