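#' Pooled jump-length distributions from tracks
#'
#' For every ordered pair of localizations in the same track separated by
#' exactly `k` frames (`k = 1..max_lag`), the Euclidean displacement is added
#' to the lag-`k` pool. Pairs whose frame separation is not an exact integer
#' lag (e.g. spanning a bridged gap) contribute only at their true frame
#' separation, so gap-bridged tracks never contaminate shorter lags.
#'
#' @param tracks track table (`track_id`, `frame`, `x`, `y`).
#' @param frame_interval frame interval (s).
#' @param max_lag largest lag (frames) to pool.
#' @return list of class `jump_data`: `frame_interval`, `jumps` (list of
#'   numeric vectors, one per lag), `n` (per-lag counts).
#' @export
compute_jump_lengths <- function(tracks, frame_interval, max_lag = 2L) {
  stopifnot(is.data.frame(tracks), max_lag >= 1, frame_interval > 0)
  max_lag <- as.integer(max_lag)
  jumps <- vector("list", max_lag)
  if (nrow(tracks) > 0) {
    tr <- tracks[order(tracks$track_id, tracks$frame), ]
    span <- max(tr$frame) - min(tr$frame) + max_lag + 2L
    key <- as.numeric(match(tr$track_id, unique(tr$track_id))) * span + tr$frame
    for (k in seq_len(max_lag)) {
      j <- match(key + k, key)
      ok <- !is.na(j)
      jumps[[k]] <- sqrt((tr$x[j[ok]] - tr$x[ok])^2 + (tr$y[j[ok]] - tr$y[ok])^2)
    }
  } else {
    jumps <- lapply(seq_len(max_lag), function(k) numeric(0))
  }
  structure(list(frame_interval = frame_interval, jumps = jumps,
                 n = vapply(jumps, length, integer(1))),
            class = "jump_data")
}

#' Configuration for the two-state jump-length fit
#'
#' @param bin_width histogram bin width (um), default 0.01.
#' @param r_max largest jump length retained (um); `NULL` uses the data
#'   maximum.
#' @param fix_sigma known localization error (um) to hold fixed, or `NULL`
#'   to fit it.
#' @param fix_fbound bound fraction to hold fixed (e.g. 0 for a
#'   single-population fit), or `NULL` to fit it.
#' @param method `"histogram"` for least squares on per-lag histograms (the
#'   default, matching standard jump-length fitting practice) or `"mle"` for
#'   maximum likelihood on the raw jumps.
#' @param escape_prob per-frame probability that a free molecule leaves the
#'   detection volume, used for an optional free-population depletion
#'   correction; `NULL` (default) disables the correction.
#' @param n_starts number of Latin-hypercube multi-start points.
#' @param seed RNG seed for the multi-start design.
#' @param d_equal_tol relative difference between the two diffusion
#'   constants below which the fit is flagged unidentifiable.
#' @param bounds named list of length-2 parameter boxes (`D_bound`,
#'   `D_free`, `F_bound`, `sigma`) for the multi-start design and optimizer.
#' @return list of class `jump_fit_config`.
#' @export
jump_fit_config <- function(bin_width = 0.01, r_max = NULL,
                            fix_sigma = NULL, fix_fbound = NULL,
                            method = c("histogram", "mle"),
                            escape_prob = NULL,
                            n_starts = 8L, seed = 1L,
                            d_equal_tol = 0.1,
                            bounds = list(D_bound = c(1e-5, 0.2),
                                          D_free = c(1e-3, 5),
                                          F_bound = c(0.02, 0.98),
                                          sigma = c(1e-4, 0.2))) {
  method <- match.arg(method)
  stopifnot(bin_width > 0, n_starts >= 1)
  structure(list(bin_width = bin_width, r_max = r_max, fix_sigma = fix_sigma,
                 fix_fbound = fix_fbound, method = method,
                 escape_prob = escape_prob, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), d_equal_tol = d_equal_tol,
                 bounds = bounds),
            class = "jump_fit_config")
}

# Rayleigh-mixture CDF of jump length r at lag k:
#   F(r) = w_b (1 - exp(-r^2 / (2 s_b^2))) + w_f (1 - exp(-r^2 / (2 s_f^2)))
# with s_state^2 = 2 (D_state k dt + sigma^2). Weights renormalized when a
# free-population depletion factor c_k < 1 is applied.
two_state_weights <- function(f_bound, k, escape_prob) {
  ck <- if (is.null(escape_prob)) 1 else (1 - escape_prob)^k
  wf <- (1 - f_bound) * ck
  c(bound = f_bound, free = wf) / (f_bound + wf)
}

two_state_cdf <- function(r, k, dt, D_bound, D_free, f_bound, sigma,
                          escape_prob = NULL) {
  s2b <- 2 * (D_bound * k * dt + sigma^2)
  s2f <- 2 * (D_free * k * dt + sigma^2)
  w <- two_state_weights(f_bound, k, escape_prob)
  w[1] * (1 - exp(-r^2 / (2 * s2b))) + w[2] * (1 - exp(-r^2 / (2 * s2f)))
}

two_state_density <- function(r, k, dt, D_bound, D_free, f_bound, sigma,
                              escape_prob = NULL) {
  s2b <- 2 * (D_bound * k * dt + sigma^2)
  s2f <- 2 * (D_free * k * dt + sigma^2)
  w <- two_state_weights(f_bound, k, escape_prob)
  w[1] * (r / s2b) * exp(-r^2 / (2 * s2b)) +
    w[2] * (r / s2f) * exp(-r^2 / (2 * s2f))
}

#' Fit the two-state diffusion kinetics model to jump-length distributions
#'
#' Estimates the bound and free diffusion constants, the bound fraction and
#' (optionally) the localization error by fitting the per-lag jump-length
#' distributions to a mixture of two Rayleigh components with per-lag scale
#' `2 (D k dt + sigma^2)`. The default objective is least squares between the
#' empirical per-lag histogram and the exact model bin probabilities
#' (integrated over each bin via the mixture CDF, so bin width introduces no
#' discretization bias); raw-jump maximum likelihood is available via the
#' config. Optimization uses multi-start (Latin hypercube) BFGS on
#' log/logit-transformed parameters. The state with the smaller diffusion
#' constant is labelled bound.
#'
#' @param jumps a `jump_data` object from [compute_jump_lengths()].
#' @param config a [jump_fit_config()].
#' @return list of class `two_state_fit` with `D_bound`, `D_free`,
#'   `F_bound`, `sigma`, `sigma_fixed`, `objective`, `converged`,
#'   `identifiability_warning`, `n_jumps`, `histograms` and the config.
#' @export
fit_two_state_jump_model <- function(jumps, config = jump_fit_config()) {
  stopifnot(inherits(jumps, "jump_data"), inherits(config, "jump_fit_config"))
  if (jumps$n[1] < 200)
    warning("fewer than 200 lag-1 jumps; fit may be unstable")
  dt <- jumps$frame_interval
  K <- length(jumps$jumps)
  r_max <- config$r_max
  if (is.null(r_max)) r_max <- max(unlist(jumps$jumps), 10 * config$bin_width)
  breaks <- seq(0, r_max + config$bin_width, by = config$bin_width)
  hist_list <- lapply(jumps$jumps, function(r) {
    r <- r[r <= max(breaks)]
    h <- graphics::hist(r, breaks = breaks, plot = FALSE)
    list(p = h$counts / max(1, length(r)), mids = h$mids, n = length(r))
  })

  free_sigma <- is.null(config$fix_sigma)
  free_fb <- is.null(config$fix_fbound)
  # theta layout: log D_bound, log D_free, [qlogis F_bound], [log sigma]
  unpack <- function(theta) {
    i <- 2L
    fb <- if (free_fb) stats::plogis(theta[(i <- i + 1L)]) else config$fix_fbound
    sg <- if (free_sigma) exp(theta[i + 1L]) else config$fix_sigma
    list(D_bound = exp(theta[1]), D_free = exp(theta[2]), F_bound = fb,
         sigma = max(sg, 1e-4))
  }
  obj <- function(theta) {
    p <- unpack(theta)
    tot <- 0
    for (k in seq_len(K)) {
      h <- hist_list[[k]]
      if (h$n == 0) next
      cdf <- two_state_cdf(breaks, k, dt, p$D_bound, p$D_free, p$F_bound,
                           p$sigma, config$escape_prob)
      if (config$method == "histogram") {
        tot <- tot + sum((diff(cdf) - h$p)^2)
      } else {
        dens <- two_state_density(jumps$jumps[[k]], k, dt, p$D_bound,
                                  p$D_free, p$F_bound, p$sigma,
                                  config$escape_prob)
        tot <- tot - sum(log(pmax(dens, 1e-300))) / jumps$n[k]
      }
    }
    if (!is.finite(tot)) tot <- 1e10
    tot
  }

  b <- config$bounds
  set.seed(config$seed)
  design <- lhs::randomLHS(config$n_starts, 4)
  starts <- cbind(
    log(b$D_bound[1]) + design[, 1] * diff(log(b$D_bound)),
    log(b$D_free[1]) + design[, 2] * diff(log(b$D_free)),
    stats::qlogis(b$F_bound[1] + design[, 3] * diff(b$F_bound)),
    log(b$sigma[1]) + design[, 4] * diff(log(b$sigma)))
  active <- c(TRUE, TRUE, free_fb, free_sigma)

  best <- NULL
  n_conv <- 0L
  for (s in seq_len(config$n_starts)) {
    th0 <- starts[s, active]
    fit <- tryCatch(
      stats::optim(th0, function(th) obj(th), method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("two-state jump model fit failed to converge from any start")
  p <- unpack(best$par)
  # labelling constraint: the slower state is the bound state
  if (p$D_bound > p$D_free) {
    tmp <- p$D_bound; p$D_bound <- p$D_free; p$D_free <- tmp
    p$F_bound <- 1 - p$F_bound
  }
  ident <- (p$D_free - p$D_bound) <= config$d_equal_tol * max(p$D_free, 1e-12)
  if (ident)
    warning("bound and free diffusion constants are nearly equal; ",
            "F_bound is not identifiable")
  model_hist <- lapply(seq_len(K), function(k) {
    cdf <- two_state_cdf(breaks, k, dt, p$D_bound, p$D_free, p$F_bound,
                         p$sigma, config$escape_prob)
    data.frame(lag = k, r_mid = hist_list[[k]]$mids,
               empirical = hist_list[[k]]$p, model = diff(cdf))
  })
  structure(list(D_bound = p$D_bound, D_free = p$D_free,
                 F_bound = p$F_bound, sigma = p$sigma,
                 sigma_fixed = !free_sigma,
                 objective = best$value, converged = n_conv > 0,
                 identifiability_warning = ident,
                 n_jumps = jumps$n, frame_interval = dt,
                 histograms = do.call(rbind, model_hist),
                 config = config, par = best$par),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state diffusion kinetics fit\n")
  cat(sprintf("  D_bound = %.4g um^2/s, D_free = %.4g um^2/s\n",
              x$D_bound, x$D_free))
  cat(sprintf("  F_bound = %.3f, sigma = %.4g um%s\n", x$F_bound, x$sigma,
              if (x$sigma_fixed) " (fixed)" else ""))
  cat(sprintf("  objective %.4g over %s jumps; converged: %s\n",
              x$objective, paste(x$n_jumps, collapse = "+"), x$converged))
  if (x$identifiability_warning)
    cat("  warning: states not identifiable (D_bound ~ D_free)\n")
  invisible(x)
}

#' Bootstrap confidence intervals for the two-state jump fit
#'
#' Resamples whole tracks with replacement, recomputes the pooled jump-length
#' distributions and refits the model from the point estimate, giving
#' percentile confidence intervals for every parameter. Resamples that fail
#' to converge are dropped and counted.
#'
#' @param tracks track table.
#' @param frame_interval frame interval (s).
#' @param n_resamples number of bootstrap resamples (the full analysis uses
#'   1000 per experimental condition).
#' @param seed integer RNG seed.
#' @param config a [jump_fit_config()].
#' @param max_lag largest lag passed to [compute_jump_lengths()].
#' @param level confidence level (default 0.95).
#' @return list of class `spt_bootstrap` with `point` (the full-data fit),
#'   `samples` (data.frame of per-resample parameter estimates), `ci`
#'   (percentile bounds), `n_resamples`, `n_dropped`, `seed`.
#' @export
bootstrap_fit <- function(tracks, frame_interval, n_resamples = 1000L,
                          seed = 1L, config = jump_fit_config(),
                          max_lag = 2L, level = 0.95) {
  stopifnot(n_resamples >= 1)
  jumps <- compute_jump_lengths(tracks, frame_interval, max_lag)
  point <- fit_two_state_jump_model(jumps, config)
  ids <- unique(tracks$track_id)
  rows_by_id <- split(seq_len(nrow(tracks)), tracks$track_id)[as.character(ids)]
  refit_cfg <- config
  set.seed(seed)
  res <- vector("list", n_resamples)
  dropped <- 0L
  for (b in seq_len(n_resamples)) {
    pick <- sample(length(ids), replace = TRUE)
    rows <- unlist(rows_by_id[pick], use.names = FALSE)
    reps <- rep.int(seq_along(pick), vapply(rows_by_id[pick], length, integer(1)))
    tr <- tracks[rows, ]
    tr$track_id <- reps
    jb <- compute_jump_lengths(tr, frame_interval, max_lag)
    fit <- tryCatch(
      suppressWarnings(refit_from(jb, point, refit_cfg)),
      error = function(e) NULL)
    if (is.null(fit)) { dropped <- dropped + 1L; next }
    res[[b]] <- data.frame(D_bound = fit$D_bound, D_free = fit$D_free,
                           F_bound = fit$F_bound, sigma = fit$sigma)
  }
  if (dropped > 0.1 * n_resamples)
    warning(sprintf("%d of %d bootstrap resamples failed to converge",
                    dropped, n_resamples))
  samples <- do.call(rbind, res)
  a <- (1 - level) / 2
  ci <- t(vapply(names(samples), function(nm)
    stats::quantile(samples[[nm]], c(a, 1 - a), names = FALSE),
    numeric(2)))
  ci <- data.frame(parameter = names(samples), lower = ci[, 1],
                   point = unlist(point[names(samples)]), upper = ci[, 2],
                   row.names = NULL)
  structure(list(point = point, samples = samples, ci = ci,
                 n_resamples = n_resamples, n_dropped = dropped,
                 level = level, seed = seed),
            class = "spt_bootstrap")
}

# single-start refit initialized at an existing point estimate
refit_from <- function(jumps, point, config) {
  cfg <- config
  cfg$n_starts <- 1L
  # reuse the point estimate's optimizer coordinates as the only start
  fit <- fit_from_start(jumps, point$par, cfg)
  fit
}

fit_from_start <- function(jumps, theta0, config) {
  cfg <- config
  # temporarily override the LHS design with the provided start: cheapest is
  # to call the full fitter with n_starts = 1 and a deterministic seed, then
  # polish from theta0 directly.
  dt <- jumps$frame_interval
  K <- length(jumps$jumps)
  r_max <- cfg$r_max
  if (is.null(r_max)) r_max <- max(unlist(jumps$jumps), 10 * cfg$bin_width)
  breaks <- seq(0, r_max + cfg$bin_width, by = cfg$bin_width)
  hist_list <- lapply(jumps$jumps, function(r) {
    r <- r[r <= max(breaks)]
    h <- graphics::hist(r, breaks = breaks, plot = FALSE)
    list(p = h$counts / max(1, length(r)), n = length(r))
  })
  free_sigma <- is.null(cfg$fix_sigma)
  free_fb <- is.null(cfg$fix_fbound)
  unpack <- function(theta) {
    i <- 2L
    fb <- if (free_fb) stats::plogis(theta[(i <- i + 1L)]) else cfg$fix_fbound
    sg <- if (free_sigma) exp(theta[i + 1L]) else cfg$fix_sigma
    list(D_bound = exp(theta[1]), D_free = exp(theta[2]), F_bound = fb,
         sigma = max(sg, 1e-4))
  }
  obj <- function(theta) {
    p <- unpack(theta)
    tot <- 0
    for (k in seq_len(K)) {
      h <- hist_list[[k]]
      if (h$n == 0) next
      cdf <- two_state_cdf(breaks, k, dt, p$D_bound, p$D_free, p$F_bound,
                           p$sigma, cfg$escape_prob)
      if (cfg$method == "histogram") {
        tot <- tot + sum((diff(cdf) - h$p)^2)
      } else {
        dens <- two_state_density(jumps$jumps[[k]], k, dt, p$D_bound,
                                  p$D_free, p$F_bound, p$sigma, cfg$escape_prob)
        tot <- tot - sum(log(pmax(dens, 1e-300))) / jumps$n[k]
      }
    }
    if (!is.finite(tot)) tot <- 1e10
    tot
  }
  fit <- stats::optim(theta0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  p <- unpack(fit$par)
  if (p$D_bound > p$D_free) {
    tmp <- p$D_bound; p$D_bound <- p$D_free; p$D_free <- tmp
    p$F_bound <- 1 - p$F_bound
  }
  structure(list(D_bound = p$D_bound, D_free = p$D_free,
                 F_bound = p$F_bound, sigma = p$sigma,
                 objective = fit$value, converged = fit$convergence == 0,
                 par = fit$par),
            class = "two_state_fit")
}

#' @export
print.spt_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap (%d resamples, %d dropped), %g%% percentile CIs\n",
              x$n_resamples, x$n_dropped, 100 * x$level))
  print(x$ci, digits = 4)
  invisible(x)
}
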