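#' Simulation parameters for switching Brownian motion
#'
#' Bundles the generative parameters for a two-state (chromatin-bound /
#' freely diffusing) molecule population imaged by time-lapse single-molecule
#' microscopy. Defaults describe a HaloTag-labelled transcription factor in a
#' cultured myoblast nucleus: movies of 800 frames at 20 Hz, a bound-state
#' diffusion constant of 0.0018 um^2/s (chromatin-bound, comparable to
#' histone H2B), a free diffusion constant of 0.5 um^2/s, equal switching
#' rates giving a bound fraction of 0.5, 20 nm localization error, and a
#' fluorophore photobleaching lifetime of 5 s.
#'
#' @param n_molecules number of molecules to simulate.
#' @param n_frames number of movie frames (default 800).
#' @param frame_interval time between frames in seconds (0.05 for 20 Hz,
#'   0.25 for 4 Hz).
#' @param fov_size numeric length-2, field-of-view width and height in um.
#' @param D_bound,D_free diffusion constants (um^2/s) of the bound and free
#'   states.
#' @param k_bind,k_unbind free-to-bound and bound-to-free switching rates
#'   (1/s). The equilibrium bound fraction is `k_bind / (k_bind + k_unbind)`.
#' @param loc_error_sigma per-axis Gaussian localization error (um).
#' @param bleach_mean mean of the exponential photobleaching lifetime (s);
#'   `Inf` disables bleaching.
#' @param escape_prob_free per-frame probability that a free molecule leaves
#'   the detection volume permanently (defocalization). Default 0.
#' @param seed integer RNG seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_molecules = 100,
                       n_frames = 800,
                       frame_interval = 0.05,
                       fov_size = c(20, 20),
                       D_bound = 0.0018,
                       D_free = 0.5,
                       k_bind = 0.235,
                       k_unbind = 0.235,
                       loc_error_sigma = 0.02,
                       bleach_mean = 5,
                       escape_prob_free = 0,
                       seed = 1L) {
  p <- list(n_molecules = as.integer(n_molecules), n_frames = as.integer(n_frames),
            frame_interval = frame_interval, fov_size = rep(fov_size, length.out = 2),
            D_bound = D_bound, D_free = D_free, k_bind = k_bind,
            k_unbind = k_unbind, loc_error_sigma = loc_error_sigma,
            bleach_mean = bleach_mean, escape_prob_free = escape_prob_free,
            seed = as.integer(seed))
  num <- unlist(p[c("frame_interval", "fov_size", "D_bound", "D_free",
                    "k_bind", "k_unbind", "loc_error_sigma", "bleach_mean",
                    "escape_prob_free")])
  if (any(is.na(num)) || any(is.nan(num)))
    stop("all simulation parameters must be finite (or Inf for bleach_mean)")
  if (p$n_molecules < 1 || p$n_frames < 1)
    stop("n_molecules and n_frames must be positive")
  if (p$frame_interval <= 0 || any(p$fov_size <= 0) || p$bleach_mean <= 0)
    stop("frame_interval, fov_size and bleach_mean must be strictly positive")
  if (p$D_bound < 0 || p$D_free < 0 || p$k_bind < 0 || p$k_unbind < 0 ||
      p$loc_error_sigma < 0)
    stop("diffusion constants, rates and loc_error_sigma must be non-negative")
  if (!is.finite(p$frame_interval) || !is.finite(p$D_free))
    stop("frame_interval and diffusion constants must be finite")
  if (p$escape_prob_free < 0 || p$escape_prob_free > 1)
    stop("escape_prob_free must be a probability in [0, 1]")
  if (p$k_bind + p$k_unbind > 0) {
    fb <- p$k_bind / (p$k_bind + p$k_unbind)
    if (fb <= 0 || fb >= 1)
      stop("equilibrium bound fraction k_bind/(k_bind+k_unbind) must lie in (0, 1)")
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Switching-diffusion simulation parameters\n")
  cat(sprintf("  %d molecules, %d frames at dt = %g s (%.0f Hz)\n",
              x$n_molecules, x$n_frames, x$frame_interval, 1 / x$frame_interval))
  cat(sprintf("  D_bound = %g, D_free = %g um^2/s; F_bound(eq) = %.3f\n",
              x$D_bound, x$D_free, x$k_bind / (x$k_bind + x$k_unbind)))
  cat(sprintf("  loc error = %g um, bleach mean = %g s, escape/frame = %g\n",
              x$loc_error_sigma, x$bleach_mean, x$escape_prob_free))
  invisible(x)
}

reflect_coord <- function(x, lim) {
  # fold positions back into [0, lim] (reflecting boundary)
  period <- 2 * lim
  r <- x %% period
  ifelse(r > lim, period - r, r)
}

#' Simulate switching Brownian trajectories with localization error
#'
#' Generates 2D trajectories of molecules that switch between a slow
#' chromatin-bound state and a fast freely-diffusing state according to a
#' two-state Markov chain sampled once per frame, with reflecting
#' field-of-view boundaries, per-axis Gaussian localization error, exponential
#' photobleaching and optional per-frame loss of free molecules from the
#' detection volume. The state recorded at frame t governs the displacement
#' from frame t to t+1; switching is evaluated at each frame boundary with
#' probability `1 - exp(-k * dt)`.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `spt_sim` with elements:
#'   \describe{
#'     \item{localizations}{data.frame with columns `frame` (0-based), `x`,
#'       `y` (um, noisy observed positions) and `molecule_id`.}
#'     \item{ground_truth}{data.frame with `molecule_id`, `frame`, `state`
#'       (`"bound"`/`"free"`), `x_true`, `y_true`, `alive`.}
#'     \item{params}{the input parameters.}
#'   }
#' @export
simulate_switching_tracks <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  free_jump <- sqrt(4 * p$D_free * p$frame_interval)
  if (any(p$fov_size < 10 * free_jump))
    warning("field of view smaller than 10x the expected free jump; ",
            "expect boundary artefacts")
  set.seed(p$seed)
  n <- p$n_molecules
  fb_eq <- if (p$k_bind + p$k_unbind > 0) p$k_bind / (p$k_bind + p$k_unbind) else 1
  bound <- stats::runif(n) < fb_eq
  x <- stats::runif(n, 0, p$fov_size[1])
  y <- stats::runif(n, 0, p$fov_size[2])
  alive <- rep(TRUE, n)
  p_surv <- if (is.finite(p$bleach_mean)) exp(-p$frame_interval / p$bleach_mean) else 1
  p_ub <- 1 - exp(-p$k_unbind * p$frame_interval)  # bound -> free
  p_bd <- 1 - exp(-p$k_bind * p$frame_interval)    # free  -> bound
  sd_b <- sqrt(2 * p$D_bound * p$frame_interval)
  sd_f <- sqrt(2 * p$D_free * p$frame_interval)

  rec <- vector("list", p$n_frames)
  for (t in seq_len(p$n_frames) - 1L) {
    if (!any(alive)) break
    idx <- which(alive)
    rec[[t + 1L]] <- data.frame(
      molecule_id = idx, frame = t,
      x_true = x[idx], y_true = y[idx],
      state = ifelse(bound[idx], "bound", "free"))
    # displacement to next frame, governed by the state recorded at this frame
    sds <- ifelse(bound[idx], sd_b, sd_f)
    x[idx] <- reflect_coord(x[idx] + stats::rnorm(length(idx), 0, sds), p$fov_size[1])
    y[idx] <- reflect_coord(y[idx] + stats::rnorm(length(idx), 0, sds), p$fov_size[2])
    # survival to the next frame: bleaching for all, escape for free molecules
    surv <- stats::runif(length(idx)) < p_surv
    esc <- !bound[idx] & (stats::runif(length(idx)) < p$escape_prob_free)
    alive[idx] <- surv & !esc
    # state switching at the frame boundary
    u <- stats::runif(length(idx))
    bound[idx] <- ifelse(bound[idx], u >= p_ub, u < p_bd)
  }
  gt <- do.call(rbind, rec)
  gt <- gt[order(gt$molecule_id, gt$frame), c("molecule_id", "frame", "state",
                                              "x_true", "y_true")]
  gt$alive <- TRUE
  rownames(gt) <- NULL
  locs <- data.frame(
    frame = gt$frame,
    x = gt$x_true + stats::rnorm(nrow(gt), 0, p$loc_error_sigma),
    y = gt$y_true + stats::rnorm(nrow(gt), 0, p$loc_error_sigma),
    molecule_id = gt$molecule_id)
  locs <- locs[order(locs$frame, locs$molecule_id), ]
  rownames(locs) <- NULL
  structure(list(localizations = locs, ground_truth = gt, params = p),
            class = "spt_sim")
}

#' Convert simulated ground truth to a track table
#'
#' Groups the simulated localizations by molecule id into a track table with
#' the layout produced by [link_localizations()] (columns `track_id`, `frame`,
#' `x`, `y`), discarding molecules observed in fewer than two frames. This is
#' the error-free linking oracle for simulated data.
#'
#' @param sim an `spt_sim` object from [simulate_switching_tracks()].
#' @return A track data.frame.
#' @export
sim_tracks <- function(sim) {
  stopifnot(inherits(sim, "spt_sim"))
  locs <- sim$localizations
  keep <- locs$molecule_id %in%
    as.integer(names(which(table(locs$molecule_id) >= 2)))
  tr <- locs[keep, ]
  tr <- tr[order(tr$molecule_id, tr$frame), ]
  data.frame(track_id = tr$molecule_id, frame = tr$frame, x = tr$x, y = tr$y,
             row.names = NULL)
}

#' Simulate residence times from a double-exponential dwell model
#'
#' Draws bound-state dwell times from the two-component exponential mixture
#' `alpha * exp(-t/tau1) + (1-alpha) * exp(-t/tau2)` (survival form), censors
#' each independently by an exponential photobleaching lifetime, and
#' optionally discretizes observed durations to whole frames (ceiling: a
#' molecule present for any part of a frame is detected in it).
#'
#' @param alpha weight of the fast (tau1) component, in \[0, 1\].
#' @param tau1,tau2 fast and slow time constants (s); `tau1 <= tau2`.
#' @param n number of events.
#' @param bleach_mean mean exponential bleaching lifetime (s); `Inf` for no
#'   censoring.
#' @param frame_interval frame interval (s) for discretization; `NULL` keeps
#'   continuous durations.
#' @param seed integer RNG seed.
#' @return A [residence_sample()] whose `censored` flags mark bleach-limited
#'   events, with the uncensored true durations in attribute
#'   `true_durations`.
#' @export
simulate_residence_events <- function(alpha, tau1, tau2, n,
                                      bleach_mean = Inf,
                                      frame_interval = NULL,
                                      seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n >= 1, tau1 > 0, tau2 > 0,
            bleach_mean > 0)
  if (tau1 > tau2) {
    warning("tau1 > tau2; components reordered so tau1 <= tau2")
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    alpha <- 1 - alpha
  }
  set.seed(seed)
  comp_fast <- stats::runif(n) < alpha
  dwell <- stats::rexp(n, rate = 1 / ifelse(comp_fast, tau1, tau2))
  bleach <- if (is.finite(bleach_mean)) stats::rexp(n, rate = 1 / bleach_mean) else rep(Inf, n)
  obs <- pmin(dwell, bleach)
  censored <- bleach < dwell
  if (!is.null(frame_interval)) {
    stopifnot(frame_interval > 0)
    obs <- ceiling(obs / frame_interval) * frame_interval
  }
  out <- residence_sample(obs, censored = censored,
                          frame_interval = if (is.null(frame_interval)) NA_real_ else frame_interval)
  attr(out, "true_durations") <- dwell
  out
}

#' Simulate a photobleaching decay profile of detected-molecule counts
#'
#' Expected count at frame t is `n0 * exp(-t * frame_interval / bleach_mean)`,
#' optionally Poisson-sampled.
#'
#' @param n0 initial number of detected molecules.
#' @param bleach_mean mean bleaching lifetime (s); `Inf` for constant counts.
#' @param frame_interval frame interval (s).
#' @param n_frames number of frames.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer RNG seed (used only for `"poisson"`).
#' @return Numeric vector of per-frame counts (frame 0 first).
#' @export
simulate_bleach_counts <- function(n0, bleach_mean, frame_interval, n_frames,
                                   noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n0 > 0, bleach_mean > 0, frame_interval > 0, n_frames >= 1)
  t <- (seq_len(n_frames) - 1) * frame_interval
  mu <- n0 * exp(-t / bleach_mean)
  if (noise == "poisson") {
    set.seed(seed)
    mu <- stats::rpois(n_frames, mu)
  }
  mu
}

#' Simulate a pair of differential-expression tables with controlled overlap
#'
#' Builds two gene tables over a shared universe with significant sets of
#' given sizes, either drawn independently or with an exact prescribed
#' overlap, and with a given probability that overlapping significant genes
#' agree in fold-change direction.
#'
#' @param n_genes universe size.
#' @param n_sig_a,n_sig_b numbers of significant genes in each table.
#' @param concordance_prob probability that an overlapping significant gene
#'   has the same log2 fold-change sign in both tables.
#' @param fc_sd standard deviation of simulated log2 fold changes.
#' @param n_overlap exact overlap between the significant sets, or `NULL`
#'   (default) to draw the two sets independently.
#' @param seed integer RNG seed.
#' @return list with elements `a` and `b`, each a data.frame with columns
#'   `gene`, `log2fc`, `significant`.
#' @export
simulate_deg_tables <- function(n_genes, n_sig_a, n_sig_b,
                                concordance_prob = 1, fc_sd = 1,
                                n_overlap = NULL, seed = 1L) {
  stopifnot(n_sig_a <= n_genes, n_sig_b <= n_genes,
            concordance_prob >= 0, concordance_prob <= 1)
  set.seed(seed)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  sig_a <- sample(genes, n_sig_a)
  if (is.null(n_overlap)) {
    sig_b <- sample(genes, n_sig_b)
  } else {
    stopifnot(n_overlap <= min(n_sig_a, n_sig_b),
              n_sig_b - n_overlap <= n_genes - n_sig_a)
    shared <- sample(sig_a, n_overlap)
    rest <- sample(setdiff(genes, sig_a), n_sig_b - n_overlap)
    sig_b <- c(shared, rest)
  }
  fc_a <- stats::rnorm(n_genes, 0, fc_sd)
  fc_b <- stats::rnorm(n_genes, 0, fc_sd)
  both <- intersect(sig_a, sig_b)
  i <- match(both, genes)
  agree <- stats::runif(length(both)) < concordance_prob
  fc_b[i] <- abs(fc_b[i]) * sign(fc_a[i]) * ifelse(agree, 1, -1)
  mk <- function(sig, fc) data.frame(gene = genes, log2fc = fc,
                                     significant = genes %in% sig)
  list(a = mk(sig_a, fc_a), b = mk(sig_b, fc_b))
}
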