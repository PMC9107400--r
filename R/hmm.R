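#' @title Two-state gamma-emission hidden Markov model for track segmentation
#' @description Internal helpers plus the exported training, decoding and
#'   segment-extraction functions. The observed variable is the squared
#'   frame-to-frame displacement (um^2); state 1 ("bound") is the state with
#'   the smaller emission mean.
#' @name hmm
NULL

SCALE_FLOOR <- 1e-8   # gamma scale floor (um^2), guards EM degeneracy
SHAPE_CEIL <- 1e3     # gamma shape ceiling
OBS_FLOOR <- 1e-12    # squared displacements floored here (um^2)

# squared frame-to-frame displacements, one sequence per track; sequences are
# split at frame gaps so every observation spans exactly one frame interval
squared_displacement_sequences <- function(tracks) {
  out <- list()
  for (rows in split(seq_len(nrow(tracks)), tracks$track_id)) {
    rows <- rows[order(tracks$frame[rows])]
    df <- diff(tracks$frame[rows])
    d2 <- diff(tracks$x[rows])^2 + diff(tracks$y[rows])^2
    brk <- cumsum(c(0, df[-length(df)] != 1))
    for (seg in split(seq_along(d2)[df == 1], brk[df == 1])) {
      if (length(seg) >= 1)
        out[[length(out) + 1L]] <- list(
          track_id = tracks$track_id[rows[1]],
          frame_start = tracks$frame[rows][seg],
          obs = pmax(d2[seg], OBS_FLOOR))
    }
  }
  out
}

# method-of-moments gamma parameters
gamma_mom <- function(x, w = rep(1, length(x))) {
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  if (v <= 0) v <- m^2 * 1e-4 + 1e-16
  shape <- m^2 / v
  list(shape = shape, scale = m / shape)
}

# weighted gamma maximum likelihood: solves log(k) - digamma(k) = s
# (s = log weighted mean - weighted mean log) by Newton iteration
gamma_wmle <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  ml <- sum(w * log(x)) / sw
  s <- log(m) - ml
  if (!is.finite(s) || s <= 0) return(gamma_mom(x, w))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # standard initializer
  for (i in 1:50) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    knew <- k - f / fp
    if (!is.finite(knew) || knew <= 0) break
    if (abs(knew - k) < 1e-12 * k) { k <- knew; break }
    k <- knew
  }
  k <- min(max(k, 1e-6), SHAPE_CEIL)
  list(shape = k, scale = max(m / k, SCALE_FLOOR))
}

hmm_emission_density <- function(obs, hmm, log = FALSE) {
  d <- cbind(stats::dgamma(obs, shape = hmm$shapes[1], scale = hmm$scales[1],
                           log = log),
             stats::dgamma(obs, shape = hmm$shapes[2], scale = hmm$scales[2],
                           log = log))
  d
}

# scaled forward-backward for one sequence; returns gamma (posteriors), xi
# sums, and the sequence log-likelihood
forward_backward <- function(obs, hmm) {
  Tn <- length(obs)
  B <- pmax(hmm_emission_density(obs, hmm), 1e-300)
  A <- hmm$transition
  alpha <- matrix(0, Tn, 2)
  cvec <- numeric(Tn)
  a <- hmm$initial * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, 2)
  beta[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1) {
    b <- A %*% (B[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  xi <- matrix(0, 2, 2)
  if (Tn > 1) for (t in 1:(Tn - 1)) {
    m <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / cvec[t + 1]
    xi <- xi + m
  }
  list(gamma = g, xi = xi, loglik = sum(log(cvec)))
}

#' Train a two-state gamma-emission HMM on squared displacements
#'
#' Baum-Welch expectation-maximization over all tracks (each track an
#' independent observation sequence) with gamma emission densities on the
#' squared frame-to-frame displacement. The M-step uses exact weighted gamma
#' maximum likelihood, so the total log-likelihood is non-decreasing across
#' iterations. Initialization is deterministic: displacements are split at
#' their median, each half seeds one state by method of moments, transition
#' matrix starts at 0.9 self / 0.1 switch with uniform initial probabilities.
#' After convergence states are ordered so state 1 (bound) has the smaller
#' emission mean.
#'
#' @param tracks track table (`track_id`, `frame`, `x`, `y`); the 4 Hz
#'   time-series tracks in the intended workflow.
#' @param frame_interval frame interval (s), stored for downstream use.
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param max_iter maximum EM iterations.
#' @param seed unused by the deterministic initializer; kept so callers can
#'   treat all model-fitting entry points uniformly.
#' @return list of class `gamma_hmm`: `shapes`, `scales` (per state),
#'   `transition`, `initial`, `loglik`, `ll_trace`, `n_iterations`,
#'   `converged`, `frame_interval`.
#' @export
fit_two_state_gamma_hmm <- function(tracks, frame_interval, tol = 1e-6,
                                    max_iter = 200L, seed = NULL) {
  seqs <- squared_displacement_sequences(tracks)
  obs_all <- unlist(lapply(seqs, `[[`, "obs"))
  if (length(obs_all) < 50)
    stop("need at least 50 displacement observations to train the HMM")
  if (stats::sd(obs_all) <= 1e-10 * mean(obs_all))
    stop("degenerate data: all squared displacements are (nearly) equal")
  med <- stats::median(obs_all)
  lo <- obs_all[obs_all <= med]; hi <- obs_all[obs_all > med]
  if (length(hi) == 0) { lo <- obs_all; hi <- obs_all }
  g1 <- gamma_mom(lo); g2 <- gamma_mom(hi)
  hmm <- list(shapes = c(g1$shape, g2$shape),
              scales = pmax(c(g1$scale, g2$scale), SCALE_FLOOR),
              transition = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
              initial = c(0.5, 0.5))

  ll_trace <- numeric(0)
  floored <- FALSE
  for (iter in seq_len(max_iter)) {
    tot_ll <- 0
    xi <- matrix(0, 2, 2)
    init <- c(0, 0)
    glist <- vector("list", length(seqs))
    for (si in seq_along(seqs)) {
      fb <- forward_backward(seqs[[si]]$obs, hmm)
      tot_ll <- tot_ll + fb$loglik
      xi <- xi + fb$xi
      init <- init + fb$gamma[1, ]
      glist[[si]] <- fb$gamma
    }
    gmat <- do.call(rbind, glist)
    ll_trace <- c(ll_trace, tot_ll)
    # M-step
    newA <- xi / rowSums(xi)
    if (any(!is.finite(newA))) newA <- hmm$transition
    newinit <- init / sum(init)
    new_em <- lapply(1:2, function(s) gamma_wmle(obs_all, gmat[, s]))
    if (any(vapply(new_em, function(e) e$scale <= SCALE_FLOOR, logical(1))))
      floored <- TRUE
    hmm$transition <- newA
    hmm$initial <- newinit
    hmm$shapes <- vapply(new_em, `[[`, numeric(1), "shape")
    hmm$scales <- vapply(new_em, `[[`, numeric(1), "scale")
    if (iter > 1 && (tot_ll - ll_trace[iter - 1]) < tol) break
  }
  if (floored)
    warning("gamma scale floor reached during EM; emissions may be degenerate")
  means <- hmm$shapes * hmm$scales
  ord <- order(means)
  hmm$shapes <- hmm$shapes[ord]
  hmm$scales <- hmm$scales[ord]
  hmm$initial <- hmm$initial[ord]
  hmm$transition <- hmm$transition[ord, ord]
  converged <- length(ll_trace) >= 2 &&
    (ll_trace[length(ll_trace)] - ll_trace[length(ll_trace) - 1]) < tol
  structure(c(hmm, list(loglik = ll_trace[length(ll_trace)],
                        ll_trace = ll_trace,
                        n_iterations = length(ll_trace),
                        converged = converged,
                        frame_interval = frame_interval,
                        state_names = c("bound", "free"))),
            class = "gamma_hmm")
}

#' @export
print.gamma_hmm <- function(x, ...) {
  cat("Two-state gamma-emission HMM on squared displacements\n")
  for (s in 1:2)
    cat(sprintf("  %-5s: shape %.4g, scale %.4g um^2 (mean %.4g um^2)\n",
                x$state_names[s], x$shapes[s], x$scales[s],
                x$shapes[s] * x$scales[s]))
  cat("  transition matrix (rows: from bound, free):\n")
  print(round(x$transition, 4))
  cat(sprintf("  log-likelihood %.4f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iterations, x$converged))
  invisible(x)
}

#' Viterbi decoding of a displacement sequence
#'
#' Returns the maximum-probability hidden-state path for one observation
#' sequence of squared displacements under a trained [fit_two_state_gamma_hmm()]
#' model. Exact ties are broken toward the bound state (state 1), applied
#' consistently at every step and at the final state. Observations with zero
#' emission density under both states are floored with a warning.
#'
#' @param obs numeric vector of squared displacements (um^2).
#' @param hmm a `gamma_hmm` object.
#' @return character vector of decoded states (`"bound"`/`"free"`), one per
#'   displacement, with the path log-probability in attribute `logprob`.
#' @export
viterbi_decode <- function(obs, hmm) {
  stopifnot(inherits(hmm, "gamma_hmm"), length(obs) >= 1)
  obs <- pmax(obs, OBS_FLOOR)
  logB <- hmm_emission_density(obs, hmm, log = TRUE)
  if (any(!is.finite(logB))) {
    warning("zero-probability observations under both states; ",
            "emission log-density floored")
    logB[!is.finite(logB)] <- log(1e-300)
  }
  logA <- log(hmm$transition)
  Tn <- length(obs)
  delta <- matrix(-Inf, Tn, 2)
  psi <- matrix(1L, Tn, 2)
  delta[1, ] <- log(hmm$initial) + logB[1, ]
  if (Tn > 1) for (t in 2:Tn) {
    for (s in 1:2) {
      cand <- delta[t - 1, ] + logA[, s]
      best <- which.max(cand)   # earliest index on ties = bound state
      psi[t, s] <- best
      delta[t, s] <- cand[best] + logB[t, s]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  out <- hmm$state_names[path]
  attr(out, "logprob") <- max(delta[Tn, ])
  out
}

#' Decode every track into bound/free step states
#'
#' Applies [viterbi_decode()] to each track's squared-displacement sequence.
#' A track of L localizations yields L-1 step states; tracks with frame gaps
#' are decoded per contiguous run.
#'
#' @param tracks track table.
#' @param hmm trained `gamma_hmm`.
#' @return data.frame of class `state_sequences`: `track_id`, `frame_start`
#'   (frame at the start of the step), `state`.
#' @export
decode_tracks <- function(tracks, hmm) {
  seqs <- squared_displacement_sequences(tracks)
  out <- lapply(seqs, function(sq) {
    data.frame(track_id = sq$track_id, frame_start = sq$frame_start,
               state = as.character(viterbi_decode(sq$obs, hmm)))
  })
  res <- do.call(rbind, out)
  class(res) <- c("state_sequences", "data.frame")
  res
}

#' Extract bound segments and residence times from decoded state sequences
#'
#' Maximal runs of decoded bound steps of length at least `min_steps` become
#' binding events. A segment's residence time is `n_steps * frame_interval`;
#' segments touching the first or last step of their track are flagged as
#' censored (the binding event extends beyond the observed track).
#'
#' @param state_seqs output of [decode_tracks()]. May carry a `nucleus_id`
#'   column, which is propagated to segments.
#' @param frame_interval frame interval (s).
#' @param min_steps minimum number of bound steps for a segment (default 2;
#'   a single-step event is indistinguishable from noise).
#' @return list with `sample` (a [residence_sample()]; censored flags mark
#'   track-edge segments) and `segments` (data.frame: `track_id`,
#'   `nucleus_id`, `start_frame`, `n_steps`, `duration`, `event_time`,
#'   `censored_left`, `censored_right`).
#' @export
extract_bound_segments <- function(state_seqs, frame_interval, min_steps = 2L) {
  stopifnot(min_steps >= 1, frame_interval > 0)
  segs <- list()
  has_nuc <- "nucleus_id" %in% names(state_seqs)
  for (rows in split(seq_len(nrow(state_seqs)), state_seqs$track_id)) {
    rows <- rows[order(state_seqs$frame_start[rows])]
    st <- state_seqs$state[rows]
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values == "bound" & r$lengths >= min_steps)) {
      segs[[length(segs) + 1L]] <- data.frame(
        track_id = state_seqs$track_id[rows[1]],
        nucleus_id = if (has_nuc) state_seqs$nucleus_id[rows[1]] else NA_character_,
        start_frame = state_seqs$frame_start[rows[starts[i]]],
        n_steps = r$lengths[i],
        duration = r$lengths[i] * frame_interval,
        event_time = state_seqs$frame_start[rows[starts[i]]] * frame_interval,
        censored_left = starts[i] == 1L,
        censored_right = ends[i] == length(st))
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(track_id = integer(0), nucleus_id = character(0),
               start_frame = integer(0), n_steps = integer(0),
               duration = numeric(0), event_time = numeric(0),
               censored_left = logical(0), censored_right = logical(0))
  sample <- if (nrow(segments) > 0)
    residence_sample(segments$duration,
                     censored = segments$censored_left | segments$censored_right,
                     frame_interval = frame_interval)
  else residence_sample(numeric(0), logical(0), frame_interval)
  list(sample = sample, segments = segments)
}

#' Per-nucleus binding-event rate
#'
#' Rate of binding-event starts per nucleus over the movie duration
#' (events/s). Nuclei present in `nucleus_ids` but with no events are
#' reported with rate 0 and a zero flag.
#'
#' @param segments segment table from [extract_bound_segments()].
#' @param movie_duration movie duration (s).
#' @param nucleus_ids optional character vector of all nuclei in the movie.
#' @return data.frame: `nucleus_id`, `n_events`, `rate`, `zero_flag`, with
#'   the mean rate in attribute `mean_rate`.
#' @export
binding_event_rate <- function(segments, movie_duration, nucleus_ids = NULL) {
  stopifnot(movie_duration > 0)
  ids <- segments$nucleus_id
  ids[is.na(ids)] <- "all"
  counts <- table(ids)
  all_ids <- union(names(counts), as.character(nucleus_ids %||% character(0)))
  if (length(all_ids) == 0) all_ids <- "all"
  n <- as.integer(counts[all_ids])
  n[is.na(n)] <- 0L
  out <- data.frame(nucleus_id = all_ids, n_events = n,
                    rate = n / movie_duration, zero_flag = n == 0L)
  attr(out, "mean_rate") <- mean(out$rate)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
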