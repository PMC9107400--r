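# shared fixtures and independent oracles used across test files

# track table from explicit coordinates
make_track <- function(track_id, frames, x, y) {
  data.frame(track_id = track_id, frame = frames, x = x, y = y)
}

# a gamma_hmm object built by hand (bypasses training)
make_hmm <- function(shapes, scales, transition, initial) {
  structure(list(shapes = shapes, scales = scales,
                 transition = transition, initial = initial,
                 loglik = NA_real_, ll_trace = numeric(0),
                 n_iterations = 0L, converged = TRUE,
                 frame_interval = 0.25,
                 state_names = c("bound", "free")),
            class = "gamma_hmm")
}

random_valid_hmm <- function() {
  a1 <- runif(1, 0.6, 0.95); a2 <- runif(1, 0.6, 0.95)
  make_hmm(shapes = runif(2, 0.5, 3),
           scales = c(runif(1, 0.001, 0.01), runif(1, 0.05, 0.5)),
           transition = matrix(c(a1, 1 - a1, 1 - a2, a2), 2, byrow = TRUE),
           initial = {
             p <- runif(1, 0.1, 0.9); c(p, 1 - p)
           })
}

# exhaustive-enumeration oracle for the best path log-probability
viterbi_brute_force <- function(obs, hmm) {
  Tn <- length(obs)
  logB <- cbind(dgamma(obs, hmm$shapes[1], scale = hmm$scales[1], log = TRUE),
                dgamma(obs, hmm$shapes[2], scale = hmm$scales[2], log = TRUE))
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  lp <- apply(paths, 1, function(s) {
    v <- log(hmm$initial[s[1]]) + logB[1, s[1]]
    if (Tn > 1) for (t in 2:Tn)
      v <- v + log(hmm$transition[s[t - 1], s[t]]) + logB[t, s[t]]
    v
  })
  max(lp)
}

# log-probability of a given state path (to verify the returned path itself)
path_logprob <- function(obs, states, hmm) {
  s <- match(states, hmm$state_names)
  logB <- cbind(dgamma(obs, hmm$shapes[1], scale = hmm$scales[1], log = TRUE),
                dgamma(obs, hmm$shapes[2], scale = hmm$scales[2], log = TRUE))
  v <- log(hmm$initial[s[1]]) + logB[1, s[1]]
  if (length(s) > 1) for (t in 2:length(s))
    v <- v + log(hmm$transition[s[t - 1], s[t]]) + logB[t, s[t]]
  v
}

# exhaustive-enumeration oracle for the upper-tail overlap p-value:
# fix one set as 1..n1 and enumerate all n2-subsets of 1..N
hypergeom_enum_pvalue <- function(m, n1, n2, N) {
  subs <- utils::combn(N, n2)
  overlaps <- colSums(subs <= n1)
  mean(overlaps >= m)
}

# per-state theoretical mean squared displacement per step
theoretical_msd_step <- function(D, dt, sigma) 4 * (D * dt + sigma^2)
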