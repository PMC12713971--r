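# Independent oracles and small fixture builders shared across tests.

# posterior state marginals by exhaustive enumeration of all S^T paths
enum_posteriors <- function(logB, pi, A) {
  Tn <- nrow(logB); S <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  logp <- apply(paths, 1L, function(z) {
    lp <- log(pi[z[1]]) + logB[1L, z[1]]
    for (t in 2:Tn)
      lp <- lp + log(A[z[t - 1L], z[t]]) + logB[t, z[t]]
    lp
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  gamma <- matrix(0, Tn, S)
  for (t in seq_len(Tn))
    for (s in seq_len(S))
      gamma[t, s] <- sum(w[paths[, t] == s])
  list(gamma = gamma,
       loglik = log(sum(exp(logp - max(logp)))) + max(logp))
}

# most-probable single path by enumeration (to contrast with posterior
# decoding)
enum_viterbi <- function(logB, pi, A) {
  Tn <- nrow(logB); S <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  logp <- apply(paths, 1L, function(z) {
    lp <- log(pi[z[1]]) + logB[1L, z[1]]
    for (t in 2:Tn)
      lp <- lp + log(A[z[t - 1L], z[t]]) + logB[t, z[t]]
    lp
  })
  paths[which.max(logp), ]
}

# forward-backward in log space (logsumexp), independent of the scaled
# implementation inside the package
logspace_fb <- function(logB, pi, A) {
  Tn <- nrow(logB); S <- ncol(logB)
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  lA <- log(A)
  la <- matrix(-Inf, Tn, S); lb <- matrix(0, Tn, S)
  la[1L, ] <- log(pi) + logB[1L, ]
  for (t in 2:Tn)
    for (s in seq_len(S))
      la[t, s] <- lse(la[t - 1L, ] + lA[, s]) + logB[t, s]
  for (t in (Tn - 1L):1L)
    for (s in seq_len(S))
      lb[t, s] <- lse(lA[s, ] + logB[t + 1L, ] + lb[t + 1L, ])
  lg <- la + lb
  lg <- lg - apply(lg, 1L, lse)
  list(gamma = exp(lg), loglik = lse(la[Tn, ]))
}

# random 3-state HMM parameters and emissions for decoding tests
random_hmm_fixture <- function(Tn, S = 3L, D = 2L) {
  pi <- stats::runif(S); pi <- pi / sum(pi)
  A <- matrix(stats::runif(S * S), S); A <- A / rowSums(A)
  logB <- matrix(stats::rnorm(Tn * S, sd = 2), Tn, S)
  list(pi = pi, A = A, logB = logB)
}

# sample a state path + Gaussian emissions from an hmm_model
sample_hmm <- function(model, Tn) {
  S <- length(model$stages); D <- ncol(model$mu)
  z <- integer(Tn)
  z[1] <- sample.int(S, 1L, prob = model$pi)
  for (t in 2:Tn)
    z[t] <- sample.int(S, 1L, prob = model$A[z[t - 1L], ])
  X <- matrix(0, Tn, D)
  for (t in seq_len(Tn))
    X[t, ] <- stats::rnorm(D, model$mu[z[t], ], sqrt(model$sigma2[z[t], ]))
  colnames(X) <- colnames(model$mu)
  list(states = z, X = X)
}

# wrap a plain feature matrix as a minimal band_series
as_band_series <- function(X, epoch_len = 30, flagged = NULL,
                           total_power = NULL) {
  structure(list(values = X, epoch_len = epoch_len, band_defs = NULL,
                 n_epochs = nrow(X),
                 total_power = if (is.null(total_power)) rowMeans(X)
                               else total_power,
                 flagged = if (is.null(flagged)) rep(FALSE, nrow(X))
                           else flagged),
            class = "band_series")
}

# Welch-style band power (periodogram averaged over 4-s segments), used
# as the spectral oracle for generated stage segments
welch_band_power <- function(x, fs, lo, hi, seg_s = 4) {
  nseg <- as.integer(seg_s * fs)
  n <- (length(x) %/% nseg) * nseg
  m <- matrix(x[seq_len(n)], nseg)
  ps <- rowMeans(abs(apply(m, 2L, stats::fft))^2) / nseg
  f <- (seq_len(nseg) - 1L) * fs / nseg
  sel <- f >= lo & f <= hi & f <= fs / 2
  mean(ps[sel])
}

# short multi-stage night used by several modules; cached per session
short_night <- local({
  cache <- NULL
  function(seed = 3) {
    if (!is.null(cache) && cache$seed == seed) return(cache$night)
    segs <- data.frame(
      stage = c("WAKE", "LIGHT", "HIDEEP", "LODEEP", "LIGHT", "REM",
                "WAKE"),
      duration_s = c(600, 1500, 900, 1200, 600, 1200, 1200))
    night <- generate_night(stage_script(segs, seed = seed))
    night$script_seed <- seed
    cache <<- list(seed = seed, night = night)
    night
  }
})

# baselined spectrogram + bands for the short night (computed once)
short_scored <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    night <- short_night()
    res <- score_recording(night$recording)
    cache <<- list(night = night, res = res)
    cache
  }
})
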