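#' Construct a Gaussian-emission hidden Markov model
#'
#' States are sleep stages; each emits the epoch feature vector from a
#' diagonal-covariance Gaussian. The diagonal family is deliberate: on a
#' single night there are only a few hundred epochs per stage, and full
#' covariances make EM fragile while adding little on dB-scale band
#' features, which are close to Gaussian and weakly correlated.
#'
#' @param stages Character vector of state names (any length >= 2).
#' @param pi Initial state distribution (sums to 1).
#' @param A Transition matrix, rows summing to 1.
#' @param mu States x features matrix of emission means (dB).
#' @param sigma2 States x features matrix of emission variances (dB^2).
#' @param var_floor Lower bound applied to all variances.
#' @return An `hmm_model`.
#' @export
hmm_model <- function(stages, pi, A, mu, sigma2, var_floor = 0.25) {
  S <- length(stages)
  mu <- as.matrix(mu); sigma2 <- as.matrix(sigma2); A <- as.matrix(A)
  stopifnot(S >= 2, length(pi) == S, nrow(A) == S, ncol(A) == S,
            nrow(mu) == S, all(dim(sigma2) == dim(mu)))
  if (abs(sum(pi) - 1) > 1e-10) stop("pi must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-10))
    stop("every row of A must sum to 1")
  if (any(pi < 0) || any(A < 0)) stop("probabilities must be non-negative")
  sigma2 <- pmax(sigma2, var_floor)
  rownames(mu) <- rownames(sigma2) <- rownames(A) <- colnames(A) <-
    names(pi) <- stages
  structure(list(stages = stages, pi = pi, A = A, mu = mu,
                 sigma2 = sigma2, var_floor = var_floor,
                 loglik_history = numeric(0)),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> %d states (%s), %d features%s\n",
              length(x$stages), paste(x$stages, collapse = ", "),
              ncol(x$mu),
              if (length(x$loglik_history))
                sprintf(", EM loglik %.2f after %d iterations",
                        utils::tail(x$loglik_history, 1),
                        length(x$loglik_history)) else ""))
  invisible(x)
}

# coerce band_series / matrix input to (features, mask)
.features_of <- function(bands) {
  if (inherits(bands, "band_series"))
    list(X = bands$values, mask = bands$flagged)
  else
    list(X = as.matrix(bands),
         mask = rep(FALSE, nrow(as.matrix(bands))))
}

# T x S log emission densities; masked epochs are treated as unobserved
# (log-density 0 for every state) so they carry no emission information
.log_emissions <- function(X, model, mask) {
  S <- length(model$stages)
  logB <- matrix(0, nrow(X), S)
  for (s in seq_len(S)) {
    v <- model$sigma2[s, ]
    logB[, s] <- -0.5 * colSums((t(X) - model$mu[s, ])^2 / v) -
      0.5 * sum(log(2 * pi * v))
  }
  logB[mask, ] <- 0
  logB
}

# scaled forward-backward; returns gamma, pairwise transition expectations
# summed over time, and the total log-likelihood
.forward_backward <- function(logB, pi, A) {
  Tn <- nrow(logB); S <- ncol(logB)
  # per-row shift keeps exp() in range without changing posteriors
  shift <- apply(logB, 1L, max)
  B <- exp(logB - shift)
  alpha <- matrix(0, Tn, S); beta <- matrix(0, Tn, S)
  cvec <- numeric(Tn)
  a <- pi * B[1L, ]
  cvec[1L] <- sum(a)
  if (!is.finite(cvec[1L]) || cvec[1L] <= 0)
    stop("forward pass underflowed at epoch 1")
  alpha[1L, ] <- a / cvec[1L]
  for (t in 2:Tn) {
    a <- (alpha[t - 1L, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    if (!is.finite(cvec[t]) || cvec[t] <= 0)
      stop("forward pass underflowed at epoch ", t)
    alpha[t, ] <- a / cvec[t]
  }
  beta[Tn, ] <- 1
  xi_sum <- matrix(0, S, S)
  for (t in (Tn - 1L):1L) {
    bb <- B[t + 1L, ] * beta[t + 1L, ]
    xi <- (alpha[t, ] %o% bb) * A
    xi_sum <- xi_sum + xi / sum(xi)
    beta[t, ] <- (A %*% bb) / cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum,
       loglik = sum(log(cvec)) + sum(shift))
}

#' Initialize the staging HMM from argmax band labels
#'
#' Each epoch is provisionally labelled with the stage whose band feature
#' is largest (band k belongs to stage k). Emission moments come from
#' those label groups, the transition matrix from the labelled transition
#' tally plus `sticky` pseudo-counts on the diagonal (plus a small
#' uniform pseudo-count so no transition starts impossible), and the
#' initial distribution puts most mass on Wake, since nights start awake.
#' A stage with no provisional epochs receives the global moments and a
#' uniform transition row.
#'
#' @param bands A `band_series` (5 features in stage order).
#' @param sticky Diagonal pseudo-count encouraging stage persistence.
#' @param var_floor Variance floor (dB^2).
#' @param pi_wake Initial-probability mass on WAKE; the rest is uniform.
#' @return An `hmm_model` over the five spectral stages.
#' @export
init_hmm <- function(bands, sticky = 5, var_floor = 0.25, pi_wake = 0.6) {
  fx <- .features_of(bands)
  X <- fx$X
  stages <- colnames(X)
  if (is.null(stages)) stages <- SPECTRAL_STAGES[seq_len(ncol(X))]
  S <- length(stages)
  if (nrow(X) < max(10L, S))
    stop("need at least ", max(10L, S), " epochs to initialize (got ",
         nrow(X), ")")
  lab <- max.col(X, ties.method = "first")
  use <- !fx$mask
  g_mu <- colMeans(X[use, , drop = FALSE])
  g_s2 <- apply(X[use, , drop = FALSE], 2L, stats::var)
  g_s2[!is.finite(g_s2)] <- var_floor
  mu <- matrix(rep(g_mu, each = S), S)
  s2 <- matrix(rep(g_s2, each = S), S)
  for (s in seq_len(S)) {
    i <- which(lab == s & use)
    if (length(i) >= 2L) {
      mu[s, ] <- colMeans(X[i, , drop = FALSE])
      s2[s, ] <- apply(X[i, , drop = FALSE], 2L, stats::var)
    } else if (length(i) == 1L) {
      mu[s, ] <- X[i, ]
    }
  }
  s2[!is.finite(s2)] <- var_floor
  counts <- matrix(0, S, S)
  for (t in seq_len(length(lab) - 1L))
    counts[lab[t], lab[t + 1L]] <- counts[lab[t], lab[t + 1L]] + 1
  A <- counts + diag(sticky, S) + 0.1
  A <- A / rowSums(A)
  pi <- rep((1 - pi_wake) / (S - 1L), S)
  pi[match("WAKE", stages, nomatch = 1L)] <- pi_wake
  model <- hmm_model(stages, pi, A, mu, s2, var_floor)
  model$init_labels <- lab
  model
}

#' Refine an HMM by expectation maximization (Baum-Welch)
#'
#' Alternates forward-backward E-steps with closed-form M-step updates of
#' the initial distribution, transition matrix and diagonal Gaussian
#' emissions. The observed-data log-likelihood is non-decreasing across
#' iterations; a decrease beyond round-off aborts with an error. Epochs
#' flagged as noise contribute no emission statistics (they are treated
#' as unobserved), so artifacts cannot drag the stage Gaussians.
#'
#' @param model An `hmm_model` (e.g. from [init_hmm()]).
#' @param bands A `band_series` or plain feature matrix.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood improvement below which EM stops.
#' @return The refined `hmm_model` with `loglik_history` filled in.
#' @export
em_fit <- function(model, bands, max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(model, "hmm_model"))
  fx <- .features_of(bands)
  X <- fx$X; mask <- fx$mask
  if (!all(is.finite(X))) stop("non-finite band features")
  if (ncol(X) != ncol(model$mu))
    stop("feature dimension does not match the model")
  ll_hist <- numeric(0)
  use <- !mask
  for (iter in seq_len(max_iter)) {
    fb <- .forward_backward(.log_emissions(X, model, mask),
                            model$pi, model$A)
    if (!is.finite(fb$loglik))
      stop("log-likelihood became non-finite at EM iteration ", iter)
    if (length(ll_hist) && fb$loglik < utils::tail(ll_hist, 1) - 1e-9)
      stop(sprintf("log-likelihood decreased at EM iteration %d (%.10g -> %.10g)",
                   iter, utils::tail(ll_hist, 1), fb$loglik))
    converged <- length(ll_hist) &&
      (fb$loglik - utils::tail(ll_hist, 1)) <
      tol * abs(utils::tail(ll_hist, 1))
    ll_hist <- c(ll_hist, fb$loglik)
    if (converged) break
    # M-step
    model$pi <- fb$gamma[1L, ] / sum(fb$gamma[1L, ])
    A <- fb$xi_sum + 1e-12
    model$A <- A / rowSums(A)
    w <- fb$gamma[use, , drop = FALSE]
    Xu <- X[use, , drop = FALSE]
    wsum <- colSums(w)
    for (s in seq_along(model$stages)) {
      if (wsum[s] < 1e-8) next  # starved stage keeps its parameters
      m <- colSums(w[, s] * Xu) / wsum[s]
      v <- colSums(w[, s] * sweep(Xu, 2L, m)^2) / wsum[s]
      model$mu[s, ] <- m
      model$sigma2[s, ] <- pmax(v, model$var_floor)
    }
    names(model$pi) <- rownames(model$A) <- colnames(model$A) <-
      model$stages
  }
  model$loglik_history <- ll_hist
  model
}

#' Posterior (maximal-probability) stage decoding
#'
#' Computes per-epoch conditional stage probabilities by scaled
#' forward-backward and assigns each epoch the stage with maximal
#' posterior probability. This is deliberately not the single
#' most-probable path (Viterbi): each epoch's call is the best marginal
#' guess given the whole night. Ties resolve by the fixed stage order of
#' the model.
#'
#' @param model A fitted `hmm_model`.
#' @param bands A `band_series` or feature matrix.
#' @return List with `hypnogram` (the decoded stages) and `posterior`
#'   (fields `gamma`, epoch x stage probabilities, and `loglik`).
#' @export
posterior_decode <- function(model, bands) {
  stopifnot(inherits(model, "hmm_model"))
  fx <- .features_of(bands)
  fb <- .forward_backward(.log_emissions(fx$X, model, fx$mask),
                          model$pi, model$A)
  colnames(fb$gamma) <- model$stages
  stages <- model$stages[max.col(fb$gamma, ties.method = "first")]
  epoch_len <- if (inherits(bands, "band_series")) bands$epoch_len else 30
  labels <- if (all(model$stages %in% SPECTRAL_STAGES)) SPECTRAL_STAGES
            else model$stages
  list(hypnogram = hypnogram(stages, epoch_len = epoch_len,
                             labels = labels),
       posterior = structure(list(gamma = fb$gamma, loglik = fb$loglik),
                             class = "posterior_matrix"))
}
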