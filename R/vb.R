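#' Hyperparameters of the variational model
#'
#' A single Dirichlet concentration `alpha0` is shared by all isoform
#' abundance components (including the noise component, ordinal 0), and
#' each isoform's paternal fraction carries a Beta(`beta1`, `beta2`) prior.
#' The default Beta(1, 1) is the non-informative prior whose posterior mean
#' adds one pseudo-count to each allele (Laplace smoothing of the
#' paternal/maternal ratio).  `alpha0 < 1` favours sparse abundance
#' profiles; it is usually chosen by [select_alpha0()].
#'
#' @param alpha0 Dirichlet concentration, > 0.
#' @param beta1,beta2 Beta prior counts for the paternal and maternal
#'   allele, > 0.
#' @return An object of class `ase_hyper`.
#' @export
ase_hyper <- function(alpha0 = 0.1, beta1 = 1, beta2 = 1) {
  stopifnot(alpha0 > 0, beta1 > 0, beta2 > 0)
  structure(list(alpha0 = alpha0, beta1 = beta1, beta2 = beta2),
            class = "ase_hyper")
}

#' Initialize the variational posterior state
#'
#' Sets every Dirichlet posterior parameter to `alpha0` (components
#' t = 0..T, where 0 is the noise component) and every Beta posterior to
#' its prior, then caches the posterior expectations.
#'
#' @param T Isoform count (>= 1).
#' @param hyper An [ase_hyper()].
#' @return An object of class `vb_state` with elements `alpha_star`
#'   (length T+1, component t stored at index t+1), `beta1_star`,
#'   `beta2_star` (length T), and cached expectation vectors `e_theta`,
#'   `elog_theta`, `e_phi`, `elog_phi`, `elog_1mphi`.
#' @export
init_state <- function(T, hyper = ase_hyper()) {
  stopifnot(T >= 1)
  st <- list(alpha_star = rep(hyper$alpha0, T + 1L),
             beta1_star = rep(hyper$beta1, T),
             beta2_star = rep(hyper$beta2, T),
             T = as.integer(T), hyper = hyper,
             N = 0, N_noise = 0)
  class(st) <- "vb_state"
  cache_expectations(st)
}

cache_expectations <- function(st) {
  st$elog_theta <- expected_log_theta(st$alpha_star)
  st$e_theta <- st$alpha_star / sum(st$alpha_star)
  ph <- expected_log_phi(st$beta1_star, st$beta2_star)
  st$elog_phi <- ph$elog_phi
  st$elog_1mphi <- ph$elog_1mphi
  st$e_phi <- ph$e_phi
  st
}

#' Dirichlet posterior expectation of log abundances
#'
#' `E[log theta_t] = digamma(alpha*_t) - digamma(sum(alpha*))`.
#'
#' @param alpha_star Positive Dirichlet parameters.
#' @return A vector of the same length.
#' @export
expected_log_theta <- function(alpha_star) {
  if (any(alpha_star <= 0)) stop("Dirichlet parameters must be > 0")
  digamma(alpha_star) - digamma(sum(alpha_star))
}

#' Beta posterior expectations for the paternal fraction
#'
#' `E[log phi] = digamma(b1) - digamma(b1 + b2)`,
#' `E[log(1 - phi)] = digamma(b2) - digamma(b1 + b2)`,
#' `E[phi] = b1 / (b1 + b2)`.
#'
#' @param beta1_star,beta2_star Positive Beta parameters (vectorized).
#' @return A list with elements `elog_phi`, `elog_1mphi`, `e_phi`.
#' @export
expected_log_phi <- function(beta1_star, beta2_star) {
  if (any(beta1_star <= 0) || any(beta2_star <= 0))
    stop("Beta parameters must be > 0")
  tot <- digamma(beta1_star + beta2_star)
  list(elog_phi = digamma(beta1_star) - tot,
       elog_1mphi = digamma(beta2_star) - tot,
       e_phi = beta1_star / (beta1_star + beta2_star))
}

#' Variational E-step: per-read responsibilities
#'
#' For every read with a non-empty candidate set, computes
#' `E[Z_nths] = rho_nths / sum(rho)` over the candidate set, with
#' `log rho = E[log theta_t] + E[log phi_t]` (or `E[log(1 - phi_t)]` for
#' the maternal haplotype) `+ log p(S|T,H) + log p(R|T,H,S)`, normalized
#' in log space.  Reads whose candidates all underflow to `-Inf` are
#' reassigned to the noise component with a warning.
#'
#' @param aln An `ase_aln` with `log_lik` and `log_pos` populated.
#' @param state A `vb_state`.
#' @return A list: `resp` (responsibility per candidate row), `alpha_add`,
#'   `beta1_add`, `beta2_add` (summed responsibilities feeding the M-step),
#'   `entropy` (`sum E_Z log E_Z`), `n_underflow`.
#' @export
e_step <- function(aln, state) {
  cand <- aln$cand
  if (!nrow(cand)) {
    return(list(resp = numeric(0), alpha_add = numeric(state$T + 1L),
                beta1_add = numeric(state$T), beta2_add = numeric(state$T),
                entropy = 0, n_underflow = 0L))
  }
  if (anyNA(cand$log_lik) || anyNA(cand$log_pos))
    stop("candidate likelihoods not populated; run compute_likelihoods()")
  out <- cpp_estep(as.integer(cand$read), as.integer(cand$t),
                   as.integer(cand$h), cand$log_lik + cand$log_pos,
                   state$elog_theta, state$elog_phi, state$elog_1mphi,
                   aln$n_reads, state$T)
  if (length(out$underflow_reads))
    warning(length(out$underflow_reads),
            " read(s) underflowed and were reassigned to the noise component")
  out$n_underflow <- length(out$underflow_reads)
  out
}

#' Variational M-step: conjugate posterior update
#'
#' `alpha*_t = alpha0 + sum_n E[Z_nt..]` (both haplotypes),
#' `beta*_{t,1} = beta1 + sum over paternal candidates`,
#' `beta*_{t,2} = beta2 + sum over maternal candidates`.  Unaligned and
#' underflowed reads add their unit responsibility to the noise component
#' t = 0 (unless dropped at fit time).
#'
#' @param es Output of [e_step()].
#' @param state The current `vb_state` (supplies `T`, hyperparameters and
#'   the noise-read count).
#' @return The updated `vb_state` with expectations re-cached.
#' @export
m_step <- function(es, state) {
  h <- state$hyper
  alpha_add <- es$alpha_add
  alpha_add[1L] <- alpha_add[1L] + state$N_noise + es$n_underflow
  state$alpha_star <- h$alpha0 + alpha_add
  state$beta1_star <- h$beta1 + es$beta1_add
  state$beta2_star <- h$beta2 + es$beta2_add
  cache_expectations(state)
}

# log of the Dirichlet normalizer G(a) = prod Gamma(a_t) / Gamma(sum a)
log_dirichlet_norm <- function(a) sum(lgamma(a)) - lgamma(sum(a))

#' Variational lower bound L(q)
#'
#' The six-term decomposition
#' `L(q) = E[log p(R, Z | theta, phi)] + E[log p(theta)] + E[log p(phi)]
#'  - E[log q(theta)] - E[log q(phi)] - E[log q(Z)]`,
#' evaluated at the supplied responsibilities and state.  Noise-component
#' reads contribute `E[log theta_0]` to the data term (their emission
#' probability is the constant 1) and zero entropy.
#'
#' @param aln An `ase_aln`.
#' @param es Output of [e_step()] (may come from an earlier state than
#'   `state`; the bound is valid for any pairing).
#' @param state A `vb_state`.
#' @return A single number, with the six components as attribute
#'   `"components"`.
#' @export
compute_elbo <- function(aln, es, state) {
  h <- state$hyper
  T <- state$T
  cand <- aln$cand
  data_term <- 0
  if (nrow(cand))
    data_term <- cpp_weighted_logrho(as.integer(cand$t), as.integer(cand$h),
                                     cand$log_lik + cand$log_pos, es$resp,
                                     state$elog_theta, state$elog_phi,
                                     state$elog_1mphi)
  n_noise <- state$N_noise + es$n_underflow
  data_term <- data_term + n_noise * state$elog_theta[1L]
  prior_a <- rep(h$alpha0, T + 1L)
  e_log_p_theta <- sum((h$alpha0 - 1) * state$elog_theta) -
    log_dirichlet_norm(prior_a)
  e_log_q_theta <- sum((state$alpha_star - 1) * state$elog_theta) -
    log_dirichlet_norm(state$alpha_star)
  e_log_p_phi <- sum((h$beta1 - 1) * state$elog_phi +
                     (h$beta2 - 1) * state$elog_1mphi) -
    T * lbeta(h$beta1, h$beta2)
  e_log_q_phi <- sum((state$beta1_star - 1) * state$elog_phi +
                     (state$beta2_star - 1) * state$elog_1mphi) -
    sum(lbeta(state$beta1_star, state$beta2_star))
  e_log_q_z <- es$entropy
  L <- data_term + e_log_p_theta + e_log_p_phi -
    e_log_q_theta - e_log_q_phi - e_log_q_z
  attr(L, "components") <- c(data = data_term,
                             e_log_p_theta = e_log_p_theta,
                             e_log_p_phi = e_log_p_phi,
                             e_log_q_theta = e_log_q_theta,
                             e_log_q_phi = e_log_q_phi,
                             e_log_q_z = e_log_q_z)
  L
}

#' Run variational Bayesian inference
#'
#' Coordinate ascent alternating [e_step()] and [m_step()] from the prior
#' initialization until convergence: the iteration stops when no abundance
#' component with `E[theta_t] > theta_floor` and no allelic fraction
#' `E[phi_t]` changes by a relative amount larger than `rel_tol` (the
#' bound `L(q)` is recorded every iteration and is non-decreasing).
#' Tracking `E[phi]` alongside `E[theta]` matters because the abundances
#' typically reach their fixed point within a few iterations while the
#' allelic fractions, driven only by the minority of reads that overlap
#' heterozygous sites, converge much more slowly; a theta-only stop would
#' systematically leave them shrunk toward 0.5.
#'
#' @param aln An `ase_aln` with likelihoods populated.
#' @param hyper An [ase_hyper()].
#' @param max_iter Iteration cap (default 1000); reaching it raises a
#'   warning but still returns the state.
#' @param rel_tol Relative-change convergence threshold on `E[theta]`
#'   (default 1e-3).
#' @param theta_floor Components below this abundance are ignored by the
#'   convergence test (default 1e-7).
#' @param drop_unaligned If `TRUE`, reads with empty candidate sets are
#'   discarded instead of being assigned to the noise component.
#' @return A list of class `vb_fit`: `state` (the converged `vb_state`),
#'   `resp` (final responsibilities), `trace` (data.frame of `L(q)` and
#'   its six components per iteration), `iterations`, `converged`.
#' @export
run_inference <- function(aln, hyper = ase_hyper(), max_iter = 1000L,
                          rel_tol = 1e-3, theta_floor = 1e-7,
                          drop_unaligned = FALSE) {
  state <- init_state(aln$T, hyper)
  n_noise <- n_noise_reads(aln)
  state$N_noise <- if (drop_unaligned) 0L else n_noise
  state$N <- aln$n_reads - if (drop_unaligned) n_noise else 0L
  trace <- vector("list", 16L)
  converged <- FALSE
  iter <- 0L
  es <- NULL
  repeat {
    iter <- iter + 1L
    theta_old <- state$e_theta
    phi_old <- state$e_phi
    es <- e_step(aln, state)
    state <- m_step(es, state)
    L <- compute_elbo(aln, es, state)
    trace[[iter]] <- c(iteration = iter, elbo = as.numeric(L),
                       attr(L, "components"))
    rel <- abs(state$e_theta - theta_old) / pmax(theta_old, 1e-300)
    rel[state$e_theta <= theta_floor] <- 0
    rel_phi <- abs(state$e_phi - phi_old) / pmax(phi_old, 1e-300)
    if (max(rel) <= rel_tol && max(rel_phi) <= rel_tol) {
      converged <- TRUE; break
    }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("maximum iterations (", max_iter, ") reached before convergence")
  trace <- as.data.frame(do.call(rbind, trace[seq_len(iter)]))
  structure(list(state = state, resp = es$resp, trace = trace,
                 iterations = iter, converged = converged),
            class = "vb_fit")
}

#' Choose the Dirichlet concentration by the variational bound
#'
#' Runs [run_inference()] for each candidate `alpha0` and returns the one
#' whose converged `L(q)` (the lower bound of the log marginal likelihood)
#' is largest; ties break toward the smaller, sparser value.
#'
#' @param aln An `ase_aln` with likelihoods populated.
#' @param grid Positive candidate values (default `c(0.01, 0.1, 1)`).
#' @param ... Passed to [run_inference()].
#' @return A list: `alpha0` (the argmax), `table` (data.frame of `alpha0`
#'   and converged `elbo`), `fit` (the winning `vb_fit`).
#' @export
select_alpha0 <- function(aln, grid = c(0.01, 0.1, 1), ...) {
  stopifnot(length(grid) >= 1L, all(grid > 0))
  grid <- sort(grid)
  fits <- lapply(grid, function(a)
    run_inference(aln, ase_hyper(alpha0 = a), ...))
  elbo <- vapply(fits, function(f) f$trace$elbo[f$iterations], numeric(1))
  best <- which.max(elbo)   # ties resolve to the smallest alpha0
  list(alpha0 = grid[best],
       table = data.frame(alpha0 = grid, elbo = elbo),
       fit = fits[[best]])
}

#' @export
print.vb_state <- function(x, ...) {
  cat("VB posterior state:", x$T, "isoforms + noise component\n")
  cat("  reads:", x$N, " (noise:", x$N_noise, ")\n")
  cat("  E[theta] range:", format(range(x$e_theta), digits = 4), "\n")
  invisible(x)
}

#' @export
print.vb_fit <- function(x, ...) {
  cat("VB fit:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  final L(q):", format(x$trace$elbo[x$iterations], digits = 8), "\n")
  invisible(x)
}
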