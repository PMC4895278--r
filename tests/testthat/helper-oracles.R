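# Independent oracles used by the tests.  These deliberately avoid the
# package's inference path: the Gibbs sampler and the exact enumeration
# work from the flat candidate table alone.

# Random small inference problem: reads with 1..max_cand candidates over
# T isoforms x 2 haplotypes, with log-weights w = log_lik + log_pos drawn
# at random.  Returns an ase_aln ready for run_inference().
make_toy_aln <- function(T = 3, n_reads = 10, max_cand = 4,
                         frac_noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  n_with <- n_reads - round(frac_noise * n_reads)
  for (r in seq_len(n_with)) {
    k <- sample.int(max_cand, 1)
    th <- unique(data.frame(t = sample.int(T, k, replace = TRUE),
                            h = sample(0:1, k, replace = TRUE)))
    rows[[r]] <- data.frame(read = r, t = th$t, h = th$h,
                            s = seq_len(nrow(th)), span = 1L,
                            log_lik = -abs(stats::rnorm(nrow(th), 2, 2)),
                            log_pos = log(1 / sample(50:200, nrow(th),
                                                     replace = TRUE)))
  }
  ase_alignments(do.call(rbind, rows), n_reads = n_reads, T = T)
}

# Collapsed-free Gibbs sampler over (Z, theta, phi) for the same model:
# theta ~ Dirichlet(alpha0) over components 0..T (0 = noise, never holds
# candidate mass), phi_t ~ Beta(beta1, beta2), read n picks a candidate
# with probability proportional to theta_t * phi-term * exp(w).
# Returns Rao-Blackwellized posterior means of theta and phi.
gibbs_ase <- function(aln, alpha0, beta1 = 1, beta2 = 1,
                      sweeps = 100000, burn = 10000, seed = 1) {
  set.seed(seed)
  cand <- aln$cand
  T <- aln$T
  groups <- split(seq_len(nrow(cand)), cand$read)
  n_noise <- aln$n_reads - length(groups)
  w <- cand$log_lik + cand$log_pos
  tvec <- cand$t; hvec <- cand$h
  theta <- rep(1 / (T + 1), T + 1)
  phi <- rep(0.5, T)
  acc_theta <- numeric(T + 1); acc_phi <- numeric(T)
  kept <- 0L
  for (it in seq_len(sweeps)) {
    lw <- w + log(theta[tvec + 1]) +
      ifelse(hvec == 0, log(phi[tvec]), log(1 - phi[tvec]))
    pick <- vapply(groups, function(idx) {
      p <- exp(lw[idx] - max(lw[idx]))
      idx[sample.int(length(idx), 1L, prob = p)]
    }, integer(1))
    n_t <- tabulate(tvec[pick], T)
    n_t0 <- tabulate(tvec[pick][hvec[pick] == 0], T)
    n_t1 <- n_t - n_t0
    a_post <- alpha0 + c(n_noise, n_t)
    g <- stats::rgamma(T + 1, a_post)
    theta <- g / sum(g)
    phi <- stats::rbeta(T, beta1 + n_t0, beta2 + n_t1)
    phi <- pmin(pmax(phi, 1e-12), 1 - 1e-12)
    if (it > burn) {
      kept <- kept + 1L
      acc_theta <- acc_theta + a_post / sum(a_post)
      acc_phi <- acc_phi + (beta1 + n_t0) / (beta1 + beta2 + n_t)
    }
  }
  list(e_theta = acc_theta / kept, e_phi = acc_phi / kept)
}

# Exact log marginal likelihood log p(R) by enumerating every joint
# candidate assignment and integrating theta and phi analytically
# (Dirichlet-multinomial and Beta-binomial conjugate integrals).
exact_log_marginal <- function(aln, alpha0, beta1 = 1, beta2 = 1) {
  cand <- aln$cand
  T <- aln$T
  groups <- split(seq_len(nrow(cand)), cand$read)
  n_noise <- aln$n_reads - length(groups)
  lG <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  prior_a <- rep(alpha0, T + 1)
  combos <- expand.grid(lapply(groups, identity))
  logp <- apply(as.matrix(combos), 1, function(idx) {
    idx <- as.integer(idx)
    n_t <- tabulate(cand$t[idx], T)
    n_t0 <- tabulate(cand$t[idx][cand$h[idx] == 0], T)
    n_t1 <- n_t - n_t0
    sum(cand$log_lik[idx] + cand$log_pos[idx]) +
      lG(prior_a + c(n_noise, n_t)) - lG(prior_a) +
      sum(lbeta(beta1 + n_t0, beta2 + n_t1) - lbeta(beta1, beta2))
  })
  m <- max(logp)
  m + log(sum(exp(logp - m)))
}

# Exact posterior means of theta and phi by the same enumeration,
# Rao-Blackwellized per assignment.  Only feasible for tiny instances.
exact_posterior <- function(aln, alpha0, beta1 = 1, beta2 = 1) {
  cand <- aln$cand
  T <- aln$T
  groups <- split(seq_len(nrow(cand)), cand$read)
  n_noise <- aln$n_reads - length(groups)
  lG <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  prior_a <- rep(alpha0, T + 1)
  combos <- as.matrix(expand.grid(groups))
  lp <- numeric(nrow(combos))
  eth <- matrix(0, nrow(combos), T + 1)
  eph <- matrix(0, nrow(combos), T)
  for (i in seq_len(nrow(combos))) {
    idx <- combos[i, ]
    n_t <- tabulate(cand$t[idx], T)
    n_t0 <- tabulate(cand$t[idx][cand$h[idx] == 0], T)
    n_t1 <- n_t - n_t0
    a_post <- prior_a + c(n_noise, n_t)
    lp[i] <- sum(cand$log_lik[idx] + cand$log_pos[idx]) +
      lG(a_post) - lG(prior_a) +
      sum(lbeta(beta1 + n_t0, beta2 + n_t1) - lbeta(beta1, beta2))
    eth[i, ] <- a_post / sum(a_post)
    eph[i, ] <- (beta1 + n_t0) / (beta1 + beta2 + n_t)
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  list(e_theta = colSums(eth * w), e_phi = colSums(eph * w))
}
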