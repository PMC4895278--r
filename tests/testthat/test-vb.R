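# a fixture of unambiguous single-candidate reads on one isoform
unambiguous_aln <- function(n_pat = 8L, n_mat = 2L, T = 1L) {
  n <- n_pat + n_mat
  ase_alignments(data.frame(read = seq_len(n), t = 1L,
                            h = rep(c(0L, 1L), c(n_pat, n_mat)),
                            s = 1L, span = 1L, log_lik = 0, log_pos = 0),
                 n_reads = n, T = T)
}

test_that("initialization puts every posterior at its prior", {
  st <- init_state(2, ase_hyper(alpha0 = 0.1))
  expect_equal(st$alpha_star, c(0.1, 0.1, 0.1))
  expect_equal(st$e_phi, c(0.5, 0.5))
  st1 <- init_state(1)
  expect_equal(st1$e_theta, c(0.5, 0.5))
})

test_that("expected log theta follows the digamma formula", {
  expect_equal(expected_log_theta(c(1, 1)), c(-1, -1))  # psi(1) - psi(2)
  expect_equal(expected_log_theta(c(2, 2)),
               rep(digamma(2) - digamma(4), 2))
  expect_equal(expected_log_theta(5), 0)
  expect_true(all(expected_log_theta(c(0.3, 2, 7)) < 0))
  expect_error(expected_log_theta(c(1, 0)), "> 0")
})

test_that("expected log phi follows the Beta formulas", {
  e <- expected_log_phi(1, 1)
  expect_equal(e$elog_phi, -1)
  expect_equal(e$e_phi, 0.5)
  expect_equal(e$elog_phi, e$elog_1mphi)
  expect_equal(expected_log_phi(9, 3)$e_phi, 0.75)
  expect_error(expected_log_phi(0, 1), "> 0")
})

test_that("E-step normalizes responsibilities as a softmax", {
  # three candidates with log rho differences (-1, -2, -3): fix theta/phi
  # expectations at zero by hand so w alone sets the weights
  aln <- ase_alignments(data.frame(read = 1L, t = 1:3, h = 0L, s = 1L,
                                   span = 1L, log_lik = c(-1, -2, -3),
                                   log_pos = 0),
                        n_reads = 1, T = 3)
  st <- init_state(3)
  st$elog_theta <- rep(0, 4); st$elog_phi <- rep(0, 3)
  es <- e_step(aln, st)
  expect_equal(es$resp, exp(c(-1, -2, -3)) / sum(exp(c(-1, -2, -3))),
               tolerance = 1e-6)
  expect_equal(round(es$resp, 5), c(0.66524, 0.24473, 0.09003))
  expect_equal(sum(es$resp), 1)
})

test_that("E-step is symmetric across haplotypes at a symmetric state", {
  aln <- ase_alignments(data.frame(read = 1L, t = 1L, h = c(0L, 1L),
                                   s = 1L, span = 1L, log_lik = -2,
                                   log_pos = log(0.01)),
                        n_reads = 1, T = 1)
  es <- e_step(aln, init_state(1))
  expect_equal(es$resp, c(0.5, 0.5))
  # single-candidate read gets responsibility 1
  es1 <- e_step(unambiguous_aln(1, 0), init_state(1))
  expect_equal(es1$resp, 1)
})

test_that("M-step adds responsibilities to the conjugate priors", {
  aln <- unambiguous_aln(10L, 0L)
  st <- init_state(1, ase_hyper(alpha0 = 0.1))
  st$N <- 10L
  es <- e_step(aln, st)
  st <- m_step(es, st)
  expect_equal(st$alpha_star, c(0.1, 10.1))
  expect_equal(st$beta1_star, 11)
  expect_equal(st$beta2_star, 1)
  # 8 paternal + 2 maternal with Beta(1,1): Laplace-smoothed 9/12
  aln2 <- unambiguous_aln(8L, 2L)
  st2 <- init_state(1)
  st2 <- m_step(e_step(aln2, st2), st2)
  expect_equal(st2$e_phi, 9 / 12)
  # an isoform with no reads keeps its prior
  aln3 <- unambiguous_aln(4L, 0L, T = 2L)
  st3 <- init_state(2)
  st3 <- m_step(e_step(aln3, st3), st3)
  expect_equal(st3$beta1_star[2], 1)
  expect_equal(st3$e_phi[2], 0.5)
})

test_that("ELBO is zero for zero reads and exact for one unambiguous read", {
  empty <- ase_alignments(data.frame(read = integer(), t = integer(),
                                     h = integer(), s = integer()),
                          n_reads = 0, T = 2)
  st <- init_state(2, ase_hyper(alpha0 = 0.7))
  es <- e_step(empty, st)
  expect_equal(as.numeric(compute_elbo(empty, es, st)), 0)
  # one unambiguous read: L(q) equals the exact log marginal likelihood
  aln <- ase_alignments(data.frame(read = 1L, t = 2L, h = 0L, s = 1L,
                                   span = 1L, log_lik = -3.2,
                                   log_pos = log(1 / 77)),
                        n_reads = 1, T = 2)
  fit <- run_inference(aln, ase_hyper(alpha0 = 0.4))
  exact <- exact_log_marginal(aln, alpha0 = 0.4)
  expect_equal(fit$trace$elbo[fit$iterations], exact, tolerance = 1e-10)
  # and the same value from direct conjugate expectations
  expect_equal(exact, -3.2 + log(1 / 77) + log(0.4 / 1.2) + log(0.5),
               tolerance = 1e-12)
})

test_that("the bound never exceeds the exact log marginal (enumeration)", {
  for (seed in 1:6) {
    aln <- make_toy_aln(T = 2, n_reads = 5, max_cand = 3, seed = seed)
    fit <- run_inference(aln, ase_hyper(alpha0 = 0.5), rel_tol = 1e-8)
    exact <- exact_log_marginal(aln, alpha0 = 0.5)
    expect_lte(fit$trace$elbo[fit$iterations], exact + 1e-9)
  }
})

test_that("responsibility and pseudo-count mass are conserved", {
  set.seed(21)
  aln <- make_toy_aln(T = 4, n_reads = 40, max_cand = 5, frac_noise = 0.1)
  hyper <- ase_hyper(alpha0 = 0.3)
  fit <- run_inference(aln, hyper)
  st <- fit$state
  # responsibilities sum to 1 per read with candidates
  sums <- tapply(fit$resp, aln$cand$read, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # sum_t (alpha*_t - alpha0) == N, counting noise reads at t = 0
  expect_equal(sum(st$alpha_star - hyper$alpha0), 40, tolerance = 1e-6)
  expect_gte(min(st$alpha_star), hyper$alpha0)
  # allele mass: (beta*1 - 1) + (beta*2 - 1) == reads on real isoforms
  expect_equal(sum(st$beta1_star - 1 + st$beta2_star - 1),
               40 - st$N_noise, tolerance = 1e-6)
  expect_equal(sum(st$e_theta), 1, tolerance = 1e-9)
})

test_that("inference converges and respects the iteration contract", {
  # unambiguous reads reach the closed form within two iterations
  fit <- run_inference(unambiguous_aln(8L, 2L), ase_hyper(alpha0 = 0.1))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
  expect_equal(fit$state$e_phi, 0.75)
  # rel_tol = 0 with a cap: exactly max_iter iterations and a warning
  aln <- make_toy_aln(T = 3, n_reads = 15, max_cand = 4, seed = 3)
  expect_warning(f2 <- run_inference(aln, rel_tol = 0, max_iter = 5L),
                 "maximum iterations")
  expect_equal(f2$iterations, 5L)
  expect_false(f2$converged)
})

test_that("the ELBO trace is non-decreasing on ambiguous problems", {
  for (seed in 11:16) {
    aln <- make_toy_aln(T = 3, n_reads = 30, max_cand = 4, seed = seed)
    fit <- run_inference(aln, ase_hyper(alpha0 = 0.2), rel_tol = 1e-6)
    expect_true(all(diff(fit$trace$elbo) >= -1e-8))
  }
})

test_that("alpha0 selection returns the bound-maximizing value", {
  aln <- make_toy_aln(T = 3, n_reads = 25, max_cand = 4, seed = 8)
  sel <- select_alpha0(aln, grid = c(0.01, 0.1, 1))
  expect_equal(nrow(sel$table), 3L)
  expect_equal(sel$alpha0, sel$table$alpha0[which.max(sel$table$elbo)])
  # a one-value grid returns that value
  sel1 <- select_alpha0(aln, grid = 0.25)
  expect_equal(sel1$alpha0, 0.25)
})

test_that("unaligned reads feed the noise component unless dropped", {
  cand <- data.frame(read = 1L, t = 1L, h = 0L, s = 1L, span = 1L,
                     log_lik = 0, log_pos = 0)
  aln <- ase_alignments(cand, n_reads = 3, T = 1)   # 2 unaligned reads
  fit <- run_inference(aln, ase_hyper(alpha0 = 0.1))
  expect_equal(fit$state$alpha_star[1], 2.1)   # noise holds both
  fit2 <- run_inference(aln, ase_hyper(alpha0 = 0.1), drop_unaligned = TRUE)
  expect_equal(fit2$state$alpha_star[1], 0.1)
  expect_equal(fit2$state$N, 1L)
})

test_that("the Gibbs oracle reproduces the exact enumeration posterior", {
  for (seed in c(2, 6)) {
    cfg <- sim_config(n_isoforms = 3, length_range = c(300, 800),
                      n_fragments = 8, seed = seed)
    d <- sim_dataset(cfg)
    aln <- toy_align(d$reads, d$tx)
    ex <- exact_posterior(aln, alpha0 = 0.1)
    gb <- gibbs_ase(aln, alpha0 = 0.1, sweeps = 30000, burn = 3000,
                    seed = 1)
    expect_lt(max(abs(gb$e_theta - ex$e_theta)), 0.01)
    expect_lt(max(abs(gb$e_phi - ex$e_phi)), 0.01)
    # the variational abundance means track the exact posterior closely
    fit <- run_inference(aln, ase_hyper(alpha0 = 0.1), rel_tol = 1e-8,
                         max_iter = 2000)
    expect_lt(max(abs(fit$state$e_theta - ex$e_theta)), 0.01)
  }
})
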