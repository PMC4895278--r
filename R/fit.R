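#' Fit allele-specific isoform expression by variational Bayes
#'
#' The top-level modelling interface: given multi-candidate read
#' alignments against a diploid transcriptome, fits the Dirichlet
#' posterior over isoform abundances and the per-isoform Beta posterior
#' over the paternal fraction by coordinate ascent on the variational
#' lower bound ([run_inference()]).  When `alpha0` has several values the
#' concentration is chosen by [select_alpha0()].
#'
#' @param aln An `ase_aln` (from [read_diploid_alignments()] or
#'   [toy_align()]); candidates missing likelihoods are completed with
#'   [compute_likelihoods()].
#' @param tx The matching `diploid_tx`.
#' @param alpha0 Dirichlet concentration, or a grid to select from by the
#'   variational bound (default `c(0.01, 0.1, 1)`).
#' @param beta Length-2 Beta prior counts, default `c(1, 1)` (add-one
#'   smoothing of the paternal/maternal ratio).
#' @param subst A [subst_matrix()] used if likelihoods must be computed.
#' @param max_iter,rel_tol,theta_floor,drop_unaligned Passed to
#'   [run_inference()].
#' @return An object of class `ase_fit`: the converged `state`, the
#'   per-isoform `records` table ([summarize_expression()]), the ELBO
#'   `trace`, `alpha0` (the value used), `alpha0_table` (grid ELBOs, when
#'   selected), `iterations`, `converged`, `N`, `N_noise`, `resp`.
#' @examples
#' cfg <- sim_config(n_isoforms = 5, n_fragments = 200, seed = 1)
#' d <- sim_dataset(cfg)
#' fit <- ase_fit(toy_align(d$reads, d$tx), d$tx, alpha0 = 0.1)
#' coef(fit, "phi")
#' @export
ase_fit <- function(aln, tx, alpha0 = c(0.01, 0.1, 1), beta = c(1, 1),
                    subst = subst_matrix(), max_iter = 1000L,
                    rel_tol = 1e-3, theta_floor = 1e-7,
                    drop_unaligned = FALSE) {
  stopifnot(inherits(aln, "ase_aln"), inherits(tx, "diploid_tx"),
            aln$T == tx$T, length(beta) == 2L)
  if (nrow(aln$cand) && (anyNA(aln$cand$log_lik) || anyNA(aln$cand$log_pos)))
    aln <- compute_likelihoods(aln, tx, subst)
  alpha0_table <- NULL
  if (length(alpha0) > 1L) {
    sel <- select_alpha0(aln, grid = alpha0, max_iter = max_iter,
                         rel_tol = rel_tol, theta_floor = theta_floor,
                         drop_unaligned = drop_unaligned)
    fit <- sel$fit
    alpha0 <- sel$alpha0
    alpha0_table <- sel$table
  } else {
    fit <- run_inference(aln, ase_hyper(alpha0, beta[1], beta[2]),
                         max_iter = max_iter, rel_tol = rel_tol,
                         theta_floor = theta_floor,
                         drop_unaligned = drop_unaligned)
  }
  structure(list(state = fit$state,
                 records = summarize_expression(fit$state, tx),
                 trace = fit$trace, resp = fit$resp,
                 alpha0 = alpha0, alpha0_table = alpha0_table,
                 iterations = fit$iterations, converged = fit$converged,
                 N = fit$state$N, N_noise = fit$state$N_noise,
                 call = match.call()),
            class = "ase_fit")
}

#' @export
print.ase_fit <- function(x, digits = 4, ...) {
  cat("Allele-specific expression fit (variational Bayes)\n")
  cat("  isoforms:", x$state$T, "  reads:", x$N,
      " (noise:", x$N_noise, ")\n")
  cat("  alpha0:", x$alpha0, "  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  final L(q):",
      format(x$trace$elbo[x$iterations], digits = 10), "\n")
  invisible(x)
}

#' @export
summary.ase_fit <- function(object, min_reads = 10, min_het_snps = 1,
                            upper = 0.75, lower = 0.25, ...) {
  calls <- call_ase(object$records, min_reads = min_reads,
                    min_het_snps = min_het_snps, upper = upper,
                    lower = lower)
  structure(list(fit = object, calls = calls,
                 status_counts = table(calls$status),
                 thresholds = c(min_reads = min_reads,
                                min_het_snps = min_het_snps,
                                upper = upper, lower = lower)),
            class = "summary.ase_fit")
}

#' @export
print.summary.ase_fit <- function(x, ...) {
  print(x$fit)
  th <- x$thresholds
  cat("\nASE calls (ratio >=", th["upper"], "or <=", th["lower"],
      "; >=", th["min_reads"], "reads, >=", th["min_het_snps"],
      "het SNPs):\n")
  print(x$status_counts)
  top <- x$calls[x$calls$status %in% c("paternal_ASE", "maternal_ASE"), ]
  if (nrow(top)) {
    top <- top[order(abs(top$ratio - 0.5), decreasing = TRUE), ]
    cat("\nStrongest calls:\n")
    print(utils::head(top, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object An `ase_fit`.
#' @param type `"theta"` (posterior mean abundance fractions, including
#'   the noise component named `<noise>`), `"phi"` (posterior mean
#'   paternal fractions) or `"counts"` (expected read counts).
#' @param ... Unused.
#' @export
coef.ase_fit <- function(object, type = c("theta", "phi", "counts"), ...) {
  type <- match.arg(type)
  r <- object$records
  switch(type,
    theta = stats::setNames(object$state$e_theta,
                            c("<noise>", r$isoform_id)),
    phi = stats::setNames(r$E_phi, r$isoform_id),
    counts = stats::setNames(r$expected_count, r$isoform_id))
}

#' @export
fitted.ase_fit <- function(object, ...) {
  stats::setNames(object$records$expected_count,
                  object$records$isoform_id)
}

#' @export
logLik.ase_fit <- function(object, ...) {
  # the variational lower bound of the log marginal likelihood
  val <- object$trace$elbo[object$iterations]
  structure(val, df = NA_integer_, class = "logLik")
}

#' Diagnostic plots for an ASE fit
#'
#' Two base-graphics panels: the ELBO trace over iterations and the
#' histogram of posterior paternal fractions for isoforms passing the
#' read/heterozygosity filter.
#'
#' @param x An `ase_fit`.
#' @param min_reads,min_het_snps Filter for the ratio histogram.
#' @param ... Unused.
#' @export
plot.ase_fit <- function(x, min_reads = 10, min_het_snps = 1, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$trace$iteration, x$trace$elbo, type = "b", pch = 16,
       xlab = "iteration", ylab = "L(q)", main = "Variational lower bound")
  r <- x$records
  keep <- (r$n_het_snps >= min_het_snps | r$het_indel_flag) &
    floor(r$expected_count) >= min_reads
  graphics::hist(r$E_phi[keep], breaks = seq(0, 1, by = 0.05),
                 xlab = "posterior paternal fraction",
                 main = "Allelic ratio (filtered isoforms)")
  invisible(x)
}
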