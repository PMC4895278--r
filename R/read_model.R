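#' Phred quality to error probability
#'
#' @param q Non-negative Phred quality score(s).
#' @return `10^(-q/10)`.
#' @examples phred_error_prob(30)
#' @export
phred_error_prob <- function(q) {
  if (any(q < 0)) stop("Phred quality must be >= 0")
  10^(-q / 10)
}

#' Quality-score dependent substitution matrix
#'
#' The per-column emission model of the read likelihood
#' \eqn{p(R_n | T_n, H_n, S_n) = \prod_x subst(r_n[x], q_n[x], c_{th}[x])}.
#' In `phred_analytic` mode the probability of reading base `r` when the
#' template base is `c` at quality `q` is `1 - eps` if `r == c` and
#' `eps / 3` otherwise, with `eps = 10^(-q/10)`; an `N` read base scores
#' 1/4 regardless of the template.  An empirical matrix (see
#' [estimate_subst_matrix()]) replaces the analytic entries by smoothed
#' observed frequencies, binned at integer Phred values capped at `qmax`.
#'
#' @param mode `"phred_analytic"` or `"empirical"`.
#' @param table For empirical mode: a 4 x (qmax+1) x 4 array of
#'   probabilities, dimensions read base (ACGT), quality 0..qmax, template
#'   base (ACGT); each `(q, c)` slice sums to 1 over read bases.
#' @param indel_open_prob Probability contribution of each inserted or
#'   deleted base in an alignment (default 1e-3).
#' @param qmax Cap for quality binning in empirical mode.
#' @return An object of class `subst_matrix`.
#' @export
subst_matrix <- function(mode = c("phred_analytic", "empirical"),
                         table = NULL, indel_open_prob = 1e-3, qmax = 40L) {
  mode <- match.arg(mode)
  if (mode == "empirical") {
    stopifnot(is.array(table), length(dim(table)) == 3L,
              dim(table)[1] == 4L, dim(table)[3] == 4L)
    sums <- apply(table, c(2, 3), sum)
    if (any(abs(sums - 1) > 1e-9))
      stop("empirical substitution table columns must sum to 1")
    qmax <- dim(table)[2] - 1L
  }
  structure(list(mode = mode, table = table,
                 indel_open_prob = indel_open_prob, qmax = as.integer(qmax)),
            class = "subst_matrix")
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat("Substitution matrix, mode:", x$mode,
      " indel_open_prob:", x$indel_open_prob, "\n")
  invisible(x)
}

#' Per-column substitution probability
#'
#' @param r Read base(s), characters among A, C, G, T, N.
#' @param q Phred qualities, same length.
#' @param c Template (reference) base(s).
#' @param m A [subst_matrix()].
#' @return Probabilities in `[0, 1]`, vectorized over the inputs.
#' @examples subst_prob("A", 30, "A")
#' @export
subst_prob <- function(r, q, c, m = subst_matrix()) {
  if (any(q < 0)) stop("Phred quality must be >= 0")
  r <- toupper(r); c <- toupper(c)
  isN <- !(r %in% c("A", "C", "G", "T")) | !(c %in% c("A", "C", "G", "T"))
  if (m$mode == "phred_analytic") {
    eps <- phred_error_prob(q)
    p <- ifelse(r == c, 1 - eps, eps / 3)
  } else {
    qb <- pmin(as.integer(round(q)), m$qmax) + 1L
    ri <- match(r, c("A", "C", "G", "T"))
    ci <- match(c, c("A", "C", "G", "T"))
    idx <- cbind(ri, qb, ci)
    p <- rep(NA_real_, length(r))
    ok <- !isN
    p[ok] <- m$table[idx[ok, , drop = FALSE]]
  }
  p[isN] <- 0.25
  p
}

#' Estimate an empirical substitution matrix from best alignments
#'
#' Counts (read base, quality, template base) triples over the aligned
#' match columns of each read's single best-scoring candidate, then
#' normalizes per (quality, template) with add-one smoothing over the four
#' read bases.  Reads whose candidates lack likelihoods are scored first
#' with the analytic matrix to pick the best candidate.
#'
#' @param aln An `ase_aln` with CIGAR-bearing candidates (from
#'   [read_diploid_alignments()]).
#' @param tx The matching `diploid_tx`.
#' @param qmax Quality cap (default 40).
#' @return A `subst_matrix` of mode `"empirical"`, or the analytic matrix
#'   with a warning if no aligned columns are available.
#' @export
estimate_subst_matrix <- function(aln, tx, qmax = 40L) {
  cand <- aln$cand
  if (!nrow(cand) || is.null(cand$cigar1)) {
    if (nrow(cand) == 0L) {
      warning("no alignments; falling back to the analytic matrix")
      return(subst_matrix("phred_analytic"))
    }
    stop("empirical estimation needs CIGAR-bearing candidates")
  }
  if (anyNA(cand$log_lik))
    aln <- compute_likelihoods(aln, tx, subst_matrix("phred_analytic"))
  cand <- aln$cand
  score <- cand$log_lik + cand$log_pos
  best <- tapply(seq_len(nrow(cand)), cand$read, function(i)
    i[which.max(score[i])])
  counts <- array(0, dim = c(4L, qmax + 1L, 4L))
  bases <- c("A", "C", "G", "T")
  add_cols <- function(seq, qual, cigar, ref, s) {
    cols <- aligned_columns(seq, qual, cigar, ref, s)
    if (!nrow(cols$m)) return(invisible(NULL))
    ri <- match(cols$m$r, bases); ci <- match(cols$m$c, bases)
    ok <- !is.na(ri) & !is.na(ci)
    for (k in which(ok)) {
      counts[ri[k], min(cols$m$q[k], qmax) + 1L, ci[k]] <<-
        counts[ri[k], min(cols$m$q[k], qmax) + 1L, ci[k]] + 1
    }
    invisible(NULL)
  }
  for (i in unlist(best)) {
    ref <- tx_seq(tx, cand$t[i], cand$h[i])
    add_cols(cand$seq1[i], cand$qual1[i], cand$cigar1[i], ref, cand$m1s[i])
    if (!is.na(cand$m2s[i]))
      add_cols(cand$seq2[i], cand$qual2[i], cand$cigar2[i], ref, cand$m2s[i])
  }
  if (sum(counts) == 0) {
    warning("no aligned match columns; falling back to the analytic matrix")
    return(subst_matrix("phred_analytic"))
  }
  tab <- counts + 1
  norm <- apply(tab, c(2, 3), sum)
  for (ci in 1:4) for (qb in seq_len(qmax + 1L))
    tab[, qb, ci] <- tab[, qb, ci] / norm[qb, ci]
  subst_matrix("empirical", table = tab)
}

#' Log prior of a start position
#'
#' The uniform placement prior `1 / (l_th - L + 1)` over the valid start
#' positions of an aligned span of length `L` on a cDNA of length `l_th`.
#' For paired-end candidates the span is the observed fragment extent.
#'
#' @param l_th cDNA length(s), bp.
#' @param span Aligned span(s), bp.
#' @return `log(1 / (l_th - span + 1))`, or `NA` where `l_th < span`
#'   (an invalid candidate, to be discarded by the caller).
#' @examples position_log_prior(200, 100)
#' @export
position_log_prior <- function(l_th, span) {
  stopifnot(all(l_th > 0), all(span > 0))
  ifelse(l_th >= span, -log(l_th - span + 1), NA_real_)
}

# Walk a CIGAR against the reference, returning aligned match columns
# (read base, quality, template base), indel base count, and soft-clipped
# base count.  `s` is the 1-based alignment start on the reference.
aligned_columns <- function(seq, qual, cigar, ref, s) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n_op <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  c_op <- sub("^\\d+", "", ops)
  rp <- 1L              # position in the read string
  gp <- s               # position on the reference
  rch <- strsplit(seq, "")[[1]]
  qch <- utf8ToInt(qual) - 33L
  rlen <- nchar(ref)
  out_r <- character(0); out_q <- integer(0); out_c <- character(0)
  n_indel <- 0L; n_soft <- 0L
  for (k in seq_along(ops)) {
    n <- n_op[k]
    switch(c_op[k],
      "M" = , "=" = , "X" = {
        if (gp + n - 1L > rlen)
          stop("CIGAR walks past the reference end")
        out_r <- c(out_r, rch[rp:(rp + n - 1L)])
        out_q <- c(out_q, qch[rp:(rp + n - 1L)])
        out_c <- c(out_c, strsplit(substr(ref, gp, gp + n - 1L), "")[[1]])
        rp <- rp + n; gp <- gp + n
      },
      "I" = { n_indel <- n_indel + n; rp <- rp + n },
      "D" = { n_indel <- n_indel + n; gp <- gp + n },
      "N" = { gp <- gp + n },
      "S" = { n_soft <- n_soft + n; rp <- rp + n },
      "H" = NULL,
      "P" = NULL)
  }
  list(m = data.frame(r = out_r, q = out_q, c = out_c,
                      stringsAsFactors = FALSE),
       n_indel = n_indel, n_soft = n_soft)
}

# log p(R | Z = 1) for one aligned mate
mate_log_lik <- function(seq, qual, cigar, ref, s, m) {
  cols <- aligned_columns(seq, qual, cigar, ref, s)
  ll <- 0
  if (nrow(cols$m))
    ll <- sum(log(subst_prob(cols$m$r, cols$m$q, cols$m$c, m)))
  list(ll = ll + cols$n_indel * log(m$indel_open_prob),
       n_soft = cols$n_soft)
}

#' Read-sequence log likelihood of one alignment candidate
#'
#' Walks the candidate's CIGAR against the cDNA sequence of its
#' (isoform, haplotype), summing `log subst(r, q, c)` over aligned
#' columns; every inserted or deleted base contributes
#' `log(indel_open_prob)`.  Soft-clipped bases are excluded from the
#' product.  Paired candidates sum both mates' contributions.
#'
#' @param aln An `ase_aln` with CIGAR-bearing candidates.
#' @param i Candidate row index.
#' @param tx The `diploid_tx`.
#' @param m A [subst_matrix()].
#' @return The log likelihood (a single number).
#' @export
candidate_log_likelihood <- function(aln, i, tx, m = subst_matrix()) {
  cand <- aln$cand
  ref <- tx_seq(tx, cand$t[i], cand$h[i])
  v <- mate_log_lik(cand$seq1[i], cand$qual1[i], cand$cigar1[i], ref,
                    cand$m1s[i], m)
  ll <- v$ll
  if (!is.null(cand$m2s) && !is.na(cand$m2s[i]))
    ll <- ll + mate_log_lik(cand$seq2[i], cand$qual2[i], cand$cigar2[i],
                            ref, cand$m2s[i], m)$ll
  ll
}

#' Fill candidate likelihoods and position priors
#'
#' Computes `log_lik` (via [candidate_log_likelihood()]) and `log_pos`
#' (via [position_log_prior()]) for every candidate of a SAM/BAM-derived
#' alignment set.  Candidates whose span exceeds the cDNA length are
#' invalid and dropped with a warning.
#'
#' @param aln An `ase_aln` from [read_diploid_alignments()].
#' @param tx The matching `diploid_tx`.
#' @param m A [subst_matrix()].
#' @return The `ase_aln` with `log_lik` and `log_pos` populated.
#' @export
compute_likelihoods <- function(aln, tx, m = subst_matrix()) {
  cand <- aln$cand
  if (!nrow(cand)) return(aln)
  lth <- tx_length(tx, cand$t, cand$h)
  lp <- position_log_prior(lth, cand$span)
  bad <- is.na(lp)
  if (any(bad)) {
    warning(sum(bad), " candidate(s) span past the cDNA end; dropped")
    cand <- cand[!bad, , drop = FALSE]
    lp <- lp[!bad]
  }
  ll <- vapply(seq_len(nrow(cand)), function(i) {
    a <- aln; a$cand <- cand
    candidate_log_likelihood(a, i, tx, m)
  }, numeric(1))
  cand$log_lik <- ll
  cand$log_pos <- lp
  aln$cand <- cand
  aln
}
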