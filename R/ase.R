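#' Summarize a fitted state into per-isoform expression records
#'
#' Expected read counts are responsibility sums: the paternal
#' (maternal) count of isoform t is `beta*_{t,1} - beta_{t,1}`
#' (`beta*_{t,2} - beta_{t,2}`), so their total over isoforms equals the
#' number of aligned reads.  The paternal fraction is the Beta posterior
#' mean `E[phi_t] = beta*_{t,1} / (beta*_{t,1} + beta*_{t,2})`.
#' Heterozygous-site annotation comes from [detect_het_sites()].
#'
#' @param state A converged `vb_state` (or a `vb_fit`).
#' @param tx The matching `diploid_tx`.
#' @return A data.frame with one row per isoform: `isoform_id`, `gene_id`,
#'   `E_theta`, `expected_count`, `expected_count_paternal`,
#'   `expected_count_maternal`, `E_phi`, `beta1_star`, `beta2_star`,
#'   `n_het_snps`, `het_indel_flag`.
#' @export
summarize_expression <- function(state, tx) {
  if (inherits(state, "vb_fit")) state <- state$state
  stopifnot(state$T == tx$T)
  h <- state$hyper
  cp <- state$beta1_star - h$beta1
  cm <- state$beta2_star - h$beta2
  het <- detect_het_sites(tx)
  data.frame(isoform_id = tx$isoform_id,
             gene_id = tx$gene_id,
             E_theta = state$e_theta[-1L],
             expected_count = cp + cm,
             expected_count_paternal = cp,
             expected_count_maternal = cm,
             E_phi = state$e_phi,
             beta1_star = state$beta1_star,
             beta2_star = state$beta2_star,
             n_het_snps = het$n_het_snps,
             het_indel_flag = het$het_indel_flag,
             stringsAsFactors = FALSE)
}

#' Call allele-specific expression from expression records
#'
#' An isoform (or gene) is called paternal-ASE when its paternal fraction
#' is at or above `upper` and maternal-ASE when at or below `lower`
#' (inclusive thresholds), provided it carries heterozygous evidence
#' (`n_het_snps >= min_het_snps`, or a heterozygous indel) and at least
#' `min_reads` assigned reads (expected counts rounded down).  Records
#' failing a filter are reported with the reason.  At gene level the ratio
#' is the expression-weighted mean of the gene's isoform ratios.
#'
#' @param records Output of [summarize_expression()] (for the model-based
#'   path) or of [baseline_ase()] (set `ratio_col = "ratio"` accordingly).
#' @param min_reads Minimum assigned reads (default 10).
#' @param min_het_snps Minimum heterozygous SNPs (default 1).
#' @param upper,lower Ratio thresholds (defaults 0.75 / 0.25).
#' @param level `"isoform"` or `"gene"`.
#' @param ratio_col Column holding the paternal fraction (default
#'   `"E_phi"`).
#' @param count_col Column holding assigned reads (default
#'   `"expected_count"`).
#' @return A data.frame: `level`, `id`, `ratio`, `status` (one of
#'   `paternal_ASE`, `maternal_ASE`, `biallelic`, `filtered`),
#'   `filter_reason`.
#' @export
call_ase <- function(records, min_reads = 10, min_het_snps = 1,
                     upper = 0.75, lower = 0.25,
                     level = c("isoform", "gene"),
                     ratio_col = "E_phi", count_col = "expected_count") {
  level <- match.arg(level)
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop("thresholds must satisfy 0 <= lower < upper <= 1")
  ratio <- records[[ratio_col]]
  count <- records[[count_col]]
  het_ok <- records$n_het_snps >= min_het_snps | records$het_indel_flag
  id <- records$isoform_id
  if (level == "gene") {
    gid <- ifelse(records$gene_id == "", records$isoform_id, records$gene_id)
    grp <- split(seq_along(ratio), gid)
    w <- count
    ratio <- vapply(grp, function(i)
      if (sum(w[i]) > 0) sum(ratio[i] * w[i]) / sum(w[i]) else mean(ratio[i]),
      numeric(1))
    count <- vapply(grp, function(i) sum(w[i]), numeric(1))
    het_ok <- vapply(grp, function(i) any(het_ok[i]), logical(1))
    id <- names(grp)
  }
  reads_ok <- floor(count) >= min_reads
  status <- rep("biallelic", length(id))
  reason <- rep("", length(id))
  status[!is.na(ratio) & ratio >= upper] <- "paternal_ASE"
  status[!is.na(ratio) & ratio <= lower] <- "maternal_ASE"
  fail <- !reads_ok | !het_ok | is.na(ratio)
  reason[fail & !reads_ok] <- "min_reads"
  reason[fail & reads_ok & !het_ok] <- "min_het_snps"
  reason[fail & reads_ok & het_ok] <- "missing_ratio"
  status[fail] <- "filtered"
  data.frame(level = level, id = id, ratio = as.numeric(ratio),
             status = status, filter_reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Best-alignment baseline for allelic ratios
#'
#' The comparator that skips model-based smoothing: each read is assigned
#' to its single best-scoring candidate (`log_lik + log_pos`); reads whose
#' best score is tied across haplotypes are uninformative and excluded
#' from allele tallies (they still count toward isoform expression).  A
#' read contributes to an isoform's paternal or maternal count only when
#' its best alignment overlaps at least one heterozygous site of that
#' isoform.  The ratio `paternal / (paternal + maternal)` carries no
#' pseudo-counts, so exact 0 and 1 ratios occur at low coverage; it is
#' reported as `NA` when no allele-discriminating reads exist.
#'
#' @param aln An `ase_aln` with likelihoods populated.
#' @param tx The matching `diploid_tx`.
#' @return A data.frame per isoform: `isoform_id`, `gene_id`,
#'   `best_count` (reads best-assigned to the isoform), `paternal_count`,
#'   `maternal_count`, `ratio`, `n_het_snps`, `het_indel_flag`.
#' @export
baseline_ase <- function(aln, tx) {
  cand <- aln$cand
  if (anyNA(cand$log_lik) || anyNA(cand$log_pos))
    stop("candidate likelihoods not populated; run compute_likelihoods()")
  het <- detect_het_sites(tx)
  out <- data.frame(isoform_id = tx$isoform_id, gene_id = tx$gene_id,
                    best_count = 0L, paternal_count = 0L,
                    maternal_count = 0L, ratio = NA_real_,
                    n_het_snps = het$n_het_snps,
                    het_indel_flag = het$het_indel_flag,
                    stringsAsFactors = FALSE)
  if (!nrow(cand)) return(out)
  score <- cand$log_lik + cand$log_pos
  best_by_read <- tapply(score, cand$read, max)
  is_best <- score >= best_by_read[as.character(cand$read)] - 1e-9
  bc <- cand[is_best, , drop = FALSE]
  # the isoform a read expresses: smallest ordinal among its best candidates
  first <- !duplicated(bc$read)
  iso_of_read <- bc$t[first]
  out$best_count <- tabulate(iso_of_read, tx$T)
  # haplotype-informative reads: best score on exactly one haplotype
  nh <- tapply(bc$h, bc$read, function(x) length(unique(x)))
  informative <- nh[as.character(bc$read)] == 1L
  bi <- bc[informative & !duplicated(bc$read), , drop = FALSE]
  if (nrow(bi)) {
    # require overlap with a het site of (t, h)
    olap <- logical(nrow(bi))
    for (key in unique(paste(bi$t, bi$h))) {
      idx <- which(paste(bi$t, bi$h) == key)
      t <- bi$t[idx[1]]; h <- bi$h[idx[1]]
      hp <- het_positions(tx, t)
      pos <- if (h == 0) hp$pos0 else hp$pos1
      if (!length(pos)) next
      a1 <- bi$m1s[idx]; b1 <- a1 + bi$m1w[idx] - 1L
      hit <- findInterval(b1, pos) - findInterval(a1 - 1L, pos) > 0L
      if (!is.null(bi$m2s) && any(!is.na(bi$m2s[idx]))) {
        a2 <- bi$m2s[idx]; b2 <- a2 + bi$m2w[idx] - 1L
        hit2 <- !is.na(a2) &
          findInterval(b2, pos) - findInterval(a2 - 1L, pos) > 0L
        hit <- hit | hit2
      }
      olap[idx] <- hit
    }
    bi <- bi[olap, , drop = FALSE]
    out$paternal_count <- tabulate(bi$t[bi$h == 0L], tx$T)
    out$maternal_count <- tabulate(bi$t[bi$h == 1L], tx$T)
  }
  denom <- out$paternal_count + out$maternal_count
  out$ratio <- ifelse(denom > 0, out$paternal_count / denom, NA_real_)
  out
}

#' Histogram of allelic ratios
#'
#' Equal-width bins on `[0, 1]`; the final bin is closed so a ratio of
#' exactly 1 falls in it.  Missing ratios are excluded.
#'
#' @param values Ratios in `[0, 1]` (NAs allowed).
#' @param n_bins Number of bins (default 20).
#' @return A data.frame: `bin_start`, `bin_end`, `count`.
#' @export
ratio_histogram <- function(values, n_bins = 20L) {
  values <- values[!is.na(values)]
  stopifnot(all(values >= 0 & values <= 1))
  br <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  data.frame(bin_start = br[-length(br)], bin_end = br[-1L],
             count = tabulate(bin, n_bins))
}

#' Write an expression table as TSV
#'
#' Tab-separated, one row per isoform, floating values at 8 significant
#' digits.  `header_lines` (e.g. a config echo) are written first as
#' `#`-prefixed comments.
#'
#' @param records Output of [summarize_expression()].
#' @param path Output file.
#' @param header_lines Optional character vector of comment lines.
#' @export
write_expression_table <- function(records, path, header_lines = NULL) {
  write_tsv_with_header(records, path, header_lines)
}

#' @rdname write_expression_table
#' @param calls Output of [call_ase()].
#' @export
write_ase_table <- function(calls, path, header_lines = NULL) {
  write_tsv_with_header(calls, path, header_lines)
}

write_tsv_with_header <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 8))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read back a table written by [write_expression_table()]
#'
#' @param path TSV file (comment lines starting with `#` are skipped).
#' @return A data.frame.
#' @export
read_expression_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
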