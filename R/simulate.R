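#' Simulation configuration
#'
#' Defaults reproduce the reference simulation design: isoforms with
#' heterozygous SNPs (about 1 per kb) and occasional short indels between
#' haplotypes, log-normal expression, 10 % paternal-ASE and 10 %
#' maternal-ASE isoforms expressing the major allele with 80 %
#' probability, and 100 bp paired-end fragments of 400 +/- 40 bp carrying
#' 0.1 % substitution, insertion and deletion errors each.  `n_isoforms`
#' defaults to the full-scale 10,000; `n_fragments` defaults to the
#' 100,000-fragment desk scale (the full-scale figure is 30 million
#' pairs).  `null_mode = TRUE` sets every allelic fraction to 0.5.
#'
#' @param n_isoforms,length_range,snps_per_kb,indel_prob Transcriptome
#'   shape: isoform count, uniform cDNA length range (bp), heterozygous
#'   SNP density between haplotypes, probability an isoform carries one
#'   1-3 bp heterozygous indel.
#' @param lognormal_mu,lognormal_sigma Natural-log scale parameters of the
#'   expression distribution.
#' @param frac_paternal_ase,frac_maternal_ase,ase_major_prob ASE design:
#'   class fractions and the major-allele probability (80:20).
#' @param n_fragments,read_len,frag_mean,frag_sd Library design.
#' @param sub_err,ins_err,del_err Per-base sequencer error rates.
#' @param null_mode All isoforms 50:50 when `TRUE`.
#' @param seed Integer seed; component generators derive their streams
#'   from it (`seed`, `seed + 1`, `seed + 2`) so a fixed seed gives
#'   byte-identical artifacts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_isoforms = 10000L, length_range = c(400L, 4000L),
                       snps_per_kb = 1, indel_prob = 0.05,
                       lognormal_mu = 4, lognormal_sigma = 1,
                       frac_paternal_ase = 0.10, frac_maternal_ase = 0.10,
                       ase_major_prob = 0.80,
                       n_fragments = 100000L, read_len = 100L,
                       frag_mean = 400, frag_sd = 40,
                       sub_err = 0.001, ins_err = 0.001, del_err = 0.001,
                       null_mode = FALSE, seed = NULL) {
  cfg <- list(n_isoforms = as.integer(n_isoforms),
              length_range = as.integer(length_range),
              snps_per_kb = snps_per_kb, indel_prob = indel_prob,
              lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
              frac_paternal_ase = frac_paternal_ase,
              frac_maternal_ase = frac_maternal_ase,
              ase_major_prob = ase_major_prob,
              n_fragments = as.integer(n_fragments),
              read_len = as.integer(read_len),
              frag_mean = frag_mean, frag_sd = frag_sd,
              sub_err = sub_err, ins_err = ins_err, del_err = del_err,
              null_mode = isTRUE(null_mode),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  rates <- c(cfg$indel_prob, cfg$frac_paternal_ase, cfg$frac_maternal_ase,
             cfg$ase_major_prob, cfg$sub_err, cfg$ins_err, cfg$del_err)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$frac_paternal_ase + cfg$frac_maternal_ase > 1)
    stop("ASE class fractions must sum to at most 1")
  if (cfg$n_isoforms < 1L || cfg$n_fragments < 1L || cfg$read_len < 1L)
    stop("counts must be positive")
  structure(cfg, class = "sim_config")
}

derived_seed <- function(cfg, offset) {
  if (is.null(cfg$seed)) return(NULL)
  (cfg$seed + offset) %% 2147483647L
}

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a diploid transcriptome
#'
#' Paternal sequences are uniform random nucleotides with lengths drawn
#' uniformly from `length_range`; the maternal copy of each isoform
#' differs by Poisson(`snps_per_kb` x kb) substitutions at uniform
#' positions and, with probability `indel_prob`, one 1-3 bp insertion or
#' deletion.
#'
#' @param cfg A [sim_config()].
#' @return A `diploid_tx`; gene identifiers equal isoform identifiers
#'   (one-isoform genes).
#' @export
sim_transcriptome <- function(cfg) {
  s <- derived_seed(cfg, 0L)
  if (!is.null(s)) set.seed(s)
  n <- cfg$n_isoforms
  len <- sample.int(cfg$length_range[2] - cfg$length_range[1] + 1L, n,
                    replace = TRUE) + cfg$length_range[1] - 1L
  big <- paste(sample(BASES, sum(len), replace = TRUE), collapse = "")
  ends <- cumsum(len)
  seq0 <- substring(big, ends - len + 1L, ends)
  seq1 <- character(n)
  for (i in seq_len(n)) {
    r <- charToRaw(seq0[i])
    n_snp <- stats::rpois(1L, cfg$snps_per_kb * len[i] / 1000)
    if (n_snp > 0L) {
      pos <- sample.int(len[i], min(n_snp, len[i]))
      for (p in pos) {
        cur <- rawToChar(r[p])
        r[p] <- charToRaw(sample(setdiff(BASES, cur), 1L))
      }
    }
    s1 <- rawToChar(r)
    if (stats::runif(1L) < cfg$indel_prob) {
      w <- sample.int(3L, 1L)
      if (stats::runif(1L) < 0.5 && len[i] > w + 1L) {   # deletion
        at <- sample.int(len[i] - w, 1L)
        s1 <- paste0(substr(s1, 1L, at),
                     substr(s1, at + w + 1L, len[i]))
      } else {                                           # insertion
        at <- sample.int(len[i], 1L)
        s1 <- paste0(substr(s1, 1L, at),
                     paste(sample(BASES, w, replace = TRUE), collapse = ""),
                     substr(s1, at + 1L, len[i]))
      }
    }
    seq1[i] <- s1
  }
  ids <- sprintf("iso%05d", seq_len(n))
  new_diploid_tx(ids, gene_id = ids, seq0 = seq0, seq1 = seq1)
}

#' Assign ground-truth expression and allelic fractions
#'
#' Expression fractions are drawn log-normal and normalized; disjoint
#' random subsets of the configured fractions get paternal-ASE
#' (`phi = ase_major_prob`) and maternal-ASE (`phi = 1 - ase_major_prob`)
#' status, the rest (and everything in null mode) stay at 0.5.
#'
#' @param cfg A [sim_config()].
#' @param tx The simulated `diploid_tx`.
#' @return A data.frame of class `sim_truth`: `isoform_id`, `theta`,
#'   `phi`, `ase_class` (`"null"`, `"paternal"`, `"maternal"`).
#' @export
assign_truth <- function(cfg, tx) {
  s <- derived_seed(cfg, 1L)
  if (!is.null(s)) set.seed(s)
  T <- tx$T
  theta <- stats::rlnorm(T, cfg$lognormal_mu, cfg$lognormal_sigma)
  theta <- theta / sum(theta)
  cls <- rep("null", T)
  phi <- rep(0.5, T)
  if (!cfg$null_mode) {
    n_p <- round(cfg$frac_paternal_ase * T)
    n_m <- round(cfg$frac_maternal_ase * T)
    pick <- sample.int(T, n_p + n_m)
    cls[pick[seq_len(n_p)]] <- "paternal"
    cls[pick[n_p + seq_len(n_m)]] <- "maternal"
    phi[cls == "paternal"] <- cfg$ase_major_prob
    phi[cls == "maternal"] <- 1 - cfg$ase_major_prob
  }
  structure(data.frame(isoform_id = tx$isoform_id, theta = theta, phi = phi,
                       ase_class = cls, stringsAsFactors = FALSE),
            class = c("sim_truth", "data.frame"))
}

#' Simulate paired-end reads with sequencing errors
#'
#' Per fragment: the isoform is drawn with probability proportional to
#' `theta` times its effective number of placements, the haplotype is
#' Bernoulli in the isoform's `phi`, the fragment length is Normal
#' (`frag_mean`, `frag_sd`) rounded and truncated to
#' `[read_len, l_th]` (re-drawn on failure), and the start is uniform
#' over valid placements.  Mate 1 reads the fragment's 5' end, mate 2 the
#' reverse complement of its 3' end.  Substitution, insertion and
#' deletion errors are applied per base; qualities are constant Phred 30,
#' matching a 0.001 substitution rate, so the analytic substitution
#' matrix is exactly calibrated to the injected errors.
#'
#' @param cfg A [sim_config()].
#' @param tx The simulated `diploid_tx`.
#' @param truth Output of [assign_truth()].
#' @return A list of class `sim_reads`: `mate1`, `mate2` (character
#'   vectors), `qual` (one quality string recycled over reads),
#'   `read_id`, and `provenance` (data.frame `t`, `h`, `s`, `frag_len`).
#' @export
sim_reads <- function(cfg, tx, truth) {
  s <- derived_seed(cfg, 2L)
  if (!is.null(s)) set.seed(s)
  n <- cfg$n_fragments
  rl <- cfg$read_len
  short <- pmin(tx$l0, tx$l1) < rl
  if (any(short))
    warning(sum(short), " isoform(s) shorter than the read length ",
            "excluded from sampling")
  eff <- pmax((tx$l0 + tx$l1) / 2 - cfg$frag_mean + 1, 1)
  w <- truth$theta * eff
  w[short] <- 0
  if (all(w == 0)) stop("no isoform is long enough to sample reads from")
  it <- sample.int(tx$T, n, replace = TRUE, prob = w)
  hh <- stats::rbinom(n, 1L, 1 - truth$phi[it])
  lth <- tx_length(tx, it, hh)
  f <- as.integer(round(stats::rnorm(n, cfg$frag_mean, cfg$frag_sd)))
  for (round_i in 1:100) {
    bad <- f < rl | f > lth
    if (!any(bad)) break
    f[bad] <- as.integer(round(stats::rnorm(sum(bad), cfg$frag_mean,
                                            cfg$frag_sd)))
  }
  bad <- f < rl | f > lth
  if (any(bad)) {          # isoform skipped for the draw; redraw the tuple
    redraw <- which(bad)
    it[redraw] <- sample.int(tx$T, length(redraw), replace = TRUE, prob = w)
    hh[redraw] <- stats::rbinom(length(redraw), 1L, 1 - truth$phi[it[redraw]])
    lth <- tx_length(tx, it, hh)
    f <- pmin(pmax(f, rl), lth)
  }
  start <- 1L + as.integer(floor(stats::runif(n) * (lth - f + 1L)))
  hap <- tx$seq0[it]
  m <- hh == 1L
  hap[m] <- tx$seq1[it[m]]
  ext <- 8L   # deletion slack read into the fragment beyond read_len
  tpl1 <- substring(hap, start, pmin(start + rl + ext - 1L, start + f - 1L))
  tpl2 <- revcomp(substring(hap, pmax(start + f - rl - ext, start),
                            start + f - 1L))
  mate1 <- cpp_apply_errors(tpl1, cfg$sub_err, cfg$ins_err, cfg$del_err, rl)
  mate2 <- cpp_apply_errors(tpl2, cfg$sub_err, cfg$ins_err, cfg$del_err, rl)
  structure(list(mate1 = mate1, mate2 = mate2,
                 qual = strrep(rawToChar(as.raw(33L + 30L)), rl),
                 read_id = sprintf("frag%07d", seq_len(n)),
                 provenance = data.frame(t = it, h = hh, s = start,
                                         frag_len = f)),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("Simulated reads:", length(x$mate1), "fragment pairs of",
      nchar(x$mate1[1]), "bp\n")
  invisible(x)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [sim_transcriptome()], [assign_truth()]
#' and [sim_reads()] under the config's derived seeds.
#'
#' @param cfg A [sim_config()].
#' @return A list: `tx`, `truth`, `reads`.
#' @export
sim_dataset <- function(cfg) {
  tx <- sim_transcriptome(cfg)
  truth <- assign_truth(cfg, tx)
  reads <- sim_reads(cfg, tx, truth)
  list(tx = tx, truth = truth, reads = reads)
}

#' Toy exact-seed aligner over a diploid transcriptome
#'
#' A test-scale stand-in for a report-all short-read aligner: the first
#' `seed_len` bases of each mate (both orientations) are matched exactly
#' against every isoform/haplotype sequence, each hit is extended without
#' gaps, and every placement with at most `max_mismatch` mismatches per
#' mate is kept.  Mates are paired on the same (isoform, haplotype) in FR
#' orientation; the fragment start is the leftmost mate start.  Candidate
#' log likelihoods assume a constant Phred quality `phred` per base,
#' matching the simulator's output.
#'
#' @param reads A `sim_reads` object, or a list with character vectors
#'   `mate1` and `mate2`.
#' @param tx A `diploid_tx`.
#' @param max_mismatch Per-mate mismatch cap (default 3).
#' @param seed_len Exact seed length (default 20).
#' @param phred Constant base quality used in the likelihood (default 30).
#' @return An `ase_aln` of fragment candidates with `log_lik` and
#'   `log_pos` populated and per-mate coordinates retained.
#' @export
toy_align <- function(reads, tx, max_mismatch = 3L, seed_len = 20L,
                      phred = 30L) {
  n <- length(reads$mate1)
  rl <- nchar(reads$mate1[1])
  stopifnot(length(reads$mate2) == n, seed_len <= rl)
  refs <- c(tx$seq0, tx$seq1)              # 1..T paternal, T+1..2T maternal
  reflen <- c(tx$l0, tx$l1)
  # oriented read blocks: 1 = mate1 fwd, 2 = mate1 rev, 3 = mate2 fwd,
  # 4 = mate2 rev ("fwd" = as aligned to the reference forward strand)
  oriented <- c(reads$mate1, revcomp(reads$mate1),
                reads$mate2, revcomp(reads$mate2))
  seeds <- substr(oriented, 1L, seed_len)
  valid <- !grepl("[^ACGT]", seeds)
  sep <- strrep("N", seed_len + 5L)
  subject <- Biostrings::DNAString(paste(refs, collapse = sep))
  ref_start <- cumsum(c(1L, reflen[-length(reflen)] + nchar(sep)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[valid]))
  mi <- Biostrings::matchPDict(pd, subject)
  cnt <- S4Vectors::elementNROWS(mi)
  pat <- rep(which(valid), cnt)
  hit_start <- BiocGenerics::start(BiocGenerics::unlist(mi))
  if (!length(pat)) {
    return(ase_alignments(
      data.frame(read = integer(), t = integer(), h = integer(),
                 s = integer(), span = integer()),
      n_reads = n, read_id = reads$read_id, T = tx$T, paired = TRUE))
  }
  ref_idx <- findInterval(hit_start, ref_start)
  pos <- hit_start - ref_start[ref_idx] + 1L
  ok <- pos >= 1L & pos + rl - 1L <= reflen[ref_idx]
  pat <- pat[ok]; ref_idx <- ref_idx[ok]; pos <- pos[ok]
  nmm <- cpp_count_mismatches(refs, ref_idx, pos, oriented, pat)
  keep <- nmm >= 0L & nmm <= max_mismatch
  hits <- data.frame(frag = (pat[keep] - 1L) %% n + 1L,
                     block = (pat[keep] - 1L) %/% n + 1L,
                     ref = ref_idx[keep], pos = pos[keep], nmm = nmm[keep])
  hits <- hits[!duplicated(hits), , drop = FALSE]
  pair_up <- function(fwd, rev, strand) {
    if (!nrow(fwd) || !nrow(rev)) return(NULL)
    names(rev) <- paste0(names(rev), "2")
    mg <- merge(fwd, rev, by.x = c("frag", "ref"),
                by.y = c("frag2", "ref2"))
    mg <- mg[mg$pos <= mg$pos2, , drop = FALSE]
    if (!nrow(mg)) return(NULL)
    data.frame(read = mg$frag, ref = mg$ref, s = mg$pos,
               span = mg$pos2 + rl - mg$pos, strand = strand,
               nmm = mg$nmm + mg$nmm2,
               m1s = if (strand == 0L) mg$pos else mg$pos2,
               m2s = if (strand == 0L) mg$pos2 else mg$pos)
  }
  cand <- rbind(
    pair_up(hits[hits$block == 1L, c("frag", "ref", "pos", "nmm")],
            hits[hits$block == 4L, c("frag", "ref", "pos", "nmm")], 0L),
    pair_up(hits[hits$block == 3L, c("frag", "ref", "pos", "nmm")],
            hits[hits$block == 2L, c("frag", "ref", "pos", "nmm")], 1L))
  if (is.null(cand) || !nrow(cand)) {
    return(ase_alignments(
      data.frame(read = integer(), t = integer(), h = integer(),
                 s = integer(), span = integer()),
      n_reads = n, read_id = reads$read_id, T = tx$T, paired = TRUE))
  }
  cand$t <- (cand$ref - 1L) %% tx$T + 1L
  cand$h <- (cand$ref - 1L) %/% tx$T
  cand$m1w <- rl; cand$m2w <- rl
  eps <- phred_error_prob(phred)
  cand$log_lik <- (2L * rl - cand$nmm) * log1p(-eps) +
    cand$nmm * log(eps / 3)
  cand$log_pos <- position_log_prior(reflen[cand$ref], cand$span)
  cand <- cand[!is.na(cand$log_pos),
               c("read", "t", "h", "s", "span", "strand", "nmm",
                 "m1s", "m1w", "m2s", "m2w", "log_lik", "log_pos")]
  ase_alignments(cand, n_reads = n, read_id = reads$read_id, T = tx$T,
                 paired = TRUE)
}

#' Evaluate estimates against simulation truth
#'
#' Root-mean-square error and Pearson correlation between
#' `log(expected_count + 1)` and `log(true fragment count + 1)` over
#' isoforms with at least one true fragment, plus per-class summaries of
#' the estimated paternal fraction restricted to isoforms passing the
#' standard comparison filter (>= `min_het_snps` heterozygous SNPs and
#' >= `min_reads` assigned reads).
#'
#' @param records Output of [summarize_expression()].
#' @param truth Output of [assign_truth()].
#' @param provenance The `provenance` element of [sim_reads()] (or a
#'   precomputed vector of true per-isoform fragment counts).
#' @param min_reads,min_het_snps The comparison filter.
#' @return A list: `rmse_log_counts`, `pearson_log_counts`,
#'   `class_summary` (data.frame of per-class mean/median `E_phi` and
#'   isoform counts among filtered isoforms), `filtered` (logical vector).
#' @export
evaluate_expression <- function(records, truth, provenance,
                                min_reads = 10, min_het_snps = 1) {
  T <- nrow(records)
  stopifnot(nrow(truth) == T,
            all(records$isoform_id == truth$isoform_id))
  true_count <- if (is.data.frame(provenance))
    tabulate(provenance$t, T) else as.numeric(provenance)
  expressed <- true_count > 0
  le <- log(records$expected_count[expressed] + 1)
  lt <- log(true_count[expressed] + 1)
  filtered <- (records$n_het_snps >= min_het_snps | records$het_indel_flag) &
    floor(records$expected_count) >= min_reads
  cls <- split(records$E_phi[filtered], truth$ase_class[filtered])
  class_summary <- data.frame(
    ase_class = names(cls),
    n = vapply(cls, length, integer(1)),
    mean_E_phi = vapply(cls, mean, numeric(1)),
    median_E_phi = vapply(cls, stats::median, numeric(1)),
    row.names = NULL)
  list(rmse_log_counts = sqrt(mean((le - lt)^2)),
       pearson_log_counts = stats::cor(le, lt),
       class_summary = class_summary,
       filtered = filtered,
       true_count = true_count)
}

#' Write simulated reads as a FASTQ pair
#'
#' @param reads A `sim_reads` object.
#' @param prefix Output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return The two paths, invisibly.
#' @export
write_sim_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (k in 1:2) {
    seqs <- if (k == 1) reads$mate1 else reads$mate2
    writeLines(as.vector(rbind(paste0("@", reads$read_id, "/", k),
                               seqs, "+", reads$qual)), paths[k])
  }
  invisible(paths)
}

#' Read a FASTQ pair into the container expected by [toy_align()]
#'
#' @param fastq1,fastq2 Paths to the two mate files.
#' @return A list with `mate1`, `mate2`, `read_id`.
#' @export
read_fastq_pair <- function(fastq1, fastq2) {
  m1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  m2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  stopifnot(length(m1) == length(m2))
  list(mate1 = unname(as.character(m1)), mate2 = unname(as.character(m2)),
       read_id = sub("/[12]$", "", sub("\\s.*$", "", names(m1))))
}

#' Export toy-aligner candidates as SAM
#'
#' Writes the paired candidates of [toy_align()] as a name-grouped SAM
#' file against the `_paternal` / `_maternal` reference naming
#' convention, with secondary alignments flagged (0x100), so the file
#' round-trips through [read_diploid_alignments()].
#'
#' @param aln An `ase_aln` from [toy_align()].
#' @param reads The `sim_reads` (or read list) that produced it.
#' @param tx The `diploid_tx`.
#' @param path Output SAM path.
#' @export
write_toy_sam <- function(aln, reads, tx, path) {
  rl <- nchar(reads$mate1[1])
  qual <- if (!is.null(reads$qual)) reads$qual else strrep("I", rl)
  refname <- c(paste0(tx$isoform_id, "_paternal"),
               paste0(tx$isoform_id, "_maternal"))
  reflen <- c(tx$l0, tx$l1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:queryname",
               paste0("@SQ\tSN:", refname, "\tLN:", reflen)), con)
  cand <- aln$cand
  if (nrow(cand)) {
    cand <- cand[order(cand$read), , drop = FALSE]
    sec <- ifelse(duplicated(cand$read), 256L, 0L)
    ref <- refname[cand$t + cand$h * tx$T]
    cig <- paste0(rl, "M")
    # strand 0: mate1 forward / mate2 reverse; strand 1: the opposite
    f1 <- 1L + 2L + 64L + ifelse(cand$strand == 1L, 16L, 32L) + sec
    f2 <- 1L + 2L + 128L + ifelse(cand$strand == 0L, 16L, 32L) + sec
    s1 <- ifelse(cand$strand == 1L, revcomp(reads$mate1[cand$read]),
                 reads$mate1[cand$read])
    s2 <- ifelse(cand$strand == 0L, revcomp(reads$mate2[cand$read]),
                 reads$mate2[cand$read])
    qn <- aln$read_id[cand$read]
    writeLines(c(paste(qn, f1, ref, cand$m1s, 255L, cig, "=", cand$m2s,
                       ifelse(cand$strand == 0L, cand$span, -cand$span),
                       s1, qual, sep = "\t"),
                 paste(qn, f2, ref, cand$m2s, 255L, cig, "=", cand$m1s,
                       ifelse(cand$strand == 0L, -cand$span, cand$span),
                       s2, qual, sep = "\t")), con)
  }
  invisible(path)
}
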