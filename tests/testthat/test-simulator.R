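test_that("config validation rejects impossible designs", {
  expect_error(sim_config(frac_paternal_ase = 0.6, frac_maternal_ase = 0.6),
               "at most 1")
  expect_error(sim_config(sub_err = 1.5), "rates")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("simulated transcriptomes are seed-reproducible", {
  cfg <- sim_config(n_isoforms = 10, seed = 4)
  tx1 <- sim_transcriptome(cfg)
  tx2 <- sim_transcriptome(cfg)
  expect_identical(tx1$seq0, tx2$seq0)
  expect_identical(tx1$seq1, tx2$seq1)
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_diploid_fasta(tx1, f1, g1)
  write_diploid_fasta(tx2, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  # and the full dataset chain is reproducible too
  d1 <- sim_dataset(cfg); d2 <- sim_dataset(cfg)
  expect_identical(d1$reads$mate1, d2$reads$mate1)
  expect_identical(d1$truth$phi, d2$truth$phi)
})

test_that("zero divergence gives identical alleles", {
  cfg <- sim_config(n_isoforms = 8, snps_per_kb = 0, indel_prob = 0,
                    seed = 5)
  tx <- sim_transcriptome(cfg)
  expect_identical(tx$seq0, tx$seq1)
})

test_that("het SNP counts follow the configured density", {
  cfg <- sim_config(n_isoforms = 500, length_range = c(1000, 1000),
                    snps_per_kb = 1, indel_prob = 0, seed = 6)
  tx <- sim_transcriptome(cfg)
  het <- detect_het_sites(tx)
  # Poisson(1) mean, within 3 standard errors
  se <- sqrt(1 / 500)
  expect_lt(abs(mean(het$n_het_snps) - 1), 3 * se + 1e-9)
})

test_that("truth assignment matches the configured design", {
  cfg <- sim_config(n_isoforms = 1000, n_fragments = 10, seed = 7)
  tx <- sim_transcriptome(cfg)
  truth <- assign_truth(cfg, tx)
  expect_equal(sum(truth$theta), 1)
  expect_equal(sum(truth$ase_class == "paternal"), 100L)
  expect_equal(sum(truth$ase_class == "maternal"), 100L)
  expect_equal(unique(truth$phi[truth$ase_class == "paternal"]), 0.8)
  expect_equal(unique(truth$phi[truth$ase_class == "maternal"]), 0.2)
  expect_true(all(truth$phi[truth$ase_class == "null"] == 0.5))
  # null mode: everything 50:50
  cfgn <- sim_config(n_isoforms = 200, null_mode = TRUE, seed = 7)
  txn <- sim_transcriptome(cfgn)
  truthn <- assign_truth(cfgn, txn)
  expect_true(all(truthn$phi == 0.5))
})

test_that("error-free reads are exact substrings of their source allele", {
  cfg <- sim_config(n_isoforms = 5, n_fragments = 50, sub_err = 0,
                    ins_err = 0, del_err = 0, seed = 8)
  d <- sim_dataset(cfg)
  pr <- d$reads$provenance
  for (i in seq_len(50)) {
    hap <- if (pr$h[i] == 0) d$tx$seq0[pr$t[i]] else d$tx$seq1[pr$t[i]]
    frag <- substr(hap, pr$s[i], pr$s[i] + pr$frag_len[i] - 1)
    expect_identical(d$reads$mate1[i], substr(frag, 1, 100))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(frag)))
    expect_identical(d$reads$mate2[i], substr(rc, 1, 100))
  }
})

test_that("injected error rates match the configuration", {
  cfg <- sim_config(n_isoforms = 10, n_fragments = 1500, ins_err = 0,
                    del_err = 0, seed = 9)
  d <- sim_dataset(cfg)
  pr <- d$reads$provenance
  hap <- ifelse(pr$h == 0, d$tx$seq0[pr$t], d$tx$seq1[pr$t])
  tpl <- substr(substring(hap, pr$s, pr$s + pr$frag_len - 1), 1, 100)
  mm <- mapply(function(a, b)
    sum(charToRaw(a) != charToRaw(b)), d$reads$mate1, tpl)
  rate <- sum(mm) / (1500 * 100)
  se <- sqrt(0.001 * 0.999 / (1500 * 100))
  expect_lt(abs(rate - 0.001), 3 * se)
})

test_that("haplotype provenance follows the allelic fractions", {
  cfg <- sim_config(n_isoforms = 40, n_fragments = 20000, seed = 10)
  d <- sim_dataset(cfg)
  pr <- d$reads$provenance
  pat_iso <- which(d$truth$ase_class == "paternal")
  sel <- pr$t %in% pat_iso
  frac_h0 <- mean(pr$h[sel] == 0)
  se <- sqrt(0.8 * 0.2 / sum(sel))
  expect_lt(abs(frac_h0 - 0.8), 3 * se)
})

test_that("isoforms shorter than the read length are excluded", {
  tx <- new_diploid_tx(c("long", "short"),
                       seq0 = c(strrep("ACGT", 150), "ACGTACGT"),
                       seq1 = c(strrep("ACGT", 150), "ACGTACGT"))
  cfg <- sim_config(n_isoforms = 2, n_fragments = 30, seed = 11)
  truth <- data.frame(isoform_id = tx$isoform_id, theta = c(0.5, 0.5),
                      phi = 0.5, ase_class = "null")
  expect_warning(r <- sim_reads(cfg, tx, truth), "shorter")
  expect_true(all(r$provenance$t == 1L))
})

test_that("the toy aligner finds shared and discriminating placements", {
  cfg <- sim_config(n_isoforms = 6, length_range = c(400, 800),
                    n_fragments = 200, sub_err = 0, ins_err = 0,
                    del_err = 0, seed = 12)
  d <- sim_dataset(cfg)
  aln <- toy_align(d$reads, d$tx)
  pr <- d$reads$provenance
  cand <- aln$cand
  het <- lapply(seq_len(d$tx$T), function(t)
    asequant:::het_positions(d$tx, t))
  for (i in seq_len(150)) {
    rows <- cand[cand$read == i, ]
    if (!nrow(rows)) next
    hp <- het[[pr$t[i]]]
    pos <- if (pr$h[i] == 0) hp$pos0 else hp$pos1
    m1 <- c(pr$s[i], pr$s[i] + 99)
    m2 <- c(pr$s[i] + pr$frag_len[i] - 100, pr$s[i] + pr$frag_len[i] - 1)
    covered <- any(pos >= m1[1] & pos <= m1[2]) ||
      any(pos >= m2[1] & pos <= m2[2])
    true_row <- rows$t == pr$t[i] & rows$h == pr$h[i] & rows$s == pr$s[i]
    expect_true(any(true_row))
    if (!covered && !hp$indel) {
      # no discriminating site under the mates: both haplotypes align
      expect_gte(nrow(rows), 2L)
    }
    if (covered && any(rows$t == pr$t[i] & rows$h != pr$h[i])) {
      # het site covered: the true haplotype scores strictly higher
      expect_gt(max(rows$log_lik[true_row]),
                max(rows$log_lik[rows$t == pr$t[i] & rows$h != pr$h[i]]))
    }
  }
  # reads from an isoform absent from the reference go unaligned
  tx_sub <- new_diploid_tx(d$tx$isoform_id[1], gene_id = d$tx$gene_id[1],
                           seq0 = d$tx$seq0[1], seq1 = d$tx$seq1[1])
  aln_sub <- toy_align(d$reads, tx_sub)
  other <- which(pr$t != 1L)
  expect_false(any(aln_sub$cand$read %in% other))
})

test_that("evaluation metrics match their definitions", {
  rec <- data.frame(isoform_id = c("a", "b", "c"), gene_id = "",
                    expected_count = c(10, 100, 1000),
                    E_phi = c(0.5, 0.8, 0.2), n_het_snps = 1L,
                    het_indel_flag = FALSE)
  truth <- data.frame(isoform_id = c("a", "b", "c"), theta = 1 / 3,
                      phi = 0.5, ase_class = "null")
  ev <- evaluate_expression(rec, truth, c(10, 100, 1000))
  expect_equal(ev$rmse_log_counts, 0)
  expect_equal(ev$pearson_log_counts, 1)
  # a constant offset in log space is returned as the RMSE
  rec2 <- rec; rec2$expected_count <- exp(log(c(10, 100, 1000) + 1) + 0.3) - 1
  ev2 <- evaluate_expression(rec2, truth, c(10, 100, 1000))
  expect_equal(ev2$rmse_log_counts, 0.3, tolerance = 1e-9)
  # hand-computed three-isoform RMSE
  rec3 <- rec; rec3$expected_count <- c(12, 90, 1100)
  ev3 <- evaluate_expression(rec3, truth, c(10, 100, 1000))
  d <- log(c(12, 90, 1100) + 1) - log(c(10, 100, 1000) + 1)
  expect_equal(ev3$rmse_log_counts, sqrt(mean(d^2)))
  expect_equal(ev3$pearson_log_counts,
               cor(log(c(12, 90, 1100) + 1), log(c(10, 100, 1000) + 1)))
  expect_error(evaluate_expression(rec, truth[1:2, ], c(1, 2)), "")
})

test_that("FASTQ output round-trips", {
  cfg <- sim_config(n_isoforms = 3, n_fragments = 20, seed = 13)
  d <- sim_dataset(cfg)
  pre <- tempfile()
  paths <- write_sim_fastq(d$reads, pre)
  back <- read_fastq_pair(paths[1], paths[2])
  expect_identical(back$mate1, d$reads$mate1)
  expect_identical(back$mate2, d$reads$mate2)
  expect_identical(back$read_id, d$reads$read_id)
})

test_that("null simulations stay mostly uncalled at the 0.75/0.25 thresholds", {
  cfg <- sim_config(n_isoforms = 100, n_fragments = 30000, null_mode = TRUE,
                    seed = 14)
  d <- sim_dataset(cfg)
  fit <- ase_fit(toy_align(d$reads, d$tx), d$tx, alpha0 = 0.1)
  calls <- call_ase(fit$records)
  considered <- calls$status != "filtered"
  frac_ase <- mean(calls$status[considered] %in%
                     c("paternal_ASE", "maternal_ASE"))
  expect_lt(frac_ase, 0.10)
})
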