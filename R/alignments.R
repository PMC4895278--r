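#' Construct a read-alignment set
#'
#' The container consumed by the inference engine: one row per alignment
#' candidate, i.e. per (isoform, haplotype, start) tuple a read (or read
#' pair) may have originated from.  Candidates are produced by
#' [read_diploid_alignments()] from SAM/BAM, by [toy_align()] from raw
#' reads, or directly by this constructor (useful for small hand-built
#' problems).  Reads with no candidates are retained: they feed the noise
#' component of the model.
#'
#' @param cand A data.frame with at least columns `read` (1-based read
#'   index), `t` (isoform ordinal), `h` (0 paternal / 1 maternal), `s`
#'   (1-based start on the cDNA) and `span` (aligned reference span, bp).
#'   Columns `log_lik` and `log_pos` may be supplied directly (e.g. for
#'   synthetic problems) or filled in later by [compute_likelihoods()].
#' @param n_reads Total number of reads (fragments), including unaligned
#'   ones; defaults to `max(cand$read)`.
#' @param read_id Optional read names, length `n_reads`.
#' @param T Isoform count; defaults to `max(cand$t)`.
#' @param paired Logical: candidates describe fragments (read pairs).
#' @return An object of class `ase_aln`.
#' @export
ase_alignments <- function(cand, n_reads = NULL, read_id = NULL, T = NULL,
                           paired = FALSE) {
  stopifnot(all(c("read", "t", "h", "s") %in% names(cand)))
  if (is.null(cand$span)) cand[["span"]] <- rep(NA_integer_, nrow(cand))
  if (is.null(cand$log_lik)) cand[["log_lik"]] <- rep(NA_real_, nrow(cand))
  if (is.null(cand$log_pos)) cand[["log_pos"]] <- rep(NA_real_, nrow(cand))
  if (is.null(n_reads)) n_reads <- if (nrow(cand)) max(cand$read) else 0L
  if (is.null(T)) T <- if (nrow(cand)) max(cand$t) else 1L
  if (is.null(read_id)) read_id <- paste0("read", seq_len(n_reads))
  if (nrow(cand)) {
    stopifnot(all(cand$read >= 1L), all(cand$read <= n_reads),
              all(cand$t >= 1L), all(cand$t <= T),
              all(cand$h %in% c(0L, 1L)))
    key <- paste(cand$read, cand$t, cand$h, cand$s,
                 if (!is.null(cand$strand)) cand$strand else 0L)
    cand <- cand[!duplicated(key), , drop = FALSE]
    cand <- cand[order(cand$read, cand$t, cand$h, cand$s), , drop = FALSE]
    rownames(cand) <- NULL
  }
  structure(list(cand = cand, n_reads = as.integer(n_reads),
                 read_id = as.character(read_id), T = as.integer(T),
                 paired = isTRUE(paired)),
            class = "ase_aln")
}

#' @export
print.ase_aln <- function(x, ...) {
  n_aln <- length(unique(x$cand$read))
  cat("Read alignments:", x$n_reads,
      if (x$paired) "fragments," else "reads,",
      nrow(x$cand), "candidates\n")
  cat("  aligned:", n_aln, " unaligned:", x$n_reads - n_aln, "\n")
  invisible(x)
}

# number of reads with empty candidate sets
n_noise_reads <- function(aln) aln$n_reads - length(unique(aln$cand$read))

#' Parse multi-alignment SAM/BAM against a diploid transcriptome
#'
#' Reads a SAM or BAM file whose reference names encode the haplotype via a
#' suffix pair (default `"_paternal"` / `"_maternal"`), as produced by
#' aligning against the concatenation of the two haplotype cDNA sets in
#' report-all mode (e.g. bowtie2 `-k`).  All primary and secondary (flag
#' 0x100) alignments are collected into each read's candidate set; SAM
#' 1-based positions are kept as-is (internal coordinates are 1-based
#' inclusive).  For paired data, mates are joined by read name: a fragment
#' candidate requires both mates on the same (isoform, haplotype) with
#' opposite strands in FR orientation, and the fragment start is the
#' leftmost mate start.  Records whose mate is missing are dropped with a
#' warning.  Unaligned reads are retained with empty candidate sets.
#'
#' @param path SAM or BAM file.
#' @param tx A `diploid_tx` the references must resolve against.
#' @param suffixes Length-2 character: reference-name suffixes identifying
#'   the paternal and maternal copies.
#' @return An `ase_aln` whose candidates carry the per-mate CIGAR, sequence
#'   and quality strings needed by [compute_likelihoods()].
#' @export
read_diploid_alignments <- function(path, tx,
                                    suffixes = c("_paternal", "_maternal")) {
  stopifnot(length(suffixes) == 2L)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")))[[1]]
  qname <- b$qname
  flag <- b$flag
  read_id <- unique(qname)
  read <- match(qname, read_id)
  unmapped <- bitwAnd(flag, 4L) > 0L
  # resolve reference names to (isoform ordinal, haplotype)
  lev <- levels(b$rname)
  lt <- rep(NA_integer_, length(lev)); lh <- rep(NA_integer_, length(lev))
  for (k in seq_along(suffixes)) {
    hit <- endsWith(lev, suffixes[k])
    lt[hit] <- match(substr(lev[hit], 1L,
                            nchar(lev[hit]) - nchar(suffixes[k])),
                     tx$isoform_id)
    lh[hit] <- k - 1L
  }
  used <- tabulate(as.integer(b$rname)[!unmapped], length(lev)) > 0L
  bad <- used & (is.na(lt) | is.na(lh))
  if (any(bad))
    stop("reference name(s) not resolvable to a known isoform/haplotype: ",
         paste(lev[bad], collapse = ", "))
  keep <- !unmapped
  rec <- data.frame(
    read = read[keep],
    t = lt[as.integer(b$rname)[keep]],
    h = lh[as.integer(b$rname)[keep]],
    pos = b$pos[keep],
    rw = GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[keep]),
    rev = bitwAnd(flag[keep], 16L) > 0L,
    paired = bitwAnd(flag[keep], 1L) > 0L,
    mate = ifelse(bitwAnd(flag[keep], 128L) > 0L, 2L, 1L),
    cigar = b$cigar[keep],
    seq = as.character(b$seq[keep]),
    qual = as.character(b$qual[keep]),
    stringsAsFactors = FALSE)
  rec$end <- rec$pos + rec$rw - 1L
  any_paired <- any(rec$paired)
  if (!nrow(rec)) {
    return(ase_alignments(
      data.frame(read = integer(), t = integer(), h = integer(),
                 s = integer(), span = integer()),
      n_reads = length(read_id), read_id = read_id, T = tx$T,
      paired = any_paired))
  }
  if (any_paired) {
    m1 <- rec[rec$mate == 1L, ]
    m2 <- rec[rec$mate == 2L, ]
    names(m2) <- paste0(names(m2), "2")
    mg <- merge(m1, m2,
                by.x = c("read", "t", "h"), by.y = c("read2", "t2", "h2"))
    ok <- mg$rev != mg$rev2 &
      ifelse(mg$rev, mg$pos2 <= mg$pos, mg$pos <= mg$pos2)
    mg <- mg[ok, , drop = FALSE]
    n_dropped <- nrow(m1) + nrow(m2) - 2L * nrow(mg)
    if (n_dropped > 0)
      warning(n_dropped, " alignment record(s) without a consistent mate ",
              "were dropped")
    cand <- data.frame(
      read = mg$read, t = mg$t, h = mg$h,
      s = pmin(mg$pos, mg$pos2),
      span = pmax(mg$end, mg$end2) - pmin(mg$pos, mg$pos2) + 1L,
      strand = as.integer(mg$rev),
      m1s = mg$pos, m1w = mg$rw, m2s = mg$pos2, m2w = mg$rw2,
      cigar1 = mg$cigar, seq1 = mg$seq, qual1 = mg$qual,
      cigar2 = mg$cigar2, seq2 = mg$seq2, qual2 = mg$qual2,
      stringsAsFactors = FALSE)
  } else {
    cand <- data.frame(
      read = rec$read, t = rec$t, h = rec$h, s = rec$pos, span = rec$rw,
      strand = as.integer(rec$rev),
      m1s = rec$pos, m1w = rec$rw, m2s = NA_integer_, m2w = NA_integer_,
      cigar1 = rec$cigar, seq1 = rec$seq, qual1 = rec$qual,
      cigar2 = NA_character_, seq2 = NA_character_, qual2 = NA_character_,
      stringsAsFactors = FALSE)
  }
  ase_alignments(cand, n_reads = length(read_id), read_id = read_id,
                 T = tx$T, paired = any_paired)
}
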