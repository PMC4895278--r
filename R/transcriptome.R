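#' Load a diploid transcriptome from paired FASTA files
#'
#' Reads paternal and maternal cDNA FASTA files and pairs sequences by
#' isoform identifier (the first whitespace-delimited token of each header).
#' Every identifier must occur exactly once in each file; the two haplotype
#' copies of an isoform may differ in sequence and in length (heterozygous
#' SNPs and indels).  Isoform ordinals are assigned in paternal-file order,
#' starting at 1; ordinal 0 is reserved for the noise component of the
#' inference engine (see [run_inference()]).
#'
#' @param paternal_fasta,maternal_fasta Paths to the two FASTA files.
#' @param gene_ids Optional named character vector mapping isoform_id to
#'   gene_id.  Isoforms without an entry get an empty gene_id.
#' @return An object of class `diploid_tx`: a list with elements
#'   `isoform_id`, `gene_id`, `seq0`/`seq1` (paternal/maternal sequences as
#'   character vectors), `l0`/`l1` (their lengths in bp), and `T` (the
#'   isoform count).
#' @examples
#' p <- tempfile(fileext = ".fa"); m <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "ACGTACGT", ">tx2", "GGGCCC"), p)
#' writeLines(c(">tx1", "ACGAACGT", ">tx2", "GGGCCC"), m)
#' tx <- read_diploid_transcriptome(p, m)
#' tx$T
#' @export
read_diploid_transcriptome <- function(paternal_fasta, maternal_fasta,
                                       gene_ids = NULL) {
  pat <- Biostrings::readDNAStringSet(paternal_fasta)
  mat <- Biostrings::readDNAStringSet(maternal_fasta)
  pid <- sub("\\s.*$", "", names(pat))
  mid <- sub("\\s.*$", "", names(mat))
  if (anyDuplicated(pid))
    stop("duplicate isoform id in paternal FASTA: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(mid))
    stop("duplicate isoform id in maternal FASTA: ",
         paste(unique(mid[duplicated(mid)]), collapse = ", "))
  only_p <- setdiff(pid, mid)
  only_m <- setdiff(mid, pid)
  if (length(only_p) || length(only_m))
    stop("unpaired isoform id(s): ",
         paste(c(only_p, only_m), collapse = ", "))
  mat <- mat[match(pid, mid)]
  seq0 <- toupper(as.character(pat))
  seq1 <- toupper(as.character(mat))
  names(seq0) <- names(seq1) <- NULL
  if (any(nchar(seq0) == 0L) || any(nchar(seq1) == 0L))
    stop("empty sequence in FASTA input")
  gid <- character(length(pid))
  if (!is.null(gene_ids)) {
    hit <- match(pid, names(gene_ids))
    gid[!is.na(hit)] <- unname(gene_ids[hit[!is.na(hit)]])
  }
  new_diploid_tx(pid, gid, seq0, seq1)
}

#' @rdname read_diploid_transcriptome
#' @param isoform_id,gene_id,seq0,seq1 Components of an in-memory
#'   transcriptome: identifiers and paternal/maternal sequences.
#' @export
new_diploid_tx <- function(isoform_id, gene_id = character(length(isoform_id)),
                           seq0, seq1) {
  stopifnot(length(isoform_id) == length(seq0),
            length(seq0) == length(seq1),
            !anyDuplicated(isoform_id))
  if (any(nchar(seq0) == 0L) || any(nchar(seq1) == 0L))
    stop("empty sequence in transcriptome")
  structure(list(isoform_id = as.character(isoform_id),
                 gene_id = as.character(gene_id),
                 seq0 = toupper(seq0), seq1 = toupper(seq1),
                 l0 = nchar(seq0), l1 = nchar(seq1),
                 T = length(isoform_id)),
            class = "diploid_tx")
}

#' @export
print.diploid_tx <- function(x, ...) {
  cat("Diploid transcriptome:", x$T, "isoforms\n")
  cat("  paternal lengths:", min(x$l0), "-", max(x$l0), "bp\n")
  cat("  maternal lengths:", min(x$l1), "-", max(x$l1), "bp\n")
  invisible(x)
}

# length of isoform t on haplotype h (0 paternal, 1 maternal), vectorized
tx_length <- function(tx, t, h) ifelse(h == 0, tx$l0[t], tx$l1[t])

tx_seq <- function(tx, t, h) if (h == 0) tx$seq0[t] else tx$seq1[t]

#' Detect heterozygous sites between the two alleles of an isoform
#'
#' For equal-length alleles, heterozygous SNPs are the positions where the
#' paternal and maternal sequences differ.  For unequal lengths the two
#' alleles are globally aligned (match +1, mismatch -1, gap -2) and SNPs are
#' counted on the aligned match columns; the indel flag records that
#' length-changing heterozygous variation exists.
#'
#' @param tx A `diploid_tx`.
#' @param t Isoform ordinal(s); default all.
#' @return A data.frame with columns `isoform_id`, `n_het_snps`,
#'   `het_indel_flag`.
#' @export
detect_het_sites <- function(tx, t = seq_len(tx$T)) {
  n <- integer(length(t)); ind <- logical(length(t))
  for (i in seq_along(t)) {
    hp <- het_positions(tx, t[i])
    n[i] <- length(hp$pos0)
    ind[i] <- hp$indel
  }
  data.frame(isoform_id = tx$isoform_id[t], n_het_snps = n,
             het_indel_flag = ind, stringsAsFactors = FALSE)
}

# Per-haplotype coordinates of substitution-type het sites, plus indel flag.
# pos0/pos1 are sorted positions on the paternal/maternal sequence.
het_positions <- function(tx, t) {
  s0 <- tx$seq0[t]; s1 <- tx$seq1[t]
  if (nchar(s0) == nchar(s1)) {
    if (s0 == s1) return(list(pos0 = integer(), pos1 = integer(),
                              indel = FALSE))
    d <- which(charToRaw(s0) != charToRaw(s1))
    return(list(pos0 = d, pos1 = d, indel = FALSE))
  }
  al <- Biostrings::pairwiseAlignment(
    s0, s1, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  a0 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  a1 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- a0 != "-" & a1 != "-"
  mm <- keep & a0 != a1
  list(pos0 = cumsum(a0 != "-")[mm], pos1 = cumsum(a1 != "-")[mm],
       indel = TRUE)
}

#' Write a diploid transcriptome as a pair of FASTA files
#'
#' @param tx A `diploid_tx`.
#' @param paternal_fasta,maternal_fasta Output paths.
#' @export
write_diploid_fasta <- function(tx, paternal_fasta, maternal_fasta) {
  s0 <- Biostrings::DNAStringSet(tx$seq0); names(s0) <- tx$isoform_id
  s1 <- Biostrings::DNAStringSet(tx$seq1); names(s1) <- tx$isoform_id
  Biostrings::writeXStringSet(s0, paternal_fasta)
  Biostrings::writeXStringSet(s1, maternal_fasta)
  invisible(NULL)
}
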