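#' Read stranded single-end alignments from SAM/BAM
#'
#' Loads primary, mapped alignments (secondary and supplementary records are
#' dropped, matching a primary-alignment-only counting policy). SAM input is
#' converted on the fly with [Rsamtools::asBam()]. Spliced alignments keep
#' their junction structure (`N` CIGAR operations become multi-block reads).
#'
#' @param path Path to a SAM or BAM file (extension decides).
#' @return A [GenomicAlignments::GAlignments] with a `qname` metadata column.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = "qname",
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    )
  )
  GenomicAlignments::readGAlignments(bam, param = param)
}

#' Drop reads aligned to rRNA reference sequences
#'
#' Removes alignments whose reference sequence is in `rrna_refs`, emulating a
#' pre-mapping filter against known rRNA sequences. Downstream library sizes
#' are computed after this filter, so rRNA reads never enter the RPKM
#' denominator. The number of removed reads is reported via a message and
#' attached as `metadata(x)$rrna_removed`.
#'
#' @param alignments A [GenomicAlignments::GAlignments].
#' @param rrna_refs Character vector of rRNA reference names (may be empty).
#' @return The filtered `GAlignments`.
#' @export
filter_rrna <- function(alignments, rrna_refs = character()) {
  stopifnot(is(alignments, "GAlignments"))
  if (length(rrna_refs) == 0) {
    S4Vectors::metadata(alignments)$rrna_removed <- 0L
    return(alignments)
  }
  hit <- as.character(GenomeInfoDb::seqnames(alignments)) %in% rrna_refs
  removed <- sum(hit)
  inform(sprintf("filter_rrna: removed %d read(s) on rRNA reference(s)", removed))
  out <- alignments[!hit]
  S4Vectors::metadata(out)$rrna_removed <- removed
  out
}

#' Tidy alignments into a block table
#'
#' One row per aligned block (0-based half-open coordinates); spliced reads
#' contribute several rows sharing a `read_id`.
#'
#' @param x A [GenomicAlignments::GAlignments] from [read_alignments()].
#' @param ... Unused.
#' @return A tibble with `read_id`, `chrom`, `strand`, `start`, `end`.
#' @export
#' @exportS3Method generics::tidy
tidy.GAlignments <- function(x, ...) {
  blocks <- GenomicAlignments::grglist(x)
  n_per <- S4Vectors::elementNROWS(blocks)
  flat <- BiocGenerics::unlist(blocks, use.names = FALSE)
  qn <- S4Vectors::mcols(x)$qname
  if (is.null(qn)) qn <- as.character(seq_along(x))
  tibble(
    read_id = rep(qn, n_per),
    chrom = as.character(GenomeInfoDb::seqnames(flat)),
    strand = rep(as.character(BiocGenerics::strand(x)), n_per),
    start = BiocGenerics::start(flat) - 1L,
    end = BiocGenerics::end(flat)
  )
}
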