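# Fixture builders and independent oracles shared across the suite.

# tiny exon table -> genome_annotation
toy_annotation <- function(exons, chrom_lengths = NULL) {
  genome_annotation(tibble::as_tibble(exons), chrom_lengths = chrom_lengths)
}

# two-gene annotation used by several counting tests:
#   geneA (+): exons [100,200) and [300,400) on chr1
#   geneB (-): exon [1000,1500) on chr1
two_gene_annotation <- function() {
  toy_annotation(tibble::tribble(
    ~gene_id, ~chrom, ~strand, ~start, ~end,
    "geneA", "chr1", "+", 100L, 200L,
    "geneA", "chr1", "+", 300L, 400L,
    "geneB", "chr1", "-", 1000L, 1500L
  ))
}

# GAlignments from a read sheet (0-based start, SAM cigar)
make_alignments <- function(reads, chrom_lengths = c(chr1 = 100000L, chr2 = 100000L)) {
  reads <- tibble::as_tibble(reads)
  ga <- GenomicAlignments::GAlignments(
    seqnames = reads$chrom,
    pos = as.integer(reads$start + 1L),
    cigar = reads$cigar,
    strand = S4Vectors::Rle(factor(reads$strand, levels = c("+", "-", "*"))),
    qname = reads$read_id
  )
  ga
}

# write the same read sheet as a SAM file
write_sam_fixture <- function(reads, path, chrom_lengths = c(chr1 = 100000L, chr2 = 100000L),
                              flags = NULL) {
  reads <- tibble::as_tibble(reads)
  if (is.null(flags)) flags <- ifelse(reads$strand == "+", 0L, 16L)
  con <- file(path, open = "wb")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), as.integer(chrom_lengths))
  ), con, sep = "\n")
  writeLines(sprintf(
    "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
    reads$read_id, flags, reads$chrom, reads$start + 1L, reads$cigar
  ), con, sep = "\n")
  close(con)
  path
}

# expand a cigar + 0-based start into aligned blocks (M advances both,
# N/D advance the reference); intentionally naive, loop-based
cigar_blocks <- function(start, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  pos <- start
  blocks <- list()
  for (op in ops) {
    len <- as.integer(sub("[A-Z=]$", "", op))
    kind <- sub("^[0-9]+", "", op)
    if (kind %in% c("M", "=", "X")) {
      blocks[[length(blocks) + 1]] <- c(pos, pos + len)
      pos <- pos + len
    } else if (kind %in% c("N", "D")) {
      pos <- pos + len
    }
  }
  do.call(rbind, blocks)
}

# brute-force per-base union-rule counting oracle, independent of the
# IRanges machinery: per read, scan every gene exon base-by-base
oracle_count <- function(reads, annotation, mode, protocol = "forward") {
  exons <- annotation$exons
  genes <- annotation$genes
  counts <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  n_amb <- 0L
  n_nof <- 0L
  for (i in seq_len(nrow(reads))) {
    blocks <- cigar_blocks(reads$start[i], reads$cigar[i])
    read_bases <- unlist(apply(blocks, 1, function(b) seq(b[1], b[2] - 1L), simplify = FALSE))
    read_strand <- reads$strand[i]
    if (protocol == "reverse") read_strand <- if (read_strand == "+") "-" else "+"
    hit_genes <- character(0)
    for (g in genes$gene_id) {
      ex_g <- exons[exons$gene_id == g, ]
      if (ex_g$chrom[1] != reads$chrom[i]) next
      if (mode == "stranded_sense" && ex_g$strand[1] != read_strand) next
      gene_bases <- unlist(purrr::map2(ex_g$start, ex_g$end, ~ seq(.x, .y - 1L)))
      if (any(read_bases %in% gene_bases)) hit_genes <- c(hit_genes, g)
    }
    if (length(hit_genes) == 1) {
      counts[hit_genes] <- counts[hit_genes] + 1L
    } else if (length(hit_genes) > 1) {
      n_amb <- n_amb + 1L
    } else {
      n_nof <- n_nof + 1L
    }
  }
  list(counts = counts, n_ambiguous = n_amb, n_no_feature = n_nof)
}

# independent hypergeometric enumeration for the two-sided Fisher test,
# built from choose() rather than dhyper()
fisher_enum_oracle <- function(cA, cB, nA, nB) {
  m <- cA + cB
  if (m == 0) return(1)
  lo <- max(0, m - nB)
  hi <- min(m, nA)
  x <- lo:hi
  logp <- lchoose(nA, x) + lchoose(nB, m - x) - lchoose(nA + nB, m)
  p <- exp(logp)
  p_obs <- p[x == cA]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# minimal counts_table constructor for unit tests
make_counts_table <- function(counts, libraries) {
  structure(
    list(counts = tibble::as_tibble(counts), libraries = tibble::as_tibble(libraries)),
    class = "counts_table"
  )
}

# one shared default-depth simulated experiment, built once per test run
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_experiment <- function() {
  if (!exists("exp", envir = .acceptance_cache)) {
    cfg <- sim_config(seed = 101)
    out <- file.path(tempdir(), "strawdeg-acceptance-sim")
    sim <- simulate_dataset(cfg, out, write_genome = FALSE)
    counts <- suppressMessages(
      quantify_libraries(sim$libraries, sim$annotation, rrna_refs = sim$rrna_refs)
    )
    expr <- build_expression_table(counts, sim$annotation)
    expr_lib <- build_expression_table(counts, sim$annotation, pooling = "per_library")
    tests <- de_test(counts, "glucose_48h", "straw_24h")
    assign("exp", list(
      config = cfg, sim = sim, counts = counts,
      expr = expr, expr_lib = expr_lib, tests = tests
    ), envir = .acceptance_cache)
  }
  get("exp", envir = .acceptance_cache)
}
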