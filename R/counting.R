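#' Count reads per gene with the union overlap rule
#'
#' For every read, the set of genes whose exon union overlaps at least one
#' base of at least one aligned block is computed. The read is counted for a
#' gene only when that set contains exactly that gene; reads hitting several
#' genes (ambiguous) or none (no-feature) are counted in the library size but
#' in no gene. In `stranded_sense` mode the candidate genes are restricted to
#' those whose strand matches the read under the library protocol
#' (`forward`: read strand equals gene strand; `reverse`: opposite);
#' `unstranded` mode ignores strand.
#'
#' @param alignments A [GenomicAlignments::GAlignments] (mapped, rRNA-filtered).
#' @param annotation A [genome_annotation].
#' @param mode `"stranded_sense"` or `"unstranded"`.
#' @param protocol `"forward"` or `"reverse"`; only used in stranded mode.
#' @return A tibble (`gene_id`, `count`) over all annotated genes, with
#'   attributes `library_size` (all input reads), `n_ambiguous` and
#'   `n_no_feature`.
#' @export
count_reads <- function(alignments, annotation,
                        mode = c("stranded_sense", "unstranded"),
                        protocol = c("forward", "reverse")) {
  mode <- match.arg(mode)
  protocol <- match.arg(protocol)
  stopifnot(is(alignments, "GAlignments"), inherits(annotation, "genome_annotation"))

  features <- annotation_features(annotation)
  gene_ids <- names(features)
  n_reads <- length(alignments)

  if (n_reads == 0) {
    out <- tibble(gene_id = annotation$genes$gene_id, count = 0L)
    attr(out, "library_size") <- 0L
    attr(out, "n_ambiguous") <- 0L
    attr(out, "n_no_feature") <- 0L
    return(out)
  }

  unseen <- setdiff(
    unique(as.character(GenomeInfoDb::seqnames(alignments))),
    unique(annotation$exons$chrom)
  )
  if (length(unseen) > 0) {
    inform(sprintf(
      "count_reads: reads on %d chromosome(s) absent from the annotation treated as no-feature: %s",
      length(unseen), paste(unseen, collapse = ", ")
    ))
  }

  blocks <- GenomicAlignments::grglist(alignments)
  if (mode == "stranded_sense" && protocol == "reverse") {
    blocks <- BiocGenerics::invertStrand(blocks)
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    blocks, features,
    ignore.strand = (mode == "unstranded")
  ))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  genes_per_read <- tabulate(q, nbins = n_reads)
  uniq <- genes_per_read[q] == 1L
  counts <- tabulate(s[uniq], nbins = length(gene_ids))

  out <- tibble(gene_id = gene_ids, count = as.integer(counts)) %>%
    right_join(tibble(gene_id = annotation$genes$gene_id), by = "gene_id") %>%
    mutate(count = coalesce(.data$count, 0L))
  attr(out, "library_size") <- n_reads
  attr(out, "n_ambiguous") <- sum(genes_per_read > 1L)
  attr(out, "n_no_feature") <- n_reads - sum(genes_per_read >= 1L)
  out
}

#' Antisense counts as the stranded/unstranded mode difference
#'
#' Natural antisense transcription is detected by comparing per-gene counts
#' produced with and without strand specificity: `AS = max(0, U - S)`. Genes
#' where the unstranded count falls below the sense count (an ambiguity
#' discrepancy between the two modes, possible when overlapping genes make a
#' read ambiguous in one mode only) are clamped at zero and reported.
#'
#' @param sense Tibble (`gene_id`, `count`) from stranded-sense counting.
#' @param unstranded Tibble (`gene_id`, `count`) from unstranded counting of
#'   the same library.
#' @return A tibble (`gene_id`, `count`) of antisense counts.
#' @export
antisense_counts <- function(sense, unstranded) {
  if (!setequal(sense$gene_id, unstranded$gene_id) ||
    nrow(sense) != nrow(unstranded)) {
    abort("antisense_counts: sense and unstranded gene universes differ")
  }
  j <- inner_join(
    sense %>% select("gene_id", sense = "count"),
    unstranded %>% select("gene_id", unstranded = "count"),
    by = "gene_id"
  )
  neg <- j %>% filter(.data$unstranded < .data$sense)
  if (nrow(neg) > 0) {
    inform(sprintf(
      "antisense_counts: %d gene(s) with unstranded < sense (residuals %s) clamped at 0",
      nrow(neg),
      paste(head(neg$unstranded - neg$sense, 5), collapse = ", ")
    ))
  }
  j %>%
    transmute(.data$gene_id, count = pmax(0L, .data$unstranded - .data$sense))
}

#' Quantify a set of stranded libraries
#'
#' Runs rRNA filtering, stranded-sense and unstranded union counting, and the
#' antisense mode-difference for each library, assembling a counts table for
#' the whole experiment.
#'
#' @param libraries A data frame with columns `library_id`, `condition`, and
#'   either `path` (SAM/BAM files) or a list column `alignments` of
#'   [GenomicAlignments::GAlignments] objects.
#' @param annotation A [genome_annotation].
#' @param protocol Library strand protocol, `"forward"` (read strand equals
#'   gene strand, the convention of forward-stranded whole-transcriptome
#'   libraries) or `"reverse"`.
#' @param rrna_refs Reference names holding rRNA sequences, removed before
#'   counting and excluded from library sizes.
#' @return A `counts_table`: list with tibbles `counts` (`gene_id`,
#'   `library_id`, `sense`, `unstranded`, `antisense`) and `libraries`
#'   (`library_id`, `condition`, `library_size`, `n_rrna_removed`,
#'   `n_ambiguous_sense`, `n_ambiguous_unstranded`).
#' @export
quantify_libraries <- function(libraries, annotation, protocol = c("forward", "reverse"),
                               rrna_refs = character()) {
  protocol <- match.arg(protocol)
  libraries <- as_tibble(libraries)
  if (!all(c("library_id", "condition") %in% names(libraries))) {
    abort("libraries must have columns library_id and condition")
  }
  if (anyDuplicated(libraries$library_id)) abort("duplicate library_id")
  if (!("path" %in% names(libraries)) && !("alignments" %in% names(libraries))) {
    abort("libraries must have a 'path' or 'alignments' column")
  }

  per_lib <- purrr::map(seq_len(nrow(libraries)), function(i) {
    aln <- if ("alignments" %in% names(libraries)) {
      libraries$alignments[[i]]
    } else {
      read_alignments(libraries$path[i])
    }
    aln <- filter_rrna(aln, rrna_refs)
    n_rrna <- S4Vectors::metadata(aln)$rrna_removed %||% 0L
    sn <- count_reads(aln, annotation, mode = "stranded_sense", protocol = protocol)
    un <- count_reads(aln, annotation, mode = "unstranded")
    as_ <- antisense_counts(sn, un)
    list(
      counts = tibble(
        gene_id = sn$gene_id,
        library_id = libraries$library_id[i],
        sense = sn$count,
        unstranded = un$count,
        antisense = as_$count[match(sn$gene_id, as_$gene_id)]
      ),
      lib = tibble(
        library_id = libraries$library_id[i],
        condition = libraries$condition[i],
        library_size = attr(sn, "library_size"),
        n_rrna_removed = n_rrna,
        n_ambiguous_sense = attr(sn, "n_ambiguous"),
        n_ambiguous_unstranded = attr(un, "n_ambiguous")
      )
    )
  })

  structure(
    list(
      counts = bind_rows(purrr::map(per_lib, "counts")),
      libraries = bind_rows(purrr::map(per_lib, "lib"))
    ),
    class = "counts_table"
  )
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf(
    "<counts_table> %d gene(s) x %d library(ies)\n",
    dplyr::n_distinct(x$counts$gene_id), nrow(x$libraries)
  ))
  print(x$libraries)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.counts_table <- function(x, ...) {
  left_join(x$counts, x$libraries, by = "library_id")
}

#' @exportS3Method generics::glance
glance.counts_table <- function(x, ...) {
  tidy(x) %>%
    group_by(.data$library_id, .data$condition) %>%
    summarise(
      library_size = .data$library_size[1],
      assigned_sense = sum(.data$sense),
      assigned_antisense = sum(.data$antisense),
      .groups = "drop"
    )
}
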