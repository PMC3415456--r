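#' Gene annotations as exon-union gene models
#'
#' A `genome_annotation` bundles stranded, possibly multi-exon gene models.
#' Internally all coordinates are 0-based half-open (`start` inclusive, `end`
#' exclusive), matching SAM/BED-adjacent interval arithmetic; GFF3/GTF input
#' is converted from its 1-based inclusive convention on read. The gene model
#' is the union of all exons of all transcripts of the gene: one expression
#' value per gene, with the exon-union length as the RPKM length term.
#'
#' @param exons A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp).
#'   When supplied, exons are validated to lie within `[0, length)`.
#'
#' @return An object of class `genome_annotation`: a list with tibbles
#'   `genes` (gene_id, chrom, strand, n_exons, union_length) and `exons`,
#'   plus `chrom_lengths`.
#' @export
genome_annotation <- function(exons, chrom_lengths = NULL) {
  exons <- as_tibble(exons)
  required <- c("gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  exons <- exons %>%
    mutate(
      gene_id = as.character(.data$gene_id),
      chrom = as.character(.data$chrom),
      strand = as.character(.data$strand),
      start = as.integer(.data$start),
      end = as.integer(.data$end)
    )
  if (any(exons$end <= exons$start)) {
    bad <- which(exons$end <= exons$start)[1]
    abort(sprintf(
      "invalid exon for gene '%s': end (%d) must exceed start (%d)",
      exons$gene_id[bad], exons$end[bad], exons$start[bad]
    ))
  }
  if (any(exons$start < 0)) abort("exon coordinates must be non-negative")
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("exon strand must be '+' or '-'")
  }
  per_gene <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      .groups = "drop"
    )
  if (any(per_gene$n_chrom > 1)) {
    abort(paste0(
      "all exons of a gene must lie on one chromosome; offending gene(s): ",
      paste(per_gene$gene_id[per_gene$n_chrom > 1], collapse = ", ")
    ))
  }
  if (any(per_gene$n_strand > 1)) {
    abort("all exons of a gene must share one strand")
  }
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[exons$chrom]
    if (anyNA(lens)) {
      abort("exon on chromosome absent from chrom_lengths")
    }
    if (any(exons$end > lens)) abort("exon extends beyond chromosome length")
  }
  genes <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      n_exons = dplyr::n(),
      union_length = union_length_1(.data$start, .data$end),
      .groups = "drop"
    )
  structure(
    list(
      genes = genes,
      exons = arrange(exons, .data$chrom, .data$start, .data$end),
      chrom_lengths = chrom_lengths
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d gene(s), %d exon(s), %d chromosome(s)\n",
    nrow(x$genes), nrow(x$exons), dplyr::n_distinct(x$exons$chrom)
  ))
  print(x$genes, n = 5)
  invisible(x)
}

# union length of one gene's exon intervals (0-based half-open)
union_length_1 <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  total <- 0L
  cur_s <- start[1]
  cur_e <- end[1]
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] > cur_e) {
        total <- total + (cur_e - cur_s)
        cur_s <- start[i]
        cur_e <- end[i]
      } else {
        cur_e <- max(cur_e, end[i])
      }
    }
  }
  as.integer(total + (cur_e - cur_s))
}

#' Exon-union length per gene
#'
#' Length of the union of a gene's exon intervals, with overlaps merged once.
#' This is the `L` (in bp) of the RPKM formula `1e9 * C / (N * L)`.
#'
#' @param annotation A [genome_annotation] (or an exon data frame with
#'   `gene_id`, `start`, `end`).
#' @return A tibble with columns `gene_id` and `union_length`.
#' @export
exon_union_length <- function(annotation) {
  exons <- if (inherits(annotation, "genome_annotation")) annotation$exons else as_tibble(annotation)
  if (nrow(exons) == 0) {
    return(tibble(gene_id = character(), union_length = integer()))
  }
  exons %>%
    group_by(.data$gene_id) %>%
    summarise(union_length = union_length_1(.data$start, .data$end), .groups = "drop")
}

#' Read a GFF3/GTF annotation into exon-union gene models
#'
#' Reads features of type `exon`, groups them by gene identifier, and converts
#' the 1-based inclusive file coordinates to the package's 0-based half-open
#' convention. Both GTF key-value attributes and GFF3 `ID=`/`Parent=` dialects
#' are accepted: the `id_attribute` column is used when present, falling back
#' to `Parent` then `ID` for GFF3 input. Gene-typed features with no exon
#' children are omitted with a warning.
#'
#' @param path Path to a GFF3 or GTF file (format detected from extension by
#'   [rtracklayer::import()]).
#' @param id_attribute Attribute naming the gene a feature belongs to
#'   (default `"gene_id"`).
#' @return A [genome_annotation].
#' @export
read_annotation <- function(path, id_attribute = "gene_id") {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(genome_annotation(tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer()
    )))
  }
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) abort(paste0("failed to parse annotation '", path, "': ", conditionMessage(e)))
  )
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0) {
    warn("annotation contains no exon features; returning an empty annotation")
    return(genome_annotation(tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer()
    )))
  }
  ids <- feature_gene_ids(ex, id_attribute)
  exons <- tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L, # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(ex)
  )
  if (any(exons$strand == "*")) abort("exon feature without strand")
  gene_feats <- gr[type == "gene"]
  if (length(gene_feats) > 0) {
    gene_ids <- feature_gene_ids(gene_feats, id_attribute, allow_id = TRUE)
    orphan <- setdiff(gene_ids, unique(ids))
    if (length(orphan) > 0) {
      warn(sprintf(
        "%d gene feature(s) with no exon children omitted: %s",
        length(orphan), paste(head(orphan, 5), collapse = ", ")
      ))
    }
  }
  chrom_lengths <- NULL
  sl <- GenomeInfoDb::seqlengths(gr)
  if (!is.null(sl) && !all(is.na(sl))) chrom_lengths <- sl[!is.na(sl)]
  genome_annotation(exons, chrom_lengths)
}

feature_gene_ids <- function(gr, id_attribute, allow_id = FALSE) {
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (!col %in% names(mc)) return(NULL)
    v <- mc[[col]]
    if (is(v, "List") || is.list(v)) {
      v <- vapply(as.list(v), function(x) if (length(x) == 0) NA_character_ else as.character(x[[1]]), character(1))
    }
    v <- as.character(v)
    if (all(is.na(v))) NULL else v
  }
  ids <- pick(id_attribute)
  if (is.null(ids)) ids <- pick("Parent")
  if (is.null(ids) && (allow_id || TRUE)) ids <- pick("ID")
  if (is.null(ids)) {
    abort(sprintf(
      "no usable gene identifier: attribute '%s' (or Parent/ID) absent from features",
      id_attribute
    ))
  }
  if (anyNA(ids)) abort("feature without gene identifier")
  ids
}

#' Write an annotation back to GTF
#'
#' Emits one `exon` feature per stored exon, converting internal 0-based
#' half-open coordinates back to 1-based inclusive. `read_annotation()` on the
#' written file round-trips to the identical gene models.
#'
#' @param annotation A [genome_annotation].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand,
    type = "exon",
    source = "strawdeg",
    gene_id = ex$gene_id,
    transcript_id = paste0(ex$gene_id, ".t1")
  )
  if (!is.null(annotation$chrom_lengths)) {
    GenomeInfoDb::seqlengths(gr) <-
      annotation$chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Summarise an annotation as a tibble
#'
#' One row per gene: chromosome, strand, exon count, exon-union length, and
#' (when a category map is supplied) the comma-joined category labels.
#'
#' @param annotation A [genome_annotation].
#' @param categories Optional category map tibble (`gene_id`, `family`), as
#'   returned by [read_category_map()].
#' @return A tibble.
#' @export
annotation_summary <- function(annotation, categories = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  out <- annotation$genes
  if (!is.null(categories)) {
    cat_str <- categories %>%
      group_by(.data$gene_id) %>%
      summarise(categories = paste(sort(unique(.data$family)), collapse = ","), .groups = "drop")
    out <- left_join(out, cat_str, by = "gene_id")
  }
  out
}

# GRangesList of reduced exons per gene, for overlap counting
annotation_features <- function(annotation) {
  ex <- annotation$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  grl <- S4Vectors::split(gr, ex$gene_id)
  GenomicRanges::reduce(grl)
}

#' @exportS3Method generics::tidy
tidy.genome_annotation <- function(x, ...) x$genes
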