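#' Reads per kilobase of exon model per million mapped reads
#'
#' `RPKM = 1e9 * C / (N * L)` for read count `C`, library size `N` (mapped,
#' rRNA-filtered reads) and exon-union length `L` in bp. Vectorised over
#' genes; `C` recycles against `L`.
#'
#' @param count Non-negative read count(s).
#' @param library_size Total mapped, rRNA-filtered reads in the library.
#' @param length Exon-union length(s) in bp.
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(100, 1e6, 1000) # 100
#' @export
rpkm <- function(count, library_size, length) {
  if (any(library_size <= 0)) abort("rpkm: library_size must be positive")
  if (any(length <= 0)) abort("rpkm: gene length must be positive (annotation error)")
  if (any(count < 0)) abort("rpkm: counts must be non-negative")
  1e9 * as.numeric(count) / (as.numeric(library_size) * as.numeric(length))
}

#' Per-gene expression table from counts
#'
#' Converts a counts table into sense and antisense RPKM values. In
#' `"combined"` pooling, counts and library sizes of a condition's replicates
#' are summed before the RPKM formula is applied (the RPKM of the pooled
#' mapping, not the mean of replicate RPKMs); `"per_library"` keeps one row
#' per replicate. Antisense RPKM uses the same exon-union length and the same
#' library denominator as sense RPKM.
#'
#' @param counts A `counts_table` from [quantify_libraries()].
#' @param annotation A [genome_annotation].
#' @param pooling `"combined"` or `"per_library"`.
#' @return An `expression_table` tibble: `gene_id`, `condition`
#'   (and `library_id` for per-library pooling), `sense_rpkm`,
#'   `antisense_rpkm`; the per-condition total mapped reads are in
#'   `attr(x, "sizes")`.
#' @export
build_expression_table <- function(counts, annotation,
                                   pooling = c("combined", "per_library")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(counts, "counts_table"), inherits(annotation, "genome_annotation"))
  if (anyNA(counts$libraries$condition)) abort("every library needs a condition label")
  lens <- exon_union_length(annotation)
  long <- tidy(counts)

  if (pooling == "combined") {
    sizes <- counts$libraries %>%
      group_by(.data$condition) %>%
      summarise(total_mapped_reads = sum(.data$library_size), .groups = "drop")
    if (any(sizes$total_mapped_reads == 0)) {
      abort(paste0(
        "condition(s) with zero total mapped reads: ",
        paste(sizes$condition[sizes$total_mapped_reads == 0], collapse = ", ")
      ))
    }
    out <- long %>%
      group_by(.data$gene_id, .data$condition) %>%
      summarise(
        sense = sum(.data$sense),
        antisense = sum(.data$antisense),
        .groups = "drop"
      ) %>%
      left_join(sizes, by = "condition") %>%
      left_join(lens, by = "gene_id") %>%
      transmute(
        .data$gene_id, .data$condition,
        sense_rpkm = rpkm(.data$sense, .data$total_mapped_reads, .data$union_length),
        antisense_rpkm = rpkm(.data$antisense, .data$total_mapped_reads, .data$union_length),
        sense_count = .data$sense,
        antisense_count = .data$antisense
      )
  } else {
    if (any(counts$libraries$library_size == 0)) abort("library with zero mapped reads")
    sizes <- counts$libraries %>%
      select("library_id", "condition", total_mapped_reads = "library_size")
    out <- long %>%
      left_join(lens, by = "gene_id") %>%
      transmute(
        .data$gene_id, .data$library_id, .data$condition,
        sense_rpkm = rpkm(.data$sense, .data$library_size, .data$union_length),
        antisense_rpkm = rpkm(.data$antisense, .data$library_size, .data$union_length),
        sense_count = .data$sense,
        antisense_count = .data$antisense
      )
  }
  structure(out,
    class = c("expression_table", class(out)),
    pooling = pooling, sizes = sizes
  )
}

#' Inter-replicate reproducibility
#'
#' Squared Pearson correlation of `log2(RPKM + 1)` across genes between two
#' replicate expression vectors. Anti-correlated vectors also give a value of
#' 1: this is R-squared of the correlation, not of a constrained slope-1 fit.
#'
#' @param expr_a,expr_b Per-gene RPKM vectors over the same genes (length
#'   >= 3).
#' @return A single R-squared value, or `NA` (with a warning) when either
#'   log-vector has zero variance.
#' @export
replicate_r_squared <- function(expr_a, expr_b) {
  if (length(expr_a) != length(expr_b)) abort("expression vectors differ in length")
  if (length(expr_a) < 3) abort("need at least 3 genes")
  a <- log2(expr_a + 1)
  b <- log2(expr_b + 1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warn("replicate_r_squared: zero variance; R-squared undefined")
    return(NA_real_)
  }
  cor(a, b)^2
}

#' All pairwise replicate R-squared values within conditions
#'
#' @param expr A per-library `expression_table`.
#' @param measure `"sense_rpkm"` (default) or `"antisense_rpkm"`.
#' @return A tibble `condition`, `library_a`, `library_b`, `r_squared`.
#' @export
replicate_correlations <- function(expr, measure = "sense_rpkm") {
  stopifnot(inherits(expr, "expression_table"))
  if (!"library_id" %in% names(expr)) {
    abort("replicate_correlations needs a per-library expression table")
  }
  wide <- expr %>%
    select("gene_id", "library_id", "condition", value = all_of(measure)) %>%
    arrange(.data$gene_id)
  conds <- unique(wide$condition)
  out <- purrr::map(conds, function(cc) {
    sub <- wide %>% filter(.data$condition == cc)
    libs <- unique(sub$library_id)
    if (length(libs) < 2) return(NULL)
    pairs <- utils::combn(libs, 2, simplify = FALSE)
    purrr::map(pairs, function(p) {
      va <- sub$value[sub$library_id == p[1]]
      vb <- sub$value[sub$library_id == p[2]]
      tibble(
        condition = cc, library_a = p[1], library_b = p[2],
        r_squared = replicate_r_squared(va, vb)
      )
    }) %>% bind_rows()
  })
  bind_rows(out)
}

#' @exportS3Method generics::glance
glance.expression_table <- function(x, ...) {
  x %>%
    group_by(across(any_of(c("condition", "library_id")))) %>%
    summarise(
      n_genes = dplyr::n(),
      total_sense_rpkm = sum(.data$sense_rpkm),
      n_antisense_expressed = sum(.data$antisense_rpkm > 1),
      .groups = "drop"
    )
}
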