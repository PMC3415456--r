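#' Summarise antisense transcription per condition
#'
#' Computes the antisense read fraction per condition (pooled antisense
#' counts over pooled mapped reads, exactly `sum(AS) / sum(N)`) and lists the
#' genes whose antisense RPKM exceeds `theta_as` in at least one condition.
#'
#' @param counts A `counts_table`.
#' @param expr A combined-pooling `expression_table` over the same genes.
#' @param theta_as Antisense RPKM threshold for the gene list (default 1).
#' @return An `antisense_summary`: list with `fractions` (per condition:
#'   `as_reads`, `total_reads`, `as_fraction`) and `genes` (`gene_id`,
#'   `max_as_rpkm`, sorted decreasing).
#' @export
antisense_summary <- function(counts, expr, theta_as = 1) {
  stopifnot(inherits(counts, "counts_table"))
  expr <- as_tibble(expr)
  if (!setequal(unique(counts$counts$gene_id), unique(expr$gene_id))) {
    abort("counts and expression tables cover different genes")
  }
  fractions <- tidy(counts) %>%
    group_by(.data$condition) %>%
    summarise(
      as_reads = sum(.data$antisense),
      total_reads = sum(.data$library_size[!duplicated(.data$library_id)]),
      .groups = "drop"
    ) %>%
    mutate(as_fraction = ifelse(.data$total_reads > 0, .data$as_reads / .data$total_reads, 0))
  genes <- expr %>%
    group_by(.data$gene_id) %>%
    summarise(max_as_rpkm = max(.data$antisense_rpkm), .groups = "drop") %>%
    filter(.data$max_as_rpkm > theta_as) %>%
    arrange(desc(.data$max_as_rpkm))
  structure(list(fractions = fractions, genes = genes, theta_as = theta_as),
    class = "antisense_summary"
  )
}

#' @export
print.antisense_summary <- function(x, ...) {
  cat("<antisense_summary>\n")
  print(x$fractions)
  cat(sprintf("%d gene(s) with antisense RPKM > %g\n", nrow(x$genes), x$theta_as))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.antisense_summary <- function(x, ...) x$fractions

#' Antisense-to-sense expression ratios per gene and condition
#'
#' For the genes whose antisense RPKM exceeds `theta_as` in at least one of
#' the two conditions, computes the ratio `rho = AS / S` per condition. A
#' sense RPKM of zero leaves the ratio undefined (`NA` with
#' `ratio_defined = FALSE`), never a division error; zero antisense gives a
#' ratio of 0.
#'
#' @param expr A combined-pooling `expression_table`.
#' @param conditions Character vector of exactly two condition labels.
#' @param theta_as Antisense RPKM threshold for inclusion (default 1).
#' @return An `antisense_records` tibble: `gene_id`, `condition`,
#'   `sense_rpkm`, `antisense_rpkm`, `ratio`, `ratio_defined`.
#' @export
as_s_ratios <- function(expr, conditions, theta_as = 1) {
  expr <- as_tibble(expr)
  if (length(conditions) != 2) abort("conditions must name exactly two conditions")
  if (!all(conditions %in% expr$condition)) abort("condition absent from expression table")
  sub <- expr %>% filter(.data$condition %in% conditions)
  keep <- sub %>%
    group_by(.data$gene_id) %>%
    summarise(max_as = max(.data$antisense_rpkm), .groups = "drop") %>%
    filter(.data$max_as > theta_as)
  out <- sub %>%
    filter(.data$gene_id %in% keep$gene_id) %>%
    mutate(
      ratio_defined = .data$sense_rpkm > 0,
      ratio = ifelse(.data$sense_rpkm > 0, .data$antisense_rpkm / .data$sense_rpkm, NA_real_)
    ) %>%
    select(
      "gene_id", "condition", "sense_rpkm", "antisense_rpkm",
      "ratio", "ratio_defined"
    ) %>%
    arrange(.data$gene_id, .data$condition)
  structure(out, class = c("antisense_records", class(out)), theta_as = theta_as)
}

#' Detect antisense:sense ratio switches between conditions
#'
#' A gene switches when antisense expression predominates in `cond_a`
#' (`rho > 1`), sense predominates in `cond_b` (`rho < 1`), and the sense
#' transcript is induced in `cond_b` by at least `min_sense_induction`-fold
#' over `cond_a`. Genes with an undefined ratio in either condition are
#' excluded with a message.
#'
#' @param records An `antisense_records` tibble from [as_s_ratios()].
#' @param cond_a Condition where antisense dominates (e.g. repressing).
#' @param cond_b Condition where sense is induced.
#' @param min_sense_induction Minimum sense RPKM fold `cond_b / cond_a`
#'   (default 20).
#' @return A tibble of switch genes with their per-condition sense/antisense
#'   RPKMs, ratios, and the sense fold change.
#' @export
detect_ratio_switch <- function(records, cond_a, cond_b, min_sense_induction = 20) {
  records <- as_tibble(records)
  if (!all(c(cond_a, cond_b) %in% records$condition)) {
    abort("cond_a/cond_b absent from the records")
  }
  wide <- records %>%
    filter(.data$condition %in% c(cond_a, cond_b)) %>%
    pivot_wider(
      id_cols = "gene_id", names_from = "condition",
      values_from = c("sense_rpkm", "antisense_rpkm", "ratio", "ratio_defined")
    )
  ra <- wide[[paste0("ratio_", cond_a)]]
  rb <- wide[[paste0("ratio_", cond_b)]]
  da <- wide[[paste0("ratio_defined_", cond_a)]]
  db <- wide[[paste0("ratio_defined_", cond_b)]]
  undef <- !(da & db)
  if (any(undef)) {
    inform(sprintf(
      "detect_ratio_switch: %d gene(s) with undefined ratio excluded", sum(undef)
    ))
  }
  sa <- wide[[paste0("sense_rpkm_", cond_a)]]
  sb <- wide[[paste0("sense_rpkm_", cond_b)]]
  sense_fold <- ifelse(sa > 0, sb / sa, Inf)
  hit <- !undef & ra > 1 & rb < 1 & sense_fold >= min_sense_induction
  wide %>%
    mutate(sense_fold = sense_fold, is_switch = hit) %>%
    filter(.data$is_switch) %>%
    select(-"is_switch")
}
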