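#' Read a gene-to-category map
#'
#' Two-column TSV (`gene_id`, `family`, e.g. `GH7`); the enzyme class (`GH`,
#' `CE`, `PL`, ...) is inferred from the family's alphabetic prefix. A gene
#' may carry several families (several rows); genes absent from the map are
#' simply uncategorised.
#'
#' @param path TSV path with a header line.
#' @return A tibble `gene_id`, `family`, `class`.
#' @export
read_category_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene_id", "family") %in% names(df))) {
    abort("category map must have columns gene_id and family")
  }
  category_map(df)
}

#' @rdname read_category_map
#' @param df A data frame with `gene_id` and `family` columns.
#' @export
category_map <- function(df) {
  df <- as_tibble(df) %>%
    mutate(
      gene_id = as.character(.data$gene_id),
      family = gsub("\\s+", "", as.character(.data$family)),
      class = toupper(sub("^([A-Za-z]+).*$", "\\1", .data$family))
    ) %>%
    distinct(.data$gene_id, .data$family, .keep_all = TRUE)
  bad <- df %>%
    group_by(.data$family) %>%
    summarise(n_class = dplyr::n_distinct(.data$class), .groups = "drop") %>%
    filter(.data$n_class > 1)
  if (nrow(bad) > 0) abort("a family maps to more than one class")
  df
}

#' Percent of total mRNA held by a gene set
#'
#' `100 * sum(RPKM over the set) / sum(RPKM over all genes)` in one
#' condition. RPKM is proportional to molar transcript abundance, so this is
#' the set's share of the mRNA population. The denominator covers every gene
#' in the expression table, categorised or not.
#'
#' @param expr A combined-pooling `expression_table` (or compatible tibble).
#' @param gene_set Character vector of gene ids (need not all be expressed).
#' @param condition Condition label.
#' @return A single percentage.
#' @export
percent_of_transcriptome <- function(expr, gene_set, condition) {
  expr <- as_tibble(expr)
  sub <- expr %>% filter(.data$condition == !!condition)
  if (nrow(sub) == 0) abort("condition absent from expression table")
  total <- sum(sub$sense_rpkm)
  if (total <= 0) abort("empty transcriptome: total RPKM is zero")
  100 * sum(sub$sense_rpkm[sub$gene_id %in% gene_set]) / total
}

#' Per-family shares of the categorised mRNA
#'
#' Shares of each category family within the total mRNA of all categorised
#' genes, in one condition, sorted in decreasing order of expression (ties
#' broken lexicographically by family). Shares sum to 100.
#'
#' @param expr A combined-pooling `expression_table`.
#' @param categories A category map tibble (`gene_id`, `family`).
#' @param condition Condition label.
#' @return A tibble `family`, `class`, `rpkm`, `share_pct`, ordered
#'   decreasing.
#' @export
family_shares <- function(expr, categories, condition) {
  expr <- as_tibble(expr)
  categories <- category_map(categories)
  if (nrow(categories) == 0) abort("empty category map")
  sub <- expr %>% filter(.data$condition == !!condition)
  per_fam <- categories %>%
    inner_join(sub, by = "gene_id") %>%
    group_by(.data$family, .data$class) %>%
    summarise(rpkm = sum(.data$sense_rpkm), .groups = "drop")
  total <- sum(per_fam$rpkm)
  if (total <= 0) {
    return(per_fam %>% mutate(share_pct = 0) %>% arrange(.data$family))
  }
  per_fam %>%
    mutate(share_pct = 100 * .data$rpkm / total) %>%
    arrange(desc(.data$share_pct), .data$family)
}

#' One gene's share of a gene set's mRNA
#'
#' `100 * RPKM(gene) / sum(RPKM over the set)` in one condition.
#'
#' @inheritParams percent_of_transcriptome
#' @param gene A gene id belonging to `gene_set`.
#' @return A single percentage.
#' @export
gene_share_of_set <- function(expr, gene, gene_set, condition) {
  if (!gene %in% gene_set) abort("gene must belong to gene_set")
  expr <- as_tibble(expr)
  sub <- expr %>%
    filter(.data$condition == !!condition, .data$gene_id %in% gene_set)
  total <- sum(sub$sense_rpkm)
  if (total <= 0) abort("gene set has zero total RPKM")
  100 * sum(sub$sense_rpkm[sub$gene_id == gene]) / total
}

#' Transcriptome summary across scopes
#'
#' Percent-of-transcriptome for the whole categorised set, each class, and
#' each family, plus each categorised gene's share of its set, in one tidy
#' table per condition.
#'
#' @param expr A combined-pooling `expression_table`.
#' @param categories A category map tibble.
#' @return A tibble `condition`, `scope` (`category_set`/`class`/`family`),
#'   `label`, `percent`.
#' @export
functional_summary <- function(expr, categories) {
  expr <- as_tibble(expr)
  categories <- category_map(categories)
  conds <- unique(expr$condition)
  purrr::map(conds, function(cc) {
    set_pct <- percent_of_transcriptome(expr, unique(categories$gene_id), cc)
    fam <- family_shares(expr, categories, cc)
    by_class <- fam %>%
      group_by(.data$class) %>%
      summarise(share_pct = sum(.data$share_pct), .groups = "drop")
    bind_rows(
      tibble(condition = cc, scope = "category_set", label = "all", percent = set_pct),
      tibble(
        condition = cc, scope = "class",
        label = by_class$class, percent = by_class$share_pct
      ),
      tibble(
        condition = cc, scope = "family",
        label = fam$family, percent = fam$share_pct
      )
    )
  }) %>% bind_rows()
}
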