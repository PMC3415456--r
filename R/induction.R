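#' Induction filter: fold change, expression floor, and significance
#'
#' Reproduces the strongly-induced gene-list rule: a gene passes when its
#' expression in the target condition is at least `fold_threshold` times the
#' baseline, its target RPKM is at least `rpkm_threshold`, and (when a test
#' table is supplied) all three count-based tests give `p < alpha`. A
#' baseline RPKM of exactly zero with a target RPKM above the expression
#' floor satisfies the fold criterion with an infinite reported fold change
#' (the zero-baseline policy). When `tests` is `NULL` the filter applies the
#' two expression criteria alone, which is how it is applied to published
#' RPKM tables that carry no count information; when `tests` is supplied,
#' genes missing from it are skipped with a warning.
#'
#' @param expr A combined-pooling `expression_table`, or any tibble with
#'   `gene_id`, `condition`, `sense_rpkm`.
#' @param baseline,target Condition labels (fold change is target/baseline).
#' @param tests Optional tibble from [de_test()] (`gene_id`, `p_lrt`,
#'   `p_fisher`, `p_mars`).
#' @param fold_threshold Minimum induction fold (default 20; must be > 1).
#' @param rpkm_threshold Minimum target-condition RPKM (default 50).
#' @param alpha Significance level applied to each of the three tests
#'   (default 0.001).
#' @param adjust `"none"` (default, raw p-values as in the original gene
#'   lists) or `"BH"` for Benjamini-Hochberg adjustment of each test column
#'   before thresholding.
#' @return A `de_result` tibble: `gene_id`, `rpkm_baseline`, `rpkm_target`,
#'   `fold_change`, the three p-values (NA when `tests` is `NULL`), and
#'   `passes_filter`.
#' @export
apply_induction_filter <- function(expr, baseline, target, tests = NULL,
                                   fold_threshold = 20, rpkm_threshold = 50,
                                   alpha = 0.001, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!(fold_threshold > 1)) abort("fold_threshold must exceed 1")
  if (!(rpkm_threshold > 0)) abort("rpkm_threshold must be positive")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  expr <- as_tibble(expr)
  if (!all(c(baseline, target) %in% expr$condition)) {
    abort("expression table lacks the baseline or target condition")
  }
  wide <- expr %>%
    filter(.data$condition %in% c(baseline, target)) %>%
    select("gene_id", "condition", "sense_rpkm") %>%
    pivot_wider(names_from = "condition", values_from = "sense_rpkm") %>%
    rename(rpkm_baseline = all_of(baseline), rpkm_target = all_of(target))

  out <- wide %>%
    mutate(
      fold_change = ifelse(.data$rpkm_baseline == 0, Inf,
        .data$rpkm_target / .data$rpkm_baseline
      ),
      fold_ok = (.data$rpkm_baseline == 0 & .data$rpkm_target >= rpkm_threshold) |
        (.data$rpkm_baseline > 0 & .data$fold_change >= fold_threshold),
      expr_ok = .data$rpkm_target >= rpkm_threshold
    )

  if (is.null(tests)) {
    out <- out %>%
      mutate(
        p_lrt = NA_real_, p_fisher = NA_real_, p_mars = NA_real_,
        passes_filter = .data$fold_ok & .data$expr_ok
      )
  } else {
    tests <- as_tibble(tests) %>% select("gene_id", "p_lrt", "p_fisher", "p_mars")
    if (adjust == "BH") {
      tests <- tests %>% mutate(across(c("p_lrt", "p_fisher", "p_mars"), ~ stats::p.adjust(.x, "BH")))
    }
    missing_tests <- setdiff(out$gene_id, tests$gene_id[stats::complete.cases(tests)])
    if (length(missing_tests) > 0) {
      warn(sprintf(
        "%d gene(s) without a complete p-value triple skipped: %s",
        length(missing_tests), paste(head(missing_tests, 5), collapse = ", ")
      ))
      out <- out %>% filter(!.data$gene_id %in% missing_tests)
    }
    out <- out %>%
      left_join(tests, by = "gene_id") %>%
      mutate(
        passes_filter = .data$fold_ok & .data$expr_ok &
          pmax(.data$p_lrt, .data$p_fisher, .data$p_mars) < alpha
      )
  }
  out <- out %>% select(-"fold_ok", -"expr_ok")
  structure(out,
    class = c("de_result", class(out)),
    baseline = baseline, target = target,
    fold_threshold = fold_threshold, rpkm_threshold = rpkm_threshold,
    alpha = alpha
  )
}

#' @exportS3Method generics::tidy
tidy.de_result <- function(x, ...) as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  tibble(
    baseline = attr(x, "baseline"),
    target = attr(x, "target"),
    n_genes = nrow(x),
    n_passing = sum(x$passes_filter),
    fold_threshold = attr(x, "fold_threshold"),
    rpkm_threshold = attr(x, "rpkm_threshold"),
    alpha = attr(x, "alpha")
  )
}
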