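#' Pipeline run configuration
#'
#' Collects the paths, labels and thresholds of one end-to-end run. All
#' stages of [run_pipeline()] are pure functions of this configuration and
#' the input files.
#'
#' @param annotation Path to a GFF3/GTF annotation.
#' @param libraries A data frame (`library_id`, `condition`, `path`) or the
#'   path of a TSV holding those columns.
#' @param out_dir Output directory for stage tables and the manifest.
#' @param baseline,target Condition labels compared by the induction filter.
#' @param categories Optional gene-to-family TSV path (or tibble).
#' @param protocol Library strand protocol (`"forward"`/`"reverse"`).
#' @param rrna_refs Reference names filtered out as rRNA.
#' @param id_attribute Gene-id attribute in the annotation.
#' @param fold_threshold,rpkm_threshold,alpha Induction-filter thresholds.
#' @param theta_as Antisense RPKM threshold.
#' @param min_sense_induction Sense fold required for a ratio switch.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(annotation, libraries, out_dir,
                            baseline, target,
                            categories = NULL,
                            protocol = "forward",
                            rrna_refs = character(),
                            id_attribute = "gene_id",
                            fold_threshold = 20, rpkm_threshold = 50,
                            alpha = 0.001, theta_as = 1,
                            min_sense_induction = 20) {
  cfg <- as.list(environment())
  if (!file.exists(cfg$annotation)) {
    abort(paste0("config error: annotation path not found: ", cfg$annotation))
  }
  if (is.character(cfg$libraries) && length(cfg$libraries) == 1) {
    if (!file.exists(cfg$libraries)) {
      abort(paste0("config error: library sheet not found: ", cfg$libraries))
    }
    cfg$libraries <- readr::read_tsv(cfg$libraries, col_types = readr::cols())
  }
  cfg$libraries <- as_tibble(cfg$libraries)
  if (!all(c("library_id", "condition", "path") %in% names(cfg$libraries))) {
    abort("config error: libraries need library_id, condition, path")
  }
  miss <- cfg$libraries$path[!file.exists(cfg$libraries$path)]
  if (length(miss) > 0) {
    abort(paste0("config error: alignment file(s) missing: ", paste(miss, collapse = ", ")))
  }
  if (!all(c(cfg$baseline, cfg$target) %in% cfg$libraries$condition)) {
    abort("config error: baseline/target condition not present in the library sheet")
  }
  if (is.character(cfg$categories) && length(cfg$categories) == 1) {
    cfg$categories <- read_category_map(cfg$categories)
  }
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  inform(sprintf(
    "[%s] done in %.1fs", name,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  res
}

#' Run the full quantification, DE, antisense and summary pipeline
#'
#' count -> rpkm -> de -> antisense -> summarise, writing every stage's
#' output as TSV under the configured output directory plus a manifest of
#' outputs with MD5 checksums. Re-running with identical inputs reproduces
#' identical checksums.
#'
#' @param config A [pipeline_config()].
#' @return A list of stage results (`annotation`, `counts`, `expression`,
#'   `expression_per_library`, `de`, `antisense`, `records`, `switches`,
#'   `summary`) plus the `manifest` tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ann <- stage("annotation", read_annotation(config$annotation, config$id_attribute))
  counts <- stage("count", quantify_libraries(
    config$libraries, ann,
    protocol = config$protocol, rrna_refs = config$rrna_refs
  ))
  expr <- stage("rpkm", build_expression_table(counts, ann, pooling = "combined"))
  expr_lib <- stage("rpkm_per_library", build_expression_table(counts, ann, pooling = "per_library"))
  tests <- stage("de_tests", de_test(counts, config$baseline, config$target))
  de <- stage("induction_filter", apply_induction_filter(
    expr, config$baseline, config$target,
    tests = tests,
    fold_threshold = config$fold_threshold,
    rpkm_threshold = config$rpkm_threshold,
    alpha = config$alpha
  ))
  asum <- stage("antisense_summary", antisense_summary(counts, expr, theta_as = config$theta_as))
  records <- stage("as_s_ratios", as_s_ratios(
    expr, c(config$baseline, config$target),
    theta_as = config$theta_as
  ))
  switches <- stage("ratio_switches", detect_ratio_switch(
    records, config$baseline, config$target,
    min_sense_induction = config$min_sense_induction
  ))
  fsum <- if (!is.null(config$categories)) {
    stage("functional_summary", functional_summary(expr, config$categories))
  } else {
    NULL
  }

  outputs <- list(
    counts = tidy(counts),
    library_stats = counts$libraries,
    expression_combined = as_tibble(expr),
    expression_per_library = as_tibble(expr_lib),
    de_results = tidy(de),
    antisense_fractions = asum$fractions,
    antisense_genes = asum$genes,
    antisense_records = as_tibble(records),
    ratio_switches = as_tibble(switches)
  )
  if (!is.null(fsum)) outputs$functional_summary <- fsum

  files <- purrr::imap_chr(outputs, function(df, nm) {
    path <- file.path(config$out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(df, path)
    path
  })
  manifest <- tibble(
    output = names(files),
    path = unname(files),
    n_rows = purrr::map_int(outputs, nrow),
    md5 = unname(tools::md5sum(unname(files)))
  )
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  inform(sprintf("pipeline complete: %d output table(s) in %s", nrow(manifest), config$out_dir))

  list(
    annotation = ann, counts = counts, expression = expr,
    expression_per_library = expr_lib, tests = tests, de = de,
    antisense = asum, records = records, switches = switches,
    summary = fsum, manifest = manifest
  )
}
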