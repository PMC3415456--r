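#' Simulation configuration for stranded RNA-seq of an induction experiment
#'
#' Defines the study conditions the generator emulates: triplicate stranded
#' 50-bp single-end libraries over a repressing (glucose-like) and an
#' inducing (straw-like) condition, a strongly induced gene subset spanning
#' 20-4000-fold, a CAZy-like category program with condition-specific mRNA
#' shares and one dominant gene under repression, an unspliced
#' natural-antisense program holding 2% of countable reads with a few
#' antisense:sense ratio-switch genes, and a residual rRNA read fraction.
#' All randomness flows from `seed`.
#'
#' @param seed Integer seed driving every draw.
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes genes are packed onto.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of the
#'   exon-union length (bp; floored at 200).
#' @param exon_count_probs Probabilities of 1..k exons per gene.
#' @param intron_length_range Intron length range (bp, uniform; >= 20).
#' @param conditions Condition labels; first is the baseline, second the
#'   induced condition.
#' @param replicates Replicates per condition.
#' @param library_size Expected reads per replicate (Poisson).
#' @param read_length Read length (bp).
#' @param baseline_sdlog Log-normal sd of the transcript-abundance draft.
#' @param induced_fraction Fraction of genes planted as induced.
#' @param induced_baseline_rpkm `c(meanlog, sdlog)` of the induced genes'
#'   baseline RPKM (repressed hydrolase-like expression).
#' @param fold_range Planted induction fold range (applied in transcript
#'   abundance space before renormalisation; ground truth records realised
#'   folds).
#' @param category_fraction Fraction of genes carrying a category label.
#' @param category_families Family label pool (class = alphabetic prefix).
#' @param category_share Named per-condition target share of total mRNA held
#'   by the category set.
#' @param dominant_gene_share Dominant gene's share of category mRNA in the
#'   baseline condition (a glucoamylase-like gene).
#' @param induced_category_fraction Fraction of induced genes drawn from the
#'   category set.
#' @param as_gene_fraction Fraction of genes with an antisense program.
#' @param as_read_fraction Target countable antisense read fraction of
#'   mapped, rRNA-filtered reads per condition.
#' @param n_switch_genes Number of induced genes whose antisense dominates in
#'   the baseline condition (ratio switch).
#' @param switch_ratio_range Baseline-condition antisense:sense RPKM ratio
#'   range for switch genes.
#' @param switch_as_reduction Multiplier on switch genes' antisense RPKM in
#'   the induced condition.
#' @param as_flank Flank (bp) by which unspliced antisense transcripts extend
#'   beyond the gene on both sides.
#' @param rrna_fraction Fraction of reads from rRNA (on a dedicated contig,
#'   removed by [filter_rrna()]).
#' @param gene_gap_range Intergenic gap range (bp); kept wide enough that
#'   antisense flanks never reach a neighbouring gene.
#' @param overlapping_pair If `TRUE`, the last two genes are placed
#'   overlapping on opposite strands (for ambiguity tests); they are excluded
#'   from the induction/antisense programs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 300L,
                       n_chroms = 4L,
                       gene_length_meanlog = log(1400),
                       gene_length_sdlog = 0.35,
                       exon_count_probs = c(0.35, 0.30, 0.20, 0.15),
                       intron_length_range = c(50L, 300L),
                       conditions = c("glucose_48h", "straw_24h"),
                       replicates = 3L,
                       library_size = 2e6,
                       read_length = 50L,
                       baseline_sdlog = 1.1,
                       induced_fraction = 0.15,
                       induced_baseline_rpkm = c(meanlog = log(3), sdlog = 0.6),
                       fold_range = c(20, 4000),
                       category_fraction = 0.15,
                       category_families = c(
                         "GH7", "GH61", "GH11", "GH62", "CE1", "GH3", "GH10",
                         "GH6", "GH12", "GH5", "GH43", "GH31", "CE16", "PL4"
                       ),
                       category_share = c(glucose_48h = 0.03, straw_24h = 0.19),
                       dominant_gene_share = 0.65,
                       induced_category_fraction = 0.75,
                       as_gene_fraction = 0.10,
                       as_read_fraction = 0.02,
                       n_switch_genes = 4L,
                       switch_ratio_range = c(2, 4),
                       switch_as_reduction = 0.3,
                       as_flank = 100L,
                       rrna_fraction = 0.05,
                       gene_gap_range = c(300L, 800L),
                       overlapping_pair = FALSE) {
  cfg <- as.list(environment())
  if (length(cfg$conditions) != 2) abort("exactly two conditions are supported")
  fracs <- c(
    cfg$induced_fraction, cfg$category_fraction, cfg$as_gene_fraction,
    cfg$as_read_fraction, cfg$rrna_fraction, cfg$category_share
  )
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$fold_range[1] < 1) abort("fold range must be >= 1")
  if (cfg$library_size <= 0) abort("library_size must be positive")
  if (any(cfg$intron_length_range < 20)) abort("introns must be >= 20 bp")
  if (min(cfg$gene_gap_range) < cfg$as_flank + cfg$read_length + 10) {
    abort("gene gaps must exceed as_flank + read_length so antisense reads stay unambiguous")
  }
  structure(cfg, class = "sim_config")
}

# run expr with a locally-seeded RNG, restoring global state afterwards
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a toy genome annotation with planted gene programs
#'
#' Packs non-overlapping multi-exon gene models onto chromosomes, assigns
#' category labels, and selects the induced, antisense and ratio-switch gene
#' sets. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list: `annotation` ([genome_annotation]), `categories` (tibble),
#'   `genes` (per-gene metadata incl. locus bounds and role flags),
#'   `rrna_refs` (name of the rRNA contig).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, generate_annotation_impl(config))
}

generate_annotation_impl <- function(cfg) {
  n <- cfg$n_genes
  if (n == 0) {
    ann <- genome_annotation(tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer()
    ), chrom_lengths = c(rRNA_1 = 5000L))
    return(list(
      annotation = ann, categories = tibble(gene_id = character(), family = character()),
      genes = tibble(gene_id = character()), rrna_refs = "rRNA_1"
    ))
  }
  ids <- sprintf("gene%03d", seq_len(n))
  k_exons <- sample(seq_along(cfg$exon_count_probs), n, replace = TRUE, prob = cfg$exon_count_probs)
  union_len <- pmax(200L, as.integer(round(rlnorm(n, cfg$gene_length_meanlog, cfg$gene_length_sdlog))))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom <- paste0("chr_", rep_len(seq_len(cfg$n_chroms), n))

  # split each union length into k exon lengths of >= 60 bp
  exon_lens <- purrr::map2(union_len, k_exons, function(L, k) {
    if (k == 1) return(L)
    w <- as.numeric(runif(k, 0.5, 1.5))
    len <- pmax(60L, as.integer(floor(L * w / sum(w))))
    len[1] <- len[1] + (L - sum(len)) # keep the union length exact
    if (len[1] < 60L) { # rebalance pathological splits
      len <- rep(L %/% k, k)
      len[1] <- len[1] + (L - sum(len))
    }
    len
  })
  intron_lens <- purrr::map(k_exons, function(k) {
    if (k == 1) return(integer(0))
    as.integer(round(runif(k - 1, cfg$intron_length_range[1], cfg$intron_length_range[2])))
  })

  # sequential packing per chromosome
  margin <- 500L + cfg$as_flank
  cursor <- setNames(rep(margin, cfg$n_chroms), paste0("chr_", seq_len(cfg$n_chroms)))
  locus_start <- integer(n)
  locus_end <- integer(n)
  exon_rows <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- chrom[i]
    s0 <- cursor[[cc]]
    starts <- integer(k_exons[i])
    ends <- integer(k_exons[i])
    pos <- s0
    for (e in seq_len(k_exons[i])) {
      starts[e] <- pos
      ends[e] <- pos + exon_lens[[i]][e]
      pos <- ends[e] + if (e < k_exons[i]) intron_lens[[i]][e] else 0L
    }
    locus_start[i] <- s0
    locus_end[i] <- ends[k_exons[i]]
    exon_rows[[i]] <- tibble(
      gene_id = ids[i], chrom = cc, strand = strand[i],
      start = starts, end = ends
    )
    gap <- as.integer(round(runif(1, cfg$gene_gap_range[1], cfg$gene_gap_range[2])))
    cursor[[cc]] <- locus_end[i] + gap
  }

  overlapping <- rep(FALSE, n)
  if (isTRUE(cfg$overlapping_pair) && n >= 2) {
    # move the last gene inside the second-to-last gene's locus, opposite strand
    i <- n
    j <- n - 1L
    shift <- (locus_start[j] + 50L) - locus_start[i]
    new_chrom <- chrom[j]
    new_strand <- if (strand[j] == "+") "-" else "+"
    exon_rows[[i]] <- exon_rows[[i]] %>%
      mutate(
        chrom = .env$new_chrom,
        strand = .env$new_strand,
        start = .data$start + shift, end = .data$end + shift
      )
    chrom[i] <- chrom[j]
    strand[i] <- exon_rows[[i]]$strand[1]
    locus_start[i] <- locus_start[i] + shift
    locus_end[i] <- locus_end[i] + shift
    overlapping[c(i, j)] <- TRUE
  }

  exons <- bind_rows(exon_rows)
  cl <- vapply(split(exons$end, exons$chrom), max, numeric(1)) + margin
  chrom_lengths <- c(setNames(as.integer(cl), names(cl)), rRNA_1 = 5000L)
  ann <- genome_annotation(exons, chrom_lengths = chrom_lengths)

  # roles: category, induced, antisense, switch
  sample_idx <- function(x, size) x[sample.int(length(x), size)]
  eligible <- which(!overlapping)
  n_cat <- round(cfg$category_fraction * n)
  cat_idx <- sort(sample_idx(eligible, min(n_cat, length(eligible))))
  dominant_idx <- if (length(cat_idx) > 0) cat_idx[1] else integer(0)
  fam_pool <- setdiff(cfg$category_families, "GH15")
  families <- rep(NA_character_, n)
  if (length(cat_idx) > 0) {
    families[cat_idx] <- sample(fam_pool, length(cat_idx), replace = TRUE)
    families[dominant_idx] <- "GH15"
  }

  n_ind <- round(cfg$induced_fraction * n)
  n_ind_cat <- min(round(cfg$induced_category_fraction * n_ind), max(0, length(cat_idx) - 1))
  ind_cat <- sample_idx(setdiff(cat_idx, dominant_idx), n_ind_cat)
  ind_non <- sample_idx(setdiff(eligible, cat_idx), n_ind - n_ind_cat)
  induced_idx <- sort(c(ind_cat, ind_non))

  # switch genes come from the induced non-category set: their repressed
  # baselines are unaffected by the category-share calibration, keeping the
  # antisense:sense ratio program within the global AS budget
  switch_pool <- setdiff(induced_idx, cat_idx)
  n_switch <- min(cfg$n_switch_genes, length(switch_pool))
  switch_idx <- sort(sample_idx(switch_pool, n_switch))
  n_as <- round(cfg$as_gene_fraction * n)
  as_other <- sample_idx(
    setdiff(eligible, union(induced_idx, dominant_idx)),
    max(0, n_as - n_switch)
  )
  as_idx <- sort(c(switch_idx, as_other))

  genes <- tibble(
    gene_id = ids, chrom = chrom, strand = strand,
    union_length = ann$genes$union_length[match(ids, ann$genes$gene_id)],
    locus_start = locus_start, locus_end = locus_end,
    family = families,
    is_category = seq_len(n) %in% cat_idx,
    is_dominant = seq_len(n) %in% dominant_idx,
    is_induced = seq_len(n) %in% induced_idx,
    is_as = seq_len(n) %in% as_idx,
    is_switch = seq_len(n) %in% switch_idx,
    is_overlapping = overlapping
  )
  categories <- genes %>%
    filter(!is.na(.data$family)) %>%
    select("gene_id", "family")
  list(annotation = ann, categories = categories, genes = genes, rrna_refs = "rRNA_1")
}

# probability that a uniformly placed antisense read (length rl) on the
# extended unspliced locus overlaps the gene's exon union
as_countable_prob <- function(exons_g, locus_start, locus_end, flank, rl) {
  ws <- locus_start - flank
  we <- locus_end + flank - rl
  total <- we - ws + 1
  merged <- IRanges::reduce(IRanges::IRanges(exons_g$start + 1L, exons_g$end))
  lo <- pmax(ws, IRanges::start(merged) - rl) # 0-based start > e.start - rl
  hi <- pmin(we, IRanges::end(merged) - 1L) # 0-based start < e.end
  good <- pmax(0, hi - lo + 1)
  sum(good) / total
}

# build the per-condition expression and antisense truth programs
build_truth <- function(cfg, sim) {
  genes <- sim$genes
  n <- nrow(genes)
  L <- as.numeric(genes$union_length)
  cond_base <- cfg$conditions[1]
  cond_ind <- cfg$conditions[2]

  draft <- rlnorm(n, meanlog = 0, sdlog = cfg$baseline_sdlog)
  r_base <- rlnorm(
    n, cfg$induced_baseline_rpkm[["meanlog"]],
    cfg$induced_baseline_rpkm[["sdlog"]]
  )
  folds <- exp(runif(n, log(cfg$fold_range[1]), log(cfg$fold_range[2])))

  ind <- genes$is_induced
  cat_set <- genes$is_category
  dom <- genes$is_dominant

  # baseline condition: iterate the induced-baseline-RPKM constraint
  t_base <- draft
  for (iter in 1:6) {
    TL <- sum(t_base * L)
    t_base[ind] <- r_base[ind] * TL / 1e9
    t_base <- calibrate_category(t_base, cat_set, dom,
      share = cfg$category_share[[cond_base]],
      dominant_share = cfg$dominant_gene_share
    )
  }
  # induced condition: apply folds in abundance space, re-calibrate the set
  t_ind <- t_base
  t_ind[ind] <- t_ind[ind] * folds[ind]
  t_ind <- calibrate_category(t_ind, cat_set, dom,
    share = cfg$category_share[[cond_ind]],
    dominant_share = NA
  )

  expr <- purrr::map2(
    list(t_base, t_ind), c(cond_base, cond_ind),
    function(tt, cc) {
      tibble(
        gene_id = genes$gene_id, condition = cc, abundance = tt,
        mrna_pct = 100 * tt / sum(tt),
        sense_share_raw = tt * L / sum(tt * L)
      )
    }
  ) %>% bind_rows()

  # antisense program: countable shares per condition
  p_cnt <- rep(NA_real_, n)
  for (i in which(genes$is_as)) {
    exg <- sim$annotation$exons %>% filter(.data$gene_id == genes$gene_id[i])
    p_cnt[i] <- as_countable_prob(
      exg, genes$locus_start[i], genes$locus_end[i],
      cfg$as_flank, cfg$read_length
    )
  }
  rho <- runif(n, cfg$switch_ratio_range[1], cfg$switch_ratio_range[2])
  u_as <- rlnorm(n, 0, 0.8)

  expr <- expr %>%
    left_join(
      genes %>% select("gene_id", "is_as", "is_switch", "is_induced", "union_length"),
      by = "gene_id"
    ) %>%
    mutate(p_countable = p_cnt[match(.data$gene_id, genes$gene_id)])

  per_cond <- expr %>%
    group_by(.data$condition) %>%
    group_split() %>%
    purrr::map(function(df) {
      idx <- match(df$gene_id, genes$gene_id)
      w <- rep(0, nrow(df))
      is_sw <- df$is_switch
      base_cond <- df$condition[1] == cond_base
      # switch genes: AS:S ratio rho in the baseline condition; reduced AS in
      # the induced condition (AS RPKM scales with countable share)
      w[is_sw] <- rho[idx[is_sw]] * df$sense_share_raw[is_sw]
      if (!base_cond) {
        base_share <- expr %>%
          filter(.data$condition == cond_base) %>%
          slice(match(df$gene_id, .data$gene_id))
        w[is_sw] <- cfg$switch_as_reduction * rho[idx[is_sw]] *
          base_share$sense_share_raw[is_sw]
      }
      other <- df$is_as & !is_sw
      rem <- cfg$as_read_fraction - sum(w)
      if (rem < 0) abort("switch-gene antisense mass exceeds the global AS budget")
      if (any(other)) w[other] <- u_as[idx[other]] / sum(u_as[idx[other]]) * rem
      df$as_countable_share <- w
      df$as_emitted_share <- ifelse(w > 0, w / df$p_countable, 0)
      df
    }) %>%
    bind_rows()

  # final composition: sense mass fills what antisense emission leaves
  per_cond <- per_cond %>%
    group_by(.data$condition) %>%
    mutate(
      sense_share = .data$sense_share_raw * (1 - sum(.data$as_emitted_share)),
      sense_rpkm_true = 1e9 * .data$sense_share / .data$union_length,
      as_rpkm_true = 1e9 * .data$as_countable_share / .data$union_length,
      ratio_true = ifelse(.data$sense_share > 0,
        .data$as_countable_share / .data$sense_share, NA_real_
      )
    ) %>%
    ungroup()

  folds_true <- per_cond %>%
    select("gene_id", "condition", "sense_rpkm_true") %>%
    pivot_wider(names_from = "condition", values_from = "sense_rpkm_true") %>%
    mutate(fold_true = .data[[cond_ind]] / .data[[cond_base]]) %>%
    select("gene_id", "fold_true")

  per_cond %>%
    left_join(folds_true, by = "gene_id") %>%
    select(
      "gene_id", "condition", "abundance", "mrna_pct", "sense_share",
      "as_countable_share", "as_emitted_share", "p_countable",
      "sense_rpkm_true", "as_rpkm_true", "ratio_true", "fold_true",
      "is_induced", "is_as", "is_switch"
    )
}

# scale the category gene set so it holds `share` of total abundance, with an
# optional dominant gene pinned to `dominant_share` of the set
calibrate_category <- function(t, cat_set, dom, share, dominant_share) {
  if (!any(cat_set) || share <= 0) return(t)
  non_mass <- sum(t[!cat_set])
  target_cat <- share / (1 - share) * non_mass
  if (!is.na(dominant_share) && any(dom)) {
    t[dom] <- dominant_share * target_cat
    rest <- cat_set & !dom
    t[rest] <- t[rest] / sum(t[rest]) * (1 - dominant_share) * target_cat
  } else {
    t[cat_set] <- t[cat_set] / sum(t[cat_set]) * target_cat
  }
  t
}

#' Simulate stranded alignments for every replicate library
#'
#' Draws per-gene read counts Poisson around `library_size x share`, places
#' sense reads uniformly on the spliced transcript (junction-spanning reads
#' get gapped alignments), places antisense reads uniformly on the unspliced
#' locus extended by `as_flank` on the opposite strand, adds rRNA reads on a
#' dedicated contig, and writes one SAM file per replicate.
#'
#' @param config A [sim_config()].
#' @param sim Output of [generate_annotation()].
#' @param truth Truth table from the expression program (built internally by
#'   [simulate_dataset()]).
#' @param out_dir Directory for the SAM files.
#' @return A tibble `library_id`, `condition`, `path`.
#' @keywords internal
simulate_alignments <- function(config, sim, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- sim$genes
  ann <- sim$annotation

  # global concatenated-transcript coordinate system for fast position mapping
  ex <- ann$exons %>% arrange(match(.data$gene_id, genes$gene_id), .data$start)
  ex_len <- ex$end - ex$start
  tx_start <- cumsum(c(0, head(ex_len, -1)))
  first_of_gene <- !duplicated(ex$gene_id)
  gene_tx_offset <- setNames(tx_start[first_of_gene], ex$gene_id[first_of_gene])
  gene_off <- unname(gene_tx_offset[genes$gene_id]) # aligned to genes order
  next_gstart <- c(ex$start[-1], NA)
  same_gene_next <- c(ex$gene_id[-1] == ex$gene_id[-nrow(ex)], FALSE)

  chrom_lengths <- ann$chrom_lengths
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), as.integer(chrom_lengths))
  )
  rl <- config$read_length

  libs <- tidyr::expand_grid(
    condition = config$conditions,
    rep = seq_len(config$replicates)
  ) %>%
    mutate(
      library_id = paste0(.data$condition, "_rep", .data$rep),
      path = file.path(out_dir, paste0(.data$library_id, ".sam"))
    )

  for (li in seq_len(nrow(libs))) {
    cc <- libs$condition[li]
    tr <- truth %>%
      filter(.data$condition == cc) %>%
      slice(match(genes$gene_id, .data$gene_id))
    lam_nonrrna <- config$library_size * (1 - config$rrna_fraction)
    n_sense <- rpois(nrow(genes), lam_nonrrna * tr$sense_share)
    n_as <- rpois(nrow(genes), lam_nonrrna * tr$as_emitted_share)
    n_rrna <- rpois(1, config$library_size * config$rrna_fraction)

    # sense reads: uniform on the spliced transcript
    g_idx <- rep(seq_len(nrow(genes)), n_sense)
    Lg <- genes$union_length[g_idx]
    d <- floor(runif(length(g_idx)) * (Lg - rl + 1))
    gd <- gene_off[g_idx] + d
    row <- findInterval(gd, tx_start)
    in_off <- gd - tx_start[row]
    gstart <- ex$start[row] + in_off
    remain <- ex_len[row] - in_off
    spliced <- rl > remain & same_gene_next[row]
    cig <- rep(paste0(rl, "M"), length(g_idx))
    if (any(spliced)) {
      a <- remain[spliced]
      gap <- next_gstart[row[spliced]] - ex$end[row[spliced]]
      cig[spliced] <- sprintf("%dM%dN%dM", a, gap, rl - a)
    }
    sense_df <- data.table::data.table(
      qname = sprintf("%s_s%d", libs$library_id[li], seq_along(g_idx)),
      flag = ifelse(genes$strand[g_idx] == "+", 0L, 16L),
      rname = genes$chrom[g_idx],
      pos = as.integer(gstart + 1L),
      mapq = 60L, cigar = cig,
      rnext = "*", pnext = 0L, tlen = 0L, seq = "*", qual = "*"
    )

    # antisense reads: uniform on the flanked unspliced locus, opposite strand
    a_idx <- rep(seq_len(nrow(genes)), n_as)
    ws <- genes$locus_start[a_idx] - config$as_flank
    we <- genes$locus_end[a_idx] + config$as_flank - rl
    s0 <- ws + floor(runif(length(a_idx)) * (we - ws + 1))
    as_df <- data.table::data.table(
      qname = sprintf("%s_a%d", libs$library_id[li], seq_along(a_idx)),
      flag = ifelse(genes$strand[a_idx] == "+", 16L, 0L),
      rname = genes$chrom[a_idx],
      pos = as.integer(s0 + 1L),
      mapq = 60L, cigar = paste0(rl, "M"),
      rnext = "*", pnext = 0L, tlen = 0L, seq = "*", qual = "*"
    )

    rr_start <- floor(runif(n_rrna) * (chrom_lengths[["rRNA_1"]] - rl))
    rrna_df <- if (n_rrna > 0) {
      data.table::data.table(
        qname = sprintf("%s_rr%d", libs$library_id[li], seq_len(n_rrna)),
        flag = sample(c(0L, 16L), n_rrna, replace = TRUE),
        rname = "rRNA_1",
        pos = as.integer(rr_start + 1L),
        mapq = 60L, cigar = paste0(rl, "M"),
        rnext = "*", pnext = 0L, tlen = 0L, seq = "*", qual = "*"
      )
    } else {
      NULL
    }

    all_df <- data.table::rbindlist(list(sense_df, as_df, rrna_df))
    con <- file(libs$path[li], open = "wb") # LF endings regardless of platform
    writeLines(header, con, sep = "\n")
    close(con)
    data.table::fwrite(all_df, libs$path[li],
      sep = "\t", col.names = FALSE,
      quote = FALSE, append = TRUE, eol = "\n"
    )
  }
  libs %>% select("library_id", "condition", "path")
}

#' Simulate a complete stranded RNA-seq dataset with ground truth
#'
#' Generates the annotation, expression/antisense truth programs and
#' per-replicate stranded SAM alignments, and writes everything (genome
#' FASTA, GTF, category TSV, truth TSVs, library sheet, config echo) under
#' `out_dir`. Byte-identical outputs under the same config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @param write_genome Write the random genome FASTA (default `TRUE`).
#' @return A list: `annotation`, `categories`, `genes`, `truth`,
#'   `libraries` (with SAM paths), `rrna_refs`, `paths`.
#' @export
simulate_dataset <- function(config, out_dir, write_genome = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_annotation(config)
  with_sim_seed(config$seed + 1L, {
    truth <- build_truth(config, sim)
    libraries <- simulate_alignments(config, sim, truth, file.path(out_dir, "alignments"))

    paths <- list(
      annotation = file.path(out_dir, "annotation.gtf"),
      categories = file.path(out_dir, "categories.tsv"),
      truth = file.path(out_dir, "truth_expression.tsv"),
      genes = file.path(out_dir, "truth_genes.tsv"),
      libraries = file.path(out_dir, "libraries.tsv"),
      config = file.path(out_dir, "config.json"),
      genome = file.path(out_dir, "genome.fa")
    )
    write_annotation(sim$annotation, paths$annotation)
    readr::write_tsv(sim$categories, paths$categories)
    readr::write_tsv(truth, paths$truth)
    readr::write_tsv(sim$genes, paths$genes)
    readr::write_tsv(libraries, paths$libraries)
    cfg_plain <- unclass(config)
    jsonlite::write_json(cfg_plain, paths$config, auto_unbox = TRUE, digits = NA)
    if (write_genome) {
      seqs <- Biostrings::DNAStringSet(vapply(
        as.integer(sim$annotation$chrom_lengths),
        function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
        character(1)
      ))
      names(seqs) <- names(sim$annotation$chrom_lengths)
      Biostrings::writeXStringSet(seqs, paths$genome)
    }
    list(
      annotation = sim$annotation, categories = sim$categories,
      genes = sim$genes, truth = truth, libraries = libraries,
      rrna_refs = sim$rrna_refs, paths = paths
    )
  })
}
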