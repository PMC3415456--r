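small_cfg <- function(...) {
  sim_config(
    seed = 13, n_genes = 30, n_chroms = 2, library_size = 3e4,
    ...
  )
}

test_that("an empty configuration yields an empty annotation", {
  sim <- generate_annotation(sim_config(seed = 1, n_genes = 0))
  expect_equal(nrow(sim$annotation$genes), 0)
})

test_that("generation is deterministic: same seed, byte-identical outputs", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  s1 <- simulate_dataset(small_cfg(), d1, write_genome = TRUE)
  s2 <- simulate_dataset(small_cfg(), d2, write_genome = TRUE)
  expect_identical(s1$truth, s2$truth)
  for (nm in c("annotation", "genome")) {
    expect_identical(
      readLines(s1$paths[[nm]])[-(1:3)], # skip the dated export comments
      readLines(s2$paths[[nm]])[-(1:3)],
      info = nm
    )
  }
  for (i in seq_len(nrow(s1$libraries))) {
    expect_identical(
      unname(tools::md5sum(s1$libraries$path[i])[[1]]),
      unname(tools::md5sum(s2$libraries$path[i])[[1]])
    )
  }
})

test_that("packed gene loci never overlap (interval-scan oracle)", {
  sim <- generate_annotation(sim_config(seed = 3, n_genes = 50, n_chroms = 1))
  g <- sim$genes[order(sim$genes$locus_start), ]
  expect_true(all(g$locus_start[-1] > g$locus_end[-nrow(g)]))
  # and exons stay within chromosome bounds
  expect_true(all(sim$annotation$exons$end <=
    sim$annotation$chrom_lengths[sim$annotation$exons$chrom]))
})

test_that("the optional overlapping pair overlaps on opposite strands", {
  sim <- generate_annotation(small_cfg(overlapping_pair = TRUE))
  ov <- sim$genes[sim$genes$is_overlapping, ]
  expect_equal(nrow(ov), 2)
  expect_equal(length(unique(ov$chrom)), 1)
  expect_setequal(ov$strand, c("-", "+"))
  expect_lt(max(ov$locus_start), min(ov$locus_end))
})

test_that("read counts follow the planted Poisson programme", {
  d <- file.path(tempdir(), "pois")
  sim <- simulate_dataset(small_cfg(), d, write_genome = FALSE)
  lib1 <- sim$libraries[1, ]
  aln <- read_alignments(lib1$path)
  blocks <- tidy(aln)
  first_blocks <- blocks[!duplicated(blocks$read_id), ]
  expected_nonrrna <- small_cfg()$library_size * (1 - small_cfg()$rrna_fraction)

  tr <- sim$truth[sim$truth$condition == lib1$condition, ]
  # zero-share genes emit zero reads; for the five highest-expression genes the
  # realised sense count lies within 4*sqrt(mean) of the Poisson mean
  top <- tr[order(-tr$sense_share), ][1:5, ]
  for (i in seq_len(nrow(top))) {
    gmeta <- sim$genes[sim$genes$gene_id == top$gene_id[i], ]
    hits <- first_blocks$chrom == gmeta$chrom &
      first_blocks$start >= gmeta$locus_start - 200 &
      first_blocks$start <= gmeta$locus_end &
      first_blocks$strand == gmeta$strand
    mu <- expected_nonrrna * top$sense_share[i]
    expect_lt(abs(sum(hits) - mu), 4 * sqrt(mu) + 1)
  }
  rrna_frac <- mean(blocks$chrom[!duplicated(blocks$read_id)] == "rRNA_1")
  expect_lt(abs(rrna_frac - small_cfg()$rrna_fraction), 0.01)
})

test_that("antisense reads cover introns of antisense genes only", {
  d <- file.path(tempdir(), "asintron")
  sim <- simulate_dataset(small_cfg(as_gene_fraction = 0.3, n_switch_genes = 2),
    d,
    write_genome = FALSE
  )
  blocks <- tidy(read_alignments(sim$libraries$path[1]))
  exons <- sim$annotation$exons

  intron_cover <- function(gid) {
    g <- sim$genes[sim$genes$gene_id == gid, ]
    ex_g <- exons[exons$gene_id == gid, ]
    ex_g <- ex_g[order(ex_g$start), ]
    if (nrow(ex_g) < 2) {
      return(NA)
    }
    istart <- ex_g$end[1]
    iend <- ex_g$start[2]
    anti <- blocks$chrom == g$chrom & blocks$strand != g$strand &
      blocks$start < iend & blocks$end > istart &
      blocks$start >= g$locus_start - 200 & blocks$end <= g$locus_end + 200
    sum(anti)
  }
  as_multi <- sim$genes$gene_id[sim$genes$is_as &
    sim$genes$gene_id %in% exons$gene_id[duplicated(exons$gene_id)]]
  plain_multi <- sim$genes$gene_id[!sim$genes$is_as &
    sim$genes$gene_id %in% exons$gene_id[duplicated(exons$gene_id)]]
  expect_gt(length(as_multi), 0)
  expect_gt(sum(vapply(as_multi, intron_cover, numeric(1)), na.rm = TRUE), 0)
  expect_equal(sum(vapply(plain_multi, intron_cover, numeric(1)), na.rm = TRUE), 0)
})

test_that("the planted countable antisense budget sums to the configured fraction", {
  sim <- simulate_dataset(small_cfg(), file.path(tempdir(), "asbudget"),
    write_genome = FALSE
  )
  per_cond <- tapply(sim$truth$as_countable_share, sim$truth$condition, sum)
  expect_equal(unname(per_cond["glucose_48h"]), 0.02, tolerance = 1e-12)
  expect_equal(unname(per_cond["straw_24h"]), 0.02, tolerance = 1e-12)
})

test_that("configuration contracts are enforced", {
  expect_error(sim_config(rrna_fraction = 1.5), "fractions")
  expect_error(sim_config(fold_range = c(0.5, 10)), "fold")
  expect_error(sim_config(gene_gap_range = c(50, 60)), "gaps")
  expect_error(sim_config(conditions = "only_one"), "two conditions")
})
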