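#' Per-lane Poisson likelihood-ratio test
#'
#' Models the count of one gene in library `i` as Poisson with mean
#' `lambda * s_i` (null) or `lambda_c(i) * s_i` (alternative, one rate per
#' condition), where `s_i` is the library size. The statistic is
#' `Lambda = 2 * sum_i x_i * log(lambda_hat_c(i) / lambda_hat)` with
#' `0 * log(.) == 0`, compared to a chi-squared distribution with 1 df.
#'
#' @param x Non-negative integer counts, one per library.
#' @param s Positive library sizes, same length.
#' @param condition Two-level condition labels, same length.
#' @return A list with `statistic` and `p_value`.
#' @export
poisson_lrt <- function(x, s, condition) {
  if (length(x) != length(s) || length(x) != length(condition)) {
    abort("x, s and condition must have equal length")
  }
  condition <- as.character(condition)
  levels <- unique(condition)
  if (length(levels) != 2) abort("poisson_lrt needs exactly two conditions")
  sA <- sum(s[condition == levels[1]])
  sB <- sum(s[condition == levels[2]])
  if (sA == 0 || sB == 0) abort("a condition has zero total library size")
  xA <- sum(x[condition == levels[1]])
  xB <- sum(x[condition == levels[2]])
  lam <- (xA + xB) / (sA + sB)
  lamA <- xA / sA
  lamB <- xB / sB
  term <- function(xx, ll) if (xx == 0) 0 else xx * log(ll / lam)
  stat <- max(0, 2 * (term(xA, lamA) + term(xB, lamB)))
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# vectorised LRT over genes: xA,xB pooled counts per gene, sA,sB scalars
poisson_lrt_vec <- function(xA, xB, sA, sB) {
  lam <- (xA + xB) / (sA + sB)
  lamA <- xA / sA
  lamB <- xB / sB
  tA <- ifelse(xA == 0, 0, xA * log(lamA / lam))
  tB <- ifelse(xB == 0, 0, xB * log(lamB / lam))
  stat <- pmax(0, 2 * (tA + tB))
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test on pooled counts
#'
#' Tests the 2x2 table `[cA, nA - cA; cB, nB - cB]` by conditioning on the
#' margins: the two-sided p-value sums the hypergeometric probabilities of
#' all tables no more likely than the observed one (minimum-likelihood rule,
#' with the conventional `1 + 1e-7` relative tie tolerance). Vectorised over
#' genes.
#'
#' @param cA,cB Pooled counts in the two conditions.
#' @param nA,nB Pooled library sizes (`nA >= cA`, `nB >= cB`).
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact <- function(cA, cB, nA, nB) {
  n <- max(length(cA), length(cB), length(nA), length(nB))
  cA <- rep_len(cA, n); cB <- rep_len(cB, n)
  nA <- rep_len(nA, n); nB <- rep_len(nB, n)
  if (any(nA <= 0) || any(nB <= 0)) abort("library sizes must be positive")
  if (any(cA > nA) || any(cB > nB)) abort("count exceeds library size")
  vapply(seq_len(n), function(i) {
    m <- cA[i] + cB[i]
    if (m == 0) return(1)
    lo <- max(0, m - nB[i])
    hi <- min(m, nA[i])
    support <- lo:hi
    probs <- dhyper(support, nA[i], nB[i], m)
    p_obs <- probs[support == cA[i]]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' MA-plot random-sampling z-test on pooled counts
#'
#' Under the null both condition counts are binomial draws from a common
#' proportion `p_hat = (cA + cB) / (nA + nB)`. With `M = log2 cA - log2 cB`
#' and `A = (log2 cA + log2 cB) / 2`, a delta-method bivariate-normal model
#' for `(M, A)` gives the conditional mean and variance of `M` given `A`; the
#' test reports `z = (M - E(M|A)) / sqrt(Var(M|A))` against the standard
#' normal. Second-order moment corrections of order `1/(n_i p_hat)^2` are
#' applied to the log-count mean and variance (validated against Monte-Carlo
#' sampling; the leading terms are the usual `(1 - p_hat)/(n_i p_hat ln^2 2)`
#' variance and `log2(n_i p_hat)` mean). Zero counts are replaced by 0.5 for
#' the M/A computation only and flagged; a degenerate `p_hat` of 0 or 1
#' yields p = 1 with a flag.
#'
#' @inheritParams fisher_exact
#' @return A tibble with columns `M`, `A`, `z`, `p_value`, `zero_adjusted`,
#'   `degenerate`.
#' @export
mars_test <- function(cA, cB, nA, nB) {
  n <- max(length(cA), length(cB), length(nA), length(nB))
  cA <- rep_len(cA, n); cB <- rep_len(cB, n)
  nA <- rep_len(nA, n); nB <- rep_len(nB, n)
  if (any(nA <= 0) || any(nB <= 0)) abort("library sizes must be positive")

  p_hat <- (cA + cB) / (nA + nB)
  degenerate <- p_hat <= 0 | p_hat >= 1
  zero_adjusted <- (cA == 0 | cB == 0) & !degenerate
  cA_adj <- ifelse(cA == 0, 0.5, cA)
  cB_adj <- ifelse(cB == 0, 0.5, cB)

  M <- log2(cA_adj) - log2(cB_adj)
  A <- (log2(cA_adj) + log2(cB_adj)) / 2

  ln2 <- log(2)
  q <- 1 - p_hat
  moments <- function(nn) {
    mu <- nn * p_hat
    mean_ln <- log(mu) - q / (2 * mu)
    var_ln <- q / mu + (2.5 * q^2 - q + 2 * p_hat * q) / mu^2
    list(mean = mean_ln / ln2, var = var_ln / ln2^2)
  }
  mA <- moments(nA)
  mB <- moments(nB)
  mean_M <- mA$mean - mB$mean
  mean_A <- (mA$mean + mB$mean) / 2
  sum_var <- mA$var + mB$var
  slope <- 2 * (mA$var - mB$var) / sum_var
  cond_mean <- mean_M + slope * (A - mean_A)
  cond_var <- 4 * mA$var * mB$var / sum_var

  z <- ifelse(degenerate, 0, (M - cond_mean) / sqrt(cond_var))
  p <- ifelse(degenerate, 1, 2 * pnorm(-abs(z)))
  tibble(
    M = ifelse(degenerate, NA_real_, M),
    A = ifelse(degenerate, NA_real_, A),
    z = z, p_value = p,
    zero_adjusted = zero_adjusted, degenerate = degenerate
  )
}

#' Run all three significance tests for every gene
#'
#' The likelihood-ratio test uses per-library (per-lane) sense counts; the
#' Fisher exact and MA-plot random-sampling tests use replicate-pooled counts
#' per condition, each method in its native form.
#'
#' @param counts A `counts_table` from [quantify_libraries()].
#' @param baseline,target The two condition labels to compare.
#' @return A tibble `gene_id`, pooled counts and sizes, `p_lrt`, `p_fisher`,
#'   `p_mars`.
#' @export
de_test <- function(counts, baseline, target) {
  stopifnot(inherits(counts, "counts_table"))
  libs <- counts$libraries
  if (!all(c(baseline, target) %in% libs$condition)) {
    abort("baseline/target condition not present in counts")
  }
  long <- tidy(counts) %>%
    filter(.data$condition %in% c(baseline, target))
  sA <- sum(libs$library_size[libs$condition == baseline])
  sB <- sum(libs$library_size[libs$condition == target])
  pooled <- long %>%
    group_by(.data$gene_id) %>%
    summarise(
      count_baseline = sum(.data$sense[.data$condition == baseline]),
      count_target = sum(.data$sense[.data$condition == target]),
      .groups = "drop"
    )
  lrt <- poisson_lrt_vec(pooled$count_baseline, pooled$count_target, sA, sB)
  fis <- fisher_exact(pooled$count_baseline, pooled$count_target, sA, sB)
  mars <- mars_test(pooled$count_baseline, pooled$count_target, sA, sB)
  pooled %>%
    mutate(
      size_baseline = sA, size_target = sB,
      p_lrt = lrt$p_value,
      p_fisher = fis,
      p_mars = mars$p_value
    )
}
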