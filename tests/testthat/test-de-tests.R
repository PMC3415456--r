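# numeric likelihood-maximisation oracle for the Poisson LRT
lrt_numeric_oracle <- function(x, s, condition) {
  ll <- function(lambda, xx, ss) sum(stats::dpois(xx, lambda * ss, log = TRUE))
  fit <- function(xx, ss) {
    if (sum(xx) == 0) {
      return(sum(stats::dpois(xx, 1e-300 * ss, log = TRUE)))
    }
    stats::optimize(ll, c(1e-12, 10) * sum(xx) / sum(ss), xx = xx, ss = ss, maximum = TRUE, tol = 1e-12)$objective
  }
  ll_null <- fit(x, s)
  levels <- unique(condition)
  ll_alt <- fit(x[condition == levels[1]], s[condition == levels[1]]) +
    fit(x[condition == levels[2]], s[condition == levels[2]])
  2 * (ll_alt - ll_null)
}

test_that("Poisson LRT is zero on exactly null inputs and all-zero counts", {
  out <- poisson_lrt(c(10, 10), c(1e6, 1e6), c("A", "B"))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  out0 <- poisson_lrt(c(0, 0, 0, 0), rep(1e6, 4), c("A", "A", "B", "B"))
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
  expect_error(poisson_lrt(c(1, 1), c(0, 1e6), c("A", "B")), "zero total")
})

test_that("Poisson LRT matches the closed form and a numeric likelihood oracle", {
  x <- c(10, 30)
  s <- c(1e6, 1e6)
  cond <- c("A", "B")
  out <- poisson_lrt(x, s, cond)
  expect_equal(out$statistic, 2 * (10 * log(0.5) + 30 * log(1.5)), tolerance = 1e-12)
  expect_equal(out$statistic, 10.46, tolerance = 1e-3)
  expect_equal(out$p_value, 1.22e-3, tolerance = 1e-2)
  expect_equal(out$statistic, lrt_numeric_oracle(x, s, cond), tolerance = 1e-6)

  # unequal lane sizes, 3+3 replicates
  x2 <- c(12, 9, 15, 40, 52, 38)
  s2 <- c(0.9, 1.1, 1.0, 1.05, 0.95, 1.0) * 1e6
  cond2 <- rep(c("A", "B"), each = 3)
  out2 <- poisson_lrt(x2, s2, cond2)
  expect_equal(out2$statistic, lrt_numeric_oracle(x2, s2, cond2), tolerance = 1e-6)
})

test_that("Fisher exact test handles symmetric and empty tables", {
  expect_equal(fisher_exact(5, 5, 100, 100), 1)
  expect_equal(fisher_exact(0, 0, 10, 10), 1)
})

test_that("Fisher exact equals independent enumeration and fisher.test", {
  # the spec's worked table
  expect_equal(fisher_exact(2, 8, 10, 10), fisher_enum_oracle(2, 8, 10, 10))
  expect_equal(
    fisher_exact(2, 8, 10, 10),
    stats::fisher.test(matrix(c(2, 8, 8, 2), 2))$p.value,
    tolerance = 1e-12
  )
  set.seed(5)
  for (i in 1:50) {
    nA <- sample(1:30, 1)
    nB <- sample(1:30, 1)
    cA <- sample(0:nA, 1)
    cB <- sample(0:nB, 1)
    expect_equal(fisher_exact(cA, cB, nA, nB), fisher_enum_oracle(cA, cB, nA, nB))
    expect_equal(
      fisher_exact(cA, cB, nA, nB),
      stats::fisher.test(matrix(c(cA, nA - cA, cB, nB - cB), 2))$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("MARS statistics vanish for symmetric inputs", {
  out <- mars_test(100, 100, 1e6, 1e6)
  expect_equal(out$M, 0)
  expect_equal(out$z, 0)
  expect_equal(out$p_value, 1)
})

test_that("MARS conditional mean follows the library-size offset", {
  # twice the library size, twice the count: M equals log2(nA/nB) and lies on
  # the conditional mean (up to the small-count moment corrections)
  out <- mars_test(200, 100, 2e6, 1e6)
  expect_equal(out$A, (log2(200) + log2(100)) / 2)
  expect_equal(out$M, 1)
  expect_lt(abs(out$z), 0.05)
  expect_gt(out$p_value, 0.98)
})

test_that("MARS degenerate and zero-count inputs are flagged, never errors", {
  deg <- mars_test(0, 0, 1e6, 1e6)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  z0 <- mars_test(0, 50, 1e6, 1e6)
  expect_true(z0$zero_adjusted)
  expect_true(is.finite(z0$z))
})

test_that("MARS moments match Monte-Carlo sampling in an asymmetric design", {
  set.seed(23)
  nA <- 2e6
  nB <- 1e6
  p <- 1e-4
  nd <- 1e5
  cA <- stats::rbinom(nd, nA, p)
  cB <- stats::rbinom(nd, nB, p)
  M <- log2(cA) - log2(cB)
  A <- (log2(cA) + log2(cB)) / 2
  fit <- stats::lm(M ~ A)

  ref <- mars_test(nA * p, nB * p, nA, nB) # z = 0 at the null centre
  expect_lt(abs(ref$z), 0.02)

  # model-implied regression of M on A (from the implementation's moments)
  q <- 1 - p
  ln2 <- log(2)
  varln <- function(mu) (q / mu + (2.5 * q^2 - q + 2 * p * q) / mu^2) / ln2^2
  meanln <- function(mu) (log(mu) - q / (2 * mu)) / ln2
  vA <- varln(nA * p)
  vB <- varln(nB * p)
  slope_model <- 2 * (vA - vB) / (vA + vB)
  resid_var_model <- 4 * vA * vB / (vA + vB)
  mean_M_model <- meanln(nA * p) - meanln(nB * p)

  slope_se <- summary(fit)$coefficients["A", "Std. Error"]
  expect_lt(abs(unname(stats::coef(fit)["A"]) - slope_model), 4 * slope_se)
  expect_lt(
    abs(mean(M) - mean_M_model),
    4 * stats::sd(M) / sqrt(nd)
  )
  rv <- stats::var(stats::residuals(fit))
  expect_lt(abs(rv - resid_var_model), 4 * rv * sqrt(2 / (nd - 1)))
})

test_that("MARS holds type-I error near nominal under the binomial null", {
  set.seed(31)
  n_genes <- 1e4
  nA <- 3e6
  nB <- 3e6
  p <- stats::runif(n_genes, 1e-5, 5e-5)
  cA <- stats::rbinom(n_genes, nA, p)
  cB <- stats::rbinom(n_genes, nB, p)
  out <- mars_test(cA, cB, nA, nB)
  rate <- mean(out$p_value < 0.001)
  se <- sqrt(0.001 * 0.999 / n_genes)
  expect_lt(abs(rate - 0.001), 5 * se) # normal-approximation tolerance
})

test_that("de_test runs all three tests per gene over a counts table", {
  ct <- make_counts_table(
    tibble::tibble(
      gene_id = rep(c("up", "flat"), each = 4),
      library_id = rep(c("A1", "A2", "B1", "B2"), 2),
      sense = c(5L, 7L, 200L, 180L, 50L, 52L, 49L, 51L),
      unstranded = c(5L, 7L, 200L, 180L, 50L, 52L, 49L, 51L),
      antisense = 0L
    ),
    tibble::tibble(
      library_id = c("A1", "A2", "B1", "B2"),
      condition = c("glu", "glu", "straw", "straw"),
      library_size = rep(1e6, 4)
    )
  )
  out <- de_test(ct, "glu", "straw")
  up <- out[out$gene_id == "up", ]
  flat <- out[out$gene_id == "flat", ]
  expect_lt(max(up$p_lrt, up$p_fisher, up$p_mars), 1e-10)
  expect_gt(min(flat$p_lrt, flat$p_fisher, flat$p_mars), 0.5)
})
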