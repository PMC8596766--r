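# Enumeration oracle for the exact two-sided Mann-Whitney p-value: evaluate
# U over every assignment of the pooled values into two groups.
mw_exact_oracle <- function(a, b) {
  pool <- c(a, b); n1 <- length(a)
  u_of <- function(ix) {
    r <- rank(pool)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  }
  ixs <- utils::combn(length(pool), n1)
  us <- apply(ixs, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Probability-summation oracle for Fisher's two-sided test on a 2x2 table.
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("descriptive quartiles match the order-statistics convention", {
  d <- describe_quartiles(c(0.18, 0.17, 0.19))
  expect_equal(d[["median"]], 0.18)
  expect_gte(d[["q1"]], 0.17); expect_lte(d[["q3"]], 0.19)
  expect_equal(describe_quartiles(7), c(q1 = 7, median = 7, q3 = 7))
  expect_equal(describe_quartiles(1:100)[["median"]], 50.5)
  expect_error(describe_quartiles(numeric(0)), "at least one")
})

test_that("Mann-Whitney exact branch matches full enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(mann_whitney(c(1, 5, 7), c(2, 3, 4))$p_value,
               mw_exact_oracle(c(1, 5, 7), c(2, 3, 4)))
  set.seed(31)
  for (k in 1:10) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    v <- sample(1000, n1 + n2)  # no ties
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    expect_equal(mann_whitney(a, b)$p_value, mw_exact_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney is symmetric and degenerates to p = 1 on identical data", {
  a <- c(3.2, 1.1, 8, 4)
  b <- c(2.5, 9, 0.3, 5.5, 6)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
  x <- c(1, 2, 3, 4)
  expect_equal(mann_whitney(x, x)$p_value, 1)
  expect_error(mann_whitney(1, c(2, 3)), ">= 2")
})

test_that("Fisher exact matches the probability-summation oracle for N <= 12", {
  obs <- fisher_exact(matrix(c(7, 4, 2, 2), nrow = 2))
  expect_equal(obs$p_value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), nrow = 2))$p_value,
               2 / choose(10, 5), tolerance = 1e-9)
  for (r1 in 0:6) for (r2 in 0:6) for (a in 0:r1) for (c1 in 0:r2) {
    if (r1 + r2 == 0 || r1 + r2 > 12) next
    tab <- matrix(c(a, c1, r1 - a, r2 - c1), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("Fisher degenerate tables give p = 1", {
  expect_equal(fisher_exact(matrix(c(3, 3, 1, 1), 2))$p_value, 1)  # equal rows
  expect_message(res <- fisher_exact(matrix(c(0, 0, 2, 3), 2)), "margin")
  expect_equal(res$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Shapiro-Wilk is calibrated on normal data and powerful on skewed data", {
  set.seed(12)
  rej <- mean(replicate(1000, shapiro_wilk(rnorm(500))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
  power <- mean(replicate(200, shapiro_wilk(rexp(50))$p_value < 0.05))
  expect_gte(power, 0.95)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(4, 10)), "constant")
})

test_that("cohort comparison reproduces arm differences from composition medians", {
  mk <- function(arm, n, f) do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(patient = paste0(arm, i), arm = arm, voi = "TX",
               frac_fibro = f[1], frac_hyaline = f[2], frac_remodel = f[3])))
  tab <- rbind(mk("BMDCT", 9, c(0.18, 0.56, 0.27)),
               mk("MFS", 6, c(0.46, 0.41, 0.18)))
  cmp <- compare_cohort(tab)
  fib <- cmp[cmp$tissue == "fibrocartilage", ]
  hya <- cmp[cmp$tissue == "hyaline-like", ]
  expect_equal(fib$diff_pp, 28)
  expect_equal(hya$diff_pp, -15)
  expect_error(compare_cohort(mk("BMDCT", 4, c(0.2, 0.5, 0.3))),
               "exactly two arms")
})

test_that("Holm adjustment is available but off by default", {
  set.seed(77)
  tab <- do.call(rbind, lapply(1:10, function(i)
    data.frame(patient = i, arm = ifelse(i <= 5, "A", "B"), voi = "TX",
               frac_fibro = runif(1), frac_hyaline = runif(1),
               frac_remodel = runif(1))))
  plain <- compare_cohort(tab)
  holm <- compare_cohort(tab, adjust = "holm")
  expect_false("p_adj" %in% names(plain))
  expect_true(all(holm$p_adj >= holm$p_value))
})
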