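# Pearson association, paired-change classification, Mann-Whitney U,
# Holm-Bonferroni and the Welch t wrapper.

test_that("pearson matches a brute-force moment computation and flags degenerate input", {
  expect_equal(pearson_association(1:10, 2 * (1:10) + 1)$r, 1.0)
  expect_equal(pearson_association(1:10, -(1:10))$r, -1.0)
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    pa <- pearson_association(x, y)
    expect_equal(pa$r, r_brute, tolerance = 1e-12)
    tstat <- r_brute * sqrt(13) / sqrt(1 - r_brute^2)
    expect_equal(pa$p, 2 * pt(-abs(tstat), 13), tolerance = 1e-12)
  }
  expect_error(pearson_association(rep(1, 5), 1:5), "zero variance")
})

test_that("under the null, |r| exceeds its 5% critical value in about 5% of samples", {
  n <- 12
  tcrit <- qt(0.975, n - 2)
  rcrit <- tcrit / sqrt(n - 2 + tcrit^2)          # 0.576 at n = 12
  expect_equal(rcrit, 0.576, tolerance = 0.001)
  set.seed(88)
  hits <- replicate(1000, {
    abs(pearson_association(rnorm(n), rnorm(n))$r) > rcrit
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.075)
})

test_that("paired changes classify on the signed 5% rule and are scale invariant", {
  expect_equal(as.character(change_classification(1.10, 1.00)), "increased")
  expect_equal(as.character(change_classification(0.97, 1.00)), "unchanged")
  expect_equal(as.character(change_classification(0.90, 1.00)), "decreased")
  # exactly +/-5% is not "a change of >5%"
  expect_equal(as.character(change_classification(1.05, 1.00)), "unchanged")
  for (c_scale in c(0.01, 3, 250)) {
    expect_equal(change_classification(1.2 * c_scale, 1.0 * c_scale),
                 change_classification(1.2, 1.0))
  }
  expect_error(change_classification(1, 0), "undefined")
})

test_that("Mann-Whitney U matches exact enumeration for small samples", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mann_whitney_u(a, b)
  # enumeration oracle: all choose(6,3) label assignments of the pooled sample
  pool <- c(a, b)
  combos <- combn(6, 3)
  U_all <- apply(combos, 2, function(ix) {
    ga <- pool[ix]; gb <- pool[-ix]
    sum(outer(ga, gb, `>`)) + 0.5 * sum(outer(ga, gb, `==`))
  })
  U_obs <- sum(outer(a, b, `>`))
  p_exact <- mean(U_all <= U_obs) + mean(U_all >= length(a) * length(b) - U_obs)
  expect_equal(res$U, U_obs)
  expect_equal(res$p, p_exact)                     # 0.1
  expect_equal(res$p, 0.1)
  # symmetry under label swap
  swap <- mann_whitney_u(b, a)
  expect_equal(swap$p, res$p)
  expect_equal(swap$U, 9 - res$U)
  # identical groups are uninformative
  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2))$p, 1)
})

test_that("Holm-Bonferroni reproduces the hand-executed step-down and controls FWER", {
  hb <- holm_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(hb$adjusted, c(0.03, 0.06, 0.06))
  expect_equal(hb$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(0.02)$adjusted, 0.02)
  expect_false(any(holm_bonferroni(rep(1, 4))$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  # family-wise error on 10^4 simulated global nulls of 5 uniform p-values
  set.seed(314)
  pmat <- matrix(runif(5e4), ncol = 5)
  fwer <- mean(apply(pmat, 1, function(p) any(holm_bonferroni(p)$reject)))
  expect_lte(fwer, 0.055)
})

test_that("the Welch t wrapper is two-sided and symmetric in its groups", {
  set.seed(9)
  a <- rnorm(10, 0, 1); b <- rnorm(12, 1, 2)
  w1 <- welch_t_test(a, b); w2 <- welch_t_test(b, a)
  expect_equal(w1$p, w2$p)
  expect_equal(w1$t, -w2$t)
  expect_lt(welch_t_test(rnorm(30, 0, 0.1), rnorm(30, 5, 0.1))$p, 1e-6)
})

test_that("correlation tables bundle r, p and Holm adjustment per collagen parameter", {
  set.seed(20)
  d <- data.frame(density = rnorm(12), alignment = rnorm(12),
                  length = rnorm(12))
  d$coupled <- d$density * 2 + rnorm(12, 0, 0.01)
  tab <- correlation_table(d, "density", c("alignment", "length", "coupled"))
  expect_equal(nrow(tab), 3L)
  expect_true(tab$significant[tab$parameter == "coupled"])
  expect_true(all(tab$p_adjusted >= tab$p))
})
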