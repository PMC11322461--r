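# classical closed-form sums of squares for a balanced full factorial
balanced_ss <- function(d, response, factors) {
  y <- d[[response]]
  grand <- mean(y)
  n <- nrow(d)
  ss <- list()
  for (k in seq_along(factors)) {
    for (comb in utils::combn(factors, k, simplify = FALSE)) {
      cellm <- stats::aggregate(y, by = d[comb], FUN = mean)
      reps <- n / nrow(cellm)
      ss_full <- sum(reps * (cellm$x - grand)^2)
      lower <- 0
      if (k > 1)
        for (kk in 1:(k - 1))
          for (sub in utils::combn(comb, kk, simplify = FALSE))
            lower <- lower + ss[[paste(sub, collapse = ":")]]
      ss[[paste(comb, collapse = ":")]] <- ss_full - lower
    }
  }
  ss
}

test_that("balanced 2x2x2 ANOVA matches classical closed-form SS", {
  set.seed(9)
  for (i in 1:5) {
    d <- expand.grid(genotype = c("WT", "TG"), sex = c("F", "M"),
                     feeding = c("dark_fed", "light_fed"),
                     rep = 1:4, stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d), 10, 2) +
      2 * (d$genotype == "TG") - 1.5 * (d$sex == "M") *
      (d$feeding == "light_fed")
    a <- factorial_anova(d, "y", c("genotype", "sex", "feeding"))
    oracle <- balanced_ss(d, "y", c("genotype", "sex", "feeding"))
    for (term in names(oracle)) {
      got <- a$sum_sq[a$term == term]
      expect_equal(got, oracle[[term]], tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
    # p-values from the F distribution
    res <- a[a$term == "Residuals", ]
    row <- a[a$term == "genotype", ]
    expect_equal(row$p,
                 pf(row$F, row$df, res$df, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("degenerate ANOVA inputs are handled per convention", {
  d <- expand.grid(g = c("a", "b"), s = c("x", "y"), rep = 1:3,
                   stringsAsFactors = FALSE)
  # constant response: all SS 0
  d$y <- 5
  a <- factorial_anova(d, "y", c("g", "s"))
  expect_true(all(a$sum_sq < 1e-20))
  # pure cell-mean response with one main effect: that F infinite, flagged
  d$y <- ifelse(d$g == "a", 1, 3)
  a2 <- factorial_anova(d, "y", c("g", "s"))
  expect_identical(attr(a2, "flag"), "zero_residual_variance")
  expect_equal(a2$F[a2$term == "g"], Inf)
  expect_lt(a2$sum_sq[a2$term == "s"], 1e-20)
  # empty cell named in the error
  d3 <- d[!(d$g == "a" & d$s == "x"), ]
  expect_error(factorial_anova(d3, "y", c("g", "s")), "g=a, s=x")
})

test_that("pairwise t matches the pooled-variance formula and t.test", {
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1), 0, 2)
    b <- rnorm(sample(3:9, 1), 1, 2)
    got <- pairwise_t(a, b)
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    t_formula <- (mean(a) - mean(b)) /
      (sp * sqrt(1 / length(a) + 1 / length(b)))
    expect_equal(got$t, t_formula, tolerance = 1e-10)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(got$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate t-test groups follow the stated conventions", {
  same <- pairwise_t(c(1, 1, 1), c(1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_identical(attr(same, "flag"), "zero_pooled_variance")
  diff <- pairwise_t(c(0, 0), c(1, 1))
  expect_true(is.infinite(diff$t))
  expect_equal(diff$p, 0)
  ident <- pairwise_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("correlation matrix: closed forms, Bonferroni arithmetic, flags", {
  x <- c(1, 2, 3, 4, 5, 6)
  xc <- x - mean(x)
  sleep <- data.frame(s1 = x, s2 = xc^2 - mean(xc^2))  # s2 orthogonal to x
  cog <- data.frame(c1 = 2 * x + 1, c2 = rnorm(6))
  res <- correlation_matrix(sleep, cog)
  expect_equal(res$r[res$sleep_metric == "s1" &
                       res$cognitive_metric == "c1"], 1, tolerance = 1e-12)
  # orthogonal-by-construction pair: r = 0
  expect_equal(res$r[res$sleep_metric == "s2" &
                       res$cognitive_metric == "c1"], 0, tolerance = 1e-12)
  # Bonferroni: m = 4 pairs here
  expect_equal(res$p_adj, pmin(1, 4 * res$p_raw))
  expect_true(all(res$p_adj >= res$p_raw))
  # affine invariance of r (positive scale)
  res2 <- correlation_matrix(
    data.frame(s1 = 3 * x + 7, s2 = sleep$s2), cog)
  expect_equal(res2$r, res$r, tolerance = 1e-12)
  # zero-variance column skipped and flagged
  res3 <- correlation_matrix(data.frame(s1 = x, s0 = rep(1, 6)), cog)
  expect_equal(nrow(res3), 2)
  expect_true(all(grepl("^s0", attr(res3, "skipped"))))
  # m = 10, p = 0.004 -> adjusted 0.04
  expect_equal(min(1, 10 * 0.004), 0.04)
})
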