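# textbook-formula oracles, written independently of the implementation path

oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_welch_f <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  w <- n / v
  mw <- sum(w * m) / sum(w)
  num <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1)) / (k^2 - 1)
  den <- 1 + 2 * (k - 2) * lam
  f <- num / den
  df2 <- 1 / (3 * lam)
  list(f = f, df1 = k - 1, df2 = df2, p = pf(f, k - 1, df2, lower.tail = FALSE))
}

test_that("Welch t matches the textbook formula to 1e-10", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  got <- tidy(welch_t_test(a, b))
  want <- oracle_welch_t(a, b)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)

  same <- tidy(welch_t_test(a, a))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  withr::with_seed(2, {
    x <- rnorm(10, sd = 0.001)
  })
  far <- tidy(welch_t_test(x, x + 1000))
  expect_lt(far$p_value, 1e-6)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("Welch one-way ANOVA matches its published formula", {
  g <- list(c(1, 2, 3, 4), c(2, 4, 6, 8, 10), c(5, 5.5, 6, 6.5, 7, 7.5))
  got <- tidy(welch_anova(g))
  want <- oracle_welch_f(g)
  expect_equal(got$statistic, want$f, tolerance = 1e-8)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2, tolerance = 1e-8)
  expect_equal(got$p_value, want$p, tolerance = 1e-8)

  ident <- tidy(welch_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  withr::with_seed(3, {
    base <- replicate(3, rnorm(6), simplify = FALSE)
  })
  base[[3]] <- base[[3]] + 100
  expect_lt(tidy(welch_anova(base))$p_value, 1e-6)

  expect_error(welch_anova(list(1:3, 1:3)), "at least 3 groups")
})

test_that("Brown-Forsythe F* reduces to the classical F for balanced groups", {
  # with equal group sizes the Brown-Forsythe statistic equals the ordinary
  # one-way ANOVA F, giving an independent oracle through aov()
  withr::with_seed(4, {
    g <- list(rnorm(8, 0, 1), rnorm(8, 0.5, 2), rnorm(8, 1, 0.5))
  })
  got <- tidy(brown_forsythe_anova(g))
  df <- data.frame(y = unlist(g), f = factor(rep(1:3, each = 8)))
  classical <- summary(aov(y ~ f, df))[[1]]
  expect_equal(got$statistic, classical[["F value"]][1], tolerance = 1e-8)
  expect_equal(got$df1, 2)
  # Satterthwaite df2 lies between min(n_i - 1) and N - k
  expect_gte(got$df2, 7)
  expect_lte(got$df2, 21)

  shifted <- list(rnorm(6), rnorm(6), rnorm(6) + 100)
  expect_lt(tidy(brown_forsythe_anova(shifted))$p_value, 1e-6)
})

test_that("two-way ANOVA matches the hand-computed balanced decomposition", {
  # fixed 2 x 2 x 5 table
  dat <- expand.grid(geno = c("control", "napb_cr"),
                     treat = c("none", "ptz"))
  dat <- dat[rep(1:4, each = 5), ]
  dat$y <- c(1.0, 1.2, 0.9, 1.1, 1.05,
             2.0, 2.3, 1.8, 2.1, 2.2,
             1.5, 1.6, 1.4, 1.7, 1.55,
             3.2, 3.5, 3.0, 3.4, 3.3)
  got <- two_way_anova_tukey(dat, "y", "geno", "treat")
  tbl <- tidy(got)

  # hand decomposition for the balanced design
  n <- 5
  cm <- tapply(dat$y, list(dat$geno, dat$treat), mean)
  gm <- mean(dat$y)
  am <- rowMeans(cm); bm <- colMeans(cm)
  ss_a <- 2 * n * sum((am - gm)^2)
  ss_b <- 2 * n * sum((bm - gm)^2)
  ss_ab <- n * sum((sweep(sweep(cm, 1, am), 2, bm) + gm)^2)
  ss_e <- sum((dat$y - cm[cbind(as.character(dat$geno),
                                as.character(dat$treat))])^2)
  ms_e <- ss_e / 16
  expect_equal(tbl$statistic[tbl$term == "geno"], (ss_a / 1) / ms_e,
               tolerance = 1e-8)
  expect_equal(tbl$statistic[tbl$term == "treat"], (ss_b / 1) / ms_e,
               tolerance = 1e-8)
  expect_equal(tbl$statistic[tbl$term == "geno:treat"], (ss_ab / 1) / ms_e,
               tolerance = 1e-8)

  tukey <- got$details$tukey
  expect_equal(nrow(tukey), choose(4, 2))
  expect_true(all(tukey$adj_p_value >= 0 & tukey$adj_p_value <= 1))

  # all cells identical: every F vanishes
  dat0 <- dat; dat0$y <- rep(1, 20)
  tbl0 <- tidy(two_way_anova_tukey(dat0, "y", "geno", "treat"))
  expect_true(all(tbl0$sum_sq < 1e-20))
})

test_that("additive two-factor data rarely show interaction", {
  withr::with_seed(5, {
    hits <- 0
    for (i in 1:100) {
      d <- expand.grid(a = c("x", "y"), b = c("u", "v"))
      d <- d[rep(1:4, each = 20), ]
      d$y <- 1 + (d$a == "y") * 0.5 + (d$b == "v") * 0.8 + rnorm(80)
      p_int <- tidy(two_way_anova_tukey(d, "y", "a", "b"))
      p_int <- p_int$p_value[p_int$term == "a:b"]
      if (p_int > 0.05) hits <- hits + 1
    }
  })
  expect_gte(hits, 90)
})

test_that("repeated-measures ANOVA handles paired pre/post designs", {
  # pre = post for every subject: no condition effect
  d0 <- data.frame(id = rep(1:6, 2), cond = rep(c("pre", "post"), each = 6),
                   y = rep(rnorm(6), 2))
  r0 <- tidy(rm_one_way_anova(d0, "y", "cond", "id"))
  expect_equal(r0$statistic, 0)

  # constant within-subject shift far above noise
  withr::with_seed(6, {
    base <- rnorm(8)
    d1 <- data.frame(id = rep(1:8, 2),
                     cond = rep(c("pre", "post"), each = 8),
                     y = c(base, base + 5 + rnorm(8, sd = 0.05)))
  })
  expect_lt(tidy(rm_one_way_anova(d1, "y", "cond", "id"))$p_value, 1e-4)

  # two conditions: F equals the squared paired t statistic
  withr::with_seed(7, {
    pre <- rnorm(10); post <- pre + rnorm(10, 0.3)
  })
  d2 <- data.frame(id = rep(1:10, 2),
                   cond = rep(c("pre", "post"), each = 10),
                   y = c(pre, post))
  f <- tidy(rm_one_way_anova(d2, "y", "cond", "id"))
  tt <- t.test(pre, post, paired = TRUE)
  expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(f$p_value, tt$p.value, tolerance = 1e-8)

  # incomplete subjects are dropped before fitting
  d3 <- rbind(d2, data.frame(id = 11, cond = "pre", y = 99))
  expect_equal(tidy(rm_one_way_anova(d3, "y", "cond", "id"))$n_subjects, 10)

  expect_error(rm_one_way_anova(d2[d2$id %in% 1:2, ], "y", "cond", "id"),
               "at least 3")
})

test_that("ROUT flags a gross outlier from a tight cluster and nothing else", {
  res <- rout_outliers(c(10.0, 10.1, 9.9, 10.05, 50))
  expect_true(res$outlier[res$value == 50])
  expect_false(any(res$outlier[res$value != 50]))
  expect_error(rout_outliers(c(1, 2)), "at least 3")
  expect_error(rout_outliers(c(1, 2, NA)), "missing")
})

test_that("ROUT at Q = 1% rarely flags clean Gaussian samples", {
  withr::with_seed(8, {
    frac <- vapply(1:50, function(i) {
      mean(rout_outliers(rnorm(100), q = 1)$outlier)
    }, numeric(1))
  })
  expect_gte(mean(frac <= 0.05), 0.95)
})

test_that("null permutations give approximately uniform p values", {
  withr::with_seed(9, {
    x <- rnorm(24)
    p <- vapply(1:200, function(i) {
      g <- sample(rep(1:2, each = 12))
      tidy(welch_t_test(x[g == 1], x[g == 2]))$p_value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("glance gives the one-line summary of a test object", {
  g <- glance(welch_t_test(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(nrow(g), 1)
  expect_true(all(c("statistic", "p_value") %in% names(g)))
})
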