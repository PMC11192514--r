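test_that("mixed ANOVA reproduces aov error strata on balanced data", {
  set.seed(61)
  dd <- expand.grid(subject = paste0("s", 1:12), hemisphere = c("L", "R"),
                    condition = c("speak", "listen"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dd$group <- ifelse(match(dd$subject, paste0("s", 1:12)) <= 6, "ctl", "aph")
  subj_eff <- rnorm(12)
  dd$value <- rnorm(nrow(dd)) + 2 * (dd$condition == "listen") +
    0.5 * (dd$group == "ctl") + subj_eff[match(dd$subject, paste0("s", 1:12))]
  a <- mixed_anova_type3(dd, "value", "subject",
                         c("hemisphere", "condition"), "group")
  f <- summary(stats::aov(value ~ group * hemisphere * condition +
                            Error(factor(subject) / (hemisphere * condition)),
                          data = dd))
  pick <- function(stratum, term) {
    tab <- f[[stratum]][[1]]
    row <- trimws(rownames(tab)) == term
    c(tab[row, "Sum Sq"], tab[row, "F value"], tab[row, "Pr(>F)"])
  }
  for (chk in list(
    list("Error: factor(subject)", "group", "group"),
    list("Error: factor(subject):hemisphere", "hemisphere", "hemisphere"),
    list("Error: factor(subject):hemisphere", "group:hemisphere", "group:hemisphere"),
    list("Error: factor(subject):condition", "condition", "condition"),
    list("Error: factor(subject):hemisphere:condition", "hemisphere:condition",
         "hemisphere:condition"))) {
    ref <- pick(chk[[1]], chk[[2]])
    got <- a[a$term == chk[[3]], ]
    expect_equal(got$ss, ref[1], tolerance = 1e-10)
    expect_equal(got$F, ref[2], tolerance = 1e-10)
    expect_equal(got$p, ref[3], tolerance = 1e-10)
  }
})

test_that("two-condition within-subject F equals the paired t squared", {
  set.seed(62)
  for (i in 1:5) {
    d <- expand.grid(subject = paste0("s", 1:9), condition = c("a", "b"),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d)) + 1.2 * (d$condition == "b")
    a <- mixed_anova_type3(d, "value", "subject", "condition")
    tt <- stats::t.test(d$value[d$condition == "a"], d$value[d$condition == "b"],
                        paired = TRUE)
    expect_equal(a$F[a$term == "condition"], unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(a$p[a$term == "condition"], tt$p.value, tolerance = 1e-10)
  }
})

test_that("mixed ANOVA validates its design", {
  d <- expand.grid(subject = paste0("s", 1:6), condition = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("x", "y"), each = 3)[match(d$subject, paste0("s", 1:6))]
  d$value <- rnorm(nrow(d))
  bad <- d
  bad$group[1] <- "y"   # s1 now appears in both groups
  expect_error(mixed_anova_type3(bad, "value", "subject", "condition", "group"),
               "more than one")
  miss <- d[-1, ]
  expect_error(mixed_anova_type3(miss, "value", "subject", "condition", "group"),
               "empty cell: subject s1")
  expect_message(
    mixed_anova_type3(miss, "value", "subject", "condition", "group",
                      drop_incomplete = TRUE),
    "dropping")
  dup <- rbind(d, d[1, ])
  expect_error(mixed_anova_type3(dup, "value", "subject", "condition", "group"),
               "duplicate")
})

test_that("ANOVA sums of squares are invariant to factor-level relabeling", {
  set.seed(63)
  d <- expand.grid(subject = paste0("s", 1:10), w = c("l", "r"),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("a", "b"), each = 5)[match(d$subject, paste0("s", 1:10))]
  d$value <- rnorm(nrow(d))
  a1 <- mixed_anova_type3(d, "value", "subject", "w", "group")
  d2 <- d
  d2$w <- ifelse(d$w == "l", "zz_left", "aa_right")
  d2$group <- ifelse(d$group == "a", "grp2", "grp1")
  a2 <- mixed_anova_type3(d2, "value", "subject", "w", "group")
  expect_equal(sort(a1$ss), sort(a2$ss), tolerance = 1e-10)
  expect_true(all(a1$p >= 0 & a1$p <= 1))
})

test_that("correlations match their closed-form/rank-recursion oracles", {
  set.seed(64)
  x <- rnorm(30)
  expect_equal(correlate(x, exp(x), "spearman")$estimate, 1)

  # partial correlation via the first-order recursion formula (independent
  # of the residualization route used by the implementation)
  n <- 200
  z <- rnorm(n)
  xx <- 0.6 * z + rnorm(n)
  yy <- -0.4 * z + 0.5 * xx + rnorm(n)
  r_xy <- cor(xx, yy); r_xz <- cor(xx, z); r_yz <- cor(yy, z)
  oracle <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  got <- correlate(xx, yy, "pearson", covariates = z)
  expect_equal(got$estimate, oracle, tolerance = 1e-10)

  rx <- rank(xx); ry <- rank(yy); rz <- rank(z)
  r_xy <- cor(rx, ry); r_xz <- cor(rx, rz); r_yz <- cor(ry, rz)
  oracle_s <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  got_s <- correlate(xx, yy, "partial_spearman", covariates = z)
  expect_equal(got_s$estimate, oracle_s, tolerance = 1e-10)
  expect_equal(got_s$n, n)

  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlate(xx, yy, "partial_spearman"), "requires covariates")
  expect_error(correlate(1:5, 1:4), "equal length")
})

test_that("plain correlations agree with cor.test", {
  set.seed(65)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  ct <- cor.test(x, y)
  got <- correlate(x, y, "pearson")
  expect_equal(got$estimate, unname(ct$estimate))
  expect_equal(got$p, ct$p.value)
  got_s <- correlate(x, y, "spearman")
  expect_equal(got_s$estimate, unname(cor.test(x, y, method = "spearman")$estimate))
})

test_that("t tests use the pooled form and guard degenerate variance", {
  a <- c(3, 3, 3)
  expect_equal(t_tests(a, a)$statistic, 0)
  expect_equal(t_tests(a, a)$p, 1)
  expect_error(t_tests(c(1, 1, 1)), "zero variance")
  expect_error(t_tests(c(1, 1, 1), c(2, 2, 2)), "zero variance")

  set.seed(66)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  got <- t_tests(x, y)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$df, 28)   # pooled df = n1 + n2 - 2
  expect_equal(got$p, ref$p.value)
  refw <- stats::t.test(x, y)
  expect_equal(t_tests(x, y, var_equal = FALSE)$df, unname(refw$parameter))
  refp <- stats::t.test(x, y, paired = TRUE)
  expect_equal(t_tests(x, y, paired = TRUE)$statistic, unname(refp$statistic))
  ref1 <- stats::t.test(x, mu = 0.2)
  expect_equal(t_tests(x, mu = 0.2)$p, ref1$p.value)
})

test_that("pure-tone averages are per-ear means over 500/1000/2000 Hz", {
  thr <- data.frame(ear = rep(c("left", "right"), each = 3),
                    freq_hz = rep(c(500, 1000, 2000), 2),
                    db_hl = c(10, 20, 30, 0, 0, 0))
  pta <- pure_tone_average(thr)
  expect_equal(unname(pta["left"]), 20)
  expect_equal(unname(pta["right"]), 0)
  thr2 <- thr
  thr2$db_hl[thr2$ear == "right" & thr2$freq_hz == 1000] <- 55
  pta2 <- pure_tone_average(thr2)
  expect_equal(unname(pta2["left"]), 20)   # left unchanged when right edited
  expect_error(pure_tone_average(thr[-2, ]), "1000 Hz.*left")
})
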