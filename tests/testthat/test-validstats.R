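test_that("with two conditions the GG-corrected RM-ANOVA is the paired t-test", {
  set.seed(1)
  for (rep in 1:10) {
    m <- cbind(NT = rnorm(6, 10), trt = rnorm(6, 11))
    res <- rm_anova_gg(m)
    expect_equal(res$epsilon, 1)
    tt <- t.test(m[, 2], m[, 1], paired = TRUE)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("epsilon stays inside its analytic bounds on random matrices", {
  set.seed(2)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    k <- sample(2:6, 1)
    res <- rm_anova_gg(matrix(rnorm(n * k), n, k))
    expect_gte(res$epsilon, 1 / (k - 1))
    expect_lte(res$epsilon, 1)
  }
})

test_that("epsilon approaches 1 under exact compound symmetry", {
  set.seed(3)
  k <- 4
  eps_by_n <- sapply(c(20, 2000), function(n) {
    subj <- rnorm(n, sd = 2)
    m <- outer(subj, rep(1, k)) + matrix(rnorm(n * k), n, k)
    rm_anova_gg(m)$epsilon
  })
  expect_gt(eps_by_n[2], eps_by_n[1] - 0.05)
  expect_gt(eps_by_n[2], 0.99)
})

test_that("RM-ANOVA matches aov and is invariant to per-subject constants", {
  set.seed(4)
  n <- 5; k <- 3
  m <- matrix(rnorm(n * k, 10), n, k)
  res <- rm_anova_gg(m)
  d <- data.frame(y = as.vector(m), subj = factor(rep(1:n, k)),
                  cond = factor(rep(1:k, each = n)))
  fit <- summary(stats::aov(y ~ cond + Error(subj), data = d))
  f_aov <- fit[["Error: Within"]][[1]]["cond", "F value"]
  expect_equal(res$F, f_aov, tolerance = 1e-10)
  shifted <- m + rnorm(n, sd = 5)  # recycled per subject (column-wise rows)
  res2 <- rm_anova_gg(shifted)
  expect_equal(res$F, res2$F, tolerance = 1e-8)
  expect_equal(res$p, res2$p, tolerance = 1e-8)
  # complete-case handling and degenerate input
  m_na <- rbind(m, c(NA, 1, 2))
  expect_equal(rm_anova_gg(m_na)$n, n)
  expect_error(rm_anova_gg(m[1, , drop = FALSE]), "insufficient")
})

test_that("dunnett_rm reduces to the paired t-test at k = 2", {
  set.seed(5)
  m <- cbind(NT = rnorm(7, 10), trt = rnorm(7, 12))
  res <- dunnett_rm(m, control = "NT")
  tt <- t.test(m[, "trt"], m[, "NT"], paired = TRUE)
  expect_equal(res$p_adj, tt$p.value, tolerance = 1e-10)
  # a condition identical to the control has t = 0, p_adj = 1
  m2 <- cbind(NT = c(1, 2, 3), a = c(1, 2, 3), b = c(2.2, 0.7, 3.6))
  res2 <- dunnett_rm(m2, "NT")
  expect_equal(res2$p_adj[res2$condition == "a"], 1)
  # fully degenerate within-subject variance is an error
  expect_error(dunnett_rm(cbind(NT = c(1, 2), a = c(2, 3)), "NT"),
               "degenerate")
})

test_that("dunnett_rm agrees with a Monte-Carlo max-|t| oracle", {
  set.seed(6)
  n <- 6; k <- 4
  subj <- rnorm(n, sd = 1.5)
  m <- outer(subj, rep(1, k)) + matrix(rnorm(n * k), n, k)
  colnames(m) <- c("NT", "a", "b", "c")
  res <- dunnett_rm(m, "NT")
  # null distribution of max_j |T_j| with correlation 1/2, df (n-1)(k-1)
  B <- 2e5
  set.seed(7)
  z0 <- rnorm(B)
  s <- sqrt(rchisq(B, (n - 1) * (k - 1)) / ((n - 1) * (k - 1)))
  mx <- rep(0, B)
  for (j in 1:(k - 1)) {
    mx <- pmax(mx, abs(sqrt(0.5) * z0 + sqrt(0.5) * rnorm(B)) / s)
  }
  for (i in seq_len(nrow(res))) {
    phat <- mean(mx >= abs(res$tstat[i]))
    tol <- 3 * sqrt(phat * (1 - phat) / B) + 3 / B
    expect_lt(abs(res$p_adj[i] - phat), tol + 1e-12)
  }
})

test_that("ttest covers the pooled, paired and degenerate cases", {
  expect_equal(ttest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(ttest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$t, 0)
  expect_equal(ttest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p, 1)
  set.seed(8)
  x <- rnorm(6, 10); y <- rnorm(6, 11)
  res <- ttest(x, y)
  expect_equal(res$p, t.test(x, y, var.equal = TRUE)$p.value)
  resw <- ttest(x, y, welch = TRUE)
  expect_equal(resw$p, t.test(x, y)$p.value)
  expect_error(ttest(c(1, 1, 1), c(2, 2, 2)), "degenerate")
  expect_error(ttest(1, c(1, 2)), "at least 2")
  # large-sample permutation cross-check of the pooled t on a fixed 6-vs-6
  x6 <- c(9.1, 10.2, 10.8, 9.7, 10.1, 9.9)
  y6 <- c(11.0, 11.8, 10.9, 12.1, 11.2, 11.5)
  obs <- ttest(x6, y6)
  pooled <- c(x6, y6)
  combs <- combn(12, 6)
  tstats <- apply(combs, 2, function(ix) {
    ttest(pooled[ix], pooled[-ix])$t
  })
  perm_p <- mean(abs(tstats) >= abs(obs$t))
  expect_lt(abs(perm_p - obs$p), 0.02)
})

test_that("2^(-dCT) follows its closed form and censors n.d. samples", {
  expect_equal(ddct(20, 20)$rel_expr, 1)
  expect_equal(ddct(21, 20)$rel_expr, 0.5)
  expect_equal(ddct(18, 20)$rel_expr, 4)
  # shift equivariance: adding c to both CTs changes nothing
  set.seed(9)
  ct_t <- runif(8, 18, 30); ct_r <- runif(8, 18, 22)
  expect_equal(ddct(ct_t + 3.3, ct_r + 3.3)$rel_expr,
               ddct(ct_t, ct_r)$rel_expr)
  # log2-domain recomputation oracle
  expect_equal(log2(ddct(ct_t, ct_r)$rel_expr), -(ct_t - ct_r))
  nd <- ddct(c(20, NA), c(20, 20), detected = c(TRUE, FALSE))
  expect_true(is.na(nd$rel_expr[2]))
  expect_equal(attr(nd, "n_detected"), 1)
  expect_error(ddct(c(20, -1), c(20, 20)), "positive")
})

test_that("luciferase normalization sets each construct's NT arm mean to 1", {
  w <- data.frame(
    construct = rep(c("WT", "WT", "WT", "MUT", "MUT"), each = 1),
    arm = c("NT", "NT", "miR", "NT", "miR"),
    firefly = c(2.0, 4.0, 1.5, 6.0, 6.3),
    renilla = c(1, 1, 1, 2, 2)
  )
  out <- luciferase_relative(w)
  expect_equal(out$rel_activity[out$construct == "WT" & out$arm == "miR"], 0.5)
  for (con in unique(out$construct)) {
    expect_equal(mean(out$rel_activity[out$construct == con &
                                         out$arm == "NT"]), 1)
  }
  # firefly == renilla everywhere -> all activities 1
  eq <- data.frame(construct = "WT", arm = c("NT", "NT", "miR"),
                   firefly = c(3, 5, 4), renilla = c(3, 5, 4))
  expect_equal(luciferase_relative(eq)$rel_activity, c(1, 1, 1))
  # scale invariance
  w2 <- transform(w, firefly = firefly * 7.7, renilla = renilla * 7.7)
  expect_equal(luciferase_relative(w2)$rel_activity, out$rel_activity)
  expect_warning(
    luciferase_relative(rbind(w, data.frame(construct = "WT", arm = "NT",
                                            firefly = 1, renilla = 0))),
    "Renilla"
  )
  expect_error(luciferase_relative(w[w$arm != "NT", ]), "NT")
})

test_that("planted luciferase repression is recovered", {
  plate <- simulate_luciferase_plate(repression = c(WT = 0.6, MUT = 1.0),
                                     n_wells = 8, seed = 10)
  out <- luciferase_relative(plate)
  wt <- mean(out$rel_activity[out$construct == "WT" & out$arm == "miR"])
  mut <- mean(out$rel_activity[out$construct == "MUT" & out$arm == "miR"])
  expect_equal(wt, 0.6, tolerance = 0.12)
  expect_equal(mut, 1.0, tolerance = 0.12)
})

test_that("CFU/ml estimation selects the countable dilution and scales", {
  counts <- rbind(rep(200, 6), rep(8, 6), rep(1, 6))
  res <- cfu_per_ml(counts, dilutions = c(3, 4, 5))
  expect_equal(res$cfu_per_ml, 8 * 100 * 10^4)
  expect_equal(res$dilution, 4)
  expect_equal(res$cv, 0)
  expect_error(cfu_per_ml(matrix(0, 3, 6), 3:5), "sparse")
  expect_error(cfu_per_ml(matrix(500, 3, 6), 3:5), "dense")
  expect_error(cfu_per_ml(rbind(rep(100, 6), rep(1, 6)), c(3, 4)), "jumps")
  expect_error(cfu_per_ml(matrix(1.5, 1, 6), 4), "integer")
})
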