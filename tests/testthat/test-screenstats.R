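fake_summaries <- function(values, roles, treatments, plate = 1) {
  data.frame(
    plate_id = plate,
    well = sprintf("W%02d", seq_along(values)),
    treatment_id = treatments, role = roles,
    pct_fitc_pos = values, mfi_fitc = values * 10,
    stringsAsFactors = FALSE
  )
}

test_that("plate normalization divides by the on-plate NT mean", {
  s <- fake_summaries(c(40, 50, 60, 25), c("NT", "NT", "NT", "miRNA"),
                      c("NT", "NT", "NT", "m1"))
  out <- normalize_plate(s, "pct_fitc_pos")
  expect_equal(out$rel_pct_fitc_pos[4], 25 / 50)
  # NT wells always average exactly 1
  expect_equal(mean(out$rel_pct_fitc_pos[out$role == "NT"]), 1)
  # recompute oracle: every well divided by the same NT mean
  expect_equal(out$rel_pct_fitc_pos, s$pct_fitc_pos / mean(c(40, 50, 60)))
  bad <- fake_summaries(c(0, 0, 5), c("NT", "NT", "miRNA"),
                        c("NT", "NT", "m1"))
  expect_error(normalize_plate(bad, "pct_fitc_pos"), "zero or undefined")
})

test_that("Dunnett adjustment reduces to the pooled t-test at k = 2", {
  g <- list(NT = c(10.1, 11.4, 9.8), m1 = c(13.0, 12.1, 14.2))
  res <- anova_dunnett(g, control = "NT")
  tt <- t.test(g$m1, g$NT, var.equal = TRUE)
  expect_equal(res$p_adj, tt$p.value, tolerance = 1e-12)
  expect_equal(res$p_unadj, tt$p.value, tolerance = 1e-12)
  expect_equal(res$tstat, unname(tt$statistic), tolerance = 1e-12)
})

test_that("treatments identical to the control give p_adj near 1", {
  g <- list(NT = c(1, 2, 3, 4), m1 = c(1, 2, 3, 4), m2 = c(4, 3, 2, 1))
  res <- anova_dunnett(g)
  expect_true(all(res$p_adj > 0.999))
})

test_that("Dunnett p-values dominate the unadjusted t-test p-values", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    g <- c(list(NT = rnorm(4)),
           setNames(lapply(seq_len(k - 1), function(i) rnorm(sample(3:5, 1))),
                    paste0("m", seq_len(k - 1))))
    res <- anova_dunnett(g)
    expect_true(all(res$p_adj >= res$p_unadj - 1e-10))
    expect_true(all(res$p_adj > 0 & res$p_adj <= 1))
    # adjusted p is monotone in |t|
    ord <- order(abs(res$tstat))
    expect_true(all(diff(res$p_adj[ord]) <= 1e-10))
  }
})

test_that("anova_dunnett matches multcomp::glht on a fixed dataset", {
  skip_if_not_installed("multcomp")
  set.seed(8)
  g <- list(NT = rnorm(4, 10), a = rnorm(3, 11), b = rnorm(5, 9),
            c = rnorm(4, 10))
  res <- anova_dunnett(g)
  d <- data.frame(
    y = unlist(g),
    grp = factor(rep(names(g), lengths(g)), levels = names(g))
  )
  fit <- stats::aov(y ~ grp, data = d)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett")))
  expect_equal(res$p_adj, as.numeric(mc$test$pvalues), tolerance = 5e-3)
})

test_that("degenerate and missing-value inputs are handled as specified", {
  expect_error(anova_dunnett(list(NT = c(1, 1), m1 = c(1, 1))), "degenerate")
  expect_warning(
    res <- anova_dunnett(list(NT = c(1, 2, NA), m1 = c(3, 4, 5))),
    "non-finite"
  )
  expect_equal(nrow(res), 1)
  expect_error(anova_dunnett(list(NT = c(NA, NA, 1), m1 = c(1, 2))),
               "fewer than 2")
  expect_error(anova_dunnett(list(m1 = c(1, 2)), control = "NT"), "control")
})

test_that("dual cut-off hit calling uses inclusive boundaries", {
  stats <- data.frame(
    mirna = c("a", "b", "c", "d", "e"),
    rel_pct = c(0.75, 0.85, 0.80, 1.20, 1.19),
    p_adj_pct = c(0.005, 0.0001, 0.01, 0.01, 0.001),
    rel_mfi = c(1, 1, 1, 1, 1),
    p_adj_mfi = c(1, 1, 1, 1, 1)
  )
  out <- call_hits(stats, hit_criteria())
  expect_equal(out$hit_pct, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$hit_mfi, rep(FALSE, 5))
  expect_equal(out$hit_any, out$hit_pct)
  expect_equal(out$direction_pct,
               c("decrease", "decrease", "decrease", "increase", "increase"))
  # p above alpha fails even with a large fold change
  out2 <- call_hits(transform(stats, p_adj_pct = 0.011), hit_criteria())
  expect_false(any(out2$hit_pct))
})

test_that("hit criteria validate their fields", {
  expect_error(hit_criteria(rel_low = 1.1), "rel_low")
  expect_error(hit_criteria(alpha = 0), "alpha")
})

test_that("two-stage intersection enforces direction and the Venn identity", {
  stage <- function(mirna, rel, p, rel_mfi = 1, p_mfi = 1) {
    call_hits(data.frame(mirna = mirna, rel_pct = rel, p_adj_pct = p,
                         rel_mfi = rel_mfi, p_adj_mfi = p_mfi),
              hit_criteria())
  }
  s1 <- stage(c("a", "b", "c"), c(0.5, 0.6, 1.5), c(0.001, 0.001, 0.001),
              rel_mfi = c(0.5, 1.0, 1.4), p_mfi = c(0.001, 1, 0.001))
  s2 <- stage(c("a", "b", "c"), c(0.55, 1.6, 1.4), c(0.002, 0.001, 0.002),
              rel_mfi = c(0.45, 1.0, 1.5), p_mfi = c(0.002, 1, 0.002))
  out <- two_stage_intersect(s1, s2)
  # a: consistent decrease on both readouts -> "both"
  expect_equal(out$venn_class[out$mirna == "a"], "both")
  # b: stage-2 direction flips -> not a final hit
  expect_false(out$final_hit[out$mirna == "b"])
  # c: consistent on both readouts
  expect_true(out$final_hit[out$mirna == "c"])
  v <- attr(out, "venn")
  expect_equal(v$pct + v$mfi - v$union, v$both)
  # stage 2 restricted to stage-1 hits
  s2_bad <- stage("zzz", 0.5, 0.001)
  expect_error(two_stage_intersect(s1, s2_bad), "not stage-1 hits")
})

test_that("venn arithmetic reproduces inclusion-exclusion", {
  v <- venn_counts(5, 7, 9)
  expect_equal(v$both, 3)
  expect_equal(v$pct_only, 2)
  expect_equal(v$mfi_only, 4)
  expect_error(venn_counts(2, 2, 9), "inconsistent")
})

test_that("hit calling is invariant to a common plate-wide rescaling", {
  sim <- simulate_screen(6, seed = 17, n_events = 2000,
                         effects = list(
                           `miR-sim-0001` = effect_profile("miR-sim-0001",
                                                           phago_effect = 0.5)
                         ))
  summaries <- gate_screen(sim, gate_config())
  h1 <- screen_stage(summaries, hit_criteria())
  scaled <- summaries
  scaled$pct_fitc_pos <- scaled$pct_fitc_pos * 3.7
  scaled$mfi_fitc <- scaled$mfi_fitc * 0.21
  h2 <- screen_stage(scaled, hit_criteria())
  expect_equal(h1$rel_pct, h2$rel_pct, tolerance = 1e-12)
  expect_equal(h1$rel_mfi, h2$rel_mfi, tolerance = 1e-12)
  expect_equal(h1$p_adj_pct, h2$p_adj_pct, tolerance = 1e-9)
  expect_identical(h1$hit_any, h2$hit_any)
  # and to the processing order of plates
  rev_summaries <- summaries[rev(seq_len(nrow(summaries))), ]
  h3 <- screen_stage(rev_summaries, hit_criteria())
  h3 <- h3[match(h1$mirna, h3$mirna), ]
  expect_equal(h1$rel_pct, h3$rel_pct)
  expect_equal(h1$p_adj_pct, h3$p_adj_pct)
})

test_that("screen_stage recovers a strongly planted effect", {
  sim <- simulate_screen(
    8, seed = 23, n_events = 2000,
    effects = list(`miR-sim-0003` = effect_profile("miR-sim-0003",
                                                   phago_effect = 0.5))
  )
  summaries <- gate_screen(sim, gate_config())
  hits <- screen_stage(summaries, hit_criteria())
  expect_true(hits$hit_pct[hits$mirna == "miR-sim-0003"])
  expect_equal(hits$direction_pct[hits$mirna == "miR-sim-0003"], "decrease")
  expect_false(any(hits$hit_any[hits$mirna != "miR-sim-0003"]))
  expect_lt(hits$rel_pct[hits$mirna == "miR-sim-0003"], 0.6)
})
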