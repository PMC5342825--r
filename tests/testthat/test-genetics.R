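# Mendelian expectations, proportion tests, Fisher's exact test,
# delta-delta-Ct, ANOVA and the Bonferroni display rule.

test_that("the balancer complementation cross expects 1/3 survival", {
  cs <- cross_spec(c("FlpStop_ND", "Balancer"), c("Null", "Balancer"),
                   scored_class = c("FlpStop_ND", "Null"))
  expect_equal(expected_survival(cs), 1 / 3)
  # survival probabilities sum to one over surviving classes
  z <- flashresp:::zygote_classes(cs)
  alive <- !(z$genotype %in% cs$lethal_keys)
  expect_equal(sum(z$prob[alive]) / sum(z$prob[alive]), 1)
})

test_that("Punnett enumeration handles no-lethal and lethal-scored cases", {
  quarter <- cross_spec(c("FlpStop_ND", "Balancer"), c("Null", "Balancer"),
                        scored_class = c("FlpStop_ND", "Null"),
                        balancer_lethal = FALSE)
  expect_equal(expected_survival(quarter), 1 / 4)
  dead <- cross_spec(c("FlpStop_D", "Balancer"), c("Null", "Balancer"),
                     lethal_genotypes = list(c("FlpStop_D", "Null")),
                     scored_class = c("FlpStop_D", "Null"))
  expect_equal(expected_survival(dead), 0)
})

test_that("the one-proportion z-test matches its closed form", {
  at_null <- one_proportion_ztest(100, 300, 1 / 3)
  expect_equal(at_null$statistic, 0)
  expect_equal(at_null$p_value, 1)
  none <- one_proportion_ztest(0, 300, 1 / 3)
  z_expect <- (-1 / 3) / sqrt((1 / 3) * (2 / 3) / 300)
  expect_equal(none$statistic, z_expect, tolerance = 1e-12)
  expect_equal(none$p_value, 2 * pnorm(-abs(z_expect)), tolerance = 1e-12)
  expect_error(one_proportion_ztest(5, 0, 0.5), "n must")
})

test_that("the z approximation tracks the exact binomial for n >= 100", {
  for (n in c(100, 300, 1000)) {
    # the approximation error is dominated by the binomial lattice, whose
    # scale is the point mass at the mode
    lattice <- dbinom(round(n / 3), n, 1 / 3)
    for (k in round(n * c(0.25, 1 / 3, 0.45))) {
      pz <- one_proportion_ztest(k, n, 1 / 3)$p_value
      pe <- one_proportion_exact(k, n, 1 / 3)$p_value
      expect_lt(abs(pz - pe), lattice)
    }
  }
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  flat <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$p_value, 1)
  set.seed(13)
  for (i in 1:60) {
    repeat {
      tab <- matrix(rmultinom(1, sample(8:40, 1), rep(1 / 4, 4)), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_enumeration_p(tab), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(tab))$p_value, p, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("delta-delta-Ct follows the printed doubling formula", {
  mk_ct <- function(shift, n_bio = 3) {
    rows <- expand.grid(tech_rep = 1:2, bio_rep = seq_len(n_bio),
                        gene = c("target", "reference"),
                        genotype = c("ND", "D"), stringsAsFactors = FALSE)
    rows$ct <- ifelse(rows$gene == "reference", 15,
                      ifelse(rows$genotype == "ND", 20, 20 + shift))
    rows
  }
  expect_equal(delta_delta_ct(mk_ct(1))$percent, 50)
  expect_equal(delta_delta_ct(mk_ct(2))$percent, 25)
  same <- delta_delta_ct(mk_ct(0))
  expect_equal(same$percent, 100)
  expect_equal(same$test$p_value, 1)
  # per-replicate values are anchored to the ND mean
  res <- delta_delta_ct(mk_ct(1))
  nd <- res$per_replicate$genotype == "ND"
  expect_equal(mean(res$per_replicate$normalized_pct[nd]), 100)
  expect_equal(res$per_replicate$normalized_pct[!nd], rep(50, 3))
  expect_error(delta_delta_ct(mk_ct(1)[mk_ct(1)$gene == "target", ]),
               "reference")
})

test_that("delta-delta-Ct is invariant to per-plate Ct offsets", {
  ct <- generate_ct_table(0.4, replicate_sd = 0.1, n_bio = 4, seed = 21)
  base <- delta_delta_ct(ct)
  shifted <- ct
  nd <- shifted$genotype == "ND"
  shifted$ct[nd] <- shifted$ct[nd] + 1.7 # whole-plate offset on one run
  res <- delta_delta_ct(shifted)
  expect_equal(res$percent, base$percent, tolerance = 1e-12)
  expect_equal(res$test$p_value, base$test$p_value, tolerance = 1e-12)
})

test_that("one-way ANOVA matches the textbook closed form", {
  same <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(19)
  for (i in 1:20) {
    g <- lapply(seq_len(sample(2:4, 1)),
                function(j) rnorm(sample(3:10, 1), mean = j / 2))
    names(g) <- paste0("g", seq_along(g))
    got <- anova_oneway(g)
    want <- anova_closed_form(g)
    expect_equal(got$statistic, want$f, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  # two groups: F equals the square of the pooled t statistic
  x <- rnorm(8); y <- rnorm(9, 1)
  expect_equal(anova_oneway(list(x = x, y = y))$statistic,
               t_closed_form(x, y)$t^2, tolerance = 1e-10)
  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Bonferroni adjustment doubles raw p and caps at one", {
  set.seed(23)
  e <- rnorm(12, 0.6); c1 <- rnorm(12); c2 <- rnorm(12)
  ph <- posthoc_bonferroni(e, c1, c2, m = 2)
  expect_equal(ph$vs_control_a$p_value,
               min(1, 2 * ph$raw_p[["control_a"]]), tolerance = 1e-12)
  expect_equal(ph$vs_control_b$p_value,
               min(1, 2 * ph$raw_p[["control_b"]]), tolerance = 1e-12)
  # raw p matches the pooled-variance closed form
  expect_equal(ph$raw_p[["control_a"]], t_closed_form(e, c1)$p,
               tolerance = 1e-10)
})

test_that("asterisks appear only when both controls differ, at the less
           significant tier", {
  set.seed(29)
  ctrl <- function(n = 20) rnorm(n, 0, 0.05)
  # strong vs control_a, moderate vs control_b: display the weaker tier
  e <- rnorm(20, 1, 0.05)
  far <- ctrl()            # |mean gap| = 1 -> astronomically significant
  near <- rnorm(20, 0.85, 0.2) # significant but weaker
  ph <- posthoc_bonferroni(e, far, near)
  expect_true(ph$display)
  expect_equal(ph$display_tier,
               significance_tier(max(ph$vs_control_a$p_value,
                                     ph$vs_control_b$p_value)))
  expect_true(ph$vs_control_a$p_value < ph$vs_control_b$p_value)

  # one comparison ns: no asterisks regardless of the other
  ph2 <- posthoc_bonferroni(e, far, e) # identical to control_b: p = 1
  expect_equal(ph2$vs_control_b$p_value, 1)
  expect_false(ph2$display)
  expect_equal(ph2$display_tier, "ns")
  expect_error(posthoc_bonferroni(1, c(1, 2), c(1, 2)), "at least 2")
})

test_that("significance tiers follow the 0.05/0.01/0.001 cutoffs", {
  expect_equal(significance_tier(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
  tr <- test_result("demo", 1.5, 0.004, 10)
  expect_equal(tr$tier, "**")
})
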