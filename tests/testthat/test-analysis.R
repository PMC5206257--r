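# log D conversion, deviation statistics, BEDROC diagnostics.

test_that("log D reproduces published per-compound values and is antisymmetric", {
  expect_equal(log_d(-55.2, -63.8), 1.51, tolerance = 0.02)
  expect_equal(log_d(-55.8, -50.5), -0.93, tolerance = 0.02)
  expect_identical(log_d(-60, -60), 0)
  set.seed(1)
  a <- rnorm(20, -60, 10); b <- rnorm(20, -60, 10)
  expect_equal(log_d(a, b), -log_d(b, a))
})

test_that("log D uncertainty propagates in quadrature", {
  # quadrature form, exact
  expect_equal(propagate_se(0.3, 0.4), 0.5 / (2.3 * 8.314 * 298 / 1000))
  expect_identical(propagate_se(0, 0), 0)
  # published per-compound values are printed at 2 decimals
  expect_equal(round(propagate_se(0.1, 0.1), 2), 0.02)
  expect_equal(round(propagate_se(1.9, 0.6), 2), 0.35)
  expect_error(propagate_se(-0.1, 0.1))
})

test_that("summary metrics match hand arithmetic and flag zero variance", {
  m <- summary_metrics(c(1, 2, 3), c(1, 1, 1))
  expect_equal(m$mad, 1)
  expect_equal(m$msd, 1)
  expect_equal(m$rmsd, sqrt(5 / 3))
  expect_equal(m$r_state, "undefined: zero variance")
  expect_true(is.na(m$r))
  ident <- summary_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ident$mad, 0)
  expect_identical(ident$rmsd, 0)
  expect_equal(ident$r, 1)
})

test_that("sign accuracy counts matches with the documented zero rule", {
  expect_equal(sign_accuracy(c(1, -2, 3), c(2, -1, 4)), 100)
  expect_equal(sign_accuracy(c(1, -2), c(-1, 2)), 0)
  # an exact zero on one side only is a mismatch; both zero matches
  expect_equal(sign_accuracy(c(0, 0), c(1, 0)), 50)
})

test_that("significance filtering excludes weak values and handles degeneracy", {
  rec <- data.frame(logd_pred = c(3, 0.1, -2), se_pred = c(0.1, 0.5, 0.1),
                    logd_exp = c(2, 1, -1), err_exp = c(0.2, 0.2, 0.2))
  # all-significant subset equals the unfiltered accuracy on that subset
  strong <- rec[c(1, 3), ]
  expect_equal(as.numeric(sign_accuracy_filtered(strong)),
               sign_accuracy(strong$logd_pred, strong$logd_exp))
  filt <- sign_accuracy_filtered(rec)
  expect_equal(attr(filt, "n_used"), 2L)
  # everything insignificant: explicit undefined result
  weak <- data.frame(logd_pred = 0.1, se_pred = 1, logd_exp = 0.1,
                     err_exp = 1)
  und <- sign_accuracy_filtered(weak)
  expect_true(is.na(und))
  expect_equal(attr(und, "n_used"), 0L)
})

test_that("deviation extremes report ids with first-occurrence tie-breaking", {
  ex <- deviation_extremes(c(1, 5, 3), c(1, 1, 1), ids = c("a", "b", "c"))
  expect_equal(ex$max, 4)
  expect_equal(ex$max_id, "b")
  expect_equal(ex$second, 2)
  expect_equal(ex$second_id, "c")
  tie <- deviation_extremes(c(2, 2), c(0, 0), ids = c("x", "y"))
  expect_equal(tie$max_id, "x")
  same <- deviation_extremes(1:4, 1:4)
  expect_equal(same$max, 0)
})

test_that("BEDROC equals the direct-summation oracle and stays in [0, 1]", {
  alpha <- 20
  N <- 100; n <- 5
  # all members in the top n ranks: near-maximal early recognition
  scores <- N:1
  member <- c(rep(TRUE, n), rep(FALSE, N - n))
  top <- bedroc(scores, member, alpha)
  expect_equal(top, bedroc_direct(1:n, N, alpha), tolerance = 1e-12)
  expect_gt(top, 0.95)
  expect_lte(top, 1)
  # reversed pattern: anti-enrichment, matches the oracle on the new ranks
  rev_member <- rev(member)
  bottom <- bedroc(scores, rev_member, alpha)
  expect_equal(bottom, bedroc_direct((N - n + 1):N, N, alpha),
               tolerance = 1e-12)
  expect_lt(bottom, 0.05)
  expect_gte(bottom, 0)
  # rank invariance under strictly monotone transforms
  set.seed(61)
  sc <- runif(40, 0.1, 5)
  mb <- seq_len(40) %in% sample(40, 8)
  expect_equal(bedroc(sc, mb, alpha), bedroc(sc^2, mb, alpha))
  expect_equal(bedroc(sc, mb, alpha), bedroc(log(sc), mb, alpha))
  expect_error(bedroc(sc, rep(TRUE, 40), alpha), "non-member")
  expect_error(bedroc(sc, rep(FALSE, 40), alpha), "member")
})

test_that("the Monte-Carlo uniform baseline matches the exhaustive average", {
  alpha <- 5; n <- 5; N <- 10
  combos <- combn(N, n)
  exhaustive <- mean(apply(combos, 2, bedroc_direct, N = N, alpha = alpha))
  mc <- uniform_bedroc(n, N, alpha, n_mc = 4000, seed = 8)
  expect_lt(abs(mc$value - exhaustive), 3 * mc$se)
  # MC standard error shrinks like 1/sqrt(n_mc)
  mc_small <- uniform_bedroc(n, N, alpha, n_mc = 250, seed = 8)
  expect_lt(mc$se, mc_small$se)
  expect_error(uniform_bedroc(10, 10, alpha))
})

test_that("bootstrap is seed-deterministic and calibrated for the mean", {
  expect_identical(as.numeric(bootstrap_se(mean, rep(3, 20), seed = 2)), 0)
  set.seed(71)
  x <- rnorm(50, 0, 2)
  b1 <- bootstrap_se(mean, x, n_boot = 500, seed = 4)
  b2 <- bootstrap_se(mean, x, n_boot = 500, seed = 4)
  expect_identical(b1, b2)
  analytic <- sd(x) / sqrt(50)
  expect_lt(abs(as.numeric(b1) - analytic) / analytic, 0.3)
})

test_that("group t-test behaves at the null and under a strong shift", {
  set.seed(81)
  pop <- abs(rnorm(40, 2, 1))
  expect_equal(group_ttest(pop, pop), 1, tolerance = 1e-12)
  shifted <- pop[1:8] + 10 * sd(pop)
  expect_lt(group_ttest(shifted, c(shifted, pop[9:40])), 1e-3)
  p <- group_ttest(pop[1:5], pop)
  expect_gte(p, 0)
  expect_lte(p, 1)
})

test_that("group report surfaces planted enrichment and filters small groups", {
  set.seed(91)
  n <- 40
  rec <- data.frame(compound_id = 1:n,
                    logd_pred = rnorm(n), logd_exp = 0,
                    groups = "", stringsAsFactors = FALSE)
  rec$logd_exp <- rec$logd_pred + rnorm(n, 0, 0.5)
  # plant a group holding the 6 worst deviations
  absdev <- abs(rec$logd_pred - rec$logd_exp)
  worst <- order(-absdev)[1:6]
  rec$groups[worst] <- "planted"
  # a diffuse group spread at random
  rec$groups[sample(setdiff(1:n, worst), 10)] <- "diffuse"
  rec$groups[rec$groups == ""] <- NA
  rep <- group_report(rec, alpha = 20, n_boot = 200, seed = 5,
                      min_members = 5, n_mc = 1000)
  planted <- rep[rep$group == "planted", ]
  expect_equal(planted$n, 6)
  expect_gt(planted$observed, planted$uniform + 2 * planted$observed_se)
  # groups below min_members are omitted
  rec2 <- rec
  rec2$groups[rec2$groups == "diffuse" & !is.na(rec2$groups)] <- NA
  rec2$groups[which(is.na(rec2$groups))[1:3]] <- "tiny"
  rep2 <- group_report(rec2, n_boot = 50, min_members = 5, n_mc = 200)
  expect_false("tiny" %in% rep2$group)
})
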