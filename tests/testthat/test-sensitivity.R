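# Hard-evidence sensitivity analysis, Delta-p, and strength of influence.

test_that("evidence on one burnout root leaves the other burnout deltas at zero", {
  rep <- univariate_sensitivity(study_network(), "EE", "high")
  expect_equal(unname(rep$delta$DP), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(rep$delta$PA), c(0, 0), tolerance = 1e-12)
  expect_equal(rep$posterior$EE[["high"]], 1)
})

test_that("deltas are antisymmetric across the two states and bounded by 100", {
  net <- random_cpts_on(study_structure(), seed = 41)
  for (v in study_variables()) for (s in c("low", "high")) {
    rep <- univariate_sensitivity(net, v, s)
    for (other in setdiff(study_variables(), v)) {
      expect_equal(rep$delta[[other]][["low"]], -rep$delta[[other]][["high"]],
                   tolerance = 1e-9)
      expect_true(all(abs(rep$delta[[other]]) <= 100))
    }
  }
})

test_that("sensitivity deltas equal enumeration-oracle posteriors minus priors", {
  net <- random_network(7, seed = 55)
  prior <- enumerate_marginals(net)
  ev <- c(V2 = "high", V5 = "low")
  rep <- multivariate_sensitivity(net, ev)
  post <- enumerate_marginals(net, ev)
  for (v in setdiff(names(net$variables), names(ev))) {
    expect_equal(rep$delta[[v]], 100 * (post[[v]] - prior[[v]]), tolerance = 1e-12)
  }
})

test_that("full evidence on the participation parents returns the published row", {
  rep <- multivariate_sensitivity(
    study_network(),
    c(EE = "high", DP = "high", PA = "high", resilience = "high", compliance = "high"))
  expect_equal(rep$posterior$participation[["high"]], 0.952, tolerance = 1e-12)
})

test_that("evidence sets are validated", {
  net <- study_network()
  expect_error(multivariate_sensitivity(net, c(EE = "high", EE = "low")),
               class = "validation_error")
  expect_error(multivariate_sensitivity(net, c(EE = "high")),
               class = "validation_error")
  expect_error(univariate_sensitivity(net, "EE", "medium"),
               class = "validation_error")
})

test_that("the full sweep covers every scenario and is deterministic", {
  net <- study_network()
  s1 <- full_sensitivity_sweep(net)
  s2 <- full_sensitivity_sweep(net)
  expect_equal(nrow(s1$univariate_table), 12)
  # 2-, 3-, 4-subsets of the four burnout/resilience variables, both states
  expect_equal(nrow(s1$multivariate_table), (6 + 4 + 1) * 2)
  expect_identical(s1$univariate_table, s2$univariate_table)
  expect_identical(s1$multivariate_table, s2$multivariate_table)
  # each tabulated cell matches an individually recomputed scenario
  raw <- full_sensitivity_sweep(net, rounded = FALSE)
  for (nm in names(raw$univariate)) {
    r <- raw$univariate[[nm]]
    direct <- univariate_sensitivity(net, names(r$evidence), r$evidence[[1]])
    expect_equal(r$delta, direct$delta, tolerance = 1e-12)
    # rounded and raw tables agree within half a percentage point
    for (v in setdiff(study_variables(), names(r$evidence)))
      expect_true(all(abs(r$delta[[v]] - round(r$delta[[v]])) <= 0.5))
  }
})

test_that("scenario-level failures are collected, not raised", {
  net <- study_network(root_marginals = c(EE = 0, DP = 0.53, PA = 0.395))
  sweep <- full_sensitivity_sweep(net)
  expect_gt(length(sweep$errors), 0)
  expect_true(all(vapply(sweep$errors, inherits, logical(1),
                         "inconsistent_evidence_error")))
  expect_lt(nrow(sweep$univariate_table), 12)
})

test_that("Delta-p follows its contingency definition", {
  # outcome independent of the antecedent
  net <- bn_network(c("A", "B"), NULL,
                    list(bn_cpt("A", character(), c(0.4, 0.6)),
                         bn_cpt("B", character(), c(0.7, 0.3))))
  expect_equal(delta_p(net, "B", "high", "A", "high"), 0, tolerance = 1e-12)
  # two-node chain with printed conditionals
  chain <- chain_network(0.5, c(low = 0.6, high = 0.1))
  # P(B=high|A=high) = 0.9, P(B=high|A=low) = 0.4
  expect_equal(delta_p(chain, "B", "high", "A", "high"), 0.5, tolerance = 1e-12)
  # study fixture vs oracle-computed conditionals
  study <- study_network()
  o_hi <- enumerate_marginals(study, c(compliance = "high"))$participation[["high"]]
  o_lo <- enumerate_marginals(study, c(compliance = "low"))$participation[["high"]]
  expect_equal(delta_p(study, "participation", "high", "compliance", "high"),
               o_hi - o_lo, tolerance = 1e-12)
  # degenerate antecedent
  det <- bn_network(c("A", "B"), data.frame(parent = "A", child = "B"),
                    list(bn_cpt("A", character(), c(1, 0)),
                         bn_cpt("B", "A", array(rep(0.5, 4), c(2, 2)))))
  expect_error(delta_p(det, "B", "high", "A", "high"),
               class = "degenerate_input_error")
})

test_that("strength of influence matches hand loops over the CPT rows", {
  net <- study_network()
  # child distribution identical across parent states -> all zeros
  flat <- bn_network(c("A", "B"), data.frame(parent = "A", child = "B"),
                     list(bn_cpt("A", character(), c(0.4, 0.6)),
                          bn_cpt("B", "A", array(c(0.3, 0.7, 0.3, 0.7), c(2, 2)))))
  s0 <- strength_of_influence(flat, "A", "B")
  expect_equal(c(s0$average, s0$maximum, s0$weighted), c(0, 0, 0))
  # deterministic flip -> all ones under the default metric
  flip <- bn_network(c("A", "B"), data.frame(parent = "A", child = "B"),
                     list(bn_cpt("A", character(), c(0.4, 0.6)),
                          bn_cpt("B", "A", array(c(1, 0, 0, 1), c(2, 2)))))
  s1 <- strength_of_influence(flip, "A", "B")
  expect_equal(c(s1$average, s1$maximum, s1$weighted), c(1, 1, 1))
  # published participation CPT, arc PA -> participation: brute-force loop
  cpt <- participation_cpt()
  co <- c("EE", "DP", "resilience", "compliance")
  grid <- expand.grid(stats::setNames(rep(list(c("low", "high")), 4), co),
                      stringsAsFactors = FALSE)
  dists <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- stats::setNames(as.character(grid[i, ]), co)
    p <- burnoutbn:::cpt_row(cpt, c(cfg, PA = "low"))
    q <- burnoutbn:::cpt_row(cpt, c(cfg, PA = "high"))
    max(abs(p - q))
  }, numeric(1))
  s <- strength_of_influence(net, "PA", "participation")
  expect_equal(s$average, mean(dists), tolerance = 1e-12)
  expect_equal(s$maximum, max(dists), tolerance = 1e-12)
  # weighted: distances weighted by the renormalized co-parent joint
  jt <- joint_table(net)
  w <- vapply(seq_len(nrow(grid)), function(i) {
    sel <- rep(TRUE, nrow(jt))
    for (v in co) sel <- sel & jt[[v]] == grid[i, v]
    sum(jt$p[sel])
  }, numeric(1))
  expect_equal(s$weighted, sum(dists * w / sum(w)), tolerance = 1e-12)
  expect_true(s$average <= s$maximum)
})

test_that("influence metrics are validated and selectable", {
  net <- study_network()
  expect_error(strength_of_influence(net, "PA", "participation", "taxicab"),
               class = "validation_error")
  expect_error(strength_of_influence(net, "participation", "EE"),
               class = "validation_error")
  for (m in c("max_abs", "euclidean", "hellinger")) {
    s <- strength_of_influence(net, "resilience", "compliance", m)
    expect_true(s$average >= 0 && s$maximum <= 1 + 1e-12)
    expect_lte(s$average, s$maximum)
  }
  tab <- strength_of_influence_table(net)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$average <= tab$maximum + 1e-12))
})
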