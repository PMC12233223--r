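# CPT estimation: crosstab MLE on complete records, EM with missing cells.

two_node_structure <- function() {
  bn_network(c("A", "B"), data.frame(parent = "A", child = "B"))
}

eight_record_fixture <- function() {
  data.frame(A = c("low", "low", "low", "low", "high", "high", "high", "high"),
             B = c("low", "low", "low", "high", "high", "high", "low", "high"),
             stringsAsFactors = FALSE)
}

test_that("crosstab MLE reproduces hand-tallied conditional frequencies", {
  fit <- mle_cpts(eight_record_fixture(), two_node_structure())
  expect_equal(burnoutbn:::cpt_row(fit$cpts$B, c(A = "low")), c(0.75, 0.25))
  expect_equal(burnoutbn:::cpt_row(fit$cpts$B, c(A = "high")), c(0.25, 0.75))
  expect_equal(as.numeric(fit$cpts$A$prob), c(0.5, 0.5))
})

test_that("unobserved parent configurations fall back to the uniform row", {
  recs <- data.frame(A = rep("low", 6), B = rep(c("low", "high"), 3))
  fit <- mle_cpts(recs, two_node_structure())
  expect_equal(burnoutbn:::cpt_row(fit$cpts$B, c(A = "high")), c(0.5, 0.5))
  expect_equal(attr(fit, "unobserved_configs")[["B"]], 1L)
})

test_that("identical records yield deterministic rows for observed configurations", {
  recs <- data.frame(A = rep("high", 5), B = rep("low", 5))
  fit <- mle_cpts(recs, two_node_structure())
  expect_equal(as.numeric(fit$cpts$A$prob), c(0, 1))
  expect_equal(burnoutbn:::cpt_row(fit$cpts$B, c(A = "high")), c(1, 0))
})

test_that("MLE equals an independent contingency-table oracle and stays normalized", {
  net <- random_network(5, seed = 9)
  recs <- sample_states(net, 400, seed = 10)
  fit <- mle_cpts(recs, net)
  for (v in names(net$variables)) {
    cpt <- fit$cpts[[v]]
    parents <- cpt$parents
    grid <- expand.grid(stats::setNames(rep(list(c("low", "high")), length(parents)),
                                        parents), stringsAsFactors = FALSE)
    if (length(parents) == 0) grid <- data.frame(row.names = 1)
    for (i in seq_len(nrow(grid))) {
      sel <- rep(TRUE, nrow(recs))
      for (p in parents) sel <- sel & recs[[p]] == grid[i, p]
      row <- burnoutbn:::cpt_row(cpt, stats::setNames(as.character(grid[i, parents]),
                                                      parents))
      expect_equal(sum(row), 1, tolerance = 1e-9)
      if (sum(sel) > 0) {
        oracle <- c(mean(recs[[v]][sel] == "low"), mean(recs[[v]][sel] == "high"))
        expect_equal(row, oracle, tolerance = 1e-12)
      } else {
        expect_equal(row, c(0.5, 0.5))
      }
    }
  }
})

test_that("MLE validates its inputs", {
  expect_error(mle_cpts(data.frame(A = character(), B = character()),
                        two_node_structure()), class = "validation_error")
  expect_error(mle_cpts(data.frame(A = c("low", NA), B = c("low", "low")),
                        two_node_structure()), class = "validation_error")
  expect_error(mle_cpts(data.frame(A = c("low", "mid"), B = c("low", "low")),
                        two_node_structure()), class = "validation_error")
})

test_that("EM on complete data equals the crosstab MLE", {
  recs <- eight_record_fixture()
  fit_em <- em_learn(recs, two_node_structure())
  fit_mle <- mle_cpts(recs, two_node_structure())
  expect_true(fit_em$converged)
  for (v in c("A", "B"))
    expect_equal(fit_em$network$cpts[[v]]$prob, fit_mle$cpts[[v]]$prob,
                 tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing and convergence is flagged", {
  net <- study_network()
  recs <- inject_missingness(sample_states(net, 500, seed = 4), 0.2, seed = 5)
  fit <- em_learn(recs, study_structure())
  expect_true(all(diff(fit$log$loglik) > -1e-8))
  expect_true(fit$converged)
  capped <- em_learn(recs, study_structure(),
                     learn_settings(max_iterations = 2))
  expect_false(capped$converged)
  expect_equal(capped$iterations, 2)
})

test_that("one EM step distributes a missing cell by the model posterior", {
  start <- chain_network(0.6, c(low = 0.7, high = 0.2))
  recs <- data.frame(A = "low", B = NA_character_)
  fit <- em_learn(recs, two_node_structure(),
                  learn_settings(max_iterations = 1, init = "cpts",
                                 init_cpts = start$cpts))
  oracle <- enumerate_marginals(start, c(A = "low"))$B
  expect_equal(burnoutbn:::cpt_row(fit$network$cpts$B, c(A = "low")),
               unname(oracle), tolerance = 1e-12)
  # the unobserved A = high configuration falls back to uniform
  expect_equal(burnoutbn:::cpt_row(fit$network$cpts$B, c(A = "high")), c(0.5, 0.5))
})

test_that("EM recovers generator CPTs from records with missing cells", {
  truth <- study_network()
  complete <- sample_states(truth, 2000, seed = 21)
  recs <- inject_missingness(complete, 0.2, seed = 22)
  fit <- em_learn(recs, study_structure())
  cpt <- fit$network$cpts$participation
  true_cpt <- truth$cpts$participation
  parents <- cpt$parents
  grid <- expand.grid(stats::setNames(rep(list(c("low", "high")), 5), parents),
                      stringsAsFactors = FALSE)
  checked <- 0
  for (i in seq_len(nrow(grid))) {
    sel <- rep(TRUE, nrow(complete))
    for (p in parents) sel <- sel & complete[[p]] == grid[i, p]
    if (sum(sel) < 50) next
    cfg <- stats::setNames(as.character(grid[i, parents]), parents)
    tru <- burnoutbn:::cpt_row(true_cpt, cfg)
    # noise-aware bound: 4 standard errors on the effective (post-missingness)
    # per-config count, floored at 0.07
    tol <- max(0.07, 4 * sqrt(max(tru[1] * tru[2], 0.01) / (0.8 * sum(sel))))
    expect_lt(max(abs(burnoutbn:::cpt_row(cpt, cfg) - tru)), tol)
    checked <- checked + 1
  }
  expect_gte(checked, 4)
})

test_that("learning is deterministic given records, settings, and seed", {
  recs <- inject_missingness(sample_states(study_network(), 300, seed = 1),
                             0.15, seed = 2)
  s <- learn_settings(init = "random", seed = 99, max_iterations = 50)
  f1 <- em_learn(recs, study_structure(), s)
  f2 <- em_learn(recs, study_structure(), s)
  expect_identical(f1$log, f2$log)
  for (v in study_variables())
    expect_identical(f1$network$cpts[[v]]$prob, f2$network$cpts[[v]]$prob)
})
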