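# Instrument scoring, reliability, medians, and dichotomization.

test_that("MBI subscale sums hit the extremes of their ranges", {
  zero <- score_instrument(rep(0, 22), mbi_spec())
  expect_equal(unlist(zero), c(EE = 0, DP = 0, PA_raw = 0))
  top <- score_instrument(rep(6, 22), mbi_spec())
  expect_equal(unlist(top), c(EE = 54, DP = 30, PA_raw = 48))
})

test_that("subscale scores equal an item-by-item summation oracle", {
  withr::with_seed(42, {
    resp <- sample(0:6, 22, replace = TRUE)
  })
  got <- score_instrument(resp, mbi_spec())
  spec <- mbi_spec()
  for (sub in names(spec$subscales)) {
    oracle <- 0
    for (ix in spec$subscales[[sub]]) oracle <- oracle + resp[ix]
    expect_equal(got[[sub]], oracle)
  }
})

test_that("subscale scores sum to the total item score for every instrument", {
  specs <- default_instrument_specs()
  withr::with_seed(7, {
    for (spec in specs) {
      m <- matrix(sample(spec$item_range[1]:spec$item_range[2],
                         10 * spec$item_count, replace = TRUE),
                  nrow = 10)
      scored <- score_instrument(m, spec)
      expect_equal(rowSums(scored), rowSums(m), ignore_attr = TRUE)
    }
  })
})

test_that("scoring validates item range, vector length, and missing items", {
  bad <- rep(0, 22); bad[5] <- 9
  err <- expect_error(score_instrument(bad, mbi_spec(), ids = "R7"),
                      class = "validation_error")
  expect_match(conditionMessage(err), "R7")
  expect_match(conditionMessage(err), "item 5")
  expect_match(conditionMessage(err), "9")
  expect_error(score_instrument(rep(0, 21), mbi_spec()), class = "validation_error")
  with_na <- rep(2, 22); with_na[3] <- NA
  expect_error(score_instrument(with_na, mbi_spec()), class = "validation_error")
  scored <- score_instrument(with_na, mbi_spec(), allow_na = TRUE)
  expect_true(is.na(scored$EE))       # item 3 belongs to EE
  expect_false(is.na(scored$DP))
})

test_that("instrument specs enforce disjoint covering subscales", {
  expect_error(instrument_spec("x", 4, c(0, 1), list(a = 1:2, b = 2:4)),
               class = "validation_error")
  expect_error(instrument_spec("x", 4, c(0, 1), list(a = 1:2, b = 4)),
               class = "validation_error")
  expect_s3_class(instrument_spec("x", 4, c(0, 1), list(a = 1:2, b = 3:4)),
                  "instrument_spec")
})

test_that("Cronbach's alpha matches hand evaluation and its invariances", {
  # perfectly parallel items
  x <- c(1, 5, 2, 4, 3)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # two items offset by a constant: unit correlation
  expect_equal(cronbach_alpha(rbind(c(1, 2), c(2, 3), c(3, 4))), 1)
  # frozen 5x4 fixture, expected value from direct formula evaluation:
  # var(total) = 17.8, sum item var = 5.0, alpha = 4/3 * (1 - 5/17.8)
  fixture <- matrix(c(2, 3, 1, 4,
                      3, 4, 2, 5,
                      1, 2, 1, 2,
                      4, 5, 3, 5,
                      2, 3, 2, 3), nrow = 5, byrow = TRUE)
  expect_equal(cronbach_alpha(fixture), 51.2 / 53.4, tolerance = 1e-12)
  # invariant under adding a constant to any item column
  shifted <- fixture; shifted[, 2] <- shifted[, 2] + 10
  expect_equal(cronbach_alpha(shifted), cronbach_alpha(fixture))
  # degenerate input is an error, not a number
  expect_error(cronbach_alpha(rbind(c(1, 2), c(2, 1), c(3, 0))),
               class = "degenerate_input_error")
  expect_error(cronbach_alpha(matrix(1, 3, 1)), class = "validation_error")
})

test_that("medians follow the standard sample-median conventions", {
  expect_equal(compute_medians(list(EE = c(1, 2, 3)))[["EE"]], 2)
  expect_equal(compute_medians(list(EE = c(1, 2, 3, 4)))[["EE"]], 2.5)
  withr::with_seed(11, {
    ee <- sample(0:54, 200, replace = TRUE)
  })
  srt <- sort(ee)
  oracle <- (srt[100] + srt[101]) / 2
  expect_equal(compute_medians(list(EE = ee))[["EE"]], oracle)
  expect_error(compute_medians(list(EE = numeric(0))), class = "validation_error")
})

test_that("dichotomization respects score directions and the tie rule", {
  med <- c(EE = 25, DP = 14, PA_raw = 24, resilience_raw = 70,
           compliance_raw = 36, participation_raw = 33)
  rules <- dichotomization_rules(med)
  scores <- data.frame(id = 1:3,
                       EE = c(30, 25, 10),       # above / tie / below
                       DP = c(14, 20, 5),        # tie / above / below
                       PA_raw = c(30, 24, 10),
                       resilience_raw = c(80, 70, 30),
                       compliance_raw = c(40, 36, 20),
                       participation_raw = c(40, 33, 20))
  st <- dichotomize(scores, rules)
  expect_equal(st$EE, c("high", "low", "low"))   # EE 30 > 25 is high; tie -> low
  expect_equal(st$DP, c("low", "high", "low"))
  # reversed constructs: raw score above (or at) the threshold is the desired low
  expect_equal(st$resilience, c("low", "low", "high"))
  expect_equal(st$PA, c("low", "low", "high"))
  expect_equal(st$compliance, c("low", "low", "high"))
  expect_equal(st$participation, c("low", "low", "high"))
  # idempotent: the states are a pure function of scores and rules
  expect_identical(dichotomize(scores, rules), st)
  # the literal safety reading flips only the safety variables
  lit <- dichotomize(scores, dichotomization_rules(med, "literal"))
  expect_equal(lit$compliance, c("high", "low", "low"))
  expect_equal(lit$participation, c("high", "low", "low"))
  expect_equal(lit$EE, st$EE)
  expect_equal(lit$resilience, st$resilience)
})

test_that("median dichotomization is balanced up to ties at the median", {
  withr::with_seed(3, {
    for (n in c(100, 101, 200)) {
      scores <- data.frame(id = seq_len(n),
                           EE = sample(0:54, n, TRUE),
                           DP = sample(0:30, n, TRUE),
                           PA_raw = sample(0:48, n, TRUE),
                           resilience_raw = sample(0:100, n, TRUE),
                           compliance_raw = sample(12:60, n, TRUE),
                           participation_raw = sample(11:55, n, TRUE))
      med <- compute_medians(scores[-1])
      st <- dichotomize(scores, dichotomization_rules(med))
      for (i in seq_along(med)) {
        con <- names(med)[i]
        var <- setdiff(names(st), "id")[i]
        ties <- sum(scores[[con]] == med[[con]])
        # ties are all assigned to "low", so the low count sits in
        # [n/2, n/2 + ties] for either score direction
        n_low <- sum(st[[var]] == "low")
        expect_gte(n_low, n / 2)
        expect_lte(n_low - n / 2, ties)
      }
    }
  })
})

test_that("dichotomize rejects missing or duplicated rules", {
  med <- c(EE = 25, DP = 14, PA_raw = 24, resilience_raw = 70,
           compliance_raw = 36, participation_raw = 33)
  expect_error(dichotomization_rules(med[-1]), class = "validation_error")
  rules <- dichotomization_rules(med)
  expect_error(dichotomize(data.frame(EE = 1), rules), class = "validation_error")
  dup <- rbind(rules, rules[1, ])
  full <- data.frame(id = 1, EE = 1, DP = 1, PA_raw = 1, resilience_raw = 1,
                     compliance_raw = 20, participation_raw = 20)
  expect_error(dichotomize(full, dup), class = "validation_error")
})
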