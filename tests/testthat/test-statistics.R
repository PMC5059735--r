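test_that("condition summaries report mean and sample SD over cells", {
  cells <- data.frame(mean_circularity = c(0.5, 0.7),
                      mean_aspect_ratio = c(2, 4))
  s <- summarizeCondition(cells, "control")
  expect_equal(s$n_cells, 2L)
  expect_equal(s$mean_circularity, 0.6)
  expect_equal(s$sd_circularity, sd(c(0.5, 0.7)))   # ~0.1414
  expect_equal(s$sd_aspect_ratio, sqrt(2))

  one <- summarizeCondition(cells[1, ], "solo")
  expect_true(is.na(one$sd_circularity))

  set.seed(3)
  big <- data.frame(mean_circularity = runif(100),
                    mean_aspect_ratio = 1 + rexp(100))
  s <- summarizeCondition(big, "sim")
  expect_equal(s$mean_aspect_ratio, sum(big$mean_aspect_ratio) / 100)
  expect_equal(s$sd_aspect_ratio,
               sqrt(sum((big$mean_aspect_ratio -
                         mean(big$mean_aspect_ratio))^2) / 99))
  expect_error(summarizeCondition(big[0, ], "none"),
               class = "mitomorph_error_empty_condition")
})

test_that("star coding is a pure function of p and the thresholds", {
  expect_equal(pStars(c(0.04, 0.009, 0.0005, 0.2)),
               c("*", "**", "***", "ns"))
  expect_equal(pStars(0.05), "ns")     # boundary: strictly below
  expect_equal(pStars(0.01), "*")
  expect_equal(pStars(0.2, thresholds = c(0.3, 0.2, 0.1)), "*")
})

test_that("group comparison agrees with a closed-form Welch computation", {
  set.seed(7)
  for (rep in seq_len(5)) {
    a <- rnorm(sample(5:40, 1), mean = runif(1, 0, 3), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(5:40, 1), mean = runif(1, 0, 3), sd = runif(1, 0.5, 2))
    res <- compareGroups(a, b, "mean_circularity")
    oracle <- bruteWelch(a, b)
    expect_equal(res$t, oracle$t, tolerance = 1e-10)
    expect_equal(res$df, oracle$df, tolerance = 1e-10)
    expect_equal(res$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("degenerate and decisive comparisons behave as expected", {
  x <- c(1, 2, 3, 4)
  same <- compareGroups(x, x, "mean_circularity")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")

  shifted <- compareGroups(c(1, 2, 3), c(11, 12, 13), "mean_aspect_ratio")
  expect_lt(shifted$p, 0.001)
  expect_equal(shifted$stars, "***")

  expect_error(compareGroups(1, c(1, 2), "x"),
               class = "mitomorph_error_group_too_small")

  ## Student's variant is the pooled-variance test
  st <- compareGroups(c(1, 2, 3, 5), c(2, 4, 6, 7), "x",
                      params = statsParams(test = "student"))
  ref <- t.test(c(1, 2, 3, 5), c(2, 4, 6, 7), var.equal = TRUE)
  expect_equal(st$p, ref$p.value)
})

test_that("dose-response table compares each condition to the control", {
  set.seed(11)
  mk <- function(circ, ar, n = 30)
    data.frame(mean_circularity = rnorm(n, circ, 0.03),
               mean_aspect_ratio = rnorm(n, ar, 0.1))
  conds <- list(control = mk(0.4, 3.5), d100 = mk(0.5, 3.0),
                d200 = mk(0.6, 2.5), d300 = mk(0.7, 2.0),
                d500 = mk(0.8, 1.5))
  tab <- doseResponseTable(conds)
  expect_equal(nrow(tab), 8L)   # 4 doses x 2 descriptors
  expect_true(all(tab$group_a == "control"))
  expect_true(all(tab$stars == "***"))

  two <- doseResponseTable(conds[1:2])
  expect_equal(nrow(two), 2L)
  expect_setequal(two$descriptor,
                  c("mean_circularity", "mean_aspect_ratio"))

  self <- doseResponseTable(list(ctrl = conds[[1]], again = conds[[1]]))
  expect_true(all(self$stars == "ns"))

  expect_error(doseResponseTable(conds[1]),
               class = "mitomorph_error_too_few_conditions")
})
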