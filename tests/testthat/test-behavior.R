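test_that("the consistency filter reproduces the study's trial bookkeeping", {
  trials <- trials_from_counts(table2_counts())
  cf <- consistency_filter(trials)
  expect_equal(nrow(cf$retained), 2156)
  expect_equal(nrow(cf$exclusions), 324)
  expect_equal(sum(cf$exclusions$reason == "unknown"), 32)
  expect_equal(nrow(cf$retained) + nrow(cf$exclusions), 2480)
  expect_equal(unname(as.matrix(cf$table)), unname(table2_counts()))
  # retained trials carry their report as final strategy
  expect_true(all(cf$retained$strategy == cf$retained$report))
})

test_that("the consistency filter handles edge cases and is idempotent", {
  consistent <- data.frame(size = c("small", "large"),
                           report = c("retrieve", "procedure"))
  cf <- consistency_filter(consistent)
  expect_equal(nrow(cf$exclusions), 0)

  unk <- data.frame(size = "small", report = "unknown")
  expect_equal(consistency_filter(unk)$exclusions$reason, "unknown")

  cf2 <- consistency_filter(cf$retained)
  expect_equal(cf2$retained$size, cf$retained$size)
  expect_equal(nrow(cf2$exclusions), 0)
})

test_that("Cohen's kappa matches hand-computed values and invariances", {
  t2 <- table2_counts()[, c("procedure", "retrieve")]
  k <- cohen_kappa(t2)
  expect_equal(round(k$agreement, 2), 0.88)
  expect_equal(round(k$kappa, 2), 0.76)
  expect_equal(k$n, 2448)

  expect_equal(cohen_kappa(diag(c(30, 70)))$kappa, 1)
  expect_equal(cohen_kappa(matrix(50, 2, 2))$kappa, 0)

  # invariant to swapping both row and column labels
  swapped <- t2[2:1, 2:1]
  expect_equal(cohen_kappa(swapped)$kappa, k$kappa)

  expect_warning(kd <- cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate")
  expect_true(is.na(kd$kappa))
})

test_that("accuracy summaries aggregate per participant then across", {
  tr <- expand.grid(participant = 1:4, trial = 1:20,
                    strategy = "retrieve", operation = "subtraction",
                    stringsAsFactors = FALSE)
  tr$correct <- TRUE
  tr$correct[tr$participant == 1][1:2] <- FALSE   # 18/20 for participant 1
  s <- summarize_accuracy(tr)
  p1 <- s$by_participant$accuracy[s$by_participant$participant == 1]
  expect_equal(p1, 0.90)
  expect_equal(s$summary$mean, mean(c(0.9, 1, 1, 1)))

  allc <- transform(tr, correct = TRUE)
  s2 <- summarize_accuracy(allc)
  expect_equal(s2$summary$mean, 1)
  expect_equal(s2$summary$sd, 0)
})

test_that("RT summaries use pooled trials and the interpolated quartiles", {
  one <- data.frame(strategy = "retrieve", operation = "subtraction", rt = 2)
  s1 <- summarize_rt(one)
  expect_equal(unlist(s1[c("min", "q1", "median", "mean", "q3", "max")]),
               c(min = 2, q1 = 2, median = 2, mean = 2, q3 = 2, max = 2))

  s2 <- summarize_rt(data.frame(strategy = "a", operation = "b",
                                rt = c(1, 2, 3, 4, 100)))
  expect_equal(s2$median, 3)
  expect_equal(s2$mean, 22)

  # linear-interpolation convention, checked against the definition
  # h = (n - 1) p + 1 applied by hand to {1, 2, 3, 4}
  s3 <- summarize_rt(data.frame(strategy = "a", operation = "b", rt = 1:4))
  expect_equal(s3$q1, 1.75)
  expect_equal(s3$q3, 3.25)
})
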