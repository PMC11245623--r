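test_that("balanced two-way ANOVA matches a hand decomposition", {
  # 2 x 2 with n = 2 per cell, chosen for clean arithmetic
  vals <- c(10, 12, 14, 16, 20, 22, 30, 32)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(rep(c("b1", "b2"), each = 2), 2)
  tab <- two_way_anova(vals, A, B)
  grand <- mean(vals)
  cm <- tapply(vals, list(A, B), mean)
  ssa <- 4 * sum((rowMeans(cm) - grand)^2)
  ssb <- 4 * sum((colMeans(cm) - grand)^2)
  ssab <- 2 * sum((cm - outer(rowMeans(cm) - grand,
                              colMeans(cm) - grand, `+`) - grand)^2)
  sse <- sum((vals - cm[cbind(A, B)])^2)
  expect_equal(tab$sum_of_squares[tab$effect == "A"], ssa)
  expect_equal(tab$sum_of_squares[tab$effect == "B"], ssb)
  expect_equal(tab$sum_of_squares[tab$effect == "A:B"], ssab)
  expect_equal(tab$sum_of_squares[tab$effect == "Residuals"], sse)
  # components add to the total and dfs to n - 1
  expect_equal(sum(tab$sum_of_squares), sum((vals - grand)^2))
  expect_equal(sum(tab$df), length(vals) - 1)
})

test_that("constant responses report zero F, not NaN", {
  tab <- two_way_anova(rep(5, 12), rep(c("a", "b"), 6),
                       rep(c("x", "y", "z"), 4))
  expect_equal(tab$sum_of_squares, rep(0, 4), tolerance = 1e-12)
  expect_identical(tab$F[tab$effect != "Residuals"], rep(0, 3))
  expect_identical(tab$p[tab$effect != "Residuals"], rep(1, 3))
})

test_that("a planted main effect is detected and the null factor is not", {
  set.seed(7)
  A <- rep(c("t200", "t300"), each = 40)
  B <- rep(rep(c("2h", "8h"), each = 20), 2)
  vals <- rnorm(80) + ifelse(A == "t300", 3, 0)
  tab <- two_way_anova(vals, A, B)
  expect_lt(tab$p[tab$effect == "A"], 1e-6)
  expect_gt(tab$p[tab$effect == "B"], 0.05)
})

test_that("design checks reject what the decomposition cannot handle", {
  expect_error(two_way_anova(rnorm(7), rep(c("a", "b"), c(3, 4)),
                             rep(c("x", "y"), c(4, 3))),
               class = "carposort_parameter_error")
  expect_error(two_way_anova(rnorm(4), rep("a", 4),
                             rep(c("x", "y"), 2)),
               class = "carposort_parameter_error")
  # single replicate per cell: additive model, no interaction row
  tab <- two_way_anova(c(1, 2, 3, 5), rep(c("a", "b"), each = 2),
                       rep(c("x", "y"), 2))
  expect_false("A:B" %in% tab$effect)
})

test_that("Tukey-Kramer calls match TukeyHSD on balanced data", {
  set.seed(8)
  g <- factor(rep(paste0("g", 1:8), each = 20))
  vals <- rnorm(160, sd = 0.5) +
    rep(c(0, 0, 0.2, 0.5, 0.5, 1.2, 2.0, 2.1), each = 20)
  fit <- aov(vals ~ g)
  ref <- TukeyHSD(fit)$g
  ms_w <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  df_w <- summary(fit)[[1]]["Residuals", "Df"]
  tk <- tukey_kramer(tapply(vals, g, mean), tapply(vals, g, length),
                     ms_w, df_w, alpha = 0.05)
  for (row in rownames(ref)) {
    pair <- strsplit(row, "-")[[1]]
    expect_equal(tk$p_value[pair[1], pair[2]], ref[row, "p adj"],
                 tolerance = 1e-6)
  }
})

test_that("Tukey-Kramer flags obvious cases", {
  tk <- tukey_kramer(c(a = 1, b = 1, c = 11), c(10, 10, 10),
                     ms_within = 1, df_within = 27)
  expect_false(tk$significant["a", "b"])
  expect_true(tk$significant["a", "c"])
  expect_error(tukey_kramer(c(1, 2), c(5, 5), 0, 8),
               class = "carposort_parameter_error")
  expect_error(tukey_kramer(c(1, 2), c(5, 5), 1, 0),
               class = "carposort_parameter_error")
})

test_that("compact letters encode exactly the non-significance relation", {
  none <- matrix(FALSE, 4, 4)
  expect_true(all(compact_letters(none)$letters == "A"))
  all_sig <- !diag(4)
  expect_identical(sort(compact_letters(all_sig)$letters),
                   c("A", "B", "C", "D"))
  # random patterns: sharing a letter must equal non-significance
  set.seed(9)
  for (rep_i in 1:100) {
    k <- sample(3:7, 1)
    sig <- matrix(FALSE, k, k)
    up <- upper.tri(sig)
    sig[up] <- runif(sum(up)) < 0.35
    sig <- sig | t(sig)
    letters_out <- strsplit(compact_letters(sig)$letters, "")
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      share <- length(intersect(letters_out[[i]], letters_out[[j]])) > 0
      expect_identical(share, !sig[i, j])
    }
  }
})

test_that("letter_summary annotates group means end to end", {
  set.seed(10)
  vals <- c(rnorm(20, 0), rnorm(20, 0.1), rnorm(20, 6))
  g <- rep(c("fresh", "c200", "c350"), each = 20)
  s <- letter_summary(vals, g)
  s <- s[match(c("fresh", "c200", "c350"), s$group), ]
  # the two near-identical groups share a letter, the far one does not
  shared <- function(a, b) length(intersect(strsplit(a, "")[[1]],
                                            strsplit(b, "")[[1]])) > 0
  expect_true(shared(s$letters[1], s$letters[2]))
  expect_false(shared(s$letters[1], s$letters[3]))
})
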