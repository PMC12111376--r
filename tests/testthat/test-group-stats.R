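test_that("one-way ANOVA matches the sum-of-squares partition", {
  d <- data.frame(value = c(4.1, 3.9, 4.3, 5.0, 5.2, 4.8, 6.1, 5.9, 6.0),
                  group = rep(c("a", "b", "c"), each = 3))
  an <- oneway_anova(d)
  or <- oracle_oneway_F(d$value, d$group)
  expect_equal(an$F, or$F, tolerance = 1e-10)
  expect_equal(an$p, or$p, tolerance = 1e-10)
  expect_equal(an$df1, 2)
  expect_equal(an$df2, 6)

  # identical groups: F = 0, p = 1
  d0 <- data.frame(value = rep(c(1, 2), 3), group = rep(c("a", "b", "c"), each = 2))
  an0 <- oneway_anova(d0)
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)

  expect_error(oneway_anova(data.frame(value = 1:3, group = "a")),
               "2 groups")
  expect_error(oneway_anova(data.frame(value = 1:3, group = c("a", "a", "b"))),
               "at least 2 observations")

  # random datasets against the oracle
  set.seed(8)
  for (i in 1:10) {
    dd <- data.frame(value = rnorm(12), group = rep(letters[1:4], 3))
    expect_equal(oneway_anova(dd)$F, oracle_oneway_F(dd$value, dd$group)$F,
                 tolerance = 1e-10)
  }
})

test_that("repeated-measures ANOVA partitions out the subject effect", {
  # toy 3 subjects x 3 times table against the hand partition
  d <- data.frame(value = c(1.0, 1.5, 2.1, 1.2, 1.9, 2.5, 0.8, 1.4, 2.2),
                  group = rep(c("t0", "t1", "t2"), 3),
                  subject = rep(1:3, each = 3))
  an <- suppressWarnings(repeated_measures_anova(d))
  or <- oracle_rm_F(d$value, d$group, d$subject)
  expect_equal(an$F, or$F, tolerance = 1e-10)
  expect_equal(an$p, or$p, tolerance = 1e-10)
  expect_equal(c(an$df1, an$df2), c(2, 4))

  # additive subject offsets with no time effect: F ~ 0
  d2 <- data.frame(value = rep(c(10, 20, 30), each = 3),
                   group = rep(c("t0", "t1", "t2"), 3),
                   subject = rep(1:3, each = 3))
  an2 <- suppressWarnings(repeated_measures_anova(d2))
  expect_equal(an2$F, 0)
  expect_equal(an2$p, 1)

  # time-constant data
  d3 <- data.frame(value = rep(5, 9), group = rep(c("t0", "t1", "t2"), 3),
                   subject = rep(1:3, each = 3))
  expect_equal(suppressWarnings(repeated_measures_anova(d3))$F, 0)

  expect_error(suppressWarnings(repeated_measures_anova(d[-1, ])),
               "unbalanced")
  expect_warning(repeated_measures_anova(d), "sphericity")
})

test_that("Tukey HSD uses the studentized range and letters the groups", {
  # all means equal: nothing significant, everything shares "a"
  t0 <- tukey_hsd(c(a = 5, b = 5, c = 5), ns = 3, MS_error = 1, df_error = 6)
  expect_false(any(t0$pairwise$significant))
  expect_equal(unname(t0$letters), rep("a", 3))

  # two groups separated by 10 SDs
  t2 <- tukey_hsd(c(lo = 0, hi = 10), ns = 5, MS_error = 1, df_error = 8)
  expect_true(all(t2$pairwise$significant))
  expect_setequal(unname(t2$letters), c("a", "b"))

  # q statistic definition
  means <- c(a = 1, b = 3.5)
  tt <- tukey_hsd(means, ns = c(4, 6), MS_error = 2, df_error = 8)
  q_hand <- abs(1 - 3.5) / sqrt(2 / 2 * (1 / 4 + 1 / 6))
  expect_equal(tt$pairwise$q, q_hand)

  expect_error(tukey_hsd(c(a = 1, b = 2), 3, MS_error = -1, df_error = 5),
               "MS_error")
  expect_error(tukey_hsd(c(a = 1, b = 2), 3, MS_error = 1, df_error = 0),
               "df_error")
})

test_that("critical values match a numerically integrated range CDF", {
  # CDF oracle sanity: P(Q < crit) = 0.95 by construction
  for (case in list(c(3, 10), c(2, 10), c(4, 20))) {
    k <- case[1]; df <- case[2]
    crit_pkg <- qtukey(0.95, k, df)
    crit_oracle <- oracle_srange_crit(k, df, alpha = 0.05)
    expect_equal(crit_pkg, crit_oracle, tolerance = 5e-3)
  }
  # the classical table entry for (k = 3, df = 10, alpha = 0.05)
  expect_equal(round(oracle_srange_crit(3, 10), 2), 3.88)
})

test_that("compact letter display satisfies share-a-letter iff not different", {
  # chain a != c, a ~ b, b ~ c
  sig <- matrix(FALSE, 3, 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  sig["a", "c"] <- sig["c", "a"] <- TRUE
  lab <- compact_letter_display(sig, means = c(a = 3, b = 2, c = 1))
  expect_equal(unname(lab), c("a", "ab", "b"))

  # all pairs different
  sig3 <- matrix(TRUE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(sig3) <- FALSE
  expect_setequal(unname(compact_letter_display(sig3)), c("a", "b", "c"))

  # asymmetric input is rejected
  bad <- sig; bad["a", "c"] <- FALSE
  expect_error(compact_letter_display(bad), "symmetric")

  # random relations: exhaustive verification of the iff condition
  set.seed(14)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    m <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(m))
    on <- sample(pairs, size = sample(0:length(pairs), 1))
    m[on] <- TRUE
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dimnames(m) <- list(letters[1:k], letters[1:k])
    lab <- compact_letter_display(m)
    for (a in 1:k) for (b in 1:k) {
      if (a == b) next
      share <- length(intersect(strsplit(lab[a], "")[[1]],
                                strsplit(lab[b], "")[[1]])) > 0
      expect_equal(share, !m[a, b])
    }
  }
})

test_that("null type-I error of the between-subjects ANOVA is nominal", {
  set.seed(1)
  reject <- vapply(1:2000, function(i) {
    d <- data.frame(value = rnorm(9), group = rep(c("a", "b", "c"), each = 3))
    oneway_anova(d)$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.04)
  expect_lte(mean(reject), 0.06)
})
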