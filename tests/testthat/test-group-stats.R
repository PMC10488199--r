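test_that("identical groups give F = 0, p = 1 and all Tukey p = 1", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- anova_oneway(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  tk <- tukey_hsd(g)
  expect_equal(tk$p_adj, 1)
})

test_that("extreme separation gives a vanishing p value", {
  g <- list(a = c(0, 0, 0.001), b = c(10, 10, 10.001))
  expect_lt(anova_oneway(g)$p, 1e-6)
})

test_that("F statistic matches the textbook sum-of-squares oracle", {
  set.seed(8)
  for (i in 1:5) {
    g <- lapply(stats::setNames(1:4, letters[1:4]), function(j)
      rnorm(sample(3:8, 1), mean = j * runif(1)))
    res <- anova_oneway(g)
    n <- lengths(g); N <- sum(n); k <- length(g)
    gm <- mean(unlist(g))
    ssb <- sum(n * (vapply(g, mean, 0) - gm)^2)
    ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
    Fo <- (ssb / (k - 1)) / (ssw / (N - k))
    expect_equal(res$F, Fo, tolerance = 1e-10)
    expect_equal(res$p, stats::pf(Fo, k - 1, N - k, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("degenerate within-group variance is rejected", {
  expect_error(anova_oneway(list(a = c(1, 1), b = c(2, 2))), "degenerate")
  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("balanced two-group Tukey equals the pooled two-sided t test", {
  set.seed(21)
  g <- list(a = rnorm(6), b = rnorm(6, 1))
  tk <- tukey_hsd(g)
  tt <- stats::t.test(g$b, g$a, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(tk$q, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-9)
})

test_that("Tukey-Kramer p values match the independent formula oracle", {
  set.seed(33)
  for (i in 1:6) {
    k <- sample(3:5, 1)
    g <- lapply(stats::setNames(seq_len(k), LETTERS[1:k]), function(j)
      rnorm(sample(3:9, 1), mean = runif(1, 0, 2)))
    tk <- tukey_hsd(g)
    want <- tukey_oracle(g)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- match(key(tk$group1, tk$group2), key(want$group1, want$group2))
    expect_false(anyNA(m))
    expect_equal(tk$p_adj, want$p[m], tolerance = 1e-6)
  }
})

test_that("Tukey p decreases as the mean difference grows", {
  base <- c(-1, 0, 1)
  p <- vapply(c(0.5, 1, 2, 4), function(d)
    tukey_hsd(list(a = base, b = base + d))$p_adj, 0)
  expect_true(all(diff(p) < 0))
})

test_that("letter display separates exactly the significant pairs", {
  mk <- function(p, groups) {
    pr <- utils::combn(groups, 2)
    structure(data.frame(group1 = pr[1, ], group2 = pr[2, ], p_adj = p),
              class = c("tukey_result", "data.frame"), alpha = 0.05)
  }
  # no significant pair: single letter
  r <- mk(rep(0.9, 3), c("a", "b", "c"))
  expect_equal(unname(letter_display(r, group_order = c("a", "b", "c"))),
               rep("a", 3))
  # all pairs significant: three distinct letters
  r2 <- mk(rep(0.001, 3), c("a", "b", "c"))
  expect_equal(unname(letter_display(r2, group_order = c("a", "b", "c"))),
               c("a", "b", "c"))
  # chain pattern a!=c, a~b, b~c -> "a", "ab", "b"
  r3 <- mk(c(0.5, 0.01, 0.6), c("A", "B", "C"))  # pairs AB, AC, BC
  expect_equal(unname(letter_display(r3, group_order = c("A", "B", "C"))),
               c("a", "ab", "b"))
})

test_that("letter sharing is equivalent to non-significance (random patterns)", {
  set.seed(12)
  for (rep_i in 1:40) {
    k <- sample(3:6, 1)
    groups <- LETTERS[1:k]
    pr <- utils::combn(groups, 2)
    p <- sample(c(0.001, 0.5), ncol(pr), TRUE)
    res <- structure(data.frame(group1 = pr[1, ], group2 = pr[2, ],
                                p_adj = p),
                     class = "data.frame", alpha = 0.05)
    cld <- letter_display(res, alpha = 0.05, group_order = groups)
    share <- function(a, b)
      length(intersect(strsplit(cld[[a]], "")[[1]],
                       strsplit(cld[[b]], "")[[1]])) > 0
    for (j in seq_len(ncol(pr)))
      expect_equal(share(pr[1, j], pr[2, j]), p[j] > 0.05)
    expect_true(all(nchar(cld) >= 1))
  }
})

test_that("letter count is minimal (enumeration oracle, <= 5 groups)", {
  set.seed(91)
  for (rep_i in 1:15) {
    k <- sample(3:5, 1)
    groups <- LETTERS[1:k]
    pr <- utils::combn(groups, 2)
    p <- sample(c(0.001, 0.5), ncol(pr), TRUE)
    res <- data.frame(group1 = pr[1, ], group2 = pr[2, ], p_adj = p)
    cld <- letter_display(res, alpha = 0.05, group_order = groups)
    used <- length(unique(unlist(strsplit(cld, ""))))
    adj <- matrix(FALSE, k, k)
    for (j in seq_len(ncol(pr))) {
      a <- match(pr[1, j], groups); b <- match(pr[2, j], groups)
      adj[a, b] <- adj[b, a] <- p[j] > 0.05
    }
    expect_equal(used, min_letters_oracle(adj))
  }
})

test_that("boxplot summary uses interpolated quartiles and extreme whiskers", {
  s <- boxplot_summary(c(1, 2, 3, 4, 5))
  expect_equal(s[c("median", "q25", "q75", "whisker_low", "whisker_high")],
               list(median = 3, q25 = 2, q75 = 4,
                    whisker_low = 1, whisker_high = 5))
  s1 <- boxplot_summary(7)
  expect_true(all(unlist(s1[1:5]) == 7))
  set.seed(2)
  v <- rnorm(37)
  s2 <- boxplot_summary(v)
  sv <- sort(v)
  # order-statistics oracle with linear interpolation (type 7)
  q_or <- function(p) {
    h <- (length(v) - 1) * p + 1
    sv[floor(h)] + (h - floor(h)) * (sv[floor(h) + 1] - sv[floor(h)])
  }
  expect_equal(s2$q25, q_or(0.25), tolerance = 1e-12)
  expect_equal(s2$median, q_or(0.5), tolerance = 1e-12)
  expect_equal(s2$q75, q_or(0.75), tolerance = 1e-12)
  expect_error(boxplot_summary(numeric()), "insufficient")
})
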