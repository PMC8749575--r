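test_that("Pearson + regression reproduces exact hand-computable cases", {
  res <- pearsonWithRegression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 0)
  expect_equal(res$p, 0)

  res2 <- pearsonWithRegression(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res2$r, 0.6)
  expect_equal(res2$slope, 0.6)
  expect_equal(res2$intercept, 1)
  expect_equal(res2$equation, "y = 1.00 + 0.60x")

  # r = 0 gives p = 1 exactly
  res3 <- pearsonWithRegression(c(-1, 0, 1), c(1, 0, 1))
  expect_identical(res3$r, 0)
  expect_identical(res3$p, 1)

  expect_error(pearsonWithRegression(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(pearsonWithRegression(1:2, 1:2), "at least 3")
  expect_error(pearsonWithRegression(1:4, 1:5), "equal length")
})

test_that("Pearson matches both textbook sums and cor.test/lm", {
  set.seed(7)
  for (k in 1:60) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- pearsonWithRegression(x, y)
    oracle <- naivePearson(x, y)
    expect_equal(res$r, oracle$r, tolerance = 1e-12)
    expect_equal(res$slope, oracle$slope, tolerance = 1e-12)
    expect_equal(res$intercept, oracle$intercept, tolerance = 1e-12)

    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    co <- coef(lm(y ~ x))
    expect_equal(res$intercept, unname(co[1]), tolerance = 1e-9)
    expect_equal(res$slope, unname(co[2]), tolerance = 1e-9)

    # the fitted line passes through the sample means
    expect_equal(mean(y), res$intercept + res$slope * mean(x),
                 tolerance = 1e-9)
  }
})

test_that("candidate bookkeeping multiplies planes, variables, traits, groups", {
  expect_identical(countCandidates(4, 2, 26, 3), 624L)
  expect_identical(countCandidates(4, 2, 26, 1), 208L)
  expect_identical(countCandidates(1, 1, 1, 1), 1L)
  expect_error(countCandidates(0, 2, 26, 3), "positive")
  expect_equal(screenPercentage(19, 624), 3.0)
  expect_equal(screenPercentage(12, 208), 5.8)
  expect_equal(screenPercentage(0, 208), 0)
  expect_error(screenPercentage(5, 4), "<=")
})

test_that("Guilford strength bands label |r| with closed-left intervals", {
  expect_equal(strengthLabel(-0.67), "moderate")
  expect_equal(strengthLabel(0), "slight")
  expect_equal(strengthLabel(-0.41), "moderate")
  expect_equal(strengthLabel(c(0.2, 0.4, 0.7, 0.9)),
               c("low", "moderate", "high", "very high"))
  expect_equal(strengthLabel(0.95), "very high")
  expect_error(strengthLabel(1.2), "exceed")
  # band edges are configurable
  expect_equal(strengthLabel(0.3, bands = c(0.1, 0.25, 0.5, 0.8)),
               "moderate")
})

test_that("the correlation screen equals per-pair recomputation and keeps its books", {
  tab <- simulateTraitTable(nPerGroup = 8, seed = 77)
  sc <- suppressMessages(correlationScreen(tab$echo, tab$traits,
                                           alpha = 0.05, pooled = FALSE))
  res <- screenTable(sc)
  expect_identical(sc@possible, 624L)
  expect_lte(sc@nSignificant, sc@possible)
  expect_equal(sc@percentage,
               round(100 * sum(res$significant) / 624, 1))

  # every emitted row matches pearsonWithRegression and the
  # regression-through-means invariant
  echoWide <- split(tab$echo, tab$echo$group)
  for (i in sample(nrow(res), 40)) {
    row <- res[i, ]
    e <- tab$echo[tab$echo$group == row$group, ]
    tr <- tab$traits[tab$traits$group == row$group, ]
    pl <- sub("-.*", "", row$input_variable)
    vr <- tolower(sub(".*-", "", row$input_variable))
    x <- e[[vr]][e$plane == pl][match(tr$bird_id,
                                      e$bird_id[e$plane == pl])]
    y <- tr[[row$output_variable]]
    ref <- pearsonWithRegression(x, y)
    expect_equal(row$r, ref$r, tolerance = 1e-9)
    expect_equal(row$p_value, ref$p, tolerance = 1e-9)
    expect_equal(row$slope, ref$slope, tolerance = 1e-9)
    expect_equal(row$intercept, ref$intercept, tolerance = 1e-9)
    expect_equal(mean(y), row$intercept + row$slope * mean(x),
                 tolerance = 1e-9)
  }

  # pooled screen ignores the group structure: 45 birds in one stratum
  sp <- suppressMessages(correlationScreen(tab$echo, tab$traits,
                                           pooled = TRUE))
  expect_identical(sp@possible, 208L)
  expect_true(all(screenTable(sp)$n == 24))
})

test_that("a screen with nothing significant is a valid empty result", {
  tab <- simulateTraitTable(nPerGroup = 10, seed = 3)
  sc <- suppressMessages(correlationScreen(tab$echo, tab$traits,
                                           alpha = 1e-9))
  expect_equal(sc@nSignificant, 0L)
  expect_equal(sc@percentage, 0)
  expect_equal(nrow(significantCorrelations(sc)), 0)
})

test_that("screens reject unmatched bird ids and degenerate strata", {
  tab <- simulateTraitTable(nPerGroup = 5, seed = 5)
  traitsBad <- tab$traits
  traitsBad$bird_id[1] <- "GHOST"
  expect_error(suppressMessages(correlationScreen(tab$echo, traitsBad)),
               "GHOST")
  echoBad <- tab$echo[tab$echo$plane != "L", ]
  expect_error(suppressMessages(correlationScreen(echoBad, tab$traits)),
               "plane coverage")
})

test_that("one-way ANOVA handles degenerate and textbook cases", {
  # three identical groups
  res <- anovaOnewayTukey(rep(5, 30), rep(c("a", "b", "c"), each = 10))
  expect_equal(anovaTerms(res)$F, 0)
  expect_equal(anovaTerms(res)$p, 1)
  expect_true(all(letterDisplay(res)$group == "a"))

  # two groups: F equals the square of the pooled t statistic
  set.seed(13)
  y <- c(rnorm(12, 0), rnorm(12, 1))
  g <- rep(c("A", "B"), each = 12)
  res2 <- anovaOnewayTukey(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(anovaTerms(res2)$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(anovaTerms(res2)$p, tt$p.value, tolerance = 1e-9)

  # matches stats::aov as engine oracle
  set.seed(14)
  y3 <- rnorm(30); g3 <- rep(c("A", "B", "C"), 10)
  res3 <- anovaOnewayTukey(y3, g3)
  at <- anova(aov(y3 ~ factor(g3)))
  expect_equal(anovaTerms(res3)$F, at$`F value`[1], tolerance = 1e-12)

  expect_error(anovaOnewayTukey(1:5, rep("a", 5)), "2 groups")
  expect_error(anovaOnewayTukey(1:3, c("a", "a", "b")), "at least 2 obs")
})

test_that("compact letters are transitive-consistent with the pairwise tests", {
  set.seed(23)
  for (k in 1:20) {
    means <- sample(0:6, 4, replace = TRUE)
    y <- unlist(lapply(means, function(m) rnorm(8, m)))
    g <- rep(letters[1:4], each = 8)
    res <- anovaOnewayTukey(y, g)
    lets <- letterDisplay(res)$group
    pw <- pairwiseComparisons(res)
    for (i in seq_len(nrow(pw))) {
      share <- any(strsplit(lets[pw$level1[i]], "")[[1]] %in%
                   strsplit(lets[pw$level2[i]], "")[[1]])
      expect_identical(share, pw$p[i] >= res@alpha,
                       label = sprintf("pair %s-%s (p=%.3g) letters %s/%s",
                                       pw$level1[i], pw$level2[i], pw$p[i],
                                       lets[pw$level1[i]],
                                       lets[pw$level2[i]]))
    }
    # every level gets at least one letter
    expect_true(all(nchar(lets) >= 1))
  }
})

test_that("well-separated group means earn three distinct Tukey letters", {
  set.seed(101)
  y <- c(rnorm(15, 73.1, 0.1), rnorm(15, 72.1, 0.2), rnorm(15, 74.2, 0.3))
  g <- rep(c("C", "Exp1", "Exp2"), each = 15)
  res <- anovaOnewayTukey(y, g)
  lets <- letterDisplay(res)$group
  expect_length(unique(lets), 3)
  # "a" belongs to the largest mean
  expect_equal(unname(lets["Exp2"]), "a")
})

test_that("two-way ANOVA main effects, LSD tests and degenerate reductions", {
  # all observations equal
  res0 <- anovaTwowayLsd(rep(3, 24), rep(c("a", "b"), each = 12),
                         rep(c("L", "T", "O1", "O2"), 6))
  expect_true(all(anovaTerms(res0)$F == 0))
  expect_true(all(anovaTerms(res0)$p == 1))

  # one plane degenerates to the one-way ANOVA
  set.seed(31)
  y <- rnorm(30); g <- rep(c("A", "B", "C"), 10)
  expect_message(res1 <- anovaTwowayLsd(y, g, rep("L", 30)), "single level")
  ref <- anovaOnewayTukey(y, g)
  expect_equal(anovaTerms(res1)$F[1], anovaTerms(ref)$F[1],
               tolerance = 1e-12)

  # balanced two-factor data: engine agrees with aov; LSD p-values equal
  # plain t tests on the residual mean square
  set.seed(32)
  g2 <- rep(c("C", "Exp1", "Exp2"), each = 20)
  p2 <- rep(rep(c("L", "T", "O1", "O2"), each = 5), 3)
  y2 <- rnorm(60) + ifelse(p2 %in% c("L", "O2"), 2, 0)
  res2 <- anovaTwowayLsd(y2, g2, p2)
  at <- anova(aov(y2 ~ factor(g2) + factor(p2)))
  expect_equal(anovaTerms(res2)$F, at$`F value`[1:2], tolerance = 1e-12)
  expect_lt(anovaTerms(res2)$p[2], 0.05)  # planted plane effect found

  mse <- at$`Mean Sq`[3]; dfres <- at$Df[3]
  pw <- pairwiseComparisons(res2)
  row <- pw[pw$term == "plane" & pw$level1 == "L" & pw$level2 == "T", ]
  mL <- mean(y2[p2 == "L"]); mT <- mean(y2[p2 == "T"])
  tman <- (mT - mL) / sqrt(mse * (2 / 15))
  expect_equal(row$p, 2 * pt(-abs(tman), dfres), tolerance = 1e-12)
  expect_equal(row$estimate, mT - mL, tolerance = 1e-12)

  # empty cell detection
  keep <- !(g2 == "C" & p2 == "L")
  expect_error(anovaTwowayLsd(y2[keep], g2[keep], p2[keep]), "empty cell")
})
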