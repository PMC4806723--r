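# The shared ANOVA/ANCOVA engine, checked against hand arithmetic,
# closed-form identities and an independent cell-means oracle.

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  d <- data.frame(g = rep(c("a", "b"), each = 3),
                  y = c(1, 2, 3, 2, 3, 4))
  tab <- fit_anova(d, model_spec("y", factors = "g"))
  term <- tab[tab$term == "g", ]
  res <- tab[tab$term == "Residuals", ]
  expect_equal(term$sumsq, 1.5)
  expect_equal(res$sumsq, 4)
  expect_equal(term$df, 1)
  expect_equal(term$den_df, 4)
  expect_equal(term$F, 1.5)
  expect_equal(term$p, pf(1.5, 1, 4, lower.tail = FALSE))
})

test_that("two balanced groups give F equal to the squared pooled t", {
  set.seed(11)
  d <- data.frame(g = rep(c("a", "b"), each = 8), y = rnorm(16))
  tab <- fit_anova(d, model_spec("y", factors = "g"))
  t2 <- t.test(y ~ g, data = d, var.equal = TRUE)$statistic^2
  expect_equal(tab$F[tab$term == "g"], unname(t2))
})

test_that("balanced factorial F and p match the cell-means oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                     rep = seq_len(n), stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d), mean = 2 * (d$A == "a2") + rnorm(1) * (d$B == "b2"))
    tab <- fit_anova(d, model_spec("y", factors = c("A", "B")))
    orc <- balanced_twoway_oracle(d, "A", "B", "y")
    got_f <- tab$F[match(c("A", "B", "A:B"), tab$term)]
    got_p <- tab$p[match(c("A", "B", "A:B"), tab$term)]
    expect_equal(got_f, unname(orc$f), tolerance = 1e-9)
    expect_equal(got_p, unname(orc$p), tolerance = 1e-9)
    expect_equal(tab$den_df[tab$term == "A"], orc$df_e)
  }
})

test_that("Type II equals sequential SS on balanced orthogonal designs", {
  set.seed(31)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:5,
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d))
  t1 <- fit_anova(d, model_spec("y", factors = c("A", "B"), ss_type = "I"))
  t2 <- fit_anova(d, model_spec("y", factors = c("A", "B"), ss_type = "II"))
  expect_equal(t2$sumsq[match(t1$term, t2$term)], t1$sumsq)
  # term SS + error SS = total SS
  expect_equal(sum(t2$sumsq), sum((d$y - mean(d$y))^2))
})

test_that("the log transform is applied before partitioning", {
  set.seed(41)
  d <- expand.grid(A = c("a1", "a2"), rep = 1:10, stringsAsFactors = FALSE)
  d$y <- exp(rnorm(nrow(d), mean = ifelse(d$A == "a2", 2, 0), sd = 0.3))
  logged <- fit_anova(d, model_spec("y", factors = "A", transform = "log"))
  raw <- fit_anova(d, model_spec("y", factors = "A"))
  manual <- d
  manual$ly <- log(manual$y)
  ref <- fit_anova(manual, model_spec("ly", factors = "A"))
  expect_equal(logged$F[1], ref$F[1])
  expect_false(isTRUE(all.equal(logged$F[1], raw$F[1])))
})

test_that("between-block terms are tested against the block stratum", {
  set.seed(51)
  d <- expand.grid(plot = 1:3, year = c("y1", "y2"), rep = 1:4,
                   stringsAsFactors = FALSE)
  d$plot <- paste(d$year, d$plot)  # plots nested in years
  d$y <- rnorm(nrow(d))
  tab <- fit_anova(d, model_spec("y", factors = "year", random = "plot"))
  yr <- tab[tab$term == "year", ]
  expect_equal(yr$den_df, 4)  # 6 plots - 1 year df - 1
  expect_identical(yr$stratum, "block")
  # Oracle: the year F in the plot stratum equals the one-way F on plot
  # means (balanced design).
  pm <- aggregate(y ~ plot + year, d, mean)
  a <- anova(lm(y ~ year, data = pm))
  expect_equal(yr$F, a[["F value"]][1], tolerance = 1e-10)
})

test_that("within-block terms keep the residual stratum and its df", {
  set.seed(61)
  d <- expand.grid(block = paste0("b", 1:6), A = c("a1", "a2"),
                   B = c("b1", "b2"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), mean = (d$block == "b1"))
  tab <- fit_anova(d, model_spec("y", factors = c("A", "B"),
                                 random = "block"))
  # 24 rows - 1 - 5 (block) - 3 (fixed) = 15 residual df
  for (trm in c("A", "B", "A:B"))
    expect_equal(tab$den_df[tab$term == trm], 15)
  expect_identical(tab$stratum[tab$term == "block"], "block")
})

test_that("REML backend agrees with the strata engine on balanced data", {
  set.seed(71)
  d <- expand.grid(block = paste0("b", 1:8), A = c("a1", "a2"),
                   B = c("b1", "b2"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + 2 * (d$A == "a2") +
    rep(rnorm(8, sd = 2), times = 4)
  s <- fit_anova(d, model_spec("y", factors = c("A", "B"),
                               random = "block"))
  r <- fit_anova(d, model_spec("y", factors = c("A", "B"),
                               random = "block"), method = "reml")
  # within-block F ratios coincide for a balanced design
  for (trm in c("A", "B", "A:B"))
    expect_equal(r$F[r$term == trm], s$F[s$term == trm],
                 tolerance = 1e-6)
})

test_that("degenerate inputs fail loudly", {
  d <- data.frame(g = rep(c("a", "b"), each = 2), y = rep(1, 4))
  expect_error(fit_anova(d, model_spec("y", factors = "g")),
               "constant")
  d2 <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                    stringsAsFactors = FALSE)
  d2$y <- rnorm(4)
  expect_error(fit_anova(d2, model_spec("y", factors = c("A", "B"))),
               "residual")
  d3 <- data.frame(A = c("a1", "a1", "a2", "a2"),
                   C = c("c1", "c1", "c2", "c2"), y = rnorm(4))
  expect_error(fit_anova(d3, model_spec("y", factors = c("A", "C"))),
               "alias|rank|residual")
  expect_error(model_spec("y", factors = "g", random = "g"),
               "random")
  expect_error(model_spec("y", factors = "g", interactions = "g:h"),
               "interactions")
  expect_error(fit_anova(d, model_spec("z", factors = "g")), "missing")
})

test_that("ancova adjusts for the covariate and validates it", {
  set.seed(81)
  # unbalanced covariate across cells: dropping it must change factor SS
  d <- data.frame(g = rep(c("a", "b"), each = 10))
  d$x <- c(rnorm(10, 0), rnorm(10, 3))
  d$y <- 0.5 * d$x + rnorm(20, sd = 0.2)
  spec <- model_spec("y", covariates = "x", factors = "g")
  with_cov <- fit_ancova(d, spec)
  without <- fit_anova(d, model_spec("y", factors = "g"))
  expect_identical(with_cov$term[1], "x")  # covariate reported first
  expect_false(isTRUE(all.equal(
    with_cov$sumsq[with_cov$term == "g"],
    without$sumsq[without$term == "g"])))
  # strong covariate, no factor effect: x term large, factor null-like
  expect_gt(with_cov$F[with_cov$term == "x"], 10)
  expect_gt(with_cov$p[with_cov$term == "g"], 0.01)
  d$x[d$g == "a"] <- 1
  expect_error(fit_ancova(d, spec), "constant within")
  expect_error(fit_ancova(d, model_spec("y", factors = "g")), "covariate")
})
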