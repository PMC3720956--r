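test_that("univariate screening ranks by explained deviance", {
  set.seed(42)
  n <- 400
  d <- data.frame(strong = rnorm(n), weak = rnorm(n), noise = rnorm(n))
  d$y <- rbinom(n, 1, plogis(2 * d$strong + 0.5 * d$weak))
  out <- univariate_screen(d, "y", family_spec("binomial"),
                           candidates = c("noise", "weak", "strong"))
  kept <- out$variable[out$retained]
  expect_equal(kept[1], "strong")
  expect_true("weak" %in% kept)
  # explained deviance is sorted descending among retained variables
  ed <- out$expl_dev[out$retained]
  expect_true(all(diff(ed) <= 0))
  expect_true(all(out$p_value[out$retained] < 0.1))
})

test_that("a perfect predictor screens in with explained deviance near 1", {
  d <- data.frame(x = c(rep(-2, 30), rep(2, 30)))
  d$y <- as.integer(d$x > 0)
  out <- univariate_screen(d, "y", family_spec("binomial"),
                           candidates = "x")
  expect_true(out$retained[1])
  expect_gt(out$expl_dev[1], 0.95)
})

test_that("null predictors are retained at about the threshold rate", {
  # under independence the likelihood-ratio p-value is uniform, so the
  # retention rate at threshold 0.1 is ~10%
  set.seed(7)
  n_rep <- 500
  kept <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- data.frame(x = rnorm(200), y = rbinom(200, 1, 0.4))
    out <- univariate_screen(d, "y", family_spec("binomial"),
                             candidates = "x")
    kept[i] <- out$retained[1]
  }
  expect_lt(abs(mean(kept) - 0.1), 0.035)
})

test_that("correlation filter drops duplicates and competing scales", {
  set.seed(1)
  n <- 300
  tbl <- data.frame(BARESOIL_1 = runif(n, 0, 100))
  tbl$BARESOIL_50 <- tbl$BARESOIL_1 + rnorm(n, sd = 30)
  tbl$BARESOIL_25 <- tbl$BARESOIL_1 + rnorm(n, sd = 30)
  tbl$copy <- tbl$BARESOIL_1
  tbl$SOIL_PH <- rnorm(n)

  # an exact copy is dropped as correlated
  out <- correlation_filter(c("BARESOIL_1", "copy"), tbl,
                            catalog = rbind(
                              variable_catalog(),
                              data.frame(name = "copy", category = "SOIL",
                                         scale = "1m", scale_group = NA,
                                         kind = "percent", unit = "%")))
  expect_equal(attr(out, "retained"), "BARESOIL_1")
  expect_match(out$reason[out$variable == "copy"], "correlated-with")

  # scale competition: only the best-ranked bare-soil scale survives,
  # even with correlations below the threshold
  cand <- c("BARESOIL_50", "BARESOIL_1", "BARESOIL_25", "SOIL_PH")
  out2 <- correlation_filter(cand, tbl)
  kept <- attr(out2, "retained")
  expect_equal(sum(grepl("^BARESOIL", kept)), 1)
  expect_equal(kept[1], "BARESOIL_50")  # rank order respected
  expect_true("SOIL_PH" %in% kept)
  expect_true(any(out2$reason == "scale-competition"))

  # independent columns all survive
  ind <- data.frame(SOIL_PH = rnorm(1000), SOIL_OM = rnorm(1000),
                    HEIGHT = rnorm(1000))
  out3 <- correlation_filter(c("SOIL_PH", "SOIL_OM", "HEIGHT"), ind)
  expect_length(attr(out3, "retained"), 3)

  # constant column is dropped with its own reason
  tbl$SOIL_OM <- 1
  out4 <- correlation_filter(c("BARESOIL_1", "SOIL_OM"), tbl)
  expect_equal(out4$reason[out4$variable == "SOIL_OM"], "constant")
})

test_that("VIF matches its closed form and the car oracle", {
  set.seed(3)
  n <- 500
  # two predictors with controlled correlation: VIF = 1 / (1 - r^2)
  x1 <- rnorm(n)
  x2 <- 0.7 * x1 + sqrt(1 - 0.49) * rnorm(n)
  tbl <- data.frame(x1 = x1, x2 = x2, y = rnorm(n))
  v <- vif_values(tbl, c("x1", "x2"))
  r2 <- cor(x1, x2)^2
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-10)

  skip_if_not_installed("car")
  fit <- lm(y ~ x1 + x2, data = tbl)
  expect_equal(unname(v), unname(car::vif(fit)), tolerance = 1e-8)

  # three orthogonal-by-construction predictors: all VIFs ~ 1 (up to the
  # small non-orthogonality with the intercept column)
  q <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  tblq <- data.frame(a = q[, 1], b = q[, 2], c = q[, 3])
  expect_equal(unname(vif_values(tblq, c("a", "b", "c"))), rep(1, 3),
               tolerance = 1e-3)
})

test_that("the VIF cascade removes exact collinearity", {
  set.seed(4)
  tbl <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  tbl$x3 <- tbl$x1 + tbl$x2
  out <- vif_cascade(tbl, c("x1", "x2", "x3"), vif_threshold = 10)
  expect_lte(length(out$retained), 2)
  expect_true(all(is.finite(out$vifs)))
  expect_true(all(out$vifs < 10))
  expect_equal(nrow(out$dropped), 1)
})

test_that("screening chain output is order-invariant and VIF-clean", {
  sv <- small_survey(seed = 17)
  ds <- assemble_datasets(sv)
  tab <- ds$ds1
  fam <- family_spec("binomial")
  a <- screen_predictors(tab, "PA", fam)
  b <- screen_predictors(tab, "PA", fam,
                         candidates = rev(abiotic_vars(tab)))
  expect_setequal(a$retained, b$retained)
  if (length(a$retained) >= 2) {
    expect_true(all(a$vifs < 10))
    rho <- cor(tab[, a$retained], method = "spearman")
    expect_true(all(abs(rho[upper.tri(rho)]) < 0.7))
  }
  # every candidate is accounted for exactly once in the report
  expect_setequal(a$report$variable, abiotic_vars(tab))
})
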