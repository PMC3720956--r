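test_that("fit_glm reproduces closed-form and null-model identities", {
  # intercept-only binomial: intercept = logit(3/10)
  d <- data.frame(y = c(rep(1, 30), rep(0, 70)))
  m <- fit_glm(d, "y", character(0), family_spec("binomial"))
  expect_equal(m$coefficients$estimate[1], qlogis(0.3), tolerance = 1e-6)
  expect_equal(m$residual_deviance, m$null_deviance)
  # AIC identity for a likelihood family
  expect_equal(m$aic, -2 * m$loglik + 2, tolerance = 1e-8)

  # residual deviance never exceeds null deviance when a term is added
  d$x <- rnorm(100)
  m2 <- fit_glm(d, "y", "x", family_spec("binomial"))
  expect_lte(m2$residual_deviance, m2$null_deviance + 1e-8)
})

test_that("perfect separation is flagged, not fatal", {
  d <- data.frame(x = c(rep(-1, 20), rep(1, 20)),
                  y = c(rep(0, 20), rep(1, 20)))
  m <- fit_glm(d, "y", "x", family_spec("binomial"))
  expect_true(m$separation)
  expect_true(all(is.finite(m$coefficients$estimate)))
})

test_that("negative-binomial fits recover coefficients and k", {
  set.seed(5)
  n <- 2000
  x <- rnorm(n)
  y <- rnbinom(n, size = 0.5, mu = exp(0.5 + 0.8 * x))
  d <- data.frame(x = x, y = y)
  m <- fit_glm(d, "y", "x", family_spec("negative_binomial"))
  expect_equal(m$coefficients$estimate[2], 0.8, tolerance = 0.1)
  expect_gt(m$family$k, 0.3)
  expect_lt(m$family$k, 0.8)

  # on Poisson data, NB and Poisson coefficients agree closely
  yp <- rpois(5000, exp(0.3 + 0.5 * rep(x, length.out = 5000)))
  dp <- data.frame(x = rep(x, length.out = 5000), y = yp)
  mp <- fit_glm(dp, "y", "x", family_spec("poisson"))
  mnb <- suppressWarnings(
    fit_glm(dp, "y", "x", family_spec("negative_binomial")))
  expect_equal(mnb$coefficients$estimate, mp$coefficients$estimate,
               tolerance = 1e-3)
})

test_that("family choice follows the dispersion and clumping rules", {
  # ungrouped binary data keeps the binomial family
  d <- data.frame(y = rbinom(200, 1, 0.3))
  expect_equal(choose_family(d, "y", "PA")$family, "binomial")

  # aggregated counts (k = 0.5): negative binomial with recovered k
  set.seed(6)
  d2 <- data.frame(y = rnbinom(1000, size = 0.5, mu = 3))
  f2 <- choose_family(d2, "y", "AB")
  expect_equal(f2$family, "negative_binomial")
  expect_gt(attr(f2, "trigger"), 0.3)
  expect_lt(attr(f2, "trigger"), 0.8)

  # equidispersed counts: Poisson chosen (huge estimated k, or the
  # sample variance dips below the mean)
  d3 <- data.frame(y = rpois(1000, 3))
  f3 <- suppressWarnings(choose_family(d3, "y", "AB"))
  expect_equal(f3$family, "poisson")

  # underdispersion: divergent k falls back to Poisson with a warning
  d4 <- data.frame(y = rep(c(2, 3), 50))
  expect_warning(f4 <- choose_family(d4, "y", "AB"), "Poisson")
  expect_equal(f4$family, "poisson")
})

test_that("stepwise AIC keeps signal and discards noise", {
  set.seed(8)
  n <- 1000
  d <- data.frame(info = rnorm(n), junk = rnorm(n))
  d$y <- rbinom(n, 1, plogis(1.5 * d$info))
  m <- stepwise_aic(d, "y", c("info", "junk"), family_spec("binomial"))
  expect_true("info" %in% m$predictors)
  expect_false("junk" %in% m$predictors)

  # a pure-noise scope collapses to the intercept-only model in most
  # replicates (retention probability ~ P(chisq_1 > 2) ~ 0.157)
  kept <- 0L
  for (i in 1:60) {
    set.seed(100 + i)
    dn <- data.frame(x = rnorm(300), y = rbinom(300, 1, 0.5))
    mn <- stepwise_aic(dn, "y", "x", family_spec("binomial"))
    if (length(mn$predictors) > 0) kept <- kept + 1L
  }
  expect_lt(kept / 60, 0.35)
  expect_gt(kept / 60, 0.02)
})

test_that("stepwise AIC agrees with MASS::stepAIC on a typical scope", {
  skip_if_not_installed("MASS")
  set.seed(9)
  n <- 500
  d <- as.data.frame(matrix(rnorm(n * 4), n,
                            dimnames = list(NULL, paste0("x", 1:4))))
  d$y <- rbinom(n, 1, plogis(1 * d$x1 - 0.8 * d$x2 + 0.1 * d$x3))
  m <- stepwise_aic(d, "y", paste0("x", 1:4), family_spec("binomial"))
  ref <- MASS::stepAIC(glm(y ~ x1 + x2 + x3 + x4, d, family = binomial()),
                       trace = 0)
  expect_setequal(m$predictors,
                  setdiff(all.vars(formula(ref)), "y"))
  expect_equal(m$aic, AIC(ref), tolerance = 1e-8)
})

test_that("Nagelkerke R2 matches a direct evaluation of the formula", {
  d <- logistic_fixture()
  m <- fit_glm(d, "y", "x", family_spec("binomial"))
  fit <- glm(y ~ x, data = d, family = binomial())
  expect_equal(nagelkerke_r2(m), nagelkerke_oracle(fit),
               tolerance = 1e-10)

  # boundary identities
  m0 <- fit_glm(d, "y", character(0), family_spec("binomial"))
  expect_equal(nagelkerke_r2(m0), 0, tolerance = 1e-12)
  dsep <- data.frame(x = c(rep(-2, 15), rep(2, 15)))
  dsep$y <- as.integer(dsep$x > 0)
  msep <- fit_glm(dsep, "y", "x", family_spec("binomial"))
  expect_gt(nagelkerke_r2(msep), 0.999)
  expect_error(nagelkerke_r2(list(null_deviance = 0,
                                  residual_deviance = 0, n = 10)),
               "undefined")
})

test_that("category deviance attributes explained deviance correctly", {
  set.seed(10)
  n <- 600
  # two near-orthogonal predictors from different catalog categories
  tbl <- data.frame(BARESOIL_1 = rnorm(n), SOIL_PH = rnorm(n))
  tbl$y <- rbinom(n, 1, plogis(1.2 * tbl$BARESOIL_1 + 0.8 * tbl$SOIL_PH))
  fam <- family_spec("binomial")
  mam <- fit_glm(tbl, "y", c("BARESOIL_1", "SOIL_PH"), fam)
  mam$response <- "y"
  cd <- category_deviance(mam, tbl)
  expect_setequal(names(cd), c("COVER", "RESISTANCE", "SOIL", "STRUCTURE"))
  expect_equal(unname(cd["RESISTANCE"]), 0)
  expect_equal(unname(cd["STRUCTURE"]), 0)
  # near-orthogonality: category contribution ~ single-term deviance drop
  m_cover_only <- fit_glm(tbl, "y", "BARESOIL_1", fam)
  approx_soil <- (m_cover_only$residual_deviance -
                    mam$residual_deviance) / mam$null_deviance * 100
  expect_equal(unname(cd["SOIL"]), approx_soil, tolerance = 1e-8)

  # single-category MAM: that category equals the total explained %
  m1 <- fit_glm(tbl, "y", "BARESOIL_1", fam)
  m1$response <- "y"
  cd1 <- category_deviance(m1, tbl)
  total <- (m1$null_deviance - m1$residual_deviance) /
    m1$null_deviance * 100
  expect_equal(unname(cd1["COVER"]), total, tolerance = 1e-10)
})

test_that("model triplets share rows and bound the FULL scope", {
  ds <- assemble_datasets(small_survey(seed = 23))
  trip <- fit_model_triplet(ds$ds1, "PA")
  expect_s3_class(trip, "model_triplet")
  expect_equal(trip$abiot$n, trip$biot$n)
  expect_true(all(trip$full$predictors %in%
                    union(trip$abiot$predictors, trip$biot$predictors)))
  expect_true(all(trip$r2 >= 0 & trip$r2 <= 1))
  # stepwise endpoint is no worse than either start point
  expect_lte(trip$abiot$criterion_value,
             trip$abiot$trace$backward_led[[1]]$criterion + 1e-9)
  expect_lte(trip$abiot$criterion_value,
             trip$abiot$trace$forward_led[[1]]$criterion + 1e-9)
})
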