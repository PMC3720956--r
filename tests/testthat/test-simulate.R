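test_that("covariate generation follows the survey design", {
  design <- survey_design()
  truth <- synthetic_truth()
  cov <- generate_covariates(design, truth, seed = 3)

  expect_equal(nrow(cov), 240)
  expect_setequal(unique(cov$location), c("A", "B"))
  # minimum spacing holds within each location
  for (loc in c("A", "B")) {
    xy <- cov[cov$location == loc, c("x", "y")]
    d <- as.matrix(dist(xy))
    expect_gte(min(d[upper.tri(d)]), design$min_point_spacing)
  }
  # percentage covers bounded
  for (v in c("BARESOIL_1", "HERB_50", "CALLUNA_25")) {
    expect_true(all(cov[[v]] >= 0 & cov[[v]] <= 100))
  }
  # habitat stratification is proportional (largest-remainder counts)
  hab <- table(cov$habitat_type[cov$location == "A"])
  expect_equal(sort(as.numeric(hab)), sort(c(36, 24, 24, 18, 18)))
})

test_that("infeasible spacing fails with a clear error", {
  d <- survey_design(n_points_per_location = 200, area_side = c(10, 10))
  expect_error(generate_covariates(d, synthetic_truth(), seed = 1),
               "spacing")
})

test_that("cross-scale correlation of cover variables is honoured", {
  # degenerate case: rho = 1 makes all scale versions identical
  d <- survey_design(n_points_per_location = 40)
  tr1 <- synthetic_truth(cross_scale_rho = 1)
  cov1 <- generate_covariates(d, tr1, seed = 5)
  expect_equal(cov1$BARESOIL_25, cov1$BARESOIL_1, tolerance = 1e-12)
  expect_equal(cov1$BARESOIL_50, cov1$BARESOIL_1, tolerance = 1e-12)

  # rho = 0.8: empirical Spearman correlation within +/- 0.05 at n = 2000
  big <- survey_design(n_locations = 1, n_points_per_location = 2000,
                       habitat_types = list(A = c(BARE_CUSHION = 0.5,
                                                  DENSE = 0.5)),
                       area_side = 600)
  cov <- generate_covariates(big, synthetic_truth(cross_scale_rho = 0.8),
                             seed = 7)
  # compare within habitat so the habitat-mean shift does not inflate rho
  sub <- cov[cov$habitat_type == "BARE_CUSHION", ]
  rho <- cor(sub$BARESOIL_25, sub$BARESOIL_1, method = "spearman")
  expect_lt(abs(rho - 0.8), 0.05)
})

test_that("response generation matches its generating model", {
  # all-zero coefficients, intercept 0: adult prevalence ~ 0.5
  d <- survey_design(n_locations = 1, n_points_per_location = 2000,
                     habitat_types = list(A = c(BARE_CUSHION = 1)),
                     area_side = 600,
                     min_larvae_threshold = 1, fine_scale_points_cap = 5)
  tr <- synthetic_truth(
    adult_pa = list(intercept = 0, coef = numeric(0)),
    adult_ab = list(intercept = 0.5, coef = numeric(0)),
    larva_ab = list(intercept = 1, coef = numeric(0)))
  sv <- simulate_survey(d, tr, seed = 21)
  expect_lt(abs(mean(sv$points$ADULT_PA) - 0.5), 0.03)

  # negative-binomial mean/variance: var = mu + mu^2 / k
  mu <- exp(1); k <- 1.2
  v_emp <- var(sv$points$LARVA_AB)
  v_th <- mu + mu^2 / k
  expect_lt(abs(v_emp / v_th - 1), 0.15)

  # Poisson limit: huge k gives variance/mean ratio ~ 1 at n = 5000
  d5 <- survey_design(n_locations = 1, n_points_per_location = 5000,
                      habitat_types = list(A = c(BARE_CUSHION = 1)),
                      area_side = 900,
                      min_larvae_threshold = 1, fine_scale_points_cap = 5)
  tr5 <- synthetic_truth(
    adult_ab = list(intercept = 1, coef = numeric(0)),
    k = c(adult_ab = 1e6, larva_ab = 1.2,
          congen_adult_ab = 1, congen_larva_ab = 1))
  sv5 <- simulate_survey(d5, tr5, seed = 22)
  ratio <- var(sv5$points$ADULT_AB) / mean(sv5$points$ADULT_AB)
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("a strong generating coefficient is recoverable by GLM", {
  # parameter-recovery: univariate logistic fit on simulated adults finds
  # the positive bare-soil effect in nearly all replicates at n = 240
  hits <- 0L
  for (s in 1:40) {
    sv <- simulate_survey(survey_design(), synthetic_truth(), seed = 400 + s)
    fit <- suppressWarnings(
      glm(ADULT_PA ~ BARESOIL_1, data = sv$points, family = binomial()))
    co <- summary(fit)$coefficients
    if (co["BARESOIL_1", 1] > 0 && co["BARESOIL_1", 4] < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 38)
})

test_that("generation is bit-identical under a fixed seed", {
  sv1 <- simulate_survey(seed = 99)
  sv2 <- simulate_survey(seed = 99)
  expect_identical(sv1$points, sv2$points)
  expect_identical(sv1$cells, sv2$cells)
  d1 <- assemble_datasets(sv1)
  d2 <- assemble_datasets(sv2)
  expect_identical(lapply(d1, as.data.frame), lapply(d2, as.data.frame))
})

test_that("neighbour counts follow the quadrat geometry", {
  m0 <- matrix(0L, 4, 4)
  expect_equal(neighbour_counts(m0, "central"), 0)
  expect_equal(neighbour_counts(m0, c(3, 2)), 0)

  m1 <- matrix(1L, 4, 4)
  expect_equal(neighbour_counts(m1, "central"), 12)
  # neighbour-set sizes: 3 at corners, 5 on edges, 8 in the interior
  sizes <- sapply(1:16, function(i) {
    neighbour_counts(m1, c((i - 1) %/% 4 + 1, (i - 1) %% 4 + 1))
  })
  expect_setequal(unique(sizes), c(3, 5, 8))
  expect_equal(sum(sizes == 3), 4)   # corners
  expect_equal(sum(sizes == 5), 8)   # edges
  expect_equal(sum(sizes == 8), 4)   # interior

  expect_error(neighbour_counts(m1, c(0, 2)), "outside")

  # a distinctive map: focal (2,2) ignores the focal cell itself
  m <- matrix(0L, 4, 4); m[2, 2] <- 10L; m[1, 1] <- 2L; m[3, 3] <- 3L
  expect_equal(neighbour_counts(m, c(2, 2)), 5)
})

test_that("abundances are conserved across nested scales", {
  sv <- small_survey(seed = 13)
  ds <- assemble_datasets(sv)
  pts <- sv$points
  for (i in sample(nrow(pts), 25)) {
    cc <- sv$cells[sv$cells$location == pts$location[i] &
                     sv$cells$point_id == pts$point_id[i], ]
    expect_equal(sum(cc$larvae), pts$LARVA_AB[i])
    central <- cc$larvae[cc$row %in% 2:3 & cc$col %in% 2:3]
    key <- ds$ds5$point_id == pts$point_id[i]
    if (pts$location[i] == attr(ds$ds5, "location")) {
      expect_equal(ds$ds5$AB[key], sum(central))
    }
  }
  # the 1 m larval table equals the point totals
  expect_equal(ds$ds3$AB,
               pts$LARVA_AB[pts$location == attr(ds$ds3, "location")])
})

test_that("fine-scale data sets obey threshold, ranking, cap and expansion", {
  sv <- simulate_survey(seed = 1)
  ds <- assemble_datasets(sv)
  # caps of 10 and 11 points expand to 160 and 176 cell rows
  expect_equal(nrow(ds$ds7), 160)
  expect_equal(nrow(ds$ds8), 176)
  expect_equal(length(unique(ds$ds7$point_id)), 10)
  expect_equal(length(unique(ds$ds8$point_id)), 11)

  # every retained point passes its location threshold
  totals7 <- tapply(ds$ds7$AB, ds$ds7$point_id, sum)
  expect_true(all(totals7 >= sv$design$min_larvae_threshold[1]))

  # retained points are those with the highest totals among all points
  ptsA <- sv$points[sv$points$location == "A", ]
  best <- sort(ptsA$LARVA_AB, decreasing = TRUE)[10]
  expect_true(all(totals7 >= min(best, sv$design$min_larvae_threshold[1])))

  # threshold 0, no cap: all points expand to 16 rows each
  d0 <- survey_design(min_larvae_threshold = 0,
                      fine_scale_points_cap = 120)
  sv0 <- simulate_survey(d0, synthetic_truth(), seed = 2)
  ds0 <- assemble_datasets(sv0)
  expect_equal(nrow(ds0$ds7), 120 * 16)

  # shortfall below the cap is reported, not fatal
  dhi <- survey_design(min_larvae_threshold = c(5000, 5000))
  svhi <- simulate_survey(dhi, synthetic_truth(), seed = 3)
  expect_message(assemble_datasets(svhi), "threshold")
})

test_that("observation tables carry their predictor roles", {
  ds <- assemble_datasets(small_survey())
  expect_setequal(biotic_vars(ds$ds1),
                  c("LARVA_PA", "LARVA_AB", "CONGEN_ADULT_PA",
                    "CONGEN_ADULT_AB"))
  expect_setequal(biotic_vars(ds$ds7), c("ADULT_AB", "NEIGH_LARVA_AB"))
  expect_true(all(abiotic_vars(ds$ds3) %in% names(ds$ds3)))
  # 1 m larval scope excludes 50 cm and 25 cm cover versions
  expect_false(any(grepl("_50$", abiotic_vars(ds$ds3))))
  expect_true("BARESOIL_25" %in% abiotic_vars(ds$ds7))
  expect_true(all(ds$ds1$PA %in% 0:1))
  expect_true(all(ds$ds3$AB >= 0))
})
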