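# Shared fixtures: small deterministic tables built in code.

# Logistic-regression fixture (n = 20, one predictor), fixed numbers so
# formula oracles are reproducible without touching the RNG.
logistic_fixture <- function() {
  data.frame(
    x = c(-1.9, -1.5, -1.2, -0.8, -0.6, -0.4, -0.3, -0.1, 0.0, 0.1,
          0.2, 0.4, 0.5, 0.7, 0.9, 1.1, 1.4, 1.6, 1.8, 2.1),
    y = c(0, 0, 0, 0, 1, 0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1, 1, 1))
}

# Tiny two-location survey for pipeline-level tests (fast to fit).
small_survey <- function(seed = 11, n_points = 80) {
  simulate_survey(survey_design(n_points_per_location = n_points),
                  synthetic_truth(), seed = seed)
}

table3_fixture <- function() {
  read_r2_table(system.file("extdata", "table3_r2.csv",
                            package = "stageniche"))
}

# Direct evaluation of the Nagelkerke formula from a glm object, coded
# independently of the package implementation.
nagelkerke_oracle <- function(fit) {
  d0 <- fit$null.deviance; d1 <- fit$deviance; n <- length(fit$y)
  (1 - exp((d1 - d0) / n)) / (1 - exp(-d0 / n))
}
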