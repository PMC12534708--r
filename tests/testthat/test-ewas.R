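make_sheet <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             tissue = rep(c("liver", "brain", "blood"), length.out = n),
             age = runif(n, 20, 90),
             sex = sample(c("F", "M"), n, replace = TRUE))
}

test_that("EWAS coefficients and SEs match the lm oracle, with and without NAs", {
  sheet <- make_sheet(30)
  set.seed(2)
  bm <- toy_bm(runif(6 * 30), 6, 30, samples = sheet$sample_id)
  bm["p02", c(3, 9)] <- NA
  ew <- fit_linear_ewas(bm, sheet)
  for (p in c("p01", "p02")) {
    ok <- !is.na(bm[p, ])
    fit <- lm(bm[p, ok] ~ age + factor(sex) + factor(tissue),
              data = sheet[ok, ])
    sm <- summary(fit)$coefficients
    got <- ew[ew$probe_id == p, ]
    expect_equal(got$estimate[got$term == "age"], sm["age", "Estimate"],
                 tolerance = 1e-8)
    expect_equal(got$se[got$term == "age"], sm["age", "Std. Error"],
                 tolerance = 1e-8)
    expect_equal(got$p_value[got$term == "age"], sm["age", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
  # constant betas: estimate 0 for age, p NA (not 0)
  bm2 <- rbind(const = rep(0.4, 30)); colnames(bm2) <- sheet$sample_id
  ewc <- fit_linear_ewas(bm2, sheet)
  expect_equal(ewc$estimate[ewc$term == "age"], 0, tolerance = 1e-12)
  expect_true(is.na(ewc$p_value[ewc$term == "age"]))
  # q >= p within each family
  expect_true(all(ew$q_value >= ew$p_value - 1e-12, na.rm = TRUE))
})

test_that("collinear designs fail loudly naming the aliased columns", {
  sheet <- make_sheet(20)
  sheet$sex <- ifelse(sheet$tissue == "liver", "F", "M")
  sheet$tissue <- ifelse(sheet$sex == "F", "liver", "brain")
  bm <- toy_bm(runif(2 * 20), 2, 20, samples = sheet$sample_id)
  expect_error(fit_linear_ewas(bm, sheet), "aliased|collinear")
})

test_that("null age p-values are calibrated and planted slopes are recovered", {
  sheet <- make_sheet(50, seed = 3)
  set.seed(4)
  bm <- toy_bm(runif(2000 * 50, 0.2, 0.8), 2000, 50, samples = sheet$sample_id)
  ew <- fit_linear_ewas(bm, sheet)
  frac <- mean(ew$p_value[ew$term == "age"] < 0.05)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), ci + 1e-9)

  slope <- 0.004
  sig <- 0.1 + outer(rep(slope, 300), sheet$age - 20) +
    matrix(rnorm(300 * 50, 0, 0.01), 300, 50)
  sig[sig < 0] <- 0; sig[sig > 1] <- 1
  dimnames(sig) <- list(paste0("a", 1:300), sheet$sample_id)
  ewa <- fit_linear_ewas(sig, sheet, covariates = "age")
  a <- ewa[ewa$term == "age", ]
  expect_gte(mean(abs(a$estimate - slope) <= 3 * a$se), 0.97)
})

test_that("LOOCV clock recovers strong age signal without leakage and deterministically", {
  cfg <- sim_config(n_probes = 400, n_samples = 30, frac_age_cpgs = 0.25,
                    noise_sd = 0.3, age_slope_range = c(0.003, 0.005),
                    replicate_frac = 0, na_rate = 0, seed = 41)
  sim <- simulate_cohort(cfg)
  cl <- loocv_clock(sim$modc, sim$sheet, seed = 8)
  expect_gte(cl$pearson_r, 0.9)
  expect_lte(cl$mae, 4)
  cl2 <- loocv_clock(sim$modc, sim$sheet, seed = 8)
  expect_identical(cl$model$weights, cl2$model$weights)
  expect_identical(cl$predictions, cl2$predictions)
  # sample-order invariance: shuffled columns give the same predictions
  perm <- sample(ncol(sim$modc))
  cl3 <- loocv_clock(sim$modc[, perm], sim$sheet, seed = 8)
  expect_equal(cl3$predictions, cl$predictions, tolerance = 1e-9)
})

test_that("clock application honors missing-probe policies", {
  model <- list(weights = c(pA = 1), intercept = 0, features = "pA",
                training_means = c(pA = 0.3))
  bm <- toy_bm(c(0.42, 0.1), 1, 2, probes = "pA")
  expect_equal(unname(apply_clock(bm, model, "error")), c(0.42, 0.1))
  bm2 <- toy_bm(c(0.5, 0.5), 1, 2, probes = "other")
  expect_error(apply_clock(bm2, model, "error"), "absent")
  # all probes absent with mean imputation: forced constant prediction
  expect_equal(unname(apply_clock(bm2, model, "mean_impute")), c(0.3, 0.3))
  # neighbor-map policy routes through substitution
  map <- data.frame(query_id = "pA", neighbor_id = "other", distance = 0.1,
                    r = 0.95, retained = TRUE)
  expect_equal(unname(apply_clock(bm2, model, "neighbor_map", map = map)),
               c(0.5, 0.5))
  # response transform is inverted on the way out
  model_t <- c(model, list(inverse_transform = exp))
  expect_equal(unname(apply_clock(bm, model_t, "error")), exp(c(0.42, 0.1)))
})

test_that("sex scores separate planted effects and break ties toward female", {
  bm <- rbind(h1 = c(0.8, 0.5), h2 = c(0.8, 0.5),
              l1 = c(0.2, 0.5), l2 = c(0.2, 0.5))
  colnames(bm) <- c("male", "tie")
  sx <- sex_score(bm, c("h1", "h2"), c("l1", "l2"))
  expect_equal(sx$score, c(0.6, 0))
  expect_identical(sx$predicted_sex, c("M", "F"))
  expect_error(sex_score(bm, "zz", "yy"), "no sex-associated probes")
})
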