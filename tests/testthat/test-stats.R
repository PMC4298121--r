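test_that("pearson and spearman match the library oracle on 100 random tables", {
  set.seed(101)
  for (k in 1:100) {
    n <- sample(5:15, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    if (k %% 2 == 0) { # force ties for the midrank path
      x <- round(x); y <- round(y, 1)
      if (var(x) == 0 || var(y) == 0) next
    }
    mp <- pearson(x, y)
    op <- cor.test(x, y)
    expect_equal(mp$estimate, unname(op$estimate), tolerance = 1e-9)
    expect_equal(mp$p_value, op$p.value, tolerance = 1e-9)
    ms <- spearman(x, y)
    os <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    expect_equal(ms$estimate, unname(os$estimate), tolerance = 1e-9)
    expect_equal(ms$p_value, os$p.value, tolerance = 1e-9)
  }
})

test_that("correlation edge cases are typed errors", {
  expect_error(pearson(1:2, 2:3), class = "vascmr_input_error")
  expect_error(pearson(rep(1, 10), rnorm(10)),
               class = "vascmr_degenerate_error")
  expect_equal(pearson(1:10, 1:10)$estimate, 1)
  expect_equal(spearman(1:10, 1:10)$estimate, 1)
  expect_equal(spearman(1:10, 10:1)$estimate, -1)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(13)
  for (k in 1:20) {
    x <- rnorm(15); y <- rnorm(15) + x
    base <- spearman(x, y)
    expect_equal(spearman(exp(x), y)$estimate, base$estimate,
                 tolerance = 1e-12)
    expect_equal(spearman(x, y^3)$estimate, base$estimate,
                 tolerance = 1e-12)
  }
})

test_that("OLS matches the normal-equations oracle on 100 random tables", {
  set.seed(202)
  for (k in 1:100) {
    n <- 10L
    dat <- data.frame(patient_id = as.character(1:n),
                      mean_sc = rnorm(n), age = rnorm(n),
                      gender = rbinom(n, 1, 0.5), pwv_distal = rnorm(n))
    if (var(dat$gender) == 0) next
    fit <- fit_linear_model(dat)
    X <- cbind(1, dat$age, dat$gender, dat$pwv_distal)
    orc <- oracle_ols(X, dat$mean_sc)
    expect_equal(fit$b, orc$b, tolerance = 1e-9)
    expect_equal(fit$se, orc$se, tolerance = 1e-9)
    expect_equal(fit$p, orc$p, tolerance = 1e-9)
    expect_equal(fit$beta[-1], orc$beta[-1], tolerance = 1e-9)
    # standardized-beta identity on every fit
    sds <- vapply(dat[c("age", "gender", "pwv_distal")], sd, numeric(1))
    expect_equal(fit$beta[-1], unname(fit$b[-1] * sds / sd(dat$mean_sc)),
                 tolerance = 1e-12)
  }
})

test_that("exact linear outcomes are recovered to machine precision", {
  set.seed(7)
  dat <- data.frame(patient_id = as.character(1:20), age = rnorm(20),
                    gender = rbinom(20, 1, .5), pwv_distal = rnorm(20))
  dat$mean_sc <- 2 + 0.5 * dat$pwv_distal
  fit <- fit_linear_model(dat)
  expect_equal(fit$b, c(2, 0, 0, 0.5), tolerance = 1e-9)
  expect_equal(attr(fit, "r_squared"), 1, tolerance = 1e-12)
  # collinearity is a typed error
  dat$age2 <- dat$age
  expect_error(fit_linear_model(dat, predictors = c("age", "age2")),
               class = "vascmr_degenerate_error")
})

test_that("cell-wise outlier removal yields the published pairwise-N pattern", {
  fx <- fixture_paper_cohort()
  flags <- data.frame(patient_id = c("P001", "P002"),
                      variable = c("mean_sc", "pwv_proximal"))
  rep <- association_matrix(remove_outlier_cells(fx, flags))
  rem <- rep[rep$dataset == "outliers_removed", ]
  getn <- function(m, v) rem$n_pairs[rem$marker == m & rem$variable == v]
  expect_identical(getn("pwv_proximal", "mean_sc"), 40L)
  expect_identical(getn("pwv_distal", "mean_sc"), 41L)
  expect_identical(getn("pwv_distal", "max_sc"), 42L)
  expect_identical(getn("pwv_proximal", "max_sc"), 41L)
  expect_identical(getn("pwv_proximal", "nwi"), 41L)
  expect_identical(getn("nwi", "max_sc"), 42L)
  # full-data variant is untouched
  expect_true(all(rep$n_pairs[rep$dataset == "full"] == 42L))
  # unknown cells are rejected
  expect_error(remove_outlier_cells(fx, data.frame(patient_id = "P999",
                                                   variable = "mean_sc")),
               class = "vascmr_input_error")
  expect_error(remove_outlier_cells(fx, data.frame(patient_id = "P001",
                                                   variable = "bogus")),
               class = "vascmr_input_error")
})

test_that("an invalid cell never changes a pair it does not touch", {
  fx <- fixture_paper_cohort()
  before <- association_matrix(fx)
  after <- association_matrix(
    remove_outlier_cells(fx, data.frame(patient_id = "P005",
                                        variable = "nwi")))
  rem_b <- before[before$dataset == "outliers_removed", ]
  rem_a <- after[after$dataset == "outliers_removed", ]
  untouched <- !(rem_a$marker == "nwi" | rem_a$variable == "nwi")
  expect_equal(rem_a$estimate[untouched], rem_b$estimate[untouched])
  expect_equal(rem_a$n_pairs[untouched], rem_b$n_pairs[untouched])
  expect_true(all(rem_a$n_pairs[!untouched] == 41L))
})

test_that("association report has the eight published pairs with correct methods", {
  rep <- association_matrix(fixture_paper_cohort())
  full <- rep[rep$dataset == "full", ]
  expect_identical(nrow(full), 8L)
  expect_true(all(full$method[full$variable == "max_sc"] == "spearman"))
  expect_true(all(full$method[full$variable != "max_sc"] == "pearson"))
  # constant mean_sc surfaces a per-pair degenerate note, others computed
  fx <- fixture_paper_cohort()
  fx$mean_sc <- 1
  rep2 <- association_matrix(fx)
  expect_true(all(is.na(rep2$estimate[rep2$variable == "mean_sc"])))
  expect_true(all(nzchar(rep2$note[rep2$variable == "mean_sc"])))
  expect_true(all(!is.na(rep2$estimate[rep2$variable != "mean_sc"])))
})

test_that("KS normality: null calibration, power, and typed errors", {
  set.seed(303)
  null_ps <- replicate(60, ks_normality(rnorm(300), n_sim = 200)$p_value)
  expect_gte(mean(null_ps > 0.05), 0.90)
  exp_ps <- replicate(20, ks_normality(rexp(1000), n_sim = 200)$p_value)
  expect_true(all(exp_ps < 0.05))
  expect_error(ks_normality(rep(1, 20)), class = "vascmr_degenerate_error")
  expect_error(ks_normality(rnorm(4)), class = "vascmr_input_error")
})

test_that("Gaussian cohort markers look normal to KS at n=42", {
  set.seed(404)
  cells <- unlist(lapply(1:8, function(s) {
    co <- generate_cohort(cohort_config(n_patients = 42, seed = s))$cohort
    vapply(list(co$age, co$nwi, co$pwv_distal, co$pwv_proximal),
           function(x) ks_normality(x, n_sim = 200)$p_value, numeric(1))
  }))
  expect_gte(mean(cells > 0.05), 0.80)   # nominal 0.95, correlated cells
})

test_that("interaction scan: combinatorics, null behavior, power", {
  set.seed(505)
  n <- 500
  dat <- data.frame(patient_id = as.character(1:n), age = rnorm(n),
                    gender = rbinom(n, 1, .5), pwv_distal = rnorm(n))
  dat$mean_sc <- 1.5 + 0.3 * dat$age + 0.2 * dat$pwv_distal + rnorm(n)
  sc <- interaction_scan(dat)
  expect_identical(nrow(sc), 3L)   # 3 predictors -> 3 product terms
  # null: over seeds, product-term p exceeds 0.05 about 95% of the time
  ps <- unlist(lapply(1:15, function(s) {
    set.seed(s)
    d <- data.frame(patient_id = as.character(1:200), age = rnorm(200),
                    gender = rbinom(200, 1, .5), pwv_distal = rnorm(200))
    d$mean_sc <- 1.5 + 0.3 * d$age + 0.2 * d$pwv_distal + rnorm(200)
    interaction_scan(d)$p_interaction
  }))
  expect_gte(mean(ps > 0.05), 0.85)
  # injected interaction is detected
  dat$mean_sc <- dat$mean_sc +
    0.8 * (dat$age - mean(dat$age)) * (dat$pwv_distal - mean(dat$pwv_distal))
  sc2 <- interaction_scan(dat)
  expect_lt(sc2$p_interaction[sc2$predictor_a == "age" &
                              sc2$predictor_b == "pwv_distal"], 1e-3)
})
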