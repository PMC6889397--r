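test_that("Kaplan-Meier estimate matches the product-limit hand cases", {
  km <- km_estimate(survival_data(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  km2 <- km_estimate(survival_data(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # no events: survival stays at 1
  km3 <- km_estimate(survival_data(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(km3$surv == 1))
  # without censoring, KM equals the empirical survival function
  set.seed(2)
  t <- rexp(50)
  km4 <- km_estimate(survival_data(t, rep(1, 50)))
  expect_equal(km4$surv, 1 - ecdf(t)(km4$time))
})

test_that("log-rank test matches the hand-computed O-E/V statistic", {
  # identical groups: statistic 0, p = 1
  sv <- survival_data(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0))
  lr <- logrank_test(sv, rep(c("a", "b"), each = 3))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  # group A events at 1, 2; group B at 3, 4; hand O-E and V:
  # t=1: E_A=1/2, V=(2*2*1*3)/(16*3); t=2: E_A=1/3, V=(1*2*1*2)/(9*2)
  # O_A - E_A = 2 - 5/6 = 7/6; V = 17/36; chisq = (7/6)^2 / (17/36) = 49/17
  sv2 <- survival_data(1:4, rep(1, 4))
  lr2 <- logrank_test(sv2, c("A", "A", "B", "B"))
  expect_equal(lr2$chisq, 49 / 17, tolerance = 1e-10)
  expect_equal(lr2$df, 1)
  # three groups: df = 2; label permutation invariance
  sv3 <- survival_data(1:6, rep(1, 6))
  g3 <- c(1, 2, 3, 1, 2, 3)
  expect_equal(logrank_test(sv3, g3)$df, 2)
  relab <- c(2, 3, 1)[g3]
  expect_equal(logrank_test(sv3, relab)$chisq, logrank_test(sv3, g3)$chisq)
  expect_error(logrank_test(sv2, rep("A", 4)), "two groups")
})

test_that("Firth-Cox agrees with the unpenalized oracle away from separation", {
  set.seed(42)
  n <- 1000
  x <- rbinom(n, 1, 0.5); z <- rnorm(n)
  t <- rexp(n, rate = exp(0.7 * x + 0.3 * z))
  cc <- rexp(n, rate = 0.5)
  sv <- survival_data(pmin(t, cc), as.integer(t <= cc))
  fit <- cox_firth_fit(cbind(x = x, z = z), sv)
  oracle <- survival::coxph(survival::Surv(sv$time, sv$event) ~ x + z,
                            ties = "breslow")
  expect_lt(max(abs(fit$beta - coef(oracle))), 0.1)
  expect_true(all(fit$ci_low < fit$hr & fit$hr < fit$ci_high))
  # the unpenalized part of our partial likelihood matches coxph exactly
  q <- mvkkm:::cox_breslow_quantities(cbind(x, z), sv$time, sv$event,
                                      coef(oracle), third = FALSE)
  expect_equal(q$loglik, oracle$loglik[2], tolerance = 1e-8)
})

test_that("Firth penalty yields a finite estimate under complete separation", {
  time <- c(1:10, 11:20)
  event <- c(rep(1, 10), rep(0, 10))
  arm <- c(rep(0, 10), rep(1, 10))
  sv <- survival_data(time, event)
  fit <- cox_firth_fit(cbind(arm = arm), sv)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta), 10)
  # grid-search maximizer of the penalized partial likelihood
  grid <- seq(-10, 10, by = 0.01)
  pl <- vapply(grid, function(b) cox_firth_loglik(cbind(arm = arm), sv, b),
               numeric(1))
  expect_lt(abs(fit$beta - grid[which.max(pl)]), 0.05)
  # the unpenalized oracle runs off to the boundary
  up <- suppressWarnings(survival::coxph(
    survival::Surv(time, event) ~ arm,
    control = survival::coxph.control(iter.max = 200)))
  expect_gt(abs(coef(up)), 20)
})

test_that("Firth-Cox rejects degenerate designs", {
  sv <- survival_data(1:6, rep(1, 6))
  expect_error(cox_firth_fit(cbind(const = rep(1, 6)), sv), "constant")
  expect_error(cox_firth_fit(cbind(x = rnorm(6)),
                             survival_data(1:6, rep(0, 6))), "no events")
})

test_that("BIC formula and its parameter-count behavior", {
  expect_equal(bic_of_fit(-100, 2, 100), 200 + 2 * log(100), tolerance = 1e-10)
  expect_equal(bic_of_fit(-50, 0, 10), 100)
  # a useless extra parameter at equal loglik costs exactly ln(n)
  expect_equal(bic_of_fit(-100, 3, 100) - bic_of_fit(-100, 2, 100), log(100))
})

test_that("AFT without censoring reduces to least squares in one iteration", {
  set.seed(3)
  X <- cbind(x = rnorm(40))
  lt <- 1 + 0.8 * X[, 1] + 0.3 * rnorm(40)
  sv <- survival_data(exp(lt), rep(1, 40))
  fit <- aft_fit_imputed(X, sv)
  ls <- lm(lt ~ X)
  expect_equal(unname(fit$intercept), unname(coef(ls)[1]), tolerance = 1e-10)
  expect_equal(unname(fit$coef), unname(coef(ls)[2]), tolerance = 1e-10)
  expect_equal(fit$iterations, 1)
})

test_that("truncated-normal imputation matches a quadrature oracle", {
  # E[Y | Y > c] for Y ~ N(mu, sigma^2) by numerical integration
  for (case in list(c(mu = 0, sigma = 1, cc = 0.5), c(0, 1, 2.5),
                    c(1.3, 0.7, 2), c(-1, 2, 3))) {
    mu <- case[1]; sigma <- case[2]; cc <- case[3]
    num <- integrate(function(y) y * dnorm(y, mu, sigma), cc, Inf,
                     rel.tol = 1e-10)$value
    den <- pnorm(cc, mu, sigma, lower.tail = FALSE)
    z <- (cc - mu) / sigma
    ours <- unname(mu + sigma * mvkkm:::truncnorm_mills(z))
    expect_equal(ours, unname(num / den), tolerance = 1e-6)
  }
})

test_that("imputed event times never fall below their censoring times", {
  set.seed(4)
  X <- cbind(x = rnorm(60))
  t <- exp(0.5 + X[, 1] + 0.4 * rnorm(60))
  cens <- runif(60) < 0.5
  obs <- ifelse(cens, t * runif(60, 0.3, 0.9), t)
  sv <- survival_data(obs, as.integer(!cens))
  fit <- aft_fit_imputed(X, sv)
  expect_true(all(fit$imputed_log_times[cens] >= log(obs[cens]) - 1e-10))
  expect_gt(fit$sigma, 0)
})

test_that("censoring-adjusted rmse follows its lower-bound contract", {
  sv <- survival_data(c(2, 5), c(1, 1))
  expect_equal(censored_rmse(c(2, 5), sv), 0)
  # censored with a prediction above the bound contributes nothing
  svc <- survival_data(c(2, 5), c(1, 0))
  expect_equal(censored_rmse(c(2, 10), svc), 0)
  # hand case on the log scale: event (T=e^2, pred=e^1), censored (c=e^1, pred=e^0)
  svh <- survival_data(c(exp(2), exp(1)), c(1, 0))
  expect_equal(censored_rmse(c(exp(1), exp(0)), svh), 1)
  expect_error(censored_rmse(c(-1, 1), sv), "nonpositive")
})

test_that("Harrell's c honors the toy conventions and the reversal identity", {
  sv <- survival_data(c(1, 2, 3), c(1, 1, 1))
  expect_equal(harrell_c(c(3, 2, 1), sv), 1)
  expect_equal(harrell_c(c(1, 2, 3), sv), 0)
  expect_equal(harrell_c(c(1, 1, 1), sv), 0.5)
  # c(risk) + c(-risk) = 1 without risk ties; cross-check against survival
  set.seed(5)
  t <- rexp(40); e <- rbinom(40, 1, 0.6); r <- rnorm(40)
  svr <- survival_data(t, e)
  expect_equal(harrell_c(r, svr) + harrell_c(-r, svr), 1)
  conc <- survival::concordance(survival::Surv(t, e) ~ r, reverse = TRUE)
  expect_equal(harrell_c(r, svr), unname(conc$concordance), tolerance = 1e-10)
})

test_that("cross-validated AFT evaluation is reproducible and event-stratified", {
  set.seed(6)
  n <- 80
  X <- cbind(x = rnorm(n))
  t <- exp(1 + X[, 1] + 0.5 * rnorm(n))
  cc <- rexp(n, 1 / exp(1.5))
  sv <- survival_data(pmin(t, cc), as.integer(t <= cc))
  r1 <- cv_evaluate(X, sv, folds = 5, repeats = 2, seed = 9)
  r2 <- cv_evaluate(X, sv, folds = 5, repeats = 2, seed = 9)
  expect_identical(r1, r2)
  expect_true(r1$c_index > 0 && r1$c_index < 1)
})

test_that("compare_stratifications reproduces the baseline for identical labels", {
  d <- small_cohort(n = 80, seed = 10)
  surv <- survival_data(d$clinical$os_time, d$clinical$os_event)
  ev <- compare_stratifications(
    list(copy_of_hr = d$clinical$high_risk, planted = d$truth$labels),
    d$clinical, surv, folds = 5, repeats = 2, seed = 1)
  base <- ev[ev$model == "High Risk / Low Risk", -1]
  copy <- ev[ev$model == "copy_of_hr", -1]
  expect_equal(copy, base, ignore_attr = TRUE)
  # a k = 3 candidate is coded with two indicators: m = 2 + age + stage = 4
  set.seed(1)
  ev3 <- compare_stratifications(
    list(k3 = sample(1:3, 80, replace = TRUE)),
    d$clinical, surv, folds = 5, repeats = 1, seed = 1)
  expect_equal(ev3$k[ev3$model == "k3"], 3)
  expect_warning(
    compare_stratifications(list(const = rep(1, 80)), d$clinical, surv,
                            folds = 5, repeats = 1, seed = 1),
    "constant")
})
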