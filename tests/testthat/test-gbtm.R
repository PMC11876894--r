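# Censored-normal GBTM: likelihood oracle checks, degenerate equivalences,
# EM behaviour, posterior assignment, prediction bands.

sim_doses_direct <- function(n, Tn, beta, pi, sigma, seed,
                             per_window_slopes = TRUE) {
  # draw transformed doses straight from the trajectory model (no claims
  # layer); beta rows are per-window-unit coefficients
  withr::with_seed(seed, {
    g <- sample.int(nrow(beta), n, replace = TRUE, prob = pi)
    w <- rep(0:(Tn - 1L), n)
    id <- rep(sprintf("S%05d", seq_len(n)), each = Tn)
    mu <- beta[g, 1][rep(seq_len(n), each = Tn)] +
      beta[g, 2][rep(seq_len(n), each = Tn)] * w
    z <- mu + stats::rnorm(n * Tn, 0, sigma)
    list(doses = data.frame(patient_id = id, window = w,
                            mme = expm1(pmax(z, 0)),
                            stringsAsFactors = FALSE),
         group = g)
  })
}

test_that("the patient log density matches its closed forms", {
  spec <- model_spec(1L, poly_order = 0L)
  # mu equal to the transformed values, sigma 1: each term is log phi(0)
  y <- rep(expm1(1.3), 5)
  ll <- patient_group_loglik(y, NULL, beta = 1.3, sigma = 1, spec = spec)
  expect_equal(ll, -5 * 0.5 * log(2 * pi))
  # one censored observation with mu at the bound: log Phi(0) = log(1/2)
  for (s in c(0.3, 1, 2))
    expect_equal(patient_group_loglik(0, NULL, beta = 0, sigma = s,
                                      spec = spec), log(0.5))
  expect_error(patient_group_loglik(y, NULL, beta = 1, sigma = 0,
                                    spec = spec), regexp = "sigma")
})

test_that("the patient log density matches a direct recomputation", {
  set.seed(55)
  spec <- model_spec(1L, poly_order = 2L)
  values <- round(stats::rexp(20, 1 / 8), 2)
  values[sample(20, 5)] <- 0
  beta <- c(1.5, 2, -1)
  sigma <- 0.7
  got <- patient_group_loglik(values, NULL, beta, sigma = sigma, spec = spec)
  # independent recomputation, term by term
  y <- log1p(values)
  t_sc <- (0:19) / 107
  mu <- beta[1] + beta[2] * t_sc + beta[3] * t_sc^2
  want <- 0
  for (k in 1:20) {
    want <- want + if (values[k] > 0)
      log(stats::dnorm(y[k], mu[k], sigma)) else
        log(stats::pnorm((0 - mu[k]) / sigma))
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("with covariates the group mean shifts by alpha x covariate", {
  spec <- model_spec(1L, poly_order = 0L)
  cv <- c(0, 1, 2)
  got <- patient_group_loglik(expm1(c(1, 1.5, 2)), cv, beta = 1, alpha = 0.5,
                              sigma = 1, spec = spec)
  expect_equal(got, 3 * (-0.5 * log(2 * pi)))   # mu = 1 + 0.5 cv matches y*
})

test_that("a K=1 uncensored identity fit equals pooled least squares", {
  set.seed(20)
  n <- 60; Tn <- 10
  id <- rep(sprintf("S%03d", 1:n), each = Tn)
  w <- rep(0:(Tn - 1), n)
  t_sc <- w / 107
  y <- 2 + 3 * t_sc + stats::rnorm(n * Tn, 0, 0.5)
  doses <- data.frame(patient_id = id, window = w, mme = y,
                      stringsAsFactors = FALSE)
  spec <- model_spec(1L, poly_order = 1L, transform = "identity",
                     censor_lower = -Inf)
  fit <- fit_gbtm(doses, NULL, spec, gbtm_control(n_starts = 1, seed = 1))
  ols <- stats::lm(y ~ t_sc)
  expect_equal(unname(fit$beta[1, ]), unname(stats::coef(ols)),
               tolerance = 1e-6)
  sig_ml <- sqrt(sum(stats::resid(ols)^2) / (n * Tn))
  expect_equal(fit$sigma, sig_ml, tolerance = 1e-6)
})

test_that("a K=1 censored fit agrees with survreg's left-censored gaussian", {
  skip_if_not_installed("survival")
  set.seed(30)
  n <- 80; Tn <- 8
  id <- rep(sprintf("S%03d", 1:n), each = Tn)
  w <- rep(0:(Tn - 1), n)
  z <- 0.6 + 1.2 * (w / 107) + stats::rnorm(n * Tn, 0, 0.8)
  doses <- data.frame(patient_id = id, window = w, mme = expm1(pmax(z, 0)),
                      stringsAsFactors = FALSE)
  fit <- fit_gbtm(doses, NULL, model_spec(1L, poly_order = 1L),
                  gbtm_control(n_starts = 1, seed = 1))
  y <- log1p(doses$mme)
  status <- as.integer(y > 0)          # 0 = left censored at 0
  sv <- survival::survreg(
    survival::Surv(y, status, type = "left") ~ I(w / 107),
    dist = "gaussian")
  expect_equal(unname(fit$beta[1, ]), unname(stats::coef(sv)),
               tolerance = 1e-4)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-4)
})

test_that("the mixture likelihood equals direct enumeration on tiny data", {
  spec <- model_spec(2L, poly_order = 1L)
  beta <- rbind(c(0.5, 1), c(2, -1))
  sigma <- 0.6; pw <- c(0.3, 0.7)
  doses <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 4),
    window = rep(0:3, 3),
    mme = c(0, 1.2, 3.5, 0, 8, 6.5, 7.2, 9.9, 2.2, 0, 0, 1.1),
    stringsAsFactors = FALSE)
  dat <- rxtraj:::prepare_gbtm_data(doses, NULL, spec)
  es <- rxtraj:::e_step(dat, list(beta = beta, alpha = c(0, 0),
                                  sigma = sigma, pi = pw),
                        spec$censor_lower)
  manual <- 0
  for (pid in c("A", "B", "C")) {
    v <- doses$mme[doses$patient_id == pid]
    lik <- sum(vapply(1:2, function(j)
      pw[j] * exp(patient_group_loglik(v, NULL, beta[j, ], sigma = sigma,
                                       spec = spec)), 0))
    manual <- manual + log(lik)
  }
  expect_equal(es$loglik, manual, tolerance = 1e-10)
  # label permutation leaves the likelihood unchanged
  es_perm <- rxtraj:::e_step(dat, list(beta = beta[2:1, ], alpha = c(0, 0),
                                       sigma = sigma, pi = pw[2:1]),
                             spec$censor_lower)
  expect_equal(es_perm$loglik, es$loglik, tolerance = 1e-12)
})

test_that("EM recovers a two-group truth and is monotone and stable", {
  beta <- rbind(c(1, 0.01), c(2.5, -0.01))
  out <- sim_doses_direct(500, 12, beta, c(0.6, 0.4), 0.3, seed = 42)
  fit <- fit_gbtm(out$doses, NULL, model_spec(2L, poly_order = 1L),
                  gbtm_control(n_starts = 3, seed = 1))
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # canonical order: ascending mean fitted dose
  expect_true(all(diff(fit$group_mean_dose) > 0))
  expect_lt(max(abs(fit$pi - c(0.6, 0.4))), 0.05)
  expect_lt(max(abs(fit$beta[, 1] - c(1, 2.5))), 0.1)
  # the per-window slope maps to slope x 107 on the scaled-time basis
  expect_lt(max(abs(fit$beta[, 2] - c(0.01, -0.01) * 107)), 0.35)

  # bias shrinks as n grows (intercept error at n=2000 within the n=500 band)
  out2 <- sim_doses_direct(2000, 12, beta, c(0.6, 0.4), 0.3, seed = 43)
  fit2 <- fit_gbtm(out2$doses, NULL, model_spec(2L, poly_order = 1L),
                   gbtm_control(n_starts = 3, seed = 1))
  expect_lt(max(abs(fit2$beta[, 1] - c(1, 2.5))), 0.05)
  expect_lt(max(abs(fit2$pi - c(0.6, 0.4))), 0.03)

  # restart stability: an independent seed lands on the same optimum
  fit_b <- fit_gbtm(out$doses, NULL, model_spec(2L, poly_order = 1L),
                    gbtm_control(n_starts = 3, seed = 99))
  expect_equal(fit_b$log_likelihood, fit$log_likelihood, tolerance = 1e-4)
})

test_that("posterior assignment is Bayes-consistent with ties to low index", {
  beta <- rbind(c(1, 0), c(3.5, 0))
  out <- sim_doses_direct(200, 10, beta, c(0.5, 0.5), 0.3, seed = 9)
  fit <- fit_gbtm(out$doses, NULL, model_spec(2L, poly_order = 1L),
                  gbtm_control(n_starts = 2, seed = 1))
  asg <- posterior_assign(fit, out$doses)
  expect_equal(rowSums(as.matrix(asg[, c("posterior_1", "posterior_2")])),
               rep(1, 200), tolerance = 1e-12)
  # 2.5-sigma-per-window separation over 10 windows: certain assignment
  expect_true(all(asg$max_posterior > 0.99))
  map <- match_groups(out$group, asg$modal_group, 2L)
  expect_equal(mean(map[asg$modal_group] == out$group), 1)

  # K = 1: posterior is identically 1
  fit1 <- fit_gbtm(out$doses, NULL, model_spec(1L, poly_order = 1L),
                   gbtm_control(n_starts = 1, seed = 1))
  asg1 <- posterior_assign(fit1, out$doses)
  expect_equal(asg1$posterior_1, rep(1, 200))
  expect_equal(unique(asg1$modal_group), 1L)

  # symmetric hand-built model, patient exactly between the groups
  hand <- structure(list(
    spec = model_spec(2L, poly_order = 0L, transform = "identity",
                      censor_lower = -Inf),
    beta = rbind(-1, 1), alpha = NULL, sigma = 1, pi = c(0.5, 0.5),
    converged = TRUE, max_window = 3L), class = "gbtm_fit")
  mid <- data.frame(patient_id = "M", window = 0:3, mme = rep(0, 4),
                    stringsAsFactors = FALSE)
  asg_m <- posterior_assign(hand, mid)
  expect_equal(asg_m$posterior_1, 0.5, tolerance = 1e-12)
  expect_equal(asg_m$modal_group, 1L)
})

test_that("BIC selection prefers the generating structure", {
  # flat single-group data: the penalty rejects a second group
  out <- sim_doses_direct(300, 8, rbind(c(1.5, 0)), 1, 0.3, seed = 77)
  sel <- select_model(out$doses, NULL, K_grid = 1:2, orders = 1L,
                      control = gbtm_control(n_starts = 2, seed = 1))
  expect_equal(attr(sel, "chosen")$n_groups, 1L)
  expect_true(all(sel$bic[sel$converged] >= attr(sel, "chosen")$bic))
  # a singleton grid is chosen trivially
  sel1 <- select_model(out$doses, NULL, K_grid = 1L, orders = 1L,
                       control = gbtm_control(n_starts = 1, seed = 1))
  expect_equal(attr(sel1, "chosen")$n_groups, 1L)
  expect_error(select_model(out$doses, NULL, K_grid = integer(0)),
               class = "rxtraj_config_error")
})

test_that("predicted trajectories are exact for flat groups and cover truth", {
  hand <- structure(list(
    spec = model_spec(1L, poly_order = 0L),
    beta = rbind(2), alpha = NULL, sigma = 0.5, pi = 1,
    converged = TRUE, max_window = 5L), class = "gbtm_fit")
  cv <- predicted_trajectory(hand, 1, level = 0)
  expect_equal(cv$mean, rep(expm1(2), 6))
  expect_equal(cv$lower, cv$mean)
  expect_equal(cv$upper, cv$mean)
  bad <- hand; bad$converged <- FALSE
  expect_error(predicted_trajectory(bad, 1, level = 0), regexp = "converge")

  # 99% delta-method band covers the true curve in >= 95% of cells
  beta <- rbind(c(1.2, 1.5))      # scaled-time units
  hits <- 0; cells <- 0
  for (rep in 1:50) {
    withr::with_seed(1000 + rep, {
      n <- 150; Tn <- 8
      id <- rep(sprintf("S%03d", 1:n), each = Tn)
      w <- rep(0:(Tn - 1), n)
      z <- beta[1] + beta[2] * (w / 107) + stats::rnorm(n * Tn, 0, 0.4)
      doses <- data.frame(patient_id = id, window = w,
                          mme = expm1(pmax(z, 0)), stringsAsFactors = FALSE)
    })
    fit <- fit_gbtm(doses, NULL, model_spec(1L, poly_order = 1L),
                    gbtm_control(n_starts = 1, seed = 1))
    V <- gbtm_vcov(fit, doses)
    cv <- predicted_trajectory(fit, 1, level = 0.99, vcov = V)
    truth <- expm1(beta[1] + beta[2] * (cv$window / 107))
    hits <- hits + sum(cv$lower <= truth & truth <= cv$upper)
    cells <- cells + nrow(cv)
  }
  expect_gte(hits / cells, 0.95)
})
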