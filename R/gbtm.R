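# Censored-normal group-based trajectory modeling (GBTM).
#
# Outcome family: the transformed dose y* = log(1 + MME) (or identity) is
# modelled, per latent group j, as y* ~ Normal(mu_jt, sigma) left-censored
# at `censor_lower` (zero-dose months sit at the censor bound and
# contribute tail mass Phi((c - mu)/sigma) instead of a density).  Group
# means are polynomials in scaled time, mu_jt = x_t' beta_j + alpha_j c_t,
# where c_t is an optional time-varying covariate (cumulative stimulant
# count).  Estimation is by EM: posteriors in the E-step, then per-group
# Newton updates of (beta_j, alpha_j) with step-halving, a shared-sigma
# line search, and closed-form mixture weights (an ECM scheme, so the
# observed-data log-likelihood is non-decreasing).

#' Specification of a trajectory model
#'
#' @param n_groups Number of latent groups K (>= 1).
#' @param poly_order Polynomial order of the time trend, shared across
#'   groups (0-3).
#' @param include_covariate Include a group-specific slope on the
#'   time-varying covariate.
#' @param transform Dose transform: `"log1p"` (default) or `"identity"`.
#' @param censor_lower Lower censoring bound on the transformed scale.
#'   Defaults to `transform(0) = 0`; use `-Inf` for an uncensored fit.
#' @param time_denominator Scaled time is `window / time_denominator`,
#'   mapping the 108-window horizon onto `[0, 1]` for conditioning.
#' @return A `model_spec` object.
#' @export
model_spec <- function(n_groups, poly_order = 2L, include_covariate = FALSE,
                       transform = c("log1p", "identity"),
                       censor_lower = NULL, time_denominator = 107) {
  transform <- match.arg(transform)
  n_groups <- check_count(n_groups, "n_groups", min = 1L)
  poly_order <- check_count(poly_order, "poly_order")
  if (poly_order > 3L) stop_config("poly_order", "must be <= 3")
  structure(list(n_groups = n_groups, poly_order = poly_order,
                 include_covariate = isTRUE(include_covariate),
                 transform = transform,
                 censor_lower = censor_lower %||% 0,
                 time_denominator = time_denominator),
            class = "model_spec")
}

#' EM fitting options
#'
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood improvement below which EM stops
#'   (the threshold is `tol * (1 + |logLik|)`).
#' @param n_starts Number of restarts (k-means++ initialisations).
#' @param seed RNG seed controlling initialisation; fits are deterministic
#'   given the seed.
#' @return A list of options.
#' @export
gbtm_control <- function(max_iter = 200L, tol = 1e-6, n_starts = 5L,
                         seed = 1L) {
  list(max_iter = as.integer(max_iter), tol = tol,
       n_starts = as.integer(n_starts), seed = as.integer(seed))
}

tf_fun <- function(spec) switch(spec$transform, log1p = log1p,
                                identity = identity)
itf_fun <- function(spec) switch(spec$transform, log1p = expm1,
                                 identity = identity)

# stack long-format doses (+ optional covariates) into observation vectors
prepare_gbtm_data <- function(doses, covariates, spec) {
  stopifnot(all(c("patient_id", "window", "mme") %in% names(doses)))
  o <- order(doses$patient_id, doses$window)
  doses <- doses[o, , drop = FALSE]
  ids <- unique(doses$patient_id)
  pid <- match(doses$patient_id, ids)
  y <- tf_fun(spec)(doses$mme)
  cl <- spec$censor_lower
  cens <- if (is.finite(cl)) y <= cl + 1e-12 else rep(FALSE, length(y))
  y[cens] <- cl
  t_sc <- doses$window / spec$time_denominator
  X <- stats::poly(t_sc, degree = max(spec$poly_order, 1L), raw = TRUE,
                   simple = TRUE)
  X <- cbind(1, X[, seq_len(spec$poly_order), drop = FALSE])
  colnames(X) <- paste0("t", 0:spec$poly_order)
  cov <- NULL
  if (spec$include_covariate) {
    if (is.null(covariates))
      stop("spec includes a covariate but none was supplied")
    key_d <- paste(doses$patient_id, doses$window, sep = "\r")
    key_c <- paste(covariates$patient_id, covariates$window, sep = "\r")
    hit <- match(key_d, key_c)
    if (anyNA(hit))
      stop("covariate series does not cover every dose window")
    cov <- as.numeric(covariates$cumulative[hit])
  }
  list(y = y, cens = cens, X = X, cov = cov, pid = pid, ids = ids,
       n = length(ids), n_obs = length(y), windows = doses$window,
       max_window = max(doses$window))
}

# per-observation censored-normal log density at mean mu
cn_obs_ll <- function(y, mu, sigma, cens, cl) {
  out <- numeric(length(y))
  if (any(!cens))
    out[!cens] <- stats::dnorm(y[!cens], mu[!cens], sigma, log = TRUE)
  if (any(cens))
    out[cens] <- stats::pnorm((cl - mu[cens]) / sigma, log.p = TRUE)
  out
}

# score pieces: u = d ll / d mu, h = -d2 ll / d mu2, dls = d ll / d log sigma
cn_obs_score <- function(y, mu, sigma, cens, cl) {
  n <- length(y)
  u <- numeric(n); h <- numeric(n); dls <- numeric(n)
  if (any(!cens)) {
    r <- (y[!cens] - mu[!cens]) / sigma
    u[!cens] <- r / sigma
    h[!cens] <- 1 / sigma^2
    dls[!cens] <- r^2 - 1
  }
  if (any(cens)) {
    z <- (cl - mu[cens]) / sigma
    lam <- inv_mills(z)
    u[cens] <- -lam / sigma
    h[cens] <- lam * (lam + z) / sigma^2
    dls[cens] <- -z * lam
  }
  list(u = u, h = h, dls = dls)
}

# weighted complete-data objective in log sigma with group means fixed:
# value, first and second derivative in one pass over the stacked groups
sigma_eval <- function(y, M, W, ls, cens, cl) {
  s <- exp(ls)
  q <- 0; g <- 0; h <- 0
  for (j in seq_len(ncol(M))) {
    w <- W[, j]
    if (any(!cens)) {
      r <- (y[!cens] - M[!cens, j]) / s
      wv <- w[!cens]
      q <- q + sum(wv * (-log(s) - 0.5 * log(2 * pi) - 0.5 * r^2))
      g <- g + sum(wv * (r^2 - 1))
      h <- h - 2 * sum(wv * r^2)
    }
    if (any(cens)) {
      z <- (cl - M[cens, j]) / s
      lam <- inv_mills(z)
      wv <- w[cens]
      q <- q + sum(wv * stats::pnorm(z, log.p = TRUE))
      g <- g - sum(wv * z * lam)
      h <- h + sum(wv * (z * lam - z^2 * lam * (z + lam)))
    }
  }
  list(q = q, g = g, h = h)
}

#' Log density of one patient's dose series under one group
#'
#' Censored-normal log-likelihood of a series: uncensored windows
#' contribute `log phi((y* - mu)/sigma) - log sigma`, censored (zero-dose)
#' windows contribute `log Phi((c - mu)/sigma)`, where
#' `mu_t = polynomial(scaled t) + alpha x covariate_t`.
#'
#' @param values Mean daily MME per window (original scale), windows
#'   0, 1, ....
#' @param covariate Optional covariate value per window.
#' @param beta Polynomial coefficients (intercept first) on the transformed
#'   scale.
#' @param alpha Covariate coefficient (ignored when `covariate` is NULL).
#' @param sigma Residual SD (> 0).
#' @param spec A [model_spec()] (its `n_groups` is irrelevant here).
#' @return The summed log density.
#' @export
patient_group_loglik <- function(values, covariate = NULL, beta, alpha = 0,
                                 sigma, spec = model_spec(1L)) {
  if (sigma <= 0) stop("sigma must be positive")
  y <- tf_fun(spec)(values)
  cl <- spec$censor_lower
  cens <- if (is.finite(cl)) y <= cl + 1e-12 else rep(FALSE, length(y))
  y[cens] <- cl
  t_sc <- (seq_along(values) - 1) / spec$time_denominator
  mu <- drop(outer(t_sc, 0:(length(beta) - 1), `^`) %*% beta)
  if (!is.null(covariate)) mu <- mu + alpha * covariate
  sum(cn_obs_ll(y, mu, sigma, cens, cl))
}

group_mu <- function(dat, beta_j, alpha_j) {
  mu <- drop(dat$X %*% beta_j)
  if (!is.null(dat$cov)) mu <- mu + alpha_j * dat$cov
  mu
}

e_step <- function(dat, par, cl) {
  K <- length(par$pi)
  llp <- matrix(0, dat$n, K)
  for (j in seq_len(K)) {
    mu <- group_mu(dat, par$beta[j, ], par$alpha[j])
    llp[, j] <- rowsum(cn_obs_ll(dat$y, mu, par$sigma, dat$cens, cl),
                       dat$pid, reorder = TRUE)
  }
  lp <- sweep(llp, 2L, log(par$pi), `+`)
  lse <- row_logsumexp(lp)
  list(loglik = sum(lse), w = exp(lp - lse), ll_pat = llp)
}

# Newton update with step halving of one group's (beta_j, alpha_j);
# iterates to convergence so a single-group model is exact ML
update_group_coef <- function(dat, theta, wv, sigma, cl, has_alpha,
                              n_newton = 6L) {
  Xa <- if (has_alpha) cbind(dat$X, cov = dat$cov) else dat$X
  qfun <- function(th) {
    mu <- drop(Xa %*% th)
    sum(wv * cn_obs_ll(dat$y, mu, sigma, dat$cens, cl))
  }
  q0 <- qfun(theta)
  for (it in seq_len(n_newton)) {
    mu <- drop(Xa %*% theta)
    sc <- cn_obs_score(dat$y, mu, sigma, dat$cens, cl)
    g <- crossprod(Xa, wv * sc$u)
    H <- crossprod(Xa * (wv * sc$h), Xa)
    diag(H) <- diag(H) + 1e-10
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    s <- 1
    repeat {
      q1 <- qfun(theta + s * drop(delta))
      if (is.finite(q1) && q1 >= q0) {
        theta <- theta + s * drop(delta); q0 <- q1; break
      }
      s <- s / 2
      if (s < 1e-6) break
    }
    if (s < 1e-6 || max(abs(s * delta)) < 1e-9) break
  }
  theta
}

m_step <- function(dat, par, w, cl) {
  K <- ncol(w)
  n_obs_w <- w[dat$pid, , drop = FALSE]
  has_alpha <- !is.null(dat$cov)
  p <- ncol(dat$X)
  for (j in seq_len(K)) {
    th <- c(par$beta[j, ], if (has_alpha) par$alpha[j])
    th <- update_group_coef(dat, th, n_obs_w[, j], par$sigma, cl, has_alpha)
    par$beta[j, ] <- th[seq_len(p)]
    if (has_alpha) par$alpha[j] <- th[p + 1L]
  }
  # shared sigma: safeguarded Newton on log sigma with group means fixed
  M <- vapply(seq_len(K), function(j) group_mu(dat, par$beta[j, ],
                                               par$alpha[j]),
              numeric(dat$n_obs))
  ls <- log(par$sigma)
  ev <- sigma_eval(dat$y, M, n_obs_w, ls, dat$cens, cl)
  for (it in 1:2) {
    if (abs(ev$g) < 1e-10) break
    step <- if (ev$h < -1e-10) -ev$g / ev$h else sign(ev$g) * 0.1
    step <- max(min(step, 0.5), -0.5)
    repeat {
      ev1 <- sigma_eval(dat$y, M, n_obs_w, ls + step, dat$cens, cl)
      if (is.finite(ev1$q) && ev1$q >= ev$q) {
        ls <- ls + step; ev <- ev1; break
      }
      step <- step / 2
      if (abs(step) < 1e-8) break
    }
    if (abs(step) < 1e-8) break
  }
  par$sigma <- exp(ls)
  par$pi <- colMeans(w)
  par
}

# weighted least-squares initial parameters from a hard assignment
init_params <- function(dat, w0, spec) {
  K <- ncol(w0)
  p <- ncol(dat$X)
  has_alpha <- !is.null(dat$cov)
  Xa <- if (has_alpha) cbind(dat$X, dat$cov) else dat$X
  beta <- matrix(0, K, p)
  alpha <- numeric(K)
  res2 <- 0
  for (j in seq_len(K)) {
    wv <- w0[dat$pid, j]
    XtW <- crossprod(Xa, wv * Xa)
    diag(XtW) <- diag(XtW) + 1e-8
    th <- drop(solve(XtW, crossprod(Xa, wv * dat$y)))
    beta[j, ] <- th[seq_len(p)]
    if (has_alpha) alpha[j] <- th[p + 1L]
    res2 <- res2 + sum(wv * (dat$y - drop(Xa %*% th))^2)
  }
  sigma <- max(sqrt(res2 / dat$n_obs), 0.05)
  list(beta = beta, alpha = alpha, sigma = sigma,
       pi = pmax(colMeans(w0), 1e-6) / sum(pmax(colMeans(w0), 1e-6)))
}

# k-means++ seeded hard assignment on per-patient (mean, slope) summaries
init_assignment <- function(dat, K) {
  n <- dat$n
  if (K == 1L) return(matrix(1, n, 1L))
  t_sc <- dat$windows / 107
  ybar <- rowsum(dat$y, dat$pid)[, 1L] / tabulate(dat$pid, n)
  tbar <- rowsum(t_sc, dat$pid)[, 1L] / tabulate(dat$pid, n)
  sxy <- rowsum(dat$y * t_sc, dat$pid)[, 1L] - tabulate(dat$pid, n) * ybar * tbar
  sxx <- rowsum(t_sc^2, dat$pid)[, 1L] - tabulate(dat$pid, n) * tbar^2
  slope <- ifelse(sxx > 1e-10, sxy / sxx, 0)
  S <- cbind(scale(ybar), ifelse(rep(stats::sd(slope) > 0, n),
                                 scale(slope), 0))
  S[!is.finite(S)] <- 0
  # k-means++ seeding
  centers <- matrix(0, K, ncol(S))
  centers[1L, ] <- S[sample.int(n, 1L), ]
  d2 <- rowSums((S - matrix(centers[1L, ], n, ncol(S), byrow = TRUE))^2)
  for (k in seq_len(K - 1L) + 1L) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k, ] <- S[sample.int(n, 1L, prob = pr), ]
    d2 <- pmin(d2, rowSums((S - matrix(centers[k, ], n, ncol(S),
                                       byrow = TRUE))^2))
  }
  cl <- tryCatch(stats::kmeans(S, centers = centers, iter.max = 10L)$cluster,
                 error = function(e) sample.int(K, n, replace = TRUE))
  if (length(unique(cl)) < K) cl <- sample.int(K, n, replace = TRUE)
  w0 <- matrix(0, n, K)
  w0[cbind(seq_len(n), cl)] <- 1
  w0
}

run_em <- function(dat, spec, control, w0) {
  cl <- spec$censor_lower
  par <- init_params(dat, w0, spec)
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(control$max_iter)) {
    es <- e_step(dat, par, cl)
    trace <- c(trace, es$loglik)
    n_iter <- iter
    if (iter > 1L &&
        abs(es$loglik - trace[iter - 1L]) <
          control$tol * (1 + abs(es$loglik))) {
      converged <- TRUE
      break
    }
    par <- m_step(dat, par, es$w, cl)
    if (any(par$pi < 1 / dat$n))
      return(list(status = "collapsed", par = par, loglik = es$loglik,
                  trace = trace, n_iter = n_iter, converged = FALSE))
  }
  list(status = "ok", par = par, loglik = trace[length(trace)],
       trace = trace, n_iter = n_iter, converged = converged)
}

count_params <- function(spec) {
  spec$n_groups * (spec$poly_order + 1L) +
    (if (spec$include_covariate) spec$n_groups else 0L) +
    1L + (spec$n_groups - 1L)
}

#' Fit a censored-normal group-based trajectory model
#'
#' Runs EM from `n_starts` k-means++ initialisations (on per-patient mean
#' and slope summaries of the transformed series) and keeps the restart
#' with the best log-likelihood.  Groups are reported in canonical order of
#' ascending mean fitted dose.  Restarts whose mixture collapses (any
#' group weight below 1/N) are discarded; if every restart collapses an
#' error of class `rxtraj_collapse_error` is signalled carrying the best
#' partial fit.
#'
#' @param doses Long dose table (`patient_id`, `window`, `mme`); patients
#'   may have different numbers of observed windows.
#' @param covariates Long covariate table (`patient_id`, `window`,
#'   `cumulative`); required when `spec$include_covariate`.
#' @param spec A [model_spec()].
#' @param control A [gbtm_control()].
#' @return A `gbtm_fit` object: `spec`, `beta` (K x (order+1)), `alpha`
#'   (K or NULL), `sigma`, `pi`, `theta` (mixture logits vs the last
#'   group), `log_likelihood`, `loglik_trace`, `n_params`, `bic`
#'   (`-2 logL + n_params log N`, N = patients), `converged`, `n_iter`,
#'   `n_patients`, `n_obs`, `group_mean_dose`.
#' @export
fit_gbtm <- function(doses, covariates = NULL, spec,
                     control = gbtm_control()) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- prepare_gbtm_data(doses, covariates, spec)
  if (dat$n < spec$n_groups)
    stop("need at least as many patients as groups")
  runs <- withr::with_seed(control$seed, {
    lapply(seq_len(control$n_starts), function(s) {
      w0 <- init_assignment(dat, spec$n_groups)
      run_em(dat, spec, control, w0)
    })
  })
  ok <- vapply(runs, function(r) r$status == "ok", TRUE)
  if (!any(ok)) {
    best <- runs[[which.max(vapply(runs, `[[`, 0, "loglik"))]]
    stop(structure(
      class = c("rxtraj_collapse_error", "error", "condition"),
      list(message = "all EM restarts collapsed to an empty group",
           call = sys.call(), best_partial = best)))
  }
  lls <- vapply(runs, function(r) if (r$status == "ok") r$loglik else -Inf, 0)
  best <- runs[[which.max(lls)]]
  par <- best$par
  K <- spec$n_groups

  # canonical order: ascending mean fitted dose (original scale)
  itf <- itf_fun(spec)
  gmean <- vapply(seq_len(K), function(j)
    mean(itf(group_mu(dat, par$beta[j, ], par$alpha[j]))), 0)
  o <- order(gmean)
  par$beta <- par$beta[o, , drop = FALSE]
  par$alpha <- par$alpha[o]
  par$pi <- par$pi[o]
  gmean <- gmean[o]

  np <- count_params(spec)
  structure(list(
    spec = spec,
    beta = par$beta,
    alpha = if (spec$include_covariate) par$alpha else NULL,
    sigma = par$sigma,
    pi = par$pi,
    theta = log(par$pi / par$pi[K]),
    log_likelihood = best$loglik,
    loglik_trace = best$trace,
    n_params = np,
    bic = -2 * best$loglik + np * log(dat$n),
    converged = best$converged,
    n_iter = best$n_iter,
    n_patients = dat$n,
    n_obs = dat$n_obs,
    max_window = dat$max_window,
    group_mean_dose = gmean,
    control = control
  ), class = "gbtm_fit")
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat(sprintf(
    "Censored-normal GBTM: K = %d, order %d%s, transform %s\n",
    x$spec$n_groups, x$spec$poly_order,
    if (x$spec$include_covariate) " + time-varying covariate" else "",
    x$spec$transform))
  cat(sprintf("  patients %d, logLik %.2f, BIC %.2f, %sconverged in %d iters\n",
              x$n_patients, x$log_likelihood, x$bic,
              if (x$converged) "" else "NOT ", x$n_iter))
  cat("  group proportions:",
      paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Fit candidate models and select the best by BIC
#'
#' @param doses,covariates As in [fit_gbtm()].
#' @param K_grid Candidate numbers of groups.
#' @param orders Candidate polynomial orders (crossed with `K_grid`).
#' @param include_covariate,transform,censor_lower Passed to
#'   [model_spec()].
#' @param control A [gbtm_control()].
#' @return A `gbtm_selection` object: a data frame of candidates
#'   (`n_groups`, `poly_order`, `log_likelihood`, `n_params`, `bic`,
#'   `converged`) sorted by BIC, with attributes `chosen` (the minimal-BIC
#'   converged spec) and `chosen_fit` (its `gbtm_fit`).
#' @export
select_model <- function(doses, covariates = NULL, K_grid, orders = 2L,
                         include_covariate = FALSE,
                         transform = "log1p", censor_lower = NULL,
                         control = gbtm_control()) {
  if (length(K_grid) < 1L) stop_config("K_grid", "must be nonempty")
  grid <- expand.grid(K = K_grid, order = orders)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sp <- model_spec(grid$K[g], grid$order[g], include_covariate,
                     transform, censor_lower)
    fit <- tryCatch(fit_gbtm(doses, covariates, sp, control),
                    rxtraj_collapse_error = function(e) NULL)
    fits[[g]] <- fit
    rows[[g]] <- data.frame(
      n_groups = grid$K[g], poly_order = grid$order[g],
      log_likelihood = if (is.null(fit)) NA_real_ else fit$log_likelihood,
      n_params = if (is.null(fit)) NA_integer_ else fit$n_params,
      bic = if (is.null(fit)) NA_real_ else fit$bic,
      converged = !is.null(fit) && fit$converged)
  }
  tab <- do.call(rbind, rows)
  conv <- which(tab$converged)
  if (length(conv) == 0L) stop("no candidate model converged")
  chosen <- conv[which.min(tab$bic[conv])]
  o <- order(tab$bic)
  out <- tab[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, chosen = tab[chosen, , drop = FALSE],
            chosen_fit = fits[[chosen]], class = c("gbtm_selection",
                                                   "data.frame"))
}

#' @export
print.gbtm_selection <- function(x, ...) {
  cat("GBTM model selection (sorted by BIC):\n")
  print.data.frame(x, row.names = FALSE)
  ch <- attr(x, "chosen")
  cat(sprintf("chosen: K = %d, order %d (BIC %.2f)\n",
              ch$n_groups, ch$poly_order, ch$bic))
  invisible(x)
}

#' Posterior trajectory-group assignment
#'
#' Bayes-rule posterior probabilities of group membership given a fitted
#' model; ties in the modal group break toward the lower group index.
#'
#' @param model A converged `gbtm_fit`.
#' @param doses,covariates Data in the layout used for fitting.
#' @return Data frame: `patient_id`, per-group `posterior_j` columns,
#'   `modal_group`, `max_posterior`.
#' @export
posterior_assign <- function(model, doses, covariates = NULL) {
  if (!model$converged) warning("model did not converge")
  dat <- prepare_gbtm_data(doses, covariates, model$spec)
  par <- list(beta = model$beta,
              alpha = model$alpha %||% numeric(model$spec$n_groups),
              sigma = model$sigma, pi = model$pi)
  es <- e_step(dat, par, model$spec$censor_lower)
  modal <- apply(es$w, 1L, which.max)
  out <- data.frame(patient_id = dat$ids, stringsAsFactors = FALSE)
  for (j in seq_len(model$spec$n_groups))
    out[[paste0("posterior_", j)]] <- es$w[, j]
  out$modal_group <- as.integer(modal)
  out$max_posterior <- es$w[cbind(seq_len(dat$n), modal)]
  out
}

param_layout <- function(model) {
  spec <- model$spec
  K <- spec$n_groups; p <- spec$poly_order + 1L
  nm <- character(0)
  if (K > 1L) nm <- paste0("theta_", seq_len(K - 1L))
  nm <- c(nm, as.vector(t(outer(seq_len(K), 0:(p - 1L),
                                function(j, d) sprintf("beta_%d_%d", j, d)))))
  if (spec$include_covariate) nm <- c(nm, paste0("alpha_", seq_len(K)))
  c(nm, "log_sigma")
}

pack_params <- function(model) {
  K <- model$spec$n_groups
  c(if (K > 1L) model$theta[seq_len(K - 1L)] - model$theta[K],
    as.vector(t(model$beta)),
    if (model$spec$include_covariate) model$alpha,
    log(model$sigma))
}

unpack_params <- function(pv, spec) {
  K <- spec$n_groups; p <- spec$poly_order + 1L
  pos <- 0L
  theta <- if (K > 1L) { v <- pv[seq_len(K - 1L)]; pos <- K - 1L; v } else
    numeric(0)
  beta <- matrix(pv[pos + seq_len(K * p)], K, p, byrow = TRUE)
  pos <- pos + K * p
  alpha <- if (spec$include_covariate) {
    v <- pv[pos + seq_len(K)]; pos <- pos + K; v
  } else numeric(K)
  sigma <- exp(pv[pos + 1L])
  et <- exp(c(theta, 0) - max(c(theta, 0)))
  list(beta = beta, alpha = alpha, sigma = sigma, pi = et / sum(et))
}

# analytic score of the observed-data log-likelihood (Fisher identity)
obs_score <- function(pv, dat, spec) {
  par <- unpack_params(pv, spec)
  cl <- spec$censor_lower
  K <- spec$n_groups
  es <- e_step(dat, par, cl)
  w <- es$w
  wobs <- w[dat$pid, , drop = FALSE]
  g_theta <- if (K > 1L) colSums(w)[seq_len(K - 1L)] -
    dat$n * par$pi[seq_len(K - 1L)] else numeric(0)
  g_beta <- numeric(0); g_alpha <- numeric(0); g_ls <- 0
  for (j in seq_len(K)) {
    mu <- group_mu(dat, par$beta[j, ], par$alpha[j])
    sc <- cn_obs_score(dat$y, mu, par$sigma, dat$cens, cl)
    g_beta <- c(g_beta, drop(crossprod(dat$X, wobs[, j] * sc$u)))
    if (spec$include_covariate)
      g_alpha <- c(g_alpha, sum(wobs[, j] * sc$u * dat$cov))
    g_ls <- g_ls + sum(wobs[, j] * sc$dls)
  }
  c(g_theta, g_beta, g_alpha, g_ls)
}

#' Parameter covariance of a fitted trajectory model
#'
#' Inverts the observed information, obtained by central-difference
#' differentiation of the analytic score (the Fisher-identity form of the
#' observed-data gradient).  Parameters are ordered as mixture logits
#' (vs the last group), per-group polynomial coefficients, per-group
#' covariate coefficients (if present), and `log(sigma)`.
#'
#' @param model A converged `gbtm_fit`.
#' @param doses,covariates The data the model was fitted to.
#' @return A named covariance matrix.
#' @export
gbtm_vcov <- function(model, doses, covariates = NULL) {
  if (!model$converged) stop("model did not converge")
  dat <- prepare_gbtm_data(doses, covariates, model$spec)
  pv <- pack_params(model)
  np <- length(pv)
  H <- matrix(0, np, np)
  for (k in seq_len(np)) {
    h <- 1e-5 * max(1, abs(pv[k]))
    e <- numeric(np); e[k] <- h
    H[, k] <- (obs_score(pv + e, dat, model$spec) -
                 obs_score(pv - e, dat, model$spec)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  V <- solve(-H)
  dimnames(V) <- list(param_layout(model), param_layout(model))
  V
}

#' Predicted group trajectory with a confidence band
#'
#' Evaluates the fitted group mean along a covariate path and
#' back-transforms to the original dose scale; the band comes from the
#' delta method on the fitted parameter covariance.
#'
#' @param model A converged `gbtm_fit`.
#' @param group Group index (canonical order, 1..K).
#' @param covariate_path Covariate value per window (recycled); ignored
#'   for models without a covariate.
#' @param level Confidence level in `[0, 1)`; `0` collapses the band onto
#'   the mean.
#' @param n_windows Number of windows to predict (default: the fitted
#'   horizon).
#' @param vcov Parameter covariance from [gbtm_vcov()]; required when
#'   `level > 0`.
#' @return Data frame: `window`, `mean`, `lower`, `upper` (mg/day MME).
#' @export
predicted_trajectory <- function(model, group, covariate_path = 0,
                                 level = 0.99, n_windows = NULL,
                                 vcov = NULL) {
  if (!model$converged) stop("model did not converge")
  spec <- model$spec
  if (group < 1L || group > spec$n_groups) stop("group out of range")
  Tn <- n_windows %||% (model$max_window + 1L)
  wins <- seq_len(Tn) - 1L
  cv <- rep_len(covariate_path, Tn)
  t_sc <- wins / spec$time_denominator
  Xp <- outer(t_sc, 0:spec$poly_order, `^`)
  mu <- drop(Xp %*% model$beta[group, ])
  if (spec$include_covariate) mu <- mu + model$alpha[group] * cv
  itf <- itf_fun(spec)
  if (level == 0) {
    se <- rep(0, Tn)
  } else {
    if (is.null(vcov))
      stop("supply vcov = gbtm_vcov(...) for a nonzero confidence level")
    nm <- param_layout(model)
    G <- matrix(0, Tn, length(nm), dimnames = list(NULL, nm))
    G[, sprintf("beta_%d_%d", group, 0:spec$poly_order)] <- Xp
    if (spec$include_covariate) G[, sprintf("alpha_%d", group)] <- cv
    se <- sqrt(pmax(rowSums((G %*% vcov[nm, nm]) * G), 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(window = wins,
             mean = itf(mu),
             lower = itf(mu - z * se),
             upper = itf(mu + z * se))
}
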