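#' Fit a Bayesian binomial mixing-proportion model
#'
#' Fits one of the model family M0-M4 for haul-level mixing proportions:
#' `East_ip ~ Binomial(N_ip, pi_ip)` with
#' `logit(pi_ip) = beta * covariates [+ Area] [+ Juvenile] [+ F(utmX)] + u_ip`,
#' where the environmental covariates (salinity, oxygen, temperature) are
#' standardized internally, `F(utmX)` is a second-order random-walk (RW2)
#' smoother over binned longitude knots (one smoother for M3, one per life
#' stage for M4, each sum-to-zero constrained with its linear component
#' estimated as a fixed effect), and `u_ip` is an exchangeable Gaussian random
#' intercept per haul - a documented simplification of a spatially correlated
#' random field.
#'
#' Models:
#' \describe{
#'   \item{M0}{covariates only (reference model)}
#'   \item{M1}{+ Area factor (west/east of the 13 degrees E split)}
#'   \item{M2}{+ Juvenile factor}
#'   \item{M3}{+ RW2 longitude smoother `F(utmX)`}
#'   \item{M4}{+ Juvenile factor and life-stage-specific smoothers}
#' }
#'
#' Inference is a deterministic Laplace scheme: for fixed variance
#' hyperparameters (RW2 scale `sigma_rw`, random-intercept scale `sigma_u`,
#' both with half-normal priors) the latent field posterior is log-concave and
#' its mode/curvature are found by Newton iteration; the hyperparameters get
#' a Laplace-approximated marginal posterior explored on a small grid around
#' its mode; posterior draws are Gaussian draws mixed over the grid. Fixed
#' effects have diffuse Normal(0, sd 10) priors. Draws are reproducible under
#' `config$seed`.
#'
#' @param data Haul observations as from [aggregate_hauls()]: columns
#'   `haul_id`, `period_id`, `utm_x`, `life_stage`, `east_count`, `n_fish`,
#'   `salinity`, `oxygen`, `temperature` (and optionally `area`).
#' @param model_id One of `"M0" ... "M4"`.
#' @param config List: `n_knots` (20), `n_draws` (1000), `seed` (1),
#'   `prior_beta_sd` (10), `prior_sigma_scale` (2), `area_split` (13),
#'   `strict` (`FALSE`: warn instead of error on non-convergence).
#' @return An object of class `mixing_fit`; see [compute_waic()],
#'   [predict_longitude_profile()], [pearson_residuals()]. Key elements:
#'   `beta` (posterior-mean fixed effects), `sigma_u`, `sigma_rw`, `waic`,
#'   `draws` (latent-field draws), `converged`.
#' @export
fit_mixing_model <- function(data, model_id = "M0", config = list()) {
  cfg <- utils::modifyList(list(n_knots = 20, n_draws = 2000, seed = 1,
                                prior_beta_sd = 10, prior_sigma_scale = 2,
                                area_split = 13, strict = FALSE), config)
  model_id <- match.arg(model_id, c("M0", "M1", "M2", "M3", "M4"))
  need <- c("haul_id", "utm_x", "life_stage", "east_count", "n_fish",
            "salinity", "oxygen", "temperature")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(data) < 2L) stop("need at least 2 haul observations")
  if (any(data$east_count < 0 | data$east_count > data$n_fish) ||
      any(data$n_fish < 1)) stop("invalid east_count / n_fish")
  if (!("area" %in% names(data))) {
    data$area <- ifelse(data$utm_x >= cfg$area_split, "east_of_13E",
                        "west_of_13E")
  }
  if (model_id == "M1" && length(unique(data$area)) < 2L) {
    stop("M1 needs both areas present")
  }
  if (model_id %in% c("M2", "M4") &&
      length(unique(data$life_stage)) < 2L) {
    stop(model_id, " needs both life stages present")
  }

  y <- data$east_count
  N <- data$n_fish
  n_obs <- length(y)

  std <- lapply(data[c("salinity", "oxygen", "temperature")], standardize)
  X <- cbind(intercept = 1,
             salinity = std$salinity$values,
             oxygen = std$oxygen$values,
             temperature = std$temperature$values)
  if (model_id == "M1") X <- cbind(X, area_east = as.numeric(data$area == "east_of_13E"))
  if (model_id %in% c("M2", "M4")) {
    X <- cbind(X, juvenile = as.numeric(data$life_stage == "juvenile"))
  }

  smoother <- model_id %in% c("M3", "M4")
  sm <- NULL
  Zg <- NULL
  lambda <- NULL
  if (smoother) {
    if (diff(range(data$utm_x)) <= 0) stop("utm_x has no spread; no smoother")
    sm <- rw2_basis(data$utm_x, cfg$n_knots)
    stages <- if (model_id == "M4") c("adult", "juvenile") else "all"
    blocks <- lapply(stages, function(st) {
      on <- if (st == "all") rep(1, n_obs) else
        as.numeric(data$life_stage == st)
      list(stage = st,
           lin = sm$lin[sm$index] * on,        # fixed-effect linear component
           Z = sm$U_pen[sm$index, , drop = FALSE] * on)
    })
    for (b in blocks) {
      X <- cbind(X, b$lin)
      colnames(X)[ncol(X)] <- paste0("utmx_lin_", b$stage)
    }
    Zg <- do.call(cbind, lapply(blocks, `[[`, "Z"))
    lambda <- rep(sm$lambda, length(blocks))
    sm$stages <- stages
  }

  haul <- factor(data$haul_id)
  U <- stats::model.matrix(~ haul - 1)
  n_haul <- nlevels(haul)

  A <- cbind(X, Zg, U)
  p_beta <- ncol(X)
  p_gamma <- if (is.null(Zg)) 0L else ncol(Zg)
  idx <- list(beta = seq_len(p_beta),
              gamma = if (p_gamma) p_beta + seq_len(p_gamma) else integer(0),
              u = p_beta + p_gamma + seq_len(n_haul))

  # prior precision diagonal as a function of theta = (log sigma_rw, log sigma_u)
  prior_prec <- function(theta) {
    q0 <- numeric(ncol(A))
    q0[idx$beta] <- 1 / cfg$prior_beta_sd^2
    if (smoother) {
      tau <- exp(-2 * theta[1])
      q0[idx$gamma] <- tau * lambda
      q0[idx$u] <- exp(-2 * theta[2])
    } else {
      q0[idx$u] <- exp(-2 * theta[1])
    }
    q0
  }
  log_prior_theta <- function(theta) {
    # half-normal on each sigma, plus the log-sigma Jacobian
    s <- cfg$prior_sigma_scale
    sum(-exp(2 * theta) / (2 * s^2) + theta)
  }

  inner <- laplace_inner_factory(A, y, N)
  obj <- function(theta) {
    fit <- inner(prior_prec(theta))
    fit$log_ml + log_prior_theta(theta)
  }

  n_theta <- if (smoother) 2L else 1L
  theta0 <- rep(log(0.5), n_theta)
  opt <- if (n_theta == 1L) {
    o <- stats::optimize(function(t) -obj(t), interval = c(-5, 3))
    list(par = o$minimum, convergence = 0L)
  } else {
    stats::optim(theta0, function(t) -obj(t), method = "Nelder-Mead",
                 control = list(reltol = 1e-6, maxit = 200))
  }
  theta_hat <- opt$par

  # small axis-aligned grid around the hyperparameter mode
  step <- 0.6
  offsets <- c(-1.2, -0.6, 0, 0.6, 1.2)
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(offsets * step), n_theta)))
  grid <- sweep(grid, 2, theta_hat, `+`)
  pts <- vector("list", nrow(grid))
  lp <- numeric(nrow(grid))
  conv <- TRUE
  for (g in seq_len(nrow(grid))) {
    f <- inner(prior_prec(grid[g, ]))
    conv <- conv && f$converged
    pts[[g]] <- f
    lp[g] <- f$log_ml + log_prior_theta(grid[g, ])
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  keep <- which(w > 1e-7)

  if (!conv || (n_theta == 2L && opt$convergence != 0L)) {
    msg <- "mixing-model fit did not fully converge"
    if (isTRUE(cfg$strict)) stop(msg) else warning(msg)
  }

  # antithetic Gaussian draws (z and -z in pairs): halves Monte-Carlo error
  # of symmetric functionals and makes the east/west label symmetry of the
  # fit exact (posterior means equal the conditional modes)
  n_pair <- ceiling(cfg$n_draws / 2)
  draws <- with_seed(substream_seed(cfg$seed, paste0("draws_", model_id)), {
    gi <- sample(keep, n_pair, replace = TRUE, prob = w[keep])
    out <- matrix(0, 2L * n_pair, ncol(A))
    for (g in unique(gi)) {
      rows <- which(gi == g)
      z <- matrix(stats::rnorm(length(rows) * ncol(A)), ncol(A))
      half <- t(backsolve(pts[[g]]$chol_H, z))
      out[rows, ] <- sweep(half, 2, pts[[g]]$mode, `+`)
      out[n_pair + rows, ] <- sweep(-half, 2, pts[[g]]$mode, `+`)
    }
    attr(out, "theta") <- grid[c(gi, gi), , drop = FALSE]
    out
  })
  colnames(draws) <- colnames(A)

  theta_draws <- attr(draws, "theta")
  sig <- exp(colMeans(theta_draws))
  fit <- structure(list(
    model_id = model_id, data = data, config = cfg,
    A = A, idx = idx, y = y, N = N,
    smoother = sm, standardizers = std,
    draws = draws,
    beta = colMeans(draws[, idx$beta, drop = FALSE]),
    sigma_rw = if (smoother) sig[1] else NA_real_,
    sigma_u = if (smoother) sig[2] else sig[1],
    theta_grid = grid, theta_weights = w, theta_hat = theta_hat,
    converged = conv
  ), class = "mixing_fit")
  fit$waic <- compute_waic(fit)
  fit$diagnostics <- list(pearson = pearson_residuals(fit))
  fit
}

# internal: RW2 smoother basis over binned knots.
# Returns knots (locations), index (obs -> knot), the penalised eigenbasis
# U_pen with eigenvalues lambda (null space of the second-difference penalty
# removed), and the normalised linear contrast `lin` spanning the penalty
# null space beyond the absorbed intercept.
rw2_basis <- function(utm_x, n_knots) {
  r <- range(utm_x)
  knots <- seq(r[1], r[2], length.out = n_knots)
  index <- pmin(pmax(round((utm_x - r[1]) / diff(r) * (n_knots - 1)) + 1, 1),
                n_knots)
  D2 <- diff(diag(n_knots), differences = 2)
  K <- crossprod(D2)
  eg <- eigen(K, symmetric = TRUE)
  pos <- eg$values > 1e-8
  lin <- seq_len(n_knots) - (n_knots + 1) / 2
  lin <- lin / sqrt(sum(lin^2))
  list(knots = knots, index = index,
       U_pen = eg$vectors[, pos, drop = FALSE],
       lambda = eg$values[pos], lin = lin)
}

# internal: factory returning a warm-started Newton solver for the latent
# field given a prior precision diagonal. Caches the last mode as the next
# start, which makes the hyperparameter grid cheap.
laplace_inner_factory <- function(A, y, N) {
  last_mode <- rep(0, ncol(A))
  At <- t(A)
  function(q0) {
    x <- last_mode
    logpost <- function(x, eta) {
      sum(stats::dbinom(y, N, stats::plogis(eta), log = TRUE)) -
        0.5 * sum(q0 * x^2)
    }
    eta <- drop(A %*% x)
    f <- logpost(x, eta)
    converged <- FALSE
    H <- NULL
    for (it in 1:60) {
      pi <- stats::plogis(eta)
      g <- drop(At %*% (y - N * pi)) - q0 * x
      W <- pmax(N * pi * (1 - pi), 1e-10)
      H <- crossprod(A * sqrt(W)) + diag(q0)
      R <- chol(H)
      step <- backsolve(R, forwardsolve(t(R), g))
      t_ls <- 1
      repeat {
        x_new <- x + t_ls * step
        eta_new <- drop(A %*% x_new)
        f_new <- logpost(x_new, eta_new)
        if (is.finite(f_new) && f_new >= f - 1e-12) break
        t_ls <- t_ls / 2
        if (t_ls < 1e-8) break
      }
      moved <- f_new - f
      x <- x_new; eta <- eta_new; f <- f_new
      if (sqrt(sum(g^2)) < 1e-6 || moved < 1e-10) { converged <- TRUE; break }
    }
    last_mode <<- x
    R <- chol(H)
    log_ml <- f + 0.5 * sum(log(q0)) - sum(log(diag(R)))
    list(mode = x, chol_H = R, log_ml = log_ml, converged = converged)
  }
}

#' Watanabe-Akaike information criterion of a mixing-model fit
#'
#' `WAIC = -2 * sum_ip [ log( mean_draws p(East_ip | draw) )
#'   - var_draws( log p(East_ip | draw) ) ]`,
#' where the per-observation likelihood is binomial with that draw's `pi_ip`
#' including the random intercept.
#'
#' @param fit A [fit_mixing_model()] result (>= 2 stored draws).
#' @param data Ignored (the fit stores its data); kept for call symmetry.
#' @return WAIC (scalar) with attributes `lppd` and `p_waic`.
#' @export
compute_waic <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "mixing_fit"))
  if (nrow(fit$draws) < 2L) stop("need at least 2 posterior draws")
  eta <- fit$draws %*% t(fit$A)                       # draws x obs
  ll <- matrix(stats::dbinom(rep(fit$y, each = nrow(eta)),
                             rep(fit$N, each = nrow(eta)),
                             stats::plogis(eta), log = TRUE),
               nrow = nrow(eta))
  m <- apply(ll, 2, max)
  lppd <- sum(m + log(colMeans(exp(sweep(ll, 2, m)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  structure(-2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Population-level Pearson residuals
#'
#' Residuals `(y - N pi) / sqrt(N pi (1 - pi))` with `pi` the posterior mean
#' of the population-level probability, i.e. excluding the haul random
#' intercept, used for model validation.
#'
#' @param fit A [fit_mixing_model()] result.
#' @return Numeric vector, one residual per haul observation.
#' @export
pearson_residuals <- function(fit) {
  stopifnot(inherits(fit, "mixing_fit"))
  cols <- c(fit$idx$beta, fit$idx$gamma)
  eta <- fit$draws[, cols, drop = FALSE] %*% t(fit$A[, cols, drop = FALSE])
  pi_hat <- colMeans(stats::plogis(eta))
  (fit$y - fit$N * pi_hat) / sqrt(fit$N * pi_hat * (1 - pi_hat))
}

#' Compare mixing models by WAIC
#'
#' Fits every requested model on the same data and tabulates WAIC and the
#' difference to the best (minimum-WAIC) model.
#'
#' @param data Haul observations.
#' @param model_ids Character vector among `M0..M4`.
#' @param config Passed to [fit_mixing_model()].
#' @return `data.frame` sorted by WAIC: `model_id`, `waic`, `p_waic`,
#'   `delta_waic`; attribute `fits` holds the fitted models when
#'   `config$keep_fits = TRUE`.
#' @export
compare_models <- function(data, model_ids = c("M0", "M1", "M2", "M3", "M4"),
                           config = list()) {
  fits <- lapply(model_ids, function(m) fit_mixing_model(data, m, config))
  names(fits) <- model_ids
  waic <- vapply(fits, function(f) as.numeric(f$waic), numeric(1))
  p_waic <- vapply(fits, function(f) attr(f$waic, "p_waic"), numeric(1))
  out <- data.frame(model_id = model_ids, waic = waic, p_waic = p_waic,
                    stringsAsFactors = FALSE)
  out <- out[order(out$waic), , drop = FALSE]
  out$delta_waic <- out$waic - out$waic[1]
  rownames(out) <- NULL
  if (isTRUE(config$keep_fits)) attr(out, "fits") <- fits
  out
}

#' Posterior longitude profile of the mixing proportion
#'
#' For a smoother model (M3/M4), the posterior median and equal-tailed 95%
#' band of the population-level eastern proportion (random intercept
#' excluded) along the longitude knots, with the continuous covariates fixed
#' at their means. Also reports the longitude at which the posterior median
#' crosses 0.5 (linear interpolation between knots; the first west-to-east
#' upward crossing, `NA` if the median never crosses).
#'
#' @param fit An M3 or M4 [fit_mixing_model()] result.
#' @param life_stage For M4, `"adult"` or `"juvenile"`; must be `NULL` for M3
#'   (M3 has no stage-specific smoother).
#' @return An object of class `longitude_profile`: list with `profile`
#'   (`data.frame`: `utm_x`, `median`, `lower`, `upper`) and `crossing`
#'   (longitude of the 0.5 crossing).
#' @export
predict_longitude_profile <- function(fit, life_stage = NULL) {
  stopifnot(inherits(fit, "mixing_fit"))
  if (is.null(fit$smoother)) stop(fit$model_id, " has no longitude smoother")
  if (fit$model_id == "M3" && !is.null(life_stage)) {
    stop("M3 has no life-stage-specific smoother; leave life_stage NULL")
  }
  stage <- if (fit$model_id == "M4") {
    match.arg(life_stage, c("adult", "juvenile"))
  } else "all"
  sm <- fit$smoother
  m <- length(sm$knots)
  d <- fit$draws
  Xn <- colnames(fit$A)
  eta <- matrix(d[, "intercept"], nrow(d), m)
  if (stage == "juvenile") eta <- eta + d[, "juvenile"]
  lin_col <- paste0("utmx_lin_", stage)
  eta <- eta + outer(d[, lin_col], sm$lin)
  block <- which(sm$stages == stage)
  ng <- length(sm$lambda)
  gcols <- fit$idx$gamma[(block - 1) * ng + seq_len(ng)]
  eta <- eta + d[, gcols, drop = FALSE] %*% t(sm$U_pen)
  p <- stats::plogis(eta)
  qs <- apply(p, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  med <- qs[2, ]
  crossing <- NA_real_
  s <- med - 0.5
  for (k in seq_len(m - 1)) {
    if (s[k] < 0 && s[k + 1] >= 0) {
      crossing <- sm$knots[k] + (0 - s[k]) / (s[k + 1] - s[k]) *
        diff(sm$knots[k:(k + 1)])
      break
    }
  }
  structure(list(profile = data.frame(utm_x = sm$knots, median = med,
                                      lower = qs[1, ], upper = qs[3, ]),
                 crossing = crossing, life_stage = stage,
                 model_id = fit$model_id),
            class = "longitude_profile")
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat("<mixing_fit> ", x$model_id, ": ", length(x$y), " haul observations, ",
      "WAIC = ", format(as.numeric(x$waic), digits = 6), "\n", sep = "")
  cat("fixed effects (posterior means):\n")
  print(round(x$beta, 3))
  invisible(x)
}

#' @export
print.longitude_profile <- function(x, ...) {
  cat("<longitude_profile> ", x$model_id,
      if (x$life_stage != "all") paste0(" (", x$life_stage, ")"),
      ": 0.5 crossing at ", format(x$crossing, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plot a longitude profile
#'
#' @param x A [predict_longitude_profile()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.longitude_profile <- function(x, ...) {
  pr <- x$profile
  graphics::plot(pr$utm_x, pr$median, type = "l", ylim = c(0, 1),
                 xlab = "longitude", ylab = "proportion eastern", ...)
  graphics::lines(pr$utm_x, pr$lower, lty = 2)
  graphics::lines(pr$utm_x, pr$upper, lty = 2)
  graphics::abline(h = 0.5, col = "grey50", lty = 3)
  if (is.finite(x$crossing)) graphics::abline(v = x$crossing, col = "red3")
  invisible(x)
}

#' Posterior summaries of fixed effects
#'
#' @param object A [fit_mixing_model()] result.
#' @param prob Credible level (default 0.95).
#' @param ... Unused.
#' @return `data.frame`: `term`, `mean`, `sd`, `lower`, `upper`.
#' @export
summary.mixing_fit <- function(object, prob = 0.95, ...) {
  b <- object$draws[, object$idx$beta, drop = FALSE]
  a <- (1 - prob) / 2
  data.frame(term = colnames(b), mean = colMeans(b),
             sd = apply(b, 2, stats::sd),
             lower = apply(b, 2, stats::quantile, probs = a),
             upper = apply(b, 2, stats::quantile, probs = 1 - a),
             row.names = NULL, stringsAsFactors = FALSE)
}
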