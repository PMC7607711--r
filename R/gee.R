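#' Fit a repeated-measures logistic model by generalized estimating equations
#'
#' Solves the GEE for a marginal binomial model with logit link under a
#' working within-subject correlation structure, and reports robust
#' (sandwich) standard errors. This is the estimator behind all the dementia
#' models in this package: each subject contributes one row per retained
#' wave, and the working correlation absorbs the within-subject dependence
#' while the mean model stays marginal.
#'
#' Estimation is Fisher scoring on the estimating equations
#' \eqn{\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0} with
#' \eqn{V_i = \phi A_i^{1/2} R(\alpha) A_i^{1/2}}; the moment estimates of
#' \eqn{\phi} and \eqn{\alpha} are refreshed between scoring steps. Waves are
#' indexed by their rank within subject, so unequal visit counts are handled
#' by aligning each subject's visits to the first, second, ... occasion. If
#' the unstructured fit fails to converge it is automatically refit with an
#' exchangeable structure and flagged in `structure_used`.
#'
#' Reported robust standard errors use the Mancl-DeRouen bias-corrected
#' sandwich by default: the plain sandwich is known to understate variability
#' when few clusters carry a term's information (here, the rare two-copy
#' carriers), which degrades confidence-interval coverage. The plain sandwich
#' and the model-based covariance remain available through [vcov.gee_fit()]
#' and `tidy(..., robust = FALSE)`.
#'
#' @param data panel tibble, one row per subject-wave.
#' @param formula model formula, e.g. `dementia ~ age + sex + score`.
#' @param id name of the subject identifier column.
#' @param wave name of the within-subject ordering column (e.g. wave year).
#' @param corstr working correlation: `"unstructured"`, `"exchangeable"` or
#'   `"independence"`.
#' @param maxit,tol scoring iteration cap and convergence tolerance on the
#'   largest coefficient update.
#' @return A `gee_fit` object; see [tidy.gee_fit()], [glance.gee_fit()],
#'   [or_table()].
#' @export
fit_gee <- function(data, formula, id = "individual_id", wave = "wave_year",
                    corstr = c("unstructured", "exchangeable", "independence"),
                    maxit = 50, tol = 1e-8) {
  corstr <- match.arg(corstr)
  vars <- all.vars(formula)
  miss <- setdiff(c(vars, id, wave), names(data))
  if (length(miss)) abort(paste0("fit_gee: columns not in data: ", toString(miss)))
  d <- as_tibble(data)[, unique(c(vars, id, wave))]
  d <- d[complete.cases(d), ]
  d <- d[order(d[[id]], d[[wave]]), ]
  if (dplyr::n_distinct(d[[id]]) < 2) abort("fit_gee: need at least 2 subjects")

  mf <- model.frame(formula, d)
  X <- model.matrix(formula, mf)
  y <- model.response(mf)
  if (!all(y %in% c(0, 1))) abort("fit_gee: outcome must be binary 0/1")
  cl <- match(d[[id]], unique(d[[id]]))
  rows <- split(seq_len(nrow(d)), cl)
  Tmax <- max(lengths(rows))
  n_par <- ncol(X)

  # independence start values (ordinary logistic fit)
  beta <- suppressWarnings(glm.fit(X, y, family = binomial())$coefficients)
  if (anyNA(beta)) abort("fit_gee: design matrix is rank deficient")

  fit_once <- function(structure) {
    b <- beta
    conv <- FALSE
    R <- diag(Tmax)
    for (it in seq_len(maxit)) {
      eta <- drop(X %*% b)
      mu <- plogis(eta)
      sa <- sqrt(mu * (1 - mu))
      if (any(sa < 1e-8))
        abort("fit_gee: fitted probabilities at 0 or 1; outcome may be separated")
      e <- (y - mu) / sa
      phi <- sum(e^2) / (length(y) - n_par)

      if (structure == "exchangeable") {
        num <- 0; den <- 0
        for (ix in rows) {
          ni <- length(ix)
          if (ni > 1) {
            se_ <- sum(e[ix])
            num <- num + (se_^2 - sum(e[ix]^2)) / 2
            den <- den + ni * (ni - 1) / 2
          }
        }
        alpha <- num / (phi * max(den - n_par, 1))
        alpha <- min(max(alpha, -1 / (Tmax - 1) + 1e-6), 0.99)
        R <- matrix(alpha, Tmax, Tmax); diag(R) <- 1
      } else if (structure == "unstructured") {
        S <- matrix(0, Tmax, Tmax); K <- matrix(0, Tmax, Tmax)
        for (ix in rows) {
          rk <- seq_along(ix)
          S[rk, rk] <- S[rk, rk] + tcrossprod(e[ix])
          K[rk, rk] <- K[rk, rk] + 1
        }
        R <- S / (phi * pmax(K - n_par, 1))
        diag(R) <- 1
        R[R > 0.99] <- 0.99; R[R < -0.99] <- -0.99
        ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < 1e-4) {  # ridge toward independence to keep R invertible
          lam <- 1e-4 - min(ev)
          R <- (R + lam * diag(Tmax)) / (1 + lam)
        }
      }

      # scoring step, caching R-submatrix inverses per occasion pattern
      inv_cache <- list()
      B <- matrix(0, n_par, n_par)
      u <- numeric(n_par)
      for (ix in rows) {
        rk <- seq_along(ix)
        key <- as.character(length(ix))
        Rinv <- inv_cache[[key]]
        if (is.null(Rinv)) {
          Rinv <- solve(R[rk, rk, drop = FALSE])
          inv_cache[[key]] <- Rinv
        }
        Ui <- X[ix, , drop = FALSE] * sa[ix]
        RU <- Rinv %*% Ui
        B <- B + crossprod(Ui, RU)
        u <- u + crossprod(RU, e[ix])
      }
      step <- tryCatch(solve(B, u), error = function(e)
        abort(paste0("fit_gee: singular estimating equations (", conditionMessage(e),
                     "); a covariate may be constant within the analytic sample ",
                     "or the outcome separated")))
      b <- b + step
      if (any(!is.finite(b)) || any(abs(b) > 30))
        abort("fit_gee: coefficients diverging; outcome may be separated")
      if (max(abs(step)) < tol) { conv <- TRUE; break }
    }

    # final pass at the converged estimate: plain sandwich and the
    # Mancl-DeRouen bias-corrected sandwich (residuals scaled by the inverse
    # cluster leverage), which restores CI coverage when few clusters carry
    # the information for a term (e.g. rare two-copy carriers)
    mu <- plogis(drop(X %*% b))
    sa <- sqrt(mu * (1 - mu))
    e <- (y - mu) / sa
    phi <- sum(e^2) / (length(y) - n_par)
    inv_cache <- list()
    B <- matrix(0, n_par, n_par)
    for (ix in rows) {
      rk <- seq_along(ix)
      key <- as.character(length(ix))
      Rinv <- inv_cache[[key]]
      if (is.null(Rinv)) {
        Rinv <- solve(R[rk, rk, drop = FALSE])
        inv_cache[[key]] <- Rinv
      }
      Ui <- X[ix, , drop = FALSE] * sa[ix]
      B <- B + crossprod(Ui, Rinv %*% Ui)
    }
    Binv <- solve(B)
    Mp <- matrix(0, n_par, n_par)
    Mmd <- matrix(0, n_par, n_par)
    for (ix in rows) {
      rk <- seq_along(ix)
      Rinv <- inv_cache[[as.character(length(ix))]]
      Ui <- X[ix, , drop = FALSE] * sa[ix]
      RU <- Rinv %*% Ui
      ui <- crossprod(RU, e[ix])
      Mp <- Mp + tcrossprod(ui)
      Gi <- Ui %*% (Binv %*% t(RU))
      adj <- solve(diag(length(ix)) - Gi, e[ix])
      uia <- crossprod(RU, adj)
      Mmd <- Mmd + tcrossprod(uia)
    }
    list(beta = b, vcov_robust = Binv %*% Mmd %*% Binv,
         vcov_robust_plain = Binv %*% Mp %*% Binv,
         vcov_model = phi * Binv, R = R, phi = phi, converged = conv,
         structure_used = structure)
  }

  res <- tryCatch(fit_once(corstr), error = function(e) e)
  if ((inherits(res, "error") || !res$converged) && corstr == "unstructured") {
    warn("fit_gee: unstructured fit did not converge; refit with exchangeable structure")
    res <- fit_once("exchangeable")
    res$structure_used <- "exchangeable (fallback)"
  }
  if (inherits(res, "error")) abort(conditionMessage(res))

  structure(list(
    coefficients = setNames(drop(res$beta), colnames(X)),
    vcov_robust = res$vcov_robust, vcov_robust_plain = res$vcov_robust_plain,
    vcov_model = res$vcov_model,
    working_correlation = res$R, phi = res$phi,
    converged = res$converged, structure_used = res$structure_used,
    n_individuals = length(rows), n_observations = nrow(d),
    formula = formula, corstr = corstr
  ), class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE (binomial, logit), working correlation:", x$structure_used, "\n")
  cat(sprintf("%d subjects, %d observations\n", x$n_individuals, x$n_observations))
  print(tidy(x, exponentiate = TRUE))
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, robust = TRUE, bias_correction = TRUE, ...) {
  if (!robust) return(object$vcov_model)
  if (bias_correction) object$vcov_robust else object$vcov_robust_plain
}

#' Tidy a GEE fit
#'
#' @param x a `gee_fit`.
#' @param exponentiate report odds ratios (and exponentiated CI bounds)
#'   instead of log-odds coefficients.
#' @param conf.level confidence level (normal quantile multiplier).
#' @param robust use sandwich standard errors (default) or model-based ones.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std.error` (always on the
#'   log-odds scale), `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.gee_fit <- function(x, exponentiate = FALSE, conf.level = 0.95,
                         robust = TRUE, ...) {
  est <- x$coefficients
  se <- sqrt(diag(if (robust) x$vcov_robust else x$vcov_model))
  z <- est / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  lo <- est - q * se; hi <- est + q * se
  if (exponentiate) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
  tibble(term = names(x$coefficients), estimate = unname(est),
         std.error = unname(se), statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))),
         conf.low = unname(lo), conf.high = unname(hi))
}

#' @rdname tidy.gee_fit
#' @export
glance.gee_fit <- function(x, ...) {
  tibble(n_individuals = x$n_individuals, n_observations = x$n_observations,
         converged = x$converged, structure_used = x$structure_used,
         dispersion = x$phi)
}

#' Odds-ratio table for a GEE fit
#'
#' One row per term with the odds ratio, robust SE on the log-odds scale, the
#' same SE as a multiplicative factor (`exp(se)`, the style some reports
#' print next to the OR), 95% CI and p-value.
#'
#' @param fit a `gee_fit`.
#' @return Tibble with `term`, `OR`, `robust_se`, `se_factor`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
or_table <- function(fit) {
  td <- tidy(fit)
  tibble(term = td$term, OR = exp(td$estimate), robust_se = td$std.error,
         se_factor = exp(td$std.error),
         ci_low = exp(td$conf.low), ci_high = exp(td$conf.high),
         p_value = td$p.value)
}
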