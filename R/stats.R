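#' Edit-distance memory score
#'
#' Serial-recall scoring: `1 - d / L`, where `d` is the Levenshtein distance
#' between target and response (substitution, insertion and deletion all
#' cost 1) and `L` the longer of the two lengths; clipped to [0, 1]. The
#' placeholder `"X"` (entered for forgotten letters) never matches a target
#' letter.
#'
#' @param target Target letter sequence (single string or character vector).
#' @param response Response sequence; may contain `"X"`.
#' @return Score in [0, 1].
#' @export
memory_score <- function(target, response) {
  collapse <- function(x) if (length(x) > 1) paste(x, collapse = "") else x
  target <- collapse(target); response <- collapse(response)
  if (is.na(target) || nchar(target) == 0) stop("empty target sequence")
  if (is.na(response)) response <- ""
  # the forgotten-letter placeholder may never match a target letter
  response <- gsub("X", "×", response, fixed = TRUE)
  d <- utils::adist(target, response)[1, 1]
  L <- max(nchar(target), nchar(response))
  min(1, max(0, 1 - d / L))
}

model_formula <- function(outcome, formula_id, random = TRUE) {
  rhs <- switch(as.character(formula_id),
                "1" = "condition",
                "2" = "condition + time",
                "3" = "condition * time",
                stop("formula id must be 1, 2 or 3"))
  if (random) rhs <- paste(rhs, "+ (1 | participant)")
  stats::as.formula(paste(outcome, "~", rhs))
}

prepare_table <- function(table) {
  df <- as.data.frame(table)
  if (!"time" %in% names(df)) df$time <- df$block
  df$participant <- factor(df$participant)
  df
}

new_model_fit <- function(type, formula_id, outcome, coefficients,
                          ranef_var, resid_var, loglik_ml, n_params, fit) {
  structure(list(type = type, formula_id = formula_id, outcome = outcome,
                 coefficients = coefficients, ranef_var = ranef_var,
                 resid_var = resid_var, loglik_ml = loglik_ml,
                 n_params = n_params, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s, model %d, outcome %s (logLik_ML %.2f)\n",
              x$type, x$formula_id, x$outcome, x$loglik_ml))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Random-intercept linear mixed model
#'
#' Fits `outcome ~ condition [+ time [+ condition:time]] + (1 | participant)`
#' by REML; fixed effects are tested with Satterthwaite-approximated degrees
#' of freedom. Condition is coded 0/1; `time` is the raw block number. A
#' maximum-likelihood refit supplies the log-likelihood used by
#' [lrt_select()].
#'
#' @param table A block table (data.frame with `participant`, `condition`,
#'   `block`, and the outcome).
#' @param outcome Outcome column name.
#' @param formula_id 1, 2 or 3 (nested model sequence).
#' @param REML Use REML for the reported fit (default TRUE); the
#'   log-likelihood for model selection always comes from an ML (re)fit.
#' @param df_method `"satterthwaite"` (default) for Satterthwaite
#'   fixed-effect tests, or `"none"` for plain Wald z tests (faster; used
#'   in large simulation studies).
#' @return A `model_fit`.
#' @export
fit_lmm <- function(table, outcome, formula_id = 1, REML = TRUE,
                    df_method = c("satterthwaite", "none")) {
  df_method <- match.arg(df_method)
  df <- prepare_table(table)
  if (nlevels(df$participant) < 2) stop("need at least 2 participants")
  fml <- model_formula(outcome, formula_id)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  if (df_method == "satterthwaite") {
    fit <- lmerTest::lmer(fml, data = df, REML = REML, control = ctrl)
    co <- as.data.frame(stats::coef(summary(fit)))
    colnames(co) <- c("estimate", "se", "df", "t", "p")
  } else {
    fit <- lme4::lmer(fml, data = df, REML = REML, control = ctrl)
    co <- as.data.frame(stats::coef(summary(fit)))
    colnames(co) <- c("estimate", "se", "t")
    co$df <- NA_real_
    co$p <- 2 * stats::pnorm(-abs(co$t))
    co <- co[, c("estimate", "se", "df", "t", "p")]
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  ml <- if (REML) lme4::refitML(fit) else fit
  new_model_fit("lmm", formula_id, outcome, co,
                ranef_var = vc$vcov[vc$grp == "participant"],
                resid_var = vc$vcov[vc$grp == "Residual"],
                loglik_ml = as.numeric(stats::logLik(ml)),
                n_params = length(lme4::fixef(fit)) + 2L, fit = fit)
}

#' Random-intercept Poisson regression for count outcomes
#'
#' Generalized linear mixed model with log link and participant random
#' intercept (Laplace approximation); `method = "glm"` drops the random
#' intercept (plain Poisson GLM). Warns when the Pearson overdispersion
#' ratio exceeds 3.
#'
#' @inheritParams fit_lmm
#' @param method `"glmm"` (default) or `"glm"`.
#' @return A `model_fit`.
#' @export
fit_glmm_poisson <- function(table, outcome, formula_id = 1,
                             method = c("glmm", "glm")) {
  method <- match.arg(method)
  df <- prepare_table(table)
  y <- df[[outcome]]
  if (any(y < 0) || any(y != round(y))) stop("outcome must be non-negative integers")
  if (all(y == 0)) stop("degenerate outcome: all counts are zero")
  if (method == "glmm") {
    fml <- model_formula(outcome, formula_id)
    fit <- lme4::glmer(fml, data = df, family = stats::poisson(),
                       control = lme4::glmerControl(calc.derivs = FALSE,
                                                    check.conv.singular = "ignore"))
    co <- as.data.frame(stats::coef(summary(fit)))
    colnames(co) <- c("estimate", "se", "z", "p")
    vc <- as.data.frame(lme4::VarCorr(fit))
    disp <- sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
    if (disp > 3) warning(sprintf("overdispersion ratio %.2f > 3", disp))
    new_model_fit("glmm_poisson", formula_id, outcome, co,
                  ranef_var = vc$vcov[vc$grp == "participant"],
                  resid_var = NA_real_,
                  loglik_ml = as.numeric(stats::logLik(fit)),
                  n_params = length(lme4::fixef(fit)) + 1L, fit = fit)
  } else {
    fml <- model_formula(outcome, formula_id, random = FALSE)
    fit <- stats::glm(fml, data = df, family = stats::poisson())
    co <- as.data.frame(stats::coef(summary(fit)))
    colnames(co) <- c("estimate", "se", "z", "p")
    new_model_fit("glm_poisson", formula_id, outcome, co,
                  ranef_var = NA_real_, resid_var = NA_real_,
                  loglik_ml = as.numeric(stats::logLik(fit)),
                  n_params = length(stats::coef(fit)), fit = fit)
  }
}

# Gauss-Hermite nodes/weights for weight exp(-x^2) (Golub-Welsch).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Adaptive Gauss-Hermite marginal log-likelihood of the cumulative-logit
# random-intercept model, vectorized across groups: the per-group posterior
# modes are found by a few Newton steps on the joint log-density (numeric
# derivatives, all groups simultaneously), then the integral is evaluated
# on mode-centered, curvature-scaled nodes.
clmm_negloglik <- function(par, y, X, gidx, ngrp, K, gh, cache = NULL) {
  # guard against line-search excursions: keep the surface finite and do not
  # let an extreme trial point poison the cached posterior modes
  if (any(!is.finite(par)) || max(abs(par)) > 30) return(1e10)
  K1 <- K - 1L
  theta <- if (K1 == 1L) par[1] else cumsum(c(par[1], exp(par[2:K1])))
  p <- ncol(X)
  beta <- if (p > 0) par[K1 + seq_len(p)] else numeric(0)
  sigma <- exp(par[K1 + p + 1L])
  eta <- if (p > 0) drop(X %*% beta) else numeric(length(y))
  up0 <- c(theta, Inf)[y] - eta
  lo0 <- c(-Inf, theta)[y] - eta
  # H(b) per group: conditional log-likelihood + random-intercept prior
  Hfun <- function(b) {
    bb <- b[gidx]
    ll <- log(pmax(stats::plogis(up0 - bb) - stats::plogis(lo0 - bb), 1e-300))
    drop(rowsum(ll, gidx, reorder = TRUE)) +
      stats::dnorm(b, 0, sigma, log = TRUE)
  }
  b <- numeric(ngrp)
  if (!is.null(cache) && !is.null(cache$b) && all(is.finite(cache$b)) &&
      max(abs(cache$b)) < 10 * (sigma + 0.5))
    b <- cache$b
  h <- 1e-3
  for (step in 1:8) {
    Hp <- Hfun(b + h); Hm <- Hfun(b - h); H0 <- Hfun(b)
    g1 <- (Hp - Hm) / (2 * h)
    g2 <- (Hp - 2 * H0 + Hm) / h^2
    g2 <- pmin(g2, -1e-8)
    db <- g1 / g2
    db <- pmin(pmax(db, -2 * sigma - 1), 2 * sigma + 1)  # damped
    b <- b - db
    if (max(abs(db)) < 1e-8) break
  }
  if (!is.null(cache) && all(is.finite(b))) cache$b <- b
  Hp <- Hfun(b + h); Hm <- Hfun(b - h); H0 <- Hfun(b)
  curv <- pmin((Hp - 2 * H0 + Hm) / h^2, -1e-8)
  s <- sqrt(-2 / curv)
  vals <- vapply(seq_along(gh$nodes), function(j)
    Hfun(b + s * gh$nodes[j]) + gh$nodes[j]^2, numeric(ngrp))
  m <- apply(vals, 1, max)
  lg <- log(s) + m + log(drop(exp(vals - m) %*% gh$weights))
  -sum(lg)
}

#' Cumulative-link (logit) mixed model for ordinal outcomes
#'
#' Proportional-odds model with a participant random intercept,
#' `logit P(y <= k) = theta_k - x'beta - b`, `b ~ N(0, sigma^2)`, estimated
#' by maximum likelihood with adaptive Gauss-Hermite quadrature (default 15
#' nodes; at least 9 recommended). The ordinal categories are the sorted
#' unique outcome values; thresholds are strictly increasing by
#' construction. Standard errors come from the numerically evaluated
#' Hessian.
#'
#' @inheritParams fit_lmm
#' @param nodes Number of quadrature nodes (default 11).
#' @return A `model_fit`; `fit` holds `theta`, `beta`, `sigma`, and the
#'   category levels.
#' @export
fit_clmm <- function(table, outcome, formula_id = 1, nodes = 11) {
  df <- prepare_table(table)
  yraw <- df[[outcome]]
  if (is.factor(yraw) && any(table(yraw) == 0)) {
    warning("empty ordinal categories dropped (merged with neighbors)")
    yraw <- droplevels(yraw)
  }
  lev <- if (is.factor(yraw)) levels(yraw) else sort(unique(yraw))
  y <- as.integer(factor(yraw, levels = lev))
  K <- length(lev)
  if (K < 2) stop("ordinal outcome needs at least 2 categories")
  rhs <- switch(as.character(formula_id), "1" = ~condition,
                "2" = ~condition + time, "3" = ~condition * time)
  X <- stats::model.matrix(rhs, df)[, -1, drop = FALSE]
  gh <- gauss_hermite(nodes)
  p <- ncol(X)
  gidx <- as.integer(df$participant)
  ngrp <- nlevels(df$participant)
  # start values: equidistant logit thresholds, zero effects
  cum <- cumsum(tabulate(y, K))[seq_len(K - 1)] / length(y)
  th0 <- stats::qlogis(pmin(0.99, pmax(0.01, cum)))
  par0 <- c(th0[1], if (K > 2) log(pmax(diff(th0), 0.05)), rep(0, p), log(0.5))
  cache <- new.env(parent = emptyenv())
  obj <- function(par) clmm_negloglik(par, y, X, gidx, ngrp, K, gh, cache)
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  opt$hessian <- stats::optimHess(opt$par, obj)
  par <- opt$par
  K1 <- K - 1L
  theta <- if (K1 == 1L) par[1] else cumsum(c(par[1], exp(par[2:K1])))
  beta <- if (p > 0) par[K1 + seq_len(p)] else numeric(0)
  sigma <- exp(par[K1 + p + 1L])
  # delta-method SEs for beta from the Hessian in the working parametrization
  se <- rep(NA_real_, length(par))
  ih <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (!is.null(ih)) se <- sqrt(pmax(0, diag(ih)))
  bi <- K1 + seq_len(p)
  co <- data.frame(estimate = beta, se = se[bi],
                   z = beta / se[bi],
                   p = 2 * stats::pnorm(-abs(beta / se[bi])))
  rownames(co) <- colnames(X)
  new_model_fit("clmm", formula_id, outcome, co,
                ranef_var = sigma^2, resid_var = NA_real_,
                loglik_ml = -opt$value, n_params = length(par),
                fit = list(theta = theta, beta = beta, sigma = sigma,
                           levels = lev, convergence = opt$convergence))
}

#' Stepwise likelihood-ratio model selection over the nested sequence
#'
#' Tests model 1 vs 2 at `alpha`; only if adding `time` improves the fit is
#' model 2 vs 3 tested. Maximum-likelihood log-likelihoods are compared
#' (chi-squared with df equal to the parameter-count difference). The
#' chosen fit is returned with the test table attached.
#'
#' @param fit1,fit2,fit3 `model_fit`s of the same outcome for formulas
#'   1, 2, 3.
#' @param alpha Selection level (default 0.05).
#' @return The chosen `model_fit`, with attribute `lrt` (data.frame).
#' @export
lrt_select <- function(fit1, fit2, fit3 = NULL, alpha = 0.05) {
  fits <- list(fit1, fit2, fit3)
  ids <- vapply(Filter(Negate(is.null), fits), `[[`, numeric(1), "formula_id")
  if (!identical(ids[1:2], c(1, 2)))
    stop("fits must be the nested formula sequence 1, 2[, 3]")
  lrt_row <- function(fa, fb) {
    df <- fb$n_params - fa$n_params
    if (df <= 0) stop("models are not nested")
    chisq <- 2 * (fb$loglik_ml - fa$loglik_ml)
    data.frame(comparison = sprintf("%d vs %d", fa$formula_id, fb$formula_id),
               chisq = chisq, df = df,
               p = stats::pchisq(max(0, chisq), df, lower.tail = FALSE))
  }
  tests <- lrt_row(fit1, fit2)
  chosen <- fit1
  if (tests$p[1] < alpha) {
    chosen <- fit2
    if (!is.null(fit3)) {
      tests <- rbind(tests, lrt_row(fit2, fit3))
      if (tests$p[2] < alpha) chosen <- fit3
    }
  }
  attr(chosen, "lrt") <- tests
  chosen
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon convention); `W` is the smaller of
#' the positive- and negative-rank sums. The two-sided p-value is exact (by
#' full enumeration of sign assignments) for n <= 12 and uses the normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List: `W`, `p`, `n` (non-zero pairs), `method`, `flagged`
#'   (TRUE when all differences are zero).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; test undefined")
    return(list(W = NA_real_, p = NA_real_, n = 0L, method = "undefined",
                flagged = TRUE))
  }
  r <- rank(abs(d))
  Vpos <- sum(r[d > 0])
  tot <- n * (n + 1) / 2
  W <- min(Vpos, tot - Vpos)
  if (n <= 12) {
    # exact null distribution of the positive-rank sum by enumeration
    sums <- vapply(0:(2^n - 1), function(mask) {
      sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    }, numeric(1))
    p <- mean(pmin(sums, tot - sums) <= W)
    method <- "exact"
  } else {
    mu <- tot / 2
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(Vpos - mu) - 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-z)
    method <- "normal-approximation"
  }
  list(W = W, p = min(1, p), n = n, method = method, flagged = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`, with a display value rounded to two significant digits the
#' way corrected thresholds are conventionally printed (0.05/3 displays as
#' 0.017, 0.05/6 as 0.0083).
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return The exact threshold, with attribute `display` (rounded).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1) {
  if (m < 1) stop("m must be at least 1")
  v <- alpha / m
  attr(v, "display") <- signif(v, 2)
  v
}

#' Fit and select the nested model sequence for one outcome
#'
#' Convenience wrapper replicating the reporting workflow: fit formulas
#' 1-3 with the family appropriate to the outcome, select by
#' likelihood-ratio testing, and return the chosen fit.
#'
#' @param table Block table.
#' @param outcome Outcome column.
#' @param family `"lmm"`, `"poisson"`, or `"clmm"`.
#' @return Chosen `model_fit` with attribute `lrt`.
#' @export
select_model <- function(table, outcome, family = c("lmm", "poisson", "clmm")) {
  family <- match.arg(family)
  fit <- switch(family,
                lmm = function(id) fit_lmm(table, outcome, id),
                poisson = function(id) fit_glmm_poisson(table, outcome, id),
                clmm = function(id) fit_clmm(table, outcome, id))
  lrt_select(fit(1), fit(2), fit(3))
}
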