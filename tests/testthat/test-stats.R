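test_that("memory scoring handles recall, blanks, and substitutions", {
  expect_equal(memory_score("BCDFHKLM", "BCDFHKLM"), 1)
  expect_equal(memory_score("BCDFHKLM", "XXXXXXXX"), 0)
  expect_equal(memory_score("BCDFHKLM", "BCDFHKLQ"), 0.875)
  expect_equal(memory_score("BC", "BC"), 1)
  expect_equal(memory_score("BC", ""), 0)
  expect_error(memory_score("", "BC"), "empty")
  # longer responses are penalized through the max-length normalization
  expect_equal(memory_score("BC", "BCDF"), 1 - 2 / 4)
})

test_that("memory scoring equals the dynamic-programming oracle", {
  set.seed(101)
  letters12 <- c("B", "C", "D", "F", "H", "K", "L", "M", "P", "Q", "S", "T")
  for (i in 1:1000) {
    L <- sample(c(2L, 8L), 1)
    target <- paste(sample(letters12, L, replace = TRUE), collapse = "")
    resp <- paste(sample(c(letters12, "X"), sample(0:9, 1), replace = TRUE),
                  collapse = "")
    want <- min(1, max(0, 1 - dp_levenshtein(target, resp) /
                            max(nchar(target), nchar(resp))))
    expect_equal(memory_score(target, resp), want)
  }
})

sim_lmm_table <- function(beta_cond = 3, beta_time = 0, sd_id = 1.5,
                          sd_res = 2, n_p = 22, n_b = 28, seed = 1) {
  set.seed(seed)
  id <- rep(seq_len(n_p), each = n_b)
  cond <- as.vector(replicate(n_p, sample(rep(0:1, n_b / 2))))
  blk <- rep(seq_len(n_b), n_p)
  y <- 10 + beta_cond * cond + beta_time * blk +
    rnorm(n_p, 0, sd_id)[id] + rnorm(n_p * n_b, 0, sd_res)
  data.frame(participant = id, condition = cond, block = blk, y = y)
}

test_that("the linear mixed model recovers planted fixed effects", {
  tab <- sim_lmm_table(beta_cond = 3.73, seed = 2)
  f <- fit_lmm(tab, "y", 1)
  est <- f$coefficients["condition", ]
  expect_equal(est$estimate, 3.73, tolerance = 0.2)
  expect_true(est$p < 0.001)
  expect_true(all(c("df", "t") %in% colnames(f$coefficients)))
  expect_gt(f$ranef_var, 0.5)                    # planted 1.5^2 intercept SD
  expect_error(fit_lmm(tab[tab$participant == 1, ], "y", 1), "2 participants")
})

test_that("zero random-intercept variance collapses to ordinary regression", {
  tab <- sim_lmm_table(sd_id = 0, n_p = 50, n_b = 200, seed = 3)
  f <- fit_lmm(tab, "y", 2)
  ols <- stats::lm(y ~ condition + block, tab)
  expect_equal(f$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-3)
  expect_lt(f$ranef_var, 1e-4)
})

test_that("the Poisson mixed model recovers a constant rate", {
  set.seed(4)
  tab <- data.frame(participant = rep(1:22, each = 28),
                    condition = rbinom(616, 1, 0.5),
                    block = rep(1:28, 22))
  tab$cnt <- rpois(616, 2)
  f <- fit_glmm_poisson(tab, "cnt", 1)
  expect_equal(f$coefficients$estimate[1], log(2), tolerance = 0.1)
  expect_error(fit_glmm_poisson(tab, "block", 1)$x, NA)  # integer outcome ok
  tab$zero <- 0L
  expect_error(fit_glmm_poisson(tab, "zero", 1), "degenerate")
  tab$neg <- -1L
  expect_error(fit_glmm_poisson(tab, "neg", 1), "non-negative")
  # plain-GLM fallback drops the random intercept
  g <- fit_glmm_poisson(tab, "cnt", 1, method = "glm")
  expect_true(is.na(g$ranef_var))
})

test_that("the cumulative-link mixed model matches a logistic mixed model
           with two categories", {
  set.seed(5)
  n_p <- 20
  id <- factor(rep(1:n_p, each = 20))
  b <- rnorm(n_p, 0, 1)[as.integer(id)]
  x <- rbinom(400, 1, 0.5)
  y <- rbinom(400, 1, plogis(-0.3 + 0.8 * x + b))
  tab <- data.frame(participant = id, condition = x, block = 1,
                    score = factor(y, ordered = TRUE))
  cm <- fit_clmm(tab, "score", 1, nodes = 15)
  gm <- lme4::glmer(y ~ x + (1 | id), family = stats::binomial(), nAGQ = 15,
                    data = data.frame(y = y, x = x, id = id))
  expect_equal(cm$coefficients$estimate, unname(lme4::fixef(gm))[2],
               tolerance = 1e-3)
  expect_equal(sqrt(cm$ranef_var), sqrt(unname(unlist(lme4::VarCorr(gm)))),
               tolerance = 1e-3)
  expect_equal(cm$loglik_ml, as.numeric(stats::logLik(gm)), tolerance = 1e-4)
})

test_that("cumulative-link thresholds are ordered and effects signed right", {
  set.seed(6)
  n_p <- 22; n_b <- 28
  id <- rep(1:n_p, each = n_b)
  cond <- as.vector(replicate(n_p, sample(rep(0:1, n_b / 2))))
  lat <- 0.8 * cond + rnorm(n_p, 0, 0.8)[id] + rlogis(n_p * n_b)
  y <- cut(lat, c(-Inf, -1, 0, 1, 2, Inf), labels = FALSE)
  tab <- data.frame(participant = id, condition = cond,
                    block = rep(1:n_b, n_p),
                    score = factor(y, ordered = TRUE))
  f <- fit_clmm(tab, "score", 1)
  expect_true(all(diff(f$fit$theta) > 0))
  expect_gt(f$coefficients$estimate, 0)
  expect_lt(f$coefficients$p, 0.01)
})

test_that("likelihood-ratio selection is stepwise over the nested sequence", {
  tab <- sim_lmm_table(beta_cond = 2, beta_time = 0.3, seed = 7)
  f1 <- fit_lmm(tab, "y", 1); f2 <- fit_lmm(tab, "y", 2); f3 <- fit_lmm(tab, "y", 3)
  sel <- lrt_select(f1, f2, f3)
  expect_gte(sel$formula_id, 2)                  # strong planted time effect
  lrt <- attr(sel, "lrt")
  expect_equal(lrt$df[1], 1)                     # one parameter added
  # without a time effect, model 1 is typically kept
  tab0 <- sim_lmm_table(beta_cond = 2, beta_time = 0, seed = 8)
  sel0 <- lrt_select(fit_lmm(tab0, "y", 1), fit_lmm(tab0, "y", 2),
                     fit_lmm(tab0, "y", 3))
  expect_equal(sel0$formula_id, 1)
  expect_error(lrt_select(f2, f1), "sequence")
})

test_that("signed-rank statistics match convention and enumeration", {
  # all-positive differences, n = 6: W = 0, exact p = 2/64
  w <- wilcoxon_signed_rank(2:7, 1:6)
  expect_equal(w$W, 0)
  expect_equal(w$p, 0.03125)
  expect_equal(w$method, "exact")
  # symmetry: swapping the samples leaves W unchanged (min-sum convention)
  set.seed(9)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$W, wilcoxon_signed_rank(y, x)$W)
  # degenerate: identical samples
  expect_warning(wd <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_true(wd$flagged)
  # exact p equals the independent enumeration oracle for n <= 8
  for (n in 5:8) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 2)
      d <- d[d != 0]
      if (length(d) < 2) next
      mine <- wilcoxon_signed_rank(d, numeric(length(d)))
      expect_equal(mine$p, enum_signed_rank(d))
    }
  }
  # and matches R's exact test for untied data
  set.seed(10)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("large-sample signed-rank p uses the normal approximation", {
  set.seed(11)
  x <- rnorm(30); y <- rnorm(30)
  mine <- wilcoxon_signed_rank(x, y)
  expect_equal(mine$method, "normal-approximation")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("Bonferroni thresholds display as conventionally printed", {
  expect_equal(as.numeric(bonferroni_alpha(0.05, 1)), 0.05)
  expect_equal(attr(bonferroni_alpha(0.05, 3), "display"), 0.017)
  expect_equal(attr(bonferroni_alpha(0.05, 6), "display"), 0.0083)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 3)), 0.05 / 3)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("select_model picks family-appropriate fits", {
  tab <- sim_lmm_table(beta_cond = 3, seed = 12)
  sel <- select_model(tab, "y", "lmm")
  expect_s3_class(sel, "model_fit")
  expect_equal(sel$type, "lmm")
  expect_false(is.null(attr(sel, "lrt")))
})
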