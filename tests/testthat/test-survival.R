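test_that("Kaplan-Meier product-limit: hand examples", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))  # S(0) = 1 implicit
  expect_equal(km$n_risk, c(3, 2, 1))

  all_cens <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))

  no_cens <- km_estimate(1:5, rep(1, 5))
  expect_equal(no_cens$surv, (4:0) / 5)  # empirical survivor fraction

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank test matches the term-by-term hypergeometric oracle", {
  times <- c(2, 4, 4, 6, 8, 9, 11, 13)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(c("a", "b"), 4)
  lr <- logrank_test(times, events, group)
  expect_equal(lr$chisq, oracle_logrank(times, events, group),
               tolerance = 1e-9)
  expect_equal(lr$p, pchisq(lr$chisq, 1, lower.tail = FALSE))
  # symmetric under label swap
  lr2 <- logrank_test(times, events, ifelse(group == "a", "b", "a"))
  expect_equal(lr2$chisq, lr$chisq, tolerance = 1e-12)
  # identical groups -> statistic 0
  t2 <- rep(c(1, 2, 3, 4), 2); e2 <- rep(c(1, 1, 0, 1), 2)
  lr3 <- logrank_test(t2, e2, rep(c("a", "b"), each = 4))
  expect_equal(lr3$chisq, 0, tolerance = 1e-12)
  expect_equal(lr3$p, 1)
  expect_error(logrank_test(t2, e2, rep("a", 8)), "2 groups")
})

test_that("Cox fit maximizes the Efron partial likelihood (grid oracle, ties)", {
  times <- c(3, 3, 5, 7, 9, 11)   # tie at t = 3
  events <- c(1, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- coxph_fit(data.frame(x = x), times, events)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, oracle_efron_loglik, 0, times = times, events = events,
               x = x)
  expect_equal(unname(fit$beta), grid[which.max(ll)], tolerance = 2e-4)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
  expect_equal(unname(fit$hr), exp(unname(fit$beta)))
  expect_true(fit$ci_lower <= fit$hr && fit$hr <= fit$ci_upper)

  # identical time/event patterns in both groups -> beta ~ 0
  t2 <- rep(c(1, 2, 3, 4, 5), 2)
  e2 <- rep(c(1, 1, 0, 1, 1), 2)
  x2 <- rep(c(0, 1), each = 5)
  fit2 <- coxph_fit(data.frame(x = x2), t2, e2)
  expect_lt(abs(fit2$beta), 1e-6)
  expect_equal(unname(fit2$hr), 1, tolerance = 1e-5)

  # duplicating every record leaves the estimate essentially unchanged
  # (exactly invariant under Breslow; Efron's within-tie averaging makes it
  # approximate, so a small relative tolerance is the correct expectation)
  set.seed(49)
  nn <- 100
  xx <- rbinom(nn, 1, 0.5)
  ttn <- rexp(nn, 0.02 * exp(0.5 * xx))
  een <- rbinom(nn, 1, 0.8)
  fit_a <- coxph_fit(data.frame(x = xx), ttn, een)
  fit_dup <- coxph_fit(data.frame(x = rep(xx, 2)), rep(ttn, 2), rep(een, 2))
  expect_equal(unname(fit_dup$beta), unname(fit_a$beta), tolerance = 0.02)

  expect_error(coxph_fit(data.frame(x = rep(1, 6)), times, events),
               "constant")
  # perfect separation (monotone likelihood) is detected
  expect_error(
    coxph_fit(data.frame(x = c(1, 1, 1, 0, 0, 0)),
              c(1, 2, 3, 10, 11, 12), rep(1, 6)),
    "diverged|converge")
})

test_that("PH assumption check: one p per covariate, flags time-varying effects", {
  set.seed(40)
  n <- 300
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.01 * exp(0.5 * x1))
  fit <- coxph_fit(data.frame(x1 = x1, x2 = x2), t_ev, rep(1, n))
  p <- ph_assumption_test(fit)
  expect_equal(names(p), c("x1", "x2"))
  expect_true(all(p >= 0 & p <= 1))

  # strong sign-switching effect violates proportionality
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(n)
    u <- runif(n)
    # hazard flips sign at t0: simulate via inverse CDF in two pieces
    t0 <- 50
    r1 <- 0.01 * exp(1.2 * x); r2 <- 0.01 * exp(-1.2 * x)
    tt <- ifelse(u > exp(-r1 * t0),
                 -log(u) / r1,
                 t0 + (-log(u) - r1 * t0) / r2)
    f <- coxph_fit(data.frame(x = x), tt, rep(1, n))
    if (ph_assumption_test(f)["x"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("concordance index equals the pair-enumeration oracle", {
  set.seed(41)
  times <- c(5, 8, 3, 9, 12, 4, 7, 10, 2, 6)
  events <- c(1, 0, 1, 1, 0, 1, 0, 1, 1, 1)
  risk <- c(2.1, 0.5, 3.0, 0.5, -1, 2.5, 1, 0, 3.5, 1.5)  # includes a tie
  ci <- concordance_index(risk, times, events)
  orc <- oracle_cindex(risk, times, events)
  expect_equal(ci$c_index, orc$c, tolerance = 1e-12)
  expect_equal(ci$n_pairs, orc$n_pairs)
  expect_equal(rownames(ci$ci), c("95%", "85%"))
  expect_true(ci$ci["85%", "lower"] >= ci$ci["95%", "lower"])

  # perfect risk ordering and constant risk
  expect_equal(concordance_index(-times, times, rep(1, 10))$c_index, 1)
  expect_equal(concordance_index(rep(1, 10), times, rep(1, 10))$c_index, 0.5)
  expect_error(concordance_index(risk, times, rep(0, 10)), "event")
})

test_that("nested risk-group models: nesting, reference, LR comparison", {
  set.seed(42)
  n <- 200
  f <- factor(rep(c("L0", "L1"), each = n / 2))
  s <- factor(sample(rep(c("MPS1", "MPS2"), n / 2)))
  lam <- 0.01 * exp(0.6 * (f == "L1") + 0.8 * (f == "L1" & s == "MPS1"))
  tt <- rexp(n, lam)
  rg <- risk_group_model(f, s, tt, rep(1, n))
  expect_equal(rg$reference, "L1 MPS1")
  expect_gte(rg$fit4$loglik, rg$fit2$loglik - 1e-9)  # nesting
  expect_equal(rg$df, 2)
  expect_equal(length(rg$fit4$beta), 3)
  expect_lt(rg$p, 0.05)  # planted within-level subtype effect is detected
  # all HRs vs the high-risk reference are below 1 here
  expect_true(all(rg$fit4$hr < 1))
  # empty cell is named
  s_bad <- factor(ifelse(f == "L0", "MPS2", as.character(s)))
  expect_error(risk_group_model(f, s_bad, tt, rep(1, n)), "L0 MPS1")
})

test_that("multivariable workflow: determinism, recovery, null screen", {
  set.seed(43)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  lam <- 0.005 * exp(0.8 * X[, 1] + 0.8 * X[, 2])
  tt <- rexp(n, lam)
  cens <- rexp(n, 0.002)
  tab <- data.frame(OS_time = pmin(tt, cens),
                    OS_event = as.numeric(tt <= cens), X)
  res <- multivariable_workflow(tab, paste0("v", 1:6), "OS", seed = 44)
  expect_false(res$null_model)
  expect_true(all(c("v1", "v2") %in% res$selected))
  expect_gt(res$risk_hr, 1)
  expect_gt(res$c_index$c_index, 0.6)
  expect_equal(rownames(res$c_index$ci), c("95%", "85%"))
  # determinism
  res2 <- multivariable_workflow(tab, paste0("v", 1:6), "OS", seed = 44)
  expect_identical(res$selected, res2$selected)
  expect_identical(res$risk_hr, res2$risk_hr)

  # all-noise candidates usually screen out to the documented null result
  set.seed(45)
  tab_null <- data.frame(OS_time = rexp(120, 0.01), OS_event = 1,
                         a = rnorm(120), b = rnorm(120))
  res3 <- multivariable_workflow(tab_null, c("a", "b"), "OS", seed = 46)
  expect_true(is.logical(res3$null_model))
  if (res3$null_model) expect_null(res3$risk_hr)
})

test_that("sliding-threshold scan: partition, exclusion, errors", {
  set.seed(47)
  n <- 120
  marker <- rnorm(n)
  tt <- rexp(n, 0.01)
  sc <- sliding_threshold_scan(marker, tt, rep(1, n),
                               fractions = c(0.1, 0.25, 0.5))
  expect_s3_class(sc, "scan_result")
  expect_equal(sc$n_top, floor(c(0.1, 0.25, 0.5) * n))
  # at f = 0.5 with even n and distinct marker, top and bottom partition all
  expect_equal(2 * sc$n_top[3], n)
  expect_true(all(is.finite(sc$hr)))
  expect_error(sliding_threshold_scan(marker, tt, rep(1, n),
                                      fractions = c(0.3, 0.6)), "0.5")
  expect_error(sliding_threshold_scan(marker[1:20], tt[1:20], rep(1, 20),
                                      fractions = 0.05), "fewer than 2")
})

test_that("log-rank and univariable Cox Wald p agree in ordering", {
  set.seed(48)
  p_lr <- numeric(40); p_cox <- numeric(40)
  for (i in 1:40) {
    n <- 80
    g <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.01 * exp(0.4 * g * (i %% 5)))
    ev <- as.numeric(tt <= quantile(tt, 0.8))
    tt <- pmin(tt, quantile(tt, 0.8))
    p_lr[i] <- logrank_test(tt, ev, g)$p
    p_cox[i] <- coxph_fit(data.frame(g = g), tt, ev)$p[1]
  }
  expect_gt(cor(p_lr, p_cox, method = "spearman"), 0.95)
})
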