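test_that("terminal regression recovers exact log-linear decline", {
  t <- c(8, 10, 12)
  p <- conc_profile("s", 5000, t, 100 * exp(-0.2 * t))
  fit <- fit_terminal_phase(p)
  expect_equal(fit$lambda_z, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$n_points, 3L)
})

test_that("manual-window fit equals brute-force least squares", {
  withr::with_seed(21, {
    for (i in 1:10) {
      t <- sort(runif(8, 0, 48))
      conc <- 500 * exp(-0.15 * t) * exp(rnorm(8, 0, 0.2))
      p <- conc_profile("s", 5000, t, conc)
      last3 <- tail(t, 3)
      fit <- fit_terminal_phase(p, window = c(last3[1], last3[3]))
      ref <- ols_oracle(last3, log(tail(conc, 3)))
      expect_equal(fit$lambda_z, -unname(ref["slope"]), tolerance = 1e-9)
      expect_equal(fit$intercept_log, unname(ref["intercept"]), tolerance = 1e-9)
    }
  })
})

test_that("degenerate terminal phases are reported unestimable", {
  flat <- conc_profile("s", 5000, c(1, 2, 3), c(10, 10, 10))
  w <- capture_warnings(fit <- fit_terminal_phase(flat))
  expect_true(any(grepl("not negative|unestimable", w)))
  expect_true(is.na(fit$lambda_z))
  expect_error(fit_terminal_phase(conc_profile("s", 5000, c(1, 2), c(5, 4))),
               ">= 3")
})

test_that("automatic window selection excludes the rise and prefers the best adjusted r2", {
  # rise to a peak then clean mono-exponential decline: the chosen window
  # must not include pre-peak points and must recover the true rate
  t <- c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12)
  conc <- c(50, 90, 100, 95 * exp(-0.25 * (2 - 2)), 95 * exp(-0.25 * (4 - 2)),
            95 * exp(-0.25 * (6 - 2)), 95 * exp(-0.25 * (8 - 2)),
            95 * exp(-0.25 * (10 - 2)), 95 * exp(-0.25 * (12 - 2)))
  fit <- fit_terminal_phase(conc_profile("s", 5000, t, conc))
  expect_gte(fit$window[1], 2)
  expect_equal(fit$lambda_z, 0.25, tolerance = 1e-10)
  # exact data: ties on adjusted r2 resolve toward the longer window
  expect_identical(fit$n_points, 6L)
})

test_that("half-life uses the conventional 0.693 constant", {
  expect_equal(half_life(0.1), 6.93)
  expect_equal(half_life(0.693), 1)
  expect_equal(half_life(0.693 / 7.88), 7.88)
  expect_error(half_life(0), "> 0")
  expect_error(half_life(-1), "> 0")
})

test_that("trapezoidal rules match closed forms and the dense oracle", {
  expect_equal(auc_trapezoid(c(0, 1), c(10, 10)), 10)
  expect_equal(auc_trapezoid(c(0, 1), c(100, 50), "linear-up/log-down"),
               50 / log(2), tolerance = 1e-9)
  expect_equal(auc_trapezoid(c(0, 1), c(100, 50), "linear-up/log-down"),
               72.1348, tolerance = 1e-5)
  expect_error(auc_trapezoid(1, 1), ">= 2")
  withr::with_seed(31, {
    for (i in 1:20) {
      pp <- random_profile_points()
      expect_equal(auc_trapezoid(pp$times, pp$conc),
                   dense_auc_oracle(pp$times, pp$conc),
                   tolerance = 1e-9)
    }
  })
})

test_that("log-down rule is exact on common exponential declines", {
  withr::with_seed(32, {
    for (i in 1:20) {
      lam <- runif(1, 0.01, 2)
      c0 <- runif(1, 1, 1000)
      t <- sort(runif(5, 0, 24))
      analytic <- c0 / lam * (exp(-lam * t[1]) - exp(-lam * t[length(t)]))
      got <- auc_trapezoid(t, c0 * exp(-lam * t), "linear-up/log-down")
      expect_equal(got, analytic, tolerance = 1e-12)
    }
  })
})

test_that("extrapolated tail areas follow the closed forms", {
  expect_equal(auc_extrapolated_tail(1, 0.1), 10)
  expect_warning(z <- auc_extrapolated_tail(0, 0.1), "no extrapolation")
  expect_equal(z, 0)
  expect_error(auc_extrapolated_tail(1, 0), "> 0")
  # truncated mono-exponential: observed (log-down) + tail = C0/lambda
  t <- seq(0, 12, by = 0.5)
  conc <- 100 * exp(-0.2 * t)
  total <- auc_trapezoid(t, conc, "linear-up/log-down") +
    auc_extrapolated_tail(conc[length(conc)], 0.2)
  expect_equal(total, 500, tolerance = 1e-9)
})

test_that("first-moment areas match analytic values", {
  t <- seq(0, 60, by = 0.05)
  conc <- 100 * exp(-0.2 * t)
  got <- aumc_inf(t, conc, lambda_z = 0.2)
  expect_equal(got, 100 / 0.2^2, tolerance = 0.005)
  expect_equal(aumc_inf(c(0, 1), c(0, 0), lambda_z = 0.2), 0)
  # tail-only closed form
  expect_equal(ncaval:::aumc_tail(10, 12, 0.1), 10 * 12 / 0.1 + 10 / 0.01)
})

test_that("MRT, clearance and Vss follow their defining quotients", {
  expect_equal(mrt(2500, 500), 5)
  expect_equal(mrt(0, 500), 0)
  expect_error(mrt(10, 0), "> 0")
  expect_equal(round(clearance(5000, 9.01), 2), 554.94)
  expect_equal(clearance(7, 7), 1)
  expect_error(clearance(-1, 2), "> 0")
  expect_equal(round(as.numeric(vss(554.94, 5.92, "paper")), 2), 93.74)
  expect_equal(round(as.numeric(vss(554.94, 5.92, "conventional")), 2), 3285.24)
  expect_equal(as.numeric(vss(10, 1, "paper")),
               as.numeric(vss(10, 1, "conventional")))
  expect_error(vss(0, 1), "> 0")
})

test_that("full NCA recovers closed-form parameters on dense mono-exponential data", {
  t <- seq(0, 60, by = 0.1)
  p <- conc_profile("s", 5000, t, 100 * exp(-0.2 * t))
  r <- run_nca(p)
  # Cl = Dose / (C0/lambda); C0 = 100 ng/mL = 0.1 ug/mL
  expect_equal(r$cl, 5000 / (0.1 / 0.2), tolerance = 0.005)
  expect_equal(r$t_half, 0.693 / 0.2)
  expect_equal(r$lambda_z, 0.2, tolerance = 1e-6)
  expect_equal(r$mrt, 1 / 0.2, tolerance = 0.005)
  # algebraic identity, exact
  expect_equal(r$cl * r$auc_inf, 5000, tolerance = 1e-9)
})

test_that("extrapolated fraction shrinks as sampling extends", {
  pct <- vapply(c(12, 24, 36, 48), function(tl) {
    t <- seq(0, tl, by = 0.25)
    run_nca(conc_profile("s", 5000, t, 100 * exp(-0.2 * t)))$pct_extrapolated
  }, numeric(1))
  expect_true(all(diff(pct) < 0))
  expect_true(all(pct >= 0 & pct < 100))
})

test_that("NCA on the noise-free tri-exponential reference recovers analytic summaries", {
  dp <- default_disposition()
  t <- c(seq(0, 12, by = 0.05), seq(12.5, 120, by = 0.5))
  p <- conc_profile("s", dp$dose, t, model_concentration(dp, t))
  r <- run_nca(p, method = "linear-up/log-down")
  A <- dp$coefficients / 1000  # ug/mL
  L <- dp$rates
  expect_equal(r$lambda_z, L[3], tolerance = 0.005)
  expect_equal(r$auc_inf, sum(A / L), tolerance = 0.005)
  expect_equal(r$mrt, sum(A / L^2) / sum(A / L), tolerance = 0.005)
  expect_equal(r$cl * r$auc_inf, dp$dose, tolerance = 1e-9)
})

test_that("unestimable terminal phase propagates as NA fields", {
  p <- conc_profile("s", 5000, 1:5, c(100, 10, 10, 10, 10))
  w <- capture_warnings(r <- run_nca(p))
  expect_true(any(grepl("unavailable", w)))
  expect_true(is.na(r$lambda_z) && is.na(r$auc_inf) && is.na(r$cl))
  expect_gt(r$auc_last, 0)
})

test_that("cohort summaries use the sample standard deviation per parameter", {
  t <- seq(0, 48, by = 0.5)
  mk <- function(c0) run_nca(conc_profile("s", 5000, t, c0 * exp(-0.2 * t)))
  two <- summarize_cohort(list(mk(100), mk(100)))
  expect_true(all(two$sd == 0, na.rm = TRUE))
  one <- summarize_cohort(list(mk(100)))
  expect_true(all(is.na(one$sd)))
  expect_error(summarize_cohort(list()), "non-empty")
  # mean/sd arithmetic on a hand-computable pair
  s <- summarize_cohort(list(mk(100), mk(150)))
  a <- s[s$parameter == "auc_inf", ]
  vals <- c(mk(100)$auc_inf, mk(150)$auc_inf)
  expect_equal(a$mean, mean(vals))
  expect_equal(a$sd, sd(vals))
  expect_equal(sd(c(4, 6)), 1.4142, tolerance = 1e-4)
  # reporting order mirrors the conventional table
  expect_identical(s$parameter[1:3], c("dose", "auc_inf", "lambda_z"))
})
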