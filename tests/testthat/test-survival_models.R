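test_that("counting-process rows tile follow-up and split at the exposure day", {
  rows <- build_counting_process(100, TRUE, exposure_day = 30,
                                 covariates = list(z = 1), stratum = 2016)
  expect_equal(rows$start, c(0, 30))
  expect_equal(rows$stop, c(30, 100))
  expect_equal(rows$event, c(FALSE, TRUE))
  expect_equal(rows$exposure, c(0L, 1L))
  expect_equal(rows$z, c(1, 1))

  one <- build_counting_process(100, FALSE)
  expect_equal(nrow(one), 1)
  expect_equal(one$exposure, 0L)

  # exposure at the end of follow-up never contributes exposed risk time
  edge <- build_counting_process(100, TRUE, exposure_day = 100)
  expect_equal(nrow(edge), 1)
  expect_equal(edge$exposure, 0L)

  expect_error(build_counting_process(100, TRUE, exposure_day = 0),
               "strictly positive")
  expect_error(build_counting_process(0, TRUE), "duration_days")
})

test_that("the table builder tiles every subject without gaps or overlaps", {
  set.seed(15)
  df <- data.frame(
    patient_id = sprintf("P%02d", 1:50),
    duration_days = sample(30:400, 50),
    discontinued = runif(50) < 0.5,
    exposure_day = ifelse(runif(50) < 0.5, NA, sample(1:200, 50)),
    stratum = sample(2015:2018, 50, replace = TRUE)
  )
  cp <- build_counting_process_table(df)
  for (chunk in split(cp, cp$patient_id)) {
    chunk <- chunk[order(chunk$start), ]
    expect_equal(chunk$start[1], 0)
    if (nrow(chunk) > 1) {
      expect_equal(chunk$start[-1], chunk$stop[-nrow(chunk)])
    }
    pid <- chunk$patient_id[1]
    expect_equal(chunk$stop[nrow(chunk)],
                 df$duration_days[df$patient_id == pid])
    expect_equal(sum(chunk$event),
                 as.integer(df$discontinued[df$patient_id == pid]))
    expect_true(all(diff(chunk$exposure) >= 0))  # 0 -> 1 at most once
  }
  zero <- df[1, ]; zero$duration_days <- 0
  expect_warning(build_counting_process_table(rbind(df, zero)),
                 "zero follow-up")
})

test_that("partial-likelihood fits match the brute-force maximiser", {
  # six-subject toy data with a tied event time
  toy <- data.frame(patient_id = sprintf("S%d", 1:6), start = 0,
                    stop = c(3, 5, 5, 8, 10, 12),
                    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                    exposure = c(1, 1, 0, 0, 1, 0))
  fit <- fit_cox(toy, strata_col = NULL)
  b_hat <- fit$coefficients$coef[fit$coefficients$term == "exposure"]
  expect_lt(abs(b_hat - cox_mle_oracle(toy$start, toy$stop, toy$event,
                                       toy$exposure)), 1e-6)
  # likelihood value at the optimum matches the hand-coded Efron likelihood
  expect_lt(abs(fit$loglik[2] -
                cox_pll_efron(b_hat, toy$start, toy$stop, toy$event,
                              toy$exposure)), 1e-8)
  set.seed(41)
  for (k in 1:15) {
    inst <- random_cox_instance(sample(5:10, 1))
    if (sum(inst$event) < 2 || length(unique(inst$exposure)) < 2) next
    f <- tryCatch(suppressWarnings(fit_cox(inst, strata_col = NULL)),
                  error = function(e) NULL)
    if (is.null(f)) next
    b <- f$coefficients$coef[1]
    if (is.na(b) || abs(b) > 5) next   # near-separation: maximiser bounded by the oracle box
    expect_lt(abs(b - cox_mle_oracle(inst$start, inst$stop, inst$event,
                                     inst$exposure)), 1e-6)
  }
})

test_that("a constant exposure column is dropped with a warning", {
  toy <- data.frame(patient_id = sprintf("S%d", 1:6), start = 0,
                    stop = c(3, 5, 6, 8, 10, 12),
                    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                    exposure = 0L, z = c(1, 0, 1, 0, 1, 0))
  expect_warning(fit <- fit_cox(toy, covariates = "z", strata_col = NULL),
                 "constant")
  expect_true(fit$exposure_dropped)
  expect_null(exposure_hr(fit))
  expect_true("z" %in% fit$coefficients$term)
})

test_that("episode splitting preserves risk sets and events", {
  cp <- data.frame(patient_id = c("A", "B"), start = c(0, 0),
                   stop = c(10, 7), event = c(TRUE, FALSE),
                   exposure = c(1L, 0L))
  sp <- split_counting_process(cp, c(3, 7, 9))
  a <- sp[sp$patient_id == "A", ]
  expect_equal(a$start, c(0, 3, 7, 9))
  expect_equal(a$stop, c(3, 7, 9, 10))
  expect_equal(a$event, c(FALSE, FALSE, FALSE, TRUE))
  b <- sp[sp$patient_id == "B", ]
  expect_equal(b$stop, c(3, 7))
  expect_false(any(b$event))
  # the split leaves the partial likelihood unchanged
  toy <- data.frame(patient_id = sprintf("S%d", 1:6), start = 0,
                    stop = c(3, 5, 5, 8, 10, 12),
                    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                    exposure = c(1, 1, 0, 0, 1, 0))
  f0 <- fit_cox(toy, strata_col = NULL)
  f1 <- fit_cox(split_counting_process(toy, c(2, 4, 6, 9)),
                strata_col = NULL)
  expect_equal(f0$coefficients$coef, f1$coefficients$coef, tolerance = 1e-10)
})

simulate_twogroup <- function(n, hazard0, hr_fun, seed) {
  # exposure fixed at baseline; event time by inversion of a possibly
  # time-varying exposed hazard; administrative censoring at day 500
  set.seed(seed)
  exposure <- rbinom(n, 1, 0.5)
  z <- rbinom(n, 1, 0.5)
  u <- runif(n)
  t <- numeric(n)
  grid <- seq(0.5, 2000, by = 0.5)
  for (i in seq_len(n)) {
    h <- hazard0 * (if (exposure[i]) hr_fun(grid) else rep(1, length(grid)))
    H <- cumsum(h) * 0.5
    j <- which(H >= -log(u[i]))[1]
    t[i] <- if (is.na(j)) 2000 else grid[j]
  }
  data.frame(patient_id = sprintf("S%04d", 1:n), start = 0,
             stop = pmin(t, 500), event = t <= 500, exposure = exposure,
             z = z, stratum = 1L)
}

test_that("the model ladder keeps the simplest model consistent with its tests", {
  # constant exposure effect, no interactions: main-effects model selected
  cp1 <- simulate_twogroup(500, 0.004, function(t) rep(0.5, length(t)),
                           seed = 2)
  lad1 <- model_ladder(cp1, covariates = "z", strata_col = "stratum")
  expect_equal(lad1$selected_id, "M1")
  expect_gte(lad1$p_ph, 0.05)

  # exposure effect decaying in time: proportional hazards flagged and the
  # log(time) interaction model selected
  cp2 <- simulate_twogroup(500, 0.004,
                           function(t) exp(-2 + 0.45 * log(t)), seed = 3)
  lad2 <- model_ladder(cp2, covariates = "z", strata_col = "stratum")
  expect_true(lad2$ph_violated)
  expect_equal(lad2$selected_id, "M3")
  # with a positive interaction the fixed-time hazard ratio grows with time
  hr46 <- hr_at_time(lad2$models$M3, c(4, 6))
  expect_gt(hr46$hr[2], hr46$hr[1])
})

test_that("fixed-time hazard ratios follow the linear-combination arithmetic", {
  manual <- list(coef = c(exposure = -1, exposure_x_logt = 0.1),
                 vcov = matrix(0, 2, 2,
                               dimnames = list(c("exposure", "exposure_x_logt"),
                                               c("exposure", "exposure_x_logt"))))
  out <- hr_at_time(manual, 4)
  expect_equal(out$hr, exp(-1 + 0.1 * log(28)))
  expect_equal(out$hr_lo, out$hr)
  # zero interaction reduces to the constant hazard ratio at every time
  flat <- list(coef = c(exposure = -0.7, exposure_x_logt = 0),
               vcov = diag(c(0.04, 0)))
  names(flat$coef) -> nm
  dimnames(flat$vcov) <- list(nm, nm)
  out2 <- hr_at_time(flat, c(4, 6))
  expect_equal(out2$hr, rep(exp(-0.7), 2))
  expect_error(hr_at_time(list(coef = c(exposure = -1)), 4), "covariance")
})
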