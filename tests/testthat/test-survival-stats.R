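# Cox partial likelihood, concordance, Kaplan-Meier, log-rank and the
# quantile cutoff stratification.

test_that("Cox loss matches closed forms and a literal term-by-term sum", {
  expect_equal(cox_loss(c(0, 0), c(1, 2), c(1, 1)), log(2), tolerance = 1e-12)
  expect_equal(cox_loss(c(0, 0, 0), 1:3, c(1, 1, 1)), log(6),
               tolerance = 1e-12)

  risks <- c(0.5, -1.2, 2.0, 0.0, 0.7)
  times <- c(2, 1, 4, 3, 5)
  events <- c(1, 1, 0, 1, 0)
  expect_equal(cox_loss(risks, times, events),
               cox_loss_literal(risks, times, events), tolerance = 1e-10)

  # Breslow: tied event times share the full risk-set denominator
  expect_equal(cox_loss(c(1, 2, 0), c(2, 2, 3), c(1, 1, 1)),
               cox_loss_literal(c(1, 2, 0), c(2, 2, 3), c(1, 1, 1)),
               tolerance = 1e-12)

  expect_warning(l0 <- cox_loss(c(1, 2), c(1, 2), c(0, 0)), "no events")
  expect_equal(l0, 0)
  expect_error(cox_loss(1, c(1, 2), c(1, 1)), "equal length")
})

test_that("Cox loss is shift-invariant and its gradient matches numerics", {
  cellfuse:::with_seed(11, {
    for (rep in 1:5) {
      n <- 20
      risks <- rnorm(n)
      times <- rexp(n) + 0.01
      events <- rbinom(n, 1, 0.7)
      if (sum(events) == 0) events[1] <- 1
      expect_equal(cox_loss(risks + 3.7, times, events),
                   cox_loss(risks, times, events), tolerance = 1e-10)
      g <- cox_loss_grad(risks, times, events)
      h <- 1e-6
      for (k in sample(n, 4)) {
        rp <- risks; rp[k] <- rp[k] + h
        rm <- risks; rm[k] <- rm[k] - h
        gn <- (cox_loss(rp, times, events) - cox_loss(rm, times, events)) /
          (2 * h)
        expect_equal(g[k], gn, tolerance = 1e-5)
      }
    }
  })
})

test_that("concordance matches hand toys and brute-force enumeration", {
  times <- 1:5
  events <- c(1, 1, 0, 1, 0)
  expect_equal(concordance_index(c(5, 4, 3, 2, 1), times, events), 1.0)
  expect_equal(concordance_index(c(3, 5, 1, 2, 4), times, events), 5 / 8)
  expect_equal(concordance_index(rep(2, 5), times, events), 0.5)
  expect_error(concordance_index(1, 1, 0), "no comparable")

  cellfuse:::with_seed(12, {
    for (rep in 1:10) {
      n <- sample(5:50, 1)
      risks <- rnorm(n)
      tms <- rexp(n) + 0.01
      evs <- rbinom(n, 1, 0.6)
      if (sum(evs) == 0) evs[1] <- 1
      expect_identical(concordance_index(risks, tms, evs),
                       cindex_bruteforce(risks, tms, evs))
      # antisymmetry when there are no risk ties
      expect_equal(concordance_index(risks, tms, evs) +
                     concordance_index(-risks, tms, evs), 1)
      # independent cross-check against survival::concordance
      sc <- survival::concordance(
        survival::Surv(tms, evs) ~ risks, reverse = TRUE)$concordance
      expect_equal(concordance_index(risks, tms, evs), unname(sc),
                   tolerance = 1e-12)
    }
  })
})

test_that("Kaplan-Meier estimates match hand product-limit tables", {
  allc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(length(allc$event_times), 0)
  expect_equal(km_survival_at(allc, c(0.5, 2.5)), c(1, 1))

  cv <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cv$event_times, c(1, 3))
  expect_equal(cv$survival_probs, c(2 / 3, 0))
  expect_equal(km_survival_at(cv, c(0.9, 1, 2.9, 3)), c(1, 2 / 3, 2 / 3, 0))

  single <- km_estimate(1, 1)
  expect_equal(single$survival_probs, 0)

  # with no censoring, KM is the empirical survival function
  cellfuse:::with_seed(13, {
    t <- sort(rexp(40) + 0.01)
    cv2 <- km_estimate(t, rep(1, 40))
    expect_equal(km_survival_at(cv2, t), 1 - seq_len(40) / 40)
  })
})

test_that("log-rank matches the hand O-E table and an independent sum", {
  same <- logrank_test(c(1, 2), c(1, 1), c(1, 2), c(1, 1))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  toy <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(toy$chi2, 49 / 17, tolerance = 1e-10)   # (7/6)^2 / (17/36)

  swapped <- logrank_test(c(3, 4), c(1, 1), c(1, 2), c(1, 1))
  expect_equal(swapped$chi2, toy$chi2, tolerance = 1e-12)

  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "nonempty")
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")

  cellfuse:::with_seed(14, {
    for (rep in 1:10) {
      na <- sample(5:50, 1); nb <- sample(5:50, 1)
      ta <- round(rexp(na), 2) + 0.01; tb <- round(rexp(nb) * 1.3, 2) + 0.01
      ea <- rbinom(na, 1, 0.7); eb <- rbinom(nb, 1, 0.7)
      if (sum(ea) + sum(eb) == 0) ea[1] <- 1
      got <- logrank_test(ta, ea, tb, eb)
      expect_equal(got$chi2, logrank_literal(ta, ea, tb, eb),
                   tolerance = 1e-8)
    }
  })
})

test_that("quantile cutoff separates planted clusters and honors the grid", {
  # two well-separated risk clusters with different hazards
  cellfuse:::with_seed(15, {
    n <- 100
    grp <- rep(c(0, 1), each = n / 2)
    risks <- grp * 5 + runif(n)
    times <- rexp(n, rate = 0.2 * exp(grp * 1.5)) + 1e-3
    events <- rep(1, n)
    cc <- optimal_quantile_cutoff(risks, times, events)
    labels <- as.integer(risks > cc$cutoff)
    expect_gte(mean(labels == grp), 0.95)

    single <- optimal_quantile_cutoff(risks, times, events,
                                      quantile_grid = 0.5)
    expect_equal(single$cutoff, unname(quantile(risks, 0.5)))
  })
  expect_error(optimal_quantile_cutoff(1:5, 1:5, rep(1, 5),
                                       quantile_grid = c(0, 1)), "quantile")
})

test_that("stratification splits at the cutoff with low-risk boundary ties", {
  risks <- c(1, 2, 3, 4, 5)
  times <- c(5, 4, 3, 2, 1)
  events <- rep(1, 5)
  expect_warning(s0 <- stratify(risks, times, events, 10), "empty")
  expect_equal(s0$p_value, 1)
  expect_true(all(s0$group == "low"))

  s1 <- stratify(risks, times, events, 3)   # median of odd distinct set
  expect_equal(as.vector(table(s1$group)), c(3, 2))
  expect_true(s1$logrank_chi2 >= 0)
})

test_that("stratification detects a planted hazard ratio of 3 reliably", {
  # 100 seeded cohorts of n = 200 with HR 3 between groups
  hits <- 0
  for (rep in 1:100) {
    cellfuse:::with_seed(3000 + rep, {
      grp <- rep(c(0, 1), each = 100)
      times <- rexp(200, rate = 0.3 * 3^grp) + 1e-4
      cens <- runif(200, 0, quantile(times, 0.9) * 2)
      obs <- pmin(times, cens)
      events <- as.integer(times <= cens)
      risks <- grp + rnorm(200, sd = 0.1)
      s <- stratify(risks, obs, events, 0.5)
      if (s$p_value < 0.05) hits <- hits + 1
    })
  }
  expect_gte(hits, 95)
})

test_that("KM export writes per-group curves", {
  cellfuse:::with_seed(16, {
    risks <- rnorm(30)
    times <- rexp(30) + 0.01
    events <- rbinom(30, 1, 0.8)
    s <- stratify(risks, times, events, median(risks))
    p <- withr::local_tempfile(fileext = ".csv")
    out <- export_km(s, times, events, p)
    expect_true(file.exists(p))
    expect_setequal(unique(out$group), c("low", "high"))
    # survival is non-increasing within each group
    for (g in unique(out$group)) {
      sv <- out$survival[out$group == g]
      expect_true(all(diff(sv) <= 1e-12))
    }
  })
})
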