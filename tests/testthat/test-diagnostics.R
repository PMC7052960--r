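# Trial confusion counts per (reading, modality) with the published
# per-cell fractions, used as parameterised cases below.
trial_cases <- list(
  onsite = list(
    NaF = list(cc = c(5, 4, 2, 44), se = 5 / 7, sp = 44 / 48, ppv = 5 / 9,
               npv = 44 / 46, acc = 49 / 55),
    FCH = list(cc = c(3, 0, 4, 48), se = 3 / 7, sp = 1, ppv = 1,
               npv = 48 / 52, acc = 51 / 55),
    `DW-MRI` = list(cc = c(4, 8, 3, 40), se = 4 / 7, sp = 40 / 48,
                    ppv = 4 / 12, npv = 40 / 43, acc = 44 / 55)),
  central = list(
    NaF = list(cc = c(6, 3, 1, 45), se = 6 / 7, sp = 45 / 48, ppv = 6 / 9,
               npv = 45 / 46, acc = 51 / 55),
    FCH = list(cc = c(4, 1, 3, 47), se = 4 / 7, sp = 47 / 48, ppv = 4 / 5,
               npv = 47 / 50, acc = 51 / 55),
    # the published central DW-MRI ppv/npv cells (3/5, 45/50) contradict the
    # row's own se/sp counts; the 2x2 implied by se = 3/7, sp = 45/48 is used
    `DW-MRI` = list(cc = c(3, 3, 4, 45), se = 3 / 7, sp = 45 / 48,
                    ppv = 3 / 6, npv = 45 / 49, acc = 48 / 55)))

test_that("accuracy_from_counts reproduces every trial cell", {
  for (rd in names(trial_cases)) {
    for (mod in names(trial_cases[[rd]])) {
      cs <- trial_cases[[rd]][[mod]]
      cc <- confusion_counts(tp = cs$cc[1], fp = cs$cc[2], fn = cs$cc[3],
                             tn = cs$cc[4])
      acc <- accuracy_from_counts(cc)
      for (stat in c("se", "sp", "ppv", "npv", "acc")) {
        expect_equal(acc[[stat]]$est, cs[[stat]], tolerance = 1e-12,
                     label = sprintf("%s %s %s", rd, mod, stat))
        expect_gte(cs[[stat]], acc[[stat]]$lo)
        expect_lte(cs[[stat]], acc[[stat]]$hi)
      }
    }
  }
})

test_that("accuracy edge cases behave", {
  perfect <- accuracy_from_counts(confusion_counts(7, 0, 0, 48))
  for (stat in c("se", "sp", "ppv", "npv", "acc")) {
    expect_equal(perfect[[stat]]$est, 1)
  }
  expect_error(confusion_counts(0, 0, 0, 0), "zero")
  expect_error(accuracy_from_counts(confusion_counts(0, 1, 0, 5)),
               "positive and one negative")
  # ppv undefined (no positive calls) is NA, not 0
  none_called <- accuracy_from_counts(confusion_counts(0, 0, 3, 10))
  expect_true(is.na(none_called$ppv$est))
})

test_that("accuracy satisfies acc = prev*se + (1-prev)*sp", {
  set.seed(5)
  for (i in 1:20) {
    cc <- confusion_counts(tp = rpois(1, 5) + 1, fp = rpois(1, 3),
                           fn = rpois(1, 2), tn = rpois(1, 20) + 1)
    a <- accuracy_from_counts(cc)
    n <- cc$tp + cc$fp + cc$fn + cc$tn
    prev <- (cc$tp + cc$fn) / n
    expect_equal(a$acc$est, prev * a$se$est + (1 - prev) * a$sp$est,
                 tolerance = 1e-12)
  }
})

test_that("Cochran Q matches hand computation and conventions", {
  # all columns identical -> no heterogeneity
  m <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 1, 0, 0))
  out <- cochran_q(m)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  # frozen: columns (1,1,0,0), (1,0,1,0), (1,1,1,0)
  # row totals R = (3,2,2,0), column totals C = (2,2,3), k = 3
  # Q = k(k-1) sum (C - mean(C))^2 / (k sum R - sum R^2) = 6*(6/9)/4 = 1
  m2 <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 1, 1, 0))
  out2 <- cochran_q(m2)
  expect_equal(out2$statistic, 1, tolerance = 1e-12)
  expect_equal(out2$p.value, stats::pchisq(1, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out2$df, 2L)
})

test_that("Cochran Q with k = 2 equals the McNemar chi-square", {
  set.seed(6)
  for (i in 1:10) {
    a <- rbinom(40, 1, 0.6)
    b <- rbinom(40, 1, 0.4)
    q <- cochran_q(cbind(a, b))
    mn <- mcnemar(a, b, exact_below = 0L)
    if (mn$b01 + mn$b10 > 0) {
      expect_equal(q$statistic, mn$statistic, tolerance = 1e-12)
    } else {
      expect_equal(q$statistic, 0)
    }
  }
})

test_that("Cochran Q on equal-accuracy synthetic trials is usually null", {
  set.seed(7)
  hits <- 0L
  n_seeds <- 40L
  for (i in seq_len(n_seeds)) {
    correctness <- matrix(rbinom(55 * 3, 1, 0.85), ncol = 3)
    if (cochran_q(correctness)$p.value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_seeds)
})

test_that("McNemar handles exact, asymptotic and degenerate branches", {
  # discordant (5, 5): symmetric
  a <- c(rep(1, 5), rep(0, 5), rep(1, 10))
  b <- c(rep(0, 5), rep(1, 5), rep(1, 10))
  out <- mcnemar(a, b, exact_below = 0L)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)
  # discordant (8, 2): exact binomial tail, 2 * P(X <= 2 | n=10)
  a2 <- c(rep(1, 8), rep(0, 2), rep(1, 5))
  b2 <- c(rep(0, 8), rep(1, 2), rep(1, 5))
  out2 <- mcnemar(a2, b2)
  expect_equal(out2$method, "exact binomial")
  expect_equal(out2$p.value, 0.109375, tolerance = 1e-12)
  # identical vectors
  expect_equal(mcnemar(a, a)$p.value, 1)
  # asymptotic branch agrees with stats::mcnemar.test without correction
  set.seed(8)
  x <- rbinom(200, 1, 0.5)
  y <- rbinom(200, 1, 0.5)
  ours <- mcnemar(x, y, exact_below = 0L)
  ref <- stats::mcnemar.test(table(factor(x, 0:1), factor(y, 0:1)),
                             correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("Cohen's kappa matches hand computation and properties", {
  # frozen 2x2 agreement table a=40 b=5 c=5 d=50:
  # po = 0.9, pe = (45*45 + 55*55)/100^2 = 0.505, kappa = 0.395/0.495
  r1 <- c(rep(1, 45), rep(0, 55))
  r2 <- c(rep(1, 40), rep(0, 5), rep(1, 5), rep(0, 50))
  expect_equal(cohen_kappa(r1, r2), 0.395 / 0.495, tolerance = 1e-12)
  # identical non-constant vectors
  expect_equal(cohen_kappa(r1, r1), 1)
  # invariance under simultaneous relabelling
  expect_equal(cohen_kappa(1 - r1, 1 - r2), cohen_kappa(r1, r2),
               tolerance = 1e-12)
  # independent raters: kappa near 0 at large n
  set.seed(9)
  x <- rbinom(20000, 1, 0.3)
  y <- rbinom(20000, 1, 0.6)
  expect_lt(abs(cohen_kappa(x, y)), 0.05)
  # both raters constant and equal: degenerate convention
  k <- cohen_kappa(rep(1, 10), rep(1, 10))
  expect_equal(as.numeric(k), 1)
  expect_true(isTRUE(attr(k, "degenerate")))
  # bounded
  for (i in 1:10) {
    a <- rbinom(30, 1, 0.5)
    b <- rbinom(30, 1, 0.5)
    k2 <- as.numeric(cohen_kappa(a, b))
    expect_gte(k2, -1)
    expect_lte(k2, 1)
  }
})

test_that("readings tables are validated and summarised", {
  tr <- generate_trial(trial_spec())
  expect_s3_class(tr, "paired_readings")
  m <- correctness_matrix(tr, "onsite")
  expect_equal(dim(m), c(55L, 3L))
  expect_true(all(m %in% 0:1))
  q <- cochran_q(tr, reading = "onsite")
  expect_equal(q$k, 3L)
  bad <- data.frame(patient_id = 1:3, truth = c(0, 1, 2),
                    call_NaF_onsite = c(0, 1, 1))
  expect_error(as_paired_readings(bad), "binary")
  expect_error(as_paired_readings(data.frame(patient_id = 1, truth = 0)),
               "no `call_")
})
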