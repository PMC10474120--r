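test_that("Jaacks recovers the true ratio exactly on noise-free data", {
  tr <- noiseless_series(3)
  est <- fit_jaacks(tr, c("A", "B"))
  expect_equal(est$r1, 3, tolerance = 1e-10)
  expect_equal(est$r2, 1 / 3, tolerance = 1e-10)
  expect_equal(est$se1, 0, tolerance = 1e-8)
  expect_equal(est$R2, 1, tolerance = 1e-10)
  # equal rates
  est1 <- fit_jaacks(noiseless_series(1), c("A", "B"))
  expect_equal(est1$r1, 1, tolerance = 1e-10)
  expect_equal(est1$r2, 1, tolerance = 1e-10)
  # identical conversion columns give slope exactly 1
  x <- seq(0.05, 0.6, length.out = 8)
  ds <- manual_dataset(seq_along(x), cbind(A = 1 - x, B = 1 - x),
                       cbind(A = x, B = x))
  expect_identical(fit_jaacks(conversions(ds), c("A", "B"))$r1, 1)
  # no consumption
  ds0 <- manual_dataset(1:4, cbind(A = rep(2, 4), B = rep(2, 4)),
                        cbind(A = rep(0, 4), B = rep(0, 4)))
  expect_error(fit_jaacks(conversions(ds0), c("A", "B")), "no consumption")
})

test_that("BSL recovers the true ratio and matches Jaacks when noiseless", {
  tr <- noiseless_series(5)
  est <- fit_bsl(tr, c("A", "B"))
  expect_equal(est$r1, 5, tolerance = 1e-3)
  jk <- fit_jaacks(tr, c("A", "B"))
  expect_rel_equal(est$r1, jk$r1, 1e-6)
  expect_rel_equal(est$r2, jk$r2, 1e-6)
  # residuals identically zero at r = 1 for equal-rate data
  tr1 <- noiseless_series(1)
  x <- tr1$x
  expect_lt(max(abs(x[, 2] - (1 - (1 - x[, 1])))), 1e-12)
  expect_equal(fit_bsl(tr1, c("A", "B"))$r1, 1, tolerance = 1e-6)
})

test_that("ideal integrated fit recovers the true ratio", {
  r_true <- ratios_from_delta(4.69)[["r1"]] # a 4.9-type ratio
  tr <- noiseless_series(r_true)
  est <- fit_ideal_integrated(tr, c("A", "B"))
  expect_rel_equal(est$r1, r_true, 1e-3)
  expect_rel_equal(est$r2, 1 / r_true, 1e-3)
  # r = 1: observed feed fraction is constant f0_A, residual 0 at r = 1
  tr1 <- noiseless_series(1, f0 = c(0.4, 0.6))
  fobs <- 0.4 * (1 - tr1$x[, 1]) /
    (0.4 * (1 - tr1$x[, 1]) + 0.6 * (1 - tr1$x[, 2]))
  expect_lt(max(abs(fobs - 0.4)), 1e-12)
  expect_equal(fit_ideal_integrated(tr1, c("A", "B"))$r1, 1,
               tolerance = 1e-6)
})

test_that("the three estimators are reparametrizations of one curve", {
  for (r in c(0.1, 0.5, 1, 2, 5, 20)) {
    tr <- noiseless_series(r)
    ests <- lapply(c("jaacks", "bsl", "ideal"),
                   function(m) fit_reactivity(tr, c("A", "B"), m))
    r1s <- vapply(ests, `[[`, numeric(1), "r1")
    r2s <- vapply(ests, `[[`, numeric(1), "r2")
    expect_lt(diff(range(r1s)) / r, 1e-6)
    expect_lt(diff(range(r2s)) * r, 1e-6)
    # ideal-consistency on noise-free data
    expect_true(all(r1s * r2s >= 0.98 & r1s * r2s <= 1.02))
  }
})

test_that("swapping the pair swaps r1 and r2 exactly for jaacks and bsl", {
  tr <- noisy_series(5, seed = 31)
  for (m in c("jaacks", "bsl")) {
    ab <- fit_reactivity(tr, c("A", "B"), m)
    ba <- fit_reactivity(tr, c("B", "A"), m)
    expect_identical(ab$r1, ba$r2)
    expect_identical(ab$r2, ba$r1)
  }
})

test_that("cross-model averaging reports mean and across-model sd", {
  mk <- function(m, r1, r2) {
    est <- fit_jaacks(noiseless_series(2), c("A", "B"))
    est$model <- m; est$r1 <- r1; est$r2 <- r2
    est
  }
  av <- average_models(list(mk("ideal", 5.2, 0.20), mk("jaacks", 4.9, 0.21),
                            mk("bsl", 4.6, 0.22)))
  expect_equal(av$r1_mean, 4.9)
  expect_equal(av$r1_sd, 0.3, tolerance = 1e-12)
  expect_equal(av$r2_mean, 0.21)
  # exclusions are honored and recorded
  av2 <- average_models(list(mk("ideal", 5.2, 0.2), mk("jaacks", 4.9, 0.21),
                             mk("bsl", 4.6, 0.22)),
                        exclude = c(bsl = "poor fit"))
  expect_equal(av2$r1_mean, mean(c(5.2, 4.9)))
  expect_identical(av2$excluded$reason, "poor fit")
  expect_warning(average_models(list(mk("ideal", 5, 0.2)),
                                exclude = character(0)), "single model")
  expect_error(average_models(list(mk("ideal", 5, 0.2)),
                              exclude = "ideal"), "no models left")
})

test_that("gradient classes follow the half-open boundaries", {
  g <- assess_gradient(4.9, 0.21)
  expect_equal(g$delta_r, 4.69)
  expect_identical(g$class, "medium")
  expect_identical(assess_gradient(ratios_from_delta(26)[["r1"]],
                                   ratios_from_delta(26)[["r2"]])$class,
                   "block")
  # boundaries are inclusive on the left class
  expect_identical(assess_gradient(2, 0.5)$class, "soft")        # 1.5
  expect_identical(assess_gradient(8, 0.5)$class, "medium")      # 7.5
  expect_identical(assess_gradient(25.5, 0.5)$class, "hard")     # 25
  expect_identical(assess_gradient(26, 0.5)$class, "block")      # 25.5
  # order-free: arguments may come in either order
  expect_equal(assess_gradient(0.21, 4.9)$delta_r, 4.69)
})

test_that("estimates stay within the reported se when truncating earlier", {
  tr6 <- noisy_series(5, seed = 17, x_max = 0.6)
  tr5 <- noisy_series(5, seed = 17, x_max = 0.5)
  for (m in c("jaacks", "bsl", "ideal")) {
    e6 <- fit_reactivity(tr6, c("A", "B"), m)
    e5 <- fit_reactivity(tr5, c("A", "B"), m)
    tol <- max(e6$se1, e5$se1, 0.02 * e6$r1)
    expect_lt(abs(e6$r1 - e5$r1), 3 * tol)
  }
})

test_that("noisy replicates recover the true ratio without material bias", {
  n_rep <- 40
  avg_r1 <- avg_r2 <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- noisy_series(5, seed = 400 + i)
    fits <- lapply(c("jaacks", "bsl", "ideal"),
                   function(m) fit_reactivity(tr, c("A", "B"), m))
    av <- average_models(fits)
    avg_r1[i] <- av$r1_mean; avg_r2[i] <- av$r2_mean
  }
  expect_lt(abs(mean(avg_r1) / 5 - 1), 0.05)
  expect_true(mean(avg_r1 * avg_r2) > 0.95 && mean(avg_r1 * avg_r2) < 1.05)
  # scatter shrinks with more data points
  sd_few <- stats::sd(vapply(1:40, function(i)
    fit_jaacks(noisy_series(5, seed = 600 + i, n_time = 20),
               c("A", "B"))$r1, numeric(1)))
  sd_many <- stats::sd(vapply(1:40, function(i)
    fit_jaacks(noisy_series(5, seed = 600 + i, n_time = 100),
               c("A", "B"))$r1, numeric(1)))
  expect_lt(sd_many, sd_few)
})

test_that("ternary systems decompose into consistent pairwise ratios", {
  rs <- rate_set(c(4, 2, 1), c("A", "B", "C"))
  cfg <- synth_config(rs, rep(1 / 3, 3), final_conversion = 0.9,
                      noise_sigma = 0)
  tr <- truncate_conversions(conversions(generate_kinetics(cfg)), 0.6)
  tt <- fit_ternary(tr)
  m <- ratio_matrix(tt)
  expect_equal(m["A", "B"], 2, tolerance = 1e-3)
  expect_equal(m["A", "C"], 4, tolerance = 4e-3)
  expect_equal(m["B", "C"], 2, tolerance = 1e-3)
  expect_equal(m["A", "C"], m["A", "B"] * m["B", "C"], tolerance = 1e-3)
  expect_equal(nrow(tt$table), 6L)
  # symmetric system: all six ratios are 1
  cfg1 <- synth_config(rate_set(c(1, 1, 1), c("A", "B", "C")),
                       rep(1 / 3, 3), final_conversion = 0.9,
                       noise_sigma = 0)
  tt1 <- fit_ternary(truncate_conversions(
    conversions(generate_kinetics(cfg1)), 0.6))
  expect_equal(tt1$table$r_mean, rep(1, 6), tolerance = 1e-6)
  # lambda flags drop a directed ratio from its average
  fl <- list(list(pair = c("A", "B"), model = "bsl", reason = "flagged"))
  ttf <- fit_ternary(tr, lambda_flags = fl)
  row <- ttf$table[ttf$table$from == "A" & ttf$table$to == "B", ]
  expect_equal(row$n_models, 2L)
  expect_false(grepl("bsl", row$models))
})

test_that("the P9 preset round-trips its gradient strengths", {
  cfg <- preset("P9", noise_sigma = 0)
  tr <- truncate_conversions(conversions(generate_kinetics(cfg)), 0.6)
  tt <- fit_ternary(tr, cfg$rates$species)
  m <- ratio_matrix(tt)
  sp <- cfg$rates$species
  d12 <- m[sp[1], sp[2]] - m[sp[2], sp[1]]
  d23 <- m[sp[2], sp[3]] - m[sp[3], sp[2]]
  expect_rel_equal(d12, 14, 0.02)
  expect_rel_equal(d23, 13, 0.02)
})
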