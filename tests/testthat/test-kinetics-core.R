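test_that("drift follows the power law and rejects bad domains", {
  expect_equal(drift(3.7, 1), 1)          # nothing consumed
  expect_equal(drift(1, 0.37), 0.37)      # equal rates, identical drift
  expect_equal(drift(2, 0.25), 0.5)       # 0.25^(1/2)
  expect_error(drift(0, 0.5), "positive")
  expect_error(drift(-1, 0.5), "positive")
  expect_error(drift(2, 0), "survival")
  expect_error(drift(2, 1.2), "survival")
})

test_that("drift is an involution under role swap", {
  rs <- c(0.02, 0.1, 0.5, 1, 2, 5.19, 24, 44)
  as <- c(1e-6, 0.01, 0.2, 0.5, 0.9, 1)
  for (r in rs) for (a in as) {
    expect_equal(drift(1 / r, drift(r, a)), a, tolerance = 1e-12)
  }
})

test_that("rate sets reproduce pairwise ratios with exact transitivity", {
  rs <- rate_set(c(4.9, 2.3, 0.7), c("x", "y", "z"))
  r_xy <- reactivity_ratio(rs, "x", "y")
  r_yz <- reactivity_ratio(rs, "y", "z")
  r_xz <- reactivity_ratio(rs, "x", "z")
  expect_equal(r_xz, r_xy * r_yz, tolerance = 1e-15)
  expect_equal(r_xy * reactivity_ratio(rs, "y", "x"), 1, tolerance = 1e-15)
  expect_error(rate_set(c(1, -2)), "> 0")
  expect_error(rate_set(c(1, 2), c("a", "a")), "unique")
})

test_that("ideal ratio pair from a gradient strength", {
  expect_equal(ratios_from_delta(0), c(r1 = 1, r2 = 1))
  for (d in c(0.5, 3, 5, 16, 24, 26)) {
    p <- ratios_from_delta(d)
    expect_equal(p[["r1"]] - p[["r2"]], d, tolerance = 1e-12)
    expect_equal(p[["r1"]] * p[["r2"]], 1, tolerance = 1e-12)
  }
  # frozen quadratic-formula values
  expect_equal(ratios_from_delta(24)[["r1"]], 24.0415945788, tolerance = 1e-9)
  expect_equal(ratios_from_delta(5)[["r1"]], 5.1925824036, tolerance = 1e-9)
  expect_error(ratios_from_delta(-1), "order the pair")
})

test_that("conversion_state matches hand arithmetic and the drift law", {
  # symmetric binary at equal rates
  st <- conversion_state(rate_set(c(1, 1)), c(0.5, 0.5), 0.5)
  expect_equal(st$X, 0.5)
  expect_equal(unname(st$f), c(0.5, 0.5))
  expect_equal(unname(st$F), c(0.5, 0.5))
  # start point: X = 0, cumulative defined by continuous limit f0
  st0 <- conversion_state(rate_set(c(4.9, 1)), c(0.55, 0.45), 1)
  expect_equal(st0$X, 0)
  expect_equal(unname(st0$F), c(0.55, 0.45))
  # hand-derived: k = (2, 1), a_A = 0.25 => a_B = 0.5
  st2 <- conversion_state(rate_set(c(2, 1)), c(0.5, 0.5), 0.25)
  expect_equal(st2$X, 0.625, tolerance = 1e-15)
  expect_equal(st2$F[["A"]], 0.6, tolerance = 1e-15)
})

test_that("mass balance holds at arbitrary states", {
  set.seed(42)
  for (i in 1:25) {
    ns <- sample(2:4, 1)
    rs <- rate_set(exp(stats::runif(ns, -3, 3)))
    f0 <- stats::runif(ns); f0 <- f0 / sum(f0)
    st <- conversion_state(rs, f0, stats::runif(1, 0.01, 1))
    expect_equal(sum(f0 * (1 - st$survival)), st$X, tolerance = 1e-12)
    expect_equal(sum(st$f), 1, tolerance = 1e-12)
    if (st$X > 0) expect_equal(sum(st$F), 1, tolerance = 1e-12)
  }
})

test_that("composition curves keep their invariants", {
  cc <- composition_curve(rate_set(c(5, 1)), c(0.3, 0.7), n_grid = 101)
  expect_true(all(abs(rowSums(cc$f) - 1) < 1e-10))
  expect_true(all(abs(rowSums(cc$F) - 1) < 1e-10))
  # incorporated amount F_i(X) * X is nondecreasing
  for (j in 1:2) expect_true(all(diff(cc$F[, j] * cc$X) > -1e-12))
  # ideal random: constant composition
  cc1 <- composition_curve(rate_set(c(1, 1)), c(0.5, 0.5), n_grid = 21)
  expect_equal(cc1$f[, 1], rep(0.5, 21), tolerance = 1e-10)
  # ternary symmetry
  cc3 <- composition_curve(rate_set(c(1, 1, 1)), rep(1 / 3, 3), n_grid = 21)
  expect_equal(max(abs(cc3$f - 1 / 3)), 0, tolerance = 1e-10)
})

test_that("composition curves agree with an independent ODE integration", {
  skip_if_not_installed("deSolve")
  f0 <- c(0.5, 0.5)
  ode_FA <- function(r, X_target) {
    # integrate the drift ODE da/db = r a / b numerically (b = survival of
    # the slower-indexed species), then read F_A off at the target X
    b_grid <- seq(1, 1e-3, length.out = 4000)
    sol <- deSolve::ode(y = c(a = 1), times = b_grid,
                        func = function(b, y, parms) list(parms * y / b),
                        parms = r, rtol = 1e-12, atol = 1e-12)
    a <- sol[, "a"]
    X <- 1 - f0[1] * a - f0[2] * b_grid
    FA <- ifelse(X > 0, f0[1] * (1 - a) / X, f0[1])
    stats::approx(X, FA, xout = X_target)$y
  }
  for (r in c(0.1, 0.5, 2, 5, 20)) {
    # stay inside the ODE solution's conversion range (its grid stops at
    # survival 1e-3 of the slower species)
    Xs <- seq(0.05, 0.7, by = 0.05)
    sv <- survival_at_conversion(rate_set(c(r, 1)), f0, Xs)
    a <- outer(sv$a_slow, sv$p, `^`)
    FA <- f0[1] * (1 - a[, 1]) / Xs
    expect_lt(max(abs(FA - ode_FA(r, Xs))), 1e-6)
  }
  # golden pair r = (5 + sqrt(29))/2 at X = 0.5
  r <- (5 + sqrt(29)) / 2
  sv <- survival_at_conversion(rate_set(c(r, 1)), f0, 0.5)
  FA <- f0[1] * (1 - sv$a_slow^sv$p[1]) / 0.5
  expect_equal(FA, ode_FA(r, 0.5), tolerance = 1e-6)
})

test_that("inconsistent ratio tables project onto a consistent rate set", {
  # perturbed views of k = (4, 2, 1)
  m <- matrix(NA_real_, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  m["A", "B"] <- 2.1; m["B", "A"] <- 1 / 1.9
  m["A", "C"] <- 3.9; m["C", "A"] <- 1 / 4.1
  m["B", "C"] <- 2.05; m["C", "B"] <- 1 / 1.95
  rs <- project_rate_set(m)
  expect_equal(rs$k[3], 1)
  expect_equal(reactivity_ratio(rs, "A", "B"), 2, tolerance = 0.05)
  expect_equal(reactivity_ratio(rs, "A", "C"), 4, tolerance = 0.05)
  # a consistent table is reproduced exactly
  mc <- outer(c(4, 2, 1), c(4, 2, 1), `/`); diag(mc) <- NA
  rsc <- project_rate_set(mc, species = c("A", "B", "C"))
  expect_equal(rsc$k, c(4, 2, 1), tolerance = 1e-12)
})
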