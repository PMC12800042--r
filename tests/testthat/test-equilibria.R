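test_that("probiotic-free reduction of the tumor-free equilibrium", {
  p <- model_parameters(g4 = 0.1, u1 = 0, u2 = 0, delta = 0.3)
  eq <- tumor_free_equilibrium(p)
  expect_true(eq$exists)
  expect_identical(eq$state[["P"]], 0)
  expect_equal(eq$state[["G"]], 0.3 / 0.4008, tolerance = 1e-14)
  expect_equal(eq$state[["C"]], (0.7 + 0.1 * 0.3 / 0.4008) / 0.7001,
               tolerance = 1e-14)
})

test_that("tumor-free equilibrium matches an independent bisection on the CD4 line", {
  p <- app1_i_params()
  eq <- tumor_free_equilibrium(p)
  expect_true(eq$exists)
  # oracle: with T = M = 0 fixed, solve the dendritic and CD4 balances
  # numerically, never using the closed form under test
  gstar <- uniroot(function(G) 0.3 - (0.4 + 0.0008) * G, c(0, 10),
                   tol = 1e-14)$root
  pstar <- 0.2 / 1
  cstar <- uniroot(function(C) 0.7 + 0.1 * gstar - (0.7 + 0.0001) * C +
                     0.15 * pstar * C / (0.25 + pstar) + 0.4 * C,
                   c(0, 100), tol = 1e-14)$root
  expect_equal(eq$state[["G"]], gstar, tolerance = 1e-9)
  expect_equal(eq$state[["C"]], cstar, tolerance = 1e-9)
  expect_equal(eq$state[["P"]], pstar, tolerance = 1e-14)
  # four-decimal values quoted throughout the analysis
  expect_equal(eq$state[["G"]], 0.74850, tolerance = 1e-5)
  expect_equal(eq$state[["C"]], 3.3194, tolerance = 1e-4)
  expect_lt(eq$residual, 1e-10)
})

test_that("nonpositive CD4 balance denominator reports nonexistence", {
  p <- model_parameters(u1 = 0.2, u2 = 0.8, delta = 0.6)
  eq <- tumor_free_equilibrium(p)
  expect_false(eq$exists)
  expect_match(eq$notes, "denominator nonpositive")
  expect_error(coexistence_scalar(1, p), "no admissible C branch")
})

test_that("equilibrium residuals vanish across random admissible draws", {
  for (p in draw_parameters(25, seed = 21)) {
    eq <- tumor_free_equilibrium(p)
    if (eq$exists) expect_lt(eq$residual, 1e-10)
  }
})

test_that("scalar coexistence function has the documented signs at T = 0", {
  # oracle values from explicit arithmetic on the printed parameter sets
  p1 <- app1_i_params()
  c0 <- (0.7 + 0.1 * (0.3 / 0.4008)) /
    (0.7001 - 0.4 - 0.15 * 0.2 / (0.25 + 0.2))
  expect_equal(coexistence_scalar(0, p1), 0.1 - 0.5 - 0.3 * c0 / 50,
               tolerance = 1e-12)
  expect_lt(coexistence_scalar(0, p1), -0.41)
  p2 <- app1_ii_params()
  c0b <- (0.7 + 0.1 * (0.3 / 0.4008)) /
    (0.7001 - 0.2 - 0.15 * 0.3 / (0.25 + 0.3))
  expect_equal(coexistence_scalar(0, p2), 0.1 - 0.01 - 0.3 * c0b / 50,
               tolerance = 1e-12)
  expect_equal(coexistence_scalar(0, p2), 0.0789, tolerance = 1e-3)
})

test_that("corrected and printed scalar reductions coincide without immune kill", {
  p <- model_parameters(omega = 0, beta1 = 0, u3 = 0.05, u1 = 0.1)
  Ts <- seq(0, 1000, length.out = 41)
  expect_equal(coexistence_scalar(Ts, p, "corrected"),
               p$g1 * (1 - Ts / p$s1) - p$u3, tolerance = 1e-14)
  expect_equal(coexistence_scalar(Ts, p, "paper_verbatim"),
               p$g1 * (1 - Ts / p$s1) - p$u3, tolerance = 1e-14)
})

test_that("coexistence root in the low-chemotherapy setting matches brute force", {
  p <- app1_ii_params()
  eqs <- find_coexistence(p)
  expect_length(eqs, 1L)
  eq <- eqs[[1]]
  expect_true(eq$exists && eq$positive)
  expect_lt(eq$residual, 1e-9)
  # brute-force oracle: dense scan of the back-substituted tumor balance,
  # written out independently, then bisection on the bracketing cell
  dc <- 0.7001 - 0.2 - 0.15 * 0.3 / (0.25 + 0.3)
  f <- function(T) {
    m <- 0.6 * T / (0.508 * (50 + T))
    g <- (0.3 + 0.3 * T / (50 + T)) / 0.4008
    cc <- (0.7 + 0.1 * g) / dc
    0.1 * (1 - T / 1000) - 0.1 * m / (50 + T) - 0.3 * cc / (50 + T) - 0.01
  }
  grid <- seq(1e-3, 1000, length.out = 1e5)
  v <- f(grid)
  i <- which(v[-1] * v[-length(v)] < 0)
  expect_length(i, 1L)
  lo <- grid[i]; hi <- grid[i + 1]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_equal(eq$state[["T"]], (lo + hi) / 2, tolerance = 1e-8)
  expect_lt(eq$state[["T"]], 1000)
  expect_gt(eq$state[["T"]], 800)
  expect_equal(eq$state[["P"]], 0.3, tolerance = 1e-14)
})

test_that("full triple dosing admits no coexistence equilibrium", {
  p <- app1_i_params()
  expect_length(find_coexistence(p), 0L)
  # exhaustive grid oracle: the scalar function is negative on (0, s1]
  expect_true(all(coexistence_scalar(seq(0.1, 1000, length.out = 5000), p) < 0))
})

test_that("residual arbitration rejects the printed scalar variant's root", {
  p <- app1_ii_params()
  corrected <- find_coexistence(p, mode = "corrected")[[1]]
  verbatim <- find_coexistence(p, mode = "paper_verbatim")
  expect_length(verbatim, 1L)
  # the roots differ, and only the corrected one satisfies the full system
  expect_gt(abs(verbatim[[1]]$state[["T"]] - corrected$state[["T"]]), 1)
  expect_lt(corrected$residual, 1e-9)
  expect_false(verbatim[[1]]$exists)
  expect_gt(verbatim[[1]]$residual, 1e-6)
})

test_that("doubling the scan resolution never loses a root", {
  for (p in draw_parameters(20, seed = 22)) {
    dc_ok <- tryCatch({coexistence_scalar(1, p); TRUE},
                      error = function(e) FALSE)
    if (!dc_ok) next
    n1 <- length(find_coexistence(p, scan_points = 2000))
    n2 <- length(find_coexistence(p, scan_points = 4000))
    expect_gte(n2, n1)
  }
})

test_that("equilibrium reports serialize to JSON", {
  eq <- tumor_free_equilibrium(app1_i_params())
  js <- jsonlite::fromJSON(equilibrium_to_json(eq))
  expect_identical(js$kind, "tumor_free")
  expect_equal(js$state$P, 0.2)
  expect_true(js$exists)
})
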