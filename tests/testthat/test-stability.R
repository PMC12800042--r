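test_that("analytic Jacobian matches central finite differences", {
  draws <- draw_parameters(20, seed = 31)
  states <- random_states(100, seed = 32)
  worst <- 0
  for (i in seq_along(states)) {
    p <- draws[[(i - 1) %% length(draws) + 1]]
    s <- states[[i]]
    J <- jacobian_matrix(p, s)
    Jfd <- fd_jacobian(p, s)
    err <- max(abs(J - Jfd) / pmax(abs(Jfd), 1e-2))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-5)
})

test_that("extended-variant Jacobian also matches finite differences", {
  p <- app3_params()
  for (s in random_states(20, seed = 33)) {
    J <- jacobian_matrix(p, s, variant = "extended")
    Jfd <- fd_jacobian(p, s, "extended")
    expect_lt(max(abs(J - Jfd) / pmax(abs(Jfd), 1e-2)), 1e-5)
  }
  expect_error(jacobian_matrix(p, state_vector(), mode = "paper_verbatim",
                               variant = "extended"), "base variant")
})

test_that("printed linearization disagrees with the derivative at the documented entries", {
  p <- app1_i_params()
  eq <- tumor_free_equilibrium(p)
  Jc <- jacobian_matrix(p, eq$state, mode = "correct")
  Jv <- jacobian_matrix(p, eq$state, mode = "paper_verbatim")
  # macrophage and dendritic recruitment columns: printed g/s^2 vs g*s/s^2
  expect_equal(Jv[2, 1], Jc[2, 1] / p$s2, tolerance = 1e-12)
  expect_equal(Jv[3, 1], Jc[3, 1] / p$s3, tolerance = 1e-12)
  # tumor diagonal: printed omega*C*/s4^2 vs omega*C*/s4
  expect_equal(Jc[1, 1] - Jv[1, 1],
               -p$omega * eq$state[["C"]] / p$s4 +
                 p$omega * eq$state[["C"]] / p$s4^2, tolerance = 1e-12)
  # probiotic column of the CD4 row: printed delta*C(1-P)/(b+P)^2 vs
  # delta*b*C/(b+P)^2
  expect_equal(Jv[4, 5] / Jc[4, 5], (1 - eq$state[["P"]]) / p$b,
               tolerance = 1e-12)
  # everywhere else the two modes agree at this equilibrium
  agree <- c(Jc[2, 2], Jc[3, 3], Jc[4, 3], Jc[4, 4], Jc[5, 5])
  expect_identical(agree, c(Jv[2, 2], Jv[3, 3], Jv[4, 3], Jv[4, 4], Jv[5, 5]))
})

test_that("tumor-free spectrum contains the closed-form eigenvalues", {
  p <- app1_i_params()
  eq <- tumor_free_equilibrium(p)
  lam <- sort(Re(jacobian_eigenvalues(jacobian_matrix(p, eq$state))))
  # closed forms: -(beta2+d1), -(beta3+d2), -vartheta, tumor eigenvalue
  # g1-u3-omega*C1*/s4, CD4 eigenvalue -(beta4+d3-u2-delta*P*/(b+P*))
  lam4 <- 0.1 - 0.5 - 0.3 * eq$state[["C"]] / 50
  lam5 <- -(0.7001 - 0.4 - 0.15 * 0.2 / 0.45)
  expect_equal(lam, sort(c(-0.508, -0.4008, -1, lam4, lam5)),
               tolerance = 1e-10)
  expect_equal(lam4, -0.4199, tolerance = 1e-4)
})

test_that("block coefficients reduce correctly for diagonal blocks", {
  R <- block_characteristic_coeffs(diag(c(-1, -2, -3, -4)))
  # elementary-symmetric oracle: e3 = -50, and R3 = -e3 = +50
  expect_equal(unname(R), c(-10, 35, 50, 24), tolerance = 1e-12)
  # all roots at -1: (l+1)^4 = l^4 + 4l^3 + 6l^2 + 4l + 1
  R1 <- block_characteristic_coeffs(diag(c(-1, -1, -1, -1)))
  expect_equal(unname(R1), c(-4, 6, 4, 1), tolerance = 1e-12)
  H <- hurwitz_determinants(R1)
  expect_equal(unname(H), c(4, 20, 64, 64), tolerance = 1e-12)
  expect_true(all(H > 0))
})

test_that("block coefficients equal the characteristic polynomial on random sparse blocks", {
  set.seed(34)
  for (i in 1:50) {
    A <- runif(10, -2, 2)
    B <- matrix(0, 4, 4)
    B[1, 1] <- A[1]; B[1, 2] <- A[2]; B[1, 4] <- A[3]
    B[2, 1] <- A[4]; B[2, 2] <- A[5]
    B[3, 1] <- A[6]; B[3, 3] <- A[7]
    B[4, 3] <- A[8]; B[4, 4] <- A[9]
    R <- block_characteristic_coeffs(B)
    # oracle: expand prod(lambda - lambda_i) from the computed spectrum
    ev <- eigen(B, only.values = TRUE)$values
    cp <- Re(Reduce(function(pp, r) c(pp, 0) - r * c(0, pp), ev, 1))
    expect_equal(cp, c(1, -R[["R1"]], R[["R2"]], R[["R3"]], R[["R4"]]),
                 tolerance = 1e-9)
  }
})

test_that("Hurwitz identities hold", {
  expect_identical(hurwitz_determinants(c(0, 1, 2, 3))[["H1"]], 0)
  set.seed(35)
  for (i in 1:20) {
    R <- runif(4, -3, 3)
    H <- hurwitz_determinants(R)
    if (abs(H[["H3"]]) > 1e-12)
      expect_equal(H[["H4"]] / H[["H3"]], R[[4]], tolerance = 1e-9)
  }
})

test_that("Matignon classification handles the canonical configurations", {
  expect_identical(matignon_classify(c(-1, -2.5), 0.9)$classification, "stable")
  expect_identical(matignon_classify(c(-1, 0.1), 0.9)$classification, "unstable")
  r <- 0.7 * exp(1i * c(1, -1) * 0.8 * pi / 2)
  expect_identical(matignon_classify(r, 0.9)$classification, "unstable")
  expect_identical(matignon_classify(r, 0.7)$classification, "stable")
  expect_identical(matignon_classify(c(-1, 1e-12), 1)$classification, "marginal")
  expect_identical(matignon_classify(c(-1, 0), 0.5)$classification, "marginal")
})

test_that("full assessment of the triple-dose tumor-free equilibrium", {
  p <- app1_i_params()
  eq <- tumor_free_equilibrium(p)
  rep <- assess_equilibrium(p, eq, alpha = 0.9)
  expect_identical(rep$classification, "stable")
  expect_true(all(rep$theorem_conditions))
  expect_true(rep$hurwitz_eigen_agree)
  expect_equal(rep$hurwitz[["H4"]],
               rep$block_coeffs[["R4"]] * rep$hurwitz[["H3"]],
               tolerance = 1e-12)
  js <- jsonlite::fromJSON(stability_to_json(rep))
  expect_identical(js$classification, "stable")
})

test_that("an untreated growing tumor is classified unstable", {
  p <- model_parameters(g1 = 0.3, omega = 0, beta1 = 0, u3 = 0, u2 = 0)
  eq <- tumor_free_equilibrium(p)
  rep <- assess_equilibrium(p, eq, alpha = 0.9)
  expect_identical(rep$classification, "unstable")
  expect_false(rep$theorem_conditions[["tumor_eigen_negative"]])
  expect_equal(rep$jacobian[1, 1], 0.3, tolerance = 1e-12)
})

test_that("Hurwitz signs and block spectra agree on random draws, and stability is monotone in alpha", {
  draws <- draw_parameters(200, seed = 36)
  tested <- 0
  for (p in draws) {
    eq <- tumor_free_equilibrium(p)
    if (!eq$exists) next
    J <- jacobian_matrix(p, eq$state)
    lam <- jacobian_eigenvalues(J[1:4, 1:4])
    if (min(abs(Re(lam))) < 1e-6) next
    H <- hurwitz_determinants(block_characteristic_coeffs(J))
    expect_identical(all(H > 0), all(Re(lam) < 0))
    # a spectrum in the open left half-plane is Matignon-stable for all alpha
    if (all(Re(jacobian_eigenvalues(J)) < 0)) {
      for (a in c(0.3, 0.6, 0.9, 1))
        expect_identical(matignon_classify(jacobian_eigenvalues(J), a)$classification,
                         "stable")
    }
    tested <- tested + 1
  }
  expect_gt(tested, 100)
})
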