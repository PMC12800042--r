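test_that("default parameters reproduce the tabulated fixed values", {
  p <- default_parameters()
  expect_identical(p$s1, 1000)
  expect_identical(c(p$s2, p$s3, p$s4), c(50, 50, 50))
  expect_identical(c(p$r1, p$r2), c(0.3, 0.7))
  expect_identical(c(p$beta1, p$omega), c(0.1, 0.3))
  expect_identical(c(p$beta2, p$beta3, p$beta4), c(0.5, 0.4, 0.7))
  expect_identical(c(p$d1, p$d2, p$d3), c(0.008, 0.0008, 0.0001))
  expect_identical(c(p$vartheta, p$b), c(1, 0.25))
  expect_identical(c(p$g5, p$g6, p$g7), c(0, 0, 0))
})

test_that("parameter validation enforces invariants and warns on range exits", {
  expect_error(model_parameters(beta2 = -0.1), "nonnegative")
  expect_error(model_parameters(vartheta = 0), "strictly positive")
  expect_error(model_parameters(s2 = 0), "strictly positive")
  expect_warning(model_parameters(g1 = 0.95), "outside the tabulated range")
  expect_warning(model_parameters(delta = 0.05), "outside the tabulated range")
  # sweeps step across the ranges: warning only, object still returned
  p <- suppressWarnings(model_parameters(g1 = 0.95))
  expect_s3_class(p, "crc_params")
  expect_equal(p$g1, 0.95)
})

test_that("origin state isolates the source terms", {
  p <- model_parameters(u1 = 0.2, u2 = 0.4, u3 = 0.5)
  expect_equal(unname(rhs_base(state_vector(), p)), c(0, 0, 0.3, 0.7, 0.2))
  pe <- app3_params()
  expect_equal(unname(rhs_extended(state_vector(), pe)), c(0, 0, 0.3, 0.7, 0.2))
})

test_that("base rates match an independent term-by-term evaluation", {
  p <- model_parameters(g1 = 0.1, g2 = 0.2, g3 = 0.3, g4 = 0.1, delta = 0.15,
                        u1 = 0.2, u2 = 0.4, u3 = 0.5)
  s <- c(T = 10, M = 1, G = 1, C = 1, P = 1)
  # oracle: each kernel written out term by term with explicit arithmetic
  kT <- 0.1 * 10 * (1 - 10 / 1000) - 0.1 * 10 * 1 / (50 + 10) -
    0.3 * 10 * 1 / (50 + 10) - 0.5 * 10
  kM <- 0.2 * 10 / (50 + 10) - 0.5 * 1 - 0.008 * 1
  kG <- 0.3 + 0.3 * 10 / (50 + 10) - 0.4 * 1 - 0.0008 * 1
  kC <- 0.7 + 0.1 * 1 - 0.7 * 1 - 0.0001 * 1 + 0.15 * 1 * 1 / (0.25 + 1) + 0.4 * 1
  kP <- 0.2 - 1 * 1
  expect_equal(unname(rhs_base(s, p)), c(kT, kM, kG, kC, kP), tolerance = 1e-14)
})

test_that("extended rates add exactly the three cross-recruitment terms", {
  pe <- app3_params()
  s <- c(T = 10, M = 1, G = 1, C = 1, P = 1)
  base <- rhs_base(s, pe)
  ext <- rhs_extended(s, pe)
  expect_equal(ext[["T"]], base[["T"]])
  expect_equal(ext[["M"]], base[["M"]] + 0.1 * 1 / (50 + 1), tolerance = 1e-14)
  expect_equal(ext[["G"]],
               base[["G"]] + 0.15 * 1 / (50 + 1) + 0.2 * 1 / (50 + 1),
               tolerance = 1e-14)
  expect_equal(ext[["C"]], base[["C"]])
  expect_equal(ext[["P"]], base[["P"]])
})

test_that("extended model reduces exactly to the base model when g5=g6=g7=0", {
  p <- model_parameters(u1 = 0.2, u2 = 0.4, u3 = 0.5)
  for (s in random_states(100, seed = 11))
    expect_identical(rhs_extended(s, p), rhs_base(s, p))
})

test_that("sigma scaling multiplies the field by sigma^(1-alpha)", {
  p <- model_parameters(u1 = 0.2, u2 = 0.4, u3 = 0.5)
  for (s in random_states(100, seed = 12)) {
    expect_identical(scaled_rhs(s, p, alpha = 1, sigma = 7), rhs_base(s, p))
    expect_identical(scaled_rhs(s, p, alpha = 0.6, sigma = 1), rhs_base(s, p))
    expect_equal(scaled_rhs(s, p, alpha = 0.5, sigma = 2),
                 sqrt(2) * rhs_base(s, p), tolerance = 1e-15)
  }
  expect_equal(unname(scaled_rhs(state_vector(), p, alpha = 0.5, sigma = 2)),
               sqrt(2) * c(0, 0, 0.3, 0.7, 0.2), tolerance = 1e-15)
})

test_that("the tumor-free face is invariant: zero tumor gives zero tumor rate", {
  p <- app1_ii_params()
  set.seed(13)
  for (i in 1:25) {
    s <- state_vector(0, runif(1, 0, 3), runif(1, 0, 3),
                      runif(1, 0, 15), runif(1, 0, 2))
    expect_identical(rhs_base(s, p)[["T"]], 0)
    expect_identical(rhs_extended(s, app3_params())[["T"]], 0)
  }
})

test_that("parameter configs round-trip through the flat key-value format", {
  p <- model_parameters(g2 = 0.6, u1 = 0.3, u2 = 0.2, u3 = 0.01)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_params_config(p, f, alpha = 0.9, sigma = 1)
  cfg <- read_params_config(f)
  expect_identical(unclass(cfg$params), unclass(p))
  expect_identical(cfg$alpha, 0.9)
  expect_identical(cfg$sigma, 1)
  writeLines(c("g1 = 0.1", "bogus = 3"), f)
  expect_error(read_params_config(f), "unknown config keys")
  writeLines(c("g1 = 0.1", "g1: 0.2"), f)
  expect_error(read_params_config(f), "duplicate")
})

test_that("state constructor rejects negative and non-finite components", {
  expect_error(state_vector(-1, 0, 0, 0, 0), "nonnegative")
  expect_error(state_vector(Inf, 0, 0, 0, 0), "finite")
  expect_identical(names(state_vector(1, 2, 3, 4, 5)),
                   c("T", "M", "G", "C", "P"))
})
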