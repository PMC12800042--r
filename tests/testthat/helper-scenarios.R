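# Parameter sets of the published numerical experiments, rebuilt in code so
# every test file can use them without touching the registry.

app1_i_params <- function() {
  model_parameters(g1 = 0.1, g2 = 0.2, g3 = 0.3, g4 = 0.1, delta = 0.15,
                   u1 = 0.2, u2 = 0.4, u3 = 0.5)
}

# coexistence setting: higher macrophage recruitment, low chemotherapy
app1_ii_params <- function() {
  model_parameters(g1 = 0.1, g2 = 0.6, g3 = 0.3, g4 = 0.1, delta = 0.15,
                   u1 = 0.3, u2 = 0.2, u3 = 0.01)
}

app2_i_params <- function() {
  model_parameters(g1 = 0.1, g2 = 0.2, g3 = 0.3, g4 = 0.1, delta = 0.15,
                   u1 = 0.1, u2 = 0.6, u3 = 0.5)
}

app3_params <- function() {
  model_parameters(g1 = 0.1, g2 = 0.2, g3 = 0.3, g4 = 0.1, delta = 0.15,
                   u1 = 0.2, u2 = 0.4, u3 = 0.5,
                   g5 = 0.1, g6 = 0.15, g7 = 0.2)
}

# random nonnegative model states with a spread of magnitudes
random_states <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    state_vector(runif(1, 0, 900), runif(1, 0, 3), runif(1, 0, 3),
                 runif(1, 0, 15), runif(1, 0, 2)))
}

fd_jacobian <- function(params, state, variant = "base") {
  # central finite differences, step scaled to the component magnitude
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    h <- 1e-5 * max(1, abs(state[[j]]))
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (rhs_model(up, params, variant) -
                 rhs_model(dn, params, variant)) / (2 * h)
  }
  J
}

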