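# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once across test files.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

random_mbi <- function(n = 16, seed = 1, spacing = c(1, 1)) {
  set.seed(seed)
  mbi_pair(matrix(runif(n * n, 0, 1.5), n, n),
           matrix(runif(n * n, -0.3, 1.2), n, n), spacing = spacing)
}

# small default-phantom physics simulation shared across tests
small_sim <- function() {
  cached("small_sim", {
    ph <- make_phantom(default_phantom_spec(n_px = 160))
    simulate_series(ph, mode = "physics", seed = 42)
  })
}

small_no_metal_sim <- function() {
  cached("small_no_metal", {
    fx <- default_fixtures(160)
    simulate_series(fx$no_metal$phantom, energies_kev = c(70, 140),
                    mode = "physics", noise = FALSE)
  })
}

interior_mask <- function(phantom, radius_mm = 90) {
  n <- phantom$spec$n_px
  coord <- (seq_len(n) - 0.5) * phantom$spacing_mm[1] - phantom$spec$fov_mm / 2
  outer(coord^2, coord^2, "+") <= radius_mm^2
}
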