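# Shared fixtures: steady-state solves are memoised inside the package
# (whorlpos:::cached_solve), so repeated use across test files is cheap.

solve_cached <- function(params) whorlpos:::cached_solve(params)

table1_solution <- function() solve_cached(model_params())
fig5b_solution <- function() solve_cached(fig5_baseline())

crossing_of <- function(params) {
  suppressWarnings(find_interface(solve_cached(params)))
}

# Pointwise (diffusion-free) steady state of the H/K pair at precursor level
# P: independent brute-force oracle, solved by root finding on H alone.
pointwise_fixed_point <- function(params, P) {
  occ <- P^params$nH / (params$KA^params$nH + P^params$nH)
  g <- function(H) {
    K <- params$prodK / (params$kK * (1 + params$inhK * H))
    params$prodH * occ / (params$kH * (1 + params$inhH * K)) - H
  }
  H <- stats::uniroot(g, c(0, params$prodH / params$kH + 1), tol = 1e-12)$root
  K <- params$prodK / (params$kK * (1 + params$inhK * H))
  list(H = H, K = K)
}

# Minimal hand-built solution object for interface/trough extraction tests.
fake_solution <- function(x, H, K, threshold = 50) {
  p <- model_params(n_grid = max(50, length(x)),
                    domain_length = max(x), trough_threshold = threshold)
  structure(list(params = p, x = x, P = rep(0, length(x)), H = H, K = K,
                 residual = 0, bc = "neumann"),
            class = "whorl_solution")
}
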