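## Shared fixtures, built in code at test time.

erf_ref <- function(x) 2 * pnorm(x * sqrt(2)) - 1

## Unified level-1 model with the crossover-tied prefactor convention.
mk_model <- function(g = 1, rg = 150, p = 2.5, background = 0,
                     q = q_grid_default()) {
  unified_model(G = g, Rg = rg, B = crossover_prefactor(
    g, rg, p, q_cross = sqrt(min(q) * max(q))), P = p,
    background = background)
}

## Independent evaluation of the level-1 unified formula (plain
## arithmetic, no package code beyond erf via pnorm).
unified_ref <- function(q, g, rg, b, p, background = 0) {
  g * exp(-q^2 * rg^2 / 3) +
    b * erf_ref(q * rg / sqrt(6))^(3 * p) * q^(-p) + background
}

## Dilute uniform-sphere profile at a given particle volume fraction.
mk_sphere <- function(radius, drho, phi) {
  layered_sphere(radius, drho, 0, phi / (4 / 3 * pi * radius^3))
}

fit_estimates <- function(fit) setNames(fit$parameters$estimate,
                                        fit$parameters$term)
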