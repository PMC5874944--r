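# Shared fixtures and independent oracles.
#
# The canonical reference field: 1.0 cm holes, 1.8 cm centre-to-centre,
# valley-to-peak 0.22, 1.5 mm penumbra sigma, 0.1 mm sampling.

canonical_geometry <- function() grid_geometry(1.0, 1.8)

canonical_profile <- function(peak_dose) {
  make_single_hole_profile(canonical_geometry(), peak_dose)
}

# printed 3-decimal (truncated) alpha/beta reference values
table1_printed <- data.frame(
  sf2        = c(0.2, 0.4, 0.5, 0.4),
  alpha_beta = c(10, 10, 10, 2.5),
  alpha      = c(0.670, 0.381, 0.288, 0.254),
  beta       = c(0.067, 0.038, 0.028, 0.101)
)

# Independent continuous-integration oracle for the grid survival fraction:
# trapezoid rule on SF(D(r)) * 2r / r_max^2 with survival written out
# directly, bypassing ring_weights()/grid_survival()/sf_lq().
trapz_grid_sf <- function(profile, alpha, beta, n = 20001) {
  r_max <- profile$radii[length(profile$radii)]
  r <- seq(0, r_max, length.out = n)
  d <- approx(profile$radii, profile$doses, xout = r, rule = 2)$y
  f <- exp(-alpha * d - beta * d^2) * 2 * r / r_max^2
  h <- r[2] - r[1]
  h * (sum(f) - (f[1] + f[n]) / 2)
}

# Full TR pipeline oracle built on the integration above and the closed-form
# quadratic EUD, independent of the package's ring-sum implementation.
trapz_tr <- function(profile, tumor, normal) {
  sf_t <- trapz_grid_sf(profile, tumor$alpha, tumor$beta)
  eud <- (-tumor$alpha +
            sqrt(tumor$alpha^2 - 4 * tumor$beta * log(sf_t))) /
    (2 * tumor$beta)
  sf_n_grid <- trapz_grid_sf(profile, normal$alpha, normal$beta)
  sf_n_eud <- exp(-normal$alpha * eud - normal$beta * eud^2)
  sf_n_grid / sf_n_eud
}

# random valid profile generator for property tests (fixed seed set by caller)
random_profile <- function() {
  spacing <- runif(1, 1.4, 2.4)
  hole <- runif(1, 0.4, spacing - 0.5)
  peak <- runif(1, 5, 25)
  model <- profile_model_params(valley_fraction = runif(1, 0.1, 0.6),
                                penumbra_sigma = runif(1, 0.5, 1.5),
                                radial_step = 0.1)
  make_single_hole_profile(grid_geometry(hole, spacing), peak, model)
}
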