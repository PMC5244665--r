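# Shared fixtures: small schemes and voxel-level simulators built in code.

study_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_study_protocol()
    cache
  }
})

full_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- bind_schemes(build_study_protocol(),
                             build_dti_shell(42, 187), build_dti_shell(42, 226))
    }
    cache
  }
})

# observed magnitudes with Rician noise and per-measurement NEX averaging
simulate_voxel_obs <- function(signal, scheme, sigma) {
  vapply(seq_along(signal), function(i) {
    n <- scheme$n_avg[i]
    mean(sqrt((signal[i] + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2))
  }, 0)
}

random_zs_params <- function() {
  list(D1 = stats::runif(1, 0.8, 1.0), D2 = stats::runif(1, 0.4, 0.6),
       theta = acos(stats::runif(1, -1, 1)), phi = stats::runif(1, 0, 2 * pi),
       D_I = stats::runif(1, 0.8, 1.0), R = stats::runif(1, 6, 9),
       f_I = stats::runif(1, 0.35, 0.55), S0 = 1,
       T2 = stats::runif(1, 0.05, 0.09))
}

axis_of <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

axial_angle_deg <- function(n1, n2) {
  acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
}
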