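# A cheap scheme keeps full-length default chains affordable: Ball has only
# three free parameters and the likelihood involves 14 measurements.
tiny_scheme <- function() {
  sch <- study_scheme()
  sub <- sch[c(which(sch$b == 0), which(sch$gx == 1 & sch$delta == 3)[1:10]), ]
  class(sub) <- class(sch)
  attr(sub, "gamma") <- GAMMA_PROTON
  sub
}

test_that("default settings draw 500 retained samples after burn-in and thinning", {
  sch <- tiny_scheme()
  truth <- list(D1 = 1.0, S0 = 1, T2 = 0.08)
  S <- composite_signal("Ball", truth, sch)
  set.seed(8)
  obs <- simulate_voxel_obs(S, sch, 0.01)
  fit <- fit_voxel(obs, sch, "Ball", 0.01, n_starts = 3, seed = 1)
  post <- sample_posterior(obs, sch, "Ball", 0.01, init = fit, seed = 11)
  expect_equal(nrow(post$samples), 500)
  expect_equal(post$settings$burn_in, 5000)
  expect_equal(post$settings$interval, 400)
  expect_gt(post$acceptance_rate, 0)
  expect_lt(post$acceptance_rate, 1)
  # all samples in bounds
  expect_true(all(post$samples$D1 >= 0.01 & post$samples$D1 <= 3))
  expect_true(all(post$samples$T2 >= 0.001 & post$samples$T2 <= 3))
})

test_that("chains are reproducible under a fixed seed", {
  sch <- tiny_scheme()
  truth <- list(D1 = 1.0, S0 = 1, T2 = 0.08)
  S <- composite_signal("Ball", truth, sch)
  set.seed(8)
  obs <- simulate_voxel_obs(S, sch, 0.01)
  fit <- fit_voxel(obs, sch, "Ball", 0.01, n_starts = 2, seed = 1)
  p1 <- sample_posterior(obs, sch, "Ball", 0.01, init = fit, n_samples = 50,
                         burn_in = 200, interval = 20, seed = 3)
  p2 <- sample_posterior(obs, sch, "Ball", 0.01, init = fit, n_samples = 50,
                         burn_in = 200, interval = 20, seed = 3)
  expect_identical(as.matrix(p1$samples), as.matrix(p2$samples))
})

test_that("sampled marginal matches the Laplace approximation on a high-SNR voxel", {
  sch <- tiny_scheme()
  truth <- list(D1 = 1.0, S0 = 1, T2 = 0.08)
  S <- composite_signal("Ball", truth, sch)
  set.seed(9)
  obs <- simulate_voxel_obs(S, sch, 0.005)
  fit <- fit_voxel(obs, sch, "Ball", 0.005, n_starts = 3, seed = 1)
  post <- sample_posterior(obs, sch, "Ball", 0.005, init = fit, seed = 21)
  # independent oracle: numeric Hessian of the log-likelihood at the optimum
  spec <- model_spec("Ball")
  llf <- mcdmri:::make_meas_loglik(sch, 0.005)
  pred <- mcdmri:::make_predictor(spec, sch)
  f0 <- unlist(fit$params)
  h <- 1e-4 * pmax(abs(f0), 1e-3)
  H <- matrix(0, 3, 3)
  llv <- function(p) llf(obs, pred(p))
  for (a in 1:3) for (b in 1:3) {
    pa <- f0; pb <- f0; pab <- f0
    pa[a] <- pa[a] + h[a]; pb[b] <- pb[b] + h[b]
    pab[a] <- pab[a] + h[a]; pab[b] <- pab[b] + h[b]
    H[a, b] <- (llv(pab) - llv(pa) - llv(pb) + llv(f0)) / (h[a] * h[b])
  }
  cov_lap <- solve(-H)
  sd_lap <- sqrt(diag(cov_lap))
  sd_mcmc <- apply(as.matrix(post$samples), 2, sd)
  expect_lt(abs(sd_mcmc[["D1"]] - sd_lap[1]) / sd_lap[1], 0.2)
  # marginal shape: KS against the Laplace normal (approximately Gaussian
  # posterior at this SNR)
  ks <- suppressWarnings(
    ks.test(post$samples$D1, "pnorm", mean = f0[1], sd = sd_lap[1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior histograms summarise chains with degenerate and angular cases", {
  const <- structure(list(
    model = "Ball",
    samples = tibble::tibble(D1 = rep(1.2, 100), S0 = rep(1, 100),
                             T2 = rep(0.08, 100)),
    settings = list(), acceptance_rate = 0.5), class = "posterior_samples")
  h <- posterior_histograms(const, bins = 10)
  d1 <- dplyr::filter(h, term == "D1")
  expect_equal(sum(d1$count > 0), 1)
  expect_equal(unique(d1$sd), 0)
  # antipodal folding maps theta > pi/2 onto the upper hemisphere
  ang <- structure(list(
    model = "Zeppelin",
    samples = tibble::tibble(theta = c(rep(0.4, 50), rep(pi - 0.4, 50)),
                             phi = c(rep(1, 50), rep(1 + pi, 50))),
    settings = list(), acceptance_rate = 0.5), class = "posterior_samples")
  h2 <- posterior_histograms(ang)
  th <- dplyr::filter(h2, term == "theta")
  expect_lt(th$mean[1], pi / 2)
  expect_equal(unique(th$sd), 0, tolerance = 1e-12)
})

test_that("lower intracellular fractions widen D_I but narrow orientation posteriors", {
  sch <- full_scheme()
  spec <- model_spec("Zeppelin-Sphere")
  base <- list(D1 = 1.0, D2 = 0.4, theta = 1.2, phi = 0.8, D_I = 0.9, R = 7.5,
               f_I = 0.5, S0 = 1, T2 = 0.07)
  lo <- base; lo$f_I <- 0.15
  run <- function(pars, seed) {
    S <- composite_signal(spec, pars, sch)
    set.seed(seed)
    obs <- simulate_voxel_obs(S, sch, 0.01)
    fit <- fit_voxel(obs, sch, spec, 0.01, n_starts = 6, seed = 1)
    sample_posterior(obs, sch, spec, 0.01, init = fit, n_samples = 250,
                     burn_in = 1000, interval = 40, seed = seed)
  }
  hi_post <- run(base, 41)
  lo_post <- run(lo, 42)
  sd_hi <- apply(as.matrix(hi_post$samples), 2, sd)
  sd_lo <- apply(as.matrix(lo_post$samples), 2, sd)
  expect_gt(sd_lo[["D_I"]], sd_hi[["D_I"]])
  # orientation dispersion on the axis itself (angle to the mean axis),
  # immune to angular wrap-around
  ax_disp <- function(post) {
    n <- cbind(sin(post$samples$theta) * cos(post$samples$phi),
               sin(post$samples$theta) * sin(post$samples$phi),
               cos(post$samples$theta))
    nbar <- colMeans(n * sign(n[, 3] + 1e-12))
    nbar <- nbar / sqrt(sum(nbar^2))
    mean(acos(pmin(1, abs(n %*% nbar))))
  }
  expect_lt(ax_disp(lo_post), ax_disp(hi_post))
})

test_that("posterior persistence writes CSV plus JSON settings sidecar", {
  p <- withr::local_tempfile(fileext = ".csv")
  post <- structure(list(
    model = "Ball",
    samples = tibble::tibble(D1 = 1:3 / 2, S0 = rep(1, 3), T2 = rep(0.1, 3)),
    settings = list(burn_in = 10, interval = 2, n_samples = 3,
                    proposal_frac = 0.01,
                    proposal_sd = c(D1 = 0.01, S0 = 0.01, T2 = 0.001),
                    seed = 1),
    acceptance_rate = 0.4), class = "posterior_samples")
  write_posterior(post, p)
  back <- read.csv(p)
  expect_equal(back$D1, c(0.5, 1, 1.5))
  side <- jsonlite::read_json(paste0(p, ".settings.json"))
  expect_equal(side$model, "Ball")
  expect_equal(side$burn_in, 10)
})
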