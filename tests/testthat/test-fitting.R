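test_that("noiseless mono-exponential data are recovered essentially exactly", {
  sch <- study_scheme()
  truth <- list(D1 = 0.8, S0 = 1, T2 = 0.08)
  S <- composite_signal("Ball", truth, sch)
  fit <- fit_voxel(S, sch, "Ball", noise = 1e-6, n_starts = 3, seed = 1)
  expect_lt(abs(fit$params$D1 - 0.8) / 0.8, 1e-5)
  expect_lt(abs(fit$params$T2 - 0.08) / 0.08, 1e-4)
  expect_lt(abs(fit$params$S0 - 1), 1e-4)
  expect_true(fit$converged)
  expect_true(is.finite(fit$lnL))
})

test_that("fits are reproducible under a fixed seed", {
  sch <- study_scheme()
  truth <- list(D1 = 1.0, D_I = 0.8, f_I = 0.4, S0 = 1, T2 = 0.07)
  S <- composite_signal("Ball-Ball", truth, sch)
  set.seed(5)
  obs <- simulate_voxel_obs(S, sch, 0.02)
  f1 <- fit_voxel(obs, sch, "Ball-Ball", 0.02, n_starts = 5, seed = 99)
  f2 <- fit_voxel(obs, sch, "Ball-Ball", 0.02, n_starts = 5, seed = 99)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$lnL, f2$lnL)
})

test_that("fit_voxel validates inputs and degrades gracefully", {
  sch <- study_scheme()
  expect_error(fit_voxel(rep(1, 5), sch, "Ball", 0.01), "does not match")
  expect_error(fit_voxel(rep(1, nrow(sch)), sch, "Ball", 0.01, n_starts = 0),
               "n_starts")
  expect_error(fit_voxel(rep(1, nrow(sch)), sch, "Ball", -1), "noise")
})

test_that("nested super-models never fall below their sub-models in lnL", {
  sch <- study_scheme()
  spec <- model_spec("Zeppelin-Sphere")
  set.seed(21)
  truth <- random_zs_params()
  S <- composite_signal(spec, truth, sch)
  obs <- simulate_voxel_obs(S, sch, 0.02)
  fits <- list()
  for (m in model_names()) {
    # warm-start each model from the already-fitted sub-models, as the
    # multi-start search does along the nesting chain
    warm <- lapply(fits, function(f) f$params)
    fits[[m]] <- fit_voxel(obs, sch, m, 0.02, n_starts = 6, seed = 7,
                           extra_starts = warm)
  }
  lnL <- vapply(fits, `[[`, 0, "lnL")
  nests <- list(c("Ball", "Zeppelin"), c("Zeppelin", "Tensor"),
                c("Ball-Ball", "Zeppelin-Ball"), c("Zeppelin-Ball", "Tensor-Ball"),
                c("Ball-Sphere", "Zeppelin-Sphere"),
                c("Zeppelin-Sphere", "Tensor-Sphere"),
                c("Ball", "Ball-Ball"), c("Zeppelin", "Zeppelin-Ball"))
  for (p in nests) {
    expect_gte(lnL[[p[2]]], lnL[[p[1]]] - 1e-6)
  }
})

test_that("Rician ML agrees with least squares in the Gaussian regime", {
  sch <- study_scheme()
  truth <- list(D1 = 0.9, S0 = 1, T2 = 0.08)
  S <- composite_signal("Ball", truth, sch)
  set.seed(31)
  obs <- simulate_voxel_obs(S, sch, 0.005)   # SNR 200 at b = 0
  ml <- fit_voxel(obs, sch, "Ball", 0.005, n_starts = 4, seed = 3)
  # independent least-squares route
  pred <- function(p) p[2] * exp(-sch$TE * 1e-3 / p[3]) * exp(-sch$b * p[1] * 1e-3)
  ls <- optim(c(0.5, max(obs), 0.1), function(p) sum((obs - pred(p))^2),
              method = "L-BFGS-B", lower = c(0.01, 1e-6, 1e-3),
              upper = c(3, 10, 3))
  for (i in seq_along(ml$params)) {
    expect_lt(abs(unlist(ml$params)[i] - ls$par[i]) / abs(ls$par[i]), 0.01)
  }
})

test_that("R pins at the 20 um bound when intracellular diffusion is unrestricted", {
  sch <- study_scheme()
  # mucinous-like voxel: free isotropic diffusion only; a fitted Sphere
  # compartment can only mimic it by running R to the bound
  truth <- list(D1 = 1.5, S0 = 1, T2 = 0.2)
  S <- composite_signal("Ball", truth, sch)
  set.seed(13)
  obs <- simulate_voxel_obs(S, sch, 0.02)
  fit <- fit_voxel(obs, sch, "Ball-Sphere", 0.02, n_starts = 6, seed = 2)
  expect_true(fit$params$R > 19 || fit$params$f_I < 0.05)
})

test_that("tidy and glance produce the expected broom-style surfaces", {
  sch <- study_scheme()
  truth <- list(D1 = 0.8, S0 = 1, T2 = 0.08)
  S <- composite_signal("Ball", truth, sch)
  fit <- fit_voxel(S, sch, "Ball", noise = 1e-4, n_starts = 2, seed = 1)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("D1", "S0", "T2"))
  gl <- generics::glance(fit)
  expect_equal(gl$k, 3)
  expect_equal(gl$n, nrow(sch))
  expect_equal(gl$AIC, -2 * gl$lnL + 2 * 3)
  expect_equal(gl$BIC, -2 * gl$lnL + 3 * log(nrow(sch)))
})

test_that("fit_volume returns a tidy per-voxel table across models", {
  sch <- study_scheme()
  dim3 <- c(2, 1, 1)
  vol <- array(0, c(dim3, nrow(sch)))
  truth <- list(D1 = 1.1, S0 = 1, T2 = 0.09)
  S <- composite_signal("Ball", truth, sch)
  set.seed(2)
  vol[1, 1, 1, ] <- simulate_voxel_obs(S, sch, 0.01)
  vol[2, 1, 1, ] <- simulate_voxel_obs(S, sch, 0.01)
  fits <- fit_volume(vol, sch, models = c("Ball", "Ball-Ball"), noise = 0.01,
                     n_starts = 2, seed = 4)
  expect_equal(nrow(fits), 4)
  expect_setequal(unique(fits$model), c("Ball", "Ball-Ball"))
  expect_true(all(is.finite(fits$lnL)))
  expect_true(all(abs(fits$D1[fits$model == "Ball"] - 1.1) < 0.1))
})
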