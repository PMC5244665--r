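test_that("model registry reproduces the published free-parameter counts", {
  k_expected <- c("Ball" = 3, "Zeppelin" = 6, "Tensor" = 8,
                  "Ball-Ball" = 5, "Zeppelin-Ball" = 8, "Tensor-Ball" = 10,
                  "Ball-Sphere" = 6, "Zeppelin-Sphere" = 9, "Tensor-Sphere" = 11)
  for (nm in names(k_expected)) {
    spec <- model_spec(nm)
    expect_equal(spec$k, unname(k_expected[nm]), info = nm)
    expect_equal(length(spec$free_params), spec$k)
  }
  one_comp <- c("Ball", "Zeppelin", "Tensor")
  for (nm in one_comp) expect_false("f_I" %in% model_spec(nm)$free_params)
})

test_that("registry accepts en-dash and squashed aliases", {
  expect_equal(model_spec("Ball–Sphere")$name, "Ball-Sphere")
  expect_equal(model_spec("ZeppelinSphere")$name, "Zeppelin-Sphere")
  expect_equal(model_spec("Ball (ADC)")$name, "Ball")
  expect_error(model_spec("Cylinder"), "unknown model")
})

test_that("ball attenuation follows exp(-bD)", {
  expect_equal(ball_signal(0, 2), 1)
  expect_equal(ball_signal(1000, 1), exp(-1))
  expect_equal(ball_signal(928, 0.6), exp(-928 * 0.6e-3), tolerance = 1e-14)
  expect_error(ball_signal(-5, 1), "non-negative")
})

fake_meas <- function(g, b) {
  tibble::tibble(gx = g[1], gy = g[2], gz = g[3], G = 100, delta = 3,
                 Delta = 30, TE = 45, n_avg = 1, b = b)
}

test_that("zeppelin reduces correctly parallel, perpendicular, and isotropic", {
  n <- c(sin(0.9) * cos(0.4), sin(0.9) * sin(0.4), cos(0.9))
  perp <- c(-sin(0.4), cos(0.4), 0)
  expect_equal(zeppelin_signal(fake_meas(n, 1000), 1.5, 0.5, 0.9, 0.4),
               exp(-1.5), tolerance = 1e-12)
  expect_equal(zeppelin_signal(fake_meas(perp, 1000), 1.5, 0.5, 0.9, 0.4),
               exp(-0.5), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    g <- rnorm(3); g <- g / sqrt(sum(g^2))
    b <- runif(1, 0, 5000)
    expect_equal(zeppelin_signal(fake_meas(g, b), 1.1, 1.1, 0.7, 0.2),
                 ball_signal(b, 1.1), tolerance = 1e-14)
  }
})

test_that("tensor matches an explicit rotation-matrix oracle and its degeneracies", {
  set.seed(7)
  for (i in 1:25) {
    g <- rnorm(3); g <- g / sqrt(sum(g^2))
    b <- runif(1, 0, 8000)
    th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi); al <- runif(1, 0, pi)
    D <- sort(runif(3, 0.1, 2.5), decreasing = TRUE)
    # oracle: build D explicitly from basis vectors
    nv <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    et <- c(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th))
    nxe <- c(nv[2] * et[3] - nv[3] * et[2], nv[3] * et[1] - nv[1] * et[3],
             nv[1] * et[2] - nv[2] * et[1])
    m2 <- cos(al) * et + sin(al) * nxe
    m3 <- c(nv[2] * m2[3] - nv[3] * m2[2], nv[3] * m2[1] - nv[1] * m2[3],
            nv[1] * m2[2] - nv[2] * m2[1])
    Dm <- D[1] * outer(nv, nv) + D[2] * outer(m2, m2) + D[3] * outer(m3, m3)
    oracle <- exp(-b * as.numeric(t(g) %*% Dm %*% g) * 1e-3)
    expect_equal(tensor_signal(fake_meas(g, b), D[1], D[2], D[3], th, ph, al),
                 oracle, tolerance = 1e-12)
    # cylindrical symmetry: D3 = D2 reduces to zeppelin independent of alpha
    expect_equal(tensor_signal(fake_meas(g, b), D[1], D[2], D[2], th, ph, al),
                 zeppelin_signal(fake_meas(g, b), D[1], D[2], th, ph),
                 tolerance = 1e-12)
    # isotropy
    expect_equal(tensor_signal(fake_meas(g, b), D[2], D[2], D[2], th, ph, al),
                 ball_signal(b, D[2]), tolerance = 1e-12)
  }
})

test_that("nested models agree exactly at degenerate parameter points", {
  set.seed(11)
  sch <- study_scheme()[sample(nrow(study_scheme()), 100), ]
  base <- list(D1 = 1.2, D2 = 1.2, D3 = 1.2, theta = 0.8, phi = 2.1,
               alpha = 0.5, D_I = 0.8, R = 8, f_I = 0.4, S0 = 1, T2 = 0.08)
  s_ball <- composite_signal("Ball", base[model_spec("Ball")$free_params], sch)
  s_zep <- composite_signal("Zeppelin", base[model_spec("Zeppelin")$free_params], sch)
  s_ten <- composite_signal("Tensor", base[model_spec("Tensor")$free_params], sch)
  expect_equal(s_zep, s_ball, tolerance = 1e-12)
  expect_equal(s_ten, s_ball, tolerance = 1e-12)
  # two-compartment chain at f_I = 0.4 with degenerate extracellular shapes
  bb <- composite_signal("Ball-Ball", base[model_spec("Ball-Ball")$free_params], sch)
  zb <- composite_signal("Zeppelin-Ball", base[model_spec("Zeppelin-Ball")$free_params], sch)
  tb <- composite_signal("Tensor-Ball", base[model_spec("Tensor-Ball")$free_params], sch)
  expect_equal(zb, bb, tolerance = 1e-12)
  expect_equal(tb, bb, tolerance = 1e-12)
})

test_that("sphere attenuation satisfies its physical limits", {
  sch <- study_scheme()
  s <- sphere_signal(sch, 1, 0.1)
  expect_true(all(s >= 0.999))                    # fully restricted tiny sphere
  expect_true(all(s <= 1 + 1e-12))
  expect_equal(sphere_signal(sch[sch$G == 0, ], 1, 8), rep(1, 4))
  # R at the upper bound approaches free diffusion for short timings; the
  # agreement is quantitative at low attenuation (wall effects grow with b:
  # at b ~ 930 the genuinely restricted signal sits ~14% above free, which
  # the Monte-Carlo walker confirms), and the approach is monotone in R
  short <- dplyr::filter(sch, delta == 3, Delta == 10, b > 0, b <= 100)
  expect_lt(max(abs(sphere_signal(short, 1, 20) / ball_signal(short$b, 1) - 1)),
            0.02)
  strong <- dplyr::filter(sch, delta == 3, Delta == 10, G == 400)[1, ]
  free <- ball_signal(strong$b, 1)
  gap <- vapply(c(10, 15, 20), function(R) sphere_signal(strong, 1, R) - free, 0)
  expect_true(all(diff(gap) < 0))
  expect_true(all(gap > 0))
  s8 <- sphere_signal(sch, 1, 8)
  expect_true(all(s8 > 0 & s8 <= 1))
})

test_that("composite signal obeys its algebraic identities", {
  sch <- study_scheme()
  spec <- model_spec("Zeppelin-Sphere")
  pars <- list(D1 = 1.2, D2 = 0.6, theta = 0.9, phi = 1.4, D_I = 0.9, R = 6.4,
               f_I = 0.44, S0 = 2.5, T2 = 0.08)
  s <- composite_signal(spec, pars, sch)
  expect_true(all(s <= pars$S0 + 1e-12))
  # f_I = 0 collapses to the extracellular shape
  p0 <- pars; p0$f_I <- 0
  zep_only <- pars[c("D1", "D2", "theta", "phi", "S0", "T2")]
  expect_equal(composite_signal(spec, p0, sch),
               composite_signal("Zeppelin", zep_only, sch), tolerance = 1e-12)
  # b = 0 TE ratio across blocks is a pure T2 decay
  b0 <- sch[sch$b == 0, ]
  s0 <- composite_signal(spec, pars, b0)
  i95 <- which(b0$TE == 95); i18 <- which(b0$TE == 18)
  expect_equal(s0[i95] / s0[i18], exp(-0.077 / pars$T2), tolerance = 1e-12)
  # monotone non-increasing in G within each (delta, Delta) block
  att <- composite_signal(spec, pars, sch)
  df <- dplyr::mutate(tibble::as_tibble(sch), s = att)
  df <- dplyr::filter(df, gx == 1 | G == 0)
  for (key in split(df, paste(df$delta, df$Delta))) {
    ord <- order(key$G)
    expect_true(all(diff(key$s[ord]) <= 1e-12))
  }
})

test_that("composite signal rejects out-of-bounds parameters by name", {
  sch <- study_scheme()[1:5, ]
  pars <- list(D1 = 1.2, D2 = 0.6, theta = 0.9, phi = 1.4, D_I = 0.9, R = 30,
               f_I = 0.44, S0 = 1, T2 = 0.08)
  expect_error(composite_signal("Zeppelin-Sphere", pars, sch), "'R'")
  pars$R <- 8; pars$D2 <- 1.5
  expect_error(composite_signal("Zeppelin-Sphere", pars, sch), "D1 >= D2")
  pars$D2 <- 0.6; pars$T2 <- NULL
  expect_error(composite_signal("Zeppelin-Sphere", pars, sch), "missing")
})
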