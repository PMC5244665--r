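local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  if (has_seed) {
    fn <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    fn <- function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
  do.call(on.exit, list(substitute(fn(), list(fn = fn)), add = TRUE),
          envir = parent.frame())
  invisible(NULL)
}

noise_sigma <- function(noise) {
  if (inherits(noise, "noise_estimate")) noise$sigma
  else if (is.numeric(noise) && length(noise) == 1 && noise > 0) noise
  else stop("noise must be a noise_estimate or a positive scalar", call. = FALSE)
}

# Moore-Penrose pseudoinverse solve (orientation init can be rank-deficient
# when only three gradient directions are available)
pinv_solve <- function(X, y) {
  s <- svd(X)
  keep <- s$d > max(s$d) * 1e-10
  s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep])
}

# Least-squares cascade: log-linear Ball fit for S0/T2/D, then a linear
# diffusion-tensor fit for orientation and eigenvalue seeds.
init_cascade <- function(data, scheme) {
  eps <- max(data) * 1e-9 + 1e-300
  ylog <- log(pmax(data, eps))
  b0 <- scheme$b == 0
  init <- list(S0 = max(data), T2 = 0.1, D1 = 0.8, D2 = 0.6, D3 = 0.5,
               theta = pi / 2, phi = 0, alpha = 0, D_I = 0.7, R = 8, f_I = 0.4)
  # T2 and S0 from the b = 0 measurements across TE blocks
  if (sum(b0) >= 2 && length(unique(scheme$TE[b0])) >= 2) {
    fit <- stats::lm.fit(cbind(1, scheme$TE[b0] * 1e-3), ylog[b0])
    slope <- fit$coefficients[2]
    if (is.finite(slope) && slope < -1e-9) {
      init$T2 <- min(max(-1 / slope, 0.0011), 2.9)
    }
    init$S0 <- exp(fit$coefficients[1])
  } else if (any(b0)) {
    init$S0 <- mean(data[b0]) * exp((min(scheme$TE) * 1e-3) / init$T2)
  }
  # low-b log-linear fit for a mean diffusivity seed (per-TE intercepts)
  low <- scheme$b > 0 & scheme$b <= 2500
  if (sum(low) >= 4) {
    Xte <- 1 * outer(scheme$TE[low], unique(scheme$TE[low]), "==")
    co <- tryCatch(stats::lm.fit(cbind(Xte, -scheme$b[low] * 1e-3), ylog[low])$coefficients,
                   error = function(e) NULL)
    if (!is.null(co)) {
      D <- co[length(co)]
      if (is.finite(D)) init$D1 <- min(max(D, 0.02), 2.9)
    }
    # linear DT fit for orientation (pseudoinverse; tolerant of 3-direction data)
    g <- cbind(scheme$gx, scheme$gy, scheme$gz)[low, , drop = FALSE]
    bb <- scheme$b[low] * 1e-3
    Xdt <- cbind(Xte, -bb * g[, 1]^2, -bb * g[, 2]^2, -bb * g[, 3]^2,
                 -2 * bb * g[, 1] * g[, 2], -2 * bb * g[, 1] * g[, 3],
                 -2 * bb * g[, 2] * g[, 3])
    co <- tryCatch(pinv_solve(Xdt, ylog[low]), error = function(e) NULL)
    if (!is.null(co)) {
      d <- co[(length(co) - 5):length(co)]
      Dm <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
      ev <- eigen(Dm, symmetric = TRUE)
      lam <- pmin(pmax(ev$values, 0.02), 2.9)
      if (all(is.finite(lam))) {
        init$D1 <- lam[1]; init$D2 <- lam[2]; init$D3 <- lam[3]
        n1 <- ev$vectors[, 1]
        fo <- fold_orientation(acos(max(-1, min(1, n1[3]))), atan2(n1[2], n1[1]))
        init$theta <- fo$theta; init$phi <- fo$phi
        # alpha from the secondary eigenvector
        e_theta <- c(cos(init$theta) * cos(init$phi),
                     cos(init$theta) * sin(init$phi), -sin(init$theta))
        n <- axis_from_angles(init$theta, init$phi)
        nxe <- c(n[2] * e_theta[3] - n[3] * e_theta[2],
                 n[3] * e_theta[1] - n[1] * e_theta[3],
                 n[1] * e_theta[2] - n[2] * e_theta[1])
        v2 <- ev$vectors[, 2]
        init$alpha <- fold_angle(atan2(sum(v2 * nxe), sum(v2 * e_theta)), pi)
      }
    }
  }
  init$D_I <- min(max(0.8 * init$D1, 0.02), 2.9)
  init
}

clamp_to_bounds <- function(par, lower, upper) pmin(pmax(par, lower), upper)

# Embed a (possibly nested sub-model) parameter set as a start for `pars`:
# absent shape parameters take their degenerate values (D2 = D1, D3 = D2,
# alpha = 0) and an absent intracellular compartment enters with f_I = 0, so
# the start reproduces the sub-model signal exactly.
complete_nested_start <- function(es, pars, fallback) {
  es <- as.list(es)
  out <- numeric(length(pars))
  for (i in seq_along(pars)) {
    p <- pars[i]
    v <- es[[p]]
    if (is.null(v) || !is.finite(v)) {
      v <- switch(p,
        D2 = es$D1, D3 = if (!is.null(es$D2)) es$D2 else es$D1,
        alpha = 0, theta = fallback[[match("theta", pars)]],
        phi = fallback[[match("phi", pars)]],
        f_I = 0, D_I = es$D1, R = 8,
        NULL)
    }
    if (is.null(v) || !is.finite(v)) v <- fallback[i]
    out[i] <- v
  }
  out
}

#' Fit a compartment model to one voxel by Rician maximum likelihood
#'
#' Box-constrained maximisation of the Rician log-likelihood over the model's
#' free parameters, using multi-start local optimisation: one start from a
#' least-squares Ball / diffusion-tensor cascade initialisation and the
#' remainder drawn uniformly within bounds from the seeded generator. The
#' extracellular fraction is eliminated via f_E = 1 - f_I. Per-measurement
#' noise is scaled by 1/sqrt(n_avg) for averaged images.
#'
#' @param data Observed magnitude signal per measurement.
#' @param scheme An `acq_scheme` of the same length.
#' @param spec A `model_spec` or model name.
#' @param noise A `noise_estimate` or positive scalar sigma.
#' @param n_starts Number of optimisation starts (>= 1).
#' @param seed Integer seed for the random starts (NULL leaves the RNG alone).
#' @param maxit Maximum iterations for the polishing searches.
#' @param explore_maxit Iteration cap for the cheap exploration pass over all
#'   starts; the best `refine_top` finishers are then polished at `maxit`.
#' @param refine_top Number of exploration results to polish.
#' @param extra_starts Optional list of named parameter vectors appended as
#'   additional warm starts (e.g. a nested sub-model's solution).
#' @return A `voxel_fit` list: `model`, `params` (named list), `lnL`, `n`,
#'   `converged`, `n_starts`, `rng_seed`, `sigma`.
#' @export
fit_voxel <- function(data, scheme, spec, noise, n_starts = 10L, seed = NULL,
                      maxit = 300L, explore_maxit = 300L, refine_top = 3L,
                      extra_starts = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (length(data) != nrow(scheme)) {
    stop("data length (", length(data), ") does not match scheme length (",
         nrow(scheme), ")", call. = FALSE)
  }
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  sigma0 <- noise_sigma(noise)
  ll_fun <- make_meas_loglik(scheme, sigma0)
  pred <- make_predictor(spec, scheme)
  pars <- spec$free_params
  lower <- vapply(spec$bounds, `[`, 0, 1)
  upper <- vapply(spec$bounds, `[`, 0, 2)
  smax <- max(data)
  if ("S0" %in% pars) {
    lower[["S0"]] <- smax * 1e-6
    upper[["S0"]] <- smax * 10
  }
  obj <- function(par) {
    ll <- ll_fun(data, pred(par))
    if (!is.finite(ll)) 1e10 else -ll
  }
  init <- init_cascade(data, scheme)
  init$S0 <- min(max(init$S0, lower[["S0"]]), upper[["S0"]])
  start1 <- clamp_to_bounds(unlist(init[pars]), lower, upper)

  local_seed(seed)
  starts <- list(start1)
  # structured starts walk the weakly identified (f_I, R) ridge from the
  # cascade base before falling back to uniform random draws
  if ("f_I" %in% pars) {
    grid <- if ("R" %in% pars) {
      expand.grid(f_I = c(0.2, 0.45, 0.7), R = c(5, 8, 12))
    } else {
      data.frame(f_I = c(0.15, 0.3, 0.45, 0.6, 0.75))
    }
    for (gi in seq_len(nrow(grid))) {
      if (length(starts) >= n_starts) break
      s <- start1
      s[match("f_I", pars)] <- grid$f_I[gi]
      if ("R" %in% pars) s[match("R", pars)] <- grid$R[gi]
      starts[[length(starts) + 1]] <- s
    }
  }
  while (length(starts) < n_starts) {
    s <- lower + stats::runif(length(pars)) * (upper - lower)
    if ("S0" %in% pars) {
      s[match("S0", pars)] <- smax * stats::runif(1, 0.5, 2)
    }
    starts[[length(starts) + 1]] <- clamp_to_bounds(s, lower, upper)
  }
  for (es in extra_starts) {
    es <- complete_nested_start(es, pars, start1)
    if (!is.null(es)) starts[[length(starts) + 1]] <- clamp_to_bounds(es, lower, upper)
  }
  run_opt <- function(s, it) {
    tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = it, factr = 1e8)),
      error = function(e) NULL)
  }
  # exploration pass over all starts, then polish the best finishers
  explored <- Filter(Negate(is.null),
                     lapply(starts, run_opt, it = min(explore_maxit, maxit)))
  best <- NULL
  any_conv <- FALSE
  if (length(explored)) {
    ord <- order(vapply(explored, `[[`, 0, "value"))
    top <- explored[ord[seq_len(min(refine_top, length(explored)))]]
    for (e in top) {
      res <- run_opt(e$par, maxit)
      if (is.null(res)) res <- e
      if (is.null(best) || res$value < best$value) best <- res
      if (res$convergence == 0) any_conv <- TRUE
    }
    if (!any_conv && !is.null(best)) {
      # iteration-capped finishes still count as converged when a
      # continuation no longer improves the objective
      cont <- run_opt(best$par, 100L)
      if (!is.null(cont)) {
        if (cont$value <= best$value &&
            best$value - cont$value < 1e-6 * (1 + abs(best$value))) {
          any_conv <- TRUE
        }
        if (cont$value < best$value) best <- cont
      }
    }
  }
  if (is.null(best)) {
    params <- as.list(start1)
    return(structure(list(model = spec$name, params = params, lnL = NA_real_,
                          n = nrow(scheme), converged = FALSE,
                          n_starts = n_starts, rng_seed = seed, sigma = sigma0),
                     class = "voxel_fit"))
  }
  params <- as.list(best$par)
  names(params) <- pars
  for (a in intersect(c("theta", "phi", "alpha"), pars)) {
    # report angles on their fundamental domain
    if (a == "phi") params$phi <- fold_angle(params$phi, 2 * pi)
    if (a == "alpha") params$alpha <- fold_angle(params$alpha, pi)
  }
  structure(list(model = spec$name, params = params, lnL = -best$value,
                 n = nrow(scheme), converged = any_conv, n_starts = n_starts,
                 rng_seed = seed, sigma = sigma0),
            class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("<%s fit: lnL = %.3f over n = %d measurements (%s)>\n",
              x$model, x$lnL, x$n,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  print(unlist(x$params))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a voxel fit into one row per parameter
#' @param x A `voxel_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.voxel_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unlist(x$params))
}

#' One-row model-level summary of a voxel fit
#' @param x A `voxel_fit`.
#' @param ... Unused.
#' @return A tibble with model name, lnL, k, n, AIC, BIC, convergence.
#' @export
glance.voxel_fit <- function(x, ...) {
  k <- model_spec(x$model)$k
  tibble::tibble(model = x$model, lnL = x$lnL, k = k, n = x$n,
                 AIC = aic(x$lnL, k), BIC = bic(x$lnL, k, x$n),
                 converged = x$converged)
}

fit_params_row <- function(fit) {
  all_pars <- names(default_bounds())
  vals <- stats::setNames(rep(NA_real_, length(all_pars)), all_pars)
  vals[names(fit$params)] <- unlist(fit$params)
  tibble::as_tibble(as.list(vals))
}

#' Fit one or more models across voxels of a 4-D volume
#'
#' Applies [fit_voxel()] over every in-mask voxel and model, returning a tidy
#' per-voxel table suitable for [select_models()].
#'
#' @param data_4d 4-D array (x, y, z, measurement).
#' @param scheme An `acq_scheme` matching the 4th dimension.
#' @param models Character vector of model names.
#' @param noise A `noise_estimate` or scalar sigma.
#' @param mask Logical/integer 3-D array of voxels to fit (default: all).
#' @param n_starts,seed,maxit Passed to [fit_voxel()]; per-voxel seeds are
#'   derived from `seed` so fits are independent and reproducible.
#' @param progress Print a progress line every 200 voxels.
#' @return A tibble with voxel indices `i, j, k_idx`, `model`, `lnL`, `k`,
#'   `n`, `converged` and one column per model parameter.
#' @export
fit_volume <- function(data_4d, scheme, models = model_names(), noise,
                       mask = NULL, n_starts = 10L, seed = 1L, maxit = 300L,
                       progress = FALSE) {
  dm <- dim(data_4d)
  if (length(dm) != 4 || dm[4] != nrow(scheme)) {
    stop("data_4d must be 4-D with 4th dimension matching the scheme (",
         nrow(scheme), ")", call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  vox <- which(mask != 0, arr.ind = TRUE)
  models <- vapply(models, normalise_model_name, "")
  out <- vector("list", nrow(vox) * length(models))
  cnt <- 0L
  for (v in seq_len(nrow(vox))) {
    i <- vox[v, 1]; j <- vox[v, 2]; k3 <- vox[v, 3]
    sig_v <- data_4d[i, j, k3, ]
    for (m in models) {
      cnt <- cnt + 1L
      vseed <- if (is.null(seed)) NULL else
        (seed + 7919L * v + 104729L * match(m, models)) %% .Machine$integer.max
      fit <- fit_voxel(sig_v, scheme, m, noise, n_starts = n_starts,
                       seed = vseed, maxit = maxit)
      out[[cnt]] <- dplyr::bind_cols(
        tibble::tibble(i = i, j = j, k_idx = k3, model = m,
                       lnL = fit$lnL, k = model_spec(m)$k, n = fit$n,
                       converged = fit$converged),
        fit_params_row(fit))
    }
    if (progress && v %% 200L == 0L) {
      message("fit_volume: ", v, " / ", nrow(vox), " voxels")
    }
  }
  dplyr::bind_rows(out)
}
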