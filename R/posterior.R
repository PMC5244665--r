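#' Metropolis-Hastings posterior sampling around a voxel fit
#'
#' Characterises per-voxel parameter uncertainty by sampling the Rician-noise
#' posterior with a Metropolis-Hastings chain started at the optimised
#' (maximum-likelihood) parameter values. Proposals are independent Gaussians
#' per parameter with standard deviation equal to 1% of the initial estimate
#' (floored at 1e-3 of the bound width for near-zero parameters); the prior is
#' flat on the parameter bound box, so out-of-bounds proposals are rejected.
#' Defaults follow the study settings: burn-in 5000 iterations, sampling
#' interval (thinning) 400, and 500 retained samples.
#'
#' @param data Observed magnitude signal per measurement.
#' @param scheme An `acq_scheme`.
#' @param spec A `model_spec` or model name.
#' @param noise A `noise_estimate` or scalar sigma.
#' @param init Named initial parameter values (normally `fit$params`), or a
#'   `voxel_fit`.
#' @param n_samples Retained samples.
#' @param burn_in Burn-in iterations.
#' @param interval Thinning interval between retained samples.
#' @param proposal_frac Proposal SD as a fraction of the initial estimate.
#' @param seed Integer RNG seed.
#' @return A `posterior_samples` object: `samples` (n_samples x k tibble),
#'   `model`, `settings`, `acceptance_rate`.
#' @export
sample_posterior <- function(data, scheme, spec, noise, init,
                             n_samples = 500L, burn_in = 5000L,
                             interval = 400L, proposal_frac = 0.01,
                             seed = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (inherits(init, "voxel_fit")) init <- init$params
  init <- validate_params(spec, init)
  sigma0 <- noise_sigma(noise)
  ll_fun <- make_meas_loglik(scheme, sigma0)
  pred <- make_predictor(spec, scheme)
  pars <- spec$free_params
  lower <- vapply(spec$bounds, `[`, 0, 1)
  upper <- vapply(spec$bounds, `[`, 0, 2)
  if ("S0" %in% pars) upper[["S0"]] <- max(max(data) * 10, init$S0 * 10)
  width <- upper - lower
  x <- unlist(init[pars])
  prop_sd <- pmax(proposal_frac * abs(x), 1e-3 * width)
  loglik <- function(par) {
    ll <- ll_fun(data, pred(par))
    if (is.finite(ll)) ll else -Inf
  }
  local_seed(seed)
  ll_cur <- loglik(x)
  total <- burn_in + n_samples * interval
  keep <- matrix(NA_real_, n_samples, length(pars))
  n_acc <- 0L; kept <- 0L
  acc_burn <- 0L
  np <- length(pars)
  # random-scan Metropolis: one randomly chosen parameter per iteration
  # (a joint update of all parameters with these proposal widths stalls when
  # some posteriors are much narrower than 1% of the estimate)
  which_par <- sample.int(np, total, replace = TRUE)
  for (it in seq_len(total)) {
    j <- which_par[it]
    prop <- x
    prop[j] <- x[j] + stats::rnorm(1) * prop_sd[j]
    if (prop[j] >= lower[j] && prop[j] <= upper[j]) {
      ll_prop <- loglik(prop)
      if (log(stats::runif(1)) < ll_prop - ll_cur) {
        x <- prop; ll_cur <- ll_prop
        n_acc <- n_acc + 1L
        if (it <= burn_in) acc_burn <- acc_burn + 1L
      }
    }
    if (it == burn_in && acc_burn == 0L) {
      stop("MCMC accepted no proposals during burn-in; ",
           "rescale the proposal (proposal_frac) or check the initial point",
           call. = FALSE)
    }
    if (it > burn_in && (it - burn_in) %% interval == 0L) {
      kept <- kept + 1L
      keep[kept, ] <- x
    }
  }
  colnames(keep) <- pars
  structure(list(
    model = spec$name,
    samples = tibble::as_tibble(as.data.frame(keep)),
    settings = list(burn_in = burn_in, interval = interval,
                    n_samples = n_samples, proposal_frac = proposal_frac,
                    proposal_sd = stats::setNames(prop_sd, pars), seed = seed),
    acceptance_rate = n_acc / total),
    class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior for %s: %d samples, acceptance rate %.2f>\n",
              x$model, nrow(x$samples), x$acceptance_rate))
  print(colMeans(as.matrix(x$samples)))
  invisible(x)
}

#' Tidy posterior samples (long format)
#' @param x A `posterior_samples`.
#' @param ... Unused.
#' @return Tibble with `draw`, `term`, `value`.
#' @export
tidy.posterior_samples <- function(x, ...) {
  df <- dplyr::mutate(x$samples, draw = dplyr::row_number())
  tidyr::pivot_longer(df, -"draw", names_to = "term", values_to = "value")
}

#' One-row summary of a posterior chain
#' @param x A `posterior_samples`.
#' @param ... Unused.
#' @return Tibble with model, draws, acceptance rate.
#' @export
glance.posterior_samples <- function(x, ...) {
  tibble::tibble(model = x$model, n_samples = nrow(x$samples),
                 acceptance_rate = x$acceptance_rate,
                 burn_in = x$settings$burn_in, interval = x$settings$interval)
}

fold_axial_theta <- function(theta, phi) {
  out <- mapply(function(t, p) unlist(fold_orientation(t, p)[c("theta", "phi")]),
                theta, phi)
  list(theta = out[1, ], phi = out[2, ])
}

#' Per-parameter histogram summaries of posterior samples
#'
#' Bin counts, means and SDs per free parameter; angular parameters are
#' summarised on their fundamental domain with antipodal folding applied to
#' (theta, phi) axis pairs.
#'
#' @param posterior A `posterior_samples`.
#' @param bins Number of histogram bins.
#' @return Tibble with one row per parameter x bin plus mean/sd columns.
#' @export
posterior_histograms <- function(posterior, bins = 25L) {
  df <- posterior$samples
  if (!nrow(df)) stop("posterior contains no samples", call. = FALSE)
  if (all(c("theta", "phi") %in% names(df))) {
    fd <- fold_axial_theta(df$theta, df$phi)
    df$theta <- fd$theta; df$phi <- fd$phi
  }
  if ("alpha" %in% names(df)) df$alpha <- fold_angle(df$alpha, pi)
  out <- lapply(names(df), function(p) {
    v <- df[[p]]
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]) * 1e-6, 1e-12)
    h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                        plot = FALSE)
    tibble::tibble(term = p, bin_lower = h$breaks[-length(h$breaks)],
                   bin_upper = h$breaks[-1], count = h$counts,
                   mean = mean(v), sd = stats::sd(v))
  })
  dplyr::bind_rows(out)
}

#' Histogram panels of the posterior parameter distributions
#' @param object A `posterior_samples`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object, one facet per parameter.
#' @export
autoplot.posterior_samples <- function(object, bins = 25L, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "count",
                  title = paste("Posterior parameter distributions:", object$model)) +
    ggplot2::theme_minimal()
}

#' Write posterior samples and settings to disk
#'
#' Samples as CSV (one column per parameter) with a JSON settings sidecar.
#' @param posterior A `posterior_samples`.
#' @param path CSV output path; the sidecar is `<path>.settings.json`.
#' @export
write_posterior <- function(posterior, path) {
  utils::write.csv(posterior$samples, path, row.names = FALSE)
  side <- posterior$settings
  side$proposal_sd <- as.list(side$proposal_sd)
  side$model <- posterior$model
  side$acceptance_rate <- posterior$acceptance_rate
  jsonlite::write_json(side, paste0(path, ".settings.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
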