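region_levels <- function() {
  c("background", "tumour-cellular", "stroma-aligned", "mucinous",
    "necrotic", "fat")
}

#' Build a structured synthetic breast-tissue phantom
#'
#' A 3-D grid (default 64 x 64 x 4 voxels at 0.25 x 0.25 x 0.5 mm, the
#' acquisition resolution) containing five tissue regions inside a circular
#' specimen cross-section surrounded by background: a fat rim, and four
#' quadrants of cellular tumour (Zeppelin-Sphere ground truth, f_I around
#' 0.44, cell radii drawn in 6-9 um), aligned stroma (Zeppelin-Ball with
#' orientation coherent over ~1 mm patches), mucinous analogue (Ball with
#' high diffusivity, no intracellular fraction, restriction radius at the
#' upper bound) and necrotic tissue (Ball with bi-exponential T2).
#' Deterministic given `seed`.
#'
#' @param dim Grid dimensions (3 integers).
#' @param voxdim Voxel size in mm.
#' @param seed Integer seed.
#' @param cellular_R Range (um) for cellular-region sphere radii.
#' @param cellular_fI Range for cellular-region intracellular fractions.
#' @return A `phantom` list: `labels` (3-D integer array, levels attribute),
#'   `truth` (tibble of per-voxel generating model and parameters), `dim`,
#'   `voxdim`, `seed`, `necrotic_t2` (the bi-exponential mixture used).
#' @export
make_phantom <- function(dim = c(64L, 64L, 4L), voxdim = c(0.25, 0.25, 0.5),
                         seed = 1L, cellular_R = c(6, 9),
                         cellular_fI = c(0.35, 0.55)) {
  dim <- as.integer(dim)
  local_seed(seed)
  cx <- (dim[1] + 1) / 2; cy <- (dim[2] + 1) / 2
  half <- min(dim[1], dim[2]) / 2
  r_out <- 0.80 * half   # specimen radius
  r_in <- 0.68 * half    # fat rim inner radius
  labels <- array(1L, dim)  # background
  coords <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                        k_idx = seq_len(dim[3]))
  rr <- sqrt((coords$i - cx)^2 + (coords$j - cy)^2)
  lab <- rep("background", nrow(coords))
  lab[rr <= r_out] <- "fat"
  inner <- rr <= r_in
  left <- coords$i < cx; top <- coords$j >= cy
  lab[inner & left & top] <- "tumour-cellular"
  lab[inner & !left & top] <- "stroma-aligned"
  lab[inner & left & !top] <- "mucinous"
  lab[inner & !left & !top] <- "necrotic"
  labels[] <- match(lab, region_levels())
  attr(labels, "levels") <- region_levels()

  fg <- which(lab != "background")
  n <- length(fg)
  tr <- tibble::tibble(
    i = coords$i[fg], j = coords$j[fg], k_idx = coords$k_idx[fg],
    region = lab[fg], model = NA_character_,
    D1 = NA_real_, D2 = NA_real_, D3 = NA_real_,
    theta = NA_real_, phi = NA_real_, alpha = NA_real_,
    D_I = NA_real_, R = NA_real_, f_I = 0, S0 = 1, T2 = NA_real_)

  # per-patch coherent orientations for the aligned stroma (patch ~ 1 mm)
  patch_px <- max(1L, round(1 / voxdim[1]))
  patch_id <- paste((coords$i[fg] - 1) %/% patch_px, (coords$j[fg] - 1) %/% patch_px)
  upatch <- unique(patch_id)
  p_theta <- stats::setNames(acos(stats::runif(length(upatch), -1, 1)), upatch)
  p_phi <- stats::setNames(stats::runif(length(upatch), 0, 2 * pi), upatch)

  reg <- tr$region
  idx <- reg == "tumour-cellular"
  m <- sum(idx)
  tr$model[idx] <- "Zeppelin-Sphere"
  tr$D1[idx] <- stats::runif(m, 0.8, 1.0)
  tr$D2[idx] <- stats::runif(m, 0.4, 0.6)
  tr$theta[idx] <- acos(stats::runif(m, -1, 1))
  tr$phi[idx] <- stats::runif(m, 0, 2 * pi)
  tr$D_I[idx] <- stats::runif(m, 0.8, 1.0)
  tr$R[idx] <- stats::runif(m, cellular_R[1], cellular_R[2])
  tr$f_I[idx] <- stats::runif(m, cellular_fI[1], cellular_fI[2])
  tr$T2[idx] <- stats::runif(m, 0.05, 0.09)

  idx <- reg == "stroma-aligned"
  m <- sum(idx)
  tr$model[idx] <- "Zeppelin-Ball"
  tr$D1[idx] <- stats::runif(m, 2.1, 2.4)
  tr$D2[idx] <- stats::runif(m, 0.8, 1.0)
  tr$theta[idx] <- p_theta[patch_id[idx]]
  tr$phi[idx] <- p_phi[patch_id[idx]]
  tr$D_I[idx] <- stats::runif(m, 0.9, 1.1)
  tr$f_I[idx] <- stats::runif(m, 0.10, 0.20)
  tr$T2[idx] <- stats::runif(m, 0.06, 0.10)

  idx <- reg == "mucinous"
  m <- sum(idx)
  tr$model[idx] <- "Ball"
  tr$D1[idx] <- stats::runif(m, 1.4, 1.6)
  tr$R[idx] <- 20          # effectively unrestricted
  tr$T2[idx] <- stats::runif(m, 0.15, 0.25)

  idx <- reg == "necrotic"
  m <- sum(idx)
  tr$model[idx] <- "Ball"
  tr$D1[idx] <- stats::runif(m, 1.0, 1.3)
  tr$T2[idx] <- 0.03       # short component; long component in necrotic_t2

  idx <- reg == "fat"
  m <- sum(idx)
  tr$model[idx] <- "Ball"
  tr$D1[idx] <- stats::runif(m, 0.05, 0.15)
  tr$T2[idx] <- stats::runif(m, 0.04, 0.06)

  structure(list(labels = labels, truth = tr, dim = dim, voxdim = voxdim,
                 seed = seed,
                 necrotic_t2 = list(fractions = c(0.6, 0.4), t2 = c(0.03, 0.2))),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s voxels at %s mm, seed %s>\n",
              paste(x$dim, collapse = "x"), paste(x$voxdim, collapse = "x"),
              x$seed))
  print(table(factor(attr(x$labels, "levels")[x$labels],
                     levels = attr(x$labels, "levels"))))
  invisible(x)
}

phantom_region_mask <- function(phantom, region) {
  lev <- attr(phantom$labels, "levels")
  array(phantom$labels == match(region, lev), phantom$dim)
}

#' Noiseless forward signals for the phantom
#'
#' @param phantom A `phantom`.
#' @param scheme An `acq_scheme`.
#' @return 4-D array (x, y, z, measurement); background voxels are zero.
#' @export
phantom_forward_signals <- function(phantom, scheme) {
  out <- array(0, c(phantom$dim, nrow(scheme)))
  tr <- phantom$truth
  preds <- list()
  for (v in seq_len(nrow(tr))) {
    mod <- tr$model[v]
    if (is.null(preds[[mod]])) preds[[mod]] <- make_predictor(mod, scheme)
    spec <- model_spec(mod)
    par <- unlist(tr[v, spec$free_params])
    out[tr$i[v], tr$j[v], tr$k_idx[v], ] <- preds[[mod]](par)
  }
  out
}

add_rician_noise <- function(signal, sigma) {
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# NEX averaging: mean of n_avg independent Rician magnitudes per measurement
add_rician_noise_navg <- function(signal, sigma, n_avg) {
  out <- add_rician_noise(signal, sigma)
  extra <- which(n_avg > 1)
  for (i in extra) {
    reps <- add_rician_noise(rep(signal[i], n_avg[i] - 1), sigma)
    out[i] <- (out[i] + sum(reps)) / n_avg[i]
  }
  out
}

#' Simulate a diffusion-weighted acquisition of the phantom
#'
#' Evaluates each voxel's generating compartment model over the scheme and
#' corrupts it with Rician noise: the magnitude of the complex signal
#' (S + g1, g2) with independent Gaussian components of SD `sigma`.
#' Measurements acquired with more than one average (`n_avg` in the scheme)
#' are the mean of that many independent magnitude draws, as in the scanner.
#'
#' @param phantom A `phantom`.
#' @param scheme An `acq_scheme`.
#' @param sigma Noise SD (signal units; ground-truth S0 is 1, so
#'   `sigma = 1/SNR`). `sigma = 0` returns the noiseless forward model.
#' @param seed Integer seed.
#' @return 4-D signal array.
#' @export
simulate_signals <- function(phantom, scheme, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  S <- phantom_forward_signals(phantom, scheme)
  if (sigma == 0) return(S)
  local_seed(seed)
  dm <- dim(S)
  n_avg <- rep(scheme$n_avg, each = prod(dm[1:3]))
  array(add_rician_noise_navg(as.vector(S), sigma, n_avg), dm)
}

#' Simulate a multi-echo T2 acquisition of the phantom
#'
#' Mono-exponential decay with each voxel's T2, except necrotic voxels which
#' decay as the phantom's stated two-component mixture (60% at 30 ms, 40% at
#' 200 ms by default); Rician noise as in [simulate_signals()], averaged over
#' `n_avg` excitations (the multi-echo acquisition used four averages).
#'
#' @param phantom A `phantom`.
#' @param echo_times Echo times in seconds (>= 2).
#' @param sigma Noise SD.
#' @param seed Integer seed.
#' @param n_avg Number of averages.
#' @return 4-D echo array (x, y, z, echo).
#' @export
simulate_multiecho <- function(phantom, echo_times = seq(0.005, 0.16, by = 0.005),
                               sigma = 0.01, seed = 1L, n_avg = 4L) {
  if (length(echo_times) < 2) stop("need at least 2 echoes", call. = FALSE)
  tr <- phantom$truth
  out <- array(0, c(phantom$dim, length(echo_times)))
  mix <- phantom$necrotic_t2
  for (v in seq_len(nrow(tr))) {
    if (tr$region[v] == "necrotic") {
      dec <- mix$fractions[1] * exp(-echo_times / mix$t2[1]) +
        mix$fractions[2] * exp(-echo_times / mix$t2[2])
    } else {
      dec <- exp(-echo_times / tr$T2[v])
    }
    out[tr$i[v], tr$j[v], tr$k_idx[v], ] <- tr$S0[v] * dec
  }
  if (sigma > 0) {
    local_seed(seed)
    out <- array(add_rician_noise_navg(as.vector(out), sigma,
                                       rep(n_avg, length(out))), dim(out))
  }
  out
}

#' Monte-Carlo random-walk oracle for restricted diffusion in a sphere
#'
#' Independent validation of the Gaussian-phase-distribution series: walkers
#' take fixed-length steps in uniformly random directions inside an
#' impermeable sphere (radial elastic reflection at the wall), accruing phase
#' under the two rectangular PGSE gradient lobes. Returns |mean exp(i phi)|
#' with its standard error.
#'
#' @param R Sphere radius (um).
#' @param D_I Intracellular diffusivity (1e-3 mm^2/s).
#' @param G Gradient strength (mT/m).
#' @param delta,Delta Pulse timings (ms).
#' @param n_walkers Number of walkers (>= 1e4 for production use).
#' @param step_frac Step length as a fraction of R (must be <= 1/10).
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1).
#' @param seed Integer seed.
#' @return List with `E` (attenuation), `se` (standard error), `n_steps`, and
#'   the effective pulse timings `delta_eff`/`Delta_eff` (ms) realised by the
#'   discrete waveform (compare analytic predictions at these timings).
#' @export
mc_sphere_oracle <- function(R, D_I, G, delta, Delta, n_walkers = 1e4,
                             step_frac = 1 / 20, gamma = GAMMA_PROTON,
                             seed = 1L) {
  if (step_frac > 1 / 10) {
    stop("step length exceeds R/10; decrease step_frac for adequate resolution",
         call. = FALSE)
  }
  R_m <- R * 1e-6
  D_m <- D_I * 1e-9
  G_T <- G * 1e-3
  d_s <- delta * 1e-3
  D_s <- Delta * 1e-3
  step <- R_m * step_frac
  # dt from the spatial step, but fine enough to resolve the gradient lobes,
  # and dividing delta exactly so the two lobes are step-balanced
  dt0 <- min(step^2 / (6 * D_m), d_s / 20)
  dt <- d_s / ceiling(d_s / dt0)
  n_steps <- round((D_s + d_s) / dt)
  step <- sqrt(6 * D_m * dt)
  Delta_eff <- round(D_s / dt) * dt
  local_seed(seed)
  res <- mc_walk_sphere_cpp(as.integer(n_walkers), as.integer(n_steps),
                            R_m, step, dt, gamma * G_T, d_s, D_s)
  list(E = res[1], se = res[2], n_steps = n_steps,
       delta_eff = delta, Delta_eff = Delta_eff * 1e3)
}
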