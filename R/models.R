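# Parameter bounds shared by all models. Diffusivities in 1e-3 mm^2/s,
# R in micrometres, T2 in seconds, angles in radians, fractions dimensionless.
# S0 is positive with its upper bound set per voxel at fit time.
default_bounds <- function() {
  list(
    D1    = c(0.01, 3),
    D2    = c(0.01, 3),
    D3    = c(0.01, 3),
    theta = c(0, pi),
    phi   = c(0, 2 * pi),
    alpha = c(0, pi),
    D_I   = c(0.01, 3),
    R     = c(0.1, 20),
    f_I   = c(0, 1),
    S0    = c(1e-9, Inf),
    T2    = c(0.001, 3)
  )
}

model_table <- function() {
  list(
    "Ball"           = list(ext = "Ball",     int = "none",
                            pars = c("D1", "S0", "T2")),
    "Zeppelin"       = list(ext = "Zeppelin", int = "none",
                            pars = c("D1", "D2", "theta", "phi", "S0", "T2")),
    "Tensor"         = list(ext = "Tensor",   int = "none",
                            pars = c("D1", "D2", "D3", "theta", "phi", "alpha", "S0", "T2")),
    "Ball-Ball"      = list(ext = "Ball",     int = "Ball",
                            pars = c("D1", "D_I", "f_I", "S0", "T2")),
    "Zeppelin-Ball"  = list(ext = "Zeppelin", int = "Ball",
                            pars = c("D1", "D2", "theta", "phi", "D_I", "f_I", "S0", "T2")),
    "Tensor-Ball"    = list(ext = "Tensor",   int = "Ball",
                            pars = c("D1", "D2", "D3", "theta", "phi", "alpha",
                                     "D_I", "f_I", "S0", "T2")),
    "Ball-Sphere"    = list(ext = "Ball",     int = "Sphere",
                            pars = c("D1", "D_I", "R", "f_I", "S0", "T2")),
    "Zeppelin-Sphere" = list(ext = "Zeppelin", int = "Sphere",
                            pars = c("D1", "D2", "theta", "phi", "D_I", "R",
                                     "f_I", "S0", "T2")),
    "Tensor-Sphere"  = list(ext = "Tensor",   int = "Sphere",
                            pars = c("D1", "D2", "D3", "theta", "phi", "alpha",
                                     "D_I", "R", "f_I", "S0", "T2"))
  )
}

normalise_model_name <- function(name) {
  x <- gsub("–|—", "-", name)   # en/em dash aliases
  x <- gsub("\\s+", "", x)
  x <- sub("\\(ADC\\)$", "", x, ignore.case = TRUE)
  x <- sub("\\(DT\\)$", "", x, ignore.case = TRUE)
  canon <- names(model_table())
  hit <- match(tolower(x), tolower(canon))
  if (is.na(hit)) {
    # camel-case aliases like "BallSphere"
    squash <- gsub("-", "", tolower(canon))
    hit <- match(tolower(x), squash)
  }
  if (is.na(hit)) {
    stop("unknown model '", name, "'; registered models: ",
         paste(canon, collapse = ", "), call. = FALSE)
  }
  canon[hit]
}

#' Registered model names
#'
#' The nine one- and two-compartment models: extracellular Ball, Zeppelin or
#' Tensor, optionally combined with an intracellular Ball (unrestricted) or
#' Sphere (restricted) compartment.
#' @return Character vector of canonical model names.
#' @export
model_names <- function() names(model_table())

#' Model specification
#'
#' Looks up a model in the registry and returns its compartment shapes,
#' ordered free-parameter list, per-parameter box bounds and free-parameter
#' count `k` (all models additionally fit the equilibrium signal S0 and the
#' relaxation constant T2; two-compartment models fit the intracellular
#' volume fraction f_I, with f_E = 1 - f_I eliminated).
#'
#' @param name Model name (canonical, en-dash, or squashed alias).
#' @return A `model_spec` list with fields `name`, `extracellular_shape`,
#'   `intracellular_shape`, `free_params`, `bounds`, `k`.
#' @examples
#' model_spec("Zeppelin-Sphere")$k  # 9
#' @export
model_spec <- function(name) {
  canon <- normalise_model_name(name)
  entry <- model_table()[[canon]]
  bounds <- default_bounds()[entry$pars]
  structure(list(
    name = canon,
    extracellular_shape = entry$ext,
    intracellular_shape = entry$int,
    free_params = entry$pars,
    bounds = bounds,
    k = length(entry$pars)
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model %s: extracellular %s, intracellular %s, k = %d>\n",
              x$name, x$extracellular_shape, x$intracellular_shape, x$k))
  cat("  free parameters:", paste(x$free_params, collapse = ", "), "\n")
  invisible(x)
}

validate_params <- function(spec, params) {
  params <- as.list(params)
  miss <- setdiff(spec$free_params, names(params))
  if (length(miss)) {
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (p in spec$free_params) {
    v <- params[[p]]
    bb <- spec$bounds[[p]]
    if (!is.finite(v) || v < bb[1] - 1e-12 || v > bb[2] + 1e-12) {
      stop("parameter '", p, "' = ", format(v), " outside bounds [",
           bb[1], ", ", bb[2], "]", call. = FALSE)
    }
  }
  ord <- intersect(c("D1", "D2", "D3"), spec$free_params)
  if (length(ord) > 1) {
    dv <- unlist(params[ord])
    if (any(diff(dv) > 1e-12)) {
      stop("diffusivities must satisfy canonical ordering D1 >= D2 >= D3",
           call. = FALSE)
    }
  }
  params
}

shape_attenuation <- function(shape, scheme, params) {
  switch(shape,
    Ball = ball_signal(scheme$b, params$D1),
    Zeppelin = zeppelin_signal(scheme, params$D1, params$D2, params$theta, params$phi),
    Tensor = tensor_signal(scheme, params$D1, params$D2, params$D3,
                           params$theta, params$phi, params$alpha),
    Sphere = sphere_signal(scheme, params$D_I, params$R),
    none = NULL,
    stop("unknown shape: ", shape, call. = FALSE))
}

#' Predicted composite signal for a model
#'
#' \deqn{S = S_0\, e^{-TE/T_2}\,(f_E E_{ext} + f_I E_{int})} with
#' \eqn{f_E = 1 - f_I}; for one-compartment models the bracket is the single
#' shape's attenuation. Intracellular Ball compartments use diffusivity `D_I`.
#'
#' @param spec A `model_spec` (or model name).
#' @param params Named list/vector of parameter values (bounds checked).
#' @param scheme An `acq_scheme`.
#' @param validate Check bounds and ordering (default TRUE).
#' @return Predicted signal per measurement (arbitrary units).
#' @export
composite_signal <- function(spec, params, scheme, validate = TRUE) {
  if (is.character(spec)) spec <- model_spec(spec)
  params <- if (validate) validate_params(spec, params) else as.list(params)
  e_ext <- shape_attenuation(spec$extracellular_shape, scheme, params)
  if (spec$intracellular_shape == "none") {
    att <- e_ext
  } else {
    int_params <- params
    int_params$D1 <- params$D_I   # intracellular Ball uses D_I
    e_int <- shape_attenuation(spec$intracellular_shape, scheme, int_params)
    att <- (1 - params$f_I) * e_ext + params$f_I * e_int
  }
  params$S0 * exp(-(scheme$TE * 1e-3) / params$T2) * att
}

# Fast closure-based predictor used by the fitting and MCMC loops: takes an
# unnamed parameter vector in spec$free_params order. Sphere attenuation is
# evaluated on the unique (G, delta, Delta) combinations only.
make_predictor <- function(spec, scheme) {
  if (is.character(spec)) spec <- model_spec(spec)
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  b <- scheme$b
  TEs <- scheme$TE * 1e-3
  gamma <- scheme_gamma(scheme)
  ip <- match(spec$free_params, spec$free_params)  # identity; index by name below
  idx <- function(p) match(p, spec$free_params)
  i_D1 <- idx("D1"); i_D2 <- idx("D2"); i_D3 <- idx("D3")
  i_th <- idx("theta"); i_ph <- idx("phi"); i_al <- idx("alpha")
  i_DI <- idx("D_I"); i_R <- idx("R"); i_fI <- idx("f_I")
  i_S0 <- idx("S0"); i_T2 <- idx("T2")
  ext <- spec$extracellular_shape
  int <- spec$intracellular_shape

  if (int == "Sphere") {
    key <- paste(scheme$G, scheme$delta, scheme$Delta)
    ukey <- !duplicated(key)
    uG <- scheme$G[ukey] * 1e-3
    ud <- scheme$delta[ukey] * 1e-3
    uD <- scheme$Delta[ukey] * 1e-3
    umap <- match(key, key[ukey])
    # exponentials are computed once per unique pulse time, then row-indexed
    del_vals <- unique(ud); del_idx <- match(ud, del_vals)
    dmd_vals <- unique(uD - ud); dmd_idx <- match(uD - ud, dmd_vals)
    # 40 series terms: tail is ~1e-11 relative over the protocol's (R, delta)
    mu <- sphere_bessel_roots(40L)
    mu2 <- mu^2
  }

  function(par) {
    ext_att <- switch(ext,
      Ball = exp(-b * par[i_D1] * 1e-3),
      Zeppelin = {
        n <- axis_from_angles(par[i_th], par[i_ph])
        ct2 <- (g[, 1] * n[1] + g[, 2] * n[2] + g[, 3] * n[3])^2
        exp(-b * ((par[i_D1] - par[i_D2]) * ct2 + par[i_D2]) * 1e-3)
      },
      Tensor = {
        Rm <- rotation_from_angles(par[i_th], par[i_ph], par[i_al])
        gr <- g %*% Rm
        exp(-b * (gr[, 1]^2 * par[i_D1] + gr[, 2]^2 * par[i_D2] +
                    gr[, 3]^2 * par[i_D3]) * 1e-3)
      })
    if (int == "none") {
      att <- ext_att
    } else if (int == "Ball") {
      att <- (1 - par[i_fI]) * ext_att + par[i_fI] * exp(-b * par[i_DI] * 1e-3)
    } else {
      Dm <- par[i_DI] * 1e-9
      Rm <- par[i_R] * 1e-6
      # roots x measurements layout: per-root factors recycle down columns
      a2 <- mu2 / Rm^2
      a2D <- a2 * Dm
      e1 <- exp(-outer(a2D, dmd_vals))[, dmd_idx, drop = FALSE]
      e2 <- exp(-outer(a2D, del_vals))[, del_idx, drop = FALSE]
      e3 <- e1 * e2          # exp(-a2D * Delta)
      e4 <- e3 * e2          # exp(-a2D * (Delta + delta))
      num <- -(2 + e1 - 2 * e2 - 2 * e3 + e4) / a2D^2 +
        outer(2 / a2D, ud)
      terms <- num / (a2 * (mu2 - 2))
      lnE <- -2 * gamma^2 * uG^2 * colSums(terms)
      att <- (1 - par[i_fI]) * ext_att + par[i_fI] * exp(lnE)[umap]
    }
    par[i_S0] * exp(-TEs / par[i_T2]) * att
  }
}
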