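#' Akaike information criterion
#'
#' \eqn{AIC = -2\ln L + 2k}.
#' @param lnL Maximised log-likelihood.
#' @param k Number of fitting parameters (>= 1).
#' @return AIC value.
#' @export
aic <- function(lnL, k) {
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  -2 * lnL + 2 * k
}

#' Bayesian information criterion
#'
#' \eqn{BIC = -2\ln L + k\ln n}, with `n` the number of data points fitted.
#' @inheritParams aic
#' @param n Number of data points (>= 1).
#' @return BIC value.
#' @export
bic <- function(lnL, k, n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  -2 * lnL + k * log(n)
}

#' Voxel-wise model selection by AIC and BIC
#'
#' Takes the tidy per-voxel fit table from [fit_volume()] (or any tibble with
#' columns `i, j, k_idx, model, lnL, k, n`) and, per voxel, ranks all models
#' by AIC and BIC. Ties are broken by parsimony (smallest `k`), then model
#' name. Voxels missing any requested model, or with non-finite lnL, are
#' flagged and excluded from summaries.
#'
#' @param fits Tidy fit table.
#' @param models Models that must be present per voxel (default: all in `fits`).
#' @return A list of class `model_selection` with elements
#'   `per_model` (per voxel x model criteria and relative criteria),
#'   `best` (per voxel winning model under each criterion),
#'   `summary` (median/quartile/range of relative criteria per model, the
#'   boxplot surface), and `flagged` (excluded voxels).
#' @export
select_models <- function(fits, models = NULL) {
  need <- c("i", "j", "k_idx", "model", "lnL", "k", "n")
  miss <- setdiff(need, names(fits))
  if (length(miss)) stop("fits is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(models)) models <- unique(fits$model)
  per <- fits |>
    dplyr::filter(.data$model %in% models) |>
    dplyr::mutate(AIC = aic(.data$lnL, .data$k),
                  BIC = bic(.data$lnL, .data$k, .data$n))
  counts <- per |>
    dplyr::group_by(.data$i, .data$j, .data$k_idx) |>
    dplyr::summarise(n_models = dplyr::n(),
                     all_finite = all(is.finite(.data$lnL)), .groups = "drop")
  flagged <- dplyr::filter(counts, .data$n_models < length(models) | !.data$all_finite)
  good <- dplyr::anti_join(per, flagged, by = c("i", "j", "k_idx"))
  good <- good |>
    dplyr::group_by(.data$i, .data$j, .data$k_idx) |>
    dplyr::mutate(relative_aic = .data$AIC - min(.data$AIC),
                  relative_bic = .data$BIC - min(.data$BIC)) |>
    dplyr::ungroup()
  pick <- function(df, crit) {
    df |>
      dplyr::group_by(.data$i, .data$j, .data$k_idx) |>
      dplyr::arrange(.data[[crit]], .data$k, .data$model, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select("i", "j", "k_idx", best = "model")
  }
  best <- dplyr::full_join(
    dplyr::rename(pick(good, "AIC"), best_aic = "best"),
    dplyr::rename(pick(good, "BIC"), best_bic = "best"),
    by = c("i", "j", "k_idx"))
  summ <- good |>
    tidyr::pivot_longer(c("relative_aic", "relative_bic"),
                        names_to = "criterion", values_to = "relative") |>
    dplyr::group_by(.data$model, .data$criterion) |>
    dplyr::summarise(median = stats::median(.data$relative),
                     q25 = stats::quantile(.data$relative, 0.25),
                     q75 = stats::quantile(.data$relative, 0.75),
                     min = min(.data$relative), max = max(.data$relative),
                     .groups = "drop")
  structure(list(per_model = good, best = best, summary = summ,
                 flagged = flagged, models = models),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model selection over %d voxels, %d models (%d flagged)>\n",
              nrow(x$best), length(x$models), nrow(x$flagged)))
  cat("BIC winners:\n")
  print(table(x$best$best_bic))
  invisible(x)
}

#' Tidy per-voxel winners from a model selection
#' @param x A `model_selection`.
#' @param ... Unused.
#' @return Tibble of voxel indices with `best_aic` and `best_bic`.
#' @export
tidy.model_selection <- function(x, ...) x$best

#' Summary statistics of relative criteria per model
#' @param x A `model_selection`.
#' @param ... Unused.
#' @return The boxplot-style summary tibble.
#' @export
glance.model_selection <- function(x, ...) x$summary

#' Boxplot of relative information criteria across voxels
#'
#' Distribution of per-voxel criterion differences from the winning model,
#' one box per candidate model, faceted by criterion (low is better).
#' @param object A `model_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_model,
                            c("relative_aic", "relative_bic"),
                            names_to = "criterion", values_to = "relative")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$relative)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "criterion - voxel minimum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Integer-coded best-model map plus JSON legend
#'
#' @param selection A `model_selection`.
#' @param dim 3-D grid dimensions.
#' @param criterion `"bic"` or `"aic"`.
#' @return List with `map` (3-D integer array, 0 = not selected/excluded) and
#'   `legend` (named integer vector).
#' @export
best_model_map <- function(selection, dim, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  col <- if (criterion == "bic") "best_bic" else "best_aic"
  codes <- stats::setNames(seq_along(selection$models), sort(selection$models))
  map <- array(0L, dim)
  b <- selection$best
  map[cbind(b$i, b$j, b$k_idx)] <- codes[b[[col]]]
  list(map = map, legend = codes)
}
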