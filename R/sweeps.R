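#' CPT parameters of the Markov stag-hunt experiments
#'
#' The canonical risk-sensitive agent of the Markov analyses: identity
#' utility, Prelec weighting `w(x) = exp(-0.5 (-log x)^0.9)`, reference
#' point `b` (default 0). [eut_params()] is the rational counterpart.
#'
#' @param reference_point Reference point `b`.
#' @param alpha,delta Prelec weighting parameters.
#' @export
markov_cpt_params <- function(reference_point = 0, alpha = 0.5, delta = 0.9) {
  cpt_params(utility_spec("identity"),
             weighting_spec("prelec", alpha = alpha, delta = delta),
             reference_point = reference_point)
}

#' Stationary-distribution sweeps over the Markov stag hunt
#'
#' Runs the long-run occupancy experiments: build level-k towers under a
#' family of parameterizations, condition the game on the tower policies,
#' and summarize each stationary distribution. Kinds:
#'
#' * `"levels_grid"`: all sophistication pairs `(k1, k2)` in
#'   `0..k_max` for one parameter set (possibly asymmetric levels).
#' * `"reference_points"`: reference points `b_values` crossed with levels
#'   `0..k_max` (symmetric levels).
#' * `"discounts"`: discount factors `beta_values` crossed with levels.
#' * `"concavity"`: utility exponents `gamma_values` (with the sweep
#'   parameter set's weighting) crossed with levels.
#' * `"agent_mix"`: named pairs of parameter sets in `mixes` (e.g.
#'   expected-utility vs CPT agents) crossed with symmetric levels.
#'
#' @param kind Sweep kind, see above.
#' @param spec A [canyon_spec()].
#' @param params Base [cpt_params()] (default [markov_cpt_params()]).
#' @param config A [planning_config()].
#' @param k_max Highest sophistication level.
#' @param b_values,beta_values,gamma_values Grids for the corresponding
#'   kinds.
#' @param mixes For `"agent_mix"`: a named list of `list(params1, params2)`
#'   pairs.
#' @return A tibble with one row per setting: setting columns (`k1`, `k2`,
#'   and `b`/`beta`/`gamma`/`mix` as applicable), `stag_mass`, `hare_mass`,
#'   `residual`, and a list-column `rho` with the full stationary vector.
#' @examples
#' \donttest{
#' run_sweep("levels_grid", fixture_canyon(4, hare = 0, stag = 3), k_max = 1)
#' }
#' @export
run_sweep <- function(kind = c("levels_grid", "reference_points",
                               "discounts", "concavity", "agent_mix"),
                      spec = canyon_spec(),
                      params = markov_cpt_params(),
                      config = planning_config(),
                      k_max = 4L,
                      b_values = c(-1, 0, 1, 2),
                      beta_values = c(0.85, 0.95),
                      gamma_values = c(0.99, 0.95),
                      mixes = list(
                        eut = list(eut_params(), eut_params()),
                        cpt = list(markov_cpt_params(), markov_cpt_params()))) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "canyon_spec"))
  kern <- joint_kernel(single_agent_kernel(spec))
  summarize_pair <- function(tower, k1, k2, setting = NULL) {
    rho <- tower_stationary(tower, k1, k2, kern)
    met <- coordination_metrics(rho, spec)
    res <- tibble::tibble(k1 = k1, k2 = k2,
                          stag_mass = met$stag_mass,
                          hare_mass = met$hare_mass,
                          residual = rho$residual,
                          rho = list(rho$rho))
    if (is.null(setting)) res else dplyr::bind_cols(setting, res)
  }
  rows <- switch(kind,
    levels_grid = {
      tower <- level_k_tower(k_max, spec, params, params, config)
      grid <- tidyr::expand_grid(k1 = 0:k_max, k2 = 0:k_max)
      purrr::map2(grid$k1, grid$k2, function(k1, k2) {
        summarize_pair(tower, k1, k2)
      })
    },
    reference_points = purrr::map(b_values, function(b) {
      p <- params
      p$reference_point <- b
      tower <- level_k_tower(k_max, spec, p, p, config)
      dplyr::bind_rows(purrr::map(0:k_max, function(k) {
        summarize_pair(tower, k, k, tibble::tibble(b = b))
      }))
    }),
    discounts = purrr::map(beta_values, function(beta) {
      cf <- config
      cf$discount_beta <- beta
      tower <- level_k_tower(k_max, spec, params, params, cf)
      dplyr::bind_rows(purrr::map(0:k_max, function(k) {
        summarize_pair(tower, k, k, tibble::tibble(beta = beta))
      }))
    }),
    concavity = purrr::map(gamma_values, function(g) {
      p <- cpt_params(utility_spec("power", gamma = g, lambda = 1),
                      params$weighting, params$reference_point)
      tower <- level_k_tower(k_max, spec, p, p, config)
      dplyr::bind_rows(purrr::map(0:k_max, function(k) {
        summarize_pair(tower, k, k, tibble::tibble(gamma = g))
      }))
    }),
    agent_mix = {
      stopifnot(is.list(mixes), length(mixes) >= 1L,
                !is.null(names(mixes)))
      purrr::imap(mixes, function(pair, nm) {
        tower <- level_k_tower(k_max, spec, pair[[1]], pair[[2]], config)
        dplyr::bind_rows(purrr::map(0:k_max, function(k) {
          summarize_pair(tower, k, k, tibble::tibble(mix = nm))
        }))
      })
    })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stationary_sweep", class(out))
  out
}

#' @export
autoplot.stationary_sweep <- function(object, ...) {
  if (all(c("k1", "k2") %in% names(object)) && !"b" %in% names(object) &&
      dplyr::n_distinct(object$k1) > 1 && dplyr::n_distinct(object$k2) > 1) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(x = .data$k1, y = .data$k2,
                                           fill = .data$stag_mass)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "sophistication k1", y = "sophistication k2",
                      fill = "stag mass") +
        ggplot2::theme_minimal())
  }
  setting <- setdiff(names(object),
                     c("k1", "k2", "stag_mass", "hare_mass", "residual",
                       "rho"))[1]
  long <- tidyr::pivot_longer(
    object[, c(setting, "k1", "stag_mass", "hare_mass")],
    c("stag_mass", "hare_mass"),
    names_to = "metric", values_to = "mass")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k1, y = .data$mass,
                                     colour = factor(.data[[setting]]),
                                     linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sophistication level k", y = "stationary mass",
                  colour = setting) +
    ggplot2::theme_minimal()
}
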