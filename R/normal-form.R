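#' Symmetric two-action normal-form game
#'
#' Payoffs follow the standard (R, S, T, P) convention: `R` when both play
#' the first action, `S` to a first-action player whose opponent plays the
#' second, `T` to a second-action player whose opponent plays the first,
#' and `P` when both play the second action.
#'
#' @param R,S,T,P Finite payoffs.
#' @param labels Character vector of two action labels (first, second).
#' @return An object of class `symmetric_game`.
#' @examples
#' stag_hunt()
#' @export
symmetric_game <- function(R, S, T, P, labels = c("A", "B")) {
  pay <- c(R = R, S = S, T = T, P = P)
  stopifnot(is.numeric(pay), all(is.finite(pay)),
            is.character(labels), length(labels) == 2L)
  structure(list(R = R, S = S, T = T, P = P, labels = labels),
            class = "symmetric_game")
}

#' @rdname symmetric_game
#' @details `stag_hunt()` is the canonical coordination instance: hunting
#'   the stag together pays 5 each, hunting alone pays -1 against a hare
#'   hunter's 1, and hare hunting always pays 1.
#' @export
stag_hunt <- function() {
  symmetric_game(R = 5, S = -1, T = 1, P = 1, labels = c("Stag", "Hare"))
}

#' @export
print.symmetric_game <- function(x, ...) {
  cat("<symmetric_game>", x$labels[1], "/", x$labels[2], "\n")
  m <- matrix(c(x$R, x$T, x$S, x$P), 2, 2,
              dimnames = list(x$labels, x$labels))
  print(m)
  invisible(x)
}

#' CPT value of an action against a mixing opponent
#'
#' When the opponent plays the first action with probability `p`, playing
#' the first action is the prospect `{R w.p. p, S w.p. 1 - p}` and playing
#' the second is `{T w.p. p, P w.p. 1 - p}`; each is valued by [cpt_value()]
#' under the agent's parameters (duplicate payoffs collapse to a certainty).
#'
#' @param game A [symmetric_game()].
#' @param action `1` (or the first label) or `2` (or the second label).
#' @param p_other_first Probability the opponent plays the first action.
#' @param params A [cpt_params()].
#' @return A single numeric value.
#' @examples
#' action_value(stag_hunt(), "Stag", 1 / 3, eut_params())
#' @export
action_value <- function(game, action, p_other_first, params = eut_params()) {
  stopifnot(inherits(game, "symmetric_game"),
            is.numeric(p_other_first),
            all(p_other_first >= 0), all(p_other_first <= 1))
  a <- resolve_action(game, action)
  pay <- if (a == 1L) c(game$R, game$S) else c(game$T, game$P)
  two_outcome_value(pay[1], pay[2], p_other_first, params)
}

# CPT value of {x w.p. p, y w.p. 1 - p}, vectorized over p; the decision
# weight of each branch depends on its gain/loss framing relative to b
two_outcome_value <- function(x, y, p, params) {
  b <- params$reference_point
  uspec <- params$utility
  wspec <- params$weighting
  if (x == y) {
    return(rep(utility(x - b, uspec), length(p)))
  }
  if (x > y) {
    hi <- x; lo <- y; q <- p
  } else {
    hi <- y; lo <- x; q <- 1 - p
  }
  psi_hi <- if (hi >= b) prob_weight(q, wspec) else 1 - prob_weight(1 - q, wspec)
  psi_lo <- if (lo >= b) 1 - prob_weight(q, wspec) else prob_weight(1 - q, wspec)
  utility(hi - b, uspec) * psi_hi + utility(lo - b, uspec) * psi_lo
}

resolve_action <- function(game, action) {
  if (is.character(action)) {
    a <- match(action, game$labels)
    if (is.na(a)) stop("unknown action label: ", action)
    return(a)
  }
  stopifnot(action %in% c(1L, 2L))
  as.integer(action)
}

#' Mixed equilibrium of a symmetric 2x2 game under CPT
#'
#' Finds all probabilities `p*` of playing the first action at which a CPT
#' agent is indifferent between its two actions when the opponent plays the
#' first action with probability `p*`. The indifference gap
#' `f(p) = V(first | p) - V(second | p)` is bracketed on a uniform grid and
#' each sign change refined by bisection. If `f` never changes sign the
#' dominating pure strategy is reported as a boundary solution.
#'
#' @param game A [symmetric_game()].
#' @param params A [cpt_params()].
#' @param n_grid Number of grid points used for bracketing (default 2001,
#'   resolving roots separated by at least 5e-4).
#' @return An object of class `mixed_equilibrium`: a list with `roots`
#'   (sorted probabilities), `boundary` (`"interior"`, `"all_first"`, or
#'   `"all_second"`), and `residuals` (indifference gaps at the roots).
#' @examples
#' mixed_equilibrium(stag_hunt(), eut_params()) # root 1/3
#' @export
mixed_equilibrium <- function(game, params = eut_params(), n_grid = 2001L) {
  stopifnot(inherits(game, "symmetric_game"), n_grid >= 2L)
  f <- function(p) {
    action_value(game, 1L, p, params) - action_value(game, 2L, p, params)
  }
  grid <- seq(0, 1, length.out = n_grid)
  fv <- f(grid)
  if (any(!is.finite(fv))) stop("non-finite indifference gap on the grid")
  roots <- grid[fv == 0]
  sgn <- sign(fv)
  for (i in seq_len(n_grid - 1L)) {
    if (sgn[i] != 0 && sgn[i + 1L] != 0 && sgn[i] != sgn[i + 1L]) {
      lo <- grid[i]; hi <- grid[i + 1L]
      flo <- fv[i]
      while (hi - lo > 1e-10) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (fm == 0) { lo <- mid; hi <- mid; break }
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    boundary <- if (all(fv > 0)) "all_first" else "all_second"
    roots <- if (boundary == "all_first") 1 else 0
    res <- structure(list(roots = roots, boundary = boundary,
                          residuals = f(roots), game = game),
                     class = "mixed_equilibrium")
    return(res)
  }
  structure(list(roots = roots, boundary = "interior",
                 residuals = vapply(roots, f, numeric(1)), game = game),
            class = "mixed_equilibrium")
}

#' @export
print.mixed_equilibrium <- function(x, ...) {
  cat("<mixed_equilibrium>", x$boundary, "\n")
  cat("  p* =", paste(signif(x$roots, 10), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.mixed_equilibrium <- function(x, ...) {
  tibble::tibble(root = x$roots, boundary = x$boundary,
                 residual = x$residuals)
}

#' Pure Nash equilibria of a symmetric 2x2 game
#'
#' Best-response enumeration over the four pure profiles. For a
#' coordination game (`R > T` and `P > S`) both symmetric profiles are
#' equilibria.
#'
#' @param game A [symmetric_game()].
#' @return A tibble with one row per pure equilibrium (columns `action_1`,
#'   `action_2` with action labels).
#' @examples
#' pure_equilibria(stag_hunt())
#' @export
pure_equilibria <- function(game) {
  stopifnot(inherits(game, "symmetric_game"))
  # payoff to the row player: pay[a_row, a_col]
  pay <- matrix(c(game$R, game$T, game$S, game$P), 2, 2)
  out <- list()
  for (a1 in 1:2) {
    for (a2 in 1:2) {
      br1 <- pay[a1, a2] >= pay[3 - a1, a2]
      br2 <- pay[a2, a1] >= pay[3 - a2, a1]
      if (br1 && br2) out[[length(out) + 1L]] <- c(a1, a2)
    }
  }
  tibble::tibble(
    action_1 = game$labels[vapply(out, `[`, integer(1), 1L)],
    action_2 = game$labels[vapply(out, `[`, integer(1), 2L)]
  )
}

#' Equilibrium probability over a two-parameter grid
#'
#' Recomputes the CPT mixed equilibrium of a symmetric game over a grid of
#' two CPT parameters, holding the others at their defaults. When several
#' indifference points exist the smallest is reported (and flagged); when
#' none exists the dominating pure strategy's probability (0 or 1) is
#' reported.
#'
#' @param game A [symmetric_game()].
#' @param axis1,axis2 Named lists `list(param = <name>, values = <numeric>)`
#'   with `param` one of `"reference_point"`, `"alpha"`, `"lambda"`,
#'   `"gamma"`.
#' @param defaults Baseline [cpt_params()] from which each grid point
#'   deviates. The defaults (`b = 0`, `alpha = 1`, `lambda = 1`,
#'   `gamma = 1`, Prelec `delta = 0.75`) make the sweep's baseline the
#'   near-identity Prelec agent.
#' @param n_grid Bracketing grid size passed to [mixed_equilibrium()].
#' @return A tibble with columns `param1`, `value1`, `param2`, `value2`,
#'   `p_star`, `n_roots`, `boundary`. Class `equilibrium_sweep`.
#' @examples
#' equilibrium_sweep(stag_hunt(),
#'   axis1 = list(param = "reference_point", values = c(-1, 0, 1)),
#'   axis2 = list(param = "alpha", values = c(0.5, 1, 2)))
#' @export
equilibrium_sweep <- function(game,
                              axis1, axis2,
                              defaults = cpt_params(
                                utility_spec("power", gamma = 1, lambda = 1),
                                weighting_spec("prelec", alpha = 1, delta = 0.75),
                                reference_point = 0),
                              n_grid = 2001L) {
  stopifnot(inherits(game, "symmetric_game"))
  check_axis <- function(ax) {
    stopifnot(is.list(ax), ax$param %in%
                c("reference_point", "alpha", "lambda", "gamma"),
              is.numeric(ax$values), length(ax$values) >= 1L)
  }
  check_axis(axis1); check_axis(axis2)
  grid <- tidyr::expand_grid(value1 = axis1$values, value2 = axis2$values)
  solve_cell <- function(v1, v2) {
    p <- set_cpt_param(defaults, axis1$param, v1)
    p <- set_cpt_param(p, axis2$param, v2)
    eq <- tryCatch(mixed_equilibrium(game, p, n_grid), error = function(e) NULL)
    if (is.null(eq)) {
      return(tibble::tibble(p_star = NA_real_, n_roots = NA_integer_,
                            boundary = NA_character_))
    }
    if (eq$boundary == "interior" && length(eq$roots) > 1L) {
      rlang::warn(sprintf(
        "multiple indifference points at (%s=%g, %s=%g): %s; reporting smallest",
        axis1$param, v1, axis2$param, v2,
        paste(signif(eq$roots, 6), collapse = ", ")))
    }
    tibble::tibble(p_star = eq$roots[1], n_roots = length(eq$roots),
                   boundary = eq$boundary)
  }
  cells <- purrr::map2(grid$value1, grid$value2, solve_cell)
  out <- dplyr::bind_cols(
    tibble::tibble(param1 = axis1$param, value1 = grid$value1,
                   param2 = axis2$param, value2 = grid$value2),
    dplyr::bind_rows(cells))
  class(out) <- c("equilibrium_sweep", class(out))
  out
}

set_cpt_param <- function(params, name, value) {
  switch(name,
    reference_point = {
      params$reference_point <- value
      params
    },
    alpha = {
      params$weighting <- weighting_spec("prelec", alpha = value,
                                         delta = params$weighting$delta)
      params
    },
    lambda = cpt_params(
      utility_spec("power", gamma = params$utility$gamma, lambda = value),
      params$weighting, params$reference_point),
    gamma = cpt_params(
      utility_spec("power", gamma = value, lambda = params$utility$lambda),
      params$weighting, params$reference_point),
    stop("unknown CPT parameter: ", name))
}

#' @export
autoplot.equilibrium_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value1, y = .data$value2,
                                       fill = .data$p_star)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = object$param1[1], y = object$param2[1],
                  fill = "P(first action)") +
    ggplot2::theme_minimal()
}
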