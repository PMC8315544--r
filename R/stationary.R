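#' Condition the Markov game on a joint policy
#'
#' Collapses the joint-action kernels into one Markov chain by averaging
#' over both agents' (state-dependent) action mixtures:
#' `P(s, s') = sum_{a1, a2} P_{a1,a2}(s, s') pi1(a1|s) pi2(a2|s)`.
#'
#' @param kernel A [joint_kernel()].
#' @param policy1,policy2 Policy matrices for agents 1 and 2.
#' @return A row-stochastic `n^2 x n^2` matrix.
#' @export
condition_chain <- function(kernel, policy1, policy2) {
  stopifnot(inherits(kernel, "joint_kernel"))
  n <- attr(kernel, "n")
  nj <- n^2
  stopifnot(is.matrix(policy1), nrow(policy1) == nj,
            is.matrix(policy2), nrow(policy2) == nj)
  P <- matrix(0, nj, nj)
  for (a1 in canyon_actions()) {
    for (a2 in canyon_actions()) {
      w <- policy1[, a1] * policy2[, a2]
      P <- P + w * kernel[[paste(a1, a2, sep = "|")]]
    }
  }
  P
}

#' Stationary distribution of a finite Markov chain
#'
#' The unique left fixed vector `rho = rho P` with unit mass, for an
#' irreducible row-stochastic chain. Irreducibility is verified first by
#' strong-connectivity search on the positive-entry graph; the solution is
#' obtained by eigen-decomposition of the transpose and polished by power
#' iteration until the sup-norm residual is below `1e-10` (pure power
#' iteration from the uniform vector is the fallback if the
#' eigen-decomposition is degenerate).
#'
#' @param chain Row-stochastic square matrix.
#' @return An object of class `stationary_distribution`: a list with `rho`
#'   (probability vector), `residual`, and `method`.
#' @examples
#' stationary_distribution(matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE))
#' @export
stationary_distribution <- function(chain) {
  stopifnot(is.matrix(chain), nrow(chain) == ncol(chain),
            all(is.finite(chain)), all(chain >= 0))
  nj <- nrow(chain)
  if (any(abs(rowSums(chain) - 1) > 1e-10)) {
    stop("chain rows must sum to 1")
  }
  g <- igraph::graph_from_adjacency_matrix(chain > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop(sprintf(
      "chain is reducible: %d communicating classes (sizes %s)",
      comp$no, sizes))
  }
  polish <- function(rho) {
    for (i in seq_len(100000L)) {
      rho_new <- as.numeric(rho %*% chain)
      rho_new <- rho_new / sum(rho_new)
      if (max(abs(rho_new - rho)) < 1e-13) {
        rho <- rho_new
        break
      }
      rho <- rho_new
    }
    rho
  }
  method <- "eigen"
  ev <- eigen(t(chain))
  near_unit <- which(abs(Mod(ev$values) - 1) < 1e-8)
  if (length(near_unit) == 1L) {
    rho <- Re(ev$vectors[, near_unit])
    rho <- abs(rho) / sum(abs(rho))
  } else {
    # aperiodic irreducible chains have one unit eigenvalue; degeneracy
    # here means numerical trouble, fall back to power iteration
    method <- "power"
    rho <- rep(1 / nj, nj)
  }
  rho <- polish(rho)
  residual <- max(abs(as.numeric(rho %*% chain) - rho))
  if (residual >= 1e-10) {
    stop(sprintf("stationary residual %.3g exceeds 1e-10", residual))
  }
  structure(list(rho = rho, residual = residual, method = method),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("<stationary_distribution>", length(x$rho), "states;",
      "residual", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Stationary distribution as a tibble of joint states
#'
#' @param x A [stationary_distribution()] over the joint states of a
#'   square canyon game.
#' @param ... Unused.
#' @return A tibble with columns `s1`, `s2`, `probability`.
#' @export
tidy.stationary_distribution <- function(x, ...) {
  n <- as.integer(round(sqrt(length(x$rho))))
  stopifnot(n^2 == length(x$rho))
  st <- joint_states(n)
  tibble::tibble(s1 = st$s1, s2 = st$s2, probability = x$rho)
}

#' @export
autoplot.stationary_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$s1, y = .data$s2,
                               fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "agent 1 position", y = "agent 2 position",
                  fill = "long-run\nprobability") +
    ggplot2::theme_minimal()
}

#' Coordination summaries of a stationary distribution
#'
#' @param rho A [stationary_distribution()] (or bare probability vector)
#'   over joint states.
#' @param spec The [canyon_spec()] the distribution refers to.
#' @return A list with `stag_mass` (probability both hunters occupy the
#'   stag position), `hare_mass` (probability at least one occupies the
#'   hare position), and `marginals` (tibble of per-agent position
#'   occupancies).
#' @export
coordination_metrics <- function(rho, spec) {
  stopifnot(inherits(spec, "canyon_spec"))
  if (inherits(rho, "stationary_distribution")) rho <- rho$rho
  n <- spec$n_positions
  stopifnot(length(rho) == n^2)
  st <- joint_states(n)
  stag_mass <- sum(rho[st$s1 == spec$stag_position &
                         st$s2 == spec$stag_position])
  hare_mass <- sum(rho[st$s1 == spec$hare_position |
                         st$s2 == spec$hare_position])
  marg <- dplyr::bind_rows(
    tibble::tibble(agent = 1L, position = 0:(n - 1L),
                   probability = as.numeric(tapply(rho, st$s1, sum))),
    tibble::tibble(agent = 2L, position = 0:(n - 1L),
                   probability = as.numeric(tapply(rho, st$s2, sum))))
  list(stag_mass = stag_mass, hare_mass = hare_mass, marginals = marg)
}

#' Stationary distribution induced by tower policies
#'
#' Conditions the joint kernel on `(pi1^(k1), pi2^(k2))` from a
#' [level_k_tower()] and solves for the stationary distribution.
#'
#' @param tower A [level_k_tower()].
#' @param k1,k2 Sophistication levels for agents 1 and 2 (at most the
#'   tower's `k_max`).
#' @param kernel Optional precomputed [joint_kernel()] for the tower's
#'   environment.
#' @return A [stationary_distribution()].
#' @export
tower_stationary <- function(tower, k1, k2 = k1,
                             kernel = joint_kernel(
                               single_agent_kernel(tower$spec))) {
  stopifnot(inherits(tower, "level_k_tower"),
            k1 >= 0, k1 <= tower$k_max, k2 >= 0, k2 <= tower$k_max)
  chain <- condition_chain(kernel, tower$agent1[[k1 + 1L]]$policy,
                           tower$agent2[[k2 + 1L]]$policy)
  stationary_distribution(chain)
}
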