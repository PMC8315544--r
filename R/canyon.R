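#' Canyon stag-hunt environment specification
#'
#' A one-dimensional hunting region of `n_positions` areas (states
#' `0 .. n_positions - 1`) on a canyon floor, occupied by two hunters.
#' One position holds hares (a small reward either hunter can collect
#' alone) and one holds stags (a large reward paid only when both hunters
#' stand on it together). Movement is noisy: the intended displacement of
#' each action succeeds with probability `p_intended`, the agent slips and
#' stays with probability `p_stay_slip`, and slips in the opposite
#' direction with probability `p_opposite_slip`; for Stay the two slip
#' masses go one step each way. Probability mass that would leave the grid
#' is added to staying.
#'
#' The default 16-position layout (hares at 3, stags at 11, rewards 1
#' and 5) is the study environment; smaller instances with the same slip
#' rule serve as test fixtures (see [fixture_canyon()]).
#'
#' @param n_positions Number of positions (at least 2).
#' @param hare_position,stag_position Prey positions, distinct, in
#'   `0 .. n_positions - 1`.
#' @param hare_reward Reward for standing on the hare position (paid
#'   unconditionally on the other hunter's position).
#' @param stag_reward Reward paid to each hunter when both stand on the
#'   stag position.
#' @param lone_stag_reward Reward for standing on the stag position alone
#'   (default 0: stags cannot be hunted alone).
#' @param p_intended,p_stay_slip,p_opposite_slip Slip model probabilities;
#'   must sum to 1.
#' @return An object of class `canyon_spec`.
#' @examples
#' canyon_spec()
#' fixture_canyon(4, hare = 0, stag = 3)
#' @export
canyon_spec <- function(n_positions = 16L, hare_position = 3L,
                        stag_position = 11L, hare_reward = 1,
                        stag_reward = 5, lone_stag_reward = 0,
                        p_intended = 0.6, p_stay_slip = 0.2,
                        p_opposite_slip = 0.2) {
  n_positions <- as.integer(n_positions)
  hare_position <- as.integer(hare_position)
  stag_position <- as.integer(stag_position)
  stopifnot(n_positions >= 2L,
            hare_position >= 0L, hare_position < n_positions,
            stag_position >= 0L, stag_position < n_positions,
            hare_position != stag_position,
            is.finite(hare_reward), is.finite(stag_reward),
            is.finite(lone_stag_reward),
            p_intended >= 0, p_stay_slip >= 0, p_opposite_slip >= 0)
  if (abs(p_intended + p_stay_slip + p_opposite_slip - 1) > 1e-12) {
    stop("slip probabilities must sum to 1")
  }
  structure(list(n_positions = n_positions, hare_position = hare_position,
                 stag_position = stag_position, hare_reward = hare_reward,
                 stag_reward = stag_reward, lone_stag_reward = lone_stag_reward,
                 p_intended = p_intended, p_stay_slip = p_stay_slip,
                 p_opposite_slip = p_opposite_slip),
            class = "canyon_spec")
}

#' @rdname canyon_spec
#' @param n,hare,stag Shorthand arguments for a reduced test canyon.
#' @param ... Passed on to `canyon_spec()`.
#' @export
fixture_canyon <- function(n, hare = 0L, stag = n - 1L, ...) {
  canyon_spec(n_positions = n, hare_position = hare, stag_position = stag, ...)
}

#' @export
print.canyon_spec <- function(x, ...) {
  cat("<canyon_spec>", x$n_positions, "positions; hare at", x$hare_position,
      sprintf("(reward %g);", x$hare_reward), "stag at", x$stag_position,
      sprintf("(joint reward %g)\n", x$stag_reward))
  cat(sprintf("  slip model: intended %g / stay %g / opposite %g\n",
              x$p_intended, x$p_stay_slip, x$p_opposite_slip))
  invisible(x)
}

#' Canyon action set
#' @return The character vector `c("left", "stay", "right")`.
#' @export
canyon_actions <- function() c("left", "stay", "right")

#' Single-agent transition kernels
#'
#' One row-stochastic `n x n` matrix per action. For Left/Right the
#' intended step gets `p_intended`, staying gets `p_stay_slip`, and the
#' opposite step gets `p_opposite_slip`; for Stay, staying gets
#' `p_intended` and the two slip masses go one step left and right.
#' Off-grid mass is clamped onto staying, which is what produces the
#' corner-only probability levels (0.4 and 0.8 under the defaults; the
#' full default set of distinct entries is {0, 0.2, 0.4, 0.6, 0.8}).
#'
#' @param spec A [canyon_spec()].
#' @return A named list of three `n x n` matrices (`left`, `stay`,
#'   `right`), class `single_agent_kernel`.
#' @examples
#' k <- single_agent_kernel(canyon_spec())
#' sort(unique(as.numeric(k$right)))
#' @export
single_agent_kernel <- function(spec = canyon_spec()) {
  stopifnot(inherits(spec, "canyon_spec"))
  n <- spec$n_positions
  # displacement probabilities per action: columns are steps -1, 0, +1
  disp <- rbind(
    left  = c(spec$p_intended, spec$p_stay_slip, spec$p_opposite_slip),
    stay  = c(spec$p_stay_slip, spec$p_intended, spec$p_opposite_slip),
    right = c(spec$p_opposite_slip, spec$p_stay_slip, spec$p_intended)
  )
  kernels <- lapply(canyon_actions(), function(a) {
    M <- matrix(0, n, n)
    for (s in seq_len(n)) {
      for (d in -1:1) {
        target <- s + d
        pr <- disp[a, d + 2L]
        if (target < 1L || target > n) target <- s # clamp off-grid to stay
        M[s, target] <- M[s, target] + pr
      }
    }
    M
  })
  names(kernels) <- canyon_actions()
  structure(kernels, class = "single_agent_kernel", n = n)
}

#' Joint transition kernels of the two-hunter Markov game
#'
#' Combines two single-agent kernels into one row-stochastic
#' `n^2 x n^2` matrix per joint action via
#' `P(a1, a2) = (I (x) P(a1) + P(a2) (x) I) / 2`: in each time step
#' exactly one of the two hunters moves (each with probability 1/2), so an
#' action of one agent can never change the other agent's position, and
#' the joint dynamics do not depend on who acts first.
#'
#' Joint states are flattened as `index = s2 * n + s1` (0-based positions);
#' helpers [joint_index()] and [joint_states()] expose the convention.
#'
#' @param kernel1,kernel2 [single_agent_kernel()] objects of equal size
#'   (agent 1 and agent 2).
#' @return A named list of `n_actions^2` matrices with names like
#'   `"left|stay"` (agent 1's action first), class `joint_kernel`.
#' @export
joint_kernel <- function(kernel1, kernel2 = kernel1) {
  stopifnot(inherits(kernel1, "single_agent_kernel"),
            inherits(kernel2, "single_agent_kernel"))
  n <- attr(kernel1, "n")
  if (attr(kernel2, "n") != n) stop("kernel size mismatch")
  I <- diag(n)
  acts <- canyon_actions()
  out <- list()
  for (a2 in acts) {
    for (a1 in acts) {
      out[[paste(a1, a2, sep = "|")]] <-
        (kronecker(I, kernel1[[a1]]) + kronecker(kernel2[[a2]], I)) / 2
    }
  }
  structure(out, class = "joint_kernel", n = n)
}

#' Joint-state indexing helpers
#'
#' Positions are 0-based; the 1-based flat index of joint state
#' `(s1, s2)` is `s2 * n + s1 + 1`.
#'
#' @param s1,s2 Positions of agents 1 and 2 (0-based, vectorized).
#' @param n Number of positions.
#' @return `joint_index()`: integer flat indices. `joint_states()`: a
#'   tibble of all joint states in flat-index order with columns `index`,
#'   `s1`, `s2`.
#' @export
joint_index <- function(s1, s2, n) {
  stopifnot(all(s1 >= 0), all(s1 < n), all(s2 >= 0), all(s2 < n))
  as.integer(s2 * n + s1 + 1L)
}

#' @rdname joint_index
#' @export
joint_states <- function(n) {
  idx <- seq_len(n^2)
  tibble::tibble(index = idx,
                 s1 = as.integer((idx - 1L) %% n),
                 s2 = as.integer((idx - 1L) %/% n))
}

#' Per-step rewards of the canyon stag hunt
#'
#' Agent `i` earns `hare_reward` whenever its own position is the hare
#' position, regardless of the other hunter; `stag_reward` when both
#' hunters stand on the stag position; `lone_stag_reward` (default 0) when
#' it stands on the stag position alone; and 0 elsewhere.
#'
#' @param spec A [canyon_spec()].
#' @param agent `1` or `2`.
#' @param s1,s2 Positions of agents 1 and 2 (0-based, vectorized).
#' @return Numeric vector of rewards.
#' @examples
#' canyon_reward(canyon_spec(), 1, s1 = c(3, 11, 11), s2 = c(7, 5, 11))
#' @export
canyon_reward <- function(spec, agent, s1, s2) {
  stopifnot(inherits(spec, "canyon_spec"), agent %in% c(1, 2))
  n <- spec$n_positions
  stopifnot(all(s1 >= 0), all(s1 < n), all(s2 >= 0), all(s2 < n))
  own <- if (agent == 1) s1 else s2
  other <- if (agent == 1) s2 else s1
  r <- numeric(length(own))
  r[own == spec$hare_position] <- spec$hare_reward
  lone <- own == spec$stag_position & other != spec$stag_position
  joint <- own == spec$stag_position & other == spec$stag_position
  r[lone] <- spec$lone_stag_reward
  r[joint] <- spec$stag_reward
  r
}

#' Reward vector over all joint states
#'
#' @param spec A [canyon_spec()].
#' @param agent `1` or `2`.
#' @return Numeric vector of length `n^2` in flat joint-state order.
#' @export
reward_vector <- function(spec, agent) {
  st <- joint_states(spec$n_positions)
  canyon_reward(spec, agent, st$s1, st$s2)
}
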