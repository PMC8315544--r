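#' Planning configuration for the CPT Bellman recursion
#'
#' @param discount_beta Discount factor in (0, 1): weight of future versus
#'   immediate reward in the value recursion.
#' @param tol Sup-norm convergence tolerance on the value function.
#' @param max_iter Iteration cap; exceeding it raises an error carrying the
#'   residual trace (the CPT backup has no contraction guarantee).
#' @param damping Step size in (0, 1]: `V <- (1 - damping) V + damping T(V)`.
#' @param tie_tol Actions whose backed-up value is within `tie_tol` of the
#'   per-state maximum share probability uniformly in the greedy policy.
#' @param approx_tol Acceptance threshold for limit-cycle plateaus. The
#'   CPT backup is not a contraction; where one-step outcomes straddle the
#'   reference point it can admit no exact fixed point and the iterates
#'   settle into a tiny limit cycle. If the residual trace plateaus below
#'   `approx_tol` the minimal-residual iterate is accepted and flagged
#'   approximate (its residual is reported alongside the result). Set to 0
#'   to demand strict convergence.
#' @return An object of class `planning_config`.
#' @export
planning_config <- function(discount_beta = 0.9, tol = 1e-8,
                            max_iter = 10000L, damping = 1, tie_tol = 1e-9,
                            approx_tol = 1e-4) {
  stopifnot(discount_beta > 0, discount_beta < 1, tol > 0,
            max_iter >= 1L, damping > 0, damping <= 1, tie_tol > 0,
            approx_tol >= 0)
  structure(list(discount_beta = discount_beta, tol = tol,
                 max_iter = as.integer(max_iter), damping = damping,
                 tie_tol = tie_tol, approx_tol = approx_tol),
            class = "planning_config")
}

#' Uniform joint-state policy
#'
#' The level-0 stereotype: in every joint state each of the three actions
#' is equally likely.
#'
#' @param spec A [canyon_spec()].
#' @return An `n^2 x 3` matrix with columns `left`, `stay`, `right`, rows
#'   in flat joint-state order, each row summing to 1.
#' @export
uniform_policy <- function(spec) {
  stopifnot(inherits(spec, "canyon_spec"))
  nj <- spec$n_positions^2
  matrix(1 / 3, nj, 3L, dimnames = list(NULL, canyon_actions()))
}

check_policy <- function(policy, spec) {
  nj <- spec$n_positions^2
  stopifnot(is.matrix(policy), nrow(policy) == nj, ncol(policy) == 3L,
            all(policy >= 0))
  if (any(abs(rowSums(policy) - 1) > 1e-12)) {
    stop("policy rows must sum to 1 within 1e-12")
  }
  invisible(policy)
}

#' Swap the two agents' roles in a joint-state object
#'
#' Maps a policy (or any per-joint-state vector/matrix) expressed over
#' states `(s1, s2)` to the same object expressed over `(s2, s1)`. For
#' identical agents, agent 2's level-k policy is the swap of agent 1's.
#'
#' @param x A policy matrix or a length-`n^2` vector in flat joint-state
#'   order.
#' @param n Number of positions.
#' @export
swap_agents <- function(x, n) {
  st <- joint_states(n)
  perm <- joint_index(st$s2, st$s1, n)
  if (is.matrix(x)) x[perm, , drop = FALSE] else x[perm]
}

# Internal planning context for one agent: successor stencil and
# displacement probabilities. Under the joint kernel at most one agent
# moves one step per transition, so every successor distribution (for any
# own action and any opponent mixture) lives on the 5-point stencil
# {own-1, own+1, other-1, other+1, stay}.
planner_ctx <- function(spec, agent, kernel = single_agent_kernel(spec)) {
  n <- spec$n_positions
  st <- joint_states(n)
  nj <- n^2
  own <- if (agent == 1) st$s1 else st$s2
  oth <- if (agent == 1) st$s2 else st$s1
  shift_idx <- function(who, d) {
    # flat index after moving `who` by d, clamped (prob there will be 0)
    if (who == "own") {
      o2 <- pmin(pmax(own + d, 0L), n - 1L)
      if (agent == 1) joint_index(o2, st$s2, n) else joint_index(st$s1, o2, n)
    } else {
      t2 <- pmin(pmax(oth + d, 0L), n - 1L)
      if (agent == 1) joint_index(st$s1, t2, n) else joint_index(t2, st$s2, n)
    }
  }
  succ <- cbind(own_m = shift_idx("own", -1L), own_p = shift_idx("own", +1L),
                oth_m = shift_idx("oth", -1L), oth_p = shift_idx("oth", +1L),
                stay = st$index)
  # displacement probabilities q(pos, action, d) for d in {-1, 0, +1},
  # with clamped off-grid mass already folded into d = 0
  disp_probs <- function(pos) {
    q <- array(0, dim = c(nj, 3L, 3L),
               dimnames = list(NULL, canyon_actions(), c("m", "z", "p")))
    for (a in canyon_actions()) {
      K <- kernel[[a]]
      at <- pos + 1L
      left_ok <- pos > 0L
      right_ok <- pos < n - 1L
      q[left_ok, a, "m"] <- K[cbind(at[left_ok], at[left_ok] - 1L)]
      q[, a, "z"] <- K[cbind(at, at)]
      q[right_ok, a, "p"] <- K[cbind(at[right_ok], at[right_ok] + 1L)]
    }
    q
  }
  list(spec = spec, agent = agent, n = n, nj = nj, succ = succ,
       q_own = disp_probs(own), q_oth = disp_probs(oth),
       reward = reward_vector(spec, agent))
}

# Opponent displacement mixture per joint state: nj x 3 (d = -1, 0, +1)
mix_other <- function(ctx, policy_other) {
  cbind(m = rowSums(policy_other * ctx$q_oth[, , "m"]),
        z = rowSums(policy_other * ctx$q_oth[, , "z"]),
        p = rowSums(policy_other * ctx$q_oth[, , "p"]))
}

# Successor probabilities on the stencil for one own action: nj x 5
stencil_probs <- function(ctx, action, qmix) {
  cbind(own_m = 0.5 * ctx$q_own[, action, "m"],
        own_p = 0.5 * ctx$q_own[, action, "p"],
        oth_m = 0.5 * qmix[, "m"],
        oth_p = 0.5 * qmix[, "p"],
        stay  = 0.5 * ctx$q_own[, action, "z"] + 0.5 * qmix[, "z"])
}

#' One-step prospect at a joint state
#'
#' The discrete distribution of `r_i(s) + beta * V(s')` over successor
#' joint states `s'`, when the acting agent plays `action` in state
#' `(s1, s2)` and the other agent mixes according to its policy. This is
#' the prospect whose CPT value the Bellman backup assigns to `(s, action)`
#' (the reference point is not subtracted here; it is applied inside
#' [cpt_value()]).
#'
#' @param spec A [canyon_spec()].
#' @param s1,s2 Joint state (0-based positions).
#' @param action One of `"left"`, `"stay"`, `"right"`.
#' @param policy_other Opponent policy matrix.
#' @param V Value function (length `n^2` vector, flat joint-state order).
#' @param params A [cpt_params()] (unused in the distribution itself but
#'   kept for interface symmetry).
#' @param config A [planning_config()] supplying the discount factor.
#' @param agent Acting agent, `1` or `2`.
#' @return A [prospect()].
#' @export
step_prospect <- function(spec, s1, s2, action, policy_other, V,
                          params = eut_params(),
                          config = planning_config(), agent = 1) {
  stopifnot(inherits(spec, "canyon_spec"), action %in% canyon_actions())
  check_policy(policy_other, spec)
  stopifnot(is.numeric(V), length(V) == spec$n_positions^2)
  ctx <- planner_ctx(spec, agent)
  s <- joint_index(s1, s2, spec$n_positions)
  qmix <- mix_other(ctx, policy_other)
  pm <- stencil_probs(ctx, action, qmix)[s, ]
  outcomes <- ctx$reward[s] + config$discount_beta * V[ctx$succ[s, ]]
  prospect(outcomes, pm)
}

# Shared iteration driver: step() maps V -> T(V).
#
# The CPT backup is not a sup-norm contraction: where one-step outcomes
# straddle the reference point the decision weights sum above 1 and the
# map is locally expansive, in which case no exact fixed point need exist
# and the iterates settle into a tiny limit cycle instead of converging
# (frozen-ordering linear solves confirm that adjacent affine pieces of
# the backup have distinct fixed points, i.e. the cycle is a property of
# the equation, not of the stepping scheme). When the residual trace
# plateaus below `approx_tol`, the iterate with the smallest Bellman
# residual seen is accepted and flagged approximate, with its residual
# reported; a genuinely diverging recursion still errors.
iterate_values <- function(step, nj, config, what) {
  V <- numeric(nj)
  trace <- numeric(config$max_iter)
  V_best <- V
  res_best <- Inf
  for (it in seq_len(config$max_iter)) {
    V_new <- step(V)
    V_new <- (1 - config$damping) * V + config$damping * V_new
    res <- max(abs(V_new - V))
    trace[it] <- res
    V <- V_new
    if (res < res_best) {
      res_best <- res
      V_best <- V
    }
    if (res < config$tol) {
      return(list(V = V, iterations = it, residual = res,
                  converged = TRUE, approximate = FALSE,
                  trace = trace[seq_len(it)]))
    }
    if (it >= 400L && it %% 100L == 0L) {
      win <- trace[(it - 199L):it]
      plateau <- max(win) < config$approx_tol &&
        (max(win) - min(win)) < 0.05 * max(win)
      if (plateau) {
        return(list(V = V_best, iterations = it, residual = res_best,
                    converged = TRUE, approximate = TRUE,
                    trace = trace[seq_len(it)]))
      }
    }
  }
  if (res_best < config$approx_tol) {
    return(list(V = V_best, iterations = config$max_iter,
                residual = res_best, converged = TRUE, approximate = TRUE,
                trace = trace))
  }
  rlang::abort(
    sprintf("%s did not converge in %d iterations (last residual %.3g)",
            what, config$max_iter, trace[config$max_iter]),
    class = "cptcoord_no_convergence", residuals = trace)
}

warn_kt1992 <- function(params) {
  if (params$weighting$kind == "kt1992") {
    rlang::warn(paste("kt1992 weighting inside the Markov solver is known",
                      "to be numerically unstable; prefer the Prelec form"),
                .frequency = "once", .frequency_id = "cptcoord_kt1992")
  }
}

#' CPT policy evaluation
#'
#' Fixed point of the CPT Bellman operator for a fixed pair of policies:
#' `V(s)` is the CPT value of the one-step prospect of
#' `r_i(s) + beta * V(s')`, with the agent's own action mixture pooled
#' *inside* the probability weighting (the successor distribution mixes
#' over both agents' actions before rank-dependent weighting). With
#' identity utility/weighting and `b = 0` this reduces to classical linear
#' policy evaluation.
#'
#' @param policy_own,policy_other Policy matrices for the evaluated agent
#'   and its opponent.
#' @param spec A [canyon_spec()].
#' @param params A [cpt_params()].
#' @param config A [planning_config()].
#' @param agent Evaluated agent, `1` or `2`.
#' @return A list with `value` (length `n^2` vector), `iterations`,
#'   `residual`.
#' @export
policy_value <- function(policy_own, policy_other, spec,
                         params = eut_params(),
                         config = planning_config(), agent = 1) {
  stopifnot(inherits(spec, "canyon_spec"))
  check_policy(policy_own, spec)
  check_policy(policy_other, spec)
  warn_kt1992(params)
  ctx <- planner_ctx(spec, agent)
  qmix <- mix_other(ctx, policy_other)
  pms <- lapply(canyon_actions(), function(a) stencil_probs(ctx, a, qmix))
  names(pms) <- canyon_actions()
  # pool own actions inside the weighting: mix successor probabilities
  pm <- Reduce(`+`, lapply(canyon_actions(), function(a) {
    policy_own[, a] * pms[[a]]
  }))
  beta <- config$discount_beta
  step <- function(V) {
    O <- ctx$reward + beta * matrix(V[ctx$succ], ctx$nj)
    cpt_value_rows(O, pm, params)
  }
  out <- iterate_values(step, ctx$nj, config, "policy evaluation")
  list(value = out$V, iterations = out$iterations, residual = out$residual,
       approximate = out$approximate)
}

#' CPT best response to an opponent policy
#'
#' Greedy CPT value iteration: `V(s) <- max_a` CPT value of the one-step
#' prospect under own action `a`. On convergence the returned policy puts
#' uniform probability on every action within `tie_tol` of the per-state
#' maximum, preserving ties exactly.
#'
#' @inheritParams policy_value
#' @return A list with `policy` (matrix), `value` (vector), `q_values`
#'   (`n^2 x 3` matrix of per-action backups at the fixed point),
#'   `iterations`, `residual`.
#' @export
best_response <- function(policy_other, spec, params = eut_params(),
                          config = planning_config(), agent = 1) {
  stopifnot(inherits(spec, "canyon_spec"))
  check_policy(policy_other, spec)
  warn_kt1992(params)
  ctx <- planner_ctx(spec, agent)
  qmix <- mix_other(ctx, policy_other)
  pms <- lapply(canyon_actions(), function(a) stencil_probs(ctx, a, qmix))
  names(pms) <- canyon_actions()
  beta <- config$discount_beta
  q_backup <- function(V) {
    O <- ctx$reward + beta * matrix(V[ctx$succ], ctx$nj)
    vapply(canyon_actions(), function(a) cpt_value_rows(O, pms[[a]], params),
           numeric(ctx$nj))
  }
  step <- function(V) {
    Q <- q_backup(V)
    pmax(Q[, 1L], Q[, 2L], Q[, 3L])
  }
  out <- iterate_values(step, ctx$nj, config, "best response")
  Q <- q_backup(out$V)
  best <- pmax(Q[, 1L], Q[, 2L], Q[, 3L])
  tied <- Q >= best - config$tie_tol
  policy <- tied / rowSums(tied)
  dimnames(policy) <- list(NULL, canyon_actions())
  list(policy = policy, value = out$V, q_values = Q,
       iterations = out$iterations, residual = out$residual,
       approximate = out$approximate)
}

#' Level-k policy tower
#'
#' Builds the bounded theory-of-mind recursion: level 0 is the uniform
#' stereotype for both agents; for `k >= 1`, agent i's level-k policy is
#' its CPT best response (under its own parameters) to the other agent's
#' level-(k-1) policy. Agents may be heterogeneous (e.g., one
#' expected-utility, one CPT agent). When both agents share identical
#' parameters the tower is computed once for agent 1 and mirrored through
#' [swap_agents()], which is exact by the left-right symmetry of the
#' construction.
#'
#' @param k_max Highest sophistication level (`>= 0`).
#' @param spec A [canyon_spec()].
#' @param params1,params2 [cpt_params()] for agents 1 and 2.
#' @param config A [planning_config()].
#' @return An object of class `level_k_tower`: for each agent, a list of
#'   levels `0..k_max`, each with `policy`, `value`, `iterations`,
#'   `residual`.
#' @examples
#' \donttest{
#' tw <- level_k_tower(2, fixture_canyon(4, hare = 0, stag = 3))
#' glance(tw)
#' }
#' @export
level_k_tower <- function(k_max, spec, params1 = eut_params(),
                          params2 = params1, config = planning_config()) {
  stopifnot(k_max >= 0, inherits(spec, "canyon_spec"))
  k_max <- as.integer(k_max)
  unif <- uniform_policy(spec)
  symmetric <- identical(params1, params2)
  lvl0 <- function(params, agent) {
    pv <- policy_value(unif, unif, spec, params, config, agent)
    list(policy = unif, value = pv$value, iterations = pv$iterations,
         residual = pv$residual, approximate = pv$approximate)
  }
  tower1 <- list(lvl0(params1, 1L))
  tower2 <- list(if (symmetric) {
    l <- tower1[[1]]
    l$value <- swap_agents(l$value, spec$n_positions)
    l
  } else lvl0(params2, 2L))
  with_level <- function(expr, agent, k) {
    tryCatch(expr, cptcoord_no_convergence = function(e) {
      rlang::abort(sprintf("agent %d, level %d: %s", agent, k, e$message),
                   class = "cptcoord_no_convergence", parent = e)
    })
  }
  for (k in seq_len(k_max)) {
    br1 <- with_level(
      best_response(tower2[[k]]$policy, spec, params1, config, agent = 1L),
      1L, k)
    tower1[[k + 1L]] <- br1[c("policy", "value", "iterations", "residual", "approximate")]
    if (symmetric) {
      tower2[[k + 1L]] <- list(
        policy = swap_agents(br1$policy, spec$n_positions),
        value = swap_agents(br1$value, spec$n_positions),
        iterations = br1$iterations, residual = br1$residual,
        approximate = br1$approximate)
    } else {
      br2 <- with_level(
        best_response(tower1[[k]]$policy, spec, params2, config, agent = 2L),
        2L, k)
      tower2[[k + 1L]] <- br2[c("policy", "value", "iterations", "residual", "approximate")]
    }
  }
  structure(list(agent1 = tower1, agent2 = tower2, k_max = k_max,
                 spec = spec, params1 = params1, params2 = params2,
                 config = config),
            class = "level_k_tower")
}

#' @export
print.level_k_tower <- function(x, ...) {
  cat("<level_k_tower> k =", 0:x$k_max, "\n")
  cat("  environment:", x$spec$n_positions, "positions;",
      "discount beta =", x$config$discount_beta, "\n")
  invisible(x)
}

#' Tower policies and values as a tibble
#'
#' @param x A [level_k_tower()].
#' @param ... Unused.
#' @return One row per (agent, level, joint state, action) with the policy
#'   probability and the state's value.
#' @export
tidy.level_k_tower <- function(x, ...) {
  st <- joint_states(x$spec$n_positions)
  one <- function(agent, k, lvl) {
    tibble::tibble(agent = agent, level = k,
                   s1 = rep(st$s1, 3L), s2 = rep(st$s2, 3L),
                   action = rep(canyon_actions(), each = nrow(st)),
                   probability = as.numeric(lvl$policy),
                   value = rep(lvl$value, 3L))
  }
  dplyr::bind_rows(
    purrr::imap(x$agent1, function(lvl, i) one(1L, i - 1L, lvl)),
    purrr::imap(x$agent2, function(lvl, i) one(2L, i - 1L, lvl)))
}

#' @rdname tidy.level_k_tower
#' @return `glance()`: one row per (agent, level) with convergence
#'   iterations, final residual, and the value of the joint stag state.
#' @export
glance.level_k_tower <- function(x, ...) {
  stag <- joint_index(x$spec$stag_position, x$spec$stag_position,
                      x$spec$n_positions)
  one <- function(agent, k, lvl) {
    tibble::tibble(agent = agent, level = k, iterations = lvl$iterations,
                   residual = lvl$residual, approximate = lvl$approximate,
                   stag_value = lvl$value[stag])
  }
  dplyr::bind_rows(
    purrr::imap(x$agent1, function(lvl, i) one(1L, i - 1L, lvl)),
    purrr::imap(x$agent2, function(lvl, i) one(2L, i - 1L, lvl)))
}
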