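# Independent oracles used across the suite: plain-loop implementations
# that deliberately avoid the package's vectorized code paths.

# random prospects / parameter sets under a fixed seed ------------------

random_prospect <- function(max_outcomes = 10) {
  k <- sample(1:max_outcomes, 1)
  o <- round(runif(k, -100, 100), 3)
  p <- runif(k)
  prospect(o, p / sum(p))
}

random_cpt_params <- function() {
  ut <- utility_spec("power", gamma = runif(1, 0.3, 1.5),
                     lambda = runif(1, 0.5, 3))
  wt <- switch(sample(3, 1),
    weighting_spec("prelec", alpha = runif(1, 0.3, 2),
                   delta = runif(1, 0.3, 1)),
    weighting_spec("kt1992", gamma_w = runif(1, 0.4, 1)),
    weighting_spec("identity"))
  cpt_params(ut, wt, reference_point = runif(1, -50, 50))
}

random_policy <- function(spec) {
  nj <- spec$n_positions^2
  m <- matrix(runif(nj * 3), nj, 3)
  m <- m / rowSums(m)
  colnames(m) <- canyon_actions()
  m
}

# dense joint kernel by explicit double loop (the Kronecker-free route) --

brute_joint_kernel <- function(k1, k2) {
  n <- attr(k1, "n")
  nj <- n^2
  out <- list()
  for (a2 in canyon_actions()) {
    for (a1 in canyon_actions()) {
      M <- matrix(0, nj, nj)
      for (s1 in 0:(n - 1)) for (s2 in 0:(n - 1)) {
        from <- s2 * n + s1 + 1
        for (t1 in 0:(n - 1)) for (t2 in 0:(n - 1)) {
          to <- t2 * n + t1 + 1
          p <- 0
          if (t2 == s2) p <- p + k1[[a1]][s1 + 1, t1 + 1] / 2
          if (t1 == s1) p <- p + k2[[a2]][s2 + 1, t2 + 1] / 2
          M[from, to] <- p
        }
      }
      out[[paste(a1, a2, sep = "|")]] <- M
    }
  }
  out
}

# policy-conditioned chain by explicit loops over the 9 action pairs ----

brute_condition_chain <- function(kernel, policy1, policy2) {
  nj <- nrow(kernel[[1]])
  P <- matrix(0, nj, nj)
  for (s in seq_len(nj)) {
    for (a1 in canyon_actions()) for (a2 in canyon_actions()) {
      P[s, ] <- P[s, ] +
        policy1[s, a1] * policy2[s, a2] *
        kernel[[paste(a1, a2, sep = "|")]][s, ]
    }
  }
  P
}

# classical expected-utility planning off the dense joint kernel -------

eut_policy_eval_solve <- function(policy1, policy2, spec, beta, agent = 1) {
  kern <- joint_kernel(single_agent_kernel(spec))
  P <- brute_condition_chain(kern, policy1, policy2)
  r <- reward_vector(spec, agent)
  solve(diag(nrow(P)) - beta * P, r)
}

eut_value_iteration <- function(policy_other, spec, beta, agent = 1,
                                tol = 1e-10, max_iter = 100000) {
  kern <- joint_kernel(single_agent_kernel(spec))
  nj <- spec$n_positions^2
  r <- reward_vector(spec, agent)
  # effective dense matrix per own action, opponent mixed row-wise
  eff <- lapply(canyon_actions(), function(a_own) {
    M <- matrix(0, nj, nj)
    for (a_oth in canyon_actions()) {
      key <- if (agent == 1) paste(a_own, a_oth, sep = "|") else
        paste(a_oth, a_own, sep = "|")
      M <- M + policy_other[, a_oth] * kern[[key]]
    }
    M
  })
  V <- numeric(nj)
  for (it in seq_len(max_iter)) {
    Q <- vapply(eff, function(M) r + beta * as.numeric(M %*% V), numeric(nj))
    V_new <- apply(Q, 1, max)
    if (max(abs(V_new - V)) < tol) return(list(V = V_new, Q = Q))
    V <- V_new
  }
  stop("oracle value iteration did not converge")
}

# exhaustive best response on a tiny canyon: enumerate every deterministic
# joint-state policy and evaluate each by exact linear solve
enumerate_best_value <- function(policy_other, spec, beta, agent = 1) {
  nj <- spec$n_positions^2
  stopifnot(nj <= 9)
  best <- rep(-Inf, nj)
  choices <- expand.grid(rep(list(1:3), nj))
  for (i in seq_len(nrow(choices))) {
    pol <- matrix(0, nj, 3, dimnames = list(NULL, canyon_actions()))
    pol[cbind(seq_len(nj), as.integer(choices[i, ]))] <- 1
    V <- if (agent == 1) {
      eut_policy_eval_solve(pol, policy_other, spec, beta, agent = 1)
    } else {
      eut_policy_eval_solve(policy_other, pol, spec, beta, agent = 2)
    }
    best <- pmax(best, V)
  }
  best
}

# one-step successor distribution by enumeration over (a_other, s') -----

brute_step_prospect <- function(spec, s1, s2, action, policy_other, V,
                                beta, agent = 1) {
  kern <- joint_kernel(single_agent_kernel(spec))
  n <- spec$n_positions
  s <- s2 * n + s1 + 1
  nj <- n^2
  probs <- numeric(nj)
  for (a_oth in canyon_actions()) {
    key <- if (agent == 1) paste(action, a_oth, sep = "|") else
      paste(a_oth, action, sep = "|")
    probs <- probs + policy_other[s, a_oth] * kern[[key]][s, ]
  }
  r <- canyon_reward(spec, agent, s1, s2)
  outcome <- r + beta * V
  keep <- probs > 0
  agg <- tapply(probs[keep], round(outcome[keep], 9), sum)
  list(outcomes = as.numeric(names(agg)), probabilities = as.numeric(agg))
}
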