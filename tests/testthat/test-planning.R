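test_that("step prospect matches enumeration over opponent actions", {
  spec <- fixture_canyon(3, hare = 0, stag = 2)
  cfg <- planning_config(discount_beta = 0.9)
  set.seed(60)
  pol <- random_policy(spec)
  V <- runif(9, 0, 10)
  for (case in 1:10) {
    s1 <- sample(0:2, 1); s2 <- sample(0:2, 1)
    a <- sample(canyon_actions(), 1)
    agent <- sample(1:2, 1)
    sp <- step_prospect(spec, s1, s2, a, pol, V, config = cfg, agent = agent)
    bf <- brute_step_prospect(spec, s1, s2, a, pol, V, 0.9, agent)
    expect_equal(sp$outcomes, bf$outcomes, tolerance = 1e-9)
    expect_equal(sp$probabilities, bf$probabilities, tolerance = 1e-12)
  }
  # flat value function, no reward: degenerate prospect
  sp0 <- step_prospect(spec, 1, 1, "stay", pol, numeric(9), config = cfg)
  expect_equal(sp0$outcomes, 0)
  expect_equal(sp0$probabilities, 1)
  # support never exceeds the five-point stencil
  spx <- step_prospect(spec, 1, 1, "left", pol, runif(9), config = cfg)
  expect_lte(length(spx$outcomes), 5L)
})

test_that("policy evaluation matches the exact linear solve in the EUT limit", {
  cfg <- planning_config(discount_beta = 0.9, tol = 1e-10)
  set.seed(61)
  # small fixture, random policies, both agents
  spec <- fixture_canyon(4, hare = 0, stag = 3)
  for (agent in 1:2) {
    p1 <- random_policy(spec)
    p2 <- random_policy(spec)
    own <- if (agent == 1) p1 else p2
    oth <- if (agent == 1) p2 else p1
    pv <- policy_value(own, oth, spec, eut_params(), cfg, agent)
    exact <- if (agent == 1) {
      eut_policy_eval_solve(p1, p2, spec, 0.9, agent = 1)
    } else {
      eut_policy_eval_solve(p1, p2, spec, 0.9, agent = 2)
    }
    expect_equal(pv$value, exact, tolerance = 1e-6)
    expect_false(pv$approximate)
  }
})

test_that("zero-reward canyons evaluate to zero value", {
  spec <- canyon_spec(4, 0, 3, hare_reward = 0, stag_reward = 0)
  pv <- policy_value(uniform_policy(spec), uniform_policy(spec), spec,
                     markov_cpt_params(), planning_config())
  expect_equal(pv$value, numeric(16))
})

test_that("best response matches classical value iteration in the EUT limit", {
  spec <- canyon_spec() # the full 256-state game
  cfg <- planning_config(discount_beta = 0.9, tol = 1e-9)
  set.seed(62)
  pol2 <- random_policy(spec)
  br <- best_response(pol2, spec, eut_params(), cfg, agent = 1)
  oracle <- eut_value_iteration(pol2, spec, 0.9, agent = 1)
  expect_equal(br$value, oracle$V, tolerance = 1e-6)
  # Bellman optimality residual at the fixed point
  expect_lt(max(abs(apply(br$q_values, 1, max) - br$value)), 1e-8)
  # greedy actions agree wherever the oracle's argmax is unambiguous
  margin <- apply(oracle$Q, 1, function(q) diff(sort(q, decreasing = TRUE)[2:1]))
  clear <- margin > 1e-6
  expect_equal(max.col(br$q_values)[clear], max.col(oracle$Q)[clear])
})

test_that("best response matches exhaustive policy enumeration on a 2-site canyon", {
  spec <- fixture_canyon(2, hare = 0, stag = 1)
  cfg <- planning_config(discount_beta = 0.9, tol = 1e-10)
  set.seed(63)
  for (agent in 1:2) {
    pol_other <- random_policy(spec)
    br <- best_response(pol_other, spec, eut_params(), cfg, agent = agent)
    best <- enumerate_best_value(pol_other, spec, 0.9, agent = agent)
    expect_equal(br$value, best, tolerance = 1e-6)
  }
})

test_that("zero rewards make every action tie into the uniform policy", {
  spec <- canyon_spec(4, 0, 3, hare_reward = 0, stag_reward = 0)
  br <- best_response(uniform_policy(spec), spec, markov_cpt_params(),
                      planning_config())
  expect_equal(br$value, numeric(16))
  expect_equal(unclass(br$policy), unclass(uniform_policy(spec)),
               ignore_attr = TRUE)
})

test_that("the one-step CPT backup is monotone in the EUT limit", {
  spec <- fixture_canyon(3, hare = 0, stag = 2)
  cfg <- planning_config(discount_beta = 0.9)
  set.seed(64)
  pol <- random_policy(spec)
  for (i in 1:10) {
    V <- runif(9, 0, 5)
    V2 <- V + runif(9, 0, 2) # V2 >= V elementwise
    s1 <- sample(0:2, 1); s2 <- sample(0:2, 1)
    a <- sample(canyon_actions(), 1)
    v_lo <- cpt_value(step_prospect(spec, s1, s2, a, pol, V, config = cfg),
                      eut_params())
    v_hi <- cpt_value(step_prospect(spec, s1, s2, a, pol, V2, config = cfg),
                      eut_params())
    expect_gte(v_hi, v_lo)
  }
})

test_that("level-k towers anchor at uniform and best-respond upward", {
  spec <- fixture_canyon(4, hare = 0, stag = 3)
  cfg <- planning_config(discount_beta = 0.9)
  tw <- level_k_tower(0, spec, markov_cpt_params(), config = cfg)
  expect_equal(unclass(tw$agent1[[1]]$policy), unclass(uniform_policy(spec)),
               ignore_attr = TRUE)
  tw2 <- level_k_tower(2, spec, markov_cpt_params(), config = cfg)
  # each level is the recorded best response to the level below
  br <- best_response(tw2$agent2[[2]]$policy, spec, markov_cpt_params(),
                      cfg, agent = 1)
  expect_equal(tw2$agent1[[3]]$policy, br$policy)
  expect_equal(tw2$agent1[[3]]$value, br$value)
})

test_that("identical agents: mirrored tower equals the direct computation", {
  spec <- fixture_canyon(4, hare = 1, stag = 3)
  cfg <- planning_config(discount_beta = 0.9)
  params <- markov_cpt_params()
  tw <- level_k_tower(2, spec, params, config = cfg)
  # direct agent-2 best responses, bypassing the swap shortcut
  br2_1 <- best_response(uniform_policy(spec), spec, params, cfg, agent = 2)
  expect_equal(tw$agent2[[2]]$policy, br2_1$policy)
  expect_equal(tw$agent2[[2]]$value, br2_1$value)
  br2_2 <- best_response(tw$agent1[[2]]$policy, spec, params, cfg, agent = 2)
  expect_equal(tw$agent2[[3]]$policy, br2_2$policy)
  expect_equal(tw$agent2[[3]]$value, br2_2$value, tolerance = 1e-7)
})

test_that("heterogeneous towers keep per-agent parameters apart", {
  spec <- fixture_canyon(4, hare = 0, stag = 3)
  cfg <- planning_config(discount_beta = 0.9)
  tw <- level_k_tower(1, spec, eut_params(), markov_cpt_params(), cfg)
  br1 <- best_response(uniform_policy(spec), spec, eut_params(), cfg, 1)
  br2 <- best_response(uniform_policy(spec), spec, markov_cpt_params(), cfg, 2)
  expect_equal(tw$agent1[[2]]$value, br1$value)
  expect_equal(tw$agent2[[2]]$value, br2$value)
})

test_that("towers are deterministic across repeated runs", {
  spec <- fixture_canyon(3, hare = 0, stag = 2)
  a <- level_k_tower(2, spec, markov_cpt_params())
  b <- level_k_tower(2, spec, markov_cpt_params())
  expect_identical(a$agent1[[3]]$value, b$agent1[[3]]$value)
  expect_identical(a$agent2[[3]]$policy, b$agent2[[3]]$policy)
})

test_that("tidy and glance expose tower structure", {
  spec <- fixture_canyon(3, hare = 0, stag = 2)
  tw <- level_k_tower(1, spec, markov_cpt_params())
  td <- tidy(tw)
  expect_equal(nrow(td), 2 * 2 * 9 * 3)
  expect_true(all(abs(tapply(td$probability,
                             interaction(td$agent, td$level, td$s1, td$s2),
                             sum) - 1) < 1e-12))
  gl <- glance(tw)
  expect_equal(nrow(gl), 4L)
  expect_true(all(gl$residual < 1e-8))
})

test_that("the planner errors with a residual trace when it diverges", {
  spec <- fixture_canyon(3, hare = 0, stag = 2)
  cfg <- planning_config(discount_beta = 0.9, max_iter = 5, approx_tol = 0)
  err <- tryCatch(
    best_response(uniform_policy(spec), spec, markov_cpt_params(), cfg),
    error = function(e) e)
  expect_s3_class(err, "cptcoord_no_convergence")
  expect_length(err$residuals, 5L)
})
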