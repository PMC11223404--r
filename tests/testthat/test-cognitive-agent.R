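# Agent dynamics: initialisation, feedback arithmetic, boundedness,
# determinism, and the central cycle-budget/inhibition trade-off.

test_that("profiles carry the tabulated level values", {
  lv <- ef_levels()
  expect_equal(unname(lv$updating), c(0.07, 0.12, 0.24, 0.37))
  expect_equal(unname(lv$inhibition), c(0.10, 0.22, 0.44, 0.65))
  expect_equal(lv$shifting$poor, c(0, 0))
  expect_equal(lv$shifting$medium, c(1, -1))
  expect_equal(lv$shifting$high, c(2, -2))
  p <- ef_profile("medium", "high", "poor")
  expect_equal(p$updating, 0.24)
  expect_equal(p$shift_toward, 2)
  expect_equal(p$shift_away, -2)
  expect_equal(p$inhibition, 0.22)
  # expert = high / 0.99
  ex <- ef_profile_expert()
  expect_equal(ex$updating, 0.37 / 0.99)
  expect_equal(ex$inhibition, 0.65 / 0.99)
})

test_that("agents initialise with uniform evidence and zero activation", {
  a <- make_agent(ef_profile("high", "high", "high"), 60, seed = 1)
  expect_equal(a$state$evidence, rep(1 / 3, 3))
  expect_equal(a$state$activation, rep(0, 3))
  expect_true(is.na(a$state$prepotent))
  expect_false(any(a$state$disconfirmed))
})

test_that("invalid cycle budgets and profiles are configuration errors", {
  expect_error(make_agent(ef_profile("high", "high", "high"), 0),
               class = "wcstsim_config_error")
  expect_error(make_agent(list(), 20), class = "wcstsim_config_error")
})

test_that("feedback updates evidence with the updating gain", {
  p <- ef_profile("high", "poor", "medium") # updating 0.37
  k <- agent_constants(decay = 1)
  st <- agent_state_init()
  st$evidence <- c(0.9, 0.05, 0.05)
  out <- process_feedback(st, "color", "incorrect", p, k)
  expect_equal(out$evidence[1], 0.9 - 0.37 * 0.9) # = 0.567
  out2 <- process_feedback(st, "shape", "correct", p, k)
  expect_equal(out2$evidence[2], 0.05 + 0.37 * (1 - 0.05))
  expect_equal(out2$prepotent, 2L)
  # zero-gain identity under a hypothetical zero updating value
  p0 <- p
  p0$updating <- 0
  out3 <- process_feedback(st, "color", "incorrect", p0, k)
  expect_equal(out3$evidence, st$evidence)
})

test_that("positive feedback clears disconfirmed flags; negative sets them", {
  p <- ef_profile("medium", "poor", "medium")
  k <- agent_constants()
  st <- agent_state_init()
  st <- process_feedback(st, "color", "incorrect", p, k)
  expect_true(st$disconfirmed[1])
  st <- process_feedback(st, "shape", "correct", p, k)
  expect_false(any(st$disconfirmed))
  expect_equal(st$prepotent, 2L)
})

test_that("activations and evidence stay in [0, 1] under random feedback", {
  set.seed(99)
  variants <- enumerate_variants()
  for (rep in 1:5) {
    i <- sample(nrow(variants), 1)
    p <- ef_profile(variants$updating[i], variants$shifting[i],
                    variants$inhibition[i])
    k <- agent_constants()
    st <- agent_state_init()
    for (t in 1:60) {
      d <- deliberate(st, p, sample(c(20, 40, 60), 1), k)
      st$activation <- d$activation
      st <- process_feedback(st, sample(1:3, 1),
                             sample(c("correct", "incorrect"), 1), p, k)
      expect_true(all(st$activation >= 0 & st$activation <= 1))
      expect_true(all(st$evidence >= 0 & st$evidence <= 1))
    }
  }
})

test_that("deliberation is deterministic given the RNG state", {
  p <- ef_profile("poor", "medium", "poor")
  k <- agent_constants()
  st <- agent_state_init()
  st$evidence <- c(0.2, 0.6, 0.4)
  set.seed(7); d1 <- deliberate(st, p, 40, k)
  set.seed(7); d2 <- deliberate(st, p, 40, k)
  expect_identical(d1, d2)
})

test_that("noise-free deliberation follows the evidence after disconfirmation", {
  # expert-grade parameters, colour just disconfirmed, evidence favouring
  # shape: the agent shifts to shape
  p <- ef_profile_expert()
  k <- agent_constants(noise_sd = 0)
  st <- agent_state_init()
  st$evidence <- c(0.2, 0.7, 0.3)
  st$activation <- c(0.9, 0.1, 0.1)
  st$prepotent <- 1L
  st$disconfirmed <- c(TRUE, FALSE, FALSE)
  expect_equal(deliberate(st, p, 20, k)$choice, 2L)
})

test_that("a small cycle budget perseveres where a large one shifts", {
  # the central mechanism: very poor inhibition cannot suppress a fully
  # active disconfirmed prepotent strategy within 20 cycles, but the same
  # per-cycle decrement suffices within 60 cycles
  p <- ef_profile("poor", "poor", "very_poor")
  k <- agent_constants(noise_sd = 0)
  st <- agent_state_init()
  st$evidence <- c(0.3, 0.8, 0) # favouring shape
  st$activation <- c(1, 0, 0)
  st$prepotent <- 1L
  st$disconfirmed <- c(TRUE, FALSE, FALSE)
  expect_equal(deliberate(st, p, 20, k)$choice, 1L) # perseveres on colour
  expect_equal(deliberate(st, p, 60, k)$choice, 2L) # shifts to shape
})

test_that("the noise-free expert completes a session with zero PE", {
  ex <- make_agent(ef_profile_expert(), 20, seed = 21,
                   constants = agent_constants(noise_sd = 0))
  s <- administer(ex, rng_seed = 21)
  expect_equal(s$pe, 0)
  expect_equal(s$categories, 6)
  expect_gte(s$correct_sorts, 60)
})

test_that("identical agents and seeds give identical choice sequences", {
  p <- ef_profile("poor", "medium", "very_poor")
  for (budget in c(20, 60)) {
    a <- make_agent(p, budget, seed = 3)
    s1 <- administer(a, rng_seed = 33)
    s2 <- administer(a, rng_seed = 33)
    expect_identical(tidy(s1)$chosen_dimension, tidy(s2)$chosen_dimension)
  }
})
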