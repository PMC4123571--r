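# Fuzzy-CA core: rule semantics, synchronous evolution, attractors and the
# matrix form.

test_that("apply_rule follows the neighbour-sum semantics with clamping", {
  # worked-example neighbourhoods
  expect_equal(apply_rule(170, FALSE, left = 0, self = 0, right = 0.25),
               0.25)
  expect_equal(apply_rule(238, FALSE, left = 0, self = 0.25, right = 0.50),
               0.75)
  expect_equal(apply_rule(238, FALSE, left = 0.25, self = 0.75,
                          right = 0.50), 1.0)     # 1.25 clamped
  # rule 204 ignores the neighbours
  for (x in c(0, 0.3, 1)) {
    expect_equal(apply_rule(204, FALSE, x, 0.50, 1 - x), 0.50)
  }
  expect_equal(apply_rule(254, FALSE, 0, 0, 0), 0)
  expect_equal(apply_rule(204, TRUE, 0.9, 0.2, 0.1), 0.8)
  expect_error(apply_rule(123, FALSE, 0, 0, 0), "invalid rule")
  expect_error(apply_rule(170, FALSE, 0, 0, 1.5), "\\[0, 1\\]")
})

test_that("one synchronous step updates all cells from the previous state", {
  g <- rule_genome(c(170, 238, 204))
  expect_equal(ca_step(g, c(0, 0.25, 0.50)), c(0.25, 0.75, 0.50))
  expect_equal(ca_step(g, c(0.25, 0.75, 0.50)), c(0.75, 1.0, 0.50))
  # identity genome
  s <- c(0.1, 0.9, 0.4, 0)
  expect_equal(ca_step(rule_genome(rep(204, 4)), s), s)
  expect_error(ca_step(g, c(0.1, 0.2)), "length")
})

test_that("ca_step agrees with an independent per-cell oracle", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      n <- sample(1:8, 1)
      rules <- sample(ca_rules(), n, replace = TRUE)
      comp <- sample(c(TRUE, FALSE), n, replace = TRUE)
      state <- runif(n)
      expect_equal(ca_step(rule_genome(rules, comp), state),
                   oracle_step(rules, comp, state))
    }
  })
})

test_that("the three-step worked trajectory is reproduced cell-for-cell", {
  tr <- ca_evolve(rule_genome(c(170, 238, 204)), c(0, 0.25, 0.50),
                  max_steps = 50)
  expect_equal(tr$states[[1]], c(0, 0.25, 0.50))
  expect_equal(tr$states[[2]], c(0.25, 0.75, 0.50))
  expect_equal(tr$states[[3]], c(0.75, 1.0, 0.50))
  expect_equal(tr$states[[4]], c(1.0, 1.0, 0.50))
  expect_equal(tr$attractor_start, 4L)
  expect_equal(tr$attractor_period, 1L)
})

test_that("rule <170,252,204> has the saturating fixed point (1,1,0.2)", {
  tr <- ca_evolve(rule_genome(c(170, 252, 204)), c(0.5, 0.5, 0.2),
                  max_steps = 50)
  expect_equal(tr$attractor_period, 1L)
  expect_equal(tr$states[[tr$attractor_start]], c(1.0, 1.0, 0.2))
})

test_that("evolution on the identity genome is a step-0 fixed point", {
  s <- c(0.2, 0.8, 0.6)
  tr <- ca_evolve(rule_genome(rep(204, 3)), s, max_steps = 5)
  expect_equal(tr$attractor_start, 1L)
  expect_equal(tr$attractor_period, 1L)
  expect_equal(attractor_states(tr)[[1]], s)
})

test_that("exceeding max_steps raises a condition carrying the partial
           trajectory", {
  # complemented identity alternates x -> 1-x; one step can never recur
  err <- tryCatch(
    ca_evolve(rule_genome(204, TRUE), 0.3, max_steps = 1),
    macadna_attractor_not_found = function(e) e)
  expect_s3_class(err, "macadna_attractor_not_found")
  expect_length(err$trajectory, 2)
  # but two steps close the period-2 cycle
  tr <- ca_evolve(rule_genome(204, TRUE), 0.3, max_steps = 5)
  expect_equal(tr$attractor_period, 2L)
})

test_that("closure: evolved cells stay inside [0,1]", {
  withr::with_seed(11, {
    for (rep in 1:30) {
      n <- sample(2:6, 1)
      g <- rule_genome(sample(ca_rules(), n, replace = TRUE),
                       sample(c(TRUE, FALSE), n, replace = TRUE))
      tr <- ca_evolve(g, random_grid_state(n), max_steps = 1000)
      rng <- range(unlist(tr$states))
      expect_gte(rng[1], 0)
      expect_lte(rng[2], 1)
    }
  })
})

test_that("non-complemented rules are monotone in every input", {
  vals <- c(0, 0.25, 0.5, 0.75, 1)
  for (r in ca_rules()) {
    for (l in vals) for (s in vals) for (ri in vals) {
      base <- apply_rule(r, FALSE, l, s, ri)
      eps <- 0.2
      expect_gte(apply_rule(r, FALSE, min(1, l + eps), s, ri), base)
      expect_gte(apply_rule(r, FALSE, l, min(1, s + eps), ri), base)
      expect_gte(apply_rule(r, FALSE, l, s, min(1, ri + eps)), base)
    }
  }
})

test_that("the worked example's transition matrix is recovered", {
  expect_equal(transition_matrix(rule_genome(c(170, 238, 204))),
               matrix(c(0, 1, 0,
                        0, 1, 1,
                        0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(transition_matrix(rule_genome(rep(204, 4))), diag(4))
  expect_equal(transition_matrix(rule_genome(rep(254, 3))),
               matrix(c(1, 1, 0,
                        1, 1, 1,
                        0, 1, 1), 3, 3, byrow = TRUE))
  expect_error(transition_matrix(rule_genome(c(170, 204), c(TRUE, FALSE))),
               "complemented")
})

test_that("matrix-form evolution equals per-cell evolution on grid states", {
  # every non-complemented genome of length 3, every state on the 0.25 grid
  S <- t(grid_states(3, k = 4))
  combos <- expand.grid(rep(list(ca_rules()), 3))
  for (i in seq_len(nrow(combos))) {
    g <- rule_genome(unlist(combos[i, ]))
    T <- transition_matrix(g)
    via_matrix <- pmin(T %*% S, 1)
    via_step <- apply(S, 2, function(s) ca_step(g, s))
    expect_equal(unname(via_matrix), unname(via_step))
  }
})

test_that("genomes round-trip through the matrix form when boundary rules
           read no missing neighbour", {
  withr::with_seed(3, {
    left_safe <- c(238, 204, 170)    # no left reference, ok at cell 1
    right_safe <- c(252, 204, 240)   # no right reference, ok at cell n
    for (rep in 1:25) {
      n <- sample(3:7, 1)
      rules <- c(sample(left_safe, 1),
                 sample(ca_rules(), n - 2, replace = TRUE),
                 sample(right_safe, 1))
      g <- rule_genome(rules)
      expect_equal(genome_from_matrix(transition_matrix(g))$rules, g$rules)
    }
  })
})

test_that("termination: every grid state reaches an attractor within
           (k+1)^n steps", {
  withr::with_seed(19, {
    for (n in 2:4) {
      for (k in c(2, 4)) {
        S <- grid_states(n, k)
        for (rep in 1:8) {
          g <- rule_genome(sample(ca_rules(), n, replace = TRUE),
                           sample(c(TRUE, FALSE), n, replace = TRUE))
          for (i in seq_len(nrow(S))) {
            tr <- ca_evolve(g, unname(unlist(S[i, ])),
                            max_steps = (k + 1)^n)
            expect_s3_class(tr, "ca_trajectory")
          }
        }
      }
    }
  })
})

test_that("attractor keys identify cycles independently of entry point", {
  g <- rule_genome(c(170, 238, 204))
  k1 <- attractor_key(ca_evolve(g, c(0, 0.25, 0.50)))
  k2 <- attractor_key(ca_evolve(g, c(0.25, 0.75, 0.50)))
  expect_identical(k1, k2)
  # distinct fixed points get distinct keys
  g2 <- rule_genome(c(170, 252, 204))
  k3 <- attractor_key(ca_evolve(g2, c(0.5, 0.5, 0.2)))
  expect_false(identical(k1, k3))
  # a 2-cycle entered at either phase canonicalizes identically
  gc <- rule_genome(c(204, 204), c(TRUE, TRUE))
  ka <- attractor_key(ca_evolve(gc, c(0.25, 0.5)))
  kb <- attractor_key(ca_evolve(gc, c(0.75, 0.5)))
  expect_identical(ka, kb)
})
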