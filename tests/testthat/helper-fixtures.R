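# Shared fixtures and an independent scalar oracle for the CA step.

# Brute-force reference for one synchronous step: per-cell loop over the
# Table of neighbour-sum rules, written independently of ca_step()'s
# vectorised path.
oracle_step <- function(rules, complemented, state) {
  n <- length(state)
  out <- numeric(n)
  reads <- list(`254` = c(TRUE, TRUE, TRUE), `252` = c(TRUE, TRUE, FALSE),
                `238` = c(FALSE, TRUE, TRUE), `250` = c(TRUE, FALSE, TRUE),
                `204` = c(FALSE, TRUE, FALSE), `240` = c(TRUE, FALSE, FALSE),
                `170` = c(FALSE, FALSE, TRUE))
  for (i in seq_len(n)) {
    trio <- c(if (i > 1) state[i - 1] else 0,
              state[i],
              if (i < n) state[i + 1] else 0)
    v <- min(1, sum(trio[reads[[as.character(rules[i])]]]))
    out[i] <- if (complemented[i]) 1 - v else v
  }
  out
}

# All states of length n on the grid {0, 1/k, ..., 1}, as columns.
grid_states <- function(n, k = 4) {
  vals <- seq(0, 1, by = 1 / k)
  as.matrix(expand.grid(rep(list(vals), n)))
}

random_grid_state <- function(n, k = 4) {
  sample(seq(0, 1, by = 1 / k), n, replace = TRUE)
}

# A small, clearly separable two-class antigen set: one class concentrated
# near all-low cells, the other near all-high.
separable_antigens <- function(n_cells = 4, n_per_class = 10, seed = 99) {
  withr::with_seed(seed, {
    lo <- replicate(n_per_class,
                    quantize_state(runif(n_cells, 0, 0.25)))
    hi <- replicate(n_per_class,
                    quantize_state(runif(n_cells, 0.75, 1)))
    antigen_set(cbind(lo, hi),
                rep(c("low", "high"), each = n_per_class))
  })
}

record_labels <- function(records) {
  stats::setNames(vapply(records, function(r) r$label, character(1)),
                  vapply(records, function(r) r$id, character(1)))
}
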