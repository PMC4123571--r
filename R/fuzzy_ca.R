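# Fuzzy cellular-automata core: bounded-sum neighbourhood rules, synchronous
# evolution, attractor detection and the linear transition-matrix form.

# The seven supported rule numbers and the neighbour offsets each one sums.
# Offsets are relative cell positions: -1 = left neighbour, 0 = self,
# +1 = right neighbour. A missing neighbour (array end) contributes 0.
.RULE_OFFSETS <- list(
  `254` = c(-1L, 0L, 1L),
  `252` = c(-1L, 0L),
  `238` = c(0L, 1L),
  `250` = c(-1L, 1L),
  `204` = c(0L),
  `240` = c(-1L),
  `170` = c(1L)
)

#' Supported fuzzy-CA rule numbers
#'
#' The seven Wolfram-style rule numbers the engine accepts. Each names a
#' bounded sum of a subset of the three-cell neighbourhood: 254 sums all
#' three neighbours, 252 the left neighbour and self, 238 self and right,
#' 250 left and right, 204 self only (identity), 240 left only, 170 right
#' only. Sums are clamped at 1 (Lukasiewicz bounded sum).
#'
#' @return Integer vector of the seven rule numbers.
#' @export
ca_rules <- function() as.integer(names(.RULE_OFFSETS))

.check_rules <- function(rules) {
  bad <- setdiff(unique(rules), ca_rules())
  if (length(bad) > 0) {
    stop("invalid rule number(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(ca_rules(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a per-cell rule genome
#'
#' A rule genome assigns one neighbourhood rule to every cell of a fuzzy CA
#' configuration. Each entry may additionally be complemented, in which case
#' the cell's next state is one minus the bounded-sum result.
#'
#' @param rules Integer vector of rule numbers, one per cell; each must be
#'   one of [ca_rules()].
#' @param complemented Logical vector (recycled to `length(rules)`) marking
#'   complemented entries.
#' @return An object of class `rule_genome`.
#' @examples
#' g <- rule_genome(c(170, 238, 204))
#' ca_step(g, c(0, 0.25, 0.50))
#' @export
rule_genome <- function(rules, complemented = FALSE) {
  rules <- as.integer(rules)
  if (length(rules) < 1) stop("genome must have length >= 1", call. = FALSE)
  .check_rules(rules)
  complemented <- rep_len(as.logical(complemented), length(rules))
  structure(list(rules = rules, complemented = complemented),
            class = "rule_genome")
}

#' @export
length.rule_genome <- function(x) length(x$rules)

#' @export
print.rule_genome <- function(x, ...) {
  tag <- ifelse(x$complemented, "'", "")
  cat("<", paste0(x$rules, tag, collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::format
format.rule_genome <- function(x, ...) {
  paste0("<", paste0(x$rules, ifelse(x$complemented, "'", ""),
                     collapse = ","), ">")
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) < 1) {
    stop("state must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(is.na(state)) || any(state < 0) || any(state > 1)) {
    stop("cell values must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate a single fuzzy-CA rule on one neighbourhood
#'
#' Computes the next state of one cell from its three-cell neighbourhood.
#' The rule's named neighbours are summed and the sum clamped at 1; a
#' complemented rule returns one minus that value.
#'
#' @param rule_number One of [ca_rules()].
#' @param complemented Logical; apply the complement.
#' @param left,self,right Cell values in `[0, 1]`. Pass 0 for a missing
#'   neighbour (null boundary).
#' @return The next cell value, in `[0, 1]`.
#' @examples
#' apply_rule(238, FALSE, left = 0, self = 0.25, right = 0.50)  # 0.75
#' apply_rule(204, TRUE, 0, 0.2, 0)                             # 0.8
#' @export
apply_rule <- function(rule_number, complemented, left, self, right) {
  .check_rules(as.integer(rule_number))
  vals <- c(`-1` = left, `0` = self, `1` = right)
  .check_state(unname(vals))
  offs <- .RULE_OFFSETS[[as.character(as.integer(rule_number))]]
  v <- min(1, sum(vals[as.character(offs)]))
  if (isTRUE(as.logical(complemented))) v <- 1 - v
  unname(v)
}

# Per-cell 0/1 masks saying whether each cell's rule reads the left
# neighbour, itself, and the right neighbour.
.genome_masks <- function(genome) {
  key <- as.character(genome$rules)
  uses <- function(off) {
    vapply(.RULE_OFFSETS[key], function(o) off %in% o, logical(1))
  }
  list(l = as.numeric(uses(-1L)),
       s = as.numeric(uses(0L)),
       r = as.numeric(uses(1L)))
}

#' One synchronous fuzzy-CA step
#'
#' Updates every cell simultaneously from the previous configuration.
#' Missing neighbours at the array ends contribute 0 (null boundary).
#'
#' @param genome A [rule_genome()] whose length equals the state length.
#' @param state Numeric vector of cell values in `[0, 1]`.
#' @return The next configuration, same length as `state`.
#' @export
ca_step <- function(genome, state) {
  .check_state(state)
  n <- length(state)
  if (length(genome) != n) {
    stop("genome length (", length(genome), ") != state length (", n, ")",
         call. = FALSE)
  }
  m <- .genome_masks(genome)
  left <- c(0, state[-n])
  right <- c(state[-1], 0)
  v <- pmin(1, left * m$l + state * m$s + right * m$r)
  ifelse(genome$complemented, 1 - v, v)
}

# Matrix form of ca_step: states are columns of an n x N matrix. Used by the
# trainer, where one antibody is evolved against every antigen at once.
.ca_step_matrix <- function(masks, complemented, M) {
  n <- nrow(M)
  if (n == 1L) {
    left <- matrix(0, 1L, ncol(M))
    right <- left
  } else {
    left <- rbind(0, M[-n, , drop = FALSE])
    right <- rbind(M[-1, , drop = FALSE], 0)
  }
  V <- pmin(left * masks$l + M * masks$s + right * masks$r, 1)
  if (any(complemented)) V[complemented, ] <- 1 - V[complemented, ]
  V
}

.state_token <- function(state) paste(round(state, 6), collapse = ",")

#' Evolve a fuzzy CA to its attractor
#'
#' Iterates [ca_step()] until a previously seen configuration recurs
#' (states are quantized to 6 decimals for recurrence detection) or
#' `max_steps` is exhausted.
#'
#' @param genome A [rule_genome()].
#' @param state Initial configuration, values in `[0, 1]`.
#' @param max_steps Maximum number of steps before giving up; exceeding it
#'   raises an error of class `macadna_attractor_not_found` that carries the
#'   partial trajectory in its `trajectory` field.
#' @return An object of class `ca_trajectory`: a list with `states` (all
#'   visited configurations, including the initial one), `attractor_start`
#'   (1-based index into `states` of the first cycle state) and
#'   `attractor_period`.
#' @examples
#' tr <- ca_evolve(rule_genome(c(170, 238, 204)), c(0, 0.25, 0.50))
#' tr$states[[tr$attractor_start]]  # the fixed point (1, 1, 0.5)
#' @export
ca_evolve <- function(genome, state, max_steps = 1000) {
  .check_state(state)
  if (max_steps < 1) stop("max_steps must be >= 1", call. = FALSE)
  states <- list(state)
  seen <- structure(1L, names = .state_token(state))
  cur <- state
  for (t in seq_len(max_steps)) {
    cur <- ca_step(genome, cur)
    tok <- .state_token(cur)
    hit <- seen[tok]
    if (!is.na(hit)) {
      return(structure(
        list(states = states, attractor_start = unname(hit),
             attractor_period = length(states) - unname(hit) + 1L),
        class = "ca_trajectory"))
    }
    states <- c(states, list(cur))
    seen[tok] <- length(states)
  }
  cond <- structure(
    class = c("macadna_attractor_not_found", "error", "condition"),
    list(message = paste0("no attractor found within ", max_steps, " steps"),
         call = sys.call(-1), trajectory = states))
  stop(cond)
}

#' @export
print.ca_trajectory <- function(x, ...) {
  for (i in seq_along(x$states)) {
    mark <- if (i >= x$attractor_start) " *" else ""
    cat(sprintf("P(%d) = (%s)%s\n", i - 1L,
                paste(format(x$states[[i]]), collapse = ", "), mark))
  }
  cat("attractor: period ", x$attractor_period, ", entered at step ",
      x$attractor_start - 1L, "\n", sep = "")
  invisible(x)
}

#' Canonical attractor identifier of a trajectory
#'
#' Two trajectories that end in the same cycle get the same key regardless
#' of where they entered it: the cycle is rotated so its lexicographically
#' smallest quantized state comes first, then serialized.
#'
#' @param trajectory A `ca_trajectory` from [ca_evolve()].
#' @return A character string identifying the attractor.
#' @export
attractor_key <- function(trajectory) {
  stopifnot(inherits(trajectory, "ca_trajectory"))
  cyc <- attractor_states(trajectory)
  toks <- vapply(cyc, .state_token, character(1))
  paste(toks, collapse = "|")
}

#' Canonical cycle states of a trajectory's attractor
#'
#' @param trajectory A `ca_trajectory`.
#' @return List of states in the cycle, rotated so the lexicographically
#'   smallest state (by its quantized serialization) is first. A fixed point
#'   is a single-state cycle.
#' @export
attractor_states <- function(trajectory) {
  stopifnot(inherits(trajectory, "ca_trajectory"))
  idx <- seq(trajectory$attractor_start,
             length.out = trajectory$attractor_period)
  cyc <- trajectory$states[idx]
  toks <- vapply(cyc, .state_token, character(1))
  first <- order(toks)[1]
  if (first > 1L) cyc <- c(cyc[first:length(cyc)], cyc[seq_len(first - 1L)])
  cyc
}

#' Transition matrix of a non-complemented genome
#'
#' For genomes without complemented entries, one CA step is the linear map
#' `clamp(T %*% state, 0, 1)` where row i of `T` has a 1 at every neighbour
#' column its rule reads. Rows are banded: only columns i-1, i, i+1 can be
#' set, and references to missing boundary neighbours are dropped (null
#' boundary).
#'
#' @param genome A [rule_genome()] with no complemented entries.
#' @return An n x n 0/1 matrix.
#' @examples
#' transition_matrix(rule_genome(c(170, 238, 204)))
#' @export
transition_matrix <- function(genome) {
  stopifnot(inherits(genome, "rule_genome"))
  if (any(genome$complemented)) {
    stop("complemented rules have no pure matrix form", call. = FALSE)
  }
  n <- length(genome)
  T <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cols <- i + .RULE_OFFSETS[[as.character(genome$rules[i])]]
    cols <- cols[cols >= 1 & cols <= n]
    T[i, cols] <- 1
  }
  T
}

#' One CA step through the matrix form
#'
#' @param T A transition matrix from [transition_matrix()].
#' @param state Numeric state vector.
#' @return `pmin(1, T %*% state)` as a plain vector.
#' @export
matrix_step <- function(T, state) {
  .check_state(state)
  pmin(1, as.numeric(T %*% state))
}

#' Recover a rule genome from a transition matrix
#'
#' Inverts [transition_matrix()]: each row's set of marked neighbour offsets
#' is matched against the rule table. Interior rows are always unambiguous.
#' At the boundary the null boundary can make rules indistinguishable (a
#' first-cell row reading only "self" matches both 204 and 252, whose left
#' reference was dropped); such rows resolve to the rule whose full offset
#' set matches the row exactly, and raise an error when no rule's in-range
#' offsets reproduce the row.
#'
#' @param T A 0/1 banded matrix.
#' @return A [rule_genome()] (non-complemented).
#' @export
genome_from_matrix <- function(T) {
  n <- nrow(T)
  stopifnot(n == ncol(T))
  rules <- integer(n)
  for (i in seq_len(n)) {
    cols <- which(T[i, ] != 0)
    if (any(abs(cols - i) > 1)) {
      stop("row ", i, " is not banded", call. = FALSE)
    }
    offs <- sort(cols - i)
    exact <- names(Filter(function(o) identical(sort(o), offs),
                          .RULE_OFFSETS))
    if (length(exact) >= 1) {
      rules[i] <- as.integer(exact[[1]])
      next
    }
    # boundary row: match after dropping out-of-range offsets
    inrange <- names(Filter(function(o) {
      keep <- o[i + o >= 1 & i + o <= n]
      identical(sort(as.integer(keep)), as.integer(offs))
    }, .RULE_OFFSETS))
    if (length(inrange) == 0) {
      stop("row ", i, " matches no supported rule", call. = FALSE)
    }
    rules[i] <- as.integer(inrange[[1]])
  }
  rule_genome(rules)
}
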