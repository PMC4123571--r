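# Clonal-selection training of rule genomes. Antibodies are candidate
# genomes; antigens are encoded, labelled sequences. An antibody's affinity
# is its training accuracy when each attractor basin is labelled by the
# majority class of the antigens draining to it. The generation loop follows
# classic clonal selection (proportional cloning, affinity-inverse
# mutation), with a reservoir-recycling modification: high-affinity mutants
# that fail to enter the memory population compete for reservoir slots
# against the old reservoir and fresh random antibodies, instead of being
# discarded.

.N_RULE_VARIANTS <- 14L   # 7 rules x complemented flag

.variant_to_rule <- function(idx) {
  rules <- ca_rules()
  list(rule = rules[((idx - 1L) %% 7L) + 1L],
       complemented = idx > 7L)
}

.random_genome <- function(n) {
  idx <- sample.int(.N_RULE_VARIANTS, n, replace = TRUE)
  rules <- ca_rules()[((idx - 1L) %% 7L) + 1L]
  rule_genome(rules, idx > 7L)
}

#' Construct an antibody
#'
#' @param genome A [rule_genome()].
#' @return Object of class `antibody` with unset affinity.
#' @export
antibody <- function(genome) {
  stopifnot(inherits(genome, "rule_genome"))
  structure(list(genome = genome, affinity = NA_real_,
                 attractor_labels = NULL, attractor_reps = NULL,
                 default_label = NA_character_),
            class = "antibody")
}

#' @export
print.antibody <- function(x, ...) {
  cat("antibody ", format(x$genome), "  affinity: ",
      ifelse(is.na(x$affinity), "unset", format(x$affinity)), "\n", sep = "")
  invisible(x)
}

#' Construct an antigen set
#'
#' @param states Numeric matrix (cells x antigens) or list of equal-length
#'   numeric state vectors; values in `[0,1]`.
#' @param labels Character vector of class labels, one per antigen.
#' @param class_universe Ordered vector of distinct labels; the order is the
#'   deterministic tie-break for attractor majority votes. Default: order of
#'   first appearance.
#' @return Object of class `antigen_set`.
#' @export
antigen_set <- function(states, labels, class_universe = NULL) {
  if (is.list(states)) states <- do.call(cbind, states)
  states <- as.matrix(states)
  if (any(is.na(states)) || any(states < 0) || any(states > 1)) {
    stop("antigen cell values must lie in [0,1]", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(states)) {
    stop("one label per antigen required", call. = FALSE)
  }
  if (is.null(class_universe)) class_universe <- unique(labels)
  if (!all(labels %in% class_universe)) {
    stop("labels outside class_universe", call. = FALSE)
  }
  structure(list(states = states, labels = labels,
                 class_universe = class_universe),
            class = "antigen_set")
}

#' @export
print.antigen_set <- function(x, ...) {
  cat(sprintf("antigen_set: %d antigens x %d cells, classes: %s\n",
              ncol(x$states), nrow(x$states),
              paste(x$class_universe, collapse = ", ")))
  invisible(x)
}

# Serialize every column of a state matrix to one token in a single
# vectorised operation. On a 0.25 grid each state packs exactly into one
# double (base-5 digits); off-grid states fall back to a string paste.
.column_tokens <- function(M, grid) {
  if (grid) {
    as.vector(crossprod(5^(seq_len(nrow(M)) - 1), round(M * 4)))
  } else {
    do.call(paste, c(lapply(seq_len(nrow(M)),
                            function(i) round(M[i, ], 6)),
                     sep = ","))
  }
}

# Evolve every column of a state matrix to its attractor under one genome.
# Returns one canonical cycle key per column plus a representative state
# (the first state of the canonical cycle) used for nearest-attractor
# fallback at prediction time. Recurrence is detected on quantized
# serializations against the full per-column history, so cycles of any
# period are found; the key is the cycle rotated to its smallest state
# token.
.batch_attractors <- function(genome, states, max_steps = 1000) {
  masks <- .genome_masks(genome)
  comp <- genome$complemented
  N <- ncol(states)
  grid <- all(abs(states * 4 - round(states * 4)) < 1e-9) &&
    nrow(states) <= 22
  keys <- character(N)
  reps <- matrix(NA_real_, nrow(states), N)
  done <- logical(N)
  hist <- matrix(if (grid) numeric(64 * N) else character(64 * N),
                 nrow = 64, ncol = N)
  shist <- vector("list", 64)
  cur <- states
  toks <- .column_tokens(cur, grid)
  for (t in seq_len(max_steps + 1L)) {
    if (t > nrow(hist)) hist <- rbind(hist, hist)   # grow by doubling
    hist[t, ] <- toks
    shist[[t]] <- cur
    cur <- .ca_step_matrix(masks, comp, cur)
    toks <- .column_tokens(cur, grid)
    hit <- !done &
      colSums(hist[seq_len(t), , drop = FALSE] ==
                rep(toks, each = t)) > 0
    for (j in which(hit)) {
      s <- which(hist[seq_len(t), j] == toks[j])[1]
      cyc <- hist[s:t, j]
      first <- order(cyc)[1]
      keys[j] <- paste(c(cyc[first:length(cyc)],
                         cyc[seq_len(first - 1L)]), collapse = "|")
      reps[, j] <- shist[[s + first - 1L]][, j]
    }
    done <- done | hit
    if (all(done)) return(list(keys = keys, reps = reps))
  }
  stop("no attractor found within ", max_steps, " steps for ",
       sum(!done), " antigen(s)", call. = FALSE)
}

.batch_attractor_keys <- function(genome, states, max_steps = 1000) {
  .batch_attractors(genome, states, max_steps)$keys
}

#' Affinity of an antibody on an antigen set
#'
#' Evolves every antigen state to its attractor under the antibody's
#' genome, labels each attractor by the majority class of the antigens
#' reaching it (ties broken by the earlier class in `class_universe`), and
#' scores the fraction of antigens whose basin label matches their own.
#' The learned attractor-to-class map and the overall majority class (the
#' fallback for attractors unseen in training) are stored on the returned
#' antibody.
#'
#' @param ab An [antibody()].
#' @param antigens An [antigen_set()] whose state length matches the genome.
#' @param max_steps CA evolution cap per antigen.
#' @return The antibody with `affinity`, `attractor_labels` and
#'   `default_label` filled in.
#' @export
affinity_of <- function(ab, antigens, max_steps = 1000) {
  stopifnot(inherits(ab, "antibody"), inherits(antigens, "antigen_set"))
  if (length(ab$genome) != nrow(antigens$states)) {
    stop("genome length != antigen state length", call. = FALSE)
  }
  res <- .batch_attractors(ab$genome, antigens$states, max_steps)
  keys <- res$keys
  labs <- antigens$labels
  uni <- antigens$class_universe
  amap <- tapply(labs, keys, function(v) {
    tab <- table(factor(v, levels = uni))
    names(tab)[which.max(tab)]          # which.max: earliest level on ties
  })
  assigned <- unname(amap[keys])
  tab_all <- table(factor(labs, levels = uni))
  ab$attractor_labels <- stats::setNames(as.character(amap), names(amap))
  first_seen <- match(names(amap), keys)
  ab$attractor_reps <- res$reps[, first_seen, drop = FALSE]
  ab$default_label <- names(tab_all)[which.max(tab_all)]
  ab$affinity <- mean(assigned == labs)
  ab
}

#' Predict class labels with a trained antibody
#'
#' @param ab An evaluated [antibody()] (after [affinity_of()] or
#'   [train_clonal()]).
#' @param states Numeric matrix (cells x sequences) or single state vector.
#' @param max_steps CA evolution cap.
#' @return Character vector of class labels. An attractor never reached
#'   during training inherits the label of the nearest labelled attractor
#'   (L1 distance between representative cycle states; ties broken by the
#'   earlier labelled attractor), falling back to the training majority
#'   class if no representative is stored.
#' @export
predict_antibody <- function(ab, states, max_steps = 1000) {
  stopifnot(inherits(ab, "antibody"))
  if (is.null(ab$attractor_labels)) {
    stop("antibody has not been evaluated; call affinity_of() first",
         call. = FALSE)
  }
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  res <- .batch_attractors(ab$genome, states, max_steps)
  out <- unname(ab$attractor_labels[res$keys])
  unseen <- is.na(out)
  if (any(unseen)) {
    if (!is.null(ab$attractor_reps)) {
      for (j in which(unseen)) {
        d <- colSums(abs(ab$attractor_reps - res$reps[, j]))
        out[j] <- unname(ab$attractor_labels[which.min(d)])
      }
    } else {
      out[unseen] <- ab$default_label
    }
  }
  out
}

#' Clonal-selection configuration
#'
#' @param N_m,N_r Memory and reservoir population sizes.
#' @param m Number of highest-affinity antibodies selected for cloning.
#' @param beta Clone-count factor: rank r receives
#'   `max(1, round(beta * (N_m + N_r) / r))` clones.
#' @param p_max,rho Mutation schedule: each clone position mutates with
#'   probability `p_max * exp(-rho * affinity)`, replacement uniform over
#'   the 14 rule variants (7 rules x complement flag).
#' @param generations Number of generations (0 = best of the random
#'   initial population).
#' @param seed RNG seed for [train_clonal()].
#' @param max_steps CA evolution cap.
#' @param recycle_reservoir Keep the reservoir-recycling modification
#'   (high-affinity leftover clones compete for reservoir slots). Disable
#'   to recover the original clonal algorithm's reservoir handling.
#' @return Object of class `clonal_config`.
#' @export
clonal_config <- function(N_m = 20L, N_r = 30L, m = 10L, beta = 1.0,
                          p_max = 0.3, rho = 3.0, generations = 50L,
                          seed = 1L, max_steps = 1000L,
                          recycle_reservoir = TRUE) {
  stopifnot(N_m >= 1, N_r >= 1, m >= 1, m <= N_m + N_r,
            p_max > 0, p_max <= 1, rho >= 0, beta > 0, generations >= 0)
  structure(list(N_m = as.integer(N_m), N_r = as.integer(N_r),
                 m = as.integer(m), beta = beta, p_max = p_max, rho = rho,
                 generations = as.integer(generations),
                 seed = as.integer(seed), max_steps = as.integer(max_steps),
                 recycle_reservoir = isTRUE(recycle_reservoir)),
            class = "clonal_config")
}

.aff <- function(pop) vapply(pop, function(a) a$affinity, numeric(1))

.genome_sig <- function(g) {
  paste(g$rules, as.integer(g$complemented), collapse = ";")
}

# Evaluate an antibody, memoizing by genome signature: identical genomes
# (unmutated clones, re-selected elites) recur constantly during training
# and their affinity on a fixed antigen set is deterministic.
.eval_ab <- function(ab, antigens, max_steps, cache = NULL) {
  if (is.null(cache)) return(affinity_of(ab, antigens, max_steps))
  sig <- .genome_sig(ab$genome)
  hit <- cache[[sig]]
  if (!is.null(hit)) return(hit)
  out <- affinity_of(ab, antigens, max_steps)
  cache[[sig]] <- out
  out
}

.sort_desc <- function(pop) pop[order(-.aff(pop))]

.mutate_genome <- function(genome, p) {
  n <- length(genome)
  hit <- stats::runif(n) < p
  if (!any(hit)) return(genome)
  idx <- sample.int(.N_RULE_VARIANTS, sum(hit), replace = TRUE)
  rules <- genome$rules
  comp <- genome$complemented
  rules[hit] <- ca_rules()[((idx - 1L) %% 7L) + 1L]
  comp[hit] <- idx > 7L
  rule_genome(rules, comp)
}

#' Run one clonal-selection generation
#'
#' Executes, in order: selection of the top-m antibodies; proportional
#' cloning; affinity-inverse mutation; re-evaluation; memory update (each
#' memory slot keeps the better of the incumbent and the best unused
#' mutant); reservoir update (old reservoir vs leftover mutants vs fresh
#' randoms — the reservoir-recycling modification; with
#' `recycle_reservoir = FALSE` the leftovers are discarded); and promotion
#' of reservoir antibodies that beat memory incumbents.
#'
#' @param population List with `memory` and `reservoir`, both lists of
#'   evaluated antibodies (as produced by [train_clonal()] internals).
#' @param antigens An [antigen_set()].
#' @param config A [clonal_config()].
#' @param cache Optional environment memoizing affinity evaluations by
#'   genome (valid for one fixed antigen set).
#' @return The updated population (memory sorted by descending affinity,
#'   sizes unchanged). Uses the global RNG stream; seed it for
#'   reproducibility.
#' @export
run_generation <- function(population, antigens, config, cache = NULL) {
  stopifnot(inherits(config, "clonal_config"))
  all_ab <- c(population$memory, population$reservoir)
  if (any(is.na(.aff(all_ab)))) {
    stop("all antibodies must be evaluated before run_generation()",
         call. = FALSE)
  }
  N <- config$N_m + config$N_r
  # (a) select top-m
  P_m <- .sort_desc(all_ab)[seq_len(config$m)]
  # (b) clone proportionally to rank, (c) mutate inversely to affinity
  clones <- list()
  for (r in seq_along(P_m)) {
    n_c <- max(1L, as.integer(round(config$beta * N / r)))
    p_mut <- config$p_max * exp(-config$rho * P_m[[r]]$affinity)
    for (k in seq_len(n_c)) {
      clones[[length(clones) + 1L]] <-
        antibody(.mutate_genome(P_m[[r]]$genome, p_mut))
    }
  }
  # (d) re-evaluate and sort the matured population
  clones <- lapply(clones, .eval_ab, antigens = antigens,
                   max_steps = config$max_steps, cache = cache)
  clones <- .sort_desc(clones)
  # (e) memory update: each slot keeps the better of incumbent vs best
  # unused clone
  memory <- .sort_desc(population$memory)
  ci <- 1L
  for (i in seq_along(memory)) {
    if (ci > length(clones)) break
    if (clones[[ci]]$affinity > memory[[i]]$affinity) {
      memory[[i]] <- clones[[ci]]
      ci <- ci + 1L
    }
  }
  leftover <- if (ci <= length(clones)) clones[ci:length(clones)] else list()
  # (f) reservoir update: fresh randoms vs old reservoir (vs leftovers when
  # recycling)
  n_cells <- nrow(antigens$states)
  fresh <- lapply(seq_len(config$N_r), function(i) {
    .eval_ab(antibody(.random_genome(n_cells)), antigens,
             config$max_steps, cache)
  })
  pool <- c(population$reservoir, fresh,
            if (config$recycle_reservoir) leftover)
  reservoir <- .sort_desc(pool)[seq_len(config$N_r)]
  # (g) promotion: memory = best N_m of memory+reservoir, rest to reservoir
  combined <- .sort_desc(c(memory, reservoir))
  list(memory = combined[seq_len(config$N_m)],
       reservoir = combined[(config$N_m + 1L):N])
}

#' Train a rule genome by clonal selection
#'
#' Seeds the RNG from `config$seed`, initializes a random antibody
#' population, and runs `config$generations` generations of
#' [run_generation()], stopping early if a perfect-affinity antibody
#' appears. Elitism guarantees the best memory affinity never decreases.
#'
#' @param antigens An [antigen_set()] with at least two classes.
#' @param config A [clonal_config()].
#' @return Object of class `clonal_fit`: `antibody` (best memory
#'   antibody), `history` (best memory affinity after initialization and
#'   after each generation), `population`, `config`.
#' @export
train_clonal <- function(antigens, config = clonal_config()) {
  stopifnot(inherits(antigens, "antigen_set"))
  if (length(unique(antigens$labels)) < 2) {
    stop("training requires at least two classes", call. = FALSE)
  }
  set.seed(config$seed)
  n_cells <- nrow(antigens$states)
  cache <- new.env(parent = emptyenv())
  init <- lapply(seq_len(config$N_m + config$N_r), function(i) {
    .eval_ab(antibody(.random_genome(n_cells)), antigens,
             config$max_steps, cache)
  })
  init <- .sort_desc(init)
  pop <- list(memory = init[seq_len(config$N_m)],
              reservoir = init[(config$N_m + 1L):(config$N_m + config$N_r)])
  history <- pop$memory[[1]]$affinity
  g <- 0L
  while (g < config$generations && history[length(history)] < 1) {
    pop <- run_generation(pop, antigens, config, cache)
    history <- c(history, pop$memory[[1]]$affinity)
    g <- g + 1L
  }
  structure(list(antibody = pop$memory[[1]], history = history,
                 population = pop, config = config),
            class = "clonal_fit")
}

#' @export
print.clonal_fit <- function(x, ...) {
  cat("clonal_fit: best affinity ", format(x$antibody$affinity),
      " after ", length(x$history) - 1L, " generation(s)\n", sep = "")
  cat("  genome: ", format(x$antibody$genome), "\n", sep = "")
  invisible(x)
}
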