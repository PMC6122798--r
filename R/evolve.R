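#' Configuration for a genetic-programming run
#'
#' Defaults follow common tree-GP practice for this problem class: a
#' population of 1000, subtree crossover and subtree mutation each applied
#' with probability 0.5, ramped half-and-half initialisation over depths
#' 2-6, a maximum tree depth of 63, and ephemeral constants drawn uniformly
#' on `[-3, 3]` at node creation. The termination budget is either a count
#' of offspring evaluations (reproducible; used throughout the tests) or
#' wall-clock seconds (the production default, 12 h).
#'
#' @param population_size number of individuals (>= 2).
#' @param crossover_rate,mutation_rate probabilities of applying subtree
#'   crossover to a selected pair and subtree mutation to each child.
#' @param sample_size tournament sample size `k` for steady-state selection
#'   (sampled without replacement; the two fittest are parents, offspring
#'   replace the worst sampled members only if fitter).
#' @param max_depth depth cap on every individual (leaf = depth 1).
#' @param init_depth length-2 ramp of initial depths.
#' @param mutation_depth length-2 ramp of depths for mutant subtrees.
#' @param const_range range of ephemeral random constants.
#' @param max_evaluations offspring-evaluation budget (after the initial
#'   population is evaluated); `NULL` to terminate on time only.
#' @param max_time wall-clock budget in seconds (default 43200 when no
#'   evaluation budget is given).
#' @param seed optional integer seed fixing the whole run.
#' @param log_every record best/median training fitness every this many
#'   offspring evaluations.
#' @return A `gp_config` list.
#' @export
gp_config <- function(population_size = 1000,
                      crossover_rate = 0.5,
                      mutation_rate = 0.5,
                      sample_size = 7,
                      max_depth = 63,
                      init_depth = c(2, 6),
                      mutation_depth = c(2, 4),
                      const_range = c(-3, 3),
                      max_evaluations = NULL,
                      max_time = NULL,
                      seed = NULL,
                      log_every = 1000) {
  stopifnot(population_size >= 2,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            sample_size >= 2, max_depth >= 1,
            length(init_depth) == 2, init_depth[1] <= init_depth[2],
            init_depth[2] <= max_depth)
  if (is.null(max_evaluations) && is.null(max_time)) max_time <- 43200
  if (!is.null(max_evaluations) && max_evaluations < 0) {
    stop("max_evaluations must be >= 0", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         sample_size = as.integer(sample_size),
         max_depth = as.integer(max_depth),
         init_depth = as.integer(init_depth),
         mutation_depth = as.integer(mutation_depth),
         const_range = const_range,
         max_evaluations = max_evaluations, max_time = max_time,
         seed = seed, log_every = as.integer(log_every)),
    class = "gp_config")
}

# ---- random tree generation ----------------------------------------------

random_terminal <- function(terminals, const_range) {
  k <- sample.int(length(terminals) + 1L, 1L)
  if (k > length(terminals)) {
    stats::runif(1, const_range[1], const_range[2])
  } else {
    as.name(terminals[k])
  }
}

random_op <- function() {
  ops <- c(.gp_binary_ops, .gp_unary_ops)
  op <- ops[sample.int(length(ops), 1L)]
  list(name = op, arity = if (op %in% .gp_binary_ops) 2L else 1L)
}

# "full": internal nodes down to exactly depth d
full_tree <- function(d, terminals, const_range) {
  if (d <= 1L) return(random_terminal(terminals, const_range))
  op <- random_op()
  args <- replicate(op$arity, full_tree(d - 1L, terminals, const_range),
                    simplify = FALSE)
  as.call(c(as.name(op$name), args))
}

# "grow": each node is drawn from the combined primitive + terminal set
grow_tree <- function(d, terminals, const_range) {
  n_prim <- length(.gp_binary_ops) + length(.gp_unary_ops)
  n_term <- length(terminals) + 1L # + ephemeral constant slot
  if (d <= 1L || sample.int(n_prim + n_term, 1L) > n_prim) {
    return(random_terminal(terminals, const_range))
  }
  op <- random_op()
  args <- replicate(op$arity, grow_tree(d - 1L, terminals, const_range),
                    simplify = FALSE)
  as.call(c(as.name(op$name), args))
}

#' Ramped half-and-half initialisation
#'
#' Generates `n` random trees, half by the "full" method and half by the
#' "grow" method, with target depths cycled uniformly over the
#' initialisation ramp.
#'
#' @param n number of trees.
#' @param terminals covariate terminal names (`"tj"` is not added
#'   automatically here; include it if wanted).
#' @param config a [gp_config()].
#' @return list of language objects, all of depth `<= max(init_depth)`.
#' @export
ramped_half_and_half <- function(n, terminals, config = gp_config()) {
  stopifnot(length(terminals) >= 1)
  depths <- rep(seq(config$init_depth[1], config$init_depth[2]),
                length.out = n)
  lapply(seq_len(n), function(i) {
    if (i %% 2L == 0L) {
      full_tree(depths[i], terminals, config$const_range)
    } else {
      grow_tree(depths[i], terminals, config$const_range)
    }
  })
}

# ---- variation operators -------------------------------------------------

#' Subtree crossover
#'
#' Swaps uniformly chosen subtrees between two parents. A child that would
#' exceed the depth cap is rejected and replaced by its parent, so the
#' operator can never produce an illegal individual. Parents are not
#' modified.
#'
#' @param t1,t2 parent language objects.
#' @param max_depth depth cap.
#' @return list of two children.
#' @export
subtree_crossover <- function(t1, t2, max_depth = 63) {
  p1 <- sample.int(tree_size(t1), 1L)
  p2 <- sample.int(tree_size(t2), 1L)
  s1 <- subtree_at(t1, p1)
  s2 <- subtree_at(t2, p2)
  c1 <- replace_at(t1, p1, s2)
  c2 <- replace_at(t2, p2, s1)
  if (tree_depth(c1) > max_depth) c1 <- t1
  if (tree_depth(c2) > max_depth) c2 <- t2
  list(c1, c2)
}

#' Subtree mutation
#'
#' Replaces a uniformly chosen node with a freshly grown random subtree
#' (grow method, depth drawn from the mutation ramp). If the result exceeds
#' the depth cap the mutation is retried a bounded number of times and
#' falls back to the unmutated tree.
#'
#' @param t a language object.
#' @param terminals terminal names.
#' @param config a [gp_config()].
#' @param retries attempts before giving up.
#' @return a mutated (or, on retry exhaustion, unchanged) language object.
#' @export
subtree_mutation <- function(t, terminals, config = gp_config(), retries = 5) {
  for (r in seq_len(retries)) {
    p <- sample.int(tree_size(t), 1L)
    d <- sample(seq(config$mutation_depth[1], config$mutation_depth[2]), 1L)
    out <- replace_at(t, p, grow_tree(d, terminals, config$const_range))
    if (tree_depth(out) <= config$max_depth) return(out)
  }
  t
}

# ---- steady-state loop ---------------------------------------------------

#' Evolve a symbolic hazard model by steady-state GP
#'
#' Initialises a population by ramped half-and-half, evaluates every member
#' with the censored-data negative log-likelihood on the training
#' person-period table, then iterates: draw `sample_size` members without
#' replacement, take the two fittest as parents, apply subtree crossover
#' with probability `crossover_rate` and subtree mutation to each child with
#' probability `mutation_rate`, evaluate the offspring, and let each
#' offspring replace the worst remaining sampled member if (and only if) it
#' is fitter. Offspring that received no variation — exact clones of their
#' parents — are never re-inserted, so a variation-free configuration
#' leaves the population invariant. The loop stops when the evaluation or
#' wall-clock budget
#' expires. The best-of-run model is the member of the *final* population
#' with the lowest negative log-likelihood on the holdout table, i.e. model
#' selection is on unseen data.
#'
#' @param train,holdout person-period tibbles sharing a covariate schema
#'   (see [to_person_period()]).
#' @param config a [gp_config()].
#' @param terminals terminal set (default: the covariate columns plus `tj`).
#' @return An object of class `gp_run`: the final population and fitness
#'   vector, the best-of-run [gp_tree()], holdout fitness, per-block
#'   statistics (`history`), and counters.
#' @export
steady_state_evolve <- function(train, holdout, config = gp_config(),
                                terminals = NULL) {
  if (nrow(train) == 0 || nrow(holdout) == 0) {
    stop("empty person-period table", call. = FALSE)
  }
  if (is.null(terminals)) terminals <- c(cohort_covariates(train), "tj")
  missing_cols <- setdiff(terminals, names(train))
  if (length(missing_cols) > 0) {
    stop("terminals absent from training table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  X_train <- as.matrix(train[terminals])
  ev_train <- as.integer(train$event)
  fitness_of <- function(prog) {
    .prog_nll(prog$code, prog$val, X_train, ev_train)
  }

  t0 <- Sys.time()
  pop <- lapply(ramped_half_and_half(config$population_size, terminals,
                                     config),
                compile_program, terminals = terminals)
  fit <- vapply(pop, fitness_of, numeric(1))

  evals <- 0L
  history <- list(list(evaluations = 0L, best_train_nll = min(fit),
                       median_train_nll = stats::median(fit)))
  next_log <- config$log_every

  budget_left <- function() {
    if (!is.null(config$max_evaluations) &&
        evals + 2L > config$max_evaluations) return(FALSE)
    if (!is.null(config$max_time) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) >=
        config$max_time) return(FALSE)
    TRUE
  }

  k <- min(config$sample_size, config$population_size)
  while (budget_left()) {
    idx <- sample.int(config$population_size, k)
    ord <- idx[order(fit[idx])]
    p1 <- pop[[ord[1]]]
    p2 <- pop[[ord[2]]]
    varied <- c(FALSE, FALSE)
    if (stats::runif(1) < config$crossover_rate) {
      kids <- px_crossover(p1, p2, config$max_depth)
      varied <- c(TRUE, TRUE)
    } else {
      kids <- list(p1, p2)
    }
    for (m in 1:2) {
      if (stats::runif(1) < config$mutation_rate) {
        kids[[m]] <- px_mutate(kids[[m]], terminals, config)
        varied[m] <- TRUE
      }
    }
    kid_fit <- c(fitness_of(kids[[1]]), fitness_of(kids[[2]]))
    evals <- evals + 2L
    # newly created (varied) offspring replace the worst sampled members,
    # only if fitter; unvaried clones of their parents are not re-inserted
    worst <- rev(ord)
    slot <- 1L
    for (m in 1:2) {
      if (varied[m] && kid_fit[m] < fit[worst[slot]]) {
        pop[[worst[slot]]] <- kids[[m]]
        fit[worst[slot]] <- kid_fit[m]
        slot <- slot + 1L
      }
    }
    if (evals >= next_log) {
      history[[length(history) + 1L]] <-
        list(evaluations = evals, best_train_nll = min(fit),
             median_train_nll = stats::median(fit))
      next_log <- next_log + config$log_every
    }
  }

  X_hold <- as.matrix(holdout[terminals])
  ev_hold <- as.integer(holdout$event)
  holdout_nll <- vapply(pop, function(prog) {
    .prog_nll(prog$code, prog$val, X_hold, ev_hold)
  }, numeric(1))
  best_idx <- which.min(holdout_nll)

  best <- gp_tree(program_to_expr(pop[[best_idx]], terminals),
                  terminals = terminals,
                  delta = attr(train, "width") %||% 1,
                  trained_intervals = max(train$j))
  population <- lapply(pop, program_to_expr, terminals = terminals)
  structure(
    list(population = population, fitness = fit,
         holdout_nll = holdout_nll,
         best_tree = best,
         best_train_nll = fit[best_idx],
         best_holdout_nll = holdout_nll[best_idx],
         history = dplyr::bind_rows(lapply(history, tibble::as_tibble)),
         evaluations = evals,
         elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         config = config, terminals = terminals),
    class = "gp_run")
}

#' @export
print.gp_run <- function(x, ...) {
  cat("<gp_run> population", length(x$population),
      "|", x$evaluations, "offspring evaluations\n")
  cat("  best train NLL  ", format(min(x$fitness)), "\n")
  cat("  best holdout NLL", format(x$best_holdout_nll), "\n")
  cat("  best-of-run:", serialize_tree(x$best_tree), "\n")
  invisible(x)
}
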