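# The genetic-algorithm loop: binary tournament selection, recombination /
# mutation, (1+lambda) elitist replacement, stopping criteria and the
# multi-execution driver.

#' GA configuration
#'
#' Defaults follow the reference setup: 100 individuals, recombination rate
#' 0.80 (80% of reproduction events cross two parents; otherwise the
#' offspring starts as a copy of one tournament-selected parent), mutation
#' rate 1.00 (every offspring mutates), stopping on reaching the maximum
#' fitness, 50 stagnant generations, or 15000 fitness evaluations; 30
#' executions per patient.
#'
#' @param population_size individuals per generation.
#' @param recombination_rate probability a reproduction event crosses two
#'   parents.
#' @param mutation_rate probability an offspring mutates.
#' @param max_evaluations evaluation budget per execution.
#' @param stagnation_generations stop after this many generations without
#'   best-fitness improvement.
#' @param max_fitness stop once best fitness reaches this value.
#' @param n_executions executions per patient.
#' @param lambda offspring per generation (half the population reproduces).
#' @param seed master seed; execution `i` uses `seed + i`.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 100L,
                      recombination_rate = 0.80,
                      mutation_rate = 1.00,
                      max_evaluations = 15000L,
                      stagnation_generations = 50L,
                      max_fitness = 1.0,
                      n_executions = 30L,
                      lambda = population_size %/% 2L,
                      seed = NULL) {
  stopifnot(population_size > 0, lambda > 0,
            recombination_rate >= 0, recombination_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            max_evaluations > 0, stagnation_generations > 0)
  structure(list(population_size = as.integer(population_size),
                 recombination_rate = recombination_rate,
                 mutation_rate = mutation_rate,
                 max_evaluations = as.integer(max_evaluations),
                 stagnation_generations = as.integer(stagnation_generations),
                 max_fitness = max_fitness,
                 n_executions = as.integer(n_executions),
                 lambda = as.integer(lambda),
                 seed = seed),
            class = "ga_config")
}

#' Binary tournament parent selection
#'
#' Repeated size-2 tournaments (sampling with replacement); the individual
#' with the higher fitness wins each tournament, until `n_parents` parents
#' (half the population by default) are chosen.
#'
#' @param fitnesses numeric vector of evaluated fitnesses.
#' @param n_parents number of parents to select.
#' @return integer vector of selected population indices.
#' @export
tournament_select <- function(fitnesses, n_parents = length(fitnesses) %/% 2L) {
  n <- length(fitnesses)
  stopifnot(n >= 1L, !anyNA(fitnesses))
  a <- sample.int(n, n_parents, replace = TRUE)
  b <- sample.int(n, n_parents, replace = TRUE)
  ifelse(fitnesses[a] >= fitnesses[b], a, b)
}

#' One reproduction event
#'
#' With probability `recombination_rate` the two parents are recombined;
#' otherwise the offspring starts as a copy of the first parent. With
#' probability `mutation_rate` the offspring then mutates by one unitary
#' neighbourhood step. Returns bookkeeping used by operator-rate audits.
#'
#' @param parent_a,parent_b `individual`s (tournament winners).
#' @param domains a [gene_domains()] object.
#' @param config a [ga_config()].
#' @return list with `offspring`, logical `recombined` and `mutated`, and
#'   `premutation` (the offspring before mutation).
#' @export
reproduction_event <- function(parent_a, parent_b, domains, config) {
  recombined <- stats::runif(1) < config$recombination_rate
  child <- if (recombined)
    recombine_individuals(parent_a, parent_b, domains)
  else new_individual(parent_a$hyper_features)
  premutation <- child
  mutated <- stats::runif(1) < config$mutation_rate
  if (mutated) child <- mutate_individual(child, domains)
  list(offspring = child, recombined = recombined, mutated = mutated,
       premutation = premutation)
}

#' Run one GA execution
#'
#' Initializes a random population, evaluates it, then loops: select half
#' the population by binary tournament, produce `lambda` offspring
#' (recombination rate 0.80, mutation rate 1.00), evaluate them, and keep
#' the best `population_size` of parents plus offspring ((1+lambda)
#' elitist replacement, so the best-fitness trajectory is non-decreasing).
#' Stops on reaching `max_fitness`, on `stagnation_generations` without
#' improvement, or on exhausting the evaluation budget. Previously
#' evaluated genotypes are served from a cache; only fresh evaluations
#' count against the budget.
#'
#' @param fitness_fn function(individual) -> numeric fitness; errors are
#'   mapped to the sentinel fitness -10.
#' @param domains a [gene_domains()] object.
#' @param config a [ga_config()].
#' @param seed integer seed for this execution (all stochastic draws flow
#'   from it).
#' @return an `execution_result`: `best` individual, `best_fitness`,
#'   `trajectory` (best per generation), `generations`, `evaluations`,
#'   `stop_reason`.
#' @export
run_execution <- function(fitness_fn, domains, config = ga_config(),
                          seed = NULL) {
  with_seed(seed, {
    cache <- new.env(parent = emptyenv())
    evals <- 0L
    evaluate <- function(ind) {
      key <- genotype_key(ind)
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      f <- tryCatch(fitness_fn(ind), error = function(e) -10)
      if (!is.finite(f)) f <- -10
      evals <<- evals + 1L
      cache[[key]] <- f
      f
    }
    pop <- lapply(seq_len(config$population_size),
                  function(i) random_individual(domains))
    for (i in seq_along(pop)) pop[[i]]$fitness <- evaluate(pop[[i]])
    fitnesses <- vapply(pop, function(p) p$fitness, numeric(1))
    best_idx <- which.max(fitnesses)
    best <- pop[[best_idx]]
    trajectory <- best$fitness
    stagnant <- 0L
    generation <- 0L
    stop_reason <- NULL
    repeat {
      if (best$fitness >= config$max_fitness - 1e-9) {
        stop_reason <- "max_fitness"; break
      }
      if (stagnant >= config$stagnation_generations) {
        stop_reason <- "stagnation"; break
      }
      if (evals >= config$max_evaluations) {
        stop_reason <- "evaluation_budget"; break
      }
      generation <- generation + 1L
      parents_idx <- tournament_select(fitnesses)
      offspring <- vector("list", config$lambda)
      for (o in seq_len(config$lambda)) {
        pair <- parents_idx[sample.int(length(parents_idx), 2L,
                                       replace = length(parents_idx) < 2L)]
        ev <- reproduction_event(pop[[pair[1L]]], pop[[pair[2L]]],
                                 domains, config)
        child <- ev$offspring
        child$fitness <- evaluate(child)
        offspring[[o]] <- child
        if (evals >= config$max_evaluations) {
          offspring <- offspring[seq_len(o)]
          break
        }
      }
      pool <- c(pop, offspring)
      pool_fit <- vapply(pool, function(p) p$fitness, numeric(1))
      # ties broken towards offspring (higher pool index): equal-fitness
      # mutants replace their parents, so the population can drift along
      # fitness plateaus instead of freezing on them
      keep <- order(pool_fit, seq_along(pool),
                    decreasing = TRUE)[seq_len(config$population_size)]
      pop <- pool[keep]
      fitnesses <- pool_fit[keep]
      new_best <- pop[[1L]]
      if (new_best$fitness > best$fitness + 1e-12) {
        best <- new_best
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      trajectory <- c(trajectory, best$fitness)
    }
    structure(list(best = best, best_fitness = best$fitness,
                   trajectory = trajectory, generations = generation,
                   evaluations = evals, stop_reason = stop_reason,
                   seed = seed),
              class = "execution_result")
  })
}

#' @export
print.execution_result <- function(x, ...) {
  cat(sprintf(
    "<execution_result> best fitness %.4f after %d generation(s), %d evaluation(s) [%s]\n",
    x$best_fitness, x$generations, x$evaluations, x$stop_reason))
  invisible(x)
}

#' Run the full multi-execution GA for one patient
#'
#' Executes the GA `n_executions` times (default 30) with per-execution
#' seeds `seed + i`, the fitness being the iterative-retraining pipeline on
#' the patient's training seizures. Results are optionally persisted as
#' one JSON record per execution.
#'
#' @param patient a [prepare_patient()] object.
#' @param domains a [gene_domains()] object (defaults to the domains
#'   restricted to the patient's electrodes).
#' @param config a [ga_config()].
#' @param min_preictal minimum pre-ictal period in minutes.
#' @param seed master seed.
#' @param out_dir optional directory for per-execution JSON results.
#' @return list of `execution_result`s.
#' @export
run_patient <- function(patient, domains = NULL, config = ga_config(),
                        min_preictal = 40, seed = NULL, out_dir = NULL) {
  stopifnot(inherits(patient, "patient_data"))
  domains <- domains %||% gene_domains(electrodes = patient$electrodes)
  seed <- seed %||% config$seed %||% 1L
  fitness_fn <- function(ind) evaluate_fitness(ind, patient, min_preictal)
  results <- lapply(seq_len(config$n_executions), function(i) {
    res <- run_execution(fitness_fn, domains, config, seed = seed + i)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      individual_to_json(res$best,
                         file.path(out_dir,
                                   sprintf("execution_%02d.json", i)))
    }
    res
  })
  results
}
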