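#' Validation fitness of one architecture
#'
#' Trains the genome's network from scratch on the dataset's training
#' partition for a short budget and returns the best validation MSE seen
#' (in scaled RT units); the trained weights are discarded.  A non-finite
#' training loss yields `Inf`, so a pathological architecture survives in
#' the population as the worst individual rather than aborting the search.
#'
#' @param genome an `rt_genome`.
#' @param dataset an `rt_dataset`.
#' @param alphabet the residue alphabet.
#' @param fixed_length encoding length (default: longest peptide present).
#' @param max_epochs fitness training budget (default 20).
#' @param batch_size minibatch size (default 64).
#' @param patience early-stop patience (default 5).
#' @param seed integer seed.
#' @return validation MSE (scaled RT units), lower is better.
#' @export
evaluate_fitness <- function(genome, dataset, alphabet = rt_alphabet(),
                             fixed_length = NULL, max_epochs = 20L,
                             batch_size = 64L, patience = 5L, seed = 1L) {
  fit <- tryCatch(
    rtnet(genome, dataset, alphabet, fixed_length,
          max_epochs = max_epochs, batch_size = batch_size,
          patience = patience, seed = seed),
    error = function(e) {
      if (grepl("diverged", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(fit)) return(Inf)
  fit$provenance$best_val_mse
}

#' Tournament parent selection
#'
#' Each parent is the lowest-MSE member of a tournament of
#' `tournament_size` individuals drawn without replacement from the
#' population.
#'
#' @param fitness numeric vector of evaluated fitness values (validation
#'   MSE, lower is better); `NA` marks an unevaluated individual and is an
#'   error.
#' @param n_pairs number of parent pairs to draw.
#' @param tournament_size individuals per tournament (default 3).
#' @return integer matrix with `n_pairs` rows and columns `a`, `b` of
#'   population indices.
#' @export
select_parents <- function(fitness, n_pairs, tournament_size = 3L) {
  if (anyNA(fitness))
    stop("all individuals must be evaluated before selection", call. = FALSE)
  n <- length(fitness)
  tournament_size <- min(tournament_size, n)
  pick <- function() {
    ix <- sample.int(n, tournament_size)
    ix[which.min(fitness[ix])]
  }
  out <- matrix(0L, nrow = n_pairs, ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  for (i in seq_len(n_pairs)) {
    out[i, 1] <- pick()
    out[i, 2] <- pick()
  }
  out
}

#' Genetic-algorithm search over network architectures
#'
#' Evolves a population of architecture genomes: every individual is
#' scored by [evaluate_fitness()] (short from-scratch training, validation
#' MSE), parents are chosen by tournament selection, children are produced
#' by uniform crossover and per-field mutation, and the best
#' `elitism_count` individuals are carried over unchanged.  Fitness values
#' are cached by genome, so an elite is not retrained.  Returns the best
#' `top_k` distinct genomes ever evaluated, ranked by validation MSE.
#'
#' @param space an [rt_search_space()].
#' @param dataset an `rt_dataset`.
#' @param alphabet the residue alphabet.
#' @param generations number of generations (default 20).
#' @param population_size individuals per generation (default 50).
#' @param top_k number of best genomes to return (default 10).
#' @param elitism_count elites copied unchanged each generation (default 1).
#' @param tournament_size tournament size for selection (default 3).
#' @param mutation_rate per-field mutation probability (default 0.1).
#' @param max_epochs fitness training budget per individual (default 20).
#' @param batch_size minibatch size (default 64).
#' @param patience early-stop patience for fitness training (default 5).
#' @param fixed_length encoding length (default: longest peptide present).
#' @param seed master seed; the search is reproducible given it.
#' @param verbose print per-generation progress.
#' @return an object of class `rt_nas`: `top` (list of
#'   `list(genome, fitness)` ranked ascending), `log` (per-generation data
#'   frame with `generation`, `best_mse`, `median_mse`, `best_genome_json`)
#'   and the call parameters.
#' @export
rt_nas <- function(space, dataset, alphabet = rt_alphabet(),
                   generations = 20L, population_size = 50L, top_k = 10L,
                   elitism_count = 1L, tournament_size = 3L,
                   mutation_rate = 0.1, max_epochs = 20L, batch_size = 64L,
                   patience = 5L, fixed_length = NULL, seed = 1L,
                   verbose = FALSE) {
  stopifnot(population_size >= top_k, generations >= 1L,
            elitism_count >= 0L, elitism_count < population_size)
  with_seed_(seed, {
    cache <- new.env(parent = emptyenv())
    evaluated <- list()  # genome json -> list(genome, fitness)
    score <- function(genome) {
      key <- as.character(genome_to_json(genome))
      if (!is.null(cache[[key]])) return(cache[[key]])
      eval_seed <- sample.int(.Machine$integer.max, 1L)
      f <- evaluate_fitness(genome, dataset, alphabet, fixed_length,
                            max_epochs = max_epochs,
                            batch_size = batch_size,
                            patience = patience, seed = eval_seed)
      cache[[key]] <- f
      evaluated[[key]] <<- list(genome = genome, fitness = f)
      f
    }
    population <- replicate(population_size, random_genome(space),
                            simplify = FALSE)
    log_rows <- vector("list", generations)
    for (gen in seq_len(generations)) {
      fitness <- vapply(population, score, numeric(1))
      ord <- order(fitness)
      best <- fitness[ord[1]]
      if (verbose)
        message(sprintf("generation %d: best %.5g median %.5g", gen, best,
                        median(fitness)))
      log_rows[[gen]] <- data.frame(
        generation = gen,
        best_mse = best,
        median_mse = median(fitness),
        best_genome_json = as.character(genome_to_json(population[[ord[1]]])),
        stringsAsFactors = FALSE)
      if (gen == generations) break
      elites <- population[ord[seq_len(elitism_count)]]
      n_children <- population_size - elitism_count
      pairs <- select_parents(fitness, ceiling(n_children / 2),
                              tournament_size)
      children <- list()
      for (i in seq_len(nrow(pairs))) {
        kids <- crossover_genomes(population[[pairs[i, 1]]],
                                  population[[pairs[i, 2]]])
        children <- c(children,
                      lapply(kids, mutate_genome, space = space,
                             rate = mutation_rate))
      }
      population <- c(elites, children[seq_len(n_children)])
    }
    ranked <- evaluated[order(vapply(evaluated, `[[`, numeric(1),
                                     "fitness"))]
    top <- unname(ranked[seq_len(min(top_k, length(ranked)))])
    structure(list(top = top,
                   log = do.call(rbind, log_rows),
                   space = space,
                   params = list(generations = generations,
                                 population_size = population_size,
                                 top_k = top_k,
                                 elitism_count = elitism_count,
                                 tournament_size = tournament_size,
                                 mutation_rate = mutation_rate,
                                 max_epochs = max_epochs,
                                 seed = seed)),
              class = "rt_nas")
  })
}

#' @export
print.rt_nas <- function(x, ...) {
  cat("Architecture search:", x$params$generations, "generations x",
      x$params$population_size, "individuals\n")
  cat("  best validation MSE:", signif(x$top[[1]]$fitness, 4),
      "(scaled RT)\n")
  cat("  per-generation best:",
      paste(signif(x$log$best_mse, 3), collapse = " "), "\n")
  invisible(x)
}
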