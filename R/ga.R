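# Genetic-algorithm descriptor-subset selection with Q2-LOO fitness and the
# QUIK collinearity rule. Chromosomes are fixed-size index sets; selection is
# size-2 tournament, crossover draws a child from the union of its parents,
# mutation swaps one descriptor for one outside the subset.

#' Genetic-algorithm configuration
#'
#' @param subset_size number of descriptors per model (default 6, the size
#'   of the arginase-I equation).
#' @param population_size chromosomes per generation (default 100).
#' @param generations number of generations (default 200).
#' @param mutation_rate per-chromosome probability of a point mutation.
#' @param crossover_rate probability a child is produced by crossover rather
#'   than copied.
#' @param elitism number of best chromosomes carried over unchanged (>= 1
#'   keeps the best-fitness trace monotone).
#' @param quik_delta QUIK acceptance threshold (default 0.05); subsets
#'   failing the rule get fitness `-Inf`.
#' @param seed RNG seed for a reproducible run.
#' @return list of class `"ga_config"`.
#' @export
ga_config <- function(subset_size = 6L, population_size = 100L,
                      generations = 200L, mutation_rate = 0.3,
                      crossover_rate = 0.9, elitism = 2L,
                      quik_delta = 0.05, seed = NULL) {
  stopifnot(subset_size >= 1, population_size >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1, elitism >= 0)
  structure(list(subset_size = as.integer(subset_size),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 elitism = as.integer(elitism),
                 quik_delta = quik_delta, seed = seed),
            class = "ga_config")
}

.subset_fitness <- function(X, y, idx, quik_delta) {
  Xs <- X[, idx, drop = FALSE]
  if (length(idx) >= 2L) {
    qk <- tryCatch(quik_filter(Xs, y, quik_delta), error = function(e) NULL)
    if (is.null(qk) || !qk$pass) return(-Inf)
  }
  q2_loo(Xs, y)
}

#' Descriptor-subset selection by genetic algorithm
#'
#' Searches fixed-size descriptor subsets maximizing leave-one-out Q2 under
#' the QUIK collinearity rule. Deterministic given `config$seed`.
#'
#' @param x descriptor pool (matrix/data.frame, named columns).
#' @param y numeric response.
#' @param config a [ga_config()].
#' @return object of class `"ga_selection"`: `best` (descriptor names),
#'   `best_fitness`, `top` (ranked unique subsets with fitness, up to 10),
#'   `trace` (per-generation best/mean fitness) and the config.
#' @export
ga_select <- function(x, y, config = ga_config()) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  p <- ncol(X); k <- config$subset_size
  if (p < k) stop("pool has fewer columns than subset_size")
  if (!is.null(config$seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(config$seed)
  }
  fit_cache <- new.env(hash = TRUE, parent = emptyenv())
  fitness <- function(idx) {
    key <- paste(idx, collapse = ",")
    f <- fit_cache[[key]]
    if (is.null(f)) {
      f <- .subset_fitness(X, y, idx, config$quik_delta)
      fit_cache[[key]] <- f
    }
    f
  }
  if (p == k) {
    idx <- seq_len(p)
    f <- fitness(idx)
    return(structure(list(best = colnames(X)[idx], best_fitness = f,
                          top = list(list(descriptors = colnames(X)[idx],
                                          fitness = f)),
                          trace = data.frame(generation = 0L, best = f,
                                             mean = f),
                          config = config), class = "ga_selection"))
  }
  npop <- config$population_size
  pop <- lapply(seq_len(npop), function(i) sort(sample.int(p, k)))
  fits <- vapply(pop, fitness, numeric(1))
  trace <- data.frame(generation = integer(), best = numeric(),
                      mean = numeric())
  record <- function(gen) {
    fin <- fits[is.finite(fits)]
    trace <<- rbind(trace, data.frame(
      generation = gen, best = if (length(fin)) max(fin) else -Inf,
      mean = if (length(fin)) mean(fin) else -Inf))
  }
  record(0L)
  tournament <- function() {
    a <- sample.int(npop, 2L)
    if (fits[a[1]] >= fits[a[2]]) pop[[a[1]]] else pop[[a[2]]]
  }
  for (gen in seq_len(config$generations)) {
    ord <- order(fits, decreasing = TRUE)
    newpop <- pop[ord[seq_len(min(config$elitism, npop))]]
    while (length(newpop) < npop) {
      p1 <- tournament()
      child <- if (stats::runif(1) < config$crossover_rate) {
        pool_u <- union(p1, tournament())
        sort(sample(pool_u, k))
      } else p1
      if (stats::runif(1) < config$mutation_rate) {
        out <- sample.int(k, 1L)
        child[out] <- sample(setdiff(seq_len(p), child), 1L)
        child <- sort(child)
      }
      newpop[[length(newpop) + 1L]] <- child
    }
    pop <- newpop
    fits <- vapply(pop, fitness, numeric(1))
    record(gen)
  }
  if (!any(is.finite(fits)))
    stop("no descriptor subset passed the QUIK rule; consider relaxing quik_delta")
  keys <- vapply(pop, paste, "", collapse = ",")
  uni <- !duplicated(keys)
  ord <- order(fits[uni], decreasing = TRUE)
  top_idx <- which(uni)[ord][seq_len(min(10L, sum(uni)))]
  top <- lapply(top_idx, function(i)
    list(descriptors = colnames(X)[pop[[i]]], fitness = fits[i]))
  best <- top[[1]]
  structure(list(best = best$descriptors, best_fitness = best$fitness,
                 top = top, trace = trace, config = config),
            class = "ga_selection")
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("GA descriptor selection: best Q2_LOO = %.4f\n  subset: %s\n",
              x$best_fitness, paste(x$best, collapse = ", ")))
  invisible(x)
}

#' Exhaustive best subset (small pools)
#'
#' Enumerates all subsets of the given size and returns the one with the
#' best Q2-LOO fitness under the same QUIK rule as [ga_select()]. Intended
#' for small pools and as an oracle for the GA.
#'
#' @inheritParams ga_select
#' @param subset_size subset size.
#' @param quik_delta QUIK threshold.
#' @return list with `best` (names) and `best_fitness`.
#' @export
exhaustive_select <- function(x, y, subset_size = 3L, quik_delta = 0.05) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  combs <- utils::combn(ncol(X), subset_size)
  fits <- apply(combs, 2, function(idx)
    .subset_fitness(X, as.numeric(y), idx, quik_delta))
  best <- which.max(fits)
  list(best = colnames(X)[combs[, best]], best_fitness = fits[best])
}
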