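## Genetic-algorithm hyperparameter search over network genomes:
## elitist half-replacement with single-point crossover and whole-genome
## mutation of the least-fit half.

GA_FAMILIES <- c("fnn2", "fnn4", "fnn8", "rnn", "cnn")

# gene bounds per family; reals are exponents of 10^-k genes
gene_bounds <- function(family, overrides = NULL) {
  common <- list(epochs = c(10, 300), lr_exp = c(0, 7))
  b <- switch(substr(family, 1, 3),
    fnn = c(common, list(neurons = c(2, 30), eps_exp = c(0, 7))),
    rnn = c(common, list(partitions = c(10, 100), neurons_per_fold = c(2, 30),
                         neurons = c(2, 30), eps_exp = c(0, 7))),
    cnn = c(common, list(conv_layers = c(1, 5), filter_size = c(2, 11),
                         filter_skip = c(2, 11), kernel_exp = c(1, 5),
                         neurons = c(2, 30), eps_exp = c(0, 7))),
    stop("unknown family: ", family, call. = FALSE))
  for (nm in names(overrides)) b[[nm]] <- overrides[[nm]]
  b
}

integer_genes <- c("epochs", "neurons", "partitions", "neurons_per_fold",
                   "conv_layers", "filter_size", "filter_skip", "kernel_exp")

#' Random genome within the search space
#'
#' Draws each hyperparameter gene uniformly over its bound: integer genes
#' uniformly over the integer range, the learning-rate and AdaGrad-epsilon
#' genes as uniform exponents `k` of `10^-k` (log-uniform rates).  The
#' dependent bound `filter_skip <= filter_size` is repaired by clamping.
#'
#' @param family one of `"fnn2"`, `"fnn4"`, `"fnn8"`, `"rnn"`, `"cnn"`.
#' @param overrides optional named list of `c(lo, hi)` bound replacements
#'   (used by reduced-scale presets).
#' @return A list of class `nn_genome` with `family` and named `genes`.
#' @export
random_genome <- function(family = GA_FAMILIES, overrides = NULL) {
  family <- match.arg(family)
  b <- gene_bounds(family, overrides)
  genes <- vapply(names(b), function(nm) {
    if (nm %in% integer_genes) {
      lo <- as.integer(b[[nm]][1]); hi <- as.integer(b[[nm]][2])
      as.numeric(sample(seq(lo, hi), 1))
    } else stats::runif(1, b[[nm]][1], b[[nm]][2])
  }, numeric(1))
  repair_genome(structure(list(family = family, genes = genes,
                               overrides = overrides),
                          class = "nn_genome"))
}

repair_genome <- function(g) {
  b <- gene_bounds(g$family, g$overrides)
  for (nm in names(g$genes)) {
    g$genes[[nm]] <- min(max(g$genes[[nm]], b[[nm]][1]), b[[nm]][2])
  }
  if (g$family == "cnn" && g$genes[["filter_skip"]] > g$genes[["filter_size"]]) {
    g$genes[["filter_skip"]] <- g$genes[["filter_size"]]
  }
  g
}

#' Translate a genome into a trainable network specification
#'
#' @param genome an `nn_genome`.
#' @param dropout_rate forwarded to [nn_spec()].
#' @return An [nn_spec()].
#' @export
genome_to_spec <- function(genome, dropout_rate = 0.9) {
  g <- genome$genes
  fam <- genome$family
  if (startsWith(fam, "fnn")) {
    nn_spec("fnn", epochs = g[["epochs"]], learning_rate = 10^-g[["lr_exp"]],
            adagrad_epsilon = 10^-g[["eps_exp"]], neurons = g[["neurons"]],
            depth = as.integer(substr(fam, 4, 4)),
            dropout_rate = dropout_rate)
  } else if (fam == "rnn") {
    nn_spec("rnn", epochs = g[["epochs"]], learning_rate = 10^-g[["lr_exp"]],
            adagrad_epsilon = 10^-g[["eps_exp"]], neurons = g[["neurons"]],
            partitions = g[["partitions"]],
            neurons_per_fold = g[["neurons_per_fold"]],
            dropout_rate = dropout_rate)
  } else {
    nn_spec("cnn", epochs = g[["epochs"]], learning_rate = 10^-g[["lr_exp"]],
            adagrad_epsilon = 10^-g[["eps_exp"]], neurons = g[["neurons"]],
            conv_layers = g[["conv_layers"]], filter_size = g[["filter_size"]],
            filter_skip = g[["filter_skip"]],
            base_kernels = 2^g[["kernel_exp"]], dropout_rate = dropout_rate)
  }
}

#' Single-point crossover of two genomes
#'
#' A cut point is drawn uniformly between gene positions; the child takes
#' the first parent's genes before the cut and the second parent's after,
#' then dependent bounds are repaired.
#'
#' @param a,b `nn_genome`s of the same family.
#' @return An `nn_genome`.
#' @export
crossover_genomes <- function(a, b) {
  if (a$family != b$family) stop("cannot cross different families",
                                 call. = FALSE)
  n <- length(a$genes)
  cut <- sample.int(n - 1, 1)
  child <- a
  child$genes[(cut + 1):n] <- b$genes[(cut + 1):n]
  repair_genome(child)
}

#' Whole-genome mutation
#'
#' With probability `rate` the genome is replaced by a completely fresh
#' random genome of the same family; otherwise it is returned unchanged.
#'
#' @param g an `nn_genome`.
#' @param rate mutation probability.
#' @return An `nn_genome`.
#' @export
mutate_genome <- function(g, rate = 0.05) {
  if (stats::runif(1) < rate) random_genome(g$family, g$overrides) else g
}

#' Evolution settings
#'
#' Defaults follow the study design: 30 generations of 30 individuals,
#' single-point crossover, the fittest half carried over unchanged (each
#' elite mating with a random member of the population to produce the
#' replacement bottom half) and 5% whole-genome mutation applied to the new
#' bottom half; fitness is validation-set accuracy.
#'
#' @param generations,population evolution size (population even).
#' @param mutation_rate mutation probability for replacement individuals.
#' @param elite_fraction surviving fraction.
#' @param bounds optional gene-bound overrides (see [random_genome()]).
#' @param dropout_rate forwarded to [genome_to_spec()].
#' @return List of class `ga_config`.
#' @export
ga_config <- function(generations = 30, population = 30,
                      mutation_rate = 0.05, elite_fraction = 0.5,
                      bounds = NULL, dropout_rate = 0.9) {
  stopifnot(population %% 2 == 0, generations >= 1)
  structure(list(generations = generations, population = population,
                 mutation_rate = mutation_rate,
                 elite_fraction = elite_fraction, bounds = bounds,
                 dropout_rate = dropout_rate),
            class = "ga_config")
}

#' Reduced-scale evolution preset
#'
#' A small population/short horizon configuration (8 individuals, 5
#' generations, epochs capped at 60) for interactive work and continuous
#' testing; the full-scale settings remain the default of [ga_config()].
#'
#' @param ... overrides passed on to [ga_config()].
#' @export
desk_ga_config <- function(...) {
  ga_config(generations = 5, population = 8,
            bounds = list(epochs = c(10, 60)), ...)
}

#' Evolve network hyperparameters
#'
#' Runs the elitist genetic algorithm: each generation is ranked by fitness
#' (by default, validation accuracy of the trained network), the top half
#' survives unchanged, and each elite mates with a random member of the
#' population (single-point crossover) to replace the bottom half, which is
#' then mutation-eligible.  Fitness values are cached by genome, and a
#' genome whose training fails scores 0 rather than aborting the run.
#'
#' @param family one of `"fnn2"`, `"fnn4"`, `"fnn8"`, `"rnn"`, `"cnn"`.
#' @param train,val [ftir_dataset()]s (z-scored) for the default fitness.
#' @param config a [ga_config()].
#' @param fitness optional function(genome) -> numeric, replacing network
#'   training (used for calibration studies).
#' @param seed optional integer seed.
#' @return List of class `ga_history`: `best` (fittest genome),
#'   `best_fitness`, `history` (tibble generation/best/mean) and
#'   `population` (final genomes).
#' @export
evolve <- function(family, train = NULL, val = NULL, config = ga_config(),
                   fitness = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fitness)) {
    stopifnot(!is.null(train), !is.null(val))
    fitness <- function(genome) {
      tryCatch({
        spec <- genome_to_spec(genome, config$dropout_rate)
        cl <- train_network(spec, train, val)
        cl$val_accuracy
      }, error = function(e) 0)
    }
  }
  cache <- new.env(parent = emptyenv())
  eval_genome <- function(g) {
    key <- paste(signif(g$genes, 12), collapse = "|")
    if (is.null(cache[[key]])) cache[[key]] <- fitness(g)
    cache[[key]]
  }
  pop <- replicate(config$population,
                   random_genome(family, config$bounds), simplify = FALSE)
  n_elite <- round(config$population * config$elite_fraction)
  hist <- vector("list", config$generations)
  for (gen in seq_len(config$generations)) {
    fit <- vapply(pop, eval_genome, numeric(1))
    ord <- order(fit, decreasing = TRUE)
    pop <- pop[ord]; fit <- fit[ord]
    hist[[gen]] <- tibble::tibble(generation = gen, best = fit[1],
                                  mean = mean(fit))
    if (gen == config$generations) break
    elites <- pop[seq_len(n_elite)]
    children <- lapply(elites, function(e) {
      partner <- pop[[sample.int(config$population, 1)]]
      mutate_genome(crossover_genomes(e, partner), config$mutation_rate)
    })
    children <- children[seq_len(config$population - n_elite)]
    pop <- c(elites, children)
  }
  structure(list(best = pop[[1]], best_fitness = fit[1],
                 history = dplyr::bind_rows(hist), population = pop),
            class = "ga_history")
}

#' @export
print.ga_history <- function(x, ...) {
  cat(sprintf("<ga_history> %s: best fitness %.4f after %d generations\n",
              x$best$family, x$best_fitness, nrow(x$history)))
  invisible(x)
}

#' @export
tidy.ga_history <- function(x, ...) x$history

#' @export
glance.ga_history <- function(x, ...) {
  tibble::tibble(family = x$best$family, best_fitness = x$best_fitness,
                 generations = nrow(x$history))
}

#' Median and quartiles of tuned hyperparameters
#'
#' Summarises the best genomes of repeated evolution runs: per gene, the
#' median and 25th/75th percentiles across runs (learning-rate and epsilon
#' exponents are reported as the rates `10^-k` themselves).
#'
#' @param histories list of `ga_history` objects (same family).
#' @return Tibble with columns `gene`, `median`, `q25`, `q75`.
#' @export
summarize_tuned <- function(histories) {
  stopifnot(length(histories) >= 1)
  genes <- purrr::map_dfr(histories, function(h) {
    g <- h$best$genes
    g[grepl("_exp$", names(g)) & names(g) != "kernel_exp"] <-
      10^-g[grepl("_exp$", names(g)) & names(g) != "kernel_exp"]
    nm <- sub("lr_exp", "learning_rate", names(g))
    nm <- sub("eps_exp", "adagrad_epsilon", nm)
    tibble::tibble(gene = nm, value = unname(g))
  })
  dplyr::summarise(dplyr::group_by(genes, .data$gene),
                   median = stats::median(.data$value),
                   q25 = unname(stats::quantile(.data$value, 0.25)),
                   q75 = unname(stats::quantile(.data$value, 0.75)),
                   .groups = "drop")
}
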