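#' Architecture search space
#'
#' Defines the allowed values for every evolvable field of a network
#' genome.  A genome describes a stack of convolutional blocks followed by
#' a fixed bidirectional GRU of 50 units and a stack of dense blocks ending
#' in a single linear output.  Convolutional blocks evolve their number of
#' feature maps, activation, dropout proportion, and whether to apply batch
#' normalization and/or max pooling; dense blocks have the same options
#' except max pooling.  The genome is fixed-width: layer slots beyond the
#' active count are carried along as inactive slots so crossover and
#' mutation operate on aligned positions.
#'
#' @param conv_layers integer range `c(min, max)` of convolutional layers.
#' @param feature_maps allowed numbers of convolutional feature maps.
#' @param activations allowed activation functions.
#' @param dropout_rates allowed dropout proportions.
#' @param dense_layers integer range of dense layers.
#' @param dense_units allowed dense layer widths.
#' @param optimizers allowed optimizers.
#' @param gru_units width of the fixed bidirectional GRU (not searched).
#' @return an object of class `rt_search_space`.
#' @export
rt_search_space <- function(conv_layers = c(1L, 4L),
                            feature_maps = c(16L, 32L, 64L, 128L),
                            activations = c("relu", "tanh", "leaky_relu"),
                            dropout_rates = c(0, 0.1, 0.25, 0.5),
                            dense_layers = c(1L, 3L),
                            dense_units = c(32L, 64L, 128L, 256L),
                            optimizers = c("adam", "rmsprop",
                                           "sgd_momentum"),
                            gru_units = 50L) {
  stopifnot(length(conv_layers) == 2L, conv_layers[1] >= 0L,
            conv_layers[1] <= conv_layers[2],
            length(dense_layers) == 2L, dense_layers[1] >= 0L,
            dense_layers[1] <= dense_layers[2],
            length(feature_maps) >= 1L, length(activations) >= 1L,
            length(dropout_rates) >= 1L, length(dense_units) >= 1L,
            length(optimizers) >= 1L, gru_units >= 1L)
  structure(list(conv_layers = as.integer(conv_layers),
                 feature_maps = as.integer(feature_maps),
                 activations = activations,
                 dropout_rates = dropout_rates,
                 dense_layers = as.integer(dense_layers),
                 dense_units = as.integer(dense_units),
                 optimizers = optimizers,
                 gru_units = as.integer(gru_units)),
            class = "rt_search_space")
}

# length-safe uniform draw (sample() treats a length-1 numeric as 1:n)
sample1 <- function(x) x[sample.int(length(x), 1L)]

random_conv_gene <- function(space) {
  list(filters = sample1(space$feature_maps),
       activation = sample1(space$activations),
       dropout = sample1(space$dropout_rates),
       batch_norm = sample1(c(TRUE, FALSE)),
       max_pool = sample1(c(TRUE, FALSE)))
}

random_dense_gene <- function(space) {
  list(units = sample1(space$dense_units),
       activation = sample1(space$activations),
       dropout = sample1(space$dropout_rates),
       batch_norm = sample1(c(TRUE, FALSE)))
}

#' Sample, mutate, cross over and validate architecture genomes
#'
#' `random_genome()` draws every evolvable field uniformly from its allowed
#' set.  `mutate_genome()` independently resamples each field (including
#' the active layer counts) with probability `rate`.  `crossover_genomes()`
#' performs uniform crossover over the aligned genome slots of two parents.
#' `validate_genome()` checks a genome against the space and errors on any
#' violation.  Layer slots are fixed-width: a genome always carries
#' `max(conv_layers)` convolutional and `max(dense_layers)` dense slots,
#' of which the first `n_conv` / `n_dense` are active.
#'
#' @param space an [rt_search_space()].
#' @return `random_genome()` and `mutate_genome()` a genome (class
#'   `rt_genome`); `crossover_genomes()` a list of two genomes.
#' @export
random_genome <- function(space) {
  n_conv <- sample1(seq(space$conv_layers[1], space$conv_layers[2]))
  n_dense <- sample1(seq(space$dense_layers[1], space$dense_layers[2]))
  g <- list(
    n_conv = n_conv,
    n_dense = n_dense,
    conv = lapply(seq_len(space$conv_layers[2]),
                  function(i) random_conv_gene(space)),
    dense = lapply(seq_len(space$dense_layers[2]),
                   function(i) random_dense_gene(space)),
    optimizer = sample1(space$optimizers),
    gru_units = space$gru_units)
  structure(g, class = "rt_genome")
}

resample_field <- function(current, choices, rate) {
  if (runif(1) < rate) sample1(choices) else current
}

#' @rdname random_genome
#' @param genome an `rt_genome`.
#' @param rate per-field mutation probability (default 0.1).
#' @export
mutate_genome <- function(genome, space, rate = 0.1) {
  g <- genome
  g$n_conv <- resample_field(g$n_conv,
                             seq(space$conv_layers[1], space$conv_layers[2]),
                             rate)
  g$n_dense <- resample_field(g$n_dense,
                              seq(space$dense_layers[1],
                                  space$dense_layers[2]), rate)
  for (i in seq_along(g$conv)) {
    g$conv[[i]]$filters <- resample_field(g$conv[[i]]$filters,
                                          space$feature_maps, rate)
    g$conv[[i]]$activation <- resample_field(g$conv[[i]]$activation,
                                             space$activations, rate)
    g$conv[[i]]$dropout <- resample_field(g$conv[[i]]$dropout,
                                          space$dropout_rates, rate)
    g$conv[[i]]$batch_norm <- resample_field(g$conv[[i]]$batch_norm,
                                             c(TRUE, FALSE), rate)
    g$conv[[i]]$max_pool <- resample_field(g$conv[[i]]$max_pool,
                                           c(TRUE, FALSE), rate)
  }
  for (i in seq_along(g$dense)) {
    g$dense[[i]]$units <- resample_field(g$dense[[i]]$units,
                                         space$dense_units, rate)
    g$dense[[i]]$activation <- resample_field(g$dense[[i]]$activation,
                                              space$activations, rate)
    g$dense[[i]]$dropout <- resample_field(g$dense[[i]]$dropout,
                                           space$dropout_rates, rate)
    g$dense[[i]]$batch_norm <- resample_field(g$dense[[i]]$batch_norm,
                                              c(TRUE, FALSE), rate)
  }
  g$optimizer <- resample_field(g$optimizer, space$optimizers, rate)
  g
}

#' @rdname random_genome
#' @param a,b parent genomes from the same space.
#' @export
crossover_genomes <- function(a, b) {
  stopifnot(length(a$conv) == length(b$conv),
            length(a$dense) == length(b$dense))
  child <- function(pick) {
    g <- a
    k <- 1
    take <- function(xa, xb) {
      v <- if (pick[k]) xa else xb
      k <<- k + 1
      v
    }
    g$n_conv <- take(a$n_conv, b$n_conv)
    g$n_dense <- take(a$n_dense, b$n_dense)
    for (i in seq_along(a$conv))
      g$conv[[i]] <- take(a$conv[[i]], b$conv[[i]])
    for (i in seq_along(a$dense))
      g$dense[[i]] <- take(a$dense[[i]], b$dense[[i]])
    g$optimizer <- take(a$optimizer, b$optimizer)
    g
  }
  n_slots <- 2L + length(a$conv) + length(a$dense) + 1L
  pick <- runif(n_slots) < 0.5
  list(child(pick), child(!pick))
}

#' @rdname random_genome
#' @export
validate_genome <- function(genome, space) {
  ok <- function(cond, what) {
    if (!cond) stop("invalid genome: ", what, call. = FALSE)
  }
  ok(genome$n_conv >= space$conv_layers[1] &&
       genome$n_conv <= space$conv_layers[2], "conv layer count")
  ok(genome$n_dense >= space$dense_layers[1] &&
       genome$n_dense <= space$dense_layers[2], "dense layer count")
  ok(length(genome$conv) == space$conv_layers[2], "conv slot width")
  ok(length(genome$dense) == space$dense_layers[2], "dense slot width")
  for (cg in genome$conv) {
    ok(cg$filters %in% space$feature_maps, "feature maps")
    ok(cg$activation %in% space$activations, "conv activation")
    ok(cg$dropout %in% space$dropout_rates, "conv dropout")
    ok(is.logical(cg$batch_norm) && is.logical(cg$max_pool),
       "conv flags")
  }
  for (dg in genome$dense) {
    ok(dg$units %in% space$dense_units, "dense units")
    ok(dg$activation %in% space$activations, "dense activation")
    ok(dg$dropout %in% space$dropout_rates, "dense dropout")
    ok(is.logical(dg$batch_norm), "dense flag")
  }
  ok(genome$optimizer %in% space$optimizers, "optimizer")
  ok(genome$gru_units == space$gru_units, "gru width")
  invisible(TRUE)
}

#' @export
print.rt_genome <- function(x, ...) {
  cat("Network genome: ", x$n_conv, " conv + BiGRU(", x$gru_units,
      ") + ", x$n_dense, " dense, optimizer ", x$optimizer, "\n", sep = "")
  for (i in seq_len(x$n_conv)) {
    cg <- x$conv[[i]]
    cat(sprintf("  conv %d: %d maps, %s, dropout %.2f%s%s\n", i,
                cg$filters, cg$activation, cg$dropout,
                if (cg$batch_norm) ", bn" else "",
                if (cg$max_pool) ", pool" else ""))
  }
  for (i in seq_len(x$n_dense)) {
    dg <- x$dense[[i]]
    cat(sprintf("  dense %d: %d units, %s, dropout %.2f%s\n", i,
                dg$units, dg$activation, dg$dropout,
                if (dg$batch_norm) ", bn" else ""))
  }
  invisible(x)
}

#' A small fixed genome useful as a default architecture
#'
#' One convolutional block of 32 feature maps (relu, no dropout) feeding
#' the bidirectional GRU and one dense block of 64 relu units, trained with
#' adam.  Used where a single reasonable architecture is needed without
#' running a search.
#'
#' @param space an [rt_search_space()] supplying the slot widths.
#' @return an `rt_genome`.
#' @export
default_genome <- function(space = rt_search_space()) {
  g <- list(
    n_conv = 1L,
    n_dense = 1L,
    conv = lapply(seq_len(space$conv_layers[2]), function(i)
      list(filters = 32L, activation = "relu", dropout = 0,
           batch_norm = FALSE, max_pool = FALSE)),
    dense = lapply(seq_len(space$dense_layers[2]), function(i)
      list(units = 64L, activation = "relu", dropout = 0,
           batch_norm = FALSE)),
    optimizer = "adam",
    gru_units = space$gru_units)
  structure(g, class = "rt_genome")
}

# serialization -------------------------------------------------------

#' @rdname random_genome
#' @export
genome_to_json <- function(genome) {
  jsonlite::toJSON(unclass(genome), auto_unbox = TRUE, digits = NA)
}

#' @rdname random_genome
#' @param json JSON string produced by `genome_to_json()`.
#' @export
genome_from_json <- function(json) {
  g <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  g$n_conv <- as.integer(g$n_conv)
  g$n_dense <- as.integer(g$n_dense)
  g$gru_units <- as.integer(g$gru_units)
  structure(g, class = "rt_genome")
}

# Translate a genome into the layer spec the computational core consumes:
# only active slots are materialized.
genome_to_spec <- function(genome, alphabet_size, fixed_length) {
  act_code <- function(a)
    match(a, c("relu", "tanh", "leaky_relu")) - 1L
  opt_code <- match(genome$optimizer,
                    c("adam", "rmsprop", "sgd_momentum")) - 1L
  conv <- lapply(head(genome$conv, genome$n_conv), function(cg)
    list(filters = as.integer(cg$filters), act = act_code(cg$activation),
         dropout = as.numeric(cg$dropout),
         batch_norm = isTRUE(cg$batch_norm),
         max_pool = isTRUE(cg$max_pool)))
  dense <- lapply(head(genome$dense, genome$n_dense), function(dg)
    list(units = as.integer(dg$units), act = act_code(dg$activation),
         dropout = as.numeric(dg$dropout),
         batch_norm = isTRUE(dg$batch_norm)))
  list(alphabet_size = as.integer(alphabet_size),
       fixed_length = as.integer(fixed_length),
       gru_units = as.integer(genome$gru_units),
       optimizer = opt_code,
       conv = conv,
       dense = dense)
}

#' Read a search space from a YAML or JSON config file
#'
#' The file may define any subset of the [rt_search_space()] arguments
#' (`conv_layers`, `feature_maps`, `activations`, `dropout_rates`,
#' `dense_layers`, `dense_units`, `optimizers`, `gru_units`); omitted
#' entries keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `rt_search_space`.
#' @export
read_search_space <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(rt_search_space))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown search-space field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  int_fields <- c("conv_layers", "feature_maps", "dense_layers",
                  "dense_units", "gru_units")
  for (f in intersect(names(cfg), int_fields))
    cfg[[f]] <- as.integer(cfg[[f]])
  do.call(rt_search_space, cfg)
}
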