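# The genetic algorithm: clonal haploid reproduction with coupled
# sequence/regulatory mutation, truncation ("high pressure") or random
# ("relaxed") survival, non-overlapping generations.

#' Simulation parameters
#'
#' One object holding every knob of a run: genome dimensions, developmental
#' depth, mutation rate, population size and the selection regime, plus the
#' regulatory and fitness sub-configurations.
#'
#' @param n Number of genes.
#' @param l Gene length in base pairs (multiple of 3).
#' @param m Developmental steps.
#' @param mu Per-base per-generation point-mutation probability.
#' @param N Population size (constant across generations).
#' @param p Selection proportion in (0, 1]; `ceiling(p * N)` organisms
#'   survive each generation.
#' @param strategy `"high_pressure"` (fittest `p` survive) or `"relaxed"`
#'   (`p` random organisms survive — the neutral control).
#' @param reg [reg_config()].
#' @param fitness [fitness_config()].
#' @param clonal_founders If `TRUE` all founders are copies of one random
#'   organism; default `FALSE` (independent random founders, so founder
#'   populations carry standing variation).
#' @param trace_every Generations between trace records in [run_branch()].
#' @return Object of class `grnevo_params`.
#' @export
sim_params <- function(n = 5, l = 3000, m = 20, mu = 5.33333e-6,
                       N = 100, p = 0.1,
                       strategy = c("high_pressure", "relaxed"),
                       reg = reg_config(), fitness = fitness_config(),
                       clonal_founders = FALSE, trace_every = 100) {
  strategy <- match.arg(strategy)
  if (n < 1 || n != floor(n)) stop("n must be a positive integer",
                                   call. = FALSE)
  if (l < 3 || l %% 3 != 0) stop("l must be a positive multiple of 3",
                                 call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]", call. = FALSE)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (p <= 0 || p > 1) stop("p must be in (0, 1]", call. = FALSE)
  stopifnot(inherits(reg, "grnevo_reg_config"),
            inherits(fitness, "grnevo_fitness_config"))
  structure(list(n = as.integer(n), l = as.integer(l), m = as.integer(m),
                 mu = mu, N = as.integer(N), p = p, strategy = strategy,
                 reg = reg, fitness = fitness,
                 clonal_founders = isTRUE(clonal_founders),
                 trace_every = as.integer(trace_every)),
            class = "grnevo_params")
}

#' Assemble an organism from a genome and regulatory parameters
#'
#' Development and fitness are evaluated immediately, so an organism's
#' expression matrix and fitness are always consistent with its genotype.
#'
#' @param genome Character vector from [init_genome()].
#' @param reg `grnevo_regparams`.
#' @param params [sim_params()].
#' @return Object of class `grnevo_organism`: list with `genome`, `reg`,
#'   `mask`, `E`, `fitness`.
#' @export
new_organism <- function(genome, reg, params) {
  mask <- coding_mask(genome)
  E <- develop(mask, reg, params$m)
  structure(list(genome = genome, reg = reg, mask = mask, E = E,
                 fitness = evaluate_fitness(E, params$fitness)),
            class = "grnevo_organism")
}

#' @export
print.grnevo_organism <- function(x, ...) {
  cat("Organism:", length(x$genome), "genes x", nchar(x$genome[1]), "bp;",
      "total fitness", format(x$fitness$total, digits = 4), "\n")
  invisible(x)
}

#' Clonal reproduction with coupled mutation
#'
#' Produces one offspring: the genome receives Jukes-Cantor point mutations
#' at rate `mu`; every synonymous or nonsynonymous event then triggers
#' exactly one regulatory mutation in the gene it hit, targeted by link
#' activity in the *parental* expression matrix
#' (see [apply_regulatory_mutation()]); nonsense events leave the
#' regulatory parameters untouched and act through the coding mask.
#' Development and fitness are recomputed for the offspring. The parent is
#' not modified; an offspring with zero mutation events is an exact clone
#' and inherits the parent's (deterministic) expression and fitness.
#'
#' @param parent `grnevo_organism`.
#' @param params [sim_params()].
#' @return A `grnevo_organism` with attributes `events` (the mutation-event
#'   tibble) and `n_reg_changes` (number of regulatory scalars actually
#'   changed, measured by comparing parameters before and after each
#'   coupled mutation).
#' @export
reproduce_organism <- function(parent, params) {
  events <- sample_point_mutations(parent$genome, params$mu)
  if (nrow(events) == 0L) {
    child <- parent
    attr(child, "events") <- events
    attr(child, "n_reg_changes") <- 0L
    return(child)
  }
  genome <- apply_mutations(parent$genome, events)
  reg <- parent$reg
  n_changes <- 0L
  for (e in seq_len(nrow(events))) {
    cls <- events$class[e]
    if (cls == "nonsense") next
    new_reg <- apply_regulatory_mutation(reg, events$gene[e], cls,
                                         parent$E, params$reg)
    n_changes <- n_changes + sum(new_reg$R != reg$R) +
      sum(new_reg$theta != reg$theta) + sum(new_reg$lam != reg$lam)
    reg <- new_reg
  }
  # mask entries only change in mutated genes
  mask <- parent$mask
  for (g in unique(events$gene)) mask[g] <- if (.has_stop(genome[g])) 0 else 1
  E <- develop(mask, reg, params$m)
  child <- structure(list(genome = genome, reg = reg, mask = mask, E = E,
                          fitness = evaluate_fitness(E, params$fitness)),
                     class = "grnevo_organism")
  attr(child, "events") <- events
  attr(child, "n_reg_changes") <- n_changes
  child
}

#' Select survivors for the next generation
#'
#' Under `"high_pressure"` the `k = ceiling(p * N)` organisms with highest
#' total fitness survive, ties broken uniformly at random; under
#' `"relaxed"` `k` organisms are drawn uniformly without replacement,
#' regardless of fitness.
#'
#' @param pop `grnevo_population`.
#' @param params [sim_params()].
#' @return List of `k` surviving organisms.
#' @export
select_survivors <- function(pop, params) {
  N <- length(pop$organisms)
  k <- ceiling(params$p * N)
  idx <- if (params$strategy == "high_pressure") {
    f <- vapply(pop$organisms, function(o) o$fitness$total, numeric(1))
    order(-f, stats::runif(N))[seq_len(k)]
  } else {
    sample.int(N, k)
  }
  pop$organisms[idx]
}

#' Advance a population one generation
#'
#' Survivors are chosen by [select_survivors()]; `N` offspring are then
#' produced by [reproduce_organism()], assigning offspring to survivors in
#' round-robin order so each survivor parents `floor(N/k)` or `ceiling(N/k)`
#' children. Population size is conserved exactly.
#'
#' @param pop `grnevo_population`.
#' @param params [sim_params()].
#' @return The next `grnevo_population` (generation index incremented), with
#'   attribute `gen_counts`: a named integer vector of this generation's
#'   `synonymous`, `nonsynonymous`, `nonsense` sequence events and
#'   `reg_changes` regulatory-parameter changes.
#' @export
next_generation <- function(pop, params) {
  surv <- select_survivors(pop, params)
  k <- length(surv)
  N <- length(pop$organisms)
  counts <- c(synonymous = 0L, nonsynonymous = 0L, nonsense = 0L,
              reg_changes = 0L)
  offspring <- vector("list", N)
  for (i in seq_len(N)) {
    child <- reproduce_organism(surv[[(i - 1L) %% k + 1L]], params)
    ev <- attr(child, "events")
    if (nrow(ev) > 0L) {
      counts["synonymous"] <- counts["synonymous"] +
        sum(ev$class == "synonymous")
      counts["nonsynonymous"] <- counts["nonsynonymous"] +
        sum(ev$class == "nonsynonymous")
      counts["nonsense"] <- counts["nonsense"] + sum(ev$class == "nonsense")
      counts["reg_changes"] <- counts["reg_changes"] +
        attr(child, "n_reg_changes")
    }
    attr(child, "events") <- NULL
    attr(child, "n_reg_changes") <- NULL
    offspring[[i]] <- child
  }
  structure(list(organisms = offspring, generation = pop$generation + 1L),
            class = "grnevo_population", gen_counts = counts)
}

#' @export
print.grnevo_population <- function(x, ...) {
  f <- vapply(x$organisms, function(o) o$fitness$total, numeric(1))
  cat("Population of", length(x$organisms), "organisms at generation",
      x$generation, "\n")
  cat("  mean fitness", format(mean(f), digits = 4),
      "| max", format(max(f), digits = 4), "\n")
  invisible(x)
}

.trace_record <- function(pop, params) {
  orgs <- pop$organisms
  comp <- function(what) mean(vapply(orgs, function(o) o$fitness[[what]],
                                     numeric(1)))
  part <- gene_participation_all(pop)
  rec <- tibble::tibble(
    generation = pop$generation,
    mean_total = comp("total"),
    mean_boundedness = comp("boundedness"),
    mean_participation = comp("participation"),
    mean_stability = comp("stability"),
    fraction_mature = comp("maturity")
  )
  for (i in seq_along(part)) rec[[paste0("p_gene", i)]] <- part[i]
  rec
}

#' Evolve a population for a fixed number of generations
#'
#' Iterates [next_generation()] `generations` times, recording a trace of
#' mean fitness components and per-gene participation at generation 0 and
#' every `trace_every` generations thereafter (the final generation is
#' always recorded), and accumulating mutation-event bookkeeping.
#'
#' @param pop Founder `grnevo_population`.
#' @param generations Number of generations (>= 0).
#' @param params [sim_params()].
#' @param trace_every Trace sampling interval; defaults to
#'   `params$trace_every`.
#' @return Object of class `grnevo_branch`: list with `population` (final),
#'   `trace` (tibble, class `grnevo_trace`), and `counts` (accumulated
#'   event/regulatory-change totals).
#' @export
run_branch <- function(pop, generations, params,
                       trace_every = params$trace_every) {
  stopifnot(generations >= 0)
  trace <- list(.trace_record(pop, params))
  totals <- c(synonymous = 0L, nonsynonymous = 0L, nonsense = 0L,
              reg_changes = 0L)
  for (g in seq_len(generations)) {
    pop <- next_generation(pop, params)
    totals <- totals + attr(pop, "gen_counts")
    if (g %% trace_every == 0L || g == generations) {
      trace[[length(trace) + 1L]] <- .trace_record(pop, params)
    }
  }
  trace <- do.call(rbind, trace)
  trace <- trace[!duplicated(trace$generation), ]
  class(trace) <- c("grnevo_trace", class(trace))
  structure(list(population = pop, trace = trace, counts = totals),
            class = "grnevo_branch")
}
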