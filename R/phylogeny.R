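# Drive the genetic algorithm branch by branch along a user-defined
# phylogeny whose branch lengths are generation counts.

#' Parse a Newick tree into a phylogeny plan
#'
#' Branch lengths are interpreted as generation counts and must be
#' nonnegative integers — generations and mutation rate are deliberately
#' separate parameters, unlike probabilistic simulators where branch length
#' conflates both. Each branch is identified by the sorted set of tip
#' labels below it (joined with `|`), which is stable under sibling
#' reordering; per-branch parameter overrides are keyed by these
#' identifiers.
#'
#' @param text A Newick string, or a path to a file containing one.
#' @param overrides Optional named list: branch identifier -> list of
#'   [sim_params()] fields to override on that branch (e.g.
#'   `list("A|B" = list(mu = 1e-4))`). Checked against the tree by
#'   [run_phylogeny()].
#' @return Object of class `grnevo_plan`: list with `tree` (an ape
#'   `phylo`), `generations` (integer per edge), `branch_ids` (per edge),
#'   `overrides`.
#' @export
parse_newick_generations <- function(text, overrides = list()) {
  tr <- if (file.exists(text)) ape::read.tree(text) else
    ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input", call. = FALSE)
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths; lengths are generation counts",
         call. = FALSE)
  }
  bad <- which(!is.finite(tr$edge.length) | tr$edge.length < 0 |
                 abs(tr$edge.length - round(tr$edge.length)) > 1e-8)
  if (length(bad) > 0L) {
    stop("branch lengths must be nonnegative integer generation counts; ",
         "offending length: ", tr$edge.length[bad[1]], call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  structure(list(tree = tr,
                 generations = as.integer(round(tr$edge.length)),
                 branch_ids = .branch_ids(tr),
                 overrides = overrides),
            class = "grnevo_plan")
}

# identifier per edge: sorted tip labels of the clade below the edge
.branch_ids <- function(tr) {
  ntip <- length(tr$tip.label)
  vapply(seq_len(nrow(tr$edge)), function(e) {
    child <- tr$edge[e, 2]
    tips <- if (child <= ntip) tr$tip.label[child] else
      ape::extract.clade(tr, child)$tip.label
    paste(sort(tips), collapse = "|")
  }, character(1))
}

#' @export
print.grnevo_plan <- function(x, ...) {
  cat("Phylogeny plan:", length(x$tree$tip.label), "tips,",
      nrow(x$tree$edge), "branches,",
      sum(x$generations), "total generations\n")
  invisible(x)
}

#' Found a population of random organisms
#'
#' Each founder gets an independently sampled genome and regulatory
#' parameter set (so founder populations carry standing variation in which
#' genes are expressed), unless `params$clonal_founders` is set, in which
#' case one random organism is cloned `N` times. Development and fitness
#' are evaluated for every founder.
#'
#' @param params [sim_params()].
#' @return A `grnevo_population` at generation 0.
#' @export
found_population <- function(params) {
  make1 <- function() {
    new_organism(init_genome(params$n, params$l),
                 init_regulatory(params$n, params$reg), params)
  }
  orgs <- if (params$clonal_founders) {
    o <- make1()
    rep(list(o), params$N)
  } else {
    replicate(params$N, make1(), simplify = FALSE)
  }
  structure(list(organisms = orgs, generation = 0L),
            class = "grnevo_population")
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in a phylogeny run flows from one master seed through
#' named substreams: each branch re-seeds R's RNG with a hash of
#' (master seed, branch identifier). Runs are therefore reproducible and
#' independent of the order in which sibling branches are visited.
#'
#' @param master_seed Integer master seed.
#' @param label Character stream label (e.g. a branch identifier).
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, label) {
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Evolve a population along a phylogeny
#'
#' Founds a root population, then traverses the tree depth-first. The
#' population at the end of each branch is copied to found each child
#' branch, so sister lineages share their ancestor's end-of-branch state
#' and evolve independently thereafter. Per-branch overrides are merged
#' over `base_params` and re-validated; each branch runs on its own RNG
#' substream (see [derive_seed()]).
#'
#' @param plan [parse_newick_generations()] result.
#' @param base_params [sim_params()] applying to every branch unless
#'   overridden.
#' @param master_seed Integer seed controlling the entire run.
#' @return Object of class `grnevo_run`: list with `tips` (named list of
#'   `grnevo_lineage` results: final population, representative sequences,
#'   representative regulatory parameters, trace, participation, counts),
#'   `traces` (per-branch trace tibbles, named by branch id), `plan`,
#'   `params`, `master_seed`.
#' @export
run_phylogeny <- function(plan, base_params, master_seed) {
  stopifnot(inherits(plan, "grnevo_plan"))
  unknown <- setdiff(names(plan$overrides), plan$branch_ids)
  if (length(unknown) > 0L) {
    stop("override refers to unknown branch: ", unknown[1], call. = FALSE)
  }
  tr <- plan$tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  set.seed(derive_seed(master_seed, "root"))
  root_pop <- found_population(base_params)
  tips <- list()
  traces <- list()

  recurse <- function(node, pop) {
    edges <- which(tr$edge[, 1] == node)
    for (e in edges) {
      bid <- plan$branch_ids[e]
      bp <- .merge_params(base_params, plan$overrides[[bid]])
      set.seed(derive_seed(master_seed, bid))
      res <- run_branch(pop, plan$generations[e], bp)
      traces[[bid]] <<- res$trace
      child <- tr$edge[e, 2]
      if (child <= ntip) {
        lab <- tr$tip.label[child]
        tips[[lab]] <<- .lineage_result(lab, res)
      } else {
        recurse(child, res$population)
      }
    }
  }
  recurse(root, root_pop)
  structure(list(tips = tips[tr$tip.label], traces = traces, plan = plan,
                 params = base_params, master_seed = master_seed),
            class = "grnevo_run")
}

.merge_params <- function(base, override) {
  if (is.null(override)) return(base)
  merged <- utils::modifyList(unclass(base), override)
  sim_params(n = merged$n, l = merged$l, m = merged$m, mu = merged$mu,
             N = merged$N, p = merged$p, strategy = merged$strategy,
             reg = merged$reg, fitness = merged$fitness,
             clonal_founders = merged$clonal_founders,
             trace_every = merged$trace_every)
}

# representative organism for a tip: the fittest in the final population
.lineage_result <- function(label, branch_res) {
  pop <- branch_res$population
  f <- vapply(pop$organisms, function(o) o$fitness$total, numeric(1))
  rep_org <- pop$organisms[[which.max(f)]]
  structure(list(tip = label,
                 population = pop,
                 sequences = rep_org$genome,
                 reg = rep_org$reg,
                 trace = branch_res$trace,
                 participation = gene_participation_all(pop),
                 counts = branch_res$counts),
            class = "grnevo_lineage")
}

#' @export
print.grnevo_run <- function(x, ...) {
  cat("Phylogeny run:", length(x$tips), "tips | master seed",
      x$master_seed, "\n")
  for (lr in x$tips) {
    cat("  ", lr$tip, ": fittest total ",
        format(max(vapply(lr$population$organisms,
                          function(o) o$fitness$total, numeric(1))),
               digits = 4), "\n", sep = "")
  }
  invisible(x)
}
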