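# Regulatory genotype: interaction matrix R, activation thresholds theta,
# decay rates lambda, and the rule coupling sequence mutations to
# regulatory-parameter mutations.

#' Regulatory initialisation / mutation configuration
#'
#' Controls how regulatory parameters are sampled at founding and resampled
#' on mutation. `value_range` should span negative (repression) as well as
#' positive (activation) values; `sparseness` is the proportion of
#' interaction-matrix cells forced to zero by an independent mask;
#' `theta_range` and `lam_range` must be nonnegative (thresholds and decay
#' rates are nonnegative by construction).
#'
#' @param value_range Length-2 numeric, range for entries of `R`.
#' @param sparseness Proportion of `R` cells zeroed, in [0, 1].
#' @param theta_range Length-2 nonnegative numeric, range for thresholds.
#' @param lam_range Length-2 nonnegative numeric, range for decay rates
#'   (per developmental step; quantity decays by `exp(-lambda)` per step).
#' @param kernel Mutation kernel: `"resample"` redraws the chosen parameter
#'   uniformly from its initialisation range (default); `"perturb"` adds
#'   Gaussian noise with sd `perturb_sd` (theta/lambda clamped at 0).
#' @param perturb_sd Standard deviation for the `"perturb"` kernel; default
#'   is 10% of the corresponding range width.
#' @param exact_mask If `TRUE`, exactly `round(sparseness * n^2)` cells are
#'   zeroed instead of i.i.d. Bernoulli masking.
#' @return An object of class `grnevo_reg_config`.
#' @export
reg_config <- function(value_range = c(-2, 2), sparseness = 0.5,
                       theta_range = c(0, 1), lam_range = c(0, 2),
                       kernel = c("resample", "perturb"),
                       perturb_sd = NULL, exact_mask = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(length(value_range) == 2L, length(theta_range) == 2L,
            length(lam_range) == 2L)
  if (value_range[1] > value_range[2] || theta_range[1] > theta_range[2] ||
      lam_range[1] > lam_range[2]) {
    stop("parameter ranges must be well-ordered (min <= max)", call. = FALSE)
  }
  if (theta_range[1] < 0 || lam_range[1] < 0) {
    stop("theta_range and lam_range must be nonnegative", call. = FALSE)
  }
  if (sparseness < 0 || sparseness > 1) {
    stop("sparseness must be in [0, 1]", call. = FALSE)
  }
  structure(list(value_range = as.numeric(value_range),
                 sparseness = as.numeric(sparseness),
                 theta_range = as.numeric(theta_range),
                 lam_range = as.numeric(lam_range),
                 kernel = kernel,
                 perturb_sd = perturb_sd,
                 exact_mask = isTRUE(exact_mask)),
            class = "grnevo_reg_config")
}

#' Sample founder regulatory parameters
#'
#' `R[i, j]` is the regulatory effect of gene `j`'s product on gene `i`.
#' Entries are uniform on `value_range`; an independently sampled mask then
#' zeroes a proportion `sparseness` of cells (i.i.d. Bernoulli per cell, or
#' an exact count when `exact_mask` is set). Thresholds and decay rates are
#' uniform on their ranges.
#'
#' @param n Number of genes.
#' @param cfg A [reg_config()] object.
#' @return Object of class `grnevo_regparams`: list with `R` (n x n matrix),
#'   `theta` and `lam` (length-n nonnegative vectors).
#' @export
init_regulatory <- function(n, cfg = reg_config()) {
  R <- matrix(stats::runif(n * n, cfg$value_range[1], cfg$value_range[2]),
              n, n)
  if (cfg$sparseness > 0) {
    if (cfg$exact_mask) {
      k <- round(cfg$sparseness * n * n)
      R[sample.int(n * n, k)] <- 0
    } else {
      R[stats::runif(n * n) < cfg$sparseness] <- 0
    }
  }
  structure(list(
    R = R,
    theta = stats::runif(n, cfg$theta_range[1], cfg$theta_range[2]),
    lam = stats::runif(n, cfg$lam_range[1], cfg$lam_range[2])
  ), class = "grnevo_regparams")
}

#' @export
print.grnevo_regparams <- function(x, ...) {
  n <- length(x$theta)
  cat("Regulatory parameters for", n, "genes\n")
  cat("  R: ", n, "x", n, " matrix, ", sum(x$R == 0), " zero cells\n",
      sep = "")
  cat("  theta:", format(x$theta, digits = 3), "\n")
  cat("  lambda:", format(x$lam, digits = 3), "\n")
  invisible(x)
}

#' Active regulatory links given a parental expression profile
#'
#' A link (target `i`, source `j`) is active when its source gene `j` is
#' expressed somewhere in the parental expression matrix (see
#' [is_expressed()]; the seed gene always counts as expressed). Activity is
#' a property of the source, so a source gene's expression activates its
#' links to every target.
#'
#' @param E Expression matrix from [develop()].
#' @return Tibble with columns `target`, `source` (1-based indices), one row
#'   per active link; zero rows if no gene is expressed.
#' @export
active_link_set <- function(E) {
  n <- nrow(E)
  src <- which(vapply(seq_len(n), function(j) is_expressed(E, j), logical(1)))
  if (length(src) == 0L) {
    return(tibble::tibble(target = integer(), source = integer()))
  }
  tibble::tibble(target = rep(seq_len(n), times = length(src)),
                 source = rep(src, each = n))
}

#' Apply one regulatory mutation coupled to a sequence mutation in gene g
#'
#' Implements the coupling rule: with probability `2/(2+n)` the mutation
#' hits `theta[g]` or `lam[g]` (each with probability `1/(2+n)`); otherwise
#' one entry of row `g` of `R` — a regulatory input to gene `g` — is chosen
#' uniformly among *active* incoming links for a nonsynonymous event, or
#' among *inactive* incoming links for a synonymous event (activity judged
#' from the parental expression matrix), and redrawn from the configured
#' kernel. If the eligible link class is empty the mutation falls back to
#' `theta[g]` or `lam[g]` with equal probability, so every coding mutation
#' produces exactly one regulatory change. Structurally zeroed (masked)
#' cells remain mutable, which lets network topology evolve.
#'
#' Nonsense events must not be passed here: they change no regulatory
#' parameter (see [nonsense_effect()]); their phenotypic effect flows
#' through the coding mask at development time.
#'
#' @param params `grnevo_regparams` of the offspring being built.
#' @param gene 1-based index of the mutated gene.
#' @param classification `"synonymous"` or `"nonsynonymous"`.
#' @param E_parent The parent's expression matrix.
#' @param cfg A [reg_config()] object (ranges and kernel).
#' @return A new `grnevo_regparams` differing from `params` in exactly one
#'   scalar among gene `g`'s `n` row entries, `theta[g]`, `lam[g]`.
#' @export
apply_regulatory_mutation <- function(params, gene, classification, E_parent,
                                      cfg = reg_config()) {
  if (!classification %in% c("synonymous", "nonsynonymous")) {
    stop("classification must be synonymous or nonsynonymous; nonsense ",
         "events do not mutate regulatory parameters", call. = FALSE)
  }
  n <- length(params$theta)
  u <- stats::runif(1)
  if (u < 2 / (2 + n)) {
    return(.mutate_theta_lam(params, gene, cfg, u < 1 / (2 + n)))
  }
  expressed <- vapply(seq_len(n), function(j) is_expressed(E_parent, j),
                      logical(1))
  eligible <- if (classification == "nonsynonymous") which(expressed) else
    which(!expressed)
  if (length(eligible) == 0L) {
    # no link of the required class: redirect to theta/lambda
    return(.mutate_theta_lam(params, gene, cfg, stats::runif(1) < 0.5))
  }
  j <- eligible[sample.int(length(eligible), 1L)]
  params$R[gene, j] <- .draw_value(params$R[gene, j], cfg$value_range, cfg,
                                   clamp0 = FALSE)
  params
}

.mutate_theta_lam <- function(params, gene, cfg, hit_theta) {
  if (hit_theta) {
    params$theta[gene] <- .draw_value(params$theta[gene], cfg$theta_range,
                                      cfg, clamp0 = TRUE)
  } else {
    params$lam[gene] <- .draw_value(params$lam[gene], cfg$lam_range, cfg,
                                    clamp0 = TRUE)
  }
  params
}

.draw_value <- function(current, range, cfg, clamp0) {
  if (cfg$kernel == "resample") {
    stats::runif(1, range[1], range[2])
  } else {
    sd <- if (is.null(cfg$perturb_sd)) 0.1 * diff(range) else cfg$perturb_sd
    v <- current + stats::rnorm(1, 0, sd)
    if (clamp0) max(v, 0) else v
  }
}

#' Regulatory effect of a nonsense mutation
#'
#' A nonsense (stop-gaining) sequence mutation changes no regulatory
#' parameter: its phenotypic consequence is carried entirely by the coding
#' mask, which zeroes the gene's quantities during development for as long
#' as the stop codon persists. The parameters stay in place, so a later
#' reversion of the stop restores a fully functional gene.
#'
#' @param params `grnevo_regparams`.
#' @return `params`, unchanged.
#' @export
nonsense_effect <- function(params) params
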