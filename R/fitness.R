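# Fitness: score an expression profile on four criteria — bounded growth,
# gene participation, expression stability, and developmental maturity —
# and combine them into one value in [0, 1].

#' Fitness configuration
#'
#' @param marker_gene Index of the maturity marker gene; `NULL` means the
#'   last gene (`n`), resolved at evaluation time. With gene 1 seeding
#'   development and gene `n` marking maturity, both ends of the network
#'   are required for a viable system.
#' @param maturity_threshold Quantity the marker gene must exceed at some
#'   developmental step (arbitrary units, same scale as the seed quantity).
#' @param stability_window Number of final steps over which stability and
#'   terminal growth are measured; `NULL` means `ceiling(m / 5)` (the final
#'   fifth of development), resolved at evaluation time.
#' @param growth_cap Terminal growth ratio (in excess of 1) at which the
#'   boundedness score reaches 0.
#' @return Object of class `grnevo_fitness_config`.
#' @export
fitness_config <- function(marker_gene = NULL, maturity_threshold = 0.5,
                           stability_window = NULL, growth_cap = 10) {
  if (maturity_threshold <= 0) {
    stop("maturity_threshold must be positive", call. = FALSE)
  }
  if (growth_cap <= 0) stop("growth_cap must be positive", call. = FALSE)
  structure(list(marker_gene = marker_gene,
                 maturity_threshold = maturity_threshold,
                 stability_window = stability_window,
                 growth_cap = growth_cap),
            class = "grnevo_fitness_config")
}

.resolve_fitness_cfg <- function(cfg, n, m) {
  if (is.null(cfg$marker_gene)) cfg$marker_gene <- n
  if (is.null(cfg$stability_window)) cfg$stability_window <- ceiling(m / 5)
  cfg$stability_window <- min(cfg$stability_window, m - 1L)
  cfg$stability_window <- max(cfg$stability_window, 1L)
  cfg
}

#' Boundedness: gene quantities must not grow without limit
#'
#' Compares the total quantity at the final step with the total one
#' stability window earlier. A terminal growth ratio `g <= 1` (flat or
#' shrinking) scores 1; beyond that the score declines linearly, reaching 0
#' at `g = 1 + growth_cap`. Runaway (non-finite) development scores 0.
#'
#' @param E Expression matrix.
#' @param cfg [fitness_config()].
#' @return Score in [0, 1].
#' @export
score_boundedness <- function(E, cfg = fitness_config()) {
  if (isTRUE(attr(E, "runaway")) || anyNA(E)) return(0)
  m <- ncol(E)
  cfg <- .resolve_fitness_cfg(cfg, nrow(E), m)
  ref <- max(1L, m - cfg$stability_window)
  g <- sum(E[, m]) / (sum(E[, ref]) + 1e-12)
  if (!is.finite(g) || g <= 1) {
    if (!is.finite(g)) return(0)
    return(1)
  }
  max(0, 1 - (g - 1) / cfg$growth_cap)
}

#' Participation: the more genes active in the system, the fitter
#'
#' @param E Expression matrix.
#' @return Fraction of genes expressed (see [is_expressed()]), in [0, 1].
#' @export
score_participation <- function(E) {
  n <- nrow(E)
  mean(vapply(seq_len(n), function(i) is_expressed(E, i), logical(1)))
}

#' Stability: expression should settle, not oscillate
#'
#' Computes, for each expressed gene, the coefficient of variation of its
#' quantities over the final `stability_window` steps, and scores
#' `1 / (1 + mean CV)`. Genes never expressed are excluded; an expressed
#' gene whose late-window quantities are all zero contributes CV 0. Runaway
#' development scores 0.
#'
#' @param E Expression matrix.
#' @param cfg [fitness_config()].
#' @return Score in (0, 1].
#' @export
score_stability <- function(E, cfg = fitness_config()) {
  if (isTRUE(attr(E, "runaway")) || anyNA(E)) return(0)
  n <- nrow(E)
  m <- ncol(E)
  cfg <- .resolve_fitness_cfg(cfg, n, m)
  idx <- (m - cfg$stability_window + 1L):m
  expressed <- which(vapply(seq_len(n), function(i) is_expressed(E, i),
                            logical(1)))
  cvs <- vapply(expressed, function(i) {
    x <- E[i, idx]
    mu <- mean(x)
    if (mu <= 0) 0 else stats::sd(x) / mu
  }, numeric(1))
  1 / (1 + mean(cvs))
}

#' Maturity: the system must have developed to completion
#'
#' Scores 1 when the marker gene's quantity exceeds `maturity_threshold` at
#' some developmental step AND the marker is expressed (> 0) at the final
#' step; 0 otherwise.
#'
#' @param E Expression matrix.
#' @param cfg [fitness_config()].
#' @return 0 or 1.
#' @export
score_maturity <- function(E, cfg = fitness_config()) {
  cfg <- .resolve_fitness_cfg(cfg, nrow(E), ncol(E))
  row <- E[cfg$marker_gene, ]
  passed <- any(row > cfg$maturity_threshold, na.rm = TRUE)
  final_on <- isTRUE(row[ncol(E)] > 0)
  as.numeric(passed && final_on)
}

#' Combine fitness components
#'
#' Total fitness is the product of the four components, which makes
#' maturity a hard gate (an immature system has fitness 0) and any
#' catastrophic failure on one criterion fatal.
#'
#' @param breakdown List with `boundedness`, `participation`, `stability`,
#'   `maturity` in [0, 1].
#' @return Total fitness in [0, 1].
#' @export
total_fitness <- function(breakdown) {
  breakdown$maturity * breakdown$boundedness * breakdown$participation *
    breakdown$stability
}

#' Evaluate all fitness criteria on an expression matrix
#'
#' @param E Expression matrix from [develop()].
#' @param cfg [fitness_config()].
#' @return List with components `boundedness`, `participation`,
#'   `stability`, `maturity`, `total`, all in [0, 1].
#' @export
evaluate_fitness <- function(E, cfg = fitness_config()) {
  b <- list(boundedness = score_boundedness(E, cfg),
            participation = score_participation(E),
            stability = score_stability(E, cfg),
            maturity = score_maturity(E, cfg))
  b$total <- total_fitness(b)
  b
}
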