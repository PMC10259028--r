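# Post-hoc measurement: sequence distances, the neutral expectation,
# participation, and stop-codon reports.

#' Proportion of differing sites between two equal-length sequences
#'
#' @param a,b Equal-length DNA strings.
#' @return p-distance in [0, 1].
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length", call. = FALSE)
  mean(utf8ToInt(a) != utf8ToInt(b))
}

#' Jukes-Cantor corrected distance
#'
#' Inverts the Jukes-Cantor substitution model to convert an observed
#' proportion of differing sites into an expected number of substitutions
#' per site: `-(3/4) * log(1 - 4p/3)`.
#'
#' @param p Observed p-distance, `0 <= p < 0.75`.
#' @return Substitutions per site (>= `p`).
#' @export
jc_distance <- function(p) {
  if (any(p < 0) || any(p >= 0.75)) {
    stop("p-distance saturated: Jukes-Cantor correction requires p < 0.75",
         call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Expected neutral divergence
#'
#' Under the per-base per-generation mutation rate `mu` and no selection,
#' the expected number of substitutions per site accumulated over a path of
#' `generations` generations is simply `mu * generations`. This is the
#' yardstick realized tip-to-tip (patristic) distances are compared to.
#'
#' @param mu Per-base per-generation mutation probability.
#' @param generations Number of generations along the path.
#' @return Expected substitutions per site.
#' @examples
#' expected_neutral_divergence(5.33333e-6, 20000)  # 0.1066666
#' @export
expected_neutral_divergence <- function(mu, generations) {
  stopifnot(mu >= 0, generations >= 0)
  mu * generations
}

#' Proportion of a population expressing a gene
#'
#' @param pop `grnevo_population`.
#' @param i 1-based gene index.
#' @return Fraction of organisms in which gene `i` is expressed.
#' @export
gene_participation <- function(pop, i) {
  mean(vapply(pop$organisms, function(o) is_expressed(o$E, i), logical(1)))
}

#' Per-gene participation vector
#'
#' @param pop `grnevo_population`.
#' @return Numeric vector: for each gene, the fraction of organisms
#'   expressing it. The seed gene's participation is always 1.
#' @export
gene_participation_all <- function(pop) {
  n <- nrow(pop$organisms[[1]]$E)
  vapply(seq_len(n), function(i) gene_participation(pop, i), numeric(1))
}

#' Stop codons per lineage for one gene
#'
#' Counts in-frame stop codons in each tip's representative sequence of a
#' gene. Genes excluded from the working network accumulate stop codons
#' like any neutrally drifting sequence; this report makes that visible.
#'
#' @param run `grnevo_run` from [run_phylogeny()].
#' @param gene 1-based gene index.
#' @return Named integer vector, one count per tip.
#' @export
stop_codon_report <- function(run, gene) {
  vapply(run$tips, function(lr) count_stop_codons(lr$sequences[gene]),
         numeric(1))
}

#' Pairwise tip distances, per gene and genome-wide
#'
#' Computes p-distances and Jukes-Cantor corrected distances between the
#' representative sequences of every pair of tips, for each gene and for
#' the concatenated genome. The JC-corrected genome-wide value is the
#' realized patristic distance comparable to
#' [expected_neutral_divergence()] on the connecting path.
#'
#' @param run `grnevo_run`.
#' @return Tibble with columns `tip_a`, `tip_b`, `gene` (gene index as
#'   character, or `"genome"`), `p`, `jc`.
#' @export
distance_report <- function(run) {
  labs <- names(run$tips)
  n <- length(run$tips[[1]]$sequences)
  out <- list()
  for (a in seq_along(labs)) for (b in seq_along(labs)) {
    if (b <= a) next
    sa <- run$tips[[a]]$sequences
    sb <- run$tips[[b]]$sequences
    for (g in seq_len(n)) {
      pg <- p_distance(sa[g], sb[g])
      out[[length(out) + 1L]] <- tibble::tibble(
        tip_a = labs[a], tip_b = labs[b], gene = as.character(g),
        p = pg, jc = jc_distance(pg))
    }
    pw <- p_distance(paste0(sa, collapse = ""), paste0(sb, collapse = ""))
    out[[length(out) + 1L]] <- tibble::tibble(
      tip_a = labs[a], tip_b = labs[b], gene = "genome",
      p = pw, jc = jc_distance(pw))
  }
  do.call(rbind, out)
}
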