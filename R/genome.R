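# Multi-gene coding genomes: sampling, point mutation under a Jukes-Cantor
# process, and mutation classification through the standard genetic code.

.BASES <- c("A", "C", "G", "T")

# standard genetic code (DNA alphabet); "*" marks stops
.GENCODE <- Biostrings::GENETIC_CODE
.STOP_CODONS <- names(.GENCODE)[.GENCODE == "*"]
.SENSE_CODONS <- names(.GENCODE)[.GENCODE != "*"]

#' Sample a random multi-gene coding genome
#'
#' Builds a genome of `n` genes, each `l` base pairs long, by drawing codons
#' uniformly from the 61 sense codons of the standard genetic code. Founder
#' genomes therefore carry intact open reading frames: no in-frame stop codon
#' is present at initialisation, so every gene starts out translatable and
#' able to participate in development.
#'
#' @param n Number of genes (positive integer).
#' @param l Gene length in base pairs; must be a positive multiple of 3.
#' @return A character vector of length `n`; element `i` is the coding
#'   sequence of gene `i` (uppercase A/C/G/T). All genes have equal length.
#' @examples
#' set.seed(1)
#' g <- init_genome(5, 30)
#' nchar(g)
#' count_stop_codons(g[1])
#' @export
init_genome <- function(n, l) {
  if (length(n) != 1L || n < 1 || n != floor(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  if (length(l) != 1L || l < 3 || l %% 3 != 0) {
    stop("`l` must be a positive multiple of 3 (whole codons), got ", l,
         call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    paste0(sample(.SENSE_CODONS, l / 3, replace = TRUE), collapse = "")
  }, character(1))
}

#' Sample point mutations across a genome
#'
#' Every base mutates independently with probability `mu` per generation;
#' a mutated base is replaced by one of the other three nucleotides with
#' equal probability (Jukes-Cantor). Each event is classified against the
#' pre-mutation codon it falls in.
#'
#' Sampling draws the total hit count from Binomial(n*l, mu) and places hits
#' uniformly without replacement, which is exactly the per-base Bernoulli
#' process (each base is hit at most once per generation).
#'
#' @param genome Character vector of gene sequences (see [init_genome()]).
#' @param mu Per-base, per-generation mutation probability in [0, 1].
#' @return A tibble of mutation events with columns `gene` (1-based gene
#'   index), `pos` (1-based position within the gene), `old`, `new`
#'   (nucleotides), and `class` (one of `"synonymous"`, `"nonsynonymous"`,
#'   `"nonsense"`). Zero rows when nothing mutated.
#' @export
sample_point_mutations <- function(genome, mu) {
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]", call. = FALSE)
  l <- nchar(genome[1])
  L <- l * length(genome)
  k <- if (mu >= 1) L else stats::rbinom(1L, L, mu)
  if (k == 0L) return(.empty_events())
  pos_flat <- sort(sample.int(L, k))
  gene <- (pos_flat - 1L) %/% l + 1L
  pos <- (pos_flat - 1L) %% l + 1L
  old <- substring(genome[gene], pos, pos)
  new <- vapply(old, function(b) sample(.BASES[.BASES != b], 1L), character(1),
                USE.NAMES = FALSE)
  cls <- character(k)
  for (e in seq_len(k)) {
    cs <- pos[e] - (pos[e] - 1L) %% 3L           # codon start
    old_codon <- substr(genome[gene[e]], cs, cs + 2L)
    new_codon <- old_codon
    substr(new_codon, pos[e] - cs + 1L, pos[e] - cs + 1L) <- new[e]
    cls[e] <- classify_mutation(old_codon, new_codon)
  }
  tibble::tibble(gene = gene, pos = pos, old = old, new = new, class = cls)
}

# constructed once: reproduction returns this constant for the (common)
# zero-mutation case, keeping the clone path allocation-free
.EMPTY_EVENTS <- tibble::tibble(gene = integer(), pos = integer(),
                                old = character(), new = character(),
                                class = character())

.empty_events <- function() .EMPTY_EVENTS

#' Classify a single-base codon change
#'
#' @param old_codon,new_codon Three-letter DNA codons differing at exactly
#'   one position.
#' @return `"nonsense"` if the new codon is a stop codon, `"synonymous"` if
#'   both codons encode the same amino acid, `"nonsynonymous"` otherwise.
#' @examples
#' classify_mutation("AAA", "AAG")  # Lys -> Lys
#' classify_mutation("TGG", "TGA")  # Trp -> stop
#' @export
classify_mutation <- function(old_codon, new_codon) {
  if (identical(old_codon, new_codon)) {
    stop("codons are identical; a mutation must change the codon",
         call. = FALSE)
  }
  d <- sum(strsplit(old_codon, "")[[1]] != strsplit(new_codon, "")[[1]])
  if (d != 1L) {
    stop("codons must differ at exactly one position (got ", d, ")",
         call. = FALSE)
  }
  new_aa <- .GENCODE[[new_codon]]
  if (new_aa == "*") return("nonsense")
  if (new_aa == .GENCODE[[old_codon]]) "synonymous" else "nonsynonymous"
}

#' Apply mutation events to a genome
#'
#' Events are applied in order; the result is the child sequence. Used by
#' [reproduce_organism()] and exported for replaying logged events.
#'
#' @param genome Character vector of gene sequences.
#' @param events Event tibble as returned by [sample_point_mutations()].
#' @return The mutated genome (same shape as `genome`).
#' @export
apply_mutations <- function(genome, events) {
  for (e in seq_len(nrow(events))) {
    g <- events$gene[e]
    substr(genome[g], events$pos[e], events$pos[e]) <- events$new[e]
  }
  genome
}

#' Coding mask of a genome
#'
#' Per-gene indicator used by development: `c[i] = 0` if gene `i` carries an
#' in-frame stop codon anywhere along its sequence, `1` otherwise. The mask
#' is a pure function of the current sequence, so a stop codon later reverted
#' by another mutation restores the gene's mask to 1.
#'
#' @param genome Character vector of gene sequences.
#' @return Numeric 0/1 vector of length `n`.
#' @export
coding_mask <- function(genome) {
  vapply(genome, function(g) if (.has_stop(g)) 0 else 1, numeric(1),
         USE.NAMES = FALSE)
}

.has_stop <- function(gene) {
  l <- nchar(gene)
  any(substring(gene, seq(1L, l, 3L), seq(3L, l, 3L)) %in% .STOP_CODONS)
}

#' Count in-frame stop codons in a gene
#'
#' @param gene A single coding sequence (length a multiple of 3).
#' @return Number of in-frame TAA/TAG/TGA codons.
#' @export
count_stop_codons <- function(gene) {
  l <- nchar(gene)
  sum(substring(gene, seq(1L, l, 3L), seq(3L, l, 3L)) %in% .STOP_CODONS)
}
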