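test_that("init_genome builds intact open reading frames of the right size", {
  set.seed(101)
  g <- init_genome(5, 3000)
  expect_length(g, 5)
  expect_true(all(nchar(g) == 3000))
  expect_true(all(vapply(g, function(x) count_stop_codons(x) == 0,
                         logical(1))))
  expect_true(all(strsplit(paste0(g, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  # minimal genome: one sense codon
  g1 <- init_genome(1, 3)
  expect_equal(nchar(g1), 3)
  expect_equal(count_stop_codons(g1), 0)
  expect_error(init_genome(2, 10), "multiple of 3")
})

test_that("initial codons are uniform over the 61 sense codons", {
  set.seed(202)
  g <- init_genome(1, 3 * 1e5)
  codons <- substring(g, seq(1, nchar(g), 3), seq(3, nchar(g), 3))
  tab <- table(codons)
  expect_length(tab, 61)  # every sense codon seen, no stops
  expect_false(any(names(tab) %in% c("TAA", "TAG", "TGA")))
  gof <- chisq.test(tab)
  expect_gt(gof$p.value, 0.01)
})

test_that("mutation sampling follows the per-base binomial process", {
  set.seed(303)
  g <- init_genome(5, 3000)  # 15,000 bp
  expect_identical(nrow(sample_point_mutations(g, 0)), 0L)

  ev <- sample_point_mutations(g, 1)
  expect_identical(nrow(ev), 15000L)
  expect_true(all(ev$old != ev$new))
  expect_true(all(ev$pos >= 1 & ev$pos <= 3000))

  # mean events per generation ~ Binomial(L, mu): L*mu = 0.08
  mu <- 5.33333e-6
  counts <- replicate(1e5, nrow(sample_point_mutations(g, mu)))
  expected <- 15000 * mu
  se <- sqrt(expected * (1 - mu) / 1e5)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # variance consistent with binomial as well
  se_var <- sqrt((mean((counts - mean(counts))^4) - var(counts)^2) /
                   length(counts))
  expect_lt(abs(var(counts) - expected * (1 - mu)), 3 * se_var)
})

test_that("every sampled event has exactly one classification", {
  set.seed(404)
  g <- init_genome(2, 300)
  ev <- sample_point_mutations(g, 0.05)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$class %in% c("synonymous", "nonsynonymous",
                                  "nonsense")))
  tab <- table(factor(ev$class, levels = c("synonymous", "nonsynonymous",
                                           "nonsense")))
  expect_identical(sum(tab), nrow(ev))
})

test_that("classify_mutation matches known genetic-code cases and contract", {
  expect_identical(classify_mutation("AAA", "AAG"), "synonymous")
  expect_identical(classify_mutation("TGG", "TGA"), "nonsense")
  expect_identical(classify_mutation("AAA", "ACA"), "nonsynonymous")
  expect_error(classify_mutation("AAA", "AAA"), "identical")
  expect_error(classify_mutation("AAA", "CCA"), "exactly one")
})

test_that("classification agrees with full-codon translation for all
           single-step changes", {
  # independent oracle: translate both codons with Biostrings::translate
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (old in sense) {
    for (new in codon_neighbours(old)) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(c(old, new)), no.init.codon = TRUE))
      want <- if (aa[2] == "*") "nonsense" else
        if (aa[1] == aa[2]) "synonymous" else "nonsynonymous"
      expect_identical(classify_mutation(old, new), want)
    }
  }
})

test_that("coding mask and stop-codon counting are pure sequence functions", {
  expect_equal(coding_mask(c("ATGTGAAAA", "ATGAAAAAA")), c(0, 1))
  set.seed(505)
  g <- init_genome(3, 30)
  expect_equal(coding_mask(g), c(1, 1, 1))

  expect_equal(count_stop_codons("TAATAGTGA"), 3)
  expect_equal(count_stop_codons("AAATAAAAA"), 1)
  expect_equal(count_stop_codons("ATAGAAAAA"), 0)  # out-of-frame TAG

  # stop introduced then reverted restores the mask
  gene <- "ATGAAAAAA"
  ev_in <- tibble::tibble(gene = 1L, pos = 4L, old = "A", new = "T",
                          class = "nonsense")
  broken <- apply_mutations(gene, ev_in)
  expect_equal(coding_mask(broken), 0)
  ev_out <- tibble::tibble(gene = 1L, pos = 4L, old = "T", new = "A",
                           class = "nonsynonymous")
  expect_equal(coding_mask(apply_mutations(broken, ev_out)), 1)
})
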