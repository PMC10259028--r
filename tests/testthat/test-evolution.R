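test_that("a mutation-free offspring is an exact clone", {
  set.seed(61)
  p <- tiny_params(mu = 0)
  org <- new_organism(init_genome(p$n, p$l), init_regulatory(p$n, p$reg), p)
  child <- reproduce_organism(org, p)
  expect_identical(child$genome, org$genome)
  expect_identical(child$reg, org$reg)
  expect_identical(unclass(child$E), unclass(org$E))
  expect_identical(child$fitness, org$fitness)
})

test_that("sequence events and regulatory changes are coupled 1-1", {
  set.seed(62)
  p <- tiny_params(n = 3, l = 300, mu = 5e-3)
  org <- new_organism(init_genome(p$n, p$l), init_regulatory(p$n, p$reg), p)
  total_events <- 0L
  total_changes <- 0L
  for (rep in 1:300) {
    child <- reproduce_organism(org, p)
    ev <- attr(child, "events")
    coding <- sum(ev$class %in% c("synonymous", "nonsynonymous"))
    changes <- sum(child$reg$R != org$reg$R) +
      sum(child$reg$theta != org$reg$theta) +
      sum(child$reg$lam != org$reg$lam)
    # per-reproduction: applied changes equal coding events exactly
    expect_identical(attr(child, "n_reg_changes"), coding)
    # observable parameter diffs can only fall short when two events hit
    # the same scalar
    expect_lte(changes, coding)
    total_events <- total_events + coding
    total_changes <- total_changes + attr(child, "n_reg_changes")
    # nonsense events never touch regulatory parameters
    if (nrow(ev) > 0 && all(ev$class == "nonsense")) {
      expect_identical(child$reg, org$reg)
    }
  }
  expect_identical(total_changes, total_events)
  expect_gt(total_events, 0L)
})

test_that("a single coding event changes exactly one regulatory scalar of
           its gene", {
  set.seed(63)
  p <- tiny_params(n = 3, l = 300, mu = 2e-4)
  org <- new_organism(init_genome(p$n, p$l), init_regulatory(p$n, p$reg), p)
  found <- 0
  while (found < 25) {
    child <- reproduce_organism(org, p)
    ev <- attr(child, "events")
    if (nrow(ev) != 1L || ev$class == "nonsense") next
    found <- found + 1
    g <- ev$gene
    diffs_in_g <- sum(child$reg$R[g, ] != org$reg$R[g, ]) +
      (child$reg$theta[g] != org$reg$theta[g]) +
      (child$reg$lam[g] != org$reg$lam[g])
    all_diffs <- sum(child$reg$R != org$reg$R) +
      sum(child$reg$theta != org$reg$theta) +
      sum(child$reg$lam != org$reg$lam)
    expect_equal(diffs_in_g, 1)
    expect_equal(all_diffs, 1)
  }
})

test_that("survivor counts and identities follow the selection strategy", {
  set.seed(64)
  p <- tiny_params(N = 5, p = 0.2)
  pop <- found_population(p)
  # plant a known fitness ranking
  for (i in 1:5) pop$organisms[[i]]$fitness$total <- (6 - i) / 10
  surv <- select_survivors(pop, p)
  expect_length(surv, 1)
  expect_equal(surv[[1]]$fitness$total, 0.5)

  p100 <- tiny_params(N = 100, p = 0.1)
  pop100 <- found_population(p100)
  expect_length(select_survivors(pop100, p100), 10)

  # relaxed survival is uniform over organisms
  pr <- tiny_params(N = 10, p = 0.3, strategy = "relaxed")
  popr <- found_population(pr)
  for (i in 1:10) popr$organisms[[i]]$fitness$total <- i / 10
  marks <- sapply(popr$organisms, function(o) o$fitness$total)
  freq <- rowMeans(replicate(4000, {
    s <- select_survivors(popr, pr)
    marks %in% sapply(s, function(o) o$fitness$total)
  }))
  se <- sqrt(0.3 * 0.7 / 4000)
  expect_true(all(abs(freq - 0.3) < 4 * se))
})

test_that("population size is conserved and runs are seed-deterministic", {
  set.seed(65)
  p <- tiny_params(N = 12, mu = 1e-3)
  pop <- found_population(p)
  for (g in 1:20) {
    pop <- next_generation(pop, p)
    expect_length(pop$organisms, 12)
  }
  expect_equal(pop$generation, 20)

  run_once <- function(seed) {
    set.seed(seed)
    b <- run_branch(found_population(p), 30, p, trace_every = 10)
    b$trace
  }
  expect_identical(run_once(123), run_once(123))
})

test_that("elitist truncation without mutation never loses the best
           genotype", {
  set.seed(66)
  p <- tiny_params(N = 20, mu = 0, p = 0.25, strategy = "high_pressure")
  pop <- found_population(p)
  best <- max(sapply(pop$organisms, function(o) o$fitness$total))
  for (g in 1:30) {
    pop <- next_generation(pop, p)
    new_best <- max(sapply(pop$organisms, function(o) o$fitness$total))
    expect_gte(new_best, best)
    best <- new_best
  }
})

test_that("trace sampling includes generation 0 and every interval", {
  set.seed(67)
  p <- tiny_params(N = 5, mu = 1e-4)
  pop <- found_population(p)
  b0 <- run_branch(pop, 0, p)
  expect_equal(nrow(b0$trace), 1)
  expect_identical(unclass(b0$population)$organisms, pop$organisms)

  b <- run_branch(pop, 500, p, trace_every = 100)
  expect_equal(b$trace$generation, seq(0, 500, by = 100))
})
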