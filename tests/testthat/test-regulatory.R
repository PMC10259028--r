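test_that("founder regulatory parameters respect ranges and sparseness", {
  set.seed(1)
  cfg <- reg_config(value_range = c(-1, 1), sparseness = 1,
                    theta_range = c(0, 1), lam_range = c(0, 2))
  expect_true(all(init_regulatory(4, cfg)$R == 0))

  cfg0 <- reg_config(value_range = c(-1, 1), sparseness = 0)
  r <- init_regulatory(4, cfg0)
  expect_true(all(r$R != 0))  # continuous uniform: zero has measure zero
  expect_true(all(r$R >= -1 & r$R <= 1))
  expect_true(all(r$theta >= 0 & r$theta <= 1))
  expect_true(all(r$lam >= 0 & r$lam <= 2))

  # Bernoulli mask hits the requested proportion on average
  cfg3 <- reg_config(sparseness = 0.3)
  draws <- replicate(1e4, sum(init_regulatory(3, cfg3)$R == 0))
  p_hat <- mean(draws) / 9
  se <- sqrt(0.3 * 0.7 / (9 * 1e4))
  expect_lt(abs(p_hat - 0.3), 3 * se)

  # exact masking zeroes exactly round(s * n^2) cells
  cfge <- reg_config(sparseness = 0.3, exact_mask = TRUE)
  expect_equal(sum(init_regulatory(10, cfge)$R == 0), 30)

  expect_error(reg_config(theta_range = c(-1, 1)), "nonnegative")
  expect_error(reg_config(value_range = c(1, -1)), "well-ordered")
})

test_that("active links are those whose source gene is expressed", {
  # only gene 1 expressed
  E <- expr_mat(c(1, 1), c(0, 0), c(0, 0))
  al <- active_link_set(E)
  expect_setequal(al$source, 1)
  expect_setequal(al$target, 1:3)
  expect_equal(nrow(al), 3)

  # all genes expressed somewhere -> all n^2 links
  E2 <- expr_mat(c(1, 0), c(0, 2), c(3, 0))
  expect_equal(nrow(active_link_set(E2)), 9)

  # nothing expressed except the seed gene (always counts)
  E3 <- expr_mat(c(0, 0), c(0, 0))
  al3 <- active_link_set(E3)
  expect_setequal(al3$source, 1)
})

test_that("a coupled regulatory mutation changes exactly one scalar of the
           gene's candidates", {
  set.seed(21)
  cfg <- reg_config(value_range = c(-1, 1), sparseness = 0.5)
  E <- expr_mat(c(1, 1), c(1, 0), c(0, 0), c(0, 1))  # genes 1,2,4 expressed
  for (cls in c("synonymous", "nonsynonymous")) {
    for (rep in 1:200) {
      params <- init_regulatory(4, cfg)
      g <- sample(4, 1)
      out <- apply_regulatory_mutation(params, g, cls, E, cfg)
      diff_R <- which(out$R != params$R)
      nd <- length(diff_R) + sum(out$theta != params$theta) +
        sum(out$lam != params$lam)
      expect_identical(nd, 1L)
      # any R change is confined to row g and the eligible source class
      if (length(diff_R) == 1L) {
        i <- (diff_R - 1) %% 4 + 1
        j <- (diff_R - 1) %/% 4 + 1
        expect_equal(i, g, ignore_attr = TRUE)
        if (cls == "nonsynonymous") expect_true(j %in% c(1, 2, 4))
        else expect_true(j == 3)
      }
      # theta/lambda changes are confined to gene g
      expect_true(all(out$theta[-g] == params$theta[-g]))
      expect_true(all(out$lam[-g] == params$lam[-g]))
      expect_true(all(out$theta >= 0) && all(out$lam >= 0))
    }
  }
})

test_that("an empty eligible link class falls back to theta/lambda", {
  set.seed(22)
  cfg <- reg_config()
  E_all <- expr_mat(c(1, 1), c(1, 0), c(2, 0))    # every source expressed
  E_none <- expr_mat(c(0, 0), c(0, 0), c(0, 0))   # only the seed gene
  for (rep in 1:100) {
    params <- init_regulatory(3, cfg)
    # synonymous wants inactive links; there are none -> theta/lambda
    out <- apply_regulatory_mutation(params, 2, "synonymous", E_all, cfg)
    expect_true(all(out$R == params$R))
    # nonsynonymous wants active links; only source 1 is expressed, so
    # either R[g,1] or theta/lambda moves, never another column
    out2 <- apply_regulatory_mutation(params, 2, "nonsynonymous", E_none,
                                      cfg)
    dR <- which(out2$R != params$R)
    if (length(dR) > 0) expect_identical(dR, 2L)  # R[2,1] in column-major
  }
})

test_that("theta/lambda allocation converges to 2/(2+n)", {
  set.seed(23)
  n <- 3
  cfg <- reg_config()
  E <- expr_mat(c(1, 1), c(1, 0), c(0, 0))
  params <- init_regulatory(n, cfg)
  hits <- replicate(2e4, {
    cls <- sample(c("synonymous", "nonsynonymous"), 1)
    out <- apply_regulatory_mutation(params, 2, cls, E, cfg)
    any(out$theta != params$theta) || any(out$lam != params$lam)
  })
  expected <- 2 / (2 + n)
  se <- sqrt(expected * (1 - expected) / length(hits))
  expect_lt(abs(mean(hits) - expected), 3 * se)
})

test_that("regulatory mutation is replayable from a seed and leaves input
           untouched", {
  cfg <- reg_config()
  E <- expr_mat(c(1, 1), c(0, 1))
  set.seed(99); params <- init_regulatory(2, cfg)
  snapshot <- unserialize(serialize(params, NULL))
  set.seed(7); a <- apply_regulatory_mutation(params, 1, "nonsynonymous",
                                              E, cfg)
  set.seed(7); b <- apply_regulatory_mutation(params, 1, "nonsynonymous",
                                              E, cfg)
  expect_identical(a, b)
  expect_identical(params, snapshot)  # pure function
})

test_that("nonsense events leave regulatory parameters intact", {
  set.seed(31)
  params <- init_regulatory(3, reg_config())
  expect_identical(nonsense_effect(params), params)
  expect_error(
    apply_regulatory_mutation(params, 1, "nonsense", expr_mat(c(1, 1)),
                              reg_config()),
    "nonsense")
})
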