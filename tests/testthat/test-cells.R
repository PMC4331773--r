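test_that("initial cells start fully modified, unmethylated, at the fixed point", {
  g <- tiny_genome()
  p <- epidrift_params()
  cell <- initial_cell(g, p)
  n_hm <- vapply(cell$chromatin, `[[`, integer(1), "n_hm")
  expect_equal(n_hm, g$genes$n_h)
  expect_true(all(!unlist(lapply(cell$chromatin, `[[`, "cpg_meth"))))
  ws <- vapply(cell$chromatin, unmethylated_fraction, numeric(1))
  expect_equal(ws, c(0, 1, 1))   # the CpG-free gene reports 0 by convention
  # an isolated unregulated gene sits at p_max * basal * theta / delta
  g1 <- fixture_genome(lengths = c(1600), n_cpg = c(8))
  c1 <- initial_cell(g1, p)
  theta <- hmt_binding_probability(8, 8, 1, p)
  expect_equal(c1$expression,
               p$p_max * p$q_p / (1 + p$q_p) * theta / p$delta,
               tolerance = 1e-7)
  # a nucleosome-free gene is fully permissive (theta = 1)
  expect_equal(cell$expression[1],
               p$p_max * p$q_p / (1 + p$q_p) * 1 / p$delta,
               tolerance = 1e-6)
})

test_that("coupled initial expression solves the network fixed point", {
  g <- generate_genome(length = 40000, seed = 9)
  p <- epidrift_params()
  cell <- initial_cell(g, p)
  theta <- vapply(seq_len(nrow(g$genes)), function(i) {
    nh <- g$genes$n_h[i]
    if (nh == 0) 1 else hmt_binding_probability(
      nh, nh, if (g$genes$n_cpg[i] > 0) 1 else 0, p)
  }, numeric(1))
  resid <- vapply(g$genes$id, function(i) {
    cell$expression[i] -
      p$p_max * oracle_theta_pro(i, g, cell$expression, p) * theta[i] / p$delta
  }, numeric(1))
  expect_lt(max(abs(resid)) / max(cell$expression), 1e-6)
})

test_that("quiescent cells never change their DNA methylation", {
  g <- tiny_genome()
  p <- epidrift_params()
  set.seed(7)
  cell <- initial_cell(g, p)
  # seed some methylation by hand, then step without divisions
  cell$chromatin[[2]]$cpg_meth <- c(TRUE, FALSE, TRUE, FALSE)
  before <- lapply(cell$chromatin, `[[`, "cpg_meth")
  for (i in 1:2000) cell <- step_cell(cell, g, p)
  after <- lapply(cell$chromatin, `[[`, "cpg_meth")
  expect_identical(before, after)
})

test_that("the absorbing full-modification state holds when k_d = 0", {
  g <- fixture_genome(lengths = c(1600), n_cpg = c(8))
  p <- epidrift_params(k_d = 0)
  set.seed(8)
  cell <- initial_cell(g, p)
  for (i in 1:300) cell <- step_cell(cell, g, p)
  expect_equal(cell$chromatin[[1]]$n_hm, 8L)
})

test_that("division conserves histones and obeys the partition law", {
  g <- fixture_genome(lengths = c(1600), n_cpg = c(8))
  p <- epidrift_params()
  set.seed(9)
  cell <- initial_cell(g, p)
  cell$environment <- "omega"
  n1s <- integer(3000)
  for (i in seq_len(3000)) {
    cell$chromatin[[1]]$n_hm <- 6L
    d <- attempt_division(cell, g, p, r_div = 1)  # divide every attempt
    expect_false(is.null(d))
    a <- d[[1]]$chromatin[[1]]$n_hm; b <- d[[2]]$chromatin[[1]]$n_hm
    expect_identical(a + b, 6L)
    expect_identical(d[[1]]$generation, cell$generation + 1L)
    expect_identical(d[[1]]$clone_id, cell$clone_id)
    n1s[i] <- a
  }
  expect_equal(mean(n1s), 3, tolerance = 0.06)     # <n_d1> = n/2
  expect_equal(var(n1s), 6 * 0.25, tolerance = 0.1)
  # empty chromatin stays empty
  cell$chromatin[[1]]$n_hm <- 0L
  d0 <- attempt_division(cell, g, p, r_div = 1)
  expect_identical(d0[[1]]$chromatin[[1]]$n_hm +
                   d0[[2]]$chromatin[[1]]$n_hm, 0L)
  # division is forbidden in the niche
  cell$environment <- "alpha"
  expect_error(attempt_division(cell, g, p), "omega")
})

test_that("mean inter-division time equals 1 / r_div", {
  g <- fixture_genome(lengths = c(150), n_cpg = c(0))
  p <- epidrift_params(r_div = 0.02)   # 50-step generations for a cheap test
  set.seed(10)
  cell <- initial_cell(g, p); cell$environment <- "omega"
  waits <- integer(400)
  for (k in seq_len(400)) {
    cell$division_progress <- 0
    t <- 0
    repeat {
      t <- t + 1
      d <- attempt_division(cell, g, p)
      if (!is.null(d)) break
    }
    waits[k] <- t
  }
  expect_equal(mean(waits), 1 / p$r_div, tolerance = 0.1)
  # geometric waiting times: sd ~ mean
  expect_equal(sd(waits), sqrt(1 - p$r_div) / p$r_div, tolerance = 0.15)
})

test_that("phenotype evaluation applies the strict marker threshold", {
  g <- tiny_genome()
  cell <- initial_cell(g)
  arp <- arp_definition(marker_ids = c(1L, 2L, 3L), ts = 2)
  cell$expression <- c(0, 0, 0)
  expect_identical(evaluate_phenotype(cell, arp), "aged")
  cell$expression <- c(2, 2, 2)
  expect_identical(evaluate_phenotype(cell, arp), "young")  # ties are young
  cell$expression <- c(0, 0, 6)
  expect_identical(evaluate_phenotype(cell, arp), "young")
  cell$expression <- c(0, 0, 5.9)
  expect_identical(evaluate_phenotype(cell, arp), "aged")
})

test_that("silenced methylated C2 genes stay silenced over long horizons", {
  # monostable chains below seven nucleosomes cannot re-establish the mark
  # once DNA methylation holds w_bs near its silenced-state value
  g <- fixture_genome(lengths = c(800), n_cpg = c(40))
  p <- epidrift_params()
  set.seed(11)
  n_lineages <- 30
  still_silenced <- logical(n_lineages)
  for (k in seq_len(n_lineages)) {
    cell <- initial_cell(g, p)
    cell$environment <- "omega"
    cs <- cell$chromatin[[1]]
    cs$n_hm <- 0L
    cs$cpg_meth <- runif(40) < 0.6
    cell$chromatin[[1]] <- cs
    for (i in 1:10000) {
      cell <- step_cell(cell, g, p)
      d <- attempt_division(cell, g, p)
      if (!is.null(d)) cell <- d[[1]]
    }
    still_silenced[k] <- cell$chromatin[[1]]$n_hm <= 2
  }
  expect_gte(mean(still_silenced), 0.99)
})

test_that("silenced bistable genes can regain the active state", {
  # an n_h = 8 gene silenced *without* methylation recovers quickly; this
  # reversibility is what distinguishes the bistable aging markers
  g <- fixture_genome(lengths = c(1600), n_cpg = c(8))
  p <- epidrift_params()
  set.seed(12)
  recovered <- logical(30)
  for (k in seq_len(30)) {
    cell <- initial_cell(g, p)
    cell$chromatin[[1]]$n_hm <- 0L
    for (i in 1:2000) {
      cell <- step_cell(cell, g, p)
      if (cell$chromatin[[1]]$n_hm >= 7) break
    }
    recovered[k] <- cell$chromatin[[1]]$n_hm >= 7
  }
  expect_gte(mean(recovered), 0.95)
})

test_that("the hypermethylation cascade has the right feedback signs", {
  # losing the histone mark raises the de novo rate; divisions then add
  # methylation; methylation lowers w_bs, which lowers binding, closing
  # the positive feedback toward stable silencing
  p <- epidrift_params()
  expect_gt(denovo_rate(0, 8, p), denovo_rate(8, 8, p))
  cs_low <- chromatin_state(8, n_hm = 0, n_cpg = 10)
  cs_after <- replicate_methylation(cs_low, denovo_rate(0, 8, p), p)
  w_before <- unmethylated_fraction(cs_low)
  set.seed(13)
  w_after <- mean(replicate(400, unmethylated_fraction(
    replicate_methylation(cs_low, denovo_rate(0, 8, p), p))))
  expect_lt(w_after, w_before)
  expect_lt(hmt_binding_probability(0, 8, w_after, p),
            hmt_binding_probability(0, 8, w_before, p))
})

test_that("cell-level and population-level methylation kernels agree", {
  # the population engine tracks methylated-site counts (sites are
  # exchangeable); its division kernel must match the per-CpG operation
  # in distribution
  g <- fixture_genome(lengths = c(1600), n_cpg = c(20))
  p <- epidrift_params()
  set.seed(14)
  pop <- new_population(g, p, n0 = 1, n_alpha = 0)
  pop$M[1, 1] <- 10L; pop$H[1, 1] <- 4L
  engine_draws <- replicate(2000, {
    d <- epidrift:::divide_cell(pop, 1L)
    d$M[1, 1]
  })
  # the law is Binomial(10, d_main) + Binomial(10, d_novo(n_d)) with the
  # partition n_d ~ Binomial(4, 1/2); compare against the per-CpG kernel
  cell_draws <- replicate(2000, {
    n1 <- rbinom(1, 4, 0.5)
    cs <- chromatin_state(8, n_hm = n1,
                          cpg_meth = c(rep(TRUE, 10), rep(FALSE, 10)))
    sum(replicate_methylation(cs, denovo_rate(n1, 8, p), p)$cpg_meth)
  })
  expect_lt(abs(mean(engine_draws) - mean(cell_draws)), 0.2)
  expect_lt(abs(var(engine_draws) - var(cell_draws)) / var(cell_draws), 0.3)
})
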