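test_that("unmethylated fraction counts sites and handles CpG-free genes", {
  expect_equal(unmethylated_fraction(chromatin_state(4, n_cpg = 6)), 1)
  cs <- chromatin_state(4, cpg_meth = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unmethylated_fraction(cs), 0.5)
  expect_equal(unmethylated_fraction(chromatin_state(4, n_cpg = 0)), 0)
  set.seed(1)
  for (i in 1:20) {
    m <- runif(17) < 0.4
    expect_equal(unmethylated_fraction(chromatin_state(3, cpg_meth = m)),
                 sum(!m) / 17)
  }
})

test_that("methyltransferase-complex binding follows the two-state form", {
  p <- epidrift_params(eps0 = 0, eps_bs = 1, eps_hm = 4)
  expect_equal(hmt_binding_probability(0, 8, 0, p), 0.5)
  # worked value: logistic(1 + 2 - 2) = logistic(1)
  p2 <- epidrift_params(eps0 = 2, eps_bs = 1, eps_hm = 4)
  expect_equal(hmt_binding_probability(4, 8, 1, p2), plogis(1),
               tolerance = 1e-12)
  expect_equal(hmt_binding_probability(4, 8, 1, p2), 0.7310586,
               tolerance = 1e-6)
  # saturation and the nucleosome-free convention
  p3 <- epidrift_params(eps0 = 2, eps_bs = 1, eps_hm = 16)
  expect_gt(hmt_binding_probability(8, 8, 1, p3), 0.999)
  expect_equal(hmt_binding_probability(0, 0, 1, p), 0)
  # strict monotonicity in modification level and in the unmethylated fraction
  p0 <- epidrift_params()
  th_n <- hmt_binding_probability(0:8, 8, 0.5, p0)
  expect_true(all(diff(th_n) > 0))
  th_w <- hmt_binding_probability(4, 8, seq(0, 1, 0.1), p0)
  expect_true(all(diff(th_w) > 0))
})

test_that("histone step matches its closed-form expectations", {
  # pure decay: k_m = 0 from the full state
  p <- epidrift_params(k_m = 0, k_d = 0.05)
  set.seed(2)
  t_end <- 20; reps <- 4000
  finals <- replicate(reps, {
    cs <- chromatin_state(8)
    for (s in 1:t_end) cs <- step_histones(cs, 1, p)
    cs$n_hm
  })
  expected <- 8 * (1 - p$k_d * p$dt)^t_end
  expect_equal(mean(finals), expected, tolerance = 0.03)
  # pure gain: one step from empty is Binomial(6, k_m * dt)
  p2 <- epidrift_params(k_m = 0.3, k_d = 0)
  draws <- replicate(reps, step_histones(chromatin_state(6, n_hm = 0), 1, p2)$n_hm)
  expect_equal(mean(draws), 6 * 0.3, tolerance = 0.05)
  expect_equal(var(draws), 6 * 0.3 * 0.7, tolerance = 0.1)
  # probability > 1 is a parameter error
  expect_error(step_histones(chromatin_state(4), 1,
                             epidrift_params(k_m = 1, dt = 1, k_d = 0.01)),
               NA)
  p_bad <- epidrift_params(k_m = 1, k_d = 0.01)
  p_bad$dt <- 1.5   # bypass constructor to hit the runtime guard
  expect_error(step_histones(chromatin_state(4), 1, p_bad), "probability")
})

test_that("stationary law without feedback is the independent-site binomial", {
  # eps_hm = 0: every nucleosome is an independent two-state chain, so the
  # stationary law is Binomial(n_h, p_up / (p_up + p_down)) exactly
  p <- epidrift_params(eps0 = 1.2, eps_bs = 0.5, eps_hm = 0,
                       k_m = 0.4, k_d = 0.05)
  for (nh in c(3, 6)) {
    theta <- hmt_binding_probability(0, nh, 0.7, p)  # constant in n
    pu <- p$k_m * theta * p$dt; pd <- p$k_d * p$dt
    want <- dbinom(0:nh, nh, pu / (pu + pd))
    got <- histone_stationary_distribution(nh, 0.7, p)$pi
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("simulated chain reproduces the master-equation stationary law", {
  # fast-mixing parameters so a short ensemble equilibrates
  p <- epidrift_params(eps0 = 6, eps_bs = 1, eps_hm = 8,
                       k_m = 0.5, k_d = 0.05)
  set.seed(3)
  for (nh in c(3, 5)) {
    exact <- histone_stationary_distribution(nh, 1, p)$pi
    sim <- simulate_histone_ensemble(nh, 1, p, n_chains = 400,
                                     burn_in = 2000, sample_steps = 2000)
    expect_lt(tv_distance(sim, exact), 0.02)
  }
})

test_that("small-step limit recovers the birth-death detailed-balance law", {
  # as dt -> 0 the simultaneous update converges to the single-jump
  # birth-death chain whose stationary law follows from detailed balance
  p <- epidrift_params(eps0 = 6, eps_bs = 1, eps_hm = 8,
                       k_m = 0.5, k_d = 0.05, dt = 0.02)
  nh <- 6
  theta <- hmt_binding_probability(0:nh, nh, 1, p)
  ratio <- (p$k_m * theta[1:nh] * (nh:1)) / (p$k_d * (1:nh))
  pi_bd <- c(1, cumprod(ratio)); pi_bd <- pi_bd / sum(pi_bd)
  got <- histone_stationary_distribution(nh, 1, p)$pi
  expect_equal(got, pi_bd, tolerance = 5e-3)
})

test_that("bistability appears at n_h = 8 in the methylated state only", {
  p <- epidrift_params()
  w_star <- 1 - p$d_novo0 / (1 - p$d_main + p$d_novo0)
  expect_equal(w_star, 0.4)
  expect_true(histone_stationary_distribution(8, w_star, p)$bimodal)
  expect_false(histone_stationary_distribution(4, w_star, p)$bimodal)
  expect_false(histone_stationary_distribution(6, w_star, p)$bimodal)
  # unmethylated chains with several nucleosomes are monostable high:
  # without DNA methylation silencing cannot stabilise
  expect_false(histone_stationary_distribution(8, 1, p)$bimodal)
  sd8 <- histone_stationary_distribution(8, 1, p)
  expect_gt(sum(sd8$pi[6:9]), 0.95)
})

test_that("de novo rate obeys the histone gate", {
  p <- epidrift_params(d_novo0 = 0.3, eps_methyl = 6)
  expect_equal(denovo_rate(0, 8, p), 0.3)
  expect_equal(denovo_rate(4, 8, p), 0.3 * exp(-3), tolerance = 1e-12)
  expect_equal(denovo_rate(4, 8, p), 0.01493612, tolerance = 1e-6)
  expect_lt(denovo_rate(8, 8, epidrift_params(eps_methyl = 40)), 1e-15)
  # nucleosome-free genes carry no protective mark
  expect_equal(denovo_rate(0, 0, p), 0.3)
})

test_that("replication-coupled methylation keeps, loses and gains sites correctly", {
  p <- epidrift_params(d_main = 1, d_novo0 = 0)
  cs <- chromatin_state(4, cpg_meth = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  set.seed(4)
  for (i in 1:50) {
    cs2 <- replicate_methylation(cs, 0, p)
    expect_identical(cs2$cpg_meth, cs$cpg_meth)
  }
  # fresh methylation of an unmethylated gene is Binomial(10, d_novo)
  p2 <- epidrift_params()
  draws <- replicate(4000, sum(replicate_methylation(
    chromatin_state(4, n_cpg = 10), 0.3, p2)$cpg_meth))
  expect_equal(mean(draws), 3, tolerance = 0.05)
  expect_equal(var(draws), 10 * 0.3 * 0.7, tolerance = 0.15)
})

test_that("per-CpG methylation reaches the two-state fixed point", {
  # repeated division at constant d_novo: p* = d_novo / (1 - d_main + d_novo)
  p <- epidrift_params(d_main = 0.8)
  d_novo <- 0.3
  cs <- chromatin_state(4, n_cpg = 2000)
  set.seed(5)
  frac <- numeric(600)
  for (i in seq_len(600)) {
    cs <- replicate_methylation(cs, d_novo, p)
    frac[i] <- mean(cs$cpg_meth)
  }
  stationary <- mean(frac[101:600])
  expect_equal(stationary, d_novo / (1 - p$d_main + d_novo), tolerance = 0.02)
})

test_that("expression follows the Euler update and its fixed point", {
  # theta_pro = theta = 1 with delta = 1 per unit time gives e* = p_max
  p <- epidrift_params(delta = 0.5, dt = 0.5)   # delta * dt < 1
  e <- 0
  for (i in 1:200) e <- step_expression(e, 1, 1, p)
  expect_equal(e, p$p_max / p$delta, tolerance = 1e-6)
  p1 <- epidrift_params(delta = 1, dt = 0.5)
  e <- 0
  for (i in 1:200) e <- step_expression(e, 1, 1, p1)
  expect_equal(e, 1000, tolerance = 1e-6)
  # silenced gene decays geometrically to zero
  p2 <- epidrift_params()
  e <- 800
  e1 <- step_expression(e, 0.5, 0, p2)
  expect_equal(e1, e * (1 - p2$delta * p2$dt))
  # Euler converges to the analytic exponential relaxation as dt -> 0
  target <- function(t, e0, estar, delta) estar + (e0 - estar) * exp(-delta * t)
  errs <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    p3 <- epidrift_params(delta = 0.4, dt = dt)
    e <- 100
    for (i in seq_len(round(10 / dt))) e <- step_expression(e, 0.6, 0.8, p3)
    abs(e - target(10, 100, p3$p_max * 0.6 * 0.8 / p3$delta, 0.4))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))        # error shrinks with dt
  expect_lt(errs[3] / errs[1], 0.5)       # roughly first order
  # instability guard
  p_bad <- epidrift_params(); p_bad$delta <- 1.2
  expect_error(step_expression(1, 1, 1, p_bad), "stable")
})

test_that("promoter occupancy saturates with strong regulators", {
  g <- generate_genome(length = 25000, seed = 8)
  p <- epidrift_params()
  ia <- g$interactions
  tgt_act <- ia$target[ia$sign == "activating"][1]
  reg_act <- ia$regulator[ia$sign == "activating" & ia$target == tgt_act][1]
  e <- rep(0, nrow(g$genes))
  base <- promoter_occupancy(tgt_act, g, e, p)
  e[reg_act] <- 1e9
  expect_gt(promoter_occupancy(tgt_act, g, e, p), 0.99)
  tgt_rep <- ia$target[ia$sign == "repressing"][1]
  reg_rep <- ia$regulator[ia$sign == "repressing" & ia$target == tgt_rep][1]
  e <- rep(0, nrow(g$genes))
  e[reg_rep] <- 1e9
  expect_lt(promoter_occupancy(tgt_rep, g, e, p), 0.01)
  expect_gt(base, 0); expect_lt(base, 1)
})

test_that("two-gene activation loop reaches the coupled fixed point", {
  # construct a two-gene genome with mutual activation, then check the
  # package's fixed point against an independent root search
  g <- fixture_genome(lengths = c(400, 400), n_cpg = c(2, 2))
  g$interactions <- tibble::tibble(target = c(1L, 2L), regulator = c(2L, 1L),
                                   sign = "activating", weight = c(2L, 2L))
  p <- epidrift_params()
  cell <- initial_cell(g, p)
  # residual of the coupled fixed-point equations, via the independent
  # re-implementation of the occupancy formula
  theta <- hmt_binding_probability(2, 2, 1, p)
  resid <- vapply(1:2, function(i) {
    cell$expression[i] -
      p$p_max * oracle_theta_pro(i, g, cell$expression, p) * theta / p$delta
  }, numeric(1))
  expect_lt(max(abs(resid)) / max(cell$expression), 1e-6)
  # cross-check one component with uniroot on the symmetric reduced equation
  f <- function(e) {
    tp <- p$q_p * (1 + 2 * e * p$delta / p$p_max) /
      (1 + p$q_p * (1 + 2 * e * p$delta / p$p_max))
    p$p_max * tp * theta / p$delta - e
  }
  root <- uniroot(f, c(0, p$p_max / p$delta))$root
  expect_equal(cell$expression[1], root, tolerance = 1e-4)
})

test_that("probabilities stay within [0, 1] across random parameter draws", {
  set.seed(6)
  for (i in 1:200) {
    p <- epidrift_params(eps0 = runif(1, 0, 15), eps_bs = runif(1, 0, 10),
                         eps_hm = runif(1, 0, 20),
                         eps_methyl = runif(1, 0, 8),
                         d_main = runif(1), d_novo0 = runif(1),
                         k_m = runif(1), k_d = runif(1))
    nh <- sample(0:10, 1)
    n <- if (nh > 0) sample(0:nh, 1) else 0L
    w <- runif(1)
    th <- hmt_binding_probability(n, nh, w, p)
    dn <- denovo_rate(n, nh, p)
    expect_true(th >= 0 && th <= 1)
    expect_true(dn >= 0 && dn <= 1)
  }
})
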