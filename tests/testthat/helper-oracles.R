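# Shared fixtures and independent oracles for the test suite.

# a small deterministic genome: one nucleosome-free gene, one C2-type,
# one bistable C1-type
tiny_genome <- function() fixture_genome(lengths = c(150, 800, 1600),
                                         n_cpg = c(0, 4, 8))

# independent naive motif scan (character-by-character, overlapping)
naive_motif_scan <- function(region, motif) {
  L <- nchar(region); m <- nchar(motif)
  if (L < m) return(integer())
  hits <- integer()
  for (s in 0:(L - m)) {
    if (substr(region, s + 1, s + m) == motif) hits <- c(hits, s)
  }
  hits
}

# brute-force all-pairs TF site scan, independent of the package routine
naive_tf_network <- function(g, prefix = g$tf_prefix, mm = g$tf_max_mismatch) {
  split1 <- function(s) strsplit(s, "")[[1]]
  seqc <- split1(g$sequence)
  comp <- c(`0` = "3", `1` = "2", `2` = "1", `3` = "0")
  out <- list()
  for (j in seq_len(nrow(g$genes))) {
    if (g$genes$length[j] < prefix) next
    motif <- comp[seqc[g$genes$start[j] + seq_len(prefix)]]
    for (i in seq_len(nrow(g$genes))) {
      L <- g$genes$length[i]
      if (L < prefix) next
      region <- seqc[g$genes$start[i] + seq_len(L)]
      n_act <- n_rep <- n_hit <- 0L
      for (s in 0:(L - prefix)) {
        mis <- sum(region[s + seq_len(prefix)] != motif)
        if (mis <= mm) {
          n_hit <- n_hit + 1L
          fidx <- g$genes$start[i] + s + prefix + 1L
          if (fidx <= length(seqc)) {
            if (as.integer(seqc[fidx]) %% 2L == 0L) n_act <- n_act + 1L
            else n_rep <- n_rep + 1L
          }
        }
      }
      if (n_hit > 0) {
        out[[length(out) + 1]] <- data.frame(
          target = g$genes$id[i], regulator = g$genes$id[j],
          sign = if (n_act >= n_rep) "activating" else "repressing",
          weight = n_hit)
      }
    }
  }
  do.call(rbind, out)
}

# vectorised ensemble simulation of the per-step histone update chain,
# used as the simulation side of the master-equation comparisons
simulate_histone_ensemble <- function(n_h, w_bs, p, n_chains, burn_in,
                                      sample_steps, thin = 1) {
  # overdispersed start: half the chains empty, half full
  state <- rep(c(0L, n_h), length.out = n_chains)
  counts <- numeric(n_h + 1)
  total <- burn_in + sample_steps
  for (s in seq_len(total)) {
    theta <- hmt_binding_probability(state, n_h, w_bs, p)
    gains <- rbinom(n_chains, n_h - state, pmin(p$k_m * theta * p$dt, 1))
    losses <- rbinom(n_chains, state, p$k_d * p$dt)
    state <- state + gains - losses
    if (s > burn_in && s %% thin == 0L) {
      tb <- tabulate(state + 1L, nbins = n_h + 1L)
      counts <- counts + tb
    }
  }
  counts / sum(counts)
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# independent re-implementation of the promoter-occupancy formula
oracle_theta_pro <- function(gene_id, g, e, p) {
  ia <- g$interactions
  sel <- ia[ia$target == gene_id, ]
  en <- e * p$delta / p$p_max
  sa <- sum(sel$weight[sel$sign == "activating"] *
            en[sel$regulator[sel$sign == "activating"]])
  sr <- sum(sel$weight[sel$sign == "repressing"] *
            en[sel$regulator[sel$sign == "repressing"]])
  p$q_p * (1 + sa) / (1 + sr + p$q_p * (1 + sa))
}

# average a clone-count curve over several scenario seeds
average_clone_curve <- function(g, seeds, steps = 5000, n0 = 50,
                                n_alpha = 10, record_every = 25,
                                preset = "no-arp-exchange") {
  curves <- lapply(seeds, function(s) {
    tr <- run_scenario(g, preset = preset, steps = steps,
                       record_every = record_every, seed = s, n0 = n0,
                       n_alpha = n_alpha)
    clone_census(tr)$summary[, c("time", "n_clones")]
  })
  tm <- curves[[1]]$time
  avg <- rowMeans(vapply(curves, function(cc)
    approx(cc$time, cc$n_clones, xout = tm, rule = 2)$y, numeric(length(tm))))
  tibble::tibble(time = tm, n_clones = avg)
}
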