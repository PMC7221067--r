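# Shared fixtures and independent oracles, built in code at test time.

# survival table from death/censoring vectors
make_surv <- function(times_a, times_b, status_a = 1, status_b = 1,
                      labels = c("A", "B"), time_unit = "days") {
  survival_table(data.frame(
    fly_id = paste0("fly", seq_len(length(times_a) + length(times_b))),
    genotype = rep(labels, c(length(times_a), length(times_b))),
    condition = "standard",
    time = c(times_a, times_b),
    status = c(rep_len(status_a, length(times_a)),
               rep_len(status_b, length(times_b)))),
    time_unit = time_unit)
}

# Independent brute-force oracle for the two-sample rank tests: walks every
# distinct death time and recomputes each risk set by naive counting.
oracle_rank_stat <- function(table, group_a, group_b, gehan = FALSE) {
  sub <- table[table$genotype %in% c(group_a, group_b), ]
  time <- sub$time
  status <- sub$status
  is_a <- sub$genotype == group_a
  U <- 0
  V <- 0
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & is_a)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & is_a)
    w <- if (gehan) n else 1
    U <- U + w * (d1 - d * n1 / n)
    if (n > 1) {
      V <- V + w^2 * d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
    }
  }
  if (V > 0) U^2 / V else 0
}

# pooled segments for one synthetic group: n_flies recordings of
# segs_per_fly 5-min windows each (25-min fly segment at the default 5)
sim_group_segments <- function(beta, noise_sd, seed0, n_flies = 6,
                               segs_per_fly = 5, genotype = "g") {
  do.call(rbind, lapply(seq_len(n_flies), function(i) {
    spec <- resp_synth_spec(
      duration_s = segs_per_fly * 300L + 360L,
      baseline_pre_s = 180L, baseline_post_s = 180L,
      smr_uW = 17.637, activity_coupling_uW = beta,
      bout_rate_per_min = 0.3, bout_mean_s = 60,
      noise_sd_ppm = noise_sd, mass_mg = 1,
      seed = seed0 + i, fly_id = sprintf("f%02d", i), genotype = genotype)
    segment_metrics(gen_resp_trace(spec))
  }))
}
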