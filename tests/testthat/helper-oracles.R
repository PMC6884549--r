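# Independent oracles used to cross-check package computations.

# Benjamini-Hochberg step-up from its textbook definition: sort, scale by
# m/rank, enforce monotonicity from the largest p downwards, cap at 1.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force fragment digestion: place a Poisson number of lesions on each
# simulated amplicon and count the fragments that survive with zero lesions.
# Written independently of the package's Monte-Carlo helper.
digest_fragments <- function(lambda, n_fragments, seed) {
  set.seed(seed)
  survived <- 0L
  block <- 20000L
  done <- 0L
  while (done < n_fragments) {
    k <- min(block, n_fragments - done)
    survived <- survived + sum(stats::rpois(k, lambda) == 0L)
    done <- done + k
  }
  survived / n_fragments
}

# Small event table with known gate outcomes for hand-computed checks.
manual_events <- function(n_live = 100, n_pos = 10, pos_intensity = 2000,
                          bg_intensity = 10) {
  tibble::tibble(
    sample_id = "manual",
    fsc_a = 50000, fsc_h = 50000, ssc_a = 30000, viability = 100,
    ch_egfp = pos_intensity,
    ch_reporter = c(rep(pos_intensity, n_pos),
                    rep(bg_intensity, n_live - n_pos))
  )
}
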