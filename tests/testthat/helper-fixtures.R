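# Shared fixtures, built in code at test time.

# Small cohort with no features, used across modules.
small_cohort <- function(n = 200, n_chrom = 2, m_per = 30, seed = 1) {
  panel <- synthetic_panel(n_chrom = n_chrom, variants_per_chrom = m_per,
                           seed = seed)
  simulate_cohort(n, panel, seed = seed + 1)
}

# Two-variant panel on distinct chromosomes with given ancestral frequencies.
two_variant_panel <- function(p11 = 0.9, p10 = 0.1, p21 = 0.85, p20 = 0.15) {
  variant_panel(chrom = c("1", "2"), pos_bp = c(1e6, 1e6),
                p1 = c(p11, p21), p0 = c(p10, p20))
}

# Cohort with a planted two-region feature spanning two chromosomes.
# Scales chosen so that PC1 tracks ancestry and PC2 locks onto the feature;
# region coordinates scale with the panel so small fixtures stay in range.
feature_cohort <- function(n = 1000, variants_per_chrom = 1200, seed = 22) {
  panel <- synthetic_panel(n_chrom = 6,
                           variants_per_chrom = variants_per_chrom,
                           seed = 21)
  width <- min(15L, max(3L, variants_per_chrom %/% 5L)) - 1L
  s2 <- (variants_per_chrom %/% 2L) * 1e4
  s5 <- (variants_per_chrom %/% 4L) * 1e4
  ft <- feature_spec(
    data.frame(chrom = c("2", "5"),
               start_bp = c(s2, s5),
               end_bp = c(s2, s5) + width * 1e4),
    carrier_freq = 0.5, strength = 0.45, id = "featA")
  list(cohort = simulate_cohort(n, panel, features = list(ft), seed = seed),
       feature = ft, panel = panel)
}

# Exclusion list that deliberately does NOT cover the planted feature.
off_target_regions <- function() {
  region_list(chrom = "3", start_bp = 2e6, end_bp = 3e6,
              build_label = "synthetic")
}

# Brute-force r^2 check used to validate ld_prune's postcondition.
max_kept_r2_within_window <- function(G, panel, keep, window_bp) {
  worst <- 0
  for (ch in unique(panel$chrom[keep])) {
    idx <- keep[panel$chrom[keep] == ch]
    idx <- idx[order(panel$pos_bp[idx])]
    if (length(idx) < 2) next
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) {
        if (panel$pos_bp[idx[b]] - panel$pos_bp[idx[a]] >= window_bp) break
        sa <- stats::sd(G[, idx[a]])
        sb <- stats::sd(G[, idx[b]])
        if (sa == 0 || sb == 0) next
        worst <- max(worst, stats::cor(G[, idx[a]], G[, idx[b]])^2)
      }
    }
  }
  worst
}
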