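# Independent oracles used to cross-check the implementation.

# brute-force two-sided rank-sum p-value: enumerate subsets with apply()
# over the mid-ranked pooled values
oracle_rank_sum <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(length(r), n1)
  w_all <- apply(subsets, 2, function(i) sum(r[i]))
  p_le <- sum(w_all <= w_obs + 1e-9) / ncol(subsets)
  p_ge <- sum(w_all >= w_obs - 1e-9) / ncol(subsets)
  min(1, 2 * min(p_le, p_ge))
}

# literal per-variant application of the sharing rules, written as plain
# set logic over data.frame rows (no vectorized shortcuts)
oracle_sharing_counts <- function(va, vb, evidence, loh_a, loh_b, samples,
                                  min_depth = 10) {
  keep <- function(v) {
    v[v$region %in% c("exonic", "splicing") &
        v$consequence != "synonymous", , drop = FALSE]
  }
  va <- keep(va)
  vb <- keep(vb)
  ev_at <- function(v, i, sample) {
    e <- evidence[evidence$sample_id == sample &
                    evidence$chrom == v$chrom[i] &
                    evidence$pos == v$pos[i] &
                    evidence$ref == v$ref[i] &
                    evidence$alt == v$alt[i], ]
    e[1, ]
  }
  in_loh <- function(v, i, seg) {
    if (is.null(seg) || nrow(seg) == 0) return(FALSE)
    seg <- seg[seg$loh %in% TRUE, , drop = FALSE]
    any(seg$contig == v$chrom[i] & v$pos[i] > seg$start &
          v$pos[i] <= seg$end)
  }
  status <- list()
  one_direction <- function(v, own, partner, partner_loh) {
    out <- character(nrow(v))
    for (i in seq_len(nrow(v))) {
      e_own <- ev_at(v, i, own)
      e_nrm <- ev_at(v, i, samples$normal)
      e_par <- ev_at(v, i, partner)
      gate <- (e_own$ref_depth + e_own$alt_depth) >= min_depth &&
        (e_nrm$ref_depth + e_nrm$alt_depth) >= min_depth &&
        isTRUE(e_own$hq_flag)
      out[i] <- if (!gate) "failed"
      else if (e_par$alt_depth >= 1) "shared"
      else if (in_loh(v, i, partner_loh)) "excluded"
      else "unique"
    }
    out
  }
  sa <- one_direction(va, samples$a, samples$b, loh_b)
  sb <- one_direction(vb, samples$b, samples$a, loh_a)
  ka <- paste(va$chrom, va$pos, va$ref, va$alt)
  kb <- paste(vb$chrom, vb$pos, vb$ref, vb$alt)
  keys <- unique(c(ka, kb))
  n <- c(shared = 0, unique_a = 0, unique_b = 0, excluded = 0, failed = 0)
  for (k in keys) {
    st <- c(sa[ka == k], sb[kb == k])
    both <- (k %in% ka) && (k %in% kb)
    if (any(st == "shared") || (both && any(st != "failed"))) {
      n["shared"] <- n["shared"] + 1
    } else if (any(st == "excluded")) {
      n["excluded"] <- n["excluded"] + 1
    } else if (any(st == "unique")) {
      if (k %in% ka) n["unique_a"] <- n["unique_a"] + 1
      else n["unique_b"] <- n["unique_b"] + 1
    } else {
      n["failed"] <- n["failed"] + 1
    }
  }
  n
}

# permutation estimate of the hypergeometric upper-tail enrichment p
oracle_enrichment_p <- function(genes, set_members, universe,
                                n_draws = 10000) {
  k_obs <- length(intersect(genes, set_members))
  hits <- replicate(n_draws, {
    draw <- sample(universe, length(genes))
    length(intersect(draw, set_members))
  })
  mean(hits >= k_obs)
}
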