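# Cancer cell fraction (CCF) estimation and clonal-structure inference.
# A finite binomial mixture over alternative read counts, fitted by EM for
# K = 1..K_max and selected by BIC, stands in for Dirichlet-process
# clustering: it is deterministic given a seed, desk-scale, and yields the
# same qualitative output (number of clones and their CCF means).

#' Estimate the cancer cell fraction of a mutation
#'
#' `ccf = vaf * (purity * copy_number + (1 - purity) * 2) /
#'        (purity * multiplicity)`, capped at 1.5. This inverts the standard
#' allele-sampling model in which a mutation on `multiplicity` of
#' `copy_number` tumor copies, in a tumor of the given purity diluted by
#' diploid normal cells, is observed at the corresponding expected VAF.
#'
#' @param alt_depth,ref_depth read counts (vectors allowed).
#' @param copy_number local tumor copy number (default 2).
#' @param purity tumor purity in (0, 1].
#' @param multiplicity mutated copies (default 1).
#' @return data.frame with `vaf`, `ccf`, and the inputs.
#' @export
estimate_ccf <- function(alt_depth, ref_depth, copy_number = 2L,
                         purity = 1, multiplicity = 1L) {
  if (any(alt_depth < 0) || any(ref_depth < 0)) {
    stop_input("estimate_ccf: negative depths")
  }
  total <- alt_depth + ref_depth
  if (any(total == 0)) stop_input("estimate_ccf: zero total depth")
  if (any(purity <= 0) || any(purity > 1)) {
    stop_input("estimate_ccf: purity must be in (0, 1]")
  }
  vaf <- alt_depth / total
  ccf <- vaf * (purity * copy_number + (1 - purity) * 2) /
    (purity * multiplicity)
  data.frame(vaf = vaf, ccf = pmin(ccf, 1.5), copy_number = copy_number,
             purity = purity, multiplicity = multiplicity)
}

#' Infer mutation multiplicity
#'
#' Multiplicity is fixed at 1 outside copy-number gains; inside a gain it
#' is `round(vaf * copy_number / purity)` clipped to `[1, copy_number]`.
#'
#' @param vaf observed variant allele fraction.
#' @param copy_number local tumor copy number.
#' @param purity tumor purity.
#' @param in_gain logical; is the site inside a gain segment?
#' @return integer multiplicities.
#' @export
infer_multiplicity <- function(vaf, copy_number, purity, in_gain) {
  m <- rep(1L, length(vaf))
  g <- which(in_gain)
  if (length(g) > 0) {
    est <- round(vaf[g] * copy_number[g] / purity)
    m[g] <- as.integer(pmin(pmax(est, 1), copy_number[g]))
  }
  m
}

# conversion factor from CCF to expected VAF for each mutation
ccf_to_vaf_factor <- function(copy_number, purity, multiplicity) {
  purity * multiplicity / (purity * copy_number + (1 - purity) * 2)
}

clamp_p <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

# component log-likelihood matrix (n x K); alt/depth/lc recycle down the
# columns of the n x K probability matrix
binom_loglik_matrix <- function(alt, depth, lc, f, ccfs) {
  p <- clamp_p(outer(f, ccfs))
  lc + alt * log(p) + (depth - alt) * log1p(-p)
}

logsumexp_rows <- function(m) {
  mx <- m[, 1]
  K <- ncol(m)
  if (K > 1) for (k in 2:K) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

# exact weighted ML for one component CCF: the weighted binomial
# log-likelihood is concave in the CCF, so a moment start plus damped
# Newton converges in a few steps; the search interval keeps the success
# probability strictly below 1 so no clamping is needed inside
mstep_ccf <- function(r, alt, depth, f, c_hi) {
  ra <- sum(r * alt)
  rda_f <- r * (depth - alt) * f
  c0 <- ra / max(sum(r * depth * f), 1e-12)
  c0 <- min(max(c0, 1e-4), c_hi)
  for (s in 1:8) {
    q <- 1 / (1 - c0 * f)
    g <- ra / c0 - sum(rda_f * q)
    gp <- -ra / c0^2 - sum(rda_f * f * q^2)
    if (!is.finite(g) || !is.finite(gp) || gp == 0) break
    c1 <- min(max(c0 - g / gp, 1e-4), c_hi)
    if (!is.finite(c1) || abs(c1 - c0) < 1e-9) {
      c0 <- if (is.finite(c1)) c1 else c0
      break
    }
    c0 <- c1
  }
  c0
}

# k-means++-style seeding on point CCF estimates
kmeanspp_init <- function(ccf_hat, K) {
  centers <- numeric(K)
  centers[1] <- ccf_hat[sample.int(length(ccf_hat), 1)]
  if (K > 1) {
    d2 <- (ccf_hat - centers[1])^2
    for (k in 2:K) {
      centers[k] <- if (sum(d2) == 0) {
        ccf_hat[sample.int(length(ccf_hat), 1)]
      } else {
        ccf_hat[sample.int(length(ccf_hat), 1, prob = d2 / sum(d2))]
      }
      d2 <- pmin(d2, (ccf_hat - centers[k])^2)
    }
  }
  pmin(pmax(centers, 0.01), 1.5)
}

fit_mixture_once <- function(alt, depth, f, K, tol, max_iter) {
  n <- length(alt)
  lc <- lchoose(depth, alt)
  c_hi <- min(1.5, (1 - 1e-6) / max(f))
  ccf_hat <- pmin((alt / depth) / f, 1.5)
  ccfs <- if (K == 1) mean(ccf_hat) else kmeanspp_init(ccf_hat, K)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  trace <- numeric(max_iter)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lm <- binom_loglik_matrix(alt, depth, lc, f, ccfs) +
      rep(log(w), each = n)
    row_ll <- logsumexp_rows(lm)
    ll <- sum(row_ll)
    trace[iter] <- ll
    resp <- exp(lm - row_ll)
    w <- pmax(colMeans(resp), 1e-12)
    w <- w / sum(w)
    for (k in seq_len(K)) {
      ccfs[k] <- mstep_ccf(resp[, k], alt, depth, f, c_hi)
    }
    # relative tolerance on the log-likelihood
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  trace <- trace[seq_len(iter)]
  lm <- binom_loglik_matrix(alt, depth, lc, f, ccfs) +
    rep(log(w), each = n)
  row_ll <- logsumexp_rows(lm)
  list(ccfs = ccfs, weights = w, loglik = sum(row_ll),
       resp = exp(lm - row_ll), trace = trace)
}

#' Cluster mutations into clones by CCF
#'
#' Fits a binomial mixture over alternative read counts: component `k`
#' places a mutation's success probability at `ccf_k` times its
#' CCF-to-VAF conversion factor (from copy number, purity and
#' multiplicity). EM is run with multiple k-means++-style restarts for
#' each `K = 1..k_max` and the number of clones is chosen by BIC
#' (`-2 logL + (2K - 1) log n`). Deterministic given `seed`.
#'
#' @param alt,depth alternative and total read counts per mutation.
#' @param copy_number,multiplicity,purity local copy state and sample
#'   purity (scalars or vectors; purity is a scalar).
#' @param k_max largest number of clusters tried (default 6).
#' @param restarts EM restarts per K (default 50).
#' @param seed RNG seed for the restarts.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter EM iteration cap.
#' @return object of class `ccf_clusters`: `K`, `means` (cluster CCFs,
#'   decreasing), `weights`, `assignment` (cluster index per mutation),
#'   `ccf` (point estimates), `bic` (per candidate K), `loglik`,
#'   `loglik_trace` of the winning run, `warning` flag for the < 5
#'   mutation fallback.
#' @export
fit_clusters <- function(alt, depth, copy_number = 2L, multiplicity = 1L,
                         purity = 1, k_max = 6L, restarts = 50L, seed = 1L,
                         tol = 1e-8, max_iter = 500L) {
  if (k_max < 1) stop_input("fit_clusters: k_max must be >= 1")
  if (any(depth <= 0)) stop_input("fit_clusters: zero read depth")
  n <- length(alt)
  cn <- rep_len(copy_number, n)
  mult <- rep_len(multiplicity, n)
  f <- ccf_to_vaf_factor(cn, purity, mult)
  ccf_hat <- pmin((alt / depth) / f, 1.5)
  if (n < 5) {
    warning("fit_clusters: fewer than 5 mutations; returning one cluster",
            call. = FALSE)
    return(structure(list(
      K = 1L, means = mean(ccf_hat), weights = 1,
      assignment = rep(1L, n), ccf = ccf_hat, bic = NA_real_,
      loglik = NA_real_, loglik_trace = numeric(0), warning = TRUE),
      class = "ccf_clusters"))
  }
  fits <- with_seed(seed, {
    lapply(seq_len(k_max), function(K) {
      best <- NULL
      nr <- if (K == 1) 1L else restarts
      for (r in seq_len(nr)) {
        fit <- fit_mixture_once(alt, depth, f, K, tol, max_iter)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      best
    })
  })
  bic <- vapply(seq_len(k_max), function(K) {
    -2 * fits[[K]]$loglik + (2 * K - 1) * log(n)
  }, numeric(1))
  K <- which.min(bic)
  fit <- fits[[K]]
  ord <- order(fit$ccfs, decreasing = TRUE)
  relabel <- match(seq_len(K), ord)
  structure(list(
    K = as.integer(K),
    means = fit$ccfs[ord],
    weights = fit$weights[ord],
    assignment = relabel[max.col(fit$resp)],
    ccf = ccf_hat,
    bic = bic,
    loglik = fit$loglik,
    loglik_trace = fit$trace,
    warning = FALSE), class = "ccf_clusters")
}

#' @export
print.ccf_clusters <- function(x, ...) {
  cat(sprintf("CCF clustering: K = %d; means = %s; weights = %s\n",
              x$K, paste(round(x$means, 3), collapse = ", "),
              paste(round(x$weights, 3), collapse = ", ")))
  invisible(x)
}

#' Select key mutations of a focus
#'
#' A mutation is *key* when its clone is clonal-scale --- assigned cluster
#' mean CCF >= `ccf_min` (default 0.5) --- and it is predicted
#' deleterious: SIFT <= 0.05 or PolyPhen-2 >= 0.957 (both bounds
#' inclusive). A missing score never satisfies its criterion.
#'
#' @param clusters a [fit_clusters()] result.
#' @param variants data.frame aligned with the clustered mutations
#'   (columns `gene`, `sift`, `polyphen`, and an id column).
#' @param ccf_min clonal-frequency threshold on the cluster mean.
#' @param sift_max,polyphen_min deleteriousness bounds.
#' @return `variants` subset of key mutations with an added
#'   `cluster_mean_ccf` column.
#' @export
select_key_mutations <- function(clusters, variants, ccf_min = 0.5,
                                 sift_max = 0.05, polyphen_min = 0.957) {
  if (nrow(variants) != length(clusters$assignment)) {
    stop_input("select_key_mutations: variants must align with clustering")
  }
  cm <- clusters$means[clusters$assignment]
  deleterious <- (!is.na(variants$sift) & variants$sift <= sift_max) |
    (!is.na(variants$polyphen) & variants$polyphen >= polyphen_min)
  key <- cm >= ccf_min & deleterious
  out <- variants[key, , drop = FALSE]
  out$cluster_mean_ccf <- cm[key]
  rownames(out) <- NULL
  out
}

#' Driver-gene recurrence across foci
#'
#' For every gene, counts the foci in which the gene carries a key
#' mutation versus the foci in which it carries any somatic mutation.
#'
#' @param focus_tables named list (one entry per focus) of data.frames
#'   with columns `gene` and logical `is_key`.
#' @return data.frame `gene`, `n_foci_key`, `n_foci_mutated`, `ratio`,
#'   sorted by decreasing ratio then key count.
#' @export
driver_recurrence <- function(focus_tables) {
  genes <- unique(unlist(lapply(focus_tables, function(t) t$gene)))
  rows <- lapply(genes, function(g) {
    any_f <- vapply(focus_tables, function(t) any(t$gene == g), logical(1))
    key_f <- vapply(focus_tables,
                    function(t) any(t$gene == g & t$is_key), logical(1))
    data.frame(gene = g, n_foci_key = sum(key_f),
               n_foci_mutated = sum(any_f),
               ratio = if (sum(any_f) == 0) 0 else sum(key_f) / sum(any_f),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ratio, -out$n_foci_key, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
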