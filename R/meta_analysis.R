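# Per-chromosome consolidation of projected QTLs into meta-QTLs.
#
# Statistical model: the projected peaks y_i are treated as one-dimensional
# observations with KNOWN standard deviations s_i derived from their 95%
# confidence intervals. A K-component Gaussian mixture with free means and
# weights but component variances fixed at each observation's s_i^2 is
# fitted by expectation-maximization; K is chosen by a majority vote of
# five penalized-likelihood criteria (AIC, AICc, AIC3, BIC, AWE). The
# consensus position of a cluster is the inverse-variance weighted mean and
# its 95% interval has width 3.92 / sqrt(sum 1/s_i^2).

CI_TO_SD_FACTOR <- 3.92  # 2 * 1.96: full width of a 95% normal interval

#' Convert a 95% confidence interval to a positional standard deviation
#'
#' Treats the interval as symmetric normal 95% bounds, so s = width / 3.92,
#' floored at `s_floor` to keep the likelihood non-singular for the
#' zero-width intervals that occur in published tables.
#'
#' @param ci_lo,ci_hi interval bounds in cM (`ci_hi >= ci_lo`).
#' @param s_floor minimum standard deviation in cM (default 0.05).
#' @return standard deviation(s) in cM.
#' @export
ci_to_sd <- function(ci_lo, ci_hi, s_floor = 0.05) {
  if (any(is.na(ci_lo)) || any(is.na(ci_hi)) || any(ci_hi < ci_lo)) {
    stop("confidence interval bounds must satisfy ci_lo <= ci_hi")
  }
  pmax((ci_hi - ci_lo) / CI_TO_SD_FACTOR, s_floor)
}

# log-likelihood of the heteroscedastic mixture at (means, weights)
mixture_loglik <- function(y, s, means, weights) {
  lw <- log(weights)
  m <- vapply(seq_along(means), function(k) {
    lw[k] + stats::dnorm(y, means[k], s, log = TRUE)
  }, numeric(length(y)))
  if (length(y) == 1L) m <- matrix(m, nrow = 1L)
  sum(row_logsumexp(m))
}

# One EM run from given initial means; variances fixed at s_i^2.
em_run <- function(y, s, means, max_iter, tol) {
  n <- length(y)
  K <- length(means)
  weights <- rep(1 / K, K)
  inv_var <- 1 / s^2
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lm <- stats::dnorm(y, matrix(means, n, K, byrow = TRUE), s,
                       log = TRUE) +
      matrix(log(weights), n, K, byrow = TRUE)
    lse <- row_logsumexp(lm)
    ll <- sum(lse)
    post <- exp(lm - lse)
    weights <- pmax(colMeans(post), 1e-12)
    weights <- weights / sum(weights)
    num <- colSums(post * y * inv_var)
    den <- colSums(post * inv_var)
    upd <- den > 0
    means[upd] <- num[upd] / den[upd]
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(loglik = ll_old, means = means, weights = weights, post = post,
       converged = converged)
}

# Classification-EM polish of a hard assignment: iteratively reassign each
# observation to the component maximizing log pi_k + log phi(y_i), with
# pi_k = n_k/n and mu_k the inverse-variance weighted cluster mean. This is
# a local ascent on the hard-assignment (classification) likelihood. An
# empty cluster is reseeded with the worst-fitting observation of a
# multi-member cluster, the standard device that keeps exactly K groups
# alive when components of the soft fit have collapsed onto each other.
cem_polish <- function(y, s, z, K, max_iter = 100L, patience = 4L) {
  n <- length(y)
  inv_var <- 1 / s^2
  cluster_means <- function(z, nk) {
    r <- rowsum(cbind(y * inv_var, inv_var), z)
    mu <- rep(NA_real_, K)
    mu[as.integer(rownames(r))] <- r[, 1L] / r[, 2L]
    mu
  }
  best_z <- z
  best_ll <- -Inf
  stale <- 0L
  for (iter in seq_len(max_iter)) {
    nk <- tabulate(z, nbins = K)
    if (n >= K) {
      while (any(nk == 0L)) {
        mu <- cluster_means(z, nk)
        fit_ll <- stats::dnorm(y, mu[z], s, log = TRUE)
        movable <- nk[z] >= 2L
        worst <- which(movable)[which.min(fit_ll[movable])]
        z[worst] <- which(nk == 0L)[1L]
        nk <- tabulate(z, nbins = K)
      }
    }
    ll <- hard_loglik(y, s, z)
    if (ll > best_ll + 1e-12) {
      best_ll <- ll
      best_z <- z
      stale <- 0L
    } else {
      # reseeding can oscillate; stop once the ascent stalls
      stale <- stale + 1L
      if (stale >= patience) break
    }
    pi_k <- nk / n
    mu <- cluster_means(z, nk)
    mu[nk == 0L] <- NA_real_
    lp <- ifelse(nk > 0L, log(pi_k), -Inf)
    score <- stats::dnorm(y, matrix(mu, n, K, byrow = TRUE), s,
                          log = TRUE) +
      matrix(lp, n, K, byrow = TRUE)
    score[is.na(score)] <- -Inf
    z_new <- max.col(score, ties.method = "first")
    if (all(z_new == z)) break
    z <- z_new
  }
  best_z
}

# Multi-start search for the best hard (classification-likelihood)
# clustering: polishes the posterior arg-max of the soft fit together with
# a family of contiguous split candidates in sorted-y order (deterministic
# quantile cuts plus seeded random cuts) and keeps the partition with the
# highest hard log-likelihood. Means are ordered, so good hard partitions
# are contiguous or nearly so; the CEM ascent handles the rest. With
# strong heteroscedasticity the optimum can be non-contiguous, which the
# reseeding excursions of cem_polish explore; small problems get the full
# excursion budget because their search spaces are the ones where such
# optima occur and the iterations are cheap, while larger well-populated
# problems converge from the contiguous starts almost immediately.
best_hard_assignment <- function(y, s, z_post, K) {
  n <- length(y)
  if (K == 1L) return(rep(1L, n))
  small <- n <= 12L
  n_random <- if (small) 30L else 12L
  patience <- if (small) 100L else 4L
  ord <- order(y)
  contiguous_z <- function(cuts) {
    lab <- integer(n)
    grp <- findInterval(seq_len(n), c(1L, sort(cuts) + 1L))
    lab[ord] <- grp
    lab
  }
  cand <- list(z_post)
  even <- unique(round(seq_len(K - 1L) * n / K))
  even <- even[even >= 1L & even <= n - 1L]
  if (length(even) == K - 1L) cand <- c(cand, list(contiguous_z(even)))
  for (r in seq_len(n_random)) {
    if (n - 1L >= K - 1L) {
      cand <- c(cand, list(contiguous_z(sample(n - 1L, K - 1L))))
    }
  }
  best_z <- NULL
  best_ll <- -Inf
  for (z0 in cand) {
    z <- cem_polish(y, s, z0, K, patience = patience)
    if (small) z <- relocate_polish(y, s, z, K)
    ll <- hard_loglik(y, s, z)
    if (ll > best_ll) {
      best_ll <- ll
      best_z <- z
    }
  }
  if (small) {
    z <- smalln_refine(y, s, best_z, K)
    if (hard_loglik(y, s, z) > best_ll) best_z <- z
  } else {
    z <- relocate_polish(y, s, best_z, K)
    if (hard_loglik(y, s, z) > best_ll) best_z <- z
  }
  best_z
}

# Best-improvement relocation search on the classification likelihood:
# repeatedly move the single observation whose reassignment to another
# cluster yields the largest likelihood gain, until no move improves.
# Complements cem_polish, whose mean-based reassignment cannot reach
# optima that are non-contiguous in y (these arise under strong
# heteroscedasticity, when a wide-interval QTL belongs with a distant
# cluster while its neighbors do not).
relocate_polish <- function(y, s, z, K, max_moves = 200L) {
  n <- length(y)
  if (n < 2L || K < 2L) return(z)
  inv_var <- 1 / s^2
  cluster_ll <- function(idx) {
    m <- sum(idx)
    if (m == 0L) return(0)
    mu <- sum(y[idx] * inv_var[idx]) / sum(inv_var[idx])
    m * log(m / n) + sum(stats::dnorm(y[idx], mu, s[idx], log = TRUE))
  }
  ll_k <- vapply(seq_len(K), function(k) cluster_ll(z == k), numeric(1L))
  for (mv in seq_len(max_moves)) {
    best_gain <- 1e-10
    best_move <- NULL
    for (i in seq_len(n)) {
      from <- z[i]
      if (sum(z == from) == 1L) next  # keep K clusters alive
      for (k in seq_len(K)) {
        if (k == from) next
        zi <- z
        zi[i] <- k
        gain <- cluster_ll(zi == from) + cluster_ll(zi == k) -
          ll_k[from] - ll_k[k]
        if (gain > best_gain) {
          best_gain <- gain
          best_move <- c(i, k)
        }
      }
    }
    if (is.null(best_move)) break
    i <- best_move[1L]; k <- best_move[2L]; from <- z[i]
    z[i] <- k
    ll_k[from] <- cluster_ll(z == from)
    ll_k[k] <- cluster_ll(z == k)
  }
  z
}

# Deeper neighborhood search used on small problems, where optima of the
# classification likelihood can require coordinated changes no sequence of
# single improving relocations reaches: exchanging two observations
# between clusters, and merging two clusters while splitting another.
# Evaluates full likelihoods directly (cheap at small n); iterates to a
# local optimum of the combined neighborhood.
smalln_refine <- function(y, s, z, K, max_rounds = 50L) {
  n <- length(y)
  if (n < 3L || K < 2L) return(z)
  best_ll <- hard_loglik(y, s, z)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    # pairwise exchanges
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (z[i] == z[j]) next
        zi <- z
        zi[c(i, j)] <- z[c(j, i)]
        ll <- hard_loglik(y, s, zi)
        if (ll > best_ll + 1e-10) {
          z <- zi
          best_ll <- ll
          improved <- TRUE
        }
      }
    }
    # merge two clusters, split another (possibly the merged one)
    labs <- sort(unique(z))
    if (length(labs) >= 2L) {
      for (a_i in seq_along(labs)[-length(labs)]) {
        for (b_i in (a_i + 1L):length(labs)) {
          a <- labs[a_i]; b <- labs[b_i]
          zm <- z
          zm[zm == b] <- a
          for (cc in sort(unique(zm))) {
            members <- which(zm == cc)
            m <- length(members)
            if (m < 2L) next
            # proper bipartitions of the cluster (fix member 1 on one side)
            for (code in seq_len(2L^(m - 1L) - 1L)) {
              sel <- members[c(FALSE, as.logical(bitwAnd(
                code, 2L^(seq_len(m - 1L) - 1L))))]
              zi <- zm
              zi[sel] <- b
              ll <- hard_loglik(y, s, zi)
              if (ll > best_ll + 1e-10) {
                z <- zi
                best_ll <- ll
                improved <- TRUE
              }
            }
          }
        }
      }
    }
    z <- relocate_polish(y, s, z, K)
    ll <- hard_loglik(y, s, z)
    if (ll > best_ll + 1e-10) {
      best_ll <- ll
      improved <- TRUE
    }
    if (!improved) break
  }
  z
}

# Hard-assignment (classification) log-likelihood of a clustering:
# sum_i log( (n_{z_i}/n) * phi(y_i; mu_{z_i}, s_i^2) ) with mu the
# inverse-variance weighted mean of each cluster.
hard_loglik <- function(y, s, z) {
  n <- length(y)
  inv_var <- 1 / s^2
  ll <- 0
  for (k in unique(z)) {
    idx <- z == k
    mu <- sum(y[idx] * inv_var[idx]) / sum(inv_var[idx])
    ll <- ll + sum(log(sum(idx) / n) +
                     stats::dnorm(y[idx], mu, s[idx], log = TRUE))
  }
  ll
}

#' Fit a heteroscedastic Gaussian mixture to projected QTL peaks
#'
#' EM for a K-component mixture in which the component variance attached to
#' observation i is fixed at its own s_i^2 (derived from the projected 95%
#' confidence interval); only the K means and K-1 free weights are
#' estimated. Initial means are placed at the 1/(K+1), ..., K/(K+1)
#' quantiles of `y`; additional seeded restarts jitter this initialization
#' and the best log-likelihood is kept, so results are deterministic given
#' `seed`. The returned hard clustering is the posterior arg-max refined by
#' a classification-EM polish.
#'
#' @param y projected peak positions, cM.
#' @param s positional standard deviations, cM (same length as `y`).
#' @param K number of components, `1 <= K <= length(y)`.
#' @param seed integer seed for restart jitter.
#' @param n_restarts number of EM restarts (default 5).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return list: `loglik` (mixture log-likelihood), `means`, `weights`
#'   (sorted by mean), `posterior` (n x K matrix), `assignment` (hard
#'   cluster labels 1..K), `hard_loglik`, `converged`, `K`.
#' @export
fit_mixture <- function(y, s, K, seed = 1L, n_restarts = 5L,
                        max_iter = 500L, tol = 1e-8) {
  n <- length(y)
  if (length(s) != n) stop("y and s must have the same length")
  if (any(s <= 0)) stop("all s must be positive")
  if (K < 1L || K > n) stop("K must satisfy 1 <= K <= length(y)")
  base_init <- as.numeric(stats::quantile(y, (1:K) / (K + 1), type = 7))
  span <- diff(range(y)) + 1e-6
  best <- NULL
  z <- NULL
  with_seed(seed, {
    inits <- list(sort(base_init))
    if (K > 1L && length(unique(y)) >= K) {
      km <- tryCatch(stats::kmeans(y, centers = K, nstart = 3L),
                     error = function(e) NULL)
      if (!is.null(km)) inits <- c(inits, list(sort(as.numeric(km$centers))))
    }
    while (length(inits) < n_restarts) {
      inits <- c(inits,
                 list(sort(base_init + stats::rnorm(K, 0, span / (K + 1)))))
    }
    for (init in inits) {
      fit <- em_run(y, s, init, max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    z_post <- max.col(best$post, ties.method = "first")
    z <- best_hard_assignment(y, s, z_post, K)
  })
  ord <- order(best$means)
  means <- best$means[ord]
  weights <- best$weights[ord]
  post <- best$post[, ord, drop = FALSE]
  # relabel hard clusters so labels ascend with cluster position
  zmu <- vapply(seq_len(K), function(k) {
    if (!any(z == k)) return(Inf)
    idx <- z == k
    sum(y[idx] / s[idx]^2) / sum(1 / s[idx]^2)
  }, numeric(1L))
  z <- match(z, order(zmu))
  list(loglik = best$loglik, means = means, weights = weights,
       posterior = post, assignment = z, hard_loglik = hard_loglik(y, s, z),
       converged = best$converged, K = K)
}

#' Choose the number of meta-QTL clusters by a five-criterion vote
#'
#' Fits the mixture for K = 1..Kmax and computes, with p = 2K - 1 free
#' parameters (K means, K - 1 weights) and L the maximized likelihood:
#' AIC = -2 ln L + 2p; AICc = AIC + 2p(p+1)/(n-p-1); AIC3 = -2 ln L + 3p;
#' BIC = -2 ln L + p ln n; AWE = -2 ln L + 2p(ln n + 1.5). Each criterion
#' votes for its minimizing K; AICc abstains entirely when its correction
#' is undefined (n <= p + 1) for any candidate K. The final K is the modal
#' vote, ties broken toward the smaller K (parsimony).
#'
#' @param y,s observations and their standard deviations, cM.
#' @param Kmax largest K considered (default `min(n, 10)`).
#' @param seed seed passed to [fit_mixture()].
#' @param ... further arguments to [fit_mixture()].
#' @return list: `table` (K, loglik, p, AIC, AICc, AIC3, BIC, AWE),
#'   `votes` (named integer vector, NA = abstained), `final_K`, `fits`
#'   (list of mixture fits indexed by K).
#' @export
select_model <- function(y, s, Kmax = NULL, seed = 1L, ...) {
  n <- length(y)
  if (n == 0L) stop("no observations")
  if (is.null(Kmax)) Kmax <- min(n, 10L)
  Kmax <- min(Kmax, n)
  fits <- vector("list", Kmax)
  tab <- data.frame(K = seq_len(Kmax), loglik = NA_real_, p = NA_integer_,
                    AIC = NA_real_, AICc = NA_real_, AIC3 = NA_real_,
                    BIC = NA_real_, AWE = NA_real_)
  for (K in seq_len(Kmax)) {
    fits[[K]] <- fit_mixture(y, s, K, seed = seed, ...)
    ll <- fits[[K]]$loglik
    p <- 2L * K - 1L
    tab$loglik[K] <- ll
    tab$p[K] <- p
    tab$AIC[K] <- -2 * ll + 2 * p
    tab$AICc[K] <- if (n - p - 1L > 0L) {
      -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
    } else NA_real_
    tab$AIC3[K] <- -2 * ll + 3 * p
    tab$BIC[K] <- -2 * ll + p * log(n)
    tab$AWE[K] <- -2 * ll + 2 * p * (log(n) + 1.5)
  }
  crit <- c("AIC", "AICc", "AIC3", "BIC", "AWE")
  votes <- vapply(crit, function(cn) {
    v <- tab[[cn]]
    if (anyNA(v)) NA_integer_ else tab$K[which.min(v)]
  }, integer(1L))
  cast <- votes[!is.na(votes)]
  counts <- table(cast)
  winners <- as.integer(names(counts)[counts == max(counts)])
  final_K <- min(winners)
  list(table = tab, votes = votes, final_K = final_K, fits = fits)
}

#' Summarize one cluster of projected QTLs as a meta-QTL
#'
#' Consensus position is the inverse-variance weighted mean
#' sum(y/s^2)/sum(1/s^2); the 95% interval has width
#' 3.92/sqrt(sum 1/s^2) centered on the position, so pooling always
#' shrinks the interval relative to the narrowest member. Flanking markers
#' are the nearest consensus-map markers at or outside each interval bound
#' (clamped to the chromosome ends).
#'
#' @param y,s member peak positions and standard deviations, cM.
#' @param chrom chromosome label.
#' @param members character vector of member QTL ids.
#' @param traits character vector of member trait codes.
#' @param consensus optional consensus `genetic_map` used to name flanking
#'   markers.
#' @return one-row data.frame: `chrom`, `position_cM`, `ci_lo_cM`,
#'   `ci_hi_cM`, `ci_cM` (width), `n_qtl`, `traits` (semicolon list),
#'   `left_marker`, `right_marker`, `members` (semicolon list).
#' @export
summarize_mqtl <- function(y, s, chrom, members = as.character(seq_along(y)),
                           traits = character(), consensus = NULL) {
  if (!length(y)) stop("empty cluster")
  w <- 1 / s^2
  position <- sum(y * w) / sum(w)
  width <- CI_TO_SD_FACTOR / sqrt(sum(w))
  ci_lo <- position - width / 2
  ci_hi <- position + width / 2
  left <- right <- NA_character_
  if (!is.null(consensus)) {
    mk <- consensus[consensus$linkage_group == chrom, , drop = FALSE]
    if (nrow(mk)) {
      at_left <- which(mk$position_cM <= ci_lo)
      left <- mk$marker[if (length(at_left)) max(at_left) else 1L]
      at_right <- which(mk$position_cM >= ci_hi)
      right <- mk$marker[if (length(at_right)) min(at_right) else nrow(mk)]
    }
  }
  data.frame(chrom = chrom, position_cM = position, ci_lo_cM = ci_lo,
             ci_hi_cM = ci_hi, ci_cM = width, n_qtl = length(y),
             traits = paste(sort(unique(traits)), collapse = ";"),
             left_marker = left, right_marker = right,
             members = paste(members, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Run the per-chromosome meta-QTL analysis
#'
#' For each chromosome with at least one successfully projected QTL the
#' mixture model selection is run, the chosen fit's hard clusters are
#' summarized as meta-QTLs, and names `MQTL_<chrom>_<i>` are assigned in
#' ascending position order (1-based).
#'
#' @param projected data.frame from [project_all()] (rows with `status !=
#'   "projected"` are ignored); must carry `qtl_id`, `chrom`, `trait`,
#'   `consensus_peak`, `consensus_ci_lo`, `consensus_ci_hi`.
#' @param consensus optional consensus `genetic_map` for flanking markers.
#' @param seed integer seed; each chromosome derives its own sub-seed.
#' @param Kmax largest cluster count considered per chromosome (capped at
#'   the number of observations; default 10).
#' @param s_floor minimum positional standard deviation, cM.
#' @return list: `mqtl` (one row per meta-QTL with `name` first) and
#'   `selection` (per-chromosome [select_model()] criterion tables).
#' @export
run_meta_analysis <- function(projected, consensus = NULL, seed = 1L,
                              Kmax = 10L, s_floor = 0.05) {
  ok <- projected[projected$status == "projected", , drop = FALSE]
  chroms <- sort(unique(ok$chrom))
  out <- list()
  selection <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    sub <- ok[ok$chrom == ch, , drop = FALSE]
    y <- sub$consensus_peak
    s <- ci_to_sd(sub$consensus_ci_lo, sub$consensus_ci_hi,
                  s_floor = s_floor)
    ms <- select_model(y, s, Kmax = min(Kmax, length(y)), seed = seed + ci)
    selection[[ch]] <- ms$table
    fit <- ms$fits[[ms$final_K]]
    rows <- lapply(sort(unique(fit$assignment)), function(k) {
      idx <- fit$assignment == k
      summarize_mqtl(y[idx], s[idx], chrom = ch,
                     members = sub$qtl_id[idx], traits = sub$trait[idx],
                     consensus = consensus)
    })
    rows <- do.call(rbind, rows)
    rows <- rows[order(rows$position_cM), , drop = FALSE]
    rows <- cbind(name = sprintf("MQTL_%s_%d", ch, seq_len(nrow(rows))),
                  rows, stringsAsFactors = FALSE)
    out[[ch]] <- rows
  }
  mqtl <- if (length(out)) do.call(rbind, out) else NULL
  if (!is.null(mqtl)) rownames(mqtl) <- NULL
  list(mqtl = mqtl, selection = selection)
}

#' Write a meta-QTL table as TSV
#'
#' Columns mirror the packaged catalog dialect: name, chromosome, flanking
#' markers, position, interval width and the semicolon-separated trait list.
#'
#' @param mqtl data.frame from [run_meta_analysis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mqtl_table <- function(mqtl, path) {
  cols <- intersect(c("name", "chrom", "left_marker", "right_marker",
                      "position_cM", "ci_cM", "n_qtl", "traits", "members"),
                    names(mqtl))
  utils::write.table(mqtl[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
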