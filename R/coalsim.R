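## Neutral coalescent simulator with recombination (Hudson-style ancestral
## recombination graph) and infinite-sites mutation, used to build null
## distributions and 95% CIs for the neutrality statistics.

#' Configuration for the neutral coalescent simulator
#'
#' @param n Sample size (haplotypes), at least 2.
#' @param theta_gene Per-gene mutation parameter (theta = 4 N mu per gene);
#'   mutations fall on branches at rate theta/2 per lineage.
#' @param rho_gene Per-gene recombination parameter (rho = 4 N r); 0 gives a
#'   single genealogy. Taken as supplied (observed-data estimates or
#'   synthetic truth); no internal estimation is performed.
#' @param L Number of sites represented (used only for per-site scaling of
#'   derived statistics; the mutation model is infinite-sites on (0, 1)).
#' @param reps Number of replicates for null distributions (default 1000).
#' @param seed Optional integer seed for reproducible replicate sets.
#' @return An object of class \code{coalescent_config}.
#' @export
coalescent_config <- function(n, theta_gene, rho_gene = 0, L = NULL,
                              reps = 1000L, seed = NULL) {
  stopifnot(n >= 2, theta_gene >= 0, rho_gene >= 0, reps >= 1)
  structure(list(n = as.integer(n), theta_gene = theta_gene,
                 rho_gene = rho_gene, L = L, reps = as.integer(reps),
                 seed = seed),
            class = "coalescent_config")
}

#' Simulate one sample under the neutral coalescent with recombination
#'
#' Event-driven simulation of the ancestral recombination graph: lineages
#' carry intervals of ancestral material on (0, 1), each interval labelled
#' with the set of sampled haplotypes descending from it. Coalescence (rate
#' k(k-1)/2), recombination (rate rho/2 per unit of breakable span) and
#' infinite-sites mutation (rate theta/2 per unit of ancestral material)
#' compete; material whose descendant set reaches the full sample has found
#' its local MRCA and is retired. Each mutation yields one segregating site
#' whose derived allele is carried by exactly the descendant set of the
#' interval it hits.
#'
#' @param config A \code{coalescent_config}. Its \code{seed}, when set, is
#'   applied before simulation (for one-off draws; \code{\link{simulate_replicates}}
#'   seeds once for the whole set).
#' @param use_seed Apply \code{config$seed} (default TRUE).
#' @return An object of class \code{coalescent_sample}: \code{n},
#'   \code{positions} (sorted mutation positions on (0,1)) and
#'   \code{counts} (derived-allele counts, parallel to positions).
#' @export
simulate_sample <- function(config, use_seed = TRUE) {
  if (use_seed && !is.null(config$seed)) set.seed(config$seed)
  n <- config$n; theta <- config$theta_gene; rho <- config$rho_gene
  lineages <- lapply(seq_len(n), function(i)
    list(segs = list(list(l = 0, r = 1, mem = i))))
  pos <- numeric(0); cnt <- integer(0)
  alen <- function(lin) sum(vapply(lin$segs, function(s) s$r - s$l, 0))
  span <- function(lin) {
    ls <- vapply(lin$segs, `[[`, 0, "l"); rs <- vapply(lin$segs, `[[`, 0, "r")
    max(rs) - min(ls)
  }
  while (length(lineages) > 0L) {
    k <- length(lineages)
    al <- vapply(lineages, alen, 0)
    sp <- vapply(lineages, span, 0)
    r_coal <- if (k >= 2L) k * (k - 1) / 2 else 0
    r_rec <- rho / 2 * sum(sp)
    r_mut <- theta / 2 * sum(al)
    total <- r_coal + r_rec + r_mut
    if (total == 0) break  # lone lineage, no mutation: nothing more happens
    u <- runif(1) * total
    if (u < r_mut) {
      i <- sample.int(k, 1L, prob = al)
      segs <- lineages[[i]]$segs
      lens <- vapply(segs, function(s) s$r - s$l, 0)
      s <- segs[[sample.int(length(segs), 1L, prob = lens)]]
      pos <- c(pos, runif(1, s$l, s$r))
      cnt <- c(cnt, length(s$mem))
    } else if (u < r_mut + r_rec) {
      i <- sample.int(k, 1L, prob = sp)
      segs <- lineages[[i]]$segs
      ls <- vapply(segs, `[[`, 0, "l"); rs <- vapply(segs, `[[`, 0, "r")
      bp <- runif(1, min(ls), max(rs))
      left <- list(); right <- list()
      for (s in segs) {
        if (s$r <= bp) left[[length(left) + 1L]] <- s
        else if (s$l >= bp) right[[length(right) + 1L]] <- s
        else {
          left[[length(left) + 1L]] <- list(l = s$l, r = bp, mem = s$mem)
          right[[length(right) + 1L]] <- list(l = bp, r = s$r, mem = s$mem)
        }
      }
      if (length(left) > 0L && length(right) > 0L) {
        lineages[[i]] <- list(segs = left)
        lineages[[length(lineages) + 1L]] <- list(segs = right)
      }
    } else {
      ij <- sample.int(k, 2L)
      merged <- .merge_lineages(lineages[[ij[1]]], lineages[[ij[2]]], n)
      lineages <- lineages[-ij]
      if (length(merged$segs) > 0L)
        lineages[[length(lineages) + 1L]] <- merged
    }
  }
  o <- order(pos)
  structure(list(n = n, positions = pos[o], counts = cnt[o]),
            class = "coalescent_sample")
}

# Merge two lineages' ancestral material by interval sweep; retire
# intervals whose descendant set is the full sample.
.merge_lineages <- function(a, b, n) {
  cuts <- sort(unique(c(
    vapply(a$segs, `[[`, 0, "l"), vapply(a$segs, `[[`, 0, "r"),
    vapply(b$segs, `[[`, 0, "l"), vapply(b$segs, `[[`, 0, "r"))))
  out <- list()
  cover <- function(segs, lo, hi) {
    for (s in segs) if (s$l <= lo && s$r >= hi) return(s$mem)
    NULL
  }
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i]; hi <- cuts[i + 1L]
    ma <- cover(a$segs, lo, hi); mb <- cover(b$segs, lo, hi)
    if (is.null(ma) && is.null(mb)) next
    mem <- sort(unique(c(ma, mb)))
    if (length(mem) >= n) next  # local MRCA reached
    if (length(out) > 0L) {
      last <- out[[length(out)]]
      if (last$r == lo && identical(last$mem, mem)) {
        out[[length(out)]]$r <- hi
        next
      }
    }
    out[[length(out) + 1L]] <- list(l = lo, r = hi, mem = mem)
  }
  list(segs = out)
}

#' @export
print.coalescent_sample <- function(x, ...) {
  cat(sprintf("coalescent_sample: n = %d, S = %d\n", x$n, length(x$counts)))
  invisible(x)
}

#' Simulate a seeded set of replicates
#'
#' @param config A \code{coalescent_config}; its \code{seed} is applied once
#'   before the first replicate, so the whole set is reproducible.
#' @return List of \code{coalescent_sample}s of length \code{config$reps}.
#' @export
simulate_replicates <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  lapply(seq_len(config$reps), function(i) simulate_sample(config, use_seed = FALSE))
}

#' Null distribution and p-value of a statistic under the neutral coalescent
#'
#' Evaluates \code{stat} on each simulated replicate, drops NA replicates
#' (typically S = 0), and reports the empirical 2.5/97.5 percentiles, the
#' null mean, and a one-tailed p-value taken on the side of the observed
#' deviation from the null median: p is the fraction of replicates as or
#' more extreme than the observed value, floored at 1/(replicates + 1) when
#' the observed value lies outside the simulated range.
#'
#' @param stat Function mapping a \code{coalescent_sample} to a scalar
#'   (e.g. \code{tajimas_d}).
#' @param observed Observed value of the statistic.
#' @param config A \code{coalescent_config}.
#' @param stat_name Label for reports.
#' @return An object of class \code{null_summary}.
#' @export
null_distribution <- function(stat, observed, config, stat_name = "stat") {
  reps <- simulate_replicates(config)
  vals <- vapply(reps, function(s) {
    v <- suppressWarnings(stat(s))
    if (is.list(v)) v <- v[[1L]]
    as.numeric(v)
  }, 0)
  n_na <- sum(is.na(vals))
  if (n_na > length(vals) / 2)
    stop(sprintf("null distribution unusable: %d of %d replicates NA (too little simulated variation)",
                 n_na, length(vals)))
  vals <- vals[!is.na(vals)]
  m <- length(vals)
  ci <- unname(quantile(vals, c(0.025, 0.975), type = 7))
  med <- median(vals)
  count <- if (!is.na(observed) && observed >= med) sum(vals >= observed)
           else if (!is.na(observed)) sum(vals <= observed)
           else NA_integer_
  p <- if (is.na(observed)) NA_real_
       else if (count == 0L) 1 / (m + 1) else count / m
  structure(list(stat_name = stat_name, null_mean = mean(vals),
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 observed = observed, reps_used = m, n_na = n_na),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("%s: observed = %s, null mean = %.3f, 95%% CI [%.3f, %.3f], p = %s\n",
              x$stat_name,
              ifelse(is.na(x$observed), "NA", sprintf("%.3f", x$observed)),
              x$null_mean, x$ci_low, x$ci_high,
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 3))))
  invisible(x)
}

#' Confidence-interval overlap decision between sympatric and allopatric samples
#'
#' The two populations are called significantly different for a statistic
#' only when the sympatric population's simulated 95% CI excludes the
#' allopatric observed value AND the allopatric CI excludes the sympatric
#' observed value (the decision requires both directions).
#'
#' @param sym,allo \code{null_summary} objects for the same statistic and
#'   gene, each carrying its population's observed value.
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} when either observed
#'   statistic is NA.
#' @export
ci_overlap_test <- function(sym, allo) {
  if (is.na(sym$observed) || is.na(allo$observed)) return(NA)
  sym_excludes <- allo$observed < sym$ci_low || allo$observed > sym$ci_high
  allo_excludes <- sym$observed < allo$ci_low || sym$observed > allo$ci_high
  sym_excludes && allo_excludes
}
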