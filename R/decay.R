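#' Loess decay curve of identity-by-descent against distance
#'
#' Locally weighted regression of an IBD field on pairwise geographic
#' distance, evaluated on a regular grid over the observed distance range.
#'
#' @param pairs data.frame of pair records with a distance column.
#' @param ibd_field name of the IBD column (e.g. `"ibd_auto_unbiased"`).
#' @param span loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param grid_n evaluation grid size (default 256).
#' @param dist_field distance column name (default `"dist_m"`).
#' @return list of class `jay_decay`: `grid` (m), `fit`, `span`,
#'   `mean_ibd`, `ibd_at_zero` (fit at smallest observed distance),
#'   `n_pairs`.
#' @export
fit_decay_curve <- function(pairs, ibd_field = "ibd_auto", span = 0.75,
                            degree = 2, grid_n = 256L, dist_field = "dist_m") {
  d <- pairs[[dist_field]]
  y <- pairs[[ibd_field]]
  ok <- is.finite(d) & is.finite(y)
  d <- d[ok]; y <- y[ok]
  if (length(d) < 10L) stop("too few pairs for a decay curve")
  if (diff(range(d)) <= 0) stop("degenerate fit: all distances equal")
  fit <- stats::loess(y ~ d, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "interpolate",
                                                     statistics = "none"))
  grid <- seq(min(d), max(d), length.out = grid_n)
  fhat <- stats::predict(fit, newdata = data.frame(d = grid))
  structure(list(grid = grid, fit = as.numeric(fhat), span = span,
                 mean_ibd = mean(y), ibd_at_zero = as.numeric(fhat[1L]),
                 n_pairs = length(d)),
            class = "jay_decay")
}

#' Half-decay distance delta of an IBD decay curve
#'
#' delta is the smallest distance at which the fitted curve drops to or
#' below the midpoint between its value at the smallest observed distance
#' and the overall mean IBD, with linear interpolation between grid
#' points. If the fitted value at the smallest distance does not exceed
#' the overall mean there is no isolation-by-distance signal and delta is
#' `NA` (a distinguished result, not an error).
#'
#' @param curve a `jay_decay` from [fit_decay_curve()].
#' @return list of class `jay_delta`: `delta` (m; `NA` if undefined),
#'   `ibd_at_zero`, `mean_ibd`.
#' @export
estimate_delta <- function(curve) {
  stopifnot(inherits(curve, "jay_decay"))
  z0 <- curve$ibd_at_zero
  mu <- curve$mean_ibd
  out <- list(delta = NA_real_, ibd_at_zero = z0, mean_ibd = mu)
  class(out) <- "jay_delta"
  if (!is.finite(z0) || z0 <= mu) return(out)
  target <- (z0 + mu) / 2
  f <- curve$fit; g <- curve$grid
  below <- which(f <= target)
  if (!length(below)) return(out)
  i <- below[1L]
  if (i == 1L) { out$delta <- g[1L]; return(out) }
  # linear interpolation between grid points i-1 and i
  out$delta <- g[i - 1L] + (g[i] - g[i - 1L]) *
    (f[i - 1L] - target) / (f[i - 1L] - f[i])
  out
}

#' Bootstrap confidence interval for delta (BCa)
#'
#' Resamples pairs with replacement, refits the loess curve and
#' recomputes delta `B` times; the interval is bias-corrected and
#' accelerated. The acceleration constant is estimated by a delete-group
#' jackknife over `jack_groups` random groups of pairs (a full
#' leave-one-pair-out jackknife is infeasible at 1e5 pairs).
#'
#' @inheritParams fit_decay_curve
#' @param B bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @param jack_groups delete-group jackknife group count (default 50).
#' @return list of class `jay_delta_ci`: `delta`, `ci_low`, `ci_high`,
#'   `n_bootstrap`, `prop_undefined`, `unstable` (TRUE when > 20% of
#'   replicates had undefined delta), plus point-estimate components.
#' @export
bootstrap_delta <- function(pairs, ibd_field = "ibd_auto", span = 0.75,
                            degree = 2, B = 1000L, conf = 0.95, seed = 1L,
                            jack_groups = 50L, dist_field = "dist_m") {
  pairs <- as.data.frame(pairs)
  ok <- is.finite(pairs[[dist_field]]) & is.finite(pairs[[ibd_field]])
  pairs <- pairs[ok, ]
  point <- estimate_delta(fit_decay_curve(pairs, ibd_field, span, degree,
                                          dist_field = dist_field))
  n <- nrow(pairs)
  one_delta <- function(dat) {
    est <- try(estimate_delta(fit_decay_curve(dat, ibd_field, span, degree,
                                              dist_field = dist_field)),
               silent = TRUE)
    if (inherits(est, "try-error")) NA_real_ else est$delta
  }
  set.seed(seed)
  boot <- vapply(seq_len(B), function(b)
    one_delta(pairs[sample.int(n, n, replace = TRUE), ]), numeric(1))
  prop_na <- mean(!is.finite(boot))
  bo <- boot[is.finite(boot)]
  out <- list(delta = point$delta, ibd_at_zero = point$ibd_at_zero,
              mean_ibd = point$mean_ibd, n_bootstrap = B,
              prop_undefined = prop_na, unstable = prop_na > 0.2,
              ci_low = NA_real_, ci_high = NA_real_)
  class(out) <- "jay_delta_ci"
  if (length(bo) < 10L || !is.finite(point$delta)) return(out)

  # BCa: bias correction from the bootstrap distribution, acceleration
  # from a delete-group jackknife
  z0 <- stats::qnorm(pmin(pmax(mean(bo < point$delta), 1 / (2 * length(bo))),
                          1 - 1 / (2 * length(bo))))
  grp <- sample(rep_len(seq_len(jack_groups), n))
  jack <- vapply(seq_len(jack_groups), function(g)
    one_delta(pairs[grp != g, ]), numeric(1))
  jack <- jack[is.finite(jack)]
  a <- if (length(jack) >= 3L && stats::sd(jack) > 0) {
    jm <- mean(jack)
    sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
  } else 0
  alpha <- (1 - conf) / 2
  za <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  qs <- stats::quantile(bo, probs = pmin(pmax(adj, 0), 1), names = FALSE,
                        type = 6)
  out$ci_low <- qs[1L]; out$ci_high <- qs[2L]
  out
}

#' Mantel correlogram in fixed distance bins
#'
#' For each closed-open distance bin [lo, hi), computes the Mantel
#' correlation between a pairwise similarity matrix and the bin-membership
#' indicator, with permutation p-values (joint row/column permutation of
#' individuals) corrected progressively from the shortest bin (Holm).
#' Pairs closer than `exclude_below` (same-territory and self pairs) are
#' excluded entirely.
#'
#' @param dist_matrix symmetric matrix of pairwise geographic distances (m).
#' @param sim_matrix symmetric matrix of pairwise similarity (e.g. IBD),
#'   same individual order.
#' @param breaks bin edges; default the 500 m scheme 250, 750, ..., 5250.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param exclude_below drop pairs closer than this (default 250 m).
#' @param min_pairs bins with fewer pairs are dropped with a warning
#'   (default 30).
#' @return data.frame of class `jay_correlogram`: `lo`, `hi`, `n_pairs`,
#'   `mantel_r`, `p_value`, `p_corrected`.
#' @export
mantel_correlogram <- function(dist_matrix, sim_matrix,
                               breaks = seq(250, 5250, by = 500),
                               n_perm = 999L, seed = 1L,
                               exclude_below = 250, min_pairs = 30L) {
  stopifnot(identical(dim(dist_matrix), dim(sim_matrix)),
            nrow(dist_matrix) == ncol(dist_matrix))
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-8 ||
      max(abs(sim_matrix - t(sim_matrix)), na.rm = TRUE) > 1e-8)
    stop("matrices must be symmetric")
  n <- nrow(dist_matrix)
  ut <- upper.tri(dist_matrix)
  keep <- ut & dist_matrix >= exclude_below & is.finite(sim_matrix)
  dvec <- dist_matrix[keep]
  bin <- findInterval(dvec, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1L
  inrange <- bin >= 1L & bin <= nb
  counts <- tabulate(bin[inrange], nbins = nb)
  use_bin <- counts >= min_pairs
  if (any(!use_bin & counts > 0))
    warning("dropping bins with fewer than ", min_pairs, " pairs")

  # per-bin Mantel r between similarity and bin-membership indicator over
  # the retained pair set
  stat_fun <- function(svec) {
    m <- mean(svec); s <- stats::sd(svec)
    vapply(which(use_bin), function(k) {
      ind <- as.numeric(bin == k)
      stats::cor(svec, ind)
    }, numeric(1))
  }
  svec0 <- sim_matrix[keep]
  obs <- stat_fun(svec0)

  set.seed(seed)
  exceed_lo <- exceed_hi <- rep(0L, sum(use_bin))
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    sp <- sim_matrix[pm, pm][keep]
    st <- stat_fun(sp)
    exceed_lo <- exceed_lo + (st <= obs)
    exceed_hi <- exceed_hi + (st >= obs)
  }
  # two-sided permutation p (include observed)
  p <- (pmin(exceed_lo, exceed_hi) + 1L) / (n_perm + 1L) * 2
  p <- pmin(p, 1)
  # progressive Holm correction from the shortest bin
  p_corr <- vapply(seq_along(p), function(k)
    stats::p.adjust(p[seq_len(k)], method = "holm")[k], numeric(1))
  out <- data.frame(lo = breaks[-length(breaks)][use_bin],
                    hi = breaks[-1L][use_bin],
                    n_pairs = counts[use_bin],
                    mantel_r = obs, p_value = p, p_corrected = p_corr)
  class(out) <- c("jay_correlogram", "data.frame")
  out
}

#' Quantile-binned means of IBD against distance
#'
#' Equal-count distance bins; mean and standard error of the IBD field
#' per bin. Ties producing empty bins are merged with a warning.
#'
#' @inheritParams fit_decay_curve
#' @param n_bins number of quantile bins (default 10).
#' @return data.frame `bin`, `dist_lo`, `dist_hi`, `dist_mid`, `n`,
#'   `mean`, `se`.
#' @export
binned_means <- function(pairs, ibd_field = "ibd_auto", n_bins = 10L,
                         dist_field = "dist_m") {
  stopifnot(n_bins >= 2L)
  d <- pairs[[dist_field]]; y <- pairs[[ibd_field]]
  ok <- is.finite(d) & is.finite(y)
  d <- d[ok]; y <- y[ok]
  qs <- stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE)
  if (anyDuplicated(qs)) {
    warning("tied quantiles: merging adjacent bins")
    qs <- unique(qs)
  }
  bin <- cut(d, qs, include.lowest = TRUE, labels = FALSE)
  agg <- function(f) tapply(y, bin, f)
  dd <- function(f) tapply(d, bin, f)
  data.frame(bin = sort(unique(bin)),
             dist_lo = as.numeric(dd(min)), dist_hi = as.numeric(dd(max)),
             dist_mid = as.numeric(dd(stats::median)),
             n = as.integer(tapply(y, bin, length)),
             mean = as.numeric(agg(mean)),
             se = as.numeric(tapply(y, bin, function(v)
               stats::sd(v) / sqrt(length(v)))))
}

#' Principal-component vs northing correlations
#'
#' PCA on the centered (mean-imputed) genotype matrix; Spearman rank
#' correlations of PC1 and PC2 scores with UTM northing. The sign of a PC
#' is arbitrary, so `abs_rho` is the reported magnitude.
#'
#' @param geno `jay_geno` matrix.
#' @param northing named numeric (by individual id) of UTM northing (m).
#' @param ids optional subset (e.g. males only).
#' @return data.frame `pc`, `rho`, `abs_rho`, `p_value`, `var_explained`.
#' @export
pc_spatial_correlation <- function(geno, northing, ids = NULL) {
  G <- unclass(geno)
  if (!is.null(ids)) G <- G[as.character(ids), , drop = FALSE]
  if (nrow(G) < 3L) stop("need at least 3 individuals")
  cm <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) {
    na <- is.na(G[, j]); if (any(na)) G[na, j] <- cm[j]
  }
  G <- sweep(G, 2L, colMeans(G), "-")
  sdv <- apply(G, 2L, stats::sd)
  G <- G[, sdv > 0, drop = FALSE]
  if (ncol(G) == 0L) stop("genotype matrix is monomorphic")
  pc <- stats::prcomp(G, center = FALSE, scale. = FALSE, rank. = 2L)
  y <- northing[rownames(G)]
  if (anyNA(y)) stop("missing northing values")
  ve <- pc$sdev[1:2]^2 / sum(pc$sdev^2)
  res <- lapply(1:2, function(k) {
    ct <- suppressWarnings(stats::cor.test(pc$x[, k], y, method = "spearman"))
    data.frame(pc = paste0("PC", k), rho = unname(ct$estimate),
               abs_rho = abs(unname(ct$estimate)),
               p_value = ct$p.value, var_explained = ve[k])
  })
  do.call(rbind, res)
}
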