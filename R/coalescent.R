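#' Distance-binned pair-class probabilities from a pedigree
#'
#' For each distance bin, estimates the probability that a pair separated
#' by that distance is parent-offspring Pp(d), full-siblings Pf(d) or
#' half-siblings Ph(d), as the class count divided by the total pair
#' count in the bin. The sex-specific variant conditions on the pair's
#' sex combination. Distances beyond the last bin clamp to it (step
#' function, no interpolation).
#'
#' @param pairs pair records with `dist_m`, `rel` and (for the
#'   sex-specific variant) `sex_a`, `sex_b`.
#' @param breaks distance bin edges (m); default 15 equal-count bins of
#'   the observed distances.
#' @param sex_specific condition on sex combination (default FALSE).
#' @return object of class `jay_classprobs`: list with `breaks` and
#'   `table` (data.table `bin`, [`sex_combo`,] `n`, `Pp`, `Pf`, `Ph`).
#' @export
estimate_pair_class_probs <- function(pairs, breaks = NULL,
                                      sex_specific = FALSE) {
  pairs <- data.table::as.data.table(pairs)
  if (is.null(breaks))
    breaks <- unique(stats::quantile(pairs$dist_m, probs = seq(0, 1, length.out = 16L),
                                     names = FALSE))
  if (length(breaks) < 2L) stop("need at least one distance bin")
  pairs[, bin := pmin(pmax(findInterval(dist_m, breaks, rightmost.closed = TRUE), 1L),
                      length(breaks) - 1L)]
  if (sex_specific) {
    pairs[, sex_combo := paste0(pmin(sex_a, sex_b) , pmax(sex_a, sex_b))]
    pairs[, sex_combo := c(FF = "FF", FM = "MF", MM = "MM")[sex_combo]]
    by <- c("bin", "sex_combo")
  } else by <- "bin"
  tab <- pairs[, list(
    n = .N,
    Pp = mean(rel %in% "PO"),
    Pf = mean(rel %in% "FS"),
    Ph = mean(rel %in% "HS")), by = by]
  grid <- if (sex_specific)
    data.table::CJ(bin = seq_len(length(breaks) - 1L),
                   sex_combo = c("MM", "MF", "FF"))
  else data.table::data.table(bin = seq_len(length(breaks) - 1L))
  tab <- merge(grid, tab, by = by, all.x = TRUE)
  empty <- is.na(tab$n)
  if (any(empty)) {
    warning("bins with zero pairs: probabilities set to 0")
    tab[empty, `:=`(n = 0L, Pp = 0, Pf = 0, Ph = 0)]
  }
  structure(list(breaks = breaks, table = tab, sex_specific = sex_specific),
            class = "jay_classprobs")
}

# look up Pp/Pf/Ph for distances d (clamped) and optional sex combos
.lookup_probs <- function(cp, d, sex_combo = NULL) {
  bin <- pmin(pmax(findInterval(d, cp$breaks, rightmost.closed = TRUE), 1L),
              length(cp$breaks) - 1L)
  tab <- cp$table
  if (cp$sex_specific) {
    if (is.null(sex_combo)) stop("sex-specific table needs sex combos")
    key <- paste(bin, sex_combo)
    i <- match(key, paste(tab$bin, tab$sex_combo))
  } else i <- match(bin, tab$bin)
  list(Pp = tab$Pp[i], Pf = tab$Pf[i], Ph = tab$Ph[i])
}

#' Mean IBD of immigrant pair classes
#'
#' E(Zm) (immigrant-immigrant) and E(Zr) (immigrant-resident) as overall
#' means, or per distance bin for the isolation-by-distance-in-immigrants
#' extension (model M4).
#'
#' @param pairs pair records with `imm_class`, `dist_m` and the IBD field.
#' @param ibd_field IBD column (default `"ibd_auto_unbiased"`).
#' @param breaks distance bin edges when `by_distance` (default: the 15
#'   equal-count scheme over all pairs).
#' @param by_distance return per-bin tables (default FALSE).
#' @return object of class `jay_immibd`: list with `Zm`, `Zr` (scalars or
#'   per-bin vectors), `breaks`, `by_distance`.
#' @export
immigrant_ibd_table <- function(pairs, ibd_field = "ibd_auto_unbiased",
                                breaks = NULL, by_distance = FALSE) {
  pairs <- data.table::as.data.table(pairs)
  y <- pairs[[ibd_field]]
  mm <- pairs$imm_class == "immigrant-immigrant" & is.finite(y)
  mr <- pairs$imm_class == "immigrant-resident" & is.finite(y)
  if (!any(mm)) stop("no immigrant-immigrant pairs")
  if (!any(mr)) stop("no immigrant-resident pairs")
  if (!by_distance)
    return(structure(list(Zm = mean(y[mm]), Zr = mean(y[mr]),
                          breaks = NULL, by_distance = FALSE),
                     class = "jay_immibd"))
  if (is.null(breaks))
    breaks <- unique(stats::quantile(pairs$dist_m, probs = seq(0, 1, length.out = 16L),
                                     names = FALSE))
  bin <- pmin(pmax(findInterval(pairs$dist_m, breaks, rightmost.closed = TRUE), 1L),
              length(breaks) - 1L)
  nb <- length(breaks) - 1L
  bmean <- function(sel) {
    v <- vapply(seq_len(nb), function(k) {
      s <- sel & bin == k
      if (any(s)) mean(y[s]) else NA_real_
    }, numeric(1))
    # carry the overall mean into empty bins
    v[!is.finite(v)] <- mean(y[sel])
    v
  }
  structure(list(Zm = bmean(mm), Zr = bmean(mr), breaks = breaks,
                 by_distance = TRUE),
            class = "jay_immibd")
}

.lookup_imm <- function(im, d) {
  if (!im$by_distance) return(list(Zm = rep(im$Zm, length(d)),
                                   Zr = rep(im$Zr, length(d))))
  bin <- pmin(pmax(findInterval(d, im$breaks, rightmost.closed = TRUE), 1L),
              length(im$breaks) - 1L)
  list(Zm = im$Zm[bin], Zr = im$Zr[bin])
}

#' Parameters for the pedigree-based spatial coalescent
#'
#' Bundles everything the backward simulation needs, resolved per model
#' level:
#' \describe{
#'   \item{M0}{sex-averaged dispersal, sex-averaged pair-class table,
#'     scalar immigration, scalar immigrant IBD.}
#'   \item{M1}{M0 + sex-specific dispersal.}
#'   \item{M2}{M1 + sex-specific pair-class (coalescent) probabilities.}
#'   \item{M3}{M2 + sex-specific immigration rates.}
#'   \item{M4}{M3 + distance-conditional immigrant IBD.}
#' }
#'
#' @param model_level `"M0"` .. `"M4"`.
#' @param curves `jay_curves`; for M0 the two sexes' draws are pooled by
#'   the simulation (sex-averaged dispersal).
#' @param class_probs sex-averaged `jay_classprobs` (M0-M1).
#' @param class_probs_sex sex-specific `jay_classprobs` (M2+).
#' @param M_male,M_female immigration probabilities (defaults 0.197 and
#'   0.345, the study values); M0-M2 use their mean.
#' @param imm_ibd scalar `jay_immibd` (M0-M3).
#' @param imm_ibd_dist distance-conditional `jay_immibd` (M4).
#' @param e_ibd named list of expected IBD values. For the autosomes a
#'   list `list(Zp=, Zf=, Zh=)`; for sex-specific use (M2+ or Z), each
#'   element a named vector over `c(MM, MF, FF)`. Default: autosomal
#'   values from [expected_relationship_ibd()].
#' @param chrom `"autosomal"` or `"z"` (controls the default `e_ibd`).
#' @param G generation cap (default 10).
#' @return list of class `jay_coalparams`.
#' @export
coalescent_params <- function(model_level = c("M4", "M3", "M2", "M1", "M0"),
                              curves,
                              class_probs = NULL, class_probs_sex = NULL,
                              M_male = 0.197, M_female = 0.345,
                              imm_ibd = NULL, imm_ibd_dist = NULL,
                              e_ibd = NULL,
                              chrom = c("autosomal", "z"),
                              G = 10L) {
  model_level <- match.arg(model_level)
  chrom <- match.arg(chrom)
  lvl <- as.integer(substr(model_level, 2, 2))
  stopifnot(G >= 1L, M_male >= 0, M_male <= 1, M_female >= 0, M_female <= 1)
  if (is.null(e_ibd)) {
    combos <- c("MM", "MF", "FF")
    e_ibd <- list(
      Zp = vapply(combos, function(s) expected_relationship_ibd(chrom, "PO", s), numeric(1)),
      Zf = vapply(combos, function(s) expected_relationship_ibd(chrom, "FS", s), numeric(1)),
      Zh = vapply(combos, function(s) expected_relationship_ibd(chrom, "HS", s), numeric(1)))
  } else {
    e_ibd <- lapply(e_ibd, function(v)
      if (length(v) == 1L) stats::setNames(rep(v, 3), c("MM", "MF", "FF")) else v)
  }
  if (lvl >= 2 && is.null(class_probs_sex))
    stop("model ", model_level, " needs a sex-specific pair-class table")
  if (lvl < 2 && is.null(class_probs))
    stop("model ", model_level, " needs a sex-averaged pair-class table")
  if (lvl >= 4 && is.null(imm_ibd_dist))
    stop("model M4 needs distance-conditional immigrant IBD")
  if (lvl < 4 && is.null(imm_ibd))
    stop("models M0-M3 need scalar immigrant IBD")
  # diagnostic: the printed bracket can exceed 1 when M is large
  cp <- if (lvl >= 2) class_probs_sex else class_probs
  Mbar <- if (lvl >= 3) max(M_male, M_female) else mean(c(M_male, M_female))
  tot <- cp$table$Pp + cp$table$Pf + cp$table$Ph + 2 * Mbar * (1 - Mbar) + Mbar^2
  if (any(tot > 1, na.rm = TRUE))
    warning("Pp+Pf+Ph+2M(1-M)+M^2 exceeds 1 in some bins; the additive ",
            "bracket is evaluated as printed")
  structure(list(model_level = model_level, level = lvl, curves = curves,
                 class_probs = class_probs, class_probs_sex = class_probs_sex,
                 M_male = M_male, M_female = M_female,
                 imm_ibd = imm_ibd, imm_ibd_dist = imm_ibd_dist,
                 e_ibd = e_ibd, chrom = chrom, G = as.integer(G)),
            class = "jay_coalparams")
}

# draw one dispersal displacement for each of n lineages of given sexes;
# M0 pools the sexes (sex-averaged curve = fair mixture of the two curves)
.coal_draw <- function(n, sexes, params) {
  if (params$level == 0L)
    sexes <- ifelse(stats::runif(n) < 0.5, "M", "F")
  d <- numeric(n)
  m <- sexes == "M"
  if (any(m))  d[m]  <- draw_dispersal(sum(m), params$curves$male)
  if (any(!m)) d[!m] <- draw_dispersal(sum(!m), params$curves$female)
  a <- stats::runif(n, 0, 2 * pi)
  cbind(d * cos(a), d * sin(a))
}

#' Expected pair IBD from the backward spatial coalescent
#'
#' Simulates `n` replicate lineage-pair distance trajectories d_1..d_G
#' backward in time from a present-day separation `d0` and evaluates
#'
#'   Z-hat = sum_g [ prod_{k<g} (1-M_a)(1-M_b)(1 - Pp(d_k) - Pf(d_k) -
#'           Ph(d_k)) ] x [ Pp(d_g)E(Zp) + Pf(d_g)E(Zf) + Ph(d_g)E(Zh) +
#'           (M_a(1-M_b)+M_b(1-M_a))E(Zr) + M_a M_b E(Zm) ]
#'
#' where d_1 is the distance after the first backward dispersal step. The
#' first step uses the focal sexes' dispersal curves; afterwards ancestor
#' sexes are randomized every generation. Immigration terms are
#' sex-specific for M3+ ((1-M)^2 and 2M(1-M) otherwise), pair-class
#' probabilities are sex-specific for M2+, and immigrant IBD is
#' distance-conditional for M4.
#'
#' @param d0 present-day pair distance(s) (m); a vector gives one
#'   replicate per element.
#' @param sexes two-letter focal sex combination (`"MM"`, `"MF"`, `"FF"`).
#' @param params a `jay_coalparams`.
#' @param n number of replicates (default `length(d0)`; `d0` is recycled).
#' @return numeric vector of n Z-hat values (one per replicate).
#' @export
expected_pair_ibd <- function(d0, sexes = "MM", params, n = length(d0)) {
  stopifnot(inherits(params, "jay_coalparams"))
  sx <- strsplit(sexes, "")[[1L]]
  stopifnot(length(sx) == 2L, all(sx %in% c("M", "F")))
  lvl <- params$level
  pa <- matrix(0, n, 2L)
  pb <- cbind(rep_len(d0, n), 0)
  sa <- rep(sx[1L], n); sb <- rep(sx[2L], n)
  zhat <- numeric(n)
  surv <- rep(1, n)
  Mfor <- function(s) ifelse(s == "M", params$M_male, params$M_female)
  for (g in seq_len(params$G)) {
    pa <- pa + .coal_draw(n, sa, params)
    pb <- pb + .coal_draw(n, sb, params)
    dg <- sqrt(rowSums((pa - pb)^2))
    combo <- paste0(pmin(sa, sb), pmax(sa, sb))
    combo <- c(FF = "FF", FM = "MF", MM = "MM")[combo]
    cp <- if (lvl >= 2) params$class_probs_sex else params$class_probs
    pr <- .lookup_probs(cp, dg, if (cp$sex_specific) combo else NULL)
    if (lvl >= 3) { Ma <- Mfor(sa); Mb <- Mfor(sb) }
    else Ma <- Mb <- rep(mean(c(params$M_male, params$M_female)), n)
    im <- .lookup_imm(if (lvl >= 4) params$imm_ibd_dist else params$imm_ibd, dg)
    Ez <- params$e_ibd
    bracket <- pr$Pp * Ez$Zp[combo] + pr$Pf * Ez$Zf[combo] +
      pr$Ph * Ez$Zh[combo] +
      (Ma * (1 - Mb) + Mb * (1 - Ma)) * im$Zr + Ma * Mb * im$Zm
    zhat <- zhat + surv * unname(bracket)
    surv <- surv * (1 - Ma) * (1 - Mb) * (1 - pr$Pp - pr$Pf - pr$Ph)
    # ancestor sexes randomized after the first backward step
    sa <- ifelse(stats::runif(n) < 0.5, "M", "F")
    sb <- ifelse(stats::runif(n) < 0.5, "M", "F")
  }
  zhat
}

#' Predicted IBD-by-distance curve
#'
#' Bins observed pair distances into `n_bins` quantiles and, for each bin
#' and requested sex combination, runs `n_sims_per_bin` replicates of
#' [expected_pair_ibd()] initialized at distances resampled from the
#' observed distances in that bin; returns per-bin mean Z-hat.
#'
#' @param params a `jay_coalparams`.
#' @param pairs observed pair records (`dist_m`, `sex_a`, `sex_b`).
#' @param sexes sex combination to predict (`"MM"`, `"MF"`, `"FF"`);
#'   pairs are filtered to it for the bin construction.
#' @param n_sims_per_bin simulation replicates per bin (default 1000).
#' @param n_bins distance quantile bins (default 15).
#' @param seed integer seed.
#' @return data.frame `bin`, `dist_mid`, `n_obs`, `zhat`.
#' @export
predict_ibd_curve <- function(params, pairs, sexes = "MM",
                              n_sims_per_bin = 1000L, n_bins = 15L,
                              seed = 1L) {
  pairs <- data.table::as.data.table(pairs)
  combo <- paste0(pmin(pairs$sex_a, pairs$sex_b), pmax(pairs$sex_a, pairs$sex_b))
  combo <- c(FF = "FF", FM = "MF", MM = "MM")[combo]
  d <- pairs$dist_m[combo == sexes]
  if (!length(d)) stop("no observed pairs of sex combination ", sexes)
  qs <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE))
  if (length(qs) - 1L < n_bins)
    warning("tied distances: fewer than ", n_bins, " distinct bins")
  bin <- cut(d, qs, include.lowest = TRUE, labels = FALSE)
  set.seed(seed)
  res <- lapply(sort(unique(bin)), function(k) {
    dk <- d[bin == k]
    d0 <- sample(dk, n_sims_per_bin, replace = TRUE)
    z <- expected_pair_ibd(d0, sexes, params, n = n_sims_per_bin)
    data.frame(bin = k, dist_mid = stats::median(dk), n_obs = length(dk),
               zhat = mean(z))
  })
  do.call(rbind, res)
}

#' Coefficient of determination of a predicted curve
#'
#' R^2 = 1 - sum (y_i - Zhat_i)^2 / sum (y_i - mean(y))^2 over distance
#' bins; can be negative when the model fits worse than the mean.
#'
#' @param observed per-bin observed mean IBD values y_i.
#' @param predicted per-bin predicted mean Z-hat_i.
#' @return scalar R^2 (<= 1).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed bin means are constant; R^2 undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit a coalescent model to observed pairs and report R^2
#'
#' Convenience wrapper: estimates all tables from `train_pairs`, builds
#' [coalescent_params()] at the requested level, predicts the curve for
#' each sex combination over `test_pairs` and reports R^2 against the
#' observed binned means.
#'
#' @param train_pairs pair records used to estimate Pp/Pf/Ph and
#'   immigrant IBD tables.
#' @param test_pairs pair records used for bin construction and observed
#'   means (defaults to `train_pairs`).
#' @param curves `jay_curves`.
#' @param model_level `"M0"`..`"M4"`.
#' @param ibd_field IBD column for observed means and immigrant tables.
#' @param sexes sex combinations to evaluate.
#' @param chrom `"autosomal"` or `"z"`.
#' @param M_male,M_female immigration rates.
#' @param n_sims_per_bin,n_bins,G,seed simulation controls.
#' @return list with `r2` (named by sex combination), `curves` (per-combo
#'   data.frames with observed and predicted bin means), `params`.
#' @export
fit_coalescent_model <- function(train_pairs, test_pairs = NULL, curves,
                                 model_level = "M4",
                                 ibd_field = "ibd_auto_unbiased",
                                 sexes = c("MM", "MF", "FF"),
                                 chrom = "autosomal",
                                 M_male = 0.197, M_female = 0.345,
                                 n_sims_per_bin = 1000L, n_bins = 15L,
                                 G = 10L, seed = 1L) {
  if (is.null(test_pairs)) test_pairs <- train_pairs
  cp_avg <- estimate_pair_class_probs(train_pairs, sex_specific = FALSE)
  cp_sex <- estimate_pair_class_probs(train_pairs, sex_specific = TRUE)
  im <- immigrant_ibd_table(train_pairs, ibd_field, by_distance = FALSE)
  imd <- immigrant_ibd_table(train_pairs, ibd_field, by_distance = TRUE)
  params <- coalescent_params(model_level, curves,
                              class_probs = cp_avg, class_probs_sex = cp_sex,
                              M_male = M_male, M_female = M_female,
                              imm_ibd = im, imm_ibd_dist = imd,
                              chrom = chrom, G = G)
  test_pairs <- data.table::as.data.table(test_pairs)
  combo <- paste0(pmin(test_pairs$sex_a, test_pairs$sex_b),
                  pmax(test_pairs$sex_a, test_pairs$sex_b))
  test_pairs[, sex_combo := c(FF = "FF", FM = "MF", MM = "MM")[combo]]
  out_curves <- list(); r2 <- c()
  for (s in sexes) {
    sub <- test_pairs[sex_combo == s]
    pred <- predict_ibd_curve(params, sub, s, n_sims_per_bin, n_bins,
                              seed = seed + match(s, sexes))
    obs <- binned_means(sub, ibd_field, n_bins = max(2L, nrow(pred)))
    k <- min(nrow(pred), nrow(obs))
    cmp <- data.frame(bin = seq_len(k),
                      dist_mid = obs$dist_mid[seq_len(k)],
                      observed = obs$mean[seq_len(k)],
                      predicted = pred$zhat[seq_len(k)])
    out_curves[[s]] <- cmp
    r2[s] <- r_squared(cmp$observed, cmp$predicted)
  }
  list(r2 = r2, curves = out_curves, params = params)
}

#' k-fold cross-validation of a coalescent model
#'
#' Splits pairs into `k` folds; estimates all tables on the training
#' folds and evaluates R^2 on the held-out fold; reports per-fold and
#' mean R^2 per sex combination.
#'
#' @inheritParams fit_coalescent_model
#' @param pairs full pair table.
#' @param k number of folds (default 2, the study design).
#' @param seed integer seed (controls fold assignment and simulations).
#' @return list with `fold_r2` (matrix folds x sex combos) and `mean_r2`.
#' @export
cross_validate <- function(pairs, curves, model_level = "M4",
                           ibd_field = "ibd_auto_unbiased",
                           sexes = c("MM", "MF", "FF"), chrom = "autosomal",
                           M_male = 0.197, M_female = 0.345,
                           n_sims_per_bin = 500L, n_bins = 15L, G = 10L,
                           k = 2L, seed = 1L) {
  stopifnot(k >= 2L)
  pairs <- data.table::as.data.table(pairs)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), nrow(pairs)))
  res <- list()
  for (f in seq_len(k)) {
    fit <- try(fit_coalescent_model(
      pairs[fold != f], pairs[fold == f], curves, model_level, ibd_field,
      sexes, chrom, M_male, M_female, n_sims_per_bin, n_bins, G,
      seed = seed * 100L + f), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("fold ", f, " skipped: ", attr(fit, "condition")$message)
      next
    }
    res[[length(res) + 1L]] <- fit$r2
  }
  if (!length(res)) stop("all folds failed")
  m <- do.call(rbind, res)
  list(fold_r2 = m, mean_r2 = colMeans(m))
}

utils::globalVariables(c("bin", "sex_combo", "Pp", "Pf", "Ph", ".N"))
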