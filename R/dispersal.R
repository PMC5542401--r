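#' Sex-specific dispersal curves
#'
#' Wraps the two per-sex sampling distributions used by the forward
#' dispersal and coalescent simulations. Each element may be an empirical
#' vector of observed distances (drawn uniformly with replacement), a
#' parametric kernel list (see [default_dispersal_kernels()]) or a single
#' number (point mass).
#'
#' @param male,female per-sex distributions.
#' @return list of class `jay_curves`.
#' @export
dispersal_curves <- function(male, female) {
  chk <- function(x, nm) {
    if (is.numeric(x)) {
      if (any(x < 0)) stop(nm, " distances must be non-negative")
      if (length(x) > 1L && length(x) < 30L)
        warning(nm, " empirical curve has fewer than 30 observations")
    } else if (!is.list(x)) stop(nm, " must be numeric or a kernel list")
    x
  }
  structure(list(male = chk(male, "male"), female = chk(female, "female")),
            class = "jay_curves")
}

# events for each lineage of a relationship plan; each event is tagged
# with how its sex is decided: "A"/"B" = focal individual's fixed sex,
# "anc" = shared-ancestor-generation individual (fixed in the
# fixed-ancestor variant, random otherwise), "rand" = always random.
.plan_events <- function(relationship) {
  switch(relationship,
    FS = list(a = c("A"), b = c("B")),
    N1 = list(a = c("A"), b = c("rand", "B")),
    C1 = list(a = c("anc", "A"), b = c("anc", "B")),
    C2 = list(a = c("rand", "rand", "A"), b = c("rand", "rand", "B")),
    stop("unknown relationship code: ", relationship))
}

#' Lineage plan for a dispersal simulation
#'
#' Describes the dispersal events separating two focal relatives: FS has
#' 2 events, N1 3, C1 4, C2 6. Sexes of the focal pair are fixed;
#' intermediate ancestors are randomized unless `ancestor_sexes` fixes the
#' shared-ancestor generation (first-cousin fixed-sex variant).
#'
#' @param relationship `"FS"`, `"N1"`, `"C1"` or `"C2"`.
#' @param focal_sexes two-letter string, e.g. `"MM"`, `"MF"`, `"FF"`.
#' @param ancestor_sexes optional two-letter string fixing the sexes of
#'   the two ancestral siblings (C1 only).
#' @return list of class `jay_plan` with `relationship`, `events`
#'   (per-lineage sex tags), `n_events`, `n_female_fixed`.
#' @export
lineage_plan <- function(relationship, focal_sexes = "MM",
                         ancestor_sexes = NULL) {
  ev <- .plan_events(relationship)
  fs <- strsplit(focal_sexes, "")[[1L]]
  stopifnot(length(fs) == 2L, all(fs %in% c("M", "F")))
  if (!is.null(ancestor_sexes)) {
    if (relationship != "C1")
      stop("fixed ancestor sexes are only defined for first cousins")
    as_ <- strsplit(ancestor_sexes, "")[[1L]]
    stopifnot(length(as_) == 2L, all(as_ %in% c("M", "F")))
  } else as_ <- NULL
  tag_sex <- function(tags, focal, anc) {
    vapply(tags, function(t) switch(t,
      A = fs[1L], B = fs[2L],
      anc = if (is.null(anc)) "rand" else anc,
      rand = "rand"), character(1))
  }
  events <- list(a = tag_sex(ev$a, fs[1L], as_[1L]),
                 b = tag_sex(ev$b, fs[2L], as_[2L]))
  nf <- sum(unlist(events) == "F")
  structure(list(relationship = relationship, events = events,
                 n_events = length(ev$a) + length(ev$b),
                 focal_sexes = focal_sexes, ancestor_sexes = ancestor_sexes,
                 n_female_fixed = nf),
            class = "jay_plan")
}

#' Simulate the geographic distance between two relatives
#'
#' Places the shared ancestral nest at the origin of an unbounded plane
#' and applies each lineage's dispersal events: each event displaces the
#' lineage by a distance drawn from the event-sex curve and a uniform
#' angle. Events tagged random draw their sex by a fair coin. Returns the
#' Euclidean distance between the two focal endpoints.
#'
#' @param plan a `jay_plan`.
#' @param curves a `jay_curves`.
#' @param n number of independent replicates (default 1).
#' @return numeric vector of distances (m).
#' @export
simulate_pair_distance <- function(plan, curves, n = 1L) {
  stopifnot(inherits(plan, "jay_plan"), inherits(curves, "jay_curves"))
  endpoint <- function(tags) {
    x <- y <- numeric(n)
    for (t in tags) {
      sex <- if (t == "rand")
        ifelse(stats::runif(n) < 0.5, "M", "F") else rep(t, n)
      d <- numeric(n)
      m <- sex == "M"
      if (any(m))  d[m]  <- draw_dispersal(sum(m), curves$male)
      if (any(!m)) d[!m] <- draw_dispersal(sum(!m), curves$female)
      a <- stats::runif(n, 0, 2 * pi)
      x <- x + d * cos(a); y <- y + d * sin(a)
    }
    cbind(x, y)
  }
  ea <- endpoint(plan$events$a)
  eb <- endpoint(plan$events$b)
  sqrt((ea[, 1L] - eb[, 1L])^2 + (ea[, 2L] - eb[, 2L])^2)
}

#' Distribution of simulated distances for a relationship
#'
#' @inheritParams simulate_pair_distance
#' @param n_reps replicates (default 10000, as in the study design).
#' @param seed integer seed.
#' @return object of class `jay_simdist`: list with `distances`, `plan`,
#'   `median`, `se_median` (bootstrap SE of the median), and a
#'   `far_relative_caveat` flag for plans with 6+ events (unbounded-plane
#'   assumption weakest there).
#' @export
simulate_distance_distribution <- function(plan, curves, n_reps = 10000L,
                                           seed = 1L) {
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  d <- simulate_pair_distance(plan, curves, n = n_reps)
  med <- stats::median(d)
  bse <- stats::sd(vapply(seq_len(200L), function(i)
    stats::median(sample(d, length(d), replace = TRUE)), numeric(1)))
  structure(list(distances = d, plan = plan, median = med, se_median = bse,
                 far_relative_caveat = plan$n_events >= 6L),
            class = "jay_simdist")
}

#' Compare simulated and observed distance distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the full distributions and
#' Wilcoxon rank-sum test on the central tendency, with a Bonferroni
#' significance threshold of 0.05 / `n_tests`.
#'
#' @param simulated,observed numeric distance vectors.
#' @param n_tests number of tests in the correction family (default 1).
#' @return data.frame with KS and Wilcoxon statistics, p-values,
#'   the Bonferroni threshold, significance flags, and a `low_power` flag
#'   when the observed sample has fewer than 5 values.
#' @export
compare_distributions <- function(simulated, observed, n_tests = 1L) {
  if (!length(simulated) || !length(observed)) stop("empty sample")
  ks <- suppressWarnings(stats::ks.test(observed, simulated))
  wt <- suppressWarnings(stats::wilcox.test(observed, simulated))
  thr <- 0.05 / n_tests
  data.frame(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
             wrs_stat = unname(wt$statistic), wrs_p = wt$p.value,
             bonferroni_threshold = thr,
             ks_significant = ks$p.value < thr,
             wrs_significant = wt$p.value < thr,
             low_power = length(observed) < 5L)
}

#' Fixed-ancestor-sex first-cousin simulation grid
#'
#' Runs the 9 sex plans (focal MM/MF/FF x ancestors MM/MF/FF) of the
#' fixed-sex first-cousin design and reports, per plan, the number of
#' female dispersal events, the median simulated distance and its
#' bootstrap SE, plus the Spearman rank correlation between female-event
#' count and median distance across plans.
#'
#' @param curves a `jay_curves`.
#' @param n_reps replicates per plan (default 10000).
#' @param seed integer seed.
#' @return list with `table` (9-row data.frame) and `spearman`
#'   (`rho`, `p_value`).
#' @export
cousin_sex_grid <- function(curves, n_reps = 10000L, seed = 1L) {
  combos <- expand.grid(focal = c("MM", "MF", "FF"),
                        anc = c("MM", "MF", "FF"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pl <- lineage_plan("C1", combos$focal[i], combos$anc[i])
    sd_ <- simulate_distance_distribution(pl, curves, n_reps,
                                          seed = seed + i)
    data.frame(focal = combos$focal[i], ancestors = combos$anc[i],
               n_female_events = pl$n_female_fixed,
               median_m = sd_$median, se_median_m = sd_$se_median)
  })
  tab <- do.call(rbind, rows)
  ct <- suppressWarnings(stats::cor.test(tab$n_female_events, tab$median_m,
                                         method = "spearman"))
  list(table = tab,
       spearman = list(rho = unname(ct$estimate), p_value = ct$p.value))
}
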