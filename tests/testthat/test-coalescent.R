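# distance-independent parameter helpers
flat_classprobs <- function(p, f, h, sex_specific = FALSE) {
  if (sex_specific) {
    tab <- data.table::CJ(bin = 1L, sex_combo = c("MM", "MF", "FF"))
    tab[, `:=`(n = 1L, Pp = p, Pf = f, Ph = h)]
  } else {
    tab <- data.table::data.table(bin = 1L, n = 1L, Pp = p, Pf = f, Ph = h)
  }
  structure(list(breaks = c(0, 1e12), table = tab,
                 sex_specific = sex_specific), class = "jay_classprobs")
}
flat_imm <- function(zm, zr) {
  structure(list(Zm = zm, Zr = zr, breaks = NULL, by_distance = FALSE),
            class = "jay_immibd")
}

test_that("pair-class probabilities equal hand-counted ratios", {
  pairs <- data.frame(
    dist_m = c(100, 200, 300, 400, 1100, 1200, 1300, 1400, 1500),
    rel    = c("PO", "PO", "FS", NA,   "HS", NA,   NA,   "PO", NA),
    sex_a  = "M", sex_b = "M")
  cp <- estimate_pair_class_probs(pairs, breaks = c(0, 1000, 2000))
  tab <- as.data.frame(cp$table)
  expect_equal(tab$Pp, c(2 / 4, 1 / 5))
  expect_equal(tab$Pf, c(1 / 4, 0))
  expect_equal(tab$Ph, c(0, 1 / 5))
  # beyond-range lookup clamps to the last bin
  lk <- jaykin:::.lookup_probs(cp, c(50, 1500, 99999))
  expect_equal(lk$Pp, c(0.5, 0.2, 0.2))
  # all-unrelated input gives an all-zero table
  none <- estimate_pair_class_probs(
    data.frame(dist_m = runif(50, 0, 100), rel = NA, sex_a = "M", sex_b = "F"),
    breaks = c(0, 100))
  expect_true(all(none$table$Pp == 0 & none$table$Pf == 0 & none$table$Ph == 0))
})

test_that("sex-specific class probabilities condition on the pair sexes", {
  pairs <- data.frame(
    dist_m = c(rep(100, 4), rep(100, 2)),
    rel = c("PO", "PO", NA, NA, "FS", NA),
    sex_a = c("M", "M", "M", "M", "F", "F"),
    sex_b = c("M", "M", "M", "M", "F", "F"))
  expect_warning(
    cp <- estimate_pair_class_probs(pairs, breaks = c(0, 1000), sex_specific = TRUE),
    "zero pairs")   # the MF cell is empty by construction
  tab <- as.data.frame(cp$table)
  expect_equal(tab$Pp[tab$sex_combo == "MM"], 0.5)
  expect_equal(tab$Pf[tab$sex_combo == "FF"], 0.5)
  expect_equal(tab$Pp[tab$sex_combo == "FF"], 0)
})

test_that("immigrant IBD tables reproduce planted values", {
  set.seed(3)
  n <- 600
  d <- runif(n, 0, 5000)
  cls <- sample(c("resident-resident", "immigrant-resident",
                  "immigrant-immigrant"), n, replace = TRUE)
  ibd <- ifelse(cls == "immigrant-immigrant", 0.1,
                ifelse(cls == "immigrant-resident", 0.05, 0)) +
    rnorm(n, 0, 0.001)
  pairs <- data.frame(dist_m = d, imm_class = cls, ibd_auto_unbiased = ibd)
  sc <- immigrant_ibd_table(pairs)
  expect_equal(sc$Zm, 0.1, tolerance = 0.005)
  expect_equal(sc$Zr, 0.05, tolerance = 0.005)
  # by-distance variant reproduces a planted gradient
  ibd2 <- ifelse(cls == "immigrant-immigrant", d * 1e-5, 0.02)
  pairs2 <- data.frame(dist_m = d, imm_class = cls, ibd_auto_unbiased = ibd2)
  bd <- immigrant_ibd_table(pairs2, breaks = seq(0, 5000, 1000),
                            by_distance = TRUE)
  expect_equal(length(bd$Zm), 5)
  expect_true(all(diff(bd$Zm) > 0))
  expect_error(immigrant_ibd_table(
    data.frame(dist_m = 1, imm_class = "resident-resident",
               ibd_auto_unbiased = 0)), "immigrant")
})

test_that("Z-hat reduces to trivial limits", {
  cur <- dispersal_curves(100, 100)
  # no coalescence, no immigration
  p0 <- coalescent_params("M0", cur, class_probs = flat_classprobs(0, 0, 0),
                          M_male = 0, M_female = 0, imm_ibd = flat_imm(0, 0))
  expect_equal(expected_pair_ibd(500, "MM", p0, n = 3), rep(0, 3))
  # certain immediate coalescence into parent-offspring
  p1 <- coalescent_params("M0", cur, class_probs = flat_classprobs(1, 0, 0),
                          M_male = 0, M_female = 0, imm_ibd = flat_imm(0, 0))
  expect_equal(expected_pair_ibd(500, "MM", p1, n = 3), rep(0.5, 3))
})

test_that("Z-hat matches the geometric-series closed form", {
  p <- 0.02; f <- 0.015; h <- 0.01; M <- 0.12; G <- 10
  cur <- dispersal_curves(200, 400)
  pars <- coalescent_params("M0", cur, class_probs = flat_classprobs(p, f, h),
                            M_male = M, M_female = M,
                            imm_ibd = flat_imm(0.02, 0.008), G = G)
  bracket <- p * 0.5 + f * 0.5 + h * 0.25 +
    2 * M * (1 - M) * 0.008 + M^2 * 0.02
  ratio <- (1 - M)^2 * (1 - p - f - h)
  closed <- bracket * sum(ratio^(0:(G - 1)))
  z <- expected_pair_ibd(1234, "MF", pars, n = 5)
  expect_lt(max(abs(z - closed)), 1e-10)
  # flat prediction curve in the distance-independent regime
  pred <- predict_ibd_curve(pars,
                            data.frame(dist_m = runif(500, 0, 5000),
                                       sex_a = "M", sex_b = "M"),
                            "MM", n_sims_per_bin = 20, n_bins = 5, seed = 2)
  expect_lt(max(abs(pred$zhat - closed)), 1e-10)
})

test_that("generation cap beyond 10 has negligible effect", {
  # magnitudes in the realistic regime: ~27% immigration, percent-level
  # close-kin probabilities at short range
  p <- 0.01; M <- 0.27
  cur <- dispersal_curves(300, 700)
  mk <- function(G) coalescent_params("M0", cur,
    class_probs = flat_classprobs(p, 0.005, 0.005), M_male = M, M_female = M,
    imm_ibd = flat_imm(0.01, 0.003), G = G)
  z10 <- expected_pair_ibd(800, "MM", mk(10L), n = 1)
  z20 <- expected_pair_ibd(800, "MM", mk(20L), n = 1)
  expect_lt(abs(z10 - z20), 1e-4)
})

test_that("Z-hat declines with initial distance for decreasing tables", {
  # step-function probabilities decreasing in distance, constant immigrants
  tab <- data.table::data.table(bin = 1:4, n = 1L,
                                Pp = c(0.2, 0.08, 0.02, 0.005),
                                Pf = c(0.1, 0.04, 0.01, 0),
                                Ph = c(0.1, 0.04, 0.01, 0))
  cp <- structure(list(breaks = c(0, 500, 1500, 3000, 1e9), table = tab,
                       sex_specific = FALSE), class = "jay_classprobs")
  cur <- dispersal_curves(300, 600)
  pars <- coalescent_params("M0", cur, class_probs = cp,
                            M_male = 0.2, M_female = 0.2,
                            imm_ibd = flat_imm(0.01, 0.004))
  set.seed(6)
  means <- vapply(c(0, 1000, 2500, 6000), function(d0)
    mean(expected_pair_ibd(d0, "MM", pars, n = 4000)), numeric(1))
  expect_true(all(diff(means) < 0.002))       # non-increasing within MC noise
  expect_gt(means[1], means[4])
})

test_that("sex-specific parameters are honoured by the model ladder", {
  cur <- dispersal_curves(100, 2000)
  cps <- flat_classprobs(0.05, 0.02, 0.02, sex_specific = TRUE)
  # missing sex-specific table is a configuration error
  expect_error(coalescent_params("M2", cur, class_probs = flat_classprobs(0.05, 0.02, 0.02),
                                 imm_ibd = flat_imm(0, 0)), "sex-specific")
  # M3 uses per-sex immigration: with female-only immigration, FF pairs
  # truncate faster than MM pairs
  pars <- coalescent_params("M3", cur, class_probs_sex = cps,
                            M_male = 0, M_female = 0.6,
                            imm_ibd = flat_imm(0, 0))
  set.seed(2)
  zmm <- mean(expected_pair_ibd(500, "MM", pars, n = 800))
  zff <- mean(expected_pair_ibd(500, "FF", pars, n = 800))
  expect_gt(zmm, zff)
})

test_that("elevated immigrant IBD on the Z raises predicted values", {
  cur <- dispersal_curves(300, 700)
  base <- list(class_probs = flat_classprobs(0.03, 0.02, 0.02),
               M_male = 0.2, M_female = 0.2)
  pa <- coalescent_params("M0", cur, class_probs = base$class_probs,
                          M_male = 0.2, M_female = 0.2,
                          imm_ibd = flat_imm(0.003, 0.001), chrom = "autosomal")
  pz <- coalescent_params("M0", cur, class_probs = base$class_probs,
                          M_male = 0.2, M_female = 0.2,
                          imm_ibd = flat_imm(0.03, 0.015), chrom = "z")
  set.seed(9)
  za <- mean(expected_pair_ibd(1000, "MM", pa, n = 1500))
  zz <- mean(expected_pair_ibd(1000, "MM", pz, n = 1500))
  expect_gt(zz, za)
})

test_that("r_squared matches hand-computed cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(2, 4, 6)), -6)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("cross-validation is deterministic and consistent on duplicates", {
  pt <- fixture_pairs()
  st <- fixture_study()
  curves <- dispersal_curves(st$dispersal$distance_m[st$dispersal$sex == "M"],
                             st$dispersal$distance_m[st$dispersal$sex == "F"])
  dup <- rbind(pt, pt)
  cv <- cross_validate(dup, curves, model_level = "M2", k = 2,
                       n_sims_per_bin = 150, n_bins = 8, seed = 31)
  full <- fit_coalescent_model(pt, NULL, curves, "M2",
                               n_sims_per_bin = 150, n_bins = 8, seed = 31)
  expect_equal(unname(cv$mean_r2["MM"]), unname(full$r2["MM"]),
               tolerance = 0.25)
  cv2 <- cross_validate(dup, curves, model_level = "M2", k = 2,
                        n_sims_per_bin = 150, n_bins = 8, seed = 31)
  expect_identical(cv$fold_r2, cv2$fold_r2)
})
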