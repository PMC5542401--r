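make_founder_geno <- function(n, L, p = NULL, seed = 1, sexes = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(L, 0.1, 0.9)
  G <- matrix(rbinom(n * L, 2L, rep(p, each = n)), n, L)
  rownames(G) <- sprintf("i%03d", seq_len(n))
  colnames(G) <- sprintf("l%04d", seq_len(L))
  if (is.null(sexes)) sexes <- rep(c("M", "F"), length.out = n)
  structure(G, chrom = rep("autosomal", L),
            sex = stats::setNames(sexes, rownames(G)),
            founder_freq = p, class = c("jay_geno", "matrix", "array"))
}

test_that("autosomal IBD: duplicated individual estimates near 1", {
  G <- make_founder_geno(2, 4000, p = rep(0.5, 4000), seed = 3)
  G[2, ] <- G[1, ]                     # duplicate
  out <- ibd_autosomal(G, freqs = rep(0.5, 4000))
  expect_gt(out$ibd_bounded, 0.98)
  expect_lt(abs(out$ibd_unbiased - 1), 0.05)
})

test_that("autosomal IBD: unrelated founders center on zero", {
  G <- make_founder_geno(40, 2000, seed = 4)
  out <- ibd_autosomal(G, freqs = attr(G, "founder_freq"))
  expect_lt(abs(mean(out$ibd_unbiased)), 0.01)
  expect_true(any(out$ibd_unbiased < 0))      # unbounded variant goes negative
  expect_true(all(out$ibd_bounded >= 0 & out$ibd_bounded <= 1))
})

test_that("autosomal IBD recovers full siblings within 3 SE", {
  st <- fixture_study()
  pt <- fixture_pairs()
  fs <- pt[pt$rel %in% "FS" & is.finite(pt$ibd_auto_unbiased), ]
  se <- sd(fs$ibd_auto_unbiased) / sqrt(nrow(fs))
  expect_lt(abs(mean(fs$ibd_auto_unbiased) - 0.5), 3 * se + 0.01)
})

test_that("bounded and unbiased variants diverge as loci shrink", {
  # on unrelated individuals with known frequencies the gap is pure
  # simplex-truncation noise: small at array scale, large on small panels
  # (the divergence that motivates the unbounded Z treatment)
  ped <- as_pedigree(data.frame(id = sprintf("f%03d", 1:80), sire = NA,
                                dam = NA, sex = rep(c("M", "F"), 40)))
  g <- gene_drop(ped, 8000, "autosomal", rng_seed = 9)
  fr <- attr(g, "founder_freq")
  big <- ibd_autosomal(g, freqs = fr)
  gap_big <- mean(abs(big$ibd_bounded - big$ibd_unbiased))
  expect_lt(gap_big, 0.025)
  few <- ibd_autosomal(g[, seq_len(250)], freqs = fr[seq_len(250)],
                       min_loci = 50)
  gap_few <- mean(abs(few$ibd_bounded - few$ibd_unbiased))
  expect_gt(gap_few, 3 * gap_big)
  # the two variants agree closely for genuinely related pairs
  st <- fixture_study()
  pt <- fixture_pairs()
  close_ <- pt[pt$r_auto >= 0.25 & is.finite(pt$ibd_auto), ]
  expect_lt(mean(abs(close_$ibd_auto - close_$ibd_auto_unbiased)), 0.01)
})

test_that("Z IBD: identical hemizygous females estimate near 1", {
  L <- 2000
  set.seed(9)
  hap <- rbinom(L, 1L, 0.5)
  G <- rbind(hap, hap)
  rownames(G) <- c("f1", "f2"); colnames(G) <- sprintf("z%04d", seq_len(L))
  G <- structure(G, chrom = rep("z", L),
                 sex = c(f1 = "F", f2 = "F"),
                 class = c("jay_geno", "matrix", "array"))
  out <- ibd_z(G, freqs = rep(0.5, L))
  expect_lt(abs(out$ibd_z_unbiased - 1), 0.1)
})

test_that("Z IBD recovers father-son sharing and unrelated pairs", {
  st <- fixture_study()
  pt <- fixture_pairs()
  co <- sex_combo_of(pt)
  fs <- pt[pt$rel %in% "PO" & co == "MM" & is.finite(pt$ibd_z_unbiased), ]
  se <- sd(fs$ibd_z_unbiased) / sqrt(nrow(fs))
  expect_lt(abs(mean(fs$ibd_z_unbiased) - 0.5), 3 * se + 0.02)
  un <- pt[is.na(pt$rel) & pt$r_auto == 0 & is.finite(pt$ibd_z_unbiased), ]
  expect_lt(abs(mean(un$ibd_z_unbiased)), 0.03)
  expect_true(any(un$ibd_z_unbiased < 0))
  # sexes are mandatory
  gz <- st$genotypes_z
  attr(gz, "sex")[] <- "U"
  expect_error(ibd_z(gz), "sexes")
})

test_that("expected relationship IBD matches conventions and the Z oracle", {
  # autosomal values are the classic coefficients, sex-independent
  for (sc in c("MM", "MF", "FF")) {
    expect_equal(expected_relationship_ibd("autosomal", "PO", sc), 0.5)
    expect_equal(expected_relationship_ibd("autosomal", "HS", sc), 0.25)
  }
  # ZW transmission logic: mother-daughter shares no Z
  expect_equal(expected_relationship_ibd("z", "PO", "FF"), 0)
  # MF parent-offspring averages father-daughter and mother-son (both 1)
  expect_equal(expected_relationship_ibd("z", "PO", "MF"), 1)
  # half-sibling averaging vs the exact allele-path enumeration oracle
  P <- function(id, sire, dam, sex)
    data.frame(id = id, sire = sire, dam = dam, sex = sex)
  hsped <- as_pedigree(rbind(
    P("f1", NA, NA, "M"), P("f2", NA, NA, "M"),
    P("m1", NA, NA, "F"), P("m2", NA, NA, "F"),
    P("pa", "f1", "m1", "M"), P("pb", "f1", "m2", "M"),   # paternal HS
    P("ma", "f1", "m1", "M"), P("mb", "f2", "m1", "M")))  # maternal HS
  oracle <- mean(c(z_enum_oracle(hsped, "pa", "pb"),
                   z_enum_oracle(hsped, "ma", "mb")))
  expect_equal(expected_relationship_ibd("z", "HS", "MM"), oracle,
               tolerance = 1e-12)
  expect_equal(expected_relationship_ibd("z", "HS", "MM"), 0.375)
  expect_error(expected_relationship_ibd("z", "C1", "MM"))
})

test_that("pair table r and genomic IBD are strongly correlated", {
  pt <- fixture_pairs()
  ok <- is.finite(pt$ibd_auto_unbiased)
  expect_gt(cor(pt$r_auto[ok], pt$ibd_auto_unbiased[ok]), 0.8)
  # immigrant classes partition all pairs
  expect_true(all(pt$imm_class %in%
    c("resident-resident", "immigrant-resident", "immigrant-immigrant")))
})
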