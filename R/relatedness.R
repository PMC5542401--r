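#' Per-locus alternate allele frequencies
#'
#' Computed from non-missing calls, accounting for ploidy on the Z
#' (females contribute one allele, males two).
#'
#' @param geno a `jay_geno` matrix (alt-allele counts; `NA` = missing).
#' @return numeric vector of alt frequencies per locus.
#' @export
allele_freqs <- function(geno) {
  sex <- attr(geno, "sex")
  chrom <- attr(geno, "chrom")
  ploidy <- matrix(2, nrow(geno), ncol(geno))
  if (!is.null(chrom) && any(chrom == "z") && !is.null(sex))
    ploidy[sex[rownames(geno)] == "F", chrom == "z"] <- 1
  ploidy[is.na(geno)] <- 0
  g0 <- geno; g0[is.na(g0)] <- 0
  colSums(g0) / pmax(colSums(ploidy), 1)
}

#' Genome-wide autosomal identity-by-descent (method of moments)
#'
#' Implements the classic genome-wide pairwise estimator: per-pair counts
#' of loci identical-in-state for 0, 1 or 2 alleles are combined with
#' population allele frequencies to solve for P(IBD=0), P(IBD=1),
#' P(IBD=2); the IBD proportion is pi-hat = P(IBD=1)/2 + P(IBD=2). The
#' `bounded` variant truncates the probabilities to the simplex (so
#' pi-hat is in [0,1]); the `unbiased` variant leaves them untransformed
#' and can be negative.
#'
#' Loci monomorphic in the frequency reference are excluded. Missing
#' genotypes are handled pairwise-complete; pairs with fewer than
#' `min_loci` shared informative loci get `NA`.
#'
#' @param geno autosomal `jay_geno` (values 0/1/2, `NA` missing).
#' @param freqs optional per-locus alt frequencies; default
#'   [allele_freqs()] of `geno`.
#' @param pairs optional data.frame `id_a`, `id_b`; default all unordered
#'   pairs.
#' @param min_loci minimum shared non-missing polymorphic loci (default 50).
#' @return data.table `id_a`, `id_b`, `n_loci`, `ibd_bounded`,
#'   `ibd_unbiased`.
#' @export
ibd_autosomal <- function(geno, freqs = NULL, pairs = NULL, min_loci = 50L) {
  if (is.null(freqs)) freqs <- allele_freqs(geno)
  keep <- freqs > 0 & freqs < 1
  if (!any(keep)) stop("no polymorphic loci")
  G <- unclass(geno)[, keep, drop = FALSE]
  p <- freqs[keep]; q <- 1 - p
  n <- nrow(G)
  if (n < 2L) stop("need at least two individuals")

  A0 <- (G == 0L); A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
  A1 <- (G == 1L); A1[is.na(A1)] <- FALSE; storage.mode(A1) <- "double"
  A2 <- (G == 2L); A2[is.na(A2)] <- FALSE; storage.mode(A2) <- "double"
  M <- (!is.na(G)); storage.mode(M) <- "double"

  N2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  N0 <- A0 %*% t(A2) + A2 %*% t(A0)

  # expected per-locus IBS-class probabilities conditional on IBD state
  w00 <- 2 * p^2 * q^2                      # P(IBS0 | IBD0)
  w10 <- 4 * p^3 * q + 4 * p * q^3          # P(IBS1 | IBD0)
  w20 <- p^4 + q^4 + 4 * p^2 * q^2          # P(IBS2 | IBD0)
  w11 <- 2 * p^2 * q + 2 * p * q^2          # P(IBS1 | IBD1)
  w21 <- p^3 + q^3 + p^2 * q + p * q^2      # P(IBS2 | IBD1)

  Mw <- function(w) M %*% (t(M) * w)        # per-pair sum over shared loci
  S00 <- Mw(w00); S10 <- Mw(w10); S20 <- Mw(w20)
  S11 <- Mw(w11); S21 <- Mw(w21)
  L <- M %*% t(M)
  N1 <- L - N0 - N2

  P0 <- N0 / S00
  P1 <- (N1 - P0 * S10) / S11
  P2 <- (N2 - P0 * S20 - P1 * S21) / L
  pi_u <- P1 / 2 + P2

  # bounded variant: truncate to the simplex, renormalize
  B0 <- pmin(pmax(P0, 0), 1)
  B1 <- pmax(P1, 0)
  B2 <- pmax(P2, 0)
  tot <- B0 + B1 + B2
  pi_b <- ifelse(tot > 0, (B1 / 2 + B2) / tot, 0)
  pi_b <- pmin(pmax(pi_b, 0), 1)

  ids <- rownames(G)
  if (is.null(pairs)) {
    idx <- which(upper.tri(L), arr.ind = TRUE)
  } else {
    a <- match(as.character(pairs$id_a), ids)
    b <- match(as.character(pairs$id_b), ids)
    if (anyNA(a) || anyNA(b)) stop("pair id not in genotype matrix")
    idx <- cbind(a, b)
  }
  out <- data.table::data.table(
    id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
    n_loci = L[idx],
    ibd_bounded = pi_b[idx],
    ibd_unbiased = pi_u[idx])
  sw <- out$id_a > out$id_b
  if (any(sw)) out[sw, `:=`(id_a = id_b, id_b = id_a)]
  low <- out$n_loci < min_loci
  if (any(low)) {
    if (all(low)) stop("no pair has enough shared informative loci")
    out[low, `:=`(ibd_bounded = NA_real_, ibd_unbiased = NA_real_)]
  }
  out[]
}

#' Z-linked identity-by-descent (hemizygous-aware, unbounded)
#'
#' Method-of-moments estimator from allele-count expectations. With
#' per-individual allele dosage fraction y = x / ploidy (ploidy 2 for
#' males, 1 for hemizygous females), E[(y_i - p)(y_j - p)] = phi_ij p q,
#' where phi is the Z kinship coefficient. The estimator
#' theta-hat = sum_l (y_i - p)(y_j - p) / sum_l p q is scaled by 2 for
#' pairs containing a male and by 1 for female-female pairs so its
#' expectation matches the ZW coefficient-of-relationship convention
#' (father-son 0.5; father-daughter and mother-son 1; identical
#' hemizygous females 1). Estimates are deliberately unbounded: bounding
#' at [0,1] would bias the small-panel Z upward.
#'
#' @param geno Z-linked `jay_geno` (males 0/1/2, females 0/1).
#' @param freqs optional alt frequencies (ploidy-weighted sample
#'   frequencies by default).
#' @param pairs optional data.frame `id_a`, `id_b`.
#' @param min_loci minimum shared informative loci (default 25).
#' @return data.table `id_a`, `id_b`, `n_loci`, `ibd_z_unbiased`.
#' @export
ibd_z <- function(geno, freqs = NULL, pairs = NULL, min_loci = 25L) {
  sex <- attr(geno, "sex")[rownames(geno)]
  if (is.null(sex) || any(!sex %in% c("M", "F")))
    stop("Z-linked IBD requires known sexes for all individuals")
  if (ncol(geno) == 0L) stop("no Z-linked loci")
  if (is.null(freqs)) freqs <- allele_freqs(geno)
  keep <- freqs > 0 & freqs < 1
  if (!any(keep)) stop("no polymorphic Z loci")
  G <- unclass(geno)[, keep, drop = FALSE]
  p <- freqs[keep]; q <- 1 - p
  ploidy <- ifelse(sex == "M", 2, 1)
  if (any(G > rep(ploidy, ncol(G)), na.rm = TRUE))
    stop("female Z genotype call of 2 detected")

  Y <- sweep(G, 1L, ploidy, "/")            # dosage fraction
  D <- sweep(Y, 2L, p, "-")                 # centered
  D[is.na(D)] <- 0
  M <- (!is.na(G)); storage.mode(M) <- "double"
  num <- D %*% t(D)
  den <- M %*% (t(M) * (p * q))
  L <- M %*% t(M)
  scale2 <- outer(sex == "F", sex == "F", "&")
  theta <- num / den
  zhat <- ifelse(scale2, theta, 2 * theta)

  ids <- rownames(G)
  if (is.null(pairs)) {
    idx <- which(upper.tri(L), arr.ind = TRUE)
  } else {
    a <- match(as.character(pairs$id_a), ids)
    b <- match(as.character(pairs$id_b), ids)
    if (anyNA(a) || anyNA(b)) stop("pair id not in genotype matrix")
    idx <- cbind(a, b)
  }
  out <- data.table::data.table(
    id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
    n_loci = L[idx], ibd_z_unbiased = zhat[idx])
  sw <- out$id_a > out$id_b
  if (any(sw)) out[sw, `:=`(id_a = id_b, id_b = id_a)]
  out[out$n_loci < min_loci, ibd_z_unbiased := NA_real_]
  out[]
}

## Expected IBD per relationship class -----------------------------------

# canonical non-inbred pedigrees realizing each (relationship, sex combo);
# returns expected IBD from the kinship recursion with the ZW scaling
.canonical_pair <- function(relationship, sex_a, sex_b) {
  P <- function(id, sire, dam, sex)
    data.frame(id = id, sire = sire, dam = dam, sex = sex,
               stringsAsFactors = FALSE)
  base <- rbind(P("gf", NA, NA, "M"), P("gm", NA, NA, "F"),
                P("f1", NA, NA, "M"), P("m1", NA, NA, "F"),
                P("f2", NA, NA, "M"), P("m2", NA, NA, "F"))
  switch(relationship,
    PO = list(ped = rbind(base, P("a", "f1", "m1", sex_a)),
              a = if (sex_b == "M") "f1" else "m1", b = "a",
              parent_first = TRUE),
    FS = list(ped = rbind(base, P("a", "f1", "m1", sex_a),
                          P("b", "f1", "m1", sex_b)), a = "a", b = "b"),
    HS = list(ped = rbind(base, P("a", "f1", "m1", sex_a),
                          P("b", "f1", "m2", sex_b),
                          P("a2", "f1", "m1", sex_a),
                          P("b2", "f2", "m1", sex_b)),
              a = c("a", "a2"), b = c("b", "b2")),   # paternal + maternal HS
    stop("unsupported relationship: ", relationship))
}

#' Expected identity-by-descent for close relationship classes
#'
#' Autosomal expectations equal the expected coefficient of relationship
#' (PO 0.5, FS 0.5, HS 0.25) regardless of sexes. Z-linked expectations
#' are computed from the ZW kinship recursion on canonical pedigrees with
#' two averaging conventions: mixed-sex parent-offspring averages
#' father-daughter and mother-son; half-siblings average the paternal and
#' maternal variants.
#'
#' @param chrom `"autosomal"` or `"z"`.
#' @param relationship `"PO"`, `"FS"` or `"HS"`.
#' @param sex_combo `"MM"`, `"MF"` or `"FF"`.
#' @return expected IBD proportion E(Z).
#' @export
expected_relationship_ibd <- function(chrom = c("autosomal", "z"),
                                      relationship = c("PO", "FS", "HS"),
                                      sex_combo = c("MM", "MF", "FF")) {
  chrom <- match.arg(chrom)
  relationship <- match.arg(relationship)
  sex_combo <- match.arg(sex_combo)
  if (chrom == "autosomal")
    return(c(PO = 0.5, FS = 0.5, HS = 0.25)[[relationship]])
  sx <- c(substr(sex_combo, 1, 1), substr(sex_combo, 2, 2))
  zval <- function(sa, sb) {
    if (relationship == "PO") {
      # parent sex sa, offspring sex sb
      cp <- .canonical_pair("PO", sb, sa)
      K <- kinship_matrix(as_pedigree(cp$ped), "z")
      phi <- K[cp$a, cp$b]
      s <- if (sa == "F" && sb == "F") 1 else 2
      return(s * phi)
    }
    cp <- .canonical_pair(relationship, sa, sb)
    K <- kinship_matrix(as_pedigree(cp$ped), "z")
    phi <- mean(K[cbind(cp$a, cp$b)])
    s <- if (sa == "F" && sb == "F") 1 else 2
    s * phi
  }
  if (relationship == "PO") {
    if (sex_combo == "MM") return(zval("M", "M"))
    if (sex_combo == "FF") return(zval("F", "F"))
    # MF: average father-daughter and mother-son
    return(mean(c(zval("M", "F"), zval("F", "M"))))
  }
  zval(sx[1], sx[2])
}

#' Build the full pairwise record table
#'
#' Joins geographic distance, genomic IBD (autosomal bounded/unbiased and
#' Z-linked unbiased), closest pedigree relationship, pedigree
#' coefficients of relationship (autosomal and Z) and immigrant class for
#' all unordered pairs of the given individuals.
#'
#' @param study a `jay_study` (or a list with `pedigree`,
#'   `genotypes_autosomal`, `genotypes_z`).
#' @param ids individuals to include; default all genotyped individuals.
#' @param max_depth relationship search depth (default 5).
#' @return data.table, one row per unordered pair: `id_a id_b sex_a sex_b
#'   dist_m ibd_auto ibd_auto_unbiased ibd_z_unbiased rel r_auto r_z
#'   imm_class`.
#' @export
build_pair_table <- function(study, ids = NULL, max_depth = 5L) {
  ped <- study$pedigree
  ga <- study$genotypes_autosomal
  gz <- study$genotypes_z
  if (is.null(ids)) ids <- rownames(if (!is.null(ga)) ga else gz)
  ids <- sort(as.character(ids))
  pr <- data.table::CJ(id_a = ids, id_b = ids)[id_a < id_b]

  pi <- match(pr$id_a, ped$id); pj <- match(pr$id_b, ped$id)
  pr[, sex_a := ped$sex[pi]]
  pr[, sex_b := ped$sex[pj]]
  pr[, dist_m := sqrt((ped$breed_x[pi] - ped$breed_x[pj])^2 +
                        (ped$breed_y[pi] - ped$breed_y[pj])^2)]
  n_imm <- ped$immigrant[pi] + ped$immigrant[pj]
  pr[, imm_class := c("resident-resident", "immigrant-resident",
                      "immigrant-immigrant")[n_imm + 1L]]

  if (!is.null(ga)) {
    # frequencies from the full sample of genotyped individuals
    fa <- allele_freqs(ga)
    ia <- ibd_autosomal(ga[ids, ], freqs = fa, pairs = pr)
    pr[, ibd_auto := ia$ibd_bounded]
    pr[, ibd_auto_unbiased := ia$ibd_unbiased]
  }
  if (!is.null(gz)) {
    fz <- allele_freqs(gz)
    iz <- ibd_z(gz[ids, ], freqs = fz, pairs = pr)
    pr[, ibd_z_unbiased := iz$ibd_z_unbiased]
  }
  rel <- closest_relationship(ped, pairs = pr, max_depth = max_depth)
  pr <- merge(pr, rel, by = c("id_a", "id_b"), all.x = TRUE, sort = TRUE)

  Ka <- kinship_matrix(ped, "autosomal", ids = ids)
  pr[, r_auto := 2 * Ka[cbind(id_a, id_b)]]
  if (all(ped$sex[match(ids, ped$id)] %in% c("M", "F"))) {
    Kz <- kinship_matrix(ped, "z", ids = ids)
    pr[, r_z := 2 * Kz[cbind(id_a, id_b)]]
  } else pr[, r_z := NA_real_]
  pr[]
}

utils::globalVariables(c(
  "sex_a", "sex_b", "dist_m", "imm_class", "ibd_auto", "ibd_auto_unbiased",
  "ibd_z_unbiased", "r_auto", "r_z", "n_loci", "rel"))
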