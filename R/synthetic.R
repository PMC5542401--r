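#' Configuration for a synthetic spatial pedigree study
#'
#' Defaults describe the emulated study system: a ~10 km x 4 km habitat,
#' 14 non-overlapping generations of breeding pairs, strongly leptokurtic
#' sex-specific natal dispersal (female median about 2.35x the male
#' median: 1,149 m vs 488 m), sex-specific immigration (0.197 for males,
#' 0.345 for females), and biallelic SNP panels on the autosomes and the Z.
#'
#' The dispersal kernel is a mixture of a half-normal body and a
#' log-normal tail. The male kernel (weight 0.7 on half-normal sigma =
#' 540 m, 0.3 on log-normal meanlog = log(1200), sdlog = 1) has median
#' ~488 m; the female kernel is the male kernel scaled by 1149/488.
#'
#' @param habitat_width_m,habitat_height_m habitat rectangle (m).
#' @param n_generations number of non-overlapping generations.
#' @param n_breeding_pairs_per_generation breeding pairs per generation.
#' @param dispersal_kernel_params named list (`male`, `female`), each a
#'   list with `w_body`, `sigma`, `meanlog`, `sdlog` (meters).
#' @param immigration_rate named numeric (`male`, `female`), probability a
#'   recruited breeder is an immigrant.
#' @param extra_pair_rate probability an offspring's sire is a male other
#'   than its dam's social mate (default 0.1). Stands in for the
#'   re-pairing and extra-pair paternity that generate half-siblings in
#'   long-term study populations; without it a strictly monogamous
#'   non-overlapping-generation design would contain no half-siblings at
#'   all.
#' @param n_autosomal_loci,n_z_loci SNP counts.
#' @param founder_allele_freq_sampler function(n) returning founder alt
#'   allele frequencies in (0,1); default Uniform(0.05, 0.95).
#' @param rng_seed integer seed.
#' @return list of class `jay_config`.
#' @export
study_config <- function(habitat_width_m = 4000,
                         habitat_height_m = 10000,
                         n_generations = 14,
                         n_breeding_pairs_per_generation = 150,
                         dispersal_kernel_params = default_dispersal_kernels(),
                         immigration_rate = c(male = 0.197, female = 0.345),
                         extra_pair_rate = 0.1,
                         n_autosomal_loci = 8000,
                         n_z_loci = 277,
                         founder_allele_freq_sampler = function(n) stats::runif(n, 0.05, 0.95),
                         rng_seed = 1L) {
  stopifnot(habitat_width_m > 0, habitat_height_m > 0,
            n_generations >= 1, n_breeding_pairs_per_generation >= 1,
            n_autosomal_loci >= 0, n_z_loci >= 0)
  imm <- immigration_rate
  if (is.null(names(imm))) names(imm) <- c("male", "female")
  if (any(imm < 0 | imm > 1)) stop("immigration rates must be in [0,1]")
  cfg <- list(habitat_width_m = habitat_width_m,
              habitat_height_m = habitat_height_m,
              n_generations = as.integer(n_generations),
              n_breeding_pairs_per_generation = as.integer(n_breeding_pairs_per_generation),
              dispersal_kernel_params = dispersal_kernel_params,
              immigration_rate = imm,
              extra_pair_rate = extra_pair_rate,
              n_autosomal_loci = as.integer(n_autosomal_loci),
              n_z_loci = as.integer(n_z_loci),
              founder_allele_freq_sampler = founder_allele_freq_sampler,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "jay_config"
  cfg
}

#' Default leptokurtic dispersal kernels
#'
#' @return named list of kernel parameter lists for `male` and `female`.
#' @export
default_dispersal_kernels <- function() {
  male <- list(w_body = 0.7, sigma = 540, meanlog = log(1200), sdlog = 1, scale = 1)
  female <- male
  female$scale <- 1149 / 488
  list(male = male, female = female)
}

#' Draw natal dispersal distances from a kernel
#'
#' @param n number of draws.
#' @param kernel a kernel parameter list (see [default_dispersal_kernels()]),
#'   or a numeric vector of empirical distances (resampled with
#'   replacement), or a single number (point mass).
#' @return non-negative distances (m).
#' @export
draw_dispersal <- function(n, kernel) {
  if (is.numeric(kernel)) {
    if (length(kernel) == 1L) return(rep(as.numeric(kernel), n))
    return(sample(as.numeric(kernel), n, replace = TRUE))
  }
  body <- stats::rbinom(n, 1L, kernel$w_body) == 1L
  d <- numeric(n)
  d[body]  <- abs(stats::rnorm(sum(body), 0, kernel$sigma))
  d[!body] <- stats::rlnorm(sum(!body), kernel$meanlog, kernel$sdlog)
  d * (if (is.null(kernel$scale)) 1 else kernel$scale)
}

# displace points by (distance, uniform angle); rejection-resample any
# destination outside [0,w] x [0,h]
.disperse_within <- function(x, y, kernel, w, h, rng_max = 1000L) {
  n <- length(x)
  nx <- rep(NA_real_, n); ny <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (it in seq_len(rng_max)) {
    if (!length(todo)) break
    d <- draw_dispersal(length(todo), kernel)
    a <- stats::runif(length(todo), 0, 2 * pi)
    px <- x[todo] + d * cos(a)
    py <- y[todo] + d * sin(a)
    ok <- px >= 0 & px <= w & py >= 0 & py <= h
    nx[todo[ok]] <- px[ok]; ny[todo[ok]] <- py[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) stop("dispersal rejection sampling failed to place individuals")
  list(x = nx, y = ny)
}

#' Forward-simulate a spatially explicit pedigree
#'
#' Builds `n_generations` of breeding pairs on a rectangular habitat.
#' Founders (generation 0) are placed uniformly at random. Each later
#' generation recruits one male and one female per breeding pair slot:
#' with probability `immigration_rate[sex]` the recruit is an immigrant
#' (uniform placement, no parents); otherwise it is the offspring of a
#' random non-sibling pairing of the previous generation's pairs and
#' disperses from its natal nest by a draw from its sex's kernel
#' (rejection-resampled to stay inside the habitat). Mates are paired at
#' random avoiding full siblings.
#'
#' @param config a `jay_config`.
#' @return list of class `jay_study` with elements `pedigree` (a
#'   `jay_pedigree` carrying coordinates), `dispersal` (data.frame `id`,
#'   `sex`, `distance_m` for non-immigrant recruits), `genotypes_autosomal`,
#'   `genotypes_z` (NULL until [gene_drop()] is run), and `config`.
#' @export
build_population <- function(config) {
  stopifnot(inherits(config, "jay_config"))
  w <- config$habitat_width_m; h <- config$habitat_height_m
  npair <- config$n_breeding_pairs_per_generation
  if (w * h < npair) stop("habitat too small for requested breeding pairs")
  withr_seed <- config$rng_seed
  set.seed(withr_seed)

  rows <- list()
  counter <- 0L
  new_ids <- function(n) {
    ids <- sprintf("I%06d", counter + seq_len(n)); counter <<- counter + n; ids
  }

  # generation 0: founders, paired as placed
  ids_m <- new_ids(npair); ids_f <- new_ids(npair)
  gen0 <- data.frame(
    id = c(ids_m, ids_f),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), each = npair),
    immigrant = FALSE, generation = 0L,
    natal_x = NA_real_, natal_y = NA_real_,
    breed_x = stats::runif(2 * npair, 0, w),
    breed_y = stats::runif(2 * npair, 0, h),
    pair = rep(seq_len(npair), 2L),
    stringsAsFactors = FALSE)
  rows[[1L]] <- gen0
  prev <- gen0
  disp <- list()

  for (g in seq_len(config$n_generations - 1L)) {
    pm <- prev[prev$sex == "M", ]
    pf <- prev[prev$sex == "F", ]
    pm <- pm[order(pm$pair), ]; pf <- pf[order(pf$pair), ]
    # nest of a breeding pair: midpoint of the two breeders' territories
    nest_x <- (pm$breed_x + pf$breed_x) / 2
    nest_y <- (pm$breed_y + pf$breed_y) / 2
    recruit <- function(sex) {
      rate <- config$immigration_rate[[if (sex == "M") "male" else "female"]]
      kern <- config$dispersal_kernel_params[[if (sex == "M") "male" else "female"]]
      imm <- stats::runif(npair) < rate
      parent_pair <- sample.int(npair, npair, replace = TRUE)
      # extra-pair paternity: sire comes from another pair, natal nest and
      # dam stay with the social pair
      sire_pair <- parent_pair
      epp <- stats::runif(npair) < config$extra_pair_rate
      if (any(epp))
        sire_pair[epp] <- sample.int(npair, sum(epp), replace = TRUE)
      id <- new_ids(npair)
      bx <- by_ <- nx <- ny <- rep(NA_real_, npair)
      # immigrants
      bx[imm] <- stats::runif(sum(imm), 0, w)
      by_[imm] <- stats::runif(sum(imm), 0, h)
      # residents disperse from natal nest
      res <- !imm
      if (any(res)) {
        nx[res] <- nest_x[parent_pair[res]]
        ny[res] <- nest_y[parent_pair[res]]
        dst <- .disperse_within(nx[res], ny[res], kern, w, h)
        bx[res] <- dst$x; by_[res] <- dst$y
      }
      data.frame(
        id = id,
        sire = ifelse(imm, NA_character_, pm$id[sire_pair]),
        dam  = ifelse(imm, NA_character_, pf$id[parent_pair]),
        sex = sex, immigrant = imm, generation = g,
        natal_x = nx, natal_y = ny, breed_x = bx, breed_y = by_,
        pair = NA_integer_, stringsAsFactors = FALSE)
    }
    males <- recruit("M"); females <- recruit("F")
    # mates pair locally: breeders share a territory, so each male takes
    # the nearest unpaired female, vetoing full siblings when any
    # non-sibling candidate remains
    males <- males[sample.int(npair), ]
    is_fs <- function(m, f)
      !is.na(males$sire[m]) && !is.na(females$sire[f]) &&
        males$sire[m] == females$sire[f] && males$dam[m] == females$dam[f]
    take <- integer(npair)
    free <- rep(TRUE, npair)
    for (i in seq_len(npair)) {
      cand <- which(free)
      d2 <- (females$breed_x[cand] - males$breed_x[i])^2 +
        (females$breed_y[cand] - males$breed_y[i])^2
      cand <- cand[order(d2)]
      pick <- cand[1L]
      for (k in cand) if (!is_fs(i, k)) { pick <- k; break }
      take[i] <- pick
      free[pick] <- FALSE
    }
    females <- females[take, ]
    males$pair <- seq_len(npair); females$pair <- seq_len(npair)
    gen <- rbind(males, females)
    disp[[length(disp) + 1L]] <- data.frame(
      id = gen$id[!gen$immigrant], sex = gen$sex[!gen$immigrant],
      distance_m = sqrt((gen$breed_x[!gen$immigrant] - gen$natal_x[!gen$immigrant])^2 +
                          (gen$breed_y[!gen$immigrant] - gen$natal_y[!gen$immigrant])^2),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- gen
    prev <- gen
  }

  ped <- do.call(rbind, rows)
  ped$pair <- NULL
  study <- list(pedigree = as_pedigree(ped),
                dispersal = if (length(disp)) do.call(rbind, disp) else
                  data.frame(id = character(), sex = character(), distance_m = numeric()),
                genotypes_autosomal = NULL, genotypes_z = NULL,
                config = config)
  class(study) <- "jay_study"
  study
}

#' Gene-drop biallelic genotypes through a pedigree
#'
#' Founders and immigrants draw alleles independently from per-locus
#' founder frequencies. Autosomal inheritance passes one uniformly random
#' allele from each parent. Z-linked inheritance: sons receive one random
#' paternal Z allele plus the maternal Z allele; daughters receive one
#' random paternal Z allele only (hemizygous, coded 0/1).
#'
#' @param ped a `jay_pedigree`.
#' @param n_loci number of biallelic loci.
#' @param chrom `"autosomal"` or `"z"`.
#' @param founder_freq_sampler function(n) giving founder alt frequencies,
#'   or a numeric vector of length `n_loci`.
#' @param rng_seed integer seed.
#' @return a `jay_geno` object: integer matrix individuals x loci of
#'   alt-allele counts with attributes `chrom` (per-locus class), `sex`
#'   (per-individual), and `founder_freq`.
#' @export
gene_drop <- function(ped, n_loci, chrom = c("autosomal", "z"),
                      founder_freq_sampler = function(n) stats::runif(n, 0.05, 0.95),
                      rng_seed = 1L) {
  chrom <- match.arg(chrom)
  ped <- as_pedigree(ped)
  if (chrom == "z" && any(ped$sex == "U"))
    stop("Z-linked gene drop requires known sexes")
  set.seed(rng_seed)
  L <- as.integer(n_loci)
  p <- if (is.function(founder_freq_sampler)) founder_freq_sampler(L) else
    rep_len(as.numeric(founder_freq_sampler), L)
  ord <- order(ped$generation)
  id <- ped$id[ord]
  fi <- match(ped$sire[ord], id)
  mi <- match(ped$dam[ord], id)
  male <- ped$sex[ord] == "M"
  n <- length(id)

  # haplotype storage: paternal and maternal allele per individual x locus
  pat <- matrix(NA_integer_, n, L)
  mat <- matrix(NA_integer_, n, L)
  draw <- function(k) matrix(stats::rbinom(k * L, 1L, rep(p, each = k)), k, L)
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    if (chrom == "autosomal") {
      pat[i, ] <- if (is.na(f)) draw(1L)[1L, ] else
        ifelse(stats::runif(L) < 0.5, pat[f, ], mat[f, ])
      mat[i, ] <- if (is.na(m)) draw(1L)[1L, ] else
        ifelse(stats::runif(L) < 0.5, pat[m, ], mat[m, ])
    } else {
      # Z: father ZZ (pat+mat slots used), mother's Z kept in pat slot
      pat[i, ] <- if (is.na(f)) draw(1L)[1L, ] else
        ifelse(stats::runif(L) < 0.5, pat[f, ], mat[f, ])
      if (male[i]) {
        mat[i, ] <- if (is.na(m)) draw(1L)[1L, ] else pat[m, ]
      }                                       # female: single Z, mat stays NA
    }
  }
  mat0 <- mat; mat0[is.na(mat0)] <- 0L      # hemizygous females: single allele
  G <- pat + mat0
  rownames(G) <- id
  colnames(G) <- sprintf("%s%05d", if (chrom == "z") "Z" else "A", seq_len(L))
  G <- G[match(ped$id, id), , drop = FALSE]
  structure(G,
            chrom = rep(chrom, L),
            sex = stats::setNames(ped$sex, ped$id),
            founder_freq = p,
            class = c("jay_geno", class(G)))
}

#' @export
`[.jay_geno` <- function(x, i, j, ..., drop = FALSE) {
  chrom <- attr(x, "chrom"); sex <- attr(x, "sex"); ff <- attr(x, "founder_freq")
  y <- unclass(x)[i, j, drop = drop]
  if (!is.matrix(y)) return(y)
  if (!missing(j)) {
    chrom <- chrom[j]
    if (!is.null(ff)) ff <- ff[j]
  }
  structure(y, chrom = chrom, sex = sex, founder_freq = ff,
            class = c("jay_geno", class(y)))
}

#' Assemble a complete synthetic study
#'
#' Runs [build_population()] then [gene_drop()] for autosomes and Z with
#' seeds derived from the study seed (one RNG stream per stage).
#'
#' @param config a `jay_config`.
#' @return a `jay_study` with genotypes filled in.
#' @export
simulate_study <- function(config) {
  study <- build_population(config)
  base <- config$rng_seed
  if (config$n_autosomal_loci > 0)
    study$genotypes_autosomal <- gene_drop(
      study$pedigree, config$n_autosomal_loci, "autosomal",
      config$founder_allele_freq_sampler, rng_seed = (base * 7L + 1L) %% 2147483647L)
  if (config$n_z_loci > 0)
    study$genotypes_z <- gene_drop(
      study$pedigree, config$n_z_loci, "z",
      config$founder_allele_freq_sampler, rng_seed = (base * 7L + 2L) %% 2147483647L)
  study
}
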