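#' Write genotypes as PED/MAP
#'
#' Six leading PED columns (family, id, sire, dam, sex, phenotype) then
#' two allele characters per locus (`A` = reference, `B` = alternate,
#' `0` = missing). Hemizygous female Z calls are written with a single
#' informative allele duplicated is avoided by writing `0` in the second
#' slot. The MAP file carries `chrom snp_id cm pos` with chromosome `1`
#' for autosomal loci and `Z` for Z-linked loci.
#'
#' @param geno a `jay_geno`.
#' @param ped a `jay_pedigree` (for parents and sexes).
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @return invisibly, the two file paths.
#' @export
write_ped <- function(geno, ped, prefix) {
  ids <- rownames(geno)
  chrom <- attr(geno, "chrom")
  sex <- attr(geno, "sex")[ids]
  pr <- ped[match(ids, ped$id), ]
  L <- ncol(geno)
  if (L > 0L) {
    map <- data.frame(chrom = ifelse(chrom == "z", "Z", "1"),
                      id = colnames(geno), cm = 0, pos = seq_len(L))
    utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  } else writeLines(character(0), paste0(prefix, ".map"))
  G <- unclass(geno)
  female_z <- outer(sex == "F", chrom == "z", "&")
  a1 <- matrix("A", nrow(G), L); a2 <- matrix("A", nrow(G), L)
  a1[which(G >= 1L)] <- "B"
  a2[which(G == 2L)] <- "B"
  a2[which(female_z & !is.na(G))] <- "0"   # hemizygous: single written allele
  a1[is.na(G)] <- "0"; a2[is.na(G)] <- "0"
  inter <- matrix(NA_character_, nrow(G), 2L * L)
  if (L > 0L) {
    inter[, seq(1L, 2L * L, by = 2L)] <- a1
    inter[, seq(2L, 2L * L, by = 2L)] <- a2
  }
  lead <- cbind("FAM1", ids,
                ifelse(is.na(pr$sire), "0", pr$sire),
                ifelse(is.na(pr$dam), "0", pr$dam),
                ifelse(sex == "M", "1", ifelse(sex == "F", "2", "0")),
                "-9")
  utils::write.table(cbind(lead, inter), paste0(prefix, ".ped"),
                     quote = FALSE, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read genotypes from PED/MAP
#'
#' Returns a `jay_geno` alt-allele-count matrix. Z loci are identified by
#' chromosome code `Z` (or `z`) in the MAP file. A diploid (homozygous
#' two-allele) Z call in a female is a validation error naming the
#' individual and locus.
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return a `jay_geno`.
#' @export
read_ped <- function(prefix) {
  mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
  if (!file.exists(mapf) || !file.exists(pedf))
    stop("missing PED/MAP files at prefix ", prefix)
  map <- if (file.size(mapf) > 0)
    utils::read.table(mapf, header = FALSE, sep = "\t",
                      col.names = c("chrom", "id", "cm", "pos"),
                      colClasses = c("character", "character",
                                     "numeric", "numeric"))
  else data.frame(chrom = character(), id = character(),
                  cm = numeric(), pos = numeric())
  lines <- readLines(pedf)
  L <- nrow(map)
  n <- length(lines)
  G <- matrix(NA_integer_, n, max(L, 0L))
  ids <- character(n); sexes <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * L)
      stop("malformed PED line ", i, ": expected ", 6L + 2L * L,
           " fields, got ", length(f))
    ids[i] <- f[2L]
    sexes[i] <- c("1" = "M", "2" = "F")[f[5L]]
    if (is.na(sexes[i])) sexes[i] <- "U"
    if (L > 0L) {
      al <- matrix(f[-(1:6)], ncol = 2L, byrow = TRUE)
      cnt <- (al[, 1L] == "B") + (al[, 2L] == "B")
      cnt[al[, 1L] == "0" & al[, 2L] == "0"] <- NA_integer_
      G[i, ] <- as.integer(cnt)
    }
  }
  rownames(G) <- ids
  colnames(G) <- map$id
  chrom <- ifelse(toupper(map$chrom) == "Z", "z", "autosomal")
  bad <- which(outer(sexes == "F", chrom == "z", "&") & G == 2L, arr.ind = TRUE)
  if (nrow(bad))
    stop("female diploid Z call: individual ", ids[bad[1L, 1L]],
         ", locus ", map$id[bad[1L, 2L]])
  structure(G, chrom = chrom, sex = stats::setNames(sexes, ids),
            founder_freq = NULL, class = c("jay_geno", class(G)))
}

#' Read a minimal VCF into a genotype matrix
#'
#' Parses GT fields only (`0/0`, `0/1`, `1/1`, phased or not; haploid
#' `0`/`1` for hemizygous calls; `./.` missing). Z-linked loci are
#' identified by CHROM equal to `Z` (case-insensitive).
#'
#' @param path VCF file path.
#' @param sexes named character vector of sexes by sample id (required to
#'   validate female Z calls; optional otherwise).
#' @return a `jay_geno`.
#' @export
read_vcf <- function(path, sexes = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1L], "#CHROM"))
    stop("not a VCF: missing #CHROM header")
  hdr <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  samples <- hdr[-(1:9)]
  body <- lines[-1L]
  n <- length(samples); L <- length(body)
  G <- matrix(NA_integer_, n, L)
  chrom <- character(L); locus <- character(L)
  for (j in seq_len(L)) {
    f <- strsplit(body[j], "\t")[[1L]]
    if (length(f) != 9L + n) stop("malformed VCF line ", j + 1L)
    chrom[j] <- f[1L]
    locus[j] <- if (f[3L] == ".") paste0(f[1L], ":", f[2L]) else f[3L]
    gt <- sub(":.*", "", f[-(1:9)])
    alleles <- strsplit(gt, "[/|]")
    G[, j] <- vapply(alleles, function(a) {
      a <- a[a != "."]
      if (!length(a)) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
  }
  rownames(G) <- samples
  colnames(G) <- locus
  cls <- ifelse(toupper(chrom) == "Z", "z", "autosomal")
  if (is.null(sexes)) sexes <- stats::setNames(rep("U", n), samples)
  bad <- which(outer(sexes[samples] == "F", cls == "z", "&") & G == 2L,
               arr.ind = TRUE)
  if (length(bad) && nrow(bad))
    stop("female diploid Z call: individual ", samples[bad[1L, 1L]],
         ", locus ", locus[bad[1L, 2L]])
  structure(G, chrom = cls, sex = sexes[samples], founder_freq = NULL,
            class = c("jay_geno", class(G)))
}

# TSV writers with a version/seed header comment ---------------------------

.write_tsv <- function(x, path, seed = NULL) {
  hdr <- sprintf("# jaykin %s%s",
                 as.character(utils::packageVersion("jaykin")),
                 if (is.null(seed)) "" else paste0(" seed=", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

#' Write a synthetic study to disk
#'
#' Emits PED/MAP genotypes (autosomal and Z combined), a pedigree TSV
#' (`id sire dam sex immigrant generation`), a coordinates TSV
#' (`id natal_x natal_y breed_x breed_y`) and a dispersal TSV
#' (`id sex distance_m`), all under `dir`.
#'
#' @param study a `jay_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
emit_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- study$pedigree
  seed <- study$config$rng_seed
  .write_tsv(data.frame(id = ped$id,
                        sire = ifelse(is.na(ped$sire), "0", ped$sire),
                        dam = ifelse(is.na(ped$dam), "0", ped$dam),
                        sex = ped$sex,
                        immigrant = as.integer(ped$immigrant),
                        generation = ped$generation),
             file.path(dir, "pedigree.tsv"), seed)
  .write_tsv(data.frame(id = ped$id,
                        natal_x = ped$natal_x, natal_y = ped$natal_y,
                        breed_x = ped$breed_x, breed_y = ped$breed_y),
             file.path(dir, "coordinates.tsv"), seed)
  .write_tsv(study$dispersal, file.path(dir, "dispersal.tsv"), seed)
  gs <- list(study$genotypes_autosomal, study$genotypes_z)
  gs <- gs[!vapply(gs, is.null, logical(1))]
  if (length(gs)) {
    combined <- do.call(cbind, lapply(gs, unclass))
    combined <- structure(combined,
                          chrom = unlist(lapply(gs, attr, "chrom")),
                          sex = attr(gs[[1L]], "sex"),
                          class = c("jay_geno", class(combined)))
    write_ped(combined, ped, file.path(dir, "genotypes"))
  } else {
    # zero-locus files are still valid
    empty <- structure(matrix(integer(), nrow(ped), 0L,
                              dimnames = list(ped$id, NULL)),
                       chrom = character(), sex = stats::setNames(ped$sex, ped$id),
                       class = "jay_geno")
    write_ped(empty, ped, file.path(dir, "genotypes"))
  }
  invisible(dir)
}

#' Read a study bundle from disk
#'
#' Counterpart of [emit_study()]: reads pedigree, coordinates, dispersal
#' and PED/MAP genotypes, splitting the genotype matrix into autosomal
#' and Z components.
#'
#' @param dir directory written by [emit_study()].
#' @return a `jay_study` (config is NULL).
#' @export
read_study <- function(dir) {
  pedtab <- .read_tsv(file.path(dir, "pedigree.tsv"))
  coords <- .read_tsv(file.path(dir, "coordinates.tsv"))
  pedtab$id <- as.character(pedtab$id)
  coords$id <- as.character(coords$id)
  pedtab$sire <- as.character(pedtab$sire)
  pedtab$dam <- as.character(pedtab$dam)
  ped <- merge(pedtab, coords, by = "id", sort = FALSE)
  ped$immigrant <- ped$immigrant == 1
  ped <- as_pedigree(ped)
  disp <- .read_tsv(file.path(dir, "dispersal.tsv"))
  disp$id <- as.character(disp$id)
  g <- read_ped(file.path(dir, "genotypes"))
  chrom <- attr(g, "chrom")
  ga <- if (any(chrom == "autosomal")) g[, chrom == "autosomal"] else NULL
  gz <- if (any(chrom == "z")) g[, chrom == "z"] else NULL
  structure(list(pedigree = ped, dispersal = disp,
                 genotypes_autosomal = ga, genotypes_z = gz, config = NULL),
            class = "jay_study")
}

#' Pairwise distances from a coordinate table
#'
#' Euclidean distances between breeding coordinates, one row per
#' unordered pair (lexicographic id order), self-pairs excluded.
#'
#' @param coords data.frame `id`, `breed_x`, `breed_y` (meters, planar).
#' @return data.table `id_a`, `id_b`, `dist_m`.
#' @export
pair_distances <- function(coords) {
  ids <- sort(as.character(coords$id))
  x <- coords$breed_x[match(ids, coords$id)]
  y <- coords$breed_y[match(ids, coords$id)]
  pr <- data.table::CJ(id_a = ids, id_b = ids)[id_a < id_b]
  i <- match(pr$id_a, ids); j <- match(pr$id_b, ids)
  pr[, dist_m := sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)]
  pr[]
}
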