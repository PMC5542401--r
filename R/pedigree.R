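#' Construct and validate a pedigree
#'
#' A pedigree is a data.frame with one row per individual and columns
#' `id`, `sire`, `dam`, `sex`, `immigrant`, `generation`, optionally with
#' planar coordinates `natal_x`, `natal_y`, `breed_x`, `breed_y` (meters).
#' Missing parents are coded `NA`. Sexes are `"M"`, `"F"` or `"U"`.
#'
#' Validation enforces: unique ids, referenced parents present, sires male
#' and dams female, an acyclic parent graph (offspring generation strictly
#' greater than both parents'), and that immigrants carry no parents.
#'
#' @param x data.frame with at least `id`, `sire`, `dam`, `sex`.
#' @return The validated data.frame with class `jay_pedigree`.
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("pedigree lacks columns: ", paste(miss, collapse = ", "))
  x$id   <- as.character(x$id)
  x$sire <- as.character(x$sire)
  x$dam  <- as.character(x$dam)
  x$sire[x$sire %in% c("", "0", "NA")] <- NA_character_
  x$dam[x$dam %in% c("", "0", "NA")]   <- NA_character_
  x$sex  <- toupper(as.character(x$sex))
  if (!all(x$sex %in% c("M", "F", "U")))
    stop("sex must be one of 'M', 'F', 'U'")
  if (anyDuplicated(x$id)) stop("duplicated individual ids")
  if (is.null(x$immigrant)) x$immigrant <- FALSE
  x$immigrant <- as.logical(x$immigrant)

  idx <- match(x$sire, x$id)
  bad <- !is.na(x$sire) & is.na(idx)
  if (any(bad)) stop("unknown sire id(s): ", paste(unique(x$sire[bad]), collapse = ", "))
  if (any(x$sex[idx[!is.na(idx)]] != "M")) stop("a referenced sire is not male")
  idx <- match(x$dam, x$id)
  bad <- !is.na(x$dam) & is.na(idx)
  if (any(bad)) stop("unknown dam id(s): ", paste(unique(x$dam[bad]), collapse = ", "))
  if (any(x$sex[idx[!is.na(idx)]] != "F")) stop("a referenced dam is not female")
  if (any(x$immigrant & (!is.na(x$sire) | !is.na(x$dam))))
    stop("immigrants must have no recorded parents")

  rownames(x) <- NULL
  if (is.null(x$generation)) x$generation <- ped_generations(x)
  gp <- x$generation[match(x$sire, x$id)]
  gm <- x$generation[match(x$dam, x$id)]
  if (any(x$generation <= gp, na.rm = TRUE) || any(x$generation <= gm, na.rm = TRUE))
    stop("pedigree is not acyclic: offspring generation must exceed both parents'")
  class(x) <- c("jay_pedigree", "data.frame")
  x
}

# Topological depth of each individual (founders = 0); errors on cycles.
ped_generations <- function(x) {
  n <- nrow(x)
  fi <- match(x$sire, x$id)
  mi <- match(x$dam, x$id)
  gen <- rep(NA_integer_, n)
  gen[is.na(fi) & is.na(mi)] <- 0L
  for (pass in seq_len(n)) {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    g1 <- gen[fi[todo]]; g1[is.na(fi[todo])] <- -1L
    g2 <- gen[mi[todo]]; g2[is.na(mi[todo])] <- -1L
    ready <- (is.na(fi[todo]) | !is.na(gen[fi[todo]])) &
             (is.na(mi[todo]) | !is.na(gen[mi[todo]]))
    if (!any(ready)) stop("pedigree contains a cycle")
    gen[todo[ready]] <- pmax(g1[ready], g2[ready]) + 1L
  }
  gen
}

#' Pedigree kinship matrix (autosomal or Z-linked)
#'
#' Recursive tabular kinship. For `chrom = "autosomal"` the classic
#' recursion: phi(i,i) = (1 + phi(f,m))/2, phi(i,j) = (phi(f,j) + phi(m,j))/2.
#' For `chrom = "z"` the ZW system is handled natively: males carry two Z
#' copies (one from each parent), females carry a single paternal Z (the W
#' is ignored), so phi(i,j) = phi(f_i, j) for female i, and founder
#' self-kinship is 1/2 (males) or 1 (females).
#'
#' @param ped a `jay_pedigree`.
#' @param chrom `"autosomal"` or `"z"`.
#' @param ids optional subset of ids for the returned matrix (computation
#'   always runs over the full pedigree).
#' @return symmetric kinship matrix with id dimnames.
#' @export
kinship_matrix <- function(ped, chrom = c("autosomal", "z"), ids = NULL) {
  chrom <- match.arg(chrom)
  ped <- as_pedigree(ped)
  if (chrom == "z" && any(ped$sex == "U"))
    stop("Z-linked kinship requires known sexes for all individuals")
  ord <- order(ped$generation)
  id <- ped$id[ord]
  fi <- match(ped$sire[ord], id)
  mi <- match(ped$dam[ord], id)
  male <- ped$sex[ord] == "M"
  n <- length(id)
  K <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    prev <- seq_len(i - 1L)
    if (chrom == "autosomal" || male[i]) {
      row <- numeric(i - 1L)
      if (!is.na(f)) row <- row + K[f, prev]
      if (!is.na(m)) row <- row + K[m, prev]
      row <- row / 2
      self <- if (chrom == "autosomal") {
        0.5 * (1 + if (!is.na(f) && !is.na(m)) K[f, m] else 0)
      } else {
        0.5 * (1 + if (!is.na(f) && !is.na(m)) K[f, m] else 0)
      }
    } else {                                  # Z-linked female: paternal Z only
      row <- if (!is.na(f)) K[f, prev] else numeric(i - 1L)
      self <- 1
    }
    K[i, prev] <- row
    K[prev, i] <- row
    K[i, i] <- self
  }
  if (!is.null(ids)) {
    j <- match(as.character(ids), id)
    if (anyNA(j)) stop("ids not in pedigree")
    K <- K[j, j, drop = FALSE]
  }
  K
}

#' Pedigree coefficient of relationship
#'
#' Twice the kinship coefficient, for autosomal or Z-linked (ZW)
#' inheritance. For the Z the doubling keeps the convention consistent
#' with the autosomal coefficient (father-son 0.5, father-daughter 1,
#' mother-daughter 0).
#'
#' @inheritParams kinship_matrix
#' @param id_a,id_b individual ids (vectorized, equal length).
#' @return numeric vector of r values.
#' @export
coefficient_of_relationship <- function(ped, id_a, id_b,
                                        chrom = c("autosomal", "z")) {
  chrom <- match.arg(chrom)
  K <- kinship_matrix(ped, chrom)
  a <- match(as.character(id_a), rownames(K))
  b <- match(as.character(id_b), rownames(K))
  if (anyNA(a) || anyNA(b)) stop("id not in pedigree")
  2 * K[cbind(a, b)]
}

## Relationship class catalogue -------------------------------------------

# code, minimal depths to the nearest common ancestor(s) (da <= db), and
# whether the configuration runs through a mated pair (2 ancestors) or a
# single shared ancestor. expected r = n_anc * 2^-(da+db).
.rel_catalogue <- function() {
  x <- rbind(
    data.frame(code = "PO",   da = 0, db = 1, n_anc = 1),
    data.frame(code = "FS",   da = 1, db = 1, n_anc = 2),
    data.frame(code = "HS",   da = 1, db = 1, n_anc = 1),
    data.frame(code = "G1",   da = 0, db = 2, n_anc = 1),
    data.frame(code = "N1",   da = 1, db = 2, n_anc = 2),
    data.frame(code = "DC1",  da = 2, db = 2, n_anc = 4),
    data.frame(code = "C1",   da = 2, db = 2, n_anc = 2),
    data.frame(code = "G2",   da = 0, db = 3, n_anc = 1),
    data.frame(code = "GN",   da = 1, db = 3, n_anc = 2),
    data.frame(code = "N2",   da = 1, db = 2, n_anc = 1),
    data.frame(code = "C0.5", da = 2, db = 2, n_anc = 1),
    data.frame(code = "C1r1", da = 2, db = 3, n_anc = 2),
    data.frame(code = "G3",   da = 0, db = 4, n_anc = 1),
    data.frame(code = "C2",   da = 3, db = 3, n_anc = 2),
    data.frame(code = "C2r1", da = 3, db = 4, n_anc = 2),
    data.frame(code = "C3",   da = 4, db = 4, n_anc = 2),
    data.frame(code = "C4",   da = 5, db = 5, n_anc = 2)
  )
  x$expected_r <- x$n_anc * 2^-(x$da + x$db)
  x
}

#' Expected coefficient of relationship for a relationship class
#'
#' @param code relationship code(s), e.g. `"PO"`, `"FS"`, `"C1"`.
#' @return numeric expected r (NA for unknown codes).
#' @export
relationship_expected_r <- function(code) {
  cat_ <- .rel_catalogue()
  cat_$expected_r[match(code, cat_$code)]
}

# Ancestor map (id, ancestor, depth) up to max_depth, self at depth 0,
# keeping the minimum depth per (id, ancestor).
.ancestor_table <- function(ped, ids, max_depth) {
  fi <- ped$sire[match(ids, ped$id)]
  mi <- ped$dam[match(ids, ped$id)]
  out <- list(data.table::data.table(id = ids, anc = ids, depth = 0L))
  cur <- data.table::data.table(id = rep(ids, 2L), anc = c(fi, mi))
  cur <- cur[!is.na(anc)]
  d <- 1L
  while (nrow(cur) && d <= max_depth) {
    cur <- unique(cur)
    out[[length(out) + 1L]] <- data.table::data.table(id = cur$id, anc = cur$anc, depth = d)
    nxt <- data.table::data.table(
      id  = rep(cur$id, 2L),
      anc = c(ped$sire[match(cur$anc, ped$id)], ped$dam[match(cur$anc, ped$id)]))
    cur <- nxt[!is.na(anc)]
    d <- d + 1L
  }
  tab <- data.table::rbindlist(out)
  tab[, list(depth = min(depth)), by = c("id", "anc")]
}

#' Closest pedigree relationship for pairs of individuals
#'
#' Finds, for each pair, the genealogically closest relationship class:
#' the configuration minimizing the combined path length to a common
#' ancestor (total meioses), with ties broken in favour of the class with
#' the larger expected coefficient of relationship. Relationships are
#' classified up to fourth cousins by default; pairs with no common
#' ancestor within `max_depth` (or whose minimal configuration has no
#' enumerated code) are reported as `NA`.
#'
#' @param ped a `jay_pedigree`.
#' @param pairs data.frame with columns `id_a`, `id_b`; if `NULL`, all
#'   unordered pairs of `ids`.
#' @param ids ids to cross when `pairs` is `NULL` (default: all).
#' @param max_depth maximum generations climbed per individual (default 5,
#'   i.e. fourth cousins).
#' @return data.table `id_a`, `id_b`, `rel`, `expected_r`.
#' @export
closest_relationship <- function(ped, pairs = NULL, ids = NULL, max_depth = 5L) {
  ped <- as_pedigree(ped)
  if (is.null(pairs)) {
    if (is.null(ids)) ids <- ped$id
    ids <- as.character(ids)
    pairs <- data.table::CJ(id_a = ids, id_b = ids)[id_a < id_b]
  } else {
    pairs <- data.table::as.data.table(pairs)[, c("id_a", "id_b")]
    pairs[, `:=`(id_a = as.character(id_a), id_b = as.character(id_b))]
    sw <- pairs$id_a > pairs$id_b
    if (any(sw)) pairs[sw, `:=`(id_a = id_b, id_b = id_a)]
  }
  if (!all(c(pairs$id_a, pairs$id_b) %in% ped$id)) stop("pair id not in pedigree")
  uids <- unique(c(pairs$id_a, pairs$id_b))
  anc <- .ancestor_table(ped, uids, max_depth)

  # join on shared ancestor -> candidate configurations per pair
  a <- data.table::copy(anc); data.table::setnames(a, c("id_a", "anc", "da"))
  b <- data.table::copy(anc); data.table::setnames(b, c("id_b", "anc", "db"))
  j <- merge(a, b, by = "anc", allow.cartesian = TRUE)
  j <- j[id_a != id_b]
  sw <- j$id_a > j$id_b
  if (any(sw)) j[sw, `:=`(id_a = id_b, id_b = id_a, da = db, db = da)]
  data.table::setkey(pairs, id_a, id_b)
  j <- j[pairs, nomatch = NULL, on = c("id_a", "id_b")]
  if (!nrow(j)) {
    return(pairs[, `:=`(rel = NA_character_, expected_r = NA_real_)][])
  }
  # drop configurations where the "common ancestor" is one of the pair but
  # the path does not reflect direct descent bookkeeping (depth 0 entries
  # pair only with the other's positive depth -> direct line PO/G1/G2/G3)
  j <- j[!(da == 0L & db == 0L)]
  j[, m := da + db]
  mins <- j[, list(m = min(m)), by = c("id_a", "id_b")]
  j <- j[mins, on = c("id_a", "id_b", "m")]
  # within the minimal total path, orient depths and count distinct ancestors
  j[, `:=`(lo = pmin(da, db), hi = pmax(da, db))]
  cfg <- j[, list(n_anc = data.table::uniqueN(anc)), by = c("id_a", "id_b", "m", "lo", "hi")]

  cat_ <- data.table::as.data.table(.rel_catalogue())
  data.table::setnames(cat_, c("da", "db"), c("lo", "hi"))
  # match on depths; pick the catalogue row with the largest n_anc not
  # exceeding the observed ancestor count (e.g. 4 ancestors at (2,2) -> DC1,
  # 2 -> C1, 1 -> C0.5)
  res <- merge(cfg, cat_, by = c("lo", "hi"), allow.cartesian = TRUE)
  res <- res[n_anc.y <= pmax(n_anc.x, 1L)]
  res <- res[order(id_a, id_b, -expected_r, lo)]
  res <- res[, .SD[1L], by = c("id_a", "id_b")]
  out <- merge(pairs, res[, c("id_a", "id_b", "code", "expected_r")],
               by = c("id_a", "id_b"), all.x = TRUE)
  data.table::setnames(out, "code", "rel")
  out[]
}

# quiet R CMD check notes for data.table NSE
utils::globalVariables(c(
  "anc", "id_a", "id_b", "da", "db", "m", "lo", "hi", "n_anc.x", "n_anc.y",
  "expected_r", "code", "depth", ".SD"))
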