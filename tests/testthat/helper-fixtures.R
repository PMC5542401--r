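# Shared fixtures and independent oracles. Expensive synthetic studies are
# built once per test run and cached here.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# mid-sized study shared by relatedness/decay tests
fixture_study <- function() {
  cached("study_mid", function() {
    cfg <- study_config(n_generations = 6,
                        n_breeding_pairs_per_generation = 50,
                        n_autosomal_loci = 2000, n_z_loci = 300,
                        rng_seed = 101L)
    simulate_study(cfg)
  })
}

fixture_pairs <- function() {
  cached("pairs_mid", function() {
    st <- fixture_study()
    ids <- st$pedigree$id[st$pedigree$generation >= 3]
    build_pair_table(st, ids = ids)
  })
}

sex_combo_of <- function(pairs) {
  co <- paste0(pmin(pairs$sex_a, pairs$sex_b), pmax(pairs$sex_a, pairs$sex_b))
  c(FF = "FF", FM = "MF", MM = "MM")[co]
}

# Hand-built pedigree whose relationship classes were enumerated manually
# (all ancestor paths traced by hand; see expected_hand_classes()).
hand_pedigree <- function() {
  P <- function(id, sire, dam, sex)
    data.frame(id = id, sire = sire, dam = dam, sex = sex,
               stringsAsFactors = FALSE)
  ped <- rbind(
    # founders
    P("A1", NA, NA, "M"), P("A2", NA, NA, "F"),
    P("B1", NA, NA, "M"), P("B2", NA, NA, "F"),
    P("Y",  NA, NA, "F"), P("U2", NA, NA, "F"),
    P("U3", NA, NA, "F"), P("U4", NA, NA, "F"),
    P("V1", NA, NA, "M"),
    P("G1m", NA, NA, "M"), P("G1f", NA, NA, "F"),
    P("G2m", NA, NA, "M"), P("G2f", NA, NA, "F"),
    P("Z1", NA, NA, "F"), P("Z2", NA, NA, "M"),
    # generation 1
    P("P1", "A1", "A2", "M"), P("P2", "A1", "A2", "F"),
    P("P3", "A1", "Y", "M"),
    P("Q1", "B1", "B2", "M"), P("Q2", "B1", "B2", "F"),
    P("H1", "G2m", "G2f", "M"), P("H2", "G2m", "G2f", "F"),
    P("M1a", "G1m", "G1f", "M"), P("M1b", "G1m", "G1f", "M"),
    # generation 2
    P("S1", "P1", "Q2", "M"), P("S2", "Q1", "P2", "F"),
    P("S4", "Q1", "U2", "F"), P("R3", "P3", "U4", "F"),
    P("F1a", "H1", "Z1", "F"), P("F1b", "Z2", "H2", "F"),
    # generation 3
    P("T1", "S1", "U3", "M"), P("T2", "V1", "S4", "F"),
    P("W1", "M1a", "F1a", "M"), P("W2", "M1b", "F1b", "M"))
  as_pedigree(ped)
}

# manually derived closest classes for hand_pedigree()
expected_hand_classes <- function() {
  data.frame(
    id_a = c("P1", "A1", "P1", "P1", "P2", "P3", "S1", "S1", "R3", "A1",
             "P2", "S4", "T1", "W1", "A1"),
    id_b = c("S1", "S1", "P2", "P3", "S1", "S1", "S2", "S4", "S1", "T1",
             "T1", "T1", "T2", "W2", "B1"),
    rel  = c("PO", "G1", "FS", "HS", "N1", "N2", "DC1", "C1", "C0.5", "G2",
             "GN", "C1r1", "C2", "C1", NA),
    stringsAsFactors = FALSE)
  # W1/W2 are simultaneously first cousins (through G1m/G1f) and second
  # cousins (through G2m/G2f); the closer class C1 must win.
}

# Exact allele-path enumeration oracle for Z-linked expected IBD on a tiny
# pedigree. Every founder Z allele is a unique symbol; each non-founder
# picks one of its father's two Z alleles (2-way choice); sons additionally
# inherit the mother's single Z deterministically. The expectation is the
# exact mean over all joint choices of the pair IBD proportion under the
# package's convention (2*phi for pairs with a male, phi for female pairs).
z_enum_oracle <- function(ped, id_a, id_b) {
  ped <- as.data.frame(ped)
  # prune to the pair's ancestor closure to keep the enumeration tiny
  keep <- character(0); frontier <- c(id_a, id_b)
  while (length(frontier)) {
    keep <- union(keep, frontier)
    i <- match(frontier, ped$id)
    frontier <- setdiff(stats::na.omit(c(ped$sire[i], ped$dam[i])), keep)
  }
  ped <- ped[ped$id %in% keep, ]
  ord <- ped$id[order(ped_generations_oracle(ped))]
  nonf <- ord[!is.na(ped$sire[match(ord, ped$id)])]
  n_choice <- length(nonf)
  vals <- numeric(0)
  for (mask in seq_len(max(2^n_choice, 1)) - 1L) {
    choice <- as.integer(intToBits(mask))[seq_len(max(n_choice, 1L))]
    alle <- list()   # id -> character vector of Z alleles (len 2 male, 1 female)
    for (id in ord) {
      i <- match(id, ped$id)
      sx <- ped$sex[i]
      if (is.na(ped$sire[i])) {
        alle[[id]] <- if (sx == "M") paste0(id, c(".1", ".2")) else paste0(id, ".1")
      } else {
        k <- match(id, nonf)
        pat <- alle[[ped$sire[i]]][choice[k] + 1L]
        alle[[id]] <- if (sx == "M") c(pat, alle[[ped$dam[i]]][1L]) else pat
      }
    }
    a <- alle[[id_a]]; b <- alle[[id_b]]
    phi <- mean(outer(a, b, "=="))
    s <- if (ped$sex[match(id_a, ped$id)] == "F" &&
             ped$sex[match(id_b, ped$id)] == "F") 1 else 2
    vals <- c(vals, s * phi)
  }
  mean(vals)
}

ped_generations_oracle <- function(ped) {
  g <- rep(0L, nrow(ped))
  repeat {
    gp <- g[match(ped$sire, ped$id)]; gp[is.na(gp)] <- -1L
    gm <- g[match(ped$dam, ped$id)]; gm[is.na(gm)] <- -1L
    g2 <- pmax(gp, gm) + 1L
    if (all(g2 == g)) return(g)
    g <- g2
  }
}
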