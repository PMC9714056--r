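#' @useDynLib amyloidhex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical one-letter amino-acid alphabet, alphabetical order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Three-letter codes in the order seqinr's aaindex vectors use.
.AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
          Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
          Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
          Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

# Chou's three PAAC properties (hydrophobicity, hydrophilicity, side-chain
# mass), raw values; standardised at bundle build time.
.PAAC_HYDROPHOBICITY <- c(
  A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
  I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78, P = 0.12, Q = -0.85,
  R = -2.53, S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
.PAAC_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
  I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
  R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
.PAAC_SIDECHAIN_MASS <- c(
  A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82,
  I = 57, K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72,
  R = 101, S = 31, T = 45, V = 43, W = 130, Y = 107)

# Sandberg et al. (1998) five z-scales.
.ZSCALES <- matrix(c(
  # z1, z2, z3, z4, z5
  0.24, -2.32, 0.60, -0.14, 1.30,   # A
  0.84, -1.67, 3.71, 0.18, -2.65,   # C
  3.98, 0.93, 1.93, -2.46, 0.75,    # D
  3.11, 0.26, -0.11, -3.04, -0.25,  # E
  -4.22, 1.94, 1.06, 0.54, -0.62,   # F
  2.05, -4.06, 0.36, -0.82, -0.38,  # G
  2.47, 1.95, 0.26, 3.90, 0.09,     # H
  -3.89, -1.73, -1.71, -0.84, 0.26, # I
  2.29, 0.89, -2.49, 1.49, 0.31,    # K
  -4.28, -1.30, -1.49, -0.72, 0.84, # L
  -2.85, -0.22, 0.47, 1.94, -0.98,  # M
  3.05, 1.62, 1.04, -1.15, 1.61,    # N
  -1.66, 0.27, 1.84, 0.70, 2.00,    # P
  1.75, 0.50, -1.44, -1.34, 0.66,   # Q
  3.52, 2.50, -3.50, 1.99, -0.17,   # R
  2.39, -1.07, 1.15, -1.39, 0.67,   # S
  0.75, -2.18, -1.12, -1.46, -0.40, # T
  -2.59, -2.64, -1.54, -0.85, -0.02,# V
  -4.36, 3.94, 0.59, 3.44, -1.59,   # W
  -2.54, 2.44, 0.43, 0.04, -1.47),  # Y
  nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET, paste0("z", 1:5)))

# Grantham (1974) residue composition, polarity and volume; the published
# integer distance matrix is reconstructed exactly from these via
# D_ij = 50.723 * sqrt(1.833 c^2 + 0.1018 p^2 + 0.000399 v^2).
.GRANTHAM_C <- c(A = 0, C = 2.75, D = 1.38, E = 0.92, F = 0, G = 0.74,
                 H = 0.58, I = 0, K = 0.33, L = 0, M = 0, N = 1.33,
                 P = 0.39, Q = 0.89, R = 0.65, S = 1.42, T = 0.71,
                 V = 0, W = 0.13, Y = 0.20)
.GRANTHAM_P <- c(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0,
                 H = 10.4, I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6,
                 P = 8.0, Q = 10.5, R = 10.5, S = 9.2, T = 8.6,
                 V = 5.9, W = 5.4, Y = 6.2)
.GRANTHAM_V <- c(A = 31, C = 55, D = 54, E = 83, F = 132, G = 3,
                 H = 96, I = 111, K = 119, L = 111, M = 105, N = 56,
                 P = 32.5, Q = 85, R = 124, S = 32, T = 61,
                 V = 84, W = 170, Y = 136)

# Dubchak-style three-way groupings behind the CTD descriptors: 13 properties,
# each splitting the 20 residues into three disjoint, exhaustive groups.
.CTD_GROUPS <- list(
  hydrophobicity_PRAM900101 = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  hydrophobicity_ARGP820101 = c("QSTNGDE", "RAHCKMV", "LYPFIW"),
  hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV", "LPFYI"),
  hydrophobicity_PONP930101 = c("KPDESNQT", "GRHA", "YMFWLCVI"),
  hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV", "FIWC"),
  hydrophobicity_ENGD860101 = c("RDKENQHYP", "SGTAW", "CVLIMF"),
  hydrophobicity_FASG890101 = c("KERSQD", "NTPG", "AYHWVMFLIC"),
  normwaalsvolume           = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarity                  = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability            = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge                    = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct           = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solventaccess             = c("ALFCGIVW", "RKQEND", "MSPTHY"))

# Five-way grouping for GAAC/EGAAC/GDPC: aliphatic, aromatic, positive,
# negative, uncharged.
.GAAC_GROUPS <- list(
  aliphatic = c("A", "G", "I", "L", "M", "V"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("C", "N", "P", "Q", "S", "T"))

# Standard-code codons per residue (sum 61) for the DDE background.
.CODON_COUNTS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
                   K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
                   T = 4, V = 4, W = 1, Y = 2)

# AAindex accessions of the eight properties driving the three
# autocorrelation families.
.AUTOCORR_ACCESSIONS <- c("CIDH920105", "BHAR880101", "CHAM820101",
                          "CHAM820102", "CHOC760101", "BIGC670101",
                          "CHAM810101", "DAYM780201")

# mean 0 / population-sd 1 standardisation over the 20 residues
.standardise20 <- function(x) {
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  (x - mu) / sdev
}

.group_index <- function(groups) {
  # integer group id per residue (1..length(groups)), A..Y order
  idx <- integer(20)
  names(idx) <- AA_ALPHABET
  for (g in seq_along(groups)) {
    letters_g <- unlist(strsplit(groups[[g]], ""))
    idx[letters_g] <- g
  }
  stopifnot(all(idx > 0L))
  idx
}

.build_aaindex_matrix <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aai <- env$aaindex
  keep <- vapply(aai, function(e) !any(is.na(e$I)), logical(1))
  aai <- aai[keep]
  accs <- vapply(aai, function(e) e$H, character(1))
  m <- t(vapply(aai, function(e) {
    v <- e$I
    names(v) <- .AA3[names(v)]
    v[AA_ALPHABET]
  }, numeric(20)))
  dimnames(m) <- list(accs, AA_ALPHABET)
  m
}

.grantham_matrix <- function() {
  d <- outer(seq_len(20), seq_len(20), function(i, j) {
    50.723 * sqrt(1.833 * (.GRANTHAM_C[i] - .GRANTHAM_C[j])^2 +
                  0.1018 * (.GRANTHAM_P[i] - .GRANTHAM_P[j])^2 +
                  0.000399 * (.GRANTHAM_V[i] - .GRANTHAM_V[j])^2)
  })
  d <- round(d)  # Grantham's table is published at integer precision
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d
}

# Synthetic physicochemical distance matrix: Euclidean distance between
# residues in the space of the three standardised Chou properties, scaled so
# the largest inter-residue distance is 1. This is a stand-in of our own
# construction (NOT the Schneider-Wrede matrix) used as the second distance
# source for the sequence-order descriptors.
.physchem_distance_matrix <- function(paac_props) {
  d <- as.matrix(stats::dist(t(paac_props)))
  d <- d / max(d)
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d
}

.tables_cache <- new.env(parent = emptyenv())

#' Physicochemical property tables behind the descriptor engine
#'
#' Builds (once per session, then cached) the bundle of residue property
#' tables that fixes the descriptor layout: the 531 complete AAindex indices
#' (from [seqinr]'s copy of the AAindex database, entries with missing residue
#' values dropped), the five z-scales, Chou's three normalised properties for
#' (amphiphilic) pseudo amino-acid composition, eight standardised
#' autocorrelation properties, two 20x20 inter-residue distance matrices
#' (Grantham, reconstructed from its published component properties, and a
#' synthetic physicochemical distance built from the three Chou properties),
#' the 13 three-way CTD groupings, the five-way composition grouping, and the
#' per-residue codon counts for the dipeptide-deviation background.
#'
#' @return An object of class `property_tables`: a list with elements
#'   `aaindex` (531 x 20 matrix), `zscales` (20 x 5), `paac_props` (3 x 20,
#'   standardised), `autocorr_props` (8 x 20, standardised), `grantham` and
#'   `physchem` (20 x 20 distance matrices), `ctd_groups`, `ctd_group_index`,
#'   `gaac_groups`, `gaac_group_index`, `codon_counts`.
#' @examples
#' tb <- property_tables()
#' dim(tb$aaindex)  # 531 20
#' @export
property_tables <- function() {
  if (!is.null(.tables_cache$bundle)) {
    return(.tables_cache$bundle)
  }
  paac_props <- rbind(
    hydrophobicity = .standardise20(.PAAC_HYDROPHOBICITY[AA_ALPHABET]),
    hydrophilicity = .standardise20(.PAAC_HYDROPHILICITY[AA_ALPHABET]),
    sidechainmass  = .standardise20(.PAAC_SIDECHAIN_MASS[AA_ALPHABET]))
  colnames(paac_props) <- AA_ALPHABET
  aaindex_mat <- .build_aaindex_matrix()
  autocorr <- aaindex_mat[.AUTOCORR_ACCESSIONS, , drop = FALSE]
  autocorr <- t(apply(autocorr, 1, .standardise20))
  colnames(autocorr) <- AA_ALPHABET
  bundle <- structure(list(
    aaindex = aaindex_mat,
    zscales = .ZSCALES,
    paac_props = paac_props,
    autocorr_props = autocorr,
    grantham = .grantham_matrix(),
    physchem = .physchem_distance_matrix(paac_props),
    ctd_groups = .CTD_GROUPS,
    ctd_group_index = lapply(.CTD_GROUPS, .group_index),
    gaac_groups = .GAAC_GROUPS,
    gaac_group_index = .group_index(
      lapply(.GAAC_GROUPS, paste, collapse = "")),
    codon_counts = .CODON_COUNTS[AA_ALPHABET]
  ), class = "property_tables")
  validate_property_tables(bundle)
  .tables_cache$bundle <- bundle
  bundle
}

#' Validate a property-table bundle
#'
#' Checks that every table covers exactly the 20 standard residues with no
#' missing values, that each CTD grouping partitions the alphabet, and that
#' distance matrices are symmetric with zero diagonal.
#'
#' @param tables a `property_tables` bundle.
#' @return `tables`, invisibly; errors on any violation.
#' @export
validate_property_tables <- function(tables) {
  stopifnot(
    inherits(tables, "property_tables"),
    nrow(tables$aaindex) == 531L,
    identical(colnames(tables$aaindex), AA_ALPHABET),
    !anyNA(tables$aaindex),
    identical(rownames(tables$zscales), AA_ALPHABET),
    identical(colnames(tables$paac_props), AA_ALPHABET),
    nrow(tables$autocorr_props) == 8L,
    identical(dim(tables$grantham), c(20L, 20L)),
    identical(dim(tables$physchem), c(20L, 20L)),
    all(diag(tables$grantham) == 0),
    all(diag(tables$physchem) == 0),
    isTRUE(all.equal(tables$grantham, t(tables$grantham))),
    isTRUE(all.equal(tables$physchem, t(tables$physchem)))
  )
  for (prop in names(tables$ctd_groups)) {
    letters_all <- sort(unlist(strsplit(tables$ctd_groups[[prop]], "")))
    if (!identical(letters_all, sort(AA_ALPHABET))) {
      stop("CTD grouping for '", prop, "' is not a partition of the alphabet")
    }
  }
  gl <- sort(unname(unlist(tables$gaac_groups)))
  stopifnot(identical(gl, sort(AA_ALPHABET)))
  invisible(tables)
}

#' Fingerprint of the property-table bundle
#'
#' A deterministic numeric checksum over every table in the bundle, so runs
#' can assert they used identical descriptor layouts.
#'
#' @param tables a `property_tables` bundle (default: the session bundle).
#' @return a single character string (md5 of the rounded table values).
#' @export
property_tables_checksum <- function(tables = property_tables()) {
  nums <- c(as.vector(tables$aaindex), as.vector(tables$zscales),
            as.vector(tables$paac_props), as.vector(tables$autocorr_props),
            as.vector(tables$grantham), as.vector(tables$physchem),
            as.vector(tables$codon_counts))
  txt <- paste(c(sprintf("%.10g", nums),
                 unlist(tables$ctd_groups),
                 unlist(tables$gaac_groups)), collapse = "|")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
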