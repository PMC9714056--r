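#' Descriptor configuration
#'
#' Holds every tunable of the descriptor engine. The defaults (`lambda = 5`,
#' `nlag = 5`, `egaac_window = 5`) are the maximum values admissible for
#' hexapeptides and are exactly the settings under which the fifteen family
#' dimensions sum to 4125 for a length-6 sequence.
#'
#' @param lambda sequence-correlation rank of the pseudo amino-acid
#'   composition families (must be < sequence length).
#' @param w weight factor of the PAAC/APAAC correlation terms.
#' @param qso_w weight factor of the quasi-sequence-order coupling terms.
#' @param nlag maximum lag of the sequence-order coupling numbers,
#'   quasi-sequence-order and autocorrelation families (< sequence length).
#' @param egaac_window sliding-window width of the enhanced grouped
#'   composition (<= sequence length).
#' @param family_order the fifteen family names, in concatenation order.
#' @return a `descriptor_config` list.
#' @examples
#' cfg <- descriptor_config()
#' descriptor_dimension(cfg, length = 6)  # 4125
#' @export
descriptor_config <- function(lambda = 5L, w = 0.05, qso_w = 0.1,
                              nlag = 5L, egaac_window = 5L,
                              family_order = DESCRIPTOR_FAMILIES) {
  stopifnot(lambda >= 1, nlag >= 1, egaac_window >= 1, w > 0, qso_w > 0,
            all(family_order %in% DESCRIPTOR_FAMILIES),
            !anyDuplicated(family_order))
  structure(list(lambda = as.integer(lambda), w = w, qso_w = qso_w,
                 nlag = as.integer(nlag),
                 egaac_window = as.integer(egaac_window),
                 family_order = family_order),
            class = "descriptor_config")
}

#' The fifteen descriptor family names in default concatenation order
#' @export
DESCRIPTOR_FAMILIES <- c("AAINDEX", "ZSCALE", "EGAAC", "DDE", "GAAC", "GDPC",
                         "CTDC", "CTDD", "PAAC", "APAAC", "QSOrder",
                         "SOCNumber", "NMBroto", "Moran", "Geary")

#' Per-family and total descriptor dimensions for a configuration
#'
#' @param config a [descriptor_config()].
#' @param length sequence length the configuration will be applied to.
#' @return named integer vector of per-family dimensions, with attribute
#'   `"total"`; `descriptor_dimension()` returns the total only.
#' @export
descriptor_dimensions <- function(config = descriptor_config(), length = 6L) {
  L <- as.integer(length)
  dims <- c(
    AAINDEX = 531L * L,
    ZSCALE = 5L * L,
    EGAAC = (L - config$egaac_window + 1L) * 5L,
    DDE = 400L,
    GAAC = 5L,
    GDPC = 25L,
    CTDC = 39L,
    CTDD = 195L,
    PAAC = 20L + config$lambda,
    APAAC = 20L + 2L * config$lambda,
    QSOrder = 2L * (20L + config$nlag),
    SOCNumber = 2L * config$nlag,
    NMBroto = 8L * config$nlag,
    Moran = 8L * config$nlag,
    Geary = 8L * config$nlag)
  dims <- dims[config$family_order]
  attr(dims, "total") <- sum(dims)
  dims
}

#' @rdname descriptor_dimensions
#' @export
descriptor_dimension <- function(config = descriptor_config(), length = 6L) {
  as.integer(attr(descriptor_dimensions(config, length), "total"))
}

# ---- sequence checks -------------------------------------------------------

.seq_to_index <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop("non-standard residue '", chars[p], "' at position ", p)
  }
  idx
}

.check_len <- function(len, minimum, what) {
  if (len < minimum) {
    stop("sequence too short for ", what, ": length ", len,
         " < required ", minimum)
  }
}

# ---- composition families --------------------------------------------------

#' Grouped amino-acid composition (GAAC)
#'
#' Frequency of the five physicochemical residue groups (aliphatic, aromatic,
#' positive, negative, uncharged); sums to 1.
#'
#' @param sequence peptide sequence over the 20 standard residues.
#' @param config a [descriptor_config()].
#' @param tables a [property_tables()] bundle.
#' @return named numeric vector of 5 group frequencies.
#' @export
gaac <- function(sequence, config = descriptor_config(),
                 tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  g <- tabulate(tables$gaac_group_index[idx], nbins = 5L) / length(idx)
  names(g) <- paste0("GAAC.", names(tables$gaac_groups))
  g
}

#' Enhanced grouped amino-acid composition (EGAAC)
#'
#' Grouped composition inside a window sliding from the N- to the C-terminus;
#' each window block sums to 1.
#'
#' @inheritParams gaac
#' @return numeric vector of length `(len - window + 1) * 5`.
#' @export
egaac <- function(sequence, config = descriptor_config(),
                  tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  win <- config$egaac_window
  .check_len(length(idx), win, sprintf("EGAAC window %d", win))
  n_win <- length(idx) - win + 1L
  out <- numeric(n_win * 5L)
  gi <- tables$gaac_group_index[idx]
  for (k in seq_len(n_win)) {
    out[(k - 1L) * 5L + 1:5] <- tabulate(gi[k:(k + win - 1L)], 5L) / win
  }
  names(out) <- paste0("EGAAC.", rep(names(tables$gaac_groups), n_win),
                       ".w", rep(seq_len(n_win), each = 5L))
  out
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' For each of the 400 ordered dipeptides d: `DDE(d) = (Dc - Tm) / sqrt(Tv)`
#' with `Dc` the observed dipeptide fraction, `Tm = (Ca/61)(Cb/61)` the
#' codon-background expectation and `Tv = Tm (1 - Tm) / (len - 1)`.
#'
#' @inheritParams gaac
#' @return named numeric vector of 400 values.
#' @export
dde <- function(sequence, config = descriptor_config(),
                tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  .check_len(length(idx), 2L, "dipeptide counting")
  n_dip <- length(idx) - 1L
  codes <- (idx[-length(idx)] - 1L) * 20L + idx[-1L]
  dc <- tabulate(codes, nbins = 400L) / n_dip
  cfrac <- tables$codon_counts / 61
  # tm[(a-1)*20 + b] = (C_a/61)(C_b/61), matching the dipeptide codes above
  tm <- rep(cfrac, each = 20L) * rep(cfrac, times = 20L)
  tv <- tm * (1 - tm) / n_dip
  out <- (dc - tm) / sqrt(tv)
  names(out) <- paste0("DDE.", rep(AA_ALPHABET, each = 20L),
                       rep(AA_ALPHABET, 20L))
  out
}

#' Grouped dipeptide composition (GDPC)
#'
#' Frequency of ordered pairs of the five residue groups; sums to 1.
#'
#' @inheritParams gaac
#' @return named numeric vector of 25 values.
#' @export
gdpc <- function(sequence, config = descriptor_config(),
                 tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  .check_len(length(idx), 2L, "dipeptide counting")
  gi <- tables$gaac_group_index[idx]
  codes <- (gi[-length(gi)] - 1L) * 5L + gi[-1L]
  out <- tabulate(codes, nbins = 25L) / (length(idx) - 1L)
  gn <- names(tables$gaac_groups)
  names(out) <- paste0("GDPC.", rep(gn, each = 5L), ".", rep(gn, 5L))
  out
}

#' CTD composition (CTDC)
#'
#' For each of 13 physicochemical properties, the fraction of residues in
#' each of its three groups (each property's triple sums to 1).
#'
#' @inheritParams gaac
#' @return named numeric vector of 39 values.
#' @export
ctdc <- function(sequence, config = descriptor_config(),
                 tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  out <- unlist(lapply(names(tables$ctd_group_index), function(prop) {
    tabulate(tables$ctd_group_index[[prop]][idx], nbins = 3L) / length(idx)
  }))
  names(out) <- paste0("CTDC.", rep(names(tables$ctd_groups), each = 3L),
                       ".G", rep(1:3, 13L))
  out
}

#' CTD distribution (CTDD)
#'
#' For each property and group: the sequence positions (as percentages of the
#' length) at which the first occurrence and the 25/50/75/100% occurrence
#' quantiles of that group fall. The quantile rank is `ceiling(fraction *
#' group count)`, floored at 1; an absent group contributes five zeros.
#'
#' @inheritParams gaac
#' @return named numeric vector of 195 values, all in \[0, 100\].
#' @export
ctdd <- function(sequence, config = descriptor_config(),
                 tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  len <- length(idx)
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  out <- numeric(0)
  for (prop in names(tables$ctd_group_index)) {
    gi <- tables$ctd_group_index[[prop]][idx]
    for (g in 1:3) {
      pos <- which(gi == g)
      if (length(pos) == 0L) {
        out <- c(out, numeric(5))
      } else {
        ranks <- pmax(1L, ceiling(fracs * length(pos)))
        out <- c(out, pos[ranks] / len * 100)
      }
    }
  }
  names(out) <- paste0("CTDD.", rep(names(tables$ctd_groups), each = 15L),
                       ".G", rep(rep(1:3, each = 5L), 13L),
                       ".p", rep(c(1, 25, 50, 75, 100), 39L))
  out
}

# ---- positional encodings --------------------------------------------------

#' AAindex positional encoding
#'
#' Value of each of the 531 complete AAindex indices at every sequence
#' position (position-major order).
#'
#' @inheritParams gaac
#' @return named numeric vector of `531 * len` values.
#' @export
aaindex_encode <- function(sequence, config = descriptor_config(),
                           tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  out <- as.vector(tables$aaindex[, idx])
  names(out) <- paste0("AAINDEX.", rep(rownames(tables$aaindex), length(idx)),
                       ".p", rep(seq_along(idx), each = nrow(tables$aaindex)))
  out
}

#' Z-scale positional encoding
#'
#' The five z-scale values of the residue at every position (position-major).
#'
#' @inheritParams gaac
#' @return named numeric vector of `5 * len` values.
#' @export
zscale_encode <- function(sequence, config = descriptor_config(),
                          tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  out <- as.vector(t(tables$zscales[idx, , drop = FALSE]))
  names(out) <- paste0("ZSCALE.", rep(colnames(tables$zscales), length(idx)),
                       ".p", rep(seq_along(idx), each = 5L))
  out
}

# ---- pseudo amino-acid composition families --------------------------------

# mean over the three standardised properties of squared differences
.paac_theta <- function(idx, lambda, props) {
  len <- length(idx)
  vapply(seq_len(lambda), function(j) {
    i <- seq_len(len - j)
    mean(vapply(seq_len(nrow(props)), function(p) {
      mean((props[p, idx[i]] - props[p, idx[i + j]])^2)
    }, numeric(1)))
  }, numeric(1))
}

#' Pseudo amino-acid composition (PAAC)
#'
#' Chou's pseudo amino-acid composition: 20 composition terms plus `lambda`
#' sequence-correlation terms built from squared differences of the three
#' standardised properties, jointly normalised so the full vector sums to 1.
#'
#' @inheritParams gaac
#' @return named numeric vector of `20 + lambda` values.
#' @export
paac <- function(sequence, config = descriptor_config(),
                 tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  .check_len(length(idx), config$lambda + 1L,
             sprintf("PAAC lambda %d", config$lambda))
  f <- tabulate(idx, nbins = 20L) / length(idx)
  theta <- .paac_theta(idx, config$lambda, tables$paac_props)
  denom <- sum(f) + config$w * sum(theta)
  out <- c(f / denom, config$w * theta / denom)
  names(out) <- c(paste0("PAAC.Xc1.", AA_ALPHABET),
                  paste0("PAAC.Xc2.lambda", seq_len(config$lambda)))
  out
}

#' Amphiphilic pseudo amino-acid composition (APAAC)
#'
#' 20 composition terms plus `2 * lambda` amphiphilic correlation terms
#' (hydrophobicity and hydrophilicity product-correlations at each lag),
#' jointly normalised to sum 1.
#'
#' @inheritParams gaac
#' @return named numeric vector of `20 + 2 * lambda` values.
#' @export
apaac <- function(sequence, config = descriptor_config(),
                  tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  .check_len(length(idx), config$lambda + 1L,
             sprintf("APAAC lambda %d", config$lambda))
  len <- length(idx)
  h <- tables$paac_props[c("hydrophobicity", "hydrophilicity"), ,
                         drop = FALSE]
  f <- tabulate(idx, nbins = 20L) / len
  tau <- numeric(2L * config$lambda)
  for (j in seq_len(config$lambda)) {
    i <- seq_len(len - j)
    for (p in 1:2) {
      tau[2L * (j - 1L) + p] <- mean(h[p, idx[i]] * h[p, idx[i + j]])
    }
  }
  denom <- sum(f) + config$w * sum(tau)
  out <- c(f / denom, config$w * tau / denom)
  names(out) <- c(paste0("APAAC.Pc1.", AA_ALPHABET),
                  paste0("APAAC.Pc2.",
                         rep(c("Hphob", "Hphil"), config$lambda),
                         ".lambda",
                         rep(seq_len(config$lambda), each = 2L)))
  out
}

# ---- sequence-order families -----------------------------------------------

.soc_tau <- function(idx, nlag, dmat) {
  len <- length(idx)
  vapply(seq_len(nlag), function(d) {
    i <- seq_len(len - d)
    sum(dmat[cbind(idx[i], idx[i + d])]^2)
  }, numeric(1))
}

#' Sequence-order coupling numbers (SOCNumber)
#'
#' `tau_d = sum_i dist(R_i, R_(i+d))^2` for lags 1..nlag, computed once for
#' the synthetic physicochemical distance matrix and once for the Grantham
#' matrix.
#'
#' @inheritParams gaac
#' @return named numeric vector of `2 * nlag` values, all >= 0.
#' @export
socnumber <- function(sequence, config = descriptor_config(),
                      tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  .check_len(length(idx), config$nlag + 1L,
             sprintf("SOCNumber nlag %d", config$nlag))
  out <- c(.soc_tau(idx, config$nlag, tables$physchem),
           .soc_tau(idx, config$nlag, tables$grantham))
  names(out) <- paste0("SOCNumber.",
                       rep(c("physchem", "grantham"), each = config$nlag),
                       ".d", rep(seq_len(config$nlag), 2L))
  out
}

#' Quasi-sequence-order descriptors (QSOrder)
#'
#' Per distance matrix: 20 composition terms `f_r / (sum f + w sum tau)`
#' followed by `nlag` coupling terms `w tau_d / (sum f + w sum tau)`; with
#' fractional composition each matrix block sums to 1.
#'
#' @inheritParams gaac
#' @return named numeric vector of `2 * (20 + nlag)` values.
#' @export
qsorder <- function(sequence, config = descriptor_config(),
                    tables = property_tables()) {
  idx <- .seq_to_index(sequence)
  .check_len(length(idx), config$nlag + 1L,
             sprintf("QSOrder nlag %d", config$nlag))
  f <- tabulate(idx, nbins = 20L) / length(idx)
  block <- function(dmat, label) {
    tau <- .soc_tau(idx, config$nlag, dmat)
    denom <- sum(f) + config$qso_w * sum(tau)
    v <- c(f / denom, config$qso_w * tau / denom)
    names(v) <- c(paste0("QSOrder.", label, ".Xr.", AA_ALPHABET),
                  paste0("QSOrder.", label, ".tau", seq_len(config$nlag)))
    v
  }
  c(block(tables$physchem, "physchem"), block(tables$grantham, "grantham"))
}

# ---- autocorrelation families ----------------------------------------------

#' Autocorrelation descriptors (Moreau-Broto, Moran, Geary)
#'
#' For each of the eight standardised properties and each lag d = 1..nlag:
#' the normalised Moreau-Broto average product, the Moran centred and
#' variance-normalised form, or the Geary squared-difference form. On
#' zero-variance sequences (homopeptides) Moran and Geary are defined as 0 so
#' that every valid input yields a finite vector.
#'
#' @inheritParams gaac
#' @param kind one of `"NMBroto"`, `"Moran"`, `"Geary"`.
#' @return named numeric vector of `8 * nlag` values.
#' @export
autocorrelation <- function(sequence, kind = c("NMBroto", "Moran", "Geary"),
                            config = descriptor_config(),
                            tables = property_tables()) {
  kind <- match.arg(kind)
  idx <- .seq_to_index(sequence)
  .check_len(length(idx), config$nlag + 1L,
             sprintf("%s nlag %d", kind, config$nlag))
  len <- length(idx)
  props <- tables$autocorr_props
  out <- numeric(nrow(props) * config$nlag)
  k <- 1L
  for (p in seq_len(nrow(props))) {
    x <- props[p, idx]
    xbar <- mean(x)
    v_pop <- mean((x - xbar)^2)       # Moran denominator (population)
    v_smp <- sum((x - xbar)^2) / (len - 1L)  # Geary denominator (sample)
    for (d in seq_len(config$nlag)) {
      i <- seq_len(len - d)
      out[k] <- switch(kind,
        NMBroto = mean(x[i] * x[i + d]),
        Moran = if (v_pop <= .Machine$double.eps) 0 else
          mean((x[i] - xbar) * (x[i + d] - xbar)) / v_pop,
        Geary = if (v_smp <= .Machine$double.eps) 0 else
          (sum((x[i] - x[i + d])^2) / (2 * (len - d))) / v_smp)
      k <- k + 1L
    }
  }
  names(out) <- paste0(kind, ".",
                       rep(rownames(props), each = config$nlag),
                       ".d", rep(seq_len(config$nlag), nrow(props)))
  out
}

# ---- full vector / matrix --------------------------------------------------

.family_fun <- function(family) {
  switch(family,
    AAINDEX = aaindex_encode,
    ZSCALE = zscale_encode,
    EGAAC = egaac,
    DDE = dde,
    GAAC = gaac,
    GDPC = gdpc,
    CTDC = ctdc,
    CTDD = ctdd,
    PAAC = paac,
    APAAC = apaac,
    QSOrder = qsorder,
    SOCNumber = socnumber,
    NMBroto = function(s, config, tables)
      autocorrelation(s, "NMBroto", config, tables),
    Moran = function(s, config, tables)
      autocorrelation(s, "Moran", config, tables),
    Geary = function(s, config, tables)
      autocorrelation(s, "Geary", config, tables),
    stop("unknown descriptor family: ", family))
}

#' Full descriptor vector for one sequence
#'
#' Concatenates the families in `config$family_order`; with the default
#' configuration a hexapeptide yields exactly 4125 named, finite values.
#'
#' @inheritParams gaac
#' @return named numeric vector.
#' @export
descriptor_vector <- function(sequence, config = descriptor_config(),
                              tables = property_tables()) {
  unlist(lapply(config$family_order, function(fam) {
    .family_fun(fam)(sequence, config = config, tables = tables)
  }), use.names = TRUE)
}

#' Descriptor matrix for a labelled dataset
#'
#' Applies [descriptor_vector()] to every record. All sequences must share
#' one length compatible with the configuration. Per-record failures are
#' re-raised with the record id attached.
#'
#' @param ds a `peptide_set` (or a data frame with `id` and `sequence`; a
#'   `label` column is carried along when present).
#' @param config a [descriptor_config()].
#' @param tables a [property_tables()] bundle.
#' @return a `feature_matrix`: list with `x` (numeric matrix, row names =
#'   ids), `ids`, and `labels` (factor or NULL).
#' @export
extract_all <- function(ds, config = descriptor_config(),
                        tables = property_tables()) {
  stopifnot(is.data.frame(ds), all(c("id", "sequence") %in% names(ds)))
  lens <- unique(nchar(ds$sequence))
  if (nrow(ds) > 0 && length(lens) != 1L) {
    stop("all sequences must have the same length; found lengths: ",
         paste(sort(lens), collapse = ", "))
  }
  if (nrow(ds) == 0L) {
    return(feature_matrix(matrix(numeric(0), nrow = 0, ncol = 0),
                          character(0), NULL))
  }
  first <- descriptor_vector(ds$sequence[1], config, tables)
  x <- matrix(NA_real_, nrow = nrow(ds), ncol = length(first),
              dimnames = list(ds$id, names(first)))
  x[1, ] <- first
  if (nrow(ds) > 1L) {
    for (r in 2:nrow(ds)) {
      x[r, ] <- tryCatch(
        unname(descriptor_vector(ds$sequence[r], config, tables)),
        error = function(e) stop("record '", ds$id[r], "': ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  if (anyDuplicated(colnames(x))) stop("descriptor names are not unique")
  labels <- if ("label" %in% names(ds)) .label_factor(ds$label) else NULL
  feature_matrix(x, ds$id, labels)
}

#' Feature matrix container
#'
#' @param x numeric matrix (rows = records, columns = named descriptors).
#' @param ids character row ids.
#' @param labels factor of class labels aligned to rows, or NULL.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(x, ids = rownames(x), labels = NULL) {
  stopifnot(is.matrix(x))
  if (!is.null(labels)) {
    labels <- .label_factor(labels)
    stopifnot(length(labels) == nrow(x))
  }
  structure(list(x = x, ids = as.character(ids), labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d records x %d descriptors%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else " (labelled)"))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' Write / read a feature matrix as TSV
#'
#' Layout: `id`, `label` (empty when unlabelled) and one column per
#' descriptor, header row carrying the descriptor names.
#'
#' @param fm a `feature_matrix`.
#' @param path file path.
#' @return `write_feature_matrix()`: `path` invisibly;
#'   `read_feature_matrix()`: a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  lab <- if (is.null(fm$labels)) "" else as.character(fm$labels)
  df <- data.frame(id = fm$ids, label = lab, fm$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  stopifnot(all(c("id", "label") %in% names(df)))
  x <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  rownames(x) <- df$id
  labels <- if (all(is.na(df$label)) || all(df$label == "")) NULL else
    df$label
  feature_matrix(x, df$id, labels)
}
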