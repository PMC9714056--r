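test_that("per-family dimensions close the 4125 ledger on hexapeptides", {
  dims <- descriptor_dimensions()
  expect_equal(unname(dims[c("AAINDEX", "ZSCALE", "EGAAC", "DDE", "GAAC",
                             "GDPC", "CTDC", "CTDD", "PAAC", "APAAC",
                             "QSOrder", "SOCNumber", "NMBroto", "Moran",
                             "Geary")]),
               c(3186L, 30L, 10L, 400L, 5L, 25L, 39L, 195L, 25L, 30L,
                 50L, 10L, 40L, 40L, 40L))
  expect_equal(attr(dims, "total"), 4125L)
  v <- descriptor_vector("NFGAIL")
  expect_length(v, 4125)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_true(all(is.finite(v)))
  # per-family vector lengths agree with the ledger
  for (fam in c("GAAC", "CTDC", "CTDD", "PAAC", "APAAC", "QSOrder")) {
    expect_equal(sum(startsWith(names(v), paste0(fam, "."))),
                 unname(dims[[fam]]))
  }
})

test_that("normalised families sum to one on random hexapeptides", {
  for (s in random_hexapeptides(20, seed = 31)) {
    expect_equal(sum(gaac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(gdpc(s)), 1, tolerance = 1e-9)
    expect_equal(sum(paac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(apaac(s)), 1, tolerance = 1e-9)
    cc <- ctdc(s)
    expect_equal(as.numeric(tapply(cc, rep(1:13, each = 3), sum)),
                 rep(1, 13), tolerance = 1e-9)
    qs <- qsorder(s)
    expect_equal(sum(qs[1:25]), 1, tolerance = 1e-9)
    expect_equal(sum(qs[26:50]), 1, tolerance = 1e-9)
    eg <- egaac(s)
    expect_equal(as.numeric(tapply(eg, rep(1:2, each = 5), sum)),
                 c(1, 1), tolerance = 1e-9)
    expect_true(all(is.finite(descriptor_vector(s))))
  }
})

test_that("homopeptides reduce to their closed forms", {
  tb <- property_tables()
  g <- gaac("AAAAAA")
  expect_equal(unname(g[["GAAC.aliphatic"]]), 1)
  expect_equal(sum(g), 1)

  eg <- egaac("AAAAAA")
  expect_length(eg, 10)
  expect_equal(unname(eg[grepl("aliphatic", names(eg))]), c(1, 1))

  p <- paac("AAAAAA")
  expect_equal(unname(p[["PAAC.Xc1.A"]]), 1)
  expect_true(all(abs(p[names(p) != "PAAC.Xc1.A"]) < 1e-12))

  a <- apaac("AAAAAA")
  # every lag term is the squared standardised property of A, prior to the
  # joint normalisation
  h1 <- tb$paac_props["hydrophobicity", "A"]
  h2 <- tb$paac_props["hydrophilicity", "A"]
  tau <- c(h1^2, h2^2)
  denom <- 1 + 0.05 * sum(rep(tau, 5))
  expect_equal(unname(a[["APAAC.Pc1.A"]]), 1 / denom, tolerance = 1e-12)
  expect_equal(unname(a[["APAAC.Pc2.Hphob.lambda3"]]), 0.05 * h1^2 / denom,
               tolerance = 1e-12)

  expect_true(all(socnumber("AAAAAA") == 0))
  qs <- qsorder("AAAAAA")
  expect_equal(unname(qs[["QSOrder.physchem.Xr.A"]]), 1)
  expect_equal(unname(qs[["QSOrder.grantham.Xr.A"]]), 1)
  expect_true(all(abs(qs[!grepl("Xr.A", names(qs), fixed = TRUE)]) < 1e-12))

  nm <- autocorrelation("AAAAAA", "NMBroto")
  pA <- tb$autocorr_props[, "A"]
  expect_equal(unname(nm), unname(rep(pA^2, each = 5)), tolerance = 1e-12)
  expect_true(all(autocorrelation("AAAAAA", "Moran") == 0))
  expect_true(all(autocorrelation("AAAAAA", "Geary") == 0))

  z <- zscale_encode("KKKKKK")
  expect_equal(unname(z), rep(unname(tb$zscales["K", ]), 6))
})

test_that("grouped composition matches a hand count for DEKRHC", {
  g <- gaac("DEKRHC")
  expect_equal(unname(g[["GAAC.negative"]]), 2 / 6)
  expect_equal(unname(g[["GAAC.positive"]]), 3 / 6)
  expect_equal(unname(g[["GAAC.uncharged"]]), 1 / 6)
  expect_equal(unname(g[["GAAC.aliphatic"]]), 0)
  expect_equal(unname(g[["GAAC.aromatic"]]), 0)
})

test_that("DDE matches direct evaluation and a brute-force oracle", {
  d <- dde("AAAAAA")
  tm <- (4 / 61)^2
  tv <- tm * (1 - tm) / 5
  expect_equal(unname(d[["DDE.AA"]]), (1 - tm) / sqrt(tv), tolerance = 1e-12)
  # absent dipeptides are negative
  expect_true(all(d[names(d) != "DDE.AA"] < 0))
  for (s in random_hexapeptides(20, seed = 13)) {
    expect_equal(unname(dde(s)), unname(oracle_dde(s)), tolerance = 1e-10)
  }
})

test_that("CTD distribution follows the ceiling-quantile convention", {
  cd <- ctdd("AAAAAA")
  block <- cd[grep("hydrophobicity_PRAM900101.G2", names(cd), fixed = TRUE)]
  expect_equal(unname(block), c(1, 2, 3, 5, 6) / 6 * 100, tolerance = 1e-9)
  # groups absent from the homopeptide contribute five zeros
  g3 <- cd[grep("hydrophobicity_PRAM900101.G3", names(cd), fixed = TRUE)]
  expect_equal(unname(g3), rep(0, 5))
  for (s in random_hexapeptides(10, seed = 21)) {
    v <- ctdd(s)
    expect_true(all(v >= 0 & v <= 100))
  }
})

test_that("positional encodings are exact lookups with local block diffs", {
  tb <- property_tables()
  a <- aaindex_encode("NFGAIL")
  expect_length(a, 3186)
  expect_equal(unname(a[["AAINDEX.ANDN920101.p1"]]),
               unname(tb$aaindex["ANDN920101", "N"]))
  # sequences differing only at position 3 differ only in .p3 names
  a2 <- aaindex_encode("NFWAIL")
  changed <- names(a)[a != a2]
  expect_true(all(grepl("\\.p3$", changed)))
  z <- zscale_encode("NFGAIL")
  z2 <- zscale_encode("NFWAIL")
  expect_true(all(grepl("\\.p3$", names(z)[z != z2])))
})

test_that("sequence-order and autocorrelation families match brute force", {
  for (s in random_hexapeptides(20, seed = 17)) {
    expect_equal(unname(socnumber(s)), unname(oracle_socnumber(s)),
                 tolerance = 1e-10)
    for (kind in c("NMBroto", "Moran", "Geary")) {
      expect_equal(unname(autocorrelation(s, kind)),
                   unname(oracle_autocorr(s, kind)), tolerance = 1e-10)
    }
  }
})

test_that("PAAC matches an explicit double-loop oracle", {
  for (s in random_hexapeptides(15, seed = 19)) {
    expect_equal(unname(paac(s)), unname(oracle_paac(s)), tolerance = 1e-10)
  }
})

test_that("composition families are permutation-invariant, order families are not", {
  s <- "NFGAIL"
  perm <- "LIAGFN"  # reversal: same residue multiset
  expect_equal(unname(gaac(s)), unname(gaac(perm)))
  expect_equal(unname(ctdc(s)), unname(ctdc(perm)))
  # targeted swap changes order-sensitive families
  swapped <- "LFGAIN"  # positions 1 and 6 exchanged
  expect_false(isTRUE(all.equal(unname(socnumber(s)),
                                unname(socnumber(swapped)))))
  expect_false(isTRUE(all.equal(unname(aaindex_encode(s)),
                                unname(aaindex_encode(swapped)))))
  expect_false(isTRUE(all.equal(unname(autocorrelation(s, "NMBroto")),
                                unname(autocorrelation(swapped, "NMBroto")))))
})

test_that("invalid residues and too-short sequences raise named errors", {
  expect_error(gaac("NFGXIL"), "'X' at position 4")
  expect_error(egaac("NFGA"), "EGAAC window 5")
  expect_error(paac("NFGA", descriptor_config()), "lambda")
  expect_error(socnumber("NFG"), "nlag")
})

test_that("extract_all equals per-family concatenation with no hidden state", {
  ds <- peptide_set(c("a", "b", "c"),
                    c("NFGAIL", "NFGAIL", "STVIEW"),
                    c("amyloid", "amyloid", "non-amyloid"))
  fm <- extract_all(ds)
  expect_equal(dim(fm$x), c(3L, 4125L))
  # identical sequences give bit-identical rows
  expect_identical(unname(fm$x["a", ]), unname(fm$x["b", ]))
  cfg <- descriptor_config()
  manual <- unlist(lapply(cfg$family_order, function(fam) {
    fn <- switch(fam,
      AAINDEX = aaindex_encode, ZSCALE = zscale_encode, EGAAC = egaac,
      DDE = dde, GAAC = gaac, GDPC = gdpc, CTDC = ctdc, CTDD = ctdd,
      PAAC = paac, APAAC = apaac, QSOrder = qsorder, SOCNumber = socnumber,
      NMBroto = function(s, ...) autocorrelation(s, "NMBroto"),
      Moran = function(s, ...) autocorrelation(s, "Moran"),
      Geary = function(s, ...) autocorrelation(s, "Geary"))
    fn("STVIEW")
  }))
  expect_equal(fm$x["c", ], manual)
  # per-record error propagation names the offending id
  bad <- data.frame(id = c("ok", "oops"), sequence = c("NFGAIL", "NFGAIL"),
                    stringsAsFactors = FALSE)
  bad$sequence[2] <- "NFGXIL"
  expect_error(extract_all(bad), "oops")
  expect_error(extract_all(data.frame(id = c("a", "b"),
                                      sequence = c("NFGAIL", "NFGA"))),
               "same length")
})

test_that("feature matrices round-trip through TSV", {
  ds <- gen_labelled_fixture(fixture_spec(5, seed = 23))
  fm <- extract_all(ds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$ids, fm$ids)
  expect_equal(back$labels, fm$labels)
  expect_equal(colnames(back$x), colnames(fm$x))
  expect_equal(unname(back$x), unname(fm$x), tolerance = 1e-12)
})

test_that("the property bundle validates and fingerprints stably", {
  tb <- property_tables()
  expect_silent(validate_property_tables(tb))
  expect_equal(property_tables_checksum(tb), property_tables_checksum(tb))
  expect_equal(nrow(tb$aaindex), 531L)
  expect_equal(unname(tb$grantham["L", "I"]), 5)
})
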