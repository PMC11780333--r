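test_that("parseCall maps every dialect token to the right call", {
  c1 <- parseCall("1|1", "PHASED")
  expect_identical(c(c1@hap1, c1@hap2, c1@phased), c("B", "B", "TRUE"))
  c2 <- parseCall("N", "SIMPLE")
  expect_identical(c(c2@hap1, c2@hap2), c("MISSING", "MISSING"))
  expect_false(c2@phased)
  c3 <- parseCall("H", "SIMPLE")
  expect_identical(c(c3@hap1, c3@hap2), c("A", "B"))
  expect_false(c3@phased)
  ## phased order is information
  c4 <- parseCall("1|0", "PHASED")
  expect_identical(c(c4@hap1, c4@hap2), c("B", "A"))
  ## unphased het canonicalized to (A, B)
  c5 <- parseCall("1/0", "UNPHASED")
  expect_identical(c(c5@hap1, c5@hap2), c("A", "B"))
  expect_false(c5@phased)
})

test_that("parseCall is total over each dialect's token set and rejects the rest", {
  for (d in listDialects()) {
    toks <- dialectTokens(d)
    expect_length(toks, if (d == "SIMPLE") 4L else 5L)
    for (t in toks) expect_s4_class(parseCall(t, d), "Call")
    ## tokens of the other dialects all fail under d
    foreign <- setdiff(unlist(lapply(listDialects(), dialectTokens)), toks)
    for (t in foreign) expect_error(parseCall(t, d), t, fixed = TRUE)
  }
  expect_error(parseCall("0/2", "UNPHASED"), "multi-allelic")
  expect_error(parseCall("0/0/0/1", "UNPHASED"), "polyploid")
  expect_error(parseCall("2|0", "PHASED"), "multi-allelic")
  expect_error(parseCall("X", "SIMPLE"), "SIMPLE")
})

test_that("token round trip is the identity up to unphased canonicalization", {
  for (d in listDialects()) {
    for (t in dialectTokens(d)) {
      back <- serializeCall(parseCall(t, d), d)
      if (d == "UNPHASED" && t == "1/0")
        expect_identical(back, "0/1")
      else
        expect_identical(back, t)
    }
  }
})

test_that("a Call cannot carry partial missingness", {
  expect_error(Call("A", "MISSING"), "MISSING")
  expect_s4_class(Call("MISSING", "MISSING"), "Call")
})

test_that("detectDialect finds the unique covering dialect", {
  expect_identical(detectDialect(c("A", "H", "N", "B")), "SIMPLE")
  expect_identical(detectDialect(c("0|1", "1|1", ".|.")), "PHASED")
  expect_identical(detectDialect(c("0/0", "./.")), "UNPHASED")
  expect_identical(detectDialect(rev(c("A", "H", "N", "B"))), "SIMPLE")
  expect_error(detectDialect(c("N", ".|.")), "dialect")
  expect_error(detectDialect(character(0)), "override")
})

test_that("normalizeTable sorts by chromosome then position and is idempotent", {
  mk <- data.frame(chrom = c("c1", "c1", "c2", "c1"),
                   name = c("a", "b", "c", "d"),
                   pos = c(300L, 100L, 50L, 100L))
  h <- matrix(0L, 4, 1)
  tab <- normalizeTable(GenotypeTable(mk, "S1", h, h, "SIMPLE"))
  expect_identical(markers(tab)$name, c("b", "d", "a", "c"))
  expect_identical(markers(tab)$pos, c(100L, 100L, 300L, 50L))
  ## duplicate (chrom, pos) pairs keep input order: b before d
  again <- normalizeTable(tab)
  expect_identical(markers(again), markers(tab))
  expect_identical(hapMatrix(again), hapMatrix(tab))
  expect_identical(tab@metadata$validation$markersPerChrom,
                   c(c1 = 3L, c2 = 1L))
})

test_that("duplicate sample or marker names are rejected by name", {
  mk <- data.frame(chrom = "c1", name = c("m1", "m1"), pos = c(1L, 2L))
  h <- matrix(0L, 2, 1)
  expect_error(GenotypeTable(mk, "S1", h, h, "SIMPLE"), "m1")
  mk2 <- data.frame(chrom = "c1", name = c("m1", "m2"), pos = c(1L, 2L))
  h2 <- matrix(0L, 2, 2)
  expect_error(GenotypeTable(mk2, c("S1", "S1"), h2, h2, "SIMPLE"), "S1")
})

test_that("table accessors expose markers, samples, dialect and calls", {
  tab <- toyTable("PHASED")
  expect_identical(dim(tab), c(4L, 2L))
  expect_identical(sampleNames(tab), c("S1", "S2"))
  expect_identical(dialect(tab), "PHASED")
  cl <- callAt(tab, "m2", "S1")            # the phased het B|A
  expect_identical(c(cl@hap1, cl@hap2), c("B", "A"))
  expect_true(cl@phased)
})
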