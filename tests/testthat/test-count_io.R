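test_that("mgatk dialect round trip reproduces the tensor exactly", {
  tensor <- random_tensor(n_cells = 5, n_loci = 6, seed = 2)
  dir <- withr::local_tempdir()
  write_fixture(tensor, "mgatk", dir)
  back <- read_mgatk(dir, barcodes = tensor$cells)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(as.matrix(back$counts[[b]]), as.matrix(tensor$counts[[b]]))
  }
  expect_equal(back$cells, tensor$cells)
  expect_equal(back$loci, tensor$loci)
})

test_that("mgatk import sums strands, respects whitelist and flags errors", {
  dir <- withr::local_tempdir()
  writeLines("10,bc1,2,3", file.path(dir, "A.txt"))
  for (b in c("C", "G", "T")) writeLines("10,bc1,0,0", file.path(dir, paste0(b, ".txt")))
  tn <- read_mgatk(dir)
  expect_equal(as.numeric(tn$counts$A), 5)  # fwd 2 + rev 3

  # whitelist: unknown barcodes dropped (reported), listed ones kept as zero
  writeLines(c("10,bc1,1,0", "10,stranger,4,4"), file.path(dir, "A.txt"))
  expect_message(tn2 <- read_mgatk(dir, barcodes = c("bc1", "bc2")), "dropped")
  expect_equal(tn2$cells, c("bc1", "bc2"))
  expect_equal(as.numeric(tn2$counts$A), c(1, 0))

  # missing base file is a hard error naming the file
  file.remove(file.path(dir, "G.txt"))
  expect_error(read_mgatk(dir), "G.txt")

  writeLines("10,bc1,0,0", file.path(dir, "G.txt"))
  writeLines(character(0), file.path(dir, "T.txt"))
  expect_error(read_mgatk(dir), "no records")

  writeLines(c("10,bc1,1,0", "11,bc1,x,0"), file.path(dir, "T.txt"))
  expect_error(read_mgatk(dir), "line 2")
})

test_that("mgatk column order is configurable", {
  dir <- withr::local_tempdir()
  writeLines("bc1,10,2,3", file.path(dir, "A.txt"))
  for (b in c("C", "G", "T")) writeLines("bc1,10,0,0", file.path(dir, paste0(b, ".txt")))
  tn <- read_mgatk(dir, col_order = c("barcode", "pos", "fwd", "rev"))
  expect_equal(tn$loci$pos, 10L)
  expect_equal(as.numeric(tn$counts$A), 5)
})

test_that("AD/DP dialect maps REF and ALT counts onto the 4-base tensor", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "1 1 1", "1 1 3"), file.path(dir, "AD.mtx"))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "1 1 1", "1 1 10"), file.path(dir, "DP.mtx"))
  writeLines("chrM\t42\tA\tG", file.path(dir, "vars.tsv"))
  writeLines("bc1", file.path(dir, "bcs.tsv"))
  tn <- read_cellsnp(file.path(dir, "AD.mtx"), file.path(dir, "DP.mtx"),
                     file.path(dir, "vars.tsv"), file.path(dir, "bcs.tsv"))
  expect_equal(as.numeric(tn$counts$A), 7)   # DP - AD on REF
  expect_equal(as.numeric(tn$counts$G), 3)   # AD on ALT
  expect_equal(as.numeric(tn$counts$C), 0)
  expect_equal(as.numeric(tn$counts$T), 0)

  # AD > DP is an error
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "1 1 1", "1 1 11"), file.path(dir, "AD.mtx"))
  expect_error(
    read_cellsnp(file.path(dir, "AD.mtx"), file.path(dir, "DP.mtx"),
                 file.path(dir, "vars.tsv"), file.path(dir, "bcs.tsv")),
    "AD exceeds DP"
  )
})

test_that("both dialects encode the same biallelic data identically", {
  tensor <- random_tensor(n_cells = 4, n_loci = 5, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(tensor, "mgatk", d1)
  write_fixture(tensor, "cellsnp", d2)
  t1 <- read_mgatk(d1, barcodes = tensor$cells)
  t2 <- read_cellsnp(file.path(d2, "cellSNP.tag.AD.mtx"),
                     file.path(d2, "cellSNP.tag.DP.mtx"),
                     file.path(d2, "cellSNP.variants.tsv"),
                     file.path(d2, "cellSNP.samples.tsv"))
  for (b in c("A", "C", "G", "T")) {
    expect_equal(as.matrix(t1$counts[[b]]), as.matrix(t2$counts[[b]]))
  }
})

test_that("exports write q-value, allele-frequency and calls tables", {
  sim <- planted_clone_sim(seed = 1, n_loci = 8)
  store <- store_open(withr::local_tempdir())
  calls <- fit_all_loci(sim$tensor, store = store)
  ms <- call_mutations(calls, store = store)

  fq <- withr::local_tempfile(fileext = ".tsv")
  export_results(store, "qvalues", fq)
  mat <- as.matrix(utils::read.delim(fq, row.names = 1, check.names = FALSE))
  expect_equal(dim(mat), dim(calls$q))
  expect_equal(unname(mat), unname(calls$q), tolerance = 1e-12)

  fa <- withr::local_tempfile(fileext = ".tsv")
  export_results(store, "af", fa)
  afm <- as.matrix(utils::read.delim(fa, row.names = 1, check.names = FALSE))
  expect_equal(unname(afm), unname(calls$af), tolerance = 1e-12)
  # cells whose reads are all WT export an allele frequency of exactly 1
  expect_true(any(calls$af == 1, na.rm = TRUE))
  expect_true(all(afm[!is.na(calls$af) & calls$af == 1] == 1))

  fc <- withr::local_tempfile(fileext = ".tsv")
  export_results(store, "calls", fc)
  tab <- utils::read.delim(fc)
  expect_named(tab, c("cell", "locus", "p", "q", "mutant"))

  # an empty mutation set exports a header-only calls table
  store2 <- store_open(withr::local_tempdir())
  calls2 <- fit_all_loci(simulate_dataset(clone_sim_spec(n_cells = 60, n_loci = 5,
                                                         seed = 3))$tensor,
                         store = store2)
  call_mutations(calls2, store = store2)
  fe <- withr::local_tempfile(fileext = ".tsv")
  export_results(store2, "calls", fe)
  expect_equal(nrow(utils::read.delim(fe)), 0)

  # requesting a stage that was never computed names the missing step
  store3 <- store_open(withr::local_tempdir())
  expect_error(export_results(store3, "qvalues", fq), "fit_all_loci")
  expect_error(export_results(store3, "calls", fq), "call_mutations")
})
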