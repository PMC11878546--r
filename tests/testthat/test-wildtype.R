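test_that("depth is the elementwise sum of the four base counts", {
  loci <- data.frame(contig = "chrM", pos = 1L)
  tn <- allele_count_tensor(
    list(A = matrix(1L), C = matrix(3L), G = matrix(4L), T = matrix(2L)),
    loci, "bc1"
  )
  expect_equal(as.numeric(compute_depth(tn)), 10)

  tn0 <- allele_count_tensor(
    list(A = matrix(0L), C = matrix(0L), G = matrix(0L), T = matrix(0L)),
    loci, "bc1"
  )
  expect_equal(as.numeric(compute_depth(tn0)), 0)
  expect_true(tn0$zero_coverage)

  tensor <- random_tensor(n_cells = 8, n_loci = 5, seed = 11)
  brute <- as.matrix(tensor$counts$A) + as.matrix(tensor$counts$C) +
    as.matrix(tensor$counts$G) + as.matrix(tensor$counts$T)
  expect_equal(as.matrix(compute_depth(tensor)), brute)
})

test_that("the WT allele is the base with the highest median count", {
  # four cells, two alleles; the first allele has counts 2,2,3,4 (median
  # 2.5) against 3,2,1,0 (median 1.5), so it wins despite losing in cell 1
  loci <- data.frame(contig = "chrM", pos = 310L)
  tn <- allele_count_tensor(
    list(A = matrix(c(2L, 2L, 3L, 4L), 1), C = matrix(c(3L, 2L, 1L, 0L), 1),
         G = matrix(0L, 1, 4), T = matrix(0L, 1, 4)),
    loci, paste0("bc", 1:4)
  )
  prof <- call_wildtype(tn)
  expect_equal(prof$wt, "A")
  expect_equal(prof$med_A, 2.5)
  expect_equal(prof$med_C, 1.5)
  expect_false(prof$tie)

  # monoallelic locus
  tn2 <- allele_count_tensor(
    list(A = matrix(c(3L, 5L), 1), C = matrix(0L, 1, 2),
         G = matrix(0L, 1, 2), T = matrix(0L, 1, 2)),
    data.frame(contig = "chrM", pos = 1L), c("b1", "b2")
  )
  expect_equal(call_wildtype(tn2)$wt, "A")

  # equal medians: earlier base in A < C < G < T wins and the tie is flagged
  tn3 <- allele_count_tensor(
    list(A = matrix(0L, 1, 2), C = matrix(c(2L, 2L), 1),
         G = matrix(c(2L, 2L), 1), T = matrix(0L, 1, 2)),
    data.frame(contig = "chrM", pos = 1L), c("b1", "b2")
  )
  expect_equal(call_wildtype(tn3)$wt, "C")
  expect_true(call_wildtype(tn3)$tie)
})

test_that("WT calling is invariant under cell permutation", {
  tensor <- random_tensor(n_cells = 10, n_loci = 6, seed = 3)
  prof <- call_wildtype(tensor)
  perm <- rev(tensor$cells)
  prof_p <- call_wildtype(tensor_subset(tensor, cells = perm))
  expect_equal(prof_p$wt, prof$wt)
  expect_equal(prof_p$med_A, prof$med_A)
})

test_that("WT read table gives wAF = m/N with NA at zero depth", {
  loci <- data.frame(contig = "chrM", pos = 1L)
  tn <- allele_count_tensor(
    list(A = matrix(c(2L, 12L, 0L), 1), C = matrix(c(3L, 0L, 0L), 1),
         G = matrix(0L, 1, 3), T = matrix(0L, 1, 3)),
    loci, c("b1", "b2", "b3")
  )
  wt <- wt_reads(tn, call_wildtype(tn))
  expect_equal(as.numeric(wt$af), c(2 / 5, 1.0, NA))

  # mutant reads N - m are non-negative everywhere
  tensor <- random_tensor(n_cells = 12, n_loci = 6, seed = 5)
  wt2 <- wt_reads(tensor, call_wildtype(tensor))
  mutant <- as.matrix(wt2$depth) - as.matrix(wt2$m)
  expect_true(all(mutant >= 0))
})

test_that("depth filter keeps cells above the threshold for both statistics", {
  loci <- data.frame(contig = "chrM", pos = c(1L, 2L))
  tn <- allele_count_tensor(
    list(A = rbind(c(10L, 0L), c(10L, 0L)), C = matrix(0L, 2, 2),
         G = matrix(0L, 2, 2), T = matrix(0L, 2, 2)),
    loci, c("deep", "empty")
  )
  expect_equal(filter_cells_by_depth(tn, 5), "deep")

  sim <- simulate_dataset(clone_sim_spec(n_cells = 100, n_loci = 10, seed = 8))
  depth <- as.matrix(compute_depth(sim$tensor))
  for (st in c("mean", "median")) {
    got <- filter_cells_by_depth(sim$tensor, 5, st)
    fn <- if (st == "mean") colMeans(depth) else apply(depth, 2, median)
    expect_equal(got, sim$tensor$cells[fn > 5])
  }
})
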