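test_that("planted clones are recovered at default thresholds", {
  sim <- planted_clone_sim(seed = 42)
  truth <- sim$truth
  calls <- fit_all_loci(sim$tensor)
  ms <- call_mutations(calls)

  planted <- truth$planted$locus_name
  expect_equal(ms$mutations$locus, planted)
  flagged <- ms$flags[planted, ]
  mut_cells <- names(truth$clones)[truth$clones == "mut"]
  expect_gte(sum(flagged[mut_cells]), 19)

  # no cell with q below threshold anywhere implies an empty set
  empty <- calls
  empty$q[] <- 1
  expect_equal(nrow(call_mutations(empty)$mutations), 0)

  # reported set shrinks as min_mutant_cells grows
  m1 <- call_mutations(calls, calling_config(min_mutant_cells = 1))
  m5 <- call_mutations(calls, calling_config(min_mutant_cells = 5))
  expect_true(all(m5$mutations$locus %in% m1$mutations$locus))
})

test_that("reported mutations shrink under tighter thresholds", {
  sim <- planted_clone_sim(seed = 8)
  calls <- fit_all_loci(sim$tensor)
  n_prev <- Inf
  for (qt in c(0.05, 0.01, 0.005)) {
    n <- nrow(call_mutations(calls, calling_config(q_threshold = qt,
                                                   min_mutant_cells = 1))$mutations)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  # flags of a reported mutation are exactly the cells counted to threshold
  ms <- call_mutations(calls)
  if (nrow(ms$mutations)) {
    expect_equal(unname(rowSums(ms$flags)), ms$mutations$n_mutant)
  }
})

test_that("precision metrics follow the subset-counting arithmetic", {
  flags <- rbind(mutA = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                 mutB = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  colnames(flags) <- paste0("c", 1:6)
  mset <- structure(list(mutations = data.frame(locus = c("mutA", "mutB"),
                                                n_mutant = c(2L, 4L)),
                         flags = flags, config = calling_config()),
                    class = "mutation_set")
  # subset = cells c1..c5: per-mutation (n,m) = (2,2) and (3,4), overall 5/6
  labels <- setNames(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), colnames(flags))
  rep <- mutation_precision(mset, labels)
  expect_equal(rep$per_mutation$precision, c(1.0, 0.75))
  expect_equal(rep$overall, 5 / 6)

  # all mutant cells inside the subset: overall precision 1
  rep2 <- mutation_precision(mset, setNames(rep(TRUE, 6), colnames(flags)))
  expect_equal(rep2$overall, 1)

  # brute-force recomputation on a random fixture
  set.seed(17)
  rf <- matrix(runif(60) < 0.3, 6, 10,
               dimnames = list(paste0("m", 1:6), paste0("c", 1:10)))
  rset <- structure(list(mutations = data.frame(locus = rownames(rf),
                                                n_mutant = rowSums(rf)),
                         flags = rf, config = calling_config()),
                    class = "mutation_set")
  lab <- setNames(runif(10) < 0.5, colnames(rf))
  got <- mutation_precision(rset, lab)
  n_i <- rowSums(rf[, lab, drop = FALSE])
  m_i <- rowSums(rf)
  keep <- n_i > 0
  expect_equal(got$per_mutation$precision, unname((n_i / m_i)[keep]))
  expect_equal(got$overall, sum(n_i[keep]) / sum(m_i[keep]))
})

test_that("lineage precision is the dominant-lineage fraction in [0.5, 1]", {
  flags <- rbind(m1 = c(rep(TRUE, 3), rep(TRUE, 3)),
                 m2 = c(rep(TRUE, 6)),
                 m3 = c(rep(TRUE, 3), rep(FALSE, 3)))
  colnames(flags) <- paste0("c", 1:6)
  mset <- structure(list(mutations = data.frame(locus = rownames(flags),
                                                n_mutant = rowSums(flags)),
                         flags = flags, config = calling_config()),
                    class = "mutation_set")
  lin <- setNames(rep(c("epithelial", "blood"), each = 3), colnames(flags))
  rep <- lineage_precision(mset, lin)
  expect_equal(rep$per_mutation$precision, c(0.5, 0.5, 1.0))
  expect_true(all(rep$per_mutation$precision >= 0.5 &
                  rep$per_mutation$precision <= 1))

  # (7, 3) split gives 0.7
  f2 <- matrix(TRUE, 1, 10, dimnames = list("m", paste0("c", 1:10)))
  ms2 <- structure(list(mutations = data.frame(locus = "m", n_mutant = 10L),
                        flags = f2, config = calling_config()),
                   class = "mutation_set")
  lin2 <- setNames(rep(c("a", "b"), c(7, 3)), colnames(f2))
  expect_equal(lineage_precision(ms2, lin2)$per_mutation$precision, 0.7)
})

test_that("preselection protects sensitivity when mutant cells are common", {
  # with 30% mutant cells, a null fitted on all cells absorbs the mutants
  # and widens; fitting on the preselected WT cells must detect at least as
  # many of the planted cells
  clones <- c(rep("mut", 60), rep("wt", 140))
  sim <- simulate_dataset(clone_sim_spec(
    n_cells = 200, n_loci = 10, clones = clones,
    planted = data.frame(locus = 4L, clone = "mut", het = 0.45),
    depth_meanlog = log(30), depth_sdlog = 0.4, seed = 14
  ))
  planted <- sim$truth$planted$locus_name
  mut_cells <- names(sim$truth$clones)[clones == "mut"]

  det <- sapply(c(TRUE, FALSE), function(pre) {
    cfg <- calling_config(preselect = pre)
    ms <- call_mutations(fit_all_loci(sim$tensor, config = cfg), cfg)
    if (planted %in% ms$mutations$locus) sum(ms$flags[planted, mut_cells]) else 0
  })
  expect_gte(det[1], det[2])
  expect_gt(det[1], 0)
})
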