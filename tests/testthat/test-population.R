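test_that("size_at follows the piecewise schedule", {
  sched <- list(phase_constant(100, 500), phase_growth(2, 50),
                phase_constant(200, 500))
  expect_equal(size_at(sched, 0), 100L)
  expect_equal(size_at(sched, 499), 100L)
  expect_equal(size_at(sched, 500), 102L)
  expect_equal(size_at(sched, 549), 200L)
  expect_equal(size_at(sched, 1049), 200L)
  expect_error(size_at(sched, 1050), "beyond")
  # zero-increment growth is identical to a constant phase
  a <- list(phase_constant(50, 10), phase_growth(0, 20))
  b <- list(phase_constant(50, 30))
  expect_equal(sapply(0:29, size_at, schedule = a),
               sapply(0:29, size_at, schedule = b))
  expect_error(size_at(list(phase_constant(10, 5), phase_growth(-3, 4)), 7),
               "< 2")
})

test_that("founding splits the sexes by the floor rule", {
  spec <- locus_spec("mt", 20, mu = 0)
  pop <- found_population(200, spec)
  expect_equal(sum(pop$sexes == 1L), 100L)
  pop3 <- found_population(3, spec)
  expect_equal(sum(pop3$sexes == 1L), 1L)
  expect_equal(sum(pop3$sexes == 2L), 2L)
  expect_error(found_population(1, spec))
  expect_error(found_population(10, spec, sex_ratio = 0.05), "empty")
})

test_that("census size tracks a three-phase schedule every generation", {
  set.seed(51)
  sched <- list(phase_constant(20, 5), phase_growth(2, 5),
                phase_constant(30, 5))
  pop <- found_population(20, locus_spec("mt", 20, mu = 0),
                          schedule = sched, mating = mating_config("polygamy"))
  for (t in 1:14) {
    pop <- step_generation(pop)
    expect_equal(length(pop$ids), size_at(sched, t))
    expect_equal(pop$generation, t)
    validate_population(pop)
  }
  expect_error(step_generation(pop), "beyond")
})

test_that("pedigree links always point at the previous generation's sexes", {
  set.seed(52)
  pop <- found_population(30, locus_spec("mt", 20, mu = 0),
                          mating = mating_config("polygamy"))
  for (t in 1:5) {
    prev <- population_members(pop)
    pop <- step_generation(pop)
    cur <- population_members(pop)
    expect_true(all(cur$mother_id %in% prev$id[prev$sex == "female"]))
    expect_true(all(cur$father_id %in% prev$id[prev$sex == "male"]))
    expect_false(any(duplicated(cur$id)))
  }
})

test_that("no mutation and a constant schedule leave the deme monomorphic", {
  set.seed(53)
  pop <- found_population(50, locus_spec("mt", 100, mu = 0))
  res <- run_generations(pop, 100)
  expect_equal(length(res$population$ids), 50L)
  st <- summarize_population(res$population)
  expect_true(all(st$S == 0))
})

test_that("pure drift conserves the founder allele set", {
  set.seed(54)
  pop <- found_population(40, locus_spec("mt", 60, mu = 0),
                          mating = mating_config("polygamy"))
  # hand two mtDNA haplotypes to the founders
  hapA <- random_dna(60); hapB <- random_dna(60)
  wA <- matesim:::cpp_encode(hapA); wB <- matesim:::cpp_encode(hapB)
  for (j in seq_len(ncol(pop$loci[[1]]$seq)))
    pop$loci[[1]]$seq[, j] <- if (j %% 2) wA else wB
  res <- run_generations(pop, 50)
  final <- pop_locus_strings(res$population, "mt")
  expect_true(all(final %in% c(hapA, hapB)))
})

test_that("identical seeds give bit-identical trajectories", {
  run <- function() {
    set.seed(99)
    pop <- found_population(40, locus_spec("autosomal", 100, mu = 1e-3),
                            mating = mating_config("polygyny"))
    res <- run_generations(pop, 20, record_every = 5)
    res
  }
  a <- run(); b <- run()
  expect_identical(a$stats, b$stats)
  expect_identical(a$population$loci[[1]]$seq, b$population$loci[[1]]$seq)
  expect_identical(a$population$ids, b$population$ids)
})

test_that("mtDNA lineage count declines in expectation under drift", {
  set.seed(55)
  nrep <- 100
  haps <- replicate(50, random_dna(30))
  h_at <- matrix(0, nrep, 3)
  for (r in seq_len(nrep)) {
    pop <- found_population(50, locus_spec("mt", 30, mu = 0),
                            mating = mating_config("polygamy"))
    for (j in seq_len(ncol(pop$loci[[1]]$seq)))
      pop$loci[[1]]$seq[, j] <- matesim:::cpp_encode(haps[j])
    res10 <- run_generations(pop, 10)
    res30 <- run_generations(res10$population, 20)
    res60 <- run_generations(res30$population, 30)
    h_at[r, ] <- c(n_haplotypes(collect_panel(res10$population, "mt")),
                   n_haplotypes(collect_panel(res30$population, "mt")),
                   n_haplotypes(collect_panel(res60$population, "mt")))
  }
  m <- colMeans(h_at)
  expect_true(m[1] > m[2] && m[2] > m[3])
})
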