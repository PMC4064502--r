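adults <- function(nf, nm) data.frame(
  id = seq_len(nf + nm),
  sex = c(rep("female", nf), rep("male", nm)),
  mother_id = NA_integer_, father_id = NA_integer_)

test_that("monogamy forms a disjoint matching of min(Nf, Nm) pairs", {
  set.seed(61)
  u <- form_unions(adults(5, 5), mating_config("monogamy"))
  expect_equal(nrow(u$pairs), 5L)
  expect_false(any(duplicated(u$pairs$female_id)))
  expect_false(any(duplicated(u$pairs$male_id)))
  u2 <- form_unions(adults(3, 7), mating_config("monogamy"))
  expect_equal(nrow(u2$pairs), 3L)
  expect_false(any(duplicated(u2$pairs$male_id)))
})

test_that("polygyny assigns each female one uniform husband", {
  set.seed(62)
  mem <- adults(50, 50)
  counts <- integer(0)
  for (i in 1:200) {
    u <- form_unions(mem, mating_config("polygyny"))
    expect_equal(nrow(u$pairs), 50L)
    expect_false(any(duplicated(u$pairs$female_id)))
    wives <- table(factor(u$pairs$male_id, levels = mem$id[mem$sex == "male"]))
    counts <- c(counts, as.integer(wives))
  }
  # wives-per-male pooled over draws ~ Binomial(50, 1/50)
  brk <- c(-0.5, 0.5, 1.5, 2.5, Inf)
  obs <- table(cut(counts, brk))
  p <- c(dbinom(0:2, 50, 1 / 50), 1 - pbinom(2, 50, 1 / 50))
  expect_gt(chisq.test(obs, p = p)$p.value, 0.001)
})

test_that("polygamy draws all female-male pairs equiprobably", {
  set.seed(63)
  mem <- adults(5, 5)
  cfg <- mating_config("polygamy")
  u <- form_unions(mem, cfg)
  expect_equal(nrow(u$pairs), 0L)
  draws <- replicate(10000, paste(draw_parents(u, mem, cfg), collapse = "-"))
  tab <- table(factor(draws, levels = as.vector(outer(
    mem$id[mem$sex == "female"], mem$id[mem$sex == "male"], paste, sep = "-"))))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("sibling relations follow shared-parent ids", {
  a <- list(mother_id = 1L, father_id = 2L)
  b <- list(mother_id = 1L, father_id = 9L)   # half sibs via mother
  c_ <- list(mother_id = 7L, father_id = 8L)
  founder <- list(mother_id = NA_integer_, father_id = NA_integer_)
  expect_true(are_siblings(a, b))
  expect_false(are_siblings(a, c_))
  expect_false(are_siblings(founder, founder))
  expect_true(are_siblings(a, a))  # self-comparison shares both parents
})

test_that("avoidance errors loudly when every pair is excluded", {
  mem <- data.frame(id = 1:2, sex = c("female", "male"),
                    mother_id = c(10L, 10L), father_id = c(11L, 12L))
  cfg <- mating_config("polygamy", avoid_siblings = TRUE, max_rejections = 50)
  u <- form_unions(mem, cfg)
  expect_error(draw_parents(u, mem, cfg), "rejections")
})

test_that("engine rejects fully-excluded sibling sets at the generation level", {
  set.seed(64)
  # one founder couple -> generation 1 is all full siblings
  pop <- found_population(2, locus_spec("mt", 20, mu = 0),
                          mating = mating_config("polygamy",
                                                 avoid_siblings = TRUE,
                                                 max_rejections = 100))
  pop <- step_generation(pop)  # children of the founder pair (not siblings of parents)
  expect_error(step_generation(pop), "rejections|generation")
})

test_that("engine pedigrees respect union structure per system", {
  set.seed(65)
  base <- function(sys) {
    pop <- found_population(60, locus_spec("mt", 20, mu = 0),
                            mating = mating_config(sys))
    step_generation(pop)
  }
  mono <- population_members(base("monogamy"))
  # each mother has one father and vice versa
  expect_true(all(tapply(mono$father_id, mono$mother_id,
                         function(x) length(unique(x))) == 1))
  expect_true(all(tapply(mono$mother_id, mono$father_id,
                         function(x) length(unique(x))) == 1))
  gyn <- population_members(base("polygyny"))
  expect_true(all(tapply(gyn$father_id, gyn$mother_id,
                         function(x) length(unique(x))) == 1))
  andr <- population_members(base("polyandry"))
  expect_true(all(tapply(andr$mother_id, andr$father_id,
                         function(x) length(unique(x))) == 1))
})

test_that("avoidance eliminates sibling parent pairs over many generations", {
  set.seed(66)
  pop <- found_population(30, locus_spec("mt", 20, mu = 0),
                          mating = mating_config("polygamy",
                                                 avoid_siblings = TRUE))
  for (t in 1:100) {
    prev <- population_members(pop)
    pop <- step_generation(pop)
    cur <- population_members(pop)
    for (i in seq_len(nrow(cur))) {
      mo <- prev[match(cur$mother_id[i], prev$id), ]
      fa <- prev[match(cur$father_id[i], prev$id), ]
      if (are_siblings(mo, fa))
        fail(sprintf("sibling mating at generation %d", t))
    }
  }
  succeed()
})

test_that("polygyny inflates male offspring-count variance over monogamy", {
  set.seed(67)
  one_var <- function(sys) {
    pop <- found_population(100, locus_spec("mt", 20, mu = 0),
                            mating = mating_config(sys))
    males <- pop$ids[pop$sexes == 2L]
    nxt <- population_members(step_generation(pop))
    counts <- table(factor(nxt$father_id, levels = males))
    var(as.numeric(counts))
  }
  nrep <- 300
  vg <- replicate(nrep, one_var("polygyny"))
  vm <- replicate(nrep, one_var("monogamy"))
  tt <- t.test(vg, vm, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})
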