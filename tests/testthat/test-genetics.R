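specs4 <- function(mu = 0) list(
  locus_spec("autosomal", 40, mu = mu),
  locus_spec("x", 40, mu = mu),
  locus_spec("y", 40, mu = mu),
  locus_spec("mt", 40, mu = mu))

test_that("founder genomes carry sex-appropriate copy numbers", {
  f <- founder_genome("female", specs4())
  m <- founder_genome("male", specs4())
  ncop <- function(g, cls) length(g$loci[[which(vapply(g$loci, function(l)
    l$class == cls, TRUE))]]$copies)
  expect_equal(ncop(f, "autosomal"), 2L)
  expect_equal(ncop(f, "x"), 2L)
  expect_equal(ncop(f, "y"), 0L)
  expect_equal(ncop(f, "mt"), 1L)
  expect_equal(ncop(m, "x"), 1L)
  expect_equal(ncop(m, "y"), 1L)
  expect_equal(ncop(m, "mt"), 1L)
})

test_that("template length mismatches are rejected", {
  expect_error(founder_genome("female", locus_spec("mt", 40),
                              template = c(mt = "ACGT")), "length")
})

test_that("uniparental loci transmit exactly at zero mutation rate", {
  set.seed(41)
  tpl <- c(autosomal = random_dna(40), x = random_dna(40),
           y = random_dna(40), mt = random_dna(40))
  mo <- founder_genome("female", specs4(), template = tpl)
  fa <- founder_genome("male", specs4(), template = tpl)
  get <- function(g, cls, k = 1) as.character(
    g$loci[[which(vapply(g$loci, function(l) l$class == cls, TRUE))]]$copies[[k]])
  son <- transmit(mo, fa, "male")
  dau <- transmit(mo, fa, "female")
  expect_identical(get(son, "y"), get(fa, "y"))
  expect_identical(get(son, "mt"), get(mo, "mt"))
  expect_identical(get(dau, "mt"), get(mo, "mt"))
  # daughter's paternal X is the father's single X, exactly
  expect_identical(get(dau, "x", 2), get(fa, "x"))
  # son carries no Y slot error cases
  expect_length(son$loci[[which(vapply(son$loci, function(l)
    l$class == "x", TRUE))]]$copies, 1L)
  expect_length(dau$loci[[which(vapply(dau$loci, function(l)
    l$class == "y", TRUE))]]$copies, 0L)
})

test_that("parent sex roles are enforced", {
  mo <- founder_genome("female", specs4())
  fa <- founder_genome("male", specs4())
  expect_error(transmit(fa, fa, "male"), "female")
  expect_error(transmit(mo, mo, "male"), "male")
})

test_that("Mendelian segregation: each maternal allele inherited half the time", {
  set.seed(42)
  spec <- locus_spec("autosomal", 40, mu = 0)
  a1 <- strrep("A", 40)
  a2 <- paste0("T", strrep("A", 39))  # distinguishable copy
  mo <- founder_genome("female", spec)
  mo$loci[[1]]$copies <- list(packed_seq(a1), packed_seq(a2))
  fa <- founder_genome("male", spec)
  n <- 2000
  got2 <- sum(replicate(n, {
    ch <- transmit(mo, fa, "female")
    as.character(ch$loci[[1]]$copies[[1]]) == a2
  }))
  se <- sqrt(0.25 / n)
  expect_lt(abs(got2 / n - 0.5), 3 * se)
})

test_that("autosomal loci segregate independently", {
  set.seed(43)
  specs <- list(locus_spec("autosomal", 40, count = 2, mu = 0))
  alt <- paste0("T", strrep("A", 39))
  mo <- founder_genome("female", specs)
  mo$loci[[1]]$copies <- list(packed_seq(strrep("A", 40)), packed_seq(alt))
  mo$loci[[2]]$copies <- list(packed_seq(strrep("A", 40)), packed_seq(alt))
  fa <- founder_genome("male", specs)
  n <- 2000
  combos <- replicate(n, {
    ch <- transmit(mo, fa, "male")
    g1 <- as.character(ch$loci[[1]]$copies[[1]]) == alt
    g2 <- as.character(ch$loci[[2]]$copies[[1]]) == alt
    paste0(as.integer(g1), as.integer(g2))
  })
  tab <- table(factor(combos, levels = c("00", "01", "10", "11")))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("a founder population is monomorphic at every locus", {
  pop <- found_population(20, specs4())
  st <- summarize_population(pop)
  expect_true(all(st$S == 0))
  expect_true(all(st$h == 1))
  expect_true(all(st$pi == 0))
  expect_true(all(st$H_A == 0))
})
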