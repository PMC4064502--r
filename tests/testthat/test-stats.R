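test_that("two-sequence toy panel has the closed-form statistics", {
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 3), strrep("A", 97))
  p <- panel_from_sequences(c(a, b))
  expect_equal(seg_sites(p), 3L)
  expect_equal(watterson_theta(p), 3)       # a_2 = 1
  expect_equal(pairwise_pi(p), 3)
  expect_equal(n_haplotypes(p), 2L)
  expect_equal(allelic_het(p), 1)           # unbiased, both haplotypes unique
  expect_equal(nei_het(p), 0.015)           # (3/100) * (1 - 1/2)
  expect_equal(watterson_theta(p, per_site = TRUE), 0.03)
})

test_that("Watterson's theta uses the harmonic number a_n", {
  base <- strrep("A", 50)
  mut_at <- function(sites) {
    ch <- strsplit(base, "")[[1]]; ch[sites] <- "C"; paste(ch, collapse = "")
  }
  # 11 segregating sites among four sequences
  p <- panel_from_sequences(c(base, mut_at(1:5), mut_at(6:9), mut_at(10:11)))
  expect_equal(seg_sites(p), 11L)
  expect_equal(watterson_theta(p), 11 / (1 + 1/2 + 1/3))
  expect_equal(watterson_theta(p), 6.0)
})

test_that("all six statistics match the naive string oracle exactly", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(2:10, 1); L <- sample(2:50, 1)
    pool <- replicate(sample(2:4, 1), random_dna(L))
    strings <- sample(pool, n, replace = TRUE)
    # sprinkle extra point differences so panels are not all duplicates
    strings <- vapply(strings, function(s) {
      if (runif(1) < 0.5) {
        j <- sample(L, 1); ch <- strsplit(s, "")[[1]]
        ch[j] <- sample(c("A", "C", "G", "T"), 1); paste(ch, collapse = "")
      } else s
    }, "", USE.NAMES = FALSE)
    p <- panel_from_sequences(strings)
    o <- oracle_stats(strings)
    expect_equal(seg_sites(p), o$S)
    expect_equal(watterson_theta(p), o$theta_w)
    expect_equal(pairwise_pi(p), o$pi)
    expect_equal(n_haplotypes(p), o$h)
    expect_equal(allelic_het(p), o$H_A)
    expect_equal(nei_het(p), o$H_N)
  }
})

test_that("statistics are invariant under panel permutation", {
  set.seed(72)
  strings <- replicate(8, random_dna(30))
  a <- summary_stats(panel_from_sequences(strings))
  b <- summary_stats(panel_from_sequences(sample(strings)))
  expect_equal(a[c("S", "theta_w", "pi", "h", "H_A", "H_N")],
               b[c("S", "theta_w", "pi", "h", "H_A", "H_N")])
})

test_that("metamorphic: duplicating every sequence", {
  set.seed(73)
  strings <- replicate(6, random_dna(25))
  p1 <- panel_from_sequences(strings)
  p2 <- panel_from_sequences(c(strings, strings))
  expect_equal(seg_sites(p2), seg_sites(p1))
  expect_equal(n_haplotypes(p2), n_haplotypes(p1))
  # H_A changes only through the n/(n-1) factor
  n <- length(strings)
  expect_equal(allelic_het(p2) / (2 * n / (2 * n - 1)),
               allelic_het(p1) / (n / (n - 1)))
  # mean pairwise distance of the doubled panel relates by pair accounting:
  # C(2n,2) pairs include n zero-distance duplicate pairs
  d1 <- pairwise_pi(p1) * choose(n, 2)
  expect_equal(pairwise_pi(p2), 4 * d1 / choose(2 * n, 2))
})

test_that("metamorphic: appending an invariant site", {
  set.seed(74)
  strings <- replicate(6, random_dna(25))
  plus <- paste0(strings, "G")
  p1 <- panel_from_sequences(strings)
  p2 <- panel_from_sequences(plus)
  expect_equal(seg_sites(p2), seg_sites(p1))
  expect_equal(pairwise_pi(p2), pairwise_pi(p1))
  expect_equal(n_haplotypes(p2), n_haplotypes(p1))
  expect_equal(allelic_het(p2), allelic_het(p1))
  expect_equal(nei_het(p2), nei_het(p1) * 25 / 26)
})

test_that("panels count chromosomes per carrier sex", {
  specs <- list(locus_spec("autosomal", 20, mu = 0), locus_spec("x", 20, mu = 0),
                locus_spec("y", 20, mu = 0), locus_spec("mt", 20, mu = 0))
  pop <- found_population(100, specs)
  expect_equal(collect_panel(pop, "autosomal")$n, 200L)
  expect_equal(collect_panel(pop, "x")$n, 150L)
  expect_equal(collect_panel(pop, "y")$n, 50L)
  expect_equal(collect_panel(pop, "mt")$n, 100L)
})

test_that("degenerate panels are rejected", {
  pop <- found_population(3, locus_spec("y", 20, mu = 0))  # 1 F + 2 M
  expect_error(summary_stats(collect_panel(pop, "y", sample_size = NULL)), NA)
  # a sample containing only the female carries no Y copy
  found <- FALSE
  for (s in 1:50) {
    set.seed(s)
    idx <- sample.int(3, 1)
    if (idx == 1) { found <- TRUE; set.seed(s); break }
  }
  expect_true(found)
  expect_error(collect_panel(pop, "y", sample_size = 1), "empty panel")
  p1 <- found_population(4, locus_spec("mt", 20, mu = 0))
  one <- collect_panel(p1, "mt")
  one$seq <- one$seq[, 1, drop = FALSE]; one$n <- 1L
  expect_error(summary_stats(one), "n >= 2")
})

test_that("per-class means aggregate across loci", {
  set.seed(75)
  pop <- found_population(30, locus_spec("autosomal", 50, count = 4, mu = 1e-3),
                          mating = mating_config("polygamy"))
  pop <- run_generations(pop, 30)$population
  st <- summarize_population(pop, class_means = TRUE)
  per <- st[!is.na(st$locus_index), ]
  agg <- st[is.na(st$locus_index), ]
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$theta_w, mean(per$theta_w))
  expect_equal(agg$pi, mean(per$pi))
})
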