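#' Locus specification
#'
#' Describes a set of unlinked loci of one inheritance class. Autosomal loci
#' are carried in two copies (maternal and paternal slots) by everyone; X in
#' two copies by females and one by males; Y in one copy by males only; mtDNA
#' in one copy by everyone and inherited maternally. Loci of the same class
#' segregate independently (free recombination between loci, none within).
#'
#' @param class One of \code{"autosomal"}, \code{"x"}, \code{"y"}, \code{"mt"}.
#' @param length Sites per locus (L), >= 1.
#' @param count Number of unlinked loci of this class.
#' @param mu Per-site per-generation mutation probability for this class.
#' @param tstv Transition:transversion ratio for this class.
#' @return An object of class \code{locus_spec}.
#' @examples
#' locus_spec("mt", length = 16000, mu = 2e-6)
#' locus_spec("autosomal", length = 3200, count = 10, mu = 3e-8)
#' @export
locus_spec <- function(class, length, count = 1, mu = 1e-6, tstv = 2) {
  code <- .class_code(class)
  stopifnot(length >= 1, count >= 1, mu >= 0, mu <= 1, tstv > 0)
  structure(list(class = .class_name(code), class_code = code,
                 length = as.integer(length), count = as.integer(count),
                 mu = as.numeric(mu), tstv = as.numeric(tstv)),
            class = "locus_spec")
}

# number of copies of a locus class carried by an individual of a given sex
# (sex: 1 female, 2 male)
.copies_for <- function(class_code, sex) {
  switch(class_code + 1L,
         rep(2L, length(sex)),                 # autosomal
         ifelse(sex == 1L, 2L, 1L),            # X
         ifelse(sex == 1L, 0L, 1L),            # Y
         rep(1L, length(sex)))                 # mt
}

.as_spec_list <- function(specs) {
  if (inherits(specs, "locus_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE, "locus_spec")))
  specs
}

#' Build a founder genome
#'
#' All copies equal the per-class template sequence (default: all-'A' of the
#' configured length), with copy numbers appropriate to \code{sex}. Founder
#' populations built this way are monomorphic; standing diversity is then
#' injected by the buffering phase (see \code{\link{buffer_population}})
#' rather than by a long burn-in.
#'
#' @param sex \code{"female"} or \code{"male"}.
#' @param specs A \code{locus_spec} or list of them.
#' @param template Optional named character vector of per-class template
#'   sequences (names among \code{"autosomal"}, \code{"x"}, \code{"y"},
#'   \code{"mt"}); lengths must match the specs.
#' @return An object of class \code{sim_genome}: a list with \code{sex} and
#'   \code{loci}, each locus carrying its \code{copies} of
#'   \code{\link{packed_seq}} (autosomal and female X: maternal then paternal
#'   slot).
#' @export
founder_genome <- function(sex, specs, template = NULL) {
  sex <- match.arg(sex, c("female", "male"))
  sexi <- if (sex == "female") 1L else 2L
  specs <- .as_spec_list(specs)
  loci <- list()
  for (sp in specs) {
    base <- if (!is.null(template) && !is.na(template[sp$class])) {
      tl <- template[[sp$class]]
      if (nchar(tl) != sp$length)
        stop("template for class '", sp$class, "' has length ", nchar(tl),
             ", expected ", sp$length)
      packed_seq(tl)
    } else {
      packed_seq(strrep("A", sp$length))
    }
    ncop <- .copies_for(sp$class_code, sexi)
    for (i in seq_len(sp$count)) {
      loci[[length(loci) + 1L]] <- list(
        class = sp$class, class_code = sp$class_code, index = i,
        length = sp$length, mu = sp$mu, tstv = sp$tstv,
        copies = rep(list(base), ncop))
    }
  }
  structure(list(sex = sex, loci = loci), class = "sim_genome")
}

#' Transmit a genome from two parents to one offspring
#'
#' Implements the sex-appropriate inheritance rules: at each autosomal locus
#' the child receives one uniformly chosen copy from each parent; the child
#' always receives one of the mother's two X copies, and a daughter
#' additionally receives the father's X; a son receives the father's Y; every
#' child receives the mother's mtDNA. Each transmitted copy then passes
#' through K2P mutation at its class's rate.
#'
#' @param mother,father \code{sim_genome} objects of the matching sexes.
#' @param child_sex \code{"female"} or \code{"male"}.
#' @return A \code{sim_genome} for the child.
#' @export
transmit <- function(mother, father, child_sex) {
  stopifnot(inherits(mother, "sim_genome"), inherits(father, "sim_genome"))
  if (mother$sex != "female") stop("'mother' must be a female genome")
  if (father$sex != "male") stop("'father' must be a male genome")
  child_sex <- match.arg(child_sex, c("female", "male"))
  if (length(mother$loci) != length(father$loci))
    stop("parent genomes carry different locus sets")
  loci <- vector("list", length(mother$loci))
  for (k in seq_along(mother$loci)) {
    ml <- mother$loci[[k]]; fl <- father$loci[[k]]
    if (ml$class != fl$class || ml$length != fl$length)
      stop("parent genomes disagree at locus ", k)
    model <- mutation_model(ml$mu, ml$tstv)
    copies <- switch(ml$class,
      autosomal = list(
        mutate_seq(ml$copies[[sample.int(2L, 1L)]], model),
        mutate_seq(fl$copies[[sample.int(2L, 1L)]], model)),
      x = {
        mat <- mutate_seq(ml$copies[[sample.int(2L, 1L)]], model)
        if (child_sex == "female")
          list(mat, mutate_seq(fl$copies[[1L]], model))
        else list(mat)
      },
      y = if (child_sex == "male")
        list(mutate_seq(fl$copies[[1L]], model)) else list(),
      mt = list(mutate_seq(ml$copies[[1L]], model)))
    cl <- ml
    cl$copies <- copies
    loci[[k]] <- cl
  }
  structure(list(sex = child_sex, loci = loci), class = "sim_genome")
}
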