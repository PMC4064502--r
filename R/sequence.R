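#' Bit-packed DNA sequences
#'
#' A \code{packed_seq} stores a DNA sequence over the strict alphabet
#' \{A, C, G, T\} at 2 bits per site (A=00, C=01, G=10, T=11), 32 sites per
#' 64-bit word, with site 0 in the lowest bits of the first word and all bits
#' beyond the last site zero. Words are held as a raw vector of 8 bytes per
#' word in little-endian byte order, so serialized state is portable.
#'
#' @param dna A single string over \{A, C, G, T\} (uppercase).
#' @return An object of class \code{packed_seq} with fields \code{length}
#'   (number of sites) and \code{words} (raw vector, \code{8 * ceiling(L/32)}
#'   bytes).
#' @examples
#' s <- packed_seq("ACGT")
#' as.character(s)
#' seq_words(packed_seq(strrep("ACGT", 80)))  # 320 bases -> 10 words
#' @export
packed_seq <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L, nzchar(dna))
  structure(list(length = nchar(dna), words = cpp_encode(dna)),
            class = "packed_seq")
}

.packed_from_raw <- function(words, length) {
  stopifnot(is.raw(words), length(words) == 8L * ((length + 31L) %/% 32L))
  structure(list(length = as.integer(length), words = words),
            class = "packed_seq")
}

#' @export
as.character.packed_seq <- function(x, ...) cpp_decode(x$words, x$length)

#' @export
print.packed_seq <- function(x, ...) {
  s <- as.character(x)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<packed_seq> %d sites in %d words: %s\n",
              x$length, seq_words(x), s))
  invisible(x)
}

#' @export
length.packed_seq <- function(x) x$length

#' Number of 64-bit storage words of a packed sequence
#'
#' Always \code{ceiling(length / 32)}: 32 nucleotides are packed into every
#' 64-bit word.
#'
#' @param x A \code{packed_seq}.
#' @return Integer word count.
#' @export
seq_words <- function(x) {
  stopifnot(inherits(x, "packed_seq"))
  length(x$words) %/% 8L
}

#' Hamming distance between two packed sequences
#'
#' Number of sites at which the two sequences carry different nucleotides,
#' computed by XOR, collapse of each 2-bit site pair, and popcount.
#'
#' @param a,b \code{packed_seq} objects of equal length.
#' @return Integer count of differing sites.
#' @examples
#' hamming(packed_seq("AAAA"), packed_seq("AATA"))
#' @export
hamming <- function(a, b) {
  stopifnot(inherits(a, "packed_seq"), inherits(b, "packed_seq"))
  if (a$length != b$length)
    stop("sequences have different lengths (", a$length, " vs ", b$length, ")")
  cpp_hamming(a$words, b$words, a$length)
}

#' Kimura two-parameter mutation model
#'
#' Parameterized by the total per-site per-generation mutation probability
#' \code{mu} and the transition:transversion probability-mass ratio
#' \code{tstv} (R). A mutation event is a transition (A<->G, C<->T) with
#' probability R/(R+1), otherwise one of the two possible transversions,
#' equiprobably. The default R = 2 is a conventional choice for vertebrate
#' nuclear DNA and is user-settable per locus class.
#'
#' @param mu Per-site per-generation mutation probability, in [0, 1].
#' @param tstv Transition:transversion ratio R, > 0.
#' @return An object of class \code{mutation_model}.
#' @export
mutation_model <- function(mu, tstv = 2) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu <= 1,
            is.numeric(tstv), length(tstv) == 1L, tstv > 0)
  structure(list(mu = as.numeric(mu), tstv = as.numeric(tstv)),
            class = "mutation_model")
}

#' Mutate a packed sequence under the K2P model
#'
#' The number of mutated sites is Binomial(L, mu); hit positions are drawn
#' uniformly without replacement (a site is hit at most once per call); each
#' hit always changes the nucleotide, to a transition with probability
#' R/(R+1). Randomness comes from R's RNG, so results are reproducible under
#' \code{set.seed()}.
#'
#' @param x A \code{packed_seq}.
#' @param model A \code{mutation_model}.
#' @return A new \code{packed_seq}; the input is unchanged.
#' @export
mutate_seq <- function(x, model) {
  stopifnot(inherits(x, "packed_seq"), inherits(model, "mutation_model"))
  .packed_from_raw(cpp_mutate(x$words, x$length, model$mu, model$tstv),
                   x$length)
}
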