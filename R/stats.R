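# column offsets of each individual's copies of one locus (engine layout:
# copies ordered by member position, slots in order within an individual)
.copy_offsets <- function(class_code, sexes) {
  cop <- .copies_for(class_code, sexes)
  c(0L, cumsum(cop))
}

#' Collect a sequence panel from a population
#'
#' Samples individuals without replacement (or takes the whole deme) and
#' gathers their copies of one locus: both copies per individual for
#' autosomal loci, two per female and one per male for X, one per male for
#' Y, one per individual for mtDNA. Diploid sampling therefore counts
#' chromosomes, not individuals: an autosomal sample of s individuals yields
#' a panel of n = 2s sequences.
#'
#' @param pop A \code{sim_population}.
#' @param class Locus class: \code{"autosomal"}, \code{"x"}, \code{"y"},
#'   \code{"mt"}.
#' @param locus_index Which locus of the class (1-based).
#' @param sample_size Number of individuals to sample without replacement;
#'   \code{NULL} takes every individual. Sampling consumes R's RNG stream.
#' @return An object of class \code{seq_panel}: locus metadata, the packed
#'   sequences (raw matrix, one column per sequence) and per-sequence
#'   carrier metadata (individual id, sex, copy slot).
#' @export
collect_panel <- function(pop, class, locus_index = 1, sample_size = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  code <- .class_code(class)
  hit <- which(vapply(pop$loci, function(l)
    l$class_code == code && l$index == locus_index, TRUE))
  if (length(hit) != 1L)
    stop("no locus of class '", .class_name(code), "' with index ", locus_index)
  l <- pop$loci[[hit]]
  N <- length(pop$ids)
  idx <- if (is.null(sample_size)) seq_len(N) else {
    stopifnot(sample_size >= 1, sample_size <= N)
    sort(sample.int(N, sample_size))
  }
  off <- .copy_offsets(code, pop$sexes)
  cols <- integer(0)
  meta_id <- integer(0); meta_sex <- integer(0); meta_slot <- integer(0)
  for (i in idx) {
    k <- off[i + 1L] - off[i]
    if (k == 0L) next
    cols <- c(cols, off[i] + seq_len(k))
    meta_id <- c(meta_id, rep(pop$ids[i], k))
    meta_sex <- c(meta_sex, rep(pop$sexes[i], k))
    meta_slot <- c(meta_slot, seq_len(k))
  }
  if (length(cols) == 0L)
    stop("empty panel: no sampled individual carries a ",
         .class_name(code), " copy")
  structure(list(
    class = .class_name(code), locus_index = as.integer(locus_index),
    length = l$length, n = length(cols),
    seq = l$seq[, cols, drop = FALSE],
    meta = data.frame(id = meta_id, sex = c("female", "male")[meta_sex],
                      slot = meta_slot)), class = "seq_panel")
}

#' @export
print.seq_panel <- function(x, ...) {
  cat(sprintf("<seq_panel> %s locus %d: n = %d sequences of %d sites\n",
              x$class, x$locus_index, x$n, x$length))
  invisible(x)
}

#' Build a panel directly from sequences
#'
#' Convenience constructor for analyses of raw sequence sets (e.g. decoded
#' strings or \code{\link{packed_seq}} objects) outside a population.
#'
#' @param seqs Character vector of equal-length ACGT strings, or list of
#'   \code{packed_seq}.
#' @param class Locus class label recorded in the panel.
#' @return A \code{seq_panel}.
#' @export
panel_from_sequences <- function(seqs, class = "autosomal") {
  if (is.character(seqs)) seqs <- lapply(seqs, packed_seq)
  stopifnot(length(seqs) >= 1, all(vapply(seqs, inherits, TRUE, "packed_seq")))
  L <- seqs[[1L]]$length
  if (!all(vapply(seqs, function(s) s$length, 1L) == L))
    stop("panel sequences must have equal length")
  structure(list(
    class = .class_name(.class_code(class)), locus_index = 1L,
    length = L, n = length(seqs),
    seq = do.call(cbind, lapply(seqs, function(s) s$words)),
    meta = data.frame(id = seq_along(seqs), sex = NA_character_,
                      slot = 1L)), class = "seq_panel")
}

.panel_stats <- function(panel) {
  stopifnot(inherits(panel, "seq_panel"))
  if (panel$n < 2L) stop("panel has n = ", panel$n, "; statistics need n >= 2")
  cpp_panel_stats(panel$seq, panel$length, seq_len(panel$n))
}

#' Summary statistics of a sequence panel
#'
#' The battery comprises the number of segregating sites S, Watterson's
#' estimator \eqn{\theta_w = S / a_n} with \eqn{a_n = \sum_{i=1}^{n-1} 1/i},
#' the mean pairwise difference \eqn{\theta_\pi} (average Hamming distance
#' over all n(n-1)/2 pairs), the number of distinct haplotypes h, the
#' unbiased allelic heterozygosity
#' \eqn{H_A = \frac{n}{n-1}(1 - \sum_k p_k^2)} over haplotype frequencies,
#' and Nei's mean per-site heterozygosity
#' \eqn{H_N = \frac{1}{L}\sum_{sites}(1 - \sum_{alleles} q^2)}.
#' \eqn{\theta_w} and \eqn{\theta_\pi} are reported in per-locus units; the
#' per-site variants divide by L.
#'
#' @param panel A \code{seq_panel} with n >= 2.
#' @param per_site Report \eqn{\theta_w} / \eqn{\theta_\pi} per site?
#' @return \code{summary_stats}: one-row data frame with columns
#'   \code{locus_class}, \code{locus_index}, \code{n}, \code{L}, \code{S},
#'   \code{theta_w}, \code{pi}, \code{h}, \code{H_A}, \code{H_N}.
#'   The single-statistic accessors return scalars.
#' @examples
#' p <- panel_from_sequences(c("AACGT", "AACGA"))
#' summary_stats(p)
#' @export
summary_stats <- function(panel, per_site = FALSE) {
  r <- .panel_stats(panel)
  div <- if (per_site) panel$length else 1
  data.frame(locus_class = panel$class, locus_index = panel$locus_index,
             n = panel$n, L = panel$length, S = r$S,
             theta_w = r$theta_w / div, pi = r$pi / div, h = r$h,
             H_A = r$H_A, H_N = r$H_N)
}

#' @rdname summary_stats
#' @export
seg_sites <- function(panel) .panel_stats(panel)$S

#' @rdname summary_stats
#' @export
watterson_theta <- function(panel, per_site = FALSE) {
  v <- .panel_stats(panel)$theta_w
  if (per_site) v / panel$length else v
}

#' @rdname summary_stats
#' @export
pairwise_pi <- function(panel, per_site = FALSE) {
  v <- .panel_stats(panel)$pi
  if (per_site) v / panel$length else v
}

#' @rdname summary_stats
#' @export
n_haplotypes <- function(panel) .panel_stats(panel)$h

#' @rdname summary_stats
#' @export
allelic_het <- function(panel) .panel_stats(panel)$H_A

#' @rdname summary_stats
#' @export
nei_het <- function(panel) .panel_stats(panel)$H_N

#' Summary statistics for every locus of a population
#'
#' One row per locus (whole deme or a sample of individuals), plus, with
#' \code{class_means = TRUE}, one row per class holding the across-locus
#' mean of each statistic (locus_index NA).
#'
#' @param pop A \code{sim_population}.
#' @param sample_size Individuals to sample without replacement (NULL = all).
#' @param class_means Append per-class across-locus means?
#' @return Data frame in the \code{\link{summary_stats}} schema.
#' @export
summarize_population <- function(pop, sample_size = NULL, class_means = FALSE) {
  rows <- lapply(pop$loci, function(l) {
    p <- collect_panel(pop, l$class, l$index, sample_size)
    summary_stats(p)
  })
  out <- do.call(rbind, rows)
  if (class_means) {
    for (cl in unique(out$locus_class)) {
      sub <- out[out$locus_class == cl, ]
      m <- sub[1, ]
      m$locus_index <- NA_integer_
      for (col in c("S", "theta_w", "pi", "h", "H_A", "H_N"))
        m[[col]] <- mean(sub[[col]])
      out <- rbind(out, m)
    }
  }
  rownames(out) <- NULL
  out
}
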