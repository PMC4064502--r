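#' Configuration of the diversity-targeted buffering phase
#'
#' The buffering phase replaces a long burn-in: starting from monomorphic
#' founders, the population evolves with all mutation rates multiplied by
#' \code{boost} until the whole-deme mean pairwise difference
#' \eqn{\theta_\pi} on the monitored locus class first reaches
#' \code{target_pi} (per-locus units). Original rates are then restored and
#' the generation counter reset to 0, so buffer generations are not counted
#' in the main run.
#'
#' @param target_pi Desired whole-deme \eqn{\theta_\pi} (per-locus), >= 0.
#' @param boost Multiplicative factor on every mutation rate during
#'   buffering, >= 1. The boosted per-site rate is capped at 0.1 to keep the
#'   K2P process far from saturation.
#' @param target_class Locus class monitored for the stopping rule;
#'   \code{NULL} picks mtDNA if configured, else the first configured class.
#' @param max_generations Safety cap on buffering length.
#' @return A \code{buffer_config}.
#' @export
buffer_config <- function(target_pi, boost = 100, target_class = NULL,
                          max_generations = 5000L) {
  stopifnot(target_pi >= 0, boost >= 1, max_generations >= 1)
  if (!is.null(target_class)) target_class <- .class_name(.class_code(target_class))
  structure(list(target_pi = as.numeric(target_pi), boost = as.numeric(boost),
                 target_class = target_class,
                 max_generations = as.integer(max_generations)),
            class = "buffer_config")
}

#' Run the buffering phase
#'
#' Evolves the population at boosted mutation rates (constant census size,
#' the configured mating system) and stops at the first generation whose
#' whole-deme \eqn{\theta_\pi} on the monitored class reaches the target.
#' Stopping monitors the whole deme, not a subsample, so the stop is a
#' deterministic function of the trajectory. If the target is already met
#' (including \code{target_pi = 0}) the population is returned unchanged.
#'
#' @param pop A \code{sim_population} (typically freshly founded).
#' @param config A \code{\link{buffer_config}}.
#' @return The buffered \code{sim_population}, generation reset to 0, with
#'   attributes \code{buffer_pi} (achieved \eqn{\theta_\pi}),
#'   \code{buffer_generations} (generations consumed) and
#'   \code{buffer_trajectory} (whole-deme \eqn{\theta_\pi} at each buffer
#'   generation, starting at the pre-buffer value). Mutation rates are
#'   untouched: the boost is applied transiently, never stored.
#' @export
buffer_population <- function(pop, config) {
  stopifnot(inherits(pop, "sim_population"), inherits(config, "buffer_config"))
  tc <- config$target_class
  if (is.null(tc)) {
    classes <- vapply(pop$loci, function(l) l$class, "")
    tc <- if ("mt" %in% classes) "mt" else classes[1L]
  }
  code <- .class_code(tc)
  if (!any(vapply(pop$loci, function(l) l$class_code == code, TRUE)))
    stop("no locus of the monitored class '", tc, "' is configured")
  bad <- vapply(pop$loci, function(l) l$mu * config$boost > 0.1, TRUE)
  if (any(bad))
    stop("boosted per-site rate exceeds 0.1 for locus class(es) ",
         paste(unique(vapply(pop$loci[bad], function(l) l$class, "")),
               collapse = ", "))
  out <- cpp_engine_buffer(pop, config$target_pi, config$boost, code,
                           config$max_generations, .mating_list(pop$mating))
  if (!out$reached)
    stop("buffering failed: theta_pi reached only ",
         signif(out$achieved_pi, 4), " of target ", config$target_pi,
         " after ", out$generations_used, " generations")
  newpop <- out$pop
  newpop$generation <- 0L
  newpop$schedule <- pop$schedule
  newpop$mating <- pop$mating
  class(newpop) <- "sim_population"
  attr(newpop, "buffer_pi") <- out$achieved_pi
  attr(newpop, "buffer_generations") <- out$generations_used
  attr(newpop, "buffer_trajectory") <- out$trajectory
  newpop
}

#' Whole-deme mean per-locus pairwise diversity of a class
#'
#' @param pop A \code{sim_population}.
#' @param class Locus class.
#' @return Mean \eqn{\theta_\pi} (per-locus units) across the class's loci.
#' @export
deme_pi <- function(pop, class) {
  stopifnot(inherits(pop, "sim_population"))
  cpp_deme_pi(pop, .class_code(class))
}

# fraction of segregating sites at which the rarest allele is a singleton
.singleton_fraction <- function(panel) {
  s <- vapply(seq_len(panel$n), function(j)
    cpp_decode(panel$seq[, j], panel$length), "")
  mat <- do.call(rbind, strsplit(s, ""))
  seg <- 0L; singleton <- 0L
  for (site in seq_len(panel$length)) {
    tab <- table(mat[, site])
    if (length(tab) > 1L) {
      seg <- seg + 1L
      if (min(tab) == 1L) singleton <- singleton + 1L
    }
  }
  if (seg == 0L) return(NA_real_)
  singleton / seg
}

#' Compare a buffered population against an equilibrium reference
#'
#' Side-by-side whole-deme summary statistics (plus the fraction of
#' segregating sites that are singletons, a site-frequency summary) for a
#' buffered population and a reference produced by a long standard-rate run
#' matched on N, locus class and diversity level. Used to check that the
#' accelerated buffering phase mimics the polymorphism and haplotype
#' patterns of standard evolution; it is a reporting tool, not part of the
#' simulation path.
#'
#' @param buffered,reference \code{sim_population} objects carrying the same
#'   locus class.
#' @param class Locus class to compare (default mtDNA).
#' @return Data frame with one row per statistic and columns
#'   \code{statistic}, \code{buffered}, \code{reference}.
#' @export
buffer_fidelity_report <- function(buffered, reference, class = "mt") {
  code <- .class_code(class)
  for (p in list(buffered, reference)) {
    stopifnot(inherits(p, "sim_population"))
    if (!any(vapply(p$loci, function(l) l$class_code == code, TRUE)))
      stop("class '", .class_name(code), "' absent from a population")
  }
  one <- function(pop) {
    pan <- collect_panel(pop, .class_name(code), 1L)
    st <- summary_stats(pan)
    c(S = st$S, theta_w = st$theta_w, pi = st$pi, h = st$h,
      H_A = st$H_A, H_N = st$H_N,
      singleton_fraction = .singleton_fraction(pan))
  }
  b <- one(buffered); r <- one(reference)
  data.frame(statistic = names(b), buffered = unname(b),
             reference = unname(r))
}
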