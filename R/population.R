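#' Demography schedule phases
#'
#' A schedule is an ordered list of phases; the population size is a
#' deterministic piecewise function of the generation index t (0-based,
#' founders at t = 0). A constant phase holds its target size; a growth
#' phase adds \code{increment} individuals per generation (negative for
#' decline) starting from the previous phase's final size.
#'
#' @param size Target census size of a constant phase (>= 2).
#' @param increment Per-generation size change of a growth phase.
#' @param duration Phase length in generations (>= 1).
#' @return A \code{demography_phase}.
#' @examples
#' sched <- list(phase_constant(100, 500), phase_growth(2, 50),
#'               phase_constant(200, 500))
#' size_at(sched, 499)  # 100
#' size_at(sched, 549)  # 200
#' @name demography
NULL

#' @rdname demography
#' @export
phase_constant <- function(size, duration) {
  stopifnot(size >= 2, duration >= 1)
  structure(list(kind = "constant", size = as.integer(size),
                 duration = as.integer(duration)),
            class = "demography_phase")
}

#' @rdname demography
#' @export
phase_growth <- function(increment, duration) {
  stopifnot(duration >= 1)
  structure(list(kind = "growth", increment = as.integer(increment),
                 duration = as.integer(duration)),
            class = "demography_phase")
}

#' Census size at a generation index under a schedule
#'
#' @param schedule List of \code{demography_phase} objects.
#' @param t Generation index, 0-based; must lie within the schedule's total
#'   duration (otherwise an error: extend the schedule or stop the run).
#' @return Integer census size.
#' @export
size_at <- function(schedule, t) {
  stopifnot(all(vapply(schedule, inherits, TRUE, "demography_phase")),
            length(schedule) >= 1, t >= 0)
  prev <- NA_integer_
  start <- 0L
  for (ph in schedule) {
    end <- start + ph$duration - 1L
    if (ph$kind == "constant") {
      cur <- ph$size
      if (t <= end) return(cur)
      prev <- cur
    } else {
      if (is.na(prev)) stop("a growth phase cannot open a schedule")
      if (t <= end) {
        sz <- prev + ph$increment * (t - start + 1L)
        if (sz < 2) stop("schedule yields size ", sz, " (< 2) at generation ", t)
        return(as.integer(sz))
      }
      prev <- prev + ph$increment * ph$duration
      if (prev < 2) stop("schedule yields size ", prev, " (< 2) within a growth phase")
    }
    start <- end + 1L
  }
  stop("generation ", t, " is beyond the schedule (total duration ", start, ")")
}

.mating_list <- function(config) {
  list(system_code = config$system_code,
       avoid_siblings = config$avoid_siblings,
       max_rejections = config$max_rejections)
}

# expand locus specs into the engine's flat per-locus entries, with founder
# sequences for the given sexes
.founder_loci <- function(specs, sexes, template = NULL) {
  loci <- list()
  for (sp in specs) {
    base <- if (!is.null(template) && !is.na(template[sp$class])) {
      tl <- template[[sp$class]]
      if (nchar(tl) != sp$length)
        stop("template for class '", sp$class, "' has length ", nchar(tl),
             ", expected ", sp$length)
      cpp_encode(tl)
    } else {
      as.raw(rep(0L, 8L * ((sp$length + 31L) %/% 32L)))
    }
    ncop <- sum(.copies_for(sp$class_code, sexes))
    for (i in seq_len(sp$count)) {
      loci[[length(loci) + 1L]] <- list(
        class = sp$class, class_code = sp$class_code, index = i,
        length = sp$length, mu = sp$mu, tstv = sp$tstv,
        seq = matrix(rep(base, ncop), nrow = length(base), ncol = ncop))
    }
  }
  loci
}

#' Found a population
#'
#' Creates N founder individuals at generation 0: \code{floor(N * sex_ratio)}
#' females, the rest males, every genome equal to the class templates
#' (default all-'A'; inject diversity with \code{\link{buffer_population}}).
#'
#' @param N Census size, >= 2.
#' @param specs A \code{\link{locus_spec}} or list of them.
#' @param sex_ratio Fraction female in (0, 1); must yield at least one of
#'   each sex.
#' @param schedule Optional demography schedule (list of
#'   \code{demography_phase}); \code{NULL} means constant at N indefinitely.
#'   If given, its size at t = 0 must equal N.
#' @param mating A \code{\link{mating_config}}.
#' @param template Optional per-class founder sequences (see
#'   \code{\link{founder_genome}}).
#' @return An object of class \code{sim_population}.
#' @examples
#' pop <- found_population(100, locus_spec("mt", 1000, mu = 1e-5),
#'                         mating = mating_config("polygamy"))
#' pop
#' @export
found_population <- function(N, specs, sex_ratio = 0.5, schedule = NULL,
                             mating = mating_config(), template = NULL) {
  stopifnot(N >= 2, sex_ratio > 0, sex_ratio < 1,
            inherits(mating, "mating_config"))
  specs <- .as_spec_list(specs)
  nf <- as.integer(floor(N * sex_ratio))
  nm <- as.integer(N) - nf
  if (nf < 1L || nm < 1L)
    stop("sex_ratio ", sex_ratio, " leaves a sex class empty at N = ", N)
  if (!is.null(schedule) && size_at(schedule, 0L) != N)
    stop("schedule size at generation 0 (", size_at(schedule, 0L),
         ") does not match N = ", N)
  sexes <- c(rep(1L, nf), rep(2L, nm))
  structure(list(
    generation = 0L,
    next_id = as.integer(N) + 1L,
    ids = seq_len(N),
    sexes = sexes,
    mother_id = rep(NA_integer_, N),
    father_id = rep(NA_integer_, N),
    loci = .founder_loci(specs, sexes, template),
    schedule = schedule,
    mating = mating), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cls <- vapply(x$loci, function(l) l$class, "")
  cat(sprintf("<sim_population> generation %d, N = %d (%d F / %d M), %s, loci: %s\n",
              x$generation, length(x$ids), sum(x$sexes == 1L),
              sum(x$sexes == 2L), x$mating$system,
              paste(sprintf("%s:%d", names(table(cls)), as.integer(table(cls))),
                    collapse = ", ")))
  invisible(x)
}

#' Members of a population as a data frame
#'
#' @param pop A \code{sim_population}.
#' @return Data frame with \code{id}, \code{sex}, \code{mother_id},
#'   \code{father_id} (parent ids are NA for founders).
#' @export
population_members <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  data.frame(id = pop$ids,
             sex = c("female", "male")[pop$sexes],
             mother_id = pop$mother_id,
             father_id = pop$father_id)
}

# target sizes for the next `gens` generations from the schedule (constant
# at current size when schedule is NULL)
.next_sizes <- function(pop, gens) {
  if (is.null(pop$schedule)) return(rep(length(pop$ids), gens))
  vapply(pop$generation + seq_len(gens),
         function(t) size_at(pop$schedule, t), integer(1))
}

.run_engine <- function(pop, sizes, record_at, mu_mult = 1) {
  out <- cpp_engine_run(pop, as.integer(sizes), as.integer(record_at),
                        .mating_list(pop$mating), mu_mult)
  newpop <- out$pop
  newpop$schedule <- pop$schedule
  newpop$mating <- pop$mating
  class(newpop) <- "sim_population"
  st <- out$stats
  stats <- data.frame(generation = st$generation,
                      locus_class = .CLASS_NAMES[st$class_code + 1L],
                      locus_index = st$locus_index,
                      n = st$n, L = st$L, S = st$S, theta_w = st$theta_w,
                      pi = st$pi, h = st$h, H_A = st$H_A, H_N = st$H_N)
  list(population = newpop, stats = stats)
}

#' Advance a population by one generation
#'
#' Generations are non-overlapping: the next census size is taken from the
#' schedule, unions are formed under the mating system, offspring sexes are
#' i.i.d. fair Bernoulli (whole vector redrawn until both sexes are
#' present), each offspring's parents are drawn by the system's rule (with
#' sibling avoidance if configured) and its genome transmitted with
#' mutation, and the members are replaced wholesale.
#'
#' @param pop A \code{sim_population}.
#' @return The advanced \code{sim_population}.
#' @export
step_generation <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  .run_engine(pop, .next_sizes(pop, 1L), integer(0))$population
}

#' Run a population forward several generations
#'
#' @param pop A \code{sim_population}.
#' @param generations Number of generations to run (must stay within the
#'   schedule).
#' @param record_every If > 0, record whole-deme summary statistics for
#'   every locus at each generation index divisible by this interval, and at
#'   the final generation.
#' @param record_at Alternatively, explicit generation indices to record.
#' @return List with \code{population} (the advanced population) and
#'   \code{stats} (data frame of recorded whole-deme statistics; zero rows
#'   if recording is off). Statistics rows carry \code{n < 2} loci (e.g. a Y
#'   locus in an all-female sample) as NA.
#' @export
run_generations <- function(pop, generations, record_every = 0,
                            record_at = NULL) {
  stopifnot(inherits(pop, "sim_population"), generations >= 1)
  if (is.null(record_at)) {
    record_at <- integer(0)
    if (record_every > 0) {
      gens <- pop$generation + seq_len(generations)
      record_at <- unique(c(gens[gens %% record_every == 0],
                            pop$generation + generations))
    }
  }
  .run_engine(pop, .next_sizes(pop, generations), record_at)
}

#' Check the structural invariants of a population
#'
#' Asserts that copy-number layout matches each member's sex for every locus
#' class (no Y copy in a female, no paternal X slot in a male), that both
#' sexes are represented, and that trailing packed bits beyond each locus
#' length are zero. Errors on violation.
#'
#' @param pop A \code{sim_population}.
#' @return Invisibly \code{TRUE}.
#' @export
validate_population <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  if (!any(pop$sexes == 1L) || !any(pop$sexes == 2L))
    stop("a sex class is empty")
  for (l in pop$loci) {
    expected <- sum(.copies_for(l$class_code, pop$sexes))
    if (ncol(l$seq) != expected)
      stop("locus ", l$class, l$index, ": ", ncol(l$seq),
           " copies stored, expected ", expected)
    # trailing bits beyond site L-1 must be zero
    W <- (l$length + 31L) %/% 32L
    rem <- l$length %% 32L
    if (rem > 0L && ncol(l$seq) > 0L) {
      lastword <- l$seq[(8L * (W - 1L) + 1L):(8L * W), , drop = FALSE]
      keep_bytes <- (2L * rem) %/% 8L  # full bytes in use
      partial_bits <- (2L * rem) %% 8L
      for (b in seq_len(8L)) {
        if (b <= keep_bytes) next
        vals <- as.integer(lastword[b, ])
        if (b == keep_bytes + 1L && partial_bits > 0L) {
          if (any(vals %/% (2L^partial_bits) != 0L))
            stop("locus ", l$class, l$index, ": nonzero trailing bits")
        } else if (any(vals != 0L)) {
          stop("locus ", l$class, l$index, ": nonzero trailing bits")
        }
      }
    }
  }
  invisible(TRUE)
}
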