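.MATING_SYSTEMS <- c("monogamy", "polygamy", "polygyny", "polyandry")

#' Mating system configuration
#'
#' Selects the marriage rule used to form unions each generation and whether
#' full/half sibling matings are prohibited. Under monogamy, min(Nf, Nm)
#' exclusive pairs are formed by a uniform random matching; under polygyny
#' every female takes a uniformly chosen husband (males may hold several
#' wives); polyandry is the mirror; polygamy forms no unions and draws an
#' independent uniform mother and father per offspring. Sibling avoidance is
#' rejection sampling of the parent pair, erroring loudly if
#' \code{max_rejections} draws all hit sibling pairs.
#'
#' @param system One of \code{"monogamy"}, \code{"polygamy"},
#'   \code{"polygyny"}, \code{"polyandry"}.
#' @param avoid_siblings Prohibit parent pairs sharing a mother or a father?
#' @param max_rejections Cap on avoidance redraws per offspring.
#' @return An object of class \code{mating_config}.
#' @export
mating_config <- function(system = "monogamy", avoid_siblings = FALSE,
                          max_rejections = 1000L) {
  system <- match.arg(tolower(system), .MATING_SYSTEMS)
  stopifnot(max_rejections >= 1)
  structure(list(system = system,
                 system_code = match(system, .MATING_SYSTEMS),
                 avoid_siblings = isTRUE(avoid_siblings),
                 max_rejections = as.integer(max_rejections)),
            class = "mating_config")
}

#' Are two individuals full or half siblings?
#'
#' True iff they share a mother id or a father id. Founders (missing parent
#' ids) are never siblings. Note that an individual compared with itself
#' shares both parents and so returns \code{TRUE}; the mating machinery never
#' queries self-pairs (parents are one female and one male).
#'
#' @param a,b Lists or one-row data frames with \code{mother_id} and
#'   \code{father_id} fields (NA for founders).
#' @return Logical.
#' @export
are_siblings <- function(a, b) {
  same <- function(x, y) !is.na(x) && !is.na(y) && x == y
  same(a$mother_id, b$mother_id) || same(a$father_id, b$father_id)
}

#' Form marriage unions for one generation
#'
#' @param members A data frame of adults with columns \code{id}, \code{sex}
#'   (\code{"female"}/\code{"male"}), \code{mother_id}, \code{father_id}
#'   (e.g. from \code{\link{population_members}}).
#' @param config A \code{\link{mating_config}}.
#' @return An object of class \code{union_set}: the mating system plus a
#'   data frame of \code{(female_id, male_id)} unions. Polygamy precomputes
#'   no unions (zero-row marker); parents are drawn per offspring.
#' @export
form_unions <- function(members, config) {
  stopifnot(is.data.frame(members), inherits(config, "mating_config"))
  fem <- members$id[members$sex == "female"]
  mal <- members$id[members$sex == "male"]
  if (length(fem) == 0L || length(mal) == 0L)
    stop("cannot form unions: a sex class is empty")
  pairs <- switch(config$system,
    monogamy = {
      k <- min(length(fem), length(mal))
      data.frame(female_id = sample(fem)[seq_len(k)],
                 male_id = sample(mal)[seq_len(k)])
    },
    polygyny = data.frame(
      female_id = fem,
      male_id = mal[sample.int(length(mal), length(fem), replace = TRUE)]),
    polyandry = data.frame(
      female_id = fem[sample.int(length(fem), length(mal), replace = TRUE)],
      male_id = mal),
    polygamy = data.frame(female_id = integer(0), male_id = integer(0)))
  structure(list(system = config$system, pairs = pairs), class = "union_set")
}

#' Draw the parent pair for one offspring
#'
#' Monogamy: a union uniformly at random. Polygyny: a uniform female, father
#' = her husband. Polyandry: a uniform male, mother = his wife. Polygamy:
#' independent uniform mother and father. With sibling avoidance on, the
#' pair is redrawn while the two share a parent id, up to
#' \code{config$max_rejections}, then errors.
#'
#' @param unions A \code{union_set} from \code{\link{form_unions}}.
#' @param members The adult data frame the unions were formed over.
#' @param config A \code{\link{mating_config}}.
#' @return Named integer vector \code{c(mother_id =, father_id =)}.
#' @export
draw_parents <- function(unions, members, config) {
  stopifnot(inherits(unions, "union_set"), inherits(config, "mating_config"))
  fem <- members$id[members$sex == "female"]
  mal <- members$id[members$sex == "male"]
  row_of <- function(id) members[match(id, members$id), , drop = FALSE]
  draw1 <- function() {
    switch(config$system,
      monogamy = {
        k <- sample.int(nrow(unions$pairs), 1L)
        c(unions$pairs$female_id[k], unions$pairs$male_id[k])
      },
      polygyny = {
        k <- sample.int(nrow(unions$pairs), 1L)
        c(unions$pairs$female_id[k], unions$pairs$male_id[k])
      },
      polyandry = {
        k <- sample.int(nrow(unions$pairs), 1L)
        c(unions$pairs$female_id[k], unions$pairs$male_id[k])
      },
      polygamy = c(fem[sample.int(length(fem), 1L)],
                   mal[sample.int(length(mal), 1L)]))
  }
  for (t in seq_len(config$max_rejections)) {
    p <- draw1()
    if (!config$avoid_siblings ||
        !are_siblings(row_of(p[1L]), row_of(p[2L])))
      return(c(mother_id = p[1L], father_id = p[2L]))
  }
  stop("no valid non-sibling parent pair after ", config$max_rejections,
       " rejections")
}
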