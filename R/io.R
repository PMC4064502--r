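.STATE_FORMAT_VERSION <- 1L

# atomic write: temp file in the target directory, then rename
.atomic_write <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    stop("failed to write '", path, "'")
  invisible(path)
}

#' Write summary-statistic rows as TSV
#'
#' Canonical schema: replicate, generation, locus_class, locus_index, n, L,
#' S, theta_w, pi, h, H_A, H_N; header row, tab-separated, decimal dot, no
#' locale formatting. Written atomically (temp file + rename).
#'
#' @param rows Data frame containing at least the schema columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_stats <- function(rows, path) {
  cols <- c("replicate", "generation", "locus_class", "locus_index",
            "n", "L", "S", "theta_w", "pi", "h", "H_A", "H_N")
  stopifnot(is.data.frame(rows), nrow(rows) >= 1, all(cols %in% names(rows)))
  rows <- rows[cols]
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(format(rows, scientific = FALSE, trim = TRUE, digits = 10),
              tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("failed to write '", path, "'")
  invisible(path)
}

#' Write sequence panels as FASTA
#'
#' One record per sequence with header
#' \code{rep<r>|gen<t>|ind<id>|<sex>|<class><locus_index>|copy<k>} and
#' 70-column line wrapping; written atomically.
#'
#' @param panels A \code{seq_panel} or list of them.
#' @param path Output path.
#' @param replicate,generation Metadata recorded in headers.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(panels, path, replicate = 1, generation = 0) {
  if (inherits(panels, "seq_panel")) panels <- list(panels)
  stopifnot(length(panels) >= 1,
            all(vapply(panels, inherits, TRUE, "seq_panel")))
  lines <- character(0)
  for (p in panels) {
    for (j in seq_len(p$n)) {
      hdr <- sprintf(">rep%d|gen%d|ind%d|%s|%s%d|copy%d",
                     replicate, generation, p$meta$id[j],
                     ifelse(is.na(p$meta$sex[j]), "unknown", p$meta$sex[j]),
                     p$class, p$locus_index, p$meta$slot[j])
      s <- cpp_decode(p$seq[, j], p$length)
      body <- substring(s, seq(1, nchar(s), 70),
                        pmin(seq(1, nchar(s), 70) + 69, nchar(s)))
      lines <- c(lines, hdr, body)
    }
  }
  .atomic_write(lines, path)
}

.raw_to_b64 <- function(r) jsonlite::base64_enc(r)
.b64_to_raw <- function(s) jsonlite::base64_dec(s)

#' Save and load simulation state
#'
#' The state file is versioned JSON carrying the complete population (all
#' genomes bit-packed, base64-encoded in the documented little-endian word
#' layout), the demography schedule, the mating configuration, an optional
#' run configuration, and the full RNG state (\code{.Random.seed}), guarded
#' by an FNV-1a checksum. A run restarted from a saved state with unchanged
#' configuration continues exactly as an unbroken run; the restart may also
#' override the mating system, schedule or rates to chain scenarios (e.g.
#' monogamy followed by polygyny, or constant size followed by growth).
#'
#' @param pop A \code{sim_population}.
#' @param path File path.
#' @param config Optional run configuration list stored alongside.
#' @return \code{save_state}: invisibly, the path. \code{load_state}: a
#'   list with \code{population}, \code{config}, \code{rng_state},
#'   \code{replicate}.
#' @export
save_state <- function(pop, path, config = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  loci <- lapply(pop$loci, function(l) {
    list(class = l$class, index = l$index, length = l$length,
         mu = l$mu, tstv = l$tstv, ncopies = ncol(l$seq),
         seq = .raw_to_b64(as.raw(l$seq)))
  })
  payload <- list(
    generation = pop$generation, next_id = pop$next_id,
    ids = pop$ids, sexes = pop$sexes,
    mother_id = pop$mother_id, father_id = pop$father_id,
    loci = loci,
    schedule = if (!is.null(pop$schedule)) lapply(pop$schedule, unclass),
    mating = list(system = pop$mating$system,
                  avoid_siblings = pop$mating$avoid_siblings,
                  max_rejections = pop$mating$max_rejections),
    config = config,
    rng_state = rng,
    replicate = attr(pop, "replicate"))
  pj <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null")
  pb <- jsonlite::base64_enc(charToRaw(pj))
  outer <- list(format_version = .STATE_FORMAT_VERSION,
                package_version = as.character(packageVersion("matesim")),
                checksum = cpp_fnv1a(charToRaw(pb)),
                payload = pb)
  .atomic_write(jsonlite::toJSON(outer, auto_unbox = TRUE), path)
}

#' @rdname save_state
#' @param restore_rng Restore \code{.Random.seed} from the file, so the
#'   continued run reproduces the unbroken trajectory?
#' @export
load_state <- function(path, restore_rng = TRUE) {
  outer <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                              simplifyVector = TRUE)
  if (!identical(as.integer(outer$format_version), .STATE_FORMAT_VERSION))
    stop("state file format version ", outer$format_version,
         " is not supported (expected ", .STATE_FORMAT_VERSION, ")")
  if (!identical(cpp_fnv1a(charToRaw(outer$payload)), outer$checksum))
    stop("state file checksum mismatch: '", path, "' is corrupted")
  payload <- jsonlite::fromJSON(rawToChar(.b64_to_raw(outer$payload)),
                                simplifyVector = FALSE)
  loci <- lapply(payload$loci, function(l) {
    r <- .b64_to_raw(l$seq)
    W8 <- 8L * ((l$length + 31L) %/% 32L)
    list(class = l$class, class_code = .class_code(l$class),
         index = as.integer(l$index), length = as.integer(l$length),
         mu = as.numeric(l$mu), tstv = as.numeric(l$tstv),
         seq = matrix(r, nrow = W8, ncol = l$ncopies))
  })
  schedule <- NULL
  if (!is.null(payload$schedule)) {
    schedule <- lapply(payload$schedule, function(ph) {
      if (ph$kind == "constant") phase_constant(ph$size, ph$duration)
      else phase_growth(ph$increment, ph$duration)
    })
  }
  tonum <- function(x) if (is.null(x)) integer(0) else
    vapply(x, function(v) if (is.null(v)) NA_integer_ else as.integer(v), 1L)
  pop <- structure(list(
    generation = as.integer(payload$generation),
    next_id = as.integer(payload$next_id),
    ids = tonum(payload$ids),
    sexes = tonum(payload$sexes),
    mother_id = tonum(payload$mother_id),
    father_id = tonum(payload$father_id),
    loci = loci,
    schedule = schedule,
    mating = mating_config(payload$mating$system,
                           payload$mating$avoid_siblings,
                           payload$mating$max_rejections)),
    class = "sim_population")
  rng <- if (is.null(payload$rng_state)) NULL else
    as.integer(unlist(payload$rng_state))
  if (restore_rng && !is.null(rng))
    assign(".Random.seed", rng, envir = globalenv())
  list(population = pop,
       config = payload$config,
       rng_state = rng,
       replicate = payload$replicate)
}
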