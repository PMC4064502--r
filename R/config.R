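# ---- spec-string parsers -----------------------------------------------

#' Parse a locus specification string
#'
#' Comma-separated \code{class:length} or \code{class:lengthxcount} items,
#' with classes \code{aut}/\code{autosomal}, \code{x}, \code{y}, \code{mt},
#' e.g. \code{"mt:16000"} or \code{"aut:3200x10,y:1000000"}.
#'
#' @param s Specification string.
#' @param mu Named per-class mutation rates (names among the classes); a
#'   single unnamed value applies to every class.
#' @param tstv Transition:transversion ratio applied to every class.
#' @return List of \code{\link{locus_spec}}.
#' @export
parse_loci <- function(s, mu = 1e-6, tstv = 2) {
  items <- strsplit(s, ",", fixed = TRUE)[[1]]
  norm <- c(aut = "autosomal", autosomal = "autosomal", x = "x", y = "y",
            mt = "mt")
  lapply(items, function(it) {
    m <- regmatches(it, regexec("^\\s*([a-z]+):(\\d+)(?:x(\\d+))?\\s*$", it))[[1]]
    if (length(m) == 0) stop("malformed locus spec item '", it, "'")
    cls <- norm[m[2]]
    if (is.na(cls)) stop("unknown locus class '", m[2], "'")
    count <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    rate <- if (!is.null(names(mu)) && cls %in% names(mu)) mu[[cls]]
            else if (is.null(names(mu))) mu[[1]]
            else stop("no mutation rate given for class '", cls, "'")
    locus_spec(cls, length = as.integer(m[3]), count = count,
               mu = rate, tstv = tstv)
  })
}

#' Parse a demography schedule string
#'
#' Comma-separated phases \code{constant:SIZE:DURATION} or
#' \code{growth:INCREMENT:DURATION} (increment may be signed), e.g.
#' \code{"constant:100:500,growth:+2:50,constant:200:500"}.
#'
#' @param s Schedule string.
#' @return List of \code{demography_phase}.
#' @export
parse_demography <- function(s) {
  items <- strsplit(s, ",", fixed = TRUE)[[1]]
  lapply(items, function(it) {
    m <- regmatches(it,
      regexec("^\\s*(constant|growth):([+-]?\\d+):(\\d+)\\s*$", it))[[1]]
    if (length(m) == 0) stop("malformed demography phase '", it, "'")
    if (m[2] == "constant")
      phase_constant(as.integer(m[3]), as.integer(m[4]))
    else phase_growth(as.integer(m[3]), as.integer(m[4]))
  })
}

.parse_mu_string <- function(s) {
  if (is.null(s) || !nzchar(s)) return(NULL)
  items <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(items) == 1 && !grepl("=", items))
    return(as.numeric(items))
  norm <- c(aut = "autosomal", autosomal = "autosomal", x = "x", y = "y",
            mt = "mt")
  kv <- strsplit(items, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) as.numeric(p[2]), 1)
  names(vals) <- vapply(kv, function(p) {
    cls <- norm[trimws(p[1])]
    if (is.na(cls)) stop("unknown locus class '", p[1], "' in --mu")
    cls
  }, "")
  as.list(vals)
}

# ---- run configuration --------------------------------------------------

.default_config <- function() {
  list(popsize = NULL, generations = 100L, replicates = 1L,
       loci = "mt:16000", mu = 1e-6, tstv = 2, mating = "monogamy",
       avoid_siblings = FALSE, demography = NULL,
       buffer_theta = 0, buffer_class = NULL, buffer_boost = 100,
       sample = NULL, stats_every = 0L, seed = 1L,
       out = "matesim", save = NULL, load = NULL, fasta = FALSE,
       workers = 1L, sex_ratio = 0.5, max_rejections = 1000L)
}

.read_command_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_-]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) == 0) stop("malformed command-file line: '", ln, "'")
    out[[gsub("-", "_", kv[2])]] <- trimws(kv[3])
  }
  out
}

.coerce_config_types <- function(cfg) {
  ints <- c("popsize", "generations", "replicates", "stats_every", "seed",
            "workers", "max_rejections")
  nums <- c("tstv", "buffer_theta", "buffer_boost", "sex_ratio")
  lgls <- c("avoid_siblings", "fasta")
  for (k in ints) if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in nums) if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in lgls) if (!is.null(cfg[[k]]))
    cfg[[k]] <- cfg[[k]] %in% c(TRUE, "TRUE", "true", "1", "yes")
  if (!is.null(cfg$sample)) cfg$sample <- as.integer(cfg$sample)
  if (is.character(cfg$mu)) cfg$mu <- .parse_mu_string(cfg$mu)
  cfg
}

#' Parse a run configuration from command-line style arguments
#'
#' Supports the full flag set of the command-line interface (see the
#' package's \code{inst/exec/matesim} script). Values from a command file
#' (\code{--config FILE}, one \code{key = value} per line, \code{#}
#' comments) are loaded first and individual flags override them.
#' Population size is the only parameter without a default.
#'
#' @param args Character vector of arguments (as from
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return A validated \code{run_config} list.
#' @export
parse_config <- function(args = character(0)) {
  spec <- list(
    optparse::make_option(c("-p", "--popsize"), type = "integer",
      help = "census population size (required)"),
    optparse::make_option(c("-g", "--generations"), type = "integer",
      default = NULL, help = "generations of the main run [default 100]"),
    optparse::make_option(c("-r", "--replicates"), type = "integer",
      default = NULL, help = "independent replicates [default 1]"),
    optparse::make_option("--loci", type = "character", default = NULL,
      help = "locus spec, e.g. 'mt:16000' or 'aut:3200x10,y:1000000'"),
    optparse::make_option("--mu", type = "character", default = NULL,
      help = "mutation rate(s): a number, or 'class=rate,...'"),
    optparse::make_option("--tstv", type = "double", default = NULL,
      help = "transition:transversion ratio [default 2]"),
    optparse::make_option("--mating", type = "character", default = NULL,
      help = "monogamy | polygamy | polygyny | polyandry"),
    optparse::make_option("--avoid-siblings", action = "store_true",
      default = NULL, dest = "avoid_siblings",
      help = "prohibit full/half-sibling matings"),
    optparse::make_option("--demography", type = "character", default = NULL,
      help = "schedule, e.g. 'constant:100:500,growth:+2:50,constant:200:500'"),
    optparse::make_option("--buffer-theta", type = "double", default = NULL,
      dest = "buffer_theta", help = "buffering target theta_pi (0 = off)"),
    optparse::make_option("--buffer-class", type = "character", default = NULL,
      dest = "buffer_class", help = "locus class monitored while buffering"),
    optparse::make_option("--buffer-boost", type = "double", default = NULL,
      dest = "buffer_boost", help = "mutation-rate boost while buffering"),
    optparse::make_option("--sample", type = "integer", default = NULL,
      help = "sample size (individuals) for reported statistics"),
    optparse::make_option("--stats-every", type = "integer", default = NULL,
      dest = "stats_every", help = "record statistics every k generations"),
    optparse::make_option("--seed", type = "integer", default = NULL,
      help = "master seed [default 1]"),
    optparse::make_option("--save", type = "character", default = NULL,
      help = "path to save final state(s)"),
    optparse::make_option("--load", type = "character", default = NULL,
      help = "path of a saved state to restart from"),
    optparse::make_option(c("-o", "--out"), type = "character", default = NULL,
      help = "output prefix [default 'matesim']"),
    optparse::make_option("--fasta", action = "store_true", default = NULL,
      help = "dump final sequences as FASTA per replicate"),
    optparse::make_option("--workers", type = "integer", default = NULL,
      help = "parallel workers over replicates [default 1]"),
    optparse::make_option("--config", type = "character", default = NULL,
      dest = "command_file", help = "command file (key = value lines)"))
  parser <- optparse::OptionParser(option_list = spec, prog = "matesim")
  opt <- optparse::parse_args(parser, args = args)
  opt$help <- NULL
  cfg <- .default_config()
  explicit <- character(0)
  if (!is.null(opt$command_file)) {
    fvals <- .coerce_config_types(.read_command_file(opt$command_file))
    cfg <- modifyList(cfg, fvals)
    explicit <- names(fvals)
    opt$command_file <- NULL
  }
  opt <- opt[!vapply(opt, is.null, TRUE)]
  if (!is.null(opt$mu)) opt$mu <- .parse_mu_string(opt$mu)
  explicit <- union(explicit, names(opt))
  cfg <- modifyList(cfg, opt)
  cfg <- .coerce_config_types(cfg)
  cfg$explicit <- explicit
  if (is.null(cfg$popsize))
    stop("population size is required (--popsize); all other parameters have defaults")
  stopifnot(cfg$generations >= 1, cfg$replicates >= 1, cfg$workers >= 1)
  structure(cfg, class = "run_config")
}

# replicate r's private seed, derived from the master seed (kept < 2^31)
.derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed %% 2147483647L) * 48271 + r * 2011) %% 2147483629)
}

.config_to_population <- function(cfg) {
  specs <- parse_loci(cfg$loci, mu = cfg$mu, tstv = cfg$tstv)
  schedule <- if (!is.null(cfg$demography)) parse_demography(cfg$demography)
  found_population(cfg$popsize, specs, sex_ratio = cfg$sex_ratio,
                   schedule = schedule,
                   mating = mating_config(cfg$mating, cfg$avoid_siblings,
                                          cfg$max_rejections))
}

# ---- replicate orchestration -------------------------------------------

.run_one_replicate <- function(r, cfg) {
  set.seed(.derive_seed(cfg$seed, r))
  if (!is.null(cfg$load)) {
    # restart: the saved state carries mating/schedule/rates; only explicitly
    # given parameters override them (scenario chaining)
    st <- load_state(cfg$load, restore_rng = FALSE)
    pop <- st$population
    expl <- cfg$explicit
    if (any(c("mating", "avoid_siblings", "max_rejections") %in% expl))
      pop$mating <- mating_config(cfg$mating, cfg$avoid_siblings,
                                  cfg$max_rejections)
    if ("demography" %in% expl && !is.null(cfg$demography))
      pop$schedule <- parse_demography(cfg$demography)
    if ("mu" %in% expl) {
      mu <- cfg$mu
      pop$loci <- lapply(pop$loci, function(l) {
        rate <- if (!is.null(names(mu)) && l$class %in% names(mu)) mu[[l$class]]
                else if (is.null(names(mu))) mu[[1]] else l$mu
        l$mu <- as.numeric(rate)
        l
      })
    }
  } else {
    pop <- .config_to_population(cfg)
    if (cfg$buffer_theta > 0)
      pop <- buffer_population(pop, buffer_config(
        cfg$buffer_theta, boost = cfg$buffer_boost,
        target_class = cfg$buffer_class))
  }
  res <- run_generations(pop, cfg$generations, record_every = cfg$stats_every)
  pop <- res$population
  stats <- res$stats
  if (nrow(stats) == 0 || max(stats$generation) < pop$generation) {
    final <- summarize_population(pop)
    final <- data.frame(generation = pop$generation,
                        locus_class = final$locus_class,
                        locus_index = final$locus_index,
                        n = final$n, L = final$L, S = final$S,
                        theta_w = final$theta_w, pi = final$pi, h = final$h,
                        H_A = final$H_A, H_N = final$H_N)
    stats <- rbind(stats, final)
  }
  if (!is.null(cfg$sample)) {
    smp <- summarize_population(pop, sample_size = cfg$sample)
    smp <- data.frame(generation = pop$generation,
                      locus_class = smp$locus_class,
                      locus_index = smp$locus_index,
                      n = smp$n, L = smp$L, S = smp$S,
                      theta_w = smp$theta_w, pi = smp$pi, h = smp$h,
                      H_A = smp$H_A, H_N = smp$H_N)
    stats <- rbind(stats, smp)
  }
  stats <- cbind(replicate = r, stats)
  fasta_path <- NULL
  if (isTRUE(cfg$fasta)) {
    panels <- lapply(pop$loci, function(l)
      collect_panel(pop, l$class, l$index))
    fasta_path <- sprintf("%s_rep%d.fasta", cfg$out, r)
    write_fasta(panels, fasta_path, replicate = r,
                generation = pop$generation)
  }
  if (!is.null(cfg$save)) {
    path <- if (cfg$replicates == 1L) cfg$save
            else sprintf("%s_rep%d%s", sub("\\.json$", "", cfg$save), r,
                         ifelse(grepl("\\.json$", cfg$save), ".json", ""))
    attr(pop, "replicate") <- r
    save_state(pop, path, config = unclass(cfg))
  }
  stats
}

#' Run a batch of independent replicate simulations
#'
#' Replicate r runs on its own RNG stream derived from \code{(seed, r)}, so
#' replicates are independent, embarrassingly parallel, and the output is
#' byte-identical for any worker count. Statistic rows are ordered
#' canonically by (replicate, generation, class, locus) and written
#' atomically, alongside a log of the resolved configuration and package
#' version. Per-replicate failures are reported with the replicate id and
#' its derived seed.
#'
#' @param config A \code{run_config} from \code{\link{parse_config}} (or a
#'   compatible list).
#' @return Invisibly, a list with \code{stats} (the combined data frame),
#'   \code{stats_path} and \code{log_path}.
#' @export
run_replicates <- function(config) {
  cfg <- config
  if (!inherits(cfg, "run_config")) {
    explicit <- names(cfg)
    cfg <- modifyList(.default_config(), cfg)
    cfg <- .coerce_config_types(cfg)
    cfg$explicit <- explicit
    class(cfg) <- "run_config"
  }
  if (is.null(cfg$popsize)) stop("population size is required")
  runner <- function(r) {
    tryCatch(.run_one_replicate(r, cfg),
             error = function(e) {
               stop("replicate ", r, " (seed ", .derive_seed(cfg$seed, r),
                    ") failed: ", conditionMessage(e), call. = FALSE)
             })
  }
  reps <- seq_len(cfg$replicates)
  results <- if (cfg$workers > 1L) {
    parallel::mclapply(reps, runner, mc.cores = cfg$workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(reps, runner)
  }
  errs <- vapply(results, inherits, TRUE, "try-error")
  if (any(errs)) stop(results[[which(errs)[1]]])
  stats <- do.call(rbind, results)
  stats <- stats[order(stats$replicate, stats$generation,
                       stats$locus_class, stats$locus_index), ]
  rownames(stats) <- NULL
  dir.create(dirname(cfg$out), showWarnings = FALSE, recursive = TRUE)
  stats_path <- paste0(cfg$out, "_stats.tsv")
  write_stats(stats, stats_path)
  log_path <- paste0(cfg$out, ".log")
  .atomic_write(jsonlite::toJSON(
    list(package = "matesim",
         version = as.character(packageVersion("matesim")),
         config = unclass(cfg)),
    auto_unbox = TRUE, pretty = TRUE, null = "null"), log_path)
  invisible(list(stats = stats, stats_path = stats_path,
                 log_path = log_path))
}

#' Command-line entry point
#'
#' Thin wrapper used by the \code{inst/exec/matesim} script:
#' parses arguments and runs the replicate batch.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the \code{\link{run_replicates}} result.
#' @export
main <- function(args = commandArgs(trailingOnly = TRUE)) {
  cfg <- parse_config(args)
  res <- run_replicates(cfg)
  message("wrote ", res$stats_path)
  invisible(res)
}
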