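# Configuration files, CSV serialization, run manifests, test fixtures and
# the command-line interface.

config_schema <- function() {
  list(top = c("variant", "duration", "seed", "sampling_interval",
               "equilibration", "equil_sampling_interval", "elastic",
               "kinetics", "counts", "ecmp_increment", "stiffening",
               "beta", "layout", "ratio_convention", "nuclear_radius"),
       elastic = c("mu_cell", "mu_ecm_base", "alpha", "cell_radius",
                   "sigma_far"))
}

#' Read a run configuration from a YAML file
#'
#' The file may specify any subset of the configuration; omitted keys take
#' the package defaults. Unknown keys (at the top level, under
#' \code{elastic}, or under \code{kinetics}) are rejected.
#'
#' @param path YAML file path.
#' @return A \code{\link{run_config}}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sch <- config_schema()
  bad <- setdiff(names(raw), sch$top)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  el <- elastic_params()
  if (!is.null(raw$elastic)) {
    bad <- setdiff(names(raw$elastic), sch$elastic)
    if (length(bad))
      stop("unknown elastic key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    args <- utils::modifyList(
      list(mu_cell = el$mu_cell, mu_ecm_base = el$mu_ecm_base,
           alpha = el$alpha, cell_radius = el$cell_radius,
           sigma_far = el$sigma_far), raw$elastic)
    el <- do.call(elastic_params, args)
  }
  kin <- if (is.null(raw$kinetics)) kinetics_params() else
    do.call(kinetics_params, as.list(raw$kinetics))
  counts <- agent_counts()
  if (!is.null(raw$counts)) {
    bad <- setdiff(names(raw$counts), names(counts))
    if (length(bad))
      stop("unknown counts key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    counts[names(raw$counts)] <- unlist(raw$counts)
  }
  args <- list(variant = raw$variant %||% "SM",
               elastic = el, kinetics = kin, counts = counts)
  for (key in c("duration", "seed", "sampling_interval", "equilibration",
                "equil_sampling_interval", "ecmp_increment", "stiffening",
                "beta", "layout", "ratio_convention", "nuclear_radius"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_to_list <- function(config) {
  el <- config$elastic
  list(variant = config$variant$name,
       duration = config$duration, seed = config$seed,
       sampling_interval = config$sampling_interval,
       equilibration = config$equilibration,
       equil_sampling_interval = config$equil_sampling_interval,
       elastic = list(mu_cell = el$mu_cell, mu_ecm_base = el$mu_ecm_base,
                      alpha = el$alpha, cell_radius = el$cell_radius,
                      sigma_far = el$sigma_far),
       kinetics = as.list(stats::setNames(as.numeric(config$kinetics),
                                          names(config$kinetics))),
       counts = as.list(config$counts),
       ecmp_increment = config$ecmp_increment,
       stiffening = config$stiffening, beta = config$beta,
       layout = config$layout,
       ratio_convention = config$ratio_convention,
       nuclear_radius = config$nuclear_radius)
}

#' Write a run configuration to YAML
#'
#' @param config A \code{\link{run_config}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Write a sampled time series as CSV
#'
#' One row per sample; the time column is in integer seconds (the 1 s step
#' calibration).
#'
#' @param sim A \code{mech_abm_sim} (or a series data.frame).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_series_csv <- function(sim, path) {
  s <- if (inherits(sim, "mech_abm_sim")) sim$series else sim
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' Read a series CSV written by \code{\link{write_series_csv}}
#' @param path File path.
#' @return Data.frame.
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' A JSON record sufficient to reproduce the run bit-for-bit: the config
#' (inline plus hash), the seed, the package version, timestamps and the
#' output paths.
#'
#' @param sim A \code{mech_abm_sim}.
#' @param path Manifest path (.json).
#' @param outputs Character vector of output file paths covered.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(sim, path, outputs = character()) {
  man <- list(config = config_to_list(sim$config),
              config_hash = config_hash(sim$config),
              seed = sim$config$seed,
              package_version = as.character(utils::packageVersion("mechabm")),
              elapsed_s = sim$elapsed,
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = outputs)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Deterministic miniature fixtures
#'
#' Small, seed-reproducible inputs that exercise each module without a full
#' run: \describe{
#'   \item{\code{toy_world_20_agents}}{2 integrins, 4 FAK and 2 of every
#'     downstream species (20 agents) in a valid world.}
#'   \item{\code{two_integrin_world}}{2 integrins and 2 FAK only.}
#'   \item{\code{triphasic_trace}}{an activation series with known
#'     changepoints: fast rise, plateau at 100, collapse to 5, long hold.}
#'   \item{\code{linear_ecmp_trace}}{a cumulative deposition curve with
#'     slopes of exactly 13/min then 33/min.}
#' }
#'
#' @param kind Fixture name.
#' @param seed Seed (fixtures are deterministic given \code{kind, seed}).
#' @return A \code{mech_abm_world} or a list with \code{time},
#'   \code{values}/\code{cumulative} and the construction ground truth.
#' @export
make_fixture <- function(kind = c("toy_world_20_agents", "triphasic_trace",
                                  "linear_ecmp_trace",
                                  "two_integrin_world"),
                         seed = 1L) {
  kind <- match.arg(kind)
  toy_counts <- function(...) {
    cn <- agent_counts()
    cn[] <- 0L
    ov <- c(...)
    cn[names(ov)] <- ov
    cn
  }
  switch(kind,
    toy_world_20_agents = {
      cfg <- run_config(variant = "SM", duration = 100, seed = seed,
                        counts = toy_counts(integrin = 2L, FAK = 4L,
                                            Ras = 2L, Raf = 2L, MEK = 2L,
                                            ERK = 2L, Runx2 = 2L,
                                            complex = 2L, ribosome = 2L))
      init_world(cfg)
    },
    two_integrin_world = {
      cfg <- run_config(variant = "SM", duration = 100, seed = seed,
                        counts = toy_counts(integrin = 2L, FAK = 2L))
      init_world(cfg)
    },
    triphasic_trace = {
      time <- seq(0, 9900, by = 100)
      values <- c(0, 60, 100, rep(100, 28), 40, rep(5, 68))
      list(time = time, values = values,
           changepoints = list(active_end = time[31],
                               stable_start = time[33]))
    },
    linear_ecmp_trace = {
      time <- seq(0, 7200, by = 60)
      cumulative <- ifelse(time <= 3600, 13 * time / 60,
                           13 * 60 + 33 * (time - 3600) / 60)
      list(time = time, cumulative = cumulative, rates = c(13, 33),
           breakpoint = 3600)
    })
}

# ------------------------------------------------------------------ CLI ----

cli_usage <- function() {
  paste(
    "usage: mech-abm <subcommand> [--flag value ...]",
    "subcommands:",
    "  run        --variant SM|USM|HM10|HM1 --duration S --seed N",
    "             [--config file.yaml] [--out dir]",
    "  replicates --n 16 [run flags]",
    "  analyze    --in dir_or_csv [--metric perk|integrin|ecmp]",
    "  sweep      --param mt_fraction|ultra_fraction --values a,b,c",
    "             [run flags]",
    "  fixtures   --kind name [--seed N] [--out dir]",
    sep = "\n")
}

parse_flags <- function(args) {
  if (length(args) %% 2 != 0)
    stop("flags must come in --name value pairs\n", cli_usage(),
         call. = FALSE)
  keys <- args[c(TRUE, FALSE)]
  vals <- args[c(FALSE, TRUE)]
  if (!all(startsWith(keys, "--")))
    stop("malformed flags\n", cli_usage(), call. = FALSE)
  stats::setNames(as.list(vals), sub("^--", "", keys))
}

cli_config <- function(fl) {
  cfg <- if (!is.null(fl$config)) read_config(fl$config) else run_config()
  if (!is.null(fl$variant))
    cfg <- utils::modifyList(cfg, list(
      variant = variant_spec(fl$variant,
                             ratio_convention = cfg$ratio_convention)))
  if (!is.null(fl$duration)) cfg$duration <- as.integer(fl$duration)
  if (!is.null(fl$seed)) cfg$seed <- as.integer(fl$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Command-line entry point
#'
#' Implements the \code{mech-abm} shell tool (see
#' \code{system.file("exec", "mech-abm", package = "mechabm")}):
#' \code{run} writes one series CSV plus a JSON manifest; \code{replicates}
#' writes one CSV per replicate plus an aggregate summary; \code{analyze}
#' applies the dynamics observables to stored CSVs and writes one JSON per
#' run; \code{sweep} varies the sensitive-threshold fraction or the
#' ultrasensitive population fraction over a grid; \code{fixtures} writes a
#' miniature fixture. Messages go to stderr.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
mech_abm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { message(cli_usage()); return(invisible(1L)) }
  sub <- args[1]
  if (!sub %in% c("run", "replicates", "analyze", "sweep", "fixtures"))
    stop("unknown subcommand '", sub, "'\n", cli_usage(), call. = FALSE)
  fl <- parse_flags(args[-1])
  out_dir <- fl$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (sub == "run") {
    cfg <- cli_config(fl)
    message(sprintf("running %s for %d s (seed %d)", cfg$variant$name,
                    cfg$duration, cfg$seed))
    sim <- run_sim(cfg)
    base <- file.path(out_dir, sprintf("run_%s_seed%d", cfg$variant$name,
                                       cfg$seed))
    write_series_csv(sim, paste0(base, ".csv"))
    write_manifest(sim, paste0(base, "_manifest.json"),
                   outputs = paste0(base, ".csv"))
    message("wrote ", base, ".csv")
  } else if (sub == "replicates") {
    cfg <- cli_config(fl)
    n <- as.integer(fl$n %||% 16)
    message(sprintf("running %d replicates of %s", n, cfg$variant$name))
    rs <- run_replicates(cfg, n = n)
    files <- character()
    for (i in seq_along(rs$runs)) {
      if (!inherits(rs$runs[[i]], "mech_abm_sim")) next
      f <- file.path(out_dir, sprintf("rep_%s_%02d.csv",
                                      cfg$variant$name, i))
      write_series_csv(rs$runs[[i]], f)
      files <- c(files, f)
    }
    agg <- aggregate_replicates(rs, "pERK")
    aggf <- file.path(out_dir, sprintf("agg_%s_pERK.csv",
                                       cfg$variant$name))
    utils::write.csv(agg, aggf, row.names = FALSE)
    write_manifest(rs$runs[[1]],
                   file.path(out_dir,
                             sprintf("replicates_%s_manifest.json",
                                     cfg$variant$name)),
                   outputs = c(files, aggf))
    message("wrote ", length(files), " replicate CSVs and ", aggf)
  } else if (sub == "analyze") {
    src <- fl[["in"]] %||% "."
    files <- if (dir.exists(src))
      list.files(src, pattern = "\\.csv$", full.names = TRUE) else src
    metric <- fl$metric %||% "perk"
    col <- switch(metric, perk = "pERK", integrin = "active_integrins",
                  ecmp = "dep_total",
                  stop("unknown metric '", metric, "'", call. = FALSE))
    for (f in files) {
      s <- read_series_csv(f)
      if (!col %in% names(s)) next
      dyn <- summarize_dynamics(s$time, s[[col]])
      ph <- detect_phases(s$time, s[[col]])
      outf <- file.path(out_dir,
                        sub("\\.csv$", sprintf("_%s_summary.json", metric),
                            basename(f)))
      jsonlite::write_json(
        list(file = basename(f), metric = metric,
             E_max = dyn$E_max, t_E_max = dyn$t_E_max, EC50 = dyn$EC50,
             t_EC50 = dyn$t_EC50, phases = ph),
        outf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      message("wrote ", outf)
    }
  } else if (sub == "sweep") {
    par <- fl$param %||% "mt_fraction"
    vals <- as.numeric(strsplit(fl$values %||% "0.01,0.1", ",")[[1]])
    cfg <- cli_config(fl)
    rows <- lapply(vals, function(v) {
      vs <- cfg$variant
      if (par == "mt_fraction") { vs$mt_sensitive <- v }
      else if (par == "ultra_fraction") {
        vs$ultrasensitive_fraction <- v; vs$sensitive_fraction <- 1 - v
      } else stop("unknown sweep param '", par, "'", call. = FALSE)
      c2 <- cfg; c2$variant <- vs
      sim <- run_sim(c2)
      s <- sim$series
      data.frame(value = v, pERK_max = max(s$pERK),
                 integrin_max = max(s$active_integrins),
                 ecmp_total = max(s$dep_total))
    })
    outf <- file.path(out_dir, sprintf("sweep_%s.csv", par))
    utils::write.csv(do.call(rbind, rows), outf, row.names = FALSE)
    message("wrote ", outf)
  } else if (sub == "fixtures") {
    kind <- fl$kind %||% "toy_world_20_agents"
    fx <- make_fixture(kind, as.integer(fl$seed %||% 1))
    outf <- file.path(out_dir, paste0(kind, ".csv"))
    if (inherits(fx, "mech_abm_world")) {
      utils::write.csv(
        data.frame(id = seq_along(fx$species),
                   name = names(species_codes())[fx$species + 1L],
                   state = fx$state, x = fx$x, y = fx$y, z = fx$z,
                   acs = fx$acs),
        outf, row.names = FALSE)
    } else {
      utils::write.csv(as.data.frame(fx[c(1, 2)]), outf, row.names = FALSE)
    }
    message("wrote ", outf)
  }
  invisible(0L)
}
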