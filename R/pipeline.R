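#' Resolve a pipeline run configuration
#'
#' Fills every unset field with its documented default and returns the
#' fully resolved configuration together with its md5 hash. The hash (and
#' the resolved values themselves) are echoed into the header of every
#' output file, so a run is auditable and reruns with the same
#' configuration are byte-identical.
#'
#' @param config a named list, or the path of a YAML file holding one.
#' @return the resolved config (class \code{run_config}) with attribute
#'   \code{hash}.
#' @export
resolve_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_missing_file("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  def <- list(
    model = "toy",
    objective = NULL,
    stages = c("fba"),
    medium = NULL,            # list(carbon_source=, uptake=) or NULL
    measurements = NULL,      # TSV path: id, value[, tol]
    fva_fraction = 1.0,
    expression = NULL,        # list(table=, condition=, mode=, gamma_low=,
                              #      gamma_high=, epsilon=)
    tolerances = list(solver = 1e-9, zero_growth = 1e-6, activity = 1e-6),
    seed = 1L,
    outdir = "gsmmr_out"
  )
  cfg <- utils::modifyList(def, config, keep.null = TRUE)
  cfg$tolerances <- utils::modifyList(def$tolerances,
                                      as.list(cfg$tolerances))
  if (!is.null(cfg$expression)) {
    edef <- list(condition = NULL, mode = "clamp", gamma_low = 3.00,
                 gamma_high = 850.56, epsilon = 1.0, table = NULL)
    cfg$expression <- utils::modifyList(edef, as.list(cfg$expression))
  }
  canon <- paste(deparse(cfg[order(names(cfg))]), collapse = "\n")
  tmp <- tempfile()
  writeLines(canon, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  structure(cfg, hash = h, class = "run_config")
}

stop_missing_file <- function(...) {
  stop(structure(class = c("gsmmr_missing_file", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_solver <- function(...) {
  stop(structure(class = c("gsmmr_solver_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

config_header <- function(cfg, extra = character()) {
  flat <- function(x, prefix = "") {
    if (is.list(x)) {
      unlist(lapply(names(x), function(nm)
        flat(x[[nm]], paste0(prefix, nm, "."))))
    } else {
      paste0("# config ", sub("\\.$", "", prefix), ": ",
             paste(format(x, trim = TRUE), collapse = ","))
    }
  }
  c(paste0("# gsmmr run, config hash ", attr(cfg, "hash")),
    unlist(lapply(names(cfg), function(nm)
      if (is.null(cfg[[nm]])) character() else flat(cfg[[nm]],
                                                    paste0(nm, ".")))),
    extra)
}

log_solve <- function(what, status, z, secs) {
  message(sprintf("[gsmmr] %s: status=%s Z=%s wall=%.3fs",
                  what, status, format(z), secs))
}

#' Run the analysis pipeline
#'
#' Wires the stages end to end: load (or generate) the model, apply the
#' medium and any measured-exchange constraints, then run the requested
#' stages among \code{"fba"}, \code{"fva"}, \code{"essentiality"} and
#' \code{"integrate"}. Writes \code{fluxes.tsv}, \code{essentiality.tsv}
#' and \code{active_reactions.tsv} (as applicable) into the output
#' directory, every file carrying the resolved configuration and its hash
#' as \code{#} header lines. Every solver call is logged with status,
#' objective and wall time.
#'
#' @param config a named list or YAML path; see \code{\link{resolve_config}}.
#' @return invisibly, \code{list(status = 0, artifacts = <paths>)}. Errors
#'   carry condition classes \code{gsmmr_missing_file} and
#'   \code{gsmmr_solver_error} so wrappers can map them to exit codes.
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()

  model <- if (identical(cfg$model, "toy")) {
    make_toy_core_model(seed = cfg$seed)
  } else {
    if (!dir.exists(cfg$model))
      stop_missing_file("model directory not found: ", cfg$model)
    read_model_dir(cfg$model)
  }
  if (!is.null(cfg$objective)) model$objective <- cfg$objective
  if (!is.null(cfg$medium)) {
    med <- minimal_medium(carbon_source = cfg$medium$carbon_source,
                          uptake = cfg$medium$uptake)
    model <- apply_medium(model, med)
  }
  if (!is.null(cfg$measurements)) {
    if (!file.exists(cfg$measurements))
      stop_missing_file("measurements file not found: ", cfg$measurements)
    meas <- utils::read.delim(cfg$measurements, comment.char = "#",
                              stringsAsFactors = FALSE)
    model <- constrain_measured_exchanges(model, meas)
  }

  states <- NULL
  mode <- NULL
  if (!is.null(cfg$expression)) {
    ex <- cfg$expression
    if (is.null(ex$table) || !file.exists(ex$table))
      stop_missing_file("expression table not found: ",
                        if (is.null(ex$table)) "(unset)" else ex$table)
    tab <- read_expression_table(ex$table)
    thr <- discretization_thresholds(ex$gamma_low, ex$gamma_high)
    states <- gene_states(tab, ex$condition, thr)
    mode <- ex$mode
  }

  tol <- cfg$tolerances$solver
  run_fba <- function(m, what) {
    t0 <- proc.time()[["elapsed"]]
    sol <- solve_fba(m, tol = tol)
    log_solve(what, sol$status, sol$objective,
              proc.time()[["elapsed"]] - t0)
    if (sol$status != "optimal")
      stop_solver(what, ": FBA not optimal (", sol$status, ")")
    sol
  }

  if ("fba" %in% cfg$stages || "fva" %in% cfg$stages) {
    sol <- run_fba(model, "fba")
    lines <- c(config_header(cfg,
                 c(paste0("# objective ", model$objective, " Z = ",
                          fmt_num(sol$objective)))),
               "reaction\tflux\tmin\tmax")
    if ("fva" %in% cfg$stages) {
      t0 <- proc.time()[["elapsed"]]
      rng <- solve_fva(model, fraction = cfg$fva_fraction, tol = tol)
      log_solve("fva", "optimal", attr(rng, "objective"),
                proc.time()[["elapsed"]] - t0)
      lo <- rng$min[match(names(sol$fluxes), rng$id)]
      hi <- rng$max[match(names(sol$fluxes), rng$id)]
    } else {
      lo <- hi <- rep(NA_real_, length(sol$fluxes))
    }
    lines <- c(lines, paste(names(sol$fluxes), fmt_num(sol$fluxes),
                            ifelse(is.na(lo), "", fmt_num(lo)),
                            ifelse(is.na(hi), "", fmt_num(hi)), sep = "\t"))
    f <- file.path(cfg$outdir, "fluxes.tsv")
    writeLines(lines, f)
    artifacts <- c(artifacts, f)
  }

  if ("essentiality" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    rep <- essentiality_scan(model, zero_tol = cfg$tolerances$zero_growth,
                             tol = tol)
    log_solve("essentiality", "optimal", rep$z_wt[1],
              proc.time()[["elapsed"]] - t0)
    lines <- c(config_header(cfg,
                 c(sprintf("# essential %d of %d genes (%.1f%%)",
                           attr(rep, "n_essential"), nrow(rep),
                           100 * attr(rep, "fraction_essential")))),
               "gene\tz_wt\tz_ko\tessential\tskipped",
               paste(rep$gene, fmt_num(rep$z_wt), fmt_num(rep$z_ko),
                     rep$essential, rep$skipped, sep = "\t"))
    f <- file.path(cfg$outdir, "essentiality.tsv")
    writeLines(lines, f)
    artifacts <- c(artifacts, f)
  }

  if ("integrate" %in% cfg$stages) {
    if (is.null(states))
      stop_missing_file("integrate stage requires an expression config")
    if (identical(mode, "clamp")) {
      m2 <- apply_expression_constraints(model, states, mode = "clamp")
      sol2 <- run_fba(m2, "integrate-clamp")
      rep2 <- active_reaction_report(m2, sol2,
                                     tol = cfg$tolerances$activity)
    } else {
      prob <- apply_expression_constraints(model, states, mode = "imat",
                                           epsilon = cfg$expression$epsilon)
      t0 <- proc.time()[["elapsed"]]
      ires <- solve_imat(prob, tol = tol)
      log_solve("integrate-imat", ires$status, ires$score,
                proc.time()[["elapsed"]] - t0)
      if (ires$status != "optimal")
        stop_solver("imat: ", ires$status)
      rep2 <- active_reaction_report(model, ires,
                                     tol = cfg$tolerances$activity)
    }
    lines <- c(config_header(cfg,
                 c(paste0("# mode ", mode),
                   paste0("# condition ", cfg$expression$condition),
                   paste0("# total_active ", attr(rep2, "total")))),
               "subsystem\tcount",
               paste(rep2$subsystem, rep2$count, sep = "\t"))
    f <- file.path(cfg$outdir, "active_reactions.tsv")
    writeLines(lines, f)
    artifacts <- c(artifacts, f)
  }

  invisible(list(status = 0L, artifacts = artifacts))
}
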