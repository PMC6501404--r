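#' @section Model dialect:
#' Models are exchanged as a directory of plain-text, UTF-8, tab-separated
#' files with \code{#} comment lines:
#' \itemize{
#'   \item \code{model.tsv} — one reaction per line; columns \code{id},
#'     \code{name}, \code{equation}, \code{lb}, \code{ub}, \code{subsystem}.
#'     Equations use \code{-->} (irreversible) or \code{<=>} (reversible),
#'     e.g. \code{"2 A_c + B_c --> C_c"}. When bounds are empty they default
#'     to \code{[0, 1000]} or \code{[-1000, 1000]} by arrow. A loose two- or
#'     three-column form (\code{id<TAB>equation}) and the colon form
#'     \code{"R1: A_c --> B_c"} are also accepted.
#'   \item \code{biomass.txt} — the single biomass equation, written as
#'     \code{"coefficient metabolite + ... --> ..."}; omitted coefficients
#'     mean 1.
#'   \item \code{exchange.tsv} — \code{id<TAB>lb<TAB>ub} bound overrides for
#'     exchange reactions.
#'   \item \code{gpr.tsv} — \code{reaction-id<TAB>boolean expression} with
#'     \code{and}/\code{or} and parentheses.
#'   \item \code{metabolites.tsv} (optional) — \code{id<TAB>name<TAB>
#'     compartment} overrides; compartments are otherwise inferred from the
#'     id suffix (\code{_c} intracellular, \code{_e} extracellular, \code{_b}
#'     boundary; no suffix means intracellular).
#' }
#' @name model_dialect
#' @keywords internal
NULL

fmt_num <- function(x) sprintf("%.15g", x)

id_re <- "^[A-Za-z0-9_.\\-]+$"

strip_comments <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  structure(lines[keep], lineno = which(keep))
}

# parse one side of an equation into a named coefficient vector
parse_side <- function(side, where) {
  side <- trimws(side)
  if (side == "") return(numeric())
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- numeric()
  for (k in seq_along(terms)) {
    toks <- strsplit(terms[k], "\\s+")[[1]]
    toks <- toks[toks != ""]
    if (length(toks) == 1L) {
      coef <- 1; id <- toks[1]
    } else if (length(toks) == 2L) {
      coef <- suppressWarnings(as.numeric(toks[1]))
      if (is.na(coef))
        stop("parse error in ", where, ", term ", k,
             ": '", toks[1], "' is neither a number nor an id")
      id <- toks[2]
    } else {
      stop("parse error in ", where, ", term ", k, ": '", terms[k], "'")
    }
    if (!grepl(id_re, id))
      stop("parse error in ", where, ", term ", k, ": bad id '", id, "'")
    out[id] <- if (id %in% names(out)) out[[id]] + coef else coef
  }
  out
}

parse_equation <- function(eq, where = "equation") {
  rev <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (rev) "<=>" else "-->"
  if (!grepl(arrow, eq, fixed = TRUE))
    stop("parse error in ", where, ": no '-->' or '<=>' arrow")
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  lhs <- parse_side(sides[1], where)
  rhs <- parse_side(sides[2], where)
  st <- numeric()
  for (id in names(lhs)) st[id] <- -lhs[[id]]
  for (id in names(rhs)) st[id] <- (if (id %in% names(st)) st[[id]] else 0) + rhs[[id]]
  list(stoich = st, reversible = rev)
}

equation_string <- function(stoich, reversible) {
  side <- function(v) {
    if (!length(v)) return("")
    v <- v[order(names(v))]
    paste(ifelse(v == 1, names(v), paste(fmt_num(v), names(v))),
          collapse = " + ")
  }
  lhs <- side(-stoich[stoich < 0])
  rhs <- side(stoich[stoich > 0])
  paste(lhs, if (reversible) "<=>" else "-->", rhs)
}

#' Parse a model file into a metabolic model
#'
#' Reads the reaction table of the package's model dialect (see
#' \code{\link{model_dialect}}). Metabolites are created on first use and
#' their compartments inferred from id suffixes; a dangling metabolite is
#' never an error.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @return a \code{metabolic_model} (objective unset).
#' @export
parse_model_file <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  dat <- strip_comments(lines)
  nums <- attr(dat, "lineno")
  if (length(dat) && grepl("^id\t", dat[1])) { dat <- dat[-1]; nums <- nums[-1] }
  reactions <- list()
  for (i in seq_along(dat)) {
    ln <- dat[i]
    where <- paste0("line ", nums[i])
    if (grepl("\t", ln, fixed = TRUE)) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 2L) stop("parse error at ", where, ": too few columns")
      id <- trimws(f[1])
      if (length(f) == 2L) {
        nm <- id; eq <- f[2]; lb <- ub <- NA; subsys <- "Unassigned"
      } else {
        nm <- trimws(f[2]); eq <- f[3]
        lb <- if (length(f) >= 4L && nzchar(trimws(f[4])))
          as.numeric(f[4]) else NA
        ub <- if (length(f) >= 5L && nzchar(trimws(f[5])))
          as.numeric(f[5]) else NA
        subsys <- if (length(f) >= 6L && nzchar(trimws(f[6])))
          trimws(f[6]) else "Unassigned"
      }
    } else if (grepl(":", ln, fixed = TRUE)) {
      id <- trimws(sub(":.*", "", ln))
      nm <- id; eq <- sub("^[^:]*:", "", ln)
      lb <- ub <- NA; subsys <- "Unassigned"
    } else stop("parse error at ", where, ": unrecognized line")
    if (!grepl(id_re, id)) stop("parse error at ", where, ": bad id '", id, "'")
    if (id %in% names(reactions))
      stop("duplicate reaction id '", id, "' at ", where)
    pe <- parse_equation(eq, where)
    if (is.na(lb)) lb <- if (pe$reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000
    reactions[[id]] <- reaction(id, pe$stoich, lb = lb, ub = ub, name = nm,
                                subsystem = subsys)
  }
  metabolic_model(build_metabolite_table(reactions), reactions)
}

#' Parse the biomass objective equation
#'
#' The biomass pseudo-reaction consumes growth precursors (amino acids,
#' nucleotides, lipids, cofactors and ATP) in fixed stoichiometry and
#' releases the hydrolysis products (ADP, phosphate, protons). The printed
#' syntax is \code{"coefficient metabolite + ... --> ..."}; an omitted
#' coefficient means 1, and scientific notation (\code{5.0E-5}) is kept
#' exactly.
#'
#' @param text the equation string (may span several lines).
#' @return object of class \code{biomass_equation} with named positive
#'   coefficient vectors \code{reactants} and \code{products}.
#' @export
parse_biomass_equation <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  eq <- paste(strip_comments(lines), collapse = " ")
  pe <- parse_equation(eq, "biomass equation")
  st <- pe$stoich
  structure(list(reactants = -st[st < 0], products = st[st > 0]),
            class = "biomass_equation")
}

#' @export
print.biomass_equation <- function(x, ...) {
  cat("Biomass equation:", length(x$reactants), "reactants,",
      length(x$products), "products\n")
  invisible(x)
}

# convert a parsed biomass equation into the objective reaction
biomass_reaction <- function(eq, id = "BIOMASS") {
  st <- c(-eq$reactants, eq$products)
  reaction(id, st, lb = 0, ub = 1000, subsystem = "Biomass")
}

#' Attach GPR rules from a GPR file
#'
#' Lines are \code{reaction-id<TAB>boolean expression}. The model's gene
#' list is rebuilt from the distinct leaves of all attached rules.
#'
#' @param text character vector of lines (or one string).
#' @param model a \code{metabolic_model}.
#' @return the model with GPRs attached.
#' @export
parse_gpr_file <- function(text, model) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  dat <- strip_comments(lines)
  if (!length(dat)) return(model)
  f <- strsplit(dat, "\t", fixed = TRUE)
  ids <- vapply(f, `[[`, "", 1L)
  unknown <- setdiff(ids, names(model$reactions))
  if (length(unknown))
    stop("GPR file names unknown reactions: ",
         paste(unknown, collapse = ", "))
  for (k in seq_along(f)) {
    model$reactions[[ids[k]]]$gpr <- parse_gpr_expression(f[[k]][2L])
  }
  model$genes <- sort(unique(unlist(lapply(model$reactions, function(r)
    if (is.null(r$gpr)) character() else gpr_leaves(r$gpr)))))
  model
}

#' Apply exchange-bound overrides from an exchange file
#'
#' Lines are \code{exchange-reaction-id<TAB>lb<TAB>ub}; bounds are
#' overwritten only for the listed reactions. An empty file leaves the model
#' unchanged.
#'
#' @param text character vector of lines (or one string).
#' @param model a \code{metabolic_model}.
#' @return the model with updated bounds.
#' @export
parse_exchange_file <- function(text, model) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  dat <- strip_comments(lines)
  for (ln in dat) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("exchange file: expected id<TAB>lb<TAB>ub: ", ln)
    id <- trimws(f[1]); lb <- as.numeric(f[2]); ub <- as.numeric(f[3])
    if (!id %in% names(model$reactions))
      stop("exchange file names unknown reaction: ", id)
    if (is.na(lb) || is.na(ub)) stop("exchange file: bad bounds for ", id)
    if (lb > ub) stop("exchange file: lb > ub for ", id)
    model$reactions[[id]]$lb <- lb
    model$reactions[[id]]$ub <- ub
  }
  model
}

#' Read a model directory
#'
#' Loads \code{model.tsv} plus the optional \code{biomass.txt} (added as the
#' objective reaction), \code{exchange.tsv}, \code{gpr.tsv} and
#' \code{metabolites.tsv} companions, then validates the assembled model.
#'
#' @param dir directory path.
#' @param biomass_id id given to the biomass reaction (default "BIOMASS").
#' @return a validated \code{metabolic_model}.
#' @export
read_model_dir <- function(dir, biomass_id = "BIOMASS") {
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("model.tsv"))) stop("missing model.tsv in ", dir)
  model <- parse_model_file(readLines(p("model.tsv")))
  if (file.exists(p("biomass.txt"))) {
    eq <- parse_biomass_equation(readLines(p("biomass.txt")))
    br <- biomass_reaction(eq, biomass_id)
    model$reactions[[biomass_id]] <- br
    model$objective <- biomass_id
  }
  overrides <- NULL
  if (file.exists(p("metabolites.tsv"))) {
    dat <- strip_comments(readLines(p("metabolites.tsv")))
    f <- strsplit(dat, "\t", fixed = TRUE)
    overrides <- data.frame(id = vapply(f, `[[`, "", 1L),
                            name = vapply(f, `[[`, "", 2L),
                            compartment = vapply(f, `[[`, "", 3L),
                            stringsAsFactors = FALSE)
    short <- c(c = "intracellular", e = "extracellular", b = "boundary")
    is_short <- overrides$compartment %in% names(short)
    overrides$compartment[is_short] <- short[overrides$compartment[is_short]]
    bad <- setdiff(overrides$compartment, compartment_classes)
    if (length(bad))
      stop("metabolites.tsv: unknown compartment ", paste(bad, collapse = ", "))
  }
  model$metabolites <- build_metabolite_table(model$reactions, overrides)
  if (file.exists(p("gpr.tsv")))
    model <- parse_gpr_file(readLines(p("gpr.tsv")), model)
  if (file.exists(p("exchange.tsv")))
    model <- parse_exchange_file(readLines(p("exchange.tsv")), model)
  validate_model(model)
  model
}

#' Write a model directory
#'
#' Emits the four dialect files (plus \code{metabolites.tsv} when any
#' metabolite name or compartment differs from what the id suffix implies)
#' deterministically: reactions sorted by id, fixed column order, stable
#' number formatting. \code{read_model_dir(write_model(m))} reproduces the
#' model component-wise.
#'
#' @param model a \code{metabolic_model}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(names(model$reactions))
  obj <- model$objective
  body_ids <- setdiff(ids, if (is.na(obj)) character() else obj)
  rows <- vapply(body_ids, function(id) {
    r <- model$reactions[[id]]
    paste(r$id, r$name, equation_string(r$stoich, r$lb < 0),
          fmt_num(r$lb), fmt_num(r$ub), r$subsystem, sep = "\t")
  }, character(1))
  writeLines(c("id\tname\tequation\tlb\tub\tsubsystem", rows),
             file.path(dir, "model.tsv"))
  if (!is.na(obj)) {
    r <- model$reactions[[obj]]
    writeLines(equation_string(r$stoich, FALSE), file.path(dir, "biomass.txt"))
  }
  exch <- is_exchange(model)
  ex_ids <- intersect(ids, names(exch)[exch])
  writeLines(vapply(ex_ids, function(id) {
    r <- model$reactions[[id]]
    paste(id, fmt_num(r$lb), fmt_num(r$ub), sep = "\t")
  }, character(1)), file.path(dir, "exchange.tsv"))
  gpr_ids <- ids[vapply(ids, function(id)
    !is.null(model$reactions[[id]]$gpr), logical(1))]
  writeLines(vapply(gpr_ids, function(id)
    paste(id, deparse_gpr(model$reactions[[id]]$gpr), sep = "\t"),
    character(1)), file.path(dir, "gpr.tsv"))
  met <- model$metabolites
  inferred <- infer_compartment(met$id)
  need <- met$name != met$id | met$compartment != inferred
  if (any(need)) {
    m <- met[need, , drop = FALSE]
    m <- m[order(m$id), , drop = FALSE]
    writeLines(paste(m$id, m$name, m$compartment, sep = "\t"),
               file.path(dir, "metabolites.tsv"))
  }
  invisible(dir)
}
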