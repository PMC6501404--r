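#' Construct a metabolic model
#'
#' A \code{metabolic_model} bundles metabolites, reactions (stoichiometry,
#' bounds, subsystem, optional gene-protein-reaction rule), the gene list and
#' the id of the biomass (objective) reaction. Metabolites belong to one of
#' three compartment classes: \code{intracellular}, \code{extracellular} or
#' \code{boundary}; boundary metabolites are the open ends of the network and
#' are excluded from the steady-state mass balance.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @param reactions named list of reaction objects from \code{\link{reaction}}.
#' @param objective id of the objective (biomass) reaction, or \code{NA}.
#' @param genes character vector of gene ids; if \code{NULL}, derived from the
#'   distinct GPR leaves.
#' @return object of class \code{metabolic_model}.
#' @seealso \code{\link{validate_model}}, \code{\link{read_model_dir}}
#' @export
metabolic_model <- function(metabolites, reactions, objective = NA_character_,
                            genes = NULL) {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions, function(r)
      if (is.null(r$gpr)) character() else gpr_leaves(r$gpr)))))
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 genes = genes, objective = objective),
            class = "metabolic_model")
}

#' Construct a reaction
#'
#' @param id reaction id (token).
#' @param stoich named numeric vector of signed stoichiometric coefficients
#'   (negative = consumed, positive = produced); must be non-empty.
#' @param lb,ub flux bounds in mmol/gDW/h; defaults \code{[0, 1000]} for
#'   irreversible and \code{[-1000, 1000]} for reversible reactions.
#' @param name free-text name (defaults to the id).
#' @param subsystem pathway category label, e.g. "Citrate cycle (TCA cycle)".
#' @param gpr optional GPR rule tree (see \code{\link{parse_gpr_expression}}).
#' @param reversible logical; used only to pick default bounds when
#'   \code{lb}/\code{ub} are missing.
#' @export
reaction <- function(id, stoich, lb = NULL, ub = NULL, name = id,
                     subsystem = "Unassigned", gpr = NULL,
                     reversible = FALSE) {
  if (is.null(lb)) lb <- if (reversible) -1000 else 0
  if (is.null(ub)) ub <- 1000
  stopifnot(length(stoich) >= 1L, !is.null(names(stoich)))
  list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
       subsystem = subsystem, gpr = gpr)
}

#' Infer a compartment class from a metabolite id suffix
#'
#' \code{_b} is boundary, \code{_e} extracellular; everything else (including
#' suffix-free ids such as the biomass precursor tokens) is intracellular.
#' @param ids character vector of metabolite ids.
#' @return character vector of compartment classes.
#' @export
infer_compartment <- function(ids) {
  ifelse(grepl("_b$", ids), "boundary",
         ifelse(grepl("_e$", ids), "extracellular", "intracellular"))
}

compartment_classes <- c("intracellular", "extracellular", "boundary")

# build the metabolite table for a set of reactions, honoring overrides
build_metabolite_table <- function(reactions, overrides = NULL) {
  ids <- sort(unique(unlist(lapply(reactions, function(r) names(r$stoich)))))
  comp <- infer_compartment(ids)
  nm <- ids
  if (!is.null(overrides) && nrow(overrides)) {
    i <- match(overrides$id, ids)
    ok <- !is.na(i)
    comp[i[ok]] <- overrides$compartment[ok]
    if (!is.null(overrides$name)) nm[i[ok]] <- overrides$name[ok]
  }
  data.frame(id = ids, name = nm, compartment = comp,
             stringsAsFactors = FALSE)
}

#' Validate a metabolic model against its structural invariants
#'
#' Checks: unique metabolite and reaction ids; legal compartment classes;
#' \code{lb <= ub}; non-empty stoichiometries; every stoichiometry key
#' resolves to a metabolite; every GPR leaf is a model gene; only exchange
#' reactions touch boundary metabolites.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly; stops with a message on violation.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids")
  if (!all(met$compartment %in% compartment_classes))
    stop("unknown compartment class: ",
         paste(setdiff(met$compartment, compartment_classes), collapse = ", "))
  ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  boundary <- met$id[met$compartment == "boundary"]
  exch <- is_exchange(model)
  for (r in model$reactions) {
    if (r$lb > r$ub) stop("reaction ", r$id, ": lb > ub")
    if (!length(r$stoich)) stop("reaction ", r$id, ": empty stoichiometry")
    missing_met <- setdiff(names(r$stoich), met$id)
    if (length(missing_met))
      stop("reaction ", r$id, ": unknown metabolites ",
           paste(missing_met, collapse = ", "))
    if (!exch[[r$id]] && any(names(r$stoich) %in% boundary))
      stop("non-exchange reaction ", r$id, " touches a boundary metabolite")
    if (!is.null(r$gpr)) {
      bad <- setdiff(gpr_leaves(r$gpr), model$genes)
      if (length(bad))
        stop("reaction ", r$id, ": GPR genes not in model: ",
             paste(bad, collapse = ", "))
    }
  }
  if (!is.na(model$objective) && !model$objective %in% ids)
    stop("objective reaction not in model: ", model$objective)
  invisible(model)
}

#' Identify exchange reactions
#'
#' An exchange reaction moves one metabolite across the system boundary:
#' either a pair \code{X_e <=> X_b} (exactly two metabolites, exactly one
#' of them boundary) or a one-sided reaction (all coefficients of the same
#' sign). Any other reaction touching a boundary metabolite is a structural
#' error caught by \code{\link{validate_model}}.
#' @param model a \code{metabolic_model}.
#' @return named logical vector over reaction ids.
#' @export
is_exchange <- function(model) {
  boundary <- model$metabolites$id[model$metabolites$compartment == "boundary"]
  out <- vapply(model$reactions, function(r) {
    bmask <- names(r$stoich) %in% boundary
    if (any(bmask)) {
      length(r$stoich) <= 2L && sum(bmask) == 1L
    } else {
      all(r$stoich > 0) || all(r$stoich < 0)
    }
  }, logical(1))
  names(out) <- vapply(model$reactions, `[[`, "", "id")
  out
}

#' Stoichiometric matrix S
#'
#' One row per non-boundary metabolite, one column per reaction. Boundary
#' metabolites are the system's open ends and carry no steady-state balance.
#' @param model a \code{metabolic_model}.
#' @return dense numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model) {
  met <- model$metabolites
  rows <- met$id[met$compartment != "boundary"]
  rids <- vapply(model$reactions, `[[`, "", "id")
  S <- matrix(0, nrow = length(rows), ncol = length(rids),
              dimnames = list(rows, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    keep <- names(st) %in% rows
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  S
}

# bounds vectors in reaction order
reaction_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lb"),
       ub = vapply(model$reactions, `[[`, 0, "ub"),
       id = vapply(model$reactions, `[[`, "", "id"))
}

#' Set bounds of one reaction
#' @param model a \code{metabolic_model}.
#' @param id reaction id.
#' @param lb,ub new bounds (either may be \code{NULL} to keep the current one).
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!id %in% names(model$reactions)) stop("unknown reaction: ", id)
  if (!is.null(lb)) model$reactions[[id]]$lb <- lb
  if (!is.null(ub)) model$reactions[[id]]$ub <- ub
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  comp <- table(factor(x$metabolites$compartment, compartment_classes))
  cat("Metabolic model:", length(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,", length(x$genes), "genes\n")
  cat("  metabolites:", comp[["intracellular"]], "intracellular,",
      comp[["extracellular"]], "extracellular,",
      comp[["boundary"]], "boundary\n")
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  cls <- classify_reactions_by_gene_count(object)
  subsys <- sort(table(vapply(object$reactions, `[[`, "", "subsystem")),
                 decreasing = TRUE)
  out <- list(n_reactions = length(object$reactions),
              n_metabolites = nrow(object$metabolites),
              n_genes = length(object$genes),
              compartments = table(factor(object$metabolites$compartment,
                                          compartment_classes)),
              gene_association = cls,
              subsystems = subsys)
  class(out) <- "summary.metabolic_model"
  out
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("Reactions:", x$n_reactions,
      "(", x$gene_association[["single"]], "single-gene,",
      x$gene_association[["multi"]], "multi-gene,",
      x$gene_association[["none"]], "without GPR )\n")
  cat("Metabolites:", x$n_metabolites, "| Genes:", x$n_genes, "\n")
  cat("Subsystems:\n")
  print(x$subsystems)
  invisible(x)
}

#' Medium specification
#'
#' A named set of exchangeable components with maximal uptake rates plus a
#' designated carbon source (which must be one of the components). Uptake
#' rates are non-negative numbers in mmol/gDW/h; they bound the influx
#' (negative exchange flux) of each component.
#'
#' @param components named numeric vector: metabolite id -> max uptake rate.
#' @param carbon_source name of the carbon source; must be a component.
#' @return object of class \code{medium_spec}.
#' @export
medium_spec <- function(components, carbon_source) {
  stopifnot(is.numeric(components), !is.null(names(components)))
  if (any(components < 0)) stop("uptake rates must be >= 0")
  if (!carbon_source %in% names(components))
    stop("carbon source must be a member of the medium components")
  structure(list(components = components, carbon_source = carbon_source),
            class = "medium_spec")
}

#' The minimal medium used for the simulations
#'
#' Water, ammonia, sulfate, phosphate, calcium, iron, hydrogen sulfide,
#' potassium, magnesium, pantothenate and nicotinate D-ribonucleotide, plus a
#' single carbon source with a bounded uptake rate. Mineral components get an
#' effectively unconstrained uptake of 1000 mmol/gDW/h.
#'
#' @param carbon_source metabolite id of the carbon source (e.g. "glc").
#' @param uptake carbon uptake bound in mmol/gDW/h (default 10.53, the
#'   experimentally observed glucose uptake rate during batch growth).
#' @export
minimal_medium <- function(carbon_source = "glc", uptake = 10.53) {
  base <- c(h2o = 1000, nh4 = 1000, so4 = 1000, pi = 1000, ca2 = 1000,
            fe3 = 1000, h2s = 1000, k = 1000, mg2 = 1000,
            `pnto-r` = 1000, nmn = 1000)
  comps <- c(base, structure(uptake, names = carbon_source))
  medium_spec(comps, carbon_source)
}
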