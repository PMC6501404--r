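#' Flux balance analysis
#'
#' Maximizes the flux through the objective (biomass) reaction subject to
#' steady-state mass balance \code{S v = 0} over all non-boundary metabolites
#' and the flux bounds \code{a_i <= v_i <= b_i}. Because the optimum is
#' usually degenerate (alternate optimal flux distributions reach the same
#' objective), the reported flux vector is post-processed by a secondary LP
#' that minimizes the total absolute flux at the fixed optimal objective;
#' this makes downstream "active reaction" accounting reproducible.
#'
#' @param model a validated \code{metabolic_model}.
#' @param objective objective reaction id (defaults to the model's).
#' @param minimize_total_flux run the flux-sum-minimizing secondary LP
#'   (default \code{TRUE}); turn off for speed when only the objective value
#'   is needed, e.g. inside deletion scans.
#' @param tol solver feasibility tolerance.
#' @return object of class \code{fba_solution}: \code{status} ("optimal",
#'   "infeasible" or "unbounded"), \code{objective} (Z) and \code{fluxes}
#'   (named vector, mmol/gDW/h). Biological infeasibility is reported in
#'   \code{status}, never thrown.
#' @export
solve_fba <- function(model, objective = model$objective,
                      minimize_total_flux = TRUE, tol = 1e-9) {
  if (is.na(objective) || !objective %in% names(model$reactions))
    stop("objective reaction not in model: ", objective)
  S <- stoich_matrix(model)
  bd <- reaction_bounds(model)
  n <- length(bd$id)
  cv <- numeric(n)
  cv[match(objective, bd$id)] <- 1
  res <- solve_lp(cv, S, rep(0, nrow(S)), bd$lb, bd$ub, tol = tol)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective = NA_real_,
                          fluxes = NULL, objective_id = objective),
                     class = "fba_solution"))
  }
  z <- res$objective
  v <- res$x
  if (minimize_total_flux) {
    v2 <- minimize_flux_at_objective(S, bd, match(objective, bd$id), z, tol)
    if (!is.null(v2)) v <- v2
  }
  names(v) <- bd$id
  structure(list(status = "optimal", objective = z, fluxes = v,
                 objective_id = objective),
            class = "fba_solution")
}

# Secondary LP: minimize sum |v_i| subject to S v = 0, bounds, and the
# objective flux pinned (within tolerance) to its optimum. Each flux is
# decomposed as v = p - q with p in [0, max(ub, 0)] intersected with the
# original bounds, so no admissible point is lost and sum(p + q) attains
# |v| at the optimum of the minimization.
minimize_flux_at_objective <- function(S, bd, obj_idx, z, tol) {
  n <- length(bd$id)
  lb <- bd$lb; ub <- bd$ub
  lb[obj_idx] <- max(lb[obj_idx], z - 1e-8)
  ub[obj_idx] <- min(ub[obj_idx], z + 1e-8)
  split <- lb < 0 & ub > 0
  # columns: all v as p-part, plus a q-part for each split variable
  qi <- which(split)
  nq <- length(qi)
  plb <- ifelse(split, 0, lb)
  pub <- ub
  A <- cbind(S, -S[, qi, drop = FALSE])
  # |v| costs: split vars pay on both parts; an all-negative variable
  # (ub <= 0) has |v| = -v, hence cost -1 on its single part
  cobj <- c(ifelse(split | lb >= 0, 1, -1), rep(1, nq))
  lbx <- c(plb, rep(0, nq))
  ubx <- c(pub, -lb[qi])
  res <- solve_lp(cobj, A, rep(0, nrow(S)), lbx, ubx,
                  maximize = FALSE, tol = tol)
  if (res$status != "optimal") return(NULL)
  v <- res$x[seq_len(n)]
  v[qi] <- v[qi] - res$x[n + seq_len(nq)]
  v
}

#' @export
print.fba_solution <- function(x, digits = 6, ...) {
  cat("FBA solution (", x$objective_id, "): status ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", Z = ", signif(x$objective, digits), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
coef.fba_solution <- function(object, ...) object$fluxes

#' @export
summary.fba_solution <- function(object, tol = 1e-6, ...) {
  act <- if (is.null(object$fluxes)) character() else
    names(object$fluxes)[abs(object$fluxes) > tol]
  out <- list(status = object$status, objective = object$objective,
              n_active = length(act), active = act)
  class(out) <- "summary.fba_solution"
  out
}

#' @export
print.summary.fba_solution <- function(x, ...) {
  cat("status:", x$status, "| Z =", x$objective,
      "|", x$n_active, "reactions carrying flux\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For every reaction, minimizes and maximizes its flux subject to the mass
#' balance, the bounds, and the requirement that the objective flux stays at
#' or above \code{fraction} times its FBA optimum. At \code{fraction = 0}
#' the objective constraint is dropped and the ranges are those reachable
#' under \code{S v = 0} alone.
#'
#' @param model a validated \code{metabolic_model}.
#' @param fraction required fraction of the optimal objective, in [0, 1]
#'   (default 1: ranges at the constrained optimum).
#' @param reactions reaction ids to analyze (default: all).
#' @param tol solver tolerance.
#' @return object of class \code{fva_result}: data.frame with columns
#'   \code{id}, \code{min}, \code{max}; attribute \code{objective} holds Z*.
#' @export
solve_fva <- function(model, fraction = 1, reactions = NULL, tol = 1e-9) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a number in [0, 1]")
  S <- stoich_matrix(model)
  bd <- reaction_bounds(model)
  n <- length(bd$id)
  lb <- bd$lb; ub <- bd$ub
  z <- NA_real_
  if (fraction > 0) {
    fba <- solve_fba(model, minimize_total_flux = FALSE, tol = tol)
    if (fba$status != "optimal")
      stop("FVA requires a finite FBA optimum; status: ", fba$status)
    z <- fba$objective
    oi <- match(model$objective, bd$id)
    lb[oi] <- max(lb[oi], fraction * z - 1e-9)
  }
  sel <- if (is.null(reactions)) bd$id else reactions
  idx <- match(sel, bd$id)
  if (anyNA(idx)) stop("unknown reactions: ",
                       paste(sel[is.na(idx)], collapse = ", "))
  vmin <- vmax <- numeric(length(idx))
  b0 <- rep(0, nrow(S))
  for (k in seq_along(idx)) {
    cv <- numeric(n); cv[idx[k]] <- 1
    lo <- solve_lp(cv, S, b0, lb, ub, maximize = FALSE, tol = tol)
    hi <- solve_lp(cv, S, b0, lb, ub, maximize = TRUE, tol = tol)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for ", sel[k], " (", lo$status, ")")
    vmin[k] <- lo$objective; vmax[k] <- hi$objective
  }
  structure(data.frame(id = sel, min = vmin, max = vmax,
                       stringsAsFactors = FALSE),
            objective = z, fraction = fraction,
            class = c("fva_result", "data.frame"))
}

#' @export
print.fva_result <- function(x, ...) {
  cat("FVA at fraction", attr(x, "fraction"),
      "of Z* =", attr(x, "objective"), "\n")
  NextMethod()
}

#' Apply a medium to a model
#'
#' Closes the uptake (lower) bound of every exchange reaction, then re-opens
#' uptake for each medium component at its stated maximal rate; the carbon
#' source gets its own uptake bound. Secretion (upper) bounds are left
#' untouched. Components are matched to the exchange reaction consuming the
#' extracellular form of the metabolite (id or \code{<id>_e}).
#'
#' @param model a \code{metabolic_model}.
#' @param medium a \code{\link{medium_spec}}.
#' @return the constrained model, with the medium recorded in
#'   \code{attr(, "medium")}.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(medium, "medium_spec"))
  exch <- names(which(is_exchange(model)))
  for (id in exch)
    model$reactions[[id]]$lb <- max(model$reactions[[id]]$lb, 0)
  for (comp in names(medium$components)) {
    hit <- exch[vapply(exch, function(id) {
      mets <- names(model$reactions[[id]]$stoich)
      comp %in% mets || paste0(comp, "_e") %in% mets
    }, logical(1))]
    if (!length(hit))
      stop("medium component has no exchange reaction: ", comp)
    model$reactions[[hit[1]]]$lb <- -medium$components[[comp]]
  }
  attr(model, "medium") <- medium
  model
}

#' Constrain exchanges to measured fluxes
#'
#' Sets each measured reaction's bounds to \code{[m - tol, m + tol]},
#' reproducing the protocol of running simulations under progressively more
#' experimentally determined constraints. A measurement window that is
#' inconsistent with mass balance surfaces as an infeasible status at solve
#' time; it is never silently relaxed.
#'
#' @param model a \code{metabolic_model}.
#' @param measurements data.frame with columns \code{id}, \code{value} and
#'   optionally \code{tol} (half-width, default 0), or a named numeric
#'   vector of exact measurements.
#' @return the constrained model.
#' @export
constrain_measured_exchanges <- function(model, measurements) {
  if (is.numeric(measurements) && !is.null(names(measurements)))
    measurements <- data.frame(id = names(measurements),
                               value = unname(measurements),
                               stringsAsFactors = FALSE)
  if (is.null(measurements$tol)) measurements$tol <- 0
  if (any(measurements$tol < 0)) stop("measurement tolerance must be >= 0")
  for (k in seq_len(nrow(measurements))) {
    id <- measurements$id[k]
    if (!id %in% names(model$reactions)) stop("unknown reaction: ", id)
    model$reactions[[id]]$lb <- measurements$value[k] - measurements$tol[k]
    model$reactions[[id]]$ub <- measurements$value[k] + measurements$tol[k]
  }
  model
}

#' Find dead-end metabolites
#'
#' A dead end is a non-boundary metabolite that can only be produced or only
#' consumed, taking reaction reversibility into account (a reversible
#' reaction can play either role). Such metabolites indicate gaps in the
#' reconstruction.
#'
#' @param model a \code{metabolic_model}.
#' @return character vector of metabolite ids.
#' @export
find_dead_end_metabolites <- function(model) {
  met <- model$metabolites
  ids <- met$id[met$compartment != "boundary"]
  producible <- consumable <- structure(logical(length(ids)), names = ids)
  for (r in model$reactions) {
    fwd <- r$ub > 0; bwd <- r$lb < 0
    for (m in names(r$stoich)) {
      if (!m %in% ids) next
      s <- r$stoich[[m]]
      if ((s > 0 && fwd) || (s < 0 && bwd)) producible[m] <- TRUE
      if ((s < 0 && fwd) || (s > 0 && bwd)) consumable[m] <- TRUE
    }
  }
  ids[xor(producible, consumable) | (!producible & !consumable)]
}

#' Find blocked reactions
#'
#' A reaction is blocked when its FVA range is \{0\} with every exchange
#' fully opened, i.e. it can never carry flux under any medium.
#'
#' @param model a \code{metabolic_model}.
#' @param tol flux magnitude below which a range endpoint counts as zero.
#' @return character vector of reaction ids.
#' @export
find_blocked_reactions <- function(model, tol = 1e-6) {
  for (id in names(which(is_exchange(model)))) {
    model$reactions[[id]]$lb <- min(model$reactions[[id]]$lb, -1000)
    model$reactions[[id]]$ub <- max(model$reactions[[id]]$ub, 1000)
  }
  rng <- solve_fva(model, fraction = 0)
  rng$id[abs(rng$min) < tol & abs(rng$max) < tol]
}
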