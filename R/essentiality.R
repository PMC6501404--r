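#' Knockout growth for a single gene deletion
#'
#' Evaluates the GPR of every reaction under deletion of \code{gene}; each
#' reaction rendered non-functional is constrained to zero flux, FBA is
#' re-solved, and the knockout objective is returned. The input model is
#' untouched (constraints are restored by value semantics).
#'
#' @param model a validated \code{metabolic_model} with an objective.
#' @param gene a gene id present in the model.
#' @param tol solver tolerance.
#' @return the knockout objective Z (0 when the knockout model is
#'   infeasible); attribute \code{"disabled"} lists the zeroed reactions.
#' @export
single_gene_deletion <- function(model, gene, tol = 1e-9) {
  if (!gene %in% model$genes) stop("gene not in model: ", gene)
  off <- reactions_disabled_by(model, gene)
  for (id in off) {
    model$reactions[[id]]$lb <- 0
    model$reactions[[id]]$ub <- 0
  }
  sol <- solve_fba(model, minimize_total_flux = FALSE, tol = tol)
  z <- if (sol$status == "optimal") sol$objective else 0
  structure(z, disabled = off)
}

#' Single-gene-deletion essentiality scan
#'
#' Deletes each model gene in turn (deterministic sorted order), re-solves
#' FBA, and calls a gene essential when the knockout objective falls below
#' \code{zero_tol}. A gene that appears in no GPR cannot affect any reaction
#' and is reported as skipped (trivially non-essential). The wild-type model
#' must grow; otherwise the scan is meaningless and aborts with a
#' diagnostic.
#'
#' @param model a validated \code{metabolic_model} with an objective.
#' @param medium optional \code{\link{medium_spec}} applied before scanning
#'   and recorded in the report.
#' @param zero_tol absolute threshold below which a knockout objective
#'   counts as zero growth (default 1e-6; LP numerics make a literal zero
#'   test unreliable).
#' @param tol solver tolerance.
#' @return object of class \code{essentiality_report}: data.frame with
#'   columns \code{gene}, \code{z_wt}, \code{z_ko}, \code{ratio},
#'   \code{essential}, \code{skipped}; attributes \code{n_essential},
#'   \code{fraction_essential}, \code{medium}, \code{zero_tol}.
#' @export
essentiality_scan <- function(model, medium = NULL, zero_tol = 1e-6,
                              tol = 1e-9) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  wt <- solve_fba(model, minimize_total_flux = FALSE, tol = tol)
  if (wt$status != "optimal" || wt$objective <= zero_tol)
    stop("wild-type model does not grow (status ", wt$status,
         ", Z = ", if (wt$status == "optimal") wt$objective else NA,
         "); essentiality scan aborted")
  z_wt <- wt$objective
  used <- sort(unique(unlist(lapply(model$reactions, function(r)
    if (is.null(r$gpr)) character() else gpr_leaves(r$gpr)))))
  genes <- sort(model$genes)
  z_ko <- numeric(length(genes))
  skipped <- !(genes %in% used)
  for (k in seq_along(genes)) {
    z_ko[k] <- if (skipped[k]) z_wt
    else as.numeric(single_gene_deletion(model, genes[k], tol = tol))
  }
  essential <- z_ko < zero_tol
  rep <- data.frame(gene = genes, z_wt = z_wt, z_ko = z_ko,
                    ratio = z_ko / z_wt, essential = essential,
                    skipped = skipped, stringsAsFactors = FALSE)
  structure(rep,
            n_essential = sum(essential),
            fraction_essential = sum(essential) / length(genes),
            medium = if (!is.null(medium)) medium else attr(model, "medium"),
            zero_tol = zero_tol,
            class = c("essentiality_report", "data.frame"))
}

#' @export
print.essentiality_report <- function(x, ...) {
  cat("Essentiality scan:", nrow(x), "genes,",
      attr(x, "n_essential"), "essential (",
      sprintf("%.1f%%", 100 * attr(x, "fraction_essential")), ")\n")
  med <- attr(x, "medium")
  if (!is.null(med))
    cat("  medium carbon source:", med$carbon_source,
        "at uptake", med$components[[med$carbon_source]], "mmol/gDW/h\n")
  invisible(x)
}

#' @export
summary.essentiality_report <- function(object, ...) {
  list(n_genes = nrow(object),
       n_essential = attr(object, "n_essential"),
       fraction_essential = attr(object, "fraction_essential"),
       essential_genes = object$gene[object$essential])
}

#' Vulnerable-subsystem statistics
#'
#' Rolls essential-gene calls up to subsystems. An essential gene counts
#' toward every subsystem containing a reaction it disables, so subsystem
#' memberships can overlap; on models where each gene maps to a single
#' subsystem the gene-weighted mean percentage equals the global essential
#' fraction.
#'
#' @param report an \code{essentiality_report}.
#' @param model the scanned \code{metabolic_model}.
#' @return data.frame with columns \code{subsystem}, \code{n_reactions},
#'   \code{n_genes}, \code{n_essential}, \code{pct_essential}, sorted by
#'   descending percentage.
#' @export
subsystem_vulnerability <- function(report, model) {
  subsys <- vapply(model$reactions, `[[`, "", "subsystem")
  rxn_genes <- lapply(model$reactions, function(r)
    if (is.null(r$gpr)) character() else gpr_leaves(r$gpr))
  sub_levels <- sort(unique(subsys))
  ess <- report$gene[report$essential]
  # an essential gene is attributed to every subsystem holding a reaction it
  # actually disables (not merely one whose GPR mentions it)
  ess_subsys <- lapply(ess, function(g)
    unique(subsys[names(model$reactions) %in% reactions_disabled_by(model, g)]))
  names(ess_subsys) <- ess
  out <- do.call(rbind, lapply(sub_levels, function(s) {
    in_sub <- subsys == s
    genes <- unique(unlist(rxn_genes[in_sub]))
    data.frame(subsystem = s,
               n_reactions = sum(in_sub),
               n_genes = length(genes),
               n_essential = sum(vapply(ess_subsys, function(z) s %in% z,
                                        logical(1))),
               stringsAsFactors = FALSE)
  }))
  out$pct_essential <- ifelse(out$n_genes > 0,
                              100 * out$n_essential / out$n_genes, 0)
  out[order(-out$pct_essential, out$subsystem), , drop = FALSE]
}
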