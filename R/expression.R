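#' Expression table of RPKM values
#'
#' Genes in rows, growth conditions in columns, values are non-negative
#' RPKM (reads per kilobase of transcript per million mapped reads).
#'
#' @param values numeric matrix (genes x conditions) with dimnames, or a
#'   data.frame with a \code{gene} column followed by condition columns.
#' @return object of class \code{expression_table} (a numeric matrix).
#' @export
expression_table <- function(values) {
  if (is.data.frame(values)) {
    g <- values$gene
    m <- as.matrix(values[setdiff(names(values), "gene")])
    rownames(m) <- g
    values <- m
  }
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (ncol(values) < 1L) stop("conditions must be non-empty")
  if (any(values < 0)) stop("RPKM values must be >= 0")
  structure(values, class = c("expression_table", "matrix"))
}

#' Read an expression table from TSV (gene column + condition columns)
#' @param path file path.
#' @return an \code{expression_table}.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  names(df)[1] <- "gene"
  expression_table(df)
}

#' Geometric bin grid for expression cutoffs
#'
#' Cutoff k equals \code{base^k} for k = 0..n-1, giving a geometric ladder
#' of candidate thresholds spanning the heavy-tailed RPKM distribution. The
#' default grid of 58 cutoffs with base 1.2 reaches from 1 to about 32,000;
#' its 38th value (index 37) is 1.2^37 = 850.56 to two decimals.
#'
#' @param base ratio between consecutive cutoffs; must exceed 1.
#' @param n number of cutoffs; at least 2.
#' @return object of class \code{bin_grid}: list with \code{base} and the
#'   ascending \code{cutoffs} vector.
#' @export
build_bin_grid <- function(base = 1.2, n = 58) {
  if (!is.numeric(base) || base <= 1) stop("base must be > 1")
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  structure(list(base = base, cutoffs = base^(0:(n - 1))),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("Geometric bin grid: base", x$base, ",", length(x$cutoffs),
      "cutoffs in [", fmt_num(x$cutoffs[1]), ",",
      fmt_num(x$cutoffs[length(x$cutoffs)]), "]\n")
  invisible(x)
}

#' Select the lower expression cutoff from the grid
#'
#' Walks the grid upward and returns the smallest cutoff that excludes at
#' least \code{target_fraction} of all genes, where a gene is excluded when
#' its RPKM is below the cutoff in every given condition. With the default
#' 10\% target on a typical RNA-seq profile this lands near 3.00 RPKM.
#'
#' @param table an \code{expression_table}.
#' @param conditions condition names to require (default: all columns).
#' @param target_fraction fraction of genes to exclude (default 0.10).
#' @param grid a \code{\link{build_bin_grid}} result.
#' @return the selected cutoff (numeric), with attributes
#'   \code{achieved_fraction} and \code{index} (0-based grid index).
#' @export
select_lower_cutoff <- function(table, conditions = colnames(table),
                                target_fraction = 0.10,
                                grid = build_bin_grid()) {
  if (!nrow(table)) stop("empty expression table")
  sub <- table[, conditions, drop = FALSE]
  for (k in seq_along(grid$cutoffs)) {
    cut <- grid$cutoffs[k]
    frac <- mean(apply(sub < cut, 1, all))
    if (frac >= target_fraction)
      return(structure(cut, achieved_fraction = frac, index = k - 1L))
  }
  stop("no grid cutoff excludes the target fraction; extend the grid")
}

#' Discretization thresholds
#'
#' The lower threshold marks genes as low/absent, the upper as highly
#' expressed. Defaults: 3.00 RPKM (excluding roughly the bottom 10\% of
#' genes) and 850.56 RPKM (grid point 1.2^37).
#'
#' @param gamma_low,gamma_high thresholds, 0 < gamma_low < gamma_high.
#' @export
discretization_thresholds <- function(gamma_low = 3.00, gamma_high = 850.56) {
  if (!(gamma_low > 0 && gamma_low < gamma_high))
    stop("need 0 < gamma_low < gamma_high")
  structure(list(gamma_low = gamma_low, gamma_high = gamma_high),
            class = "discretization_thresholds")
}

#' Discretize RPKM values into expression states
#'
#' State -1 (low/absent): \code{g < gamma_low}, which always includes
#' \code{g = 0}. State 0 (moderate): \code{gamma_low <= g <= gamma_high} —
#' both boundaries inclusive to moderate. State 1 (high):
#' \code{g > gamma_high}.
#'
#' @param g non-negative RPKM value(s).
#' @param thresholds a \code{\link{discretization_thresholds}}.
#' @return integer vector of states in \{-1, 0, 1\}.
#' @export
discretize_gene <- function(g, thresholds = discretization_thresholds()) {
  if (any(g < 0)) stop("RPKM must be >= 0")
  ifelse(g < thresholds$gamma_low, -1L,
         ifelse(g > thresholds$gamma_high, 1L, 0L))
}

#' Gene states for one condition
#'
#' @param table an \code{expression_table}.
#' @param condition condition (column) name.
#' @param thresholds a \code{\link{discretization_thresholds}}.
#' @return named integer vector of states over the table's genes.
#' @export
gene_states <- function(table, condition,
                        thresholds = discretization_thresholds()) {
  if (!condition %in% colnames(table)) stop("unknown condition: ", condition)
  g <- table[, condition]
  structure(discretize_gene(as.numeric(g), thresholds), names = rownames(table))
}

# reaction states via GPR min/max logic; reactions without GPR are state 0
reaction_states <- function(model, states) {
  out <- vapply(model$reactions, function(r)
    if (is.null(r$gpr)) 0L else reaction_expression_state(r$gpr, states),
    integer(1))
  names(out) <- names(model$reactions)
  out
}

#' Integrate expression states into flux constraints
#'
#' Maps gene states onto reaction states through the GPR rules (AND = min,
#' OR = max), then either \emph{clamps} bounds — the literal reading of the
#' integration rule: a low (state -1) reaction is constrained to zero flux
#' and a high (state 1) reaction has its flux capacity extended to magnitude
#' 1000 — or builds an iMAT-style MILP in which binary indicators reward
#' high reactions carrying at least \code{epsilon} flux and low reactions
#' carrying at most \code{epsilon}, and the solver maximizes total
#' agreement.
#'
#' @param model a validated \code{metabolic_model}.
#' @param states named integer gene-state vector (see
#'   \code{\link{gene_states}}); genes absent from it count as state 0.
#' @param mode \code{"clamp"} (default) or \code{"imat"}.
#' @param epsilon iMAT flux-activity threshold (default 1.0 mmol/gDW/h).
#' @return clamp mode: the constrained model, with
#'   \code{attr(, "reaction_states")}. imat mode: an \code{imat_problem} to
#'   pass to \code{\link{solve_imat}}.
#' @export
apply_expression_constraints <- function(model, states,
                                         mode = c("clamp", "imat"),
                                         epsilon = 1.0) {
  mode <- match.arg(mode)
  rs <- reaction_states(model, states)
  if (!is.na(model$objective) && rs[[model$objective]] == -1L) {
    warning("biomass reaction has expression state -1; not clamped")
    rs[[model$objective]] <- 0L
  }
  if (mode == "clamp") {
    for (id in names(rs)) {
      if (rs[[id]] == -1L) {
        model$reactions[[id]]$lb <- 0
        model$reactions[[id]]$ub <- 0
      } else if (rs[[id]] == 1L) {
        r <- model$reactions[[id]]
        model$reactions[[id]]$ub <- 1000
        if (r$lb < 0) model$reactions[[id]]$lb <- -1000
      }
    }
    attr(model, "reaction_states") <- rs
    return(model)
  }
  structure(list(model = model, reaction_states = rs, epsilon = epsilon),
            class = "imat_problem")
}

#' Solve an iMAT-style agreement-maximization problem
#'
#' Exact branch-and-bound over per-reaction indicator choices. A high
#' (state 1) reaction is satisfied when it carries at least \code{epsilon}
#' flux in either direction; a low (state -1) reaction when its absolute
#' flux is at most \code{epsilon}. The search maximizes the number of
#' satisfied reactions subject to mass balance and bounds, pruning branches
#' whose LP relaxation of already-fixed choices is infeasible or whose
#' optimistic score cannot beat the incumbent. Reactions are processed in
#' fixed id order and choices in a fixed sequence, so the result is
#' deterministic.
#'
#' @param problem an \code{imat_problem} from
#'   \code{\link{apply_expression_constraints}}.
#' @param tol solver tolerance.
#' @return object of class \code{imat_result}: \code{score} (number of
#'   satisfied state-constrained reactions), \code{satisfied} (named
#'   logical), \code{fluxes} (a witness flux vector) and \code{n_constrained}.
#' @export
solve_imat <- function(problem, tol = 1e-9) {
  stopifnot(inherits(problem, "imat_problem"))
  model <- problem$model
  eps <- problem$epsilon
  rs <- problem$reaction_states
  S <- stoich_matrix(model)
  bd <- reaction_bounds(model)
  b0 <- rep(0, nrow(S))
  dec <- names(rs)[rs != 0L]
  dec <- dec[order(dec)]
  n_dec <- length(dec)

  # choice list per decision reaction: each choice is a bounds patch
  # (possibly empty = "miss") plus a satisfaction flag
  choices_for <- function(id) {
    i <- match(id, bd$id)
    st <- rs[[id]]
    ch <- list()
    if (st == 1L) {
      if (bd$ub[i] >= eps)
        ch <- c(ch, list(list(lb = max(bd$lb[i], eps), ub = bd$ub[i],
                              sat = TRUE)))
      if (bd$lb[i] <= -eps)
        ch <- c(ch, list(list(lb = bd$lb[i], ub = min(bd$ub[i], -eps),
                              sat = TRUE)))
    } else {
      ch <- c(ch, list(list(lb = max(bd$lb[i], -eps), ub = min(bd$ub[i], eps),
                            sat = TRUE)))
    }
    c(ch, list(list(lb = bd$lb[i], ub = bd$ub[i], sat = FALSE)))
  }
  all_choices <- lapply(dec, choices_for)

  best <- list(score = -1L, x = NULL, sat = logical(n_dec))
  sat_now <- logical(n_dec)
  lb <- bd$lb; ub <- bd$ub

  recurse <- function(k, n_sat, lb, ub) {
    if (n_sat + (n_dec - k + 1L) <= best$score) return()  # bound
    if (k > n_dec) {
      feas <- lp_feasible(S, b0, lb, ub, tol = tol)
      if (feas && n_sat > best$score) {
        best <<- list(score = n_sat, x = attr(feas, "x"),
                      sat = sat_now)
      }
      return()
    }
    i <- match(dec[k], bd$id)
    for (ch in all_choices[[k]]) {
      if (ch$lb > ch$ub) next
      lb2 <- lb; ub2 <- ub
      lb2[i] <- ch$lb; ub2[i] <- ch$ub
      if (ch$sat && !lp_feasible(S, b0, lb2, ub2, tol = tol)) next
      sat_now[k] <<- ch$sat
      recurse(k + 1L, n_sat + ch$sat, lb2, ub2)
    }
    sat_now[k] <<- FALSE
  }
  recurse(1L, 0L, lb, ub)

  if (best$score < 0L) {
    return(structure(list(score = NA_integer_, satisfied = NULL,
                          fluxes = NULL, n_constrained = n_dec,
                          status = "infeasible"),
                     class = "imat_result"))
  }
  fluxes <- best$x
  names(fluxes) <- bd$id
  structure(list(score = best$score,
                 satisfied = structure(best$sat, names = dec),
                 fluxes = fluxes, n_constrained = n_dec,
                 status = "optimal"),
            class = "imat_result")
}

#' @export
print.imat_result <- function(x, ...) {
  cat("iMAT agreement: ", x$score, " of ", x$n_constrained,
      " state-constrained reactions satisfied (", x$status, ")\n", sep = "")
  invisible(x)
}

#' Active-reaction report
#'
#' Counts the reactions carrying flux (\code{|v| > tol}) in a solution,
#' grouped by subsystem (transport reactions form their own
#' "Transportation" group in the subsystem labels). Uses the
#' flux-sum-minimized optimum to suppress spurious activity from degenerate
#' cycles; the per-subsystem counts always sum to the total.
#'
#' @param model the \code{metabolic_model} that produced the solution.
#' @param solution an \code{fba_solution} (or any object with
#'   \code{$fluxes}).
#' @param tol activity threshold on absolute flux (default 1e-6).
#' @param include_exchanges count exchange pseudo-reactions too (default
#'   \code{FALSE}: only metabolic and transport reactions, as in pathway
#'   accounting).
#' @return object of class \code{active_reaction_report}: data.frame
#'   (\code{subsystem}, \code{count}); attributes \code{total} and
#'   \code{active} (the reaction ids).
#' @export
active_reaction_report <- function(model, solution, tol = 1e-6,
                                   include_exchanges = FALSE) {
  v <- solution$fluxes
  if (is.null(v)) stop("solution carries no flux vector")
  act <- names(v)[abs(v) > tol]
  if (!include_exchanges) {
    exch <- is_exchange(model)
    act <- act[!exch[act]]
  }
  subsys <- vapply(model$reactions[act], `[[`, "", "subsystem")
  tab <- table(subsys)
  df <- data.frame(subsystem = as.character(names(tab)),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  df <- df[order(df$subsystem), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, total = length(act), active = act,
            class = c("active_reaction_report", "data.frame"))
}

#' @export
print.active_reaction_report <- function(x, ...) {
  cat("Active reactions:", attr(x, "total"), "\n")
  NextMethod()
}

#' Expression fold change between two conditions
#'
#' Ratio of a gene's RPKM in the numerator condition over the denominator
#' condition. A zero denominator is reported as \code{Inf} with a warning
#' flag rather than an error.
#'
#' @param table an \code{expression_table}.
#' @param gene gene id.
#' @param cond_num,cond_den condition names for numerator and denominator.
#' @param digits optional rounding of the reported ratio (e.g. 1 or 2);
#'   default \code{NULL} reports the exact ratio.
#' @return the fold change (numeric scalar).
#' @export
fold_change <- function(table, gene, cond_num, cond_den, digits = NULL) {
  if (!gene %in% rownames(table)) stop("unknown gene: ", gene)
  num <- table[gene, cond_num]
  den <- table[gene, cond_den]
  if (den == 0) {
    warning("denominator RPKM is zero for ", gene, "; fold change infinite")
    return(Inf)
  }
  fc <- as.numeric(num / den)
  if (!is.null(digits)) round(fc, digits) else fc
}
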