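# run expr under a fixed Mersenne-Twister seed without disturbing the
# caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Specification for synthetic data generation
#'
#' @param seed integer seed; generation is fully deterministic given it
#'   (Mersenne-Twister, recorded here).
#' @param topology one of \code{"random"}, \code{"chain"}, \code{"diamond"},
#'   \code{"core"}.
#' @param n_segments backbone length of random models (chain: its length).
#' @param uptake substrate uptake bound, mmol/gDW/h.
#' @param conditions condition labels for expression tables.
#' @param sigma log-sd of the gene-level log-normal RPKM baseline (heavy
#'   tail spanning 0 to beyond 10^3).
#' @param sigma_cond log-sd of the condition-specific noise around each
#'   gene's baseline; expression is strongly correlated across conditions,
#'   as in real transcriptomes.
#' @param fraction_zero fraction of genes planted as exact zero (unexpressed
#'   in every condition), in [0, 1).
#' @param target_low_fraction total fraction of genes planted below ~3 RPKM
#'   (zeros included) in every condition.
#' @export
synthetic_spec <- function(seed = 1L, topology = c("random", "chain",
                                                   "diamond", "core"),
                           n_segments = 8L, uptake = 10,
                           conditions = c("glucose", "GlcNAc", "glycerol"),
                           sigma = 2, sigma_cond = 0.15,
                           fraction_zero = 0.02,
                           target_low_fraction = 0.10) {
  topology <- match.arg(topology)
  stopifnot(fraction_zero >= 0, fraction_zero < 1,
            target_low_fraction > fraction_zero)
  structure(list(seed = as.integer(seed), topology = topology,
                 n_segments = as.integer(n_segments), uptake = uptake,
                 conditions = conditions, sigma = sigma,
                 sigma_cond = sigma_cond,
                 fraction_zero = fraction_zero,
                 target_low_fraction = target_low_fraction,
                 rng = "Mersenne-Twister"),
            class = "synthetic_spec")
}

#' Toy central-metabolism model with known ground truth
#'
#' A ~30-reaction network shaped like bacterial central carbon metabolism:
#' glucose transport, glycolysis, a pentose phosphate branch feeding the
#' R5P biomass precursor, pyruvate dehydrogenase, a lumped TCA cycle
#' (citrate synthase \code{CS} under gene \code{gCS} plus the lumped
#' oxidation \code{TCA1}), fermentation outlets (ethanol, acetate,
#' 2,3-butanediol), oxidative phosphorylation and free cofactor
#' dissipation. Biomass consumes one R5P and 27 ATP. GPRs mix single genes,
#' isozyme ORs (glucose transport, butanediol dehydrogenase) and complex
#' ANDs (PFK/aldolase, ATP synthase).
#'
#' With glucose uptake U the analytic optimum is Z = U/2 (default U = 10,
#' Z = 5): a fully respired glucose yields 24 ATP, a pentose-branch glucose
#' yields one R5P plus 3 ATP, and the 27-ATP biomass cost balances the two
#' routes one-to-one. Knockout arithmetic gives the exact essential set
#' {gALD, gGAPD, gHEX, gPFK, gPGI, gRPI, gZWF}; silencing \code{gCS} zeroes
#' the TCA branch while growth persists at Z = U/3 on glycolytic and
#' fermentative ATP.
#'
#' @param seed recorded in the model attributes; the construction itself is
#'   deterministic.
#' @param uptake glucose uptake bound (default 10 mmol/gDW/h).
#' @return a validated \code{metabolic_model} with attributes
#'   \code{optimal_growth}, \code{essential_genes}, \code{tca_reactions},
#'   \code{ppp_reactions}, \code{citrate_synthase_gene}, \code{seed}.
#' @export
make_toy_core_model <- function(seed = 1L, uptake = 10) {
  g <- parse_gpr_expression
  rx <- list(
    reaction("EX_glc", c(glc_e = -1, glc_b = 1), lb = -uptake, ub = 1000,
             subsystem = "Exchange"),
    reaction("EX_co2", c(co2_e = -1, co2_b = 1), lb = 0, ub = 1000,
             subsystem = "Exchange"),
    reaction("EX_etoh", c(etoh_e = -1, etoh_b = 1), lb = 0, ub = 1000,
             subsystem = "Exchange"),
    reaction("EX_ac", c(ac_e = -1, ac_b = 1), lb = 0, ub = 1000,
             subsystem = "Exchange"),
    reaction("EX_btd", c(btd_e = -1, btd_b = 1), lb = 0, ub = 1000,
             subsystem = "Exchange"),
    reaction("EX_biomass", c(biomass_e = -1, biomass_b = 1), lb = 0,
             ub = 1000, subsystem = "Exchange"),
    reaction("T_glc", c(glc_e = -1, glc_c = 1), subsystem = "Transportation",
             gpr = g("gPTS1 or gPTS2")),
    reaction("T_co2", c(co2_c = -1, co2_e = 1),
             subsystem = "Transportation"),
    reaction("T_etoh", c(etoh_c = -1, etoh_e = 1),
             subsystem = "Transportation", gpr = g("gTe")),
    reaction("T_ac", c(ac_c = -1, ac_e = 1), subsystem = "Transportation",
             gpr = g("gTa")),
    reaction("T_btd", c(btd_c = -1, btd_e = 1),
             subsystem = "Transportation", gpr = g("gTb")),
    reaction("HEX", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
             subsystem = "Glycolysis / Gluconeogenesis", gpr = g("gHEX")),
    reaction("PGI", c(g6p_c = -1, f6p_c = 1), reversible = TRUE,
             subsystem = "Glycolysis / Gluconeogenesis", gpr = g("gPGI")),
    reaction("PFKALD", c(f6p_c = -1, atp_c = -1, t3p_c = 2, adp_c = 1),
             subsystem = "Glycolysis / Gluconeogenesis",
             gpr = g("gPFK and gALD")),
    reaction("GLY3", c(t3p_c = -1, adp_c = -2, nad_c = -1, pyr_c = 1,
                       atp_c = 2, nadh_c = 1),
             subsystem = "Glycolysis / Gluconeogenesis", gpr = g("gGAPD")),
    reaction("G6PDH", c(g6p_c = -1, nad_c = -2, ru5p_c = 1, co2_c = 1,
                        nadh_c = 2),
             subsystem = "Pentose phosphate pathway", gpr = g("gZWF")),
    reaction("RPI", c(ru5p_c = -1, r5p_c = 1), reversible = TRUE,
             subsystem = "Pentose phosphate pathway", gpr = g("gRPI")),
    reaction("PDH", c(pyr_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1,
                      nadh_c = 1),
             subsystem = "Pyruvate metabolism", gpr = g("gPDH")),
    reaction("CS", c(accoa_c = -1, oaa_c = -1, cit_c = 1),
             subsystem = "Citrate cycle (TCA cycle)", gpr = g("gCS")),
    reaction("TCA1", c(cit_c = -1, nad_c = -3, adp_c = -1, oaa_c = 1,
                       co2_c = 2, nadh_c = 3, atp_c = 1),
             subsystem = "Citrate cycle (TCA cycle)", gpr = g("gTCA")),
    reaction("ADH", c(accoa_c = -1, nadh_c = -2, etoh_c = 1, nad_c = 2),
             subsystem = "Pyruvate metabolism", gpr = g("gADH")),
    reaction("ACK", c(accoa_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
             subsystem = "Pyruvate metabolism", gpr = g("gACK")),
    reaction("BTD", c(pyr_c = -2, nadh_c = -1, btd_c = 1, co2_c = 2,
                      nad_c = 1),
             subsystem = "Butanoate metabolism",
             gpr = g("gBDH1 or gBDH2")),
    reaction("ATPS", c(nadh_c = -1, adp_c = -2, nad_c = 1, atp_c = 2),
             subsystem = "Oxidative phosphorylation",
             gpr = g("gATPA and gATPB")),
    reaction("NADHOX", c(nadh_c = -1, nad_c = 1),
             subsystem = "Oxidative phosphorylation"),
    reaction("ATPM", c(atp_c = -1, adp_c = 1),
             subsystem = "Oxidative phosphorylation"),
    reaction("BIOMASS", c(r5p_c = -1, atp_c = -27, adp_c = 27,
                          biomass_e = 1),
             subsystem = "Biomass")
  )
  model <- metabolic_model(build_metabolite_table(rx), rx,
                           objective = "BIOMASS")
  validate_model(model)
  structure(model,
            optimal_growth = uptake / 2,
            essential_genes = c("gALD", "gGAPD", "gHEX", "gPFK", "gPGI",
                                "gRPI", "gZWF"),
            tca_reactions = c("CS", "TCA1"),
            ppp_reactions = c("G6PDH", "RPI"),
            citrate_synthase_gene = "gCS",
            seed = as.integer(seed))
}

#' Expression profiles for the toy core model
#'
#' Three-condition RPKM table over the toy model's genes. Every gene sits
#' in the moderate band (50 RPKM) except the citrate-synthase gene
#' \code{gCS}: highly expressed under glucose and glycerol (above the upper
#' threshold) and silenced (below 3 RPKM) under GlcNAc, mirroring the
#' condition-dependent TCA shutdown the integration pipeline is meant to
#' expose.
#'
#' @param model the toy core model.
#' @return an \code{expression_table} with conditions glucose, GlcNAc,
#'   glycerol.
#' @export
make_toy_expression_profiles <- function(model) {
  genes <- model$genes
  m <- matrix(50, nrow = length(genes), ncol = 3,
              dimnames = list(genes, c("glucose", "GlcNAc", "glycerol")))
  cs <- attr(model, "citrate_synthase_gene")
  m[cs, ] <- c(1200, 1.5, 1000)
  expression_table(m)
}

#' Random metabolic model with planted essential genes
#'
#' Builds a feasible linear backbone from substrate to biomass out of
#' segments whose gene-essentiality status is known by construction:
#' a \emph{single} segment (one reaction, one gene — essential, a cut
#' vertex), an \emph{isozyme} segment (two parallel reactions with distinct
#' genes — neither essential) or a \emph{complex} segment (one reaction
#' gated by an AND of two genes — both essential). Random secreted
#' side-branches with their own genes are added off backbone nodes; they
#' can always carry zero flux, so their genes are never essential. The
#' wild-type optimum is exactly the substrate uptake (all yields are 1).
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a validated \code{metabolic_model}; attributes
#'   \code{ground_truth_essentials}, \code{optimal_growth}, \code{seed}.
#' @export
make_random_model <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    k <- max(2L, spec$n_segments)
    rx <- list(
      reaction("EX_sub", c(sub_e = -1, sub_b = 1), lb = -spec$uptake,
               ub = 1000, subsystem = "Exchange"),
      reaction("EX_biomass", c(biomass_e = -1, biomass_b = 1), lb = 0,
               ub = 1000, subsystem = "Exchange")
    )
    essentials <- character()
    gene_i <- 0L
    new_gene <- function() {
      gene_i <<- gene_i + 1L
      sprintf("g%03d", gene_i)
    }
    node <- function(i) if (i == 0L) "sub_e" else sprintf("M%02d_c", i)
    seg_types <- switch(spec$topology,
      chain = rep("single", k),
      diamond = c("single", "iso", "single"),
      random = sample(c("single", "iso", "complex"), k, replace = TRUE,
                      prob = c(0.5, 0.25, 0.25)),
      core = stop("use make_toy_core_model() for the core topology"))
    k <- length(seg_types)
    for (i in seq_len(k)) {
      from <- node(i - 1L); to <- node(i)
      st <- structure(c(-1, 1), names = c(from, to))
      if (seg_types[i] == "single") {
        gg <- new_gene()
        essentials <- c(essentials, gg)
        rx <- c(rx, list(reaction(sprintf("R%02d", i), st,
                                  subsystem = "Backbone",
                                  gpr = gpr_gene(gg))))
      } else if (seg_types[i] == "iso") {
        ga <- new_gene(); gb <- new_gene()
        rx <- c(rx, list(
          reaction(sprintf("R%02da", i), st, subsystem = "Backbone",
                   gpr = gpr_gene(ga)),
          reaction(sprintf("R%02db", i), st, subsystem = "Backbone",
                   gpr = gpr_gene(gb))))
      } else {
        ga <- new_gene(); gb <- new_gene()
        essentials <- c(essentials, ga, gb)
        rx <- c(rx, list(reaction(sprintf("R%02d", i), st,
                                  subsystem = "Backbone",
                                  gpr = gpr_and(gpr_gene(ga),
                                                gpr_gene(gb)))))
      }
      # optional secreted side product off this node (never essential)
      if (i < k && spec$topology == "random" && runif(1) < 0.4) {
        gg <- new_gene()
        w_e <- sprintf("W%02d_e", i); w_b <- sprintf("W%02d_b", i)
        rx <- c(rx, list(
          reaction(sprintf("S%02d", i),
                   structure(c(-1, 1), names = c(to, w_e)),
                   subsystem = "Side branch", gpr = gpr_gene(gg)),
          reaction(sprintf("EX_W%02d", i),
                   structure(c(-1, 1), names = c(w_e, w_b)),
                   lb = 0, ub = 1000, subsystem = "Exchange")))
      }
    }
    rx <- c(rx, list(reaction("BIOMASS",
                              structure(c(-1, 1),
                                        names = c(node(k), "biomass_e")),
                              subsystem = "Biomass")))
    model <- metabolic_model(build_metabolite_table(rx), rx,
                             objective = "BIOMASS")
    validate_model(model)
    structure(model,
              ground_truth_essentials = sort(essentials),
              optimal_growth = spec$uptake,
              seed = spec$seed)
  })
}

#' Synthetic RPKM expression table
#'
#' Each gene gets a log-normal baseline expression level (heavy tail
#' spanning 0 to beyond 10^3) shared across conditions, multiplied by
#' small condition-specific log-normal noise — mirroring the strong
#' cross-condition correlation of real transcriptomes. A planted fraction
#' of genes is exactly zero in every condition, and the baseline log-mean
#' is calibrated (by numerical integration over the noise) so that the
#' fraction of genes falling below the pivot in \emph{all} conditions
#' matches \code{target_low_fraction}. The pivot sits at 1.2^5.5, between
#' geometric-grid points 5 and 6, so cutoff selection at the default 10\%
#' target lands on grid value 1.2^6 = 2.99. Designated genes can be
#' planted as condition-specific highs (drawn above the upper threshold).
#'
#' @param model a \code{metabolic_model} (its genes form the rows) or a
#'   character vector of gene ids.
#' @param spec a \code{\link{synthetic_spec}} (seed, conditions, sigma,
#'   zero fraction, low-tail target).
#' @param n_extra_genes additional non-model "genomic background" genes to
#'   include (cutoff selection in the field operates on all genomic genes,
#'   not only the modeled ones).
#' @param high_genes named list: condition -> gene ids forced above the
#'   upper threshold in that condition.
#' @return an \code{expression_table}; attribute \code{planted} records the
#'   analytic low-tail and high-tail masses.
#' @export
make_expression_table <- function(model, spec = synthetic_spec(),
                                  n_extra_genes = 0L,
                                  high_genes = list()) {
  genes <- if (is.character(model)) model else model$genes
  if (n_extra_genes > 0L)
    genes <- c(genes, sprintf("bg%04d", seq_len(n_extra_genes)))
  n <- length(genes)
  pivot <- 1.2^5.5
  K <- length(spec$conditions)
  p_nz <- (spec$target_low_fraction - spec$fraction_zero) /
    (1 - spec$fraction_zero)
  sg <- spec$sigma; sc <- spec$sigma_cond
  # P(baseline * noise_j < pivot for all K conditions) as a function of the
  # baseline log-mean; solve for the mean that plants the target mass
  p_excl <- function(mu) {
    stats::integrate(function(x)
      stats::dnorm(x, mu, sg) *
        stats::pnorm((log(pivot) - x) / sc)^K,
      lower = mu - 8 * sg, upper = mu + 8 * sg)$value
  }
  meanlog <- stats::uniroot(function(mu) p_excl(mu) - p_nz,
                            lower = log(pivot) - 8 * sg,
                            upper = log(pivot) + 8 * sg,
                            tol = 1e-10)$root
  p_high <- (1 - spec$fraction_zero) *
    stats::pnorm((log(850.56) - meanlog) / sqrt(sg^2 + sc^2),
                 lower.tail = FALSE)
  with_local_seed(spec$seed, {
    base <- stats::rnorm(n, meanlog, sg)
    zeros <- sample.int(n, size = round(spec$fraction_zero * n))
    m <- matrix(0, nrow = n, ncol = K,
                dimnames = list(genes, spec$conditions))
    for (j in seq_len(K)) {
      vals <- exp(base + stats::rnorm(n, 0, sc))
      vals[zeros] <- 0
      m[, j] <- vals
      hg <- intersect(high_genes[[spec$conditions[j]]], genes)
      if (length(hg))
        m[hg, j] <- 850.56 * stats::runif(length(hg), 1.5, 6)
    }
    structure(expression_table(m),
              planted = list(low_fraction = spec$target_low_fraction,
                             high_fraction = p_high,
                             meanlog = meanlog, sigma = sg,
                             sigma_cond = sc))
  })
}
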