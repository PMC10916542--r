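# Bundled toy models with closed-form optima. They stand in for published
# genome-scale reconstructions in every desk-scale test: round-number
# kcat/mw values keep the expected optima exact rationals, and BiGG-like
# id conventions (compartment suffixes, EX_/LNK_ prefixes) exercise the
# same id-handling code paths as real models.

toy_pool <- function(size) pool_budget(ptot = size, f = 1, sigma = 1)

# enzyme with mw/kcat == cost, using round numbers (mw = 1, kcat = 1/cost)
cost_enzyme <- function(cost) {
  if (cost <= 0) return(NULL)
  list(kcat = 1 / cost, mw = 1)
}

toy_converter_strain <- function(id, inputs, outputs, rxn_id, cost, pool) {
  st <- c(stats::setNames(rep(-1, length(inputs)), inputs),
          stats::setNames(rep(+1, length(outputs)), outputs))
  strain_model(
    id = id,
    mets = metabolites(unique(c(inputs, outputs)), compartment = "e"),
    reactions = list(reaction(rxn_id, st, ub = 1000,
                              enzyme = cost_enzyme(cost))),
    pool = toy_pool(pool)
  )
}

#' Two-strain linear-pathway toy community (TOY2)
#'
#' Strain A converts glucose to itaconate at enzyme cost `cost_up`
#' (g enzyme per unit flux) against pool `pool_up`; strain B converts
#' itaconate to product at `cost_down` against `pool_down`. Glucose,
#' itaconate, and product are shared; glucose uptake is capped. With
#' normalized ratio fractions (m, n) the optimal shared product flux has
#' the closed form `min(pool_up/cost_up/m, pool_down/cost_down/n,
#' glc_cap)` (see [toy2_expected()]): with the defaults it is maximized at
#' ratio 2:1, where it equals 3.
#'
#' @param cost_up,cost_down Enzyme cost per unit flux of the upstream /
#'   downstream conversion (0 = unconstrained, no annotation).
#' @param pool_up,pool_down Strain enzyme pools (g gDW^-1).
#' @param glc_cap Shared glucose uptake bound (mmol gDW^-1 h^-1).
#' @param ratio Inoculation ratio `c(A = , B = )`.
#' @return A `community_model` with objective reaction
#'   `"EX_prod_e_shared"`.
#' @export
make_toy2 <- function(cost_up = 0.5, cost_down = 1.0,
                      pool_up = 1, pool_down = 1,
                      glc_cap = 10, ratio = c(A = 2, B = 1)) {
  A <- toy_converter_strain("toyA", "glc_e", "ita_e", "CONVup", cost_up, pool_up)
  B <- toy_converter_strain("toyB", "ita_e", "prod_e", "CONVdn", cost_down, pool_down)
  cm <- assemble_community(
    list(namespace_model(A, "A"), namespace_model(B, "B")),
    shared_ids = c("glc_e", "ita_e", "prod_e"),
    ratio = normalize_ratio(ratio),
    directions = c(glc_e = "import", "ita_e@A" = "export",
                   "ita_e@B" = "import", prod_e = "export"))
  cm <- add_shared_exchange(cm, "glc_e", uptake_ub = glc_cap, secretion_ub = 0)
  cm <- add_shared_exchange(cm, "prod_e", uptake_ub = 0, secretion_ub = 1000)
  attr(cm, "objective") <- "EX_prod_e_shared"
  cm
}

#' Closed-form optimum of TOY2
#'
#' @inheritParams make_toy2
#' @return The optimal shared product flux at the given ratio.
#' @export
toy2_expected <- function(ratio = c(A = 2, B = 1), cost_up = 0.5,
                          cost_down = 1.0, pool_up = 1, pool_down = 1,
                          glc_cap = 10) {
  f <- normalize_ratio(ratio)
  cap_up <- if (cost_up > 0) (pool_up / cost_up) / f[["A"]] else Inf
  cap_down <- if (cost_down > 0) (pool_down / cost_down) / f[["B"]] else Inf
  min(cap_up, cap_down, glc_cap)
}

#' Single-strain overflow-metabolism toy
#'
#' One strain with two catabolic routes: respiration (high ATP yield,
#' expensive enzyme) and fermentation (low yield, cheap enzyme, secretes
#' acetate). Maximizing ATP turnover under the enzyme pool reproduces
#' overflow metabolism: below the uptake threshold `pool/resp_cost` all
#' flux is respiratory and no acetate appears; above it the pool forces a
#' respiration/fermentation mix and acetate is secreted.
#'
#' @param resp_yield,ferm_yield ATP per glucose of each route.
#' @param resp_cost,ferm_cost Enzyme cost per unit flux.
#' @param ferm_acetate Acetate secreted per fermentation flux.
#' @param pool Enzyme pool (g gDW^-1).
#' @param uptake Glucose uptake bound.
#' @return A `strain_model` with objective reaction `"ATPM"`.
#' @export
make_overflow_toy <- function(resp_yield = 26, ferm_yield = 12,
                              resp_cost = 0.1, ferm_cost = 0.02,
                              ferm_acetate = 2, pool = 1, uptake = 10) {
  m <- strain_model(
    id = "toy_overflow",
    mets = metabolites(c("glc_e", "atp_c", "ac_e")),
    reactions = list(
      reaction("EX_glc_e_reverse", c(glc_e = 1), ub = uptake, kind = "exchange"),
      reaction("RESP", c(glc_e = -1, atp_c = resp_yield),
               enzyme = cost_enzyme(resp_cost)),
      reaction("FERM", c(glc_e = -1, atp_c = ferm_yield, ac_e = ferm_acetate),
               enzyme = cost_enzyme(ferm_cost)),
      reaction("ATPM", c(atp_c = -1)),
      reaction("EX_ac_e", c(ac_e = -1), kind = "exchange")
    ),
    pool = toy_pool(pool)
  )
  attr(m, "objective") <- "ATPM"
  m
}

#' Closed-form optimum of the overflow toy
#'
#' @inheritParams make_overflow_toy
#' @return `list(atp, acetate, resp, ferm)` at the given uptake bound.
#' @export
overflow_expected <- function(uptake, resp_yield = 26, ferm_yield = 12,
                              resp_cost = 0.1, ferm_cost = 0.02,
                              ferm_acetate = 2, pool = 1) {
  if (uptake * resp_cost <= pool) {
    resp <- uptake; ferm <- 0
  } else {
    # vertex where both uptake and pool bind
    ferm <- (uptake * resp_cost - pool) / (resp_cost - ferm_cost)
    resp <- uptake - ferm
  }
  list(atp = resp_yield * resp + ferm_yield * ferm,
       acetate = ferm_acetate * ferm, resp = resp, ferm = ferm)
}

#' Three-strain nonlinear-pathway toy community (TOY3)
#'
#' Modules CA and SAA each convert glucose to an intermediate; module RA
#' condenses both intermediates 1:1 into the product. With default costs
#' (1/2, 1/3, 1) and unit pools, the optimal inoculation ratio on the
#' 13-point grid is CA:SAA:RA = 2:3:1 with shared product flux 6. The
#' `merge` argument produces the two-strain variants in which two modules
#' are carried by one strain (sharing one pool), for allocation-strategy
#' comparisons.
#'
#' @param cost_ca,cost_saa,cost_ra Enzyme costs per unit flux.
#' @param pools Per-strain pools (recycled as needed).
#' @param glc_cap Shared glucose uptake bound. Both branch modules draw on
#'   it, so the default (20) is set high enough that the enzyme pools, not
#'   the substrate, bind at the community optimum.
#' @param ratio Inoculation ratio over the strains of the chosen variant.
#' @param merge `NULL` (three strains) or one of `"CA+SAA"`, `"SAA+RA"`,
#'   `"CA+RA"`.
#' @return A `community_model` with objective `"EX_prod_e_shared"`.
#' @export
make_toy3 <- function(cost_ca = 0.5, cost_saa = 1 / 3, cost_ra = 1.0,
                      pools = c(1, 1, 1), glc_cap = 20,
                      ratio = NULL, merge = NULL) {
  ra_strain <- function(id, extra_rxn = NULL, extra_cost = NULL, pool) {
    mets <- c("ca_e", "saa_e", "prod_e")
    if (!is.null(extra_rxn)) mets <- c(mets, "glc_e")
    rxns <- list(reaction("CONVra", c(ca_e = -1, saa_e = -1, prod_e = 1),
                          enzyme = cost_enzyme(cost_ra)))
    if (!is.null(extra_rxn)) {
      out <- if (extra_rxn == "CONVca") "ca_e" else "saa_e"
      rxns[[extra_rxn]] <- reaction(extra_rxn,
                                    stats::setNames(c(-1, 1), c("glc_e", out)),
                                    enzyme = cost_enzyme(extra_cost))
    }
    strain_model(id, metabolites(mets, compartment = "e"), rxns,
                 pool = toy_pool(pool))
  }
  if (is.null(merge)) {
    subs <- list(
      namespace_model(toy_converter_strain("toyCA", "glc_e", "ca_e",
                                           "CONVca", cost_ca, pools[1]), "CA"),
      namespace_model(toy_converter_strain("toySAA", "glc_e", "saa_e",
                                           "CONVsaa", cost_saa, pools[2]), "SAA"),
      namespace_model(ra_strain("toyRA", pool = pools[3]), "RA"))
    if (is.null(ratio)) ratio <- c(CA = 2, SAA = 3, RA = 1)
    dirs <- c(glc_e = "import", "ca_e@CA" = "export", "ca_e@RA" = "import",
              "saa_e@SAA" = "export", "saa_e@RA" = "import", prod_e = "export")
  } else if (merge == "CA+SAA") {
    up <- strain_model("toyUP", metabolites(c("glc_e", "ca_e", "saa_e"),
                                            compartment = "e"),
                       list(reaction("CONVca", c(glc_e = -1, ca_e = 1),
                                     enzyme = cost_enzyme(cost_ca)),
                            reaction("CONVsaa", c(glc_e = -1, saa_e = 1),
                                     enzyme = cost_enzyme(cost_saa))),
                       pool = toy_pool(pools[1]))
    subs <- list(namespace_model(up, "UP"),
                 namespace_model(ra_strain("toyRA", pool = pools[2]), "RA"))
    if (is.null(ratio)) ratio <- c(UP = 1, RA = 1)
    dirs <- c(glc_e = "import", "ca_e@UP" = "export", "ca_e@RA" = "import",
              "saa_e@UP" = "export", "saa_e@RA" = "import", prod_e = "export")
  } else if (merge == "SAA+RA") {
    dn <- ra_strain("toyDN", extra_rxn = "CONVsaa", extra_cost = cost_saa,
                    pool = pools[2])
    subs <- list(
      namespace_model(toy_converter_strain("toyCA", "glc_e", "ca_e",
                                           "CONVca", cost_ca, pools[1]), "CA"),
      namespace_model(dn, "DN"))
    if (is.null(ratio)) ratio <- c(CA = 1, DN = 1)
    dirs <- c(glc_e = "import", "ca_e@CA" = "export", "ca_e@DN" = "import",
              prod_e = "export")
  } else if (merge == "CA+RA") {
    dn <- ra_strain("toyDN", extra_rxn = "CONVca", extra_cost = cost_ca,
                    pool = pools[2])
    subs <- list(
      namespace_model(toy_converter_strain("toySAA", "glc_e", "saa_e",
                                           "CONVsaa", cost_saa, pools[1]), "SAA"),
      namespace_model(dn, "DN"))
    if (is.null(ratio)) ratio <- c(SAA = 1, DN = 1)
    dirs <- c(glc_e = "import", "saa_e@SAA" = "export", "saa_e@DN" = "import",
              prod_e = "export")
  } else stop("unknown merge variant '", merge, "'")
  shared <- switch(merge %||% "none",
                   none = c("glc_e", "ca_e", "saa_e", "prod_e"),
                   "CA+SAA" = c("glc_e", "ca_e", "saa_e", "prod_e"),
                   "SAA+RA" = c("glc_e", "ca_e", "prod_e"),
                   "CA+RA" = c("glc_e", "saa_e", "prod_e"))
  cm <- assemble_community(subs, shared_ids = shared,
                           ratio = normalize_ratio(ratio), directions = dirs)
  cm <- add_shared_exchange(cm, "glc_e", uptake_ub = glc_cap, secretion_ub = 0)
  cm <- add_shared_exchange(cm, "prod_e", uptake_ub = 0, secretion_ub = 1000)
  attr(cm, "objective") <- "EX_prod_e_shared"
  cm
}

#' Closed-form optimum of the three-strain TOY3 community
#'
#' The product flux is capped by each module's amplified enzyme capacity
#' `(pool/cost)/m_x` and by the shared glucose bound, which both branch
#' modules draw on (total uptake is twice the product flux).
#'
#' @inheritParams make_toy3
#' @param ratio Named ratio `c(CA = , SAA = , RA = )`.
#' @return Optimal shared product flux.
#' @export
toy3_expected <- function(ratio, cost_ca = 0.5, cost_saa = 1 / 3,
                          cost_ra = 1.0, pools = c(1, 1, 1), glc_cap = 20) {
  f <- normalize_ratio(ratio)
  min((pools[1] / cost_ca) / f[[1]],
      (pools[2] / cost_saa) / f[[2]],
      (pools[3] / cost_ra) / f[[3]],
      glc_cap / 2)
}

#' Default inoculation-ratio grids
#'
#' Two-strain sweeps use the 8-point grid 9:1, 4:1, 3:1, 2:1, 1:1, 1:2,
#' 1:4, 1:9; three-strain sweeps use a 13-point grid of small integer
#' ratios (including 2:3:1).
#'
#' @param tags Strain tags (length 2 or 3).
#' @return A list of named ratio vectors.
#' @export
default_ratio_grid <- function(tags) {
  k <- length(tags)
  raw <- if (k == 2) {
    list(c(9, 1), c(4, 1), c(3, 1), c(2, 1), c(1, 1),
         c(1, 2), c(1, 4), c(1, 9))
  } else if (k == 3) {
    list(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1), c(1, 1, 2),
         c(2, 2, 1), c(2, 1, 2), c(1, 2, 2),
         c(3, 1, 1), c(1, 3, 1), c(1, 1, 3),
         c(2, 3, 1), c(3, 2, 1), c(1, 2, 3))
  } else stop("default grids exist for 2 or 3 strains only")
  lapply(raw, function(r) stats::setNames(r, tags))
}

#' Degenerate parallel-pathway toy for pFBA tests
#'
#' Two stoichiometrically identical, cost-free routes carry the optimum,
#' so the flux split is non-unique but the parsimonious total flux is.
#'
#' @param cap Source bound.
#' @return A `strain_model` with objective `"EX_p"`.
#' @export
make_parallel_toy <- function(cap = 4) {
  m <- strain_model(
    id = "toy_parallel",
    mets = metabolites(c("m_c", "p_c")),
    reactions = list(
      reaction("SRC", c(m_c = 1), ub = cap, kind = "exchange"),
      reaction("P1", c(m_c = -1, p_c = 1)),
      reaction("P2", c(m_c = -1, p_c = 1)),
      reaction("EX_p", c(p_c = -1), kind = "exchange")
    ))
  attr(m, "objective") <- "EX_p"
  m
}
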