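## Deterministic toy-community fixtures.
##
## Three small networks with engineered, analytically-checkable behaviour:
##
## * ToyA -- glucose consumer.  Its glucose assimilation route obligately
##   secretes acetate (overflow metabolism) and couples product P1 to
##   growth; a slower salvage route re-assimilates extracellular acetate at
##   useful yield, so in monoculture ToyA enjoys a second growth phase on
##   its own overflow.
## * ToyB -- acetate specialist.  Cannot touch glucose; grows only on
##   acetate and couples product P2 to growth.  Zero growth in monoculture
##   on glucose-only media; thrives next to ToyA (acetate cross-feeding).
## * ToyC -- glucose competitor with no secretion.  Slower glucose drain
##   than ToyA, but a fast acetate scavenging route of near-zero biomass
##   yield: it strips ToyA's overflow acetate and squanders it.  In
##   co-culture each species deprives the other of a major part of its
##   solo growth (glucose share for ToyC, the acetate salvage phase for
##   ToyA), the engineered basis for a competitive (-/-) interaction call.
##
## All stoichiometries are fixed constants: the generator is fully
## deterministic, and the seed argument only stamps provenance metadata.

toy_metabolite_table <- function(ids) {
  info <- list(
    glc__D_e = c("e", "C6H12O6"), glc__D_c = c("c", "C6H12O6"),
    ac_e = c("e", "C2H3O2"), ac_c = c("c", "C2H3O2"),
    p1_e = c("e", "C3H8O3"), p2_e = c("e", "C4H10O4"),
    o2_e = c("e", "O2"), x_c = c("c", NA), xb_c = c("c", NA),
    xc_c = c("c", NA))
  data.frame(
    id = ids,
    compartment = vapply(ids, function(i) info[[i]][1], character(1)),
    formula = vapply(ids, function(i) info[[i]][2], character(1)),
    stringsAsFactors = FALSE)
}

build_toy <- function(id, met_ids, rxns, objective) {
  mets <- toy_metabolite_table(met_ids)
  S <- matrix(0, length(met_ids), length(rxns),
              dimnames = list(met_ids, names(rxns)))
  lb <- ub <- numeric(length(rxns))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    S[names(r$stoich), j] <- unlist(r$stoich)
    lb[j] <- r$bounds[1]
    ub[j] <- r$bounds[2]
  }
  metabolic_model(id = id, metabolites = mets, stoichiometry = S,
                  reactions = data.frame(id = names(rxns), lb = lb, ub = ub,
                                         stringsAsFactors = FALSE),
                  objective = objective)
}

toy_a <- function() {
  build_toy(
    "toyA",
    c("glc__D_e", "glc__D_c", "ac_e", "ac_c", "x_c", "p1_e", "o2_e"),
    list(
      EX_glc__D_e = list(stoich = list(glc__D_e = -1), bounds = c(-1000, 1000)),
      EX_ac_e    = list(stoich = list(ac_e = -1),      bounds = c(-1000, 1000)),
      EX_p1_e    = list(stoich = list(p1_e = -1),      bounds = c(0, 1000)),
      EX_o2_e    = list(stoich = list(o2_e = -1),      bounds = c(-1000, 1000)),
      ## glucose assimilation with obligate acetate overflow
      GLCt       = list(stoich = list(glc__D_e = -1, glc__D_c = 1),
                        bounds = c(0, 12)),
      GLCBIO     = list(stoich = list(glc__D_c = -40, x_c = 1, ac_e = 40),
                        bounds = c(0, 1000)),
      ## slower acetate salvage at useful yield (second growth phase)
      ACt        = list(stoich = list(ac_e = -1, ac_c = 1), bounds = c(0, 6)),
      ACBIO      = list(stoich = list(ac_c = -15, x_c = 1), bounds = c(0, 1000)),
      BIOMASS_A  = list(stoich = list(x_c = -1, p1_e = 0.4),
                        bounds = c(0, 1000))),
    "BIOMASS_A")
}

toy_b <- function() {
  build_toy(
    "toyB",
    c("ac_e", "ac_c", "xb_c", "p2_e"),
    list(
      EX_ac_e   = list(stoich = list(ac_e = -1), bounds = c(-1000, 1000)),
      EX_p2_e   = list(stoich = list(p2_e = -1), bounds = c(0, 1000)),
      ACt_B     = list(stoich = list(ac_e = -1, ac_c = 1), bounds = c(0, 20)),
      ACBIO_B   = list(stoich = list(ac_c = -15, xb_c = 1), bounds = c(0, 1000)),
      BIOMASS_B = list(stoich = list(xb_c = -1, p2_e = 0.5),
                       bounds = c(0, 1000))),
    "BIOMASS_B")
}

toy_c <- function() {
  build_toy(
    "toyC",
    c("glc__D_e", "glc__D_c", "ac_e", "ac_c", "xc_c"),
    list(
      EX_glc__D_e = list(stoich = list(glc__D_e = -1), bounds = c(-1000, 1000)),
      EX_ac_e     = list(stoich = list(ac_e = -1),     bounds = c(-1000, 1000)),
      GLCt_C      = list(stoich = list(glc__D_e = -1, glc__D_c = 1),
                         bounds = c(0, 11.5)),
      GLCBIO_C    = list(stoich = list(glc__D_c = -20, xc_c = 1),
                         bounds = c(0, 1000)),
      ## fast acetate scavenging at near-zero biomass yield
      ACt_C       = list(stoich = list(ac_e = -1, ac_c = 1), bounds = c(0, 30)),
      ACJUNK_C    = list(stoich = list(ac_c = -1000, xc_c = 1),
                         bounds = c(0, 1000)),
      BIOMASS_C   = list(stoich = list(xc_c = -1, glc__D_c = -0.001),
                         bounds = c(0, 1000))),
    "BIOMASS_C")
}

#' Fixture media component table
#'
#' Minimal components (glucose plus inorganic salts) plus the extra carbon
#' and nutrient sources that distinguish the rich medium.
#'
#' @return data.frame with columns `metabolite_id`,
#'   `concentration_mmol_per_L`, `richness`.
#' @export
toy_media_table <- function() {
  data.frame(
    metabolite_id = c("glc__D_e", "nh4_e", "pi_e",
                      "ac_e", "succ_e", "xyl__D_e"),
    concentration_mmol_per_L = rep(10, 6),
    richness = c(rep("minimal", 3), rep("rich", 3)),
    stringsAsFactors = FALSE)
}

#' Generate the deterministic toy community
#'
#' Returns the three engineered toy models and the fixture media table.
#' The construction is fully deterministic; `seed` is only recorded in the
#' returned object so that downstream manifests can echo it.
#'
#' Engineered ground truths (on the minimal glucose medium, default
#' conditions): ToyB alone does not grow; ToyA alone grows on glucose and
#' then on its own secreted acetate; ToyA+ToyB cross-feed acetate with both
#' members growing; ToyA+ToyC mutually suppress each other via the shared
#' glucose pool and acetate scavenging.
#'
#' @param seed integer recorded as provenance (the fixtures themselves do
#'   not depend on it).
#' @return list with `models` (list of three `metabolic_model`s),
#'   `media_table` and `seed`.
#' @export
generate_toy_community <- function(seed = 1) {
  list(models = list(toyA = toy_a(), toyB = toy_b(), toyC = toy_c()),
       media_table = toy_media_table(), seed = as.integer(seed))
}

#' Write toy fixtures to disk
#'
#' Emits each toy model in the requested format plus the media TSV;
#' byte-identical across calls with the same arguments.
#'
#' @param dir output directory (created if needed).
#' @param seed provenance seed, see [generate_toy_community()].
#' @param format `"json"` or `"sbml"`.
#' @return character vector of written paths, invisibly.
#' @export
write_toy_community <- function(dir, seed = 1, format = c("json", "sbml")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix <- generate_toy_community(seed)
  ext <- if (format == "json") ".json" else ".xml"
  paths <- character(0)
  for (m in fix$models) {
    p <- file.path(dir, paste0(m$id, ext))
    write_model(m, p, format)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "toy_media.tsv")
  write_media_table(fix$media_table, mp)
  invisible(c(paths, mp))
}

#' Availability-limited sensitivity fixture
#'
#' A degenerate regime built for kinetics-sensitivity checks: a dense
#' inoculum on a dilute medium, so the per-step availability term
#' `S/(X*dt)` undercuts the Michaelis-Menten transport term for every
#' `V_max` in [1, 50] and `K_m` in [0.01, 1].  Growth then depends only on
#' what is in the pool, not on the kinetic parameters.
#'
#' @return list with `models` (ToyA + ToyC), `medium` and `config` ready
#'   for [lhs_sensitivity()].
#' @export
toy_saturated_setup <- function() {
  med <- medium("dilute-dense", c(glc__D_e = 0.1), "anaerobic")
  cfg <- sim_config(dt = 0.1, horizon = 2, initial_biomass = 12,
                    averaging_window = 5)
  list(models = list(toy_a(), toy_c()), medium = med, config = cfg)
}
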