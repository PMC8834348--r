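.preset_env <- new.env(parent = emptyenv())

preset_db <- function() {
  if (is.null(.preset_env$db)) {
    path <- system.file("extdata", "condition_presets.json", package = "raftdyn")
    .preset_env$db <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  .preset_env$db
}

#' Available condition presets
#'
#' @return character vector of preset names.
#' @export
preset_conditions <- function() names(preset_db()$conditions)

#' Condition preset: simulation parameters and published ground truth
#'
#' Returns the stored preset for one experimental condition of the study the
#' package emulates: sphingomyelin (SM-BODIPY) and phosphatidylcholine
#' (PC-BODIPY) lipid analogues and GPI-anchored eGFP-Thy-1 probed by svFCS,
#' and Flot2-mEGFP probed by FRAP, each in control cells, MPP1-knockdown
#' cells and (where measured) after raft-disrupting treatments (zaragozic
#' acid + myriocin, methyl-beta-cyclodextrin) or MPP1 re-expression.
#'
#' svFCS presets carry a `law` block (published diffusion-law parameters:
#' intercept `t0_ms`, effective coefficient `d_eff`, their SEMs and the
#' cell-to-cell coefficient of variation used by law-level round trips) and
#' a calibrated particle-level `sim` block (returned as a [sim_config()]
#' plus domain parameters). FRAP presets carry a `frap` block (published
#' half-time and mobile fraction). Trapping strength across the particle
#' presets is ordered Thy1_control > SM_control > SM_rescue > SM_ZA_Myr >
#' SM_KnD; the PC presets have no trapping at all.
#'
#' @param condition one of [preset_conditions()].
#' @param n_particles,duration,seed overrides applied to the returned
#'   [sim_config()].
#' @return list with elements `condition`, `config` (a [sim_config()]),
#'   `domains` (list with `radius`, `area_fraction`), `detection` (bin
#'   time, brightness, background), `waists`, and `law` and/or `frap`
#'   ground-truth blocks.
#' @examples
#' p <- condition_preset("SM_control")
#' p$law$t0_ms
#' @export
condition_preset <- function(condition, n_particles = NULL, duration = 5,
                             seed = NULL) {
  db <- preset_db()
  if (!condition %in% names(db$conditions))
    stop("unknown condition '", condition, "'; see preset_conditions()")
  p <- db$conditions[[condition]]
  s <- p$sim
  cfg <- sim_config(box_size = s$box_size,
                    n_particles = n_particles %||% s$n_particles,
                    dt = s$dt, duration = duration,
                    d_out = s$d_out, d_in = s$d_in,
                    p_enter = s$p_enter, p_escape = s$p_escape, seed = seed)
  list(condition = condition, config = cfg,
       domains = list(radius = s$radius, area_fraction = s$area_fraction),
       detection = db$detection, waists = db$waists_um,
       law = p$law, frap = p$frap)
}

#' FRAP ground truth for a preset condition
#'
#' @param condition a preset with a FRAP block (`Flot2_control`,
#'   `Flot2_KnD`, `Flot2_MbCD`).
#' @return list with `t_half_s`, `t_half_sd_s`, `mobile_pct`,
#'   `mobile_sd_pct`.
#' @export
frap_preset <- function(condition) {
  p <- condition_preset(condition)
  if (is.null(p$frap))
    stop("condition '", condition, "' has no FRAP ground truth")
  p$frap
}
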