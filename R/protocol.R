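#' The staged minimization/heating/equilibration/production protocol
#'
#' Returns the full staged protocol used to prepare and run the restrained
#' ribosome subsystem, as data: eleven minimization rounds that ramp the
#' positional restraint weight down from 100 to 1 kcal/mol/A^2 (steepest
#' descent first, conjugate gradient for the balance of each round), a 20 ps
#' heating step at a 2 fs timestep with all residues restrained at
#' 20 kcal/mol/A^2, a 3 ns equilibration at a 1 fs timestep with inherited
#' velocities, and production at 300 K sampled at 100 frames per ns with only
#' the onion shell restrained. The solvent environment (truncated octahedral
#' box, 12 A margin, TIP3P water, Na+ counter-ions) is recorded for the MD
#' engine; no simulation is run here.
#'
#' The restraint-weight ramp was designed against the criterion that each
#' round's total energy drop be smaller than the previous round's in the same
#' or fewer steps, with per-round convergence judged by the energy slope
#' approaching zero; those criteria are carried as documentation fields
#' (`design_notes`) because they describe how the schedule was designed, not a
#' runtime computation.
#'
#' @param production_ns Production run length in ns (a per-study choice; the
#'   schedule carries it as configuration, default 35).
#' @param pre_restraint_md_ps Optional stabilisation MD (0, 10 or 100 ps)
#'   inserted before the onion-shell coordinates are fixed, used to stabilise
#'   runs that would otherwise terminate early.
#' @return An object of class `car_schedule`.
#' @export
default_schedule <- function(production_ns = 35, pre_restraint_md_ps = 0) {
  if (!pre_restraint_md_ps %in% c(0, 10, 100)) {
    rlang::abort("pre_restraint_md_ps must be 0, 10 or 100", class = "car_config_error")
  }
  sched <- list(
    minimization = tibble::tibble(
      round = 1:11,
      steps = c(20000L, 10000L, 5000L, 3000L, 3000L, 2000L, 2000L, 2000L, 2000L, 2000L, 2000L),
      sd_steps = c(2500L, 2500L, 2500L, 2500L, 2500L, 2000L, 2000L, 2000L, 2000L, 2000L, 2000L),
      weight = c(100, 75, 65, 55, 45, 30, 20, 15, 10, 5, 1)
    ),
    heating = list(duration_ps = 20, timestep_fs = 2, restraint_weight = 20),
    equilibration = list(
      duration_ns = 3, timestep_fs = 1, restraint_weight = 20,
      inherit_velocities = TRUE
    ),
    production = list(
      frames_per_ns = 100, temperature_K = 300, duration_ns = production_ns,
      timestep_fs = 2, restraint = "onion_shell"
    ),
    environment = list(
      box = "truncated_octahedron", solvent_margin_A = 12,
      water_model = "TIP3P", counter_ion = "Na+"
    ),
    pre_restraint_md_ps = pre_restraint_md_ps,
    design_notes = list(
      round_convergence = "energy slope asymptotically approaches 0 within the round",
      weight_ramp = "each round's total energy drop is less than the previous round's, in the same or fewer steps"
    )
  )
  validate_schedule(sched)
  structure(sched, class = "car_schedule")
}

validate_schedule <- function(p) {
  m <- p$minimization
  if (nrow(m) == 0) rlang::abort("schedule has no minimization rounds", class = "car_config_error")
  if (any(m$sd_steps <= 0 | m$sd_steps > m$steps)) {
    rlang::abort("steepest-descent steps must be in (0, total steps]", class = "car_config_error")
  }
  if (any(m$weight <= 0)) rlang::abort("restraint weights must be positive", class = "car_config_error")
  if (is.unsorted(rev(m$weight))) {
    rlang::abort("restraint weights must be non-increasing across rounds", class = "car_config_error")
  }
  invisible(p)
}

#' @export
print.car_schedule <- function(x, ...) {
  cat(sprintf(
    "<car_schedule> %d minimization rounds (weights %g -> %g), heating %g ps, equilibration %g ns, production %g frames/ns at %g K\n",
    nrow(x$minimization), max(x$minimization$weight), min(x$minimization$weight),
    x$heating$duration_ps, x$equilibration$duration_ns,
    x$production$frames_per_ns, x$production$temperature_K
  ))
  invisible(x)
}

#' Render a protocol schedule as engine input documents
#'
#' Produces one document per stage: one per minimization round plus heating,
#' equilibration and production (the environment block travels inside the
#' production document). The `generic_json` dialect round-trips exactly
#' through [parse_schedule()]; `amber_mdin` renders AMBER-style mdin text with
#' `ntr`/`restraint_wt` lines consistent with the restraint mask.
#'
#' @param p A `car_schedule`.
#' @param dialect `"generic_json"` or `"amber_mdin"`.
#' @param mask Restraint mask string used for the `restraintmask` lines of the
#'   mdin dialect (default a placeholder).
#' @return Named character vector of documents (`min_01` ... `heating`,
#'   `equilibration`, `production`).
#' @export
render_schedule <- function(p, dialect = c("generic_json", "amber_mdin"),
                            mask = ":ONION") {
  if (!inherits(p, "car_schedule")) rlang::abort("expected a car_schedule", class = "car_config_error")
  dialect <- rlang::arg_match(dialect)
  validate_schedule(p)
  m <- p$minimization
  docs <- character(0)
  if (dialect == "generic_json") {
    for (i in seq_len(nrow(m))) {
      docs[sprintf("min_%02d", i)] <- as.character(jsonlite::toJSON(
        list(stage = "minimization", round = m$round[i], steps = m$steps[i],
             sd_steps = m$sd_steps[i], weight = m$weight[i]),
        auto_unbox = TRUE, digits = NA
      ))
    }
    docs["heating"] <- as.character(jsonlite::toJSON(
      c(list(stage = "heating"), p$heating), auto_unbox = TRUE, digits = NA
    ))
    docs["equilibration"] <- as.character(jsonlite::toJSON(
      c(list(stage = "equilibration"), p$equilibration), auto_unbox = TRUE, digits = NA
    ))
    docs["production"] <- as.character(jsonlite::toJSON(
      list(
        stage = "production", production = p$production, environment = p$environment,
        pre_restraint_md_ps = p$pre_restraint_md_ps, design_notes = p$design_notes
      ),
      auto_unbox = TRUE, digits = NA
    ))
    return(docs)
  }
  for (i in seq_len(nrow(m))) {
    docs[sprintf("min_%02d", i)] <- paste0(
      sprintf("Minimization round %d\n", m$round[i]),
      " &cntrl\n",
      "  imin=1,\n",
      sprintf("  maxcyc=%d,\n", m$steps[i]),
      sprintf("  ncyc=%d,\n", m$sd_steps[i]),
      "  ntr=1,\n",
      sprintf("  restraint_wt=%g,\n", m$weight[i]),
      sprintf("  restraintmask='%s',\n", mask),
      " /\n"
    )
  }
  heat_steps <- round(p$heating$duration_ps * 1000 / p$heating$timestep_fs)
  docs["heating"] <- paste0(
    "Heating\n &cntrl\n  imin=0, irest=0, ntx=1,\n",
    sprintf("  nstlim=%d,\n", heat_steps),
    sprintf("  dt=%g,\n", p$heating$timestep_fs / 1000),
    "  tempi=0.0, temp0=300.0, ntt=1,\n",
    "  ntr=1,\n",
    sprintf("  restraint_wt=%g,\n", p$heating$restraint_weight),
    "  restraintmask='ALL',\n /\n"
  )
  eq_steps <- round(p$equilibration$duration_ns * 1e6 / p$equilibration$timestep_fs)
  docs["equilibration"] <- paste0(
    "Equilibration\n &cntrl\n",
    sprintf(
      "  imin=0, irest=%d, ntx=%d,\n",
      as.integer(p$equilibration$inherit_velocities),
      if (p$equilibration$inherit_velocities) 5L else 1L
    ),
    sprintf("  nstlim=%d,\n", eq_steps),
    sprintf("  dt=%g,\n", p$equilibration$timestep_fs / 1000),
    "  temp0=300.0, ntt=1,\n  ntr=1,\n",
    sprintf("  restraint_wt=%g,\n", p$equilibration$restraint_weight),
    "  restraintmask='ALL',\n /\n"
  )
  prod_steps <- round(p$production$duration_ns * 1e6 / p$production$timestep_fs)
  ntwx <- round(1e6 / p$production$timestep_fs / p$production$frames_per_ns)
  docs["production"] <- paste0(
    "Production\n &cntrl\n  imin=0, irest=1, ntx=5,\n",
    sprintf("  nstlim=%d,\n", prod_steps),
    sprintf("  dt=%g,\n", p$production$timestep_fs / 1000),
    sprintf("  temp0=%g, ntt=1,\n", p$production$temperature_K),
    sprintf("  ntwx=%d,\n", ntwx),
    "  ntr=1,\n",
    sprintf("  restraint_wt=%g,\n", 20),
    sprintf("  restraintmask='%s',\n", mask),
    " /\n",
    sprintf(
      "! environment: %s box, %g A solvent margin, %s water, %s counter-ions\n",
      p$environment$box, p$environment$solvent_margin_A,
      p$environment$water_model, p$environment$counter_ion
    )
  )
  docs
}

#' Parse generic_json schedule documents back into a schedule
#'
#' Inverse of `render_schedule(p, "generic_json")`.
#'
#' @param docs Named character vector of JSON documents.
#' @return A `car_schedule` equal to the one rendered.
#' @export
parse_schedule <- function(docs) {
  parsed <- lapply(docs, jsonlite::fromJSON)
  stages <- vapply(parsed, function(d) d$stage, character(1))
  mins <- parsed[stages == "minimization"]
  m <- dplyr::bind_rows(lapply(mins, function(d) {
    tibble::tibble(
      round = as.integer(d$round), steps = as.integer(d$steps),
      sd_steps = as.integer(d$sd_steps), weight = as.double(d$weight)
    )
  })) |> dplyr::arrange(.data$round)
  heat <- parsed[[which(stages == "heating")]]
  eq <- parsed[[which(stages == "equilibration")]]
  prod <- parsed[[which(stages == "production")]]
  sched <- list(
    minimization = m,
    heating = heat[setdiff(names(heat), "stage")],
    equilibration = eq[setdiff(names(eq), "stage")],
    production = prod$production,
    environment = prod$environment,
    pre_restraint_md_ps = prod$pre_restraint_md_ps,
    design_notes = prod$design_notes
  )
  validate_schedule(sched)
  structure(sched, class = "car_schedule")
}
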