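# Synthetic survey generator: households, communities (villages), panda
# survey tables and a village adjacency list with the statistical structure
# the niche evaluation assumes.

# Draw one variable from its spec; records SD-clipping notes instead of
# warning so bulk generation stays quiet (notes end up in the run manifest).
draw_variable <- function(spec, n, notes_env = NULL, name = "") {
  note <- function(msg) {
    if (!is.null(notes_env)) notes_env$notes <- c(notes_env$notes, msg)
  }
  quiet <- function(expr) {
    withCallingHandlers(expr, pandaniche_sd_clip = function(w) {
      note(paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  switch(spec$kind,
    "truncated-normal" = {
      cal <- quiet(calibrate_truncated_normal(spec$mean, spec$sd,
                                              spec$lower, spec$upper))
      rtruncnorm(n, cal$mu, cal$sigma, spec$lower, spec$upper)
    },
    "bernoulli" = stats::rbinom(n, 1L, spec$p),
    "ordinal3" = {
      cal <- quiet(calibrate_ordinal3(spec$mean, spec$sd))
      sample(1:3, n, replace = TRUE, prob = cal$probs)
    },
    "categorical" = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
    stop("unknown variable kind: ", spec$kind, call. = FALSE)
  )
}

community_ids <- function(n) sprintf("C%02d", seq_len(n))
reserve_ids <- function(n) sprintf("R%d", seq_len(n))

# Map village -> reserve in contiguous near-equal blocks.
community_reserve_map <- function(config) {
  sizes <- block_sizes(config$n_communities, config$n_reserves)
  data.frame(
    community_id = community_ids(config$n_communities),
    reserve_id = rep(reserve_ids(config$n_reserves), times = sizes),
    stringsAsFactors = FALSE
  )
}

# Village-level aging-response multipliers: mean aging_effect, spread set by
# aging_heterogeneity (village responses differ with local energy and
# livelihood alternatives). Deterministic under the root seed.
community_aging_effects <- function(config) {
  n <- config$n_communities
  if (config$aging_heterogeneity <= 0 || config$aging_effect == 0) {
    eff <- rep(config$aging_effect, n)
  } else {
    k <- (1 / config$aging_heterogeneity^2 - 1) / 2
    set.seed(substream_seed(config$seed, "households/aging_response"))
    omega <- 2 * stats::rbeta(n, k, k)
    eff <- pmin(1, config$aging_effect * omega)
  }
  stats::setNames(eff, community_ids(n))
}

#' Generate a synthetic household survey table
#'
#' Draws one row per household with the variable set of the study-area
#' questionnaire: labor structure, resource-use quantities and revenues,
#' regulation perceptions, and constraint variables. Continuous bounded
#' variables come from truncated normals moment-matched after truncation;
#' ordinal variables from categorical distributions matching the printed
#' mean exactly. Households whose primary laborer is at or above the age
#' threshold (the old-age group) have their resource-use quantities
#' (`UA_cropland`, `UA_fuelwood`) multiplied by `1 - e_c`, where `e_c` is
#' the village-level aging effect with mean `aging_effect`; revenues
#' (`I_* = UA_* * rate_*`) fall proportionally.
#'
#' Output is deterministic under a fixed config: every variable is drawn
#' from its own seed substream.
#'
#' @param config A [scenario_config()] object.
#' @return A `data.frame` with one row per household. SD-clipping notes from
#'   the moment-matching step are attached as attribute `calibration_notes`.
#' @examples
#' hh <- generate_households(scenario_config(n_households = 40,
#'   n_communities = 4, n_reserves = 2, seed = 7))
#' @export
generate_households <- function(config) {
  stopifnot(inherits(config, "panda_scenario"))
  n <- config$n_households
  notes <- new.env()
  notes$notes <- character()

  sizes <- block_sizes(n, config$n_communities,
                       config$households_per_community)
  out <- data.frame(
    household_id = sprintf("H%05d", seq_len(n)),
    community_id = rep(community_ids(config$n_communities), times = sizes),
    stringsAsFactors = FALSE
  )
  for (v in names(config$variable_specs)) {
    set.seed(substream_seed(config$seed, paste0("households/", v)))
    out[[v]] <- draw_variable(config$variable_specs[[v]], n, notes, v)
  }

  oag <- out$primary_laborer_age >= config$age_threshold
  eff <- community_aging_effects(config)[out$community_id]
  for (v in c("UA_cropland", "UA_fuelwood")) {
    out[[v]][oag] <- out[[v]][oag] * (1 - eff[oag])
  }
  out$I_cropland <- out$UA_cropland * out$rate_cropland
  out$I_fuelwood <- out$UA_fuelwood * out$rate_fuelwood

  attr(out, "calibration_notes") <- unique(notes$notes)
  out
}

#' Generate a synthetic community (village) attribute table
#'
#' One row per village with land, labor and change-rate attributes at the
#' two observation years (2013 and 2018): total and available cultivated
#' land (`TACL`, `AACL`), total forestland and available fuelwood land
#' (`TAFL`, `AAFL`), regional population and household labor-force counts
#' (`TPR`, `LFQH`), and the three resource-use change rates `x8`--`x10`
#' (cultivated-land area, fuelwood-cutting distance, fuelwood labor-hours)
#' on `[0, 1]`. Availability ratios are drawn as fractions, so
#' `AACL <= TACL`, `AAFL <= TAFL`, and `LFQH <= TPR` hold by construction.
#'
#' @param config A [scenario_config()] object.
#' @return A `data.frame` with one row per community.
#' @export
generate_communities <- function(config) {
  stopifnot(inherits(config, "panda_scenario"))
  n <- config$n_communities
  draw <- function(key, mean, sd, lower, upper) {
    set.seed(substream_seed(config$seed, paste0("communities/", key)))
    cal <- suppressWarnings(
      calibrate_truncated_normal(mean, sd, lower, upper))
    rtruncnorm(n, cal$mu, cal$sigma, lower, upper)
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  map <- community_reserve_map(config)
  out <- data.frame(
    community_id = map$community_id,
    reserve_id = map$reserve_id,
    stringsAsFactors = FALSE
  )
  set.seed(substream_seed(config$seed, "communities/inside_reserve"))
  out$inside_reserve <- stats::rbinom(n, 1L, 0.5)

  out$TACL_2013 <- draw("TACL", 80, 30, 10, 200)          # hm2
  frac_acl <- draw("AACL_frac", 0.60, 0.15, 0.05, 0.95)
  out$AACL_2013 <- frac_acl * out$TACL_2013
  out$TACL_2018 <- out$TACL_2013 *
    (1 + draw("TACL_growth", -0.08, 0.05, -0.30, 0.10))
  frac_acl18 <- clamp(frac_acl + draw("AACL_frac_shift", -0.05, 0.04,
                                      -0.30, 0.20), 0.01, 0.99)
  out$AACL_2018 <- frac_acl18 * out$TACL_2018

  out$TAFL_2013 <- draw("TAFL", 400, 150, 50, 1200)       # hm2 forestland
  frac_afl <- draw("AAFL_frac", 0.35, 0.10, 0.02, 0.90)
  out$AAFL_2013 <- frac_afl * out$TAFL_2013
  out$TAFL_2018 <- out$TAFL_2013 *
    (1 + draw("TAFL_growth", 0.02, 0.04, -0.15, 0.20))
  frac_afl18 <- clamp(frac_afl + draw("AAFL_frac_shift", -0.03, 0.03,
                                      -0.20, 0.15), 0.01, 0.99)
  out$AAFL_2018 <- frac_afl18 * out$TAFL_2018

  out$TPR_2013 <- round(draw("TPR", 900, 300, 200, 2500)) # persons
  frac_lf <- draw("LFQH_frac", 0.45, 0.10, 0.05, 0.90)
  out$LFQH_2013 <- round(frac_lf * out$TPR_2013)
  out$TPR_2018 <- round(out$TPR_2013 *
    (1 + draw("TPR_growth", -0.06, 0.05, -0.30, 0.15)))
  frac_lf18 <- clamp(frac_lf + draw("LFQH_frac_shift", -0.04, 0.03,
                                    -0.20, 0.10), 0.02, 0.95)
  out$LFQH_2018 <- round(frac_lf18 * out$TPR_2018)

  out$x8_2013 <- draw("x8", 0.22, 0.12, 0, 1)
  out$x8_2018 <- clamp(out$x8_2013 + draw("x8_shift", 0.05, 0.06,
                                          -0.5, 0.5), 0, 1)
  out$x9_2013 <- draw("x9", 0.18, 0.10, 0, 1)
  out$x9_2018 <- clamp(out$x9_2013 + draw("x9_shift", 0.05, 0.06,
                                          -0.5, 0.5), 0, 1)
  out$x10_2013 <- draw("x10", 0.20, 0.12, 0, 1)
  out$x10_2018 <- clamp(out$x10_2013 + draw("x10_shift", 0.06, 0.06,
                                            -0.5, 0.5), 0, 1)
  out
}

#' Generate a synthetic giant-panda survey table
#'
#' One row per nature reserve with habitat area and wild population at the
#' 3rd and 4th national giant panda surveys, staple-food bamboo area and
#' reserve area. The 4th-survey habitat area is constructed as
#' `AGPH3rd * (1 + rate)` with a reserve-specific change rate, so the
#' habitat change-rate index recovers the drawn rate exactly.
#'
#' @param config A [scenario_config()] object.
#' @return A `data.frame` with one row per reserve.
#' @export
generate_panda_survey <- function(config) {
  stopifnot(inherits(config, "panda_scenario"))
  n <- config$n_reserves
  draw <- function(key, mean, sd, lower, upper) {
    set.seed(substream_seed(config$seed, paste0("panda/", key)))
    cal <- suppressWarnings(
      calibrate_truncated_normal(mean, sd, lower, upper))
    rtruncnorm(n, cal$mu, cal$sigma, lower, upper)
  }
  out <- data.frame(reserve_id = reserve_ids(n), stringsAsFactors = FALSE)
  out$AGPH3rd <- draw("AGPH3rd", 30000, 15000, 2000, 90000)   # hm2
  hab_rate <- draw("habitat_rate", 0.12, 0.10, -0.30, 0.60)
  out$AGPH4th <- out$AGPH3rd * (1 + hab_rate)
  out$PGPH3rd <- pmax(1, round(draw("PGPH3rd", 30, 15, 2, 120)))
  pop_rate <- draw("pop_rate", 0.10, 0.12, -0.40, 0.80)
  out$PGPH4th <- pmax(1, round(out$PGPH3rd * (1 + pop_rate)))
  out$ANR <- draw("ANR", 45000, 20000, 5000, 150000)          # hm2
  out$ASFB <- draw("ASFB_frac", 0.45, 0.15, 0.05, 0.95) * out$ANR
  out
}

#' Generate the village adjacency list
#'
#' Villages attached to the same nature reserve are chained in order, so
#' each reserve contributes a path of neighboring-village pairs. Overlap
#' statistics are computed along these pairs by default.
#'
#' @param config A [scenario_config()] object.
#' @return A `data.frame` with columns `community_a` and `community_b`; zero
#'   rows if every reserve has a single village.
#' @export
generate_adjacency <- function(config) {
  stopifnot(inherits(config, "panda_scenario"))
  map <- community_reserve_map(config)
  pairs <- do.call(rbind, lapply(split(map$community_id, map$reserve_id),
    function(ids) {
      if (length(ids) < 2) return(NULL)
      data.frame(community_a = ids[-length(ids)], community_b = ids[-1],
                 stringsAsFactors = FALSE)
    }))
  if (is.null(pairs)) {
    pairs <- data.frame(community_a = character(), community_b = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  pairs
}

#' Write the synthetic survey tables to a directory
#'
#' Writes `households.csv`, `communities.csv`, `panda_survey.csv` and
#' `adjacency.csv` (UTF-8, header row, `.` decimal separator). Re-running
#' with an identical configuration produces byte-identical files.
#'
#' @param config A [scenario_config()] object.
#' @param dir Output directory; created if missing.
#' @return Invisibly, a named character vector of the file paths written,
#'   with the generator's calibration notes in attribute
#'   `calibration_notes`.
#' @export
write_survey_tables <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hh <- generate_households(config)
  tables <- list(
    households = hh,
    communities = generate_communities(config),
    panda_survey = generate_panda_survey(config),
    adjacency = generate_adjacency(config)
  )
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    path
  }, character(1))
  attr(paths, "calibration_notes") <- attr(hh, "calibration_notes")
  invisible(paths)
}
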