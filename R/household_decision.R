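# Household resource-utilization decision model: belief updating, pattern
# importance, four-factor final decision, and micro-to-macro aggregation of
# household decisions to village-level utilization indexes.

#' Classify a household into the old-age or young-adult group
#'
#' A household belongs to the old-age group (OAG) when its primary laborer
#' is at or above the threshold age (55 years by default, boundary
#' inclusive); otherwise to the young-adult group (YAG).
#'
#' @param age Numeric vector of primary-laborer ages in years.
#' @param threshold Classification threshold in years.
#' @return Character vector of `"OAG"` / `"YAG"`.
#' @examples
#' classify_age_group(c(54, 55, 60))
#' @export
classify_age_group <- function(age, threshold = 55) {
  if (any(!is.finite(age))) {
    stop("data error: missing or non-finite primary laborer age", call. = FALSE)
  }
  ifelse(age >= threshold, "OAG", "YAG")
}

#' Update household belief from perception
#'
#' One exponential-smoothing step of the household's belief (its cognition
#' of the current resource-utilization state under reserve regulation)
#' toward its current perception:
#' `belief' = smoothing * perception + (1 - smoothing) * belief`.
#'
#' @param belief Current belief in `[0, 1]`; vectorized.
#' @param perception Current perception in `[0, 1]`; vectorized.
#' @param smoothing Weight on the new perception, in `[0, 1]`.
#' @return Updated belief, in `[0, 1]`.
#' @examples
#' update_belief(0.2, 0.6, 0.5)  # 0.4
#' @export
update_belief <- function(belief, perception, smoothing = 0.5) {
  if (!is.finite(smoothing) || smoothing < 0 || smoothing > 1) {
    stop("invalid parameter: smoothing must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(belief >= 0 & belief <= 1), all(perception >= 0 & perception <= 1))
  smoothing * perception + (1 - smoothing) * belief
}

#' Per-pattern importance of resource utilization
#'
#' The importance of utilization pattern `k` (cropland, fuelwood) for a
#' household is its revenue-weighted share of use:
#' `importance_k = UA_k * I_k / sum_k(UA_k * I_k)`.
#' A household with no utilization at all (`sum UA * I = 0`) is a valid
#' observation (non-farm households exist in the sample): it receives zero
#' importance on every pattern and is flagged.
#'
#' @param UA Matrix (or vector for one household) of utilization
#'   quantities, one column per pattern; non-negative.
#' @param I Matrix of per-pattern revenues, same shape; non-negative.
#' @return A list with `importance` (rows sum to 1, or to 0 for
#'   non-utilizing households) and logical `no_utilization`.
#' @examples
#' pattern_importance(c(2, 1), c(3, 4))$importance  # 0.6 0.4
#' @export
pattern_importance <- function(UA, I) {
  UA <- rbind(UA)
  I <- rbind(I)
  stopifnot(identical(dim(UA), dim(I)))
  if (any(UA < 0) || any(I < 0)) {
    stop("data error: UA and I must be non-negative", call. = FALSE)
  }
  prod <- UA * I
  tot <- rowSums(prod)
  none <- tot == 0
  imp <- prod / ifelse(none, 1, tot)
  imp[none, ] <- 0
  dimnames(imp) <- dimnames(UA)
  list(importance = imp, no_utilization = unname(none))
}

# Rescale an ordinal on {1..k} to [0, 1].
rescale_ordinal <- function(x, k) (x - 1) / (k - 1)

#' Four-factor scores of the final decision model
#'
#' Computes, per household, the `[0, 1]` scores of the four factors acting
#' on the final resource-utilization decision:
#' * `ecological_value_identity`: the household's belief;
#' * `social_pressure`: mean of the two regulation perceptions rescaled
#'   from `[1, 5]` to `[0, 1]`;
#' * `environmental_constraints`: mean of rescaled soil quality (inverted,
#'   poor soil = strong constraint), land fragmentation (clipped to
#'   `[0, 1]`), fuelwood slope, the fuelwood restriction flag, and fuelwood
#'   distance relative to the 16 km survey maximum;
#' * `labor_literacy`: mean of rescaled education and health levels (high =
#'   strong labor capacity).
#'
#' @param households Household table with the perception, constraint and
#'   literacy columns of [generate_households()].
#' @param belief Numeric vector of beliefs in `[0, 1]`, recycled if scalar.
#' @return A `data.frame` of the four scores, one row per household.
#' @export
factor_scores <- function(households, belief) {
  h <- households
  n <- nrow(h)
  belief <- rep_len(belief, n)
  stopifnot(all(belief >= 0 & belief <= 1))
  social <- (rescale_ordinal(h$perception_planting_regulation, 5) +
             rescale_ordinal(h$perception_fuelwood_regulation, 5)) / 2
  constraints <- (rescale_ordinal(4 - h$soil_quality, 3) +
                  pmin(pmax(h$land_fragmentation, 0), 1) +
                  rescale_ordinal(h$fuel_slope, 3) +
                  h$fuel_restriction +
                  h$fuel_distance_km / 16) / 5
  literacy <- (rescale_ordinal(h$education_level, 3) +
               rescale_ordinal(h$health_level, 3)) / 2
  data.frame(
    ecological_value_identity = belief,
    social_pressure = social,
    environmental_constraints = constraints,
    labor_literacy = literacy
  )
}

#' Normalized factor weights from salience coefficients
#'
#' `w_x = a_x / sum(a_x)` for the four factors (ecological value identity,
#' social pressure, environmental constraints, labor literacy).
#'
#' @param a Numeric vector of four non-negative salience coefficients.
#' @return Numeric vector of four weights summing to 1.
#' @export
factor_weights <- function(a) {
  if (length(a) != 4 || any(!is.finite(a)) || any(a < 0)) {
    stop("invalid salience: need four finite non-negative coefficients",
         call. = FALSE)
  }
  if (sum(a) == 0) {
    stop("invalid salience: all coefficients are zero", call. = FALSE)
  }
  a / sum(a)
}

#' Final per-pattern decision intensity
#'
#' Combines the pattern importance with the four factor scores. Each factor
#' contributes a multiplicative modulation `m_x` in `[0, 1]`: by default
#' stronger ecological value identity, social pressure and environmental
#' constraints suppress utilization (`m_x = 1 - score`), while stronger
#' labor capacity enables it (`m_x = score`). The final intensity is
#' `final_k = sum_x(w_x * m_x) * importance_k`, which lies in
#' `[0, importance_k]` and reduces to the importance itself when every
#' modulation equals 1.
#'
#' @param importance Importance matrix (rows = households, columns =
#'   patterns), e.g. from [pattern_importance()].
#' @param scores Factor-score `data.frame` from [factor_scores()], or a
#'   modulation matrix if `modulation = "identity"`.
#' @param salience Four salience coefficients `a_x`; see [factor_weights()].
#' @param suppressive Named logical vector saying, per factor, whether a
#'   high score suppresses utilization (`m = 1 - score`) rather than
#'   enabling it (`m = score`).
#' @param modulation `"score"` (default) converts scores to modulations via
#'   `suppressive`; `"identity"` takes `scores` as modulations directly.
#' @return Matrix of final intensities with the shape of `importance`.
#' @export
final_decision <- function(importance, scores, salience = c(1, 1, 1, 1),
                           suppressive = c(ecological_value_identity = TRUE,
                                           social_pressure = TRUE,
                                           environmental_constraints = TRUE,
                                           labor_literacy = FALSE),
                           modulation = c("score", "identity")) {
  modulation <- match.arg(modulation)
  w <- factor_weights(salience)
  m <- as.matrix(scores)
  stopifnot(ncol(m) == 4, all(m >= 0 & m <= 1))
  if (modulation == "score") {
    flip <- suppressive[colnames(m)]
    if (any(is.na(flip))) flip <- rep_len(unname(suppressive), 4)
    m <- sweep(m, 2, as.numeric(flip), function(x, f) f * (1 - x) + (1 - f) * x)
  }
  gate <- as.vector(m %*% w)
  importance <- rbind(importance)
  importance * gate
}

#' Aggregate household decisions to community x age-group level
#'
#' Maps micro-level household decisions onto the village evaluation units:
#' for every community and age group, the utilization decision per pattern
#' is the unweighted mean (optionally the `UA`-weighted mean) of the
#' member households' intensities. Community/group cells with no member
#' households get `NA`.
#'
#' @param decisions Household-level `data.frame` holding `community_id`,
#'   `age_group`, and the intensity columns.
#' @param cols Named character vector mapping output index names to
#'   intensity columns, by default `c(x1 = "final_cropland",
#'   x2 = "final_fuelwood")`.
#' @param weights Optional column name holding aggregation weights (e.g. a
#'   `UA` column); `NULL` for the unweighted mean.
#' @return A `data.frame` with one row per community x age group, the
#'   aggregated columns named as in `names(cols)`, and `n_households`.
#' @export
aggregate_to_community <- function(decisions,
                                   cols = c(x1 = "final_cropland",
                                            x2 = "final_fuelwood"),
                                   weights = NULL) {
  if (nrow(decisions) == 0) {
    stop("data error: empty decision table", call. = FALSE)
  }
  stopifnot(all(c("community_id", "age_group", cols) %in% names(decisions)))
  comms <- sort(unique(decisions$community_id))
  groups <- c("OAG", "YAG")
  grid <- expand.grid(community_id = comms, age_group = groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(decisions$community_id, decisions$age_group)
  gkey <- paste(grid$community_id, grid$age_group)
  w <- if (is.null(weights)) rep(1, nrow(decisions)) else decisions[[weights]]
  for (j in seq_along(cols)) {
    num <- tapply(decisions[[cols[j]]] * w, key, sum)
    den <- tapply(w, key, sum)
    val <- num / den
    grid[[names(cols)[j]]] <- unname(val[gkey])
  }
  grid$n_households <- unname(table(key)[gkey])
  grid$n_households[is.na(grid$n_households)] <- 0L
  grid$n_households <- as.integer(grid$n_households)
  grid
}

#' Run the full household decision model
#'
#' Applies the belief update, pattern importance, factor scores and final
#' decision to a household table, and derives the intensity layers used by
#' the niche evaluation. The current-period utilization intensity of
#' pattern `k` is `importance_k * magnitude_k`, where `magnitude_k` is the
#' household's utilization quantity relative to twice the population mean
#' (clipped to 1), so that a population-wide weakening of resource
#' extraction is visible at village level. The next-period intensity
#' applies the four-factor gate on top.
#'
#' @param households Table from [generate_households()].
#' @param salience Four factor-salience coefficients.
#' @param smoothing Belief smoothing weight, see [update_belief()].
#' @param prior_belief Belief before the perception update, in `[0, 1]`.
#' @param age_threshold OAG/YAG classification threshold in years.
#' @param suppressive Passed to [final_decision()].
#' @return Household-level `data.frame` with importance, factor gate, final
#'   intensities, and current/next-period intensity layers per pattern.
#' @export
decide_households <- function(households, salience = c(1, 1, 1, 1),
                              smoothing = 0.5, prior_belief = 0.5,
                              age_threshold = 55,
                              suppressive = c(ecological_value_identity = TRUE,
                                              social_pressure = TRUE,
                                              environmental_constraints = TRUE,
                                              labor_literacy = FALSE)) {
  h <- households
  perception <- (rescale_ordinal(h$perception_planting_regulation, 5) +
                 rescale_ordinal(h$perception_fuelwood_regulation, 5)) / 2
  belief <- update_belief(prior_belief, perception, smoothing)
  imp <- pattern_importance(cbind(h$UA_cropland, h$UA_fuelwood),
                            cbind(h$I_cropland, h$I_fuelwood))
  scores <- factor_scores(h, belief)
  fin <- final_decision(imp$importance, scores, salience,
                        suppressive = suppressive)
  gate <- ifelse(imp$no_utilization, 0,
                 ifelse(rowSums(imp$importance) > 0,
                        rowSums(fin) / pmax(rowSums(imp$importance), 1e-300), 0))

  # utilization magnitude relative to the regional norm (both groups pooled)
  mag <- function(ua) pmin(1, ua / (2 * mean(ua)))
  mag_crop <- mag(h$UA_cropland)
  mag_fuel <- mag(h$UA_fuelwood)

  data.frame(
    household_id = h$household_id,
    community_id = h$community_id,
    age_group = classify_age_group(h$primary_laborer_age, age_threshold),
    belief = belief,
    no_utilization = imp$no_utilization,
    importance_cropland = imp$importance[, 1],
    importance_fuelwood = imp$importance[, 2],
    gate = gate,
    final_cropland = fin[, 1],
    final_fuelwood = fin[, 2],
    intensity_state_cropland = imp$importance[, 1] * mag_crop,
    intensity_state_fuelwood = imp$importance[, 2] * mag_fuel,
    intensity_next_cropland = fin[, 1] * mag_crop,
    intensity_next_fuelwood = fin[, 2] * mag_fuel,
    stringsAsFactors = FALSE
  )
}

#' Community utilization decision layers
#'
#' Aggregates the current-period and next-period utilization intensities to
#' community x age-group level, producing the state value and the
#' state-to-next increment of the two utilization decision indexes.
#'
#' @param decisions Output of [decide_households()].
#' @param weights Optional weighting column, see [aggregate_to_community()].
#' @return A `data.frame` with `x1_state`, `x1_next`, `x2_state`, `x2_next`
#'   per community x age group.
#' @export
community_decision_layers <- function(decisions, weights = NULL) {
  agg <- aggregate_to_community(decisions,
    cols = c(x1_state = "intensity_state_cropland",
             x1_next = "intensity_next_cropland",
             x2_state = "intensity_state_fuelwood",
             x2_next = "intensity_next_fuelwood"),
    weights = weights)
  agg
}

#' Community mean perceptions per age group
#'
#' Group-specific community means of the two regulation-intensity
#' perceptions, on their original 1--5 scale; these feed the constraint
#' dimension of the index matrix.
#'
#' @param households Table from [generate_households()].
#' @param age_threshold OAG/YAG classification threshold in years.
#' @return A `data.frame` with `community_id`, `age_group`, `x6`
#'   (planting-regulation perception), `x7` (fuelwood-regulation
#'   perception).
#' @export
summarize_perceptions <- function(households, age_threshold = 55) {
  h <- households
  h$age_group <- classify_age_group(h$primary_laborer_age, age_threshold)
  agg <- aggregate_to_community(
    data.frame(community_id = h$community_id, age_group = h$age_group,
               x6 = h$perception_planting_regulation,
               x7 = h$perception_fuelwood_regulation,
               stringsAsFactors = FALSE),
    cols = c(x6 = "x6", x7 = "x7"))
  agg[, c("community_id", "age_group", "x6", "x7")]
}
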