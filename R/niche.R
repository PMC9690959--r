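# Ecological niche evaluation: 4-dimension / 14-index community matrix,
# standardization, coefficient-of-variation weights, state + potential
# adjusted values, relative and comprehensive niche widths, and niche
# overlap with old-age vs young-adult group comparison.

#' Index metadata for the niche evaluation matrix
#'
#' The 14 measurement indexes and their four dimensions:
#' `X1` resource-utilization strength (x1 cropland decision, x2 fuelwood
#' decision), `X2` resource-utilization support (x3 available cultivated
#' land share, x4 available fuelwood land share, x5 practitioner share),
#' `X3` resource-utilization constraints (x6--x7 regulation perceptions,
#' x8--x10 resource-use change rates), `X4` giant panda sustainable habitat
#' (x11 habitat change rate, x12 population change rate, x13 bamboo area
#' share, x14 bamboo per panda). `direction` is `-1` for indexes where a
#' larger value means more pressure on habitat (the two utilization
#' decisions) and `+1` otherwise.
#'
#' @return A `data.frame` with columns `index`, `dimension`, `direction`.
#' @export
index_metadata <- function() {
  data.frame(
    index = paste0("x", 1:14),
    dimension = c("X1", "X1", "X2", "X2", "X2",
                  "X3", "X3", "X3", "X3", "X3", "X4", "X4", "X4", "X4"),
    direction = c(-1, -1, rep(1, 12)),
    stringsAsFactors = FALSE
  )
}

#' Build the community x age-group index matrix
#'
#' Assembles the 14-index evaluation matrix with a state layer (2013
#' values) and a potential layer (2013-to-2018 increment) for every
#' evaluation unit (community x age group):
#' * x1, x2 from the aggregated utilization decisions (state and
#'   next-period increment);
#' * x3 = AACL/TACL, x4 = AAFL/TAFL, x5 = LFQH/TPR at both years;
#' * x6, x7 group-specific community mean perceptions (potential 0, single
#'   cross-section);
#' * x8--x10 community change-rate fields at both years;
#' * x11 = (AGPH4th - AGPH3rd)/AGPH3rd, x12 = (PGPH4th - PGPH3rd)/PGPH3rd,
#'   x13 = ASFB/ANR, x14 = ASFB/PGPH4th, reserve-level values broadcast to
#'   member communities (potential 0, the change rate is itself the index).
#'
#' Community/group cells without member households are dropped with a
#' warning.
#'
#' @param community_decisions Output of [community_decision_layers()].
#' @param communities Table from [generate_communities()].
#' @param panda_survey Table from [generate_panda_survey()].
#' @param perceptions Output of [summarize_perceptions()].
#' @return An object of class `panda_index_matrix`: a list with `rows`
#'   (community, reserve, age group), numeric matrices `state` and
#'   `potential` (rows x 14), and `meta` ([index_metadata()]).
#' @export
build_index_matrix <- function(community_decisions, communities,
                               panda_survey, perceptions) {
  meta <- index_metadata()
  req <- function(ok, index, where) {
    if (any(!ok)) {
      stop(sprintf("data error: zero denominator for %s in %s", index,
                   paste(where[!ok], collapse = ", ")), call. = FALSE)
    }
  }
  cm <- communities
  req(cm$TACL_2013 > 0 & cm$TACL_2018 > 0, "x3", cm$community_id)
  req(cm$TAFL_2013 > 0 & cm$TAFL_2018 > 0, "x4", cm$community_id)
  req(cm$TPR_2013 > 0 & cm$TPR_2018 > 0, "x5", cm$community_id)
  ps <- panda_survey
  req(ps$AGPH3rd > 0, "x11", ps$reserve_id)
  req(ps$PGPH3rd > 0, "x12", ps$reserve_id)
  req(ps$ANR > 0, "x13", ps$reserve_id)
  req(ps$PGPH4th > 0, "x14", ps$reserve_id)

  rows <- merge(community_decisions, perceptions,
                by = c("community_id", "age_group"), all.x = TRUE)
  keep <- !is.na(rows$x1_state) & !is.na(rows$x6)
  if (any(!keep)) {
    warning(sprintf("dropping %d community/group cells with no households",
                    sum(!keep)))
    rows <- rows[keep, , drop = FALSE]
  }
  rows <- merge(rows, cm, by = "community_id")
  rows <- merge(rows, ps, by = "reserve_id")
  rows <- rows[order(rows$community_id, rows$age_group), , drop = FALSE]

  n <- nrow(rows)
  state <- potential <- matrix(0, n, 14,
                               dimnames = list(NULL, meta$index))
  state[, "x1"] <- rows$x1_state
  potential[, "x1"] <- rows$x1_next - rows$x1_state
  state[, "x2"] <- rows$x2_state
  potential[, "x2"] <- rows$x2_next - rows$x2_state
  state[, "x3"] <- rows$AACL_2013 / rows$TACL_2013
  potential[, "x3"] <- rows$AACL_2018 / rows$TACL_2018 - state[, "x3"]
  state[, "x4"] <- rows$AAFL_2013 / rows$TAFL_2013
  potential[, "x4"] <- rows$AAFL_2018 / rows$TAFL_2018 - state[, "x4"]
  state[, "x5"] <- rows$LFQH_2013 / rows$TPR_2013
  potential[, "x5"] <- rows$LFQH_2018 / rows$TPR_2018 - state[, "x5"]
  state[, "x6"] <- rows$x6
  state[, "x7"] <- rows$x7
  for (j in c("x8", "x9", "x10")) {
    state[, j] <- rows[[paste0(j, "_2013")]]
    potential[, j] <- rows[[paste0(j, "_2018")]] - state[, j]
  }
  state[, "x11"] <- (rows$AGPH4th - rows$AGPH3rd) / rows$AGPH3rd
  state[, "x12"] <- (rows$PGPH4th - rows$PGPH3rd) / rows$PGPH3rd
  state[, "x13"] <- rows$ASFB / rows$ANR
  state[, "x14"] <- rows$ASFB / rows$PGPH4th

  structure(list(
    rows = data.frame(community_id = rows$community_id,
                      reserve_id = rows$reserve_id,
                      age_group = rows$age_group,
                      stringsAsFactors = FALSE),
    state = state, potential = potential, meta = meta
  ), class = "panda_index_matrix")
}

#' Z-score standardization of index columns
#'
#' Centers and scales each column to mean 0 and sample standard deviation 1
#' (denominator `n - 1`).
#'
#' @param x Numeric matrix or data frame with at least two rows.
#' @return A matrix of standardized values.
#' @examples
#' standardize_indexes(cbind(a = c(2, 4, 6)))  # -1 0 1
#' @export
standardize_indexes <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("data error: need at least 2 rows", call. = FALSE)
  if (anyNA(x)) stop("data error: missing values in index matrix",
                     call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  bad <- sds <= 0 | !is.finite(sds)
  if (any(bad)) {
    stop("degenerate column: zero variance in ",
         paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Coefficient-of-variation index weights
#'
#' Per-index weights from the coefficient of variation of the raw adjusted
#' columns: `V_j = sd_j / |mean_j|`, normalized to `W_j = V_j / sum(V)`.
#' Dimension weights are the sums of their member-index weights (already
#' normalized across all 14 indexes). Computed on the pre-rescaling
#' adjusted values; a z-scored column would have mean 0 and an undefined
#' coefficient of variation.
#'
#' @param x Numeric matrix of raw adjusted index values (rows = evaluation
#'   units).
#' @param meta Index metadata; defaults to [index_metadata()] restricted to
#'   the columns of `x`.
#' @return A list with `V`, `W` (named per index, `sum(W) == 1`) and `w_d`
#'   (named per dimension, `sum(w_d) == 1`).
#' @examples
#' compute_weights(cbind(a = c(1, 2, 3), b = c(2, 2.5, 3)))
#' @export
compute_weights <- function(x, meta = NULL) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  if (any(abs(mu) < 1e-9)) {
    stop("weight undefined: column mean is zero for ",
         paste(colnames(x)[abs(mu) < 1e-9], collapse = ", "), call. = FALSE)
  }
  V <- apply(x, 2, stats::sd) / abs(mu)
  W <- V / sum(V)
  if (is.null(meta)) {
    m <- index_metadata()
    meta <- m[m$index %in% colnames(x), , drop = FALSE]
  }
  if (!is.null(colnames(x)) && all(colnames(x) %in% meta$index)) {
    dim_of <- meta$dimension[match(colnames(x), meta$index)]
    w_d <- tapply(W, dim_of, sum)
    w_d <- stats::setNames(as.numeric(w_d), names(w_d))
  } else {
    w_d <- NULL
  }
  list(V = V, W = W, w_d = w_d)
}

#' State-plus-potential adjusted index values
#'
#' The absolute niche value of an evaluation unit on index `j` is
#' `R = S + A * (P / period_years)`: the current state plus the annualized
#' potential (increment) scaled by the conversion coefficient `A` (the
#' dimensional transformation window is one year). Columns are then
#' min--max rescaled to `[eps, 1]` so every value is strictly positive, as
#' the width and overlap formulas require; for negative-direction indexes
#' (larger value = more habitat pressure) the rescaling is reversed when
#' `apply_direction` is `TRUE`. `rescale = "zscore_shifted"` instead shifts
#' the z-scored column by its minimum plus `eps`.
#'
#' @param im A `panda_index_matrix`, or a list with `state`, `potential`
#'   and `meta` entries.
#' @param A Conversion coefficient per index, scalar or length-14.
#' @param period_years Observation window used to annualize the potential.
#' @param rescale `"minmax"` (default), `"zscore_shifted"`, or `"none"`
#'   (raw adjusted values, no positivity guarantee).
#' @param apply_direction Reverse the rescaling of negative-direction
#'   columns (used for the habitat-level width evaluation); set `FALSE` to
#'   keep the utilization orientation (used for the resource-use overlap
#'   profiles).
#' @param eps Lower bound of the rescaled range.
#' @param on_constant `"error"` raises a degenerate-column error when a
#'   column has `max == min`; `"uniform"` maps such a column to all ones.
#' @return A list with `raw` (adjusted values before rescaling), `scaled`,
#'   and `meta`.
#' @export
adjusted_values <- function(im, A = 1, period_years = 5,
                            rescale = c("minmax", "zscore_shifted", "none"),
                            apply_direction = TRUE, eps = 1e-6,
                            on_constant = c("error", "uniform")) {
  rescale <- match.arg(rescale)
  on_constant <- match.arg(on_constant)
  S <- as.matrix(im$state)
  P <- as.matrix(im$potential)
  stopifnot(identical(dim(S), dim(P)))
  A <- rep_len(A, ncol(S))
  raw <- S + sweep(P, 2, A / period_years, `*`)
  meta <- im$meta
  dir <- if (!is.null(meta)) meta$direction[match(colnames(raw), meta$index)]
         else rep(1, ncol(raw))
  dir[is.na(dir)] <- 1
  if (!apply_direction) dir <- rep(1, ncol(raw))

  scaled <- raw
  if (rescale != "none") {
    for (j in seq_len(ncol(raw))) {
      x <- raw[, j]
      if (rescale == "zscore_shifted") {
        s <- stats::sd(x)
        if (s <= 0) {
          if (on_constant == "error") {
            stop("degenerate column: constant adjusted values in ",
                 colnames(raw)[j], call. = FALSE)
          }
          scaled[, j] <- 1
          next
        }
        z <- (x - mean(x)) / s
        if (dir[j] < 0) z <- -z
        scaled[, j] <- z - min(z) + eps
      } else {
        rngj <- range(x)
        if (diff(rngj) <= 0) {
          if (on_constant == "error") {
            stop("degenerate column: constant adjusted values in ",
                 colnames(raw)[j], call. = FALSE)
          }
          scaled[, j] <- 1
          next
        }
        u <- (x - rngj[1]) / diff(rngj)
        if (dir[j] < 0) u <- 1 - u
        scaled[, j] <- eps + (1 - eps) * u
      }
    }
  }
  list(raw = raw, scaled = scaled, meta = meta)
}

#' Relative ecological niche width of one dimension
#'
#' For each index `k`, an evaluation unit's share is its adjusted value
#' divided by the sum of adjusted values over all units. The relative niche
#' width of dimension `d` for unit `i` is the weighted average of its
#' member-index shares, `N_d(i) = sum_{k in d} (W_k / w_d) * share_ik`, so
#' widths are in `(0, 1)` and sum to 1 over units within every dimension.
#'
#' @param scaled Strictly positive matrix of rescaled adjusted values.
#' @param weights Output of [compute_weights()].
#' @param dimension Dimension id, e.g. `"X1"`.
#' @param meta Index metadata, defaults to [index_metadata()].
#' @return Numeric vector of widths, one per row of `scaled`.
#' @export
relative_niche_width <- function(scaled, weights, dimension,
                                 meta = index_metadata()) {
  idx <- meta$index[meta$dimension == dimension]
  idx <- intersect(idx, colnames(scaled))
  if (length(idx) == 0) {
    stop("spec error: dimension ", dimension, " has no indexes", call. = FALSE)
  }
  stopifnot(all(scaled[, idx] > 0))
  shares <- sweep(scaled[, idx, drop = FALSE], 2,
                  colSums(scaled[, idx, drop = FALSE]), `/`)
  wk <- weights$W[idx]
  if (sum(wk) == 0) {
    # dimension carries no discriminating information (all member indexes
    # have zero variation): every unit holds an equal share
    return(rep(1 / nrow(shares), nrow(shares)))
  }
  as.vector(shares %*% (wk / sum(wk)))
}

#' Comprehensive ecological niche width
#'
#' The dimension-weighted aggregate of the four relative niche widths,
#' `M_i = sum_d N_d(i) * w_d`. Because each dimension's widths sum to 1
#' across evaluation units and the dimension weights sum to 1, `M` also
#' sums to 1 across units.
#'
#' @param N Matrix of per-dimension widths (rows = units, columns =
#'   dimensions).
#' @param w_d Named dimension weights summing to 1.
#' @return Numeric vector of comprehensive widths.
#' @examples
#' comprehensive_niche(rbind(c(0.1, 0.2, 0.3, 0.4)),
#'                     c(X1 = .25, X2 = .25, X3 = .25, X4 = .25))
#' @export
comprehensive_niche <- function(N, w_d) {
  N <- rbind(N)
  if (!is.null(colnames(N)) && !is.null(names(w_d))) {
    if (!all(colnames(N) %in% names(w_d))) {
      stop("data error: missing dimension weight for ",
           paste(setdiff(colnames(N), names(w_d)), collapse = ", "),
           call. = FALSE)
    }
    w_d <- w_d[colnames(N)]
  }
  stopifnot(ncol(N) == length(w_d))
  as.vector(N %*% w_d)
}

#' Ecological niche overlap (Pianka cosine form)
#'
#' The overlap of two evaluation units is the cosine similarity of their
#' resource-ownership profiles: with `P_ij` the share of resource `i` in
#' unit `j`'s profile,
#' `O_jk = sum_i(P_ij * P_ik) / sqrt(sum_i P_ij^2 * sum_i P_ik^2)`.
#' The value lies in `[0, 1]`, is symmetric, and equals 1 for identical
#' profiles. Profiles are row-normalized to sum to 1 first (the cosine is
#' invariant to that scaling). A zero profile yields `NA` (undefined
#' overlap).
#'
#' @param profile_j,profile_k Non-negative resource profiles of equal
#'   length.
#' @return The overlap value, or `NA_real_` for a zero profile.
#' @examples
#' niche_overlap(c(1, 0), c(0.5, 0.5))  # 0.7071
#' @export
niche_overlap <- function(profile_j, profile_k) {
  stopifnot(length(profile_j) == length(profile_k),
            all(profile_j >= 0), all(profile_k >= 0))
  sj <- sum(profile_j)
  sk <- sum(profile_k)
  if (sj == 0 || sk == 0) return(NA_real_)
  pj <- profile_j / sj
  pk <- profile_k / sk
  min(1, sum(pj * pk) / sqrt(sum(pj^2) * sum(pk^2)))
}

#' Pairwise niche overlap matrix
#'
#' @param profiles Non-negative matrix, one profile per row.
#' @return Symmetric matrix of overlaps with unit diagonal (rows with a
#'   zero profile give `NA`).
#' @export
overlap_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  O <- matrix(NA_real_, n, n, dimnames = list(rownames(profiles),
                                              rownames(profiles)))
  for (j in seq_len(n)) {
    for (k in j:n) {
      O[j, k] <- O[k, j] <- niche_overlap(profiles[j, ], profiles[k, ])
    }
  }
  O
}

#' OAG/YAG overlap ratio and its sign classification
#'
#' The ratio of the old-age group's overlap to the young-adult group's
#' overlap for the same community pair. A ratio in `(0, 1)` is a positive
#' difference (aging reduces ecological competition), a ratio in
#' `(1, +Inf)` a negative difference; a ratio of exactly 1, a zero
#' young-adult overlap, or a missing overlap is undefined.
#'
#' @param o_oag,o_yag Overlap values in `[0, 1]`; vectorized.
#' @return A `data.frame` with `ratio` and `classification` (one of
#'   `"positive"`, `"negative"`, `"undefined"`).
#' @examples
#' overlap_ratio(0.4, 0.5)  # ratio 0.8, positive
#' @export
overlap_ratio <- function(o_oag, o_yag) {
  stopifnot(length(o_oag) == length(o_yag))
  ratio <- ifelse(!is.na(o_yag) & o_yag > 0, o_oag / o_yag, NA_real_)
  classification <- ifelse(is.na(ratio), "undefined",
                    ifelse(ratio < 1, "positive",
                    ifelse(ratio > 1, "negative", "undefined")))
  data.frame(ratio = ratio, classification = classification,
             stringsAsFactors = FALSE)
}

#' Evaluate niche widths and overlaps from an index matrix
#'
#' Runs the full niche evaluation: forms adjusted values, computes
#' coefficient-of-variation weights on the raw adjusted columns,
#' habitat-level (direction-adjusted) widths per dimension and the
#' comprehensive width for every community x age-group unit, and niche
#' overlaps between neighboring communities within each age group on the
#' utilization-oriented profiles, together with the OAG/YAG overlap ratio.
#'
#' @param im A `panda_index_matrix` from [build_index_matrix()].
#' @param adjacency Adjacency table with columns `community_a`,
#'   `community_b`; ignored when `all_pairs` is `TRUE`.
#' @param A Conversion coefficient, see [adjusted_values()].
#' @param period_years Observation window in years.
#' @param standardization Rescaling used for the niche computations, one of
#'   `"minmax"` or `"zscore_shifted"`.
#' @param all_pairs Compute overlaps for every community pair instead of
#'   the adjacency list.
#' @param on_constant Degenerate-column handling, see [adjusted_values()].
#' @return A list of class `panda_niche` with `widths` (per unit: `N_X1`
#'   .. `N_X4`, `M`), `overlaps` (per pair: per-group overlap, ratio,
#'   classification), `weights`, `standardized` (z-scored adjusted values,
#'   reported for reference), and `adjusted`.
#' @export
evaluate_niche <- function(im, adjacency = NULL, A = 1, period_years = 5,
                           standardization = c("minmax", "zscore_shifted"),
                           all_pairs = FALSE,
                           on_constant = c("error", "uniform")) {
  standardization <- match.arg(standardization)
  on_constant <- match.arg(on_constant)
  adj <- adjusted_values(im, A = A, period_years = period_years,
                         rescale = standardization, apply_direction = TRUE,
                         on_constant = on_constant)
  weights <- compute_weights(adj$raw, meta = im$meta)
  dims <- unique(im$meta$dimension)
  N <- sapply(dims, function(d) {
    relative_niche_width(adj$scaled, weights, d, meta = im$meta)
  })
  N <- matrix(N, ncol = length(dims), dimnames = list(NULL, dims))
  M <- comprehensive_niche(N, weights$w_d)
  widths <- cbind(im$rows,
                  stats::setNames(as.data.frame(N), paste0("N_", dims)),
                  M = M)

  # overlap on utilization-oriented profiles
  prof <- adjusted_values(im, A = A, period_years = period_years,
                          rescale = standardization, apply_direction = FALSE,
                          on_constant = on_constant)$scaled
  overlaps <- compute_pair_overlaps(prof, im$rows, adjacency, all_pairs)

  std <- tryCatch(standardize_indexes(adj$raw), error = function(e) NULL)
  structure(list(widths = widths, overlaps = overlaps, weights = weights,
                 standardized = std, adjusted = adj),
            class = "panda_niche")
}

compute_pair_overlaps <- function(profiles, rows, adjacency, all_pairs) {
  comms <- sort(unique(rows$community_id))
  if (all_pairs) {
    if (length(comms) < 2) {
      pairs <- data.frame(community_a = character(),
                          community_b = character(),
                          stringsAsFactors = FALSE)
    } else {
      cmb <- utils::combn(comms, 2)
      pairs <- data.frame(community_a = cmb[1, ], community_b = cmb[2, ],
                          stringsAsFactors = FALSE)
    }
  } else if (is.null(adjacency) || nrow(adjacency) == 0) {
    pairs <- data.frame(community_a = character(), community_b = character(),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- adjacency[, c("community_a", "community_b")]
  }
  if (nrow(pairs) == 0) {
    return(data.frame(community_a = character(), community_b = character(),
                      O_OAG = numeric(), O_YAG = numeric(),
                      ratio = numeric(), classification = character(),
                      stringsAsFactors = FALSE))
  }
  get_profile <- function(comm, grp) {
    i <- which(rows$community_id == comm & rows$age_group == grp)
    if (length(i) != 1) return(NULL)
    profiles[i, ]
  }
  ov <- function(comm_a, comm_b, grp) {
    pa <- get_profile(comm_a, grp)
    pb <- get_profile(comm_b, grp)
    if (is.null(pa) || is.null(pb)) return(NA_real_)
    niche_overlap(pa, pb)
  }
  pairs$O_OAG <- mapply(ov, pairs$community_a, pairs$community_b,
                        MoreArgs = list(grp = "OAG"))
  pairs$O_YAG <- mapply(ov, pairs$community_a, pairs$community_b,
                        MoreArgs = list(grp = "YAG"))
  rc <- overlap_ratio(pairs$O_OAG, pairs$O_YAG)
  pairs$ratio <- rc$ratio
  pairs$classification <- rc$classification
  rownames(pairs) <- NULL
  pairs
}
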