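# Group-delocalization trajectory analysis: aggregate per-pair
# delocalization predictions into group-group time series, detect binding
# events as prominent interior extrema, match electronic against
# geometric events within a time tolerance, and rank the dominant
# pairwise contributions behind a contact.
#
# A binding event is an interior local maximum of the (bin-averaged)
# group-group delocalization series; the geometric counterpart is a local
# minimum of the center-of-mass distance. An electronic event with no
# geometric partner within the tolerance flags an orientation-driven
# contact that plain distances cannot see.

#' Infer the atom count from a canonical pair-array length
#' @param n_delta length of a 2P array.
#' @return M with M(M-1)/2 == n_delta.
#' @keywords internal
#' @noRd
.M_from_pairs <- function(n_delta) {
  M <- (1 + sqrt(1 + 8 * n_delta)) / 2
  if (abs(M - round(M)) > 1e-9) {
    stop("length ", n_delta, " is not a valid pair-array length M(M-1)/2")
  }
  as.integer(round(M))
}

#' Group-group delocalization
#'
#' `delta(G1, G2) = sum_{i in G1} sum_{j in G2} delta(i, j)`, reading each
#' unordered pair once. Exactly bilinear-additive over disjoint group
#' partitions; the group value is not learned, it is the sum of the
#' physically additive pairwise outputs.
#'
#' @param delta length-M(M-1)/2 vector in canonical pair order.
#' @param G1,G2 disjoint sets of 1-based atom indices.
#' @param M atom count (default inferred from `length(delta)`).
#' @return scalar group delocalization (electrons).
#' @export
group_delocalization <- function(delta, G1, G2, M = .M_from_pairs(length(delta))) {
  G1 <- as.integer(G1); G2 <- as.integer(G2)
  if (length(G1) == 0L || length(G2) == 0L) stop("groups must be non-empty")
  if (length(intersect(G1, G2)) > 0L) {
    stop("groups overlap; inter-group delocalization is undefined for shared atoms")
  }
  if (any(c(G1, G2) < 1L) || any(c(G1, G2) > M)) stop("atom index out of range")
  grid <- expand.grid(i = G1, j = G2)
  sum(delta[pair_flat_index(grid$i, grid$j, M)])
}

#' Center-of-mass distance between two atom groups
#'
#' @param mol a `molecule` (one trajectory frame).
#' @param G1,G2 non-empty sets of 1-based atom indices.
#' @param masses per-atom masses (amu) for the whole molecule; defaults
#'   to standard atomic masses of the elements present.
#' @return Euclidean distance between the mass-weighted centroids, Angstrom.
#' @export
center_of_mass_distance <- function(mol, G1, G2, masses = NULL) {
  if (length(G1) == 0L || length(G2) == 0L) stop("groups must be non-empty")
  if (is.null(masses)) masses <- .param_mass(mol$Z)
  com <- function(idx) {
    w <- masses[idx]
    colSums(mol$R[idx, , drop = FALSE] * w) / sum(w)
  }
  sqrt(sum((com(as.integer(G1)) - com(as.integer(G2)))^2))
}

#' Construct a trajectory series
#'
#' @param times strictly increasing time stamps, fs.
#' @param values per-frame scalar values (electrons for delocalization
#'   series, Angstrom for distance series).
#' @param label series label (e.g. `"CO2:NH2_1"`).
#' @param kind `"electronic"` or `"geometric"`.
#' @return object of class `trajectory_series`.
#' @export
trajectory_series <- function(times, values, label = "",
                              kind = c("electronic", "geometric")) {
  kind <- match.arg(kind)
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("series values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label, kind = kind),
            class = "trajectory_series")
}

#' Build the group-delocalization series of a trajectory
#'
#' @param deltas list of per-frame canonical delta vectors (predicted or
#'   reference).
#' @param times frame times, fs.
#' @param G1,G2 disjoint atom index sets.
#' @param label series label.
#' @return a `trajectory_series` of kind "electronic".
#' @export
group_delta_series <- function(deltas, times, G1, G2, label = "") {
  values <- vapply(deltas, group_delocalization, numeric(1), G1 = G1, G2 = G2)
  trajectory_series(times, values, label, "electronic")
}

#' Build the center-of-mass distance series of a trajectory
#'
#' @param frames list of `molecule` frames.
#' @param times frame times, fs.
#' @param G1,G2 atom index sets.
#' @param label series label.
#' @param masses optional per-atom masses.
#' @return a `trajectory_series` of kind "geometric".
#' @export
com_distance_series <- function(frames, times, G1, G2, label = "",
                                masses = NULL) {
  values <- vapply(frames, center_of_mass_distance, numeric(1),
                   G1 = G1, G2 = G2, masses = masses)
  trajectory_series(times, values, label, "geometric")
}

#' Bin-average a trajectory series
#'
#' Non-overlapping consecutive bins of fixed width; the output time is
#' the bin midpoint and the value the arithmetic mean of the in-bin
#' values. A trailing partial bin is kept.
#'
#' @param series a `trajectory_series`.
#' @param width bin width, fs (> the time step).
#' @return a `trajectory_series` on the binned grid.
#' @export
bin_average <- function(series, width) {
  stopifnot(inherits(series, "trajectory_series"))
  if (width <= 0) stop("bin width must be > 0")
  step <- min(diff(series$times))
  if (width < step) {
    stop("bin width ", width, " fs is smaller than the time step ", step, " fs")
  }
  t0 <- series$times[1]
  bin <- floor((series$times - t0) / width)
  lev <- unique(bin)             # already increasing; keep numeric order
  mid <- t0 + (lev + 0.5) * width
  vals <- as.numeric(tapply(series$values, factor(bin, levels = lev), mean))
  trajectory_series(mid, vals, series$label, series$kind)
}

# Strict interior local maxima of v with topographic prominence.
.find_peaks <- function(v) {
  n <- length(v)
  if (n < 3L) return(data.frame(index = integer(0), prominence = numeric(0)))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  prom <- vapply(idx, function(p) {
    # walk left/right until a strictly higher point; prominence is the
    # peak height above the higher of the two valley floors encountered
    left <- v[seq_len(p - 1L)]
    higher_l <- which(left > v[p])
    base_l <- if (length(higher_l)) min(v[(max(higher_l) ):p]) else min(left)
    right <- v[(p + 1L):n]
    higher_r <- which(right > v[p])
    base_r <- if (length(higher_r)) min(v[p:(p + min(higher_r))]) else min(right)
    v[p] - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Detect binding events in a trajectory series
#'
#' Electronic events are prominent interior local maxima of the
#' delocalization series; geometric events are local minima of the
#' center-of-mass distance (detected as maxima of the negated series with
#' the same prominence rule). Events closer than `min_separation` are
#' merged, keeping the more prominent (earlier on ties).
#'
#' @param series a `trajectory_series` (length >= 3); typically
#'   bin-averaged first (see [bin_average()]).
#' @param min_prominence minimum peak prominence, in the series' value
#'   unit; default 10 percent of the series range.
#' @param min_separation minimum time separation between reported events,
#'   fs.
#' @return an `event_table` data.frame with columns `time`, `value`,
#'   `kind`, `prominence`.
#' @export
detect_events <- function(series, min_prominence = NULL, min_separation = 50) {
  stopifnot(inherits(series, "trajectory_series"))
  if (length(series$values) < 3L) stop("series too short for event detection")
  v <- if (series$kind == "geometric") -series$values else series$values
  if (is.null(min_prominence)) {
    min_prominence <- 0.1 * diff(range(v))
  }
  pk <- .find_peaks(v)
  pk <- pk[pk$prominence >= min_prominence & pk$prominence > 0, , drop = FALSE]
  pk <- pk[order(series$times[pk$index]), , drop = FALSE]
  # merge events closer than min_separation, keeping the more prominent
  keep <- logical(nrow(pk))
  if (nrow(pk) > 0L) {
    ord <- order(-pk$prominence, series$times[pk$index])
    taken <- numeric(0)
    for (k in ord) {
      tk <- series$times[pk$index[k]]
      if (all(abs(taken - tk) >= min_separation)) {
        keep[k] <- TRUE
        taken <- c(taken, tk)
      }
    }
  }
  pk <- pk[keep, , drop = FALSE]
  out <- data.frame(time = series$times[pk$index],
                    value = series$values[pk$index],
                    kind = rep(series$kind, nrow(pk)),
                    prominence = pk$prominence)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Match electronic and geometric event tables
#'
#' Greedy nearest-time one-to-one matching: candidate pairs are examined
#' in order of increasing time offset (ties toward the earlier event) and
#' accepted while both members are unmatched and the offset is within the
#' tolerance. Unmatched events are labeled `"electronic-only"` /
#' `"geometric-only"`.
#'
#' @param electronic,geometric `event_table`s over the same time span.
#' @param tolerance matching tolerance, fs (default 10).
#' @return data.frame with columns `time`, `value`, `kind`, `status`,
#'   `matched_time`; the fraction of events matched
#'   (2 * pairs / total events) is attached as attribute
#'   `match_fraction`.
#' @export
match_events <- function(electronic, geometric, tolerance = 10) {
  ne <- nrow(electronic); ng <- nrow(geometric)
  match_e <- rep(NA_real_, ne); match_g <- rep(NA_real_, ng)
  if (ne > 0L && ng > 0L) {
    cand <- expand.grid(e = seq_len(ne), g = seq_len(ng))
    cand$dt <- abs(electronic$time[cand$e] - geometric$time[cand$g])
    cand <- cand[cand$dt <= tolerance, , drop = FALSE]
    cand <- cand[order(cand$dt, electronic$time[cand$e]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      e <- cand$e[r]; g <- cand$g[r]
      if (is.na(match_e[e]) && is.na(match_g[g])) {
        match_e[e] <- geometric$time[g]
        match_g[g] <- electronic$time[e]
      }
    }
  }
  rows_e <- if (ne > 0L) data.frame(
    time = electronic$time, value = electronic$value, kind = "electronic",
    status = ifelse(is.na(match_e), "electronic-only", "both"),
    matched_time = match_e) else NULL
  rows_g <- if (ng > 0L) data.frame(
    time = geometric$time, value = geometric$value, kind = "geometric",
    status = ifelse(is.na(match_g), "geometric-only", "both"),
    matched_time = match_g) else NULL
  out <- rbind(rows_e, rows_g)
  if (is.null(out)) {
    out <- data.frame(time = numeric(0), value = numeric(0),
                      kind = character(0), status = character(0),
                      matched_time = numeric(0))
  }
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  n_pairs_matched <- sum(!is.na(match_e))
  attr(out, "match_fraction") <- if (ne + ng > 0L) {
    2 * n_pairs_matched / (ne + ng)
  } else NA_real_
  out
}

#' Rank the pairwise contributions dominating a group-group contact
#'
#' Inter-group pairs sorted by delocalization, descending; ties broken by
#' lexicographic (i, j) order. Shares are relative to the group total and
#' sum to 1 over the full inter-group list when the total is positive.
#'
#' @param delta canonical per-pair delocalization vector.
#' @param G1,G2 disjoint atom index sets.
#' @param k number of top contributions to return (>= 1).
#' @param M atom count (default inferred).
#' @return data.frame with columns `i`, `j`, `delta`, `share`, at most
#'   `k` rows; attribute `zero_total` is `TRUE` when the group total is
#'   not positive (empty table, not an error).
#' @export
dominant_pair_contributions <- function(delta, G1, G2, k = 5L,
                                        M = .M_from_pairs(length(delta))) {
  if (k < 1L) stop("k must be >= 1")
  G1 <- as.integer(G1); G2 <- as.integer(G2)
  if (length(intersect(G1, G2)) > 0L) stop("groups overlap")
  grid <- expand.grid(a = G1, b = G2)
  i <- pmin(grid$a, grid$b); j <- pmax(grid$a, grid$b)
  d <- delta[pair_flat_index(i, j, M)]
  total <- sum(d)
  if (total <= 0) {
    out <- data.frame(i = integer(0), j = integer(0), delta = numeric(0),
                      share = numeric(0))
    attr(out, "zero_total") <- TRUE
    return(out)
  }
  keep <- d > 0          # zero-valued pairs carry no share
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  ord <- order(-d, i, j)
  out <- data.frame(i = i[ord], j = j[ord], delta = d[ord],
                    share = d[ord] / total)
  attr(out, "zero_total") <- FALSE
  utils::head(out, k)
}
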