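# Surrogate-label generator: synthetic molecules with physically
# consistent one- and two-body labels that are closed under the same sum
# rules as the real-space reference quantities they stand in for.
#
#   * charges: exact electronegativity-equalization solve with a total
#     charge constraint -> sum(q) = 0 to machine precision;
#   * electron structure: distance-decaying bond orders delta_ij with
#     lambda_A = N_A - 1/2 sum_B delta_AB, so the electron-count sum rule
#     holds by construction;
#   * energies: Coulomb + Born-Mayer pair terms and quadratic atomic
#     self-energies, additive to an exactly stored total.
#
# The functional forms reproduce the qualitative structure of the target
# descriptors (electroneutrality, distance decay of delocalization,
# additive energies) while remaining exactly solvable. They make no claim
# of quantum-chemical accuracy.

.named_by_Z <- function(x) stats::setNames(x, as.character(element_number(names(x))))

#' Surrogate-model parameters
#'
#' All per-element vectors are named by atomic number. Defaults state the
#' benchmark world used across the test suite:
#' * CHON element pool (proportions 0.5/0.3/0.1/0.1 for H/C/N/O),
#'   4-9 atoms per molecule;
#' * electronegativities/hardnesses ordered H < C < N < O so that charge
#'   flows toward O, giving per-atom charges of a few tenths of an
#'   electron;
#' * bond orders `delta_ij = s_i s_j exp(-(r_ij - r0_ij)/kappa)` with
#'   `r0_ij` the sum of covalent radii, clipped to [0, delta_max];
#' * pair energies `q_i q_j / r_ij + a_ij exp(-b r_ij)` (a.u.);
#' * no label noise (`sigma_noise = 0`): records are exactly closed under
#'   the sum rules.
#'
#' @param preset `"chon"` (default) or `"water"` (H/O pool emulating
#'   water-cluster energetics).
#' @param sigma_noise Gaussian label noise added to the local labels
#'   after the exact totals are stored (same unit as each property).
#' @param min_dist minimum allowed interatomic distance, Angstrom.
#' @param box_scale box side is `box_scale * M^(1/3)` Angstrom.
#' @param M_range integer range of atoms per molecule.
#' @return object of class `surrogate_params` (a named list).
#' @export
surrogate_params <- function(preset = c("chon", "water"), sigma_noise = 0,
                             min_dist = 1.5, box_scale = 3.0,
                             M_range = c(4L, 9L)) {
  preset <- match.arg(preset)
  pool <- switch(preset,
                 chon = c(H = 0.5, C = 0.3, N = 0.1, O = 0.1),
                 water = c(H = 2 / 3, O = 1 / 3))
  p <- list(
    preset = preset,
    pool = .named_by_Z(pool),
    M_range = as.integer(M_range),
    chi = .named_by_Z(c(H = 0.30, C = 0.50, N = 0.65, O = 0.80)),
    eta = .named_by_Z(c(H = 2.00, C = 1.60, N = 1.70, O = 1.80)),
    coulomb_gamma = 1.0,
    s = .named_by_Z(c(H = 0.40, C = 0.80, N = 0.75, O = 0.70)),
    rcov = .named_by_Z(c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)),
    kappa = 0.5,
    delta_max = 3.0,
    r_floor = 0.5,
    a_rep = .named_by_Z(c(H = 0.8, C = 1.5, N = 1.4, O = 1.3)),
    b_rep = 2.2,
    e0 = .named_by_Z(c(H = -0.5, C = -37.8, N = -54.6, O = -75.1)),
    sigma_noise = sigma_noise,
    min_dist = min_dist,
    box_scale = box_scale
  )
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  if (min_dist <= 0) stop("min_dist must be > 0")
  structure(p, class = "surrogate_params")
}

#' Screened (Klopman-Ohno) Coulomb kernel
#'
#' `J(r) = 1 / sqrt(r^2 + gamma^2)`: behaves as 1/r at long range and
#' saturates to 1/gamma at short range.
#'
#' @param r distances, Angstrom (vectorized).
#' @param gamma screening length, Angstrom (> 0).
#' @return kernel values.
#' @export
coulomb_kernel <- function(r, gamma = 1.0) {
  if (gamma <= 0) stop("screening length gamma must be > 0")
  1 / sqrt(r^2 + gamma^2)
}

.param_by_Z <- function(vec, Z, what) {
  v <- vec[as.character(Z)]
  if (anyNA(v)) {
    stop("surrogate parameter '", what, "' undefined for element(s): ",
         paste(element_symbol(unique(Z[is.na(v)])), collapse = ", "))
  }
  unname(v)
}

#' Generate a random molecular geometry
#'
#' Elements are drawn from the configured pool and coordinates are
#' rejection-sampled in a cubic box until all pairwise distances exceed
#' the configured minimum.
#'
#' @param params a [surrogate_params()].
#' @param M atom count; if `NULL`, drawn uniformly from `params$M_range`.
#' @param seed optional integer seed (deterministic output if given).
#' @param id molecule id label.
#' @return a `molecule`.
#' @export
generate_geometry <- function(params, M = NULL, seed = NULL, id = "mol") {
  stopifnot(inherits(params, "surrogate_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(M)) M <- sample(params$M_range[1]:params$M_range[2], 1L)
  M <- as.integer(M)
  if (M < 1L) stop("atom count must be >= 1")
  Z <- as.integer(sample(names(params$pool), M, replace = TRUE,
                         prob = params$pool))
  side <- params$box_scale * M^(1 / 3)
  R <- matrix(NA_real_, M, 3)
  for (k in seq_len(M)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      x <- stats::runif(3, 0, side)
      if (k == 1L ||
          all(sqrt(colSums((t(R[seq_len(k - 1L), , drop = FALSE]) - x)^2)) >=
              params$min_dist)) {
        R[k, ] <- x
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place atom ", k, " of ", M, " at min_dist = ",
           params$min_dist, "; increase box_scale")
    }
  }
  molecule(Z, R, id = id)
}

#' Surrogate atomic charges via electronegativity equalization
#'
#' Minimizes `sum_i (chi_i q_i + eta_i q_i^2 / 2) +
#' 1/2 sum_{i != j} q_i q_j J(r_ij)` subject to `sum q = 0`, solved
#' exactly as an (M+1) x (M+1) linear system with a Lagrange multiplier.
#' The Coulomb kernel is screened at short range in the usual
#' Klopman-Ohno form, `J(r) = 1 / sqrt(r^2 + gamma^2)`, which keeps the
#' equalization problem well conditioned at bonding distances (a bare
#' 1/r kernel over-polarizes and can produce multi-electron charges).
#' The constraint makes the molecule electroneutral to machine
#' precision.
#'
#' @param mol a `molecule`.
#' @param params a [surrogate_params()].
#' @return numeric vector of per-atom charges (electrons), summing to 0.
#' @export
surrogate_charges <- function(mol, params) {
  M <- n_atoms(mol)
  chi <- .param_by_Z(params$chi, mol$Z, "chi")
  eta <- .param_by_Z(params$eta, mol$Z, "eta")
  if (M == 1L) return(0)
  J <- matrix(0, M, M)
  pr <- enumerate_pairs(M)
  d <- pair_distances(mol)
  J[cbind(pr$i, pr$j)] <- coulomb_kernel(d, params$coulomb_gamma)
  J <- J + t(J)
  diag(J) <- eta
  A <- rbind(cbind(J, 1), c(rep(1, M), 0))
  rhs <- c(-chi, 0)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop("electronegativity-equalization system is singular: ",
         conditionMessage(e), call. = FALSE)
  })
  q <- sol[seq_len(M)]
  # re-impose the constraint exactly against rounding
  q - mean(q)
}

#' Surrogate electron-count structure (N_A, lambda, delta)
#'
#' Bond orders decay exponentially with distance,
#' `delta_ij = s_i s_j exp(-(r_ij - r0_ij)/kappa)` clipped to
#' `[0, delta_max]`; populations come from the surrogate charges
#' (`N_A = Z_A - q_A`) and `lambda_A = N_A - 1/2 sum_B delta_AB`, so the
#' electron-count sum rule closes by construction.
#'
#' @param mol a `molecule`.
#' @param params a [surrogate_params()].
#' @return list with `N_A`, `lambda` (length M), `delta`
#'   (length M(M-1)/2, canonical order), `Q`.
#' @export
surrogate_electron_structure <- function(mol, params) {
  M <- n_atoms(mol)
  q <- surrogate_charges(mol, params)
  N_A <- mol$Z - q
  if (M == 1L) {
    return(list(N_A = N_A, lambda = N_A, delta = numeric(0), Q = q))
  }
  s <- .param_by_Z(params$s, mol$Z, "s")
  rcov <- .param_by_Z(params$rcov, mol$Z, "rcov")
  pr <- enumerate_pairs(M)
  d <- pair_distances(mol)
  r0 <- rcov[pr$i] + rcov[pr$j]
  delta <- s[pr$i] * s[pr$j] * exp(-(d - r0) / params$kappa)
  delta <- pmin(pmax(delta, 0), params$delta_max)
  half_sum <- numeric(M)
  acc <- 0.5 * delta
  for (k in seq_along(acc)) {
    half_sum[pr$i[k]] <- half_sum[pr$i[k]] + acc[k]
    half_sum[pr$j[k]] <- half_sum[pr$j[k]] + acc[k]
  }
  lambda <- N_A - half_sum
  if (any(lambda < 0)) {
    bad <- which(lambda < 0)[1]
    stop("surrogate parameters yield lambda < 0 for atom ", bad, " (",
         element_symbol(mol$Z[bad]), ", lambda = ",
         signif(lambda[bad], 4), "); retune s/kappa rather than clipping")
  }
  list(N_A = N_A, lambda = lambda, delta = delta, Q = q)
}

#' Surrogate IQA-like energies
#'
#' `E_inter_ij = q_i q_j / r_ij + a_ij exp(-b r_ij)` (a.u., `a_ij` the
#' geometric mean of the per-element repulsion prefactors) and
#' `E_intra_A = e0(Z_A) + eta_A q_A^2 / 2`; the exact additive total is
#' returned alongside.
#'
#' @param mol a `molecule`.
#' @param params a [surrogate_params()].
#' @return list with `E_intra` (length M), `E_inter` (canonical pair
#'   order) and the exact `E_total`, all a.u.
#' @export
surrogate_iqa <- function(mol, params) {
  M <- n_atoms(mol)
  q <- surrogate_charges(mol, params)
  eta <- .param_by_Z(params$eta, mol$Z, "eta")
  e0 <- .param_by_Z(params$e0, mol$Z, "e0")
  E_intra <- e0 + 0.5 * eta * q^2
  if (M == 1L) {
    return(list(E_intra = E_intra, E_inter = numeric(0), E_total = sum(E_intra)))
  }
  a <- .param_by_Z(params$a_rep, mol$Z, "a_rep")
  pr <- enumerate_pairs(M)
  d <- pair_distances(mol)
  if (any(d < params$r_floor)) {
    stop("interatomic distance below r_floor = ", params$r_floor,
         " Angstrom; geometry too compressed for the surrogate energy model")
  }
  E_inter <- q[pr$i] * q[pr$j] / d + sqrt(a[pr$i] * a[pr$j]) * exp(-params$b_rep * d)
  list(E_intra = E_intra, E_inter = E_inter, E_total = sum(E_intra) + sum(E_inter))
}

#' Build the fully labeled record of one molecule
#'
#' Computes all surrogate properties and (optionally) adds Gaussian label
#' noise to the local values only, after the exact molecular totals have
#' been stored in `extras`, so the sum-rule residual of noisy labels is a
#' known quantity.
#'
#' @param mol a `molecule`.
#' @param params a [surrogate_params()].
#' @return a `local_record` with 1P properties `Q`, `N_A`, `lambda`,
#'   `E_intra`, 2P properties `delta`, `E_inter`, and extras `E_total`,
#'   `N_total`.
#' @export
surrogate_record <- function(mol, params) {
  es <- surrogate_electron_structure(mol, params)
  en <- surrogate_iqa(mol, params)
  props_1p <- list(Q = es$Q, N_A = es$N_A, lambda = es$lambda,
                   E_intra = en$E_intra)
  props_2p <- list(delta = es$delta, E_inter = en$E_inter)
  if (params$sigma_noise > 0) {
    props_1p <- lapply(props_1p, function(v) v + stats::rnorm(length(v), 0, params$sigma_noise))
    props_2p <- lapply(props_2p, function(v) v + stats::rnorm(length(v), 0, params$sigma_noise))
  }
  local_record(mol, props_1p, props_2p,
               units = c(Q = "e", N_A = "e", lambda = "e", delta = "e",
                         E_intra = "au", E_inter = "au"),
               extras = list(E_total = en$E_total, N_total = sum(mol$Z)))
}

#' Generate a labeled surrogate dataset
#'
#' Deterministic given `seed`; the generating parameters and seed are
#' attached as the `manifest` attribute (and serialized alongside when
#' `path` is given).
#'
#' @param n_molecules number of records (>= 1).
#' @param params a [surrogate_params()].
#' @param seed integer seed.
#' @param path optional output path for [write_dataset()].
#' @return list of `local_record`s (invisibly when written to `path`).
#' @export
generate_dataset <- function(n_molecules, params = surrogate_params(),
                             seed = 1L, path = NULL) {
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  set.seed(seed)
  records <- vector("list", n_molecules)
  for (k in seq_len(n_molecules)) {
    mol <- tryCatch(
      generate_geometry(params, id = sprintf("%s-%06d", params$preset, k)),
      error = function(e) stop("record ", k, ": ", conditionMessage(e),
                               call. = FALSE))
    records[[k]] <- tryCatch(
      surrogate_record(mol, params),
      error = function(e) stop("record ", k, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  attr(records, "manifest") <- list(n_molecules = n_molecules, seed = seed,
                                    params = unclass(params))
  if (!is.null(path)) {
    write_dataset(records, path)
    manifest_path <- paste0(path, ".manifest.json")
    writeLines(as.character(jsonlite::toJSON(attr(records, "manifest"),
                                             digits = I(17), auto_unbox = TRUE)),
               manifest_path)
    return(invisible(records))
  }
  records
}

# ---------------------------------------------------------------------------
# Scripted binding trajectories

.rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)
  ), 3, 3, byrow = TRUE)
}

#' Default host: two amine-like binding groups on a carbon scaffold
#'
#' @return list of groups, each `list(name, Z, R)`; coordinates Angstrom.
#' @export
default_host <- function() {
  nh2 <- function(origin) {
    list(Z = c(7L, 1L, 1L),
         R = rbind(origin,
                   origin + c(0.85, 0.0, 0.55),
                   origin + c(-0.85, 0.0, 0.55)))
  }
  g1 <- nh2(c(0, 0, 0))
  g2 <- nh2(c(9, 0, 0))
  list(
    list(name = "NH2_1", Z = g1$Z, R = g1$R),
    list(name = "NH2_2", Z = g2$Z, R = g2$R),
    list(name = "scaffold", Z = c(6L, 6L, 6L),
         R = rbind(c(2.5, 0.3, 1.8), c(4.5, 0.0, 2.2), c(6.5, 0.3, 1.8)))
  )
}

#' Default guest: a linear CO2-like rigid molecule
#' @return `list(Z, R)` centered on its carbon; Angstrom.
#' @export
default_guest <- function() {
  list(Z = c(8L, 6L, 8L),
       R = rbind(c(-1.16, 0, 0), c(0, 0, 0), c(1.16, 0, 0)))
}

#' Generate a scripted host-guest binding trajectory
#'
#' A rigid guest is moved along a scripted path relative to a static
#' host. Two event kinds are supported:
#' * `"approach"`: the guest center of mass travels from a remote parking
#'   position to `d_contact` Angstrom from the target group's centroid
#'   (reached at the `contact` frame) and back - both the group-guest
#'   delocalization and the center-of-mass distance peak/dip there;
#' * `"rotation"`: the guest sits at a station `d_station` Angstrom from
#'   the group with its center of mass fixed and rotates so that one
#'   terminal atom points at the group at the `contact` frame - an
#'   orientation-only contact: the delocalization peaks while the
#'   center-of-mass distance stays flat.
#'
#' The ground-truth table records, per scheduled event, the frame at
#' which the minimum group-guest interatomic distance is smallest within
#' the event window.
#'
#' @param schedule data.frame with columns `group` (host group name),
#'   `approach`, `contact`, `retreat` (frame numbers) and `kind`
#'   (`"approach"` or `"rotation"`).
#' @param n_frames total number of frames (1 fs per frame).
#' @param host list of host groups (default [default_host()]).
#' @param guest rigid guest definition (default [default_guest()]).
#' @param d_contact closest center-of-mass approach for approach events,
#'   Angstrom.
#' @param d_station center-of-mass standoff for rotation events, Angstrom.
#' @param d_drift slow monotone outward drift of the station during a
#'   rotation event, Angstrom; keeps the distance series free of strict
#'   minima without materially moving the guest.
#' @param seed integer seed (kept for interface symmetry; the script is
#'   deterministic).
#' @return list with `frames` (list of `molecule`s), `times` (fs),
#'   `groups` (named list of 1-based atom index vectors, including
#'   `guest`), `truth` (data.frame `group`, `kind`, `frame`),
#'   `masses` (per-atom masses, amu).
#' @export
generate_binding_trajectory <- function(schedule = NULL, n_frames = 1000L,
                                        host = default_host(),
                                        guest = default_guest(),
                                        d_contact = 2.6, d_station = 3.4,
                                        d_drift = 0.15, seed = 1L) {
  if (is.null(schedule)) {
    schedule <- data.frame(
      group = c("NH2_1", "NH2_2"),
      approach = c(150L, 550L),
      contact = c(300L, 700L),
      retreat = c(450L, 850L),
      kind = c("approach", "rotation"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("group", "approach", "contact", "retreat", "kind") %in%
                  names(schedule)))
  if (any(schedule$approach >= schedule$contact) ||
      any(schedule$contact >= schedule$retreat) ||
      any(schedule$retreat > n_frames)) {
    stop("schedule frames must satisfy approach < contact < retreat <= n_frames")
  }
  host_Z <- unlist(lapply(host, `[[`, "Z"), use.names = FALSE)
  host_R <- do.call(rbind, lapply(host, `[[`, "R"))
  sizes <- vapply(host, function(g) length(g$Z), integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  groups <- stats::setNames(
    lapply(seq_along(host), function(g) offsets[g] + seq_len(sizes[g])),
    vapply(host, `[[`, character(1), "name"))
  n_host <- length(host_Z)
  groups$guest <- n_host + seq_along(guest$Z)
  centroids <- lapply(groups[names(groups) != "guest"], function(idx) {
    colMeans(host_R[idx, , drop = FALSE])
  })
  # parking standoff: far enough that group-guest delocalization is
  # negligible, close enough that all pair distances stay inside the
  # distance range the surrogate training molecules exhibit (roughly
  # <= 10 Angstrom), i.e. a trained model interpolates along the whole
  # trajectory instead of extrapolating at the rest positions
  parking <- c(4.5, -7.5, 0)

  guest_R0 <- sweep(guest$R, 2, colMeans(guest$R))   # COM at origin
  smooth01 <- function(u) u * u * (3 - 2 * u)        # C1 easing

  place_guest <- function(frame) {
    com <- parking
    Rg <- guest_R0
    for (k in seq_len(nrow(schedule))) {
      ev <- schedule[k, ]
      if (frame < ev$approach || frame > ev$retreat) next
      ctr <- centroids[[ev$group]]
      if (is.null(ctr)) stop("unknown host group '", ev$group, "'")
      dir_out <- parking - ctr
      dir_out <- dir_out / sqrt(sum(dir_out^2))
      if (ev$kind == "approach") {
        target <- ctr + d_contact * dir_out
        u <- if (frame <= ev$contact) {
          (frame - ev$approach) / (ev$contact - ev$approach)
        } else {
          (ev$retreat - frame) / (ev$retreat - ev$contact)
        }
        com <- parking + smooth01(u) * (target - parking)
      } else if (ev$kind == "rotation") {
        # orientation-only contact: smooth travel to a station, then a
        # slow monotone outward drift of the center of mass while the
        # guest rotates, so the distance series shows no minimum near
        # the contact frame while the delocalization peaks there
        t_in <- ev$approach + 0.25 * (ev$contact - ev$approach)
        t_out <- ev$retreat - 0.25 * (ev$retreat - ev$contact)
        station <- ctr + d_station * dir_out
        drift_total <- d_drift
        if (frame <= t_in) {
          u <- (frame - ev$approach) / (t_in - ev$approach)
          com <- parking + smooth01(u) * (station - parking)
          phi <- 0
        } else if (frame >= t_out) {
          far <- station + drift_total * dir_out
          u <- (frame - t_out) / (ev$retreat - t_out)
          com <- far + smooth01(u) * (parking - far)
          phi <- 0
        } else {
          dr <- drift_total * (frame - t_in) / (t_out - t_in)
          com <- station + dr * dir_out
          u <- if (frame <= ev$contact) {
            (frame - t_in) / (ev$contact - t_in)
          } else {
            (t_out - frame) / (t_out - ev$contact)
          }
          phi <- smooth01(u) * (pi / 2)
        }
        # rotate the guest axis from tangential toward the group centroid
        tangent <- c(dir_out[2], -dir_out[1], 0)
        if (sum(tangent^2) < 1e-12) tangent <- c(0, 0, 1)
        tangent <- tangent / sqrt(sum(tangent^2))
        # align the guest x-axis with the tangent, then tilt toward the group
        xhat <- c(1, 0, 0)
        axis_align <- pracma_cross(xhat, tangent)
        if (sum(axis_align^2) < 1e-12) {
          R_align <- diag(3) * sign(sum(xhat * tangent))
        } else {
          R_align <- .rotation_about(axis_align,
                                     acos(max(-1, min(1, sum(xhat * tangent)))))
        }
        Rm <- .rotation_about(pracma_cross(dir_out, tangent), phi)
        Rg <- guest_R0 %*% t(R_align) %*% t(Rm)
      } else {
        stop("unknown event kind '", ev$kind, "'")
      }
      break
    }
    sweep(Rg, 2, com, `+`)
  }

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    Rg <- place_guest(f)
    R_all <- rbind(host_R, Rg)
    dmin <- min(stats::dist(R_all))
    if (dmin < 0.7) {
      stop("overlapping atoms at frame ", f, " (min distance ",
           signif(dmin, 3), " Angstrom)")
    }
    frames[[f]] <- molecule(c(host_Z, guest$Z), R_all,
                            id = sprintf("frame%04d", f))
  }

  # ground truth: approach events culminate at the frame of closest
  # group-guest approach; rotation events at the scripted orientation
  # apex (their distance metric is deliberately featureless there)
  truth <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(k) {
    ev <- schedule[k, ]
    if (ev$kind == "rotation") {
      return(data.frame(group = ev$group, kind = ev$kind, frame = ev$contact))
    }
    window <- ev$approach:ev$retreat
    gidx <- groups[[ev$group]]
    dmin <- vapply(window, function(f) {
      Rf <- frames[[f]]$R
      min(as.matrix(stats::dist(rbind(Rf[gidx, , drop = FALSE],
                                      Rf[groups$guest, , drop = FALSE])))[
        seq_along(gidx), length(gidx) + seq_along(groups$guest)])
    }, numeric(1))
    data.frame(group = ev$group, kind = ev$kind,
               frame = window[which.min(dmin)])
  }))

  masses <- .param_mass(c(host_Z, guest$Z))
  list(frames = frames, times = as.numeric(seq_len(n_frames) - 1L),
       groups = groups, truth = truth, masses = masses,
       schedule = schedule)
}

# cross product (avoid a dependency for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# standard atomic masses (amu) for the elements the package works with
.param_mass <- function(Z) {
  masses <- c(`1` = 1.008, `6` = 12.011, `7` = 14.007, `8` = 15.999)
  m <- masses[as.character(Z)]
  if (anyNA(m)) {
    stop("no tabulated mass for element(s): ",
         paste(element_symbol(unique(Z[is.na(m)])), collapse = ", "))
  }
  unname(m)
}
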