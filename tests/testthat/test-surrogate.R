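test_that("generated geometries honor the minimum-distance constraint deterministically", {
  p <- surrogate_params()
  mol <- generate_geometry(p, seed = 3)
  expect_true(all(pair_distances(mol) >= p$min_dist))
  expect_identical(generate_geometry(p, seed = 3), mol)
  lone <- generate_geometry(p, M = 1, seed = 4)
  expect_equal(n_atoms(lone), 1L)
  expect_true(all(is.finite(lone$R)))
  # an impossible packing is refused with advice
  tight <- surrogate_params(min_dist = 5, box_scale = 1.0)
  expect_error(generate_geometry(tight, M = 9, seed = 5), "box_scale")
})

test_that("surrogate charges: symmetry zeroes, electronegativity signs, closed form", {
  p <- surrogate_params()
  homo <- molecule(c(6, 6), rbind(c(0, 0, 0), c(1.8, 0, 0)))
  expect_equal(max(abs(surrogate_charges(homo, p))), 0, tolerance = 1e-12)
  # O is more electronegative than H: H positive, O negative
  hetero <- molecule(c(1, 8), rbind(c(0, 0, 0), c(1.6, 0, 0)))
  q <- surrogate_charges(hetero, p)
  expect_gt(q[1], 0); expect_lt(q[2], 0)
  expect_lt(abs(sum(q)), 1e-12)
})

test_that("diatomic charges match the analytic equalization solution to 1e-12", {
  # independent closed form for M = 2: substituting q' = -q into
  #   E(q) = chi1 q + eta1 q^2/2 + chi2 q' + eta2 q'^2/2 + q q' J(r)
  # gives E = (chi1 - chi2) q + (eta1 + eta2 - 2 J) q^2 / 2, hence
  #   q = (chi2 - chi1) / (eta1 + eta2 - 2 J(r)).
  p <- surrogate_params()
  set.seed(77)
  for (k in 1:100) {
    Z <- sample(c(1, 6, 7, 8), 2)
    r <- runif(1, 1.0, 6.0)
    mol <- molecule(Z, rbind(c(0, 0, 0), c(r, 0, 0)))
    chi <- p$chi[as.character(Z)]; eta <- p$eta[as.character(Z)]
    J <- coulomb_kernel(r, p$coulomb_gamma)
    q_closed <- (chi[2] - chi[1]) / (eta[1] + eta[2] - 2 * J)
    q <- surrogate_charges(mol, p)
    expect_equal(q[1], unname(q_closed), tolerance = 1e-12)
    expect_equal(q[2], -q[1], tolerance = 1e-14)
  }
  # second, fully numerical oracle: 1-D minimization of the stated energy
  Z <- c(1, 8); r <- 1.7
  chi <- p$chi[as.character(Z)]; eta <- p$eta[as.character(Z)]
  J <- coulomb_kernel(r, p$coulomb_gamma)
  Efun <- function(q) chi[1] * q + eta[1] * q^2 / 2 +
    chi[2] * (-q) + eta[2] * q^2 / 2 - q^2 * J
  q_num <- stats::optimize(Efun, c(-2, 2), tol = 1e-12)$minimum
  mol <- molecule(Z, rbind(c(0, 0, 0), c(r, 0, 0)))
  expect_equal(surrogate_charges(mol, p)[1], q_num, tolerance = 1e-8)
})

test_that("electron structure decays to the dissociation limit and closes the sum rule", {
  p <- surrogate_params()
  far <- molecule(c(8, 8), rbind(c(0, 0, 0), c(40, 0, 0)))
  es <- surrogate_electron_structure(far, p)
  expect_lt(es$delta, 1e-10)
  expect_equal(es$lambda, es$N_A, tolerance = 1e-10)
  # delta at the reference separation equals s_i s_j exactly
  r0 <- p$rcov[["6"]] + p$rcov[["8"]]
  pair <- molecule(c(6, 8), rbind(c(0, 0, 0), c(r0, 0, 0)))
  es2 <- surrogate_electron_structure(pair, p)
  expect_equal(es2$delta, unname(p$s[["6"]] * p$s[["8"]]), tolerance = 1e-12)
  for (rec in fix_records(20, seed = 61)) {
    expect_lt(abs(reconstruct_N(rec$props_1p$lambda, rec$props_2p$delta) -
                  sum(rec$molecule$Z)), 1e-10)
    expect_true(all(rec$props_1p$lambda >= 0))
    expect_true(all(rec$props_2p$delta >= 0))
    expect_lt(abs(sum(rec$props_1p$Q)), 1e-12)
  }
})

test_that("surrogate energies close additively and keep Coulomb q-symmetry", {
  p <- surrogate_params()
  mol <- fix_random_mol(71)
  en <- surrogate_iqa(mol, p)
  expect_equal(reconstruct_E(en$E_intra, en$E_inter), en$E_total,
               tolerance = 1e-12)
  # distant neutral-ish atoms: interaction terms vanish
  far <- molecule(c(6, 6), rbind(c(0, 0, 0), c(60, 0, 0)))
  enf <- surrogate_iqa(far, p)
  expect_lt(abs(enf$E_inter), 1e-8)
  expect_equal(enf$E_total, sum(enf$E_intra), tolerance = 1e-10)
  # q_i q_j is invariant under flipping both charges: rebuild by hand
  hetero <- molecule(c(1, 8), rbind(c(0, 0, 0), c(1.6, 0, 0)))
  q <- surrogate_charges(hetero, p)
  r <- 1.6
  coul <- q[1] * q[2] / r
  expect_equal((-q[1]) * (-q[2]) / r, coul)
})

test_that("label noise is applied only after the exact totals are stored", {
  p <- surrogate_params(sigma_noise = 0.05)
  set.seed(5)
  mol <- generate_geometry(p, seed = 5)
  rec <- surrogate_record(mol, p)
  # noisy locals no longer close the rules ...
  resid_N <- abs(reconstruct_N(rec$props_1p$lambda, rec$props_2p$delta) -
                 sum(mol$Z))
  expect_gt(resid_N, 1e-6)
  # ... but the stored totals are the exact pre-noise values
  clean <- surrogate_record(mol, surrogate_params())
  expect_equal(rec$extras$E_total, clean$extras$E_total, tolerance = 1e-12)
  expect_identical(rec$extras$N_total, sum(mol$Z))
})

test_that("surrogate labels vary smoothly with geometry", {
  p <- surrogate_params()
  mol <- fix_random_mol(81)
  base <- surrogate_electron_structure(mol, p)
  prev <- Inf
  for (h in c(1e-2, 1e-3, 1e-4)) {
    R2 <- mol$R; R2[2, 1] <- R2[2, 1] + h
    es <- surrogate_electron_structure(molecule(mol$Z, R2), p)
    dmax <- max(abs(es$delta - base$delta), abs(es$Q - base$Q),
                abs(es$lambda - base$lambda))
    expect_lt(dmax, prev)
    prev <- dmax
  }
  expect_lt(prev, 1e-3)
})

test_that("datasets are reproducible and match the configured element pool", {
  p <- surrogate_params()
  path1 <- withr::local_tempfile(fileext = ".jsonl")
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  generate_dataset(60, p, seed = 9, path = path1)
  generate_dataset(60, p, seed = 9, path = path2)
  expect_identical(readLines(path1), readLines(path2))
  recs <- read_dataset(path1)
  Z <- unlist(lapply(recs, function(r) r$molecule$Z))
  counts <- table(factor(Z, levels = names(p$pool)))
  chisq <- suppressWarnings(stats::chisq.test(counts, p = p$pool))
  expect_gt(chisq$p.value, 1e-4)
  manifest <- jsonlite::fromJSON(paste0(path1, ".manifest.json"))
  expect_equal(manifest$seed, 9)

  # the water-like preset stays within its H/O pool and closes the rules
  wrecs <- generate_dataset(10, surrogate_params("water"), seed = 2)
  expect_true(all(unlist(lapply(wrecs, function(r) r$molecule$Z)) %in% c(1L, 8L)))
  expect_true(all(check_sum_rules(wrecs, tol = 1e-10)$ok))
})

test_that("binding trajectories script approach and orientation events with ground truth", {
  # single approach-retreat: one interior maximum in the group delta series
  sched <- data.frame(group = "NH2_1", approach = 100L, contact = 200L,
                      retreat = 300L, kind = "approach")
  traj <- generate_binding_trajectory(sched, n_frames = 400L)
  expect_length(traj$frames, 400L)
  expect_equal(traj$truth$frame, 200L, tolerance = 2)
  p <- surrogate_params()
  deltas <- lapply(traj$frames, function(f) surrogate_electron_structure(f, p)$delta)
  es <- group_delta_series(deltas, traj$times, traj$groups$NH2_1, traj$groups$guest)
  v <- es$values
  interior_max <- which(v[2:399] > v[1:398] & v[2:399] > v[3:400]) + 1L
  # strict interior maxima cluster at the contact; none elsewhere
  expect_true(all(abs(interior_max - 201L) <= 2))
  expect_gt(max(v), 10 * v[1])

  # guest held far away: flat, essentially zero delta
  null_sched <- sched[0, ]
  traj0 <- generate_binding_trajectory(null_sched, n_frames = 50L)
  d0 <- lapply(traj0$frames, function(f) surrogate_electron_structure(f, p)$delta)
  e0 <- group_delta_series(d0, traj0$times, traj0$groups$NH2_1, traj0$groups$guest)
  expect_lt(max(e0$values), 1e-4)   # parked ~8 A away: delta is negligible
  expect_lt(diff(range(e0$values)), 1e-12)

  expect_error(generate_binding_trajectory(
    data.frame(group = "NH2_1", approach = 10L, contact = 5L, retreat = 20L,
               kind = "approach"), n_frames = 30L), "approach < contact")
})
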