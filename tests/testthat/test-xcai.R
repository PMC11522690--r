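test_that("group delocalization sums inter-group pairs exactly once", {
  M <- 8
  set.seed(2)
  delta <- runif(n_pairs(M))
  expect_equal(group_delocalization(delta, 3, 7),
               delta[pair_flat_index(3, 7, M)])
  # additivity over a disjoint split of the first group
  expect_equal(group_delocalization(delta, c(1, 2, 3), c(6, 7)),
               group_delocalization(delta, c(1, 2), c(6, 7)) +
                 group_delocalization(delta, 3, c(6, 7)),
               tolerance = 1e-12)
  expect_equal(group_delocalization(rep(0, n_pairs(M)), c(1, 2), c(3, 4)), 0)
  expect_error(group_delocalization(delta, c(1, 2), c(2, 3)), "overlap")
  expect_error(group_delocalization(delta, integer(0), 3), "non-empty")
})

test_that("group aggregation is bilinear-additive over random partitions", {
  set.seed(31)
  for (rep_ in 1:20) {
    M <- sample(6:12, 1)
    delta <- runif(n_pairs(M))
    atoms <- sample(M)
    g1 <- atoms[1:3]; g2 <- atoms[4:5]; g3 <- atoms[6:M]
    expect_equal(group_delocalization(delta, c(g1, g2), g3),
                 group_delocalization(delta, g1, g3) +
                   group_delocalization(delta, g2, g3),
                 tolerance = 1e-12)
  }
})

test_that("center-of-mass distances reduce, vanish and translate correctly", {
  mol <- molecule(c(1, 8), rbind(c(0, 0, 0), c(0, 0, 2.5)))
  expect_equal(center_of_mass_distance(mol, 1, 2),
               interatomic_distance(mol, 1, 2))
  # symmetric diatomic group vs its own midpoint atom
  mid <- molecule(c(6, 1, 1), rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, -1)))
  expect_equal(center_of_mass_distance(mid, c(2, 3), 1), 0, tolerance = 1e-12)
  mol2 <- molecule(mol$Z, mol$R + rep(c(3, -2, 7), each = 2))
  expect_lt(abs(center_of_mass_distance(mol, 1, 2) -
                center_of_mass_distance(mol2, 1, 2)), 1e-12)
  expect_error(center_of_mass_distance(mol, integer(0), 2), "non-empty")
})

test_that("bin averaging uses midpoints, keeps partial bins, validates width", {
  s <- trajectory_series(0:99, rep(0.7, 100), kind = "electronic")
  b <- bin_average(s, 10)
  expect_true(all(b$values == 0.7))
  expect_equal(b$times[1], 5)
  whole <- bin_average(s, 1000)
  expect_length(whole$values, 1)
  expect_equal(whole$values, 0.7)
  alt <- trajectory_series(0:19, rep(c(0, 1), 10), kind = "electronic")
  expect_true(all(bin_average(alt, 2)$values == 0.5))
  # trailing partial bin is kept
  s2 <- trajectory_series(0:24, c(rep(1, 20), rep(3, 5)), kind = "electronic")
  b2 <- bin_average(s2, 10)
  expect_length(b2$values, 3)
  expect_equal(b2$values[3], 3)
  expect_error(bin_average(s, 0.5), "smaller than the time step")
  expect_error(trajectory_series(c(0, 1, 1), 1:3), "strictly increasing")
})

test_that("event detection finds prominent extrema of the right polarity", {
  t <- 0:200
  expect_equal(nrow(detect_events(
    trajectory_series(t, t * 0.01, kind = "electronic"))), 0L)
  tri <- c(seq(0, 1, length.out = 101), seq(0.99, 0, length.out = 100))
  ev <- detect_events(trajectory_series(t, tri, kind = "electronic"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time, 100)
  # geometric series: minima are the events
  evg <- detect_events(trajectory_series(t, 5 - tri + 1, kind = "geometric"))
  expect_equal(evg$time, 100)
  expect_error(detect_events(trajectory_series(0:1, c(1, 2))), "too short")
})

test_that("event detection is invariant to time shifts and value rescaling", {
  set.seed(7)
  base <- abs(stats::filter(rnorm(300), rep(1 / 20, 20), sides = 2))
  base[is.na(base)] <- 0
  s1 <- trajectory_series(0:299, base, kind = "electronic")
  e1 <- detect_events(s1, min_prominence = 0.05, min_separation = 30)
  s2 <- trajectory_series(1000:1299, base, kind = "electronic")
  e2 <- detect_events(s2, min_prominence = 0.05, min_separation = 30)
  expect_equal(e2$time, e1$time + 1000)
  s3 <- trajectory_series(0:299, base * 7, kind = "electronic")
  e3 <- detect_events(s3, min_prominence = 0.05 * 7, min_separation = 30)
  expect_equal(e3$time, e1$time)
  expect_equal(e3$value, e1$value * 7, tolerance = 1e-12)
})

test_that("event matching is one-to-one within tolerance and reports the fraction", {
  ev <- function(times, kind) {
    structure(data.frame(time = times, value = seq_along(times), kind = kind,
                         prominence = 1),
              class = c("event_table", "data.frame"))
  }
  same <- match_events(ev(c(100, 500), "electronic"), ev(c(100, 500), "geometric"))
  expect_true(all(same$status == "both"))
  expect_equal(attr(same, "match_fraction"), 1.0)
  near <- match_events(ev(100, "electronic"), ev(105, "geometric"), tolerance = 10)
  expect_true(all(near$status == "both"))
  far <- match_events(ev(100, "electronic"), ev(150, "geometric"), tolerance = 10)
  expect_setequal(far$status, c("electronic-only", "geometric-only"))
  expect_equal(attr(far, "match_fraction"), 0)
  # one geometric event cannot match two electronic ones
  crowd <- match_events(ev(c(100, 104), "electronic"), ev(102, "geometric"))
  expect_equal(sum(crowd$status == "both"), 2L)  # one e + the g it matched
  expect_equal(sum(crowd$status == "electronic-only"), 1L)
})

test_that("dominant pair contributions rank, normalize and break ties deterministically", {
  M <- 6
  delta <- rep(0, n_pairs(M))
  delta[pair_flat_index(1, 4, M)] <- 0.3
  top <- dominant_pair_contributions(delta, c(1, 2), c(4, 5), k = 3)
  expect_equal(nrow(top), 1L)  # only nonzero pairs carry shares
  expect_equal(top$share, 1.0)
  expect_equal(c(top$i, top$j), c(1, 4))

  delta[pair_flat_index(2, 5, M)] <- 0.3
  two <- dominant_pair_contributions(delta, c(1, 2), c(4, 5), k = 5)
  expect_equal(two$share[1:2], c(0.5, 0.5))
  expect_true(two$i[1] == 1 && two$j[1] == 4)  # lexicographic tie-break
  full <- dominant_pair_contributions(delta, c(1, 2), c(4, 5), k = 100)
  expect_equal(sum(full$share), 1.0, tolerance = 1e-12)

  zero <- dominant_pair_contributions(rep(0, n_pairs(M)), c(1, 2), c(4, 5), k = 2)
  expect_equal(nrow(zero), 0L)
  expect_true(attr(zero, "zero_total"))
  expect_error(dominant_pair_contributions(delta, c(1, 4), c(4, 5), 1), "overlap")
})
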