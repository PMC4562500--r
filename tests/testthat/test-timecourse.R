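test_that("method merging follows the mean / single-method rules", {
  obs <- data.frame(
    allele_id = c("m1", "m1", "m2", "m1"),
    day = c(9, 9, 9, 13),
    method = c("sanger", "wgs", "wgs", "wgs"),
    frequency = c(0.4, 0.6, 0.7, 0.2))
  knots <- merge_method_frequencies(obs)
  expect_equal(knots$frequency[knots$allele_id == "m1" & knots$day == 9], 0.5)
  expect_equal(knots$frequency[knots$allele_id == "m2"], 0.7)
  ## no observation at a day: no knot emitted
  expect_false(any(knots$day == 11))
  ## merging already-merged knots is a no-op (idempotence)
  again <- merge_method_frequencies(
    data.frame(allele_id = knots$allele_id, day = knots$day,
               method = "wgs", frequency = knots$frequency))
  expect_equal(again$frequency, knots$frequency)
})

test_that("invalid observations are rejected with row context", {
  bad <- data.frame(allele_id = "m1", day = 1, method = "wgs",
                    frequency = 1.2)
  expect_error(merge_method_frequencies(bad), "outside \\[0, 1\\]")
  dup <- data.frame(allele_id = c("m1", "m1"), day = c(1, 1),
                    method = c("wgs", "wgs"), frequency = c(0.1, 0.2))
  expect_error(merge_method_frequencies(dup), "duplicate")
})

test_that("linkage groups average members, then Sanger", {
  knots <- data.frame(allele_id = c("m2", "m3", "m4"),
                      day = c(9, 9, 9),
                      frequency = c(0.3, 0.5, 0.8))
  out <- resolve_linkage(knots, list(c("m2", "m3")))
  expect_equal(out$frequency[out$allele_id == "m2+m3"], 0.4)
  expect_equal(out$frequency[out$allele_id == "m4"], 0.8)  # pass-through

  with_sanger <- resolve_linkage(
    knots, list(c("m2", "m3")),
    sanger_linked = data.frame(group = 1, day = 9, frequency = 0.6))
  expect_equal(with_sanger$frequency[with_sanger$allele_id == "m2+m3"], 0.5)

  three <- data.frame(allele_id = c("a", "b", "c"), day = 2,
                      frequency = c(0.3, 0.4, 0.5))
  out3 <- resolve_linkage(three, list(c("a", "b", "c")))
  expect_equal(out3$frequency, 0.4)  # generalized mean over all members

  ## missing member: group skipped at that day with a warning
  expect_warning(
    res <- resolve_linkage(knots[-1, ], list(c("m2", "m3"))),
    "missing a member")
  expect_false(any(res$allele_id == "m2+m3"))
})

test_that("ancestral clamping zeroes everything after the first zero", {
  expect_equal(clamp_ancestral(c(1.0, 0.4, 0.0, 0.1)), c(1.0, 0.4, 0, 0))
  expect_equal(clamp_ancestral(c(1.0, 0.6, 0.2)), c(1.0, 0.6, 0.2))
  ## clamping twice equals clamping once
  once <- clamp_ancestral(c(0.8, 0, 0.3, 0.2))
  expect_equal(clamp_ancestral(once), once)
  df <- clamp_ancestral(data.frame(day = c(0, 4, 9, 14),
                                   frequency = c(1, 0.4, 0, 0.1)))
  expect_equal(df$frequency, c(1, 0.4, 0, 0))
})

test_that("quadratic spline interpolates knots exactly and clips", {
  knots <- data.frame(day = c(0, 4, 9, 14), frequency = c(0, 0.7, 0.1, 0.9))
  cur <- interpolate_trajectory(knots, step = 0.5)
  at_knots <- cur[cur$day %in% knots$day, ]
  expect_equal(at_knots$frequency_raw, knots$frequency)
  expect_equal(at_knots$source, rep("knot", 4))
  expect_true(all(cur$frequency >= 0 & cur$frequency <= 1))
  expect_equal(cur$frequency, pmin(pmax(cur$frequency_raw, 0), 1))

  ## two knots degrade to the linear segment
  lin <- interpolate_trajectory(
    data.frame(day = c(0, 10), frequency = c(0, 1)), step = 1)
  expect_equal(lin$frequency[lin$day == 5], 0.5)

  expect_warning(one <- interpolate_trajectory(
    data.frame(day = 3, frequency = 0.2)), "fewer than 2")
  expect_equal(one$frequency, 0.2)
})

test_that("the spline is piecewise quadratic with continuous derivative", {
  knots <- data.frame(day = c(0, 3, 7, 12, 20),
                      frequency = c(0, 0.6, 0.2, 0.9, 0.4))
  cur <- interpolate_trajectory(knots, step = 0.01)
  x <- cur$day; y <- cur$frequency_raw
  ## constant second difference inside each segment (quadratic pieces)
  for (i in seq_len(nrow(knots) - 1L)) {
    sel <- which(x > knots$day[i] + 0.02 & x < knots$day[i + 1L] - 0.02)
    d2 <- diff(y[sel], differences = 2)
    expect_lt(max(abs(d2 - mean(d2))), 1e-8)
  }
  ## first-derivative continuity at interior knots
  for (k in knots$day[c(-1, -nrow(knots))]) {
    i <- which.min(abs(x - k))
    left <- (y[i - 1] - y[i - 2]) / 0.01
    right <- (y[i + 2] - y[i + 1]) / 0.01
    expect_lt(abs(left - right), 0.05)
  }
  ## the first segment is the linear closure condition
  sel1 <- which(x <= knots$day[2])
  expect_lt(max(abs(diff(y[sel1], differences = 2))), 1e-10)
})

test_that("full reconstruction reproduces the hand-computed golden output", {
  rec <- reconstruct_timecourse(golden_obs(), golden_clones())
  k <- rec$knots

  ## m1: mean of methods at day 4, single-method days, day-0 anchor
  m1 <- k[k$allele_id == "m1", ]
  expect_equal(m1$day, c(0, 4, 9, 14))
  expect_equal(m1$frequency, c(0, 0.15, 0.40, 0.60))

  ## linked lineage m2+m3: member mean at day 9 (no Sanger clones there),
  ## member mean then Sanger average at day 14:
  ## wgs (0.6 + 0.7)/2 = 0.65; clones 6/10 = 0.6; final 0.625
  ml <- k[k$allele_id == "m2+m3", ]
  expect_equal(ml$day, c(0, 9, 14))
  expect_equal(ml$frequency, c(0, 0.40, 0.625))

  ## ancestral series clamped at zero and spline passes through knots
  anc <- k[k$allele_id == "ancestral", ]
  expect_equal(anc$frequency, c(0.7, 0.3, 0))
  cur <- rec$curves
  for (a in unique(k$allele_id)) {
    ka <- k[k$allele_id == a, ]
    ca <- cur[cur$allele_id == a & cur$source == "knot", ]
    expect_equal(ca$frequency[match(ka$day, ca$day)], ka$frequency)
  }
  expect_true(all(cur$frequency >= 0 & cur$frequency <= 1))
})

test_that("reconstruction error shrinks with sequencing depth", {
  ## round trip through the sequencing generator at rising coverage
  days <- c(0, 4, 9, 14, 19)
  truth <- data.frame(
    lineage_id = rep(c("L1", "L2"), each = 5), day = rep(days, 2),
    frequency = c(0, 0.1, 0.3, 0.55, 0.7, 0, 0.05, 0.2, 0.3, 0.25))
  rmse_at <- function(cov, seed) {
    sc <- synth_config(seed = seed, coverage = cov, n_clones = 200)
    se <- gen_sequencing_observations(
      truth, haplotypes = list(L1 = "m1", L2 = c("m2", "m3")), config = sc)
    rec <- reconstruct_timecourse(se$observations, se$clones)
    k <- rec$knots
    err <- c(
      k$frequency[k$allele_id == "m1" & k$day %in% days] -
        truth$frequency[truth$lineage_id == "L1"][
          match(k$day[k$allele_id == "m1" & k$day %in% days], days)],
      k$frequency[k$allele_id %in% c("m2+m3", "m3+m2") & k$day %in% days] -
        truth$frequency[truth$lineage_id == "L2"][
          match(k$day[k$allele_id %in% c("m2+m3", "m3+m2") &
                        k$day %in% days], days)])
    sqrt(mean(err^2))
  }
  ## average over a few seeds to make the ordering stable
  rm30 <- mean(vapply(1:4, function(s) rmse_at(30, s), numeric(1)))
  rm100 <- mean(vapply(1:4, function(s) rmse_at(100, s + 10), numeric(1)))
  rm300 <- mean(vapply(1:4, function(s) rmse_at(300, s + 20), numeric(1)))
  expect_gt(rm30, rm100)
  expect_gt(rm100, rm300)
})
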