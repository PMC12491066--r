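test_that("control subtraction is pointwise and validates grids", {
  ramp <- default_ramp()
  s <- melt_curve(ramp, seq(0, 3000, length.out = 71))
  expect_equal(subtract_control(s, flat_curve(0))$rfu, s$rfu)
  expect_equal(subtract_control(s, flat_curve(400))$rfu, s$rfu - 400)
  short <- melt_curve(seq(25, 94), rep(0, 70))
  expect_error(subtract_control(s, short), "grids differ")
  other <- melt_curve(ramp, rep(0, 71), channel = "JOE")
  expect_error(subtract_control(s, other), "channel mismatch")
})

test_that("curve summaries use raw extrema, subtracted amplitude, low-T ties", {
  ramp <- default_ramp()
  rising <- melt_curve(ramp, seq(0, 3000, length.out = 71))
  s <- summarize_curve(rising, flat_curve(0))
  expect_equal(s$f_max, 3000)
  expect_equal(s$f_min, 0)
  expect_equal(s$t_at_max, 95)
  expect_equal(s$delta_f, 3000)

  const <- summarize_curve(flat_curve(500), flat_curve(500))
  expect_equal(const$delta_f, 0)
  expect_equal(const$f_max, 500)

  y <- rep(0, 71); y[ramp == 40] <- 900; y[ramp == 60] <- 900
  tie <- summarize_curve(melt_curve(ramp, y), flat_curve(0))
  expect_equal(tie$t_at_max, 40)

  bad <- melt_curve(ramp, c(NA, rep(1, 70)))
  expect_error(summarize_curve(bad, flat_curve(0)), "non-finite")
})

test_that("the threshold rule table assigns each printed score", {
  expect_identical(score_summary(curve_summary(3200, 100, 42, 2800)), 10L)
  expect_identical(score_summary(curve_summary(3000, 100, 42, 2000)), 8L)
  expect_identical(score_summary(curve_summary(3000, 100, 42, 1200)), 5L)
  expect_identical(score_summary(curve_summary(3000, 100, 62, 2900)), 3L)
  expect_identical(score_summary(curve_summary(3000, 100, 75, 2900)), 1L)
  expect_identical(score_summary(curve_summary(200, 50, 40, 150)), 0L)
  # band boundaries tile: 2500 RFU belongs to the 8 band, 70 degC to rule 3
  expect_identical(score_summary(curve_summary(3000, 100, 42, 2500)), 8L)
  expect_identical(score_summary(curve_summary(3000, 100, 42, 2500.01)), 10L)
  expect_identical(score_summary(curve_summary(3000, 100, 42, 1500)), 8L)
  expect_identical(score_summary(curve_summary(3000, 100, 42, 1000)), 5L)
  expect_identical(score_summary(curve_summary(3000, 100, 70, 2900)), 3L)
  expect_identical(score_summary(curve_summary(3000, 100, 55, 2900)), 3L)
})

test_that("scoring is total over finite summaries and respects precedence", {
  set.seed(101)
  valid <- c(0L, 1L, 3L, 5L, 8L, 10L)
  n <- 10000L
  f_min <- runif(n, -4000, 4000)
  f_max <- f_min + runif(n, 0, 6000)
  t_max <- runif(n, 25, 95)
  delta <- runif(n, -1000, 6000)
  scores <- vapply(seq_len(n), function(i)
    score_summary(curve_summary(f_max[i], f_min[i], t_max[i], delta[i])),
    integer(1))
  expect_true(all(scores %in% valid))
  # precedence: anything matching the score-10 conditions scores 10
  top <- f_max > 1000 & f_min > -1000 & delta > 2500 & t_max < 55
  expect_true(all(scores[top] == 10L))
  expect_gt(sum(top), 0L)
})

test_that("score is monotone in amplitude at fixed favourable geometry", {
  deltas <- c(900, 1200, 2000, 2600)
  scores <- vapply(deltas, function(d)
    score_summary(curve_summary(f_max = d, f_min = 0, t_at_max = 40, delta_f = d)),
    integer(1))
  expect_identical(scores, c(0L, 5L, 8L, 10L))
  expect_false(is.unsorted(scores))
})

test_that("well score is the channel maximum with the winner recorded", {
  ramp <- default_ramp()
  chs <- names(padsf_channels())
  curves <- lapply(chs, function(ch) {
    if (ch == "TAMRA") rule_curve(1200, channel = ch)       # score 5
    else if (ch == "ROX") rule_curve(3000, channel = ch)    # score 10
    else flat_curve(100, channel = ch)
  })
  well <- screen_well("D1", "WT_ind01", "fibril", curves,
                      protein_variant = "WT", inducer_id = 1L)
  ctrl <- screen_well("D1", "polyanion_01", "polyanion_only",
                      lapply(chs, function(ch) flat_curve(0, channel = ch)),
                      inducer_id = 1L)
  controls <- screen_run("ctl", 1L, list(ctrl))
  sc <- score_well(well, controls)
  expect_identical(sc$well_score, 10L)
  expect_identical(sc$best_channel, "ROX")
  expect_identical(unname(sc$channel_scores[c("TAMRA", "ROX", "FAM")]),
                   c(5L, 10L, 0L))

  orphan <- screen_well("D2", "WT_ind01", "fibril", curves,
                        protein_variant = "WT", inducer_id = 1L)
  expect_error(score_well(orphan, controls), "missing matched control")
})

test_that("replicate aggregation sums well scores and is symmetric", {
  sim <- gen_screen(n_dyes = 6L, conditions = small_conditions(),
                    archetype_mix = small_mix(), noise_sd = 40, seed = 9L)
  st1 <- score_screen(sim$replicates[[1L]], sim$controls[[1L]])
  st2 <- score_screen(sim$replicates[[2L]], sim$controls[[2L]])
  a12 <- aggregate_replicates(st1, st2)
  a21 <- aggregate_replicates(st2, st1)
  expect_identical(a12, a21)
  w1 <- well_scores(st1, "fibril"); w2 <- well_scores(st2, "fibril")
  k <- paste(a12$dye_id, a12$sample_id)
  expect_equal(a12$additive_score,
               w1$well_score[match(k, paste(w1$dye_id, w1$sample_id))] +
                 w2$well_score[match(k, paste(w2$dye_id, w2$sample_id))])
  expect_true(all(a12$additive_score >= 0 & a12$additive_score <= 20))

  st1_cut <- st1[st1$dye_id != "D001", , drop = FALSE]
  attr(st1_cut, "replicate_index") <- 1L
  class(st1_cut) <- class(st1)
  expect_error(aggregate_replicates(st1_cut, st2), "not shared")
})

test_that("triage applies the additive cutoff and the monomer filter", {
  add <- structure(
    data.frame(dye_id = c("A", "A", "B", "C"),
               sample_id = c("s1", "s2", "s1", "s1"),
               additive_score = c(20L, 10L, 20L, 18L)),
    class = c("additive_score_table", "data.frame"))
  mono <- structure(
    data.frame(dye_id = c("A", "B", "C"), sample_id = "tau_monomer",
               sample_type = "monomer", channel = "FAM",
               score = c(0L, 10L, 0L), well_score = c(0L, 10L, 0L),
               best_channel = "FAM"),
    class = c("score_table", "data.frame"), replicate_index = 1L)
  out <- triage_hits(add, mono)
  expect_setequal(out$dye_id, c("A", "B"))        # C at 18 misses the bar
  expect_true(out$hit[out$dye_id == "A"])
  expect_false(out$hit[out$dye_id == "B"])        # monomer-reactive
  expect_true(out$monomer_flag[out$dye_id == "B"])
  expect_false(any(out$monomer_flag & out$hit))   # flagged never in hit list

  cur <- triage_hits(add, mono, curated_additions = "C")
  expect_true(cur$curated[cur$dye_id == "C"])
  expect_true(cur$hit[cur$dye_id == "C"])
  expect_error(triage_hits(add, mono, curated_additions = "Z"),
               "no monomer-control score.*Z")
})

test_that("hit rate matches exact rational arithmetic for all n <= N <= 1000", {
  for (N in c(1:50, 306, 500, 1000)) {
    n <- 0:N
    expect_equal(hit_rate(n, N), oracle_hit_rate(n, N))
  }
  expect_equal(hit_rate(0, 306), 0.0)
  expect_error(hit_rate(1, 0), "positive")
  expect_error(hit_rate(-1, 10), "lie in")
})

test_that("the s.d. activity rule is inclusive at the threshold", {
  mono <- c(90, 100, 110)  # mean 100, sd 10
  expect_equal(sd(mono), 10)
  expect_true(sd_activity_call(130, mono))
  expect_false(sd_activity_call(129.9, mono))
  expect_true(sd_activity_call(100, mono, k = 0))
  expect_error(sd_activity_call(130, c(100, 100)), "zero variance")
  expect_error(sd_activity_call(130, 100), ">= 2 monomer")
})

test_that("heatmap clustering orders deterministically with ties by id", {
  add <- structure(
    data.frame(dye_id = rep(c("A", "B", "C"), each = 2),
               sample_id = rep(c("s1", "s2"), 3),
               additive_score = c(5L, 5L, 5L, 5L, 105L, 105L)),
    class = c("additive_score_table", "data.frame"))
  ord <- cluster_order(add)
  # identical rows A and B stay adjacent; the distant row C is terminal
  pos <- match(c("A", "B", "C"), ord$row_order)
  expect_equal(abs(pos[1] - pos[2]), 1L)
  expect_true(pos[3] %in% c(1L, 3L))

  one <- structure(data.frame(dye_id = "A", sample_id = "s1",
                              additive_score = 20L),
                   class = c("additive_score_table", "data.frame"))
  o1 <- cluster_order(one)
  expect_identical(o1$row_order, "A")
  expect_identical(o1$col_order, "s1")
  expect_error(cluster_order(one[0, ]), "empty")

  expect_identical(cluster_order(add), cluster_order(add))
})
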