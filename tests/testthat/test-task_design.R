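test_that("difficulty table applies the 90-degree exclusion and orders levels", {
  dt <- build_difficulty_table()
  expect_equal(nrow(dt), 15L)
  expect_equal(dt$level, 1:15)
  expect_true(all(dt$min_distance + dt$variance <= 90))
  # bijection onto the retained pairs
  expect_equal(anyDuplicated(paste(dt$min_distance, dt$variance)), 0L)
  # easiest level has the most distant, most homogeneous distractors
  expect_equal(dt$min_distance[1], 75)
  expect_equal(dt$variance[1], 10)
  expect_equal(dt$min_distance[15], 5)
  expect_equal(dt$variance[15], 40)

  pilot <- build_difficulty_table(c(5, 15, 25, 45, 65))
  expect_equal(nrow(pilot), 14L)

  expect_equal(nrow(build_difficulty_table(80, 20)), 0L)
  expect_error(build_difficulty_table(numeric(0), 10), "non-empty")
})

test_that("trajectories step one level per probe and clamp at the endpoints", {
  expect_equal(make_trajectory("inc_easy", 10), 1:10)
  tr <- make_trajectory("inc_mid", 10)
  expect_equal(min(which(tr == 15L)), 8L)
  expect_equal(tr[9:10], c(15L, 15L))
  expect_equal(make_trajectory("fixed", 5), rep(8L, 5))
  expect_equal(make_trajectory("dec_hard", 15), 15:1)
  expect_error(make_trajectory("inc_easy", 0), "positive")

  for (cond in pm_conditions) {
    lev <- make_trajectory(cond, 15)
    expect_true(all(lev >= 1 & lev <= 15))
    expect_true(all(abs(diff(lev)) <= 1))
    # steps of 0 only at an endpoint (or in the fixed condition)
    flat <- which(diff(lev) == 0)
    if (cond != "fixed")
      expect_true(all(lev[flat] %in% c(1L, 15L)))
  }
  # monotone while the range allows it
  expect_true(all(diff(make_trajectory("inc_mid", 8)) == 1))
  expect_true(all(diff(make_trajectory("dec_mid", 7)) == -1))
})

test_that("arrow arrays respect orientation bands and the anti-pop-out rule", {
  spec <- list(min_distance = 75, variance = 10)
  bands_ok <- function(th) {
    (th >= 75 & th <= 85) | (th >= 95 & th <= 105) |
      (th >= 255 & th <= 265) | (th >= 275 & th <= 285)
  }
  set.seed(1)
  prev <- NULL
  all_ori <- c()
  for (i in 1:100) {
    arr <- sample_arrow_array(spec, prev, target_present = TRUE)
    d <- arr$orientations[-arr$target_slot]
    expect_true(all(bands_ok(d)))
    if (!is.null(prev)) {
      same <- setdiff(seq_along(arr$orientations),
                      c(arr$target_slot, prev$target_slot))
      dd <- abs(arr$orientations[same] - prev$orientations[same]) %% 360
      expect_true(all(pmin(dd, 360 - dd) >= 5))
    }
    expect_identical(arr$orientations[arr$target_slot], 0)
    all_ori <- c(all_ori, d)
    prev <- arr
  }
  expect_true(all((all_ori >= 5 & all_ori <= 175) |
                    (all_ori >= 185 & all_ori <= 355)))

  # reflection arithmetic: 80 flipped horizontally -> 280
  expect_equal((360 - 80) %% 360, 280)
  set.seed(2)
  wide <- sample_arrow_array(list(min_distance = 5, variance = 40),
                             target_present = FALSE)
  expect_length(wide$orientations, 10L)
  expect_true(is.na(wide$target_slot))
})

test_that("session designs satisfy the factorial, catch and balance structure", {
  des <- generate_session(6, seed = 7)
  tl <- des[!duplicated(des$trial), ]
  expect_equal(nrow(tl), 90L)
  for (b in 1:6) {
    blk <- tl[tl$block == b, ]
    expect_equal(nrow(blk), 15L)
    # every PM type x condition combination exactly once per block
    expect_equal(sort(table(blk$pm_type, blk$condition)), rep(1L, 15L),
                 ignore_attr = TRUE)
    expect_equal(sum(blk$is_catch), 5L)
    expect_true(all(blk$n_probes[blk$is_catch] < 8))
    expect_true(all(blk$n_probes[!blk$is_catch] >= 8 &
                      blk$n_probes[!blk$is_catch] <= 15))
  }
  # one-third non-PM; equal probe totals per PM type (blocks divisible by 3)
  expect_equal(mean(tl$pm_type == "none"), 1 / 3)
  totals <- tapply(tl$n_probes, tl$pm_type, sum)
  expect_equal(length(unique(totals)), 1L)
  # the PM target marks the end of the trial: exactly one final probe each
  expect_equal(sum(des$is_final_probe), 90L)
  expect_true(all(des$probe[des$is_final_probe] ==
                    des$n_probes[des$is_final_probe]))
  # catch counterbalancing: over a 3-block span every combination is catch once
  span1 <- tl[tl$block <= 3, ]
  expect_equal(unname(table(paste(span1$pm_type, span1$condition),
                            span1$is_catch)[, "TRUE"]), rep(1L, 15L))

  expect_identical(generate_session(2, seed = 9), generate_session(2, seed = 9))
  expect_error(generate_session(0), "positive")
})

test_that("localizer blocks hold 60 probes in 8 bounded-length trials", {
  loc <- generate_localizer_design(2, seed = 3)
  expect_equal(nrow(loc), 120L)
  for (b in 1:2) {
    blk <- loc[loc$block == b, ]
    expect_equal(nrow(blk), 60L)
    lens <- blk$n_probes[!duplicated(blk$trial)]
    expect_length(lens, 8L)
    expect_true(all(lens >= 2 & lens <= 12))
    expect_equal(sum(lens), 60L)
  }
  expect_true(all(loc$condition %in% setdiff(pm_conditions, "fixed")))
})

test_that("event tables round-trip through TSV", {
  des <- generate_session(1, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(des, path)
  back <- read_events(path)
  expect_equal(back$difficulty_level, des$difficulty_level)
  expect_equal(back$onset_s, des$onset_s)
  expect_equal(back$pm_type, des$pm_type)
})
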