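th_fix <- occ_thresholds(th_lower = 1, th_bed = 1.5, th_upper = 2)

pw <- function(top, mid, bed) c(Ptop = top, Pmid = mid, Pbed = bed)

run_seq <- function(powers_list, init = occ_state_init()) {
  st <- init
  out <- character(length(powers_list))
  for (i in seq_along(powers_list)) {
    st <- occ_step(st, powers_list[[i]], th_fix)
    out[i] <- st$value
  }
  list(states = out, final = st)
}

test_that("zone partition is disjoint, complete, and sized as specified", {
  z <- zone_layout(20, 128)
  expect_length(z$bed_bins, 9)
  expect_length(z$mid_bins, 5)
  expect_setequal(c(z$bed_bins, z$mid_bins, z$top_bins), 0:127)
  expect_length(intersect(z$bed_bins, z$mid_bins), 0)
  # physical spans at the configured bin size: ~40 cm bed layer, and the mid
  # layer is five of the rounded 4.51 cm bins = 22.55 cm
  bs <- range_bin_size(fixture_cfg())
  expect_equal(9 * bs, 0.40, tolerance = 0.02)
  expect_equal(5 * round(bs * 100, 2), 22.55)
  expect_error(zone_layout(3, 128), "fit")
})

test_that("calibration finds the strongest bin and flags ties", {
  cfg <- fixture_cfg()
  s <- breather_scene(0.9, duration = 12, seed = 2)
  rtm <- build_range_time_matrix(synthesize_if_signal(s, cfg), cfg)
  lay <- calibrate_zones(rtm)
  expect_equal(lay$bed_center_bin, range_to_bin(0.9, cfg))

  flat <- rtm
  flat$values <- matrix(1 + 0i, 128, 600)
  flat$values[c(21, 31), ] <- 2 + 0i      # equal maxima at bins 20 and 30
  expect_warning(lay2 <- calibrate_zones(flat), "tie")
  expect_equal(lay2$bed_center_bin, 20L)  # lowest-index maximum chosen
  short <- rtm
  short$values <- rtm$values[, 1:100]
  expect_error(calibrate_zones(short), "10 s")
  empty <- rtm
  empty$values <- rtm$values[, 0, drop = FALSE]
  expect_error(calibrate_zones(empty), "empty")
})

test_that("zone powers average amplitude per zone at 5 Hz frames", {
  lay <- zone_layout(20, 64)
  vals <- matrix(0 + 0i, 64, 20)
  vals[lay$bed_bins + 1L, ] <- 1 + 0i
  rtm <- list(values = vals, frame_rate = 50, bin_size = 0.045, bin0_range = 0)
  class(rtm) <- "range_time_matrix"
  p <- zone_powers(rtm, lay, group = 10L)
  expect_equal(nrow(p), 2L)
  expect_equal(unname(p[1, ]), c(0, 0, 1))
  expect_equal(attr(p, "frame_rate"), 5)
  zero <- rtm
  zero$values <- matrix(0 + 0i, 64, 10)
  expect_equal(unname(zone_powers(zero, lay)[1, ]), c(0, 0, 0))
})

test_that("documented transition rules hold", {
  # NoBody is maintained while Pbed < th_upper, for any Ptop/Pmid
  r <- run_seq(list(pw(5, 5, 1.9), pw(0, 0, 1.9)))
  expect_equal(r$states, c("NoBody", "NoBody"))
  # NoBody -> NearBed on Pbed >= th_upper
  r <- run_seq(list(pw(0, 0, 2.0)))
  expect_equal(r$states, "NearBed")
  # NearBed -> BadSignal when all zones quiet
  st <- list(value = "NearBed", count = 0L)
  expect_equal(occ_step(st, pw(0.5, 0.5, 1.0), th_fix)$value, "BadSignal")
  # NearBed -> ToBed when Pbed >= th_bed and Ptop < th_upper
  expect_equal(occ_step(st, pw(1.5, 0.5, 1.6), th_fix)$value, "ToBed")
  # LieInBed maintained / left per the three-way condition
  lie <- list(value = "LieInBed", count = 0L)
  expect_equal(occ_step(lie, pw(0.5, 0.5, 1.6), th_fix)$value, "LieInBed")
  expect_equal(occ_step(lie, pw(1.2, 0.5, 1.6), th_fix)$value, "FromBed")
  expect_equal(occ_step(lie, pw(0.5, 0.5, 1.2), th_fix)$value, "FromBed")
  expect_error(occ_step(list(value = "Nope", count = 0L), pw(0, 0, 0), th_fix),
               "unknown")
})

test_that("15-frame debounce gates entry: 14 qualifying frames never suffice", {
  entry <- pw(0.5, 0.5, 1.8)
  seqs <- c(list(pw(0, 0, 2.2)), rep(list(entry), 14))
  r <- run_seq(seqs)
  expect_false("LieInBed" %in% r$states)
  expect_equal(r$final$value, "ToBed")
  # one non-qualifying frame resets the counter
  r2 <- run_seq(c(seqs, list(pw(2.5, 0, 1.8)), rep(list(entry), 14)))
  expect_false("LieInBed" %in% r2$states)
  # the 15th consecutive qualifying frame triggers
  r3 <- run_seq(c(list(pw(0, 0, 2.2)), rep(list(entry), 15)))
  expect_equal(r3$final$value, "LieInBed")
})

test_that("FromBed debounces symmetrically and routes by bed power", {
  lie <- list(value = "LieInBed", count = 0L)
  # brief flicker returns to LieInBed
  st <- occ_step(lie, pw(1.2, 0.5, 1.6), th_fix)
  expect_equal(st$value, "FromBed")
  st <- occ_step(st, pw(0.5, 0.5, 1.6), th_fix)
  expect_equal(st$value, "LieInBed")
  # sustained departure with high bed power -> NearBed
  st <- lie
  for (i in 1:16) st <- occ_step(st, pw(2.5, 0.5, 2.5), th_fix)
  expect_equal(st$value, "NearBed")
  # sustained quiet departure -> BadSignal, then NoBody after 15 quiet frames
  st <- lie
  for (i in 1:16) st <- occ_step(st, pw(0.2, 0.2, 0.2), th_fix)
  expect_equal(st$value, "BadSignal")
  for (i in 1:15) st <- occ_step(st, pw(0.2, 0.2, 0.2), th_fix)
  expect_equal(st$value, "NoBody")
})

test_that("every state is reachable and exitable under a power sweep", {
  # brute-force driver over threshold-relative orderings of the three powers;
  # record the whole trajectory so transient (debouncing) states count
  levels3 <- c(0.5, 1.2, 2.5)        # below th_lower / between / above th_upper
  bedlv <- c(1.0, 1.6, 2.5)          # below th_bed / above th_bed / above th_upper
  combos <- expand.grid(top = levels3, mid = levels3, bed = bedlv)
  seen <- character()
  exited <- character()
  for (i in seq_len(nrow(combos))) {
    for (j in seq_len(nrow(combos))) {
      st <- occ_state_init()
      traj <- character(40)
      for (k in 1:20) {
        st <- occ_step(st, pw(combos$top[i], combos$mid[i], combos$bed[i]),
                       th_fix)
        traj[k] <- st$value
      }
      for (k in 1:20) {
        st <- occ_step(st, pw(combos$top[j], combos$mid[j], combos$bed[j]),
                       th_fix)
        traj[20 + k] <- st$value
      }
      seen <- union(seen, traj)
      r <- rle(traj)
      if (length(r$values) > 1) {
        exited <- union(exited, r$values[-length(r$values)])
      }
    }
  }
  all_states <- c("NoBody", "NearBed", "ToBed", "LieInBed", "FromBed", "BadSignal")
  expect_setequal(seen, all_states)
  expect_setequal(exited, all_states)
})

test_that("a scripted bed entry reaches LieInBed once, at least 3 s after onset", {
  cfg <- fixture_cfg()
  tl <- occupancy_timeline(c("empty", "approach", "in_bed"),
                           c(0, 15, 22), c(15, 22, 120))
  s <- scene_script(duration = 120, scatterers = body_scatterers(0.9, cfg),
                    occupancy = tl, noise_sigma = 0.5, seed = 13)
  scen <- generate_occupancy_scenario(s, cfg)
  lay <- zone_layout(range_to_bin(0.9, cfg), nrow(scen$rtm$values))
  nf <- mean(Mod(scen$rtm$values[lay$bed_bins + 1L, 1:(14 * 50)]))
  th <- occ_thresholds(nf)
  powers <- zone_powers(scen$rtm, lay)
  states <- occ_run(powers, th)
  entries <- sum(diff(c(FALSE, states == "LieInBed")) == 1)
  expect_equal(entries, 1L)
  t_lie <- (which(states == "LieInBed")[1] - 1) / attr(powers, "frame_rate")
  expect_gte(t_lie - 22, 3)       # debounce delays entry by >= 3 s
  expect_lt(t_lie - 22, 10)
})

test_that("segment_recording returns scripted in-bed spans", {
  cfg <- fixture_cfg()
  # two in-bed blocks separated by an empty interval
  tl <- occupancy_timeline(
    c("empty", "approach", "in_bed", "leaving", "empty", "approach", "in_bed"),
    c(0, 12, 18, 80, 88, 110, 116),
    c(12, 18, 80, 88, 110, 116, 180))
  s <- scene_script(duration = 180, scatterers = body_scatterers(0.9, cfg),
                    occupancy = tl, noise_sigma = 0.5, seed = 14)
  scen <- generate_occupancy_scenario(s, cfg)
  lay <- zone_layout(range_to_bin(0.9, cfg), nrow(scen$rtm$values))
  nf <- mean(Mod(scen$rtm$values[lay$bed_bins + 1L, 1:(10 * 50)]))
  th <- occ_thresholds(nf)
  spans <- segment_recording(scen$rtm, lay, th)
  expect_equal(nrow(spans), 2L)
  expect_lt(abs(spans$start[1] - 18), 5 + 3)   # entry delayed by debounce
  expect_lt(abs(spans$end[1] - 80), 5)
  expect_lt(abs(spans$start[2] - 116), 5 + 3)

  # all-empty night: no spans
  s0 <- scene_script(duration = 60, scatterers = body_scatterers(0.9, cfg),
                     occupancy = occupancy_timeline("empty", 0, 60),
                     noise_sigma = 0.5, seed = 15)
  scen0 <- generate_occupancy_scenario(s0, cfg)
  spans0 <- segment_recording(scen0$rtm, lay, th)
  expect_equal(nrow(spans0), 0L)
})
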