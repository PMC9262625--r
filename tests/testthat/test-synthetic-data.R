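test_that("presets encode the study's exchange regimes", {
  sp <- preset("dbd_300K")
  expect_equal(sp$clusters[[1]]$k_ex, 1640)
  expect_equal(sp$clusters[[1]]$p_B, 0.042)
  expect_equal(sp$clusters[[2]]$k_ex, 420)
  expect_equal(sp$clusters[[2]]$p_B, 0.146)
  expect_length(sp$clusters[[1]]$members, 14)
  expect_setequal(sp$clusters[[2]]$members, c("I139", "V210", "L212"))

  sp2 <- preset("rhr_300K")
  expect_equal(sp2$clusters[[1]]$k_ex, 1600)
  expect_equal(sp2$clusters[[1]]$p_B, 0.051)
  expect_equal(sp2$clusters[[2]]$k_ex, 660)
  expect_equal(sp2$clusters[[2]]$p_B, 0.14)

  sp3 <- preset("dbd_290K")
  expect_equal(sp3$clusters[[1]]$k_ex, 480)
  expect_equal(sp3$clusters[[1]]$p_B, 0.029)

  sp4 <- preset("rhr_mhc_h2_bound")
  expect_named(sp4$fields, "18.8T")
  loop <- c("L67", "L97", "I139", "V147", "V210", "L212", "I237")
  expect_length(intersect(unlist(lapply(sp4$clusters, `[[`, "members")),
                          loop), 0)

  expect_error(preset("nope"), "dbd_300K")
})

test_that("planted ground truth matches the preset design", {
  gen <- make_dispersion_dataset(preset("dbd_300K", seed = 1))
  tr <- gen$truth
  expect_length(tr$dispersing_residues, 18)
  ## every dispersing methyl carries noiseless Rex above the design floor
  disp_keys <- tr$rex_truth$key[tr$rex_truth$residue_id %in%
                                  tr$dispersing_residues]
  expect_true(all(tr$rex_truth[disp_keys, "rex_truth"] > 8))
  ## non-dispersing residues are generated exchange-free
  flat_keys <- setdiff(tr$rex_truth$key, disp_keys)
  expect_true(all(vapply(tr$params[flat_keys], function(p) p$p_B, 0) == 0))
  expect_true(all(tr$rex_truth[flat_keys, "rex_truth"] == 0))

  ## DNA-bound preset: loop-proximal residues all flat, persistent pair not
  genb <- make_dispersion_dataset(preset("rhr_mhc_h2_bound", seed = 1))
  loop <- c("L67", "L97", "I139", "V147", "V210", "L212", "I237")
  expect_length(intersect(genb$truth$dispersing_residues, loop), 0)
  expect_setequal(genb$truth$dispersing_residues, c("I104", "V233"))
})

test_that("dataset generation is deterministic and noiseless data equal the model", {
  sp <- preset("dbd_300K", seed = 5)
  g1 <- make_dispersion_dataset(sp)
  g2 <- make_dispersion_dataset(sp)
  expect_identical(g1$dataset, g2$dataset)
  g3 <- make_dispersion_dataset(sp, seed = 6)
  expect_false(identical(g1$dataset$r2eff_s, g3$dataset$r2eff_s))
  ## structural truth is a property of the preset, not of the noise seed
  expect_identical(g1$truth$params, g3$truth$params)

  sp0 <- preset("dbd_300K", noise_sigma = 0)
  g0 <- make_dispersion_dataset(sp0, seed = 1)
  key <- g0$truth$clusters[[1]]$members[1]
  prof <- collapse_duplicates(methyl_subset(g0$dataset, key))
  prof <- prof[prof$field_label == "18.8T", ]
  cv <- dispersion_curve(g0$truth$params[[key]],
                         default_fields()[["18.8T"]], sp0$schedule)
  expect_equal(prof$r2eff_s[match(cv$nu_cpmg, prof$nu_cpmg_hz)], cv$r2eff,
               tolerance = 1e-12)
})

test_that("generated schedules and duplicates match the acquisition design", {
  sch <- default_schedule()
  expect_equal(sch$t_relax, 0.02)
  expect_length(sch$nu_cpmg, 18)
  expect_true(all(n_refocusing_pulses(sch$nu_cpmg, sch$t_relax) %% 2 == 0))
  gen <- make_dispersion_dataset(preset("dbd_300K", seed = 1))
  one <- gen$dataset[gen$dataset$residue_id == "L42" &
                       gen$dataset$methyl_id == "a" &
                       gen$dataset$field_label == "18.8T", ]
  counts <- table(one$nu_cpmg_hz)
  expect_equal(as.integer(counts[c("200", "6000")]), c(2L, 2L))
  expect_true(all(counts[setdiff(names(counts), c("200", "6000"))] == 1))
})

test_that("peak-list scenarios plant the intended splits deterministically", {
  p1 <- make_peaklists("kB_proto", seed = 1)
  p2 <- make_peaklists("kB_proto", seed = 1)
  expect_identical(p1$bound, p2$bound)

  ## free scenario: bound identical to free up to the state label
  pf <- make_peaklists("free", seed = 2)
  expect_equal(pf$bound$dH_ppm, pf$free$dH_ppm)
  expect_equal(pf$bound$dC_ppm, pf$free$dC_ppm)
  expect_equal(pf$bound$intensity, pf$free$intensity)

  ## V112 appears twice per methyl in the kB proto complex
  v112 <- p1$bound[abs(p1$bound$dH_ppm -
                         p1$free$dH_ppm[p1$free$assignment == "V112a"]) < 0.1 &
                     abs(p1$bound$dC_ppm -
                           p1$free$dC_ppm[p1$free$assignment == "V112a"]) < 0.5, ]
  expect_equal(nrow(v112), 2)
  expect_true("V112" %in% p1$truth$split_residues)

  expect_error(make_peaklists("unknown"), "scenario")

  ## peak lists round-trip through the TSV format
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(p1$free, path)
  back <- read_peaklist(path)
  expect_equal(back$dH_ppm, p1$free$dH_ppm)
  expect_identical(back$assignment, p1$free$assignment)
})
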