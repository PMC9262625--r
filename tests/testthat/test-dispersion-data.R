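test_that("R2,eff from intensities inverts the constant-time decay", {
  rec <- data.frame(nu_cpmg_hz = c(NA, 200, 1000),
                    intensity = c(1, 0.5, 1))
  prof <- r2eff_from_intensities(rec, t_relax = 0.02)
  expect_equal(prof$r2eff_s[prof$nu_cpmg_hz == 200], log(2) / 0.02,
               tolerance = 1e-12)          # 34.657 s^-1
  expect_equal(prof$r2eff_s[prof$nu_cpmg_hz == 1000], 0)

  ## round trip: synthesise intensities from a known curve, recover it
  fld <- field_context("18.8T", 201.2)
  sch <- default_schedule()
  par <- exchange_params(1640, 0.042, 1.2, c("18.8T" = 15))
  r2 <- bm_r2eff(par, fld, sch)
  rec <- data.frame(nu_cpmg_hz = c(NA, sch$nu_cpmg),
                    intensity = c(1, exp(-r2 * sch$t_relax)))
  prof <- r2eff_from_intensities(rec, t_relax = sch$t_relax)
  expect_equal(prof$r2eff_s[match(sch$nu_cpmg, prof$nu_cpmg_hz)], r2,
               tolerance = 1e-12)

  expect_warning(
    r2eff_from_intensities(data.frame(nu_cpmg_hz = c(NA, 200),
                                      intensity = c(1, 1.05)), 0.02),
    "negative")
  expect_error(
    r2eff_from_intensities(data.frame(nu_cpmg_hz = c(NA, 200),
                                      intensity = c(1, -1)), 0.02),
    "intensities")
  expect_error(
    r2eff_from_intensities(data.frame(nu_cpmg_hz = 200, intensity = 1),
                           0.02),
    "reference")
})

.mini_dataset <- function(pairs) {
  ## one methyl, one field; `pairs` is a list of c(nu, r1, r2)
  do.call(rbind, lapply(pairs, function(p)
    data.frame(residue_id = "L1", aa = "L", methyl_id = "a",
               field_label = "18.8T", nu_cpmg_hz = p[1],
               r2eff_s = p[-1], sigma_s = NA_real_)))
}

test_that("duplicate-based sigma pools squared half-differences per field", {
  ## identical duplicates: estimate collapses to the floor
  d <- .mini_dataset(list(c(200, 20, 20), c(6000, 15, 15)))
  expect_equal(unname(estimate_sigma_from_duplicates(d)["18.8T"]), 0.1)

  ## hand-computed two-pair case: diffs 2*delta1 and 2*delta2 pool to
  ## sqrt(delta1^2 + delta2^2) ... scaled by sqrt(2) per the half-diff rule
  d <- .mini_dataset(list(c(200, 21, 19), c(6000, 15.5, 14.5)))
  expect_equal(unname(estimate_sigma_from_duplicates(d)["18.8T"]),
               sqrt(((21 - 19)^2 / 2 + (15.5 - 14.5)^2 / 2) / 2),
               tolerance = 1e-12)

  ## Monte Carlo sanity: with many pairs the pooled estimate approaches
  ## the true noise level
  set.seed(42)
  sigma_true <- 0.3
  pairs <- lapply(1:30, function(i)
    c(i * 10, 15 + rnorm(1, 0, sigma_true), 15 + rnorm(1, 0, sigma_true)))
  d <- .mini_dataset(pairs)
  est <- unname(estimate_sigma_from_duplicates(d)["18.8T"])
  expect_lt(abs(est - sigma_true) / sigma_true, 0.3)

  expect_error(estimate_sigma_from_duplicates(
    .mini_dataset(list(c(200, 20)))), "duplicate")
})

test_that("observed Rex is the low-minus-high two-point displacement", {
  flat <- data.frame(nu_cpmg_hz = c(100, 200, 3000, 6000),
                     r2eff_s = c(15, 15, 15, 15))
  expect_equal(rex_observed(flat), 0)

  two <- data.frame(nu_cpmg_hz = c(100, 6000), r2eff_s = c(22, 15))
  expect_equal(rex_observed(two), 7)

  expect_error(rex_observed(data.frame(nu_cpmg_hz = 100, r2eff_s = 15)),
               "two points")

  ## noiseless two-site curve: displacement matches the curve ends and is
  ## non-negative
  fld <- field_context("18.8T", 201.2)
  sch <- default_schedule()
  par <- exchange_params(1640, 0.042, 1.0, c("18.8T" = 15))
  cv <- dispersion_curve(par, fld, sch)
  prof <- data.frame(nu_cpmg_hz = cv$nu_cpmg, r2eff_s = cv$r2eff)
  ord <- order(cv$nu_cpmg)
  expect_equal(rex_observed(prof),
               mean(cv$r2eff[ord][1:2]) -
                 mean(cv$r2eff[ord][length(ord) - 1:0]))
  expect_gte(rex_observed(prof), 0)
})

test_that("the dispersion screen finds exactly the planted residues", {
  gen <- make_dispersion_dataset(preset("dbd_300K", seed = 1))
  hits <- screen_dispersing(gen$dataset, threshold = 5)
  expect_setequal(hits, gen$truth$dispersing_residues)
  expect_length(hits, 18)

  ## monotone in the threshold; infinite threshold screens out everything
  hits10 <- screen_dispersing(gen$dataset, threshold = 10)
  expect_true(all(hits10 %in% hits))
  expect_length(screen_dispersing(gen$dataset, threshold = Inf), 0)

  ## an all-flat dataset yields an empty set
  flat_spec <- dataset_spec(residues = data.frame(residue_id = c("L1", "V2"),
                                                  aa = c("L", "V")),
                            clusters = list(), struct_seed = 9L)
  flat <- make_dispersion_dataset(flat_spec, seed = 1)
  expect_length(screen_dispersing(flat$dataset, threshold = 5), 0)
})

test_that("dispersion tables round-trip losslessly and intensity dialect converts", {
  gen <- make_dispersion_dataset(preset("dbd_300K", seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dispersion_table(gen$dataset, path)
  back <- read_dispersion_table(path)
  expect_identical(back[names(gen$dataset)], gen$dataset)

  ## intensity dialect
  ipath <- withr::local_tempfile(fileext = ".tsv")
  fld <- field_context("18.8T", 201.2)
  sch <- default_schedule()
  par <- exchange_params(420, 0.146, 0.8, c("18.8T" = 15))
  r2 <- bm_r2eff(par, fld, sch)
  tab <- data.frame(residue_id = "V210", aa = "V", methyl_id = "a",
                    field_label = "18.8T",
                    nu_cpmg_hz_or_REF = c("REF", "REF", sch$nu_cpmg, 200),
                    intensity = c(1, 1, exp(-r2 * sch$t_relax),
                                  exp(-r2[sch$nu_cpmg == 200] * sch$t_relax)),
                    replicate_index = c(1, 2, rep(1, length(r2)), 2))
  write.table(tab, ipath, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_intensity_table(ipath, t_relax = sch$t_relax)
  prof <- collapse_duplicates(ds)
  expect_equal(prof$r2eff_s[match(sch$nu_cpmg, prof$nu_cpmg_hz)], r2,
               tolerance = 1e-9)
  expect_equal(unique(ds$sigma_s), 0.1)   # exact duplicates -> floor
})
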