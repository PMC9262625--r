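fields <- default_fields()
sch <- default_schedule()

## noiseless two-field dataset for a handful of methyls sharing a process
.make_members <- function(kex, pB, dws, noise = 0, seed = 1,
                          ids = sprintf("L%d", seq_along(dws))) {
  res <- data.frame(residue_id = ids, aa = substr(ids, 1, 1))
  spec <- dataset_spec(residues = res,
                       clusters = list(list(members = ids, k_ex = kex,
                                            p_B = pB)),
                       noise_sigma = noise, min_rex = 0, struct_seed = 77L)
  gen <- make_dispersion_dataset(spec, seed = seed)
  ## overwrite the drawn dw with the requested ones (methyl "a"/"d1");
  ## keep only one methyl per residue for compactness
  keep <- gen$dataset$methyl_id %in% c("a", "d1")
  d <- gen$dataset[keep, , drop = FALSE]
  truth <- gen$truth
  list(dataset = d, truth = truth)
}

test_that("noiseless two-field data return the generating parameters", {
  mm <- .make_members(1640, 0.042, c(1.0, 0.7), noise = 0)
  d <- mm$dataset
  d$sigma_s <- 0.3           # weights only; data are exact
  key <- "L1.a"
  fit <- fit_individual(methyl_subset(d, key), fields, sch)
  tp <- mm$truth$params[[key]]
  expect_true(fit$converged)
  expect_equal(fit$params$k_ex, tp$k_ex, tolerance = 1e-3)
  expect_equal(fit$params$p_B, tp$p_B, tolerance = 1e-3)
  expect_equal(fit$params$dw_ppm, tp$dw_ppm, tolerance = 1e-3)
  expect_equal(unname(fit$params$r20_by_field[["18.8T"]]),
               unname(tp$r20_by_field[["18.8T"]]), tolerance = 1e-3)
  expect_lt(fit$chi2, 1e-8)
})

test_that("model selection prefers flat for flat data and exchange for dispersing data", {
  flat_spec <- dataset_spec(residues = data.frame(residue_id = "L5", aa = "L"),
                            clusters = list(), struct_seed = 5L)
  d <- make_dispersion_dataset(flat_spec, seed = 2)$dataset
  dm <- methyl_subset(d, "L5.a")
  fe <- fit_individual(dm, fields, sch)
  ff <- fit_flat(dm, fields, sch)
  expect_identical(as.character(model_select(fe, ff, dm)), "flat")

  mm <- .make_members(1640, 0.042, 1.0, noise = 0.3, seed = 3)
  dm <- methyl_subset(mm$dataset, "L1.a")
  fe <- fit_individual(dm, fields, sch)
  ff <- fit_flat(dm, fields, sch)
  expect_identical(as.character(model_select(fe, ff, dm)), "exchange")
  ## alpha = 0 can never be significant
  expect_identical(as.character(model_select(fe, ff, dm, alpha = 0)),
                   "flat")
})

.stub_fit <- function(key, kex) {
  structure(list(key = key, residue_id = sub("\\.[^.]*$", "", key),
                 methyl_id = sub("^.*\\.", "", key), model = "exchange",
                 params = exchange_params(kex, 0.05, 1,
                                          c("18.8T" = 15)),
                 converged = TRUE),
            class = "cpmg_fit")
}

test_that("k_ex clustering splits at log-gaps and respects the residue-span rule", {
  ## two planted rate groups separate cleanly
  fits <- c(lapply(1:4, function(i)
    .stub_fit(sprintf("L%d.a", i), 1640 * exp(rnorm(1, 0, 0.02)))),
    lapply(5:7, function(i)
      .stub_fit(sprintf("V%d.a", i), 420 * exp(rnorm(1, 0, 0.02)))))
  cand <- cluster_by_kex(fits)
  expect_length(cand, 2)
  expect_setequal(cand[[1]], sprintf("L%d.a", 1:4))
  expect_setequal(cand[[2]], sprintf("V%d.a", 5:7))

  ## identical rates give one candidate with everything
  fits_eq <- lapply(1:5, function(i) .stub_fit(sprintf("L%d.a", i), 1000))
  expect_length(cluster_by_kex(fits_eq), 1)
  expect_length(cluster_by_kex(fits_eq)[[1]], 5)

  ## a single fit yields no partition
  expect_length(cluster_by_kex(fits_eq[1]), 0)

  ## prochiral methyls of one residue alone never form a candidate
  pair <- list(.stub_fit("L106.a", 5000), .stub_fit("L106.b", 5050))
  expect_length(cluster_by_kex(pair), 0)
})

test_that("chi2-ratio membership rule behaves at and around the boundary", {
  expect_true(accept_member(1.0, 1.0))
  expect_true(accept_member(1.9, 1.0))
  expect_false(accept_member(2.1, 1.0))
  expect_false(accept_member(2.0, 1.0))        # strict inequality
  ## perfect individual fits
  expect_true(accept_member(0, 0))
  expect_true(accept_member(1e-14, 0))
  expect_false(accept_member(0.5, 0))
})

test_that("cluster-global fit recovers shared parameters and ejects outliers", {
  mm <- .make_members(1640, 0.042, rep(1, 3), noise = 0)
  d <- mm$dataset
  d$sigma_s <- 0.3
  keys <- c("L1.a", "L2.a", "L3.a")
  ind <- lapply(keys, function(k)
    fit_individual(methyl_subset(d, k), fields, sch))
  names(ind) <- keys
  cl <- fit_cluster_global(d, keys, ind, fields, sch)
  expect_setequal(cl$members, keys)
  expect_equal(cl$k_ex, 1640, tolerance = 1e-3)
  expect_equal(cl$p_B, 0.042, tolerance = 1e-3)
  for (k in keys)
    expect_equal(cl$per_member[[k]]$dw_ppm,
                 mm$truth$params[[k]]$dw_ppm, tolerance = 1e-3)

  ## plant one member with a four-fold different rate among noisy
  ## same-process members: the outlier must be ejected
  mmN <- .make_members(1640, 0.042, rep(1, 3), noise = 0.25, seed = 8)
  out <- .make_members(410, 0.042, 1.0, noise = 0.25, seed = 9, ids = "V9")
  d2 <- rbind(mmN$dataset, out$dataset)
  d2$sigma_s <- 0.25
  ind2 <- lapply(setNames(nm = c(keys, "V9.a")), function(k)
    fit_individual(methyl_subset(d2, k), fields, sch))
  cl2 <- fit_cluster_global(d2, c(keys, "V9.a"), ind2, fields, sch)
  expect_true("V9.a" %in% cl2$ejected)
  expect_setequal(cl2$members, keys)
  ## objective over retained members decreases across ejection rounds
  expect_true(all(diff(cl2$trace) < 0))

  ## two members with identical data: shared fit equals the individual fit
  dup <- methyl_subset(d, "L1.a")
  dup$residue_id <- "L8"
  d3 <- rbind(methyl_subset(d, "L1.a"), dup)
  ind3 <- list("L1.a" = ind[["L1.a"]],
               "L8.a" = fit_individual(methyl_subset(d3, "L8.a"), fields, sch))
  cl3 <- fit_cluster_global(d3, c("L1.a", "L8.a"), ind3, fields, sch)
  expect_equal(cl3$k_ex, ind[["L1.a"]]$params$k_ex, tolerance = 1e-4)
  expect_equal(cl3$p_B, ind[["L1.a"]]$params$p_B, tolerance = 1e-4)
})

test_that("Monte Carlo uncertainties are seeded, deterministic and scale with noise", {
  mm <- .make_members(1640, 0.042, 1.0, noise = 0.3, seed = 4)
  dm <- methyl_subset(mm$dataset, "L1.a")
  fit <- fit_individual(dm, fields, sch)
  f1 <- monte_carlo_sigmas(fit, dm, fields, sch, n_reps = 30, seed = 11)
  f2 <- monte_carlo_sigmas(fit, dm, fields, sch, n_reps = 30, seed = 11)
  expect_identical(f1$param_sigmas, f2$param_sigmas)
  expect_gt(f1$param_sigmas[["k_ex"]], 0)

  ## vanishing noise -> vanishing parameter uncertainty
  dm0 <- dm
  dm0$sigma_s <- 1e-4
  fit0 <- fit_individual(dm0, fields, sch)
  f0 <- monte_carlo_sigmas(fit0, dm0, fields, sch, n_reps = 20, seed = 11)
  expect_lt(f0$param_sigmas[["k_ex"]] / f1$param_sigmas[["k_ex"]], 0.05)

  ## same order of magnitude as the study's +/- 47 s^-1 for one methyl
  expect_gt(f1$param_sigmas[["k_ex"]], 10)
  expect_lt(f1$param_sigmas[["k_ex"]], 300)
})
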